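# Internal helpers shared across modules.

# Heavy-atom test: element column preferred, atom-name leading character as
# fallback (PDB files vary in element completeness).
is_heavy_atom <- function(element, atom_name) {
  el <- toupper(trimws(element))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    # leading alphabetic character of the atom name
    lead <- toupper(sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", atom_name[miss]))
    el[miss] <- lead
  }
  !(el %in% c("H", "D"))
}

vec_norm <- function(v) sqrt(sum(v * v))

cross3 <- function(a, b) {
  a <- unname(a); b <- unname(b)
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Squared Euclidean cross-distance between two n x 3 coordinate matrices.
cross_dist2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) -
    2 * tcrossprod(a, b)
}

atom_coords <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
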