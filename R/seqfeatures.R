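AA_LEVELS <- c("-", "A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
               "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Read an aligned FASTA file
#'
#' @param path aligned FASTA (gap character `-`).
#' @return object of class `alignment`: list with `ids` and `aa`, a character
#'   matrix (rows = sequences, columns = alignment positions).
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  make_alignment(names(ss), as.character(ss))
}

#' Construct an alignment from id / sequence vectors
#'
#' @param ids unique sequence identifiers.
#' @param seqs aligned sequences, all the same length.
#' @return an `alignment` object.
#' @export
make_alignment <- function(ids, seqs) {
  ids <- sub("\\s.*$", "", ids)  # FASTA descriptions after first whitespace
  if (anyDuplicated(ids)) stop("duplicate sequence ids", call. = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("alignment rows differ in length", call. = FALSE)
  }
  aa <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(aa) <- ids
  structure(list(ids = ids, aa = aa), class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d sequences x %d columns\n",
              nrow(x$aa), ncol(x$aa)))
  invisible(x)
}

#' Write an alignment as aligned FASTA
#'
#' @param alignment an `alignment` object.
#' @param path output file.
#' @export
write_alignment <- function(alignment, path) {
  seqs <- apply(alignment$aa, 1L, paste0, collapse = "")
  writeLines(as.vector(rbind(paste0(">", alignment$ids), seqs)), path)
  invisible(path)
}

#' Map alignment columns to reference residue numbers
#'
#' The k-th non-gap character of the reference row corresponds to reference
#' residue number k (1-based). Gap columns in the reference row are unmapped.
#' All residue coordinates in this package are expressed in this reference
#' (TropB-style) numbering.
#'
#' @param alignment an `alignment`.
#' @param reference_id id of the reference sequence in the alignment.
#' @return object of class `reference_map`: list with `col_to_res` (integer
#'   per column, `NA` when unmapped) and `res_to_col`.
#' @export
map_reference_numbering <- function(alignment, reference_id) {
  i <- match(reference_id, alignment$ids)
  if (is.na(i)) stop("reference id not in alignment: ", reference_id,
                     call. = FALSE)
  row <- alignment$aa[i, ]
  nongap <- row != "-"
  col_to_res <- rep(NA_integer_, length(row))
  col_to_res[nongap] <- seq_len(sum(nongap))
  if (!any(nongap)) warning("reference row is all gaps", call. = FALSE)
  res_to_col <- which(nongap)
  structure(list(col_to_res = col_to_res, res_to_col = res_to_col,
                 reference_id = reference_id),
            class = "reference_map")
}

residue_set <- function(resnos, provenance) {
  structure(sort(unique(as.integer(resnos))), provenance = provenance)
}

# Minimum heavy-atom distance selection shared by the two shell selectors.
residues_within <- function(protein, target_xyz, cutoff) {
  heavy <- is_heavy_atom(protein$element, protein$atom_name)
  prot <- protein[heavy, , drop = FALSE]
  d2 <- cross_dist2(atom_coords(prot), target_xyz)
  near <- apply(d2, 1L, min) <= cutoff^2 + 1e-12
  unique(prot$resno[near])
}

#' Select binding-site residues around the top docked poses
#'
#' A residue belongs to the binding site iff any of its heavy atoms lies
#' within `cutoff` (inclusive) of any ligand heavy atom of any of the supplied
#' top poses (union over ligands). The FAD cofactor is not a candidate
#' residue.
#'
#' @param receptor a [complex_structure()].
#' @param top_poses list of [pose()] objects, one top pose per ligand, in the
#'   receptor frame.
#' @param cutoff contact cutoff in Angstrom (default 4.5, inclusive).
#' @return sorted integer vector of residue numbers with a `provenance`
#'   attribute `"binding_site"`.
#' @export
select_binding_site_residues <- function(receptor, top_poses, cutoff = 4.5) {
  if (length(top_poses) == 0L) stop("empty pose list", call. = FALSE)
  if (inherits(top_poses, "pose")) top_poses <- list(top_poses)
  lig <- do.call(rbind, lapply(top_poses, function(p) atom_coords(p$atoms)))
  residue_set(residues_within(receptor$protein, lig, cutoff), "binding_site")
}

#' Select second-shell residues around the binding site
#'
#' Residues (excluding binding-site members themselves) with a heavy atom
#' within `cutoff` of any heavy atom of any binding-site residue.
#'
#' @param receptor a [complex_structure()].
#' @param binding_site residue numbers from [select_binding_site_residues()].
#' @param cutoff contact cutoff in Angstrom (default 4.5, inclusive).
#' @return sorted integer vector with `provenance` `"second_shell"`.
#' @export
select_second_shell <- function(receptor, binding_site, cutoff = 4.5) {
  if (length(binding_site) == 0L) stop("empty binding site", call. = FALSE)
  heavy <- is_heavy_atom(receptor$protein$element, receptor$protein$atom_name)
  prot <- receptor$protein[heavy, , drop = FALSE]
  bs_xyz <- atom_coords(prot[prot$resno %in% binding_site, , drop = FALSE])
  res <- residues_within(receptor$protein, bs_xyz, cutoff)
  residue_set(setdiff(res, binding_site), "second_shell")
}

#' Union of residue sets across enzymes
#'
#' All sets must already be expressed in reference numbering.
#'
#' @param sets list of residue-number vectors.
#' @return sorted integer union with `provenance` `"union"`.
#' @export
residues_of_interest_union <- function(sets) {
  if (length(sets) == 0L) {
    warning("union over zero residue sets is empty", call. = FALSE)
    return(residue_set(integer(0), "union"))
  }
  residue_set(unlist(sets), "union")
}

#' Build the sequence feature matrix for sequence-function modeling
#'
#' Restricts the alignment to columns that map to residues of interest and
#' have a gap fraction of at most `gap_threshold` (strictly more than the
#' threshold drops the column). Each retained column is one categorical
#' feature (the gap is its own category), preserving
#' one-SHAP-value-per-residue semantics. Optional label columns are validated
#' against their codomains: stereochemistry in \{-1, 0, 1\}
#' (S, R/S, R) and reactivity in \{0, 1\}.
#'
#' @param alignment an `alignment`.
#' @param roi residues of interest (reference numbering), or `NULL` to keep
#'   all alignment columns (gap filter only).
#' @param refmap a [map_reference_numbering()] result; required when `roi`
#'   is given.
#' @param labels optional data.frame with rownames or an `id` column matching
#'   alignment ids and columns `stereochemistry` and/or `reactivity`.
#' @param gap_threshold maximum tolerated gap fraction (default 0.10).
#' @return object of class `feature_matrix`: list with `aa` (character matrix
#'   of retained columns, named `res<k>` or `col<k>`), `residues` (reference
#'   numbers or `NA`), and `labels`.
#' @export
build_feature_matrix <- function(alignment, roi = NULL, refmap = NULL,
                                 labels = NULL, gap_threshold = 0.10) {
  aa <- alignment$aa
  if (is.null(roi)) {
    cols <- seq_len(ncol(aa))
    residues <- rep(NA_integer_, length(cols))
  } else {
    if (is.null(refmap)) stop("refmap required when roi is given", call. = FALSE)
    roi <- sort(unique(as.integer(roi)))
    unmapped <- roi[roi > length(refmap$res_to_col) | roi < 1L]
    if (length(unmapped) > 0L) {
      stop("residue(s) of interest not mapped to alignment columns: ",
           paste(unmapped, collapse = ", "), call. = FALSE)
    }
    cols <- refmap$res_to_col[roi]
    residues <- roi
  }
  gap_frac <- colMeans(aa[, cols, drop = FALSE] == "-")
  keep <- gap_frac <= gap_threshold
  cols <- cols[keep]; residues <- residues[keep]
  if (length(cols) == 0L) stop("no columns retained", call. = FALSE)
  sub <- aa[, cols, drop = FALSE]
  colnames(sub) <- ifelse(is.na(residues), paste0("col", cols),
                          paste0("res", residues))
  lab <- NULL
  if (!is.null(labels)) {
    labels <- as.data.frame(labels)
    ids <- if ("id" %in% names(labels)) labels$id else rownames(labels)
    i <- match(alignment$ids, ids)
    if (anyNA(i)) stop("labels missing for sequence(s): ",
                       paste(alignment$ids[is.na(i)][1:3], collapse = ", "),
                       call. = FALSE)
    lab <- labels[i, setdiff(names(labels), "id"), drop = FALSE]
    rownames(lab) <- alignment$ids
    if ("stereochemistry" %in% names(lab) &&
        !all(lab$stereochemistry %in% c(-1, 0, 1))) {
      stop("stereochemistry labels must lie in {-1, 0, 1}", call. = FALSE)
    }
    if ("reactivity" %in% names(lab) && !all(lab$reactivity %in% c(0, 1))) {
      stop("reactivity labels must lie in {0, 1}", call. = FALSE)
    }
  }
  structure(list(aa = sub, residues = residues, ids = alignment$ids,
                 labels = lab),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d enzymes x %d residue columns%s\n",
              nrow(x$aa), ncol(x$aa),
              if (is.null(x$labels)) "" else
                paste0(" + labels (", paste(names(x$labels), collapse = ", "),
                       ")")))
  invisible(x)
}

#' Integer label encoding of a feature matrix
#'
#' Encodes each amino-acid category (gap included) over a fixed, alphabetical
#' level set so the encoding is stable across folds and datasets.
#'
#' @param fm a [build_feature_matrix()] result.
#' @return integer matrix suitable for tree models.
#' @export
encode_features <- function(fm) {
  m <- matrix(match(fm$aa, AA_LEVELS), nrow = nrow(fm$aa),
              dimnames = dimnames(fm$aa))
  if (anyNA(m)) {
    # unseen symbols map to the catch-all category
    m[is.na(m)] <- match("X", AA_LEVELS)
  }
  m
}

#' Stereochemistry training labels from per-ligand calls
#'
#' Default (`"mode"`): modal label across ligands via
#' [consensus_stereochemistry()], encoded R = 1, S = -1, R/S (incl. ties) = 0.
#' Variant (`"mean"`): encode each per-ligand label the same way, average, and
#' take the sign; means with absolute value below `racemic_band` are racemic 0.
#'
#' @param per_ligand_labels list (one element per enzyme) of character vectors
#'   of per-ligand labels `"R"`, `"S"`, `"R/S"`.
#' @param method `"mode"` (default) or `"mean"`.
#' @param racemic_band half-width of the racemic band for `"mean"`.
#' @return integer vector in \{-1, 0, 1\}.
#' @export
stereo_labels <- function(per_ligand_labels, method = c("mode", "mean"),
                          racemic_band = 0.25) {
  method <- match.arg(method)
  code <- c(R = 1, S = -1, `R/S` = 0)
  vapply(per_ligand_labels, function(labs) {
    if (method == "mode") {
      unname(code[consensus_stereochemistry(labs)])
    } else {
      m <- mean(code[labs])
      if (abs(m) < racemic_band) 0 else sign(m)
    }
  }, numeric(1))
}
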