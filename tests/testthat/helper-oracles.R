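# Independent oracle implementations and in-code fixtures shared by the
# suite. Every oracle re-derives its quantity by a different route than the
# package code it checks.

# Direct evaluation of the Boltzmann R-fraction formula (no energy shift).
oracle_rfrac <- function(sizes, energies, calls, temperature = 300,
                         kB = 0.0019872) {
  w <- sizes * exp(-energies / (kB * temperature))
  sum(w[calls == "R"]) / sum(w)
}

# Build an annotated cluster_set directly from sizes / energies / calls.
fake_cluster_set <- function(sizes, energies, calls) {
  ord <- order(energies, seq_along(energies))
  clusters <- lapply(ord, function(i) {
    list(member_pose_ids = integer(sizes[i]), size = sizes[i],
         representative_pose_id = i, energy = energies[i],
         angle = NA_real_, stereo_call = calls[i])
  })
  structure(list(clusters = clusters, radius = 1), class = "cluster_set")
}

random_cluster_args <- function(n_clusters) {
  list(sizes = sample(1:50, n_clusters, replace = TRUE),
       energies = stats::runif(n_clusters, -20, 5),
       calls = sample(c("R", "S"), n_clusters, replace = TRUE))
}

# Naive leader clustering re-implementation (same visiting order contract).
oracle_leader_partition <- function(coord_list, radius) {
  n_atoms <- nrow(coord_list[[1L]])
  assignment <- integer(length(coord_list))
  leader_coords <- list()
  for (i in seq_along(coord_list)) {
    placed <- FALSE
    for (k in seq_along(leader_coords)) {
      rmsd <- sqrt(sum((coord_list[[i]] - leader_coords[[k]])^2) / n_atoms)
      if (rmsd <= radius) { assignment[i] <- k; placed <- TRUE; break }
    }
    if (!placed) {
      leader_coords[[length(leader_coords) + 1L]] <- coord_list[[i]]
      assignment[i] <- length(leader_coords)
    }
  }
  assignment
}

# Multiclass MCC via the indicator-matrix covariance formulation (Gorodkin),
# a different route than the confusion-matrix formula in the package.
oracle_mcc <- function(observed, predicted, classes) {
  X <- outer(observed, classes, `==`) * 1
  Y <- outer(predicted, classes, `==`) * 1
  cxy <- sum(vapply(seq_along(classes), function(k) {
    stats::cov(X[, k], Y[, k])
  }, numeric(1)))
  cxx <- sum(vapply(seq_along(classes), function(k) stats::var(X[, k]),
                    numeric(1)))
  cyy <- sum(vapply(seq_along(classes), function(k) stats::var(Y[, k]),
                    numeric(1)))
  if (cxx == 0 || cyy == 0) return(NA_real_)
  cxy / sqrt(cxx * cyy)
}

# Macro F1 from per-class precision/recall computed on the raw label vectors.
oracle_macro_f1 <- function(observed, predicted, classes) {
  f1 <- vapply(classes, function(cl) {
    tp <- sum(observed == cl & predicted == cl)
    fp <- sum(observed != cl & predicted == cl)
    fn <- sum(observed == cl & predicted != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

# Logistic maximum likelihood via a general-purpose optimizer.
oracle_logistic_mle <- function(X, y) {
  nll <- function(beta) {
    eta <- drop(cbind(1, X) %*% beta)
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- stats::optim(rep(0, ncol(X) + 1L), nll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  fit$par
}

# Minimal multi-model PDB text written in code (no stored fixtures).
write_pose_pdb <- function(path, energies, shift = seq_along(energies) - 1,
                           n_atoms = 3L) {
  con <- file(path, "w")
  on.exit(close(con))
  base <- matrix(c(0, 0, 0, 1.4, 0, 0, 0, 1.4, 0, 1.4, 1.4, 0), ncol = 3,
                 byrow = TRUE)[seq_len(n_atoms), , drop = FALSE]
  names_ <- c("C1", "C2", "O1", "C4")[seq_len(n_atoms)]
  elems <- c("C", "C", "O", "C")[seq_len(n_atoms)]
  for (m in seq_along(energies)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(sprintf("REMARK ENERGY %.4f", energies[m]), con)
    xyz <- sweep(base, 2L, c(shift[m], 0, 0), `+`)
    writeLines(sprintf(
      "HETATM%5d %-4s LIG A   1    %8.3f%8.3f%8.3f  1.00%6.2f          %2s",
      seq_len(n_atoms), names_, xyz[, 1], xyz[, 2], xyz[, 3],
      energies[m], elems), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  path
}

write_receptor_pdb <- function(path, with_fad = TRUE) {
  lines <- c(
    "ATOM      1  CA  ALA A  10       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A  10       1.500   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A  11       4.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CZ  ARG A 206       0.000   4.000   0.000  1.00  0.00           C")
  if (with_fad) {
    lines <- c(lines,
      "HETATM    5  C4A FAD A 500       0.000   0.000   5.000  1.00  0.00           C",
      "HETATM    6  N5  FAD A 500       1.000   0.000   5.500  1.00  0.00           N")
  }
  writeLines(c(lines, "END"), path)
  path
}

# Hand-built pose at explicit coordinates.
make_pose <- function(xyz, names_ = paste0("C", seq_len(nrow(xyz))),
                      elements = rep("C", nrow(xyz)), energy = -1,
                      pose_id = 1L) {
  pose(pose_id,
       atom_table(names_, elements, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
       energy = energy)
}

rotation_matrix <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3,
               byrow = TRUE)
  diag(3) * cos(a) + sin(a) * ux + (1 - cos(a)) * tcrossprod(u)
}
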