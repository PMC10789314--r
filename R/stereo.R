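#' Unit normal of the ligand ring plane
#'
#' The normal is the normalized cross product `(a2 - a1) x (a3 - a1)` of the
#' three named ring atoms, so its orientation follows the right-hand rule on
#' the given atom order: reversing the order flips the normal, which is what
#' makes the downstream R/S call chirality-aware.
#'
#' @param pose a [pose()].
#' @param ring_atoms character vector of 3 distinct ligand atom names on the
#'   (resorcinol) ring, in order.
#' @return unit 3-vector.
#' @export
ring_plane_normal <- function(pose, ring_atoms) {
  if (length(ring_atoms) != 3L || anyDuplicated(ring_atoms)) {
    stop("ring_atoms must be 3 distinct atom names", call. = FALSE)
  }
  idx <- match(ring_atoms, pose$atoms$atom_name)
  if (anyNA(idx)) {
    stop("ring atom(s) not found in pose: ",
         paste(ring_atoms[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  p <- atom_coords(pose$atoms)[idx, , drop = FALSE]
  n <- cross3(p[2L, ] - p[1L, ], p[3L, ] - p[1L, ])
  nn <- vec_norm(n)
  if (nn < 1e-9) {
    stop("degenerate geometry: ring atoms are collinear", call. = FALSE)
  }
  n / nn
}

#' Angle between the ring-plane normal and the ligand-to-FAD vector
#'
#' The reference vector points from the mean ligand heavy-atom coordinate to
#' the FAD reference atom (the flavin-ring atom that bonds the hydroperoxyl
#' group in the activated cofactor, C4alpha). The returned angle lies in
#' \[0, 180\] degrees.
#'
#' @inheritParams ring_plane_normal
#' @param fad_atom the FAD reference position: a numeric xyz 3-vector or a
#'   one-row atom table.
#' @return angle in degrees.
#' @export
pose_angle <- function(pose, ring_atoms, fad_atom) {
  if (is.data.frame(fad_atom)) fad_atom <- as.numeric(atom_coords(fad_atom)[1L, ])
  stopifnot(is.numeric(fad_atom), length(fad_atom) == 3L)
  n <- ring_plane_normal(pose, ring_atoms)
  centroid <- colMeans(atom_coords(pose$atoms))
  v <- fad_atom - centroid
  nv <- vec_norm(v)
  if (nv < 1e-9) {
    stop("degenerate geometry: FAD reference coincides with ligand centroid",
         call. = FALSE)
  }
  u <- v / nv
  # atan2 form is well conditioned at 0 and 180 degrees, unlike acos
  atan2(vec_norm(cross3(n, u)), sum(n * u)) * 180 / pi
}

#' Classify a pose angle as S, R, or degenerate
#'
#' Angles below 90 degrees indicate an S pose (ring face toward the FAD),
#' angles above 90 an R pose. Angles within `tol` of 90 are degenerate: the
#' ring plane contains the FAD direction and no face is presented.
#'
#' @param angle angle in degrees, in \[0, 180\].
#' @param tol degeneracy tolerance around 90 degrees.
#' @return `"S"`, `"R"`, or `"degenerate"`.
#' @export
classify_pose <- function(angle, tol = 1e-9) {
  if (!is.finite(angle) || angle < 0 || angle > 180) {
    stop("angle must lie in [0, 180] degrees", call. = FALSE)
  }
  if (abs(angle - 90) <= tol) return("degenerate")
  if (angle < 90) "S" else "R"
}

#' Cluster docked poses by fixed-frame heavy-atom RMSD
#'
#' Deterministic greedy leader clustering in the receptor frame (no
#' superposition): poses are visited in ascending-energy order; each pose
#' joins the first existing cluster whose leader is within `radius` RMSD,
#' otherwise it opens a new cluster with itself as leader. Because of the
#' visiting order the leader is always the lowest-energy member, so it is also
#' the cluster representative whose energy ranks the cluster. Ties in
#' representative energy are broken by lower representative pose id.
#'
#' @param ensemble a [pose_ensemble()].
#' @param radius clustering radius in Angstrom (default 1.0).
#' @return an object of class `cluster_set`: list with `clusters` (each a list
#'   with `member_pose_ids`, `size`, `representative_pose_id`, `energy`,
#'   `angle`, `stereo_call`) ranked by ascending representative energy, and
#'   `radius`.
#' @export
cluster_poses <- function(ensemble, radius = 1.0) {
  if (!is.finite(radius) || radius <= 0) {
    stop("radius must be positive", call. = FALSE)
  }
  poses <- ensemble$poses  # already ascending in energy
  coords <- lapply(poses, function(p) atom_coords(p$atoms))
  n_atoms <- nrow(coords[[1L]])
  leaders <- integer(0)        # indices into `poses`
  members <- list()
  for (i in seq_along(poses)) {
    assigned <- FALSE
    for (k in seq_along(leaders)) {
      d2 <- sum((coords[[i]] - coords[[leaders[k]]])^2) / n_atoms
      if (sqrt(d2) <= radius) {
        members[[k]] <- c(members[[k]], i)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      leaders <- c(leaders, i)
      members[[length(leaders)]] <- i
    }
  }
  energies <- pose_energies(ensemble)
  ids <- vapply(poses, `[[`, integer(1), "pose_id")
  clusters <- lapply(seq_along(leaders), function(k) {
    mem <- members[[k]]
    rep_i <- mem[which.min(energies[mem])]
    list(member_pose_ids = ids[mem], size = length(mem),
         representative_pose_id = ids[rep_i], energy = energies[rep_i],
         angle = NA_real_, stereo_call = NA_character_)
  })
  e <- vapply(clusters, `[[`, numeric(1), "energy")
  r <- vapply(clusters, `[[`, integer(1), "representative_pose_id")
  clusters <- clusters[order(e, r)]
  structure(list(clusters = clusters, radius = radius,
                 enzyme_id = ensemble$enzyme_id, ligand_id = ensemble$ligand_id),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters (radius %.2f A), sizes: %s\n",
              length(x$clusters), x$radius,
              paste(vapply(x$clusters, `[[`, integer(1), "size"),
                    collapse = " ")))
  invisible(x)
}

#' Annotate clusters with representative angles and R/S calls
#'
#' Computes [pose_angle()] for each cluster representative and classifies it
#' with [classify_pose()].
#'
#' @param clusters a `cluster_set` from [cluster_poses()].
#' @param ensemble the [pose_ensemble()] the clusters were built from.
#' @inheritParams pose_angle
#' @param tol degeneracy tolerance passed to [classify_pose()].
#' @return the `cluster_set` with `angle` and `stereo_call` filled in.
#' @export
annotate_cluster_stereo <- function(clusters, ensemble, ring_atoms, fad_atom,
                                    tol = 1e-9) {
  ids <- vapply(ensemble$poses, `[[`, integer(1), "pose_id")
  clusters$clusters <- lapply(clusters$clusters, function(cl) {
    p <- ensemble$poses[[match(cl$representative_pose_id, ids)]]
    cl$angle <- pose_angle(p, ring_atoms, fad_atom)
    cl$stereo_call <- classify_pose(cl$angle, tol = tol)
    cl
  })
  clusters
}

#' Boltzmann-weighted R fraction of a clustered pose ensemble
#'
#' Each cluster i is a mesostate with degeneracy `g_i` (cluster size) and
#' energy `E_i` (representative pose energy, kcal/mol). Its Boltzmann weight
#' is `g_i * exp(-(E_i - E_min) / (kB * T))`; subtracting the minimum energy
#' is numerically stabilizing and mathematically neutral (the weight ratio is
#' shift invariant). `R_frac` is the weight of R-called clusters over the
#' total weight Z. Degenerate (90-degree) clusters contribute to Z but never
#' to the numerator, i.e. they are conservatively counted as non-R.
#'
#' @param clusters an annotated `cluster_set` (see [annotate_cluster_stereo()]).
#' @param temperature temperature in Kelvin (default 300).
#' @param boltzmann_constant kB in kcal/(mol K) (default 0.0019872).
#' @return an object of class `stereo_result`: list with `r_frac`,
#'   `partition_value` (Z on the shifted energy scale), `label`
#'   (via [label_from_rfrac()]), and `per_cluster_weights`.
#' @export
boltzmann_rfrac <- function(clusters, temperature = 300,
                            boltzmann_constant = 0.0019872) {
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be positive", call. = FALSE)
  }
  cl <- clusters$clusters
  if (length(cl) == 0L) stop("empty cluster set", call. = FALSE)
  calls <- vapply(cl, `[[`, character(1), "stereo_call")
  if (anyNA(calls)) {
    stop("clusters lack stereo calls; run annotate_cluster_stereo() first",
         call. = FALSE)
  }
  if (all(calls == "degenerate")) {
    stop("undefined stereochemistry: all clusters are degenerate",
         call. = FALSE)
  }
  if (any(calls == "degenerate")) {
    warning("degenerate cluster(s) contribute to Z but not to R_frac",
            call. = FALSE)
  }
  g <- vapply(cl, `[[`, numeric(1), "size")
  e <- vapply(cl, `[[`, numeric(1), "energy")
  w <- g * exp(-(e - min(e)) / (boltzmann_constant * temperature))
  z <- sum(w)
  r_frac <- sum(w[calls == "R"]) / z
  structure(list(r_frac = r_frac, partition_value = z,
                 label = label_from_rfrac(r_frac), per_cluster_weights = w,
                 temperature = temperature),
            class = "stereo_result")
}

#' @export
print.stereo_result <- function(x, ...) {
  cat(sprintf("<stereo_result> R_frac = %.4f -> %s (T = %g K, %d clusters)\n",
              x$r_frac, x$label, x$temperature, length(x$per_cluster_weights)))
  invisible(x)
}

#' Stereochemistry label from the R fraction
#'
#' `R_frac > 0.8` is called R, `R_frac < 0.2` is called S, everything in
#' between — including the endpoints, which the cutoff rule leaves unassigned —
#' is racemic `R/S`.
#'
#' @param r_frac fraction in \[0, 1\].
#' @return `"R"`, `"S"`, or `"R/S"`.
#' @export
label_from_rfrac <- function(r_frac) {
  if (!is.finite(r_frac) || r_frac < 0 || r_frac > 1) {
    stop("r_frac must lie in [0, 1]", call. = FALSE)
  }
  if (r_frac > 0.8) "R" else if (r_frac < 0.2) "S" else "R/S"
}

#' Consensus stereochemistry across ligands
#'
#' The modal label across per-ligand calls; any tie among modes is racemic.
#'
#' @param labels character vector of `"R"`, `"S"`, `"R/S"` labels (nonempty).
#' @return the consensus label.
#' @export
consensus_stereochemistry <- function(labels) {
  if (length(labels) == 0L) stop("empty label list", call. = FALSE)
  bad <- !(labels %in% c("R", "S", "R/S"))
  if (any(bad)) {
    stop("invalid stereochemistry label(s): ",
         paste(unique(labels[bad]), collapse = ", "), call. = FALSE)
  }
  counts <- table(labels)
  modes <- names(counts)[counts == max(counts)]
  if (length(modes) > 1L) "R/S" else modes
}

#' End-to-end stereochemistry prediction for one enzyme-ligand pair
#'
#' Convenience wrapper: clusters the ensemble, annotates representative
#' angles and R/S calls, and computes the Boltzmann-weighted R fraction.
#'
#' @inheritParams cluster_poses
#' @inheritParams pose_angle
#' @inheritParams boltzmann_rfrac
#' @param tol degeneracy tolerance for [classify_pose()].
#' @return list with `clusters` (annotated `cluster_set`) and `result`
#'   (`stereo_result`).
#' @export
predict_stereochemistry <- function(ensemble, ring_atoms, fad_atom,
                                    radius = 1.0, temperature = 300,
                                    boltzmann_constant = 0.0019872,
                                    tol = 1e-9) {
  cs <- cluster_poses(ensemble, radius = radius)
  cs <- annotate_cluster_stereo(cs, ensemble, ring_atoms, fad_atom, tol = tol)
  res <- boltzmann_rfrac(cs, temperature = temperature,
                         boltzmann_constant = boltzmann_constant)
  list(clusters = cs, result = res)
}
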