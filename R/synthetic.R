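AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

random_rotation <- function() {
  q <- qr(matrix(stats::rnorm(9), 3L))
  r <- qr.Q(q)
  if (det(r) < 0) r[, 1L] <- -r[, 1L]
  r
}

#' Generate a toy receptor-ligand complex with a controlled ring angle
#'
#' Builds a planar six-carbon ring ligand whose plane normal makes exactly
#' `angle` degrees with the vector from the ring centroid to a synthetic FAD
#' reference atom (`C4A`). Decoration atoms are placed in-plane in symmetric
#' pairs (one atom at the centroid when the count is odd) so the heavy-atom
#' mean stays on the ring axis; the first decoration atom is the phenolate
#' oxygen `O1` used as the anion anchor. The minimal receptor shell carries an
#' arginine (residue 206) with a `CZ` atom at a controlled distance from `O1`,
#' one contact residue within 4.5 Angstrom of the ring, one second-shell
#' residue behind it, and one remote residue. The whole complex is rotated and
#' translated rigidly by a seeded random frame, which leaves every angle and
#' distance intact.
#'
#' @param angle target ring-normal angle, degrees in \[0, 180\].
#' @param n_decoration_atoms extra in-plane ligand atoms (default 2).
#' @param seed seed for the rigid frame.
#' @param fad_distance centroid-to-C4A distance, Angstrom.
#' @param cz_distance O1-to-CZ distance, Angstrom (used when decorations
#'   exist; otherwise measured from the centroid).
#' @param energy docking energy assigned to the pose, kcal/mol.
#' @return list with `receptor` ([complex_structure()]), `pose` ([pose()]),
#'   `ring_atoms` (`c("C1","C2","C3")`), and `fad_atom` (xyz of `C4A`).
#' @export
generate_toy_complex <- function(angle, n_decoration_atoms = 2, seed = 1,
                                 fad_distance = 5, cz_distance = 4,
                                 energy = -10) {
  if (!is.finite(angle) || angle < 0 || angle > 180) {
    stop("angle must lie in [0, 180] degrees", call. = FALSE)
  }
  lig <- ring_template(angle, n_decoration_atoms)
  fad_xyz <- c(0, 0, fad_distance)
  anchor <- if (nrow(lig) > 6L) as.numeric(lig[7L, c("x", "y", "z")]) else
    c(0, 0, 0)
  cz <- anchor + c(0, cz_distance, 0)
  prot <- rbind(
    data.frame(atom_name = "CZ", element = "C", resno = 206L, resname = "ARG",
               x = cz[1L], y = cz[2L], z = cz[3L]),
    data.frame(atom_name = "CA", element = "C", resno = 206L, resname = "ARG",
               x = cz[1L] + 2, y = cz[2L] + 2, z = cz[3L]),
    data.frame(atom_name = "CA", element = "C", resno = 100L, resname = "LEU",
               x = 4.9, y = 0, z = 0),
    data.frame(atom_name = "CB", element = "C", resno = 150L, resname = "SER",
               x = 7.4, y = 0, z = 0),
    data.frame(atom_name = "CA", element = "C", resno = 300L, resname = "GLY",
               x = 25, y = 0, z = 0)
  )
  withr::with_seed(seed, {
    rot <- random_rotation()
    shift <- stats::runif(3L, -5, 5)
  })
  apply_frame <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(rot)
    df$x <- xyz[, 1L] + shift[1L]
    df$y <- xyz[, 2L] + shift[2L]
    df$z <- xyz[, 3L] + shift[3L]
    df
  }
  lig <- apply_frame(lig)
  prot <- apply_frame(prot)
  fad_xyz <- as.numeric(rot %*% fad_xyz + shift)
  fad <- atom_table("C4A", "C", resno = 500L, resname = "FAD", chain = "A",
                    x = fad_xyz[1L], y = fad_xyz[2L], z = fad_xyz[3L])
  receptor <- complex_structure(
    atom_table(prot$atom_name, prot$element, prot$resno, prot$resname, "A",
               prot$x, prot$y, prot$z),
    fad, enzyme_id = "toy")
  lig_pose <- pose(1L,
                   atom_table(lig$atom_name, lig$element, 1L, "LIG", "A",
                              lig$x, lig$y, lig$z),
                   energy = energy)
  list(receptor = receptor, pose = lig_pose,
       ring_atoms = c("C1", "C2", "C3"), fad_atom = fad_xyz)
}

# Planar ring + in-plane decorations in the canonical frame: the ring centroid
# sits at the origin, the FAD direction is +z, and the ring normal (from the
# C1,C2,C3 right-hand rule) makes `angle` degrees with +z.
ring_template <- function(angle, n_decoration_atoms = 2) {
  a <- angle * pi / 180
  e1 <- c(cos(a), 0, -sin(a))
  e2 <- c(0, 1, 0)  # e1 x e2 = (sin a, 0, cos a), the ring normal
  theta <- seq(0, by = pi / 3, length.out = 6L)
  ring <- t(vapply(theta, function(t)
    1.4 * (cos(t) * e1 + sin(t) * e2), numeric(3)))
  names_ <- paste0("C", 1:6)
  elems <- rep("C", 6L)
  if (n_decoration_atoms > 0L) {
    dec <- matrix(0, n_decoration_atoms, 3L)
    n_pairs <- n_decoration_atoms %/% 2L
    for (p in seq_len(n_pairs)) {
      phi <- pi / 6 + (p - 1L) * pi / 12
      pos <- 2.3 * (cos(phi) * e1 + sin(phi) * e2)
      dec[2L * p - 1L, ] <- pos
      dec[2L * p, ] <- -pos
    }
    # odd leftover atom sits on the centroid itself
    dec_names <- c("O1", if (n_decoration_atoms > 1L)
      paste0("D", 2:n_decoration_atoms))
    dec_elems <- c("O", rep("C", max(0L, n_decoration_atoms - 1L)))
    ring <- rbind(ring, dec)
    names_ <- c(names_, dec_names)
    elems <- c(elems, dec_elems)
  }
  data.frame(atom_name = names_, element = elems,
             x = ring[, 1L], y = ring[, 2L], z = ring[, 3L],
             stringsAsFactors = FALSE)
}

#' Generate a pose ensemble with a known cluster partition
#'
#' Each row of `cluster_spec` plants one cluster: a ring-ligand template at
#' orientation `angle`, translated to the center `(cx, cy, cz)`, with
#' `n_members` copies jittered by rigid-body translations drawn uniformly in
#' a ball of radius `jitter`. The first member carries `base_energy` exactly
#' (so it is the representative); the others are strictly higher by up to
#' `energy_spread`. Because jitter is pure translation, the fixed-frame RMSD
#' between two members equals the distance between their translation offsets,
#' which makes cluster-recovery bounds analytic: the true partition is
#' recovered exactly whenever `jitter <= 0.4 * radius` and centers are at
#' least `3 * radius` apart.
#'
#' @param cluster_spec data.frame with columns `n_members`, `base_energy`,
#'   `energy_spread`, `jitter`, `cx`, `cy`, `cz`, and optional `angle`
#'   (degrees, default 0).
#' @param seed RNG seed.
#' @param n_decoration_atoms forwarded to the ligand template.
#' @param enzyme_id,ligand_id identifiers.
#' @return a [pose_ensemble()] with attributes `truth` (integer cluster id
#'   per pose id) and `fad_reference` (a far-away FAD position on the +z axis
#'   so member jitter barely perturbs pose angles).
#' @export
generate_pose_ensemble <- function(cluster_spec, seed = 1,
                                   n_decoration_atoms = 2,
                                   enzyme_id = "sim", ligand_id = "lig") {
  cs <- as.data.frame(cluster_spec)
  need <- c("n_members", "base_energy", "energy_spread", "jitter",
            "cx", "cy", "cz")
  if (!all(need %in% names(cs))) {
    stop("cluster_spec missing columns: ",
         paste(setdiff(need, names(cs)), collapse = ", "), call. = FALSE)
  }
  if (is.null(cs$angle)) cs$angle <- 0
  centers <- as.matrix(cs[, c("cx", "cy", "cz")])
  if (nrow(cs) > 1L) {
    dmin <- min(stats::dist(centers))
    if (max(cs$jitter) >= dmin / 2) {
      stop("separability violated: jitter must stay below half the minimum ",
           "inter-center distance", call. = FALSE)
    }
  }
  withr::with_seed(seed, {
    poses <- list()
    truth <- integer(0)
    pid <- 0L
    for (i in seq_len(nrow(cs))) {
      tpl <- ring_template(cs$angle[i], n_decoration_atoms)
      for (m in seq_len(cs$n_members[i])) {
        off <- if (m == 1L) c(0, 0, 0) else {
          u <- stats::rnorm(3L)
          u / vec_norm(u) * cs$jitter[i] * stats::runif(1L)^(1 / 3)
        }
        en <- if (m == 1L) cs$base_energy[i] else
          cs$base_energy[i] + 1e-6 + stats::runif(1L) * cs$energy_spread[i]
        pid <- pid + 1L
        poses[[pid]] <- pose(
          pid,
          atom_table(tpl$atom_name, tpl$element, 1L, "LIG", "A",
                     tpl$x + centers[i, 1L] + off[1L],
                     tpl$y + centers[i, 2L] + off[2L],
                     tpl$z + centers[i, 3L] + off[3L]),
          energy = en)
        truth[pid] <- i
      }
    }
  })
  ens <- pose_ensemble(poses, enzyme_id = enzyme_id, ligand_id = ligand_id)
  attr(ens, "truth") <- truth
  attr(ens, "fad_reference") <- c(0, 0, 1e4)
  ens
}

#' Configuration for the planted-determinant screen simulator
#'
#' Defaults emulate a desk-scale functional screen: 300 enzymes, 60 aligned
#' residue columns, an F/Y stereochemistry switch and an I/V reactivity
#' switch planted at distinct columns, uniform background composition with
#' 2\% gaps, and a 10\% label noise rate.
#'
#' @param n_enzymes,n_columns screen dimensions.
#' @param stereo_switch_column,stereo_alleles planted stereochemistry
#'   determinant: allele 1 codes S (-1), allele 2 codes R (+1).
#' @param reactivity_switch_column,reactivity_alleles planted reactivity
#'   determinant: allele 1 codes reactive (1), allele 2 unreactive (0).
#' @param label_noise probability that a label is replaced (stereo: by one of
#'   the other two classes; reactivity: flipped); must stay below 0.5 so the
#'   planted signal dominates.
#' @param background_freqs amino-acid frequencies of non-switch columns.
#' @param gap_prob per-position gap probability in non-switch columns.
#' @param seed RNG seed.
#' @return a validated list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_enzymes = 300, n_columns = 60,
                              stereo_switch_column = 20,
                              stereo_alleles = c("F", "Y"),
                              reactivity_switch_column = 40,
                              reactivity_alleles = c("I", "V"),
                              label_noise = 0.1,
                              background_freqs = NULL,
                              gap_prob = 0.02, seed = 1) {
  if (stereo_switch_column == reactivity_switch_column ||
      stereo_switch_column > n_columns || reactivity_switch_column > n_columns) {
    stop("switch columns must be distinct and within n_columns", call. = FALSE)
  }
  if (!is.finite(label_noise) || label_noise < 0 || label_noise >= 0.5) {
    stop("label_noise must lie in [0, 0.5)", call. = FALSE)
  }
  if (gap_prob < 0 || gap_prob > 1) stop("gap_prob must lie in [0, 1]",
                                         call. = FALSE)
  if (is.null(background_freqs)) {
    background_freqs <- stats::setNames(rep(1 / 20, 20L), AA20)
  }
  structure(list(n_enzymes = n_enzymes, n_columns = n_columns,
                 stereo_switch_column = stereo_switch_column,
                 stereo_alleles = stereo_alleles,
                 reactivity_switch_column = reactivity_switch_column,
                 reactivity_alleles = reactivity_alleles,
                 label_noise = label_noise,
                 background_freqs = background_freqs,
                 gap_prob = gap_prob, seed = seed),
            class = "screen_sim_config")
}

#' Generate a planted-determinant screen dataset
#'
#' Sequences are drawn column-wise from the background composition, except at
#' the two planted switch columns, whose alleles are drawn 50/50 and
#' deterministically set the stereochemistry (allele 1 -> -1/S, allele 2 ->
#' +1/R) and reactivity (allele 1 -> 1, allele 2 -> 0) labels before noise is
#' applied. All other columns are independent of the labels.
#'
#' @param config a [screen_sim_config()].
#' @return list with `alignment`, `labels` (data.frame `id`,
#'   `stereochemistry`, `reactivity`), and `truth` (planted columns, alleles,
#'   and pre-noise labels).
#' @export
generate_screen_dataset <- function(config = screen_sim_config()) {
  stopifnot(inherits(config, "screen_sim_config"))
  n <- config$n_enzymes; p <- config$n_columns
  withr::with_seed(config$seed, {
    bg_symbols <- c(names(config$background_freqs), "-")
    bg_prob <- c((1 - config$gap_prob) * config$background_freqs,
                 config$gap_prob)
    aa <- matrix(sample(bg_symbols, n * p, replace = TRUE, prob = bg_prob),
                 n, p)
    stereo_allele <- sample(config$stereo_alleles, n, replace = TRUE)
    react_allele <- sample(config$reactivity_alleles, n, replace = TRUE)
    aa[, config$stereo_switch_column] <- stereo_allele
    aa[, config$reactivity_switch_column] <- react_allele
    stereo_clean <- ifelse(stereo_allele == config$stereo_alleles[1L], -1, 1)
    react_clean <- ifelse(react_allele == config$reactivity_alleles[1L], 1, 0)
    stereo <- stereo_clean
    noisy_s <- stats::runif(n) < config$label_noise
    stereo[noisy_s] <- vapply(stereo_clean[noisy_s], function(l)
      sample(setdiff(c(-1, 0, 1), l), 1L), numeric(1))
    react <- react_clean
    noisy_r <- stats::runif(n) < config$label_noise
    react[noisy_r] <- 1 - react[noisy_r]
  })
  ids <- sprintf("enz%04d", seq_len(n))
  alignment <- make_alignment(ids, apply(aa, 1L, paste0, collapse = ""))
  labels <- data.frame(id = ids, stereochemistry = stereo, reactivity = react,
                       stringsAsFactors = FALSE)
  truth <- list(stereo_column = config$stereo_switch_column,
                stereo_alleles = config$stereo_alleles,
                reactivity_column = config$reactivity_switch_column,
                reactivity_alleles = config$reactivity_alleles,
                stereo_clean = stereo_clean, reactivity_clean = react_clean,
                config = config)
  list(alignment = alignment, labels = labels, truth = truth)
}

#' Generate a descriptor table from a known logistic model
#'
#' Descriptors are drawn standard normal; labels are Bernoulli with
#' inverse-logit probabilities from the stated linear model. Used as the
#' simulate-and-refit oracle for the reactivity classifier.
#'
#' @param true_coefficients named coefficient vector (default: one per
#'   [REACTIVITY_DESCRIPTORS] entry).
#' @param intercept intercept of the linear model.
#' @param n number of rows (at least 50).
#' @param seed RNG seed.
#' @return list with `descriptors` (data.frame), `labels` (0/1),
#'   `probabilities`, `coefficients`, `intercept`.
#' @export
generate_descriptor_table <- function(true_coefficients = NULL, intercept = 0,
                                      n = 1000, seed = 1) {
  if (is.null(true_coefficients)) {
    true_coefficients <- stats::setNames(
      c(-0.2, 0.5, -0.8, -1.0, 1.2), REACTIVITY_DESCRIPTORS)
  }
  if (n < 50) stop("n must be at least 50", call. = FALSE)
  p <- length(true_coefficients)
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, names(true_coefficients)))
    prob <- stats::plogis(intercept + drop(x %*% true_coefficients))
    y <- stats::rbinom(n, 1L, prob)
  })
  list(descriptors = as.data.frame(x), labels = y, probabilities = prob,
       coefficients = true_coefficients, intercept = intercept)
}
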