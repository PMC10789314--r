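test_that("ring-plane normal follows the right-hand rule and rotates with the pose", {
  p <- make_pose(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(ring_plane_normal(p, c("C1", "C2", "C3")), c(0, 0, 1))
  # antisymmetry under order reversal
  expect_equal(ring_plane_normal(p, c("C1", "C3", "C2")), c(0, 0, -1))
  # equivariance: rotating the atoms rotates the normal identically
  for (seed in 1:5) {
    set.seed(seed)
    R <- rotation_matrix(rnorm(3), runif(1, 10, 170))
    pr <- make_pose(t(R %*% t(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))))
    expect_equal(ring_plane_normal(pr, c("C1", "C2", "C3")),
                 as.numeric(R %*% c(0, 0, 1)), tolerance = 1e-12)
  }
})

test_that("collinear ring atoms are a degenerate geometry", {
  p <- make_pose(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_error(ring_plane_normal(p, c("C1", "C2", "C3")), "collinear")
  expect_error(ring_plane_normal(p, c("C1", "C2")), "3 distinct")
})

test_that("pose angle spans parallel, orthogonal, and antiparallel geometry", {
  # planar triangle in z = 0 with centroid at origin; normal (0,0,1)
  tri <- rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0), c(-0.5, -sqrt(3) / 2, 0))
  p <- make_pose(tri)
  ring <- c("C1", "C2", "C3")
  expect_equal(pose_angle(p, ring, c(0, 0, 5)), 0)
  expect_equal(pose_angle(p, ring, c(0, 0, -5)), 180)
  expect_equal(pose_angle(p, ring, c(5, 0, 0)), 90)
  expect_error(pose_angle(p, ring, c(0, 0, 0)), "degenerate")
})

test_that("the angle rule assigns S below 90 and R above 90 degrees", {
  expect_equal(classify_pose(45), "S")
  expect_equal(classify_pose(135), "R")
  expect_equal(classify_pose(90), "degenerate")
  expect_equal(classify_pose(90 + 1e-12), "degenerate")
  expect_equal(classify_pose(0), "S")
  expect_equal(classify_pose(180), "R")
  expect_error(classify_pose(181), "0, 180")
  expect_error(classify_pose(-1), "0, 180")
})

test_that("identical and far-apart poses cluster trivially", {
  xyz <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(0, 1.4, 0))
  same <- pose_ensemble(lapply(1:3, function(i)
    make_pose(xyz, energy = -i, pose_id = i)))
  cs <- cluster_poses(same)
  expect_length(cs$clusters, 1L)
  expect_equal(cs$clusters[[1L]]$size, 3L)
  expect_equal(cs$clusters[[1L]]$energy, -3)
  far <- pose_ensemble(list(make_pose(xyz, energy = -1),
                            make_pose(xyz + 10, energy = -2, pose_id = 2L)))
  cs2 <- cluster_poses(far)
  expect_length(cs2$clusters, 2L)
  expect_equal(vapply(cs2$clusters, `[[`, integer(1), "size"), c(1L, 1L))
  expect_error(cluster_poses(far, radius = 0), "positive")
})

test_that("clustering matches a brute-force leader oracle and partitions poses", {
  for (seed in 1:8) {
    spec <- data.frame(n_members = c(20, 15, 15), base_energy = c(0, 0.5, 1),
                       energy_spread = 3, jitter = 0.8,
                       cx = c(0, 6, -6), cy = c(0, 3, 3), cz = 0)
    ens <- generate_pose_ensemble(spec, seed = seed)
    cs <- cluster_poses(ens, radius = 1)
    # oracle partition on the same ascending-energy visiting order
    coords <- lapply(ens$poses, function(p) atom_coords(p$atoms))
    oracle <- oracle_leader_partition(coords, radius = 1)
    got <- integer(length(ens$poses))
    ids <- vapply(ens$poses, `[[`, integer(1), "pose_id")
    for (k in seq_along(cs$clusters)) {
      got[match(cs$clusters[[k]]$member_pose_ids, ids)] <- k
    }
    # same partition up to cluster relabeling: label pairing is a bijection
    expect_equal(length(unique(paste(got, oracle))), length(unique(got)))
    expect_equal(length(unique(got)), length(unique(oracle)))
    # partition invariant: every pose id in exactly one cluster
    all_ids <- unlist(lapply(cs$clusters, `[[`, "member_pose_ids"))
    expect_setequal(all_ids, ids)
    expect_equal(anyDuplicated(all_ids), 0L)
    # every representative is the minimum-energy member of its cluster
    e <- pose_energies(ens)
    for (cl in cs$clusters) {
      expect_equal(e[match(cl$representative_pose_id, ids)],
                   min(e[match(cl$member_pose_ids, ids)]))
    }
  }
})

test_that("Boltzmann R fraction matches closed forms", {
  one_r <- fake_cluster_set(5, -3, "R")
  expect_equal(boltzmann_rfrac(one_r)$r_frac, 1)
  sym <- fake_cluster_set(c(2, 2), c(-1, -1), c("R", "S"))
  expect_equal(boltzmann_rfrac(sym)$r_frac, 0.5)
  # energies 0 and kB*T*ln(2) give weights 1 and 1/2 -> R_frac = 2/3
  kT <- 0.0019872 * 300
  two <- fake_cluster_set(c(1, 1), c(0, kT * log(2)), c("R", "S"))
  expect_equal(boltzmann_rfrac(two)$r_frac, 2 / 3, tolerance = 1e-12)
})

test_that("R fraction matches the brute-force oracle and is shift invariant", {
  set.seed(202)
  for (i in 1:50) {
    a <- random_cluster_args(sample(2:12, 1))
    got <- suppressWarnings(
      boltzmann_rfrac(fake_cluster_set(a$sizes, a$energies, a$calls))$r_frac)
    want <- oracle_rfrac(a$sizes, a$energies, a$calls)
    expect_equal(got, want, tolerance = 1e-12)
    shifted <- suppressWarnings(boltzmann_rfrac(
      fake_cluster_set(a$sizes, a$energies + 37.5, a$calls))$r_frac)
    expect_equal(shifted, got, tolerance = 1e-12)
  }
})

test_that("temperature limits recover the minimum-energy call and size fractions", {
  sizes <- c(3, 7, 2); energies <- c(-5, -2, 0); calls <- c("R", "S", "R")
  cs <- fake_cluster_set(sizes, energies, calls)
  expect_equal(boltzmann_rfrac(cs, temperature = 1e-4)$r_frac, 1)
  expect_equal(boltzmann_rfrac(cs, temperature = 1e9)$r_frac,
               sum(sizes[calls == "R"]) / sum(sizes), tolerance = 1e-6)
  cs_s <- fake_cluster_set(sizes, energies, c("S", "R", "R"))
  expect_equal(boltzmann_rfrac(cs_s, temperature = 1e-4)$r_frac, 0)
})

test_that("degenerate clusters count toward Z but never toward R", {
  cs <- fake_cluster_set(c(1, 1), c(0, 0), c("R", "degenerate"))
  expect_warning(res <- boltzmann_rfrac(cs), "degenerate")
  expect_equal(res$r_frac, 0.5)
  all_deg <- fake_cluster_set(c(1, 2), c(0, 1), c("degenerate", "degenerate"))
  expect_error(suppressWarnings(boltzmann_rfrac(all_deg)),
               "undefined stereochemistry")
})

test_that("R fraction cutoffs map to labels with racemic endpoints", {
  expect_equal(label_from_rfrac(0.9), "R")
  expect_equal(label_from_rfrac(0.1), "S")
  expect_equal(label_from_rfrac(0.8), "R/S")
  expect_equal(label_from_rfrac(0.2), "R/S")
  expect_equal(label_from_rfrac(0.5), "R/S")
  expect_error(label_from_rfrac(1.2), "\\[0, 1\\]")
})

test_that("consensus stereochemistry is the mode with racemic ties", {
  expect_equal(consensus_stereochemistry(c("R", "R", "S", "R/S")), "R")
  expect_equal(consensus_stereochemistry(c("R", "S")), "R/S")
  expect_equal(consensus_stereochemistry(c("S", "S", "S", "S")), "S")
  expect_error(consensus_stereochemistry(character(0)), "empty")
  expect_error(consensus_stereochemistry(c("R", "Q")), "invalid")
})

test_that("reversing the ring atom order mirrors every call and the R fraction", {
  spec <- data.frame(n_members = c(8, 6, 5), base_energy = c(0, 0.4, 1.1),
                     energy_spread = 1, jitter = 0.3,
                     cx = c(0, 8, 16), cy = 0, cz = 0,
                     angle = c(30, 150, 120))
  ens <- generate_pose_ensemble(spec, seed = 21)
  fad <- attr(ens, "fad_reference")
  fwd <- predict_stereochemistry(ens, c("C1", "C2", "C3"), fad)
  rev <- predict_stereochemistry(ens, c("C1", "C3", "C2"), fad)
  a_f <- vapply(fwd$clusters$clusters, `[[`, numeric(1), "angle")
  a_r <- vapply(rev$clusters$clusters, `[[`, numeric(1), "angle")
  expect_equal(a_r, 180 - a_f, tolerance = 1e-9)
  c_f <- vapply(fwd$clusters$clusters, `[[`, character(1), "stereo_call")
  c_r <- vapply(rev$clusters$clusters, `[[`, character(1), "stereo_call")
  expect_equal(c_r, c(S = "R", R = "S")[c_f], ignore_attr = TRUE)
  expect_equal(rev$result$r_frac, 1 - fwd$result$r_frac, tolerance = 1e-12)
})
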