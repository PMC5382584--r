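test_that("center of mass matches the direct mass-weighted sum", {
  topo <- topology(make_atoms(2L, mass = 1))
  fr <- rbind(c(1, 0, 0), c(-1, 0, 0))
  expect_equal(center_of_mass(topo, atom_selection(1:2), fr), c(0, 0, 0))
  expect_equal(center_of_mass(topo, atom_selection(1L), fr), c(1, 0, 0))

  set.seed(5)
  m <- stats::runif(50, 0.5, 30)
  topo50 <- topology(make_atoms(50L, mass = m))
  fr50 <- matrix(stats::rnorm(150), ncol = 3L)
  expect_equal(center_of_mass(topo50, atom_selection(1:50), fr50),
               oracle_com(m, fr50), tolerance = 1e-10)
  expect_error(center_of_mass(topo, atom_selection(integer()), fr), "empty")
})

test_that("principal axis follows the gyration tensor and the N-to-C convention", {
  topo <- topology(make_atoms(10L))
  line <- cbind(0, 0, seq(0, 9))
  expect_equal(principal_axis(topo, atom_selection(1:10), line), c(0, 0, 1))
  # same points in reversed selection-order flip the sign
  expect_equal(principal_axis(topo, atom_selection(1:10), line[10:1, ]),
               c(0, 0, -1))
  # ideal helix about a known axis, within 2 degrees
  sys <- make_complex_trajectory(trajectory_spec(1L, 0, 0L, seed = 1))
  bb <- select_atoms(sys$topology, "chain L and backbone")
  ax <- principal_axis(sys$topology, bb, sys$trajectory$frames[[1L]])
  expect_lt(acos(min(1, sum(ax * c(0, 0, 1)))) * 180 / pi, 2)
  # degenerate configurations are refused
  sq <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
  topo4 <- topology(make_atoms(4L))
  expect_error(principal_axis(topo4, atom_selection(1:4), sq), "degenerate")
})

test_that("Kabsch superposition recovers constructed rigid transforms", {
  set.seed(9)
  x <- matrix(stats::rnorm(30), ncol = 3L)
  id <- kabsch_superpose(x, x)
  expect_equal(id$rotation, diag(3), tolerance = 1e-10)
  expect_equal(id$rmsd, 0, tolerance = 1e-10)

  tr <- kabsch_superpose(x + 5, x)
  expect_equal(tr$rmsd, 0, tolerance = 1e-10)
  expect_equal(tr$translation, c(-5, -5, -5), tolerance = 1e-8)

  rot <- rotation_about_z(25)
  y <- x %*% t(rot)
  rec <- kabsch_superpose(y, x)
  expect_equal(rec$rotation %*% rot, diag(3), tolerance = 1e-6)
  expect_lt(rec$rmsd, 1e-8)

  expect_error(kabsch_superpose(x[1:2, ], x[1:2, ]), "at least 3")
})

test_that("Kabsch RMSD is optimal: never above unaligned RMSD or a rotation grid search", {
  set.seed(21)
  for (rep in 1:5) {
    a <- matrix(stats::rnorm(15), ncol = 3L)
    b <- matrix(stats::rnorm(15), ncol = 3L)
    fit <- kabsch_superpose(a, b)
    unaligned <- sqrt(mean(rowSums((a - b)^2)))
    expect_lte(fit$rmsd, unaligned + 1e-12)
    # brute-force search over random rotations (centered coordinates)
    ac <- sweep(a, 2L, colMeans(a)); bc <- sweep(b, 2L, colMeans(b))
    grid_best <- min(vapply(1:4000, function(i) {
      sqrt(mean(rowSums((ac %*% t(random_rotation()) - bc)^2)))
    }, numeric(1L)))
    expect_lte(fit$rmsd, grid_best + 1e-3)
  }
})

test_that("RMSD series is zero on rigid-motion trajectories and tracks jitter otherwise", {
  topo <- topology(make_atoms(100L))
  set.seed(13)
  base <- matrix(stats::rnorm(300, sd = 5), ncol = 3L)
  rigid <- lapply(1:6, function(f) {
    sweep(base %*% t(random_rotation()), 2L, stats::rnorm(3, sd = 10), `+`)
  })
  sel <- atom_selection(1:100)
  r <- backbone_rmsd_series(topo, trajectory(rigid), sel,
                            reference_frame = base)
  expect_true(all(r$values < 1e-8))

  # jitter sigma = 0.5: mean fitted RMSD near sqrt(3)*sigma*sqrt(1 - 2/n)
  sigma <- 0.5
  jit <- lapply(1:40, function(f) {
    base + matrix(stats::rnorm(300, sd = sigma), ncol = 3L)
  })
  rj <- backbone_rmsd_series(topo, trajectory(jit), sel,
                             reference_frame = base)
  expected <- sqrt(3) * sigma * sqrt(1 - 2 / 100)
  expect_lt(abs(mean(rj$values) - expected) / expected, 0.2)
})

test_that("helical rotation recovers constructed carrier rotations", {
  sched <- c(0, 10, 38.44, 90, 180, 120)
  sys <- make_complex_trajectory(
    trajectory_spec(6L, sched, rep(0L, 6), noise_sigma = 0, seed = 2))
  lig <- select_atoms(sys$topology, "chain L and backbone")
  car <- select_atoms(sys$topology, "chain A or chain B")
  th <- helical_rotation_series(sys$topology, sys$trajectory, lig, car)
  expect_identical(th$values[1L], 0)           # theta(0) is exactly zero
  expect_equal(th$values, sched, tolerance = 1e-4)
  expect_true(all(th$values >= 0 & th$values <= 180))
})

test_that("helical rotation is invariant under global rigid motion of frames", {
  sched <- c(0, 25, 50)
  sys <- make_complex_trajectory(
    trajectory_spec(3L, sched, rep(0L, 3), noise_sigma = 0, seed = 4))
  lig <- select_atoms(sys$topology, "chain L and backbone")
  car <- select_atoms(sys$topology, "chain A or chain B")
  th0 <- helical_rotation_series(sys$topology, sys$trajectory, lig, car)
  set.seed(77)
  moved <- lapply(sys$trajectory$frames, function(fr) {
    sweep(fr %*% t(random_rotation()), 2L, stats::rnorm(3, sd = 20), `+`)
  })
  th1 <- helical_rotation_series(sys$topology,
                                 trajectory(moved, sys$trajectory$times),
                                 lig, car)
  expect_equal(th1$values, th0$values, tolerance = 1e-6)
})

test_that("a carrier center of mass on the helix axis is an error, not a number", {
  # symmetric square of atoms around the axis: projection below 0.5 A
  n_res <- 20L
  topo <- make_peptide_topology(n_res)
  at <- make_atoms(4L, chain_id = "A", res_name = "CAR")
  at$serial <- nrow(topo$atoms) + 1:4
  full <- topology(rbind(topo$atoms, at),
                   list(ligand = seq_len(nrow(topo$atoms)),
                        carrier = nrow(topo$atoms) + 1:4))
  helix <- make_complex_trajectory(trajectory_spec(1L, 0, 0L, seed = 1))
  lig_xyz <- helix$trajectory$frames[[1L]][
    select_atoms(helix$topology, "chain L and backbone"), ]
  sq <- rbind(c(9, 0, 10), c(-9, 0, 10), c(0, 9, 20), c(0, -9, 20))
  fr <- rbind(lig_xyz, sq)
  expect_error(
    helical_rotation_series(full, trajectory(list(fr, fr)),
                            select_atoms(full, "chain L and backbone"),
                            select_atoms(full, "chain A")),
    "axis")
})

test_that("signed rotation distinguishes handedness; unsigned folds to [0, 180]", {
  sched <- c(0, 20, 340)   # +20 and -20 about the axis
  sys <- make_complex_trajectory(
    trajectory_spec(3L, sched, rep(0L, 3), noise_sigma = 0, seed = 6))
  lig <- select_atoms(sys$topology, "chain L and backbone")
  car <- select_atoms(sys$topology, "chain A or chain B")
  uns <- helical_rotation_series(sys$topology, sys$trajectory, lig, car)
  sgn <- helical_rotation_series(sys$topology, sys$trajectory, lig, car,
                                 signed = TRUE)
  expect_equal(uns$values, c(0, 20, 20), tolerance = 1e-4)
  expect_equal(abs(sgn$values), c(0, 20, 20), tolerance = 1e-4)
  expect_lt(sgn$values[2L] * sgn$values[3L], 0)  # opposite signs
})

test_that("convergence detection finds the plateau entry time", {
  # constant series converges immediately
  const <- scalar_series(seq(0, 10, 0.5), rep(2, 21))
  cv <- convergence_time(const, window = 2, tolerance = 0.1)
  expect_equal(cv$time, 0)
  expect_equal(cv$plateau, 2)

  # strictly increasing ramp with tight tolerance never converges
  ramp <- scalar_series(seq(0, 50, 0.5), seq(0, 5, length.out = 101))
  expect_null(convergence_time(ramp, window = 5, tolerance = 0.05))

  # rise to 2.43 A by 20 ns then flat noise: entry in [15, 25] ns
  set.seed(8)
  t <- seq(0, 60, 0.1)
  v <- ifelse(t < 20, 2.43 * t / 20, 2.43) + stats::rnorm(length(t), 0, 0.05)
  cv2 <- convergence_time(scalar_series(t, v), window = 5, tolerance = 0.3)
  expect_gte(cv2$time, 15)
  expect_lte(cv2$time, 25)
  expect_equal(cv2$plateau, 2.43, tolerance = 0.1)

  expect_error(convergence_time(scalar_series(numeric(), numeric())),
               "empty")
})
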