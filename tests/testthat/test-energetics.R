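two_atom_topo <- function(charge = c(1, -1), sigma = 0, eps = 0, born = 0) {
  topology(make_atoms(2L, name = c("X1", "X2"), chain_id = c("A", "B"),
                      charge = charge, lj_sigma = sigma, lj_epsilon = eps,
                      born_radius = born))
}

test_that("electrostatics reproduce the Coulomb and screened-GB closed forms", {
  topo <- two_atom_topo()
  fr <- rbind(c(0, 0, 0), c(10, 0, 0))
  a <- atom_selection(1L); b <- atom_selection(2L)

  vac <- pair_interaction_energy(topo, fr, a, b, energy_model(use_gb = FALSE))
  expect_equal(vac$elec, -332.0636 / 10, tolerance = 1e-10)

  # zero Born radii: f_GB = r, the fully screened (1/eps_w) limit
  gb <- pair_interaction_energy(topo, fr, a, b, energy_model(use_gb = TRUE))
  expect_equal(gb$elec, -332.0636 / 78.5 / 10, tolerance = 1e-10)
  expect_lt(abs(gb$elec - (-0.4231)), 1e-4)

  # the screened limit is approached monotonically as radii shrink
  prev <- Inf
  for (rb in c(10, 5, 2)) {
    e <- pair_interaction_energy(two_atom_topo(born = rb), fr, a, b,
                                 energy_model())$elec
    expect_lt(abs(e - gb$elec), prev)
    prev <- abs(e - gb$elec)
  }
})

test_that("Lennard-Jones term has its root at sigma and minimum -eps at 2^(1/6) sigma", {
  sij <- 3.4; eij <- 0.2
  topo <- two_atom_topo(charge = c(0, 0), sigma = sij, eps = eij)
  a <- atom_selection(1L); b <- atom_selection(2L)
  at_sigma <- pair_interaction_energy(topo, rbind(c(0, 0, 0), c(sij, 0, 0)),
                                      a, b, energy_model())
  expect_equal(at_sigma$vdw, 0, tolerance = 1e-10)
  at_min <- pair_interaction_energy(
    topo, rbind(c(0, 0, 0), c(2^(1 / 6) * sij, 0, 0)), a, b, energy_model())
  expect_equal(at_min$vdw, -eij, tolerance = 1e-10)
})

test_that("a 30-atom random system matches the naive double-loop oracle", {
  set.seed(41)
  n <- 30L
  at <- make_atoms(n, chain_id = rep(c("A", "B"), each = 15L),
                   charge = stats::runif(n, -0.8, 0.8),
                   lj_sigma = stats::runif(n, 2.5, 4),
                   lj_epsilon = stats::runif(n, 0.05, 0.3),
                   born_radius = sample(c(0, 1.2, 1.7), n, replace = TRUE))
  topo <- topology(at)
  fr <- matrix(stats::runif(n * 3L, 0, 20), ncol = 3L)
  # keep pairs clash-free
  while (TRUE) {
    d <- pair_distances(fr, 1:15, 16:30)
    if (min(d) > 1) break
    fr <- matrix(stats::runif(n * 3L, 0, 20), ncol = 3L)
  }
  a <- atom_selection(1:15); b <- atom_selection(16:30)
  for (use_gb in c(TRUE, FALSE)) {
    got <- pair_interaction_energy(topo, fr, a, b,
                                   energy_model(use_gb = use_gb))
    want <- oracle_pair_energy(at, fr, 1:15, 16:30, use_gb = use_gb)
    expect_equal(got$elec, want$elec, tolerance = 1e-8)
    expect_equal(got$vdw, want$vdw, tolerance = 1e-8)
    expect_equal(got$total, want$total, tolerance = 1e-8)
  }
  # minimum-image variant against the same oracle
  box <- c(15, 15, 15)
  got_mi <- pair_interaction_energy(topo, fr, a, b, energy_model(),
                                    box = box)
  want_mi <- oracle_pair_energy(at, fr, 1:15, 16:30, box = box)
  expect_equal(got_mi$total, want_mi$total, tolerance = 1e-8)
})

test_that("pair energies are symmetric, additive over groups, and GB-bounded", {
  set.seed(43)
  n <- 24L
  at <- make_atoms(n, chain_id = rep(c("A", "B"), each = 12L),
                   charge = stats::runif(n, 0.05, 0.5),  # like-signed
                   lj_sigma = 3, lj_epsilon = 0.1, born_radius = 1.5)
  topo <- topology(at)
  fr <- matrix(stats::runif(n * 3L, 0, 25), ncol = 3L)
  a <- atom_selection(1:12); b <- atom_selection(13:24)
  eab <- pair_interaction_energy(topo, fr, a, b, energy_model())
  eba <- pair_interaction_energy(topo, fr, b, a, energy_model())
  expect_identical(eab$total, eba$total)

  a1 <- atom_selection(1:6); a2 <- atom_selection(7:12)
  e1 <- pair_interaction_energy(topo, fr, a1, b, energy_model())
  e2 <- pair_interaction_energy(topo, fr, a2, b, energy_model())
  expect_equal(eab$total, e1$total + e2$total, tolerance = 1e-10)

  # for like-signed charges: 0 < GB-screened < vacuum electrostatics
  vac <- pair_interaction_energy(topo, fr, a, b,
                                 energy_model(use_gb = FALSE))
  expect_gt(eab$elec, 0)
  expect_lt(eab$elec, vac$elec)

  expect_error(pair_interaction_energy(topo, fr, a, a1, energy_model()),
               "disjoint")
  clash <- fr; clash[13L, ] <- fr[1L, ] + c(0.01, 0, 0)
  expect_error(pair_interaction_energy(topo, clash, a, b, energy_model()),
               "clash")
})

test_that("per-cluster enthalpies average member frames; closer charged groups bind tighter", {
  at <- make_atoms(4L, chain_id = c("A", "A", "B", "B"),
                   charge = c(0.5, 0.5, -0.5, -0.5), born_radius = 1.5)
  topo <- topology(at)
  near <- rbind(c(0, 0, 0), c(2, 0, 0), c(8, 0, 0), c(10, 0, 0))
  far <- rbind(c(0, 0, 0), c(2, 0, 0), c(15, 0, 0), c(17, 0, 0))
  traj <- trajectory(list(near, near, far, far, near))
  mk <- function(id, frames) structure(list(id = id, member_frames = frames),
                                       class = "Cluster")
  rep_ <- cluster_mean_enthalpy(topo, traj, list(mk(1L, c(1L, 2L, 5L)),
                                                 mk(2L, 3:4)),
                                atom_selection(1:2), atom_selection(3:4),
                                energy_model())
  expect_equal(rep_$n_frames, c(3L, 2L))
  expect_equal(rep_$sd_kcal, c(0, 0), tolerance = 1e-10)
  expect_gt(abs(rep_$mean_kcal[1L]), abs(rep_$mean_kcal[2L]))
  expect_equal(rep_$abs_mean_kcal, abs(rep_$mean_kcal))
  expect_equal(rep_$mean_kcal, rep_$elec_kcal + rep_$vdw_kcal,
               tolerance = 1e-10)

  # single-frame cluster: n 1, sd 0
  one <- cluster_mean_enthalpy(topo, traj, list(mk(1L, 3L)),
                               atom_selection(1:2), atom_selection(3:4),
                               energy_model())
  expect_equal(one$n_frames, 1L)
  expect_equal(one$sd_kcal, 0)
  expect_warning(
    cluster_mean_enthalpy(topo, traj, list(mk(1L, integer())),
                          atom_selection(1:2), atom_selection(3:4),
                          energy_model()),
    "no member")
})
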