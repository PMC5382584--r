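# helper: peptide + explicit water-oxygen positions in a single frame
water_system <- function(n_waters, box = NULL) {
  bb <- make_atoms(8L, name = rep(c("N", "CA", "C", "O"), 2L),
                   element = rep(c("N", "C", "C", "O"), 2L),
                   res_id = rep(1:2, each = 4L), chain_id = "L")
  # 4-residue chain so 'first and last two' spans everything: residues 3,4
  bb2 <- make_atoms(8L, name = rep(c("N", "CA", "C", "O"), 2L),
                    element = rep(c("N", "C", "C", "O"), 2L),
                    res_id = rep(3:4, each = 4L), chain_id = "L")
  wat <- make_atoms(n_waters, name = "O", element = "O", res_name = "HOH",
                    res_id = seq_len(n_waters), chain_id = "W")
  at <- rbind(bb, bb2, wat)
  at$serial <- seq_len(nrow(at))
  topology(at, list(ligand = 1:16, solvent = 16L + seq_len(n_waters)))
}

test_that("terminal hydration counts waters within the cutoff, each once", {
  topo <- water_system(8L)
  fr <- matrix(0, 24L, 3L)
  fr[1:16, ] <- cbind(seq(0, 7.5, 0.5), 0, 0)   # peptide along x
  # 3 waters at 4.0 A from residue-1 atoms, 5 at 10 A from everything
  fr[17:19, ] <- cbind(0:2 * 0.5, 4.0, 0)
  fr[20:24, ] <- cbind(3, 0, 10 + 0:4 * 3)
  traj <- trajectory(list(fr))
  h <- terminal_hydration_series(topo, traj, "L", hydration_spec(2L, 5.0))
  expect_equal(h$values, 3)

  # boundary convention: exactly at the cutoff is counted
  fr2 <- fr
  fr2[20L, ] <- c(0, 5.0, 0)   # exactly 5.0 A from atom 1
  h2 <- terminal_hydration_series(topo, trajectory(list(fr2)), "L")
  expect_equal(h2$values, 4)

  # enlarging the cutoff never decreases the count
  for (cut in c(3, 4, 5, 7, 11)) {
    hc <- terminal_hydration_series(topo, trajectory(list(fr)), "L",
                                    hydration_spec(2L, cut))$values
    if (cut > 3) expect_gte(hc, prev)
    prev <- hc
  }
})

test_that("hydration uses minimum-image distances across the periodic boundary", {
  topo <- water_system(1L)
  fr <- matrix(0, 17L, 3L)
  fr[1:16, ] <- cbind(seq(0, 7.5, 0.5), 0, 0)
  fr[17L, ] <- c(76, 0, 0)   # unwrapped 76 A; in an 80 A box this is 4 A
  h_box <- terminal_hydration_series(topo,
                                     trajectory(list(fr), box = c(80, 80, 80)),
                                     "L")
  expect_equal(h_box$values, 1)
  h_nobox <- terminal_hydration_series(topo, trajectory(list(fr)), "L")
  expect_equal(h_nobox$values, 0)

  # invariance under translation by integer multiples of the box
  fr3 <- fr + matrix(rep(c(160, -80, 80), each = 17L), ncol = 3L)
  h3 <- terminal_hydration_series(topo,
                                  trajectory(list(fr3), box = c(80, 80, 80)),
                                  "L")
  expect_equal(h3$values, h_box$values)
})

test_that("a topology without waters yields a zero series with a warning", {
  topo <- make_peptide_topology(6L)
  fr <- matrix(stats::rnorm(nrow(topo$atoms) * 3L), ncol = 3L)
  expect_warning(
    h <- terminal_hydration_series(topo, trajectory(list(fr)), "L"),
    "no waters")
  expect_equal(h$values, 0)
})

test_that("hydration and contact agree with the all-pairs brute-force oracle", {
  # random <=500-atom system: 10-residue peptide, a CB probe, a pocket,
  # 100 waters scattered so many straddle the periodic boundary
  set.seed(31)
  pep <- make_peptide_topology(10L)
  extra <- make_atoms(3L, name = c("CB", "CA", "CA"),
                      element = "C", res_id = c(10L, 1L, 2L),
                      chain_id = c("L", "A", "A"),
                      res_name = c("ALA", "CAR", "CAR"))
  wat <- make_atoms(100L, name = "O", element = "O", res_name = "HOH",
                    res_id = 1:100, chain_id = "W")
  at <- rbind(pep$atoms, extra, wat)
  at$serial <- seq_len(nrow(at))
  topo <- topology(at, list(ligand = 1:41, carrier = 42:43,
                            solvent = 43L + 1:100))
  expect_lte(nrow(at), 500L)
  n <- nrow(at)
  box <- c(30, 30, 30)
  frames <- lapply(1:20, function(f) {
    matrix(stats::runif(n * 3L, -45, 45), ncol = 3L)  # spans 3 box lengths
  })
  traj <- trajectory(frames, box = box)
  waters <- 43L + 1:100
  term <- with(at, which(chain_id == "L" & res_id %in% c(1, 2, 9, 10) &
                           element != "H"))
  h <- terminal_hydration_series(topo, traj, "L")
  cs <- contact_spec("L", 10L, atom_selection(42:43), cutoff = 4.5)
  cc <- residue_contact_series(topo, traj, cs)
  for (f in seq_len(20L)) {
    fr <- frames[[f]]
    expect_equal(h$values[f],
                 oracle_hydration_count(fr, waters, term, 5.0, box))
    expect_equal(cc$distance$values[f],
                 oracle_min_dist(fr, 41L, 42:43, box), tolerance = 1e-10)
    expect_equal(cc$contact$values[f],
                 as.numeric(oracle_min_dist(fr, 41L, 42:43, box) <= 4.5))
  }
})

test_that("generator schedules are recovered exactly by the observables", {
  sys <- make_complex_trajectory(trajectory_spec(
    10L, rotation_schedule = seq(0, 45, 5),
    hydration_schedule = c(5L, 5L, 0L, 0L, 3L, 7L, 2L, 0L, 1L, 6L),
    contact_schedule = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE,
                         FALSE, FALSE, TRUE),
    noise_sigma = 0.3, seed = 31))
  gt <- sys$ground_truth
  h <- terminal_hydration_series(sys$topology, sys$trajectory, "L")
  expect_equal(h$values, as.numeric(gt$hydration_schedule))
  cc <- residue_contact_series(
    sys$topology, sys$trajectory,
    contact_spec("L", gt$probe_res_id, atom_selection(gt$pocket_indices)))
  expect_equal(cc$contact$values, as.numeric(gt$contact_schedule))
})

test_that("contact series handles boundaries and degenerate probes", {
  at <- rbind(
    make_atoms(4L, name = c("N", "CA", "C", "O"),
               element = c("N", "C", "C", "O"), res_id = 1L,
               chain_id = "L", res_name = "ALA"),
    make_atoms(1L, name = "CB", element = "C", res_id = 1L, chain_id = "L",
               res_name = "ALA"),
    make_atoms(2L, name = "CA", element = "C", res_id = 1:2, chain_id = "A",
               res_name = "CAR"))
  at$serial <- seq_len(nrow(at))
  topo <- topology(at, list(ligand = 1:5, carrier = 6:7))
  pocket <- select_atoms(topo, "chain A")
  fr <- matrix(0, 7L, 3L)
  fr[5L, ] <- c(0, 0, 0)           # CB probe
  fr[6:7, ] <- rbind(c(20, 0, 0), c(24, 0, 0))
  r <- residue_contact_series(topo, trajectory(list(fr)),
                              contact_spec("L", 1L, pocket))
  expect_equal(r$contact$values, 0)
  expect_equal(r$distance$values, 20)

  fr[6L, ] <- c(4.5, 0, 0)         # exactly at the cutoff: in contact
  r2 <- residue_contact_series(topo, trajectory(list(fr)),
                               contact_spec("L", 1L, pocket))
  expect_equal(r2$contact$values, 1)

  # a probe with no side-chain heavy atoms is an error
  topo_gly <- topology(at[c(1:4, 6:7), ], list(ligand = 1:4, carrier = 5:6))
  expect_error(residue_contact_series(topo_gly, trajectory(list(fr[c(1:4, 6:7), ])),
                                      contact_spec("L", 1L,
                                                   select_atoms(topo_gly, "chain A"))),
               "side-chain")
})
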