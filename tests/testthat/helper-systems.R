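# Small hand-built systems used across test files.

# bare atoms data.frame with sensible defaults
make_atoms <- function(n, name = "CA", element = "C", res_name = "ALA",
                       res_id = seq_len(n), chain_id = "A", mass = 12.011,
                       charge = 0, lj_sigma = 0, lj_epsilon = 0,
                       born_radius = 0) {
  data.frame(serial = seq_len(n), name = name, element = element,
             res_name = res_name, res_id = res_id, chain_id = chain_id,
             mass = mass, charge = charge, lj_sigma = lj_sigma,
             lj_epsilon = lj_epsilon, born_radius = born_radius,
             stringsAsFactors = FALSE)
}

# ligand helix of n_res residues (chain L, backbone N/CA/C/O) plus
# optional 3-site waters
make_peptide_topology <- function(n_res = 10L, n_waters = 0L) {
  bb <- make_atoms(4L * n_res,
                   name = rep(c("N", "CA", "C", "O"), n_res),
                   element = rep(c("N", "C", "C", "O"), n_res),
                   res_name = "ALA",
                   res_id = rep(seq_len(n_res), each = 4L),
                   chain_id = "L")
  if (n_waters > 0L) {
    wat <- make_atoms(3L * n_waters,
                      name = rep(c("O", "H1", "H2"), n_waters),
                      element = rep(c("O", "H", "H"), n_waters),
                      res_name = "HOH",
                      res_id = rep(seq_len(n_waters), each = 3L),
                      chain_id = "W")
    wat$serial <- nrow(bb) + seq_len(nrow(wat))
    at <- rbind(bb, wat)
    topology(at, list(ligand = seq_len(nrow(bb)),
                      solvent = nrow(bb) + seq_len(nrow(wat))))
  } else {
    topology(bb, list(ligand = seq_len(nrow(bb))))
  }
}

# a small four-state schedule used by several population tests: contiguous
# segments so dwell intervals equal the segments exactly
four_state_segments <- function() {
  data.frame(start_ns = c(0, 15.1, 40.1, 70.1),
             end_ns = c(15, 40, 70, 80),
             rotation = c(1, 21, 39, 39),
             hydration = c(12L, 7L, 2L, 9L))
}
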