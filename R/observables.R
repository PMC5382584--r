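# Solvation and contact observables with minimum-image periodic boundaries.

# minimum-image displacement-corrected squared distances between two
# coordinate blocks; box = NULL means raw (non-periodic) distances
.min_image_dist2 <- function(a, b, box = NULL) {
  # a: n x 3, b: m x 3 -> n x m matrix of squared distances
  n <- nrow(a); m <- nrow(b)
  d2 <- matrix(0, n, m)
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], `-`)
    if (!is.null(box)) dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  d2
}

#' Minimum-image distances between two atom sets in one frame
#'
#' @param frame `n_atoms x 3` coordinate matrix (Angstrom).
#' @param idx_a,idx_b atom index vectors.
#' @param box optional orthorhombic box lengths (length 3); `NULL` disables
#'   periodic wrapping.
#' @return `length(idx_a) x length(idx_b)` distance matrix (Angstrom).
#' @export
pair_distances <- function(frame, idx_a, idx_b, box = NULL) {
  sqrt(.min_image_dist2(frame[idx_a, , drop = FALSE],
                        frame[idx_b, , drop = FALSE], box))
}

#' Hydration-count specification
#'
#' @param terminal_residue_count residues counted at each ligand terminus
#'   (default 2, i.e. the first and last two residues).
#' @param cutoff shell cutoff in Angstrom (default 5.0); the boundary is
#'   inclusive (a water exactly at the cutoff is counted).
#' @return an object of class `HydrationSpec`.
#' @export
hydration_spec <- function(terminal_residue_count = 2L, cutoff = 5.0) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (terminal_residue_count < 1L) stop("terminal_residue_count must be >= 1")
  structure(list(terminal_residue_count = as.integer(terminal_residue_count),
                 cutoff = cutoff), class = "HydrationSpec")
}

.water_oxygen_indices <- function(topology) {
  a <- topology$atoms
  sol <- topology$groups$solvent
  sol[a$res_name[sol] %in% WATER_RESNAMES &
        (toupper(a$name[sol]) %in% WATER_OXYGEN_NAMES)]
}

.terminal_heavy_indices <- function(topology, ligand_chain, n_res) {
  a <- topology$atoms
  on_chain <- which(a$chain_id == ligand_chain &
                      !(a$res_name %in% WATER_RESNAMES))
  if (!length(on_chain)) stop("no atoms on ligand chain ", ligand_chain)
  res <- sort(unique(a$res_id[on_chain]))
  if (length(res) < 2L * n_res) {
    stop("ligand chain has fewer than ", 2L * n_res, " residues")
  }
  term_res <- c(utils::head(res, n_res), utils::tail(res, n_res))
  on_chain[a$res_id[on_chain] %in% term_res &
             toupper(a$element[on_chain]) != "H"]
}

#' Terminal hydration-shell time series
#'
#' Per frame, the number of distinct water oxygens whose minimum-image
#' distance to any heavy atom of the first or last `terminal_residue_count`
#' residues of the ligand chain is at most the cutoff. Each water is counted
#' once even if it is near both termini.
#'
#' @param topology a [topology()] with a non-empty solvent group.
#' @param trajectory a [trajectory()].
#' @param ligand_chain chain id of the bound helix.
#' @param spec a [hydration_spec()].
#' @return a [scalar_series()] of integer counts.
#' @export
terminal_hydration_series <- function(topology, trajectory,
                                      ligand_chain = "L",
                                      spec = hydration_spec()) {
  stopifnot(inherits(spec, "HydrationSpec"))
  waters <- .water_oxygen_indices(topology)
  if (!length(waters)) {
    warning("no waters in topology: hydration series is all zero")
    return(scalar_series(trajectory$times, rep(0, n_frames(trajectory)),
                         "terminal hydration (waters)"))
  }
  term <- .terminal_heavy_indices(topology, ligand_chain,
                                  spec$terminal_residue_count)
  cut2 <- spec$cutoff^2
  vals <- vapply(seq_len(n_frames(trajectory)), function(f) {
    d2 <- .min_image_dist2(
      trajectory$frames[[f]][waters, , drop = FALSE],
      trajectory$frames[[f]][term, , drop = FALSE],
      frame_box(trajectory, f))
    sum(apply(d2, 1L, min) <= cut2)
  }, numeric(1L))
  scalar_series(trajectory$times, vals, "terminal hydration (waters)")
}

#' Contact specification
#'
#' @param probe_chain,probe_res_id chain id and residue number of the probe
#'   residue whose side-chain heavy atoms are tracked.
#' @param pocket_atoms `AtomSelection` of the induced-pocket atoms.
#' @param cutoff contact cutoff in Angstrom (default 4.5), inclusive.
#' @return an object of class `ContactSpec`.
#' @export
contact_spec <- function(probe_chain, probe_res_id, pocket_atoms,
                         cutoff = 4.5) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (!length(pocket_atoms)) stop("pocket_atoms must be non-empty")
  structure(list(probe_chain = probe_chain,
                 probe_res_id = as.integer(probe_res_id),
                 pocket_atoms = pocket_atoms, cutoff = cutoff),
            class = "ContactSpec")
}

#' Residue-to-pocket contact time series
#'
#' Per frame, the minimum-image minimum heavy-atom distance between the
#' probe residue's side chain and the pocket atoms, and a 0/1 contact flag
#' (1 iff distance <= cutoff).
#'
#' @param topology a [topology()].
#' @param trajectory a [trajectory()].
#' @param spec a [contact_spec()].
#' @return list of two [scalar_series()]: `contact` (0/1) and
#'   `distance` (Angstrom).
#' @export
residue_contact_series <- function(topology, trajectory, spec) {
  stopifnot(inherits(spec, "ContactSpec"))
  a <- topology$atoms
  probe <- which(a$chain_id == spec$probe_chain &
                   a$res_id == spec$probe_res_id)
  if (!length(probe)) {
    stop("probe residue ", spec$probe_chain, ":", spec$probe_res_id,
         " not found")
  }
  side <- probe[!(toupper(a$name[probe]) %in% BACKBONE_NAMES) &
                  toupper(a$element[probe]) != "H"]
  if (!length(side)) {
    stop("probe residue has no side-chain heavy atoms")
  }
  pocket <- as.integer(spec$pocket_atoms)
  dmin <- vapply(seq_len(n_frames(trajectory)), function(f) {
    d2 <- .min_image_dist2(trajectory$frames[[f]][side, , drop = FALSE],
                           trajectory$frames[[f]][pocket, , drop = FALSE],
                           frame_box(trajectory, f))
    sqrt(min(d2))
  }, numeric(1L))
  list(contact = scalar_series(trajectory$times,
                               as.numeric(dmin <= spec$cutoff),
                               "pocket contact (0/1)"),
       distance = scalar_series(trajectory$times, dmin,
                                "probe-pocket min distance (A)"))
}
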