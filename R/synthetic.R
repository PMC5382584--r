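# Synthetic carrier-ligand-water systems and assay traces with known ground
# truth. The geometry emulates the statistical structure of a chaperone
# dimer bound to a single transmembrane helix: a fixed 20-residue ideal
# alpha-helix backbone (chain L) along z, two rigid carrier arcs (chains A,
# B) forming a groove around it, oxygen-only waters, and a probe side-chain
# pseudo-atom driven by a contact schedule. The carrier is rigid-rotated
# about the ligand axis frame by frame; the ligand stays fixed, so the
# construction frame coincides with the analysis frame (everything is
# aligned to the ligand backbone).
#
# Shell waters and the probe atom are placed exactly each frame (after the
# per-atom jitter of the protein), so hydration counts and contact flags are
# recovered exactly at any noise level.

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic complex trajectory
#'
#' @param n_frames number of frames (>= 1).
#' @param rotation_schedule carrier rotation about the ligand axis per frame,
#'   degrees (length `n_frames`).
#' @param hydration_schedule integer waters in the terminal shells per frame.
#' @param contact_schedule optional logical per frame: probe side chain in
#'   the induced pocket (default all FALSE).
#' @param dt frame spacing, ns (default 0.1).
#' @param noise_sigma per-atom Gaussian jitter of the protein atoms,
#'   Angstrom (default 0).
#' @param box orthorhombic box lengths, Angstrom (default 80 cubic);
#'   `NULL` for no box.
#' @param n_bulk_waters waters kept in the bulk at all times (default 50).
#' @param seed RNG seed (default 1).
#' @return an object of class `TrajectorySpec`.
#' @export
trajectory_spec <- function(n_frames, rotation_schedule, hydration_schedule,
                            contact_schedule = NULL, dt = 0.1,
                            noise_sigma = 0, box = c(80, 80, 80),
                            n_bulk_waters = 50L, seed = 1L) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (is.null(contact_schedule)) contact_schedule <- rep(FALSE, n_frames)
  if (length(rotation_schedule) != n_frames ||
      length(hydration_schedule) != n_frames ||
      length(contact_schedule) != n_frames) {
    stop("schedules must have length n_frames")
  }
  if (any(hydration_schedule < 0) ||
      any(hydration_schedule != round(hydration_schedule))) {
    stop("hydration_schedule must be non-negative integers")
  }
  structure(list(n_frames = n_frames, dt = dt,
                 rotation_schedule = as.numeric(rotation_schedule),
                 hydration_schedule = as.integer(hydration_schedule),
                 contact_schedule = as.logical(contact_schedule),
                 noise_sigma = noise_sigma, box = box,
                 n_bulk_waters = as.integer(n_bulk_waters),
                 seed = as.integer(seed)),
            class = "TrajectorySpec")
}

# ideal alpha-helix backbone: 100 deg twist, 1.5 A rise per residue
.helix_backbone <- function(n_res) {
  res <- seq_len(n_res)
  phi <- (res - 1) * 100 * pi / 180
  z <- (res - 1) * 1.5
  bb <- list(
    N  = cbind(1.9 * cos(phi - 0.49), 1.9 * sin(phi - 0.49), z - 0.9),
    CA = cbind(2.3 * cos(phi), 2.3 * sin(phi), z),
    C  = cbind(2.0 * cos(phi + 0.45), 2.0 * sin(phi + 0.45), z + 1.0),
    O  = cbind(3.1 * cos(phi + 0.55), 3.1 * sin(phi + 0.55), z + 1.3)
  )
  coords <- do.call(rbind, lapply(res, function(i) {
    rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$O[i, ])
  }))
  list(coords = coords,
       name = rep(c("N", "CA", "C", "O"), n_res),
       element = rep(c("N", "C", "C", "O"), n_res),
       res_id = rep(res, each = 4L))
}

# carrier arcs: chains A and B on a cylinder around the helix; deliberately
# asymmetric (A spans 120 deg, B only 40) so the combined center of mass
# sits several Angstrom off the axis, giving the rotation metric a long
# lever arm
.CARRIER_RING_Z <- seq(0, 30, by = 1.5)
.CARRIER_ANGLES_A <- seq(30, 150, by = 10)
.CARRIER_ANGLES_B <- seq(240, 260, by = 10)

.carrier_arcs <- function() {
  build <- function(angles_deg, chain) {
    ang <- angles_deg * pi / 180
    coords <- do.call(rbind, lapply(.CARRIER_RING_Z, function(z) {
      cbind(9.7 * cos(ang), 9.7 * sin(ang), z)
    }))
    n <- nrow(coords)
    list(coords = coords, chain = rep(chain, n))
  }
  a <- build(.CARRIER_ANGLES_A, "A")
  b <- build(.CARRIER_ANGLES_B, "B")
  list(coords = rbind(a$coords, b$coords),
       chain = c(a$chain, b$chain))
}

#' Generate a synthetic carrier-ligand-water trajectory
#'
#' Builds the system described in the package vignette and animates it
#' according to the spec's schedules. Ground truth (the schedules, the
#' pocket residue ids, the seed) is returned alongside the data so analysis
#' results can be checked exactly.
#'
#' @param spec a [trajectory_spec()].
#' @return list with `topology`, `trajectory`, `params` (a `ParamTable`
#'   covering every atom) and `ground_truth`.
#' @export
make_complex_trajectory <- function(spec) {
  stopifnot(inherits(spec, "TrajectorySpec"))
  n_res_lig <- 20L
  max_shell <- max(spec$hydration_schedule)
  if (max_shell > 400L) {
    stop("hydration count exceeds placeable shell sites (400)")
  }

  lig <- .helix_backbone(n_res_lig)
  car <- .carrier_arcs()
  n_lig <- nrow(lig$coords)
  n_car <- nrow(car$coords)

  # probe side-chain pseudo-atom on the last ligand residue
  probe_res <- n_res_lig
  n_wat <- max_shell + spec$n_bulk_waters

  atoms <- data.frame(
    serial = seq_len(n_lig + 1L + n_car + n_wat),
    name = c(lig$name, "NE2",
             rep("CA", n_car),
             rep("O", n_wat)),
    element = c(lig$element, "N", rep("C", n_car), rep("O", n_wat)),
    res_name = c(ifelse(lig$res_id == probe_res, "HIS", "ALA"), "HIS",
                 rep("CAR", n_car),
                 rep("HOH", n_wat)),
    res_id = c(lig$res_id, probe_res,
               seq_len(n_car),
               seq_len(n_wat)),
    chain_id = c(rep("L", n_lig + 1L), car$chain, rep("W", n_wat)),
    stringsAsFactors = FALSE
  )
  atoms$mass <- .element_mass(atoms$element)
  atoms$charge <- 0; atoms$lj_sigma <- 0; atoms$lj_epsilon <- 0
  atoms$born_radius <- 0

  idx_lig <- 1:(n_lig + 1L)
  idx_probe <- n_lig + 1L
  idx_car <- (n_lig + 1L) + seq_len(n_car)
  idx_wat <- (n_lig + 1L + n_car) + seq_len(n_wat)

  # pocket: three chain-A carrier atoms on the topmost (C-terminal) ring
  n_ring_a <- length(.CARRIER_ANGLES_A)
  top_ring <- which(rep(.CARRIER_RING_Z, each = n_ring_a) == 30)
  pocket_local <- top_ring[c(6L, 7L, 8L)]   # angles 80, 90, 100 deg
  idx_pocket <- idx_car[pocket_local]

  topo <- topology(atoms, list(carrier = idx_car, ligand = idx_lig,
                               solvent = idx_wat))

  # anchors for shell waters: heavy backbone atoms of the terminal residues
  term_res <- c(1:2, (n_res_lig - 1L):n_res_lig)
  anchors <- which(lig$res_id %in% term_res & lig$name != "")  # all backbone
  # parked positions: bulk lattice at radius 28-34, z 8-22 (far from the
  # termini, the probe, and the pocket in minimum-image terms)
  bulk_ang <- (seq_len(n_wat) * 2.399963)  # golden-angle spiral
  bulk_r <- 28 + 6 * ((seq_len(n_wat) * 7L) %% 11L) / 11
  bulk_z <- 8 + 14 * ((seq_len(n_wat) * 5L) %% 13L) / 13
  bulk_xyz <- cbind(bulk_r * cos(bulk_ang), bulk_r * sin(bulk_ang), bulk_z)

  # rotation axis and center exactly as the rotation analysis defines them:
  # the principal (gyration) axis of the ligand backbone, oriented N->C,
  # through its mass-weighted center of mass
  bb_mass <- .element_mass(lig$element)
  lig_com <- colSums(lig$coords * bb_mass) / sum(bb_mass)
  lig_com_xy <- lig_com[1:2]
  cc <- sweep(lig$coords, 2L, colMeans(lig$coords))
  helix_axis <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors[, 1L]
  if (helix_axis[3L] < 0) helix_axis <- -helix_axis   # helix is built along +z

  base <- matrix(0, nrow(atoms), 3L)
  base[setdiff(idx_lig, idx_probe), ] <- lig$coords
  base[idx_car, ] <- car$coords
  base[idx_wat, ] <- bulk_xyz

  frames <- .with_seed(spec$seed, {
    lapply(seq_len(spec$n_frames), function(f) {
      fr <- base
      # rigid carrier rotation about the ligand principal axis through the
      # ligand backbone center of mass (Rodrigues formula)
      th <- spec$rotation_schedule[f] * pi / 180
      a <- helix_axis
      kmat <- matrix(c(0, -a[3L], a[2L], a[3L], 0, -a[1L],
                       -a[2L], a[1L], 0), 3L, 3L, byrow = TRUE)
      rot <- diag(3) + sin(th) * kmat + (1 - cos(th)) * (kmat %*% kmat)
      rel <- sweep(fr[idx_car, , drop = FALSE], 2L, lig_com)
      fr[idx_car, ] <- sweep(rel %*% t(rot), 2L, lig_com, `+`)
      # per-atom jitter of the carrier; the ligand is held fixed so the
      # construction frame stays the exact analysis reference frame
      if (spec$noise_sigma > 0) {
        fr[idx_car, ] <- fr[idx_car, ] +
          matrix(stats::rnorm(length(idx_car) * 3L, 0, spec$noise_sigma),
                 ncol = 3L)
      }
      # probe: in the pocket (<= 4 A of the pocket set) or far away (> 8 A)
      pocket_xyz <- fr[idx_pocket, , drop = FALSE]
      if (spec$contact_schedule[f]) {
        ctr <- colMeans(pocket_xyz)
        inward <- c(lig_com_xy - ctr[1:2], 0)
        inward <- inward / sqrt(sum(inward^2))
        fr[idx_probe, ] <- ctr + 3.0 * inward
      } else {
        # opposite side of the helix from the (rotated) pocket
        ctr <- colMeans(pocket_xyz)
        outward <- c(lig_com_xy - ctr[1:2], 0)
        outward <- outward / sqrt(sum(outward^2))
        fr[idx_probe, ] <- c(lig_com_xy, 28) + 4.0 * outward
      }
      # shell waters: exact placement 3.0-4.9 A from a terminal heavy atom
      k <- spec$hydration_schedule[f]
      if (k > 0L) {
        anch <- anchors[1L + (seq_len(k) - 1L) %% length(anchors)]
        d <- stats::runif(k, 3.0, 4.9)
        u <- matrix(stats::rnorm(3L * k), ncol = 3L)
        # push outward from the axis so placements never cross the helix
        u[, 1:2] <- abs(u[, 1:2]) * sign(fr[anch, 1:2, drop = FALSE] -
                                           matrix(lig_com_xy, k, 2L,
                                                  byrow = TRUE))
        u <- u / sqrt(rowSums(u^2))
        fr[idx_wat[seq_len(k)], ] <- fr[anch, , drop = FALSE] + d * u
      }
      fr
    })
  })

  params <- .synthetic_params(atoms)
  topo <- apply_param_table(topo, params)$topology

  traj <- trajectory(frames, dt = spec$dt,
                     box = if (is.null(spec$box)) NULL else spec$box)
  list(topology = topo, trajectory = traj, params = params,
       ground_truth = list(
         rotation_schedule = spec$rotation_schedule,
         hydration_schedule = spec$hydration_schedule,
         contact_schedule = spec$contact_schedule,
         dt = spec$dt, seed = spec$seed,
         ligand_chain = "L", probe_res_id = probe_res,
         pocket_indices = idx_pocket,
         pocket_res_ids = atoms$res_id[idx_pocket]))
}

# parameter table covering every (res_name, atom name) pair in the system
.synthetic_params <- function(atoms) {
  key <- unique(atoms[, c("res_name", "name", "element")])
  ref <- list(
    "ALA N" = c(-0.42, 3.25, 0.17, 1.55), "ALA CA" = c(0.03, 3.40, 0.11, 1.70),
    "ALA C" = c(0.60, 3.40, 0.09, 1.70), "ALA O" = c(-0.57, 2.96, 0.21, 1.50),
    "HIS N" = c(-0.42, 3.25, 0.17, 1.55), "HIS CA" = c(0.03, 3.40, 0.11, 1.70),
    "HIS C" = c(0.60, 3.40, 0.09, 1.70), "HIS O" = c(-0.57, 2.96, 0.21, 1.50),
    "HIS NE2" = c(-0.28, 3.25, 0.17, 1.55),
    "CAR CA" = c(0.09, 3.40, 0.11, 1.70),
    "HOH O" = c(-0.834, 3.15, 0.152, 1.50)
  )
  rows <- lapply(seq_len(nrow(key)), function(i) {
    p <- ref[[paste(key$res_name[i], key$name[i])]]
    if (is.null(p)) p <- c(0, 3.4, 0.1, 1.7)
    data.frame(res_name = key$res_name[i], atom_name = key$name[i],
               charge = p[1L], lj_sigma = p[2L], lj_epsilon = p[3L],
               born_radius = p[4L],
               mass = .element_mass(key$element[i]))
  })
  d <- do.call(rbind, rows)
  class(d) <- c("ParamTable", "data.frame")
  d
}

#' Piecewise state schedules for a synthetic trajectory
#'
#' Turns a table of dwell segments (one conformational state each) into
#' per-frame rotation/hydration/contact schedules. Frames inside a segment
#' take that state's values (with optional within-state rotation jitter);
#' frames in gaps between segments interpolate linearly between the
#' neighbouring states (a transition), frames before the first / after the
#' last segment take the nearest state.
#'
#' @param segments data.frame with columns `start_ns`, `end_ns`, `rotation`
#'   (deg), `hydration` (integer count) and optionally `contact` (logical);
#'   segments must be ordered and non-overlapping.
#' @param dt frame spacing, ns (default 0.1).
#' @param rotation_jitter within-state rotation s.d., deg (default 0.4).
#' @param seed RNG seed for the jitter (default 1).
#' @return list with `rotation_schedule`, `hydration_schedule`,
#'   `contact_schedule`, `n_frames`, `times`, and `segment_frames` (list of
#'   frame-index ranges, one per segment).
#' @export
make_cluster_schedule <- function(segments, dt = 0.1, rotation_jitter = 0.4,
                                  seed = 1L) {
  if (!nrow(segments)) stop("empty segment list")
  req <- c("start_ns", "end_ns", "rotation", "hydration")
  if (length(setdiff(req, names(segments)))) {
    stop("segments needs columns ", paste(req, collapse = ", "))
  }
  if (any(segments$end_ns <= segments$start_ns)) {
    stop("each segment must have end_ns > start_ns")
  }
  if (nrow(segments) > 1L &&
      any(segments$start_ns[-1L] < segments$end_ns[-nrow(segments)])) {
    stop("segments must be ordered and non-overlapping")
  }
  if (is.null(segments$contact)) segments$contact <- FALSE
  n_frames <- floor(segments$end_ns[nrow(segments)] / dt + 1e-9) + 1L
  # round away float drift so segment boundaries compare exactly
  times <- round((seq_len(n_frames) - 1L) * dt, 9L)
  seg_of <- rep(NA_integer_, n_frames)
  for (s in seq_len(nrow(segments))) {
    seg_of[times >= segments$start_ns[s] & times <= segments$end_ns[s]] <- s
  }
  rot <- numeric(n_frames); hyd <- numeric(n_frames)
  con <- logical(n_frames)
  in_seg <- !is.na(seg_of)
  rot[in_seg] <- segments$rotation[seg_of[in_seg]]
  hyd[in_seg] <- segments$hydration[seg_of[in_seg]]
  con[in_seg] <- segments$contact[seg_of[in_seg]]
  if (any(!in_seg)) {
    # gaps: linear interpolation between neighbouring segment states
    anchor_t <- c(rbind(segments$start_ns, segments$end_ns))
    anchor_rot <- rep(segments$rotation, each = 2L)
    anchor_hyd <- rep(segments$hydration, each = 2L)
    out <- which(!in_seg)
    rot[out] <- stats::approx(anchor_t, anchor_rot, times[out],
                              rule = 2L)$y
    hyd[out] <- round(stats::approx(anchor_t, anchor_hyd, times[out],
                                    rule = 2L)$y)
    prev_seg <- findInterval(times[out], segments$start_ns)
    con[out] <- segments$contact[pmax(1L, prev_seg)]
  }
  if (rotation_jitter > 0) {
    rot <- .with_seed(seed, rot + stats::rnorm(n_frames, 0, rotation_jitter))
  }
  list(rotation_schedule = rot, hydration_schedule = as.integer(hyd),
       contact_schedule = con, n_frames = n_frames, times = times,
       segment_frames = lapply(seq_len(nrow(segments)), function(s) {
         range(which(seg_of == s))
       }))
}

#' Specification of a synthetic NADH-coupled assay trace
#'
#' @param specific_activity true specific activity, nmol ATP/min/mg.
#' @param enzyme_mass mg enzyme in the well (default 0.01).
#' @param volume reaction volume, litres (default 200 uL).
#' @param extinction_coeff NADH molar extinction (default 6220).
#' @param path_length cm (default 0.55).
#' @param duration_min trace length, minutes (default 5).
#' @param sample_interval_s seconds between readings (default 5).
#' @param noise_sigma Gaussian absorbance noise, AU (default 0.002).
#' @param nadh_mM starting NADH concentration, mM (default 0.3).
#' @param seed RNG seed.
#' @return an object of class `AssaySpec`.
#' @export
assay_spec <- function(specific_activity, enzyme_mass = 0.01,
                       volume = 200e-6, extinction_coeff = NADH_EXTINCTION,
                       path_length = 0.55, duration_min = 5,
                       sample_interval_s = 5, noise_sigma = 0.002,
                       nadh_mM = 0.3, seed = 1L) {
  vals <- c(specific_activity, enzyme_mass, volume, extinction_coeff,
            path_length, duration_min, sample_interval_s, nadh_mM)
  if (any(vals < 0) || any(vals[-1L] == 0)) {
    stop("assay parameters must be positive (activity may be zero)")
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(as.list(environment()), class = "AssaySpec")
}

#' Generate a synthetic A340 assay trace
#'
#' `A340(t) = A0 - eps * l * rate * t + N(0, noise_sigma)` with
#' `rate [M/s] = specific_activity * enzyme_mass / volume` converted from
#' nmol/min, and `A0 = eps * l * [NADH]0`. Errors if the implied NADH
#' consumption would exhaust the starting NADH before the end of the trace.
#'
#' @param spec an [assay_spec()].
#' @param enzyme,condition labels forwarded to the trace metadata.
#' @return an [assay_trace()].
#' @export
make_assay_trace <- function(spec, enzyme = "synthetic",
                             condition = "basal") {
  stopifnot(inherits(spec, "AssaySpec"))
  rate_M_s <- spec$specific_activity * spec$enzyme_mass / spec$volume *
    1e-9 / 60
  dur_s <- spec$duration_min * 60
  nadh0 <- spec$nadh_mM * 1e-3
  if (rate_M_s * dur_s >= nadh0) {
    stop(sprintf(
      "NADH would be depleted at %.0f s, before the %.0f s trace ends",
      nadh0 / rate_M_s, dur_s))
  }
  a0 <- spec$extinction_coeff * spec$path_length * nadh0
  times <- seq(0, dur_s, by = spec$sample_interval_s)
  slope <- -spec$extinction_coeff * spec$path_length * rate_M_s
  a340 <- .with_seed(spec$seed, {
    a0 + slope * times + stats::rnorm(length(times), 0, spec$noise_sigma)
  })
  assay_trace(times, a340, enzyme = enzyme, condition = condition,
              enzyme_mass = spec$enzyme_mass, volume = spec$volume,
              path_length = spec$path_length,
              extinction_coeff = spec$extinction_coeff)
}

#' Write a synthetic system to disk
#'
#' Emits the multi-model PDB, the parameter TSV and a JSON ground-truth
#' sidecar (schedules, seed, pocket definition).
#'
#' @param system output of [make_complex_trajectory()].
#' @param dir output directory (created if needed).
#' @param stem file stem (default `"synthetic"`).
#' @return named character vector of the three paths, invisibly.
#' @export
write_synthetic_system <- function(system, dir, stem = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    pdb = file.path(dir, paste0(stem, ".pdb")),
    params = file.path(dir, paste0(stem, "_params.tsv")),
    truth = file.path(dir, paste0(stem, "_truth.json"))
  )
  write_pdb_models(system$topology, system$trajectory, paths["pdb"])
  write_param_table(system$params, paths["params"])
  jsonlite::write_json(system$ground_truth, paths["truth"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
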