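# Pairwise interaction enthalpy surrogate: screened Coulomb with a
# generalized-Born solvent term plus Lennard-Jones, summed over inter-group
# atom pairs and averaged per population cluster. This is a fixed-radius
# pairwise GB model: no surface-area (nonpolar) term and no per-snapshot
# effective-radius recomputation.

COULOMB_KCAL <- 332.0636  # kcal * Angstrom / (mol * e^2)

#' Interaction-energy model parameters
#'
#' @param eps_protein solute (protein interior) dielectric, >= 1 (default 1).
#' @param eps_water solvent dielectric, >= 1 (default 78.5).
#' @param use_gb include the generalized-Born solvent screening term
#'   (default TRUE); with `FALSE` the electrostatics are plain Coulomb in
#'   `eps_protein`.
#' @param cutoff optional pair-distance cutoff in Angstrom (`NULL` = none);
#'   when set, pair energies are truncated and shifted to zero at the cutoff.
#' @return an object of class `EnergyModel`.
#' @export
energy_model <- function(eps_protein = 1.0, eps_water = 78.5, use_gb = TRUE,
                         cutoff = NULL) {
  if (eps_protein < 1 || eps_water < 1) stop("dielectrics must be >= 1")
  if (!is.null(cutoff) && cutoff <= 0) stop("cutoff must be positive")
  structure(list(eps_protein = eps_protein, eps_water = eps_water,
                 use_gb = isTRUE(use_gb), cutoff = cutoff,
                 coulomb_constant = COULOMB_KCAL), class = "EnergyModel")
}

# raw pair energy matrices given distances and parameter vectors
.pair_energy_terms <- function(r, qa, qb, sa, sb, ea, eb, ra, rb, model) {
  qq <- outer(qa, qb)
  ke <- model$coulomb_constant
  if (model$use_gb) {
    rr <- outer(ra, rb)                       # Ri * Rj
    fgb <- sqrt(r^2 + rr * exp(-r^2 / (4 * rr)))
    fgb[rr == 0] <- r[rr == 0]                # zero Born radius: f_GB = r
    elec <- ke * qq * (1 / (model$eps_protein * r) -
                         (1 / model$eps_protein - 1 / model$eps_water) / fgb)
  } else {
    elec <- ke * qq / (model$eps_protein * r)
  }
  sij <- outer(sa, sb, `+`) / 2               # Lorentz
  eij <- sqrt(outer(ea, eb))                  # Berthelot
  sr6 <- (sij / r)^6
  vdw <- 4 * eij * (sr6^2 - sr6)
  vdw[eij == 0] <- 0
  list(elec = elec, vdw = vdw)
}

#' Inter-group interaction energy for one frame
#'
#' Sums, over all pairs with one atom in `group_a` and one in `group_b`
#' (minimum-image distances), a screened-Coulomb/generalized-Born
#' electrostatic term and a Lennard-Jones term with Lorentz-Berthelot
#' combining. The GB pair function is
#' `f_GB = sqrt(r^2 + Ri*Rj*exp(-r^2/(4*Ri*Rj)))`, reducing to `r` when
#' either Born radius is zero. Favorable interactions are negative.
#'
#' @param topology a [topology()] with charges and LJ/Born parameters set.
#' @param frame `n_atoms x 3` coordinates (Angstrom).
#' @param group_a,group_b disjoint `AtomSelection`s.
#' @param model an [energy_model()].
#' @param box optional orthorhombic box lengths for minimum-image distances.
#' @return list with `total`, `elec` and `vdw` (kcal/mol).
#' @export
pair_interaction_energy <- function(topology, frame, group_a, group_b,
                                    model = energy_model(), box = NULL) {
  stopifnot(inherits(model, "EnergyModel"))
  ia <- as.integer(group_a); ib <- as.integer(group_b)
  if (!length(ia) || !length(ib)) stop("groups must be non-empty")
  if (length(intersect(ia, ib))) stop("groups must be disjoint")
  at <- topology$atoms
  if (anyNA(at$charge[c(ia, ib)])) stop("missing charge parameters")
  r <- sqrt(.min_image_dist2(frame[ia, , drop = FALSE],
                             frame[ib, , drop = FALSE], box))
  if (any(r < 0.1)) {
    p <- which(r < 0.1, arr.ind = TRUE)[1L, ]
    stop(sprintf("atomic clash: atoms %d and %d at %.3f A",
                 ia[p[1L]], ib[p[2L]], r[p[1L], p[2L]]))
  }
  terms <- .pair_energy_terms(r, at$charge[ia], at$charge[ib],
                              at$lj_sigma[ia], at$lj_sigma[ib],
                              at$lj_epsilon[ia], at$lj_epsilon[ib],
                              at$born_radius[ia], at$born_radius[ib], model)
  elec <- terms$elec
  vdw <- terms$vdw
  if (!is.null(model$cutoff)) {
    # truncate and shift each pair term to zero at the cutoff
    shift <- .pair_energy_terms(matrix(model$cutoff, nrow(r), ncol(r)),
                                at$charge[ia], at$charge[ib],
                                at$lj_sigma[ia], at$lj_sigma[ib],
                                at$lj_epsilon[ia], at$lj_epsilon[ib],
                                at$born_radius[ia], at$born_radius[ib],
                                model)
    inside <- r <= model$cutoff
    elec <- (elec - shift$elec) * inside
    vdw <- (vdw - shift$vdw) * inside
  }
  list(total = sum(elec) + sum(vdw), elec = sum(elec), vdw = sum(vdw))
}

#' Per-cluster mean interaction enthalpy
#'
#' Evaluates [pair_interaction_energy()] on every member frame of each
#' completed cluster and reports mean, standard deviation and components.
#' Empty clusters are skipped with a warning.
#'
#' @param topology a [topology()].
#' @param trajectory a [trajectory()].
#' @param clusters completed clusters from [assign_frames()].
#' @param group_a,group_b disjoint `AtomSelection`s (carrier and ligand).
#' @param model an [energy_model()].
#' @return An `EnergyReport`: data.frame with columns `cluster`, `n_frames`,
#'   `mean_kcal`, `sd_kcal`, `abs_mean_kcal`, `elec_kcal`, `vdw_kcal`.
#' @export
cluster_mean_enthalpy <- function(topology, trajectory, clusters,
                                  group_a, group_b, model = energy_model()) {
  rows <- lapply(clusters, function(cl) {
    if (!length(cl$member_frames)) {
      warning("cluster ", cl$id, " has no member frames; skipped")
      return(NULL)
    }
    e <- vapply(cl$member_frames, function(f) {
      en <- pair_interaction_energy(topology, trajectory$frames[[f]],
                                    group_a, group_b, model,
                                    box = frame_box(trajectory, f))
      c(en$total, en$elec, en$vdw)
    }, numeric(3L))
    tot <- e[1L, ]
    data.frame(cluster = cl$id, n_frames = length(cl$member_frames),
               mean_kcal = mean(tot),
               sd_kcal = if (length(tot) > 1L) stats::sd(tot) else 0,
               abs_mean_kcal = abs(mean(tot)),
               elec_kcal = mean(e[2L, ]), vdw_kcal = mean(e[3L, ]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cluster = integer(), n_frames = integer(),
                      mean_kcal = numeric(), sd_kcal = numeric(),
                      abs_mean_kcal = numeric(), elec_kcal = numeric(),
                      vdw_kcal = numeric())
  }
  class(out) <- c("EnergyReport", "data.frame")
  out
}

#' Write an energy report as JSON
#'
#' @param report an `EnergyReport` from [cluster_mean_enthalpy()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_energy_report <- function(report, path) {
  jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
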