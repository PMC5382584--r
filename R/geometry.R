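# Geometric observables: superposition, RMSD, principal axis, the
# helical-rotation metric, and plateau/convergence detection.

#' Mass-weighted center of mass
#'
#' @param topology a [topology()]; masses must be set.
#' @param selection an `AtomSelection` (non-empty).
#' @param frame `n_atoms x 3` coordinate matrix (Angstrom).
#' @return length-3 numeric vector (Angstrom).
#' @export
center_of_mass <- function(topology, selection, frame) {
  if (!length(selection)) stop("empty selection")
  m <- topology$atoms$mass[selection]
  tm <- sum(m)
  if (tm <= 0) stop("zero total mass in selection")
  colSums(frame[selection, , drop = FALSE] * m) / tm
}

#' Principal (helical) axis of a selection
#'
#' Unit eigenvector of the largest-eigenvalue direction of the coordinate
#' covariance (gyration) tensor. The sign is oriented so the axis points from
#' the first selected residue toward the last (N-terminus to C-terminus for a
#' backbone selection in residue order).
#'
#' @inheritParams center_of_mass
#' @return unit length-3 vector.
#' @export
principal_axis <- function(topology, selection, frame) {
  if (length(selection) < 3L) stop("need at least 3 atoms for an axis")
  x <- frame[selection, , drop = FALSE]
  xc <- sweep(x, 2L, colMeans(x))
  cv <- crossprod(xc) / nrow(xc)
  eg <- eigen(cv, symmetric = TRUE)
  lam <- eg$values
  if (lam[1L] <= 0 || (lam[1L] - lam[2L]) / lam[1L] < 1e-6) {
    stop("degenerate principal axis: top eigenvalue not unique")
  }
  a <- eg$vectors[, 1L]
  # orient along the selection order: first half -> second half
  n <- nrow(x)
  half <- max(1L, floor(n / 2))
  dirv <- colMeans(x[(n - half + 1L):n, , drop = FALSE]) -
    colMeans(x[1:half, , drop = FALSE])
  if (sum(a * dirv) < 0) a <- -a
  a / sqrt(sum(a^2))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares optimal proper rotation plus translation mapping `mobile`
#' onto `reference`, optionally mass-weighted, with reflection correction.
#'
#' @param mobile,reference `n x 3` coordinate matrices, equal `n >= 3`.
#' @param weights optional non-negative weights (e.g. masses), length `n`.
#' @return list with `rotation` (3x3, det +1), `translation` (length 3; the
#'   fitted position is `mobile %*% t(rotation) + translation`) and `rmsd`
#'   (post-fit weighted RMSD, Angstrom). Class `RigidTransform`.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  if (!is.matrix(mobile) || !is.matrix(reference) ||
      ncol(mobile) != 3L || ncol(reference) != 3L ||
      nrow(mobile) != nrow(reference)) {
    stop("mobile and reference must be n x 3 matrices of equal n")
  }
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 atoms to superpose")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) <= 0) {
    stop("invalid weights")
  }
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  pm <- sweep(mobile, 2L, cm)
  pr <- sweep(reference, 2L, cr)
  h <- t(pm * w) %*% pr
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cr - as.vector(rot %*% cm)
  fitted <- pm %*% t(rot)
  rmsd <- sqrt(sum(w * rowSums((fitted - pr)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
            class = "RigidTransform")
}

#' Apply a rigid transform to coordinates
#'
#' @param transform a `RigidTransform` from [kabsch_superpose()].
#' @param coords `n x 3` matrix.
#' @return transformed `n x 3` matrix.
#' @export
apply_transform <- function(transform, coords) {
  sweep(coords %*% t(transform$rotation), 2L, transform$translation, `+`)
}

.weighted_rmsd <- function(a, b, w) {
  w <- w / sum(w)
  sqrt(sum(w * rowSums((a - b)^2)))
}

#' Backbone RMSD time series
#'
#' Per frame: superpose on `fit_selection` against the reference coordinates
#' (mass-weighted), then report the mass-weighted RMSD over
#' `measure_selection`.
#'
#' @param topology a [topology()].
#' @param trajectory a [trajectory()].
#' @param fit_selection atoms used for the superposition.
#' @param measure_selection atoms the RMSD is reported over (defaults to
#'   `fit_selection`).
#' @param reference_frame `n_atoms x 3` reference coordinates (defaults to
#'   frame 1).
#' @return a [scalar_series()] in Angstrom.
#' @export
backbone_rmsd_series <- function(topology, trajectory, fit_selection,
                                 measure_selection = fit_selection,
                                 reference_frame = trajectory$frames[[1L]]) {
  if (!length(fit_selection) || !length(measure_selection)) {
    stop("selections must be non-empty")
  }
  mfit <- topology$atoms$mass[fit_selection]
  mmeas <- topology$atoms$mass[measure_selection]
  ref_fit <- reference_frame[fit_selection, , drop = FALSE]
  ref_meas <- reference_frame[measure_selection, , drop = FALSE]
  vals <- vapply(trajectory$frames, function(fr) {
    tr <- kabsch_superpose(fr[fit_selection, , drop = FALSE], ref_fit, mfit)
    .weighted_rmsd(apply_transform(tr, fr[measure_selection, , drop = FALSE]),
                   ref_meas, mmeas)
  }, numeric(1L))
  scalar_series(trajectory$times, vals, "backbone RMSD (A)")
}

#' Helical rotation time series
#'
#' The rotation of the carrier about the ligand helix axis: each frame is
#' superposed onto frame 1 on the ligand backbone; the vector from the ligand
#' backbone center of mass to the carrier center of mass is projected off the
#' ligand principal axis (computed at frame 1); the reported angle is between
#' that projection at time zero and at time t. Unsigned range is
#' `[0, 180]` degrees with `theta(0) = 0` exactly; with `signed = TRUE` the
#' angle about `+axis` in `(-180, 180]` is returned.
#'
#' @param topology a [topology()].
#' @param trajectory a [trajectory()].
#' @param ligand_backbone `AtomSelection` of ligand backbone atoms (>= 3).
#' @param carrier `AtomSelection` of carrier atoms (non-empty).
#' @param signed report a signed angle about the +axis (default FALSE).
#' @return a [scalar_series()] in degrees.
#' @export
helical_rotation_series <- function(topology, trajectory, ligand_backbone,
                                    carrier, signed = FALSE) {
  if (length(ligand_backbone) < 3L) stop("ligand backbone needs >= 3 atoms")
  if (!length(carrier)) stop("carrier selection is empty")
  ref <- trajectory$frames[[1L]]
  ref_lig <- ref[ligand_backbone, , drop = FALSE]
  mlig <- topology$atoms$mass[ligand_backbone]
  axis <- principal_axis(topology, ligand_backbone, ref)

  project_off <- function(v) v - sum(v * axis) * axis

  p0 <- NULL
  vals <- vapply(seq_len(n_frames(trajectory)), function(f) {
    fr <- trajectory$frames[[f]]
    tr <- kabsch_superpose(fr[ligand_backbone, , drop = FALSE], ref_lig, mlig)
    fr_al <- apply_transform(tr, fr)
    v <- center_of_mass(topology, carrier, fr_al) -
      center_of_mass(topology, ligand_backbone, fr_al)
    p <- project_off(v)
    if (sqrt(sum(p^2)) < 0.5) {
      stop(sprintf("undefined rotation angle at frame %d: %s", f,
                   "carrier center of mass lies on the helix axis"))
    }
    if (f == 1L) {
      p0 <<- p
      return(0)
    }
    cr <- c(p0[2L] * p[3L] - p0[3L] * p[2L],
            p0[3L] * p[1L] - p0[1L] * p[3L],
            p0[1L] * p[2L] - p0[2L] * p[1L])
    ang <- atan2(sqrt(sum(cr^2)), sum(p0 * p)) * 180 / pi
    if (signed && sum(cr * axis) < 0) ang <- -ang
    ang
  }, numeric(1L))
  scalar_series(trajectory$times, vals, "helical rotation (deg)")
}

#' Detect convergence to a plateau
#'
#' The plateau value is the mean of the final 20% of the series. The series
#' is scanned with forward-looking running-window means; the convergence time
#' is the earliest time from which every subsequent window mean stays within
#' `tolerance` of the plateau.
#'
#' @param series a [scalar_series()].
#' @param window running-window length in ns (default 5).
#' @param tolerance allowed deviation from the plateau, in the units of the
#'   series (default 0.3).
#' @return list with `time` (ns) and `plateau` (series units), or `NULL` if
#'   the series never settles.
#' @export
convergence_time <- function(series, window = 5, tolerance = 0.3) {
  stopifnot(inherits(series, "ScalarSeries"))
  n <- length(series)
  if (n == 0L) stop("empty series")
  t <- series$times
  v <- series$values
  span <- t[n] - t[1L]
  if (n > 1L && window >= span) stop("window must be shorter than the series")
  tail_start <- max(1L, ceiling(0.8 * n))
  plateau <- mean(v[tail_start:n])
  wmean <- vapply(seq_len(n), function(i) {
    mean(v[t >= t[i] & t <= t[i] + window])
  }, numeric(1L))
  ok <- abs(wmean - plateau) <= tolerance
  # earliest index from which all subsequent windows are ok
  bad <- which(!ok)
  first <- if (!length(bad)) 1L else if (max(bad) == n) NA_integer_ else
    max(bad) + 1L
  if (is.na(first)) return(NULL)
  list(time = t[first], plateau = plateau)
}
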