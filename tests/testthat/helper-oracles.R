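# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain double loops and direct formula transcriptions.

# scalar minimum-image distance between two points
oracle_mi_dist <- function(p, q, box = NULL) {
  d <- p - q
  if (!is.null(box)) {
    for (k in 1:3) {
      while (d[k] > box[k] / 2) d[k] <- d[k] - box[k]
      while (d[k] < -box[k] / 2) d[k] <- d[k] + box[k]
    }
  }
  sqrt(sum(d^2))
}

# waters within cutoff of any target atom, counted once each
oracle_hydration_count <- function(frame, water_idx, target_idx, cutoff,
                                   box = NULL) {
  n <- 0L
  for (w in water_idx) {
    for (t in target_idx) {
      if (oracle_mi_dist(frame[w, ], frame[t, ], box) <= cutoff) {
        n <- n + 1L
        break
      }
    }
  }
  n
}

oracle_min_dist <- function(frame, idx_a, idx_b, box = NULL) {
  best <- Inf
  for (i in idx_a) for (j in idx_b) {
    best <- min(best, oracle_mi_dist(frame[i, ], frame[j, ], box))
  }
  best
}

oracle_com <- function(masses, coords) {
  acc <- c(0, 0, 0); tot <- 0
  for (i in seq_along(masses)) {
    acc <- acc + masses[i] * coords[i, ]
    tot <- tot + masses[i]
  }
  acc / tot
}

# direct transcription of the pairwise GB + LJ energy, one pair at a time
oracle_pair_energy <- function(atoms, frame, idx_a, idx_b,
                               eps_p = 1, eps_w = 78.5, use_gb = TRUE,
                               box = NULL) {
  ke <- 332.0636
  elec <- 0; vdw <- 0
  for (i in idx_a) for (j in idx_b) {
    r <- oracle_mi_dist(frame[i, ], frame[j, ], box)
    qq <- atoms$charge[i] * atoms$charge[j]
    if (use_gb) {
      rr <- atoms$born_radius[i] * atoms$born_radius[j]
      fgb <- if (rr == 0) r else sqrt(r^2 + rr * exp(-r^2 / (4 * rr)))
      elec <- elec + ke * qq * (1 / (eps_p * r) -
                                  (1 / eps_p - 1 / eps_w) / fgb)
    } else {
      elec <- elec + ke * qq / (eps_p * r)
    }
    sij <- (atoms$lj_sigma[i] + atoms$lj_sigma[j]) / 2
    eij <- sqrt(atoms$lj_epsilon[i] * atoms$lj_epsilon[j])
    if (eij > 0 && sij > 0) {
      vdw <- vdw + 4 * eij * ((sij / r)^12 - (sij / r)^6)
    }
  }
  list(total = elec + vdw, elec = elec, vdw = vdw)
}

# random rotation matrix (uniform axis, uniform angle)
random_rotation <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  k <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3L, 3L, byrow = TRUE)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

rotation_about_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
         3L, 3L, byrow = TRUE)
}
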