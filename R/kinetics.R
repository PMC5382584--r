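# NADH-coupled ATPase assay analysis. ATP hydrolysis is regenerated by a
# pyruvate-kinase / lactate-dehydrogenase couple so that NADH oxidation
# (loss of A340) reports ATP turnover 1:1; the initial-rate slope of the
# A340 trace converts to a specific activity in nmol ATP / min / mg enzyme.

#' NADH extinction coefficient at 340 nm (M^-1 cm^-1)
#' @export
NADH_EXTINCTION <- 6220

#' Construct an assay trace
#'
#' @param times time points in seconds, strictly increasing.
#' @param a340 absorbance at 340 nm, same length.
#' @param enzyme enzyme label.
#' @param condition condition label (e.g. `"basal"`, `"arsenite"`,
#'   `"antimonite"`).
#' @param enzyme_mass enzyme amount in the well, mg.
#' @param volume reaction volume, litres (default 200 uL).
#' @param path_length optical path, cm (default 0.55, a 200 uL well).
#' @param extinction_coeff NADH molar extinction at 340 nm (default 6220).
#' @return an object of class `AssayTrace`.
#' @export
assay_trace <- function(times, a340, enzyme = "", condition = "basal",
                        enzyme_mass = 0.01, volume = 200e-6,
                        path_length = 0.55,
                        extinction_coeff = NADH_EXTINCTION) {
  times <- as.numeric(times); a340 <- as.numeric(a340)
  if (length(times) != length(a340)) stop("times/a340 length mismatch")
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  if (any(!is.finite(a340))) stop("a340 must be finite")
  structure(list(times = times, a340 = a340,
                 meta = list(enzyme = enzyme, condition = condition,
                             enzyme_mass = enzyme_mass, volume = volume,
                             path_length = path_length,
                             extinction_coeff = extinction_coeff)),
            class = "AssayTrace")
}

#' @export
print.AssayTrace <- function(x, ...) {
  cat(sprintf("AssayTrace '%s' (%s): %d points over %.0f s\n",
              x$meta$enzyme, x$meta$condition, length(x$times),
              diff(range(x$times))))
  invisible(x)
}

#' Fit the initial rate of an A340 trace
#'
#' Ordinary least squares over a time window. For an active ATPase the slope
#' is negative (NADH is consumed); a positive slope triggers a warning.
#'
#' @param trace an [assay_trace()].
#' @param window `(start, end)` in seconds (default: whole trace).
#' @return list with `slope` (AU/s), `stderr`, `r_squared`, `n`.
#' @export
fit_initial_rate <- function(trace, window = range(trace$times)) {
  stopifnot(inherits(trace, "AssayTrace"))
  keep <- trace$times >= window[1L] & trace$times <= window[2L]
  if (sum(keep) < 3L) stop("need at least 3 points in the fit window")
  t <- trace$times[keep]; a <- trace$a340[keep]
  fit <- stats::lm(a ~ t)
  sm <- suppressWarnings(summary(fit))  # noiseless traces fit exactly
  slope <- unname(stats::coef(fit)[2L])
  if (slope > 1e-9 && sm$coefficients[2L, 2L] < slope) {
    warning("positive A340 slope: trace does not look like NADH consumption")
  }
  list(slope = slope,
       stderr = unname(sm$coefficients[2L, 2L]),
       r_squared = if (is.null(sm$r.squared)) NA_real_ else sm$r.squared,
       n = sum(keep))
}

#' Choose the longest near-linear initial window
#'
#' Scans prefixes of the trace and returns the longest window starting at the
#' first point whose linear fit has `r^2 >= min_r2`.
#'
#' @param trace an [assay_trace()].
#' @param min_r2 linearity threshold (default 0.99).
#' @return `(start, end)` in seconds.
#' @export
auto_rate_window <- function(trace, min_r2 = 0.99) {
  n <- length(trace$times)
  best <- c(trace$times[1L], trace$times[min(3L, n)])
  for (j in n:3L) {
    w <- c(trace$times[1L], trace$times[j])
    r <- fit_initial_rate(trace, w)
    if (!is.na(r$r_squared) && r$r_squared >= min_r2) return(w)
  }
  best
}

#' Convert an A340 slope to a specific activity
#'
#' `activity = |slope| / (eps * path) [M/s] * volume [L] * 60 [s/min]
#'  * 1e9 [nmol/mol] / enzyme_mass [mg]`, in nmol ATP per minute per mg,
#' using 1:1 NADH:ATP coupling.
#'
#' @param slope fitted A340 slope in AU/s.
#' @param enzyme_mass mg of enzyme.
#' @param volume reaction volume in litres.
#' @param path_length optical path in cm.
#' @param extinction_coeff NADH molar extinction, M^-1 cm^-1.
#' @return specific activity, nmol/min/mg.
#' @export
specific_activity <- function(slope, enzyme_mass, volume,
                              path_length = 0.55,
                              extinction_coeff = NADH_EXTINCTION) {
  if (!is.finite(slope)) stop("slope must be finite")
  if (extinction_coeff <= 0 || path_length <= 0 || volume <= 0 ||
      enzyme_mass <= 0) {
    stop("extinction, path length, volume and mass must be positive")
  }
  abs(slope) / (extinction_coeff * path_length) * volume * 60 * 1e9 /
    enzyme_mass
}

#' Specific activity directly from a trace
#'
#' Convenience wrapper: [fit_initial_rate()] then [specific_activity()] using
#' the trace metadata.
#'
#' @param trace an [assay_trace()].
#' @param window fit window `(start, end)` seconds; default whole trace.
#' @return list with `activity` (nmol/min/mg), `slope`, `stderr`,
#'   `r_squared`.
#' @export
trace_activity <- function(trace, window = range(trace$times)) {
  r <- fit_initial_rate(trace, window)
  m <- trace$meta
  act <- specific_activity(r$slope, m$enzyme_mass, m$volume, m$path_length,
                           m$extinction_coeff)
  c(list(activity = act), r)
}

#' Build an activity table
#'
#' @param enzyme,condition character vectors (recycled as usual).
#' @param vmax maximal specific activities, nmol/min/mg, >= 0.
#' @param uncertainty one standard error per value (NA when unreported).
#' @return an `ActivityTable` data.frame.
#' @export
activity_table <- function(enzyme, condition, vmax, uncertainty = NA_real_) {
  if (any(vmax < 0, na.rm = TRUE)) stop("vmax must be >= 0")
  d <- data.frame(enzyme = enzyme, condition = condition, vmax = vmax,
                  uncertainty = uncertainty, stringsAsFactors = FALSE)
  class(d) <- c("ActivityTable", "data.frame")
  d
}

#' Relative Vmax versus the basal (no-oxyanion) condition
#'
#' For each enzyme, divides every condition's Vmax by that enzyme's basal
#' Vmax. The ratio for the basal row is exactly 1. Full-precision ratios are
#' returned in `relative`; `relative_rounded` applies the requested decimals.
#'
#' @param table an [activity_table()] with one `basal` row per enzyme.
#' @param rounding decimals for the rounded column (default 2).
#' @return the table with `relative` and `relative_rounded` columns added.
#' @export
relative_vmax <- function(table, rounding = 2L) {
  stopifnot(inherits(table, "ActivityTable"))
  basal <- table[table$condition == "basal", ]
  if (anyDuplicated(basal$enzyme)) stop("duplicate basal rows")
  b <- basal$vmax[match(table$enzyme, basal$enzyme)]
  if (anyNA(b)) {
    stop("missing basal condition for enzyme(s): ",
         paste(unique(table$enzyme[is.na(b)]), collapse = ", "))
  }
  if (any(b == 0)) stop("zero basal Vmax")
  table$relative <- table$vmax / b
  table$relative_rounded <- round(table$relative, rounding)
  table
}

#' Oxyanion-effect report
#'
#' One row per enzyme with basal, arsenite and antimonite Vmax and the
#' relative Vmax of each oxyanion condition versus basal. Ratio
#' uncertainties are propagated as
#' `ratio * sqrt((sd_a/a)^2 + (sd_b/b)^2)`.
#'
#' @param table an [activity_table()].
#' @param path optional TSV output path.
#' @param rounding decimals for the rounded relative columns (default 2).
#' @return data.frame with columns `enzyme`, `basal`, `arsenite`,
#'   `relative_arsenite`, `antimonite`, `relative_antimonite` plus
#'   propagated uncertainties.
#' @export
oxyanion_effect_report <- function(table, path = NULL, rounding = 2L) {
  tab <- relative_vmax(table, rounding)
  enzymes <- unique(tab$enzyme)
  get_row <- function(e, cond) tab[tab$enzyme == e & tab$condition == cond, ]
  rows <- lapply(enzymes, function(e) {
    b <- get_row(e, "basal")
    out <- data.frame(enzyme = e, basal = b$vmax, basal_sd = b$uncertainty,
                      arsenite = NA_real_, relative_arsenite = NA_real_,
                      relative_arsenite_sd = NA_real_,
                      antimonite = NA_real_, relative_antimonite = NA_real_,
                      relative_antimonite_sd = NA_real_)
    for (cond in c("arsenite", "antimonite")) {
      r <- get_row(e, cond)
      if (nrow(r) == 1L) {
        ratio <- r$relative
        sd <- ratio * sqrt((r$uncertainty / r$vmax)^2 +
                             (b$uncertainty / b$vmax)^2)
        out[[cond]] <- r$vmax
        out[[paste0("relative_", cond)]] <- ratio
        out[[paste0("relative_", cond, "_sd")]] <- sd
      }
    }
    out
  })
  rep <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(rep, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  rep
}

#' Published oxyanion-response activities of ArsA-family ATPases
#'
#' Reference maximal specific activities (nmol/min/mg, mean and one standard
#' error where reported) of ArsA-family enzymes without oxyanions and in the
#' presence of arsenite or antimonite: the two C. reinhardtii ArsA proteins,
#' yeast Get3, human ASNA-1, and E. coli ArsA. TRC40/Get3-like enzymes show
#' strong oxyanion-independent basal activity; the bacterial arsenite-pump
#' ArsA is strongly oxyanion-stimulated.
#'
#' @return an [activity_table()].
#' @export
atpase_reference_activities <- function() {
  activity_table(
    enzyme = c(rep("Cr-ArsA1", 3), rep("Cr-ArsA2", 3), "Get3",
               rep("ASNA-1", 3), rep("Ec-ArsA", 3)),
    condition = c(rep(c("basal", "arsenite", "antimonite"), 2), "basal",
                  rep(c("basal", "arsenite", "antimonite"), 2)),
    vmax = c(400, 470, 418,
             480, 470, 377,
             418,
             17, 31, 17,
             0.06, 0.24, 1.91),
    uncertainty = c(25, 31, 26,
                    40, 35, 20,
                    20,
                    1, 3, NA,
                    NA, NA, NA)
  )
}

#' Write an assay trace as TSV
#'
#' Columns `time_s` and `a340`; metadata goes in a JSON sidecar when
#' `meta_path` is given.
#'
#' @param trace an [assay_trace()].
#' @param path TSV output path.
#' @param meta_path optional JSON metadata path.
#' @return `path`, invisibly.
#' @export
write_assay_trace <- function(trace, path, meta_path = NULL) {
  utils::write.table(data.frame(time_s = trace$times, a340 = trace$a340),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    jsonlite::write_json(trace$meta, meta_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read an assay trace from TSV (+ optional JSON metadata)
#'
#' @param path TSV with columns `time_s`, `a340`.
#' @param meta_path optional JSON metadata sidecar.
#' @return an [assay_trace()].
#' @export
read_assay_trace <- function(path, meta_path = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  meta <- if (!is.null(meta_path)) jsonlite::read_json(meta_path,
                                                       simplifyVector = TRUE)
  else list()
  do.call(assay_trace, c(list(times = d[[1L]], a340 = d[[2L]]), meta))
}
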