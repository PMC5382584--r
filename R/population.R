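# 2-D frequency analysis: population binning of paired observables, cluster
# extraction by connected components of high-occupancy bins, frame
# assignment with occupancy and dwell intervals, per-cluster average
# structures.

#' 2-D population histogram of two paired series
#'
#' Bins are half-open `[edge, edge + width)`; edges start at
#' `floor(min/width) * width` on each axis so bin boundaries fall on
#' multiples of the bin width. The total count equals the number of frames.
#'
#' @param x,y [scalar_series()] sharing the same time base.
#' @param x_bin_width,y_bin_width bin widths in the units of each series.
#' @return An object of class `Histogram2D`: list with `x_edges`, `y_edges`,
#'   `counts` (matrix, x rows by y columns), `times`, and each frame's bin
#'   indices `frame_bins` (n x 2).
#' @export
histogram2d <- function(x, y, x_bin_width, y_bin_width) {
  stopifnot(inherits(x, "ScalarSeries"), inherits(y, "ScalarSeries"))
  if (length(x) != length(y) || any(x$times != y$times)) {
    stop("x and y must share the same times")
  }
  if (x_bin_width <= 0 || y_bin_width <= 0) {
    stop("bin widths must be positive")
  }
  bx <- floor(x$values / x_bin_width)
  by <- floor(y$values / y_bin_width)
  x0 <- min(bx); y0 <- min(by)
  nx <- max(bx) - x0 + 1L
  ny <- max(by) - y0 + 1L
  ix <- bx - x0 + 1L
  iy <- by - y0 + 1L
  counts <- matrix(0L, nx, ny)
  for (f in seq_along(ix)) {
    counts[ix[f], iy[f]] <- counts[ix[f], iy[f]] + 1L
  }
  structure(list(
    x_edges = (x0:(x0 + nx)) * x_bin_width,
    y_edges = (y0:(y0 + ny)) * y_bin_width,
    counts = counts,
    times = x$times,
    frame_bins = cbind(ix, iy),
    x_label = x$label, y_label = y$label
  ), class = "Histogram2D")
}

#' @export
print.Histogram2D <- function(x, ...) {
  cat(sprintf("Histogram2D: %d x %d bins, %d frames binned\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Write a 2-D histogram as a TSV matrix
#'
#' Rows are x bins, columns y bins; row/column names carry the lower bin
#' edges.
#'
#' @param hist a [histogram2d()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_histogram_tsv <- function(hist, path) {
  m <- hist$counts
  rownames(m) <- utils::head(hist$x_edges, -1L)
  colnames(m) <- utils::head(hist$y_edges, -1L)
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

.bin_centers <- function(edges) (utils::head(edges, -1L) + edges[-1L]) / 2

# 8-connected component labelling of a logical matrix, flood-fill
.label_components <- function(sig) {
  lab <- matrix(0L, nrow(sig), ncol(sig))
  nxt <- 0L
  for (j in seq_len(ncol(sig))) for (i in seq_len(nrow(sig))) {
    if (sig[i, j] && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(i, j))
      lab[i, j] <- nxt
      while (length(queue)) {
        p <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1L] + di; jj <- p[2L] + dj
          if (ii >= 1L && ii <= nrow(sig) && jj >= 1L && jj <= ncol(sig) &&
              sig[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- nxt
            queue[[length(queue) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

#' Extract significant population clusters from a 2-D histogram
#'
#' Bins whose count is at least `occupancy_threshold` times the maximum bin
#' count are significant; clusters are 8-connected components of significant
#' bins. Clusters are indexed chronologically: cluster 1 contains the
#' earliest frame of any cluster (matching the convention of numbering the
#' initial state first). Centroids are count-weighted means of bin centers.
#'
#' @param hist a [histogram2d()].
#' @param occupancy_threshold fraction of the maximum bin count in (0, 1]
#'   (default 0.10).
#' @return list of `Cluster` objects, each a list with `id`, `bins`
#'   (two-column matrix of bin indices) and `centroid`; complete them with
#'   [assign_frames()].
#' @export
find_clusters <- function(hist, occupancy_threshold = 0.10) {
  stopifnot(inherits(hist, "Histogram2D"))
  if (occupancy_threshold <= 0 || occupancy_threshold > 1) {
    stop("occupancy_threshold must be in (0, 1]")
  }
  if (sum(hist$counts) == 0L) stop("empty histogram")
  sig <- hist$counts >= occupancy_threshold * max(hist$counts)
  lab <- .label_components(sig)
  k <- max(lab)
  if (k == 0L) return(list())
  # chronological order: earliest frame falling in each component
  frame_lab <- lab[hist$frame_bins]
  first_frame <- vapply(seq_len(k), function(g) {
    hit <- which(frame_lab == g)
    if (length(hit)) min(hit) else .Machine$integer.max
  }, numeric(1L))
  ord <- order(first_frame)
  xc <- .bin_centers(hist$x_edges)
  yc <- .bin_centers(hist$y_edges)
  lapply(seq_len(k), function(rank) {
    g <- ord[rank]
    bins <- which(lab == g, arr.ind = TRUE)
    w <- hist$counts[bins]
    centroid <- c(sum(xc[bins[, 1L]] * w), sum(yc[bins[, 2L]] * w)) / sum(w)
    structure(list(id = rank, bins = unname(bins), centroid = centroid,
                   member_frames = integer(), occupancy_pct = NA_real_,
                   dwell_intervals = list()),
              class = "Cluster")
  })
}

#' @export
print.Cluster <- function(x, ...) {
  cat(sprintf(
    "Cluster %d: %d bins, centroid (%.2f, %.2f), occupancy %s, %d interval(s)\n",
    x$id, nrow(x$bins), x$centroid[1L], x$centroid[2L],
    if (is.na(x$occupancy_pct)) "unassigned" else
      sprintf("%.2f%%", x$occupancy_pct),
    length(x$dwell_intervals)))
  invisible(x)
}

#' Assign frames to clusters; compute occupancy and dwell intervals
#'
#' Each frame is assigned to the cluster owning its bin, or left unassigned
#' if its bin is not significant. Occupancy is the percentage of all frames
#' assigned; dwell intervals are maximal runs of consecutive assigned frames
#' reported as (time of first, time of last) in ns. A cluster the trajectory
#' revisits has several intervals.
#'
#' @param clusters output of [find_clusters()].
#' @param hist the same [histogram2d()] the clusters came from.
#' @return the clusters, completed with `member_frames`, `occupancy_pct` and
#'   `dwell_intervals`.
#' @export
assign_frames <- function(clusters, hist) {
  stopifnot(inherits(hist, "Histogram2D"))
  nfr <- length(hist$times)
  owner <- matrix(0L, nrow(hist$counts), ncol(hist$counts))
  for (cl in clusters) owner[cl$bins] <- cl$id
  frame_cluster <- owner[hist$frame_bins]
  lapply(clusters, function(cl) {
    members <- which(frame_cluster == cl$id)
    cl$member_frames <- members
    cl$occupancy_pct <- 100 * length(members) / nfr
    cl$dwell_intervals <- .runs_to_intervals(members, hist$times)
    cl
  })
}

.runs_to_intervals <- function(members, times) {
  if (!length(members)) return(list())
  brk <- c(0L, which(diff(members) > 1L), length(members))
  lapply(seq_len(length(brk) - 1L), function(r) {
    run <- members[(brk[r] + 1L):brk[r + 1L]]
    c(start_ns = times[run[1L]], end_ns = times[run[length(run)]])
  })
}

#' Write a cluster report as JSON
#'
#' @param clusters completed clusters from [assign_frames()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(clusters, path) {
  rep <- lapply(clusters, function(cl) {
    list(id = cl$id,
         n_frames = length(cl$member_frames),
         occupancy_pct = cl$occupancy_pct,
         centroid = as.numeric(cl$centroid),
         dwell_intervals = lapply(cl$dwell_intervals, as.numeric))
  })
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Per-cluster average structure
#'
#' All member frames are superposed onto the first member frame using the
#' alignment selection (mass-weighted), then averaged without weighting.
#'
#' @param topology a [topology()].
#' @param trajectory a [trajectory()].
#' @param cluster a completed `Cluster` with at least one member frame.
#' @param alignment_selection `AtomSelection` used for superposition
#'   (typically the ligand backbone).
#' @return An `AverageStructure`: list with `coordinates` (n_atoms x 3),
#'   `n_contributing` and `alignment_selection`.
#' @export
cluster_average_structure <- function(topology, trajectory, cluster,
                                      alignment_selection) {
  if (!length(cluster$member_frames)) stop("cluster has no member frames")
  sel <- as.integer(alignment_selection)
  msel <- topology$atoms$mass[sel]
  ref <- trajectory$frames[[cluster$member_frames[1L]]]
  ref_sel <- ref[sel, , drop = FALSE]
  acc <- matrix(0, nrow(ref), 3L)
  for (f in cluster$member_frames) {
    fr <- trajectory$frames[[f]]
    tr <- kabsch_superpose(fr[sel, , drop = FALSE], ref_sel, msel)
    acc <- acc + apply_transform(tr, fr)
  }
  structure(list(coordinates = acc / length(cluster$member_frames),
                 n_contributing = length(cluster$member_frames),
                 alignment_selection = alignment_selection),
            class = "AverageStructure")
}

#' Write an average structure as single-model PDB
#'
#' @param topology a [topology()].
#' @param avg an `AverageStructure` from [cluster_average_structure()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_average_structure <- function(topology, avg, path) {
  write_pdb_models(topology, trajectory(list(avg$coordinates), times = 0),
                   path)
}
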