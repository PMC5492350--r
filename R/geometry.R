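#' Interatomic distance as a function of simulation time
#'
#' Computes the per-frame Euclidean distance between two single-atom
#' selections over the full trajectory -- canonically the heme iron
#' (\code{"atom_name=FE and residue_name=HEM"}) and lanosterol's C30 methyl
#' carbon (\code{"atom_name=C30"}), whose separation reports whether the
#' substrate sits in a catalytically competent position over the heme.
#'
#' @param traj an [MDTrajectory-class].
#' @param sel_a,sel_b selections (expression strings or
#'   [AtomSelection-class]) each resolving exactly one atom.
#' @param structure_label label stored in the result.
#' @return a [DistanceSeries-class]
#' @export
distanceSeries <- function(traj, sel_a, sel_b,
                           structure_label = "structure") {
  stopifnot(is(traj, "MDTrajectory"))
  ia <- resolveSingleAtom(traj, sel_a, "sel_a")
  ib <- resolveSingleAtom(traj, sel_b, "sel_b")
  d <- sqrt(rowSums((traj@coords[, ia, , drop = FALSE] -
                     traj@coords[, ib, , drop = FALSE])^2, dims = 1))
  new("DistanceSeries", structure_label = structure_label,
      times_ps = traj@times_ps, distances_angstrom = as.numeric(d))
}

#' Summary statistics of a distance series
#'
#' Standard sample statistics (sample, n-1, standard deviation) over a frame
#' window, used e.g. to compare the mean heme-Fe to C30 separation between a
#' variant and the wild type.
#'
#' @param series a [DistanceSeries-class] (or plain numeric vector).
#' @param window integer \code{c(start, end)}, 1-based inclusive positions;
#'   default the full series.
#' @return a list with \code{mean}, \code{sd}, \code{min}, \code{max},
#'   \code{n}.
#' @export
seriesSummary <- function(series, window = NULL) {
  x <- if (is(series, "DistanceSeries")) series@distances_angstrom
       else as.numeric(series)
  if (is.null(window)) window <- c(1L, length(x))
  window <- as.integer(window)
  if (length(window) != 2L || window[1L] > window[2L] ||
      window[1L] < 1L || window[2L] > length(x))
    stopf("invalid summary window [%s]", paste(window, collapse = ", "))
  v <- x[window[1L]:window[2L]]
  list(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0,
       min = min(v), max = max(v), n = length(v))
}

#' Centred running average of a distance series
#'
#' Smoothing companion to the raw trace, for plots that overlay both. Edge
#' windows are truncated rather than dropped.
#'
#' @param series a [DistanceSeries-class] or numeric vector.
#' @param width window width in frames (default 100).
#' @return numeric vector of the same length.
#' @export
runningAverage <- function(series, width = 100L) {
  x <- if (is(series, "DistanceSeries")) series@distances_angstrom
       else as.numeric(series)
  if (width < 1L) stopf("width must be >= 1")
  n <- length(x)
  half <- width %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Write distance series as TSV
#'
#' Columns \code{structure_label}, \code{time_ps},
#' \code{distance_angstrom}.
#'
#' @param series a [DistanceSeries-class] or list of them.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDistanceTSV <- function(series, path) {
  if (is(series, "DistanceSeries")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(structure_label = s@structure_label, time_ps = s@times_ps,
               distance_angstrom = s@distances_angstrom,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Plot one or more distance series
#'
#' Raw traces with an optional running-average overlay, one line per
#' structure, in the style of distance-versus-simulation-time figures.
#'
#' @param x a [DistanceSeries-class] or list of them.
#' @param smooth_width running-average width in frames; 0 disables the
#'   overlay (default 100).
#' @param ... further arguments passed to \code{matplot}.
#' @return invisibly, \code{NULL}.
#' @export
plotDistanceSeries <- function(x, smooth_width = 100L, ...) {
  if (is(x, "DistanceSeries")) x <- list(x)
  cols <- grDevices::hcl.colors(max(length(x), 2L), "Dark 3")
  ylim <- range(unlist(lapply(x, slot, "distances_angstrom")))
  graphics::plot(NA, xlim = range(unlist(lapply(x, slot, "times_ps"))),
                 ylim = ylim, xlab = "sim. time [ps]",
                 ylab = "Fe-C30 distance [\u00c5]", ...)
  for (i in seq_along(x)) {
    s <- x[[i]]
    graphics::lines(s@times_ps, s@distances_angstrom,
                    col = grDevices::adjustcolor(cols[i], 0.35))
    if (smooth_width > 0L)
      graphics::lines(s@times_ps, runningAverage(s, smooth_width),
                      col = cols[i], lwd = 2)
  }
  graphics::legend("topleft", bty = "n", lwd = 2, col = cols[seq_along(x)],
                   legend = vapply(x, slot, "", "structure_label"))
  invisible(NULL)
}
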