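#' Block-averaged standard error of a correlated series
#'
#' Splits the series into \code{n_blocks} contiguous blocks (as equal in size
#' as possible) and returns the standard deviation of the block means divided
#' by \code{sqrt(n_blocks)}. Blocking absorbs the short-range autocorrelation
#' typical of per-frame simulation observables, so the estimate is a more
#' honest standard error of the trajectory mean than the naive
#' \code{sd/sqrt(n)}.
#'
#' @param series an [EnergySeries-class] or numeric vector.
#' @param n_blocks number of blocks, at least 2 and at most the series
#'   length.
#' @return non-negative standard error.
#' @export
blockStandardError <- function(series, n_blocks = 10L) {
  x <- if (is(series, "EnergySeries")) series@values else as.numeric(series)
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 2L) stopf("n_blocks must be >= 2")
  if (length(x) < n_blocks)
    stopf("series length %d < n_blocks %d", length(x), n_blocks)
  grp <- as.integer(cut(seq_along(x), breaks = n_blocks, labels = FALSE))
  bm <- vapply(split(x, grp), mean, numeric(1))
  stats::sd(bm) / sqrt(n_blocks)
}

#' Trajectory-average binding enthalpy
#'
#' The binding enthalpy is estimated as the difference of trajectory-average
#' internal energies,
#' \deqn{E_b = \langle U_{cmplx}\rangle - \langle U_{m1}\rangle -
#'       \langle U_{m2}\rangle,}
#' where each average is taken over the entire trajectory of its own,
#' separately simulated system (so series lengths may differ). More negative
#' \eqn{E_b} means more favourable binding. The standard error is the
#' quadrature sum of the three per-series block standard errors; a series
#' shorter than two blocks contributes zero error.
#'
#' @param u_cmplx,u_m1,u_m2 [EnergySeries-class] objects (or numeric
#'   vectors): complex, component 1, component 2.
#' @param n_blocks blocks for [blockStandardError] (default 10).
#' @return a [BindingEnergyResult-class]
#' @examples
#' bindingEnthalpy(rep(10, 5), rep(3, 5), rep(5, 5))  # e_b = 2, se = 0
#' @export
bindingEnthalpy <- function(u_cmplx, u_m1, u_m2, n_blocks = 10L) {
  vals <- lapply(list(u_cmplx, u_m1, u_m2), function(s) {
    if (is(s, "EnergySeries")) s@values else as.numeric(s)
  })
  if (any(vapply(vals, length, 0L) == 0L))
    stopf("all three energy series must be non-empty")
  unit <- if (is(u_cmplx, "EnergySeries")) u_cmplx@unit else "kcal/mol"
  means <- vapply(vals, mean, numeric(1))
  ses <- vapply(vals, function(x) {
    nb <- min(n_blocks, length(x))
    if (nb < 2L) 0 else blockStandardError(x, nb)
  }, numeric(1))
  names(means) <- names(ses) <- c("complex", "component1", "component2")
  new("BindingEnergyResult",
      e_b = means[[1L]] - means[[2L]] - means[[3L]],
      se = sqrt(sum(ses^2)), means = means, ses = ses,
      n_frames = vapply(vals, length, 0L), n_blocks = as.integer(n_blocks),
      unit = unit)
}

#' Compare binding enthalpies across variants
#'
#' Orders labelled [BindingEnergyResult-class] objects from most to least
#' favourable (ascending \eqn{E_b}), flags estimates indistinguishable from
#' zero (\eqn{|E_b| < 2\,se}, the "almost zero binding" situation), and
#' tabulates all pairwise differences with propagated standard errors.
#'
#' @param results named list of [BindingEnergyResult-class] objects
#'   (at least 2).
#' @return a list with \code{table} (\code{data.frame}: label, e_b, se,
#'   near_zero, ordered most favourable first) and \code{pairwise}
#'   (\code{data.frame}: label_a, label_b, delta, se_delta).
#' @export
compareVariants <- function(results) {
  if (length(results) < 2L) stopf("need at least two labelled results")
  if (is.null(names(results)) || any(!nzchar(names(results))))
    stopf("results must be a named list")
  eb <- vapply(results, slot, numeric(1), "e_b")
  se <- vapply(results, slot, numeric(1), "se")
  ord <- order(eb)
  tab <- data.frame(label = names(results)[ord], e_b = unname(eb[ord]),
                    se = unname(se[ord]),
                    near_zero = unname(abs(eb[ord]) < 2 * se[ord]),
                    stringsAsFactors = FALSE)
  pairs <- utils::combn(seq_along(ord), 2)
  pw <- data.frame(
    label_a = tab$label[pairs[1, ]], label_b = tab$label[pairs[2, ]],
    delta = tab$e_b[pairs[1, ]] - tab$e_b[pairs[2, ]],
    se_delta = sqrt(tab$se[pairs[1, ]]^2 + tab$se[pairs[2, ]]^2),
    stringsAsFactors = FALSE)
  list(table = tab, pairwise = pw)
}

#' Write a variant comparison as TSV
#'
#' @param comparison result of [compareVariants].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeComparisonTSV <- function(comparison, path) {
  utils::write.table(comparison$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
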