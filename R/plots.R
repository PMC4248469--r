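#' Per-position error profile of a simulated read set
#'
#' Empirical per-position error rate across reads, against the configured
#' linear ramp. Useful to confirm the 3'-weighted error model.
#'
#' @param object A [sim_reads()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sim_reads
#' @export
autoplot.sim_reads <- function(object, ...) {
  L <- object$config$read_len
  n <- nrow(object$reads)
  emp <- tibble::tibble(
    position = seq_len(L),
    rate = tabulate(object$truth$pos, nbins = L) / n
  )
  ramp <- tibble::tibble(
    position = seq_len(L),
    rate = object$config$r5 +
      (object$config$r3 - object$config$r5) * (seq_len(L) - 1) / max(L - 1, 1)
  )
  ggplot2::ggplot(emp, ggplot2::aes(x = .data$position, y = .data$rate)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(data = ramp, colour = "red") +
    ggplot2::labs(x = "read position", y = "per-base error rate",
                  title = "Injected error profile (red: configured ramp)") +
    ggplot2::theme_minimal()
}

#' Edit positions of a correction run
#'
#' Where along the read corrections were applied; with a 3'-weighted error
#' model the histogram should rise toward the 3' end.
#'
#' @param object A [run_correction()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot correction_run
#' @export
autoplot.correction_run <- function(object, ...) {
  ggplot2::ggplot(object$edits, ggplot2::aes(x = .data$pos)) +
    ggplot2::geom_histogram(binwidth = 1) +
    ggplot2::labs(x = "read position", y = "corrections",
                  title = "Applied corrections by read position") +
    ggplot2::theme_minimal()
}

#' Occupancy-versus-coverage diagnostic
#'
#' Plots Bloom filter occupancies from several [run_correction()] runs
#' against their coverages. With `alpha = 7 / C` the points should be
#' nearly flat: the subsample density, and hence both filters' loads, are
#' coverage-invariant.
#'
#' @param runs List of `correction_run` objects.
#' @param coverages Numeric vector of the corresponding fold coverages.
#' @return A ggplot.
#' @export
plot_occupancy_scaling <- function(runs, coverages) {
  stopifnot(length(runs) == length(coverages))
  d <- dplyr::bind_rows(lapply(seq_along(runs), function(i) {
    r <- runs[[i]]$report
    tibble::tibble(coverage = coverages[i],
                   filter = c("A (subsample)", "B (solid)"),
                   occupancy = c(r$occupancy_a, r$occupancy_b))
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$coverage, y = .data$occupancy,
                                  colour = .data$filter)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::expand_limits(y = 0) +
    ggplot2::labs(x = "fold coverage", y = "fraction of bits set",
                  title = "Filter occupancy is near-constant in coverage") +
    ggplot2::theme_minimal()
}
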