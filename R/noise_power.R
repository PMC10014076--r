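#' Decompose a dose-response channel into signal and noise power
#'
#' Signal power is the variation of the mean output across stimulant doses:
#' the population variance (divide by the number of doses D) of the
#' per-dose means. Noise power is the background variability of the
#' channel: the unweighted average across doses of the per-dose output
#' variance. Their ratio is the channel's signal-to-noise ratio. All three
#' are computed on the dataset's transformed scale (log10 by default
#' upstream), the same scale used for capacity estimation.
#'
#' @param dataset a [dose_response_dataset()] with >= 2 doses and >= 2
#'   cells per dose.
#' @param across_dose_variance `"population"` (1/D, default) or `"sample"`
#'   (1/(D-1)) for the variance of the per-dose means.
#' @return object of class `noise_decomposition` with `doses`, `mean_i`,
#'   `var_i`, `signal_power`, `noise_power`, `snr`.
#' @export
decompose <- function(dataset,
                      across_dose_variance = c("population", "sample")) {
  stopifnot(inherits(dataset, "dose_response_dataset"))
  across_dose_variance <- match.arg(across_dose_variance)
  if (length(dataset$doses) < 2L) stop("decomposition needs >= 2 doses")
  n_i <- cells_per_dose(dataset)
  if (any(n_i < 2L)) {
    stop("sample-size error: dose ",
         format(dataset$doses[which(n_i < 2L)[1]]),
         " has fewer than 2 cells (variance undefined)")
  }
  mean_i <- vapply(dataset$outputs, mean, numeric(1))
  var_i <- vapply(dataset$outputs, stats::var, numeric(1))
  d <- length(mean_i)
  signal_power <- if (across_dose_variance == "population") {
    sum((mean_i - mean(mean_i))^2) / d
  } else {
    stats::var(mean_i)
  }
  noise_power <- mean(var_i)
  structure(list(doses = dataset$doses, mean_i = mean_i, var_i = var_i,
                 signal_power = signal_power, noise_power = noise_power,
                 snr = signal_power / noise_power),
            class = "noise_decomposition")
}

#' @export
print.noise_decomposition <- function(x, ...) {
  cat("<noise_decomposition> signal ", format(signif(x$signal_power, 4)),
      ", noise ", format(signif(x$noise_power, 4)),
      ", SNR ", format(signif(x$snr, 4)), "\n", sep = "")
  invisible(x)
}

#' Compare signal-to-noise ratios between two channel groups
#'
#' Two-sided Wilcoxon rank-sum test on the per-replicate SNR values of two
#' groups of decomposed channels.
#'
#' @param a,b lists of [decompose()] results (one per biological
#'   replicate), each non-empty.
#' @return list with `statistic` (rank sum of group a), `p_value`, and the
#'   SNR vectors `snr_a`, `snr_b`.
#' @export
snr_compare <- function(a, b) {
  grab <- function(g, label) {
    if (length(g) == 0) stop("domain error: empty group ", label)
    if (inherits(g, "noise_decomposition")) g <- list(g)
    vapply(g, function(d) {
      stopifnot(inherits(d, "noise_decomposition"))
      d$snr
    }, numeric(1))
  }
  snr_a <- grab(a, "a"); snr_b <- grab(b, "b")
  w <- wilcoxon_rank_sum(snr_a, snr_b)
  list(statistic = w$statistic, p_value = w$p_value,
       snr_a = snr_a, snr_b = snr_b)
}
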