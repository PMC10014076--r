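#' Configuration for the two-population mixture reporter simulator
#'
#' Emulates the population structure of an NF-kB-GFP reporter line: at every
#' dose each cell is either basal or activated, and the two subpopulations
#' are broad overlapping log-normal fluorescence distributions (no clean
#' two-state separation). The fraction of activated cells follows a
#' four-parameter logistic curve in dose, so activation probability — not a
#' shift of a single tight peak — carries the dose information.
#'
#' Defaults are chosen to resemble measured reporter dose responses: basal
#' cells centered at 10^2 fluorescence units with 0.35 decades SD, active
#' cells at 10^3.2 with 0.45 decades SD, activation probability rising from
#' 0.05 to 0.95 across 12 half-log-spaced doses (unstimulated included),
#' 5000 cells per dose.
#'
#' @param doses ascending non-negative doses (dose 0 = unstimulated).
#' @param n_cells_per_dose cells simulated at each dose.
#' @param basal_log_mean,basal_log_sd log10-scale mean and SD of the basal
#'   population.
#' @param active_log_mean,active_log_sd log10-scale mean and SD of the
#'   activated population; `active_log_mean` must exceed `basal_log_mean`.
#' @param p_min,p_max floor and ceiling of the activation probability.
#' @param ec50 dose of half-maximal activation probability.
#' @param hill Hill slope of the activation curve.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return a `mixture_reporter_config` list.
#' @export
mixture_reporter_config <- function(doses = c(0, 10^seq(-2.5, 2.5, by = 0.5)),
                                    n_cells_per_dose = 5000L,
                                    basal_log_mean = 2.0, basal_log_sd = 0.35,
                                    active_log_mean = 3.2, active_log_sd = 0.45,
                                    p_min = 0.05, p_max = 0.95,
                                    ec50 = 1, hill = 1, seed = 1L) {
  if (!(p_min >= 0 && p_max <= 1 && p_min <= p_max)) {
    stop("config error: need 0 <= p_min <= p_max <= 1")
  }
  if (!(active_log_mean > basal_log_mean)) {
    stop("config error: activated population must be brighter than basal")
  }
  if (basal_log_sd <= 0 || active_log_sd <= 0) {
    stop("config error: population SDs must be positive")
  }
  if (ec50 <= 0 || hill <= 0) stop("config error: ec50 and hill must be positive")
  if (n_cells_per_dose < 1L) stop("config error: need >= 1 cell per dose")
  structure(list(doses = sort(as.numeric(doses)),
                 n_cells_per_dose = as.integer(n_cells_per_dose),
                 basal_log_mean = basal_log_mean, basal_log_sd = basal_log_sd,
                 active_log_mean = active_log_mean, active_log_sd = active_log_sd,
                 p_min = p_min, p_max = p_max, ec50 = ec50, hill = hill,
                 seed = as.integer(seed)),
            class = "mixture_reporter_config")
}

# 4PL activation probability; dose 0 sits on the lower asymptote.
activation_probability <- function(dose, p_min, p_max, ec50, hill) {
  frac <- ifelse(dose <= 0, 0, 1 / (1 + (ec50 / dose)^hill))
  p_min + (p_max - p_min) * frac
}

#' Simulate a mixture-reporter dose-response dataset
#'
#' For each dose `d`, each cell independently activates with probability
#' `p(d)` from the 4PL activation curve, then draws its log10 output from
#' the activated or basal normal population. Draws are made cell by cell in
#' dose order (one uniform for activation, one normal deviate per cell), so
#' a seed fully determines the dataset. Outputs are on the log10 scale
#' (`transform_tag = "log10"`).
#'
#' @param config a [mixture_reporter_config()].
#' @param receptor,ligand,replicate condition labels for the dataset.
#' @return a [dose_response_dataset()].
#' @export
simulate_mixture_reporter <- function(config,
                                      receptor = "synthetic",
                                      ligand = "synthetic",
                                      replicate = 1L) {
  stopifnot(inherits(config, "mixture_reporter_config"))
  with_local_seed(config$seed, {
    outputs <- lapply(config$doses, function(d) {
      p <- activation_probability(d, config$p_min, config$p_max,
                                  config$ec50, config$hill)
      n <- config$n_cells_per_dose
      active <- stats::runif(n) < p
      z <- stats::rnorm(n)
      ifelse(active,
             config$active_log_mean + config$active_log_sd * z,
             config$basal_log_mean + config$basal_log_sd * z)
    })
    dose_response_dataset(config$doses, outputs, receptor = receptor,
                          ligand = ligand, replicate = replicate,
                          transform_tag = "log10")
  })
}

#' Configuration for the known-channel simulator
#'
#' Oracle mode: the channel is specified exactly by a row-stochastic
#' conditional matrix, so its true capacity is computable analytically
#' ([true_capacity()]) and estimator accuracy can be measured. Each input
#' symbol emits one of a set of well-separated output centers plus optional
#' Gaussian jitter.
#'
#' @param conditional row-stochastic matrix Q(j|i), rows = inputs.
#' @param n_cells_per_dose cells per input symbol.
#' @param output_centers strictly increasing centers, one per output
#'   symbol; when jitter > 0 they must be separated by more than 6 x
#'   `output_jitter_sd` so binning can recover the symbol.
#' @param output_jitter_sd non-negative Gaussian jitter SD.
#' @param seed integer seed.
#' @return a `known_channel_config` list.
#' @export
known_channel_config <- function(conditional, n_cells_per_dose = 5000L,
                                 output_centers = NULL,
                                 output_jitter_sd = 0.02, seed = 1L) {
  Q <- as.matrix(conditional)
  if (any(Q < 0) || any(abs(rowSums(Q) - 1) > 1e-12)) {
    stop("config error: conditional rows must be non-negative and sum to 1 ",
         "(tolerance 1e-12)")
  }
  k <- ncol(Q)
  if (is.null(output_centers)) output_centers <- seq_len(k)
  output_centers <- as.numeric(output_centers)
  if (length(output_centers) != k) {
    stop("config error: one output center per output symbol")
  }
  if (any(diff(output_centers) <= 0)) {
    stop("config error: output centers must be strictly increasing")
  }
  if (output_jitter_sd < 0) stop("config error: jitter SD must be >= 0")
  if (output_jitter_sd > 0 &&
      any(diff(output_centers) <= 6 * output_jitter_sd)) {
    stop("config error: output centers must be separated by > 6 x jitter SD")
  }
  structure(list(conditional = Q,
                 n_cells_per_dose = as.integer(n_cells_per_dose),
                 output_centers = output_centers,
                 output_jitter_sd = output_jitter_sd,
                 seed = as.integer(seed)),
            class = "known_channel_config")
}

#' Simulate a dataset from an exactly known discrete channel
#'
#' For input `i` (dose labels 1..n_inputs), draws `n_cells_per_dose` output
#' symbols from row `i` of the conditional matrix and emits
#' `output_centers[j] + Normal(0, output_jitter_sd)`.
#'
#' @param config a [known_channel_config()].
#' @param receptor,ligand,replicate condition labels.
#' @return a [dose_response_dataset()] whose true capacity is
#'   `true_capacity(config$conditional)`.
#' @export
simulate_known_channel <- function(config,
                                   receptor = "known_channel",
                                   ligand = "known_channel",
                                   replicate = 1L) {
  stopifnot(inherits(config, "known_channel_config"))
  Q <- config$conditional
  with_local_seed(config$seed, {
    outputs <- lapply(seq_len(nrow(Q)), function(i) {
      j <- sample.int(ncol(Q), config$n_cells_per_dose, replace = TRUE,
                      prob = Q[i, ])
      config$output_centers[j] +
        stats::rnorm(config$n_cells_per_dose, 0, config$output_jitter_sd)
    })
    dose_response_dataset(seq_len(nrow(Q)), outputs, receptor = receptor,
                          ligand = ligand, replicate = replicate,
                          transform_tag = "known_channel")
  })
}

#' Destroy the dose-output association by permuting cells across doses
#'
#' Pools all cells and deals them back to the doses at random (preserving
#' per-dose counts), which breaks any dependence of output on dose: the
#' shuffled dataset is a sample from an independence null with capacity 0.
#'
#' @param dataset a [dose_response_dataset()].
#' @param seed integer seed.
#' @return a shuffled [dose_response_dataset()].
#' @export
shuffle_dose_labels <- function(dataset, seed = 1L) {
  stopifnot(inherits(dataset, "dose_response_dataset"))
  pooled <- unlist(dataset$outputs, use.names = FALSE)
  n_i <- cells_per_dose(dataset)
  with_local_seed(seed, {
    perm <- sample.int(length(pooled))
    shuffled <- split(pooled[perm], rep(seq_along(n_i), n_i))
    dose_response_dataset(dataset$doses, unname(shuffled),
                          receptor = dataset$condition$receptor,
                          ligand = dataset$condition$ligand,
                          replicate = dataset$condition$replicate,
                          transform_tag = dataset$transform_tag,
                          dose_unit = dataset$dose_unit)
  })
}
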