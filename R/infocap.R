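#' Bin single-cell outputs on a rectangular grid
#'
#' Discretizes the continuous output axis into `n_bins` bins shared across
#' all doses, so that cells fall on an indexed rectangular grid (dose index
#' i, output bin j). Edges are computed from the pooled outputs of all
#' doses: `equal_frequency` uses pooled quantiles (robust to the heavy right
#' tails of reporter fluorescence), `equal_width` splits the pooled range
#' evenly. Bins are half-open `[e_j, e_{j+1})` with the last bin closed, so
#' every cell lands in exactly one bin.
#'
#' Duplicate quantile edges (fewer distinct values than bins) are collapsed;
#' the effective bin count is reported in the `effective_bins` attribute.
#'
#' @param dataset a [dose_response_dataset()].
#' @param n_bins integer >= 2, number of output bins requested.
#' @param scheme `"equal_frequency"` (default) or `"equal_width"`.
#' @return list with `bin_edges` (length effective_bins + 1), `counts`
#'   (matrix N_ij, rows = doses, columns = bins) and `effective_bins`.
#' @export
bin_output <- function(dataset, n_bins,
                       scheme = c("equal_frequency", "equal_width")) {
  stopifnot(inherits(dataset, "dose_response_dataset"))
  scheme <- match.arg(scheme)
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) stop("domain error: n_bins must be >= 2")
  pooled <- unlist(dataset$outputs, use.names = FALSE)
  edges <- pooled_bin_edges(pooled, n_bins, scheme)
  counts <- do.call(rbind, lapply(dataset$outputs, bin_counts, edges))
  rownames(counts) <- format(dataset$doses, trim = TRUE)
  list(bin_edges = edges, counts = counts,
       effective_bins = length(edges) - 1L)
}

pooled_bin_edges <- function(pooled, n_bins, scheme) {
  rng <- range(pooled)
  if (scheme == "equal_width") {
    if (rng[1] == rng[2]) return(c(rng[1], rng[2]))  # single degenerate bin
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  } else {
    probs <- seq(0, 1, length.out = n_bins + 1L)
    edges <- unname(stats::quantile(pooled, probs, type = 7))
    edges <- unique(edges)
    if (length(edges) == 1L) edges <- c(edges, edges)
  }
  edges
}

# Assign values to half-open bins [e_j, e_{j+1}), last bin closed.
bin_counts <- function(values, edges) {
  k <- length(edges) - 1L
  idx <- findInterval(values, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  tabulate(idx, nbins = k)
}

#' Joint input-output distribution on the binned grid
#'
#' Combines the count grid N_ij with an input distribution over doses into
#' the joint probability `P_ij = w_i * N_ij / N_i` (the empirical
#' conditional output distribution of each dose, weighted by the input
#' probability of that dose).
#'
#' @param counts numeric matrix N_ij (rows = doses, columns = output bins),
#'   every row with a positive sum wherever its weight is nonzero.
#' @param input_weights probability vector over doses (sums to 1).
#' @return object of class `joint_distribution` with `counts`, `total`,
#'   `input_weights`, `joint_p`.
#' @export
estimate_joint <- function(counts, input_weights) {
  counts <- as.matrix(counts)
  input_weights <- as.numeric(input_weights)
  if (length(input_weights) != nrow(counts)) {
    stop("one input weight per dose row required")
  }
  if (any(input_weights < 0) || abs(sum(input_weights) - 1) > 1e-9) {
    stop("input_weights must be a probability vector")
  }
  n_i <- rowSums(counts)
  if (any(n_i == 0 & input_weights > 0)) {
    stop("domain error: zero-cell dose with nonzero input weight")
  }
  cond <- counts
  ok <- n_i > 0
  cond[ok, ] <- counts[ok, , drop = FALSE] / n_i[ok]
  joint_p <- input_weights * cond
  structure(list(counts = counts, total = sum(counts),
                 input_weights = input_weights, joint_p = joint_p),
            class = "joint_distribution")
}

#' Entropies and mutual information of a joint distribution
#'
#' Shannon entropies in bits with the `0 log 0 = 0` convention. The mutual
#' information between dose and output is `I_xy = H_x + H_y - H_xy`.
#'
#' @param joint a [estimate_joint()] result, or a joint probability matrix.
#' @return list with `H_x`, `H_y`, `H_xy`, `I_xy` (bits).
#' @export
info_summary <- function(joint) {
  p <- if (inherits(joint, "joint_distribution")) joint$joint_p else as.matrix(joint)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("joint probabilities must be non-negative and sum to 1")
  }
  H <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  H_x <- H(rowSums(p)); H_y <- H(colSums(p)); H_xy <- H(p)
  list(H_x = H_x, H_y = H_y, H_xy = H_xy, I_xy = H_x + H_y - H_xy)
}

# Mutual information (bits) of input distribution p over conditional Q.
mi_bits <- function(p, Q) {
  q_y <- as.vector(p %*% Q)
  tot <- 0
  for (i in seq_along(p)) {
    if (p[i] <= 0) next
    row <- Q[i, ]
    nz <- row > 0
    tot <- tot + p[i] * sum(row[nz] * (log2(row[nz]) - log2(q_y[nz])))
  }
  tot
}

#' Channel capacity of a discrete memoryless channel (Blahut-Arimoto)
#'
#' Alternating maximization of mutual information over input distributions
#' for a channel given by its conditional output matrix. Iterates until the
#' standard upper and lower capacity bounds (max and mean of the per-input
#' divergences D(Q_i || q)) differ by less than `tol`, which brackets the
#' true capacity.
#'
#' @param conditional row-stochastic matrix Q(j|i), rows = inputs.
#' @param tol positive convergence tolerance in bits.
#' @param max_iter iteration cap; reaching it raises a warning reporting the
#'   remaining bounds gap.
#' @return list with `bits` (capacity), `optimal_input` (capacity-achieving
#'   input distribution), `iterations`, `gap`, `converged`.
#' @export
blahut_arimoto <- function(conditional, tol = 1e-9, max_iter = 10000L) {
  Q <- as.matrix(conditional)
  check_stochastic(Q)
  if (!is.finite(tol) || tol <= 0) stop("tol must be positive")
  m <- nrow(Q)
  # drop output columns empty under every input (cannot carry information)
  Q <- Q[, colSums(Q) > 0, drop = FALSE]
  p <- rep(1 / m, m)
  lgQ <- ifelse(Q > 0, log2(Q), 0)
  row_neg_entropy <- rowSums(Q * lgQ)  # sum_j Q_ij log2 Q_ij
  it <- 0L; gap <- Inf
  repeat {
    it <- it + 1L
    q_y <- as.vector(p %*% Q)
    # per-input divergence D(Q_i || q_y) in bits; q_y floored so columns
    # starved of input mass cannot produce NaN (their Q weight is 0 there)
    d <- row_neg_entropy - as.vector(Q %*% log2(pmax(q_y, 1e-300)))
    lower <- sum(p * d)      # = I(p; Q)
    upper <- max(d)
    gap <- upper - lower
    if (gap < tol || it >= max_iter) break
    w <- p * 2^d
    p <- w / sum(w)
  }
  if (gap >= tol) {
    warning("Blahut-Arimoto reached max_iter with bounds gap ",
            format(gap), " bits")
  }
  list(bits = max(0, sum(p * d)), optimal_input = p,
       iterations = it, gap = gap, converged = gap < tol)
}

check_stochastic <- function(Q) {
  if (any(!is.finite(Q)) || any(Q < 0)) {
    stop("domain error: conditional must be non-negative and finite")
  }
  if (any(abs(rowSums(Q) - 1) > 1e-8)) {
    stop("domain error: conditional rows must sum to 1")
  }
  invisible(TRUE)
}

#' Exact capacity of a known discrete channel
#'
#' Analytic oracle for validating capacity estimation on simulated data:
#' runs [blahut_arimoto()] on the specified conditional matrix to a 1e-12
#' bounds gap, which brackets the true capacity of the discrete memoryless
#' channel to that precision.
#'
#' @param conditional row-stochastic matrix Q(j|i).
#' @return capacity in bits (non-negative scalar).
#' @export
true_capacity <- function(conditional) {
  blahut_arimoto(conditional, tol = 1e-12, max_iter = 100000L)$bits
}

#' Estimate channel capacity from a dose-response dataset
#'
#' The full estimator: (1) bin the pooled single-cell outputs
#' ([bin_output()]); (2) form the empirical conditional `P(j|i) = N_ij /
#' N_i`; (3) maximize mutual information over input distributions on the
#' measured dose alphabet with [blahut_arimoto()]; (4) optionally remove the
#' positive finite-sample bias by re-estimating on random subsamples at
#' fractions 0.5-1.0 of the cells per dose and extrapolating a straight
#' line of capacity versus inverse total sample size to infinite data; (5)
#' optionally bootstrap cells within each dose for a 95 percent percentile
#' confidence interval. Deterministic given `seed`.
#'
#' @param dataset a [dose_response_dataset()] with >= 2 doses and >= 50
#'   cells per dose.
#' @param n_bins integer, or `"auto"` to choose by [select_bin_count()].
#' @param bias_correction logical; extrapolate to infinite sample size.
#' @param n_bootstrap integer; 0 disables the confidence interval.
#' @param seed integer seed for subsampling and bootstrap.
#' @param scheme binning scheme, see [bin_output()].
#' @param bin_candidates candidate bin counts used when `n_bins = "auto"`.
#' @param subsample_fractions fractions of cells per dose used for the bias
#'   extrapolation.
#' @param subsample_repeats random subsample repeats per fraction.
#' @return object of class `capacity_estimate`: `bits` (bias-corrected when
#'   requested), `bits_uncorrected`, `ci_low`, `ci_high`, `optimal_input`,
#'   `n_bins`, `effective_bins`, `bias_curve` (data.frame inv_n, bits),
#'   `n_bootstrap`, `seed`, `ci_flag`.
#' @export
estimate_capacity <- function(dataset, n_bins = "auto",
                              bias_correction = TRUE,
                              n_bootstrap = 0L, seed = 1L,
                              scheme = "equal_frequency",
                              bin_candidates = c(8L, 16L, 32L),
                              subsample_fractions = c(0.5, 0.625, 0.75, 0.875, 1),
                              subsample_repeats = 10L,
                              min_cells = 50L) {
  stopifnot(inherits(dataset, "dose_response_dataset"))
  if (length(dataset$doses) < 2L) stop("capacity needs >= 2 doses")
  n_i <- cells_per_dose(dataset)
  if (any(n_i < min_cells)) {
    low <- dataset$doses[which(n_i < min_cells)[1]]
    stop("sample-size error: dose ", format(low), " has fewer than ",
         min_cells, " cells")
  }
  if (identical(n_bins, "auto")) {
    n_bins <- select_bin_count(dataset, candidates = bin_candidates,
                               scheme = scheme, seed = seed,
                               subsample_fractions = subsample_fractions,
                               subsample_repeats = subsample_repeats,
                               min_cells = min_cells)
  }
  n_bins <- as.integer(n_bins)

  point <- capacity_once(dataset$outputs, n_bins, scheme)
  if (point$effective_bins < 2L) {
    stop("degeneracy error: fewer than 2 effective output bins")
  }

  with_local_seed(seed, {
    bias_curve <- NULL
    bits <- point$bits
    if (bias_correction) {
      fit <- bias_extrapolate(dataset$outputs, n_bins, scheme,
                              subsample_fractions, subsample_repeats)
      bias_curve <- fit$curve
      bits <- fit$intercept
    }
    ci_low <- NA_real_; ci_high <- NA_real_; ci_flag <- FALSE
    if (n_bootstrap > 0L) {
      boots <- vapply(seq_len(n_bootstrap), function(b) {
        res <- lapply(dataset$outputs, function(v) {
          v[sample.int(length(v), length(v), replace = TRUE)]
        })
        if (bias_correction) {
          bias_extrapolate(res, n_bins, scheme,
                           subsample_fractions, subsample_repeats)$intercept
        } else {
          capacity_once(res, n_bins, scheme)$bits
        }
      }, numeric(1))
      qs <- unname(stats::quantile(boots, c(0.025, 0.975), type = 7))
      ci_low <- qs[1]; ci_high <- qs[2]
      ci_flag <- !(ci_low <= bits && bits <= ci_high)
    }
    structure(list(bits = bits, bits_uncorrected = point$bits,
                   ci_low = ci_low, ci_high = ci_high,
                   optimal_input = point$optimal_input,
                   n_bins = n_bins, effective_bins = point$effective_bins,
                   bias_curve = bias_curve, n_bootstrap = as.integer(n_bootstrap),
                   seed = as.integer(seed), ci_flag = ci_flag,
                   doses = dataset$doses),
              class = "capacity_estimate")
  })
}

#' @export
print.capacity_estimate <- function(x, ...) {
  cat("<capacity_estimate> ", format(round(x$bits, 4)), " bits", sep = "")
  if (!is.na(x$ci_low)) {
    cat(" [95% CI ", format(round(x$ci_low, 4)), ", ",
        format(round(x$ci_high, 4)), "]", sep = "")
  }
  cat("\n  bins: ", x$n_bins, " (effective ", x$effective_bins,
      "); uncorrected ", format(round(x$bits_uncorrected, 4)), " bits\n",
      sep = "")
  invisible(x)
}

# One pass: bin outputs, form empirical conditional, run Blahut-Arimoto.
capacity_once <- function(outputs, n_bins, scheme) {
  pooled <- unlist(outputs, use.names = FALSE)
  edges <- pooled_bin_edges(pooled, n_bins, scheme)
  counts <- do.call(rbind, lapply(outputs, bin_counts, edges))
  eff <- sum(colSums(counts) > 0)
  if (eff < 2L) {
    return(list(bits = 0, optimal_input = rep(1 / nrow(counts), nrow(counts)),
                effective_bins = eff))
  }
  cond <- counts / rowSums(counts)
  ba <- blahut_arimoto(cond, tol = 1e-4, max_iter = 50000L)
  list(bits = ba$bits, optimal_input = ba$optimal_input,
       effective_bins = eff)
}

# Capacity vs 1/N line fit over random subsamples; intercept is the
# infinite-data extrapolation (finite-sample capacity bias is positive on
# average, so the intercept lies below the full-sample estimate).
bias_extrapolate <- function(outputs, n_bins, scheme, fractions, repeats) {
  n_i <- vapply(outputs, length, integer(1))
  inv_n <- numeric(0); caps <- numeric(0)
  for (f in fractions) {
    keep <- pmax(2L, floor(f * n_i))
    if (f >= 1) {
      # full-sample subsamples are all identical; compute once, keep the
      # repeat weight in the regression
      cap <- capacity_once(outputs, n_bins, scheme)$bits
      caps <- c(caps, rep(cap, repeats))
      inv_n <- c(inv_n, rep(1 / sum(n_i), repeats))
    } else {
      for (r in seq_len(repeats)) {
        sub <- mapply(function(v, k) v[sample.int(length(v), k)], outputs,
                      keep, SIMPLIFY = FALSE)
        caps <- c(caps, capacity_once(sub, n_bins, scheme)$bits)
        inv_n <- c(inv_n, 1 / sum(keep))
      }
    }
  }
  fit <- stats::lm(caps ~ inv_n)
  list(intercept = max(0, unname(stats::coef(fit)[1])),
       curve = data.frame(inv_n = inv_n, bits = caps))
}

#' Capacity as a function of the maximum dose
#'
#' Re-estimates channel capacity on every prefix of the ascending dose
#' series of length >= 2 (the unstimulated dose, the first element, is
#' always retained), tracing how much information the channel carries when
#' the stimulant range is capped at increasing maximum concentrations.
#'
#' @inheritParams estimate_capacity
#' @param ... passed to [estimate_capacity()].
#' @return data.frame with one row per prefix: `max_dose`, `n_doses`,
#'   `bits`, `ci_low`, `ci_high`; the estimates themselves in attribute
#'   `"estimates"`.
#' @export
capacity_vs_max_dose <- function(dataset, ...) {
  stopifnot(inherits(dataset, "dose_response_dataset"))
  d <- length(dataset$doses)
  if (d < 2L) stop("capacity needs >= 2 doses")
  ests <- lapply(2:d, function(k) {
    estimate_capacity(restrict_doses(dataset, k), ...)
  })
  out <- data.frame(
    max_dose = dataset$doses[2:d],
    n_doses = 2:d,
    bits = vapply(ests, function(e) e$bits, numeric(1)),
    ci_low = vapply(ests, function(e) e$ci_low, numeric(1)),
    ci_high = vapply(ests, function(e) e$ci_high, numeric(1))
  )
  attr(out, "estimates") <- ests
  out
}

#' Choose an output bin count by plateau stability
#'
#' Runs the bias-corrected estimator at each candidate bin count and
#' returns the smallest candidate whose estimate lies within 0.02 bits of
#' the median across candidates — the beginning of the plateau where the
#' estimate has stopped depending on the discretization. If no plateau
#' exists (range across candidates > 0.2 bits) a warning is raised and the
#' median candidate is returned.
#'
#' @inheritParams estimate_capacity
#' @param candidates integer vector (>= 2 values, each >= 2) of bin counts
#'   to profile.
#' @return the selected integer bin count, with the full profile
#'   (data.frame `n_bins`, `bits`) in attribute `"profile"`.
#' @export
select_bin_count <- function(dataset, candidates = c(8L, 16L, 32L),
                             scheme = "equal_frequency", seed = 1L,
                             subsample_fractions = c(0.5, 0.625, 0.75, 0.875, 1),
                             subsample_repeats = 10L, min_cells = 50L) {
  candidates <- sort(unique(as.integer(candidates)))
  if (length(candidates) < 2L || any(candidates < 2L)) {
    stop("domain error: need >= 2 candidate bin counts, each >= 2")
  }
  bits <- vapply(candidates, function(k) {
    estimate_capacity(dataset, n_bins = k, bias_correction = TRUE,
                      n_bootstrap = 0L, seed = seed, scheme = scheme,
                      subsample_fractions = subsample_fractions,
                      subsample_repeats = subsample_repeats,
                      min_cells = min_cells)$bits
  }, numeric(1))
  med <- stats::median(bits)
  if (diff(range(bits)) > 0.2) {
    warning("no binning plateau: capacity range across candidates is ",
            format(diff(range(bits))), " bits; returning the median candidate")
    sel <- candidates[ceiling(length(candidates) / 2)]
  } else {
    ok <- which(abs(bits - med) <= 0.02)
    sel <- if (length(ok) > 0) candidates[min(ok)] else
      candidates[which.min(abs(bits - med))]
  }
  structure(sel, profile = data.frame(n_bins = candidates, bits = bits))
}
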