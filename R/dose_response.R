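#' Four-parameter logistic dose-response prediction
#'
#' `y = bottom + (top - bottom) / (1 + (ec50 / x)^hill)`, evaluated at
#' `x = 0` in the limit (`y -> bottom` for `hill > 0`), so an unstimulated
#' control anchors the lower asymptote.
#'
#' @param x doses (non-negative).
#' @param bottom,top lower and upper asymptotes.
#' @param ec50 dose of half-maximal response (positive).
#' @param hill Hill slope (positive).
#' @return predicted responses.
#' @export
predict_4pl <- function(x, bottom, top, ec50, hill) {
  y <- rep(bottom, length(x))
  pos <- x > 0
  y[pos] <- bottom + (top - bottom) / (1 + (ec50 / x[pos])^hill)
  y
}

rss_4pl <- function(par, x, y, w) {
  # par = (bottom, top, log10 ec50, hill)
  pred <- predict_4pl(x, par[1], par[2], 10^par[3], par[4])
  sum(w * (y - pred)^2)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of the 4PL model, parameterized internally in
#' log10(EC50) for stable optimization over concentration decades.
#' Initialization takes bottom/top from the response extremes and EC50 from
#' the dose nearest the half-range crossing; a small multi-start over Hill
#' slopes {0.5, 1, 2} guards against local minima, keeping the best-RSS
#' solution. Bounds: hill in [0.1, 10]; EC50 within [min positive dose /
#' 100, max dose x 100] so flat data cannot drive the midpoint to infinity.
#' Non-convergence is flagged on the returned fit, not raised.
#'
#' @param doses non-negative doses, >= 4 distinct positive values (a dose 0
#'   control is allowed and anchors `bottom`).
#' @param responses finite responses, one per dose point.
#' @param weights optional non-negative weights (default 1).
#' @return object of class `dose_response_fit` with `bottom`, `top`,
#'   `ec50`, `hill`, `rss`, `n_points`, `converged`.
#' @export
fit_4pl <- function(doses, responses, weights = NULL) {
  x <- as.numeric(doses); y <- as.numeric(responses)
  if (length(x) != length(y)) stop("doses and responses must match in length")
  if (any(!is.finite(x)) || any(x < 0)) stop("doses must be finite and >= 0")
  if (any(!is.finite(y))) stop("responses must be finite")
  if (length(unique(x[x > 0])) < 4L) {
    stop("domain error: >= 4 distinct positive doses required")
  }
  w <- if (is.null(weights)) rep(1, length(x)) else as.numeric(weights)
  if (length(w) != length(x) || any(w < 0)) stop("bad weights")

  xp <- sort(unique(x[x > 0]))
  lo <- c(-Inf, -Inf, log10(min(xp) / 100), 0.1)
  hi <- c(Inf, Inf, log10(max(xp) * 100), 10)
  b0 <- min(y); t0 <- max(y)
  half <- (b0 + t0) / 2
  e0 <- xp[which.min(abs(vapply(xp, function(d)
    mean(y[x == d]), numeric(1)) - half))]

  best <- NULL
  for (h0 in c(0.5, 1, 2)) {
    fit <- tryCatch(
      stats::optim(c(b0, t0, log10(e0), h0), rss_4pl, x = x, y = y, w = w,
                   method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 1000, factr = 1e4, ndeps = rep(1e-6, 4))),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence != 0) {
      # a restart from the candidate optimum distinguishes line-search
      # breakdown at the solution (common when RSS is near zero) from a
      # genuinely unconverged fit
      fit2 <- tryCatch(
        stats::optim(fit$par, rss_4pl, x = x, y = y, w = w,
                     method = "L-BFGS-B", lower = lo, upper = hi,
                     control = list(maxit = 1000, factr = 1e4, ndeps = rep(1e-6, 4))),
        error = function(e) NULL)
      if (!is.null(fit2)) {
        if (fit2$convergence == 0 ||
            abs(fit2$value - fit$value) <= 1e-10 * (1 + abs(fit$value))) {
          fit2$convergence <- 0
        }
        if (fit2$value <= fit$value) fit <- fit2
      }
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(bottom = NA_real_, top = NA_real_, ec50 = NA_real_,
                          hill = NA_real_, rss = NA_real_,
                          n_points = length(x), converged = FALSE,
                          message = "all optimizer starts failed"),
                     class = "dose_response_fit"))
  }
  structure(list(bottom = best$par[1], top = best$par[2],
                 ec50 = 10^best$par[3], hill = best$par[4],
                 rss = best$value, n_points = length(x),
                 converged = best$convergence == 0,
                 message = best$message %||% ""),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("<dose_response_fit> EC50 ", format(signif(x$ec50, 5)),
      ", hill ", format(signif(x$hill, 4)),
      ", bottom ", format(signif(x$bottom, 4)),
      ", top ", format(signif(x$top, 4)),
      ", RSS ", format(signif(x$rss, 4)),
      if (!x$converged) " (NOT converged)" else "", "\n", sep = "")
  invisible(x)
}

#' Fold change in sensitivity between two fitted curves
#'
#' `ec50_a / ec50_b` with `a` the reference: values above 1 mean channel
#' `b` responds at lower stimulant concentrations (is more sensitive).
#'
#' @param fit_a,fit_b converged [fit_4pl()] results.
#' @return positive scalar fold change.
#' @export
ec50_fold_change <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "dose_response_fit"),
            inherits(fit_b, "dose_response_fit"))
  if (!isTRUE(fit_a$converged) || !isTRUE(fit_b$converged)) {
    stop("domain error: both fits must have converged")
  }
  fit_a$ec50 / fit_b$ec50
}

# Joint RSS of two datasets sharing log10(ec50), all other parameters free.
rss_shared_ec50 <- function(par, xa, ya, wa, xb, yb, wb) {
  # par = (bottom_a, top_a, hill_a, bottom_b, top_b, hill_b, shared lec50)
  e <- 10^par[7]
  sum(wa * (ya - predict_4pl(xa, par[1], par[2], e, par[3]))^2) +
    sum(wb * (yb - predict_4pl(xb, par[4], par[5], e, par[6]))^2)
}

#' Compare two EC50s with the extra-sum-of-squares F test
#'
#' Fits a full model (separate 4PL per dataset, 8 parameters) and a null
#' model sharing a single EC50 (7 parameters; bottom, top and hill stay
#' per-dataset), then tests whether freeing the EC50 improves the fit:
#' `F = ((RSS_null - RSS_full) / 1) / (RSS_full / df_full)` with
#' `df_full = n_a + n_b - 8`.
#'
#' @param doses_a,responses_a,doses_b,responses_b the two dose-response
#'   datasets, each satisfying [fit_4pl()] preconditions.
#' @return list with `F`, `df1` (= 1), `df2`, `p_value`, `fit_a`, `fit_b`,
#'   `rss_null`, `rss_full`.
#' @export
compare_ec50_f_test <- function(doses_a, responses_a, doses_b, responses_b) {
  fa <- fit_4pl(doses_a, responses_a)
  fb <- fit_4pl(doses_b, responses_b)
  if (!isTRUE(fa$converged) || !isTRUE(fb$converged)) {
    stop("diagnostics error: a per-dataset 4PL fit did not converge")
  }
  xa <- as.numeric(doses_a); ya <- as.numeric(responses_a)
  xb <- as.numeric(doses_b); yb <- as.numeric(responses_b)
  wa <- rep(1, length(xa)); wb <- rep(1, length(xb))
  rss_full <- fa$rss + fb$rss
  df_full <- length(xa) + length(xb) - 8L

  xp <- sort(unique(c(xa[xa > 0], xb[xb > 0])))
  lo <- c(-Inf, -Inf, 0.1, -Inf, -Inf, 0.1, log10(min(xp) / 100))
  hi <- c(Inf, Inf, 10, Inf, Inf, 10, log10(max(xp) * 100))
  starts <- list(
    c(fa$bottom, fa$top, fa$hill, fb$bottom, fb$top, fb$hill,
      log10(sqrt(fa$ec50 * fb$ec50))),
    c(fa$bottom, fa$top, fa$hill, fb$bottom, fb$top, fb$hill,
      log10(fa$ec50)),
    c(fa$bottom, fa$top, fa$hill, fb$bottom, fb$top, fb$hill,
      log10(fb$ec50))
  )
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, rss_shared_ec50, xa = xa, ya = ya, wa = wa,
                   xb = xb, yb = yb, wb = wb,
                   method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 1000, factr = 1e4, ndeps = rep(1e-6, 7))),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("diagnostics error: shared-EC50 fit failed")
  polish <- tryCatch(
    stats::optim(best$par, rss_shared_ec50, xa = xa, ya = ya, wa = wa,
                 xb = xb, yb = yb, wb = wb,
                 method = "L-BFGS-B", lower = lo, upper = hi,
                 control = list(maxit = 1000, factr = 1e4, ndeps = rep(1e-6, 7))),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value < best$value) best <- polish
  rss_null <- best$value
  scale <- sum(ya^2) + sum(yb^2)
  if (rss_full <= 1e-12 * max(scale, 1)) {
    # both curves fit essentially exactly; the extra parameter explains
    # nothing measurable
    if (rss_null - rss_full <= 1e-12 * max(scale, 1)) {
      return(list(F = 0, df1 = 1L, df2 = df_full, p_value = 1,
                  fit_a = fa, fit_b = fb,
                  rss_null = rss_null, rss_full = rss_full))
    }
    return(list(F = Inf, df1 = 1L, df2 = df_full, p_value = 0,
                fit_a = fa, fit_b = fb,
                rss_null = rss_null, rss_full = rss_full))
  }
  Fstat <- max(0, (rss_null - rss_full) / 1) / (rss_full / df_full)
  list(F = Fstat, df1 = 1L, df2 = df_full,
       p_value = stats::pf(Fstat, 1, df_full, lower.tail = FALSE),
       fit_a = fa, fit_b = fb, rss_null = rss_null, rss_full = rss_full)
}

#' Per-dose response summary for curve fitting
#'
#' Collapses a single-cell dataset to one response value per dose. The
#' default is the geometric mean of per-cell fluorescence, computed from
#' log10-scale outputs as `10^mean`; `"mean"` averages the transformed
#' outputs directly.
#'
#' @param dataset a [dose_response_dataset()] whose outputs are on a log10
#'   scale.
#' @param statistic `"geometric_mean"` (default) or `"mean"`.
#' @return data.frame with columns `dose` and `response`.
#' @export
dose_response_summary <- function(dataset,
                                  statistic = c("geometric_mean", "mean")) {
  stopifnot(inherits(dataset, "dose_response_dataset"))
  statistic <- match.arg(statistic)
  m <- vapply(dataset$outputs, mean, numeric(1))
  data.frame(dose = dataset$doses,
             response = if (statistic == "geometric_mean") 10^m else m)
}
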