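#' Continuous dose-response modeling with model-5 Hill and Exponential families
#'
#' The two four-parameter families recommended for continuous endpoints are
#' fitted by maximum likelihood with multiplicative lognormal errors (normal
#' errors on the log response):
#' \deqn{exponential5: y = a\,[c - (c-1)\exp(-(x/b)^d)]}
#' \deqn{hill5:        y = a\,[1 + (c-1)\,x^d/(b^d + x^d)]}
#' with background `a > 0`, potency `b > 0` (uM), maximum fold change `c > 1`
#' for an increasing response, and shape `d > 0`. A constant (null) model
#' serves as the no-response reference for AIC selection.
#'
#' @name bmc_model
NULL

## model curve; x may contain 0 (both families return a at x = 0)
.dr_curve <- function(family, x, a, b, c, d) {
  switch(family,
    exponential5 = a * (c - (c - 1) * exp(-(x / b)^d)),
    hill5 = a * (1 + (c - 1) * x^d / (b^d + x^d)),
    null_constant = rep(a, length(x)),
    stop("unknown family: ", family)
  )
}

#' Replace zero responses ahead of the log transform
#'
#' Percent endpoints can be exactly zero at low concentrations; the lognormal
#' error model needs positive responses. Zeros are replaced by half the
#' smallest positive observed response in the dataset, and the number of
#' replacements is recorded in attribute `"n_zero_replaced"`.
#'
#' @param responses Numeric responses (>= 0).
#' @return Positive responses with the attribute set.
#' @export
handle_zero_responses <- function(responses) {
  zero <- responses == 0
  if (any(zero)) {
    pos <- responses[responses > 0]
    if (!length(pos)) stop("all responses are zero; nothing to model")
    responses[zero] <- min(pos) / 2
  }
  attr(responses, "n_zero_replaced") <- sum(zero)
  responses
}

.lognormal_loglik <- function(sse, n, logy_sum) {
  sig2 <- max(sse / n, 1e-12)
  -n / 2 * (log(2 * pi * sig2) + 1) - logy_sum
}

#' Fit one dose-response family
#'
#' Maximum-likelihood fit under the lognormal error model, using a
#' deterministic multi-start Nelder-Mead search over log-transformed
#' parameters (start grid: `a` from the lowest-concentration responses, `b`
#' over concentration quartiles, `c` from the observed maximum fold change,
#' `d` over 0.5/1/2). AIC is `2k - 2 logLik` with `k` = number of curve
#' parameters plus one for the residual variance.
#'
#' @param concentrations Concentrations in uM (>= 0; may include 0).
#' @param responses Positive responses (percent endpoint); see
#'   [handle_zero_responses()].
#' @param family `"exponential5"`, `"hill5"`, or `"null_constant"`.
#' @param d_max Upper bound on the shape parameter `d` (default 4).
#'   Unconstrained fits can collapse to step-like curves with implausibly
#'   steep slopes and degenerate confidence intervals; bounding the shape is
#'   standard benchmark-dose practice.
#' @return Object of class `dose_response_fit`: list with `family`, `a`, `b`,
#'   `c`, `d`, `sigma` (residual sd on the log scale), `log_likelihood`,
#'   `aic`, `n_points`, `max_modeled_concentration`, `converged`.
#' @export
fit_family <- function(concentrations,
                       responses,
                       family = c("exponential5", "hill5", "null_constant"),
                       d_max = 4) {
  family <- match.arg(family)
  x <- as.numeric(concentrations)
  y <- as.numeric(responses)
  if (length(x) != length(y)) stop("length mismatch")
  if (any(y <= 0)) stop("responses must be positive (see handle_zero_responses)")
  n <- length(y)
  logy <- log(y)
  logy_sum <- sum(logy)

  if (family == "null_constant") {
    if (n < 1) stop("need at least one point")
    a <- exp(mean(logy))
    sse <- sum((logy - mean(logy))^2)
    ll <- .lognormal_loglik(sse, n, logy_sum)
    return(.dr_fit(family, a, NA, NA, NA, sqrt(max(sse / n, 0)), ll,
      2 * 2 - 2 * ll, n, max(x), TRUE))
  }

  if (n < 5) stop("need at least 5 points for a 4-parameter family")

  sse_fun <- function(th) {
    a <- exp(th[1]); b <- exp(th[2]); c <- 1 + exp(th[3]); d <- exp(th[4])
    if (d > d_max) {
      return(1e10)
    }
    mu <- .dr_curve(family, x, a, b, c, d)
    if (any(!is.finite(mu)) || any(mu <= 0)) {
      return(1e10)
    }
    sum((logy - log(mu))^2)
  }

  xlow <- x == min(x)
  a0 <- exp(mean(logy[xlow]))
  c0 <- max(max(y) / a0, 1.2)
  pos <- x[x > 0]
  b_grid <- unique(quantile(pos, c(0.25, 0.5, 0.75), type = 7))
  d_grid <- c(0.5, 1, 2)
  best <- NULL
  for (b0 in b_grid) {
    for (d0 in d_grid) {
      th0 <- c(log(a0), log(b0), log(c0 - 1), log(d0))
      opt <- tryCatch(
        optim(th0, sse_fun, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-12)),
        error = function(e) NULL
      )
      if (!is.null(opt) && is.finite(opt$value) &&
        (is.null(best) || opt$value < best$value)) {
        best <- opt
      }
    }
  }
  if (is.null(best) || best$value >= 1e10) {
    return(.dr_fit(family, NA, NA, NA, NA, NA, NA, NA, n, max(x), FALSE, d_max))
  }
  th <- best$par
  sse <- best$value
  ll <- .lognormal_loglik(sse, n, logy_sum)
  .dr_fit(
    family, exp(th[1]), exp(th[2]), 1 + exp(th[3]), exp(th[4]),
    sqrt(max(sse / n, 0)), ll, 2 * 5 - 2 * ll, n, max(x), TRUE, d_max
  )
}

.dr_fit <- function(family, a, b, c, d, sigma, ll, aic, n, xmax, converged,
                    d_max = NA_real_) {
  structure(
    list(
      family = family, a = a, b = b, c = c, d = d, sigma = sigma,
      log_likelihood = ll, aic = aic, n_points = n,
      max_modeled_concentration = xmax, converged = converged, d_max = d_max
    ),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("<dose_response_fit> ", x$family,
    if (!x$converged) " (not converged)", "\n", sep = "")
  if (x$converged && x$family != "null_constant") {
    cat(sprintf(
      "  a = %.4g  b = %.4g uM  c = %.4g  d = %.4g  sigma = %.3g\n",
      x$a, x$b, x$c, x$d, x$sigma
    ))
  } else if (x$converged) {
    cat(sprintf("  a = %.4g\n", x$a))
  }
  cat(sprintf("  logLik = %.3f  AIC = %.3f  n = %d\n",
    x$log_likelihood, x$aic, x$n_points))
  invisible(x)
}

#' Select a model by AIC against the constant reference
#'
#' The best converged full-family fit is retained only when its AIC beats the
#' constant model by more than `aic_margin`; otherwise the dataset is declared
#' to have no concentration-response.
#'
#' @param fits List of `dose_response_fit` objects including a
#'   `null_constant` fit and at least one full family.
#' @param aic_margin AIC improvement required over the constant model
#'   (default 2).
#' @return List of class `model_selection` with `fit` (the chosen
#'   `dose_response_fit`, or `NULL`), `no_response` (logical), `reason`, and
#'   `aic` (named vector of the candidate AICs).
#' @export
select_model <- function(fits, aic_margin = 2) {
  fams <- vapply(fits, function(f) f$family, character(1))
  if (!"null_constant" %in% fams) stop("fits must include a null_constant fit")
  null_fit <- fits[[match("null_constant", fams)]]
  full <- fits[fams != "null_constant"]
  full <- full[vapply(full, function(f) isTRUE(f$converged), logical(1))]
  aics <- setNames(
    vapply(fits, function(f) f$aic, numeric(1)),
    fams
  )
  if (!length(full)) {
    return(structure(
      list(fit = NULL, no_response = TRUE, reason = "no_converged_fit", aic = aics),
      class = "model_selection"
    ))
  }
  best <- full[[which.min(vapply(full, function(f) f$aic, numeric(1)))]]
  if (best$aic < null_fit$aic - aic_margin) {
    structure(
      list(fit = best, no_response = FALSE, reason = "aic", aic = aics),
      class = "model_selection"
    )
  } else {
    structure(
      list(fit = NULL, no_response = TRUE, reason = "no_dose_response", aic = aics),
      class = "model_selection"
    )
  }
}

#' Benchmark concentration from a fitted curve
#'
#' Inverts the fitted model at the benchmark response, a fractional increase
#' over background (`y = a (1 + bmr)`):
#' \deqn{hill5:         BMC = b\,(bmr/(c-1-bmr))^{1/d}}
#' \deqn{exponential5:  BMC = b\,(-\ln((c-1-bmr)/(c-1)))^{1/d}}
#' When the fitted plateau is below the benchmark response (`c <= 1 + bmr`)
#' the BMC does not exist and `NA` is returned.
#'
#' @param fit A `dose_response_fit`.
#' @param bmr Benchmark response as a fractional increase (0.30 for %MN,
#'   0.60 for %hypodiploid).
#' @return BMC in uM, or `NA`.
#' @export
bmc_from_fit <- function(fit, bmr) {
  stopifnot(inherits(fit, "dose_response_fit"), bmr > 0)
  if (fit$family == "null_constant" || !isTRUE(fit$converged)) {
    return(NA_real_)
  }
  if (fit$c <= 1 + bmr) {
    return(NA_real_)
  }
  switch(fit$family,
    hill5 = fit$b * (bmr / ((fit$c - 1) - bmr))^(1 / fit$d),
    exponential5 = fit$b * (-log((fit$c - 1 - bmr) / (fit$c - 1)))^(1 / fit$d)
  )
}

#' Profile-likelihood confidence bounds for the BMC
#'
#' The likelihood is reparameterized so the BMC is itself a parameter
#' (`b` is recovered from `(bmc, c, d)`), and the two-sided bounds at
#' `level` are where the profile deviance crosses the F-calibrated threshold
#' `n log(1 + qF(level, 1, n-4)/(n-4))` — the standard small-sample
#' calibration for nonlinear regression with estimated residual variance.
#' An upper bound that never crosses within a wide search range is reported
#' as `NA` with `unbounded_upper = TRUE`.
#'
#' @param fit Selected full-family `dose_response_fit`.
#' @param concentrations,responses The data the fit was computed from
#'   (responses already zero-handled).
#' @param bmr Benchmark response (fractional increase).
#' @param level Two-sided confidence level (default 0.90).
#' @return List with `bmcl`, `bmcu`, `level`, `unbounded_upper`.
#' @export
bmc_confidence <- function(fit, concentrations, responses, bmr, level = 0.90) {
  stopifnot(inherits(fit, "dose_response_fit"))
  bmc_hat <- bmc_from_fit(fit, bmr)
  if (is.na(bmc_hat)) {
    return(list(bmcl = NA_real_, bmcu = NA_real_, level = level,
      unbounded_upper = FALSE))
  }
  x <- as.numeric(concentrations)
  y <- as.numeric(responses)
  n <- length(y)
  logy <- log(y)
  family <- fit$family

  b_from_bmc <- function(bmc, c, d) {
    g <- switch(family,
      hill5 = (bmr / (c - 1 - bmr))^(1 / d),
      exponential5 = (-log((c - 1 - bmr) / (c - 1)))^(1 / d)
    )
    bmc / g
  }

  th_hat <- c(log(fit$a), log(fit$c - 1 - bmr), log(fit$d))

  ## inner maximization over (a, c, d) at fixed BMC; started from both the
  ## global optimum and the previous profile step so the profile envelope is
  ## tracked tightly
  d_max <- if (is.null(fit$d_max) || is.na(fit$d_max)) Inf else fit$d_max
  prof_sse <- function(bmc, th_start) {
    obj <- function(th) {
      a <- exp(th[1]); c <- 1 + bmr + exp(th[2]); d <- exp(th[3])
      if (d > d_max) {
        return(1e10)
      }
      b <- b_from_bmc(bmc, c, d)
      mu <- .dr_curve(family, x, a, b, c, d)
      if (any(!is.finite(mu)) || any(mu <= 0)) {
        return(1e10)
      }
      sum((logy - log(mu))^2)
    }
    best <- NULL
    for (th0 in unique(list(th_start, th_hat))) {
      opt <- tryCatch(
        optim(th0, obj, method = "Nelder-Mead",
          control = list(maxit = 1000, reltol = 1e-10)),
        error = function(e) NULL
      )
      if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
    }
    if (is.null(best)) list(value = 1e10, par = th_start) else best
  }

  sse_hat <- n * fit$sigma^2
  ## re-polish at the point estimate: the profile at bmc_hat is a valid
  ## candidate for the global optimum under the reparameterization
  sse_hat <- min(sse_hat, prof_sse(bmc_hat, th_hat)$value)
  thresh <- n * log(1 + qf(level, 1, n - 4) / (n - 4))
  dev_of <- function(sse) n * (log(max(sse, 1e-12)) - log(max(sse_hat, 1e-12)))

  walk <- function(direction) {
    factor <- if (direction < 0) 1 / 1.4 else 1.4
    th <- th_hat
    prev_bmc <- bmc_hat
    prev_dev <- 0
    for (i in 1:80) {
      bmc_i <- prev_bmc * factor
      if (direction > 0 && bmc_i > 1e6 * max(x)) {
        return(list(bound = NA_real_, unbounded = TRUE))
      }
      if (direction < 0 && bmc_i < bmc_hat * 1e-12) {
        return(list(bound = NA_real_, unbounded = TRUE))
      }
      opt <- prof_sse(bmc_i, th)
      dev_i <- dev_of(opt$value)
      if (dev_i >= thresh) {
        root <- tryCatch(
          uniroot(
            function(lb) dev_of(prof_sse(exp(lb), th)$value) - thresh,
            lower = min(log(prev_bmc), log(bmc_i)),
            upper = max(log(prev_bmc), log(bmc_i)),
            tol = 1e-4
          ),
          error = function(e) NULL
        )
        if (is.null(root)) {
          return(list(bound = bmc_i, unbounded = FALSE))
        }
        return(list(bound = exp(root$root), unbounded = FALSE))
      }
      th <- opt$par
      prev_bmc <- bmc_i
      prev_dev <- dev_i
    }
    list(bound = NA_real_, unbounded = TRUE)
  }

  lo <- walk(-1)
  hi <- walk(+1)
  list(
    bmcl = lo$bound, bmcu = hi$bound, level = level,
    unbounded_upper = isTRUE(hi$unbounded)
  )
}

#' Full dose-response analysis of one dataset
#'
#' Convenience wrapper: zero-handling, fits of the constant and both full
#' families, AIC selection, BMC inversion, and (optionally) the 90 percent
#' profile-likelihood interval.
#'
#' @param concentrations,responses Data for one chemical x S9 condition
#'   (non-cytotoxic and adequate concentrations plus the concurrent control).
#' @param bmr Benchmark response (fractional increase).
#' @param aic_margin See [select_model()].
#' @param ci Logical; compute the profile interval (default `FALSE`).
#' @param level Confidence level for the interval.
#' @param d_max Shape-parameter bound, see [fit_family()].
#' @return List with `selection` ([select_model()] result), `fits`, `bmc`,
#'   `bmcl`, `bmcu`, `n_zero_replaced`.
#' @export
fit_dose_response <- function(concentrations, responses, bmr = 0.30,
                              aic_margin = 2, ci = FALSE, level = 0.90,
                              d_max = 4) {
  y <- handle_zero_responses(responses)
  fits <- lapply(
    c("null_constant", "exponential5", "hill5"),
    function(f) {
      tryCatch(fit_family(concentrations, y, f, d_max = d_max),
        error = function(e) NULL)
    }
  )
  fits <- fits[!vapply(fits, is.null, logical(1))]
  sel <- select_model(fits, aic_margin = aic_margin)
  bmc <- if (!sel$no_response) bmc_from_fit(sel$fit, bmr) else NA_real_
  bmcl <- bmcu <- NA_real_
  if (ci && !is.na(bmc)) {
    cires <- bmc_confidence(sel$fit, concentrations, y, bmr, level)
    bmcl <- cires$bmcl
    bmcu <- cires$bmcu
  }
  list(
    selection = sel, fits = fits, bmc = bmc, bmcl = bmcl, bmcu = bmcu,
    n_zero_replaced = attr(y, "n_zero_replaced")
  )
}
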