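# Internal Levenberg-Marquardt wrapper shared by all curve fits: multi-start
# with deterministic jitter, clean failure conditions, and a uniform summary.

fk_with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Jittered copies of a start list (multiplicative +-jitter; additive for
# zero-valued starts). Deterministic: jitter draws use a fixed local seed so
# repeated fits of the same data are identical.
fk_jitter_starts <- function(start, n, jitter) {
  if (n <= 0L) return(list())
  fk_with_seed(190283L, lapply(seq_len(n), function(i) {
    lapply(start, function(v) {
      f <- stats::runif(length(v), 1 - jitter, 1 + jitter)
      a <- stats::runif(length(v), -jitter, jitter)
      ifelse(v == 0, a, v * f)
    })
  }))
}

fk_fit_nls <- function(formula, data, start, lower = NULL, upper = NULL,
                       weights = NULL, n_starts = 5L, jitter = 0.2,
                       extra_starts = list(), context = "model") {
  if (nrow(data) < length(start))
    fk_invalid_input(sprintf("%s fit: fewer points (%d) than parameters (%d)",
                             context, nrow(data), length(start)))
  ctrl <- minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-13, ptol = 1e-13)
  starts <- c(list(start), extra_starts,
              fk_jitter_starts(start, n_starts - 1L, jitter))
  best <- NULL
  best_dev <- Inf
  last_err <- NULL
  for (s in starts) {
    args <- list(formula, data = data, start = s, control = ctrl)
    if (!is.null(lower)) args$lower <- lower
    if (!is.null(upper)) args$upper <- upper
    if (!is.null(weights)) {
      data$.fk_w <- weights
      args$data <- data
      args$weights <- quote(.fk_w)
    }
    fit <- tryCatch(do.call(minpack.lm::nlsLM, args), error = identity,
                    warning = identity)
    if (inherits(fit, "condition")) {
      last_err <- fit
      next
    }
    dev <- stats::deviance(fit)
    if (is.finite(dev) && dev < best_dev) {
      best <- fit
      best_dev <- dev
    }
  }
  if (is.null(best)) {
    msg <- if (is.null(last_err)) "no start converged"
           else conditionMessage(last_err)
    fk_fit_failure(sprintf("%s fit did not converge after %d starts (%s)",
                           context, length(starts), msg),
                   best_residual = best_dev)
  }
  best
}

# Uniform extraction of parameters, asymptotic errors and covariance.
fk_fit_summary <- function(fit) {
  par <- stats::coef(fit)
  V <- tryCatch(stats::vcov(fit), error = function(e) {
    matrix(NA_real_, length(par), length(par),
           dimnames = list(names(par), names(par)))
  })
  se <- sqrt(pmax(diag(V), 0))
  names(se) <- names(par)
  list(par = par, se = se, cov = V,
       deviance = stats::deviance(fit),
       sigma = tryCatch(summary(fit)$sigma, error = function(e) NA_real_),
       fitted = as.numeric(stats::fitted(fit)),
       residuals = as.numeric(stats::resid(fit)),
       aic = tryCatch(stats::AIC(fit), error = function(e) NA_real_),
       n = length(stats::resid(fit)))
}

# Linear baseline estimates from the outer `frac` of points at each end.
fk_edge_baselines <- function(x, y, frac = 0.2) {
  n <- length(x)
  k <- max(2L, ceiling(frac * n))
  lo <- seq_len(k)
  hi <- seq(n - k + 1L, n)
  fit_lo <- stats::coef(stats::lm(y[lo] ~ x[lo]))
  fit_hi <- stats::coef(stats::lm(y[hi] ~ x[hi]))
  list(low = c(intercept = unname(fit_lo[1]), slope = unname(fit_lo[2])),
       high = c(intercept = unname(fit_hi[1]), slope = unname(fit_hi[2])))
}

# 5-point moving-average smoother used when locating transition midpoints.
fk_smooth5 <- function(y) {
  n <- length(y)
  if (n < 5L) return(y)
  as.numeric(stats::filter(y, rep(1 / 5, 5), sides = 2)) -> s
  s[is.na(s)] <- y[is.na(s)]
  s
}
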