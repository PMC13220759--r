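#' Truncated negative-binomial probability mass function
#'
#' Negative binomial with mean `mu` and dispersion `theta` (variance
#' `mu + mu^2/theta`), restricted to values strictly above the truncation
#' point `t` and renormalized by the surviving mass. `t = -1` recovers the
#' untruncated distribution.
#'
#' @param y integer quantiles.
#' @param mu,theta mean and dispersion of the parent distribution (both
#'   positive).
#' @param t truncation point; support is `t+1, t+2, ...`.
#' @param log return log-probabilities?
#' @return probabilities (0 for `y <= t`).
#' @export
dtnb <- function(y, mu, theta, t = 0L, log = FALSE) {
  if (any(!is.finite(mu)) || any(!is.finite(theta)) || any(mu <= 0) ||
      any(theta <= 0))
    stop("mu and theta must be finite and positive")
  lp <- dnbinom(y, size = theta, mu = mu, log = TRUE)
  if (t >= 0)
    lp <- lp - pnbinom(t, size = theta, mu = mu,
                       lower.tail = FALSE, log.p = TRUE)
  lp[y <= t] <- -Inf
  if (log) lp else exp(lp)
}

# --- internal likelihood machinery -------------------------------------
#
# The negative log-likelihood and its analytic gradient for the TNB
# log-link regression. Special functions are evaluated once per unique
# count, and the truncation mass (t <= 2 in practice) by the pmf
# recursion p_k = p_{k-1} (theta+k-1)/k * mu/(theta+mu), so one
# evaluation costs a handful of elementary vector operations.
tnb_negll_factory <- function(X, y, t) {
  uy <- sort(unique(y)); idx <- match(y, uy); slfy <- sum(lfactorial(y))
  p <- ncol(X)
  function(par) {
    beta <- par[seq_len(p)]
    theta <- exp(min(max(par[p + 1L], -12), 16))
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- exp(eta)
    lth <- log(theta); dgth <- digamma(theta)
    ltm <- log(theta + mu)
    ll <- sum((lgamma(uy + theta) - lgamma(theta))[idx]) - slfy +
      theta * sum(lth - ltm) + sum(y * (eta - ltm))
    de <- y - mu * (y + theta) / (mu + theta)
    dt <- (digamma(uy + theta) - dgth)[idx] + lth + 1 - ltm -
      (theta + y) / (theta + mu)
    if (t >= 0L) {
      r <- mu / (theta + mu)
      pk <- exp(theta * (lth - ltm))
      S <- 1 - pk
      deT <- pk * (-mu * theta / (mu + theta))
      dtT <- pk * (lth + 1 - ltm - theta / (theta + mu))
      if (t >= 1L) for (k in seq_len(t)) {
        pk <- pk * (theta + k - 1) / k * r
        S <- S - pk
        deT <- deT + pk * (k - mu * (k + theta) / (mu + theta))
        dtT <- dtT + pk * (digamma(k + theta) - dgth + lth + 1 - ltm -
                             (theta + k) / (theta + mu))
      }
      # the subtraction cancels catastrophically when nearly all mass sits
      # at or below t; recompute those survivals from the accurate tail
      small <- S < 1e-6
      if (any(small))
        S[small] <- pnbinom(t, size = theta, mu = mu[small],
                            lower.tail = FALSE)
      S <- pmax(S, 1e-290)
      ll <- ll - sum(log(S))
      de <- de + deT / S
      dt <- dt + dtT / S
    }
    list(negll = -ll, grad = c(-drop(crossprod(X, de)), -sum(dt) * theta))
  }
}

# Column standardization helper: returns scaled design (with intercept) and
# the transform needed to map coefficients back to the original scale.
standardize_design <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  list(X = cbind(`(Intercept)` = 1, Xs), center = ctr, scale = scl)
}

#' Fit the truncated negative-binomial baseline regression
#'
#' Maximum-likelihood fit of `ln(mu) = beta0 + sum_l beta_l X_l` with
#' counts following a truncated negative binomial with dispersion `theta`
#' and truncation point `t`. Only records with burden strictly above `t`
#' lie in the support and enter the likelihood; by default at least 5000
#' such records are required, guarding against overfitting the
#' background. Optimization is bounded quasi-Newton (BFGS on
#' `(beta, log theta)`) with analytic gradients; predictors are
#' standardized internally for conditioning and coefficients are reported
#' on the original scale. Starting values come from a least-squares fit
#' of `log(y)` and a method-of-moments dispersion.
#'
#' @param y integer burdens, one per gene pair.
#' @param X predictor matrix (no intercept column), e.g. from
#'   [pair_predictors()].
#' @param t truncation point (0, 1 or 2; `-1` for no truncation).
#' @param min_pairs minimum number of in-support records.
#' @param start optional warm-start parameter vector on the standardized
#'   scale, `(beta_std, log theta)`.
#' @param compute_se also return approximate standard errors from the
#'   observed information (numerical Hessian at the optimum)?
#' @param max_iter,reltol optimizer controls.
#' @return an object of class `tnb_model`: coefficients on the original
#'   scale (`beta`), `theta`, `t`, `loglik`, `converged`, `n_pairs_fit`,
#'   and `residual_scale`, the empirical mean/sd of the deviance residuals
#'   over the fit set used to standardize them.
#' @export
fit_tnb <- function(y, X, t = 0L, min_pairs = 5000L, start = NULL,
                    compute_se = FALSE, max_iter = 500L, reltol = 1e-9) {
  X <- as.matrix(X)
  in_support <- y > t
  n_fit <- sum(in_support)
  if (n_fit < min_pairs)
    stop(errorCondition(
      sprintf("only %d gene pairs with burden > t = %d (minimum %d); stopping to avoid overfitting",
              n_fit, t, min_pairs),
      class = c("eb_stop_rule", "error")))
  yf <- y[in_support]
  Xf <- X[in_support, , drop = FALSE]
  # winsorize covariates: a single pair with an extreme covariate (for
  # example an enormous control burden) is a high-leverage point that can
  # anchor its own baseline and mask itself from the purification step
  caps <- apply(Xf, 2L, stats::quantile, probs = 0.995, names = FALSE)
  Xf <- pmin(Xf, rep(caps, each = nrow(Xf)))
  sd_ <- standardize_design(Xf)
  Xs <- sd_$X
  p <- ncol(Xs)

  if (is.null(start)) {
    b0 <- qr.coef(qr(Xs), log(pmax(yf, 0.5)))
    b0[is.na(b0)] <- 0
    m <- mean(yf); v <- var(yf)
    th0 <- if (is.finite(v) && v > m) m^2 / (v - m) else 10
    start <- c(b0, log(min(max(th0, 0.05), 1e3)))
  }
  f <- tnb_negll_factory(Xs, yf, t)
  opt <- optim(start, function(p_) f(p_)$negll, function(p_) f(p_)$grad,
               method = "BFGS",
               control = list(maxit = max_iter, reltol = reltol))

  beta_std <- opt$par[seq_len(p)]
  theta <- exp(opt$par[p + 1L])
  beta <- beta_std[-1L] / sd_$scale
  beta0 <- beta_std[1L] - sum(beta_std[-1L] * sd_$center / sd_$scale)
  beta_full <- c(`(Intercept)` = beta0,
                 setNames(beta, colnames(X) %||% paste0("X", seq_along(beta))))

  model <- structure(list(
    beta = beta_full, theta = theta, t = t,
    loglik = -opt$value, converged = opt$convergence == 0L,
    n_pairs_fit = n_fit,
    par_std = opt$par, center = sd_$center, scale = sd_$scale,
    x_range = rbind(lo = apply(Xf, 2L, min), hi = caps),
    residual_scale = NULL, se = NULL
  ), class = "tnb_model")

  # standardization constants for the deviance residuals, from the fit set
  mu_fit <- predict_mu(model, X[in_support, , drop = FALSE])
  d_raw <- tnb_deviance(yf, mu_fit, theta, t)
  model$residual_scale <- c(mean = mean(d_raw), sd = max(sd(d_raw), 1e-12))

  if (compute_se) {
    H <- stats::optimHess(opt$par, function(p_) f(p_)$negll,
                          function(p_) f(p_)$grad)
    V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p + 1, p + 1))
    se_std <- sqrt(pmax(diag(V), 0))
    se <- se_std[seq_len(p)]
    se[-1L] <- se[-1L] / sd_$scale
    # intercept SE on the original scale omits center/scale covariance terms
    model$se <- setNames(se, names(beta_full))
    model$se_log_theta <- se_std[p + 1L]
  }
  model
}

#' @export
print.tnb_model <- function(x, ...) {
  cat(sprintf("<tnb_model> t = %d, theta = %.4g, loglik = %.2f, n_fit = %d%s\n",
              x$t, x$theta, x$loglik, x$n_pairs_fit,
              if (x$converged) "" else " (NOT converged)"))
  print(round(x$beta, 6))
  invisible(x)
}

#' Predicted baseline burden
#'
#' Inverts the log link: `mu = exp(beta0 + sum_l beta_l X_l)`. Predictor
#' values are clamped to the range observed in the background fit set
#' before the link is applied: coefficients estimated on the background
#' cannot be extrapolated beyond its support, and without the guard a
#' pair whose control burden (or feature product) lies far outside the
#' background range receives an exponentially extrapolated baseline that
#' can mask even a very strong enrichment. The linear predictor is also
#' clipped to `[-30, 30]` against overflow.
#'
#' @param model a fitted [fit_tnb()] model.
#' @param X predictor matrix on the original scale.
#' @return expected baseline burdens.
#' @export
predict_mu <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(model$x_range)) {
    for (j in seq_len(ncol(X))) {
      X[, j] <- pmin(pmax(X[, j], model$x_range["lo", j]),
                     model$x_range["hi", j])
    }
  }
  eta <- drop(cbind(1, X) %*% model$beta)
  exp(pmin(pmax(eta, -30), 30))
}

# log pmf of the TNB at scalar theta/t, vector mu and y (elementary ops)
tnb_logpmf_scalar_theta <- function(y, mu, theta, t) {
  lp <- lgamma(y + theta) - lgamma(theta) - lfactorial(y) +
    theta * (log(theta) - log(theta + mu)) + y * (log(mu) - log(theta + mu))
  if (t >= 0) {
    pk <- exp(theta * (log(theta) - log(theta + mu)))
    S <- 1 - pk
    if (t >= 1) for (k in seq_len(t)) {
      pk <- pk * (theta + k - 1) / k * mu / (theta + mu)
      S <- S - pk
    }
    small <- S < 1e-6
    if (any(small))
      S[small] <- pnbinom(t, size = theta, mu = mu[small],
                          lower.tail = FALSE)
    lp <- lp - log(pmax(S, 1e-290))
  }
  lp
}

# Saturated TNB log-likelihood: max over mu of log pmf(y; mu), cached per
# unique count (theta and t fixed). For the untruncated NB the maximum is
# at mu = y; truncation shifts it, so a 1-D search on log mu is used.
tnb_saturated_loglik <- function(y, theta, t) {
  uy <- sort(unique(y))
  # far above the truncation point the surviving mass is ~1 and the
  # maximizing mu is y itself; the 1-D search is only needed near t
  small <- uy <= t + 40L
  ls <- numeric(length(uy))
  if (any(!small)) {
    yy <- uy[!small]
    ls[!small] <- tnb_logpmf_scalar_theta(yy, pmax(yy, 1e-8), theta, t)
  }
  if (any(small)) {
    ls[small] <- vapply(uy[small], function(yy) {
      if (t < 0L) return(tnb_logpmf_scalar_theta(yy, max(yy, 1e-8), theta, t))
      o <- optimize(function(lm) -tnb_logpmf_scalar_theta(yy, exp(lm), theta, t),
                    interval = c(log(1e-6), log(yy + 10) + 1), tol = 1e-8)
      -o$objective
    }, numeric(1))
  }
  ls[match(y, uy)]
}

# mean of the truncated distribution
tnb_mean <- function(mu, theta, t) {
  if (t < 0L) return(mu)
  pk <- exp(theta * (log(theta) - log(theta + mu)))
  S <- 1 - pk
  ex <- 0
  if (t >= 1) for (k in seq_len(t)) {
    pk <- pk * (theta + k - 1) / k * mu / (theta + mu)
    S <- S - pk
    ex <- ex + k * pk
  }
  (mu - ex) / pmax(S, 1e-290)
}

# Raw deviance residuals under the TNB likelihood: signed square root of
# twice the saturated-minus-fitted log-likelihood, sign from the
# truncated-mean comparison.
tnb_deviance <- function(y, mu, theta, t) {
  ll_fit <- tnb_logpmf_scalar_theta(y, mu, theta, t)
  ll_sat <- tnb_saturated_loglik(y, theta, t)
  sign(y - tnb_mean(mu, theta, t)) * sqrt(pmax(2 * (ll_sat - ll_fit), 0))
}

#' Standardized deviance residual and enrichment p-value
#'
#' For each gene pair the deviance residual of the observed burden against
#' its fitted baseline is standardized with the background fit set's
#' empirical mean and standard deviation (stored in the model) and referred
#' to the standard normal: `p = 1 - Phi(d')`, a one-sided upper-tail test
#' of burden enrichment. Pairs with burden at or below the truncation
#' point lie outside the model support and cannot exhibit enrichment;
#' they receive `d' = -Inf` and `p = 1`.
#'
#' @param model fitted [fit_tnb()] model.
#' @param y observed burdens.
#' @param X predictor matrix on the original scale.
#' @return list with `d_std`, `p_value` and `mu_hat`.
#' @export
deviance_pvalue <- function(model, y, X) {
  mu <- predict_mu(model, X)
  d_std <- rep(-Inf, length(y))
  p <- rep(1, length(y))
  in_sup <- y > model$t
  if (any(in_sup)) {
    d <- tnb_deviance(y[in_sup], mu[in_sup], model$theta, model$t)
    ds <- (d - model$residual_scale["mean"]) / model$residual_scale["sd"]
    d_std[in_sup] <- ds
    p[in_sup] <- pnorm(ds, lower.tail = FALSE)
  }
  list(d_std = d_std, p_value = p, mu_hat = mu)
}

#' Mean log fold change of a p-value set
#'
#' Calibration measure: the mean over ranked p-values of the absolute
#' log2 ratio between the observed order statistic and its expectation
#' `r / (n + 1)` under uniformity. 0 indicates perfect calibration; a set
#' of p-values uniformly halved from their expectations scores 1.
#'
#' @param p p-values in `(0, 1]` (zeros are floored to the smallest
#'   positive double with a warning).
#' @return nonnegative scalar.
#' @export
mlfc <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 2L) stop("mlfc needs at least 2 p-values")
  if (any(p <= 0)) {
    warning("p-values of 0 floored to .Machine$double.xmin")
    p[p <= 0] <- .Machine$double.xmin
  }
  n <- length(p)
  mean(abs(log2(sort(p) * (n + 1) / seq_len(n))))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity;
#' ties share identical q-values.
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
bh_fdr <- function(p) p.adjust(p, method = "BH")
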