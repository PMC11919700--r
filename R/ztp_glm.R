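#' Zero-truncated Poisson regression
#'
#' Fits a log-linear regression for counts observed conditionally on being at
#' least 1 (a "positive Poisson" regression).  This is the bias model for
#' proximity-ligation bin-pair counts: systematic covariates (effective
#' fragment size, GC content, mappability, ChIP enrichment, log genomic
#' distance) enter linearly on the log rate, and the likelihood is the
#' Poisson likelihood conditioned on \eqn{X \ge 1},
#' \deqn{\ell(\beta) = \sum_i x_i \log\mu_i - \mu_i - \log(1 - e^{-\mu_i}) -
#'   \log x_i!, \qquad \mu_i = \exp(c_i^\top\beta).}
#'
#' Fitting uses Fisher scoring with the analytic score
#' \eqn{C^\top(x - m(\mu))}, where \eqn{m(\mu) = \mu/(1-e^{-\mu})} is the
#' truncated mean, and expected information weights
#' \eqn{w = m(1 + \mu - m)} (the truncated variance); a step-halving guard
#' keeps the log-likelihood non-decreasing.  Covariates are internally
#' standardized (z-scored) for numerical stability and the coefficients are
#' reported on both the original and the standardized scale.
#'
#' @param formula model formula; the response is the count vector.
#' @param data a `data.frame` holding the response and covariates.
#' @param start optional starting coefficients on the standardized scale.
#' @param standardize z-score non-constant covariate columns before fitting
#'   (the default; coefficients are always back-transformed to the raw scale).
#' @param tol convergence tolerance on the relative log-likelihood change.
#' @param maxit maximum number of Fisher scoring iterations.
#'
#' @return An object of class `"ztp_glm"` with components `coefficients`
#'   (raw scale), `coefficients_std` (standardized scale), `vcov`, `fitted.values`
#'   (the rate \eqn{\mu}), `linear.predictors`, `logLik`, `ll_trace`,
#'   `iter`, `converged`, `y`, `terms` and the usual bookkeeping.  Methods:
#'   [coef()], [vcov()], [logLik()], [predict.ztp_glm()], [fitted()],
#'   [residuals.ztp_glm()], [simulate.ztp_glm()], [summary.ztp_glm()],
#'   [plot.ztp_glm()].
#'
#' @details
#' All responses must be `>= 1` (pairs with zero counts are unobservable
#' under the truncated model and must be removed upstream); fewer than 500
#' observations or a rank-deficient covariate matrix is an error, as is
#' non-convergence within `maxit` iterations.
#'
#' @examples
#' d <- data.frame(z = rnorm(1000))
#' d$y <- rztpois(1000, exp(1 + 0.5 * d$z))
#' fit <- ztp_glm(y ~ z, d, min_n = 100)
#' coef(fit)
#' @export
ztp_glm <- function(formula, data, start = NULL, standardize = TRUE,
                    tol = 1e-8, maxit = 100L, min_n = 500L) {
  mf <- stats::model.frame(formula, data)
  mt <- attr(mf, "terms")
  y <- stats::model.response(mf)
  X <- stats::model.matrix(mt, mf)
  if (any(y < 1)) stop("ztp_glm() requires all counts >= 1 (zero-truncated model)")
  if (nrow(X) < min_n)
    stop("ztp_glm() needs at least ", min_n, " observations; got ", nrow(X))
  if (qr(X)$rank < ncol(X))
    stop("covariate matrix is rank deficient; drop collinear columns")

  # standardize non-constant columns for a well-conditioned information matrix
  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  if (standardize) {
    vary <- apply(X, 2, function(v) stats::sd(v) > 0)
    ctr[vary] <- colMeans(X[, vary, drop = FALSE])
    scl[vary] <- apply(X[, vary, drop = FALSE], 2, stats::sd)
  }
  Z <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")

  beta <- if (is.null(start)) {
    b <- rep(0, ncol(Z))
    ic <- which(apply(Z, 2, function(v) all(v == v[1])))
    if (length(ic)) b[ic[1]] <- log(mean(y)) / Z[1, ic[1]]
    b
  } else rep_len(start, ncol(Z))

  loglik <- function(b) {
    eta <- pmin(pmax(drop(Z %*% b), -30), 30)
    mu <- exp(eta)
    sum(y * eta - mu - .log1mexp(mu) - lgamma(y + 1))
  }

  ll <- loglik(beta)
  trace <- ll
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- pmin(pmax(drop(Z %*% beta), -30), 30)
    mu <- exp(eta)
    m <- ztpois_mean(mu)
    w <- pmax(m * (1 + mu - m), 1e-10)
    score <- drop(crossprod(Z, y - m))
    info <- crossprod(Z * sqrt(w))
    step <- solve(info, score)
    # step halving: keep the log-likelihood non-decreasing
    fac <- 1
    repeat {
      cand <- beta + fac * step
      llc <- loglik(cand)
      if (llc >= ll - 1e-12 || fac < 1e-4) break
      fac <- fac / 2
    }
    beta <- cand
    trace <- c(trace, llc)
    if (abs(llc - ll) < tol * (abs(ll) + tol)) {
      ll <- llc
      converged <- TRUE
      break
    }
    ll <- llc
  }
  if (!converged)
    stop("ztp_glm() did not converge in ", maxit,
         " iterations (last log-likelihood ", format(ll), ")")

  eta <- pmin(pmax(drop(Z %*% beta), -30), 30)
  mu <- exp(eta)
  m <- ztpois_mean(mu)
  w <- pmax(m * (1 + mu - m), 1e-10)
  info <- crossprod(Z * sqrt(w))
  vcov_std <- solve(info)

  # back-transform to the raw scale: beta_raw_j = beta_std_j / scl_j for
  # covariates; the intercept absorbs the centering offsets
  ic <- which(colnames(X) == "(Intercept)")
  braw <- beta / scl
  vr <- t(diag(1 / scl, length(scl))) %*% vcov_std %*% diag(1 / scl, length(scl))
  if (length(ic)) {
    off <- -sum((ctr / scl * beta)[-ic])
    braw[ic] <- beta[ic] + off
    L <- diag(1 / scl, length(scl))
    L[ic, ] <- -ctr / scl
    L[ic, ic] <- 1
    vr <- L %*% vcov_std %*% t(L)
  }
  names(braw) <- colnames(X)
  dimnames(vr) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)

  structure(list(
    coefficients = braw,
    coefficients_std = beta,
    vcov = vr,
    vcov_std = vcov_std,
    fitted.values = mu,
    truncated.mean = m,
    linear.predictors = eta,
    logLik = ll,
    ll_trace = trace,
    iter = it,
    converged = converged,
    y = y,
    n = length(y),
    center = ctr, scale = scl,
    terms = mt,
    xlevels = stats::.getXlevels(mt, mf),
    x_range = apply(X, 2, range),
    call = match.call()
  ), class = "ztp_glm")
}

#' @export
coef.ztp_glm <- function(object, standardized = FALSE, ...) {
  if (standardized) object$coefficients_std else object$coefficients
}

#' @export
vcov.ztp_glm <- function(object, standardized = FALSE, ...) {
  if (standardized) object$vcov_std else object$vcov
}

#' @export
logLik.ztp_glm <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
nobs.ztp_glm <- function(object, ...) object$n

#' @export
fitted.ztp_glm <- function(object, ...) object$fitted.values

#' Predict from a zero-truncated Poisson regression
#'
#' @param object a fitted [ztp_glm()] model.
#' @param newdata optional `data.frame`; the training data are used if absent.
#' @param type `"response"` for the parent Poisson rate \eqn{\mu},
#'   `"link"` for the linear predictor, `"truncated"` for the conditional
#'   mean \eqn{E(X \mid X \ge 1) = \mu/(1-e^{-\mu})}.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.ztp_glm <- function(object, newdata = NULL,
                            type = c("response", "link", "truncated"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$linear.predictors
  } else {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
    X <- stats::model.matrix(tt, mf)
    out <- X > matrix(object$x_range[2, ], nrow(X), ncol(X), byrow = TRUE) |
           X < matrix(object$x_range[1, ], nrow(X), ncol(X), byrow = TRUE)
    if (any(out))
      message("predict.ztp_glm: ", sum(rowSums(out) > 0),
              " rows have covariates outside the training range")
    eta <- pmin(pmax(drop(X %*% object$coefficients), -30), 30)
  }
  switch(type,
         link = eta,
         response = exp(eta),
         truncated = ztpois_mean(exp(eta)))
}

#' @export
residuals.ztp_glm <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  mu <- object$fitted.values
  m <- object$truncated.mean
  r <- object$y - m
  if (type == "pearson") r <- r / sqrt(ztpois_var(mu))
  r
}

#' @export
simulate.ztp_glm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted.values
  out <- as.data.frame(replicate(nsim, rztpois(length(mu), mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.ztp_glm <- function(x, ...) {
  cat("Zero-truncated Poisson regression\n")
  cat("Call: ", deparse(x$call), "\n\n")
  cat("Coefficients (raw scale):\n")
  print(round(x$coefficients, 4))
  cat("\nn =", x$n, " logLik =", format(x$logLik),
      " iterations =", x$iter, "\n")
  invisible(x)
}

#' Summary of a zero-truncated Poisson regression
#'
#' @param object a fitted [ztp_glm()] model.
#' @param ... unused.
#' @return a `summary.ztp_glm` object with a Wald coefficient table
#'   (estimate, s.e., z, p) on the raw covariate scale.
#' @export
summary.ztp_glm <- function(object, ...) {
  est <- object$coefficients
  se <- sqrt(diag(object$vcov))
  z <- est / se
  tab <- cbind(Estimate = est, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(call = object$call, coefficients = tab,
                 coefficients_std = object$coefficients_std,
                 logLik = object$logLik, n = object$n, iter = object$iter),
            class = "summary.ztp_glm")
}

#' @export
print.summary.ztp_glm <- function(x, ...) {
  cat("Zero-truncated Poisson regression\n")
  cat("Call: ", deparse(x$call), "\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("\nStandardized-scale coefficients:\n")
  print(round(x$coefficients_std, 4))
  cat("\nn =", x$n, " logLik =", format(x$logLik), "\n")
  invisible(x)
}

#' @export
plot.ztp_glm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(log10(x$fitted.values), residuals(x),
                 xlab = "log10 fitted rate", ylab = "Pearson residual",
                 pch = ".", ...)
  graphics::abline(h = 0, col = 2)
  p <- ztp_pvalue(x$y, x$fitted.values)
  graphics::plot(stats::ppoints(length(p)), sort(p), pch = ".",
                 xlab = "uniform quantile", ylab = "ordered tail p-value",
                 main = "calibration (discrete: super-uniform)")
  graphics::abline(0, 1, col = 2)
  invisible(x)
}
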