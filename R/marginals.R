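#' Moment-matched marginal distributions
#'
#' The cohort generator draws each metric from a marginal matched to a target
#' mean and standard deviation: a log-normal for strictly positive rates and
#' volumes, a logit-normal for quantities bounded in (0, 1) (perfusion
#' fraction, volume fractions). Both are parameterized so that the marginal
#' mean and SD equal the targets; the log-normal match is closed-form, the
#' logit-normal match is solved numerically.
#'
#' @param mean,sd Target mean and standard deviation (sd > 0, and for
#'   `"logitnormal"` 0 < mean < 1).
#' @param family `"lognormal"` or `"logitnormal"`.
#' @return An object of class `"qimnet_marginal"` with a quantile function
#'   accessible through [marginal_quantile()].
#' @examples
#' m <- match_marginal(0.18, 0.06, "lognormal")
#' q <- marginal_quantile(m, c(0.25, 0.5, 0.75))
#' @export
match_marginal <- function(mean, sd, family = c("lognormal", "logitnormal")) {
  family <- match.arg(family)
  stopifnot(sd > 0, mean > 0)
  if (family == "lognormal") {
    s2 <- log1p((sd / mean)^2)
    par <- c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
  } else {
    stopifnot(mean < 1)
    par <- logitnormal_match(mean, sd)
  }
  structure(list(family = family, mean = mean, sd = sd, par = par),
            class = "qimnet_marginal")
}

# Solve (mu, sigma) of a logit-normal to match mean/sd; moments by Gaussian
# quadrature on the probit scale.
logitnormal_match <- function(mean, sd) {
  z <- qnorm((seq_len(512) - 0.5) / 512)
  moments <- function(mu, sigma) {
    x <- plogis(mu + sigma * z)
    c(mean(x), sqrt(mean((x - mean(x))^2)))
  }
  obj <- function(p) {
    m <- moments(p[1], exp(p[2]))
    (m[1] - mean)^2 + (m[2] - sd)^2
  }
  init <- c(qlogis(mean), log(sd / (mean * (1 - mean))))
  fit <- optim(init, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  m <- moments(fit$par[1], exp(fit$par[2]))
  if (abs(m[1] - mean) > 1e-4 * mean || abs(m[2] - sd) > 0.02 * sd)
    stop("logit-normal moment match failed for mean=", mean, " sd=", sd)
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' @rdname match_marginal
#' @param marginal A `"qimnet_marginal"` object.
#' @param p Probabilities.
#' @export
marginal_quantile <- function(marginal, p) {
  if (marginal$family == "lognormal") {
    qlnorm(p, marginal$par[["meanlog"]], marginal$par[["sdlog"]])
  } else {
    plogis(marginal$par[["mu"]] + marginal$par[["sigma"]] * qnorm(p))
  }
}
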