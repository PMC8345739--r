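#' Rank-correlation specification for the synthetic cohort
#'
#' Bundles the target Spearman correlation matrix and the per-metric marginal
#' distributions the cohort generator must reproduce. The default uses the
#' packaged reference correlation fixture ([table2_correlations()]) and the
#' cohort summary marginals ([qi_metric_defaults()]).
#'
#' Sampling uses a Gaussian copula: a target Spearman correlation
#' `rho_s` is mapped to the latent Pearson correlation
#' \eqn{r = 2 \sin(\pi \rho_s / 6)}, the latent matrix is repaired to positive
#' semi-definiteness by clipping eigenvalues at 1e-8 and renormalizing the
#' diagonal, and latent normals are pushed through the marginal quantile
#' functions. Rank correlations survive the monotone quantile transform, so
#' the sample Spearman matrix converges to the target for any marginals.
#'
#' @param metric_names Ordered metric names.
#' @param target_rank_corr Symmetric target Spearman matrix in `[-1, 1]`
#'   with unit diagonal, dimnames = metric names.
#' @param marginals Named list of [match_marginal()] objects, one per metric.
#' @return An object of class `"qimnet_corr_spec"`.
#' @export
correlation_spec <- function(metric_names = qi_metrics(),
                             target_rank_corr = table2_correlations()$rho,
                             marginals = default_marginals(metric_names)) {
  m <- as.matrix(target_rank_corr)
  stopifnot(identical(rownames(m), metric_names),
            identical(colnames(m), metric_names),
            isSymmetric(m), all(diag(m) == 1), all(abs(m) <= 1),
            identical(sort(names(marginals)), sort(metric_names)))
  latent <- 2 * sin(pi * m / 6)
  ev <- eigen(latent, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    vals <- pmax(ev$values, 1e-8)
    latent <- ev$vectors %*% (vals * t(ev$vectors))
    latent <- cov2cor(latent)
  }
  chk <- min(eigen(latent, symmetric = TRUE, only.values = TRUE)$values)
  if (chk < 0)
    stop("latent correlation not PSD after repair; smallest eigenvalue ", chk)
  dimnames(latent) <- dimnames(m)
  structure(list(metric_names = metric_names, target_rank_corr = m,
                 latent = latent, marginals = marginals[metric_names]),
            class = "qimnet_corr_spec")
}

#' @rdname correlation_spec
#' @export
default_marginals <- function(metric_names = qi_metrics()) {
  d <- qi_metric_defaults()
  d <- d[match(metric_names, d$metric), ]
  if (anyNA(d$metric)) stop("no default marginal for some requested metrics")
  out <- lapply(seq_len(nrow(d)), function(i)
    match_marginal(d$mean[i], d$sd[i], d$family[i]))
  names(out) <- d$metric
  out
}

#' Sample lesion ground truth
#'
#' Draws `n_lesions` lesions whose metric vector follows the copula model of
#' a [correlation_spec()], and derives the internally consistent kinetic
#' quantities the signal simulators need: the PET washout rate
#' `k2 = K1 / DV` (so the distribution-volume identity holds exactly) and a
#' blood volume fraction `vb` drawn from its own marginal.
#'
#' @param n_lesions Number of lesions (>= 3).
#' @param spec A [correlation_spec()].
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A data.frame, one row per lesion: `lesion_id`, the metrics of the
#'   spec, plus `vb` and `k2` when the spec contains the PET metrics.
#' @examples
#' truth <- sample_ground_truth(5, correlation_spec(), seed = 1)
#' stopifnot(all(truth$DV == truth$K1 / truth$k2))
#' @export
sample_ground_truth <- function(n_lesions, spec = correlation_spec(),
                                seed = 20210803L) {
  stopifnot(n_lesions >= 3, inherits(spec, "qimnet_corr_spec"))
  set.seed(seed)
  p <- length(spec$metric_names)
  L <- chol(spec$latent + diag(1e-12, p))
  z <- matrix(rnorm(n_lesions * p), n_lesions, p) %*% L
  u <- pnorm(z)
  x <- vapply(seq_len(p), function(j)
    marginal_quantile(spec$marginals[[j]], u[, j]), numeric(n_lesions))
  colnames(x) <- spec$metric_names
  out <- data.frame(lesion_id = sprintf("lesion_%02d", seq_len(n_lesions)),
                    x, check.names = FALSE)
  if (all(c("K1", "DV") %in% spec$metric_names)) {
    defs <- qi_metric_defaults()
    vbrow <- defs[defs$metric == "vb", ]
    mvb <- match_marginal(vbrow$mean, vbrow$sd, vbrow$family)
    out$vb <- marginal_quantile(mvb, runif(n_lesions))
    out$k2 <- out$K1 / out$DV
    out$DV <- out$K1 / out$k2  # re-derive so the identity is bit-exact
  }
  validate_ground_truth(out)
  out
}

validate_ground_truth <- function(truth) {
  rate_cols <- intersect(c("ADC", "D", "Dstar", "Ktrans", "ve", "tau_i",
                           "K1", "k3max", "k3mean", "DV", "Vt_PET", "Vt_MRI"),
                         names(truth))
  for (cl in rate_cols)
    if (any(truth[[cl]] <= 0)) stop("non-positive ground-truth ", cl)
  for (cl in intersect(c("f", "ve", "vb"), names(truth)))
    if (any(truth[[cl]] <= 0 | truth[[cl]] >= 1))
      stop("ground-truth ", cl, " outside (0,1)")
  if (all(c("D", "Dstar") %in% names(truth)) &&
      any(truth$Dstar <= truth$D))
    stop("ground truth violates D* > D")
  if (all(c("K1", "k2", "DV") %in% names(truth)) &&
      any(truth$DV != truth$K1 / truth$k2))
    stop("DV != K1/k2 in ground truth")
  invisible(truth)
}
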