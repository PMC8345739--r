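#' Spearman correlation matrix with significance
#'
#' Pairwise-complete Spearman rank correlations between metric columns, with
#' two-sided p-values from the t approximation
#' `t = rho sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' (midranks for ties), and the conventional strength bands
#' |rho| < 0.3 weak, 0.3-0.5 moderate, 0.5-1.0 strong. Constant columns
#' yield undefined correlations (NA) and are flagged.
#'
#' @param table Data.frame of lesions x metrics; a `lesion_id` column is
#'   ignored. Missing values allowed (pairwise complete, >= 4 pairs).
#' @param bh Apply a Benjamini-Hochberg correction to the p-values
#'   (default off: the network convention thresholds raw p).
#' @return List with matrices `rho`, `p`, `n` (pairs used), character
#'   matrix `strength`, and `constant` (flagged metric names).
#' @examples
#' tab <- data.frame(a = 1:10, b = (1:10)^2, c = rnorm(10))
#' spearman_matrix(tab)$rho["a", "b"]
#' @export
spearman_matrix <- function(table, bh = FALSE) {
  x <- table[, setdiff(names(table), "lesion_id"), drop = FALSE]
  x <- as.matrix(x)
  m <- ncol(x)
  constant <- colnames(x)[apply(x, 2, function(v)
    length(unique(v[!is.na(v)])) <= 1)]
  rho <- p <- nmat <- matrix(NA_real_, m, m,
                             dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(m)) {
    for (j in i:m) {
      ok <- complete.cases(x[, i], x[, j])
      n <- sum(ok)
      nmat[i, j] <- nmat[j, i] <- n
      if (i == j) { rho[i, j] <- 1; p[i, j] <- 0; next }
      if (n < 4) next
      if (colnames(x)[i] %in% constant || colnames(x)[j] %in% constant) next
      r <- cor(x[ok, i], x[ok, j], method = "spearman")
      rho[i, j] <- rho[j, i] <- r
      p[i, j] <- p[j, i] <- spearman_p(r, n)
    }
  }
  if (bh) {
    ut <- upper.tri(p)
    p[ut] <- stats::p.adjust(p[ut], method = "BH")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  strength <- matrix(as.character(cut(abs(rho), c(0, 0.3, 0.5, 1),
                                      labels = c("weak", "moderate", "strong"),
                                      include.lowest = TRUE)),
                     m, m, dimnames = dimnames(rho))
  list(rho = rho, p = p, n = nmat, strength = strength, constant = constant)
}

#' @rdname spearman_matrix
#' @param rho A single Spearman correlation.
#' @param n Sample size.
#' @export
spearman_p <- function(rho, n) {
  if (is.na(rho) || n < 3) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(tstat), df = n - 2)
}

#' Paired volume comparison (Wilcoxon signed-rank test)
#'
#' Two-sided Wilcoxon signed-rank test on paired samples, zero differences
#' dropped, midrank ties; exact when the reduced sample is small and
#' tie-free, normal approximation otherwise.
#'
#' @param v1,v2 Paired measurements (e.g. cm3 tumor volumes), equal length
#'   >= 5.
#' @return List with `statistic` (V), `p`, `n_used`, `flag` (`"ok"` or
#'   `"all_zero"`).
#' @export
compare_volumes <- function(v1, v2) {
  stopifnot(length(v1) == length(v2), length(v1) >= 5)
  d <- v1 - v2
  d <- d[d != 0]
  if (length(d) == 0)
    return(list(statistic = NA_real_, p = 1, n_used = 0L, flag = "all_zero"))
  wt <- suppressWarnings(wilcox.test(d, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n_used = length(d), flag = "ok")
}

#' Build the significance network
#'
#' Undirected signed weighted graph over a configured metric set: an edge
#' joins metrics i and j iff their Spearman p-value is below `alpha`; the
#' edge weight is the signed correlation. Isolated metrics remain as nodes.
#'
#' @param rho,p Correlation and p-value matrices (as from
#'   [spearman_matrix()] or the packaged fixture).
#' @param include Metrics to keep as nodes (default: the 16-metric network
#'   set, [qi_network_metrics()]).
#' @param alpha Significance level.
#' @return An [igraph::graph] with vertex attribute `name` and edge
#'   attributes `weight` (= rho), `rho`, `p`.
#' @examples
#' fx <- table2_correlations()
#' g <- build_significance_network(fx$rho, ifelse(fx$significant, 0.01, 0.5))
#' igraph::degree(g)["Ktrans"]
#' @export
build_significance_network <- function(rho, p,
                                       include = qi_network_metrics(),
                                       alpha = 0.05) {
  if (length(include) == 0) stop("empty metric inclusion list")
  stopifnot(all(include %in% rownames(rho)), identical(dim(rho), dim(p)))
  r <- rho[include, include]
  q <- p[include, include]
  edges <- which(upper.tri(q) & !is.na(q) & q < alpha, arr.ind = TRUE)
  el <- data.frame(from = include[edges[, 1]], to = include[edges[, 2]],
                   weight = r[edges], rho = r[edges], p = q[edges])
  igraph::graph_from_data_frame(el, directed = FALSE,
                                vertices = data.frame(name = include))
}

#' OLS regression of a metric on its network neighbors
#'
#' Ordinary least squares of `target ~ predictors` with the overall-F
#' p-value and `adjusted R2 = 1 - (1 - R2)(n - 1)/(n - k - 1)`.
#'
#' @param table Metric data.frame (lesions x metrics).
#' @param target Response metric name.
#' @param predictors Predictor metric names.
#' @return List with `r2`, `adj_r2`, `p`, `n`, `rank_deficient` flag.
#' @export
regress_on_neighbors <- function(table, target, predictors) {
  stopifnot(target %in% names(table), all(predictors %in% names(table)))
  d <- table[, c(target, predictors)]
  d <- d[complete.cases(d), ]
  n <- nrow(d); k <- length(predictors)
  if (n <= k + 1) stop("need more observations than predictors + 1")
  fit <- lm(stats::reformulate(sprintf("`%s`", predictors),
                               sprintf("`%s`", target)), data = d)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  pval <- if (is.null(fstat)) NA_real_ else
    unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  list(r2 = sm$r.squared, adj_r2 = sm$adj.r.squared, p = pval, n = n,
       rank_deficient = fit$rank < k + 1)
}
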