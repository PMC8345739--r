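test_that("Spearman matrix handles monotone pairs, ties and constants", {
  set.seed(1)
  tab <- data.frame(a = 1:10, b = exp(1:10), c = rnorm(10),
                    k = rep(2, 10))
  sp <- spearman_matrix(tab)
  expect_equal(sp$rho["a", "b"], 1)
  expect_equal(sp$p["a", "b"], 0)
  expect_identical(sp$constant, "k")
  expect_true(all(is.na(sp$rho["k", c("a", "b", "c")])))
  expect_true(isSymmetric(sp$rho))
  expect_identical(sp$strength["a", "b"], "strong")
})

test_that("the t-approximation reproduces the published significance", {
  p <- spearman_p(0.48, 27)
  expect_equal(p, 0.011, tolerance = 0.03)
  expect_equal(round(p, 2), 0.01)
})

test_that("Spearman p matches the exact permutation law at n = 6", {
  set.seed(8)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(6)
    exact <- spearman_exact_p6(x, y)
    approx_p <- spearman_matrix(data.frame(x = x, y = y))$p["x", "y"]
    expect_lt(abs(approx_p - exact), 0.12)
  }
})

test_that("Spearman rho is invariant under monotone transforms", {
  set.seed(4)
  x <- rlnorm(27); y <- x + rnorm(27)
  r0 <- spearman_matrix(data.frame(x = x, y = y))$rho["x", "y"]
  r1 <- spearman_matrix(data.frame(x = log(x), y = y^3))$rho["x", "y"]
  expect_equal(r0, r1)
})

test_that("paired volume comparison behaves across regimes", {
  v <- c(5, 8, 12, 3, 9, 14, 7, 11)
  eq <- compare_volumes(v, v)
  expect_equal(eq$p, 1)
  expect_identical(eq$flag, "all_zero")
  set.seed(2)
  v1 <- rlnorm(27, log(10), 0.5)
  expect_lt(compare_volumes(v1, v1 + 20)$p, 0.01)
  # exact signed-rank law at n = 8
  set.seed(3)
  for (i in 1:5) {
    a <- rnorm(8); b <- rnorm(8)
    got <- compare_volumes(a, b)$p
    expect_equal(got, wilcoxon_exact_p(a - b), tolerance = 1e-12)
  }
})

test_that("significance network edges follow (p, alpha, include) exactly", {
  fx <- table2_correlations()
  p <- ifelse(fx$significant, 0.01, 0.5)
  net <- build_significance_network(fx$rho, p)
  expect_equal(igraph::vcount(net), 16)
  expect_equal(unname(igraph::degree(net)["Ktrans"]), 7)
  expect_equal(unname(igraph::degree(net)["K1"]), 6)
  expect_equal(igraph::ecount(net), 37)
  # edge weights carry the signed correlation
  e <- igraph::as_data_frame(net)
  k1k <- e[(e$from == "Ktrans" & e$to == "K1") |
           (e$from == "K1" & e$to == "Ktrans"), ]
  expect_equal(k1k$weight, 0.48)
  expect_equal(igraph::ecount(build_significance_network(fx$rho, p,
                                                         alpha = 0)), 0)
  # all-significant: complete graph
  pall <- matrix(0.001, 16, 16,
                 dimnames = list(qi_network_metrics(), qi_network_metrics()))
  rall <- matrix(0.5, 16, 16, dimnames = dimnames(pall)); diag(rall) <- 1
  expect_equal(igraph::ecount(build_significance_network(rall, pall)),
               16 * 15 / 2)
  expect_error(build_significance_network(fx$rho, p, include = character(0)),
               "empty")
})

test_that("neighbor regression returns R2, adjusted R2 and the F p-value", {
  set.seed(6)
  d <- data.frame(x1 = rnorm(27), x2 = rnorm(27), x3 = rnorm(27))
  d$y_exact <- 2 * d$x1 - d$x2 + 0.5 * d$x3
  expect_equal(suppressWarnings(
    regress_on_neighbors(d, "y_exact", c("x1", "x2", "x3"))$r2), 1)
  d$y_noise <- rnorm(27)
  fit <- regress_on_neighbors(d, "y_noise", c("x1", "x2", "x3"))
  expect_equal(fit$adj_r2, 1 - (1 - fit$r2) * 26 / 23, tolerance = 1e-12)
  big <- data.frame(x1 = rnorm(1000), y = rnorm(1000))
  expect_lt(regress_on_neighbors(big, "y", "x1")$r2, 0.02)
  # the published pair: R2 = 0.45 with n = 27, k = 3 gives adjusted 0.38
  expect_equal(round(1 - (1 - 0.45) * 26 / 23, 2), 0.38)
})

test_that("synthetic cohorts reproduce the fixture's edge sign pattern", {
  fx <- table2_correlations()
  incl <- qi_network_metrics()
  target_sign <- sign(fx$rho[incl, incl])
  spec <- correlation_spec()
  agree <- vapply(1:50, function(s) {
    x <- sample_ground_truth(27, spec, seed = 3000 + s)
    sp <- spearman_matrix(x[, c("lesion_id", qi_metrics())])
    net <- build_significance_network(sp$rho, sp$p, incl, 0.05)
    e <- igraph::as_data_frame(net)
    if (nrow(e) == 0) return(NA_real_)
    mean(sign(e$rho) == target_sign[cbind(e$from, e$to)])
  }, numeric(1))
  expect_gte(median(agree, na.rm = TRUE), 0.8)
})
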