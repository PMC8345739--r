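# Exact convolution of a piecewise-linear input with an exponential kernel.
#
# Computes I(t_k) = int_0^{t_k} exp(-lambda (t_k - s)) x(s) ds where x is
# linear between the sample points. This is the workhorse behind both the
# Tofts concentration integral and the two-tissue-compartment solution; a
# recursion over segments keeps it O(n) and exact for piecewise-linear
# inputs (no quadrature error), which matters at 5-8 s frame spacing.
#
# lambda = 0 reduces to the cumulative trapezoid; small lambda*dt uses a
# series to avoid cancellation in (dt - (1-E)/lambda)/lambda.
exp_conv_pwl <- function(times, x, lambda) {
  n <- length(times)
  stopifnot(length(x) == n, n >= 1, lambda >= 0, !is.unsorted(times))
  out <- numeric(n)
  if (n == 1) return(out)
  dt <- diff(times)
  if (lambda == 0) {
    return(cumsum(c(0, (x[-n] + x[-1]) / 2 * dt)))
  }
  E <- exp(-lambda * dt)
  g1 <- -expm1(-lambda * dt) / lambda            # int_0^dt e^{-lambda u} du
  u <- lambda * dt
  g2 <- ifelse(u < 1e-4,
               dt^2 / 2 * (1 - u / 3 + u^2 / 12),
               (dt - g1) / lambda)               # int_0^dt u e^{-lambda (dt-u)} du / dt ... see below
  # Segment contribution with x(s) = c0 + c1 (s - t_k):
  #   int_{0}^{dt} e^{-lambda (dt - s)} (c0 + c1 s) ds = c0 g1 + c1 g2'
  # where g2' = (dt - g1)/lambda evaluated stably above.
  c0 <- x[-n]
  c1 <- diff(x) / dt
  .exp_recur_cpp(E, c0 * g1 + c1 * g2)
}

# Refine a time grid to at most dt_fine spacing, keeping the original points
# and any extra knots (e.g. bolus arrival); returns grid and the index of the
# original times within it.
refine_grid <- function(times, dt_fine, knots = numeric(0)) {
  lo <- min(times, 0)
  hi <- max(times)
  fine <- seq(lo, hi, by = dt_fine)
  grid <- sort(unique(c(times, fine, knots[knots >= lo & knots <= hi])))
  list(grid = grid, idx = match(times, grid))
}
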