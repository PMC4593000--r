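# Independent oracles used across the suite. These deliberately avoid the
# package's own closed forms: the growth model is checked against numerical
# ODE integration and root finding, the statistics against hand-rolled
# implementations of the textbook formulas.

# numerically integrate dx/dt = r x (1 - (x/K)^nu) from x(0) = x0
ode_density <- function(t, x0, r, K, nu) {
  deriv <- function(t, state, parms) {
    list(parms$r * state[1] * (1 - (state[1] / parms$K)^parms$nu))
  }
  times <- sort(unique(c(0, t)))
  out <- deSolve::ode(y = c(x = x0), times = times, func = deriv,
                      parms = list(r = r, K = K, nu = nu),
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  unname(out[match(t, out[, "time"]), "x"])
}

# first doubling time by root finding on the analytical solution
mdr_rootfind <- function(x0, r, K, nu) {
  if (K <= 2 * x0 || r == 0) return(0)
  f <- function(t) glogistic_density(t, x0, r, K, nu) - 2 * x0
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  1 / stats::uniroot(f, c(0, upper), tol = 1e-14)$root
}

# two-tailed Welch t-test from the textbook formulas
welch_p_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * stats::pt(-abs(tstat), df)
}

# Benjamini-Hochberg step-up, literal implementation
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(n)
  q[ord] <- q_sorted
  q
}

# random valid generalized-logistic parameter sets
random_params <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      x0 = runif(n, 1e-4, 0.1),
      r = runif(n, 0.5, 10),
      nu = runif(n, 0.2, 5),
      K = runif(n, 1, 10) * 0.3
    )
  })
}

# drop non-structural attributes so tables can be compared by content
strip_attrs <- function(x) {
  x <- as.data.frame(x)
  attributes(x) <- attributes(x)[c("names", "class", "row.names")]
  x
}

make_timecourse <- function(gene, t, y, barcode = "P1", row = 1, col = 1,
                            background = "control") {
  tibble::tibble(barcode = barcode, row = row, col = col, gene = gene,
                 background = background, temperature = 30,
                 expt_time_days = t, density = y)
}
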