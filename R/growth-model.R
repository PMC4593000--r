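# Generalized logistic growth model and the fitness measures derived from it.
#
# The model is dx/dt = r x (1 - (x/K)^nu) with analytical solution
#   x(t) = K / (1 + ((K/x0)^nu - 1) exp(-r nu t))^(1/nu)
# where x0 is the cell density at inoculation (a shared constant for all spots
# on all plates), r a growth-rate parameter (per day), K the carrying capacity
# and nu a dimensionless shape parameter controlling curve symmetry (nu = 1
# recovers the ordinary logistic).

# log(1 + exp(z)) without overflow
log1pexp <- function(z) {
  out <- z
  lo <- z < -37
  mid <- !lo & z <= 33
  out[lo] <- exp(z[lo])
  out[mid] <- log1p(exp(z[mid]))
  out
}

# log(expm1(L)) for L >= 0 without overflow; L = 0 maps to -Inf
logexpm1 <- function(L) {
  out <- L
  small <- L <= 709
  out[small] <- log(expm1(L[small]))
  out
}

check_glogistic_params <- function(x0, r, K, nu) {
  ok <- is.finite(x0) & is.finite(r) & is.finite(K) & is.finite(nu)
  if (!all(ok)) {
    abort("growth parameters must be finite", class = "qfascreen_error_params")
  }
  if (any(x0 <= 0)) {
    abort("`x0` must be positive", class = "qfascreen_error_params")
  }
  if (any(K < x0)) {
    abort("`K` must be >= `x0`", class = "qfascreen_error_params")
  }
  if (any(r < 0)) {
    abort("`r` must be non-negative", class = "qfascreen_error_params")
  }
  if (any(nu <= 0)) {
    abort("`nu` must be positive", class = "qfascreen_error_params")
  }
  invisible(TRUE)
}

# unchecked core used inside the least-squares loop
.glogistic_density <- function(t, x0, r, K, nu) {
  log_term <- logexpm1(nu * log(K / x0)) - r * nu * t
  K * exp(-log1pexp(log_term) / nu)
}

#' Cell density under the generalized logistic growth model
#'
#' Evaluates the analytical solution of the generalized logistic equation
#' `dx/dt = r x (1 - (x/K)^nu)` started from density `x0` at time zero:
#' `x(t) = K / (1 + ((K/x0)^nu - 1) exp(-r nu t))^(1/nu)`.
#'
#' @param t Time since inoculation, in days. Vectorised; must be `>= 0`.
#' @param x0 Cell density at inoculation (arbitrary density units, `> 0`).
#' @param r Growth-rate parameter, per day (`>= 0`).
#' @param K Carrying capacity, same units as `x0` (`>= x0`).
#' @param nu Dimensionless shape parameter (`> 0`); `nu = 1` gives the
#'   ordinary logistic curve.
#'
#' @return A numeric vector of densities, one per element of `t`;
#'   non-decreasing in `t`, equal to `x0` at `t = 0` and approaching `K`.
#' @examples
#' glogistic_density(c(0, log(99)), x0 = 1, r = 1, K = 100, nu = 1)
#' @export
glogistic_density <- function(t, x0, r, K, nu) {
  check_glogistic_params(x0, r, K, nu)
  if (any(!is.finite(t) | t < 0)) {
    abort("`t` must be finite and non-negative", class = "qfascreen_error_params")
  }
  .glogistic_density(t, x0, r, K, nu)
}

#' Maximum doubling potential (MDP)
#'
#' The number of population doublings between inoculation density and
#' carrying capacity, `log2(K / x0)`.
#'
#' @inheritParams glogistic_density
#' @return Doublings (dimensionless); zero when `K = x0`.
#' @examples
#' glogistic_mdp(x0 = 1, K = 1024)
#' @export
glogistic_mdp <- function(x0, K) {
  if (any(!is.finite(x0) | x0 <= 0)) {
    abort("`x0` must be positive", class = "qfascreen_error_params")
  }
  if (any(!is.finite(K) | K < x0)) {
    abort("`K` must be >= `x0`", class = "qfascreen_error_params")
  }
  log(K / x0) / log(2)
}

#' Maximum doubling rate (MDR)
#'
#' The reciprocal of the time taken for the fitted culture to first double
#' from its inoculation density,
#' `MDR = r nu / ln(((K/x0)^nu - 1) / ((K/(2 x0))^nu - 1))`.
#' In the dilute-inoculum limit `x0/K -> 0` this tends to `r / ln 2`.
#' A culture that can never double (`K <= 2 x0`) or does not grow (`r = 0`)
#' has `MDR = 0`.
#'
#' @inheritParams glogistic_density
#' @return Doublings per day.
#' @examples
#' glogistic_mdr(x0 = 1e-9, r = log(2), K = 1, nu = 1) # ~1 doubling/day
#' @export
glogistic_mdr <- function(x0, r, K, nu) {
  check_glogistic_params(x0, r, K, nu)
  out <- numeric(length(r + x0 + K + nu))
  grows <- K > 2 * x0 & r > 0
  if (any(grows)) {
    L1 <- logexpm1(nu * log(K / x0))
    L2 <- logexpm1(nu * log(pmax(K / (2 * x0), 1)))
    out[grows] <- (r * nu / (L1 - L2))[grows]
  }
  out
}

#' Scalar fitness: MDR times MDP
#'
#' @inheritParams glogistic_density
#' @return Fitness in doublings^2 per day; zero whenever either factor is zero.
#' @export
glogistic_fitness <- function(x0, r, K, nu) {
  glogistic_mdr(x0, r, K, nu) * glogistic_mdp(x0, K)
}

#' Control parameters for growth-curve fitting
#'
#' Bounds and the deterministic multistart grid used by [fit_growth()].
#' Fitting is bounded least squares on the linear density scale; each curve is
#' optimised from a fixed 3 x 3 x 3 grid of `(r, K, nu)` starting values so the
#' fit is reproducible without any random restarts.
#'
#' @param r_min,r_max Bounds on the growth-rate parameter (per day).
#' @param K_mult Upper bound on `K` as a multiple of the largest observed
#'   density of the curve.
#' @param nu_min,nu_max Bounds on the shape parameter.
#' @param r_starts,nu_starts Multistart values for `r` and `nu`.
#' @param K_start_mult Multistart values for `K`, as multiples of the largest
#'   observed density.
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @return A named list of class `qfa_fit_control`.
#' @export
growth_fit_control <- function(r_min = 1e-6, r_max = 50, K_mult = 10,
                               nu_min = 0.1, nu_max = 10,
                               r_starts = c(0.5, 3, 15),
                               nu_starts = c(0.5, 1, 2),
                               K_start_mult = c(0.95, 1.1, 2),
                               maxiter = 100) {
  stopifnot(r_min > 0, r_max > r_min, K_mult >= 1, nu_min > 0, nu_max > nu_min)
  structure(list(r_min = r_min, r_max = r_max, K_mult = K_mult,
                 nu_min = nu_min, nu_max = nu_max, r_starts = r_starts,
                 nu_starts = nu_starts, K_start_mult = K_start_mult,
                 maxiter = maxiter),
            class = "qfa_fit_control")
}

# Fit one curve. Returns list(r, K, nu, rss, converged).
fit_one_curve <- function(t, y, x0, ctrl) {
  n <- length(y)
  if (n < 4) {
    return(list(r = 0, K = x0, nu = 1, rss = sum((y - x0)^2), converged = FALSE))
  }
  if (all(y <= x0)) {
    return(list(r = 0, K = x0, nu = 1, rss = sum((y - x0)^2), converged = TRUE))
  }
  K_hi <- max(ctrl$K_mult * max(y), x0 * 1.001)
  lower <- c(ctrl$r_min, x0, ctrl$nu_min)
  upper <- c(ctrl$r_max, K_hi, ctrl$nu_max)
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  starts <- expand.grid(
    r = clamp(ctrl$r_starts, lower[1], upper[1]),
    K = clamp(ctrl$K_start_mult * max(y), lower[2], upper[2]),
    nu = clamp(ctrl$nu_starts, lower[3], upper[3])
  )
  resid_fn <- function(p) y - .glogistic_density(t, x0, p[1], p[2], p[3])
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = as.numeric(starts[i, ]), lower = lower, upper = upper,
        fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = ctrl$maxiter)
      )),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$deviance) || !(fit$info %in% 1:4)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    return(list(r = 0, K = x0, nu = 1, rss = sum((y - x0)^2), converged = FALSE))
  }
  p <- as.numeric(best$par)
  list(r = p[1], K = p[2], nu = p[3], rss = best$deviance, converged = TRUE)
}

#' Default shared inoculation density
#'
#' The inoculation density `x0` is treated as a single constant shared by all
#' spots on all plates of an experiment. The default estimate is the 5th
#' percentile of the first-timepoint densities across all cultures.
#'
#' @param data A time-course table as read by [read_timecourses()].
#' @return A single positive density.
#' @export
default_x0 <- function(data) {
  first <- data %>%
    group_by(.data$barcode, .data$row, .data$col) %>%
    slice(which.min(.data$expt_time_days)) %>%
    ungroup()
  x0 <- unname(quantile(first$density, 0.05))
  if (!is.finite(x0) || x0 <= 0) {
    abort("cannot estimate a positive `x0` from the first-timepoint densities",
          class = "qfascreen_error_params")
  }
  x0
}

#' Fit generalized logistic growth curves and derive fitness
#'
#' Fits the generalized logistic model independently to every culture in a
#' time-course table by bounded least squares on the linear density scale,
#' holding the inoculation density `x0` fixed, then derives the maximum
#' doubling rate (MDR), maximum doubling potential (MDP) and their product,
#' the scalar fitness.
#'
#' Curves with fewer than four observations cannot constrain the three free
#' parameters and receive the degenerate fallback (`r = 0`, `K = x0`,
#' `converged = FALSE`). Curves whose density never exceeds `x0` are treated
#' as dead (`K = x0`, `r = 0`, fitness 0). Cultures whose fitted capacity
#' cannot sustain a single doubling (`K <= 2 x0`) are flagged `never_doubles`
#' and get `MDR = 0`, hence fitness 0.
#'
#' @param data A time-course table with columns `barcode`, `row`, `col`,
#'   `gene`, `background`, `temperature`, `expt_time_days`, `density`
#'   (see [read_timecourses()]).
#' @param x0 Shared inoculation density; `NULL` (default) uses [default_x0()].
#' @param control A [growth_fit_control()] list.
#' @return A tibble of class `qfa_fitness`, one row per culture:
#'   `culture_id`, `barcode`, `row`, `col`, `gene`, `background`,
#'   `temperature`, `n_obs`, `r`, `K`, `nu`, `rss`, `converged`,
#'   `never_doubles`, `mdr`, `mdp`, `fitness`. The shared `x0` and control
#'   settings are stored as attributes.
#' @examples
#' sim <- simulate_screen_pair(sim_config(n_genes = 4, n_replicates = 2, seed = 1))
#' fit <- fit_growth(sim$control)
#' glance(fit)
#' @export
fit_growth <- function(data, x0 = NULL, control = growth_fit_control()) {
  check_timecourse_columns(data)
  if (is.null(x0)) x0 <- default_x0(data)
  stopifnot(is.numeric(x0), length(x0) == 1, x0 > 0)

  nested <- data %>%
    arrange(.data$barcode, .data$row, .data$col, .data$expt_time_days) %>%
    group_by(.data$barcode, .data$row, .data$col, .data$gene,
             .data$background, .data$temperature) %>%
    summarise(t = list(.data$expt_time_days), y = list(.data$density),
              .groups = "drop")

  fits <- purrr::map2(nested$t, nested$y, fit_one_curve, x0 = x0, ctrl = control)

  out <- nested %>%
    select(-"t", -"y") %>%
    mutate(
      culture_id = sprintf("%s_r%02d_c%02d", .data$barcode,
                           as.integer(.data$row), as.integer(.data$col)),
      n_obs = lengths(nested$y),
      r = purrr::map_dbl(fits, "r"),
      K = purrr::map_dbl(fits, "K"),
      nu = purrr::map_dbl(fits, "nu"),
      rss = purrr::map_dbl(fits, "rss"),
      converged = purrr::map_lgl(fits, "converged"),
      never_doubles = .data$K <= 2 * x0 | .data$r == 0,
      mdr = glogistic_mdr(x0, .data$r, .data$K, .data$nu),
      mdp = glogistic_mdp(x0, .data$K),
      fitness = .data$mdr * .data$mdp
    ) %>%
    select("culture_id", "barcode", "row", "col", "gene", "background",
           "temperature", "n_obs", "r", "K", "nu", "rss", "converged",
           "never_doubles", "mdr", "mdp", "fitness")

  structure(out, class = c("qfa_fitness", class(out)),
            x0 = x0, control = control)
}

#' @export
tidy.qfa_fitness <- function(x, ...) {
  as_tibble(x) %>%
    tidyr::pivot_longer(c("r", "K", "nu", "mdr", "mdp", "fitness"),
                        names_to = "term", values_to = "estimate") %>%
    select("culture_id", "gene", "background", "term", "estimate")
}

#' @export
glance.qfa_fitness <- function(x, ...) {
  tibble(
    n_cultures = nrow(x),
    n_converged = sum(x$converged),
    n_never_doubles = sum(x$never_doubles),
    median_rss = median(x$rss),
    x0 = attr(x, "x0")
  )
}

#' @export
autoplot.qfa_fitness <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$background, y = .data$fitness)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.3, size = 0.6) +
    ggplot2::labs(x = NULL, y = "fitness (MDR x MDP, doublings²/day)") +
    ggplot2::theme_bw()
}
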