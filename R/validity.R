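# Applicability machinery for the moment expansion: relative deviations
# Delta_r, the accuracy eps_a, gamma(beta, v), the limiting curves v_L and
# v_L0, and advisory regime classification.

#' Relative deviation of the moment expansion from the exact average
#'
#' `(approx - exact)/exact` for one component pair at given lag times; the
#' exact value comes from adaptive quadrature.  Points where the exact
#' average has decayed below `1e-12` are excluded (returned as `NA`): the
#' ratio is meaningless at a fully decayed tail.
#'
#' @param pair one of `"22"`, `"23"`, `"32"`, `"33"`.
#' @param t lag times (s, `> 0`), vectorised.
#' @param params an [fcs_params] object.
#' @param order 2 for the two-term moment expansion, 1 for the first-order
#'   (fast-reaction) truncation.
#' @param n_gl if `> 0`, use the Gauss-Legendre fast path for the exact
#'   values.
#' @return relative deviations (`NA` where excluded).
#' @export
relative_deviation <- function(pair, t, params, order = 2, n_gl = 0L) {
  pair <- check_pair(pair)
  stopifnot(inherits(params, "fcs_params"))
  exact <- vapply(t, function(ti) {
    if (n_gl > 0L) exact_average_gs_gl(pair, ti, params, n_gl)
    else exact_average_gs(pair, ti, params)
  }, numeric(1))
  approx <- if (order == 2) approx_average_gs(pair, t, params)
  else first_order_average_gs(pair, t, params)
  ifelse(abs(exact) < 1e-12, NA_real_, (approx - exact) / exact)
}

#' Accuracy of the moment expansion
#'
#' `eps_a`: the maximum of `|Delta_r|` over the component pairs 22, 32, 33
#' (23 equals 32 after normalisation) and a log-spaced time grid.  The
#' expansion is considered valid when `eps_a < epsilon` with
#' `epsilon = 0.01` as the working accuracy for FCS.
#'
#' @param params an [fcs_params] object.
#' @param t_grid lag-time grid; default 48 log-spaced points on
#'   `[1e-2, 1e3] * tau_B`.
#' @param order,n_gl passed to [relative_deviation()].
#' @param stop_above optional early-exit threshold: once the running
#'   maximum exceeds it the sweep stops (used by the bisection in
#'   [limiting_v()], where only the comparison with `epsilon` matters).
#' @return the achieved maximum `eps_a`.
#' @export
accuracy <- function(params, t_grid = NULL, order = 2, n_gl = 160L,
                     stop_above = Inf) {
  stopifnot(inherits(params, "fcs_params"))
  if (is.null(t_grid))
    t_grid <- params$diffusion$tau_B * 10^seq(-2, 3, length.out = 48)
  worst <- 0
  for (pair in c("22", "32", "33")) {
    dr <- relative_deviation(pair, t_grid, params, order = order, n_gl = n_gl)
    worst <- max(worst, abs(dr), na.rm = TRUE)
    if (worst > stop_above) return(worst)
  }
  worst
}

#' Rate parameter gamma as a function of beta and v
#'
#' `gamma = sqrt(k23 k32)` expressed through the dimensionless variables:
#' `gamma = (sqrt((1-beta)/beta)/tau_B + sqrt(beta/(1-beta))/tau_D) / v`.
#' Over beta at fixed `v` it attains its minimum at
#' `beta_min = tau_D/(tau_D + tau_B)`, and `gamma_min` is inversely
#' proportional to `v` -- the worst case for the expansion accuracy.
#'
#' @param beta bound fraction in (0, 1), vectorised.
#' @param v dimensionless relaxation/diffusion balance (`> 0`).
#' @param tau_D,tau_B diffusion times (s); `tau_D = Inf` allowed.
#' @return gamma values (s^-1).
#' @export
gamma_of_beta <- function(beta, v, tau_D, tau_B) {
  if (any(beta <= 0 | beta >= 1)) stop("'beta' must lie in (0, 1)")
  if (v <= 0) stop("'v' must be positive")
  tD_inv <- if (is.infinite(tau_D)) 0 else 1 / tau_D
  (sqrt((1 - beta) / beta) / tau_B + sqrt(beta / (1 - beta)) * tD_inv) / v
}

# beta grid used for the inner maximisation: coarse sweep of (0,1) refined
# around beta_min = tau_D/(tau_D + tau_B), where gamma is smallest.
validity_beta_grid <- function(tau_ratio, n = 25L) {
  beta_min <- 1 / (1 + tau_ratio)
  base <- seq(0.05, 0.95, length.out = n - 12L)
  refine <- beta_min + seq(-0.12, 0.12, length.out = 12L)
  sort(unique(pmin(pmax(c(base, refine), 0.02), 0.98)))
}

# eps_a maximised over beta for fixed (tau_ratio, v); the workhorse of the
# v_L bisection.
accuracy_over_beta <- function(tau_ratio, v, omega = 5, order = 2,
                               beta_grid = NULL, t_chi = NULL, n_gl = 160L,
                               stop_above = Inf) {
  if (is.null(beta_grid)) beta_grid <- validity_beta_grid(tau_ratio)
  if (is.null(t_chi)) t_chi <- 10^seq(-2, 3, length.out = 48)
  worst <- 0
  for (beta in beta_grid) {
    p <- fcs_params_dimensionless(tau_ratio, beta, v, omega = omega)
    worst <- max(worst, accuracy(p, t_grid = t_chi * p$diffusion$tau_B,
                                 order = order, n_gl = n_gl,
                                 stop_above = stop_above))
    if (worst > stop_above) break
  }
  worst
}

#' Limiting value of v for the moment expansion
#'
#' The largest `v` such that the expansion accuracy `eps_a` (maximised over
#' beta and a log time grid) stays below `epsilon`.  Found by bisection on
#' `v`; `order = 2` gives `v_L` (two-term expansion), `order = 1` gives
#' `v_L0` (first-order truncation), which is roughly an order of magnitude
#' smaller.  Only `tau_B/tau_D <= 0.30` is supported -- beyond that the
#' equal-coefficient assumption for macromolecule and complex is itself in
#' doubt.  `v_L` is nondecreasing in `tau_ratio`.
#'
#' @param tau_ratio `tau_B/tau_D` in `[0, 0.30]` (0 = immobile sites).
#' @param epsilon required accuracy (default 0.01).
#' @param order 2 for `v_L`, 1 for `v_L0`.
#' @param omega focal-volume aspect ratio used in the sweep.
#' @param v_lo,v_hi initial bisection bracket.
#' @param tol relative bisection tolerance on `v` (default 2%, matching the
#'   1-2 significant figures of the quoted boundary values).
#' @param beta_scan `"full"` (default) maximises the deviation over the
#'   whole beta grid -- the genuine worst case, which at small `tau_ratio`
#'   is reached in the hybrid corner (`beta` near 1, `k32 << k23`) where
#'   the expansion's averages are known to deteriorate; `"beta_min"`
#'   evaluates only at `beta_min = tau_D/(tau_D + tau_B)`, the worst-gamma
#'   argument, which yields a more permissive boundary there.
#' @param beta_grid,t_chi,n_gl inner-maximisation grids (see
#'   [accuracy()]).
#' @return the boundary value of `v`.
#' @export
limiting_v <- function(tau_ratio, epsilon = 0.01, order = 2, omega = 5,
                       v_lo = 0.02, v_hi = 25, tol = 0.02,
                       beta_scan = c("full", "beta_min"),
                       beta_grid = NULL, t_chi = NULL, n_gl = 160L) {
  if (tau_ratio < 0 || tau_ratio > 0.30)
    stop("unsupported regime: tau_B/tau_D must lie in [0, 0.30]")
  beta_scan <- match.arg(beta_scan)
  if (is.null(beta_grid) && beta_scan == "beta_min")
    beta_grid <- 1 / (1 + tau_ratio)
  f <- function(v) accuracy_over_beta(tau_ratio, v, omega = omega,
                                      order = order, beta_grid = beta_grid,
                                      t_chi = t_chi, n_gl = n_gl,
                                      stop_above = 1.2 * epsilon) - epsilon
  flo <- f(v_lo)
  if (flo > 0) stop(sprintf("eps_a already exceeds epsilon at v = %g", v_lo))
  fhi <- f(v_hi)
  if (fhi < 0) return(v_hi)  # boundary beyond the searched range
  lo <- v_lo
  hi <- v_hi
  while (hi / lo > 1 + 2 * tol) {
    mid <- sqrt(lo * hi)
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  sqrt(lo * hi)
}

# Advisory v_L / v_L0 lookup, precomputed with limiting_v() at omega = 5 on
# a tau_ratio grid (production grids).  Used only by classify_regime() so
# that a classification does not cost minutes; all quantitative work calls
# limiting_v() directly.
VL_TABLE <- data.frame(
  tau_ratio = c(0.001, 0.01, 0.05, 1 / 6, 0.30),
  v_L  = c(0.229, 0.320, 0.624, 1.80, 6.66),
  v_L0 = c(0.0221, 0.0291, 0.0481, 0.114, 0.249)
)

vl_lookup <- function(tau_ratio, order = 2) {
  col <- if (order == 2) "v_L" else "v_L0"
  stats::approx(VL_TABLE$tau_ratio, log(VL_TABLE[[col]]),
                xout = min(max(tau_ratio, 0.001), 0.30), rule = 2)$y |> exp()
}

#' Regime classification and diagnostics
#'
#' Classifies a parameter point into the advisory regimes: pure diffusion
#' (`k23 << k32`), hybrid (`k32 << k23`), reaction-dominant
#' (`tau_B k23 << 1` with slow detachment), slow reaction (both relaxation
#' times long against the diffusion times), effective diffusion (`v` well
#' below the first-order boundary), fast reaction (`v < v_L0`), or
#' intermediate (`v < v_L`).  "Much smaller" is operationalised as a ratio
#' below 0.1.  The labels are advisory: `v > v_L` does not automatically
#' mean the expansion fails (its weight in `G(t)` may be negligible), so
#' the object carries the raw diagnostics and a confidence note rather than
#' a hard rejection.
#'
#' @param params an [fcs_params] object.
#' @param epsilon required accuracy for the validity comparison.
#' @param v_L,v_L0 boundary values; by default interpolated from a table
#'   precomputed with [limiting_v()] at `omega = 5`.  Pass explicit values
#'   (e.g. freshly bisected) for quantitative work.
#' @param compute_accuracy also evaluate `eps_a` for this parameter point
#'   (costs a quadrature sweep)?
#' @return object of class `fcs_regime`: fields `v`, `v_L`, `v_L0`,
#'   `epsilon`, `epsilon_a`, `gamma_min`, `beta_min`, `label`, `valid`,
#'   `note`, and `t_t` (fast-diffusion transition time, `D = 0` only).
#' @export
classify_regime <- function(params, epsilon = 0.01, v_L = NULL, v_L0 = NULL,
                            compute_accuracy = FALSE) {
  stopifnot(inherits(params, "fcs_params"))
  sc <- params$scheme
  d <- params$diffusion
  tau_ratio <- d$tau_ratio
  if (is.null(v_L)) v_L <- vl_lookup(tau_ratio, order = 2)
  if (is.null(v_L0)) v_L0 <- vl_lookup(tau_ratio, order = 1)
  v <- params$v
  beta_min <- 1 / (1 + tau_ratio)
  # immobile sites: the gamma minimum is the (unattained) beta -> 1 limit
  gamma_min <- if (d$immobile) 0
  else gamma_of_beta(beta_min, v, d$tau_D, d$tau_B)
  rd <- d$tau_B * sc$k23 < 0.1
  label <-
    if (sc$k23 / sc$k32 < 0.1) "pure_diffusion"
    else if (sc$k32 / sc$k23 < 0.1) {
      if (rd) "reaction_dominant" else "hybrid"
    }
    else if (rd && (d$immobile || d$tau_D * sc$k32 < 0.1)) {
      if (d$immobile) "reaction_dominant" else "slow_reaction"
    }
    else if (v < 0.1 * v_L0) "effective_diffusion_ok"
    else if (v < v_L0) "fast_reaction"
    else "intermediate"
  valid <- v < v_L
  note <- if (valid)
    sprintf("v = %.3g < v_L = %.3g: moment expansion accurate to %.3g", v, v_L, epsilon)
  else
    sprintf(paste0("v = %.3g > v_L = %.3g: expansion accuracy not guaranteed, ",
                   "but it may still hold where the affected averages carry ",
                   "little weight in G(t)"), v, v_L)
  eps_a <- if (compute_accuracy) accuracy(params) else NA_real_
  structure(list(v = v, v_L = v_L, v_L0 = v_L0, epsilon = epsilon,
                 epsilon_a = eps_a, gamma_min = gamma_min,
                 beta_min = beta_min, label = label, valid = valid,
                 note = note,
                 t_t = if (d$immobile) transition_time(params) else NA_real_),
            class = "fcs_regime")
}

#' @export
print.fcs_regime <- function(x, ...) {
  cat("FCS reaction-diffusion regime diagnostics\n")
  cat(sprintf("  label: %s\n", x$label))
  cat(sprintf("  v = %.4g, v_L = %.4g, v_L0 = %.4g (epsilon = %.3g)\n",
              x$v, x$v_L, x$v_L0, x$epsilon))
  if (!is.na(x$epsilon_a))
    cat(sprintf("  achieved accuracy eps_a = %.4g\n", x$epsilon_a))
  cat(sprintf("  gamma_min = %.4g /s at beta_min = %.4g\n",
              x$gamma_min, x$beta_min))
  if (!is.na(x$t_t)) cat(sprintf("  transition time t_t = %.4g s\n", x$t_t))
  cat(" ", x$note, "\n")
  invisible(x)
}
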