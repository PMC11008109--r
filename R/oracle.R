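# Independent brute-force oracles.  These deliberately avoid every closed
# form used by the main engine: the occupation sampler runs exact-event
# (Gillespie) two-state paths, and the single-species ACF is evaluated as a
# direct wave-vector integral of the Gaussian-filtered free-diffusion
# propagator.  They live in the package, not only in the tests, so any
# parameter point can be audited; both are slow paths.

#' Sample two-state occupation fractions (Gillespie oracle)
#'
#' Exact-event simulation of the fictitious 2 <-> 3 reaction with rates
#' `k23` (2 -> 3) and `k32` (3 -> 2): for each path, the fraction `rho` of
#' the interval `[0, t]` spent in the bound state 3, the end state and the
#' number of switches.  Conditioning on an end state is done by
#' partitioning the returned sample, never by reweighting.  One integer
#' seed fully determines the draw; paths are simulated in lockstep
#' (vectorised over paths), so the draw for a given `(seed, n_paths)` is
#' reproducible.
#'
#' @param scheme an [fcs_params] object or a list with `k23`, `k32`.
#' @param t interval length (s, `> 0`).
#' @param start_state 2 (free) or 3 (bound).
#' @param n_paths number of paths (`>= 1`).
#' @param seed mandatory integer seed.
#' @return data frame of class `fcs_occupation_sample` with columns
#'   `start_state`, `end_state`, `rho`, `n_switches`.
#' @export
sample_occupation <- function(scheme, t, start_state = 2L, n_paths, seed) {
  scheme <- as_scheme(scheme)
  if (length(t) != 1L || !is.finite(t) || t <= 0) stop("'t' must be positive")
  if (!start_state %in% c(2L, 3L)) stop("'start_state' must be 2 or 3")
  if (n_paths < 1L) stop("'n_paths' must be at least 1")
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  set.seed(seed)
  rates <- c(`2` = scheme$k23, `3` = scheme$k32)
  state <- rep.int(start_state, n_paths)
  clock <- numeric(n_paths)
  t3 <- numeric(n_paths)
  nsw <- integer(n_paths)
  active <- rep.int(TRUE, n_paths)
  while (any(active)) {
    idx <- which(active)
    r <- rates[as.character(state[idx])]
    dt <- ifelse(r > 0, stats::rexp(length(idx), pmax(r, .Machine$double.xmin)), Inf)
    stay <- pmin(dt, t - clock[idx])
    in3 <- state[idx] == 3L
    t3[idx][in3] <- t3[idx][in3] + stay[in3]
    clock[idx] <- clock[idx] + dt
    switched <- clock[idx] < t
    sw <- idx[switched]
    state[sw] <- 5L - state[sw]
    nsw[sw] <- nsw[sw] + 1L
    active[idx[!switched]] <- FALSE
  }
  out <- data.frame(start_state = rep.int(start_state, n_paths),
                    end_state = state, rho = t3 / t, n_switches = nsw)
  class(out) <- c("fcs_occupation_sample", class(out))
  out
}

#' Single-species ACF by direct wave-vector integration
#'
#' Evaluates the one-component diffusion autocorrelation as the wave-vector
#' integral of the Gaussian-filtered free-diffusion Green's function (no
#' use of the closed form): the transverse and axial factors are computed
#' by adaptive quadrature over `q` and normalised to 1 at `t = 0`.
#'
#' @param t lag time (s, `>= 0`), scalar.
#' @param tau diffusion time `L^2/(4D)` (s).
#' @param omega aspect ratio `H/L`.
#' @return correlation value; agrees with [gs()] to better than 1e-6
#'   relative.
#' @export
gs_bruteforce <- function(t, tau, omega) {
  if (length(t) != 1L || t < 0) stop("'t' must be a nonnegative scalar")
  # units L = 1, D = 1/(4 tau); filter exp(-q^2 L^2/4) transverse (2D,
  # weight q from the radial measure), exp(-q_z^2 H^2/4) axial.
  D <- 1 / (4 * tau)
  trans <- function(s) stats::integrate(function(q) q * exp(-q^2 * (0.25 + D * s)),
                                        0, Inf, rel.tol = 1e-10)$value
  axial <- function(s) stats::integrate(function(q) exp(-q^2 * (omega^2 / 4 + D * s)),
                                        0, Inf, rel.tol = 1e-10)$value
  (trans(t) / trans(0)) * (axial(t) / axial(0))
}
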