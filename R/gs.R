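# Single-species diffusion autocorrelation for a 3D Gaussian observation
# volume, its second derivative, closed-form antiderivatives, and the two
# classical reference models (effective diffusion, two-component diffusion).

#' Single-species diffusion autocorrelation
#'
#' Autocorrelation of a freely diffusing fluorescent species observed through
#' a 3D Gaussian focal volume with aspect ratio `omega = H/L`:
#' `gs(chi) = (1 + chi)^-1 (1 + chi/omega^2)^-1/2` with `chi = t/tau` the lag
#' in units of the diffusion time `tau = L^2/(4D)`.  Normalised to 1 at
#' `chi = 0` and strictly decreasing.  `omega = Inf` gives the 2D limit
#' `(1 + chi)^-1` (axial decay suppressed).
#'
#' @param chi dimensionless lag `t/tau`, vectorised, must be `>= 0`.
#' @param omega aspect ratio `H/L` (`> 0`, possibly `Inf`).
#' @return correlation values in `(0, 1]`.
#' @examples
#' gs(0, 5)        # 1
#' gs(1, 5)
#' @export
gs <- function(chi, omega) {
  if (any(chi < 0)) stop("'chi' must be nonnegative")
  if (length(omega) != 1L || is.na(omega) || omega <= 0)
    stop("'omega' must be a single positive number")
  if (is.infinite(omega)) return(1 / (1 + chi))
  1 / ((1 + chi) * sqrt(1 + chi / omega^2))
}

#' Second derivative of the single-species autocorrelation
#'
#' Analytic `d^2 gs / d chi^2`; positive for all `chi >= 0` (gs is convex),
#' which is what makes `gs(t/tau_rho)` an increasing convex function of the
#' occupation fraction `rho`.
#'
#' @inheritParams gs
#' @return second-derivative values (`> 0`).
#' @export
gs_dd <- function(chi, omega) {
  if (any(chi < 0)) stop("'chi' must be nonnegative")
  if (length(omega) != 1L || is.na(omega) || omega <= 0)
    stop("'omega' must be a single positive number")
  A <- 1 / (1 + chi)
  if (is.infinite(omega)) return(2 * A^3)
  B <- 1 / sqrt(1 + chi / omega^2)
  2 * A^3 * B + A^2 * B^3 / omega^2 + 0.75 * A * B^5 / omega^4
}

# Antiderivative of gs(chi, omega) w.r.t. chi (any constant offset); used for
# the closed-form slow-reaction coupling integral and the fast-diffusion
# averages.  Increasing in chi.
gs_antideriv <- function(chi, omega) {
  if (is.infinite(omega)) return(log1p(chi))
  s <- sqrt(chi + omega^2)
  if (omega > 1) {
    c0 <- sqrt(omega^2 - 1)
    (omega / c0) * log((s - c0) / (s + c0))
  } else if (omega < 1) {
    c0 <- sqrt(1 - omega^2)
    -(2 * omega / c0) * atan(c0 / s)
  } else {
    -2 / s
  }
}

# Antiderivative of chi * gs(chi, omega): integrate (1 + chi) gs - gs.
gs_chi_antideriv <- function(chi, omega) {
  if (is.infinite(omega)) return(chi - log1p(chi))
  2 * omega * sqrt(chi + omega^2) - gs_antideriv(chi, omega)
}

# Mean of gs(t/tau_rho) under the uniform density of rho on [0, 1]:
# (tau_Delta / t) * int_{chi_D}^{chi_B} gs.  Degenerates to gs(chi_B) when
# the two diffusion times coincide.
gs_uniform_mean <- function(t, params) {
  d <- params$diffusion
  chi_B <- t / d$tau_B
  if (d$tau_Delta_inv <= 0) return(gs(chi_B, params$volume$omega))
  chi_D <- t * d$tau_D_inv
  out <- (gs_antideriv(chi_B, params$volume$omega) -
            gs_antideriv(chi_D, params$volume$omega)) / (t * d$tau_Delta_inv)
  out[t == 0] <- 1
  out
}

#' Effective-diffusion autocorrelation (fast-reaction limit)
#'
#' The `R -> infinity` limit of the full model: the reacting dye behaves as a
#' single species with the population-averaged diffusion coefficient
#' `D_beta = (1 - beta) D_B + beta D` and effective quantum yield
#' `Q_beta = (1 - beta) Q_B + beta Q_C`, alongside the freely diffusing
#' species-1 (macromolecule) term.  Depends on the equilibrium constant only,
#' not on the individual rate constants.
#'
#' @param t lag times (s), vectorised.
#' @param params an [fcs_params] object.
#' @return autocorrelation values `G_inf(t)`.
#' @export
effective_diffusion_acf <- function(t, params) {
  stopifnot(inherits(params, "fcs_params"))
  om <- params$volume$omega
  b <- params$scheme$beta
  br <- params$brightness
  N <- params$numbers
  tau_beta_inv <- (1 - b) / params$diffusion$tau_B + b * params$diffusion$tau_D_inv
  NT <- N$N2 + N$N3
  (br$Q_C^2 * N$N1 * gs(t * params$diffusion$tau_D_inv, om) +
     br$Q_beta^2 * NT * gs(t * tau_beta_inv, om)) / params$n_bar^2
}

#' Two-component (noninteracting) diffusion autocorrelation
#'
#' The `R -> 0` limit: free dye (`N_B`, brightness `Q_B`, diffusion time
#' `tau_B`) and complex (`N_C = N1 + N3`, brightness `Q_C`, diffusion time
#' `tau_D`) diffuse independently with no chemical exchange.
#'
#' @inheritParams effective_diffusion_acf
#' @return autocorrelation values.
#' @export
two_component_acf <- function(t, params) {
  stopifnot(inherits(params, "fcs_params"))
  om <- params$volume$omega
  br <- params$brightness
  N <- params$numbers
  (br$Q_B^2 * N$N2 * gs(t / params$diffusion$tau_B, om) +
     br$Q_C^2 * (N$N1 + N$N3) * gs(t * params$diffusion$tau_D_inv, om)) /
    params$n_bar^2
}
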