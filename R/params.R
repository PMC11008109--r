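# Model parameters for the reversible-binding FCS model A + B <-> C.
#
# Physical boundary units: lengths in micrometres, times in seconds,
# diffusion coefficients in um^2/s, concentrations in molecules/um^3 (so
# that N_i = C_i * V directly).  All internal computation is carried out in
# dimensionless form (t/tau_B, tau_B/tau_D, beta, v).

#' Build model parameters from physical quantities
#'
#' Constructs the full parameter set for the reversible binding of a
#' fluorescent dye B to a macromolecule A forming a complex C, with the
#' macromolecule and complex sharing one diffusion coefficient `D` and the
#' dye diffusing with `D_B > D`.  All derived quantities are computed here:
#' the linearised rates `k_A = k_plus*C_B`, `k_B = k_plus*C_A`,
#' `k_C = k_minus`; the fictitious-reaction rates `k23 = k_B`,
#' `k32 = k_A + k_C`; the chemical relaxation rate `R = k23 + k32` and
#' `beta = k23/R`; `gamma = sqrt(k23*k32)`; diffusion times; the species
#' 1/2/3 amplitudes `C1 = k_A*C_C/k32`, `C2 = C_B`, `C3 = k_C*C_C/k32`
#' (which satisfy `C1 + C3 = C_C` and `C3/C2 = k23/k32`); and the
#' dimensionless reaction/diffusion balance
#' `v = 1/(k23*tau_B) + 1/(k32*tau_D)`.
#'
#' `D = 0` (immobile macromolecule and complex) is fully supported:
#' `tau_D` is then infinite and is represented internally through
#' `tau_D_inv = 0`.  `D = D_B` is allowed as a degenerate case (flagged);
#' `D > D_B` is rejected because the equal-coefficient assumption for A and
#' C breaks down there.
#'
#' @param k_plus forward (binding) rate constant, um^3 s^-1.
#' @param k_minus backward (dissociation) rate constant, s^-1.
#' @param C_A,C_B,C_C equilibrium concentrations, molecules/um^3; must obey
#'   detailed balance `C_C/(C_A*C_B) = k_plus/k_minus` to relative 1e-10.
#' @param D diffusion coefficient of macromolecule and complex, um^2/s
#'   (`>= 0`).
#' @param D_B dye diffusion coefficient, um^2/s (`> 0`).
#' @param L,H beam radius and axial dimension of the Gaussian focal
#'   volume, um.
#' @param Q_B,Q_C quantum yields (brightness) of free dye and complex;
#'   nonnegative, not both zero.
#' @return an object of class `fcs_params`.
#' @examples
#' p <- fcs_params(k_plus = 10, k_minus = 1e3, C_A = 50, C_B = 20, C_C = 10,
#'                 D = 50, D_B = 470, L = 0.2, H = 1, Q_B = 1, Q_C = 1.5)
#' p$scheme$beta
#' @export
fcs_params <- function(k_plus, k_minus, C_A, C_B, C_C, D, D_B, L, H,
                       Q_B, Q_C) {
  for (nm in c("k_plus", "k_minus", "C_A", "C_B", "C_C", "D_B", "L", "H")) {
    val <- get(nm)
    if (length(val) != 1L || !is.finite(val) || val <= 0)
      stop(sprintf("'%s' must be a single positive number", nm))
  }
  if (length(D) != 1L || !is.finite(D) || D < 0)
    stop("'D' must be a single nonnegative number")
  if (D > D_B)
    stop("unsupported regime: D > D_B; the model assumes the macromolecule ",
         "and complex diffuse no faster than the dye (studied up to D/D_B < 0.3)")
  K <- k_plus / k_minus
  resid <- abs(C_C / (C_A * C_B) - K) / K
  if (resid > 1e-10)
    stop(sprintf(paste0("equilibrium inconsistency: C_C/(C_A*C_B) deviates ",
                        "from k_plus/k_minus by relative %.3g (tolerance 1e-10)"),
                 resid))
  k_A <- k_plus * C_B
  k_B <- k_plus * C_A
  k_C <- k_minus
  scheme <- new_reaction_scheme(k23 = k_B, k32 = k_A + k_C,
                                k_plus = k_plus, k_minus = k_minus,
                                k_A = k_A, k_B = k_B, k_C = k_C,
                                C_A = C_A, C_B = C_B, C_C = C_C)
  C1 <- k_A * C_C / scheme$k32
  C3 <- k_C * C_C / scheme$k32
  new_fcs_params(scheme = scheme, D = D, D_B = D_B, L = L, H = H,
                 Q_B = Q_B, Q_C = Q_C,
                 C1 = C1, C2 = C_B, C3 = C3,
                 source = "physical")
}

#' Build model parameters from the dimensionless set
#'
#' Parameterises the model by the three independent dimensionless quantities
#' used throughout the validity analysis -- the diffusion-time ratio
#' `tau_ratio = tau_B/tau_D`, the bound fraction `beta = k23/R` of the
#' fictitious 2 <-> 3 reaction, and `v = 1/(k23*tau_B) + 1/(k32*tau_D)` --
#' plus the geometry and amplitude information required to assemble a full
#' correlation curve.  `tau_B` sets the unit of time;
#' `R*tau_B = (1/beta + tau_ratio/(1-beta))/v`.
#'
#' @param tau_ratio `tau_B/tau_D` in `[0, 1]`; 0 means an immobile
#'   macromolecule (`D = 0`), 1 the degenerate equal-coefficient case.
#' @param beta bound fraction of the fictitious reaction, in (0, 1).
#' @param v dimensionless relaxation/diffusion balance (`> 0`).
#' @param omega focal-volume aspect ratio `H/L` (default 5).
#' @param tau_B dye diffusion time, s (unit of time; default 1).
#' @param N1,N23 mean numbers of species-1 molecules and of dye-carrying
#'   molecules (`N2 + N3`) in the sampling volume; `N2 = (1-beta)*N23`,
#'   `N3 = beta*N23`.
#' @param Q_B,Q_C quantum yields of free dye and complex.
#' @param L beam radius, um (default 1; only fixes absolute scales).
#' @return an object of class `fcs_params` (physical concentrations `NA`).
#' @examples
#' p <- fcs_params_dimensionless(1/6, 0.5, 1)
#' dimensionless_view(p)$R_tau_B  # 7/3
#' @export
fcs_params_dimensionless <- function(tau_ratio, beta, v, omega = 5,
                                     tau_B = 1, N1 = 0, N23 = 1,
                                     Q_B = 1, Q_C = 1, L = 1) {
  if (length(tau_ratio) != 1L || !is.finite(tau_ratio) ||
      tau_ratio < 0 || tau_ratio > 1)
    stop("'tau_ratio' must lie in [0, 1]")
  if (length(beta) != 1L || !is.finite(beta) || beta <= 0 || beta >= 1)
    stop("'beta' must lie strictly inside (0, 1)")
  if (length(v) != 1L || !is.finite(v) || v <= 0)
    stop("'v' must be positive")
  stopifnot(tau_B > 0, L > 0, omega > 0, N23 >= 0, N1 >= 0)
  R <- (1 / beta + tau_ratio / (1 - beta)) / (v * tau_B)
  k23 <- R * beta
  k32 <- R * (1 - beta)
  scheme <- new_reaction_scheme(k23 = k23, k32 = k32,
                                k_plus = NA_real_, k_minus = NA_real_,
                                k_A = NA_real_, k_B = NA_real_,
                                k_C = NA_real_,
                                C_A = NA_real_, C_B = NA_real_,
                                C_C = NA_real_)
  D_B <- L^2 / (4 * tau_B)
  D <- tau_ratio * D_B
  V <- pi^1.5 * L^2 * (omega * L)
  new_fcs_params(scheme = scheme, D = D, D_B = D_B, L = L, H = omega * L,
                 Q_B = Q_B, Q_C = Q_C,
                 C1 = N1 / V, C2 = (1 - beta) * N23 / V,
                 C3 = beta * N23 / V,
                 source = "dimensionless")
}

new_reaction_scheme <- function(k23, k32, k_plus, k_minus, k_A, k_B, k_C,
                                C_A, C_B, C_C) {
  R <- k23 + k32
  list(k_plus = k_plus, k_minus = k_minus,
       C_A = C_A, C_B = C_B, C_C = C_C,
       k_A = k_A, k_B = k_B, k_C = k_C,
       k23 = k23, k32 = k32,
       R = R, beta = k23 / R,
       gamma = sqrt(k23 * k32),
       t_f = 1 / k23, t_b = 1 / k32)
}

new_fcs_params <- function(scheme, D, D_B, L, H, Q_B, Q_C, C1, C2, C3,
                           source) {
  if (Q_B < 0 || Q_C < 0 || (Q_B == 0 && Q_C == 0))
    stop("quantum yields must be nonnegative and not both zero")
  beta <- scheme$beta
  tau_B <- L^2 / (4 * D_B)
  tau_D_inv <- 4 * D / L^2
  volume <- list(L = L, H = H, omega = H / L, V = pi^1.5 * L^2 * H)
  diffusion <- list(D = D, D_B = D_B,
                    tau_B = tau_B,
                    tau_D = if (D > 0) L^2 / (4 * D) else Inf,
                    tau_D_inv = tau_D_inv,
                    tau_Delta_inv = 1 / tau_B - tau_D_inv,
                    tau_ratio = D / D_B,
                    immobile = (D == 0),
                    degenerate = (D == D_B))
  brightness <- list(Q_B = Q_B, Q_C = Q_C,
                     Q1 = Q_C, Q2 = Q_B, Q3 = Q_C,
                     Q_beta = (1 - beta) * Q_B + beta * Q_C)
  V <- volume$V
  numbers <- list(N_A = scheme$C_A * V, N_B = C2 * V,
                  N_C = (C1 + C3) * V,
                  N1 = C1 * V, N2 = C2 * V, N3 = C3 * V,
                  C1 = C1, C2 = C2, C3 = C3)
  v <- 1 / (scheme$k23 * tau_B) + tau_D_inv / scheme$k32
  structure(list(volume = volume, scheme = scheme, diffusion = diffusion,
                 brightness = brightness, numbers = numbers,
                 n_bar = Q_B * numbers$N2 + Q_C * (numbers$N1 + numbers$N3),
                 v = v, source = source),
            class = "fcs_params")
}

#' Dimensionless view of a parameter set
#'
#' Returns the three independent dimensionless parameters of the model
#' (`tau_B/tau_D`, `beta`, `v`) plus `R*tau_B`; the exact inverse of
#' [fcs_params_dimensionless()]'s derivation.
#'
#' @param params an [fcs_params] object.
#' @return list with `tau_ratio`, `beta`, `v`, `R_tau_B`.
#' @export
dimensionless_view <- function(params) {
  stopifnot(inherits(params, "fcs_params"))
  list(tau_ratio = params$diffusion$tau_ratio,
       beta = params$scheme$beta,
       v = params$v,
       R_tau_B = params$scheme$R * params$diffusion$tau_B)
}

#' @export
print.fcs_params <- function(x, ...) {
  s <- x$scheme; d <- x$diffusion
  cat("FCS reaction-diffusion model parameters (", x$source, ")\n", sep = "")
  cat(sprintf("  k23 = %.6g /s, k32 = %.6g /s, R = %.6g /s, beta = %.4f\n",
              s$k23, s$k32, s$R, s$beta))
  cat(sprintf("  tau_B = %.6g s, tau_D = %.6g s (tau_B/tau_D = %.4g), v = %.4g\n",
              d$tau_B, d$tau_D, d$tau_ratio, x$v))
  cat(sprintf("  L = %.4g um, omega = %.3g, V = %.4g um^3\n",
              x$volume$L, x$volume$omega, x$volume$V))
  cat(sprintf("  Q_B = %.3g, Q_C = %.3g; N1 = %.4g, N2 = %.4g, N3 = %.4g, n_bar = %.4g\n",
              x$brightness$Q_B, x$brightness$Q_C,
              x$numbers$N1, x$numbers$N2, x$numbers$N3, x$n_bar))
  invisible(x)
}
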