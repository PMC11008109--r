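# Assembly of the full autocorrelation function G(t).
#
# The exact route averages gs(t/tau_rho) over the occupation densities by
# adaptive quadrature (endpoint atoms handled analytically); the closed-form
# route replaces each average by a two-term moment expansion around the mean
# occupation fraction.  Both share the same propagator prefactors (masses),
# so a transcription error in the prefactors cannot make the routes agree
# spuriously.

ACF_METHODS <- c("exact", "moment_expansion", "first_order", "effective",
                 "two_component", "slow_reaction", "fast_diffusion")

# inverse diffusion time at occupation fraction rho
tau_rho_inv <- function(rho, params) {
  (1 - rho) / params$diffusion$tau_B + rho * params$diffusion$tau_D_inv
}

# Integration window for the continuous part of Phi_pair: at large Rt the
# density concentrates, and blind adaptive quadrature can miss the peak.
# Bracket using the moments of the continuous part (atoms removed).
phi_cont_window <- function(pair, x, beta) {
  cm <- phi_cont_moments_x(pair, x, beta)
  if (cm$cmass <= 1e-300) return(c(0, 1))
  lo <- max(0, cm$mean_rho - 40 * cm$sigma)
  hi <- min(1, cm$mean_rho + 40 * cm$sigma)
  if (hi - lo > 0.9) c(0, 1) else c(lo, hi)
}

# The gs factor decays with chi(rho) = t*((1-rho)/tau_B + rho/tau_D), which
# can vary by orders of magnitude across [0, 1] (a boundary layer near
# rho = 1 when the macromolecule is slow and t >> tau_B).  Split the
# integration at the points where chi crosses 3, 30 and 300 so neither
# quadrature path can overlook the layer.
integration_pieces <- function(t, params, win) {
  chi_B <- t / params$diffusion$tau_B
  chi_D <- t * params$diffusion$tau_D_inv
  pts <- win
  if (chi_B > chi_D) {
    for (cc in c(3, 30, 300)) {
      if (cc < chi_B && cc > chi_D) {
        r <- (chi_B - cc) / (chi_B - chi_D)
        if (r > win[1] && r < win[2]) pts <- c(pts, r)
      }
    }
  }
  sort(unique(pts))
}

#' Exact averaged single-species autocorrelation
#'
#' The exact correlation component `G_pair(t)`: endpoint-atom contributions
#' (`atom0 * gs(t/tau_B)`, `atom1 * gs(t/tau_D)`) plus adaptive quadrature
#' of the unnormalised continuous density times `gs(t/tau_rho)` over (0, 1).
#' Includes the propagator prefactor (mass), so at `t = 0` the diagonal
#' pairs give 1 and the cross pairs 0.
#'
#' @param pair one of `"22"`, `"23"`, `"32"`, `"33"`.
#' @param t lag time (s, `> 0`); scalar.
#' @param params an [fcs_params] object.
#' @param abs.tol absolute quadrature tolerance.
#' @return averaged correlation value.
#' @export
exact_average_gs <- function(pair, t, params, abs.tol = 1e-9) {
  pair <- check_pair(pair)
  stopifnot(inherits(params, "fcs_params"))
  if (length(t) != 1L || !is.finite(t) || t < 0) stop("'t' must be nonnegative")
  if (t == 0) return(if (pair %in% c("22", "33")) 1 else 0)
  sc <- params$scheme
  om <- params$volume$omega
  x <- sc$R * t
  beta <- sc$beta
  atoms <- phi_atoms_x(pair, x, beta)
  acc <- atoms$atom0 * gs(t / params$diffusion$tau_B, om) +
    atoms$atom1 * gs(t * params$diffusion$tau_D_inv, om)
  if (params$diffusion$degenerate) {
    # tau_rho constant in rho: average is mass * gs(t/tau_D)
    mom <- phi_moments_x(pair, x, beta)
    return(unname((mom$mass - atoms$atom0 - atoms$atom1) *
                    gs(t / params$diffusion$tau_B, om) + acc))
  }
  win <- phi_cont_window(pair, x, beta)
  pts <- integration_pieces(t, params, win)
  f <- function(rho) phi_cont_x(pair, x, beta, rho) * gs(t * tau_rho_inv(rho, params), om)
  total <- 0
  for (k in seq_len(length(pts) - 1L)) {
    res <- tryCatch(
      stats::integrate(f, pts[k], pts[k + 1L], rel.tol = 1e-10,
                       abs.tol = abs.tol / (length(pts) - 1L),
                       subdivisions = 400L),
      error = function(e) e)
    if (inherits(res, "error") || res$message != "OK") {
      achieved <- if (inherits(res, "error")) NA_real_ else res$abs.error
      stop(sprintf("quadrature failed for pair %s at t = %g (achieved abs. error %g)",
                   pair, t, achieved))
    }
    total <- total + res$value
  }
  unname(acc + total)
}

# Fast fixed-order Gauss-Legendre version, used by the validity sweeps where
# hundreds of thousands of smooth bracketed integrals are needed.
exact_average_gs_gl <- function(pair, t, params, n_gl = 160L) {
  sc <- params$scheme
  om <- params$volume$omega
  x <- sc$R * t
  beta <- sc$beta
  atoms <- phi_atoms_x(pair, x, beta)
  acc <- atoms$atom0 * gs(t / params$diffusion$tau_B, om) +
    atoms$atom1 * gs(t * params$diffusion$tau_D_inv, om)
  win <- phi_cont_window(pair, x, beta)
  pts <- integration_pieces(t, params, win)
  f <- function(rho) phi_cont_x(pair, x, beta, rho) * gs(t * tau_rho_inv(rho, params), om)
  total <- 0
  for (k in seq_len(length(pts) - 1L))
    total <- total + gl_integrate(f, pts[k], pts[k + 1L], n = n_gl)
  unname(acc + total)
}

#' Moment-expansion averaged autocorrelation (closed form)
#'
#' Closed-form counterpart of [exact_average_gs()]: the endpoint atoms stay
#' as exact exponential-prefactor terms (`exp(-k23 t) gs(t/tau_B)` for pair
#' 22, `exp(-k32 t) gs(t/tau_D)` for 33) and the continuous remainder is
#' expanded to two terms around its mean occupation fraction:
#' `cmass * (gs(t/tau_pair) + 0.5 * gs''(t/tau_pair) * (t/tau_Delta)^2 * sigma^2)`
#' with `1/tau_pair = (1 - <rho>)/tau_B + <rho>/tau_D` built from the
#' continuous-part mean and `1/tau_Delta = 1/tau_B - 1/tau_D`.
#' Higher-order terms are deliberately omitted; this is the closed-form
#' route for intermediate-rate reactions.
#'
#' @inheritParams exact_average_gs
#' @param t lag times (s), vectorised.
#' @return averaged correlation values.
#' @export
approx_average_gs <- function(pair, t, params) {
  approx_average_impl(pair, t, params, order = 2L)
}

approx_average_impl <- function(pair, t, params, order) {
  pair <- check_pair(pair)
  stopifnot(inherits(params, "fcs_params"))
  if (any(t < 0)) stop("'t' must be nonnegative")
  out <- numeric(length(t))
  zero <- t == 0
  out[zero] <- if (pair %in% c("22", "33")) 1 else 0
  if (any(!zero)) {
    tt <- t[!zero]
    d <- params$diffusion
    om <- params$volume$omega
    cm <- phi_cont_moments_x(pair, params$scheme$R * tt, params$scheme$beta)
    chi <- tt * ((1 - cm$mean_rho) / d$tau_B + cm$mean_rho * d$tau_D_inv)
    cont <- cm$cmass * gs(chi, om)
    if (order >= 2L)
      cont <- cont + cm$cmass * 0.5 * gs_dd(chi, om) *
        (tt * d$tau_Delta_inv)^2 * cm$sigma^2
    out[!zero] <- cm$atom0 * gs(tt / d$tau_B, om) +
      cm$atom1 * gs(tt * d$tau_D_inv, om) + cont
  }
  out
}

#' First-order averaged autocorrelation (fast-reaction form)
#'
#' One-term truncation of the moment expansion: the exact atom terms plus
#' `cmass * gs(t/tau_pair)` with the time-dependent diffusion time built
#' from the continuous-part mean occupation fraction.  Valid for fast
#' reactions (`v < v_L0`); reproduces the effective-diffusion components as
#' `R -> infinity`.
#'
#' @inheritParams approx_average_gs
#' @return averaged correlation values.
#' @export
first_order_average_gs <- function(pair, t, params) {
  approx_average_impl(pair, t, params, order = 1L)
}

#' Rigorous bounds on the exact averaged autocorrelation
#'
#' Because `gs(t/tau_rho)` is an increasing convex function of `rho`, every
#' exact average is bracketed by a Jensen lower bound evaluated at the mean
#' occupation fraction and a chord upper bound mixing `gs(t/tau_B)` and
#' `gs(t/tau_D)`.  Both bounds are combinations of `exp(-k23 t)` and
#' `exp(-k32 t)` with time-dependent amplitudes (the masses and first
#' moments of the occupation densities).
#'
#' @inheritParams approx_average_gs
#' @return list with vectors `lower` and `upper`.
#' @export
avg_gs_bounds <- function(pair, t, params) {
  pair <- check_pair(pair)
  stopifnot(inherits(params, "fcs_params"))
  if (any(t <= 0)) stop("'t' must be positive")
  mom <- phi_moments_x(pair, params$scheme$R * t, params$scheme$beta)
  om <- params$volume$omega
  chi_mean <- t * ((1 - mom$mean_rho) / params$diffusion$tau_B +
                     mom$mean_rho * params$diffusion$tau_D_inv)
  M1 <- mom$mass * mom$mean_rho
  list(lower = mom$mass * gs(chi_mean, om),
       upper = (mom$mass - M1) * gs(t / params$diffusion$tau_B, om) +
         M1 * gs(t * params$diffusion$tau_D_inv, om))
}

slow_reaction_check <- function(params) {
  sc <- params$scheme
  d <- params$diffusion
  r1 <- d$tau_B * sc$k23
  r2 <- if (d$immobile) 0 else d$tau_D * sc$k32
  if (r1 > 0.1 || r2 > 0.1)
    warning(sprintf(paste0("slow-reaction approximation outside its regime: ",
                           "tau_B*k23 = %.3g, tau_D*k32 = %.3g (want << 1)"),
                    r1, r2))
  invisible(NULL)
}

# Component averages for one method on a scalar t > 0 (exact route).
component_values_exact <- function(t, params, n_gl = 0L) {
  if (n_gl > 0L) {
    c(G22 = exact_average_gs_gl("22", t, params, n_gl),
      G23 = exact_average_gs_gl("23", t, params, n_gl),
      G32 = exact_average_gs_gl("32", t, params, n_gl),
      G33 = exact_average_gs_gl("33", t, params, n_gl))
  } else {
    c(G22 = exact_average_gs("22", t, params),
      G23 = exact_average_gs("23", t, params),
      G32 = exact_average_gs("32", t, params),
      G33 = exact_average_gs("33", t, params))
  }
}

# Vectorised closed-form component averages for t > 0.
component_values_vec <- function(tt, params, method) {
  sc <- params$scheme
  d <- params$diffusion
  om <- params$volume$omega
  beta <- sc$beta
  chi_B <- tt / d$tau_B
  chi_D <- tt * d$tau_D_inv
  out <- switch(method,
    moment_expansion = cbind(G22 = approx_average_gs("22", tt, params),
                             G23 = approx_average_gs("23", tt, params),
                             G32 = approx_average_gs("32", tt, params),
                             G33 = approx_average_gs("33", tt, params)),
    first_order = cbind(G22 = first_order_average_gs("22", tt, params),
                        G23 = first_order_average_gs("23", tt, params),
                        G32 = first_order_average_gs("32", tt, params),
                        G33 = first_order_average_gs("33", tt, params)),
    effective = {
      tau_beta_inv <- (1 - beta) / d$tau_B + beta * d$tau_D_inv
      gb <- gs(tt * tau_beta_inv, om)
      cbind(G22 = (1 - beta) * gb, G23 = (1 - beta) * gb,
            G32 = beta * gb, G33 = beta * gb)
    },
    two_component = cbind(G22 = gs(chi_B, om), G23 = 0 * tt, G32 = 0 * tt,
                          G33 = gs(chi_D, om)),
    slow_reaction = {
      a <- sc$k23 * tt
      b <- sc$k32 * tt
      J0 <- gs_uniform_mean(tt, params)
      cbind(G22 = exp(-a) * gs(chi_B, om),
            G23 = b * J0,
            G32 = a * J0,
            G33 = exp(-b) * gs(chi_D, om))
    },
    fast_diffusion = {
      a <- sc$k23 * tt
      b <- sc$k32 * tt
      # D = 0: gs(t/tau_rho) = gs((1-rho) t / tau_B); its normalising
      # integral and mean follow from the gs antiderivatives.
      I0 <- gs_antideriv(chi_B, om) - gs_antideriv(0, om)
      Iy <- gs_chi_antideriv(chi_B, om) - gs_chi_antideriv(0, om)
      Nphi <- I0 / chi_B                      # int_0^1 gs(t/tau_rho) drho
      rho_s <- 1 - Iy / (chi_B * I0)          # gs-weighted mean of rho
      x <- sc$R * tt
      f <- function(pair) vapply(seq_along(tt), function(i)
        phi_cont_x(pair, x[i], beta, rho_s[i]), numeric(1))
      cbind(G22 = exp(-a) * gs(chi_B, om) + Nphi * f("22"),
            G23 = Nphi * f("23"),
            G32 = Nphi * f("32"),
            G33 = exp(-b) + Nphi * f("33"))
    },
    stop("unknown method: ", method))
  out
}

#' Correlation components on a time grid
#'
#' Evaluates the five correlation components: `G11(t) = gs(t/tau_D)` (free
#' diffusion of the macromolecule-like species 1) and the four reacting-dye
#' components `G22`, `G23`, `G32`, `G33`, by the selected averaging route,
#' together with the assembled correlation `G(t)`.  At `t = 0` the
#' components equal the Kronecker delta, and `(1-beta) G32 = beta G23`
#' holds at all times.
#'
#' @param t_grid strictly increasing lag times (s, `>= 0`).
#' @param params an [fcs_params] object.
#' @param method one of `"exact"`, `"moment_expansion"`, `"first_order"`,
#'   `"effective"`, `"two_component"`, `"slow_reaction"`,
#'   `"fast_diffusion"`.
#' @param n_gl if `> 0`, use the fixed-order Gauss-Legendre fast path for
#'   the exact route instead of adaptive quadrature.
#' @return data frame of class `fcs_acf` with columns `t`, `G11`, `G22`,
#'   `G23`, `G32`, `G33`, `G`; the method used is stored in
#'   `attr(, "method")`.
#' @export
component_acfs <- function(t_grid, params, method = "exact", n_gl = 0L) {
  stopifnot(inherits(params, "fcs_params"))
  method <- match.arg(method, ACF_METHODS)
  if (any(t_grid < 0) || any(diff(t_grid) <= 0))
    stop("'t_grid' must be nonnegative and strictly increasing")
  if (method == "fast_diffusion" && !params$diffusion$immobile)
    stop("fast_diffusion requires an immobile macromolecule (D = 0); ",
         "the fast-diffusion/effective-diffusion transition does not occur ",
         "for D != 0")
  if (method == "slow_reaction") slow_reaction_check(params)
  om <- params$volume$omega
  n <- length(t_grid)
  comp <- matrix(NA_real_, n, 4,
                 dimnames = list(NULL, c("G22", "G23", "G32", "G33")))
  pos <- t_grid > 0
  # value at t = 0: Kronecker delta for every route except the
  # effective-diffusion model, whose own amplitude is the R -> infinity
  # (pre-averaged) one
  comp[!pos, ] <- if (method == "effective")
    rep(c(1 - params$scheme$beta, 1 - params$scheme$beta,
          params$scheme$beta, params$scheme$beta), each = sum(!pos))
  else rep(c(1, 0, 0, 1), each = sum(!pos))
  if (any(pos)) {
    if (method == "exact") {
      for (i in which(pos))
        comp[i, ] <- component_values_exact(t_grid[i], params, n_gl = n_gl)
    } else {
      comp[pos, ] <- component_values_vec(t_grid[pos], params, method)
    }
  }
  out <- data.frame(t = t_grid,
                    G11 = gs(t_grid * params$diffusion$tau_D_inv, om),
                    comp)
  out$G <- assemble_acf(out, params)
  attr(out, "method") <- method
  class(out) <- c("fcs_acf", class(out))
  out
}

# Combine components with Table-1 quantum yields and mean molecule numbers.
assemble_acf <- function(comp, params) {
  br <- params$brightness
  N <- params$numbers
  (br$Q1^2 * N$N1 * comp$G11 +
     br$Q2^2 * N$N2 * comp$G22 +
     br$Q3^2 * N$N3 * comp$G33 +
     br$Q2 * br$Q3 * (N$N2 * comp$G32 + N$N3 * comp$G23)) / params$n_bar^2
}

#' Full FCS autocorrelation curve
#'
#' Assembles `G(t)` from the species-1/2/3 components with the quantum
#' yields `Q1 = Q_C`, `Q2 = Q_B`, `Q3 = Q_C` and mean molecule numbers.
#' `G(0)` equals the standard FCS amplitude
#' `(Q_C^2 (N1 + N3) ... ) / n_bar^2` obtained with `G_ij(0) = delta_ij`.
#'
#' @inheritParams component_acfs
#' @param method as in [component_acfs()], or `"auto"`: exact quadrature
#'   for grids of at most 256 points, moment expansion otherwise.
#' @return an [fcs_curve] with the lag grid and `G` values; the engine used
#'   is recorded in `meta$method`.
#' @export
full_acf <- function(t_grid, params, method = c("auto", ACF_METHODS),
                     n_gl = 0L) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (length(t_grid) <= 256L) "exact" else "moment_expansion"
  comp <- component_acfs(t_grid, params, method, n_gl = n_gl)
  fcs_curve(lag = comp$t, g = comp$G, meta = list(method = method))
}

#' Slow-reaction autocorrelation (two-component + reaction coupling)
#'
#' Closed-form `G(t)` for slow reactions (`tau_B k23 << 1`,
#' `tau_D k32 << 1`) and `t << 1/gamma`: the two-component diffusion curve
#' with exponentially decaying amplitudes plus cross terms proportional to
#' `k23` that couple reaction and diffusion through the uniform average of
#' `gs(t/tau_rho)`.  With `k23 = 0` it reduces exactly to
#' [two_component_acf()].
#'
#' @inheritParams component_acfs
#' @return an [fcs_curve].
#' @export
slow_reaction_acf <- function(t_grid, params) {
  full_acf(t_grid, params, method = "slow_reaction")
}

#' Fast-diffusion autocorrelation (immobile macromolecules)
#'
#' For `D = 0` and fast dye diffusion, the weight `gs(t/tau_rho)` acts as a
#' probability density concentrating at `rho = 1`; each exact average is
#' approximated by the density evaluated at the `gs`-weighted mean
#' occupation fraction times the uniform `gs` integral, plus the endpoint
#' atoms (so `G33 ~ exp(-k32 t)` survives at long times).
#'
#' @inheritParams component_acfs
#' @return an [fcs_curve].
#' @export
fast_diffusion_acf <- function(t_grid, params) {
  full_acf(t_grid, params, method = "fast_diffusion")
}

#' Fast-diffusion to effective-diffusion transition time
#'
#' `t_t = 4 beta^2 (1 - beta)^2 / (R^2 tau_B)`: the time at which the
#' spread of the occupation density (`sigma^2 ~ 2 beta(1-beta)/(Rt)`)
#' matches the spread of the `gs` weight (`~ sqrt(tau_B/t)`).  Only defined
#' for immobile macromolecules; `t_t -> infinity` as `tau_B -> 0` and
#' `t_t -> 0` as `R -> infinity`.
#'
#' @param params an [fcs_params] object with `D = 0`.
#' @return transition time (s).
#' @export
transition_time <- function(params) {
  stopifnot(inherits(params, "fcs_params"))
  if (!params$diffusion$immobile)
    stop("transition_time is defined only for immobile macromolecules (D = 0)")
  sc <- params$scheme
  4 * sc$beta^2 * (1 - sc$beta)^2 / (sc$R^2 * params$diffusion$tau_B)
}

#' Default logarithmic lag grid
#'
#' 64 points per decade over `[1e-3, 1e4] * tau_B` by default, matching the
#' log-spaced lag axis of hardware correlators.
#'
#' @param params an [fcs_params] object.
#' @param tmin,tmax grid limits in units of `tau_B`.
#' @param per_decade points per decade.
#' @return numeric vector of lag times (s).
#' @export
default_lag_grid <- function(params, tmin = 1e-3, tmax = 1e4,
                             per_decade = 64) {
  n <- ceiling(log10(tmax / tmin) * per_decade)
  params$diffusion$tau_B * 10^seq(log10(tmin), log10(tmax), length.out = n)
}
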