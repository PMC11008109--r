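# Two-state occupation-time machinery for the fictitious reaction 2 <-> 3
# (free and bound dye).  Over a lag t the dye spends a fraction rho of the
# time bound; the densities Phi_{i'j'}(t, rho), conditioned on the initial
# and final state, carry endpoint atoms (paths that never switch) plus a
# continuous part built from modified Bessel functions I0/I1 -- the same
# structure as the Skellam distribution of the net number of transitions.
#
# Conventions.  a = k23*t, b = k32*t, u = a*(1-rho), w = b*rho,
# zeta = 2*sqrt(u*w).  The unnormalised densities integrate (atoms included)
# to the two-state propagator probabilities ("masses", the prefactors of the
# exact correlation components):
#   mass_22 = (1-beta) + beta*exp(-Rt)        atom exp(-a) at rho = 0
#   mass_33 = beta + (1-beta)*exp(-Rt)        atom exp(-b) at rho = 1
#   mass_32 = beta*(1-exp(-Rt))               start 2, end 3 (no atoms)
#   mass_23 = (1-beta)*(1-exp(-Rt))           start 3, end 2 (no atoms)
# The normalised densities of the two cross pairs coincide.

PHI_PAIRS <- c("22", "23", "32", "33")

as_scheme <- function(x) {
  if (inherits(x, "fcs_params")) return(x$scheme)
  if (is.list(x) && all(c("k23", "k32") %in% names(x))) {
    if (is.null(x$R)) x$R <- x$k23 + x$k32
    if (is.null(x$beta)) x$beta <- x$k23 / x$R
    return(x)
  }
  stop("'scheme' must be an fcs_params object or a list with k23 and k32")
}

check_pair <- function(pair) {
  pair <- as.character(pair)
  if (length(pair) != 1L || !pair %in% PHI_PAIRS)
    stop("'pair' must be one of ", paste(PHI_PAIRS, collapse = ", "))
  pair
}

#' Skellam probability mass function
#'
#' Distribution of the difference of two independent Poisson counts with
#' means `a` and `b`: `P(n) = exp(-a-b) (a/b)^(n/2) I_|n|(2 sqrt(ab))`.
#' In the reaction context `n` is the net number of 2->3 transitions over a
#' lag with `a = k23 t`, `b = k32 t`.  Evaluated with exponentially scaled
#' Bessel functions so that means up to 1e6 and beyond stay finite.
#'
#' @param n integer quantiles (vectorised).
#' @param a,b nonnegative Poisson means.
#' @return probabilities.
#' @examples
#' sum(skellam_pmf(-50:50, 3, 7))  # ~1
#' @export
skellam_pmf <- function(n, a, b) {
  if (length(a) != 1L || length(b) != 1L || !is.finite(a) || !is.finite(b) ||
      a < 0 || b < 0)
    stop("'a' and 'b' must be single nonnegative numbers")
  if (any(n != round(n))) stop("'n' must be integer-valued")
  if (b == 0) return(ifelse(n >= 0, stats::dpois(pmax(n, 0), a), 0))
  if (a == 0) return(ifelse(n <= 0, stats::dpois(pmax(-n, 0), b), 0))
  z <- 2 * sqrt(a * b)
  # log scale: -(sqrt(a)-sqrt(b))^2 + (n/2) log(a/b) + log I_|n|(z) - z
  logp <- -(sqrt(a) - sqrt(b))^2 + (n / 2) * (log(a) - log(b)) +
    vapply(abs(n), function(nu) log_bessel_i_scaled(z, nu), numeric(1))
  exp(logp)
}

# log(I_nu(z) e^-z) robust to both large argument and large order: R's
# besselI where it works, the Hankel branch for large z at small order,
# and the leading Olver uniform asymptotic when the order itself is large
# (relative error O(1/nu)).
log_bessel_i_scaled <- function(z, nu) {
  if (z < 5e4 || nu <= 1) {
    val <- if (nu <= 1) bessel_i_scaled(z, nu)
           else besselI(z, nu, expon.scaled = TRUE)
    if (is.finite(val) && val > 0) return(log(val))
    if (nu <= 1) return(-Inf)
  }
  if (z == 0) return(-Inf)
  zp <- z / nu
  r <- sqrt(1 + zp^2)
  eta <- r + log(zp / (1 + r))
  nu * eta - z - 0.5 * log(2 * pi * nu) - 0.5 * log(r)
}

# Exponentially scaled modified Bessel function I_nu(z) * exp(-z).
# R's besselI underflows internally for z beyond ~1.5e5 even when scaled;
# switch to the Hankel large-argument expansion there (relative error
# ~1e-19 at the 5e4 crossover for nu = 0, 1).
bessel_i_scaled <- function(z, nu) {
  out <- numeric(length(z))
  big <- z >= 5e4
  if (any(!big)) out[!big] <- besselI(z[!big], nu, expon.scaled = TRUE)
  if (any(big)) {
    zb <- z[big]
    mu <- 4 * nu^2
    out[big] <- (1 - (mu - 1) / (8 * zb) +
                   (mu - 1) * (mu - 9) / (128 * zb^2) -
                   (mu - 1) * (mu - 9) * (mu - 25) / (3072 * zb^3)) /
      sqrt(2 * pi * zb)
  }
  out
}

# Unnormalised continuous part of Phi_pair at occupation fractions rho,
# dimensionless inputs x = R*t, beta.  Vectorised over rho.
phi_cont_x <- function(pair, x, beta, rho) {
  a <- beta * x
  b <- (1 - beta) * x
  u <- a * (1 - rho)
  w <- b * rho
  z <- 2 * sqrt(u * w)
  expfac <- exp(-(sqrt(u) - sqrt(w))^2)   # = exp(z - u - w)
  small <- z < 1e-8
  if (pair == "22") {
    # b * sqrt(u/w) * I1(z) * exp(-u-w); limit u*(1 + z^2/8) exp(-u-w) at z->0
    out <- numeric(length(rho))
    if (any(small))
      out[small] <- b * u[small] * (1 + z[small]^2 / 8) * exp(-u[small] - w[small])
    if (any(!small))
      out[!small] <- b * sqrt(u[!small] / w[!small]) *
        bessel_i_scaled(z[!small], 1) * expfac[!small]
    out
  } else if (pair == "33") {
    out <- numeric(length(rho))
    if (any(small))
      out[small] <- a * w[small] * (1 + z[small]^2 / 8) * exp(-u[small] - w[small])
    if (any(!small))
      out[!small] <- a * sqrt(w[!small] / u[!small]) *
        bessel_i_scaled(z[!small], 1) * expfac[!small]
    out
  } else {
    pref <- if (pair == "32") a else b
    i0 <- ifelse(small, (1 + z^2 / 4) * exp(-u - w),
                 bessel_i_scaled(z, 0) * expfac)
    pref * i0
  }
}

phi_mass_x <- function(pair, x, beta) {
  em <- exp(-x)
  switch(pair,
         "22" = (1 - beta) + beta * em,
         "33" = beta + (1 - beta) * em,
         "32" = beta * (1 - em),
         "23" = (1 - beta) * (1 - em))
}

phi_atoms_x <- function(pair, x, beta) {
  zero <- numeric(length(x))
  switch(pair,
         "22" = list(atom0 = exp(-beta * x), atom1 = zero),
         "33" = list(atom0 = zero, atom1 = exp(-(1 - beta) * x)),
         list(atom0 = zero, atom1 = zero))
}

#' Occupation-fraction probability density
#'
#' Continuous part of the density `Phi_pair(t, rho)` of the fraction of the
#' lag interval spent in the bound state, conditioned on the initial and
#' final dye states (pair `"22"`, `"23"`, `"32"`, `"33"`; first index final,
#' second initial).  By default the unnormalised convention is used, in
#' which atoms plus the integral of the continuous part equal the pair's
#' propagator mass (the prefactor of the exact correlation component); with
#' `normalized = TRUE` the mass is divided out, and the two cross densities
#' `"23"` and `"32"` coincide exactly.  Endpoint atoms (`exp(-k23 t)` at
#' `rho = 0` for pair 22, `exp(-k32 t)` at `rho = 1` for 33) are reported by
#' [occupation_density()], never folded into the continuous part.
#'
#' @param pair one of `"22"`, `"23"`, `"32"`, `"33"`.
#' @param t lag time (s, `> 0`).
#' @param rho occupation fractions in `[0, 1]` (vectorised).
#' @param scheme an [fcs_params] object or a list with `k23`, `k32`.
#' @param normalized divide by the pair mass?
#' @return density values (nonnegative).
#' @export
phi <- function(pair, t, rho, scheme, normalized = FALSE) {
  pair <- check_pair(pair)
  scheme <- as_scheme(scheme)
  if (length(t) != 1L || !is.finite(t) || t <= 0) stop("'t' must be positive")
  if (any(rho < 0 | rho > 1)) stop("'rho' must lie in [0, 1]")
  x <- scheme$R * t
  out <- phi_cont_x(pair, x, scheme$beta, rho)
  if (normalized) out <- out / phi_mass_x(pair, x, scheme$beta)
  out
}

#' Small-Rt limiting form of the occupation density
#'
#' Leading-order continuous part obtained from `I0(zeta) ~ 1`,
#' `I1(zeta) ~ zeta/2`, valid when `gamma*t` is small (slow reaction):
#' `Phi_22 ~ a b (1-rho) exp(-t k_rho)`, `Phi_33 ~ a b rho exp(-t k_rho)`,
#' `Phi_32 ~ a exp(-t k_rho)`, `Phi_23 ~ b exp(-t k_rho)` with
#' `k_rho = (1-rho) k23 + rho k32`; atoms as in the exact density.
#'
#' @inheritParams phi
#' @return density values.
#' @export
phi_small_Rt <- function(pair, t, rho, scheme, normalized = FALSE) {
  pair <- check_pair(pair)
  scheme <- as_scheme(scheme)
  if (length(t) != 1L || !is.finite(t) || t <= 0) stop("'t' must be positive")
  if (any(rho < 0 | rho > 1)) stop("'rho' must lie in [0, 1]")
  x <- scheme$R * t
  beta <- scheme$beta
  a <- beta * x
  b <- (1 - beta) * x
  ek <- exp(-a * (1 - rho) - b * rho)
  out <- switch(pair,
                "22" = a * b * (1 - rho) * ek,
                "33" = a * b * rho * ek,
                "32" = a * ek,
                "23" = b * ek)
  if (normalized) out <- out / phi_mass_x(pair, x, beta)
  out
}

#' Gaussian (large-Rt) asymptotic occupation density
#'
#' For `Rt >> 1` every occupation density concentrates around the bound
#' fraction `beta` with variance of order `(Rt)^-1`.  This routine returns a
#' moment-matched Gaussian approximant: a normal density truncated to
#' `[0, 1]`, carrying the pair's exact closed-form mean, standard deviation
#' and mass.  A warning is issued below `Rt = 50` where the approximation is
#' not meaningful.
#'
#' @inheritParams phi
#' @return density values.
#' @export
phi_gaussian_asymptotic <- function(pair, t, rho, scheme, normalized = FALSE) {
  pair <- check_pair(pair)
  scheme <- as_scheme(scheme)
  if (length(t) != 1L || !is.finite(t) || t <= 0) stop("'t' must be positive")
  if (any(rho < 0 | rho > 1)) stop("'rho' must lie in [0, 1]")
  x <- scheme$R * t
  if (x < 50)
    warning(sprintf("Gaussian asymptotic used at Rt = %.3g < 50", x))
  mom <- phi_moments(pair, t, scheme)
  z0 <- stats::pnorm((1 - mom$mean_rho) / mom$sigma) -
    stats::pnorm(-mom$mean_rho / mom$sigma)
  dens <- stats::dnorm(rho, mom$mean_rho, mom$sigma) / z0
  if (normalized) dens else mom$mass * dens
}

# Closed-form normalised moments of Phi_pair, dimensionless arguments;
# vectorised over x.  Below x = 1e-3 the closed forms lose ~1e-9 relative
# accuracy to cancellation (numerator and denominator both vanish), so a
# series in x (to O(x^6)) takes over there.
phi_moments_x <- function(pair, x, beta) {
  b <- beta
  em <- exp(-x)
  small <- x < 0.02
  m1 <- numeric(length(x))
  m2 <- numeric(length(x))
  if (pair %in% c("22", "33")) {
    mass <- phi_mass_x(pair, x, b)
    if (any(!small)) {
      xs <- x[!small]; e <- em[!small]
      core <- b * (1 - b) * ((1 + e) - 2 * (1 - e) / xs)
      if (pair == "22") {
        m1[!small] <- core / mass[!small]
        A <- -b^2 * xs^2 + 6 * b^2 * xs - 12 * b^2 + b * xs^2 - 8 * b * xs +
          18 * b + 2 * xs - 6
        B <- b^2 * xs^2 + 6 * b^2 * xs + 12 * b^2 - 2 * b * xs^2 -
          10 * b * xs - 18 * b + xs^2 + 4 * xs + 6
        m2[!small] <- b * (A + B * e) / (xs^2 * mass[!small])
      } else {
        m1[!small] <- 1 - core / mass[!small]
        A <- b^3 * xs^2 - 6 * b^3 * xs + 12 * b^3 + 6 * b^2 * xs -
          18 * b^2 + 6 * b
        B <- -b^3 * xs^2 - 6 * b^3 * xs - 12 * b^3 + 3 * b^2 * xs^2 +
          12 * b^2 * xs + 18 * b^2 - 3 * b * xs^2 - 6 * b * xs - 6 * b + xs^2
        m2[!small] <- (A + B * e) / (xs^2 * mass[!small])
      }
    }
    if (any(small)) {
      xs <- x[small]
      if (pair == "22") {
        m1[small] <- xs^2 * (b * (1/6 - b/6) + xs * (b * (b * (1/4 - b/6) - 1/12) +
          xs * (b * (b * (b * (1/3 - b/6) - 23/120) + 1/40) +
          xs * (b * xs * (b * (b * (b * (b * (1/2 - b/6) - 97/180) + 11/45) - 67/1680) + 1/1008) +
          b * (b * (b * (b * (5/12 - b/6) - 31/90) + 1/10) - 1/180)))))
        m2[small] <- xs^2 * (b * (1/12 - b/12) + xs * (b * (b * (3/20 - b/10) - 1/20) +
          xs * (b * (b * (b * (1/5 - b/10) - 7/60) + 1/60) +
          xs * (b * xs * (b * (b * (b * (b * (3/10 - b/10) - 409/1260) + 47/315) - 73/2880) + 1/1344) +
          b * (b * (b * (b * (1/4 - b/10) - 131/630) + 13/210) - 1/252)))))
      } else {
        m1[small] <- 1 + xs^2 * (b * (b/6 - 1/6) + xs * (b * (b * (1/4 - b/6) - 1/12) +
          xs * (b * (b * (b * (b/6 - 1/3) + 23/120) - 1/40) +
          xs * (b * xs * (b * (b * (b * (b * (b/6 - 1/2) + 97/180) - 11/45) + 67/1680) - 1/1008) +
          b * (b * (b * (b * (5/12 - b/6) - 31/90) + 1/10) - 1/180)))))
        m2[small] <- 1 + xs^2 * (b * (b/4 - 1/4) + xs * (b * (b * (7/20 - 7*b/30) - 7/60) +
          xs * (b * (b * (b * (7*b/30 - 7/15) + 4/15) - 1/30) +
          xs * (b * xs * (b * (b * (b * (b * (7*b/30 - 7/10) + 949/1260) - 107/315) + 1097/20160) - 5/4032) +
          b * (b * (b * (b * (7/12 - 7*b/30) - 101/210) + 29/210) - 1/140)))))
      }
    }
  } else {
    mass <- phi_mass_x(pair, x, b)
    if (any(!small)) {
      xs <- x[!small]; e <- em[!small]
      m1[!small] <- (b - (1 - b) * e + (1 - 2 * b) * (1 - e) / xs) / (1 - e)
      A <- b^2 * xs^2 - 6 * b^2 * xs + 12 * b^2 + 4 * b * xs - 12 * b + 2
      B <- b^2 * xs^2 + 6 * b^2 * xs + 12 * b^2 - 2 * b * xs^2 -
        8 * b * xs - 12 * b + xs^2 + 2 * xs + 2
      m2[!small] <- (A - B * e) / (xs^2 * (1 - e))
    }
    if (any(small)) {
      xs <- x[small]
      m1[small] <- 1/2 + xs * (b/6 - 1/12 +
        xs^2 * (-b/360 + 1/720 + xs^2 * (b/15120 - 1/30240)))
      m2[small] <- 1/3 + xs * (b/6 - 1/12 + xs * (b * (b/60 - 1/60) + 1/360 +
        xs * (-b/360 + 1/720 + xs * (b * (1/2520 - b/2520) - 1/15120 +
        xs * (b/15120 - 1/30240 + xs * (b * (b/100800 - 1/100800) + 1/604800))))))
    }
  }
  list(mass = mass, mean_rho = m1, mean_rho2 = m2,
       sigma = sqrt(pmax(m2 - m1^2, 0)))
}

# Moments of the continuous part of Phi_pair (atoms removed), used by the
# moment expansion: the endpoint atoms enter the correlation components as
# exact exponential-prefactor terms, so only the continuous remainder is
# expanded.  Obtained from the total moments by subtracting the atom
# contributions; the O(x^2) cancellations at small x are harmless because
# the continuous mass itself is O(x^2) there and carries negligible weight.
phi_cont_moments_x <- function(pair, x, beta) {
  mom <- phi_moments_x(pair, x, beta)
  atoms <- phi_atoms_x(pair, x, beta)
  cmass <- pmax(mom$mass - atoms$atom0 - atoms$atom1, 0)
  safe <- pmax(cmass, 1e-300)
  m1 <- pmin(pmax((mom$mass * mom$mean_rho - atoms$atom1) / safe, 0), 1)
  m2 <- pmin(pmax((mom$mass * mom$mean_rho2 - atoms$atom1) / safe, 0), 1)
  list(cmass = cmass, atom0 = atoms$atom0, atom1 = atoms$atom1,
       mean_rho = m1, mean_rho2 = m2, sigma = sqrt(pmax(m2 - m1^2, 0)))
}

#' Closed-form moments of the occupation density
#'
#' Mass (propagator prefactor), normalised first and second moments and
#' standard deviation of `Phi_pair(t, rho)`, including the endpoint atoms.
#' Evaluated from closed forms derived by convolving the two-state
#' propagator; below `Rt = 0.02` a series expansion replaces the closed
#' forms, whose numerator and denominator both vanish in that limit
#' (cancellation would otherwise exceed ~1e-9 relative).
#' `mean_rho -> beta` and `sigma^2 ~ 2 beta (1-beta) / (Rt)` as
#' `Rt -> infinity`.
#'
#' @inheritParams phi
#' @return list with `mass`, `mean_rho`, `mean_rho2`, `sigma` (vectorised
#'   over `t`).
#' @export
phi_moments <- function(pair, t, scheme) {
  pair <- check_pair(pair)
  scheme <- as_scheme(scheme)
  if (any(t <= 0)) stop("'t' must be positive")
  phi_moments_x(pair, scheme$R * t, scheme$beta)
}

#' Full occupation-density object
#'
#' Bundles the endpoint atoms, the continuous part (as a function), the
#' total mass and the closed-form moments of `Phi_pair(t, rho)`.
#'
#' @inheritParams phi
#' @return object of class `fcs_occupation` with fields `pair`, `t`,
#'   `atom0`, `atom1`, `density` (unnormalised, callable), `mass`,
#'   `mean_rho`, `mean_rho2`, `sigma`.
#' @export
occupation_density <- function(pair, t, scheme) {
  pair <- check_pair(pair)
  scheme <- as_scheme(scheme)
  if (length(t) != 1L || !is.finite(t) || t <= 0) stop("'t' must be positive")
  x <- scheme$R * t
  beta <- scheme$beta
  atoms <- phi_atoms_x(pair, x, beta)
  mom <- phi_moments_x(pair, x, beta)
  structure(list(pair = pair, t = t, Rt = x, beta = beta,
                 atom0 = atoms$atom0, atom1 = atoms$atom1,
                 density = function(rho) phi_cont_x(pair, x, beta, rho),
                 mass = mom$mass, mean_rho = mom$mean_rho,
                 mean_rho2 = mom$mean_rho2, sigma = mom$sigma),
            class = "fcs_occupation")
}

#' @export
print.fcs_occupation <- function(x, ...) {
  cat(sprintf("Occupation density Phi_%s at Rt = %.4g (beta = %.3f)\n",
              x$pair, x$Rt, x$beta))
  cat(sprintf("  mass = %.6g, atoms (rho=0, rho=1) = (%.3g, %.3g)\n",
              x$mass, x$atom0, x$atom1))
  cat(sprintf("  <rho> = %.6g, sd = %.6g\n", x$mean_rho, x$sigma))
  invisible(x)
}
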