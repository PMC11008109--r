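sch <- list(k23 = 2, k32 = 3)   # beta = 0.4, R = 5

test_that("atoms + continuous part integrate to the propagator masses", {
  for (pair in c("22", "23", "32", "33")) {
    for (x in c(0.05, 0.7, 5, 60)) {
      for (beta in c(0.2, 0.5, 0.85)) {
        od <- occupation_density(pair, x, list(k23 = beta, k32 = 1 - beta))
        total <- od$atom0 + od$atom1 +
          integrate(od$density, 0, 1, rel.tol = 1e-11)$value
        expect_equal(total, od$mass, tolerance = 1e-9)
        expect_gte(od$mean_rho2 - od$mean_rho^2, -1e-14)  # sigma^2 >= 0
      }
    }
  }
})

test_that("masses obey start-state conservation and monotonicity in time", {
  tg <- 10^seq(-3, 2, length.out = 25)
  for (beta in c(0.25, 0.6)) {
    s <- list(k23 = beta, k32 = 1 - beta)  # R = 1, t = Rt
    m22 <- phi_moments("22", tg, s)$mass
    m32 <- phi_moments("32", tg, s)$mass
    m33 <- phi_moments("33", tg, s)$mass
    m23 <- phi_moments("23", tg, s)$mass
    expect_equal(m22 + m32, rep(1, length(tg)))
    expect_equal(m33 + m23, rep(1, length(tg)))
    # positive, monotone: diagonal masses decay, cross masses grow
    # (non-strict at the tail where exp(-Rt) underflows)
    expect_true(all(diff(m22) <= 0) && all(diff(m33) <= 0))
    expect_true(all(diff(m32) >= 0) && all(diff(m23) >= 0))
    expect_true(m22[2] < m22[1] && m32[2] > m32[1])
    expect_true(all(c(m22, m32, m33, m23) > 0))
  }
})

test_that("normalised cross densities coincide: Phi_23 = Phi_32", {
  rho <- c(0.05, 0.3, 0.5, 0.77, 0.95)
  for (beta in c(0.3, 0.5, 0.8)) {
    s <- list(k23 = 10 * beta, k32 = 10 * (1 - beta))  # Rt = 10 at t = 1
    expect_equal(phi("23", 1, rho, s, normalized = TRUE),
                 phi("32", 1, rho, s, normalized = TRUE))
  }
  expect_error(phi("22", 1, 1.2, sch), "0, 1")
  expect_error(phi("21", 1, 0.5, sch), "pair")
})

test_that("closed-form moments equal quadrature moments of phi", {
  # (Rt, beta) = (3, 0.3)
  s <- list(k23 = 0.9, k32 = 2.1)
  for (pair in c("22", "23", "32", "33")) {
    od <- occupation_density(pair, 1, s)
    m1q <- (od$atom1 + integrate(function(r) r * od$density(r), 0, 1,
                                 rel.tol = 1e-12)$value) / od$mass
    m2q <- (od$atom1 + integrate(function(r) r^2 * od$density(r), 0, 1,
                                 rel.tol = 1e-12)$value) / od$mass
    expect_equal(od$mean_rho, m1q, tolerance = 1e-8)
    expect_equal(od$mean_rho2, m2q, tolerance = 1e-8)
  }
})

test_that("closed-form moments match Markov occupation sampling", {
  # (Rt, beta) = (1, 0.7)
  s <- list(k23 = 0.7, k32 = 0.3)
  sm <- sample_occupation(s, 1, start_state = 2L, n_paths = 2e5, seed = 31)
  for (end in c(2L, 3L)) {
    sel <- sm$rho[sm$end_state == end]
    pair <- if (end == 2L) "22" else "32"
    mom <- phi_moments(pair, 1, s)
    se1 <- sd(sel) / sqrt(length(sel))
    expect_lt(abs(mom$mean_rho - mean(sel)), 3 * se1)
    se2 <- sd(sel^2) / sqrt(length(sel))
    expect_lt(abs(mom$mean_rho2 - mean(sel^2)), 3 * se2)
  }
})

test_that("occupation histogram matches atoms plus continuous density", {
  # Rt = 2, beta = 0.4, start free
  s <- list(k23 = 0.8, k32 = 1.2)
  sm <- sample_occupation(s, 1, start_state = 2L, n_paths = 2e5, seed = 77)
  n <- nrow(sm)
  # atom at rho = 0: paths that never switch
  atom0 <- exp(-0.8)
  obs0 <- mean(sm$rho == 0)
  expect_lt(abs(obs0 - atom0), 3 * sqrt(atom0 * (1 - atom0) / n))
  # interior histogram against the summed continuous densities
  brk <- seq(0.05, 0.95, by = 0.15)
  dens <- function(r) phi("22", 1, r, s) + phi("32", 1, r, s)
  for (i in seq_len(length(brk) - 1)) {
    pexp <- integrate(dens, brk[i], brk[i + 1], rel.tol = 1e-10)$value
    pobs <- mean(sm$rho > brk[i] & sm$rho <= brk[i + 1])
    expect_lt(abs(pobs - pexp), 3 * sqrt(pexp * (1 - pexp) / n) + 1e-12)
  }
})

test_that("moments approach beta with (Rt)^-1 scaling", {
  s <- list(k23 = 0.4, k32 = 0.6)
  m100 <- phi_moments("22", 100, s)
  m400 <- phi_moments("22", 400, s)
  expect_equal((m100$mean_rho - 0.4) / (m400$mean_rho - 0.4), 4,
               tolerance = 0.1)
  expect_equal(m100$sigma^2 / m400$sigma^2, 4, tolerance = 0.1)
  # large-Rt variance amplitude: sigma^2 ~ 2 beta (1 - beta) / Rt
  expect_equal(m400$sigma^2, 2 * 0.4 * 0.6 / 400, tolerance = 0.02)
})

test_that("series and closed-form moment branches agree at the switch", {
  for (pair in c("22", "32", "33")) {
    for (beta in c(0.15, 0.5, 0.9)) {
      lo <- fcsrd:::phi_moments_x(pair, 0.02 * (1 - 1e-9), beta)
      hi <- fcsrd:::phi_moments_x(pair, 0.02 * (1 + 1e-9), beta)
      expect_lt(abs(lo$mean_rho - hi$mean_rho), 1e-10)
      expect_lt(abs(lo$mean_rho2 - hi$mean_rho2), 1e-10)
    }
  }
})

test_that("Gaussian asymptotic concentrates at beta with (Rt)^-1 variance", {
  s <- list(k23 = 0.5, k32 = 0.5)
  rho <- seq(0, 1, length.out = 801)
  for (pair in c("22", "32", "33")) {
    # total-variation distance to the exact density at Rt = 100
    g <- phi_gaussian_asymptotic(pair, 100, rho, s, normalized = TRUE)
    e <- phi(pair, 100, rho, s, normalized = TRUE)
    tv <- 0.5 * mean(abs(g - e))  # atoms are ~exp(-50), negligible here
    expect_lt(tv, 0.05)
    # centre tends to beta
    expect_equal(rho[which.max(g)], 0.5, tolerance = 0.05)
    # variance scales as (Rt)^-1
    v100 <- sum(rho^2 * g) / sum(g) - (sum(rho * g) / sum(g))^2
    g400 <- phi_gaussian_asymptotic(pair, 400, rho, s, normalized = TRUE)
    v400 <- sum(rho^2 * g400) / sum(g400) - (sum(rho * g400) / sum(g400))^2
    expect_equal(v100 / v400, 4, tolerance = 0.1)
  }
  expect_warning(phi_gaussian_asymptotic("22", 10, 0.5, s), "Rt")
})

test_that("small-Rt limit: structure and accuracy", {
  s <- list(k23 = 0.4, k32 = 0.6)  # R = 1, t = Rt
  # no transitions as Rt -> 0: mass of 22 tends to 1, all at rho = 0
  od <- occupation_density("22", 1e-6, s)
  expect_equal(od$mass, 1, tolerance = 1e-5)
  expect_equal(od$atom0, 1, tolerance = 1e-6)
  expect_lt(od$mean_rho, 1e-6)
  # leading-order density matches the exact one at Rt = 1e-3
  rho <- seq(0.01, 0.99, length.out = 21)
  for (pair in c("22", "23", "32", "33"))
    expect_lt(max(abs(phi_small_Rt(pair, 1e-3, rho, s) -
                        phi(pair, 1e-3, rho, s))), 1e-4)
  # cross mass is O(Rt): ratio test at 1e-2 vs 1e-3
  mr <- phi_moments("32", 1e-2, s)$mass / phi_moments("32", 1e-3, s)$mass
  expect_equal(mr, 10, tolerance = 0.01)
})
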