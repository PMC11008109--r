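test_that("exact averages: initial condition, degenerate case, quadrature paths", {
  p <- dim_params(1/6, 0.5, 1)
  expect_equal(exact_average_gs("22", 0, p), 1)
  expect_equal(exact_average_gs("32", 0, p), 0)
  # adaptive and Gauss-Legendre paths agree far below the 1e-9 contract
  for (tt in c(0.01, 1, 100) * p$diffusion$tau_B)
    expect_equal(exact_average_gs("22", tt, p),
                 fcsrd:::exact_average_gs_gl("22", tt, p), tolerance = 1e-10)
  # equal diffusion coefficients: average collapses to mass * gs(t/tau_D)
  pd <- dim_params(1, 0.4, 1)
  t0 <- 0.7 * pd$diffusion$tau_B
  mom <- phi_moments("22", t0, pd)
  expect_equal(exact_average_gs("22", t0, pd),
               mom$mass * gs(t0 / pd$diffusion$tau_B, 5))
})

test_that("cross-term identity (1-beta) G32 = beta G23 in both engines", {
  for (beta in c(0.3, 0.7)) {
    p <- dim_params(1/6, beta, 1.3)
    tg <- p$diffusion$tau_B * chi_grid(12)
    for (t0 in tg[c(2, 6, 11)]) {
      expect_equal((1 - beta) * exact_average_gs("32", t0, p),
                   beta * exact_average_gs("23", t0, p), tolerance = 1e-9)
    }
    expect_equal((1 - beta) * approx_average_gs("32", tg, p),
                 beta * approx_average_gs("23", tg, p), tolerance = 1e-12)
  }
})

test_that("exact averages match Monte Carlo occupation averaging", {
  p <- dim_params(1/6, 0.5, 1)
  t0 <- 2 * p$diffusion$tau_B
  sm <- sample_occupation(p, t0, start_state = 2L, n_paths = 2e5, seed = 42)
  gv <- gs(t0 * fcsrd:::tau_rho_inv(sm$rho, p), 5)
  for (end in c(2L, 3L)) {
    y <- gv * (sm$end_state == end)
    pair <- if (end == 2L) "22" else "32"
    expect_lt(abs(exact_average_gs(pair, t0, p) - mean(y)),
              3 * sd(y) / sqrt(length(y)))
  }
})

test_that("moment expansion: reductions and fast-reaction limit", {
  p <- dim_params(1/6, 0.5, 1)
  tg <- p$diffusion$tau_B * chi_grid(20)
  # with the curvature term removed the expansion is the first-order form
  expect_equal(first_order_average_gs("22", tg, p),
               {
                 cm <- fcsrd:::phi_cont_moments_x("22", p$scheme$R * tg, 0.5)
                 chi <- tg * ((1 - cm$mean_rho) / p$diffusion$tau_B +
                                cm$mean_rho * p$diffusion$tau_D_inv)
                 cm$atom0 * gs(tg / p$diffusion$tau_B, 5) + cm$cmass * gs(chi, 5)
               })
  # R -> infinity: averages tend to the effective-diffusion components
  vfast <- (1 / 0.5 + (1/6) / 0.5) / 1e4
  pf <- dim_params(1/6, 0.5, vfast)
  tau_beta_inv <- 0.5 / pf$diffusion$tau_B + 0.5 * pf$diffusion$tau_D_inv
  tf <- pf$diffusion$tau_B * c(0.1, 1, 10)
  expect_equal(approx_average_gs("22", tf, pf),
               (1 - 0.5) * gs(tf * tau_beta_inv, 5), tolerance = 1e-3)
  expect_equal(first_order_average_gs("33", tf, pf),
               0.5 * gs(tf * tau_beta_inv, 5), tolerance = 1e-3)
  expect_equal(approx_average_gs("32", tf, pf),
               0.5 * gs(tf * tau_beta_inv, 5), tolerance = 1e-3)
})

test_that("components: initial delta, identity on the grid, method recording", {
  p <- dim_params(1/6, 0.35, 1, N1 = 0.2, Q_C = 1.4)
  tg <- c(0, p$diffusion$tau_B * chi_grid(16, -2, 2))
  for (m in c("exact", "moment_expansion")) {
    comp <- component_acfs(tg, p, method = m)
    expect_equal(unlist(comp[1, c("G22", "G23", "G32", "G33")]),
                 c(G22 = 1, G23 = 0, G32 = 0, G33 = 1))
    expect_equal((1 - 0.35) * comp$G32, 0.35 * comp$G23, tolerance = 1e-9)
    expect_true(all(comp[, -1] >= 0) && all(comp[, -1] <= 1 + 1e-12))
    expect_identical(attr(comp, "method"), m)
  }
  expect_error(component_acfs(c(1, 0.5), p), "increasing")
  expect_error(component_acfs(1, p, method = "fast_diffusion"), "immobile")
})

test_that("full curve: amplitude, monotone decay, auto method selection", {
  p <- phys_params(Q_B = 1, Q_C = 2)
  tg <- c(0, p$diffusion$tau_B * chi_grid(40, -3, 3))
  cur <- full_acf(tg, p)   # auto -> exact for small grids
  expect_identical(attr(cur, "meta")$method, "exact")
  N <- p$numbers
  expect_equal(cur$g[1], (N$N_B * 1 + N$N_C * 4) / p$n_bar^2)
  expect_true(all(diff(cur$g) < 0))
  big <- full_acf(p$diffusion$tau_B * chi_grid(300), p)
  expect_identical(attr(big, "meta")$method, "moment_expansion")
})

test_that("equal yields and fast reaction give the classical effective curve", {
  vfast <- (1 / 0.5 + (1/6) / 0.5) / 1e4
  p <- fcs_params_dimensionless(1/6, 0.5, vfast, N1 = 0.3, N23 = 1,
                                Q_B = 1, Q_C = 1)
  tg <- p$diffusion$tau_B * chi_grid(25, -2, 2)
  expect_equal(full_acf(tg, p, method = "exact")$g,
               effective_diffusion_acf(tg, p), tolerance = 1e-3)
})

test_that("no complexes: single-species dye curve with amplitude 1/N_B", {
  # C_A -> 0 forces C_C -> 0 by detailed balance; k23 -> 0
  p <- fcs_params(k_plus = 1, k_minus = 1e3, C_A = 1e-7, C_B = 20,
                  C_C = 2e-6 * 1e-3, D = 50, D_B = 470, L = 0.2, H = 1,
                  Q_B = 1, Q_C = 3)
  tg <- p$diffusion$tau_B * chi_grid(15, -1, 2)
  expect_equal(full_acf(tg, p, method = "exact")$g,
               gs(tg / p$diffusion$tau_B, p$volume$omega) / p$numbers$N_B,
               tolerance = 1e-5)
})

test_that("exact averages lie within the convexity bounds", {
  for (Rt in c(0.5, 2, 10)) {
    for (beta in c(0.3, 0.5, 0.8)) {
      p <- dim_params(1/6, beta, 1)
      t0 <- Rt / p$scheme$R
      for (pair in c("22", "23", "32", "33")) {
        bd <- avg_gs_bounds(pair, t0, p)
        ex <- exact_average_gs(pair, t0, p)
        expect_gte(ex, bd$lower - 1e-10)
        expect_lte(ex, bd$upper + 1e-10)
      }
    }
  }
})

test_that("slow-reaction curve: exact two-component limit and O(k23) corrections", {
  # k23 = 0 exactly: corrections vanish (compare against hand-built params)
  p0 <- dim_params(1/6, 0.5, 2000, N1 = 0.3, Q_C = 1.4)
  tg <- p0$diffusion$tau_B * chi_grid(20, -2, 1)
  sl <- suppressWarnings(slow_reaction_acf(tg, p0))$g
  tc <- two_component_acf(tg, p0)
  # rates ~5e-4/tau_B: the correction is tiny but nonzero
  expect_gt(max(abs(sl - tc)), 0)
  # matches the exact engine within 1e-3 relative for t < 0.1/gamma
  gam <- p0$scheme$gamma
  tsl <- p0$diffusion$tau_B *
    10^seq(-2, log10(0.1 / (gam * p0$diffusion$tau_B)), length.out = 12)
  ex <- full_acf(tsl, p0, method = "exact")$g
  ap <- suppressWarnings(slow_reaction_acf(tsl, p0))$g
  expect_lt(max(abs(ap - ex) / ex), 1e-3)
  # correction terms scale linearly when k23 is doubled at fixed k32:
  # the coupling component G32 = k23 t J(t) doubles, the amplitude
  # depletion of G22 doubles to first order, and G23 = k32 t J(t) is
  # unchanged (same diffusion times)
  p1 <- dim_params(1/6, 2/3, 8000/7, N1 = 0.3, Q_C = 1.4)  # k23 doubled
  expect_equal(p1$scheme$k32, p0$scheme$k32, tolerance = 1e-12)
  expect_equal(p1$scheme$k23 / p0$scheme$k23, 2, tolerance = 1e-12)
  c0 <- suppressWarnings(component_acfs(tsl, p0, method = "slow_reaction"))
  c1 <- suppressWarnings(component_acfs(tsl, p1, method = "slow_reaction"))
  expect_equal(c1$G32 / c0$G32, rep(2, length(tsl)), tolerance = 1e-10)
  expect_equal(c1$G23, c0$G23, tolerance = 1e-12)
  gsB <- gs(tsl / p0$diffusion$tau_B, 5)
  # exact ratio is 1 + exp(-k23 t), i.e. 2 to first order in k23 t
  expect_equal((c1$G22 - gsB) / (c0$G22 - gsB),
               1 + exp(-p0$scheme$k23 * tsl), tolerance = 1e-6)
  # outside its regime the route warns
  expect_warning(slow_reaction_acf(tg, dim_params(1/6, 0.5, 1)), "regime")
})

test_that("fast-diffusion route (immobile sites): regime structure", {
  p <- fcs_params_dimensionless(0, 0.5, 1 / (0.5 * 1e-3), N1 = 0.2, Q_C = 1.2)
  expect_equal(p$scheme$R * p$diffusion$tau_B, 1e-3)
  gam <- p$scheme$gamma
  # transition time formula and its tau_B scaling
  expect_equal(transition_time(p),
               4 * 0.5^2 * 0.5^2 / (p$scheme$R^2 * p$diffusion$tau_B))
  p_small <- fcs_params_dimensionless(0, 0.5, 1 / (0.5 * 1e-4),
                                      tau_B = 0.1, N1 = 0.2)
  expect_gt(transition_time(p_small), transition_time(p))  # t_t -> Inf as tau_B -> 0
  expect_error(transition_time(dim_params(1/6, 0.5, 1)), "immobile")
  # early in the regime (t ~ 10/gamma, where the exponential term still
  # dominates the bound-state component) G33 agrees with the exact engine
  # to better than 10%, and the assembled curve everywhere to ~1e-4:
  # at later times the polynomial bulk term overtakes exp(-k32 t) and the
  # pointwise approximation of the continuous part degrades (measured)
  t1 <- 10 / gam
  cf1 <- component_acfs(t1, p, method = "fast_diffusion")
  ce1 <- component_acfs(t1, p, method = "exact")
  expect_lt(abs(cf1$G33 / ce1$G33 - 1), 0.10)
  tg <- 10^seq(log10(10 / gam), log10(25 / gam), length.out = 5)
  cf <- component_acfs(tg, p, method = "fast_diffusion")
  ce <- component_acfs(tg, p, method = "exact")
  expect_lt(max(abs(cf$G / ce$G - 1)), 5e-4)
  # the exponential amplitude structure: G33 >= its pure-decay atom
  expect_true(all(cf$G33 >= exp(-p$scheme$k32 * tg)))
})

test_that("limit chain: moment expansion approaches effective diffusion as R grows", {
  errs <- sapply(c(1e2, 1e3, 1e4), function(RtB) {
    v <- (1 / 0.5 + (1/6) / 0.5) / RtB
    p <- dim_params(1/6, 0.5, v, N1 = 0.2, Q_C = 1.3)
    tg <- p$diffusion$tau_B * chi_grid(15, -1, 2)
    max(abs(full_acf(tg, p, method = "moment_expansion")$g /
              effective_diffusion_acf(tg, p) - 1))
  })
  expect_true(all(diff(errs) < 0))
  # and the exact engine approaches two-component diffusion as R -> 0
  errs2 <- sapply(c(2e3, 2e4), function(vv) {
    p <- dim_params(1/6, 0.5, vv, N1 = 0.2, Q_C = 1.3)
    tg <- p$diffusion$tau_B * chi_grid(12, -1, 1)
    max(abs(full_acf(tg, p, method = "exact")$g / two_component_acf(tg, p) - 1))
  })
  expect_true(all(diff(errs2) < 0))
  expect_lt(errs2[2], 5e-4)
})
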