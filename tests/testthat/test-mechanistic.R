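test_that("capacity ratio is (1/K_pf)(V_f/V_p)", {
  expect_equal(capacity_ratio(1, 1, 1), 1)
  expect_equal(capacity_ratio(10, 5, 1), 0.5)
  expect_equal(capacity_ratio(1e6, 1, 1), 1e-6)
  expect_error(capacity_ratio(0, 1, 1), class = "salivamigr_domain_error")
  expect_error(capacity_ratio(1, -1, 1), class = "salivamigr_domain_error")
})

test_that("deviation time scales as d_p^2/D_p, matches high-precision evaluation, and is near-continuous at alpha = 0.2", {
  # alpha = 1: logistic term collapses to 0.3552/(1 + 85.88)
  expect_equal(deviation_time(0.1, 1e-10, 1),
               (0.1^2 / 1e-10) * 0.3552 / (1 + 85.88), tolerance = 1e-14)
  # large-alpha limit: prefactor -> 0.3552
  expect_equal(deviation_time(0.1, 1e-10, 1e12) / (0.1^2 / 1e-10), 0.3552,
               tolerance = 1e-6)
  # exact d^2/D scaling: prefactor depends only on alpha
  for (a in c(0.01, 0.2, 0.5, 3)) {
    p1 <- deviation_time(0.1, 1e-10, a) * 1e-10 / 0.1^2
    p2 <- deviation_time(0.4, 3e-9, a) * 3e-9 / 0.4^2
    expect_equal(p1, p2, tolerance = 1e-12)
  }
  # the two branches agree within ~10% at the switch point under log10
  lo <- deviation_time(0.1, 1e-10, 0.2)                      # alpha <= 0.2 branch
  hi <- deviation_time(0.1, 1e-10, 0.2 + 1e-12)              # alpha > 0.2 branch
  expect_lt(abs(lo / hi - 1), 0.1)
})

test_that("short-term fraction follows the square-root diffusion law", {
  expect_equal(short_term_fraction(0.1, 1e-10, 0), 0)
  t <- c(10, 500, 3600)
  expect_equal(short_term_fraction(0.1, 1e-10, 4 * t),
               2 * short_term_fraction(0.1, 1e-10, t), tolerance = 1e-14)
  expect_equal(short_term_fraction(0.1, 1e-10, 3600),
               20 * sqrt(3.6e-7 / pi), tolerance = 1e-14)
  expect_error(short_term_fraction(0.1, 1e-10, -1), class = "salivamigr_domain_error")
})

test_that("saturation coefficients clamp as specified with exact values at alpha = 1", {
  co <- saturation_coefficients(1)
  expect_identical(co$A, 0.8)
  expect_identical(co$B, 0.5)
  expect_identical(co$C, 0.004)       # x3 = 0.08 < 0.3 -> floor
  co_hi <- saturation_coefficients(1e10)
  expect_identical(co_hi$A, 1)
  expect_identical(co_hi$B, 0.9)
  co_lo <- saturation_coefficients(1e-10)
  expect_identical(co_lo$A, 0.7)
  expect_identical(co_lo$B, 0.3)
  expect_identical(co_lo$C, 0.004)
  for (a in 10^seq(-8, 8, length.out = 33)) {
    co <- saturation_coefficients(a)
    expect_true(co$A >= 0.7 && co$A <= 1)
    expect_true(co$B >= 0.3 && co$B <= 0.9)
    expect_true(co$C == 0.004 || (co$C > 0.3 && co$C <= 1))
  }
})

test_that("migrated fraction agrees with the branch formulas at the edges", {
  r0 <- migrated_fraction(0, 1e-10, 100, 0.2, 50, 10)
  expect_equal(r0$f_mgr, 0)
  expect_identical(r0$regime, "short_term_diffusion")

  # at t_dev exactly both branches give f_tdev
  r <- migrated_fraction(1, 1e-10, 100, 0.2, 50, 10)
  td <- r$saturation$t_dev
  at <- migrated_fraction(td, 1e-10, 100, 0.2, 50, 10)
  just_after <- migrated_fraction(td * (1 + 1e-12), 1e-10, 100, 0.2, 50, 10)
  expect_equal(at$f_mgr, r$saturation$f_tdev, tolerance = 1e-12)
  expect_lt(abs(just_after$f_mgr - at$f_mgr), 1e-9)

  # t -> infinity approaches the equilibrium plateau alpha/(1+alpha)
  alpha <- r$saturation$alpha
  t_inf <- td + 60 / (r$saturation$C * r$saturation$beta)
  far <- migrated_fraction(t_inf, 1e-10, 100, 0.2, 50, 10)
  expect_equal(far$f_mgr, alpha / (1 + alpha), tolerance = 1e-9)
  expect_identical(far$regime, "saturation")
})

test_that("migrated fraction matches the independent single-expression oracle", {
  grid <- random_migration_inputs(250, seed = 202)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    got <- migrated_fraction(g$t, g$D, g$K, g$d, g$v_p, g$v_f)$f_mgr
    expect_equal(got, table1_oracle(g$t, g$D, g$K, g$d, g$v_p, g$v_f),
                 tolerance = 1e-12)
  }
})

test_that("fraction respects bounds and is monotone in time and diffusivity", {
  grid <- random_migration_inputs(60, seed = 7)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    alpha <- capacity_ratio(g$K, g$v_f, g$v_p)
    ts <- 10^seq(0, 8, length.out = 25)
    fs <- vapply(ts, function(t)
      migrated_fraction(t, g$D, g$K, g$d, g$v_p, g$v_f)$f_mgr, numeric(1))
    expect_true(all(fs >= 0))
    expect_true(all(fs <= alpha / (1 + alpha) + 1e-12))
    expect_true(all(diff(fs) >= -1e-12))
  }
  # monotone in D_p within the short-term regime
  f_slow <- migrated_fraction(60, 1e-12, 100, 0.2, 50, 10)
  f_fast <- migrated_fraction(60, 1e-10, 100, 0.2, 50, 10)
  expect_identical(f_slow$regime, "short_term_diffusion")
  expect_gte(f_fast$f_mgr, f_slow$f_mgr)
})

test_that("pathological geometry clamps at the plateau with a warning instead of failing", {
  # extreme retention (alpha ~ 1e-40): the equilibrium plateau falls below
  # the short-term fraction already migrated at t_dev
  res <- migrated_fraction(1, 1e-8, 1e38, 0.05, 100, 1)
  expect_equal(res$f_mgr, res$saturation$alpha / (1 + res$saturation$alpha))
  expect_gt(length(result_warnings(res)), 0)
})

test_that("migration rate applies the per-10cm2 mass convention and is linear in c0", {
  # f = 0.01, m0 = c0 * density * a_contact * d_p = 500*1*10*0.2 = 1000 ug
  expect_equal(migration_rate(0.01, t_min = 60, c0 = 500, density = 1,
                              d_p = 0.2, a_contact = 10),
               0.01 * 1000 / (1 * 60), tolerance = 1e-14)
  expect_equal(migration_rate(0, t_min = 60, c0 = 500, density = 1, d_p = 0.2), 0)
  r1 <- migration_rate(0.02, 30, c0 = 100, density = 1.3, d_p = 0.1)
  r2 <- migration_rate(0.02, 30, c0 = 200, density = 1.3, d_p = 0.1)
  expect_equal(r2, 2 * r1, tolerance = 1e-14)
  # contact area cancels in the per-10cm2 normalization
  expect_equal(migration_rate(0.02, 30, 100, 1.3, 0.1, a_contact = 5),
               migration_rate(0.02, 30, 100, 1.3, 0.1, a_contact = 50),
               tolerance = 1e-14)
  expect_error(migration_rate(0.01, t_min = 0, c0 = 100, density = 1, d_p = 0.1),
               class = "salivamigr_domain_error")
})
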