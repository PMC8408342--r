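test_that("level-based decomposition matches its closed-form construction", {
  # country built with y = 1.0, e = 0.10, h = 0.05
  gdp0 <- 1000; gge_gdp0 <- 0.25; ghd_gge0 <- 0.08
  gge0 <- gdp0 * gge_gdp0
  ghd0 <- gge0 * ghd_gge0
  gdp1 <- gdp0 * 2.0
  gge1 <- gdp1 * gge_gdp0 * 1.10
  ghd1 <- gge1 * ghd_gge0 * 1.05
  d <- decompose_gghed(gdp0, gdp1, gge0, gge1, ghd0, ghd1)
  expect_equal(d$g, 2.0 * 1.10 * 1.05 - 1, tolerance = 1e-12)
  expect_equal(d$y, 1.0, tolerance = 1e-12)
  expect_equal(d$e, 0.10, tolerance = 1e-12)
  expect_equal(d$h, 0.05, tolerance = 1e-12)
  expect_equal(d$s_y, log(2) / log(2.31), tolerance = 1e-12)
  expect_equal(d$s_e, log(1.1) / log(2.31), tolerance = 1e-12)
  expect_equal(d$s_h, log(1.05) / log(2.31), tolerance = 1e-12)
  expect_lt(abs(d$residual), 1e-12)
  expect_equal(d$s_y + d$s_e + d$s_h, 1, tolerance = 1e-12)
})

test_that("no change in any level yields zero rates and undefined shares", {
  d <- decompose_gghed(100, 100, 25, 25, 2, 2)
  expect_equal(c(d$g, d$y, d$e, d$h), c(0, 0, 0, 0))
  expect_false(d$shares_defined)
  expect_true(is.na(d$s_y))
})

test_that("decomposition rejects invalid levels and warns on implausible ones", {
  expect_error(decompose_gghed(0, 1, 1, 1, 1, 1), "positive")
  expect_error(decompose_gghed(1, 1, 1, 1, NA, 1), "positive")
  expect_warning(decompose_gghed(100, 200, 10, 20, 15, 18), "exceeds GGE")
})

test_that("component_share handles levels and ratio values alike", {
  # ratio pair in percent units; only the pair ratio matters
  s <- component_share(4.4, 4.8, 21479.8, 63651.65)
  expect_equal(round(s, 4), 0.0801)
  expect_equal(round_half_up(100 * s), 8.0)
  expect_equal(component_share(0.044, 0.048, 21479.8, 63651.65), s)
  expect_equal(component_share(7, 7, 10, 20), 0)
  expect_error(component_share(1, 2, 10, 10), "zero")
  expect_error(component_share(-1, 2, 10, 20), "positive")
})

test_that("three component shares from one consistent record sum to 1", {
  gdp <- c(500, 1700); gge_gdp <- c(0.22, 0.27); ghd_gge <- c(0.05, 0.065)
  ghd <- gdp * gge_gdp * ghd_gge
  s <- component_share(gdp[1], gdp[2], ghd[1], ghd[2]) +
    component_share(gge_gdp[1], gge_gdp[2], ghd[1], ghd[2]) +
    component_share(ghd_gge[1], ghd_gge[2], ghd[1], ghd[2])
  expect_equal(s, 1, tolerance = 1e-12)
})

test_that("growth_from_component_rates composes rates multiplicatively", {
  expect_equal(growth_from_component_rates(0, 0, 0), 0)
  expect_equal(round_half_up(100 * growth_from_component_rates(
    1.508, 0.091, 0.083)), 196.3)
  expect_error(growth_from_component_rates(-1.5, 0, 0), "positive")
  withr::with_seed(17, {
    for (i in 1:30) {
      r <- stats::runif(3, -0.9, 3)
      g <- growth_from_component_rates(r[1], r[2], r[3])
      expect_lt(abs(log1p(g) - sum(log1p(r))), 1e-12)
    }
  })
})

test_that("log identity is exact on random level-based decompositions", {
  withr::with_seed(23, {
    for (i in 1:30) {
      gdp <- stats::rlnorm(2, 10, 1)
      gge <- gdp * stats::runif(2, 0.1, 0.5)
      ghd <- gge * stats::runif(2, 0.02, 0.2)
      d <- decompose_gghed(gdp[1], gdp[2], gge[1], gge[2], ghd[1], ghd[2])
      expect_lt(abs(d$residual), 1e-12)
      if (d$shares_defined) {
        expect_equal(d$s_y + d$s_e + d$s_h, 1, tolerance = 1e-10)
      }
    }
  })
})

test_that("shares are symmetric in component order and g is monotone", {
  d <- decompose_from_rates(y = 0.4, e = 0.1, h = 0.25)
  d_perm <- decompose_from_rates(y = 0.25, e = 0.4, h = 0.1)
  expect_setequal(round(c(d$s_y, d$s_e, d$s_h), 12),
                  round(c(d_perm$s_y, d_perm$s_e, d_perm$s_h), 12))
  # increasing any end level strictly increases g
  base <- decompose_gghed(100, 200, 25, 60, 2, 6)
  expect_gt(decompose_gghed(100, 200, 25, 60, 2, 6.5)$g, base$g)
})

test_that("decompose_from_rates reports the rounding residual, never hides it", {
  # rates as printed at one decimal from a rounded source
  d <- decompose_from_rates(y = 1.508, e = 0.091, h = 0.083, g = 1.963)
  expect_equal(d$s_y + d$s_e + d$s_h, 1 - d$residual / d$Lg,
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(d$residual, 0)))
  expect_error(decompose_from_rates(y = -1.2, e = 0, h = 0), "undefined")
})

test_that("group decomposition recovers generator parameters", {
  # noise-free homogeneous groups: recovery to 1e-9 relative
  gen <- generate_panel(synthetic_config(focus = NULL, seed = 3))
  ex <- apply_inclusion_filters(gen$panel)
  asg <- assign_income_groups(ex, gen$truth$classification)
  dec <- group_decomposition(gen$panel, asg, 2000, 2015)
  truth <- gen$truth$group_rates
  for (grp in truth$group) {
    row <- dec[dec$group == grp, ]
    tr <- truth[truth$group == grp, ]
    expect_equal(row$y_pct / 100, tr$y, tolerance = 1e-9)
    expect_equal(row$e_pct / 100, tr$e, tolerance = 1e-9)
    expect_equal(row$h_pct / 100, tr$h, tolerance = 1e-9)
    expect_equal(row$g_pct / 100, tr$g, tolerance = 1e-9)
    expect_lt(abs(row$residual_nats), 1e-12)
  }
  # lognormal noise: recovery within sampling tolerance
  gen_n <- generate_panel(synthetic_config(focus = NULL, noise_sigma = 0.02,
                                           seed = 4))
  dec_n <- group_decomposition(gen_n$panel,
                               assign_income_groups(
                                 apply_inclusion_filters(gen_n$panel),
                                 gen_n$truth$classification),
                               2000, 2015)
  for (grp in truth$group) {
    expect_equal(dec_n$y_pct[dec_n$group == grp] / 100,
                 truth$y[truth$group == grp], tolerance = 0.15)
    expect_lt(abs(dec_n$residual_nats[dec_n$group == grp]), 1e-12)
  }
})
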