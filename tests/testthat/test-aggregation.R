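test_that("aggregate levels are exact member sums", {
  panel <- make_panel(
    make_record("AAA", 2000, gghe_d = 10, che = 47),
    make_record("BBB", 2000, gghe_d = 32, che = 69)
  )
  asg <- single_group_assignment(panel)
  # single-member group
  solo <- single_group_assignment(make_panel(make_record("AAA", 2000,
                                                         gghe_d = 10,
                                                         che = 47)))
  expect_equal(aggregate_level(make_panel(make_record("AAA", 2000,
                                                      gghe_d = 10,
                                                      che = 47)),
                               solo, "gghe_d", years = 2000)$value, 10)
  cell <- aggregate_level(panel, asg, "gghe_d", years = 2000)
  expect_equal(cell$value, 42)
  expect_equal(cell$n_countries, 2)
})

test_that("aggregate sum matches a brute-force loop on a 50-member group", {
  gen <- generate_panel(synthetic_config(
    groups = dplyr::mutate(fiscalspace:::default_group_params()[1, ],
                           n_countries = 50L),
    focus = NULL, seed = 5
  ))
  asg <- single_group_assignment(gen$panel)
  cell <- aggregate_level(gen$panel, asg, "gdp", years = 2015)
  acc <- 0
  for (cc in unique(gen$panel$iso3)) {
    acc <- acc + gen$panel$gdp[gen$panel$iso3 == cc &
                                 gen$panel$year == 2015]
  }
  expect_equal(cell$value, acc, tolerance = 1e-12)
})

test_that("aggregate ratios are denominator-weighted means of member ratios", {
  panel <- make_panel(
    make_record("AAA", 2000, gghe_d = 10, gge = 100),
    make_record("BBB", 2000, gghe_d = 30, gge = 100)
  )
  asg <- single_group_assignment(panel)
  r <- aggregate_ratio(panel, asg, "gghe_d", "gge", years = 2000)
  expect_equal(r$value, 0.20)
  w <- stats::weighted.mean(c(0.10, 0.30), c(100, 100))
  expect_equal(r$value, w)
  # country-weighted average differs when denominators differ
  panel2 <- make_panel(
    make_record("AAA", 2000, gghe_d = 30, gge = 300),
    make_record("BBB", 2000, gghe_d = 15, gge = 50)
  )
  asg2 <- single_group_assignment(panel2)
  agg <- aggregate_ratio(panel2, asg2, "gghe_d", "gge", years = 2000)$value
  cw <- country_weighted_average(panel2, asg2, "gghe_d", "gge",
                                 years = 2000)$value
  expect_equal(cw, mean(c(0.10, 0.30)))
  expect_lt(agg, cw)
  expect_equal(agg, 45 / 350)
})

test_that("aggregate ratio stays within member ratio extrema (property)", {
  gen <- default_generated()
  asg <- single_group_assignment(gen$panel)
  for (yr in c(2000, 2008, 2015)) {
    r <- aggregate_ratio(gen$panel, asg, "gghe_d", "gdp", years = yr)$value
    member <- gen$panel[gen$panel$year == yr, ]
    ratios <- member$gghe_d / member$gdp
    expect_gte(r, min(ratios))
    expect_lte(r, max(ratios))
  }
})

test_that("complete-pairs rule drops members missing either component", {
  panel <- make_panel(
    make_record("AAA", 2000, gghe_d = 10, gge = 100),
    make_record("BBB", 2000, gghe_d = NA_real_, gge = 1000, che = 50),
    make_record("CCC", 2000, gghe_d = 30, gge = 100)
  )
  asg <- single_group_assignment(panel)
  r <- aggregate_ratio(panel, asg, "gghe_d", "gge", years = 2000)
  expect_equal(r$value, 40 / 200)
  expect_equal(r$n_countries, 2)
})

test_that("composition shares reproduce per-capita arithmetic and sum to 1", {
  # group whose per-capita aggregates are CHE 31.2 and GGHE-D 8.7
  panel <- make_panel(
    make_record("AAA", 2000, population = 1e6, gghe_d = 8.7 * 1,
                ext = 1.3, oop = 18.9, vpp = 1.0, pvt_other = 1.3,
                che = 31.2)
  )
  asg <- single_group_assignment(panel)
  shares <- composition_shares(panel, asg, years = 2000)
  ghd <- shares$share[shares$component == "gghe_d"]
  expect_equal(round(ghd, 4), 0.2788)
  expect_equal(round(100 * ghd), 28)

  # all-OOP record
  oop_only <- make_panel(make_record("BBB", 2000, gghe_d = 0, ext = 0,
                                     oop = 50, vpp = 0, pvt_other = 0))
  s2 <- composition_shares(oop_only, single_group_assignment(oop_only),
                           years = 2000)
  expect_equal(s2$share[s2$component == "oop"], 1)
  expect_equal(sum(s2$share), 1)

  # additively built synthetic group sums to 1 within 1e-12
  gen <- default_generated()
  asg3 <- single_group_assignment(gen$panel)
  s3 <- composition_shares(gen$panel, asg3, years = c(2000, 2015))
  sums <- tapply(s3$share, s3$year, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("missing components count zero in composition and are flagged", {
  panel <- make_panel(
    make_record("AAA", 2000, ext = NA_real_, che = 60)
  )
  asg <- single_group_assignment(panel)
  s <- composition_shares(panel, asg, years = 2000)
  expect_equal(s$share[s$component == "ext"], 0)
  expect_true(s$flagged[s$component == "ext"])
  expect_false(s$flagged[s$component == "oop"])
})

test_that("identical members make country-weighted equal the aggregate", {
  panel <- make_panel(
    make_record("AAA", 2000), make_record("BBB", 2000),
    make_record("CCC", 2000)
  )
  asg <- single_group_assignment(panel)
  agg <- aggregate_ratio(panel, asg, "oop", "che", years = 2000)$value
  cw <- country_weighted_average(panel, asg, "oop", "che",
                                 years = 2000)$value
  expect_equal(agg, cw)
})

test_that("a dominant member pulls the aggregate ratio toward its own", {
  rows <- lapply(1:9, function(i) {
    make_record(sprintf("S%02d", i), 2000, gghe_d = 5, gge = 100)
  })
  big <- make_record("BIG", 2000, gghe_d = 300, gge = 1000)
  panel <- make_panel(dplyr::bind_rows(rows), big)
  asg <- single_group_assignment(panel)
  agg <- aggregate_ratio(panel, asg, "gghe_d", "gge", years = 2000)$value
  cw <- country_weighted_average(panel, asg, "gghe_d", "gge",
                                 years = 2000)$value
  # independent weighted-mean computation fixes the divergence sign
  ratios <- c(rep(0.05, 9), 0.30)
  weights <- c(rep(100, 9), 1000)
  expect_equal(agg, stats::weighted.mean(ratios, weights))
  expect_equal(sign(agg - cw), sign(stats::weighted.mean(ratios, weights) -
                                      mean(ratios)))
  expect_gt(abs(agg - 0.30), 0) # tracks but does not equal the dominant
  expect_lt(abs(agg - 0.30), abs(cw - 0.30))
})

test_that("per-capita value times population sum recovers the level sum", {
  gen <- default_generated()
  asg <- single_group_assignment(gen$panel)
  pc <- per_capita(gen$panel, asg, "che", years = 2015)$value
  pop <- aggregate_level(gen$panel, asg, "population", years = 2015)$value
  lvl <- aggregate_level(gen$panel, asg, "che", years = 2015)$value
  expect_equal(pc * pop, lvl, tolerance = 1e-12)
})

test_that("ratios are invariant under uniform rescaling", {
  panel <- anchor_panel(n = 4)
  asg <- single_group_assignment(panel)
  scaled <- tibble::as_tibble(panel)
  for (col in c("gghe_d", "gge", "gdp", "che", "oop", "ext", "vpp",
                "pvt_other", "population")) {
    scaled[[col]] <- scaled[[col]] * 1000
  }
  scaled <- as_fin_panel(scaled)
  asg2 <- single_group_assignment(scaled)
  expect_equal(
    aggregate_ratio(panel, asg, "gghe_d", "gge", years = 2000)$value,
    aggregate_ratio(scaled, asg2, "gghe_d", "gge", years = 2000)$value
  )
  expect_equal(
    country_weighted_average(panel, asg, "gghe_d", "gge", years = 2000)$value,
    country_weighted_average(scaled, asg2, "gghe_d", "gge",
                             years = 2000)$value
  )
})

test_that("aggregation errors are informative", {
  panel <- anchor_panel(n = 2)
  asg <- single_group_assignment(panel)
  expect_error(aggregate_level(panel, asg, "nonsense", years = 2000),
               "unknown indicator")
  expect_error(aggregate_level(panel, asg, "gdp", years = 2000,
                               groups = "XYZ"), "unknown reporting group")
})
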