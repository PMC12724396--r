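test_that("attributable-number arithmetic: flat curve gives zero HAF and
           a known RR gives the textbook attributable number", {
  vs <- var_basis_spec()
  dates <- seq(as.Date("2010-05-01"), as.Date("2010-09-30"), by = "day")
  tmean <- seq(10, 30, length.out = length(dates))
  table <- quantile(tmean, 0:100 / 100)
  deaths <- rep(10L, length(dates))
  ser <- data.frame(date = dates, tmean = tmean, deaths = deaths)

  flat <- center_curve(reduced_curve(rep(0, 4), var_spec = vs), 50)
  out <- attributable_numbers(ser, flat, table)
  expect_equal(out$haf, 0)
  expect_equal(out$an_total, 0)

  # linear curve reaching log-RR = log(2) at the hottest day (linear
  # functions lie exactly in the quadratic spline space once the dropped
  # intercept column is folded in): RR = 2 with 10 deaths gives
  # AN = (2 - 1)/2 * 10 = 5
  xs <- seq(0, 100, 0.5)
  cfull <- qr.solve(bspline_basis(xs, vs, intercept = TRUE),
                    log(2) * (xs - 50) / 50)
  curve <- center_curve(reduced_curve(cfull[-1] - cfull[1],
                                      var_spec = vs), 50)
  pr <- predict(curve, 100)
  expect_equal(pr$rr, 2, tolerance = 1e-8)
  af <- 1 - exp(-pr$logrr)
  expect_equal(10 * af, 5, tolerance = 1e-8)

  expect_error(attributable_numbers(ser,
                                    reduced_curve(cfull[-1] - cfull[1],
                                                  var_spec = vs),
                                    table), "centered")
})

test_that("attributable fractions stay in [0, 1) under the flooring rule", {
  set.seed(2)
  vs <- var_basis_spec()
  dates <- seq(as.Date("2011-01-01"), as.Date("2013-12-31"), by = "day")
  tmean <- 15 + 8 * cos(2 * pi * (seq_along(dates) - 196) / 365.25) +
    rnorm(length(dates), 0, 3)
  ser <- data.frame(date = dates, tmean = tmean,
                    deaths = rpois(length(dates), 12))
  table <- pct_table(tmean, dates)
  cf <- rnorm(4, 0, 0.5)
  curve <- reduced_curve(cf, var_spec = vs)
  curve <- center_curve(curve, find_mmt(curve)$mmt)
  out <- attributable_numbers(ser, curve, table)
  expect_true(all(out$days$af >= 0 & out$days$af < 1))
  expect_true(out$haf >= 0 & out$haf < 100)
})

test_that("attributable death rate arithmetic and scaling laws", {
  expect_equal(had_rate(50, 1e6, 5), 1)
  expect_equal(had_rate(0, 5e5, 3), 0)
  expect_equal(had_rate(80, 2e6, 4), had_rate(80, 1e6, 4) / 2)
  expect_error(had_rate(10, 0, 5), "population")
  expect_error(had_rate(10, 1000, 0), "n_years")
})

test_that("scenario contrast arithmetic mirrors the relative-difference
           definition", {
  # HAF 4% -> 3% is a 25% reduction
  expect_equal((3 - 4) / 4 * 100, -25)
  coh <- small_cohort(n_cities = 6, years = c(2003, 2014), seed = 55)
  cfg <- run_config(n_samples = 120, seed = 9)
  s1 <- first_stage(coh, cfg)
  md <- assemble_meta_dataset(s1, coh$catalogue)
  fit <- fit_meta(md, "model3")
  att <- monte_carlo_attribution(fit, md, coh, cfg)
  tab <- att$table
  for (i in seq_len(nrow(tab))) {
    if (tab$haf_counterfactual[i] != 0)
      expect_equal(tab$haf_change[i],
                   (tab$haf_factual[i] - tab$haf_counterfactual[i]) /
                     tab$haf_counterfactual[i] * 100, tolerance = 1e-10)
    expect_equal(tab$had_difference[i],
                 tab$had_factual[i] - tab$had_counterfactual[i],
                 tolerance = 1e-10)
  }
  # aggregation additivity: overall AN equals the sum over locations,
  # in the point estimate and in every Monte-Carlo sample
  loc <- tab$scope_type == "location"
  ov <- tab$scope_type == "overall"
  expect_equal(sum(tab$an_factual[loc]), tab$an_factual[ov],
               tolerance = 1e-10)
  for (s in att$samples) {
    expect_equal(sum(s$an_factual[s$scope_type == "location"]),
                 s$an_factual[s$scope_type == "overall"],
                 tolerance = 1e-10)
    expect_equal(sum(s$an_counterfactual[s$scope_type == "location"]),
                 s$an_counterfactual[s$scope_type == "overall"],
                 tolerance = 1e-10)
  }
  # empirical CIs bracket the scenario point estimates sensibly
  expect_true(all(tab$haf_change_lo <= tab$haf_change_hi))
})

test_that("Monte-Carlo machinery: CIs collapse when the coefficient
           covariance vanishes, and runs are seed-reproducible", {
  coh <- small_cohort(n_cities = 4, years = c(2004, 2012), seed = 77)
  cfg <- run_config(n_samples = 120, seed = 4)
  s1 <- first_stage(coh, cfg)
  md <- assemble_meta_dataset(s1, coh$catalogue)
  fit <- fit_meta(md, "model3")
  fit0 <- fit
  fit0$vcov_beta <- matrix(0, length(fit$beta), length(fit$beta))
  att0 <- monte_carlo_attribution(fit0, md, coh, cfg)
  expect_equal(att0$table$haf_change_lo, att0$table$haf_change,
               tolerance = 1e-10)
  expect_equal(att0$table$haf_change_hi, att0$table$haf_change,
               tolerance = 1e-10)

  a1 <- monte_carlo_attribution(fit, md, coh, cfg, seed = 101)
  a2 <- monte_carlo_attribution(fit, md, coh, cfg, seed = 101)
  expect_identical(a1$table, a2$table)
  a3 <- monte_carlo_attribution(fit, md, coh, cfg, seed = 102)
  expect_false(identical(a1$table$haf_change_lo,
                         a3$table$haf_change_lo))
  expect_warning(monte_carlo_attribution(fit, md, coh, cfg,
                                         n_samples = 50),
                 "Monte-Carlo")

  # sampling the random effects as well cannot narrow the intervals
  cfg_re <- cfg
  cfg_re$sample_random_effects <- TRUE
  a4 <- monte_carlo_attribution(fit, md, coh, cfg_re, seed = 101)
  ov <- a1$table$scope_type == "overall"
  w_fixed <- a1$table$haf_factual_hi[ov] - a1$table$haf_factual_lo[ov]
  w_re <- a4$table$haf_factual_hi[ov] - a4$table$haf_factual_lo[ov]
  expect_gte(w_re, 0.8 * w_fixed)
})

test_that("a protective fitted HPP coefficient implies factual HAF below
           counterfactual on every post-implementation unit", {
  coh <- small_cohort(n_cities = 8, years = c(2000, 2014),
                      hpp_effect = 0.6, seed = 31)
  cfg <- run_config(n_samples = 120, seed = 2)
  s1 <- first_stage(coh, cfg)
  md <- assemble_meta_dataset(s1, coh$catalogue)
  fit <- fit_meta(md, "model3")
  jh <- which(fit$coef_names == "hpp")
  hpp_block <- fit$beta_mat[, jh]
  vs <- md$var_spec
  # the HPP block as a curve: effect on log-RR above the MMT region
  delta <- drop(bspline_basis(seq(80, 99, 1), vs) %*% hpp_block -
                  rep(drop(bspline_basis(70, vs) %*% hpp_block), 20))
  # with this seed the fitted effect is uniformly protective above the
  # MMT region, so the sign-coherence implication must hold unit-wise
  expect_true(all(delta < 0))
  att <- monte_carlo_attribution(fit, md, coh, cfg)
  post <- att$units$hpp == 1
  expect_true(all(att$units$an_factual[post] <=
                    att$units$an_counterfactual[post] + 1e-8))
})
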