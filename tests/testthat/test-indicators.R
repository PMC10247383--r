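test_that("tree and palm allometries match single-line evaluations", {
  expect_equal(agb_tree(0.5, 10, 10), 0.0673 * 500^0.976, tolerance = 1e-12)
  expect_equal(agb_tree(0.5, 10, 10), 28.98, tolerance = 1e-3)
  # unit argument of the power law
  expect_equal(agb_tree(1, 1, 1), 0.0673)
  # power-law homogeneity in the combined argument
  expect_equal(agb_tree(0.5, 10, 20), 2^0.976 * agb_tree(0.5, 10, 10))
  expect_equal(agb_tree(2 * 0.4, 7, 3), 2^0.976 * agb_tree(0.4, 7, 3))
  expect_equal(agb_palm(5), 71.797 * 5 - 7.0872)
  expect_equal(agb_palm(1), 64.7098, tolerance = 1e-4)
  expect_error(agb_palm(7.0872 / 71.797), "positive biomass")
})

test_that("plot-level biomass converts units correctly", {
  # one 100 kg tree on 100 m^2, no palms -> 10 t/ha
  expect_equal(total_agb(100, numeric(0), 100), 10)
  expect_equal(total_agb(numeric(0), numeric(0), 100), 0)
  # linearity in the masses
  expect_equal(total_agb(c(50, 70), c(200, 300), 400, 90),
               2 * total_agb(c(25, 35), c(100, 150), 400, 90))
  # palms contribute mean mass times stand density
  expect_equal(total_agb(numeric(0), c(100, 300), 100, 120),
               200 * 120 / 1000)
})

test_that("basal-area increment follows the matched-tree formula", {
  expect_equal(ba_increment(2, 4, 25), (pi / 4) * (16 - 4) / 25)
  expect_equal(ba_increment(c(3, 5), c(3, 5), 100), 0)
  expect_equal(ba_increment(c(2, 2), c(4, 4), 25),
               2 * ba_increment(2, 4, 25))
  expect_warning(ba_increment(5, 3, 25), "shrank")
})

test_that("daily temperature amplitude is the median 7:00-15:00 difference", {
  series <- expand.grid(day = 1:99, hour = c(7, 15))
  series$temp_c <- ifelse(series$hour == 7, 24, 32)
  expect_equal(microclimate_amplitude(series), 8)
  # constant series
  series$temp_c <- 26
  expect_equal(microclimate_amplitude(series), 0)
  # one wild day cannot move the median
  series$temp_c <- ifelse(series$hour == 7, 24, 32)
  series$temp_c[series$day == 50 & series$hour == 15] <- 60
  expect_equal(microclimate_amplitude(series), 8)
  # days missing a reading are dropped; none left -> error
  expect_error(microclimate_amplitude(
    data.frame(day = 1, hour = 7, temp_c = 24)), "no day")
})

test_that("litter annualization and the outlier rule behave as specified", {
  # constant 5 g per trap over 24 semi-monthly dates -> 480 g/m2/yr
  lit <- expand.grid(date = 1:24, trap = 1:4)
  lit$mass_g <- 5
  expect_equal(litter_annualize(lit), (5 / 0.25) * 24)
  # one extreme date is excluded and the rest are untouched
  set.seed(61)
  lit$mass_g <- 5 + stats::rnorm(nrow(lit), 0, 0.3)
  base_dates <- tapply(lit$mass_g, lit$date, stats::median)
  lit2 <- lit
  lit2$mass_g[lit2$date == 12] <- 5 + 10 * stats::sd(base_dates) * 20
  out <- litter_annualize(lit2)
  manual <- mean(base_dates[-12]) * 24 / 0.25
  expect_equal(out, manual, tolerance = 0.05)
  # an envelope that excludes everything raises
  expect_error(litter_annualize(lit, reference_values = rep(1000, 50)),
               "excluded as outliers")
})

test_that("infiltration correction is the cross-calibration line", {
  expect_equal(kfs_correct(0), 1.44)
  expect_equal(kfs_correct(10), 6.94)
  expect_equal(kfs_correct(c(2, 4)), c(1.44 + 1.1, 1.44 + 2.2))
})

test_that("soil indicators use molar masses and reciprocals", {
  # equal molar amounts give a C:N of exactly 1
  expect_equal(soil_indicators(12.0107, 14.0067, 0.1, 1)$inv_cn, 1)
  out <- soil_indicators(1.2, 0.14, 0.3, 1.25)
  expect_equal(out$inv_cn, 1 / ((1.2 / 12.0107) / (0.14 / 14.0067)),
               tolerance = 1e-12)
  expect_equal(out$inv_cn, 0.1001, tolerance = 1e-3)
  expect_equal(out$decompaction, 0.8)
  expect_equal(out$soil_p, 0.3)
  expect_error(soil_indicators(1, 0, 1, 1), "nitrogen")
  expect_error(soil_indicators(1, 1, 1, 0), "bulk density")
})

test_that("pollination rate is a guarded fruit-to-flower ratio", {
  expect_equal(pollination_rate(10, 40), 0.25)
  expect_equal(pollination_rate(0, 40), 0)
  expect_true(is.na(pollination_rate(0, 0)))
  expect_warning(pollination_rate(5, 2), "more fruits")
})

test_that("assembled functioning panel is complete and oriented", {
  ds <- tiny_dataset(seed = 19)
  fi <- assemble_indicators(ds)
  expect_equal(ncol(fi) - 1, 20)
  expect_setequal(setdiff(names(fi), "plot_id"),
                  functioning_effects()$indicator)
  expect_false(anyNA(fi))
  # buffering is a negated amplitude: all values negative, and islands
  # (which the generator buffers) sit above the controls on average
  isl <- ds$design$plot_type == "island"
  expect_true(all(fi$microclimate_buffering < 0))
  expect_gt(mean(fi$microclimate_buffering[isl]),
            mean(fi$microclimate_buffering[!isl]))
})
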