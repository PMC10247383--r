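test_that("reference yield is the median of the reference palms", {
  rec <- function(y) data.frame(position = "reference", annual_yield = y)
  expect_equal(reference_yield(rec(c(100, 120, 80))), 100)
  expect_equal(reference_yield(rec(c(100, 120))), 110)
  expect_error(reference_yield(data.frame(position = "inside",
                                          annual_yield = 1)),
               "no reference")
  # many synthetic reference palms concentrate around their mean
  set.seed(41)
  meds <- replicate(50, reference_yield(rec(stats::rnorm(34, 150, 20))))
  expect_lt(abs(mean(meds) - 150), 2)
})

test_that("the worked toy decomposition reproduces by independent arithmetic", {
  plot <- list(plot_id = "I01", n_felled = 2, n_in = 3, n_adj = 4)
  rec <- data.frame(position = c(rep("inside", 3), "adjacent1"),
                    annual_yield = c(90, 90, 90, 110))
  out <- per_island_change(plot, rec, y_ref = 100)
  expect_equal(out$y_foregone, 200)    # 2 * 100
  expect_equal(out$y_remain_change, -30) # 3 * (90 - 100)
  expect_equal(out$y_spillover, 40)    # 4 * (110 - 100)
  expect_equal(out$delta_y_island, -190)
})

test_that("the decomposition identity holds exactly on fuzzed records", {
  set.seed(43)
  for (i in 1:100) {
    plot <- list(plot_id = "x", n_felled = sample(0:10, 1),
                 n_in = sample(1:10, 1), n_adj = sample(1:8, 1))
    rec <- data.frame(
      position = c(rep("inside", plot$n_in),
                   rep("adjacent1", sample(1:3, 1)),
                   rep("adjacent2", sample(0:2, 1))),
      annual_yield = NA)
    rec$annual_yield <- stats::rexp(nrow(rec), 1 / 150)
    y_ref <- stats::rexp(1, 1 / 150)
    out <- per_island_change(plot, rec, y_ref)
    expect_equal(out$delta_y_island,
                 out$y_spillover + out$y_remain_change - out$y_foregone)
    # positions 2-3 never enter: dropping them changes nothing
    out2 <- per_island_change(plot, rec[rec$position != "adjacent2", ], y_ref)
    expect_equal(out, out2)
  }
})

test_that("control-like plots with reference-level palms show no change", {
  plot <- list(plot_id = "C01", n_felled = 0, n_in = 1, n_adj = 4)
  rec <- data.frame(position = "inside", annual_yield = 100)
  out <- per_island_change(plot, rec, y_ref = 100)
  expect_equal(out$delta_y_island, 0)
  # a pure spillover shift of +10 on 2 adjacent palms
  plot2 <- list(plot_id = "I02", n_felled = 0, n_in = 1, n_adj = 2)
  rec2 <- data.frame(position = c("inside", "adjacent1", "adjacent1"),
                     annual_yield = c(100, 110, 110))
  expect_equal(per_island_change(plot2, rec2, 100)$delta_y_island, 20)
})

test_that("translating all yields moves only the foregone term", {
  plot <- list(plot_id = "I03", n_felled = 3, n_in = 2, n_adj = 5)
  rec <- data.frame(position = c("inside", "inside", "adjacent1"),
                    annual_yield = c(120, 140, 160))
  y_ref <- 100
  base <- per_island_change(plot, rec, y_ref)
  cshift <- 25
  rec2 <- rec
  rec2$annual_yield <- rec$annual_yield + cshift
  shifted <- per_island_change(plot, rec2, y_ref + cshift)
  expect_equal(shifted$y_spillover, base$y_spillover)
  expect_equal(shifted$y_remain_change, base$y_remain_change)
  expect_equal(shifted$y_foregone, plot$n_felled * (y_ref + cshift))
})

test_that("data-consistency errors fire", {
  plot <- list(plot_id = "I04", n_felled = 1, n_in = 2, n_adj = 1)
  expect_error(per_island_change(plot,
                                 data.frame(position = "adjacent1",
                                            annual_yield = 100), 100),
               "no inside yield records")
})

test_that("expansion factors and per-area yields follow the density rules", {
  expect_equal(expansion_factor(3, 400), 75)
  expect_equal(expansion_factor(12, 1000), 120)
  expect_equal(expansion_factor(thinned = FALSE), 120)
  # 40% felled from a conventional stand
  expect_equal(expansion_factor(0.6 * 12, 1000), 72)
  expect_error(expansion_factor(3, 0), "positive")
  expect_equal(per_area_yield(150, 120), 18000)
  expect_equal(per_area_yield(0, 120), 0)
})

test_that("yield-change table covers the design and keeps the identity", {
  ds <- tiny_dataset(seed = 13)
  ycl <- yield_change_table(ds$design, ds$yields)
  expect_setequal(ycl$plot_id, ds$design$plot_id)
  expect_equal(ycl$delta_y_island,
               ycl$y_spillover + ycl$y_remain_change - ycl$y_foregone)
  # controls fell no palms
  ctrl <- ycl$plot_id %in% ds$design$plot_id[ds$design$plot_type == "control"]
  expect_true(all(ycl$y_foregone[ctrl] == 0))
})
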