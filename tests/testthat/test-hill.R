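test_that("Hill numbers match their defining formulas", {
  # uniform community: all orders give the species count
  for (q in c(0, 1, 2)) {
    expect_equal(hill_number(c(10, 10, 10, 10), q), 4)
  }
  # skewed community, frozen values from direct evaluation of the formulas
  expect_equal(hill_number(c(8, 1, 1), 0), 3)
  expect_equal(hill_number(c(8, 1, 1), 1), 1.894656, tolerance = 1e-5)
  expect_equal(hill_number(c(8, 1, 1), 2), 1.515152, tolerance = 1e-6)
  # single species
  for (q in c(0, 1, 2)) expect_equal(hill_number(5, q), 1)
  expect_error(hill_number(c(0, 0), 0), "all-zero")
})

test_that("Hill numbers agree with an independent reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(99)
  for (i in 1:20) {
    v <- stats::rpois(sample(3:15, 1), 4) + 1
    expect_equal(hill_number(v, 1), exp(vegan::diversity(v, "shannon")),
                 tolerance = 1e-10)
    expect_equal(hill_number(v, 2), vegan::diversity(v, "invsimpson"),
                 tolerance = 1e-10)
    # analytic richness rarefaction vs vegan's hypergeometric rarefy
    m <- sample(seq_len(sum(v)), 1)
    expect_equal(rarefy_hill(v, m = m, q = 0),
                 suppressWarnings(as.numeric(vegan::rarefy(v, m))),
                 tolerance = 1e-10)
  }
})

test_that("Hill ordering and replication invariance hold for random vectors", {
  set.seed(101)
  for (i in 1:50) {
    v <- stats::rpois(sample(2:20, 1), lambda = stats::runif(1, 0.5, 10))
    if (sum(v) == 0) v[1] <- 1
    h <- vapply(c(0, 1, 2), function(q) hill_number(v, q), numeric(1))
    expect_true(h[1] >= h[2] && h[2] >= h[3] && h[3] >= 1 - 1e-12)
    for (q in c(0, 1, 2)) {
      expect_equal(hill_number(2 * v, q), hill_number(v, q))
    }
  }
})

test_that("analytic richness rarefaction matches the hypergeometric oracle", {
  expect_equal(rarefy_hill(c(2, 2, 2), m = 2, q = 0), 1.8)
  # exhaustive enumeration for small totals
  set.seed(55)
  for (i in 1:20) {
    v <- stats::rpois(sample(2:5, 1), 2)
    if (sum(v) < 2) v <- v + 1
    m <- sample(seq_len(sum(v)), 1)
    expect_equal(rarefy_hill(v, m = m, q = 0), enum_rarefy(v, m, 0),
                 tolerance = 1e-12)
  }
  # full sample returns observed richness
  v <- c(4, 3, 1)
  expect_equal(rarefy_hill(v, m = sum(v), q = 0), hill_number(v, 0))
})

test_that("richness rarefaction is bounded by q0 and non-decreasing in m", {
  set.seed(77)
  for (i in 1:20) {
    v <- stats::rpois(sample(3:8, 1), 3) + 1
    vals <- vapply(seq_len(sum(v)), function(m) rarefy_hill(v, m, q = 0),
                   numeric(1))
    expect_true(all(diff(vals) >= -1e-12))
    expect_lte(max(vals), hill_number(v, 0) + 1e-12)
  }
})

test_that("resampled rarefaction converges to the enumeration oracle", {
  v <- c(8, 1, 1)
  for (q in c(1, 2)) {
    oracle <- enum_rarefy(v, m = 3, q = q)
    est <- rarefy_hill(v, m = 3, q = q, n_resamples = 4000, seed = 9)
    expect_equal(est, oracle, tolerance = 0.02)
  }
  # beyond the sample size: observed value with a warning
  expect_warning(out <- rarefy_hill(v, m = 20, q = 0), "exceeds")
  expect_equal(out, 3)
  expect_error(rarefy_hill(v, m = 0), "m must be")
})

test_that("plot-wise diversity table matches per-plot counting", {
  ds <- tiny_dataset(seed = 4)
  div <- plotwise_diversity(ds$abundances["birds"], rarefy_spec = list())
  q0 <- div[div$q == 0, ]
  manual <- rowSums(ds$abundances$birds > 0)
  expect_equal(q0$value[match(names(manual), q0$plot_id)], unname(manual))
  # uniform counts give identical orders
  tab <- matrix(c(3, 3, 3, 3), nrow = 1,
                dimnames = list("P1", paste0("s", 1:4)))
  d2 <- plotwise_diversity(list(x = tab), rarefy_spec = list())
  expect_equal(unique(d2$value), 4)
  # empty sample propagates as missing, not zero
  tab0 <- matrix(c(0, 2, 0, 1), nrow = 2,
                 dimnames = list(c("P1", "P2"), c("s1", "s2")))
  d3 <- plotwise_diversity(list(x = tab0), rarefy_spec = list())
  expect_true(all(is.na(d3$value[d3$plot_id == "P1"])))
  expect_false(anyNA(d3$value[d3$plot_id == "P2"]))
})
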