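# shared toy construction: island-only covariates from the real design
sem_covariates <- function() {
  d <- build_design(seed = 1)
  isl <- d$plot_type == "island"
  list(zedge = as.numeric(scale(log(d$edge_m[isl]))),
       zdiv = as.numeric(scale(log(d$diversity[isl] + 1))))
}

test_that("Fisher's C follows its closed form and ignores claim order", {
  for (k in c(1, 3, 7)) {
    fc <- fisher_c(rep(0.5, k))
    expect_equal(fc$statistic, -2 * k * log(0.5), tolerance = 1e-12)
    expect_equal(fc$statistic, 1.386294 * k, tolerance = 1e-5)
    expect_equal(fc$df, 2 * k)
  }
  p <- c(0.1, 0.5, 0.9, 0.3)
  expect_equal(fisher_c(p)$statistic, fisher_c(rev(p))$statistic)
  expect_error(fisher_c(c(0.5, 0)), "p_values")
})

test_that("standardized simple-regression slopes equal correlations", {
  set.seed(81)
  for (i in 1:20) {
    x <- stats::rnorm(30)
    y <- stats::rnorm(30, 0.5 * x)
    fit <- stats::lm(y ~ x)
    expect_equal(unname(treeislandr:::.std_coefs(fit)), stats::cor(x, y),
                 tolerance = 1e-12)
  }
})

test_that("a perfectly explained outcome gives unit path and pseudo-R2", {
  cv <- sem_covariates()
  set.seed(82)
  dat <- data.frame(log_area = cv$zedge, log_div = cv$zdiv,
                    complexity = stats::rnorm(52),
                    dominance = stats::rnorm(52))
  dat$outcome <- dat$log_area # outcome IS the covariate
  fit <- suppressWarnings(
    fit_piecewise_sem(dat, add_paths = "none", transform = FALSE))
  b <- fit$paths
  expect_equal(b$beta_std[b$from == "log_area" & b$to == "outcome" &
                            b$type == "direct"], 1, tolerance = 1e-10)
  expect_equal(unname(fit$pseudo_r2["outcome"]), 1, tolerance = 1e-10)
})

test_that("the basis set, df and claims match the assumed causal order", {
  cv <- sem_covariates()
  set.seed(83)
  dat <- data.frame(log_area = cv$zedge, log_div = cv$zdiv,
                    complexity = 0.6 * cv$zdiv + stats::rnorm(52, 0, 0.5),
                    dominance = 0.6 * cv$zedge + stats::rnorm(52, 0, 0.5))
  dat$outcome <- 0.4 * cv$zedge + stats::rnorm(52, 0, 0.6)
  fit <- fit_piecewise_sem(dat, add_paths = "none", transform = FALSE)
  expect_equal(nrow(fit$claims), 5)
  expect_equal(fit$df, 10)
  expect_equal(fit$fisher_c, -2 * sum(log(fit$claims$p)), tolerance = 1e-12)
  # adding both mediator paths removes their two claims
  fit2 <- fit_piecewise_sem(dat, add_paths = c("complexity", "dominance"),
                            transform = FALSE)
  expect_equal(nrow(fit2$claims), 3)
  expect_equal(fit2$df, 6)
  expect_error(fit_piecewise_sem(transform(dat, log_div = 0)),
               "unidentifiable")
})

test_that("mediated generation adds the mediator paths and recovers signs", {
  cv <- sem_covariates()
  set.seed(84)
  comp <- 0.6 * cv$zdiv + stats::rnorm(52, 0, 0.4)
  dom <- 0.6 * cv$zedge + stats::rnorm(52, 0, 0.4)
  dat <- data.frame(log_area = cv$zedge, log_div = cv$zdiv,
                    complexity = comp, dominance = dom,
                    outcome = 0.6 * comp + 0.6 * dom +
                      stats::rnorm(52, 0, 0.4))
  fit <- fit_piecewise_sem(dat, transform = FALSE)
  expect_setequal(fit$added_paths, c("complexity", "dominance"))
  ind <- fit$paths[grepl("indirect", fit$paths$type), ]
  expect_equal(nrow(ind), 2)
  expect_true(all(ind$beta_std > 0))
  # indirect effects are exact products of their constituent paths
  d1 <- fit$paths[fit$paths$type == "direct", ]
  via_c <- d1$beta_std[d1$from == "log_div" & d1$to == "complexity"] *
    d1$beta_std[d1$from == "complexity" & d1$to == "outcome"]
  expect_equal(ind$beta_std[grepl("complexity", ind$type)], via_c,
               tolerance = 1e-12)
})

test_that("total OLS effect decomposes exactly into direct plus mediated", {
  # construct mediator residuals orthogonal to the full treatment set so the
  # omitted-variable identity is exact at machine precision
  cv <- sem_covariates()
  set.seed(85)
  X <- cbind(1, cv$zedge, cv$zdiv)
  resid_on <- function(e) stats::residuals(stats::lm(e ~ X[, -1]))
  comp <- 0.7 * cv$zdiv + resid_on(stats::rnorm(52, 0, 0.5))
  dom <- 0.7 * cv$zedge + resid_on(stats::rnorm(52, 0, 0.5))
  out <- 0.5 * comp + 0.4 * dom # no outcome noise
  dat <- data.frame(log_area = cv$zedge, log_div = cv$zdiv,
                    complexity = comp, dominance = dom, outcome = out)
  fit <- suppressWarnings(
    fit_piecewise_sem(dat, add_paths = c("complexity", "dominance"),
                      transform = FALSE))
  # total effect from the reduced regression
  total <- stats::coef(stats::lm(out ~ cv$zedge + cv$zdiv))
  d1 <- fit$paths[fit$paths$type == "direct", ]
  raw <- function(from, to) {
    m <- fit$models[[c(outcome = "outcome", complexity = "complexity",
                       dominance = "dominance")[to]]]
    stats::coef(m)[[c(log_area = "area", log_div = "div",
                      complexity = "complexity",
                      dominance = "dominance")[from]]]
  }
  expect_equal(unname(total["cv$zdiv"]),
               raw("log_div", "outcome") +
                 raw("log_div", "complexity") * raw("complexity", "outcome"),
               tolerance = 1e-9)
  expect_equal(unname(total["cv$zedge"]),
               raw("log_area", "outcome") +
                 raw("log_area", "dominance") * raw("dominance", "outcome"),
               tolerance = 1e-9)
})

test_that("non-normal residuals trigger the ordered-quantile transform", {
  cv <- sem_covariates()
  set.seed(86)
  dat <- data.frame(log_area = cv$zedge, log_div = cv$zdiv,
                    complexity = stats::rnorm(52),
                    dominance = stats::rnorm(52),
                    outcome = exp(stats::rnorm(52, 0, 1.5))) # lognormal
  fit <- fit_piecewise_sem(dat, add_paths = "none")
  expect_true("outcome" %in% fit$transformed)
  sw <- stats::shapiro.test(stats::residuals(fit$models$outcome))
  expect_gt(sw$p.value, 0.01) # transform actually normalized the residuals
  # ordernorm is monotone and standard-normal shaped
  x <- stats::rexp(100)
  expect_equal(order(ordernorm(x)), order(x))
  expect_equal(mean(ordernorm(x)), 0, tolerance = 1e-10)
})
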