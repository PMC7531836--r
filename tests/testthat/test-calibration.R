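test_that("normalized SSR follows its definition", {
  expect_equal(ssr(list(y = c(1, 2), m = c(2, 2))), 0.5)
  expect_equal(ssr(list(y = c(3, 3), m = c(3, 3))), 0)
  ## duplicating every point leaves the n-normalized score unchanged
  d1 <- list(y = c(1, 2, 4), m = c(1.5, 2, 3))
  d2 <- list(y = rep(d1$y, 2), m = rep(d1$m, 2))
  expect_equal(ssr(d1), ssr(d2))
  expect_error(ssr(list(y = numeric(0), m = numeric(0))), "empty")
  ## multi-dataset objective is the plain sum
  prob <- list(datasets = list(d1, d1))
  expect_equal(ssr_sum(prob), 2 * ssr(d1))
  expect_equal(ssr_sum(list(datasets = list(d1))), ssr(d1))
  expect_error(ssr_sum(list(datasets = list())), "no datasets")
})

test_that("coordinate descent recovers separable optima and never worsens", {
  ## separable quadratic in two log-scale parameters, optimum (3, 0.2)
  make_ds <- function(target, n = 4) list(
    y = rep(0, n),
    predict = function(x) rep(log10(x[[target]]) - log10(truth[[target]]), n))
  truth <- c(a = 3, b = 0.2)
  prob <- calibration_problem(
    datasets = list(make_ds("a"), make_ds("b")),
    start = c(a = 1, b = 1), span = 5)
  fit <- coordinate_descent(prob, tolx = 1e-4)
  expect_true(fit$converged)
  expect_equal(unname(fit$par["a"]), 3, tolerance = 1e-2)
  expect_equal(unname(fit$par["b"]), 0.2, tolerance = 1e-2)
  expect_lt(fit$objective, 1e-6)
  ## each iteration updates exactly one parameter and the objective is
  ## non-increasing
  expect_true(all(diff(c(ssr_sum(prob, prob$start), fit$log$objective)) <= 0))
  ## starting at the optimum terminates immediately with no update
  prob2 <- calibration_problem(datasets = list(make_ds("a"), make_ds("b")),
                               start = c(a = 3, b = 0.2), span = 5)
  fit2 <- coordinate_descent(prob2, tolx = 1e-4)
  expect_true(fit2$converged)
  expect_lte(nrow(fit2$log), 1)
  expect_equal(unname(fit2$par["a"]), 3, tolerance = 1e-2)
})

test_that("the Hill steepness is recoverable from seeded synthetic data", {
  recover <- function(seed) {
    df <- generate_fixture(fixture_spec("hill_curve", sigma = 0.02, n = 15,
                                        seed = seed))
    prob <- calibration_problem(
      datasets = list(list(
        y = df$percent,
        predict = function(x) percent_hemolysis(
          df$mac_per_cell, hemolysis_model(gamma = x[["gamma"]],
                                           mac50 = x[["mac50"]])))),
      start = c(gamma = 1, mac50 = 0.5), span = 2)
    coordinate_descent(prob, tolx = 1e-3, tolfun_rel = 1e-4,
                       max_iter = 100)$par[["gamma"]]
  }
  gam <- vapply(1:10, recover, 0)
  expect_lt(abs(median(gam) - 1.60) / 1.60, 0.05)
})

test_that("local sensitivity reports exact relative changes on a toy", {
  ## f(x) = x^2 at x = 1: +10% input gives +21% output
  tab <- local_sensitivity(function(p) p[["x"]]^2, c(x = 1),
                           deltas = c(0.01, 0.10))
  up10 <- tab$relative_change[tab$parameter == "x" & tab$delta == 0.10]
  expect_equal(up10, 0.21, tolerance = 1e-12)
  dn1 <- tab$relative_change[tab$parameter == "x" & tab$delta == -0.01]
  expect_equal(dn1, -0.0199, tolerance = 1e-12)
  ## a parameter the model never reads produces zero change
  tab2 <- local_sensitivity(function(p) p[["x"]]^2, c(x = 1, unused = 5),
                            deltas = 0.10)
  expect_true(all(tab2$relative_change[tab2$parameter == "unused"] == 0))
})

test_that("rabbit-assay MAC formation is most sensitive to C3, FB, FD and FH", {
  tab <- rabbit_assay_sensitivity(
    species = c("C3", "FB", "FD", "FH", "C5", "C6", "C7", "C8", "C9", "FI"),
    deltas = 0.10, opts = fast_opts)
  agg <- aggregate(abs(tab$relative_change), list(species = tab$parameter),
                   mean)
  sens <- setNames(agg$x, agg$species)
  top <- c("C3", "FB", "FD", "FH")
  rest <- setdiff(names(sens), top)
  expect_gt(min(sens[top]), max(sens[rest]))
})
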