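# Detection power, blind-scheme success, and segregation-parameter fitting.

test_that("detection power follows the binomial complement closed form", {
  rules <- neutral_rules()
  tri <- fig_trisomic_parent(rules)
  tst <- tester_parent(rules)
  expect_equal(trisomy_detection_power(0, tri, tst, no_nd(), rules), 0)
  # uniform model, equal viabilities: diagnostic mass q = 2/12 + 1/12 = 1/4
  expect_equal(trisomy_detection_power(10, tri, tst, no_nd(), rules),
               1 - 0.75^10, tolerance = 1e-12)
  # a disomic parent (d = 0) has no diagnostic class at any n
  dis <- fig_disomic_parent(rules)
  expect_equal(trisomy_detection_power(c(1, 10, 1000), dis, tst, no_nd(),
                                       rules), c(0, 0, 0))
  # monotone non-decreasing in n
  pw <- trisomy_detection_power(0:60, tri, tst, no_nd(), rules)
  expect_true(all(diff(pw) >= 0))
  # with equal viabilities the diagnostic mass equals the disomic-gamete
  # mass x 1/2, which the half-disomic law fixes at 1/4 under any bias
  biased <- segregation_model(c(0.9, 0.05, 0.05), c(0.95, 0.95, 0.5), 0)
  expect_equal(trisomy_detection_power(5, tri, tst, biased, rules),
               1 - 0.75^5, tolerance = 1e-12)
})

test_that("blind-scheme success probability matches the closed form and limits", {
  expect_equal(blind_scheme_success_probability(12, 0.2), 1 - 0.8^12)
  expect_equal(blind_scheme_success_probability(0, 0.5), 0)
  rules <- neutral_rules()
  res <- cross(fig_trisomic_parent(rules), tester_parent(rules),
               no_nd(), rules)
  # uniform model: among Df-bearing candidates, 1/6 / (1/6 + 2/6) = 1/3
  p <- founder_disomic_prob(res, df_label)
  expect_equal(p, 1 / 3, tolerance = 1e-12)
  expect_equal(blind_scheme_success_probability(12, p), 1 - (2 / 3)^12,
               tolerance = 1e-12)
  # strong co-segregation of Df with its partners: monosomic Df gametes
  # vanish and the blind scheme fails -- every line is trisomic
  cosg <- segregation_model(c(0.5, 0.5, 0), c(1, 1, 0.5), 0)
  res0 <- cross(fig_trisomic_parent(rules), tester_parent(rules),
                cosg, rules)
  p0 <- founder_disomic_prob(res0, df_label)
  expect_equal(p0, 0)
  expect_equal(blind_scheme_success_probability(12, p0), 0)
  expect_error(blind_scheme_success_probability(3, 1.5), "founder_disomic")
})

test_that("the MLE recovers known pairing weights from simulated counts", {
  rules <- neutral_rules()
  tri <- abc_trisomic()
  tst <- tester_parent(rules)
  set.seed(61)
  for (i in 1:4) {
    truth <- as.numeric(rmultinom(1, 1000, rep(1, 3))) / 1000
    cnt <- simulate_progeny_counts(tri, tst,
                                   segregation_model(truth, 0.5, 0),
                                   rules, n = 10000, seed = 700 + i)
    fit <- suppressWarnings(
      fit_segregation_params(cnt, tri, tst, no_nd(), rules,
                             seed = 800 + i))
    expect_lt(max(abs(fit$pairing_weights - truth)), 0.05)
    expect_equal(fit$convergence, 0L)
  }
})

test_that("uniform counts give the uniform MLE and agree with the grid oracle", {
  rules <- neutral_rules()
  tri <- abc_trisomic()
  tst <- tester_parent(rules)
  res <- cross(tri, tst, no_nd(), rules)
  keys <- res$classes$class[res$classes$frequency_adjusted > 0]
  cnt <- setNames(rep(100L, length(keys)), keys)
  fit <- fit_segregation_params(cnt, tri, tst, no_nd(), rules, seed = 5)
  expect_equal(fit$pairing_weights, rep(1 / 3, 3), tolerance = 1e-3)
  grid <- fit_segregation_grid(cnt, tri, tst, no_nd(), rules, step = 0.1)
  expect_lte(grid$logLik, fit$logLik + 1e-6)
})

test_that("all-trisomic-partner counts drive the MLE to the simplex boundary", {
  rules <- neutral_rules()
  tri <- fig_trisomic_parent(rules)  # Df / U / U
  tst <- tester_parent(rules)
  # counts generated with no monosomic-Df gametes at all (p3 = 1)
  cnt <- simulate_progeny_counts(tri, tst,
                                 segregation_model(c(0, 0, 1), 0.5, 0),
                                 rules, n = 5000, seed = 77)
  # classes from monosomic-Df gametes (Df without a partner chromosome)
  # never occur in the generated data
  mono_df <- grepl("^Df", names(cnt)) & !grepl("unc-13", names(cnt))
  expect_false(any(mono_df))
  expect_warning(
    fit <- fit_segregation_params(cnt, tri, tst, no_nd(), rules, seed = 9),
    "boundary")
  expect_true(fit$boundary)
  expect_gt(fit$pairing_weights[3], 0.97)
  grid <- fit_segregation_grid(cnt, tri, tst, no_nd(), rules, step = 0.05)
  expect_equal(grid$pairing_weights[3], 1)
})

test_that("log-likelihood at the MLE dominates the generating parameters", {
  rules <- neutral_rules()
  tri <- abc_trisomic()
  tst <- tester_parent(rules)
  pred_ll <- function(pairing, cnt) {
    res <- cross(tri, tst, segregation_model(pairing, 0.5, 0), rules)
    p <- setNames(res$classes$frequency_adjusted, res$classes$class)
    sum(cnt * log(pmax(p[names(cnt)], 1e-12)))
  }
  set.seed(13)
  for (i in 1:3) {
    truth <- as.numeric(rmultinom(1, 1000, rep(1, 3))) / 1000
    cnt <- simulate_progeny_counts(tri, tst,
                                   segregation_model(truth, 0.5, 0),
                                   rules, n = 2000, seed = 500 + i)
    fit <- suppressWarnings(
      fit_segregation_params(cnt, tri, tst, no_nd(), rules, seed = 600 + i))
    expect_gte(fit$logLik, pred_ll(truth, cnt) - 1e-6)
  }
})

test_that("fit -> simulate -> refit is stable", {
  rules <- neutral_rules()
  tri <- abc_trisomic()
  tst <- tester_parent(rules)
  cnt <- simulate_progeny_counts(tri, tst,
                                 segregation_model(c(0.5, 0.2, 0.3), 0.5, 0),
                                 rules, n = 8000, seed = 21)
  fit1 <- suppressWarnings(
    fit_segregation_params(cnt, tri, tst, no_nd(), rules, seed = 22))
  cnt2 <- simulate_progeny_counts(tri, tst, fit1$model, rules,
                                  n = 8000, seed = 23)
  fit2 <- suppressWarnings(
    fit_segregation_params(cnt2, tri, tst, no_nd(), rules, seed = 24))
  expect_lt(max(abs(fit2$pairing_weights - fit1$pairing_weights)), 0.05)
})

test_that("fitting validates its inputs", {
  rules <- neutral_rules()
  tst <- tester_parent(rules)
  dis <- fig_disomic_parent(rules)
  cnt <- c("x" = 5)
  expect_error(fit_segregation_params(cnt, dis, tst, rules = rules),
               "trisomic")
  tri <- abc_trisomic()
  expect_error(fit_segregation_params(c("not a class" = 5), tri, tst,
                                      no_nd(), rules), "observable")
})
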