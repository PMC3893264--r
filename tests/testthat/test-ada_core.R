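test_that("significance scores match hand-computed sums on a worked example", {
  sites <- data.frame(
    p_mid = c(0.05, 0.15, 0.5),
    weight = c(2, 1, 1),
    direction = c("deleterious_inclined", "protective_inclined",
                  "deleterious_inclined"))
  s <- significance_scores(sites, thresholds = c(0.10, 0.20))
  # theta = 0.10 admits only site 1: S_D = 2 * (-ln 0.05); theta = 0.20 adds
  # site 2 to the protective score; site 3 (p = 0.5) never contributes
  expect_equal(s$S_D, c(2 * 2.99573227355399, 2 * 2.99573227355399),
               tolerance = 1e-12)
  expect_equal(s$S_P, c(0, 1.89711998488588), tolerance = 1e-12)
})

test_that("single-site example and degenerate grids behave as stated", {
  sites <- data.frame(p_mid = c(0.05, 0.5), weight = c(1, 1),
                      direction = "deleterious_inclined")
  s <- significance_scores(sites, thresholds = 0.10)
  expect_equal(s$S_D, -log(0.05))
  expect_equal(s$S_P, 0)
  # no P-value below any threshold -> zero vectors
  s0 <- significance_scores(data.frame(p_mid = 0.4, weight = 3,
                                       direction = "deleterious_inclined"),
                            thresholds = c(0.1, 0.2))
  expect_equal(s0$S_D, c(0, 0))
  # tied sites contribute to neither score
  st <- significance_scores(data.frame(p_mid = 0.01, weight = 1,
                                       direction = "tied"),
                            thresholds = 0.2)
  expect_equal(st$S_D + st$S_P, 0)
})

test_that("scores are linear in the weights and monotone in the threshold", {
  set.seed(11)
  for (r in 1:20) {
    K <- sample(3:12, 1)
    sites <- data.frame(
      p_mid = runif(K),
      weight = rexp(K) + 0.1,
      direction = sample(c("deleterious_inclined", "protective_inclined",
                           "tied"), K, replace = TRUE))
    thr <- sort(runif(5, 0.01, 0.9))
    s <- significance_scores(sites, thr)
    expect_true(all(diff(s$S_D) >= 0))
    expect_true(all(diff(s$S_P) >= 0))
    sites2 <- sites; sites2$weight <- 2 * sites$weight
    s2 <- significance_scores(sites2, thr)
    expect_equal(s2$S_D, 2 * s$S_D)
    expect_equal(s2$S_P, 2 * s$S_P)
  }
})

test_that("ada_statistic combines the direction scores elementwise", {
  expect_equal(ada_statistic(c(3, 4), c(1, 5)), c(3, 5))
  expect_equal(ada_statistic(c(3, 4), c(1, 5), mode = "sum"), c(4, 9))
  expect_equal(ada_statistic(c(3, 4), c(0, 0)), c(3, 4))
  expect_equal(ada_statistic(c(3, 4), c(0, 0), mode = "sum"), c(3, 4))
  expect_error(ada_statistic(1:3, 1:2), "equal length")
})

test_that("threshold grids are validated", {
  d <- case_control_data(matrix(c(0L, 1L), 2, 1), c(1, 0))
  expect_error(ada_test(d, thresholds = c(0.2, 0.1), B = 10), "increasing")
  expect_error(ada_test(d, thresholds = c(0, 0.1), B = 10), "in \\(0, 1\\)")
})

test_that("adjusted P matches complete enumeration on an 8-subject fixture", {
  set.seed(99)
  G <- matrix(rbinom(8 * 3, 2, 0.25), 8, 3)
  pheno <- rep(c(1, 0), each = 4)
  d <- case_control_data(G, pheno, polarise = FALSE)
  # offset from round fractions: an attainable mid-P exactly on a cutoff
  # would make the strict p < theta rule depend on the last float bit
  thr <- c(0.3123, 0.5123, 0.7123)
  fit <- ada_test(d, thresholds = thr, B = 1, max_maf = NULL,
                  exhaustive = TRUE)
  expect_equal(fit$B, choose(8, 4))
  ora <- oracle_ada_exhaustive(G, pheno, thr)
  expect_equal(fit$adjusted_p, ora)

  # a second fixture with unbalanced strata
  G2 <- matrix(rbinom(7 * 4, 2, 0.3), 7, 4)
  ph2 <- c(1, 1, 1, 0, 0, 0, 0)
  d2 <- case_control_data(G2, ph2, polarise = FALSE)
  fit2 <- ada_test(d2, thresholds = thr, B = 1, max_maf = NULL,
                   exhaustive = TRUE)
  expect_equal(fit2$adjusted_p, oracle_ada_exhaustive(G2, ph2, thr))
})

test_that("complete separation attains the minimum adjusted P-value", {
  # one causal site carried by every case and no control
  G <- matrix(0L, 20, 2)
  G[1:10, 1] <- 1L
  G[c(2, 15), 2] <- 1L
  d <- case_control_data(G, rep(c(1, 0), each = 10))
  fit <- ada_test(d, B = 500, seed = 3, max_maf = NULL)
  expect_equal(fit$adjusted_p, 1 / 501)
})

test_that("results are bit-identical across runs with the same seed", {
  set.seed(5)
  G <- matrix(rbinom(60 * 10, 2, 0.04), 60, 10)
  d <- case_control_data(G, rep(c(1, 0), each = 30))
  f1 <- ada_test(d, B = 300, seed = 17)
  f2 <- ada_test(d, B = 300, seed = 17)
  expect_identical(unclass(f1), unclass(f2))
  # and the caller's RNG stream is untouched
  set.seed(1); before <- runif(1)
  set.seed(1)
  suppressWarnings(invisible(ada_test(d, B = 50, seed = 2)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("observed scores are non-decreasing in the threshold index", {
  set.seed(21)
  for (r in 1:5) {
    G <- matrix(rbinom(80 * 15, 2, 0.05), 80, 15)
    d <- case_control_data(G, rep(c(1, 0), each = 40))
    fit <- suppressWarnings(ada_test(d, B = 50, seed = r))
    expect_true(all(diff(fit$S_D) >= 0))
    expect_true(all(diff(fit$S_P) >= 0))
    expect_true(all(diff(fit$statistic) >= 0))
    expect_gte(fit$adjusted_p, 1 / 51)
    expect_lte(fit$adjusted_p, 1)
    expect_equal(fit$statistic, pmax(fit$S_D, fit$S_P))
  }
})

test_that("sum mode reduces to S_D + S_P", {
  set.seed(31)
  G <- matrix(rbinom(40 * 6, 2, 0.08), 40, 6)
  d <- case_control_data(G, rep(c(1, 0), each = 20))
  fit <- ada_test(d, B = 100, seed = 4, statistic_mode = "sum")
  expect_equal(fit$statistic, fit$S_D + fit$S_P)
})

test_that("an empty region yields adjusted P = 1 with a warning", {
  G <- matrix(1L, 12, 1)
  G[1:4, 1] <- 0L   # pooled MAF 2/3 -> polarised to 1/3, above any rare cut
  d <- case_control_data(G, rep(c(1, 0), 6))
  expect_warning(fit <- ada_test(d, B = 100, max_maf = 0.05), "MAF filter")
  expect_equal(fit$adjusted_p, 1)
  expect_equal(fit$statistic, rep(0, 11))
})

test_that("small B triggers a resolution warning", {
  G <- matrix(c(0L, 1L, 0L, 0L), 2, 2)
  d <- case_control_data(G, c(1, 0))
  expect_warning(ada_test(d, B = 20, max_maf = NULL), "resolution")
})

test_that("print and summary report the adjusted P-value and grid", {
  set.seed(8)
  G <- matrix(rbinom(40 * 5, 2, 0.06), 40, 5)
  d <- case_control_data(G, rep(c(1, 0), each = 20))
  fit <- ada_test(d, B = 100, seed = 9)
  expect_output(print(fit), "adjusted P-value")
  s <- summary(fit)
  expect_equal(nrow(s$table), 11)
  expect_output(print(s), "Per-threshold")
})
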