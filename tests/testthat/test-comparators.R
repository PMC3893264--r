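# 6-subject fixture for hand-checked scores: 3 cases then 3 controls.
ws_fixture <- function() {
  G <- matrix(c(1L, 1L, 0L, 1L, 0L, 0L,    # v1: controls carry 1 allele
                2L, 0L, 0L, 0L, 0L, 0L),   # v2: cases only
              nrow = 6)
  case_control_data(G, c(1, 1, 1, 0, 0, 0), polarise = FALSE)
}

test_that("sigma-MidP statistic is the weighted Fisher sum over unequal-count sites", {
  set.seed(12)
  G <- matrix(rbinom(80 * 8, 2, 0.05), 80, 8)
  d <- case_control_data(G, rep(c(1, 0), each = 40))
  res <- sigma_midp_test(d, B = 200, seed = 5, max_maf = NULL)
  sc <- site_scan(d)
  keep <- sc$case_count != sc$control_count
  expect_equal(res$statistic,
               sum(sc$weight[keep] * (-2 * log(sc$p_mid[keep]))),
               tolerance = 1e-12)
  expect_gte(res$p_value, 1 / 201)
})

test_that("a single informative site gives the -2 log p closed form", {
  # one site, every case carries it, no control does; weight w and p from
  # the per-site scan reproduce the statistic w * (-2 ln p)
  G <- matrix(0L, 10, 1); G[1:2, 1] <- 1L
  d <- case_control_data(G, rep(c(1, 0), each = 5))
  sc <- site_scan(d)
  res <- sigma_midp_test(d, B = 100, seed = 1, max_maf = NULL)
  expect_equal(res$statistic, sc$weight * (-2 * log(sc$p_mid)))
})

test_that("all-tied regions yield statistic 0 and P = 1", {
  G <- matrix(rep(c(1L, 0L, 1L, 0L), 3), 4, 3)  # identical case/control counts
  d <- case_control_data(G, c(1, 1, 0, 0))
  expect_warning(res <- sigma_midp_test(d, B = 50, seed = 1, max_maf = NULL),
                 "equal case/control")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("fixed-threshold tests detect complete separation and respect the cut", {
  G <- matrix(0L, 40, 2)
  G[1:20, 1] <- 1L                      # MAF 0.25 site, cases only
  G[c(1, 3, 22), 2] <- 1L               # rare site, mixed
  d <- case_control_data(G, rep(c(1, 0), each = 20))
  # with maf_cut above 0.25 the separating site is collapsed: minimal P
  res <- fixed_threshold_test(d, maf_cut = 0.3, B = 400, seed = 2,
                              max_maf = NULL)
  expect_equal(res$p_value, 1 / 401)
  expect_gt(res$statistic, 0)
  # with maf_cut = 1% only the rare site qualifies
  res1 <- fixed_threshold_test(d, maf_cut = 0.05, B = 100, seed = 2,
                               max_maf = NULL)
  expect_equal(res1$method, "t5")
  sc <- colSums(G[1:20, 2, drop = FALSE]) / 20 -
        colSums(G[21:40, 2, drop = FALSE]) / 20
  expect_equal(res1$statistic, unname(sc))
})

test_that("identical case and control score distributions give statistic 0", {
  G <- matrix(rep(c(1L, 1L, 0L, 0L), 2), 4, 2)
  d <- case_control_data(G, c(1, 0, 1, 0))
  res <- fixed_threshold_test(d, maf_cut = 0.5, B = 50, seed = 1,
                              max_maf = NULL)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("no qualifying variant yields P = 1 with a warning", {
  G <- matrix(0L, 20, 1); G[1:10, 1] <- 1L  # MAF 0.25
  d <- case_control_data(G, rep(c(1, 0), each = 10))
  expect_warning(res <- fixed_threshold_test(d, maf_cut = 0.01, B = 50,
                                             seed = 1, max_maf = NULL),
                 "no variant below")
  expect_equal(res$p_value, 1)
})

test_that("weighted-sum rank statistic matches a hand computation", {
  d <- ws_fixture()
  # controls carry m = (1, 0) minor alleles; q = (m+1)/(2*3+2)
  w <- 1 / sqrt(3 * (c(1, 0) + 1) / 8 * (1 - (c(1, 0) + 1) / 8))
  x <- as.vector(d$genotypes %*% w)
  r <- rank(x)                      # average ranks, as in the test
  expect_equal(weighted_sum_test(d, B = 50, seed = 1,
                                 max_maf = NULL)$statistic,
               sum(r[1:3]))
})

test_that("all-zero dosages put the rank sum at its null expectation", {
  G <- matrix(0L, 8, 2)
  d <- case_control_data(G, rep(c(1, 0), each = 4))
  res <- weighted_sum_test(d, B = 50, seed = 1, max_maf = NULL)
  expect_equal(res$statistic, 4 * 9 / 2)   # n_case * (n + 1) / 2
  expect_equal(res$p_value, 1)
})

test_that("VT with a single variant matches the fixed-threshold test", {
  set.seed(44)
  G <- matrix(rbinom(60, 2, 0.08), 60, 1)
  d <- case_control_data(G, rep(c(1, 0), each = 30))
  # same seed -> same permutation stream; |z| is a monotone rescaling of the
  # |mean-score difference|, so the permutation P-values coincide
  pv_vt <- variable_threshold_test(d, B = 300, seed = 6, max_maf = NULL)$p_value
  pv_t <- fixed_threshold_test(d, maf_cut = 0.5, B = 300, seed = 6,
                               max_maf = NULL)$p_value
  expect_equal(pv_vt, pv_t)
})

test_that("VT picks a threshold under 0.5% when the signal is that rare", {
  # 500/500: a MAF 0.2% site perfectly case-specific, a balanced 4% site
  G <- matrix(0L, 1000, 2)
  G[1:4, 1] <- 1L                       # 4/2000 = 0.2%, cases only
  G[c(1:40, 501:540), 2] <- 1L          # 80/2000 = 4%, balanced
  d <- case_control_data(G, rep(c(1, 0), each = 500))
  res <- variable_threshold_test(d, B = 100, seed = 3, max_maf = NULL)
  expect_lte(res$chosen_maf, 0.005)
})

test_that("rv_compare reports every requested method on shared permutations", {
  set.seed(70)
  G <- matrix(rbinom(100 * 12, 2, 0.04), 100, 12)
  d <- case_control_data(G, rep(c(1, 0), each = 50))
  cmp <- rv_compare(d, B = 200, seed = 8)
  expect_setequal(cmp$method, c("ada", "sigma_midp", "t1", "t5", "ws", "vt"))
  expect_true(all(cmp$p_value >= 1 / 201 & cmp$p_value <= 1))
  # individual tests with the same seed reproduce the shared-engine values
  expect_equal(cmp$p_value[cmp$method == "sigma_midp"],
               sigma_midp_test(d, B = 200, seed = 8)$p_value)
  expect_equal(cmp$p_value[cmp$method == "ada"],
               ada_test(d, B = 200, seed = 8)$adjusted_p)
})

test_that("the comparators are valid under the permutation null", {
  # small smoke calibration; the full-scale check lives in the acceptance suite
  pool <- generate_pool(K_neutral = 60, d = 3, r_isk = 100, seed = 202,
                        n_hap = 4000)
  model <- disease_model(pool, par = 0)
  methods <- c("ada", "sigma_midp", "t1", "t5", "ws", "vt")
  pv <- matrix(NA_real_, 150, length(methods),
               dimnames = list(NULL, methods))
  for (r in seq_len(nrow(pv))) {
    dat <- sample_case_control(pool, model, n_cases = 100, n_controls = 100,
                               seed = 300 + r)
    pv[r, ] <- adarv:::analyse_replicate(dat, B = 199, methods = methods,
                                         ada_grids = list(d = seq(0.1, 0.2, 0.01)))
  }
  for (m in methods) {
    rate <- mean(pv[, m] <= 0.05)
    expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(pv)))
  }
})
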