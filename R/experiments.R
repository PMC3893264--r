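#' Region preset: neutral-variant count for a given number of causal sites
#'
#' The simulation presets tie region size to the causal count `d`: regions
#' carrying 3, 5, 10, 15, 20 causal variants span roughly 3.6 to 25.6 kb and
#' contain about 60, 100, 200, 300, 400 neutral variants respectively.
#'
#' @param d causal-site count.
#' @return neutral-site count (20x interpolation for non-preset `d`).
#' @export
region_preset <- function(d) {
  presets <- c(`3` = 60, `5` = 100, `10` = 200, `15` = 300, `20` = 400)
  out <- unname(presets[as.character(d)])
  ifelse(is.na(out), 20L * as.integer(d), as.integer(out))
}

# One simulated replicate analysed by all requested methods on shared
# permutations.  `ada_grids` is a named list of threshold grids; the engine
# runs once on their sorted union and each grid is scored as a subset, so
# grid comparisons are exactly paired.  Returns a named vector of P-values.
analyse_replicate <- function(data, B, methods, ada_grids, max_maf = 0.05,
                              statistic_mode = "max") {
  ada_names <- if (length(ada_grids) == 1L) "ada"
               else paste0("ada_", names(ada_grids))
  all_names <- c(if ("ada" %in% methods) ada_names,
                 setdiff(methods, "ada"))
  data <- tryCatch(maf_filter(data, max_maf),
                   adarv_empty_region = function(e) NULL)
  if (is.null(data))
    return(structure(rep(1, length(all_names)), names = all_names))

  union_thr <- sort(unique(round(unlist(ada_grids), 10)))
  prep <- engine_prep(data, need_vt = "vt" %in% methods)
  pm <- engine_perms(prep, B)
  out <- engine_run(prep, pm, union_thr, methods = methods)

  pv <- numeric(0)
  if ("ada" %in% methods) {
    Sfull <- matrix(0, length(union_thr), B + 1L)
    for (j in seq_along(union_thr))
      Sfull[j, ] <- ada_statistic(out$SD[j, ], out$SP[j, ], statistic_mode)
    pv <- vapply(ada_grids, function(g) {
      idx <- match(round(g, 10), union_thr)
      ada_pvalues(Sfull[idx, , drop = FALSE])$adjusted_p
    }, numeric(1))
    names(pv) <- ada_names
  }
  for (mth in setdiff(methods, "ada")) {
    pv[[mth]] <- switch(mth,
      sigma_midp = perm_pvalue(out$sigma),
      t1 = perm_pvalue(abs(out$t1)),
      t5 = perm_pvalue(abs(out$t5)),
      ws = perm_pvalue(abs(out$ws - prep$n_case * (prep$n + 1) / 2)),
      vt = perm_pvalue(out$vt))
  }
  pv[all_names]
}

# Simulate n_pools x n_replicates data sets under one scenario and return
# the replicate x method P-value matrix.  Pool and replicate seeds are
# derived deterministically from `seed` alone (never from the scenario), so
# runs across scenarios with the same seed are paired.
run_scenario <- function(r_isk, par, d, n_pools, n_replicates, B, methods,
                         ada_grids, n_cases, n_controls, f0, max_maf, seed,
                         pool_args = list()) {
  K_neutral <- region_preset(d)
  pvals <- NULL
  for (i in seq_len(n_pools)) {
    pool <- do.call(generate_pool,
                    c(list(K_neutral = K_neutral, d = d, r_isk = r_isk,
                           seed = seed + i * 100000L), pool_args))
    model <- disease_model(pool, par = par, f0 = f0)
    for (r in seq_len(n_replicates)) {
      pv <- with_seed(seed + i * 100000L + r, {
        dat <- sample_case_control(pool, model, n_cases, n_controls)
        analyse_replicate(dat, B, methods, ada_grids, max_maf)
      })
      if (is.null(pvals))
        pvals <- matrix(NA_real_, n_pools * n_replicates, length(pv),
                        dimnames = list(NULL, names(pv)))
      pvals[(i - 1L) * n_replicates + r, ] <- pv
    }
  }
  pvals
}

rejection_table <- function(pvals, alpha, extra = NULL) {
  rows <- expand.grid(method = colnames(pvals), alpha = alpha,
                      stringsAsFactors = FALSE)
  n <- nrow(pvals)
  rows$rejections <- mapply(function(m, a) sum(pvals[, m] <= a),
                            rows$method, rows$alpha)
  rows$n <- n
  rows$rate <- rows$rejections / n
  rows$se <- sqrt(rows$rate * (1 - rows$rate) / n)
  if (!is.null(extra)) rows <- cbind(extra, rows, row.names = NULL)
  rows
}

#' Empirical type-I error of the permutation tests
#'
#' Simulates null case-control data (PAR = 0: disease independent of
#' genotype) from `n_pools` haplotype pools with `n_replicates` samples
#' each, runs the requested tests, and tabulates rejection rates at the
#' nominal levels.  All methods share each replicate's permutations, so the
#' table rows are paired.
#'
#' @param n_pools number of independently generated haplotype pools.
#' @param n_replicates case-control samples per pool.
#' @param B permutations per test.
#' @param d causal-count region preset (sets the neutral-site count via
#'   [region_preset()]; with PAR = 0 the causal sites are inert).
#' @param r_isk nominal deleterious percentage for the pool layout
#'   (irrelevant under the null; kept for symmetry with [run_power()]).
#' @param alpha nominal significance levels.
#' @param methods tests to run (see [rv_compare()]).
#' @param thresholds ADA truncation grid.
#' @param n_cases,n_controls sample sizes.
#' @param f0 baseline penetrance.
#' @param max_maf pooled-sample MAF filter.
#' @param seed integer seed; the run is deterministic given it.
#' @return data frame with columns `method`, `alpha`, `rejections`, `n`,
#'   `rate`, `se`; the replicate-level P-values are attached as
#'   `attr(, "pvalues")`.
#' @examples
#' \donttest{
#' run_type1(n_pools = 2, n_replicates = 10, B = 99, seed = 1)
#' }
#' @export
run_type1 <- function(n_pools = 20, n_replicates = 100, B = 1000, d = 20,
                      r_isk = 80, alpha = c(0.01, 0.05), methods = "ada",
                      thresholds = seq(0.10, 0.20, by = 0.01),
                      n_cases = 500, n_controls = 500, f0 = 0.01,
                      max_maf = 0.05, seed = 1) {
  pvals <- run_scenario(r_isk = r_isk, par = 0, d = d, n_pools = n_pools,
                        n_replicates = n_replicates, B = B, methods = methods,
                        ada_grids = list(default = thresholds),
                        n_cases = n_cases, n_controls = n_controls, f0 = f0,
                        max_maf = max_maf, seed = seed)
  out <- rejection_table(pvals, alpha)
  attr(out, "pvalues") <- pvals
  out
}

#' Empirical power of the permutation tests over a scenario grid
#'
#' For each scenario (a combination of deleterious percentage `r_isk`,
#' per-variant PAR and causal count `d`) simulates `n_pools x n_replicates`
#' case-control samples and tabulates rejection rates.  Pool and replicate
#' seeds depend only on `seed`, never on the scenario, so power values are
#' paired across scenarios (and, within a replicate, across methods and ADA
#' threshold grids).
#'
#' @inheritParams run_type1
#' @param scenarios data frame with columns `r_isk`, `par`, `d`.
#' @param ada_grids named list of ADA truncation-threshold grids; each grid
#'   is scored from one engine run on their union, so grid comparisons are
#'   exact pairings.  Multiple grids are reported as methods `ada_<name>`.
#' @return data frame with the scenario columns plus `method`, `alpha`,
#'   `rejections`, `n`, `rate`, `se`; per-scenario P-value matrices are
#'   attached as `attr(, "pvalues")`.
#' @export
run_power <- function(scenarios = data.frame(r_isk = 80, par = 0.003, d = 20),
                      n_pools = 20, n_replicates = 25, B = 1000,
                      alpha = c(0.01, 0.05), methods = "ada",
                      ada_grids = list(default = seq(0.10, 0.20, by = 0.01)),
                      n_cases = 500, n_controls = 500, f0 = 0.01,
                      max_maf = 0.05, seed = 1) {
  stopifnot(all(c("r_isk", "par", "d") %in% names(scenarios)))
  out <- NULL
  pv_list <- list()
  for (s in seq_len(nrow(scenarios))) {
    sc <- scenarios[s, ]
    pvals <- run_scenario(r_isk = sc$r_isk, par = sc$par, d = sc$d,
                          n_pools = n_pools, n_replicates = n_replicates,
                          B = B, methods = methods, ada_grids = ada_grids,
                          n_cases = n_cases, n_controls = n_controls,
                          f0 = f0, max_maf = max_maf, seed = seed)
    out <- rbind(out, rejection_table(pvals, alpha, extra = sc))
    pv_list[[s]] <- pvals
  }
  attr(out, "pvalues") <- pv_list
  out
}
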