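# Burden-test comparators, all under the same phenotype-permutation engine
# as ada_test() so that power comparisons on shared data are paired.

burden_result <- function(statistic, p_value, method, B, extra = NULL) {
  structure(c(list(statistic = statistic, p_value = p_value, method = method,
                   B = B), extra), class = "rv_burden")
}

#' @export
print.rv_burden <- function(x, ...) {
  label <- c(sigma_midp = "sigma-MidP weighted Fisher combination",
             t1 = "fixed-threshold burden test (MAF < 1%)",
             t5 = "fixed-threshold burden test (MAF < 5%)",
             ws = "weighted-sum rank test (Madsen-Browning)",
             vt = "variable-threshold burden test")[x$method]
  cat("\n\t", label, "\n\n", sep = "")
  cat(sprintf("statistic = %.4g, permutation P = %.4g (B = %d)\n\n",
              x$statistic, x$p_value, x$B))
  invisible(x)
}

# Shared front half of every comparator: MAF filter (empty region -> P = 1
# with warning), seeding, engine prep and permutation draw.
comparator_run <- function(data, B, seed, method, max_maf,
                           recompute_weights = TRUE, ...) {
  stopifnot(inherits(data, "case_control_data"))
  if (length(B) != 1L || is.na(B) || B < 1) stop("B must be a positive integer")
  if (!is.null(max_maf)) {
    data <- tryCatch(maf_filter(data, max_maf),
                     adarv_empty_region = function(e) NULL)
    if (is.null(data)) {
      warning("no variant passes the MAF filter; P = 1")
      return(NULL)
    }
  }
  with_seed(seed, {
    prep <- engine_prep(data, need_vt = method == "vt")
    pm <- engine_perms(prep, B)
    list(prep = prep,
         out = engine_run(prep, pm, methods = method,
                          recompute_weights = recompute_weights, ...))
  })
}

#' sigma-MidP test: weighted Fisher combination of per-site mid-P values
#'
#' The statistic is `sum_i w_i * (-2 log p_i)` over the sites with *unequal*
#' case and control minor-allele counts (equal-count sites are excluded as
#' carrying no directional information), with mid-P Fisher exact per-site
#' P-values and Madsen-Browning weights recomputed inside each phenotype
#' permutation.  Large statistics are extreme, so the permutation P-value is
#' one-sided on the combined statistic (the per-site mid-P values are already
#' two-sided).
#'
#' @inheritParams ada_test
#' @return an object of class `rv_burden`.
#' @export
sigma_midp_test <- function(data, B = 1000, seed = NULL, max_maf = 0.05) {
  run <- comparator_run(data, B, seed, "sigma_midp", max_maf)
  if (is.null(run)) return(burden_result(0, 1, "sigma_midp", B))
  stat <- run$out$sigma
  if (stat[1L] == 0)
    warning("every site has equal case/control counts (or no evidence); ",
            "statistic 0, P = 1")
  burden_result(stat[1L], perm_pvalue(stat), "sigma_midp", B)
}

#' Fixed-threshold burden test (T1 / T5)
#'
#' Each subject's genetic score is the total minor-allele count over variants
#' whose pooled-sample MAF is strictly below `maf_cut`; the statistic is the
#' case-minus-control difference in mean score, tested two-tailed against
#' the phenotype-permutation distribution of its absolute value.
#'
#' @inheritParams ada_test
#' @param maf_cut collapsing threshold: 0.01 gives the classical T1 test,
#'   0.05 gives T5.
#' @return an object of class `rv_burden` (`method` `"t1"` or `"t5"`).
#' @export
fixed_threshold_test <- function(data, maf_cut = 0.01, B = 1000, seed = NULL,
                                 max_maf = 0.05) {
  if (!(maf_cut > 0 && maf_cut <= 0.5)) stop("maf_cut must be in (0, 0.5]")
  method <- if (isTRUE(all.equal(maf_cut, 0.05))) "t5" else "t1"
  run <- if (method == "t1")
    comparator_run(data, B, seed, method, max_maf, t1_cut = maf_cut)
  else comparator_run(data, B, seed, method, max_maf, t5_cut = maf_cut)
  if (is.null(run)) return(burden_result(0, 1, method, B))
  stat <- run$out[[method]]
  if (!any(run$prep$maf < maf_cut)) {
    warning("no variant below maf_cut; P = 1")
    return(burden_result(0, 1, method, B))
  }
  burden_result(stat[1L], perm_pvalue(abs(stat)), method, B,
                extra = list(maf_cut = maf_cut))
}

#' Weighted-sum (Madsen-Browning) rank test
#'
#' Per-subject scores `sum_i dosage_i * w_i` use the control-estimated
#' inverse binomial-SD weights, recomputed inside each permutation; the
#' statistic is the sum of the case subjects' score ranks (ties averaged).
#' The two-tailed comparison is on the absolute deviation of the rank sum
#' from its null expectation `n_case * (n + 1) / 2`.
#'
#' @inheritParams ada_test
#' @return an object of class `rv_burden`.
#' @export
weighted_sum_test <- function(data, B = 1000, seed = NULL, max_maf = 0.05) {
  run <- comparator_run(data, B, seed, "ws", max_maf)
  if (is.null(run)) return(burden_result(0, 1, "ws", B))
  stat <- run$out$ws
  centre <- run$prep$n_case * (run$prep$n + 1) / 2
  burden_result(stat[1L], perm_pvalue(abs(stat - centre)), "ws", B,
                extra = list(expected = centre))
}

#' Variable-threshold burden test
#'
#' For every candidate MAF threshold `t` in the sorted set of observed
#' pooled-sample MAFs, the per-subject score counts minor alleles at
#' variants with MAF <= t (equivalently "< t'" for t' just above each
#' observed MAF, so the candidate set spans every distinct collapsing rule
#' the data admit).  Each threshold yields a two-sample z-score of the
#' case/control mean-score difference, standardised by the pooled
#' per-subject score variance; the statistic is the maximum |z| over
#' thresholds, compared against its own permutation distribution, so the
#' threshold search costs no validity.
#'
#' @inheritParams ada_test
#' @return an object of class `rv_burden`, with `chosen_maf`, the threshold
#'   attaining the maximum |z| in the observed data.
#' @export
variable_threshold_test <- function(data, B = 1000, seed = NULL,
                                    max_maf = 0.05) {
  run <- comparator_run(data, B, seed, "vt", max_maf)
  if (is.null(run)) return(burden_result(0, 1, "vt", B))
  stat <- run$out$vt
  chosen <- vt_chosen_threshold(run$prep)
  burden_result(stat[1L], perm_pvalue(stat), "vt", B,
                extra = list(chosen_maf = chosen))
}

# Observed argmax threshold of the VT scan (recomputed in R for reporting).
vt_chosen_threshold <- function(prep) {
  a <- colSums_cases(prep)
  o <- prep$vt$ord + 1L
  cumA <- cumsum(a[o])
  bnd <- prep$vt$bnd == 1L
  zs <- abs((cumA[bnd] / prep$n_case -
             (prep$vt$cumtot - cumA[bnd]) / prep$n_ctrl) /
            sqrt(prep$vt$var * (1 / prep$n_case + 1 / prep$n_ctrl)))
  zs[prep$vt$var <= 0] <- 0
  mafs <- prep$maf[o][bnd]
  mafs[which.max(zs)]
}

#' Run ADA and the burden comparators on shared permutations
#'
#' All requested methods are evaluated on one set of phenotype permutations
#' drawn from a single stream, so the resulting P-values (and hence power
#' estimates across simulated replicates) are paired.
#'
#' @inheritParams ada_test
#' @param methods subset of `c("ada", "sigma_midp", "t1", "t5", "ws", "vt")`.
#' @param thresholds ADA truncation-threshold grid.
#' @return data frame with one row per method: `method`, `statistic`
#'   (observed; for ADA the maximal per-threshold score), `p_value`.
#' @export
rv_compare <- function(data, methods = c("ada", "sigma_midp", "t1", "t5",
                                         "ws", "vt"),
                       thresholds = seq(0.10, 0.20, by = 0.01),
                       B = 1000, seed = NULL, max_maf = 0.05,
                       statistic_mode = c("max", "sum")) {
  methods <- match.arg(methods, several.ok = TRUE)
  statistic_mode <- match.arg(statistic_mode)
  stopifnot(inherits(data, "case_control_data"))
  if (!is.null(max_maf)) {
    data <- tryCatch(maf_filter(data, max_maf),
                     adarv_empty_region = function(e) NULL)
    if (is.null(data)) {
      warning("no variant passes the MAF filter; P = 1 for every method")
      return(data.frame(method = methods, statistic = 0, p_value = 1))
    }
  }
  with_seed(seed, {
    prep <- engine_prep(data, need_vt = "vt" %in% methods)
    pm <- engine_perms(prep, B)
    out <- engine_run(prep, pm, thresholds, methods = methods)
    pv <- vapply(methods, function(mth) {
      switch(mth,
        ada = {
          S <- matrix(0, length(thresholds), B + 1L)
          for (j in seq_along(thresholds))
            S[j, ] <- ada_statistic(out$SD[j, ], out$SP[j, ], statistic_mode)
          c(max(S[, 1L]), ada_pvalues(S)$adjusted_p)
        },
        sigma_midp = c(out$sigma[1L], perm_pvalue(out$sigma)),
        t1 = c(out$t1[1L], perm_pvalue(abs(out$t1))),
        t5 = c(out$t5[1L], perm_pvalue(abs(out$t5))),
        ws = {
          centre <- prep$n_case * (prep$n + 1) / 2
          c(out$ws[1L], perm_pvalue(abs(out$ws - centre)))
        },
        vt = c(out$vt[1L], perm_pvalue(out$vt)))
    }, numeric(2))
    data.frame(method = methods, statistic = pv[1L, ], p_value = pv[2L, ],
               row.names = NULL)
  })
}
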