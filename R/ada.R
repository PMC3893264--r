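#' Direction-stratified truncated significance scores
#'
#' For each candidate truncation threshold `theta_j` the deleterious score
#' accumulates, over deleterious-inclined sites whose mid-P value falls
#' strictly below `theta_j`, the weighted negative log P-value
#' `w_i * (-log p_i)`; the protective score does the same over
#' protective-inclined sites.  Tied sites (equal case and control
#' minor-allele frequencies) contribute to neither.
#'
#' @param sites a data frame as returned by [site_scan()] (columns `p_mid`,
#'   `direction`, `weight`).
#' @param thresholds strictly increasing truncation thresholds in (0, 1).
#' @return list with numeric vectors `S_D` and `S_P`, one entry per threshold.
#' @examples
#' s <- data.frame(p_mid = c(0.05, 0.5), weight = c(1, 1),
#'                 direction = "deleterious_inclined")
#' significance_scores(s, thresholds = 0.10)  # S_D = -log(0.05)
#' @export
significance_scores <- function(sites, thresholds = seq(0.10, 0.20, by = 0.01)) {
  check_thresholds(thresholds)
  stopifnot(is.data.frame(sites), nrow(sites) >= 1L)
  contrib <- sites$weight * (-log(sites$p_mid))
  del <- sites$direction == "deleterious_inclined"
  pro <- sites$direction == "protective_inclined"
  S_D <- vapply(thresholds, function(th)
    sum(contrib[del & sites$p_mid < th]), numeric(1))
  S_P <- vapply(thresholds, function(th)
    sum(contrib[pro & sites$p_mid < th]), numeric(1))
  list(S_D = S_D, S_P = S_P)
}

#' Combine the deleterious and protective score vectors
#'
#' The default (`"max"`) takes the elementwise maximum of the two
#' direction-stratified scores, so the test reacts to whichever direction
#' carries more evidence; `"sum"` adds them, which helps only when
#' deleterious and protective variants are comparably numerous.
#'
#' @param S_D,S_P equal-length numeric vectors.
#' @param mode `"max"` (default) or `"sum"`.
#' @return numeric vector of per-threshold statistics.
#' @export
ada_statistic <- function(S_D, S_P, mode = c("max", "sum")) {
  mode <- match.arg(mode)
  if (length(S_D) != length(S_P)) stop("S_D and S_P must have equal length")
  if (mode == "max") pmax(S_D, S_P) else S_D + S_P
}

check_thresholds <- function(thresholds) {
  if (length(thresholds) < 1L || anyNA(thresholds) ||
      any(thresholds <= 0) || any(thresholds >= 1) ||
      any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing values in (0, 1)")
  invisible(thresholds)
}

#' The ADA rare-variant association test
#'
#' Adaptive combination of per-site P-values.  Each variant contributes
#' two-sided mid-P Fisher exact evidence on its case/control allele-count
#' table, weighted by the Madsen-Browning control-frequency weight.
#' Contributions are truncated at each of `J` candidate thresholds and
#' accumulated separately over deleterious- and protective-inclined sites;
#' the per-threshold statistic is the larger of the two direction scores
#' (or their sum, see `statistic_mode`).  Because the truncation threshold
#' is chosen adaptively -- the test takes the smallest per-threshold
#' permutation P-value across the grid -- a second permutation layer converts
#' that minimum into an *adjusted* P-value that is valid despite the search:
#' each permuted sample is allowed its own optimal threshold.
#'
#' Phenotype labels are permuted with case/control counts fixed; per-site
#' mid-P values, directions and weights are recomputed on each permuted
#' sample (set `recompute_weights = FALSE` to freeze the observed weights,
#' for comparison).  The per-threshold P-value of the observed sample uses
#' the add-one estimator `(1 + #{S_b >= S}) / (B + 1)`; permuted samples are
#' ranked against the other permutations only.
#'
#' @param data a [case_control_data] object.
#' @param thresholds candidate truncation thresholds; default the 11-point
#'   grid 0.10, 0.11, ..., 0.20.  Thresholds below 0.10 risk truncating away
#'   true rare-variant signals (single-site tests are underpowered), larger
#'   ones admit more neutral noise.
#' @param B number of phenotype permutations (>= 1); the adjusted P-value
#'   resolution is `1/(B+1)`.
#' @param seed optional integer; makes the permutation stream (and therefore
#'   the whole result) reproducible without disturbing the caller's RNG.
#' @param statistic_mode see [ada_statistic()].
#' @param max_maf pooled-sample MAF filter applied before testing
#'   (default 0.05); `NULL` to skip.
#' @param recompute_weights recompute Madsen-Browning weights (and
#'   directions, mid-P values) inside each permutation; the default `TRUE`
#'   replicates the full observed-data pipeline under the null.
#' @param exhaustive replace random permutations by complete enumeration of
#'   all case/control assignments (feasible only for very small samples);
#'   `B` is then ignored.
#' @return object of class `ada_test`: per-threshold scores `S_D`, `S_P`,
#'   `statistic`, `per_threshold_p`, the minimum P-value `min_p`, the
#'   `adjusted_p` in `[1/(B+1), 1]`, the threshold attaining the minimum,
#'   and the per-site scan of the observed data.
#' @references Madsen BE, Browning SR (2009) PLoS Genet 5:e1000384.
#' @examples
#' pool <- generate_pool(K_neutral = 60, d = 3, r_isk = 100, seed = 1)
#' model <- disease_model(pool, par = 0.005)
#' dat <- sample_case_control(pool, model, n_cases = 100, n_controls = 100,
#'                            seed = 2)
#' ada_test(dat, B = 200, seed = 3)
#' @export
ada_test <- function(data, thresholds = seq(0.10, 0.20, by = 0.01),
                     B = 1000, seed = NULL,
                     statistic_mode = c("max", "sum"),
                     max_maf = 0.05, recompute_weights = TRUE,
                     exhaustive = FALSE) {
  statistic_mode <- match.arg(statistic_mode)
  check_thresholds(thresholds)
  stopifnot(inherits(data, "case_control_data"))
  if (!exhaustive && (length(B) != 1L || is.na(B) || B < 1))
    stop("B must be a positive integer")

  if (!is.null(max_maf)) {
    data <- tryCatch(maf_filter(data, max_maf),
                     adarv_empty_region = function(e) NULL)
    if (is.null(data)) {
      warning("no variant passes the MAF filter; the region carries no ",
              "testable signal (adjusted P = 1)")
      return(empty_ada_result(thresholds, B, statistic_mode))
    }
  }
  if (!exhaustive && B < 100)
    warning("B = ", B, " permutations gives adjusted-P resolution ",
            signif(1 / (B + 1), 3), "; increase B for reporting")

  J <- length(thresholds)
  with_seed(seed, {
    prep <- engine_prep(data)
    pm <- if (exhaustive) engine_perms_exhaustive(prep)
          else engine_perms(prep, B)
    out <- engine_run(prep, pm, thresholds, methods = "ada",
                      recompute_weights = recompute_weights)
    Bi <- ncol(pm) - 1L
    S <- matrix(0, J, Bi + 1L)
    for (j in seq_len(J))
      S[j, ] <- ada_statistic(out$SD[j, ], out$SP[j, ], statistic_mode)
    pv <- ada_pvalues(S)
    structure(list(S_D = out$SD[, 1L], S_P = out$SP[, 1L],
                   statistic = S[, 1L],
                   thresholds = thresholds,
                   per_threshold_p = pv$per_threshold_p,
                   min_p = pv$min_p, adjusted_p = pv$adjusted_p,
                   chosen_threshold = thresholds[which.min(pv$per_threshold_p)],
                   B = Bi, statistic_mode = statistic_mode,
                   exhaustive = exhaustive,
                   n_case = prep$n_case, n_ctrl = prep$n_ctrl, K = prep$K,
                   recompute_weights = recompute_weights,
                   seed = seed, sites = site_scan(data)),
              class = "ada_test")
  })
}

empty_ada_result <- function(thresholds, B, statistic_mode) {
  J <- length(thresholds)
  structure(list(S_D = numeric(J), S_P = numeric(J), statistic = numeric(J),
                 thresholds = thresholds, per_threshold_p = rep(1, J),
                 min_p = 1, adjusted_p = 1, chosen_threshold = thresholds[1L],
                 B = B, statistic_mode = statistic_mode, exhaustive = FALSE,
                 n_case = NA_integer_, n_ctrl = NA_integer_, K = 0L,
                 recompute_weights = TRUE, seed = NULL, sites = NULL),
            class = "ada_test")
}

#' @export
print.ada_test <- function(x, ...) {
  cat("\n\tADA adaptive combination of P-values\n\n")
  cat(sprintf("%d variants, %s cases / %s controls\n", x$K,
              format(x$n_case), format(x$n_ctrl)))
  cat(sprintf("thresholds: %s (J = %d), statistic: %s of S_D and S_P\n",
              paste(range(x$thresholds), collapse = " - "),
              length(x$thresholds), x$statistic_mode))
  cat(sprintf("%s permutations%s\n", format(x$B),
              if (x$exhaustive) " (exhaustive enumeration)" else ""))
  cat(sprintf("min per-threshold P = %.4g at theta = %.2f\n",
              x$min_p, x$chosen_threshold))
  cat(sprintf("adjusted P-value = %.4g\n\n", x$adjusted_p))
  invisible(x)
}

#' @export
summary.ada_test <- function(object, ...) {
  tab <- data.frame(threshold = object$thresholds,
                    S_D = object$S_D, S_P = object$S_P,
                    statistic = object$statistic,
                    p = object$per_threshold_p)
  structure(list(table = tab, adjusted_p = object$adjusted_p,
                 chosen_threshold = object$chosen_threshold,
                 B = object$B), class = "summary.ada_test")
}

#' @export
print.summary.ada_test <- function(x, ...) {
  cat("Per-threshold ADA scores and permutation P-values:\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("\nadjusted P-value = %.4g (B = %d, optimal theta = %.2f)\n",
              x$adjusted_p, x$B, x$chosen_threshold))
  invisible(x)
}

#' Per-threshold profile plot of an ADA test
#'
#' Shows the deleterious and protective significance scores across the
#' candidate truncation thresholds (left axis) and the per-threshold
#' permutation P-values (right axis), marking the adaptively chosen
#' threshold.
#'
#' @param x an `ada_test` object.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.ada_test <- function(x, ...) {
  op <- graphics::par(mar = c(5, 4, 3, 4))
  on.exit(graphics::par(op))
  graphics::matplot(x$thresholds, cbind(x$S_D, x$S_P), type = "b",
                    pch = c(19, 1), lty = c(1, 2), col = c("firebrick", "navy"),
                    xlab = "truncation threshold", ylab = "significance score",
                    main = "ADA per-threshold profile", ...)
  graphics::par(new = TRUE)
  graphics::plot(x$thresholds, x$per_threshold_p, type = "l", col = "grey40",
                 axes = FALSE, xlab = "", ylab = "",
                 ylim = c(0, max(x$per_threshold_p) * 1.05))
  graphics::axis(4)
  graphics::mtext("per-threshold P", side = 4, line = 2.5)
  graphics::abline(v = x$chosen_threshold, lty = 3)
  graphics::legend("topleft", bty = "n",
                   legend = c("S_D (deleterious)", "S_P (protective)",
                              "per-threshold P"),
                   col = c("firebrick", "navy", "grey40"),
                   pch = c(19, 1, NA), lty = c(1, 2, 1))
  invisible(x)
}
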