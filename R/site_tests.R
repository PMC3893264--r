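#' Two-sided mid-P Fisher exact test for a 2x2 allele-count table
#'
#' The table compares minor/major allele counts between case and control
#' chromosomes:
#' \preformatted{
#'            minor  major
#'   cases      a      b
#'   controls   c      d
#' }
#' Conditioning on both margins, the case minor-allele count follows a
#' hypergeometric distribution.  The two-sided mid-P value sums the
#' probabilities of all tables strictly less probable than the observed one
#' plus half the probability of tables exactly as probable (the observed
#' table included).  Mid-P is less conservative than the classical exact
#' P-value and is the per-site evidence the ADA and sigma-MidP statistics
#' combine.
#'
#' Probability-equality comparisons use a relative tolerance of 1e-12 so that
#' equiprobable tables are not misclassified by floating-point noise.  When
#' only one table is attainable (e.g. a monomorphic site, a = c = 0) the site
#' carries no evidence and the value 1 is returned.
#'
#' @param a,b,c,d non-negative integer cell counts (minor/major alleles in
#'   cases and controls).
#' @return mid-P value in (0, 1].
#' @examples
#' midp_fisher(8, 992, 1, 999)
#' midp_fisher(0, 1000, 0, 1000)  # monomorphic: 1
#' @export
midp_fisher <- function(a, b, c, d) {
  stopifnot(length(a) == 1, length(b) == 1, length(c) == 1, length(d) == 1)
  if (anyNA(c(a, b, c, d)) || any(c(a, b, c, d) < 0) ||
      any(c(a, b, c, d) != floor(c(a, b, c, d))))
    stop("cell counts must be non-negative integers")
  nA <- a + b; nU <- c + d
  if (nA <= 0 || nU <= 0) stop("both margins (case and control chromosomes) must be positive")
  m <- a + c
  tab <- midp_table(m, nA, nU)
  tab[a + 1L]
}

# Mid-P lookup for all case minor-allele counts a = 0..m at fixed margins:
# nA case chromosomes, nU control chromosomes, m pooled minor alleles.
# Entries outside the hypergeometric support are NA (unreachable).
midp_table <- function(m, nA, nU) {
  lo <- max(0L, m - nU); hi <- min(m, nA)
  out <- rep(NA_real_, m + 1L)
  k <- lo:hi
  if (length(k) == 1L) {            # single attainable table: no evidence
    out[k + 1L] <- 1
    return(out)
  }
  pr <- dhyper(k, m, nA + nU - m, nA)
  tol <- 1e-12
  lt <- outer(pr, pr, function(pk, pa) pk < pa * (1 - tol))
  eq <- outer(pr, pr, function(pk, pa) abs(pk - pa) <= tol * pa)
  mid <- as.vector(crossprod(pr, lt)) + 0.5 * as.vector(crossprod(pr, eq))
  out[k + 1L] <- pmin(mid, 1)
  out
}

#' Direction of a variant site's association
#'
#' A site is *deleterious-inclined* when its minor-allele frequency is larger
#' in cases than in controls, *protective-inclined* when larger in controls,
#' and *tied* when the two frequencies are equal.  Tied sites contribute to
#' neither of the direction-stratified significance scores.
#'
#' @inheritParams midp_fisher
#' @return one of `"deleterious_inclined"`, `"protective_inclined"`, `"tied"`.
#' @export
site_direction <- function(a, b, c, d) {
  fd <- a * (c + d)          # a/(a+b) vs c/(c+d), cross-multiplied
  fp <- c * (a + b)
  if (fd > fp) "deleterious_inclined"
  else if (fd < fp) "protective_inclined"
  else "tied"
}

#' Madsen-Browning variant weight from control allele counts
#'
#' `q = (m + 1) / (2n + 2)` is the add-one smoothed minor-allele frequency
#' among the `n` unaffected individuals carrying `m` minor alleles; the
#' weight is the reciprocal binomial standard deviation
#' `1 / sqrt(n * q * (1 - q))`.  Rarer-in-controls variants receive larger
#' weights; the smoothing keeps `q` strictly inside (0, 1) so the weight is
#' always finite and positive.
#'
#' @param m minor-allele count in controls, `0 <= m <= 2n`.
#' @param n number of control individuals (>= 1).
#' @return positive weight(s); vectorised over `m`.
#' @export
mb_weight <- function(m, n) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be a positive integer")
  if (anyNA(m) || any(m < 0) || any(m > 2 * n))
    stop("m must lie in [0, 2n]")
  q <- (m + 1) / (2 * n + 2)
  1 / sqrt(n * q * (1 - q))
}

#' Per-variant association scan
#'
#' Applies [midp_fisher()], [site_direction()] and [mb_weight()] to every
#' variant of a case-control data set, on chromosome-level (allele count)
#' 2x2 tables.
#'
#' @param data a [case_control_data] object (normally after [maf_filter()]).
#' @return a data frame of class `adarv_sites` with one row per variant, in
#'   input order: `variant_id`, `case_count`, `control_count`, `p_mid`,
#'   `direction`, `weight`.
#' @examples
#' d <- case_control_data(matrix(c(1, 0, 0, 0, 1, 1, 0, 0), nrow = 4),
#'                        c(1, 1, 0, 0))
#' site_scan(d)
#' @export
site_scan <- function(data) {
  stopifnot(inherits(data, "case_control_data"))
  G <- data$genotypes
  case <- data$phenotype == 1L
  n_case <- sum(case); n_ctrl <- sum(!case)
  a <- colSums(G[case, , drop = FALSE])
  c_ <- colSums(G[!case, , drop = FALSE])
  m <- a + c_

  # mid-P via shared lookup tables (sites with equal pooled counts share one)
  p_mid <- numeric(length(m))
  for (mm in unique(m)) {
    tab <- midp_table(mm, 2L * n_case, 2L * n_ctrl)
    idx <- which(m == mm)
    p_mid[idx] <- tab[a[idx] + 1L]
  }
  fd <- a * n_ctrl; fp <- c_ * n_case
  direction <- ifelse(fd > fp, "deleterious_inclined",
                      ifelse(fd < fp, "protective_inclined", "tied"))
  res <- data.frame(variant_id = data$variant_ids,
                    case_count = as.integer(a),
                    control_count = as.integer(c_),
                    p_mid = p_mid,
                    direction = direction,
                    weight = mb_weight(c_, n_ctrl),
                    row.names = NULL)
  class(res) <- c("adarv_sites", "data.frame")
  res
}

#' Export per-site results as TSV
#'
#' @param sites result of [site_scan()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_site_results <- function(sites, path) {
  write.table(as.data.frame(sites), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
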