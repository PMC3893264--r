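# Independent oracles used to validate the package's computations.
# These deliberately share no code with the package internals: probabilities
# come from log-binomial-coefficient arithmetic, scores and permutation
# P-values from plain loops.

# Two-sided mid-P by exhaustive enumeration of the hypergeometric support,
# probabilities via lchoose.
oracle_midp <- function(a, b, c, d) {
  nA <- a + b; nU <- c + d; m <- a + c
  lo <- max(0, m - nU); hi <- min(m, nA)
  ks <- lo:hi
  if (length(ks) == 1) return(1)
  logp <- lchoose(nA, ks) + lchoose(nU, m - ks) - lchoose(nA + nU, m)
  pr <- exp(logp)
  pr <- pr / sum(pr)                      # renormalise enumeration error
  p0 <- pr[ks == a]
  tol <- 1e-12
  smaller <- pr < p0 * (1 - tol)
  equal <- abs(pr - p0) <= tol * p0
  min(sum(pr[smaller]) + 0.5 * sum(pr[equal]), 1)
}

# Per-site statistics by direct loops (no shared lookup tables).
oracle_sites <- function(G, pheno) {
  ncase <- sum(pheno == 1); nctrl <- sum(pheno == 0)
  t(sapply(seq_len(ncol(G)), function(i) {
    a <- sum(G[pheno == 1, i]); cc <- sum(G[pheno == 0, i])
    p <- oracle_midp(a, 2 * ncase - a, cc, 2 * nctrl - cc)
    dir <- sign(a / ncase - cc / nctrl)
    q <- (cc + 1) / (2 * nctrl + 2)
    w <- 1 / sqrt(nctrl * q * (1 - q))
    c(p = p, dir = dir, w = w)
  }))
}

# Direction-stratified truncated scores, max statistic, by loops.
oracle_S <- function(G, pheno, thresholds) {
  st <- oracle_sites(G, pheno)
  sapply(thresholds, function(th) {
    sd_ <- 0; sp_ <- 0
    for (i in seq_len(nrow(st))) {
      if (st[i, "p"] < th && st[i, "dir"] != 0) {
        contrib <- st[i, "w"] * (-log(st[i, "p"]))
        if (st[i, "dir"] > 0) sd_ <- sd_ + contrib else sp_ <- sp_ + contrib
      }
    }
    max(sd_, sp_)
  })
}

# Adjusted P-value by complete enumeration of case/control assignments,
# mirroring the two-layer estimator conventions:
#   observed p_j = (1 + #{b: S_bj >= S_j}) / (B + 1)
#   permuted p_bj = #{b': S_b'j >= S_bj} / B
#   adjusted = (1 + #{b: min_j p_bj <= min_j p_j}) / (B + 1)
oracle_ada_exhaustive <- function(G, pheno, thresholds) {
  n <- nrow(G); ncase <- sum(pheno == 1)
  combs <- utils::combn(n, ncase)
  B <- ncol(combs)
  J <- length(thresholds)
  S_obs <- oracle_S(G, pheno, thresholds)
  S_perm <- matrix(0, B, J)
  for (b in seq_len(B)) {
    ph <- integer(n); ph[combs[, b]] <- 1L
    S_perm[b, ] <- oracle_S(G, ph, thresholds)
  }
  p_obs <- sapply(seq_len(J), function(j)
    (1 + sum(S_perm[, j] >= S_obs[j])) / (B + 1))
  p_perm <- matrix(0, B, J)
  for (b in seq_len(B))
    for (j in seq_len(J))
      p_perm[b, j] <- sum(S_perm[, j] >= S_perm[b, j]) / B
  minp_obs <- min(p_obs)
  minp_b <- apply(p_perm, 1, min)
  (1 + sum(minp_b <= minp_obs)) / (B + 1)
}

# Small deterministic toy data set builder.
toy_data <- function(G, pheno, ...) {
  case_control_data(G, pheno, ...)
}
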