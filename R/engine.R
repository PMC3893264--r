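# Internal glue between case_control_data and the C++ permutation engine.
#
# engine_prep() derives everything that is invariant under phenotype
# permutation: the subject-major sparse genotype layout, the pooled per-site
# minor-allele totals, shared mid-P lookup tables (sites with equal pooled
# counts share one table because both margins are fixed), the weight lookup
# indexed by control minor-allele count, and the variable-threshold scan
# order/variances.

engine_prep <- function(data, need_vt = FALSE) {
  G <- data$genotypes
  n <- nrow(G); K <- ncol(G)
  n_case <- sum(data$phenotype == 1L)
  n_ctrl <- n - n_case
  mtot <- as.integer(colSums(G))

  nz <- which(G != 0L)
  rows <- (nz - 1L) %% n + 1L
  ord <- order(rows)
  sub_site <- ((nz - 1L) %/% n)[ord]            # 0-based site index
  sub_dose <- as.integer(G[nz])[ord]
  ptr <- c(0L, cumsum(tabulate(rows, n)))

  um <- sort(unique(mtot))
  tabs <- lapply(um, midp_table, nA = 2L * n_case, nU = 2L * n_ctrl)
  starts <- cumsum(c(0L, um + 1L))
  midp_off <- starts[match(mtot, um)]
  midp_flat <- unlist(tabs, use.names = FALSE)
  midp_flat[is.na(midp_flat)] <- 1              # unreachable entries

  wtab <- mb_weight(0:max(mtot), n_ctrl)
  maf <- mtot / (2 * n)

  vt <- list(ord = integer(), bnd = integer(), var = numeric(),
             cumtot = numeric())
  if (need_vt) {
    o <- order(maf)
    mo <- maf[o]
    bnd <- c(mo[-1] != mo[-K], TRUE)
    nb <- sum(bnd)
    vvar <- numeric(nb); vcum <- numeric(nb)
    s <- numeric(n); bi <- 0L; ct <- 0
    for (q in seq_len(K)) {
      i <- o[q]
      s <- s + G[, i]
      ct <- ct + mtot[i]
      if (bnd[q]) {
        bi <- bi + 1L
        vvar[bi] <- var(s)
        vcum[bi] <- ct
      }
    }
    vt <- list(ord = o - 1L, bnd = as.integer(bnd), var = vvar, cumtot = vcum)
  }

  list(ptr = ptr, site = sub_site, dose = sub_dose, n = n, K = K,
       n_case = n_case, n_ctrl = n_ctrl, mtot = mtot,
       midp_off = as.integer(midp_off), midp_flat = midp_flat,
       wtab = wtab, maf = maf, vt = vt,
       case_idx0 = which(data$phenotype == 1L) - 1L)
}

# Random phenotype permutations: one column of 0-based case-subject indices
# per permutation, drawn from the current RNG stream.  Column 1 is observed.
engine_perms <- function(prep, B) {
  pm <- matrix(0L, prep$n_case, B + 1L)
  pm[, 1L] <- prep$case_idx0
  for (b in seq_len(B))
    pm[, b + 1L] <- sample.int(prep$n, prep$n_case) - 1L
  pm
}

# All distinct case/control assignments (exhaustive permutation null).
engine_perms_exhaustive <- function(prep, limit = 2e5) {
  nc <- choose(prep$n, prep$n_case)
  if (nc > limit)
    stop("exhaustive enumeration of ", nc, " assignments refused (limit ",
         limit, ")")
  cm <- utils::combn(prep$n, prep$n_case) - 1L
  cbind(prep$case_idx0, cm)
}

engine_run <- function(prep, perm_case, thresholds = numeric(),
                       methods = "ada", recompute_weights = TRUE,
                       wfixed = NULL, t1_cut = 0.01, t5_cut = 0.05) {
  do <- c(ada = "ada" %in% methods, sigma = "sigma_midp" %in% methods,
          t1 = "t1" %in% methods, t5 = "t5" %in% methods,
          ws = "ws" %in% methods, vt = "vt" %in% methods)
  if (is.null(wfixed))
    wfixed <- mb_weight(prep$mtot - colSums_cases(prep), prep$n_ctrl)
  rv_engine_cpp(prep$ptr, prep$site, prep$dose,
                prep$K, prep$n_case, prep$n_ctrl,
                perm_case, prep$mtot, prep$midp_off, prep$midp_flat,
                prep$wtab, wfixed, recompute_weights,
                as.numeric(thresholds),
                do[["ada"]], do[["sigma"]], do[["t1"]], do[["t5"]],
                do[["ws"]], do[["vt"]],
                prep$maf < t1_cut, prep$maf < t5_cut,
                prep$vt$ord, prep$vt$bnd, prep$vt$var, prep$vt$cumtot)
}

# Observed control minor-allele counts (for fixed-weight mode).
colSums_cases <- function(prep) {
  a <- integer(prep$K)
  for (s in prep$case_idx0 + 1L) {
    e <- (prep$ptr[s] + 1L):prep$ptr[s + 1L]
    if (prep$ptr[s + 1L] > prep$ptr[s])
      a[prep$site[e] + 1L] <- a[prep$site[e] + 1L] + prep$dose[e]
  }
  a
}

# Two-layer permutation P-values from a J x (B+1) score matrix whose first
# column is the observed sample.
#   p_j (observed)  = (1 + #{b: S_jb >= S_j}) / (B + 1)
#   p_jb (permuted) = #{b': S_jb' >= S_jb} / B        (leave-observed-out)
#   adjusted        = (1 + #{b: min_j p_jb <= min_j p_j}) / (B + 1)
ada_pvalues <- function(S) {
  J <- nrow(S); B <- ncol(S) - 1L
  obs <- S[, 1L]
  perm <- S[, -1L, drop = FALSE]
  p_obs <- (1 + rowSums(perm >= obs)) / (B + 1)
  pp <- matrix(0, J, B)
  for (j in seq_len(J)) {
    r <- rank(perm[j, ], ties.method = "min")
    pp[j, ] <- (B - r + 1) / B
  }
  minp_obs <- min(p_obs)
  minp_b <- do.call(pmin, lapply(seq_len(J), function(j) pp[j, ]))
  adjusted <- (1 + sum(minp_b <= minp_obs)) / (B + 1)
  list(per_threshold_p = p_obs, min_p = minp_obs, adjusted_p = adjusted)
}

# Add-one two-tailed permutation P for a scalar statistic vector (col 1
# observed); `magnitude` has already been applied by the caller.
perm_pvalue <- function(stat) {
  B <- length(stat) - 1L
  (1 + sum(stat[-1L] >= stat[1L])) / (B + 1)
}
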