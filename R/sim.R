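#' Generate a synthetic haplotype pool
#'
#' Emulates the coalescent-simulated chromosome pools used in rare-variant
#' power studies: a 2N x K binary haplotype matrix (default 10,000
#' chromosomes) whose site frequencies follow a rare-skewed spectrum and
#' whose sites are locally correlated.
#'
#' Population MAFs are drawn with density proportional to `1/x` on
#' `maf_range` (log-uniform), so most sites are rare -- the shape neutral
#' site-frequency spectra take.  Linkage is induced by a block-wise Gaussian
#' copula: sites are partitioned into blocks of mean size `block_mean`, and
#' within a block each haplotype's allele indicators share a latent factor
#' with correlation `block_cor`.  Marginally every column is an independent
#' Bernoulli(`maf`) sample across haplotypes, so realised column frequencies
#' are exactly binomial around the target MAF while neighbouring sites are
#' dependent, which is what permutation-based tests are sensitive to.
#'
#' `d` causal sites are drawn among sites with population MAF below
#' `causal_maf_max` (1%, the rare-variant convention);
#' `ceiling(d * r_isk / 100)` of them are marked deleterious and the rest
#' protective.  If a draw of the frequency spectrum yields fewer than `d`
#' sufficiently rare sites it is redrawn (up to 10 attempts, with a warning).
#'
#' @param K_neutral number of neutral (non-causal) sites.
#' @param d number of causal sites.
#' @param r_isk percentage (0-100) of causal sites that are deleterious.
#' @param seed optional integer seed.
#' @param n_hap number of chromosomes in the pool (default 10,000).
#' @param maf_range support of the log-uniform population MAF spectrum.
#' @param causal_maf_max causal sites are drawn below this population MAF.
#' @param block_mean mean LD-block size in sites.
#' @param block_cor latent within-block correlation in [0, 1).
#' @return an object of class `haplotype_pool`: `haplotypes` (2N x K 0/1
#'   integer matrix), `maf` (population MAFs), `causal_idx`, `is_protective`
#'   (logical over the causal sites), `variant_ids`.
#' @examples
#' pool <- generate_pool(K_neutral = 60, d = 3, r_isk = 100, seed = 1,
#'                       n_hap = 2000)
#' pool
#' @export
generate_pool <- function(K_neutral, d, r_isk, seed = NULL, n_hap = 10000,
                          maf_range = c(5e-5, 0.05), causal_maf_max = 0.01,
                          block_mean = 10, block_cor = 0.5) {
  stopifnot(d >= 1, r_isk >= 0, r_isk <= 100, K_neutral >= 0,
            block_cor >= 0, block_cor < 1)
  K <- K_neutral + d
  with_seed(seed, {
    maf <- NULL
    for (attempt in seq_len(10L)) {
      cand <- rlogunif(K, maf_range[1], maf_range[2])
      if (sum(cand < causal_maf_max) >= d) { maf <- cand; break }
      warning("fewer than d sites below causal_maf_max; redrawing spectrum")
    }
    if (is.null(maf))
      stop("could not draw ", d, " sites with MAF < ", causal_maf_max,
           " in 10 attempts; enlarge K_neutral or maf_range")

    H <- matrix(0L, n_hap, K)
    start <- 1L
    r <- sqrt(block_cor)
    while (start <= K) {
      len <- min(1L + stats::rpois(1L, max(block_mean - 1, 0)), K - start + 1L)
      cols <- start:(start + len - 1L)
      z0 <- rnorm(n_hap)                      # shared latent factor
      for (i in cols) {
        u <- pnorm(r * z0 + sqrt(1 - block_cor) * rnorm(n_hap))
        H[, i] <- as.integer(u < maf[i])
      }
      start <- start + len
    }

    causal_idx <- sort(sample(which(maf < causal_maf_max), d))
    n_del <- ceiling(d * r_isk / 100)
    is_protective <- rep(TRUE, d)
    if (n_del > 0)
      is_protective[sample.int(d, n_del)] <- FALSE
    structure(list(haplotypes = H, maf = maf, causal_idx = causal_idx,
                   is_protective = is_protective,
                   variant_ids = paste0("V", seq_len(K))),
              class = "haplotype_pool")
  })
}

rlogunif <- function(n, lo, hi) lo * (hi / lo)^runif(n)

#' @export
print.haplotype_pool <- function(x, ...) {
  cat("haplotype_pool:", nrow(x$haplotypes), "chromosomes,",
      ncol(x$haplotypes), "sites;", length(x$causal_idx), "causal (",
      sum(!x$is_protective), "deleterious /", sum(x$is_protective),
      "protective )\n")
  invisible(x)
}

#' Genotype relative risk implied by a per-variant PAR
#'
#' Under the population-attributable-risk parameterisation, a deleterious
#' causal variant with population MAF `maf` and attributable risk `par` has
#' per-allele genotype relative risk
#' `GRR = 1 + par / ((1 - par) * maf)`; a protective variant takes the
#' reciprocal, so the effect direction is flipped while deleterious and
#' protective variants of equal MAF and PAR have reciprocal risks.  `par = 0`
#' gives `GRR = 1` (the null).
#'
#' Note the asymmetry this construction creates on the odds-ratio scale:
#' for equal MAF and PAR the deleterious carrier odds ratio exceeds the
#' reciprocal of the protective one, so deleterious variants are the easier
#' to detect.
#'
#' @param par population attributable risk of the variant, in [0, 1).
#' @param maf population minor-allele frequency, in (0, 0.5).
#' @param protective flip the effect direction.
#' @return genotype relative risk (vectorised over `par`/`maf`/`protective`).
#' @examples
#' par_to_grr(0.003, 0.005)         # ~1.60
#' par_to_grr(0.003, 0.005, TRUE)   # reciprocal
#' @export
par_to_grr <- function(par, maf, protective = FALSE) {
  if (anyNA(par) || any(par < 0) || any(par >= 1))
    stop("par must lie in [0, 1)")
  if (anyNA(maf) || any(maf <= 0) || any(maf >= 0.5))
    stop("maf must lie in (0, 0.5)")
  grr <- 1 + par / ((1 - par) * maf)
  ifelse(protective, 1 / grr, grr)
}

#' Disease model for a haplotype pool
#'
#' Converts a per-variant PAR into per-causal-site genotype relative risks
#' for the pool's causal sites (deleterious sites get `GRR > 1`, protective
#' sites the reciprocal `GRR < 1`), with a multiplicative penetrance on the
#' baseline `f0`.
#'
#' @param pool a [haplotype_pool].
#' @param par per-variant population attributable risk (scalar, or one value
#'   per causal site).
#' @param f0 baseline penetrance: disease probability for a subject carrying
#'   no causal minor alleles (default 1%).
#' @return object of class `disease_model`: `par`, `f0`, `grr`, `causal_idx`,
#'   `is_protective`.
#' @export
disease_model <- function(pool, par, f0 = 0.01) {
  stopifnot(inherits(pool, "haplotype_pool"), f0 > 0, f0 <= 1)
  d <- length(pool$causal_idx)
  par <- rep_len(par, d)
  grr <- par_to_grr(par, pool$maf[pool$causal_idx], pool$is_protective)
  structure(list(par = par, f0 = f0, grr = grr,
                 causal_idx = pool$causal_idx,
                 is_protective = pool$is_protective),
            class = "disease_model")
}

#' @export
print.disease_model <- function(x, ...) {
  cat("disease_model: f0 =", x$f0, ", PAR =",
      paste(unique(x$par), collapse = "/"), "\n")
  cat("  GRR range:", signif(min(x$grr), 4), "-", signif(max(x$grr), 4), "\n")
  invisible(x)
}

#' Penetrance of a causal-site genotype
#'
#' Multiplicative across causal sites and alleles:
#' `P(disease) = min(1, f0 * prod_j GRR_j ^ g_j)` where `g_j` is the
#' minor-allele dosage at causal site `j`.  The clip at 1 keeps the
#' penetrance a valid probability for extreme multi-carrier genotypes.
#'
#' @param genotype dosage vector over the causal sites (length `d`), or an
#'   `n x d` matrix of such vectors.
#' @param model a [disease_model].
#' @return affection probability (vector of length `n`).
#' @examples
#' pool <- generate_pool(60, 3, 100, seed = 1, n_hap = 2000)
#' m <- disease_model(pool, par = 0.003)
#' affection_probability(c(0, 0, 0), m)  # = f0
#' @export
affection_probability <- function(genotype, model) {
  stopifnot(inherits(model, "disease_model"))
  g <- if (is.matrix(genotype)) genotype else matrix(genotype, nrow = 1)
  if (ncol(g) != length(model$grr))
    stop("genotype must cover the ", length(model$grr), " causal sites")
  pmin(1, model$f0 * exp(g %*% log(model$grr))[, 1])
}

#' Sample a case-control data set from a haplotype pool
#'
#' Pairs of chromosomes are drawn from the pool with replacement; each
#' subject's disease status is Bernoulli with probability
#' [affection_probability()] of its causal-site dosages.  Draws continue
#' until both the case and the control quota are filled (surplus draws of a
#' filled stratum are discarded), so the design is case-control sampling
#' from the population the pool defines.  Under the null (every GRR equal
#' to 1) affection is independent of genotype and both strata are drawn
#' directly, which is the same distribution without the rejection step.
#'
#' @param pool a [haplotype_pool].
#' @param model a [disease_model] built on the same pool.
#' @param n_cases,n_controls stratum quotas (default 500/500).
#' @param seed optional integer seed.
#' @param max_draws safety cap on the number of subjects drawn; default
#'   `200 * (n_cases / f0 + n_controls / (1 - f0))`, far above the expected
#'   requirement, so hitting it signals a degenerate model.
#' @return a [case_control_data] over all K pool sites, cases first.
#' @export
sample_case_control <- function(pool, model, n_cases = 500, n_controls = 500,
                                seed = NULL, max_draws = NULL) {
  stopifnot(inherits(pool, "haplotype_pool"), inherits(model, "disease_model"),
            n_cases >= 1, n_controls >= 1)
  f0 <- model$f0
  if (is.null(max_draws))
    max_draws <- ceiling(200 * (n_cases / f0 + n_controls / max(1 - f0, 1e-6)))
  n_hap <- nrow(pool$haplotypes)
  Hc <- pool$haplotypes[, model$causal_idx, drop = FALSE]

  if (all(model$grr == 1)) {
    # Null model: affection is Bernoulli(f0) independently of genotype, so
    # the case and control strata are both plain random pairs from the pool
    # and rejection sampling reduces, exactly in distribution, to drawing
    # the two quotas directly.
    return(with_seed(seed, {
      nd <- n_cases + n_controls
      i1 <- sample.int(n_hap, nd, replace = TRUE)
      i2 <- sample.int(n_hap, nd, replace = TRUE)
      G <- pool$haplotypes[i1, , drop = FALSE] +
           pool$haplotypes[i2, , drop = FALSE]
      case_control_data(G, c(rep(1L, n_cases), rep(0L, n_controls)),
                        variant_ids = pool$variant_ids)
    }))
  }

  with_seed(seed, {
    case_pairs <- matrix(0L, 0L, 2L)
    ctrl_pairs <- matrix(0L, 0L, 2L)
    drawn <- 0L
    chunk <- max(2L * (n_cases + n_controls),
                 ceiling(1.2 * n_cases / max(f0, 1e-6)))
    while (nrow(case_pairs) < n_cases || nrow(ctrl_pairs) < n_controls) {
      if (drawn >= max_draws)
        stop("case-control sampling exceeded ", max_draws, " draws (",
             nrow(case_pairs), "/", n_cases, " cases, ",
             nrow(ctrl_pairs), "/", n_controls,
             " controls); check f0 and the disease model")
      nd <- min(chunk, max_draws - drawn)
      drawn <- drawn + nd
      i1 <- sample.int(n_hap, nd, replace = TRUE)
      i2 <- sample.int(n_hap, nd, replace = TRUE)
      pr <- affection_probability(Hc[i1, , drop = FALSE] +
                                  Hc[i2, , drop = FALSE], model)
      aff <- runif(nd) < pr
      if (nrow(case_pairs) < n_cases && any(aff)) {
        take <- which(aff)[seq_len(min(sum(aff), n_cases - nrow(case_pairs)))]
        case_pairs <- rbind(case_pairs, cbind(i1[take], i2[take]))
      }
      if (nrow(ctrl_pairs) < n_controls && any(!aff)) {
        take <- which(!aff)[seq_len(min(sum(!aff),
                                        n_controls - nrow(ctrl_pairs)))]
        ctrl_pairs <- rbind(ctrl_pairs, cbind(i1[take], i2[take]))
      }
      chunk <- max(chunk, ceiling(1.2 * (n_cases - nrow(case_pairs)) /
                                    max(f0, 1e-6)))
    }
    pairs <- rbind(case_pairs, ctrl_pairs)
    G <- pool$haplotypes[pairs[, 1L], , drop = FALSE] +
         pool$haplotypes[pairs[, 2L], , drop = FALSE]
    case_control_data(G, c(rep(1L, n_cases), rep(0L, n_controls)),
                      variant_ids = pool$variant_ids)
  })
}
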