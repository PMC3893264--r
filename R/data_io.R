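#' Case-control genotype data
#'
#' The canonical in-memory container consumed by every test in the package:
#' a subject-by-variant matrix of minor-allele dosages (0/1/2), a binary
#' phenotype, and variant metadata.
#'
#' By default columns are re-polarised so that dosages always count the minor
#' allele *in the pooled case+control sample*: if the stored allele has pooled
#' frequency above 0.5, dosages are flipped to `2 - dosage`.  All downstream
#' formulas (mid-P tables, weights, genetic scores) are written in terms of
#' minor-allele counts, so polarisation is applied at construction.
#'
#' @param genotypes integer matrix, subjects in rows, variants in columns,
#'   entries in `{0,1,2}` with no missing values.
#' @param phenotype vector of 0 (control) / 1 (case), length `nrow(genotypes)`.
#' @param variant_ids unique variant labels; defaults to column names.
#' @param positions optional integer coordinates, one per variant.
#' @param subject_ids optional subject labels; defaults to row names.
#' @param polarise flip columns whose pooled allele frequency exceeds 0.5 so
#'   that dosages count the pooled-sample minor allele.
#' @return An object of class `case_control_data`: a list with elements
#'   `genotypes`, `phenotype`, `variant_ids`, `positions`, `subject_ids`,
#'   and `flipped` (which columns were re-polarised).
#' @examples
#' g <- matrix(c(0, 1, 0, 2, 0, 0, 1, 1), nrow = 4)
#' d <- case_control_data(g, c(1, 1, 0, 0), variant_ids = c("v1", "v2"))
#' d
#' @export
case_control_data <- function(genotypes, phenotype,
                              variant_ids = colnames(genotypes),
                              positions = NULL, subject_ids = rownames(genotypes),
                              polarise = TRUE) {
  genotypes <- as.matrix(genotypes)
  if (anyNA(genotypes))
    stop("genotypes contain missing values; drop incomplete subjects first")
  if (!all(genotypes %in% c(0L, 1L, 2L)))
    stop("genotype dosages must all be 0, 1 or 2")
  storage.mode(genotypes) <- "integer"
  n <- nrow(genotypes)
  K <- ncol(genotypes)
  if (K < 1L) stop("at least one variant is required")
  phenotype <- as.integer(phenotype)
  if (length(phenotype) != n)
    stop("phenotype length does not match the number of subjects")
  if (anyNA(phenotype) || !all(phenotype %in% c(0L, 1L)))
    stop("phenotype must be binary: 1 = case, 0 = control")
  if (sum(phenotype == 1L) < 1L || sum(phenotype == 0L) < 1L)
    stop("need at least one case and one control")
  if (is.null(variant_ids)) variant_ids <- paste0("V", seq_len(K))
  variant_ids <- as.character(variant_ids)
  if (anyDuplicated(variant_ids)) stop("variant_ids must be unique")
  if (!is.null(positions)) {
    positions <- as.integer(positions)
    if (length(positions) != K) stop("positions must have one entry per variant")
  }
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(n))

  flipped <- logical(K)
  if (polarise) {
    freq <- colSums(genotypes) / (2 * n)
    flipped <- freq > 0.5
    if (any(flipped))
      genotypes[, flipped] <- 2L - genotypes[, flipped, drop = FALSE]
  }
  dimnames(genotypes) <- list(subject_ids, variant_ids)
  structure(list(genotypes = genotypes, phenotype = phenotype,
                 variant_ids = variant_ids, positions = positions,
                 subject_ids = as.character(subject_ids), flipped = flipped),
            class = "case_control_data")
}

#' @export
print.case_control_data <- function(x, ...) {
  cat("case_control_data:", nrow(x$genotypes), "subjects (",
      sum(x$phenotype == 1L), "cases /", sum(x$phenotype == 0L), "controls ),",
      ncol(x$genotypes), "variants\n")
  invisible(x)
}

#' Number of subjects / variants
#' @param data a [case_control_data] object.
#' @return integer count.
#' @export
n_variants <- function(data) ncol(data$genotypes)

#' Pooled-sample minor allele frequencies
#'
#' Allele counts over the combined case+control sample divided by the total
#' chromosome count `2n`, folded to the minor allele.
#'
#' @param data a [case_control_data] object.
#' @return numeric vector of length `n_variants(data)`.
#' @export
pooled_maf <- function(data) {
  f <- unname(colSums(data$genotypes)) / (2 * nrow(data$genotypes))
  pmin(f, 1 - f)
}

#' Filter variants by pooled-sample minor allele frequency
#'
#' Retains variants whose minor-allele frequency in the combined case+control
#' sample is at most `max_maf` (the boundary is retained: a site at exactly
#' 5% survives the default filter).  Monomorphic sites (MAF 0) pass the filter
#' and are neutralised downstream by the mid-P convention.
#'
#' @param data a [case_control_data] object.
#' @param max_maf retention bound, in (0, 0.5]; default 0.05, the conventional
#'   cut separating rare/low-frequency variation from common polymorphism.
#' @return a new, filtered `case_control_data` object; the input is unchanged.
#'   If no variant survives, an error of class `adarv_empty_region` is raised.
#' @export
maf_filter <- function(data, max_maf = 0.05) {
  stopifnot(inherits(data, "case_control_data"))
  if (!(is.numeric(max_maf) && length(max_maf) == 1L &&
        max_maf > 0 && max_maf <= 0.5))
    stop("max_maf must be a single value in (0, 0.5]")
  keep <- pooled_maf(data) <= max_maf
  if (!any(keep))
    stop(structure(class = c("adarv_empty_region", "error", "condition"),
                   list(message = sprintf(
                     "no variant with pooled MAF <= %g remains", max_maf),
                     call = sys.call())))
  case_control_data(data$genotypes[, keep, drop = FALSE], data$phenotype,
                    variant_ids = data$variant_ids[keep],
                    positions = if (!is.null(data$positions)) data$positions[keep],
                    subject_ids = data$subject_ids,
                    polarise = FALSE)
}

#' Read genotypes and phenotype into a case_control_data object
#'
#' Two on-disk dialects are supported:
#' \describe{
#'   \item{`vcf`}{a VCF v4.x file with GT fields.  Multi-allelic records are
#'     split into one variant per alternate allele, with the dosage counting
#'     copies of that allele.  Subjects with any missing genotype (`./.` or a
#'     `.` allele) are dropped, and the number dropped is reported.}
#'   \item{`matrix`}{a tab-delimited dosage table: header row of variant IDs,
#'     first column of subject IDs, entries 0/1/2.}
#' }
#' The phenotype file is tab-separated with two columns, subject ID and
#' status (1 = case, 0 = control); a header row is detected automatically.
#' Subjects present in both files are kept, in phenotype-file order.
#'
#' @param path genotype file.
#' @param phenotype_path phenotype table.
#' @param format `"vcf"`, `"matrix"`, or `"auto"` (by file extension).
#' @param polarise see [case_control_data()].
#' @return a [case_control_data] object.
#' @export
read_genotypes <- function(path, phenotype_path,
                           format = c("auto", "vcf", "matrix"),
                           polarise = TRUE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "matrix"
  pheno <- read_phenotype(phenotype_path)

  geno <- switch(format,
                 vcf = read_vcf_dosages(path),
                 matrix = read_matrix_dosages(path))

  common <- intersect(pheno$subject_id, rownames(geno$dosage))
  if (length(common) == 0L)
    stop("no subject IDs are shared between the genotype and phenotype files")
  ord <- pheno$subject_id[pheno$subject_id %in% common]  # phenotype-file order
  dos <- geno$dosage[ord, , drop = FALSE]
  status <- pheno$status[match(ord, pheno$subject_id)]

  miss <- rowSums(is.na(dos)) > 0
  if (any(miss)) {
    message(sum(miss), " subject(s) dropped because of missing genotypes")
    dos <- dos[!miss, , drop = FALSE]
    status <- status[!miss]
    if (nrow(dos) == 0L) stop("all subjects have missing genotypes")
  }
  case_control_data(dos, status, variant_ids = colnames(dos),
                    positions = geno$positions, subject_ids = rownames(dos),
                    polarise = polarise)
}

read_phenotype <- function(path) {
  raw <- read.table(path, header = FALSE, sep = "\t",
                    colClasses = "character", fill = FALSE)
  if (ncol(raw) < 2L) stop("phenotype file needs two columns: subject ID, status")
  if (suppressWarnings(is.na(as.numeric(raw[1, 2]))))  # header row
    raw <- raw[-1, , drop = FALSE]
  status <- suppressWarnings(as.numeric(raw[[2]]))
  if (anyNA(status) || !all(status %in% c(0, 1)))
    stop("phenotype status must be 0 (control) or 1 (case)")
  list(subject_id = as.character(raw[[1]]), status = as.integer(status))
}

read_matrix_dosages <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                    check.names = FALSE)
  dos <- as.matrix(tab)
  if (!is.numeric(dos)) stop("dosage matrix entries must be numeric")
  list(dosage = dos, positions = NULL)
}

# VCF -> subjects x variants dosage matrix (NA where GT missing), splitting
# multi-allelic records into one column per alternate allele.
read_vcf_dosages <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0L) stop("VCF contains no variant records")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fix <- vcf@fix
  alt_list <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",",
                       fixed = TRUE)
  subjects <- colnames(gt)
  cols <- list(); ids <- character(); pos <- integer()
  for (v in seq_len(nrow(gt))) {
    alleles <- strsplit(gt[v, ], "[/|]")
    for (k in seq_along(alt_list[[v]])) {
      dose <- vapply(alleles, function(al) {
        if (length(al) == 0L || anyNA(al) || any(al == "."))
          return(NA_real_)
        sum(al == as.character(k))
      }, numeric(1))
      cols[[length(cols) + 1L]] <- dose
      ids <- c(ids, paste0(fix[v, "CHROM"], ":", fix[v, "POS"], "_",
                           fix[v, "REF"], "/", alt_list[[v]][k]))
      pos <- c(pos, as.integer(fix[v, "POS"]))
    }
  }
  dosage <- do.call(cbind, cols)
  dimnames(dosage) <- list(subjects, ids)
  list(dosage = dosage, positions = pos)
}

#' Write the tab-delimited dosage matrix dialect
#'
#' Inverse of the `matrix` format of [read_genotypes()]: header row of
#' variant IDs, first column of subject IDs, tab-separated dosages.
#'
#' @param data a [case_control_data] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(data, path) {
  stopifnot(inherits(data, "case_control_data"))
  tab <- data.frame(subject_id = data$subject_ids, data$genotypes,
                    check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a phenotype table
#'
#' @param data a [case_control_data] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(data, path) {
  tab <- data.frame(subject_id = data$subject_ids, status = data$phenotype)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
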