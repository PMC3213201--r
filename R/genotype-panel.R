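#' Construct a genotype panel
#'
#' A genotype panel bundles an `n x m` dosage matrix (counts of the A1
#' allele, values 0/1/2 or `NA` for missing) with per-sample and per-SNP
#' metadata. It is the substrate of every stage of the pipeline: quality
#' control, association, polygenic scoring and GRM construction all
#' consume a panel.
#'
#' @param dosages integer/numeric matrix, samples in rows, SNPs in
#'   columns; entries in `{0, 1, 2, NA}`.
#' @param samples data frame with columns `sample_id`, `family_id`,
#'   `sex` (`"male"`, `"female"` or `"unknown"`) and `batch`; one row
#'   per dosage row. Missing columns are filled with defaults
#'   (`family_id = sample_id`, `sex = "unknown"`, `batch = "B1"`).
#' @param snps data frame with columns `snp_id`, `chromosome` (1-22),
#'   `position` (1-based), `a1`, `a2`; one row per dosage column.
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `dosages`, `samples`, `snps`.
#' @export
genotype_panel <- function(dosages, samples, snps) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (is.null(samples$family_id)) samples$family_id <- samples$sample_id
  if (is.null(samples$sex)) samples$sex <- "unknown"
  if (is.null(samples$batch)) samples$batch <- "B1"
  panel <- structure(
    list(dosages = dosages, samples = samples, snps = snps),
    class = "genotype_panel"
  )
  validate_panel(panel)
  rownames(panel$dosages) <- samples$sample_id
  colnames(panel$dosages) <- snps$snp_id
  panel
}

validate_panel <- function(panel) {
  d <- panel$dosages
  if (nrow(d) < 1L || ncol(d) < 1L)
    stop("panel must contain at least one sample and one SNP")
  if (nrow(panel$samples) != nrow(d))
    stop("sample metadata rows (", nrow(panel$samples),
         ") do not match dosage rows (", nrow(d), ")")
  if (nrow(panel$snps) != ncol(d))
    stop("SNP metadata rows do not match dosage columns")
  if (anyDuplicated(panel$samples$sample_id))
    stop("duplicate sample ids")
  if (anyDuplicated(panel$snps$snp_id))
    stop("duplicate SNP ids")
  if (any(panel$samples$sample_id == ""))
    stop("empty sample id")
  bad <- !(d %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (!all(panel$snps$chromosome %in% 1:22))
    stop("autosomes only: chromosome must be in 1..22")
  if (any(panel$snps$a1 == panel$snps$a2))
    stop("A1 and A2 alleles must differ")
  invisible(panel)
}

#' @export
print.genotype_panel <- function(x, ...) {
  n <- nrow(x$dosages); m <- ncol(x$dosages)
  miss <- mean(is.na(x$dosages))
  cat(sprintf("genotype_panel: %d samples x %d SNPs (%.2f%% missing)\n",
              n, m, 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosages)

#' Subset a genotype panel by sample and/or SNP ids
#'
#' @param panel a [genotype_panel()].
#' @param sample_ids,snp_ids character vectors of ids to keep (in the
#'   given order); `NULL` keeps everything.
#' @return A `genotype_panel` restricted to the requested ids.
#' @export
subset_panel <- function(panel, sample_ids = NULL, snp_ids = NULL) {
  ri <- if (is.null(sample_ids)) seq_len(nrow(panel$dosages)) else
    match(sample_ids, panel$samples$sample_id)
  ci <- if (is.null(snp_ids)) seq_len(ncol(panel$dosages)) else
    match(snp_ids, panel$snps$snp_id)
  if (anyNA(ri)) stop("unknown sample id(s)")
  if (anyNA(ci)) stop("unknown SNP id(s)")
  genotype_panel(panel$dosages[ri, ci, drop = FALSE],
                 panel$samples[ri, , drop = FALSE],
                 panel$snps[ci, , drop = FALSE])
}

# allele frequency of A1 per SNP from non-missing dosages
allele_freq <- function(panel) {
  colMeans(panel$dosages, na.rm = TRUE) / 2
}

# minor allele frequency per SNP
minor_allele_freq <- function(panel) {
  p <- allele_freq(panel)
  pmin(p, 1 - p)
}

per_marker_call_rate <- function(panel) {
  colMeans(!is.na(panel$dosages))
}

per_sample_call_rate <- function(panel) {
  rowMeans(!is.na(panel$dosages))
}
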