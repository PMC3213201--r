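#' Read a PLINK bed/bim/fam fileset
#'
#' Reads the binary SNP-major PLINK 1 format. Dosages count the A1
#' allele (the fifth .bim column): the 2-bit codes 00/10/11 map to
#' dosage 2/1/0 and 01 maps to missing, samples ordered as in .fam and
#' SNPs as in .bim.
#'
#' @param prefix path stem; `prefix.bed`, `prefix.bim` and
#'   `prefix.fam` must exist.
#' @return A [genotype_panel()].
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("missing file: ", f)

  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("family_id", "sample_id", "pat",
                                            "mat", "sex_code", "pheno"),
                              colClasses = c("character", "character",
                                             "character", "character",
                                             "integer", "character"))
  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("chromosome", "snp_id", "cm",
                                            "position", "a1", "a2"),
                              colClasses = c("integer", "character", "numeric",
                                             "integer", "character",
                                             "character"))
  n <- nrow(fam_df)
  m <- nrow(bim_df)

  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3L ||
      raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("malformed .bed magic bytes")
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported")
  bps <- ceiling(n / 4)           # bytes per SNP
  if (length(raw) != 3L + bps * m)
    stop("truncated .bed: expected ", 3L + bps * m, " bytes, got ",
         length(raw))

  bytes <- matrix(as.integer(raw[-(1:3)]), nrow = bps, ncol = m)
  # 2-bit genotype code -> A1 dosage
  code_map <- c(2L, NA_integer_, 1L, 0L)
  full <- matrix(NA_integer_, nrow = 4L * bps, ncol = m)
  shift <- c(1L, 4L, 16L, 64L)
  for (k in 1:4) {
    rows <- seq.int(k, by = 4L, length.out = bps)
    full[rows, ] <- code_map[(bytes %/% shift[k]) %% 4L + 1L]
  }
  dos <- full[seq_len(n), , drop = FALSE]

  samples <- data.frame(sample_id = fam_df$sample_id,
                        family_id = fam_df$family_id,
                        sex = c("male", "female")[match(fam_df$sex_code, 1:2)],
                        batch = "B1",
                        stringsAsFactors = FALSE)
  samples$sex[is.na(samples$sex)] <- "unknown"
  snps <- bim_df[, c("snp_id", "chromosome", "position", "a1", "a2")]
  genotype_panel(dos, samples, snps)
}

#' Write a genotype panel as PLINK bed/bim/fam
#'
#' Inverse of [read_plink()]; the written fileset round-trips (batch
#' labels live outside the PLINK formats and are not preserved).
#'
#' @param panel a [genotype_panel()].
#' @param prefix path stem to write to.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  validate_panel(panel)
  n <- nrow(panel$dosages)
  m <- ncol(panel$dosages)
  bps <- ceiling(n / 4)

  # dosage -> 2-bit code; pad tail samples with code 0
  dose_code <- function(d) ifelse(is.na(d), 1L, c(3L, 2L, 0L)[d + 1L])
  codes <- matrix(0L, nrow = 4L * bps, ncol = m)
  codes[seq_len(n), ] <- dose_code(panel$dosages)
  shift <- c(1L, 4L, 16L, 64L)
  bytes <- matrix(0L, nrow = bps, ncol = m)
  for (k in 1:4) {
    rows <- seq.int(k, by = 4L, length.out = bps)
    bytes <- bytes + codes[rows, , drop = FALSE] * shift[k]
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)

  sex_code <- match(panel$samples$sex, c("male", "female"))
  sex_code[is.na(sex_code)] <- 0L
  fam <- data.frame(panel$samples$family_id, panel$samples$sample_id,
                    "0", "0", sex_code, "-9")
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  bim <- data.frame(panel$snps$chromosome, panel$snps$snp_id, 0,
                    panel$snps$position, panel$snps$a1, panel$snps$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(prefix)
}

#' Read/write the plain-text dosage dialect
#'
#' A human-readable fixture format: a header row of SNP ids, then one
#' row per sample (`sample_id` followed by 0/1/2/NA dosages).
#'
#' @param path file path.
#' @param snps optional SNP metadata data frame (as in
#'   [genotype_panel()]); defaults place all SNPs on chromosome 1 with
#'   consecutive positions and alleles A/B.
#' @param samples optional sample metadata.
#' @return A [genotype_panel()].
#' @export
read_dosage_text <- function(path, snps = NULL, samples = NULL) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  ids <- as.character(tab[[1L]])
  dos <- as.matrix(tab[, -1L, drop = FALSE])
  if (is.null(snps))
    snps <- data.frame(snp_id = colnames(dos), chromosome = 1L,
                       position = seq_len(ncol(dos)), a1 = "A", a2 = "B",
                       stringsAsFactors = FALSE)
  if (is.null(samples))
    samples <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  genotype_panel(dos, samples, snps)
}

#' @rdname read_dosage_text
#' @param panel a [genotype_panel()] to write.
#' @export
write_dosage_text <- function(panel, path) {
  tab <- data.frame(sample_id = panel$samples$sample_id,
                    panel$dosages, check.names = FALSE)
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
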