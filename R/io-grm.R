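#' Read a GCTA binary GRM
#'
#' Reads the `grm.bin` / `grm.N.bin` / `grm.id` triple: 4-byte
#' little-endian floats holding the lower triangle (including the
#' diagonal) in row-major order, plus the per-pair non-missing SNP
#' counts and a two-column id file.
#'
#' @param prefix path stem; `prefix.grm.bin` and `prefix.grm.id` must
#'   exist (`prefix.grm.N.bin` is optional).
#' @return A `grm` object: list with `A` (n x n symmetric matrix), `N`
#'   (n x n pair SNP counts, or NULL), `ids` (data frame `family_id`,
#'   `sample_id`).
#' @export
read_grm_bin <- function(prefix) {
  idf <- paste0(prefix, ".grm.id")
  binf <- paste0(prefix, ".grm.bin")
  nf <- paste0(prefix, ".grm.N.bin")
  if (!file.exists(idf)) stop("missing file: ", idf)
  if (!file.exists(binf)) stop("missing file: ", binf)
  ids <- utils::read.table(idf, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("family_id", "sample_id"),
                           colClasses = "character")
  n <- nrow(ids)
  ntri <- n * (n + 1) / 2
  vals <- readBin(binf, what = "numeric", size = 4L, n = file.size(binf) / 4,
                  endian = "little")
  if (length(vals) != ntri)
    stop("grm.bin holds ", length(vals), " values; expected n(n+1)/2 = ",
         ntri, " for the ", n, " ids in grm.id")
  A <- matrix(0, n, n)
  A[upper.tri(A, diag = TRUE)] <- vals   # row-major lower tri == col-major upper
  A <- A + t(A) - diag(diag(A))
  dimnames(A) <- list(ids$sample_id, ids$sample_id)
  N <- NULL
  if (file.exists(nf)) {
    nv <- readBin(nf, what = "numeric", size = 4L, n = file.size(nf) / 4,
                  endian = "little")
    if (length(nv) != ntri) stop("grm.N.bin length mismatch")
    N <- matrix(0, n, n)
    N[upper.tri(N, diag = TRUE)] <- nv
    N <- N + t(N) - diag(diag(N))
    dimnames(N) <- dimnames(A)
  }
  new_grm(A, N, ids)
}

#' Write a GRM in GCTA binary format
#'
#' @param grm a `grm` object (see [read_grm_bin()], [compute_grm()]).
#' @param prefix path stem to write to.
#' @return `prefix`, invisibly.
#' @export
write_grm_bin <- function(grm, prefix) {
  n <- nrow(grm$A)
  ut <- upper.tri(grm$A, diag = TRUE)
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(grm$A[ut], con, size = 4L, endian = "little")
  close(con)
  if (!is.null(grm$N)) {
    con <- file(paste0(prefix, ".grm.N.bin"), "wb")
    writeBin(grm$N[ut], con, size = 4L, endian = "little")
    close(con)
  }
  utils::write.table(grm$ids[, c("family_id", "sample_id")],
                     paste0(prefix, ".grm.id"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(prefix)
}

new_grm <- function(A, N, ids) {
  structure(list(A = A, N = N, ids = ids), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d samples, mean diagonal %.4f\n",
              nrow(x$A), mean(diag(x$A))))
  invisible(x)
}
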