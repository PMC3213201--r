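# Internal numerical helpers shared across modules.

# Mean-impute missing dosages per SNP and standardize columns by
# sqrt(2 p (1 - p)) with p the sample A1 frequency. Columns that are
# monomorphic (or entirely missing) come back as zeros.
standardize_dosages <- function(dos) {
  p <- colMeans(dos, na.rm = TRUE) / 2
  mu <- 2 * p
  sd <- sqrt(2 * p * (1 - p))
  Z <- sweep(dos, 2, mu, "-")
  Z[is.na(Z)] <- 0
  ok <- sd > 0 & !is.na(sd)
  Z[, ok] <- sweep(Z[, ok, drop = FALSE], 2, sd[ok], "/")
  Z[, !ok] <- 0
  Z
}

# design matrix from a covariate data frame: numeric columns as-is,
# character/factor columns one-hot with the first level dropped
covariate_design <- function(covariates, n) {
  cols <- list(intercept = rep(1, n))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
    for (nm in names(covariates)) {
      v <- covariates[[nm]]
      if (is.numeric(v)) {
        cols[[nm]] <- as.numeric(v)
      } else {
        lev <- sort(unique(as.character(v)))
        for (l in lev[-1])
          cols[[paste0(nm, "_", l)]] <- as.numeric(as.character(v) == l)
      }
    }
  }
  do.call(cbind, cols)
}

# residualize y on a design matrix (with intercept) via QR
residualize <- function(y, X) {
  qr_x <- qr(X)
  as.numeric(qr.resid(qr_x, y))
}
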