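#' Default sex-specific risk-score regression coefficients
#'
#' The published Cox-model coefficients for the general cardiovascular
#' disease 10-year risk functions, on log-transformed continuous
#' predictors. The linear predictor is
#' \deqn{LP = \beta_1 \ln(age) + \beta_2 \ln(TC) + \beta_3 \ln(HDL) +
#'   \beta_{SBP} \ln(SBP) + \beta_{smk}\,smoker + \beta_{dm}\,diabetic}
#' with the treated or untreated SBP coefficient chosen by treatment
#' status (exactly one SBP term per subject).
#'
#' @return list with elements `male` and `female`, each a named vector
#'   with entries `log_age`, `log_tc`, `log_hdl`, `log_sbp_untreated`,
#'   `log_sbp_treated`, `smoking`, `diabetes`.
#' @export
frs_coefficients <- function() {
  list(
    male = c(log_age = 3.06117, log_tc = 1.1237, log_hdl = -0.93263,
             log_sbp_untreated = 1.933303, log_sbp_treated = 1.99881,
             smoking = 0.65451, diabetes = 0.57367),
    female = c(log_age = 2.32888, log_tc = 1.20904, log_hdl = -0.70833,
               log_sbp_untreated = 2.76157, log_sbp_treated = 2.82263,
               smoking = 0.52873, diabetes = 0.69154)
  )
}

#' Compute the risk-score linear predictor for a cohort
#'
#' Vectorized over the rows of `covariates`. The analysis phenotype is
#' the sex-specific linear predictor; the 10-year risk probability
#' `1 - S0 ^ exp(LP - LPbar)` is only computed when baseline-survival
#' constants are supplied via `baseline` (they are cohort-calibration
#' constants, not defaults of this package).
#'
#' @param covariates data frame with columns `sample_id`, `sex`
#'   (`"male"`/`"female"`), `age`, `total_chol`, `hdl`, `sbp`,
#'   `bp_treated`, `smoker`, `diabetic`. An optional logical
#'   `hdl_imputed` column (from [impute_hdl_cohort_mean()]) is carried
#'   through.
#' @param coefs coefficient set, defaults to [frs_coefficients()].
#' @param baseline optional list with per-sex `s0` and `lp_bar`
#'   entries, e.g. `list(male = c(s0 = ..., lp_bar = ...), ...)`.
#' @return data frame with `sample_id`, `linear_predictor`,
#'   `ten_year_risk` (NA unless `baseline` given) and `hdl_imputed`.
#' @export
compute_frs <- function(covariates, coefs = frs_coefficients(),
                        baseline = NULL) {
  req <- c("sample_id", "sex", "age", "total_chol", "hdl", "sbp",
           "bp_treated", "smoker", "diabetic")
  miss <- setdiff(req, names(covariates))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!all(covariates$sex %in% c("male", "female")))
    stop("unknown sex; must be 'male' or 'female'")
  cont <- c("age", "total_chol", "hdl", "sbp")
  for (col in cont)
    if (any(covariates[[col]] <= 0, na.rm = TRUE))
      stop("non-positive ", col, ": log-transformed predictors must be > 0")
  for (col in c("bp_treated", "smoker", "diabetic"))
    if (!all(covariates[[col]] %in% c(0, 1)))
      stop(col, " must be 0/1")

  B <- do.call(rbind, coefs[covariates$sex])
  sbp_beta <- ifelse(covariates$bp_treated == 1,
                     B[, "log_sbp_treated"], B[, "log_sbp_untreated"])
  lp <- B[, "log_age"] * log(covariates$age) +
    B[, "log_tc"] * log(covariates$total_chol) +
    B[, "log_hdl"] * log(covariates$hdl) +
    sbp_beta * log(covariates$sbp) +
    B[, "smoking"] * covariates$smoker +
    B[, "diabetes"] * covariates$diabetic

  risk <- rep(NA_real_, length(lp))
  if (!is.null(baseline)) {
    for (s in c("male", "female")) {
      i <- covariates$sex == s
      risk[i] <- 1 - baseline[[s]][["s0"]] ^
        exp(lp[i] - baseline[[s]][["lp_bar"]])
    }
  }
  data.frame(sample_id = covariates$sample_id,
             linear_predictor = as.numeric(lp),
             ten_year_risk = risk,
             hdl_imputed = if (!is.null(covariates$hdl_imputed))
               covariates$hdl_imputed else FALSE,
             stringsAsFactors = FALSE)
}

#' Log-transform a risk-score vector
#'
#' The analyses run on a logarithmic transform of the score so that
#' outliers do not get unusual leverage. When any score is
#' non-positive the transform is `ln(x - min(x) + 1)` (the shift is
#' recorded in the `"shift"` attribute); otherwise plain `ln(x)`.
#' Either way the transform is strictly monotone in the score.
#'
#' @param score numeric vector of risk scores (e.g. linear predictors).
#' @return transformed vector with attribute `shift` (0 when no shift
#'   was needed).
#' @export
log_risk_score <- function(score) {
  if (any(!is.finite(score))) stop("scores must be finite")
  if (any(score <= 0)) {
    shift <- -min(score) + 1
    out <- log(score + shift)
  } else {
    shift <- 0
    out <- log(score)
  }
  attr(out, "shift") <- shift
  out
}

#' Impute missing HDL with a donor-cohort mean
#'
#' Reproduces the original-cohort rule: HDL was unmeasured at the
#' baseline exam, so the mean HDL of donors measured at a later exam
#' is applied to every subject missing HDL; subjects with an observed
#' HDL are untouched.
#'
#' @param cohort data frame with an `hdl` column (NA = missing).
#' @param donor_exam_values non-empty numeric vector of donor HDL
#'   measurements.
#' @return `cohort` with NA HDL replaced by `mean(donor_exam_values)`
#'   and a logical `hdl_imputed` column.
#' @export
impute_hdl_cohort_mean <- function(cohort, donor_exam_values) {
  donor_exam_values <- donor_exam_values[!is.na(donor_exam_values)]
  if (!length(donor_exam_values)) stop("empty donor vector")
  miss <- is.na(cohort$hdl)
  cohort$hdl[miss] <- mean(donor_exam_values)
  cohort$hdl_imputed <- miss
  cohort
}

#' Definite-diabetes indicator
#'
#' A subject is diabetic iff treated for diabetes or with a blood
#' glucose reading of at least 200 mg/dL.
#'
#' @param treated_flag 0/1 treatment indicator.
#' @param glucose_mg_dl glucose in mg/dL; `NA` means no reading.
#' @return integer 0/1 vector.
#' @export
diabetes_from_glucose <- function(treated_flag, glucose_mg_dl) {
  g <- ifelse(is.na(glucose_mg_dl), -Inf, glucose_mg_dl)
  as.integer(treated_flag == 1 | g >= 200)
}

#' Subjects eligible for risk scoring
#'
#' Scores are only computed for subjects with complete predictor
#' information; imputed HDL (see [impute_hdl_cohort_mean()]) counts as
#' present.
#'
#' @param covariates covariate data frame (as for [compute_frs()]).
#' @return character vector of eligible `sample_id`s.
#' @export
eligible_subjects <- function(covariates) {
  req <- c("sex", "age", "total_chol", "hdl", "sbp",
           "bp_treated", "smoker", "diabetic")
  ok <- stats::complete.cases(covariates[, req])
  covariates$sample_id[ok]
}
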