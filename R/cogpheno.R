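# Normative cognitive scoring: HC-referenced regression norms, domain
# Z-scores, average cognition, and CP / MCI / CI classification.

#' Fit normative models on healthy controls
#'
#' Regression-based norms: for each of the seven cognitive domains, a linear
#' model of the raw domain score on age (years), sex (0 = F, 1 = M) and
#' education (binary high/low) is fitted on healthy controls only. The
#' residual standard deviation (denominator `n - p`) provides the scaling of
#' the later Z-scores, so patient scores are expressed relative to what is
#' expected for a control of the same age, sex and education.
#'
#' @param hc_scores Data frame / matrix of raw domain scores for HC subjects
#'   (columns = the 7 domains, rows = subjects).
#' @param hc_covariates Data frame with columns `age`, `sex`,
#'   `education_high` for the same subjects.
#' @return Object of class `normative_model`: per-domain coefficients and
#'   residual SD.
#' @export
fit_normative <- function(hc_scores, hc_covariates) {
  hc_scores <- as.matrix(hc_scores)
  n <- nrow(hc_scores)
  if (n < 10) stop_invalid("need at least 10 HC subjects to fit norms (got %d)", n)
  req <- c("age", "sex", "education_high")
  if (!all(req %in% names(hc_covariates)))
    stop_invalid("hc_covariates must contain: %s", paste(req, collapse = ", "))
  if (anyNA(hc_covariates[req]))
    stop_invalid("covariates must be complete (no missing values)")
  X <- cbind(intercept = 1, age = hc_covariates$age, sex = hc_covariates$sex,
             education_high = hc_covariates$education_high)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_invalid("rank-deficient normative design; collinear column(s): %s",
                 paste(bad, collapse = ", "))
  }
  p <- ncol(X)
  coef <- qr.coef(qrX, hc_scores)
  resid <- hc_scores - X %*% coef
  rsd <- sqrt(colSums(resid^2) / (n - p))
  if (any(rsd < 1e-8))
    stop_invalid(
      "degenerate normative fit: residual SD ~ 0 for domain(s) %s",
      paste(colnames(hc_scores)[rsd < 1e-8], collapse = ", "))
  structure(list(coef = coef, residual_sd = rsd,
                 domains = colnames(hc_scores), n = n),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat("<normative_model> fitted on", x$n, "HC;",
      length(x$domains), "domains\n")
  invisible(x)
}

#' Covariate-corrected domain Z-scores
#'
#' `z = (observed - predicted(age, sex, education)) / residual SD`, per
#' domain. Missing raw scores propagate to missing Z-scores (never imputed).
#'
#' @param raw_scores Data frame / matrix of raw domain scores (columns must
#'   match the model's domains).
#' @param covariates Data frame with `age`, `sex`, `education_high`.
#' @param model A [fit_normative()] model.
#' @return Matrix of Z-scores, one column per domain.
#' @export
domain_z <- function(raw_scores, covariates, model) {
  if (!inherits(model, "normative_model"))
    stop_invalid("model must come from fit_normative()")
  raw_scores <- as.matrix(raw_scores)
  if (is.null(colnames(raw_scores))) colnames(raw_scores) <- model$domains
  raw_scores <- raw_scores[, model$domains, drop = FALSE]
  X <- cbind(1, covariates$age, covariates$sex, covariates$education_high)
  pred <- X %*% model$coef
  sweep(raw_scores - pred, 2, model$residual_sd, "/")
}

#' Classify cognitive status from 7 domain Z-scores
#'
#' Cognitively impaired (CI): at least two of the seven domains with
#' `Z <= -2`. Mildly cognitively impaired (MCI): at least two domains with
#' `Z <= -1.5`, not fulfilling the CI criterion. Otherwise cognitively
#' preserved (CP). Thresholds are inclusive.
#'
#' By default all 7 domains must be observed; with `missing = "lenient"` a
#' subject is classified if the observed domains already settle the class
#' (e.g. two observed domains at `Z <= -2` imply CI regardless of the rest),
#' and an error is raised only when the class is genuinely ambiguous.
#'
#' @param z Numeric vector of 7 Z-scores, or a matrix with 7 columns.
#' @param missing Policy for missing domains: `"strict"` (default, refuse)
#'   or `"lenient"`.
#' @return Factor with levels `CP < MCI < CI` (ordered).
#' @examples
#' classify_cognition(c(-2, -2.3, 0, 0, 0, 0, 0))   # CI
#' classify_cognition(c(-2.5, -1.6, 0, 0, 0, 0, 0)) # MCI
#' classify_cognition(c(-2.5, 0, 0, 0, 0, 0, 0))    # CP
#' @export
classify_cognition <- function(z, missing = c("strict", "lenient")) {
  missing <- match.arg(missing)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  z <- as.matrix(z)
  if (ncol(z) != 7) stop_invalid("expected 7 domain Z-scores, got %d", ncol(z))
  n_na <- rowSums(is.na(z))
  n2 <- rowSums(z <= -2, na.rm = TRUE)
  n15 <- rowSums(z <= -1.5, na.rm = TRUE)
  cls <- ifelse(n2 >= 2, "CI", ifelse(n15 >= 2, "MCI", "CP"))
  if (any(n_na > 0)) {
    if (missing == "strict")
      stop_invalid("cannot classify: %d subject(s) with missing domain Z-scores",
                   sum(n_na > 0))
    # lenient: missing domains can only push the class up, so a class is
    # safe when the missing domains could not change it.
    amb <- n_na > 0 & ((cls == "CP" & n15 + n_na >= 2) |
                         (cls == "MCI" & n2 + n_na >= 2))
    if (any(amb))
      stop_invalid("cannot classify %d subject(s): missing domains leave the class ambiguous",
                   sum(amb))
  }
  factor(cls, levels = c("CP", "MCI", "CI"), ordered = TRUE)
}

#' Average cognition
#'
#' Arithmetic mean of the seven domain Z-scores.
#' @param z Vector of 7 Z-scores or matrix with 7 columns.
#' @return Scalar (or vector) mean Z.
#' @export
average_cognition <- function(z) {
  if (is.null(dim(z))) return(mean(z))
  rowMeans(as.matrix(z))
}

#' Average sub-test Z-scores into one score per domain
#'
#' Helper for batteries where a domain has several sub-tests: sub-test
#' Z-scores are averaged into a unique Z-score per domain.
#'
#' @param subtest_z Data frame / matrix of sub-test Z-scores.
#' @param domain_of Character vector assigning each column to a domain.
#' @return Matrix with one column per domain (in `cognitive_domains()` order
#'   where present).
#' @export
average_subtests <- function(subtest_z, domain_of) {
  subtest_z <- as.matrix(subtest_z)
  if (length(domain_of) != ncol(subtest_z))
    stop_invalid("domain_of must label every sub-test column")
  doms <- intersect(cognitive_domains(), unique(domain_of))
  out <- sapply(doms, function(d)
    rowMeans(subtest_z[, domain_of == d, drop = FALSE]))
  matrix(out, ncol = length(doms), dimnames = list(NULL, doms))
}

#' Cognitive profiles for a whole cohort
#'
#' Fits normative models on the cohort's healthy controls (by default
#' separately at each timepoint, so follow-up scores are referenced to
#' follow-up controls, absorbing learning effects; set
#' `per_timepoint = FALSE` to reference both visits to baseline controls),
#' scores every subject, and classifies CP/MCI/CI.
#'
#' @param cohort A `fixel_cohort`.
#' @param per_timepoint Fit HC norms per timepoint (default TRUE).
#' @return Data frame: subject, timepoint, z_<domain> columns, `average_z`,
#'   `class`.
#' @export
cognitive_profiles <- function(cohort, per_timepoint = TRUE) {
  cg <- cohort$cognition
  subj <- cohort$subjects
  doms <- cognitive_domains()
  out <- list()
  for (tp in sort(unique(cg$timepoint))) {
    rows <- cg[cg$timepoint == tp, ]
    cov <- subj[match(paste0(rows$subject, "|", tp),
                      paste0(subj$subject, "|", subj$timepoint)), ]
    ref_tp <- if (per_timepoint) tp else 1L
    ref_rows <- cg[cg$timepoint == ref_tp, ]
    ref_cov <- subj[match(paste0(ref_rows$subject, "|", ref_tp),
                          paste0(subj$subject, "|", subj$timepoint)), ]
    hc <- ref_cov$group == "HC"
    model <- fit_normative(ref_rows[hc, doms], ref_cov[hc, ])
    z <- domain_z(rows[, doms], cov, model)
    colnames(z) <- paste0("z_", doms)
    out[[length(out) + 1L]] <- data.frame(
      subject = rows$subject, timepoint = tp, z,
      average_z = average_cognition(z),
      class = classify_cognition(z),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
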