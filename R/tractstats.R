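# Tract-of-interest statistics: covariate-adjusted one-way ANOVA (ANCOVA)
# with Bonferroni post-hocs, and longitudinal linear mixed models.

#' Bonferroni correction
#'
#' `min(1, p * family_size)`, vectorized.
#' @param p_values Numeric vector of raw p-values.
#' @param family_size Number of tests in the family (>= 1).
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni <- function(p_values, family_size) {
  if (family_size < 1) stop_invalid("family_size must be >= 1")
  pmin(1, p_values * family_size)
}

#' Covariate-adjusted group comparison for one tract (ANCOVA)
#'
#' Linear model with the group factor coded as indicators plus continuous /
#' binary covariates. The group effect is tested by the partial F comparing
#' the full model against the covariate-only model:
#' `F = ((RSS_reduced - RSS_full)/q) / (RSS_full/(n - p))`.
#' Covariate-adjusted group means (evaluated at the covariate means) are
#' reported with 95% confidence intervals, and all pairwise group contrasts
#' are Bonferroni-corrected within the tract's family of pairs.
#'
#' @param values Numeric outcome (one tract's metric per subject).
#' @param group Factor (or character) of group membership, >= 2 levels with
#'   >= 2 subjects each.
#' @param covariates Data frame of covariates (e.g. age, sex, head_scale,
#'   optionally education_high and treatment; factors allowed).
#' @return Object of class `ancova_result`: `F`, `df`, `p`,
#'   `adjusted_means` (with 95% CI), `posthoc` (pairwise table),
#'   `family_size`, and the underlying `fit`.
#' @export
ancova_tract <- function(values, group, covariates = NULL) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop_invalid("need at least 2 groups")
  if (any(table(group) < 2)) stop_invalid("every group needs n >= 2")
  n <- length(values)
  dat <- data.frame(.y = values, .g = group)
  cov_terms <- character(0)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    covariates <- as.data.frame(covariates)
    if (anyNA(covariates)) stop_invalid("covariates must be complete")
    dat <- cbind(dat, covariates)
    cov_terms <- names(covariates)
  }
  rhs_full <- paste(c(".g", cov_terms), collapse = " + ")
  rhs_red <- if (length(cov_terms)) paste(cov_terms, collapse = " + ") else "1"
  full <- stats::lm(stats::as.formula(paste(".y ~", rhs_full)), data = dat)
  if (any(is.na(stats::coef(full)))) {
    bad <- names(stats::coef(full))[is.na(stats::coef(full))]
    stop_invalid("confounded/rank-deficient ANCOVA design (aliased: %s)",
                 paste(bad, collapse = ", "))
  }
  red <- stats::lm(stats::as.formula(paste(".y ~", rhs_red)), data = dat)
  rss_full <- sum(stats::residuals(full)^2)
  rss_red <- sum(stats::residuals(red)^2)
  q <- nlevels(group) - 1
  p_par <- length(stats::coef(full))
  df2 <- n - p_par
  Fstat <- ((rss_red - rss_full) / q) / (rss_full / df2)
  pval <- stats::pf(Fstat, q, df2, lower.tail = FALSE)

  # adjusted means at covariate means (factors at their observed proportions)
  newdat <- lapply(dat[cov_terms], function(col) {
    if (is.numeric(col)) mean(col) else col
  })
  grid <- data.frame(.g = factor(levels(group), levels = levels(group)))
  for (v in cov_terms) {
    col <- dat[[v]]
    if (is.numeric(col)) grid[[v]] <- mean(col)
    else grid[[v]] <- factor(levels(as.factor(col))[1],
                             levels = levels(as.factor(col)))
  }
  pr <- stats::predict(full, newdata = grid, se.fit = TRUE)
  tq <- stats::qt(0.975, df2)
  adjusted_means <- data.frame(
    group = levels(group), mean = pr$fit, se = pr$se.fit,
    ci_lo = pr$fit - tq * pr$se.fit, ci_hi = pr$fit + tq * pr$se.fit,
    stringsAsFactors = FALSE)

  res <- structure(list(F = Fstat, df = c(q, df2), p = pval,
                        adjusted_means = adjusted_means,
                        family_size = choose(nlevels(group), 2),
                        fit = full, group_levels = levels(group), n = n),
                   class = "ancova_result")
  res$posthoc <- posthoc_pairwise(res)
  res
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("<ancova_result> F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  invisible(x)
}

#' Bonferroni-corrected pairwise group contrasts
#'
#' t-tests on covariate-adjusted group differences from a fitted ANCOVA,
#' multiplied by the number of group pairs (capped at 1).
#'
#' @param ancova_fit An `ancova_result`.
#' @return Data frame: `group1`, `group2`, `difference`, `se`, `t`, `p_raw`,
#'   `p_bonferroni`.
#' @export
posthoc_pairwise <- function(ancova_fit) {
  fit <- ancova_fit$fit
  lev <- ancova_fit$group_levels
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  # dummy coding: effect of level l relative to reference is coef ".g<l>"
  eff <- stats::setNames(rep(0, length(lev)), lev)
  pos <- stats::setNames(rep(NA_integer_, length(lev)), lev)
  for (l in lev[-1]) {
    nm <- paste0(".g", l)
    eff[l] <- cf[[nm]]
    pos[l] <- which(names(cf) == nm)
  }
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  df2 <- ancova_fit$df[2]
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    difference = NA_real_, se = NA_real_, t = NA_real_,
                    p_raw = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    a <- pairs[1, i]; b <- pairs[2, i]
    ctr <- rep(0, length(cf))
    if (!is.na(pos[a])) ctr[pos[a]] <- 1
    if (!is.na(pos[b])) ctr[pos[b]] <- -1
    d <- eff[a] - eff[b]
    se <- sqrt(drop(t(ctr) %*% V %*% ctr))
    out$difference[i] <- d
    out$se[i] <- se
    out$t[i] <- d / se
    out$p_raw[i] <- 2 * stats::pt(abs(d / se), df2, lower.tail = FALSE)
  }
  out$p_bonferroni <- bonferroni(out$p_raw, m)
  out
}

#' Longitudinal linear mixed model for one tract
#'
#' Random-intercept model per subject with fixed effects
#' `group + time + group:time + covariates`, fitted by REML (lme4).
#' Inference on fixed effects uses the large-sample normal approximation.
#' Per-phenotype time slopes (`time + group:time` contrasts) are reported
#' with their standard errors and p-values.
#'
#' @param data Data frame with one row per subject x timepoint.
#' @param value,subject,group,time Column names (defaults `"value"`,
#'   `"subject"`, `"group"`, `"time_years"`).
#' @param covariates Character vector of additional fixed-effect columns
#'   (default none; typical use: baseline age and sex).
#' @return Object of class `lmm_result`: `fixed` (estimate/SE/z/p),
#'   `slopes` per group, `varcomp` (random-intercept and residual
#'   variances), and the `lme4` fit.
#' @export
lmm_longitudinal <- function(data, value = "value", subject = "subject",
                             group = "group", time = "time_years",
                             covariates = character(0)) {
  d <- data.frame(.y = data[[value]], .subj = data[[subject]],
                  .g = droplevels(as.factor(data[[group]])),
                  .t = data[[time]])
  for (v in covariates) d[[v]] <- data[[v]]
  if (nlevels(d$.g) < 2) stop_invalid("need at least 2 groups")
  if (max(table(d$.subj)) < 2)
    stop_invalid(paste("no subject has repeated measures; the random-intercept",
                       "variance is unidentifiable - fit a cross-sectional model instead"))
  rhs <- paste(c(".g * .t", covariates, "(1 | .subj)"), collapse = " + ")
  fit <- suppressMessages(lme4::lmer(
    stats::as.formula(paste(".y ~", rhs)), data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")))
  fe <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(V))
  z <- fe / se
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  fixed <- data.frame(term = names(fe), estimate = unname(fe), se = se,
                      z = z, p = p, row.names = NULL)

  lev <- levels(d$.g)
  slope_rows <- lapply(lev, function(g) {
    ctr <- stats::setNames(rep(0, length(fe)), names(fe))
    ctr[".t"] <- 1
    inter <- paste0(".g", g, ":.t")
    if (inter %in% names(fe)) ctr[inter] <- 1
    est <- sum(ctr * fe)
    s <- sqrt(drop(t(ctr) %*% V %*% ctr))
    data.frame(group = g, slope = est, se = s, z = est / s,
               p = 2 * stats::pnorm(abs(est / s), lower.tail = FALSE))
  })
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(fixed = fixed, slopes = do.call(rbind, slope_rows),
                 varcomp = c(subject = vc$vcov[vc$grp == ".subj"],
                             residual = vc$vcov[vc$grp == "Residual"]),
                 fit = fit),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat("<lmm_result>\n")
  print(x$slopes, digits = 4)
  invisible(x)
}

#' Group analysis across all tracts
#'
#' Runs [ancova_tract()] for one metric across every tract of a tract metric
#' table at one timepoint, Bonferroni-correcting the tract-level model
#' p-values across the tracts tested (the family). Group membership can be
#' the clinical phenotype or a supplied per-subject label (e.g. cognitive
#' class with HC added). Effect sizes are reported as percent decrease
#' relative to the HC adjusted mean.
#'
#' @param tract_table Output of [tract_metric_table()].
#' @param subjects Cohort `subjects` data frame.
#' @param metric One of `"mean_fd"`, `"mean_logfc"`, `"mean_fdc"`.
#' @param timepoint Timepoint to analyse (default 1).
#' @param group_by Column of `subjects` holding the grouping (default
#'   `"group"`), or a named vector `subject -> label`.
#' @param covariates Covariate column names (default age, sex, head_scale).
#' @param treatment How to enter treatment as confound: `"none"`,
#'   `"binary"` (any treatment vs none) or `"category"`.
#' @return Data frame with one row per tract: F, p, `p_bonferroni`,
#'   family size, per-group adjusted means and percent effects; attribute
#'   `results` holds the full `ancova_result` objects.
#' @export
tract_group_analysis <- function(tract_table, subjects, metric = "mean_fdc",
                                 timepoint = 1L, group_by = "group",
                                 covariates = c("age", "sex", "head_scale"),
                                 treatment = c("none", "binary", "category")) {
  treatment <- match.arg(treatment)
  tt <- tract_table[tract_table$timepoint == timepoint, ]
  sub <- subjects[subjects$timepoint == timepoint, ]
  idx <- match(tt$subject, sub$subject)
  if (is.character(group_by) && length(group_by) == 1) {
    grp <- sub[[group_by]][idx]
  } else {
    grp <- group_by[tt$subject]
  }
  covs <- sub[idx, covariates, drop = FALSE]
  if (treatment == "binary")
    covs$treatment <- as.integer(sub$treatment[idx] != "none")
  if (treatment == "category")
    covs$treatment <- factor(sub$treatment[idx])
  tracts <- unique(tt$tract)
  fam <- length(tracts)
  fits <- list()
  rows <- lapply(tracts, function(tr) {
    sel <- tt$tract == tr
    fit <- ancova_tract(tt[[metric]][sel], grp[sel], covs[sel, , drop = FALSE])
    fits[[tr]] <<- fit
    am <- fit$adjusted_means
    hc <- am$mean[am$group == "HC"]
    eff <- if (length(hc) == 1 && metric != "mean_logfc")
      effect_size_percent(am$mean, hc) else rep(NA_real_, nrow(am))
    row <- data.frame(tract = tr, metric = metric, F = fit$F, p = fit$p,
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(am))) {
      row[[paste0("mean_", am$group[i])]] <- am$mean[i]
      row[[paste0("effect_pct_", am$group[i])]] <- eff[i]
    }
    row
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- bonferroni(out$p, fam)
  out$family_size <- fam
  attr(out, "results") <- fits
  out
}

#' Longitudinal analysis across all tracts
#'
#' Fits [lmm_longitudinal()] per tract for one metric, using both
#' timepoints, with Bonferroni correction of the group x time interaction
#' p-value across tracts.
#'
#' @inheritParams tract_group_analysis
#' @param covariates Fixed-effect covariates (default baseline age and sex).
#' @return Data frame with per-tract interaction p-values and per-group
#'   slopes; attribute `results` holds the `lmm_result` objects.
#' @export
tract_longitudinal_analysis <- function(tract_table, subjects,
                                        metric = "mean_fdc",
                                        covariates = c("age_baseline", "sex")) {
  key <- paste0(tract_table$subject, "|", tract_table$timepoint)
  skey <- paste0(subjects$subject, "|", subjects$timepoint)
  idx <- match(key, skey)
  d0 <- data.frame(subject = tract_table$subject,
                   tract = tract_table$tract,
                   value = tract_table[[metric]],
                   group = subjects$group[idx],
                   time_years = subjects$time_years[idx],
                   sex = subjects$sex[idx],
                   stringsAsFactors = FALSE)
  base_age <- subjects$age[subjects$timepoint == 1L]
  names(base_age) <- subjects$subject[subjects$timepoint == 1L]
  d0$age_baseline <- base_age[d0$subject]
  tracts <- unique(d0$tract)
  fam <- length(tracts)
  fits <- list()
  rows <- lapply(tracts, function(tr) {
    d <- d0[d0$tract == tr, ]
    fit <- lmm_longitudinal(d, covariates = intersect(covariates, names(d)))
    fits[[tr]] <<- fit
    inter <- fit$fixed[grepl(":", fit$fixed$term), ]
    row <- data.frame(tract = tr, metric = metric,
                      p_interaction = min(inter$p),
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(fit$slopes)))
      row[[paste0("slope_", fit$slopes$group[i])]] <- fit$slopes$slope[i]
    row
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- bonferroni(out$p_interaction, fam)
  out$family_size <- fam
  attr(out, "results") <- fits
  out
}
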