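#' Scan subcortical volumes for linear and quadratic associations with SWB
#'
#' For every region x hemisphere volume column, fits the kinship mixed model
#' `swb ~ volume + volume^2 + ICV + sex + age_mri + study` with the
#' genetic-relatedness random effect, the volume entering as a Z-score (and
#' its square) unless `standardize = FALSE`. Each term is tested with a
#' single-coefficient F (Satterthwaite denominator df) and flagged against
#' the Bonferroni alpha for the 14 tests (0.05 / 14 = 0.0036).
#'
#' @param cohort Cohort tibble (see [simulate_cohort()] for the layout).
#' @param regions Character vector of region names (default: every
#'   `volume_<region>_<l|r>` column present).
#' @param outcome Outcome column (default `"swb"`).
#' @param standardize Z-score the volume before forming the terms.
#' @param standardize_icv Z-score the ICV covariate (default `TRUE`).
#' @param alpha Familywise significance level per term (default 0.05/14).
#' @param kinship Optional prebuilt kinship matrix.
#' @param ddf_method Denominator-df method, see [test_fixed_term()].
#' @return Tibble of class `swb_assoc_scan`, one row per region x
#'   hemisphere: `lin_est`, `lin_se`, `lin_df`, `lin_f`, `lin_p`,
#'   `lin_sig`, and the same for `quad_*`.
#' @export
association_scan <- function(cohort, regions = NULL, outcome = "swb",
                             standardize = TRUE, standardize_icv = TRUE,
                             alpha = 0.05 / 14, kinship = NULL,
                             ddf_method = "satterthwaite") {
  vol_cols <- grep("^volume_", names(cohort), value = TRUE)
  if (!is.null(regions)) {
    want <- paste0("volume_", rep(regions, each = 2), "_", c("l", "r"))
    missing_cols <- setdiff(want, names(cohort))
    if (length(missing_cols)) {
      stop("requested region column(s) absent: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    vol_cols <- want
  }
  if (is.null(kinship)) kinship <- build_kinship(cohort)
  # one eigendecomposition serves every region when the data are complete
  used <- c(outcome, vol_cols, "icv", "sex", "age_mri", "study")
  if (!inherits(kinship, "swb_kinship_eigen") &&
      !anyNA(cohort[, intersect(used, names(cohort))])) {
    kinship <- kinship_decompose(kinship)
  }
  rows <- dplyr::bind_rows(lapply(vol_cols, function(vc) {
    fit <- fit_region_model(cohort, vc, outcome = outcome,
                            standardize = standardize,
                            standardize_icv = standardize_icv,
                            kinship = kinship)
    lin <- test_fixed_term(fit, "vol_lin", ddf_method)
    quad <- test_fixed_term(fit, "vol_quad", ddf_method)
    parts <- strsplit(sub("^volume_", "", vc), "_")[[1]]
    tibble::tibble(
      region = paste(parts[-length(parts)], collapse = "_"),
      hemisphere = toupper(parts[length(parts)]),
      lin_est = lin$estimate, lin_se = lin$std.error, lin_df = lin$df,
      lin_f = lin$statistic, lin_p = lin$p.value,
      quad_est = quad$estimate, quad_se = quad$std.error, quad_df = quad$df,
      quad_f = quad$statistic, quad_p = quad$p.value
    )
  }))
  rows$lin_sig <- rows$lin_p < alpha
  rows$quad_sig <- rows$quad_p < alpha
  attr(rows, "alpha") <- alpha
  class(rows) <- c("swb_assoc_scan", class(rows))
  rows
}

# shared design construction for the region models
region_model_frame <- function(cohort, vol_col, outcome, standardize,
                               standardize_icv, extra = character(0),
                               drop_quadratic = FALSE) {
  needed <- c(outcome, vol_col, "icv", "sex", "age_mri", "study", extra)
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols)) {
    stop("missing covariate column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  v <- cohort[[vol_col]]
  if (standardize) v <- zscore(v)
  df <- tibble::tibble(
    .outcome = cohort[[outcome]],
    vol_lin = v,
    vol_quad = v^2,
    icv_cov = if (standardize_icv) zscore(cohort$icv) else cohort$icv,
    sex = factor(cohort$sex),
    age_mri = cohort$age_mri,
    study = stats::relevel(factor(cohort$study),
                           ref = as.character(max(cohort$study)))
  )
  for (e in extra) df[[e]] <- cohort[[e]]
  if (drop_quadratic) df$vol_quad <- NULL
  df
}

fit_region_model <- function(cohort, vol_col, outcome = "swb",
                             standardize = TRUE, standardize_icv = TRUE,
                             kinship = NULL, extra = character(0),
                             drop_quadratic = FALSE, interactions = FALSE) {
  df <- region_model_frame(cohort, vol_col, outcome, standardize,
                           standardize_icv, extra, drop_quadratic)
  rhs <- c(if ("vol_lin" %in% names(df)) "vol_lin",
           if ("vol_quad" %in% names(df)) "vol_quad",
           "icv_cov", "sex", "age_mri", "study", extra)
  if (interactions) rhs <- c(rhs, "study:vol_lin", "study:vol_quad")
  fml <- stats::reformulate(rhs, response = ".outcome")
  if (is.null(kinship)) kinship <- build_kinship(cohort)
  fit_kinship_lmm(df, fml, kinship = kinship)
}

#' Post-hoc robustness battery for a region association
#'
#' Refits the region model under one of the documented modifications:
#' alternative outcomes (`outcome_sat`, `outcome_hap`), dropping the
#' quadratic term (`drop_quadratic`), unstandardized volumes
#' (`raw_volumes`), extra covariates (`add_age_swb`, `add_symptom_score`),
#' or study-by-volume interactions (`study_interactions`). The interaction
#' variant returns omnibus F tests of the 4 study-by-linear and 4
#' study-by-quadratic contrasts (alpha 0.05/4 = 0.0125) plus the individual
#' contrasts against reference study 5 (alpha 0.05).
#'
#' @param cohort Cohort tibble.
#' @param region Region name (default `"hippocampus"`).
#' @param variant One of the modification names above.
#' @param kinship Optional prebuilt kinship matrix.
#' @return For refit variants, a tibble shaped like one scan row per
#'   hemisphere. For `study_interactions`, a tibble of omnibus and contrast
#'   tests with their alphas.
#' @export
posthoc_battery <- function(cohort, region = "hippocampus",
                            variant = c("outcome_sat", "outcome_hap",
                                        "drop_quadratic", "raw_volumes",
                                        "add_age_swb", "add_symptom_score",
                                        "study_interactions"),
                            kinship = NULL) {
  variant <- match.arg(variant)
  if (is.null(kinship)) kinship <- build_kinship(cohort)
  cols <- paste0("volume_", region, "_", c("l", "r"))
  if (variant == "study_interactions") {
    return(dplyr::bind_rows(lapply(cols, function(vc) {
      fit <- fit_region_model(cohort, vc, kinship = kinship, interactions = TRUE)
      hemi <- toupper(sub(".*_", "", vc))
      nm <- fit$coef_names
      int_lin <- grep(":vol_lin$|^vol_lin:", nm, value = TRUE)
      int_quad <- grep(":vol_quad$|^vol_quad:", nm, value = TRUE)
      omni <- function(terms, label) {
        res <- test_fixed_term(fit, terms)
        tibble::tibble(hemisphere = hemi, test = paste0("omnibus_", label),
                       contrast = NA_character_, statistic = res$statistic,
                       df = res$df, p.value = res$p.value, alpha = 0.05 / 4)
      }
      contrasts <- function(terms, label) {
        purrr::map_dfr(terms, function(tm) {
          res <- test_fixed_term(fit, tm)
          tibble::tibble(hemisphere = hemi, test = paste0("contrast_", label),
                         contrast = tm, statistic = res$statistic,
                         df = res$df, p.value = res$p.value, alpha = 0.05)
        })
      }
      dplyr::bind_rows(omni(int_lin, "linear"), omni(int_quad, "quadratic"),
                       contrasts(int_lin, "linear"), contrasts(int_quad, "quadratic"))
    })))
  }
  spec <- switch(variant,
    outcome_sat = list(outcome = "sat"),
    outcome_hap = list(outcome = "hap"),
    drop_quadratic = list(drop_quadratic = TRUE),
    raw_volumes = list(standardize = FALSE),
    add_age_swb = list(extra = "age_swb"),
    add_symptom_score = list(extra = "symptom_class")
  )
  dplyr::bind_rows(lapply(cols, function(vc) {
    fit <- do.call(fit_region_model,
                   c(list(cohort = cohort, vol_col = vc, kinship = kinship), spec))
    parts <- strsplit(sub("^volume_", "", vc), "_")[[1]]
    lin <- test_fixed_term(fit, "vol_lin")
    out <- tibble::tibble(
      variant = variant,
      region = paste(parts[-length(parts)], collapse = "_"),
      hemisphere = toupper(parts[length(parts)]),
      lin_est = lin$estimate, lin_se = lin$std.error, lin_df = lin$df,
      lin_f = lin$statistic, lin_p = lin$p.value
    )
    if ("vol_quad" %in% fit$coef_names) {
      quad <- test_fixed_term(fit, "vol_quad")
      out$quad_est <- quad$estimate; out$quad_se <- quad$std.error
      out$quad_df <- quad$df; out$quad_f <- quad$statistic
      out$quad_p <- quad$p.value
    }
    out
  }))
}

#' Mean SWB within low / medium / high volume strata
#'
#' Partitions the sample by the Z-scored volume into low (Z <= -0.5),
#' medium (-0.5 < Z < 0.5) and high (Z >= 0.5) strata -- outer strata closed
#' at the cutoffs -- and summarizes the outcome within each.
#'
#' @param cohort Cohort tibble.
#' @param region Region whose volume defines the strata.
#' @param hemisphere `"both"` (mean of left and right, default), `"l"`, `"r"`.
#' @param outcome Outcome column (default `"swb"`).
#' @return Tibble with `stratum` (`low`, `medium`, `high`), `n`, `mean`,
#'   `sd`; empty strata keep `n = 0` with `NA` moments.
#' @export
swb_by_volume_strata <- function(cohort, region = "hippocampus",
                                 hemisphere = c("both", "l", "r"),
                                 outcome = "swb", standardize = TRUE) {
  hemisphere <- match.arg(hemisphere)
  cols <- paste0("volume_", region, "_",
                 if (hemisphere == "both") c("l", "r") else hemisphere)
  v <- rowMeans(cohort[, cols, drop = FALSE])
  z <- if (standardize) zscore(v) else v
  stratum <- factor(dplyr::case_when(z <= -0.5 ~ "low",
                                     z >= 0.5 ~ "high",
                                     TRUE ~ "medium"),
                    levels = c("low", "medium", "high"))
  y <- cohort[[outcome]]
  purrr::map_dfr(levels(stratum), function(s) {
    yi <- y[stratum == s]
    tibble::tibble(stratum = s, n = length(yi),
                   mean = if (length(yi)) mean(yi) else NA_real_,
                   sd = if (length(yi) > 1) stats::sd(yi) else NA_real_)
  })
}

#' One-way two-group ANOVA from summary statistics
#'
#' Reconstructs the classical one-way F test from group sizes, means and
#' standard deviations: between-group sum of squares about the weighted
#' grand mean over the pooled within-group mean square, with
#' `n1 + n2 - 2` denominator degrees of freedom.
#'
#' @param n1,m1,s1 Size, mean, SD of group 1 (`n1 >= 2`, `s1 > 0`).
#' @param n2,m2,s2 Size, mean, SD of group 2.
#' @return Tibble with `statistic` (F), `df1`, `df2`, `p.value`.
#' @export
#' @examples
#' two_group_anova_from_summary(23, 21.5, 4.7, 35, 27.2, 2.2)
two_group_anova_from_summary <- function(n1, m1, s1, n2, m2, s2) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2", call. = FALSE)
  if (s1 <= 0 || s2 <= 0) stop("standard deviations must be positive", call. = FALSE)
  grand <- (n1 * m1 + n2 * m2) / (n1 + n2)
  ssb <- n1 * (m1 - grand)^2 + n2 * (m2 - grand)^2
  ssw <- (n1 - 1) * s1^2 + (n2 - 1) * s2^2
  df2 <- n1 + n2 - 2
  F_ <- ssb / (ssw / df2)
  tibble::tibble(statistic = F_, df1 = 1, df2 = df2,
                 p.value = stats::pf(F_, 1, df2, lower.tail = FALSE))
}
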