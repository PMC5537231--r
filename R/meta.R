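#' Fixed-effect inverse-variance (WLS) pooling of study estimates
#'
#' Pools per-study regression estimates with weights `w_i = 1 / SE_i^2`:
#' pooled estimate `sum(w * est) / sum(w)`, pooled SE `1 / sqrt(sum(w))`.
#' The primary p-value is two-tailed normal on `z = est / SE`; a secondary
#' `p_t` from a t distribution on `k - 1` df is also reported, since the
#' two reference distributions differ noticeably with few studies.
#'
#' @param data Data frame with columns `estimate` and `se` (one row per
#'   study), or a numeric vector of estimates if `se` is given separately.
#' @param se Standard errors when `data` is a bare numeric vector.
#' @return Tibble with `estimate`, `se`, `z`, `p.value` (normal),
#'   `p_t` (t on k-1 df), `k`.
#' @export
#' @examples
#' pool_fixed(data.frame(estimate = c(0.135, 0.252, -0.006, -0.037, 0.058),
#'                       se = c(0.275, 0.081, 0.195, 0.107, 0.080)))
pool_fixed <- function(data, se = NULL) {
  if (is.numeric(data) && !is.null(se)) {
    data <- tibble::tibble(estimate = data, se = se)
  }
  if (!all(c("estimate", "se") %in% names(data))) {
    stop("`data` needs columns `estimate` and `se`", call. = FALSE)
  }
  if (nrow(data) < 1) stop("at least one study required", call. = FALSE)
  if (any(!is.finite(data$se)) || any(data$se <= 0)) {
    stop("standard errors must be finite and positive", call. = FALSE)
  }
  w <- 1 / data$se^2
  est <- sum(w * data$estimate) / sum(w)
  se_p <- 1 / sqrt(sum(w))
  z <- est / se_p
  k <- nrow(data)
  tibble::tibble(
    estimate = est, se = se_p, z = z,
    p.value = 2 * stats::pnorm(-abs(z)),
    p_t = 2 * stats::pt(-abs(z), df = max(k - 1, 1)),
    k = k
  )
}

#' Per-study region model fits for meta-analysis
#'
#' Runs the region association model (without the study factor) separately
#' within each study subset and returns the linear and quadratic volume-term
#' estimates per hemisphere, ready for [pool_fixed()].
#'
#' @param cohort Cohort tibble.
#' @param region Region name (default `"hippocampus"`).
#' @param standardize Z-score volumes within the full cohort before
#'   subsetting (matching the pooled-sample transform).
#' @return Tibble with `study`, `hemisphere`, `term` (`linear`/`quadratic`),
#'   `estimate`, `se`, `df`, `statistic`, `p.value`.
#' @export
per_study_fits <- function(cohort, region = "hippocampus", standardize = TRUE) {
  cols <- paste0("volume_", region, "_", c("l", "r"))
  z <- cohort
  if (standardize) for (vc in cols) z[[vc]] <- zscore(z[[vc]])
  dplyr::bind_rows(lapply(sort(unique(z$study)), function(s) {
    sub <- z[z$study == s, , drop = FALSE]
    K <- build_kinship(sub)
    dplyr::bind_rows(lapply(cols, function(vc) {
      df <- tibble::tibble(
        .outcome = sub$swb,
        vol_lin = sub[[vc]], vol_quad = sub[[vc]]^2,
        icv_cov = as.numeric(scale(sub$icv)),
        sex = factor(sub$sex), age_mri = sub$age_mri
      )
      rhs <- c("vol_lin", "vol_quad", "icv_cov",
               if (nlevels(df$sex) > 1) "sex", "age_mri")
      fit <- tryCatch(
        fit_kinship_lmm(df, stats::reformulate(rhs, ".outcome"), kinship = K),
        error = function(e) stop("study ", s, ": ", conditionMessage(e),
                                 call. = FALSE)
      )
      purrr::map_dfr(c(linear = "vol_lin", quadratic = "vol_quad"),
                     function(tm) test_fixed_term(fit, tm),
                     .id = "term") |>
        dplyr::transmute(study = s,
                         hemisphere = toupper(sub(".*_", "", vc)),
                         term = .data$term, estimate = .data$estimate,
                         se = .data$std.error, df = .data$df,
                         statistic = .data$statistic, p.value = .data$p.value)
    }))
  }))
}

#' Pool per-study fits into a meta-analytic table
#'
#' Convenience wrapper: runs [per_study_fits()] and appends the
#' [pool_fixed()] row per hemisphere x term, mirroring a per-study estimate
#' table with a final pooled row.
#'
#' @inheritParams per_study_fits
#' @return Tibble with the per-study rows plus `study = "Pooled"` rows.
#' @export
meta_table <- function(cohort, region = "hippocampus") {
  fits <- per_study_fits(cohort, region)
  pooled <- fits |>
    dplyr::group_by(.data$hemisphere, .data$term) |>
    dplyr::group_modify(~ {
      p <- pool_fixed(.x)
      tibble::tibble(study = "Pooled", estimate = p$estimate, se = p$se,
                     df = nrow(.x) - 1, statistic = p$z, p.value = p$p.value)
    }) |>
    dplyr::ungroup()
  dplyr::bind_rows(dplyr::mutate(fits, study = as.character(.data$study)), pooled)
}
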