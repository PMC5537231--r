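#' First-stage instrument strength in a kinship mixed model
#'
#' Regresses the exposure on the polygenic-score instrument plus covariates
#' with the genetic-relatedness random effect and returns the
#' single-coefficient F test of the instrument. Conventionally F < 10 flags
#' a weak instrument.
#'
#' @param data Data frame (typically the DNA subsample of a cohort).
#' @param exposure,instrument Column names.
#' @param covariates Character vector of covariate column names; `"study"`
#'   and `"sex"` enter as factors.
#' @param kinship Optional prebuilt kinship matrix over `data` rows.
#' @return Tibble with `statistic` (F), `df`, `p.value`, `weak` flag.
#' @export
instrument_strength <- function(data, exposure, instrument,
                                covariates = character(0), kinship = NULL) {
  if (stats::sd(data[[instrument]], na.rm = TRUE) == 0) {
    stop("instrument `", instrument, "` has zero variance", call. = FALSE)
  }
  fit <- stage_lmm(data, exposure, c(instrument, covariates), kinship)
  res <- test_fixed_term(fit, instrument)
  tibble::tibble(statistic = res$statistic, df = res$df,
                 p.value = res$p.value, weak = res$statistic < 10)
}

stage_lmm <- function(data, lhs, rhs_cols, kinship) {
  df <- tibble::tibble(.y = data[[lhs]])
  rhs <- character(0)
  for (v in rhs_cols) {
    df[[v]] <- if (v %in% c("study", "sex")) factor(data[[v]]) else data[[v]]
    rhs <- c(rhs, v)
  }
  if (!length(rhs)) rhs <- "1"
  if (is.null(kinship)) kinship <- build_kinship(data)
  tryCatch(
    fit_kinship_lmm(df, stats::reformulate(rhs, ".y"), kinship = kinship),
    error = function(e) {
      if (grepl("rank deficient", conditionMessage(e))) {
        stop("instrument or covariates collinear: ", conditionMessage(e),
             call. = FALSE)
      }
      stop(e)
    }
  )
}

#' Assign equal-sized strata by residual order
#'
#' Codes each observation 1..k by contiguous blocks of the sorted residuals
#' (empirical tertiles for k = 3). When n is not a multiple of k, the
#' lower strata take the extra members (sizes differ by at most one). Ties
#' are broken by stable input order.
#'
#' @param residuals Numeric vector (first-stage residual "environmental"
#'   variance components).
#' @param k Number of strata (default 3; `2 <= k <= n`).
#' @return Integer vector of stratum codes 1..k.
#' @export
#' @examples
#' residual_strata(9:1)
residual_strata <- function(residuals, k = 3) {
  n <- length(residuals)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (n < k) stop("need at least k observations", call. = FALSE)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  rk <- rank(residuals, ties.method = "first")
  rep(seq_len(k), times = sizes)[rk]
}

#' Two-stage least-squares Mendelian randomization with residual strata
#'
#' Stage 1 regresses the exposure on the instrument plus covariates in a
#' kinship mixed model; stage 2 regresses the outcome on the fitted
#' (genetically predicted) exposure, the covariates, a stratum main effect
#' and a fitted-exposure-by-stratum interaction, where strata are
#' equal-sized groups of the stage-1 residual "environmental" variance.
#' The stratum terms probe for nonlinearity of the causal relation; set
#' `n_strata = 0` for the plain 2SLS second stage.
#'
#' Naive second-stage standard errors understate the uncertainty of the
#' causal estimate because the fitted exposure is itself estimated; the
#' corrected SE rescales by the residual variance recomputed with the
#' observed exposure at the second-stage coefficients, and is the default
#' basis for `estimate_se`.
#'
#' @param data Data frame.
#' @param outcome,exposure,instrument Column names.
#' @param covariates Covariate column names included in both stages.
#' @param kinship Optional prebuilt kinship matrix.
#' @param n_strata Number of residual strata (default 3; 0 disables).
#' @return A list of class `swb_2sls`: `direction`, `stage1` (instrument F
#'   tibble), `causal` (estimate, naive and corrected SE, F, df, p),
#'   `interaction` (omnibus F of the interaction contrasts, or NULL),
#'   and the two stage fits.
#' @export
two_sls <- function(data, outcome, exposure, instrument,
                    covariates = character(0), kinship = NULL, n_strata = 3) {
  if (is.null(kinship)) kinship <- build_kinship(data)
  s1 <- stage_lmm(data, exposure, c(instrument, covariates), kinship)
  inst_test <- test_fixed_term(s1, instrument)
  d2 <- data
  d2$.xhat <- s1$fitted
  rhs <- c(".xhat", covariates)
  if (n_strata >= 2) {
    d2$.stratum <- factor(residual_strata(s1$residuals, n_strata))
    rhs <- c(rhs, ".stratum", ".xhat:.stratum")
  }
  s2 <- stage_lmm2(d2, outcome, rhs, kinship)
  causal <- test_fixed_term(s2, ".xhat")
  # sandwich-style correction: residual variance with the observed exposure
  beta <- s2$beta
  X <- s2$model_X
  Xc <- X
  xhat_cols <- grep("^\\.xhat", colnames(X))
  ratio <- data[[exposure]][s2$keep] / d2$.xhat[s2$keep]
  ratio[!is.finite(ratio)] <- 1
  for (j in xhat_cols) {
    Xc[, j] <- Xc[, j] * ratio
  }
  r_corr <- d2[[outcome]][s2$keep] - drop(Xc %*% beta)
  r_naive <- s2$residuals
  infl <- sqrt(sum(r_corr^2) / sum(r_naive^2))
  est_se_naive <- causal$std.error
  est_se <- est_se_naive * infl
  interaction <- NULL
  if (n_strata >= 2) {
    int_terms <- grep("^\\.xhat:", s2$coef_names, value = TRUE)
    it <- test_fixed_term(s2, int_terms)
    interaction <- tibble::tibble(statistic = it$statistic, df = it$df,
                                  p.value = it$p.value)
  }
  structure(list(
    direction = paste(exposure, "on", outcome),
    stage1 = inst_test,
    causal = tibble::tibble(
      estimate = causal$estimate, se = est_se, se_naive = est_se_naive,
      statistic = causal$statistic, df = causal$df, p.value = causal$p.value
    ),
    interaction = interaction,
    stage1_fit = s1, stage2_fit = s2
  ), class = "swb_2sls")
}

# stage-2 variant of stage_lmm that keeps the raw design available and
# accepts interaction terms in rhs
stage_lmm2 <- function(data, lhs, rhs, kinship) {
  df <- tibble::tibble(.y = data[[lhs]])
  vars <- unique(unlist(strsplit(rhs, ":", fixed = TRUE)))
  for (v in vars) {
    df[[v]] <- if (v %in% c("study", "sex")) factor(data[[v]]) else data[[v]]
  }
  fml <- stats::reformulate(rhs, ".y")
  fit <- fit_kinship_lmm(df, fml, kinship = kinship)
  mf <- stats::model.frame(fml, df, na.action = stats::na.pass)
  mf <- mf[fit$keep, , drop = FALSE]
  fit$model_X <- stats::model.matrix(stats::terms(mf), mf)
  fit
}

#' Bidirectional Mendelian randomization for a region
#'
#' Runs [two_sls()] in both causal directions (well-being on volume, volume
#' on well-being) for the left and right hemisphere, using the SWB and
#' region polygenic scores as instruments, on the DNA-available subsample,
#' with sex, age at MRI, study and the nuisance principal components as
#' covariates in both stages.
#'
#' @param cohort Cohort tibble.
#' @param region Region name with `pgs_<region-short>_l/r` score columns
#'   (default `"hippocampus"`, scores `pgs_hip_l`, `pgs_hip_r`).
#' @param use_dna_only Restrict to `dna_available` persons (default).
#' @param n_strata Residual strata passed to [two_sls()].
#' @return Tibble of class `swb_mr_table`: one row per direction x
#'   hemisphere with first-stage and second-stage F / df / p, the causal
#'   estimate and corrected SE, and the stratum-interaction test.
#' @export
bidirectional_mr <- function(cohort, region = "hippocampus",
                             use_dna_only = TRUE, n_strata = 3) {
  short <- if (region == "hippocampus") "hip" else region
  needed <- c("pgs_swb", paste0("pgs_", short, "_", c("l", "r")))
  miss <- setdiff(needed, names(cohort))
  if (length(miss)) {
    stop("missing polygenic-score column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d <- if (use_dna_only && "dna_available" %in% names(cohort)) {
    cohort[cohort$dna_available, , drop = FALSE]
  } else cohort
  pcs <- grep("^pc_", names(d), value = TRUE)
  covs <- c("sex", "age_mri", if (length(unique(d$study)) > 1) "study", pcs)
  K <- build_kinship(d)
  cells <- tidyr::expand_grid(direction = c("swb_on_volume", "volume_on_swb"),
                              hemisphere = c("L", "R"))
  purrr::pmap_dfr(cells, function(direction, hemisphere) {
    vol_col <- paste0("volume_", region, "_", tolower(hemisphere))
    d$.vol_z <- zscore(d[[vol_col]])
    pgs_vol <- paste0("pgs_", short, "_", tolower(hemisphere))
    if (direction == "swb_on_volume") {
      res <- two_sls(d, outcome = vol_col, exposure = "swb",
                     instrument = "pgs_swb", covariates = covs,
                     kinship = K, n_strata = n_strata)
    } else {
      res <- two_sls(d, outcome = "swb", exposure = vol_col,
                     instrument = pgs_vol, covariates = covs,
                     kinship = K, n_strata = n_strata)
    }
    tibble::tibble(
      direction = direction, hemisphere = hemisphere,
      stage1_f = res$stage1$statistic, stage1_df = res$stage1$df,
      stage1_p = res$stage1$p.value,
      estimate = res$causal$estimate, se = res$causal$se,
      causal_f = res$causal$statistic, causal_df = res$causal$df,
      causal_p = res$causal$p.value,
      interaction_f = res$interaction$statistic %||% NA_real_,
      interaction_df = res$interaction$df %||% NA_real_,
      interaction_p = res$interaction$p.value %||% NA_real_
    )
  })
}
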