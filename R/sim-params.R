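#' Simulation parameters for the synthetic twin-family cohort
#'
#' Builds and validates the parameter set consumed by [simulate_cohort()].
#' Defaults reproduce a five-study twin-family design of 724 persons
#' (302 male / 422 female) composed of MZ and DZ twin pairs, single twins and
#' additional full siblings, with study-specific age distributions,
#' subcortical volume scales, additive heritabilities, a planted concave
#' relation between hippocampal volume and subjective well-being (SWB), and
#' polygenic scores with weak-instrument-scale predictive power.
#'
#' @param composition Tibble with columns `study`, `mz_pair`, `dz_pair`,
#'   `mz_single`, `dz_single`, `sib` giving family-type counts per study.
#'   `NULL` uses the default five-study composition; supply
#'   `n_families_per_study` instead for a generic stochastic composition.
#' @param n_families_per_study Integer vector (one per study) used only when
#'   `composition` is `NULL` at call time and a generic design is wanted.
#' @param mz_fraction Probability a generic family is an MZ pair.
#' @param sib_count_distribution Probabilities of 0, 1, 2 extra siblings per
#'   generic family.
#' @param h2_targets Named list of additive heritabilities in `[0, 1]`:
#'   `swb`, `hip_l`, `hip_r`, `vol_other`, `icv`.
#' @param d2_targets Named list of dominance variance proportions (default all
#'   zero; `h2 + d2 <= 1` per trait is enforced).
#' @param rg_swb_vol,re_swb_vol Genetic / unshared-environmental correlation
#'   between SWB and hippocampal volume, each in `[-1, 1]`.
#' @param rg_lr,re_lr Genetic / environmental correlation between left and
#'   right hippocampal volume.
#' @param lin_beta,quad_beta Linear and quadratic effect of the standardized
#'   hippocampal volume on SWB, in SWB scale units (per SD and per SD^2).
#'   A negative `quad_beta` plants the concave relation.
#' @param swb_mean,swb_sd Mean and SD of the SWB composite (SAT-scale units).
#' @param sat_hap_disc SD of the SAT-vs-HAP discrepancy component; controls
#'   the SAT-HAP correlation (default gives about 0.75).
#' @param vol_means,vol_sds Named numeric vectors (mm^3) over the seven
#'   regions `caudate, putamen, pallidum, thalamus, hippocampus, amygdala,
#'   accumbens`.
#' @param icv_mean,icv_sd Intracranial volume mean and SD (mm^3).
#' @param age_table Tibble of per-study age distributions (means, SDs, ranges
#'   for age at SWB assessment and age at MRI, and their target correlation).
#' @param sex_table Tibble with per-study male/female counts.
#' @param sex_effect_swb,sex_effect_vol Additive male-minus-female shifts on
#'   SWB (scale units) and on volumes (SD units); default 0 (no sex effect).
#' @param pgs_r2_exposure Named list: variance fraction of each exposure
#'   explained by its polygenic-score instrument (`swb`, `hip`).
#' @param n_dna Number of persons with DNA available (MR subsample size).
#' @param selection_spec Tibble with columns `study`, `cor`, `prop_high`,
#'   `prop_low` driving [apply_symptom_selection()]; `cor` is the latent
#'   symptom-SWB correlation, the proportions are the quantile cut masses.
#' @param n_pc_covariates Number of nuisance principal-component columns.
#' @param include_triplet Label the sibling attached to one study-5 MZ-pair
#'   family as a DZ co-sibling triplet member (kinship identical either way).
#' @param seed Integer seed; every stochastic operation draws from one stream
#'   seeded here unless overridden at call time.
#'
#' @return A validated list of class `swb_sim_params`.
#' @export
#' @examples
#' p <- sim_params(seed = 1)
#' sum(default_composition()$mz_pair) * 2
sim_params <- function(composition = default_composition(),
                       n_families_per_study = NULL,
                       mz_fraction = 0.5,
                       sib_count_distribution = c(0.6, 0.3, 0.1),
                       h2_targets = list(swb = 0.44, hip_l = 0.76, hip_r = 0.79,
                                         vol_other = 0.8, icv = 0.8),
                       d2_targets = list(swb = 0, hip_l = 0, hip_r = 0,
                                         vol_other = 0, icv = 0),
                       rg_swb_vol = 0.07,
                       re_swb_vol = 0.18,
                       rg_lr = 0.95,
                       re_lr = 0.30,
                       lin_beta = 0.75,
                       quad_beta = -0.33,
                       swb_mean = 24.9,
                       swb_sd = 4.1,
                       sat_hap_disc = 1.55,
                       vol_means = c(caudate = 3700, putamen = 5600,
                                     pallidum = 1800, thalamus = 7600,
                                     hippocampus = 4200, amygdala = 1650,
                                     accumbens = 620),
                       vol_sds = c(caudate = 450, putamen = 600,
                                   pallidum = 250, thalamus = 750,
                                   hippocampus = 400, amygdala = 230,
                                   accumbens = 110),
                       icv_mean = 1.5e6,
                       icv_sd = 1.5e5,
                       age_table = default_age_table(),
                       sex_table = default_sex_table(),
                       sex_effect_swb = 0,
                       sex_effect_vol = 0,
                       pgs_r2_exposure = list(swb = 0.009, hip = 0.017),
                       n_dna = 636,
                       selection_spec = default_selection_spec(),
                       n_pc_covariates = 11,
                       include_triplet = FALSE,
                       seed = 1L) {
  if (is.null(composition)) {
    if (is.null(n_families_per_study)) {
      stop("supply either `composition` or `n_families_per_study`",
           call. = FALSE)
    }
  }
  params <- list(
    composition = composition,
    n_families_per_study = n_families_per_study,
    mz_fraction = mz_fraction,
    sib_count_distribution = sib_count_distribution,
    h2_targets = h2_targets,
    d2_targets = d2_targets,
    rg_swb_vol = rg_swb_vol, re_swb_vol = re_swb_vol,
    rg_lr = rg_lr, re_lr = re_lr,
    lin_beta = lin_beta, quad_beta = quad_beta,
    swb_mean = swb_mean, swb_sd = swb_sd, sat_hap_disc = sat_hap_disc,
    vol_means = vol_means, vol_sds = vol_sds,
    icv_mean = icv_mean, icv_sd = icv_sd,
    age_table = age_table, sex_table = sex_table,
    sex_effect_swb = sex_effect_swb, sex_effect_vol = sex_effect_vol,
    pgs_r2_exposure = pgs_r2_exposure,
    n_dna = n_dna,
    selection_spec = selection_spec,
    n_pc_covariates = n_pc_covariates,
    include_triplet = include_triplet,
    seed = as.integer(seed)
  )
  validate_sim_params(params)
  structure(params, class = "swb_sim_params")
}

#' Default per-study family composition
#'
#' Family-type counts for the five MRI studies: complete MZ pairs, complete
#' DZ pairs, single MZ twins, single DZ twins, and extra full siblings
#' attached round-robin to twin-pair families. Totals per study are 58, 244,
#' 58, 130 and 234 persons (724 overall). The study-5 count of 37 MZ-pair
#' families includes one family carrying an attached co-sibling.
#'
#' @return Tibble with one row per study.
#' @export
default_composition <- function() {
  tibble::tibble(
    study = 1:5,
    mz_pair   = c(26L, 69L, 24L, 15L, 37L),
    dz_pair   = c(1L, 45L, 2L, 30L, 45L),
    mz_single = c(3L, 6L, 6L, 8L, 0L),
    dz_single = c(1L, 4L, 0L, 11L, 9L),
    sib       = c(0L, 6L, 0L, 21L, 61L)
  )
}

#' @rdname default_composition
#' @export
default_sex_table <- function() {
  tibble::tibble(study = 1:5,
                 male = c(20L, 92L, 22L, 64L, 104L),
                 female = c(38L, 152L, 36L, 66L, 130L))
}

#' @rdname default_composition
#' @export
default_age_table <- function() {
  tibble::tibble(
    study = 1:5,
    swb_mean = c(18.1, 31.3, 32.6, 37.6, 17.2),
    swb_sd   = c(2.1, 10.5, 6.4, 7.3, 1.5),
    swb_min  = c(14.5, 16.5, 22.6, 25.0, 14.8),
    swb_max  = c(27.0, 57.5, 45.3, 67.2, 22.3),
    mri_mean = c(14.7, 34.0, 30.0, 28.7, 10.0),
    mri_sd   = c(1.5, 10.2, 5.9, 6.5, 1.3),
    mri_min  = c(11.0, 19.0, 20.0, 19.1, 9.0),
    mri_max  = c(18.0, 57.0, 42.0, 55.9, 15.0),
    age_cor  = c(0.59, 0.98, 0.94, 0.93, 0.91)
  )
}

#' @rdname default_composition
#' @export
default_selection_spec <- function() {
  tibble::tibble(
    study = 1:3,
    cor = -0.6,
    prop_high = c(23 / 58, 75 / 244, 23 / 58),
    prop_low = c(35 / 58, 167 / 244, 35 / 58)
  )
}

validate_sim_params <- function(p) {
  frac_in_01 <- function(x) all(is.finite(x)) && all(x >= 0) && all(x <= 1)
  for (nm in names(p$h2_targets)) {
    h2 <- p$h2_targets[[nm]]
    d2 <- if (nm %in% names(p$d2_targets)) p$d2_targets[[nm]] else 0
    if (!frac_in_01(h2)) stop("h2_targets$", nm, " must lie in [0, 1]", call. = FALSE)
    if (!frac_in_01(d2)) stop("d2_targets$", nm, " must lie in [0, 1]", call. = FALSE)
    if (h2 + d2 > 1) stop("h2_targets$", nm, " + d2_targets$", nm, " exceeds 1", call. = FALSE)
  }
  for (nm in c("rg_swb_vol", "re_swb_vol", "rg_lr", "re_lr")) {
    if (abs(p[[nm]]) > 1) stop(nm, " must lie in [-1, 1]", call. = FALSE)
  }
  if (!frac_in_01(unlist(p$pgs_r2_exposure))) {
    stop("pgs_r2_exposure entries must lie in [0, 1]", call. = FALSE)
  }
  if (p$swb_sd <= 0) stop("swb_sd must be positive", call. = FALSE)
  if (any(p$vol_sds <= 0) || any(p$vol_means <= 0)) {
    stop("vol_means and vol_sds must be positive", call. = FALSE)
  }
  if (abs(sum(p$sib_count_distribution) - 1) > 1e-8 ||
      any(p$sib_count_distribution < 0)) {
    stop("sib_count_distribution must be nonnegative and sum to 1", call. = FALSE)
  }
  # generating correlation matrices must be PSD, checked at construction
  for (mat in c("genetic", "environmental")) {
    R <- if (mat == "genetic") {
      corr3(p$rg_swb_vol, p$rg_lr)
    } else {
      corr3(p$re_swb_vol, p$re_lr)
    }
    ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-10) {
      stop("correlation parameters (", mat,
           ") do not form a positive-semidefinite matrix", call. = FALSE)
    }
  }
  invisible(p)
}

# 3x3 correlation over (swb, vol_left, vol_right)
corr3 <- function(r_swb_vol, r_lr) {
  matrix(c(1, r_swb_vol, r_swb_vol,
           r_swb_vol, 1, r_lr,
           r_swb_vol, r_lr, 1), 3, 3)
}
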