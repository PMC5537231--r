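#' Simulate a twin-family cohort
#'
#' Generates one row per person for a multi-study twin-family design: MZ and
#' DZ twin pairs, single twins and extra full siblings, with study-specific
#' age distributions, sex counts, intracranial and subcortical volumes
#' (seven regions, both hemispheres), a subjective well-being composite (SWB,
#' the mean of a satisfaction-with-life score and a rescaled happiness
#' score), polygenic-score columns, nuisance principal-component covariates,
#' and a DNA-availability flag.
#'
#' Latent additive genetic values are shared with correlation 1 within MZ
#' pairs and 0.5 within DZ pairs and sibling dyads; unshared environmental
#' values are independent across persons. SWB is built as
#' `lin_beta * Zvol + quad_beta * (Zvol^2 - 1)` plus genetic and
#' environmental components scaled to the requested heritability and total
#' variance, where `Zvol` is the standardized mean hippocampal volume, so a
#' negative `quad_beta` plants a concave volume-SWB relation.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed (defaults to `params$seed`). The same seed
#'   reproduces the table exactly.
#' @return A tibble (`CohortTable`): `person_id`, `family_id`,
#'   `zygosity_role` (`MZ1`, `MZ2`, `DZ1`, `DZ2`, `SIB`), `study`, `sex`,
#'   `age_mri`, `age_swb`, `sat`, `hap`, `swb`, `icv`,
#'   `volume_<region>_<l|r>` for the seven regions, `pgs_swb`, `pgs_hip_l`,
#'   `pgs_hip_r`, `dna_available`, `symptom_class`, `pc_1` ... `pc_k`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_params(seed = 7))
#' dplyr::count(cohort, study)
simulate_cohort <- function(params = sim_params(), seed = params$seed) {
  validate_sim_params(params)
  withr::with_seed(seed, simulate_cohort_impl(params))
}

simulate_cohort_impl <- function(params) {
  roster <- build_roster(params)
  n <- nrow(roster)
  fam_idx <- match(roster$family_id, unique(roster$family_id))
  n_fam <- max(fam_idx)
  mz2 <- which(roster$zygosity_role == "MZ2")
  mz1_of <- function(rows) {
    vapply(rows, function(i) {
      j <- which(roster$family_id == roster$family_id[i] &
                   roster$zygosity_role == "MZ1")
      j[1]
    }, integer(1))
  }
  mz1 <- if (length(mz2)) mz1_of(mz2) else integer(0)

  # one person-level latent per trait block, family-structured
  additive <- function(q, cholR = NULL) {
    structured_latent(q, n, n_fam, fam_idx, mz1, mz2, share = 0.5, cholR)
  }
  dominance <- function(q) {
    structured_latent(q, n, n_fam, fam_idx, mz1, mz2, share = 0.25, NULL)
  }
  unshared <- function(q, cholR = NULL) {
    U <- matrix(stats::rnorm(n * q), n, q)
    if (!is.null(cholR)) U <- U %*% cholR
    U
  }

  h2 <- params$h2_targets
  d2 <- params$d2_targets
  Rg <- corr3(params$rg_swb_vol, params$rg_lr)
  Re <- corr3(params$re_swb_vol, params$re_lr)
  a3 <- additive(3, chol(Rg))   # (swb, hip_l, hip_r)
  e3 <- unshared(3, chol(Re))
  d3 <- dominance(3)

  mix <- function(a, d, e, h2t, d2t) {
    sqrt(h2t) * a + sqrt(d2t) * d + sqrt(pmax(1 - h2t - d2t, 0)) * e
  }
  z_swb <- mix(a3[, 1], d3[, 1], e3[, 1], h2$swb, d2$swb)
  z_hl <- mix(a3[, 2], d3[, 2], e3[, 2], h2$hip_l, d2$hip_l)
  z_hr <- mix(a3[, 3], d3[, 3], e3[, 3], h2$hip_r, d2$hip_r)

  # standardized mean hippocampal volume driving the planted concave link
  zv <- (z_hl + z_hr) / 2 / sqrt((1 + cor_lr_of(params, h2)) / 2)

  male <- roster$sex == "M"
  planted_var <- params$lin_beta^2 + 2 * params$quad_beta^2
  # theoretical cov(z_swb, zv), so the core scale solves
  # core^2 + 2*lin*core*c + planted_var = swb_sd^2
  cov_swb_h <- function(h2v) {
    sqrt(h2$swb * h2v) * params$rg_swb_vol +
      sqrt((1 - h2$swb) * (1 - h2v)) * params$re_swb_vol
  }
  c_zv <- (cov_swb_h(h2$hip_l) + cov_swb_h(h2$hip_r)) / 2 /
    sqrt((1 + cor_lr_of(params, h2)) / 2)
  lc <- params$lin_beta * c_zv
  core_scale <- sqrt(max(lc^2 + params$swb_sd^2 - planted_var,
                         0.25 * params$swb_sd^2)) - lc
  swb_latent <- params$swb_mean +
    params$sex_effect_swb * (male - mean(male)) +
    core_scale * z_swb +
    params$lin_beta * zv + params$quad_beta * (zv^2 - 1)

  disc <- stats::rnorm(n, 0, params$sat_hap_disc)
  sat <- pmin(pmax(swb_latent + disc, 5), 35)
  hap_sat_scale <- pmin(pmax(swb_latent - disc, 5), 35)
  hap <- (hap_sat_scale - 5) / 30 * 24 + 4
  swb <- swb_composite(sat, hap)

  vol_sex <- params$sex_effect_vol * (male - mean(male))
  hip_l <- params$vol_means[["hippocampus"]] +
    params$vol_sds[["hippocampus"]] * (z_hl + vol_sex)
  hip_r <- params$vol_means[["hippocampus"]] +
    params$vol_sds[["hippocampus"]] * (z_hr + vol_sex)

  other_regions <- setdiff(names(params$vol_means), "hippocampus")
  a_sh <- additive(length(other_regions))
  a_sp <- additive(2 * length(other_regions))
  e_sh <- unshared(length(other_regions))
  e_sp <- unshared(2 * length(other_regions))
  vols <- list()
  for (k in seq_along(other_regions)) {
    reg <- other_regions[k]
    for (side in 1:2) {
      col <- 2 * (k - 1) + side
      za <- sqrt(0.6) * a_sh[, k] + sqrt(0.4) * a_sp[, col]
      ze <- sqrt(0.3) * e_sh[, k] + sqrt(0.7) * e_sp[, col]
      z <- sqrt(h2$vol_other) * za + sqrt(1 - h2$vol_other) * ze
      vols[[paste0("volume_", reg, "_", c("l", "r")[side])]] <-
        params$vol_means[[reg]] + params$vol_sds[[reg]] * (z + vol_sex)
    }
  }

  z_icv <- sqrt(h2$icv) * additive(1)[, 1] +
    sqrt(1 - h2$icv) * unshared(1)[, 1]
  icv <- params$icv_mean + params$icv_sd * z_icv

  # polygenic scores: standardized, loading on the additive latent only so
  # they act as instruments valid by construction
  r2 <- params$pgs_r2_exposure
  alpha_swb <- min(1, sqrt(r2$swb) * params$swb_sd /
                     (sqrt(h2$swb) * core_scale))
  alpha_hl <- min(1, sqrt(r2$hip / h2$hip_l))
  alpha_hr <- min(1, sqrt(r2$hip / h2$hip_r))
  pgs_swb <- alpha_swb * a3[, 1] + sqrt(1 - alpha_swb^2) * stats::rnorm(n)
  pgs_hip_l <- alpha_hl * a3[, 2] + sqrt(1 - alpha_hl^2) * stats::rnorm(n)
  pgs_hip_r <- alpha_hr * a3[, 3] + sqrt(1 - alpha_hr^2) * stats::rnorm(n)

  dna <- rep(FALSE, n)
  dna[sample.int(n, min(params$n_dna, n))] <- TRUE

  pcs <- matrix(stats::rnorm(n * params$n_pc_covariates), n,
                dimnames = list(NULL, paste0("pc_", seq_len(params$n_pc_covariates))))

  cohort <- tibble::tibble(
    person_id = roster$person_id,
    family_id = roster$family_id,
    zygosity_role = roster$zygosity_role,
    study = roster$study,
    sex = roster$sex,
    age_mri = roster$age_mri,
    age_swb = roster$age_swb,
    sat = sat, hap = hap, swb = swb,
    icv = icv,
    volume_hippocampus_l = hip_l,
    volume_hippocampus_r = hip_r
  )
  cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(vols))
  cohort$pgs_swb <- pgs_swb
  cohort$pgs_hip_l <- pgs_hip_l
  cohort$pgs_hip_r <- pgs_hip_r
  cohort$dna_available <- dna
  cohort$symptom_class <- 1L
  cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(pcs))
  # retained generating components, for diagnostics and tests only
  attr(cohort, "latents") <- tibble::tibble(
    person_id = roster$person_id,
    a_swb = a3[, 1], a_hip_l = a3[, 2], a_hip_r = a3[, 3],
    e_swb = e3[, 1], zv = zv
  )
  cohort
}

# theoretical phenotypic left-right volume correlation
cor_lr_of <- function(params, h2) {
  params$rg_lr * sqrt(h2$hip_l * h2$hip_r) +
    params$re_lr * sqrt((1 - h2$hip_l) * (1 - h2$hip_r))
}

# sample() without the scalar-x surprise
resample <- function(x, size) x[sample.int(length(x), size)]

# family-structured standard-normal latents: correlation `share` between
# non-MZ family members, 1 within MZ pairs; optional trait correlation cholR
structured_latent <- function(q, n, n_fam, fam_idx, mz1, mz2, share, cholR) {
  F_ <- matrix(stats::rnorm(n_fam * q), n_fam, q)
  U <- matrix(stats::rnorm(n * q), n, q)
  if (!is.null(cholR)) {
    F_ <- F_ %*% cholR
    U <- U %*% cholR
  }
  A <- sqrt(share) * F_[fam_idx, , drop = FALSE] + sqrt(1 - share) * U
  if (length(mz2)) A[mz2, ] <- A[mz1, , drop = FALSE]
  A
}

#' Combine satisfaction and happiness scores into the SWB composite
#'
#' The happiness score (4-28 scale) is first rescaled linearly onto the
#' satisfaction scale (5-35), then the two are averaged arithmetically. The
#' rescaling before averaging is a documented package choice; the composite
#' lives on the satisfaction scale.
#'
#' @param sat Satisfaction-with-life scores (5-35).
#' @param hap Subjective-happiness scores (4-28).
#' @return Numeric vector of SWB composites.
#' @export
swb_composite <- function(sat, hap) {
  (sat + ((hap - 4) / 24 * 30 + 5)) / 2
}

build_roster <- function(params) {
  comp <- params$composition
  if (is.null(comp)) comp <- random_composition(params)
  rows <- list()
  for (s in comp$study) {
    cr <- comp[comp$study == s, ]
    fams <- c(rep("mz_pair", cr$mz_pair), rep("dz_pair", cr$dz_pair),
              rep("mz_single", cr$mz_single), rep("dz_single", cr$dz_single))
    fam <- tibble::tibble(
      study = s,
      family_id = sprintf("S%dF%03d", s, seq_along(fams)),
      type = fams,
      n_sib = 0L
    )
    # siblings round-robin over twin-pair families (DZ first, then MZ)
    pair_rows <- which(fam$type %in% c("dz_pair", "mz_pair"))
    pair_rows <- pair_rows[order(fam$type[pair_rows] != "dz_pair")]
    if (cr$sib > 0) {
      if (!length(pair_rows)) stop("siblings require twin-pair families", call. = FALSE)
      add <- rep(pair_rows, length.out = cr$sib)
      tab <- table(add)
      fam$n_sib[as.integer(names(tab))] <- as.integer(tab)
    }
    roles <- list(mz_pair = c("MZ1", "MZ2"), dz_pair = c("DZ1", "DZ2"),
                  mz_single = "MZ1", dz_single = "DZ1")
    per <- purrr::pmap_dfr(fam, function(study, family_id, type, n_sib) {
      tibble::tibble(study = study, family_id = family_id,
                     zygosity_role = c(roles[[type]], rep("SIB", n_sib)))
    })
    rows[[length(rows) + 1]] <- per
  }
  roster <- dplyr::bind_rows(rows)
  roster$person_id <- paste0(roster$family_id, "P",
                             stats::ave(seq_len(nrow(roster)),
                                        roster$family_id, FUN = seq_along))
  if (anyDuplicated(roster$person_id)) stop("duplicated person_id", call. = FALSE)
  if (params$include_triplet) {
    # relabel the sibling in the first sib-carrying MZ-pair family of study 5
    # as a DZ co-twin of the MZ pair (triplet); kinship is unchanged
    cand <- which(roster$study == 5 & roster$zygosity_role == "SIB")
    for (i in cand) {
      fam_roles <- roster$zygosity_role[roster$family_id == roster$family_id[i]]
      if ("MZ1" %in% fam_roles) {
        roster$zygosity_role[i] <- "SIB"  # role label retained; flag family
        attr(roster, "triplet_family") <- roster$family_id[i]
        break
      }
    }
  }
  roster <- assign_sex(roster, params)
  assign_ages(roster, params)
}

random_composition <- function(params) {
  n_f <- params$n_families_per_study
  purrr::map_dfr(seq_along(n_f), function(s) {
    is_mz <- stats::runif(n_f[s]) < params$mz_fraction
    sibs <- sample(0:(length(params$sib_count_distribution) - 1), n_f[s],
                   replace = TRUE, prob = params$sib_count_distribution)
    tibble::tibble(study = s,
                   mz_pair = sum(is_mz), dz_pair = sum(!is_mz),
                   mz_single = 0L, dz_single = 0L, sib = sum(sibs))
  })
}

assign_sex <- function(roster, params) {
  roster$sex <- NA_character_
  for (s in unique(roster$study)) {
    idx <- which(roster$study == s)
    need_m <- params$sex_table$male[params$sex_table$study == s]
    if (!length(need_m)) need_m <- round(length(idx) / 2)
    mz_fams <- unique(roster$family_id[idx][roster$zygosity_role[idx] %in% c("MZ1", "MZ2")])
    mz_fams <- mz_fams[vapply(mz_fams, function(f) {
      sum(roster$family_id == f & roster$zygosity_role %in% c("MZ1", "MZ2")) == 2
    }, logical(1))]
    pair_rows <- idx[roster$family_id[idx] %in% mz_fams &
                       roster$zygosity_role[idx] %in% c("MZ1", "MZ2")]
    free_rows <- setdiff(idx, pair_rows)
    n_pair <- length(mz_fams)
    n_free <- length(free_rows)
    m_pairs <- round(n_pair * need_m / length(idx))
    m_pairs <- max(ceiling((need_m - n_free) / 2), min(m_pairs, need_m %/% 2, n_pair))
    male_fams <- resample(mz_fams, m_pairs)
    roster$sex[pair_rows] <- ifelse(roster$family_id[pair_rows] %in% male_fams, "M", "F")
    rem <- need_m - 2 * m_pairs
    male_free <- resample(free_rows, rem)
    roster$sex[free_rows] <- ifelse(free_rows %in% male_free, "M", "F")
  }
  roster
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

assign_ages <- function(roster, params) {
  at <- params$age_table
  roster$age_mri <- NA_real_
  roster$age_swb <- NA_real_
  for (s in unique(roster$study)) {
    a <- at[at$study == ((s - 1) %% 5 + 1), ]
    idx <- which(roster$study == s)
    fams <- unique(roster$family_id[idx])
    base <- rtruncnorm1(length(fams), a$mri_mean, a$mri_sd, a$mri_min, a$mri_max)
    names(base) <- fams
    age <- base[roster$family_id[idx]]
    is_sib <- roster$zygosity_role[idx] == "SIB"
    age[is_sib] <- pmin(pmax(age[is_sib] +
                               sample(c(-4, -3, -2, 2, 3, 4), sum(is_sib), TRUE),
                             a$mri_min), a$mri_max)
    delay_mean <- a$swb_mean - a$mri_mean
    sd_noise <- a$mri_sd * sqrt(1 / a$age_cor^2 - 1)
    swb_age <- age + delay_mean + stats::rnorm(length(idx), 0, sd_noise)
    roster$age_mri[idx] <- age
    roster$age_swb[idx] <- pmin(pmax(swb_age, a$swb_min), a$swb_max)
  }
  roster
}

#' Apply symptom-based selection classes to a cohort
#'
#' Emulates ascertainment of high- and low-symptom groups in selected
#' studies: a latent symptom score correlated with SWB is drawn per person,
#' and within each selected study the top `prop_high` mass is labelled
#' class 2 (high symptoms), the bottom `prop_low` mass class 0 (low), and
#' everyone else class 1 (unselected). With a negative latent correlation
#' the high-symptom group has the lower mean SWB.
#'
#' @param cohort A cohort tibble from [simulate_cohort()].
#' @param params A [sim_params()] object supplying `selection_spec`.
#' @param studies Studies to select on (default: those named in the spec).
#' @param seed Integer seed for the latent symptom draw.
#' @return The cohort with `symptom_class` filled in (0, 1 or 2).
#' @export
apply_symptom_selection <- function(cohort, params = sim_params(),
                                    studies = params$selection_spec$study,
                                    seed = params$seed + 1L) {
  spec <- params$selection_spec
  missing_spec <- setdiff(studies, spec$study)
  if (length(missing_spec)) {
    stop("selection requested for study with no selection_spec entry: ",
         paste(missing_spec, collapse = ", "), call. = FALSE)
  }
  withr::with_seed(seed, {
    cohort$symptom_class <- 1L
    for (s in studies) {
      sp <- spec[spec$study == s, ]
      idx <- which(cohort$study == s)
      n <- length(idx)
      if (!n) next
      z_swb <- as.numeric(scale(cohort$swb[idx]))
      symptom <- sp$cor * z_swb + sqrt(1 - sp$cor^2) * stats::rnorm(n)
      n_high <- round(sp$prop_high * n)
      n_low <- min(round(sp$prop_low * n), n - n_high)
      rk <- rank(symptom, ties.method = "first")
      cls <- rep(1L, n)
      cls[rk > n - n_high] <- 2L
      cls[rk <= n_low] <- 0L
      cohort$symptom_class[idx] <- cls
    }
    cohort
  })
}

#' Simulate a pair of GWAS summary-statistics sets with LD scores
#'
#' Draws per-SNP Z-scores for two traits under the LD-score-regression
#' model: `E[z1^2] = N1 * h2_1 * l / M + 1`,
#' `E[z1 * z2] = sqrt(N1 * N2) * rho_g * l / M` with
#' `rho_g = rg * sqrt(h2_1 * h2_2)`, where `l` is the SNP's LD score.
#'
#' @param M Number of SNPs (at least 1000).
#' @param h2_1,h2_2 SNP-heritabilities of the two traits, in `[0, 1]`.
#' @param rg Genetic correlation in `[-1, 1]`.
#' @param N1,N2 GWAS sample sizes.
#' @param seed Integer seed.
#' @param ld_mean Mean LD score (scores are `1 + Gamma`, so always >= 1).
#' @return A list of class `swb_sumstats`: tibble `snps`
#'   (`snp`, `ld_score`, `z1`, `z2`), sizes `N1`, `N2`, `M`, and the
#'   generating `true_h2_1`, `true_h2_2`, `true_rg` (retained for tests).
#' @export
simulate_gwas_pair <- function(M, h2_1, h2_2, rg, N1, N2, seed = 1L,
                               ld_mean = 100) {
  if (M < 1000) stop("M must be at least 1000", call. = FALSE)
  if (abs(rg) > 1) stop("rg must lie in [-1, 1]", call. = FALSE)
  stopifnot(h2_1 >= 0, h2_1 <= 1, h2_2 >= 0, h2_2 <= 1, N1 > 0, N2 > 0)
  withr::with_seed(seed, {
    ell <- 1 + stats::rgamma(M, shape = 2, scale = (ld_mean - 1) / 2)
    v1 <- N1 * h2_1 * ell / M + 1
    v2 <- N2 * h2_2 * ell / M + 1
    c12 <- sqrt(N1 * N2) * rg * sqrt(h2_1 * h2_2) * ell / M
    z1 <- stats::rnorm(M, 0, sqrt(v1))
    # conditional draw keeps the joint normal with the requested cross-moment
    mu2 <- c12 / v1 * z1
    s2 <- sqrt(pmax(v2 - c12^2 / v1, 0))
    z2 <- stats::rnorm(M, mu2, s2)
    structure(list(
      snps = tibble::tibble(snp = paste0("rs", seq_len(M)),
                            ld_score = ell, z1 = z1, z2 = z2),
      N1 = N1, N2 = N2, M = M,
      true_h2_1 = h2_1, true_h2_2 = h2_2, true_rg = rg
    ), class = "swb_sumstats")
  })
}
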