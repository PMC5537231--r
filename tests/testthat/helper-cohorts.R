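# Shared fixtures, built once per test run.

# the default 724-person five-study cohort
default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(sim_params(seed = 1))
    cache
  }
})

# large single-study twin-pair cohort for parameter-recovery checks:
# left hippocampus h2 = 0.76, right h2 = 0.44, hemispheres independent
pair_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      comp <- tibble::tibble(study = 1L, mz_pair = 2500L, dz_pair = 2500L,
                             mz_single = 0L, dz_single = 0L, sib = 0L)
      p <- sim_params(
        composition = comp,
        sex_table = tibble::tibble(study = 1L, male = 5000L, female = 5000L),
        h2_targets = list(swb = 0.44, hip_l = 0.76, hip_r = 0.44,
                          vol_other = 0.8, icv = 0.8),
        rg_lr = 0, re_lr = 0, n_dna = 0, seed = 5
      )
      cache <<- simulate_cohort(p)
    }
    cache
  }
})

# compact two-study design for pipeline-level tests
small_sim_params <- function(seed = 11, ...) {
  comp <- tibble::tibble(
    study = 1:2,
    mz_pair = c(12L, 10L), dz_pair = c(10L, 12L),
    mz_single = c(1L, 0L), dz_single = c(0L, 1L), sib = c(4L, 4L)
  )
  sim_params(
    composition = comp,
    sex_table = tibble::tibble(study = 1:2, male = c(24L, 25L),
                               female = c(25L, 24L)),
    selection_spec = tibble::tibble(study = 1L, cor = -0.6,
                                    prop_high = 0.3, prop_low = 0.4),
    n_dna = 80, n_pc_covariates = 2, seed = seed, ...
  )
}

# pedigree of n unrelated singletons (identity kinship)
singleton_cohort <- function(n) {
  tibble::tibble(person_id = paste0("p", seq_len(n)),
                 family_id = paste0("f", seq_len(n)),
                 zygosity_role = "MZ1")
}

# draw y ~ N(mu, sigma_g^2 K + sigma_e^2 I) given a chol factor of V
draw_mvn <- function(V_chol, n_draws = 1) {
  n <- ncol(V_chol)
  matrix(stats::rnorm(n * n_draws), n_draws, n) %*% V_chol
}

# subset a pair cohort to its first n_mz MZ-pair and n_dz DZ-pair families
pair_subset <- function(co, n_mz, n_dz) {
  mzf <- unique(co$family_id[co$zygosity_role == "MZ1"])
  dzf <- unique(co$family_id[co$zygosity_role == "DZ1"])
  co[co$family_id %in% c(utils::head(mzf, n_mz), utils::head(dzf, n_dz)), ]
}
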