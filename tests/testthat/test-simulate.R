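test_that("default cohort reproduces the study design", {
  co <- default_cohort()
  expect_equal(dplyr::count(co, study)$n, c(58, 244, 58, 130, 234))
  expect_equal(nrow(co), 724)
  expect_equal(sum(co$sex == "M"), 302)
  expect_equal(sum(co$sex == "F"), 422)
  expect_equal(sum(co$dna_available), 636)
})

test_that("the same seed reproduces the table exactly", {
  a <- simulate_cohort(sim_params(seed = 33))
  b <- simulate_cohort(sim_params(seed = 33))
  expect_identical(a, b)
})

test_that("cohort structural invariants hold", {
  co <- default_cohort()
  expect_equal(anyDuplicated(co$person_id), 0L)
  vols <- as.matrix(dplyr::select(co, "icv", dplyr::starts_with("volume_")))
  expect_true(all(vols > 0))
  # SWB is exactly the stated combination of SAT and rescaled HAP
  expect_equal(co$swb, swb_composite(co$sat, co$hap))
  expect_true(all(co$sat >= 5 & co$sat <= 35))
  expect_true(all(co$hap >= 4 & co$hap <= 28))
  fam_ok <- vapply(split(co$zygosity_role, co$family_id), function(z) {
    sum(z == "MZ1") <= 1 && sum(z == "DZ1") <= 1 &&
      !(any(z %in% c("MZ1", "MZ2")) && any(z %in% c("DZ1", "DZ2")))
  }, logical(1))
  expect_true(all(fam_ok))
  expect_gt(stats::cor(co$age_mri, co$age_swb), 0.9)
})

test_that("latent additive values share 1.0 within MZ and 0.5 within DZ pairs", {
  co <- pair_cohort()
  lat <- attr(co, "latents")
  lat$family_id <- co$family_id
  lat$role <- co$zygosity_role
  pick <- function(role) lat[lat$role == role, ]
  mz <- dplyr::inner_join(pick("MZ1"), pick("MZ2"), by = "family_id")
  expect_equal(mz$a_hip_l.x, mz$a_hip_l.y)  # identical, not just correlated
  expect_equal(mz$a_swb.x, mz$a_swb.y)
  dz <- dplyr::inner_join(pick("DZ1"), pick("DZ2"), by = "family_id")
  r_dz <- stats::cor(dz$a_hip_l.x, dz$a_hip_l.y)
  expect_lt(abs(r_dz - 0.5), 3 * (1 - 0.25) / sqrt(nrow(dz)))
})

test_that("twin-pair phenotype correlations match the heritability targets", {
  co <- add_twin_traits(pair_cohort())
  by_role <- function(role, col) co[[col]][co$zygosity_role == role]
  # h2 = 0.76 trait: r_MZ ~ h2, r_DZ ~ h2/2, each within 3 Monte-Carlo SE
  r_mz <- stats::cor(by_role("MZ1", "t_vol_l"), by_role("MZ2", "t_vol_l"))
  r_dz <- stats::cor(by_role("DZ1", "t_vol_l"), by_role("DZ2", "t_vol_l"))
  se <- function(r, n) (1 - r^2) / sqrt(n)
  expect_lt(abs(r_mz - 0.76), 3 * se(0.76, 2500))
  expect_lt(abs(r_dz - 0.38), 3 * se(0.38, 2500))
})

test_that("phenotypic variances are on target in large samples", {
  co <- pair_cohort()
  expect_lt(abs(stats::var(co$swb) / 4.1^2 - 1), 0.05)
  expect_lt(abs(stats::var(co$volume_hippocampus_l) / 400^2 - 1), 0.05)
  expect_lt(abs(stats::var(co$icv) / 1.5e5^2 - 1), 0.05)
})

test_that("a concave planted link orders the volume strata low < mid <= high", {
  co <- pair_cohort()
  strata <- swb_by_volume_strata(co)
  expect_lt(strata$mean[strata$stratum == "low"],
            strata$mean[strata$stratum == "medium"])
  expect_lte(strata$mean[strata$stratum == "medium"],
             strata$mean[strata$stratum == "high"] + 0.1)
})

test_that("invalid parameters are rejected with the offending field named", {
  expect_error(sim_params(h2_targets = list(swb = 1.2, hip_l = 0.7,
                                            hip_r = 0.7, vol_other = 0.8,
                                            icv = 0.8)),
               "h2_targets\\$swb")
  expect_error(sim_params(h2_targets = list(swb = 0.7, hip_l = 0.7,
                                            hip_r = 0.7, vol_other = 0.8,
                                            icv = 0.8),
                          d2_targets = list(swb = 0.5, hip_l = 0, hip_r = 0,
                                            vol_other = 0, icv = 0)),
               "exceeds 1")
  expect_error(sim_params(rg_swb_vol = 1.4), "rg_swb_vol")
  # jointly extreme correlations cannot form a PSD generating matrix
  expect_error(sim_params(rg_swb_vol = 0.9, rg_lr = -0.9),
               "positive-semidefinite")
})

test_that("symptom selection assigns classes per spec and direction", {
  co <- default_cohort()
  p <- sim_params(seed = 1)
  expect_true(all(co$symptom_class == 1L))  # selection off at generation
  sel <- apply_symptom_selection(co, p)
  s3 <- sel[sel$study == 3, ]
  expect_equal(sum(s3$symptom_class == 2), 23)
  expect_equal(sum(s3$symptom_class == 0), 35)
  expect_true(all(sel$symptom_class[sel$study %in% 4:5] == 1))
  for (s in 1:3) {
    ss <- sel[sel$study == s, ]
    expect_lt(mean(ss$swb[ss$symptom_class == 2]),
              mean(ss$swb[ss$symptom_class == 0]))
  }
  expect_error(apply_symptom_selection(co, p, studies = 4),
               "no selection_spec")
})

test_that("selection gap matches the truncated-normal oracle", {
  co <- pair_cohort()
  p <- sim_params(
    selection_spec = tibble::tibble(study = 1, cor = -0.5,
                                    prop_high = 0.1, prop_low = 0.1),
    seed = 5
  )
  sel <- apply_symptom_selection(co, p)
  z <- as.numeric(scale(co$swb))
  # closed form: E[z_swb | symptom in top decile] = cor * phi(q90)/0.1
  oracle <- -0.5 * stats::dnorm(stats::qnorm(0.9)) / 0.1
  emp_high <- mean(z[sel$symptom_class == 2])
  emp_low <- mean(z[sel$symptom_class == 0])
  expect_lt(abs(emp_high - oracle), 0.12)
  expect_lt(abs(emp_low - (-oracle)), 0.12)
})

test_that("simulated GWAS pairs follow the LD-score moments", {
  pair <- simulate_gwas_pair(5000, 0.3, 0.3, 0, 30000, 30000, seed = 9)
  prods <- pair$snps$z1 * pair$snps$z2
  expect_lt(abs(mean(prods)), 3 * stats::sd(prods) / sqrt(length(prods)))
  expect_true(all(pair$snps$ld_score >= 1))
  expect_identical(simulate_gwas_pair(2000, 0.2, 0.2, 0.5, 1e4, 1e4, seed = 2),
                   simulate_gwas_pair(2000, 0.2, 0.2, 0.5, 1e4, 1e4, seed = 2))
  expect_error(simulate_gwas_pair(500, 0.2, 0.2, 0, 1e4, 1e4), "M must")
  expect_error(simulate_gwas_pair(2000, 0.2, 0.2, 1.5, 1e4, 1e4), "rg")
})
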