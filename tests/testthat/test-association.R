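test_that("the full scan emits 14 region rows at the Bonferroni alpha", {
  co <- default_cohort()
  scan <- association_scan(co)
  expect_equal(nrow(scan), 14)
  expect_equal(attr(scan, "alpha"), 0.05 / 14)
  expect_setequal(unique(scan$hemisphere), c("L", "R"))
  expect_equal(scan$lin_sig, scan$lin_p < 0.05 / 14)
  # the planted hippocampal signal is detected
  hip <- scan[scan$region == "hippocampus", ]
  expect_true(all(hip$lin_sig))
  # false positives among the 12 null regions stay rare at this alpha
  other <- scan[scan$region != "hippocampus", ]
  expect_lte(sum(other$lin_sig) + sum(other$quad_sig), 2)
})

test_that("significance flags are invariant to cohort row order", {
  co <- default_cohort()
  scan1 <- association_scan(co, regions = "hippocampus")
  perm <- withr::with_seed(4, sample(nrow(co)))
  scan2 <- association_scan(co[perm, ], regions = "hippocampus")
  expect_equal(scan1$lin_f, scan2$lin_f, tolerance = 1e-6)
  expect_equal(scan1$lin_sig, scan2$lin_sig)
  expect_equal(scan1$quad_sig, scan2$quad_sig)
})

test_that("dropping the Z-transform is a reparameterization of the same curve", {
  co <- default_cohort()
  K <- build_kinship(co)
  fz <- fit_region_model(co, "volume_hippocampus_l", kinship = K)
  fr <- fit_region_model(co, "volume_hippocampus_l", standardize = FALSE,
                         kinship = K)
  expect_gt(abs(fz$beta[["vol_lin"]] - fr$beta[["vol_lin"]]), 1e-3)
  expect_equal(fz$fitted, fr$fitted, tolerance = 1e-5)
  # the quadratic term's F is unchanged, as in the unstandardized refit
  tz <- test_fixed_term(fz, "vol_quad")
  tr <- test_fixed_term(fr, "vol_quad")
  expect_equal(tz$statistic, tr$statistic, tolerance = 1e-5)
})

test_that("post-hoc variants refit the model as documented", {
  co <- apply_symptom_selection(default_cohort(), sim_params(seed = 1))
  K <- build_kinship(co)
  sat <- posthoc_battery(co, variant = "outcome_sat", kinship = K)
  expect_equal(nrow(sat), 2)
  expect_true(all(is.finite(sat$lin_f)))
  dq <- posthoc_battery(co, variant = "drop_quadratic", kinship = K)
  expect_false("quad_est" %in% names(dq))
  covs <- posthoc_battery(co, variant = "add_symptom_score", kinship = K)
  expect_true(all(is.finite(covs$lin_p)))
  expect_error(posthoc_battery(co, variant = "no_such_variant"))
})

test_that("dropping an absent quadratic term leaves the linear estimate alone", {
  params <- small_sim_params(seed = 21, quad_beta = 0)
  co <- simulate_cohort(params)
  K <- build_kinship(co)
  full <- fit_region_model(co, "volume_hippocampus_l", kinship = K)
  red <- fit_region_model(co, "volume_hippocampus_l", kinship = K,
                          drop_quadratic = TRUE)
  expect_lt(abs(full$beta[["vol_lin"]] - red$beta[["vol_lin"]]),
            0.5 * full$se[["vol_lin"]])
})

test_that("study interactions test 4 contrasts against reference study 5", {
  co <- default_cohort()
  res <- posthoc_battery(co, variant = "study_interactions")
  omni <- res[grepl("omnibus", res$test), ]
  expect_equal(nrow(omni), 4)  # linear + quadratic per hemisphere
  expect_true(all(omni$alpha == 0.05 / 4))
  ctr <- res[grepl("contrast", res$test), ]
  expect_equal(nrow(ctr), 16)  # 4 studies x 2 terms x 2 hemispheres
  expect_true(all(ctr$alpha == 0.05))
  expect_false(any(grepl("study5", ctr$contrast)))
})

test_that("volume strata use closed outer cutoffs and exhaust the sample", {
  base <- tibble::tibble(
    person_id = paste0("p", 1:6), family_id = paste0("f", 1:6),
    zygosity_role = "SIB", study = 1, sex = "F", age_mri = 30, age_swb = 30,
    sat = 25, hap = 20, swb = c(10, 20, 30, 25, 24, 26), icv = 1.5e6
  )
  # mean-0, SD-1 construction keeps the Z-scores exactly at the cutoffs
  zvals <- c(-0.5, 0.5, -1.5, 1.5, 0, 0)
  base$volume_hippocampus_l <- 4200 + 400 * zvals
  base$volume_hippocampus_r <- base$volume_hippocampus_l
  res <- swb_by_volume_strata(base)
  expect_equal(sum(res$n), 6)
  expect_equal(res$n, c(2, 2, 2))  # z = -0.5 and z = +0.5 land in the outer strata
  # all-medium case (volumes supplied on the Z scale): one non-empty stratum
  base$volume_hippocampus_l <- c(-0.4, -0.2, 0, 0.1, 0.2, 0.3)
  base$volume_hippocampus_r <- base$volume_hippocampus_l
  res2 <- swb_by_volume_strata(base, hemisphere = "l", standardize = FALSE)
  expect_equal(res2$n[res2$stratum == "low"], 0)
  expect_equal(res2$n[res2$stratum == "high"], 0)
  expect_true(is.na(res2$mean[res2$stratum == "low"]))
})

test_that("summary-statistic ANOVA matches published and oracle values", {
  res <- two_group_anova_from_summary(23, 21.5, 4.7, 35, 27.2, 2.2)
  expect_equal(res$statistic, 38.8, tolerance = 0.002)
  expect_equal(res$df2, 56)
  expect_lt(res$p.value, 0.001)
  # equal means give F = 0
  expect_equal(two_group_anova_from_summary(10, 5, 1, 12, 5, 2)$statistic, 0)
  # brute-force identity: reconstruct raw samples with those exact moments
  make <- function(n, m, s) m + s * zscore(seq_len(n))
  g1 <- make(23, 21.5, 4.7); g2 <- make(35, 27.2, 2.2)
  tt <- stats::t.test(g1, g2, var.equal = TRUE)
  expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p.value, tt$p.value, tolerance = 1e-10)
  expect_error(two_group_anova_from_summary(1, 5, 1, 12, 5, 2), "n >= 2")
  expect_error(two_group_anova_from_summary(10, 5, 0, 12, 5, 2), "positive")
})

test_that("missing covariate columns are reported by name", {
  co <- default_cohort()
  co$icv <- NULL
  expect_error(association_scan(co, regions = "hippocampus"), "icv")
  expect_error(association_scan(default_cohort(), regions = "cerebellum"),
               "volume_cerebellum_l")
})
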