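test_that("expected twin covariance follows the ADE block structure", {
  a <- matrix(2); d <- matrix(1); e <- matrix(3)
  mz <- expected_twin_cov(a, d, e, "MZ")
  expect_equal(mz, matrix(c(6, 3, 3, 6), 2))
  dz <- expected_twin_cov(a, d, e, "DZ")
  expect_equal(dz[1, 2], 0.5 * 2 + 0.25 * 1)
  z0 <- expected_twin_cov(matrix(0), matrix(0), e, "MZ")
  expect_equal(z0, diag(c(3, 3)))
})

test_that("expected twin covariance is symmetric PSD for PSD components", {
  withr::local_seed(61)
  for (i in 1:20) {
    p <- sample(2:4, 1)
    rand_psd <- function() {
      L <- matrix(stats::rnorm(p * p), p); tcrossprod(L)
    }
    S <- expected_twin_cov(rand_psd(), rand_psd(), rand_psd(),
                           sample(c("MZ", "DZ"), 1))
    expect_equal(S, t(S))
    expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("pair assembly builds 2p vectors and guards identifiability", {
  co <- add_twin_traits(default_cohort())
  traits <- c("t_swb", "t_vol_l", "t_vol_r", "t_vol_l2", "t_vol_r2")
  td <- assemble_twin_pairs(co, traits)
  expect_equal(ncol(td$MZ$y), 10)  # 10 x 10 covariance structure
  expect_equal(td$p, 5)
  # row shuffling leaves the assembled vectors invariant up to pair order
  perm <- withr::with_seed(3, sample(nrow(co)))
  td2 <- assemble_twin_pairs(co[perm, ], traits)
  key <- function(m) apply(round(m, 8), 1, paste, collapse = "|")
  expect_setequal(key(td$MZ$y), key(td2$MZ$y))
  expect_setequal(key(td$DZ$y), key(td2$DZ$y))
  # no DZ pairs: ADE and AE are unidentified
  mz_only <- co[co$zygosity_role %in% c("MZ1", "MZ2"), ]
  td_mz <- assemble_twin_pairs(mz_only, "t_vol_l", covariates = NULL)
  expect_equal(nrow(td_mz$DZ$y), 0)
  expect_error(fit_biometric(td_mz, "ADE"), "unidentified")
  # zygosity conflicts are caught
  bad <- co[co$family_id %in% co$family_id[1], ]
  bad$zygosity_role <- c("MZ1", "DZ2")[seq_len(nrow(bad)) %% 2 + 1]
  expect_error(assemble_twin_pairs(bad, "t_vol_l"), "zygosity conflict")
})

test_that("saturated fit maximizes the pair likelihood (direct-search oracle)", {
  co <- add_twin_traits(pair_cohort())
  td <- assemble_twin_pairs(pair_subset(co, 40, 40), "t_vol_l",
                            covariates = NULL)
  sat <- fit_saturated(td)
  # independent oracle: optimize the same Gaussian likelihood directly over
  # (mu, chol(Sigma_MZ), chol(Sigma_DZ)) with a generic optimizer
  negll <- function(par) {
    mu <- par[1]
    build <- function(l) {
      L <- matrix(c(l[1], l[2], 0, l[3]), 2)
      tcrossprod(L)
    }
    smz <- build(par[2:4]); sdz <- build(par[5:7])
    ll <- 0
    for (z in c("MZ", "DZ")) {
      S <- if (z == "MZ") smz else sdz
      Y <- td[[z]]$y
      R <- sweep(Y, 2, c(mu, mu))
      W <- solve(S)
      ll <- ll - 0.5 * (nrow(Y) * (2 * log(2 * pi) +
                                     determinant(S)$modulus[1]) +
                          sum((R %*% W) * R))
    }
    -ll
  }
  start <- c(mean(td$MZ$y), 1, 0.5, 0.5, 1, 0.3, 0.7)
  op <- stats::optim(start, negll, method = "BFGS",
                     control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(sat$loglik, -op$value, tolerance = 1e-6)
  # sample covariance is close but not exactly the constrained-mean ML
  expect_equal(sat$sigma_mz[1, 2],
               stats::cov(td$MZ$y)[1, 2] * (39 / 40), tolerance = 0.05)
})

test_that("saturated twin correlations recover the generating values", {
  co <- add_twin_traits(pair_cohort())
  td <- assemble_twin_pairs(co, "t_vol_l", covariates = NULL)
  sat <- fit_saturated(td)
  r <- sat$twin_correlations
  se <- function(rho, n) (1 - rho^2) / sqrt(n)
  expect_lt(abs(r$r[r$zygosity == "MZ"] - 0.76), 3 * se(0.76, 2500))
  expect_lt(abs(r$r[r$zygosity == "DZ"] - 0.38), 3 * se(0.38, 2500))
})

test_that("AE maximum likelihood recovers planted heritability", {
  co <- add_twin_traits(pair_cohort())
  td <- assemble_twin_pairs(co, "t_vol_l", covariates = NULL)
  fit <- fit_biometric(td, "AE")
  expect_lt(abs(fit$h2[["t_vol_l"]] - 0.76), 0.03)
  # the saturated likelihood dominates any constrained model on the same data
  sat <- fit_saturated(td)
  expect_gte(sat$loglik, fit$loglik - 1e-6)
  # implied MZ correlation exceeds implied DZ correlation under AE
  td_fit <- tidy(fit)
  expect_gt(td_fit$r_mz, td_fit$r_dz)
  # Falconer heuristic agrees with ML within sampling error
  satr <- sat$twin_correlations
  falconer <- 2 * (satr$r[satr$zygosity == "MZ"] - satr$r[satr$zygosity == "DZ"])
  expect_lt(abs(falconer - fit$h2[["t_vol_l"]]), 0.08)
})

test_that("environment-only data yield near-zero heritability", {
  withr::local_seed(71)
  n <- 600
  mk <- function(role1, role2, m) {
    tibble::tibble(
      person_id = paste0(role1, seq_len(2 * m)),
      family_id = rep(paste0(role1, "f", seq_len(m)), each = 2),
      zygosity_role = rep(c(role1, role2), m),
      trait = stats::rnorm(2 * m)
    )
  }
  co <- dplyr::bind_rows(mk("MZ1", "MZ2", n), mk("DZ1", "DZ2", n))
  td <- assemble_twin_pairs(co, "trait", covariates = NULL)
  fit <- fit_biometric(td, "AE")
  expect_lt(fit$h2[["trait"]], 0.12)
  imp <- tidy(fit)
  expect_lt(abs(imp$r_mz), 0.12)
  expect_lt(abs(imp$r_mz - imp$r_dz), 0.12)
})

test_that("ADE on AE-generated data leaves D small and droppable", {
  co <- add_twin_traits(pair_cohort())
  td <- assemble_twin_pairs(pair_subset(co, 750, 750), "t_vol_l", covariates = NULL)
  ade <- fit_biometric(td, "ADE")
  ae <- fit_biometric(td, "AE")
  expect_lt(ade$d2[["t_vol_l"]], 0.25)
  lrt <- likelihood_ratio_test(ade, ae)
  expect_equal(lrt$df, 1)
  expect_true(lrt$boundary)
  expect_lt(lrt$chisq, stats::qchisq(0.999, 1))
})

test_that("the genetic-covariance drop has the 4-parameter structure", {
  co <- add_twin_traits(simulate_cohort(sim_params(seed = 6)))
  traits <- c("t_swb", "t_vol_l", "t_vol_r", "t_vol_l2", "t_vol_r2")
  td <- assemble_twin_pairs(co, traits, covariates = NULL,
                            keep_incomplete = FALSE)
  ae <- fit_biometric(td, "AE")
  ae_nog <- fit_biometric(td, "AE", drop_a_cross = TRUE)
  lrt <- likelihood_ratio_test(ae, ae_nog)
  expect_equal(lrt$df, 4)  # the four SWB-volume genetic covariances
  expect_gte(lrt$chisq, 0)
  expect_true(lrt$p.value >= 0 && lrt$p.value <= 1)
  ae_noe <- fit_biometric(td, "AE", drop_e_cross = TRUE)
  expect_equal(likelihood_ratio_test(ae, ae_noe)$df, 4)
})

test_that("likelihood-ratio testing validates nesting and observations", {
  co <- add_twin_traits(pair_cohort())
  td <- assemble_twin_pairs(pair_subset(co, 250, 250), "t_vol_l", covariates = NULL)
  ae <- fit_biometric(td, "AE")
  expect_error(likelihood_ratio_test(ae, ae), "fewer parameters")
  # identical models give chi-square 0, p = 1
  ade <- fit_biometric(td, "ADE")
  self_test <- tibble::tibble(chisq = 2 * (ade$loglik - ade$loglik))
  expect_equal(chi2_sf(self_test$chisq, 1), 1)
  # fits on different observations are refused
  td_less <- assemble_twin_pairs(pair_subset(co, 150, 150), "t_vol_l", covariates = NULL)
  ae_less <- fit_biometric(td_less, "AE", drop_a_cross = FALSE)
  e_less <- fit_biometric(td_less, "E")
  expect_error(likelihood_ratio_test(ae, e_less), "different observations")
  # chi-square equals twice the log-likelihood gap
  e_fit <- fit_biometric(td, "E")
  lrt <- likelihood_ratio_test(ae, e_fit)
  expect_equal(lrt$chisq, 2 * (ae$loglik - e_fit$loglik))
})

test_that("chi-square survival matches published value and quadrature", {
  expect_lt(abs(chi2_sf(1.41, 4) - 0.842), 5e-4)
  expect_equal(chi2_sf(0, 7), 1)
  # adaptive-quadrature oracle for the upper tail
  quad <- stats::integrate(function(u) stats::dchisq(u, 15), 9.27, Inf,
                           rel.tol = 1e-10)$value
  expect_equal(chi2_sf(9.27, 15), quad, tolerance = 1e-6)
  expect_error(chi2_sf(-1, 4), "nonnegative")
  expect_error(chi2_sf(1, 0), "df")
})
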