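test_that("zscore standardizes with the n-1 denominator and inverts", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  x <- stats::rnorm(50, 10, 3)
  z <- zscore(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  expect_equal(z * stats::sd(x) + mean(x), x, tolerance = 1e-10)
  expect_error(zscore(rep(2, 5)), "constant")
})

test_that("kinship matrix has the MZ/DZ/sibling block structure", {
  mz <- tibble::tibble(person_id = c("a", "b"), family_id = "f",
                       zygosity_role = c("MZ1", "MZ2"))
  expect_equal(unclass(build_kinship(mz)),
               matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b"))))
  single <- tibble::tibble(person_id = "a", family_id = "f",
                           zygosity_role = "MZ1")
  expect_equal(unname(unclass(build_kinship(single))), matrix(1))
  dzsib <- tibble::tibble(person_id = c("a", "b", "c"), family_id = "f",
                          zygosity_role = c("DZ1", "DZ2", "SIB"))
  K <- unname(unclass(build_kinship(dzsib)))
  expect_equal(K, matrix(c(1, .5, .5, .5, 1, .5, .5, .5, 1), 3))
  dup <- tibble::tibble(person_id = c("a", "a"), family_id = c("f", "g"),
                        zygosity_role = c("MZ1", "MZ1"))
  expect_error(build_kinship(dup), "more than once")
})

test_that("fixed effects equal the generalized-least-squares closed form", {
  withr::local_seed(42)
  ped <- tibble::tibble(
    person_id = paste0("p", 1:120), family_id = rep(paste0("f", 1:60), each = 2),
    zygosity_role = rep(c("MZ1", "MZ2"), 30 * 2)[1:120]
  )
  ped$zygosity_role[61:120] <- rep(c("DZ1", "DZ2"), 30)
  K <- unclass(build_kinship(ped))
  V <- 0.6 * K + 0.4 * diag(120)
  df <- tibble::tibble(x1 = stats::rnorm(120), x2 = stats::rnorm(120))
  df$y <- drop(1 + 0.5 * df$x1 + draw_mvn(chol(V)))
  fit <- fit_kinship_lmm(df, y ~ x1 + x2, kinship = build_kinship(ped))
  # direct matrix-formula oracle at the fitted variance components
  Vhat <- fit$sigma2_g * K + fit$sigma2_e * diag(120)
  X <- cbind(1, df$x1, df$x2)
  beta_gls <- solve(t(X) %*% solve(Vhat) %*% X, t(X) %*% solve(Vhat, df$y))
  expect_equal(unname(fit$beta), drop(beta_gls), tolerance = 1e-8)
})

test_that("identity kinship collapses to ordinary least squares", {
  withr::local_seed(7)
  ped <- singleton_cohort(150)
  df <- tibble::tibble(x = stats::rnorm(150))
  df$y <- 2 + 0.3 * df$x + stats::rnorm(150)
  fit <- fit_kinship_lmm(df, y ~ x, kinship = build_kinship(ped))
  ols <- stats::lm(y ~ x, data = df)
  expect_equal(unname(fit$beta), unname(stats::coef(ols)), tolerance = 1e-7)
  # components are individually unidentified; their sum is the ML variance
  expect_equal(fit$sigma2_g + fit$sigma2_e,
               sum(stats::resid(ols)^2) / 150, tolerance = 1e-6)
})

test_that("variance components are recovered in twin-structured data", {
  withr::local_seed(99)
  n_pair <- 500
  ped <- tibble::tibble(
    person_id = paste0("p", seq_len(2 * n_pair)),
    family_id = rep(paste0("f", seq_len(n_pair)), each = 2),
    zygosity_role = c(rep(c("MZ1", "MZ2"), n_pair / 2),
                      rep(c("DZ1", "DZ2"), n_pair / 2))
  )
  K <- unclass(build_kinship(ped))
  V <- 0.6 * K + 0.4 * diag(nrow(K))
  df <- tibble::tibble(y = drop(draw_mvn(chol(V))))
  fit <- fit_kinship_lmm(df, y ~ 1, kinship = build_kinship(ped))
  # ~3 SE bounds at this size
  expect_lt(abs(fit$sigma2_g - 0.6), 0.15)
  expect_lt(abs(fit$sigma2_e - 0.4), 0.10)
})

test_that("ML solution is a local optimum of the likelihood", {
  withr::local_seed(13)
  ped <- tibble::tibble(
    person_id = paste0("p", 1:80), family_id = rep(paste0("f", 1:40), each = 2),
    zygosity_role = rep(c("DZ1", "DZ2"), 40)
  )
  K <- unclass(build_kinship(ped))
  df <- tibble::tibble(y = drop(draw_mvn(chol(0.5 * K + 0.5 * diag(80)))))
  fit <- fit_kinship_lmm(df, y ~ 1, kinship = build_kinship(ped))
  loglik_at <- function(sg, se) {
    V <- sg * K + se * diag(80)
    r <- df$y - mean(df$y)
    mu <- drop(solve(t(rep(1, 80)) %*% solve(V, rep(1, 80)),
                     t(rep(1, 80)) %*% solve(V, df$y)))
    r <- df$y - mu
    -0.5 * (80 * log(2 * pi) + determinant(V)$modulus[1] +
              drop(t(r) %*% solve(V, r)))
  }
  base <- loglik_at(fit$sigma2_g, fit$sigma2_e)
  expect_equal(base, fit$loglik, tolerance = 1e-6)
  for (eps in c(0.9, 1.1)) {
    expect_lte(loglik_at(fit$sigma2_g * eps, fit$sigma2_e), base + 1e-8)
    expect_lte(loglik_at(fit$sigma2_g, fit$sigma2_e * eps), base + 1e-8)
  }
})

test_that("single-coefficient F equals the squared Wald ratio", {
  co <- default_cohort()
  fit <- fit_region_model(co, "volume_hippocampus_l")
  res <- test_fixed_term(fit, "vol_lin")
  expect_equal(res$statistic, (res$estimate / res$std.error)^2)
  expect_error(test_fixed_term(fit, "not_a_term"), "unknown term")
})

test_that("with identity kinship the F test matches classical ANOVA", {
  withr::local_seed(21)
  n <- 90
  ped <- singleton_cohort(n)
  df <- tibble::tibble(g = factor(rep(c("a", "b"), each = n / 2)),
                       y = stats::rnorm(n))
  fit <- fit_kinship_lmm(df, y ~ g, kinship = build_kinship(ped))
  res <- test_fixed_term(fit, "gb", ddf_method = "residual")
  # textbook one-way ANOVA oracle from group means
  m <- tapply(df$y, df$g, mean)
  ssb <- sum(table(df$g) * (m - mean(df$y))^2)
  ssw <- sum((df$y - m[df$g])^2)
  f_oracle <- ssb / (ssw / (n - 2))
  # ML residual variance uses n, the ANOVA uses n - 2; rescale
  expect_equal(res$statistic * (n - 2) / n, f_oracle, tolerance = 1e-6)
})

test_that("null p-values are uniform in twin-structured simulations", {
  withr::local_seed(123)
  n_pair <- 100
  ped <- tibble::tibble(
    person_id = paste0("p", seq_len(2 * n_pair)),
    family_id = rep(paste0("f", seq_len(n_pair)), each = 2),
    zygosity_role = c(rep(c("MZ1", "MZ2"), n_pair / 2),
                      rep(c("DZ1", "DZ2"), n_pair / 2))
  )
  ed <- kinship_decompose(build_kinship(ped))
  Vc <- chol(0.5 * unclass(build_kinship(ped)) + 0.5 * diag(2 * n_pair))
  x <- stats::rnorm(2 * n_pair)
  pvals <- vapply(seq_len(200), function(i) {
    df <- tibble::tibble(x = x, y = drop(draw_mvn(Vc)))
    fit <- fit_kinship_lmm(df, y ~ x, kinship = ed)
    test_fixed_term(fit, "x")$p.value
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("rank-deficient designs are rejected with the aliased columns", {
  co <- default_cohort()[1:50, ]
  df <- tibble::tibble(y = co$swb, a = co$age_mri, b = co$age_mri * 2)
  expect_error(fit_kinship_lmm(df, y ~ a + b, kinship = build_kinship(co[1:50, ])),
               "rank deficient.*b")
})
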