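#' Univariate LD-score regression for SNP-heritability
#'
#' Regresses squared association Z-scores on per-SNP LD scores under the
#' expectation `E[z^2] = N * h2 * l / M + intercept`, so the heritability is
#' `slope * M / N`. Weights follow the standard heteroskedasticity form
#' `1 / (2 * (N * h2 * l / M + 1)^2 * l)` computed from a first unweighted
#' pass (set `weighted = FALSE` for plain least squares). Standard errors
#' come from a delete-one block jackknife over contiguous SNP blocks.
#'
#' @param z Vector of association Z-scores.
#' @param ell LD scores (all >= 1).
#' @param N GWAS sample size.
#' @param M Number of SNPs the heritability refers to (default `length(z)`).
#' @param n_blocks Jackknife blocks (default 200, reduced for small M so
#'   every block has at least 2 SNPs).
#' @param weighted Use LDSC weights (default) or unweighted regression.
#' @param constrain_intercept Fix the intercept at 1 instead of estimating.
#' @return Tibble with `h2`, `h2_se`, `intercept`, `intercept_se`,
#'   `n_blocks`.
#' @export
h2_regression <- function(z, ell, N, M = length(z), n_blocks = 200,
                          weighted = TRUE, constrain_intercept = FALSE) {
  stopifnot(length(z) == length(ell))
  if (any(!is.finite(z)) || any(!is.finite(ell))) {
    stop("z and ell must be finite", call. = FALSE)
  }
  if (any(ell < 1)) stop("LD scores must be >= 1 (a SNP is in LD with itself)",
                         call. = FALSE)
  n_blocks <- adjust_blocks(length(z), n_blocks)
  fit <- ldsc_wreg(z^2, ell, N = N, M = M, n_blocks = n_blocks,
                   weighted = weighted, constrain_intercept = constrain_intercept,
                   scale = N / M)
  tibble::tibble(h2 = fit$coef, h2_se = fit$se,
                 intercept = fit$intercept, intercept_se = fit$intercept_se,
                 n_blocks = n_blocks)
}

adjust_blocks <- function(n_snps, n_blocks) {
  n_blocks <- min(n_blocks, floor(n_snps / 2))
  if (n_blocks < 2) stop("fewer SNPs than jackknife blocks", call. = FALSE)
  n_blocks
}

# weighted regression of `resp` on `ell`, slope rescaled by 1/scale so the
# returned coefficient is on the h2 / rho_g scale; block-jackknife SE
ldsc_wreg <- function(resp, ell, N, M, n_blocks, weighted,
                      constrain_intercept, scale) {
  n <- length(resp)
  block <- ceiling(seq_len(n) / (n / n_blocks))
  block[block > n_blocks] <- n_blocks
  w <- rep(1, n)
  if (weighted) {
    sl0 <- unweighted_slope(resp, ell, constrain_intercept)
    expz <- pmax(sl0 * ell + 1, 0.05)
    w <- 1 / (2 * expz^2 * pmax(ell, 1))
  }
  est <- function(keep) {
    x <- ell[keep]; y <- resp[keep]; wk <- w[keep]
    if (constrain_intercept) {
      slope <- sum(wk * x * (y - 1)) / sum(wk * x^2)
      c(slope, 1)
    } else {
      sw <- sum(wk)
      mx <- sum(wk * x) / sw; my <- sum(wk * y) / sw
      slope <- sum(wk * (x - mx) * (y - my)) / sum(wk * (x - mx)^2)
      c(slope, my - slope * mx)
    }
  }
  full <- est(rep(TRUE, n))
  jack <- vapply(seq_len(n_blocks), function(b) est(block != b),
                 numeric(2))
  # delete-one jackknife variance
  jk_se <- function(theta_full, theta_del) {
    g <- n_blocks
    ps <- g * theta_full - (g - 1) * theta_del
    sqrt(stats::var(ps) / g)
  }
  list(coef = full[1] / scale, se = jk_se(full[1], jack[1, ]) / scale,
       intercept = full[2], intercept_se = jk_se(full[2], jack[2, ]))
}

unweighted_slope <- function(resp, ell, constrain_intercept) {
  if (constrain_intercept) {
    sum(ell * (resp - 1)) / sum(ell^2)
  } else {
    stats::cov(ell, resp) / stats::var(ell)
  }
}

#' Bivariate LD-score regression for the genetic correlation
#'
#' Estimates each trait's SNP-heritability by [h2_regression()], the
#' genetic covariance by regressing `z1 * z2` on the LD scores
#' (`rho_g = slope * M / sqrt(N1 * N2)`), and reports
#' `rg = rho_g / sqrt(h2_1 * h2_2)` with a delete-one block-jackknife SE of
#' the full ratio (all three regressions recomputed per left-out block),
#' `Z = rg / SE` and the two-tailed normal p-value.
#'
#' @param pair A [simulate_gwas_pair()] object, or a list with elements
#'   `snps` (tibble `ld_score`, `z1`, `z2`), `N1`, `N2`, `M`.
#' @param n_blocks Jackknife blocks (default 200, auto-reduced).
#' @param weighted Use LDSC weights.
#' @return Tibble of class `swb_ldsc`: `h2_1`, `h2_2`, `rho_g`, `rg`,
#'   `rg_se`, `z`, `p.value`, `intercept_1`, `intercept_2`,
#'   `intercept_cross`, `defined` (FALSE when an estimated h2 is
#'   nonpositive, in which case `rg` is NA).
#' @export
rg_regression <- function(pair, n_blocks = 200, weighted = TRUE) {
  s <- pair$snps
  n <- nrow(s)
  n_blocks <- adjust_blocks(n, n_blocks)
  block <- ceiling(seq_len(n) / (n / n_blocks))
  block[block > n_blocks] <- n_blocks
  scale1 <- pair$N1 / pair$M
  scale2 <- pair$N2 / pair$M
  scale12 <- sqrt(pair$N1 * pair$N2) / pair$M

  w <- rep(1, n)
  if (weighted) {
    e1 <- pmax(unweighted_slope(s$z1^2, s$ld_score, FALSE) * s$ld_score + 1, 0.05)
    e2 <- pmax(unweighted_slope(s$z2^2, s$ld_score, FALSE) * s$ld_score + 1, 0.05)
    w <- 1 / (2 * e1 * e2 * pmax(s$ld_score, 1))
  }
  slope_int <- function(y, keep) {
    x <- s$ld_score[keep]; yy <- y[keep]; wk <- w[keep]
    sw <- sum(wk)
    mx <- sum(wk * x) / sw; my <- sum(wk * yy) / sw
    slope <- sum(wk * (x - mx) * (yy - my)) / sum(wk * (x - mx)^2)
    c(slope, my - slope * mx)
  }
  rg_of <- function(keep) {
    f1 <- slope_int(s$z1^2, keep)
    f2 <- slope_int(s$z2^2, keep)
    fx <- slope_int(s$z1 * s$z2, keep)
    h1 <- f1[1] / scale1; h2 <- f2[1] / scale2; rho <- fx[1] / scale12
    rg <- if (h1 > 0 && h2 > 0) rho / sqrt(h1 * h2) else NA_real_
    c(h1, h2, rho, rg, f1[2], f2[2], fx[2])
  }
  full <- rg_of(rep(TRUE, n))
  defined <- is.finite(full[4])
  rg_se <- NA_real_
  if (defined) {
    jack <- vapply(seq_len(n_blocks), function(b) rg_of(block != b)[4], numeric(1))
    ok <- is.finite(jack)
    g <- sum(ok)
    ps <- g * full[4] - (g - 1) * jack[ok]
    rg_se <- sqrt(stats::var(ps) / g)
  }
  z <- if (defined && is.finite(rg_se) && rg_se > 0) full[4] / rg_se else NA_real_
  out <- tibble::tibble(
    h2_1 = full[1], h2_2 = full[2], rho_g = full[3],
    rg = full[4], rg_se = rg_se, z = z,
    p.value = if (is.finite(z)) z_two_tailed(z) else NA_real_,
    intercept_1 = full[5], intercept_2 = full[6], intercept_cross = full[7],
    defined = defined
  )
  class(out) <- c("swb_ldsc", class(out))
  out
}

#' Two-tailed normal p-value
#'
#' `2 * (1 - Phi(|z|))` with `Phi` the standard normal CDF.
#'
#' @param z Finite Z statistic.
#' @return Two-tailed p-value.
#' @export
#' @examples
#' z_two_tailed(-0.695)
z_two_tailed <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite", call. = FALSE)
  2 * stats::pnorm(-abs(z))
}
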