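#' Add the five twin-model trait columns to a cohort
#'
#' The multivariate twin model uses SWB, the Z-scored left and right region
#' volumes, and their squares. Volumes are standardized over the full cohort
#' (covariate-free) before squaring; the means model carries study, age and
#' sex instead.
#'
#' @param cohort Cohort tibble.
#' @param region Region name (default `"hippocampus"`).
#' @return The cohort with columns `t_swb`, `t_vol_l`, `t_vol_r`,
#'   `t_vol_l2`, `t_vol_r2` appended.
#' @export
add_twin_traits <- function(cohort, region = "hippocampus") {
  zl <- zscore(cohort[[paste0("volume_", region, "_l")]])
  zr <- zscore(cohort[[paste0("volume_", region, "_r")]])
  cohort$t_swb <- cohort$swb
  cohort$t_vol_l <- zl
  cohort$t_vol_r <- zr
  cohort$t_vol_l2 <- zl^2
  cohort$t_vol_r2 <- zr^2
  cohort
}

#' Assemble MZ and DZ twin pairs as stacked trait vectors
#'
#' Builds one length-2p observation vector per twin pair (twin 1 traits then
#' twin 2 traits). Single twins are retained as incomplete pairs with
#' missing entries for full-information handling; extra siblings are
#' excluded from twin modeling.
#'
#' @param cohort Cohort tibble.
#' @param traits Character vector of trait columns (order defines the trait
#'   order; put SWB first if covariance-drop tests on it are planned).
#' @param covariates Columns for the per-trait means model (default study,
#'   age at MRI, sex); `NULL` for intercept-only means.
#' @param keep_incomplete Retain single twins as half-missing pairs.
#' @return List of class `swb_twin_data`: per zygosity a matrix `y`
#'   (pairs x 2p) and covariate matrices `x1`, `x2` (pairs x q), plus trait
#'   and design metadata.
#' @export
assemble_twin_pairs <- function(cohort, traits,
                                covariates = c("study", "age_mri", "sex"),
                                keep_incomplete = TRUE) {
  stopifnot(all(traits %in% names(cohort)))
  p <- length(traits)
  roles <- cohort$zygosity_role
  twin_rows <- which(roles %in% c("MZ1", "MZ2", "DZ1", "DZ2"))
  sub <- cohort[twin_rows, , drop = FALSE]
  # covariate design built once so dummy coding matches across groups
  if (is.null(covariates)) {
    X <- matrix(1, nrow(sub), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    cdf <- tibble::as_tibble(sub[, covariates, drop = FALSE])
    for (v in intersect(c("study", "sex"), covariates)) {
      cdf[[v]] <- factor(cdf[[v]])
      if (nlevels(cdf[[v]]) < 2) cdf[[v]] <- NULL
    }
    X <- stats::model.matrix(~., data = cdf)
  }
  TM <- as.matrix(sub[, traits, drop = FALSE])
  fam_rows <- split(seq_len(nrow(sub)), sub$family_id)
  conflict <- vapply(fam_rows, function(rr) {
    zr <- sub$zygosity_role[rr]
    any(zr %in% c("MZ1", "MZ2")) && any(zr %in% c("DZ1", "DZ2"))
  }, logical(1))
  if (any(conflict)) {
    stop("zygosity conflict within family ",
         names(fam_rows)[which(conflict)[1]], call. = FALSE)
  }
  out <- list()
  for (zyg in c("MZ", "DZ")) {
    r1 <- paste0(zyg, "1"); r2 <- paste0(zyg, "2")
    has_zyg <- vapply(fam_rows, function(rr) {
      any(sub$zygosity_role[rr] %in% c(r1, r2))
    }, logical(1))
    ylist <- list(); x1l <- list(); x2l <- list()
    for (rows in fam_rows[has_zyg]) {
      zr <- sub$zygosity_role[rows]
      i1 <- rows[zr == r1][1]
      i2 <- rows[zr == r2][1]
      y1 <- if (!is.na(i1)) TM[i1, ] else rep(NA_real_, p)
      y2 <- if (!is.na(i2)) TM[i2, ] else rep(NA_real_, p)
      if (all(is.na(c(y1, y2)))) next
      if (!keep_incomplete && (anyNA(y1) || anyNA(y2))) next
      ylist[[length(ylist) + 1]] <- c(y1, y2)
      x1l[[length(x1l) + 1]] <- X[if (!is.na(i1)) i1 else i2, ]
      x2l[[length(x2l) + 1]] <- X[if (!is.na(i2)) i2 else i1, ]
    }
    out[[zyg]] <- list(
      y = do.call(rbind, ylist) %||% matrix(numeric(0), 0, 2 * p),
      x1 = do.call(rbind, x1l) %||% matrix(numeric(0), 0, ncol(X)),
      x2 = do.call(rbind, x2l) %||% matrix(numeric(0), 0, ncol(X))
    )
  }
  structure(list(MZ = out$MZ, DZ = out$DZ, p = p, traits = traits,
                 q = ncol(X), x_names = colnames(X)),
            class = "swb_twin_data")
}

#' Expected twin-pair covariance under ADE components
#'
#' For MZ pairs the within-twin blocks are `Sigma_A + Sigma_D + Sigma_E`
#' and the cross-twin blocks `Sigma_A + Sigma_D`; for DZ pairs the
#' cross-twin blocks are `0.5 * Sigma_A + 0.25 * Sigma_D`, the expected
#' additive and dominance genetic correlations among DZ twins.
#'
#' @param sigma_a,sigma_d,sigma_e p x p component covariance matrices.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return The symmetric 2p x 2p expected covariance matrix.
#' @export
#' @examples
#' expected_twin_cov(matrix(2), matrix(1), matrix(3), "DZ")
expected_twin_cov <- function(sigma_a, sigma_d, sigma_e, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  within <- sigma_a + sigma_d + sigma_e
  cross <- if (zygosity == "MZ") sigma_a + sigma_d else 0.5 * sigma_a + 0.25 * sigma_d
  cross <- (cross + t(cross)) / 2
  rbind(cbind(within, cross), cbind(cross, within))
}

# --- internal FIML machinery ------------------------------------------------

# precompute per missingness-pattern sufficient statistics
twin_groups <- function(td) {
  groups <- list()
  for (zyg in c("MZ", "DZ")) {
    g <- td[[zyg]]
    if (!nrow(g$y)) next
    pat <- apply(!is.na(g$y), 1, function(o) paste(which(o), collapse = ","))
    for (pt in unique(pat)) {
      rows <- which(pat == pt)
      obs <- as.integer(strsplit(pt, ",")[[1]])
      Y <- g$y[rows, obs, drop = FALSE]
      X1 <- g$x1[rows, , drop = FALSE]
      X2 <- g$x2[rows, , drop = FALSE]
      groups[[length(groups) + 1]] <- list(
        zyg = zyg, obs = obs, n = length(rows), Y = Y, X1 = X1, X2 = X2,
        Syy = crossprod(Y),
        C = list(crossprod(X1), crossprod(X1, X2), crossprod(X2, X1), crossprod(X2)),
        M1 = crossprod(X1, Y), M2 = crossprod(X2, Y)
      )
    }
  }
  groups
}

# concentrated log-likelihood: GLS-profiled means given Sigma_MZ / Sigma_DZ
twin_loglik_profiled <- function(groups, sigma_mz, sigma_dz, p, q) {
  d <- p * q
  A <- matrix(0, d, d)
  b <- numeric(d)
  info <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    S <- (if (g$zyg == "MZ") sigma_mz else sigma_dz)[g$obs, g$obs, drop = FALSE]
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    W <- chol2inv(ch)
    logdet <- 2 * sum(log(diag(ch)))
    m <- length(g$obs)
    tw <- ifelse(g$obs > p, 2L, 1L)     # which twin each observed element is
    tr <- ifelse(g$obs > p, g$obs - p, g$obs)  # which trait
    Ag <- matrix(0, d, d)
    bg <- numeric(d)
    for (r in seq_len(m)) {
      ir <- (tr[r] - 1) * q + seq_len(q)
      Mr <- if (tw[r] == 1) g$M1 else g$M2
      bg[ir] <- bg[ir] + drop(Mr %*% W[r, ])
      for (s in seq_len(m)) {
        is_ <- (tr[s] - 1) * q + seq_len(q)
        Crs <- g$C[[(tw[r] - 1) * 2 + tw[s]]]
        Ag[ir, is_] <- Ag[ir, is_] + W[r, s] * Crs
      }
    }
    A <- A + Ag
    b <- b + bg
    info[[k]] <- list(W = W, logdet = logdet, Ag = Ag, bg = bg)
  }
  beta <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  ll <- 0
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    i <- info[[k]]
    quad <- sum(i$W * g$Syy) - 2 * sum(i$bg * beta) +
      drop(t(beta) %*% i$Ag %*% beta)
    ll <- ll - 0.5 * (g$n * length(g$obs) * log(2 * pi) +
                        g$n * i$logdet + quad)
  }
  list(loglik = ll, beta = beta)
}

ltri_index <- function(p) which(lower.tri(diag(p), diag = TRUE))

# mask: TRUE entries of the lower triangle that are free parameters
chol_mask <- function(p, drop_cross = FALSE) {
  m <- lower.tri(diag(p), diag = TRUE)
  if (drop_cross && p > 1) m[2:p, 1] <- FALSE  # zero covariances with trait 1
  m
}

unpack_chol <- function(theta, p, mask) {
  L <- matrix(0, p, p)
  L[mask] <- theta
  L
}

#' Fit a biometric (ADE / AE / E) twin covariance model by maximum likelihood
#'
#' Estimates the additive genetic (A), dominance genetic (D) and unshared
#' environmental (E) covariance components of the traits from MZ and DZ
#' pair data, by full-information maximum likelihood over all observed
#' entries. Each included component is parameterized through its Cholesky
#' factor, so estimates are positive semi-definite by construction; the
#' per-trait means are profiled out exactly by generalized least squares at
#' every likelihood evaluation.
#'
#' @param td [assemble_twin_pairs()] data.
#' @param model `"ADE"`, `"AE"` or `"E"`.
#' @param drop_a_cross,drop_e_cross Constrain the covariances between trait
#'   1 and all other traits to zero in A (resp. E); used for the omnibus
#'   genetic / environmental correlation tests.
#' @param n_restarts Extra jittered starts if the first optimization fails.
#' @param reltol Relative convergence tolerance on the log-likelihood.
#' @return Object of class `swb_twin_fit`: component matrices, `h2` per
#'   trait, genetic (`rg`) and environmental (`re`) correlation matrices,
#'   `loglik`, `n_par`, means `beta`, and convergence info.
#' @export
fit_biometric <- function(td, model = c("ADE", "AE", "E"),
                          drop_a_cross = FALSE, drop_e_cross = FALSE,
                          n_restarts = 4, reltol = 1e-10) {
  model <- match.arg(model)
  p <- td$p; q <- td$q
  if (model %in% c("ADE", "AE")) {
    if (!nrow(td$MZ$y) || !nrow(td$DZ$y)) {
      stop(model, " model is unidentified without both MZ and DZ pairs",
           call. = FALSE)
    }
  }
  comps <- switch(model, ADE = c("A", "D", "E"), AE = c("A", "E"), E = "E")
  masks <- list(
    A = chol_mask(p, drop_a_cross),
    D = chol_mask(p, FALSE),
    E = chol_mask(p, drop_e_cross)
  )[comps]
  sizes <- vapply(masks, sum, integer(1))
  groups <- twin_groups(td)

  S0 <- start_phenotypic_cov(td)
  prop <- switch(model, ADE = c(A = 0.4, D = 0.15, E = 0.45),
                 AE = c(A = 0.5, E = 0.5), E = c(E = 1))
  theta0 <- unlist(lapply(comps, function(cm) {
    L <- tryCatch(t(chol(prop[[cm]] * S0 + 1e-8 * mean(diag(S0)) * diag(p))),
                  error = function(e) diag(sqrt(prop[[cm]] * diag(S0)), p))
    L[masks[[cm]]]
  }))

  build <- function(theta) {
    out <- list(A = matrix(0, p, p), D = matrix(0, p, p), E = matrix(0, p, p))
    off <- 0
    for (cm in comps) {
      L <- unpack_chol(theta[off + seq_len(sizes[[cm]])], p, masks[[cm]])
      out[[cm]] <- tcrossprod(L)
      off <- off + sizes[[cm]]
    }
    out
  }
  obj <- function(theta) {
    cm <- build(theta)
    res <- twin_loglik_profiled(groups,
                                expected_twin_cov(cm$A, cm$D, cm$E, "MZ"),
                                expected_twin_cov(cm$A, cm$D, cm$E, "DZ"),
                                p, q)
    if (is.null(res) || !is.finite(res$loglik)) return(1e10)
    -res$loglik
  }
  best <- NULL
  for (r in 0:n_restarts) {
    th <- if (r == 0) theta0 else {
      theta0 * withr::with_seed(1000L + r,
                                stats::runif(length(theta0), 0.6, 1.4))
    }
    op <- tryCatch(stats::nlminb(th, obj, control = list(rel.tol = reltol,
                                                         iter.max = 2000,
                                                         eval.max = 5000)),
                   error = function(e) NULL)
    if (!is.null(op) && is.finite(op$objective)) {
      if (is.null(best) || op$objective < best$objective - 1e-9) best <- op
      if (op$convergence == 0 && r >= 1) break
      if (op$convergence == 0 && r == 0) break
    }
  }
  if (is.null(best)) {
    stop("twin model failed to converge after restarts; ",
         "check pair counts and trait scaling", call. = FALSE)
  }
  cm <- build(best$par)
  res <- twin_loglik_profiled(groups,
                              expected_twin_cov(cm$A, cm$D, cm$E, "MZ"),
                              expected_twin_cov(cm$A, cm$D, cm$E, "DZ"),
                              p, q)
  ph <- cm$A + cm$D + cm$E
  safe_cor <- function(S) {
    d <- sqrt(pmax(diag(S), 0))
    out <- S / outer(d, d)
    out[!is.finite(out)] <- NA_real_
    dimnames(out) <- list(td$traits, td$traits)
    out
  }
  structure(list(
    model = model, traits = td$traits,
    sigma_a = cm$A, sigma_d = cm$D, sigma_e = cm$E, sigma_ph = ph,
    h2 = stats::setNames(diag(cm$A) / diag(ph), td$traits),
    d2 = stats::setNames(diag(cm$D) / diag(ph), td$traits),
    rg = safe_cor(cm$A), re = safe_cor(cm$E),
    beta = res$beta, loglik = res$loglik,
    n_par = sum(sizes) + p * q,
    n_cov_par = sum(sizes),
    n_pairs = c(MZ = nrow(td$MZ$y), DZ = nrow(td$DZ$y)),
    n_obs = sum(vapply(groups, function(g) g$n * length(g$obs), numeric(1))),
    drop_a_cross = drop_a_cross, drop_e_cross = drop_e_cross,
    convergence = best$convergence
  ), class = "swb_twin_fit")
}

# crude phenotypic covariance for starting values: covariate-adjusted
# complete-entry covariance across twin individuals
start_phenotypic_cov <- function(td) {
  p <- td$p
  Y <- rbind(td$MZ$y[, seq_len(p), drop = FALSE],
             td$MZ$y[, p + seq_len(p), drop = FALSE],
             td$DZ$y[, seq_len(p), drop = FALSE],
             td$DZ$y[, p + seq_len(p), drop = FALSE])
  S <- stats::cov(Y, use = "pairwise.complete.obs")
  S[!is.finite(S)] <- 0
  # ridge toward the diagonal if degenerate
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * max(ev)) S <- S + 0.05 * mean(diag(S)) * diag(p)
  S
}

#' Fit the saturated twin model
#'
#' Estimates unconstrained MZ and DZ 2p x 2p covariance matrices with the
#' per-trait covariate means model, by exact maximum likelihood on complete
#' pairs (iterating the generalized-least-squares means and the residual
#' covariance to convergence). Returns the baseline log-likelihood and the
#' per-trait cross-twin correlations.
#'
#' @param td [assemble_twin_pairs()] data (incomplete pairs are dropped
#'   here; biometric fits handle them by full information).
#' @param tol Convergence tolerance on the log-likelihood.
#' @return Object of class `swb_twin_sat` with `sigma_mz`, `sigma_dz`,
#'   `twin_correlations` tibble, `loglik`, `n_par`, `beta`.
#' @export
fit_saturated <- function(td, tol = 1e-10) {
  p <- td$p; q <- td$q
  complete <- lapply(c("MZ", "DZ"), function(z) {
    g <- td[[z]]
    keep <- stats::complete.cases(g$y)
    list(y = g$y[keep, , drop = FALSE], x1 = g$x1[keep, , drop = FALSE],
         x2 = g$x2[keep, , drop = FALSE])
  })
  names(complete) <- c("MZ", "DZ")
  for (z in c("MZ", "DZ")) {
    if (nrow(complete[[z]]$y) < p + 1) {
      stop("need more than p complete ", z,
           " pairs for the saturated model", call. = FALSE)
    }
  }
  td2 <- structure(list(MZ = complete$MZ, DZ = complete$DZ, p = p,
                        traits = td$traits, q = q, x_names = td$x_names),
                   class = "swb_twin_data")
  groups <- twin_groups(td2)
  smz <- stats::cov(complete$MZ$y); sdz <- stats::cov(complete$DZ$y)
  ll_old <- -Inf
  for (it in 1:200) {
    res <- twin_loglik_profiled(groups, smz, sdz, p, q)
    if (is.null(res)) stop("singular covariance estimate; more data needed",
                           call. = FALSE)
    # covariance update given means: mean residual cross-products
    for (z in c("MZ", "DZ")) {
      g <- complete[[z]]
      fitted <- matrix(0, nrow(g$y), 2 * p)
      for (s in seq_len(2 * p)) {
        trait <- ifelse(s > p, s - p, s)
        Xs <- if (s > p) g$x2 else g$x1
        fitted[, s] <- Xs %*% res$beta[(trait - 1) * q + seq_len(q)]
      }
      R <- g$y - fitted
      S <- crossprod(R) / nrow(R)
      if (z == "MZ") smz <- S else sdz <- S
    }
    if (abs(res$loglik - ll_old) < tol * (abs(res$loglik) + 1)) break
    ll_old <- res$loglik
  }
  res <- twin_loglik_profiled(groups, smz, sdz, p, q)
  rtw <- purrr::map_dfr(c("MZ", "DZ"), function(z) {
    S <- if (z == "MZ") smz else sdz
    tibble::tibble(
      zygosity = z, trait = td$traits,
      r = vapply(seq_len(p), function(t) {
        S[t, p + t] / sqrt(S[t, t] * S[p + t, p + t])
      }, numeric(1))
    )
  })
  structure(list(
    sigma_mz = smz, sigma_dz = sdz, traits = td$traits,
    twin_correlations = rtw, beta = res$beta, loglik = res$loglik,
    n_par = 2 * p * (2 * p + 1) + p * q,
    n_obs = sum(vapply(groups, function(g) g$n * length(g$obs), numeric(1))),
    n_pairs = c(MZ = nrow(complete$MZ$y), DZ = nrow(complete$DZ$y))
  ), class = "swb_twin_sat")
}

#' Likelihood-ratio (chi-square difference) test of nested twin models
#'
#' @param full,nested Fitted models (`swb_twin_fit` / `swb_twin_sat`) with
#'   the nested parameter set a subset of the full set.
#' @return Tibble with `chisq`, `df`, `p.value`. When a variance component
#'   sits on the boundary of its space under the null, the naive chi-square
#'   p-value is conservative; it is reported as-is with a `boundary` flag
#'   when the comparison drops a whole component (e.g. ADE vs AE).
#' @export
likelihood_ratio_test <- function(full, nested) {
  if (nested$n_par >= full$n_par) {
    stop("`nested` must have fewer parameters than `full`", call. = FALSE)
  }
  if (!is.null(full$n_obs) && !is.null(nested$n_obs) &&
      full$n_obs != nested$n_obs) {
    stop("fits use different observations (", full$n_obs, " vs ",
         nested$n_obs, "); refit both on the same pairs ",
         "(e.g. `keep_incomplete = FALSE` when comparing to the saturated ",
         "model)", call. = FALSE)
  }
  chisq <- 2 * (full$loglik - nested$loglik)
  if (chisq < -1e-6) {
    stop("nested model has higher likelihood than full; models are not nested ",
         "or the full fit did not converge", call. = FALSE)
  }
  chisq <- max(chisq, 0)
  df <- full$n_par - nested$n_par
  boundary <- inherits(full, "swb_twin_fit") && inherits(nested, "swb_twin_fit") &&
    full$model == "ADE" && nested$model %in% c("AE", "E")
  tibble::tibble(chisq = chisq, df = df, p.value = chi2_sf(chisq, df),
                 boundary = boundary)
}

#' Upper-tail chi-square probability
#'
#' @param x Nonnegative statistic.
#' @param df Degrees of freedom (>= 1).
#' @return `P(Chi2_df >= x)`.
#' @export
#' @examples
#' chi2_sf(1.41, 4)
chi2_sf <- function(x, df) {
  if (any(df < 1)) stop("df must be at least 1", call. = FALSE)
  if (any(x < 0)) stop("x must be nonnegative", call. = FALSE)
  stats::pchisq(x, df, lower.tail = FALSE)
}

#' @export
print.swb_twin_fit <- function(x, ...) {
  cat("Twin", x$model, "model:", length(x$traits), "traits,",
      x$n_pairs["MZ"], "MZ /", x$n_pairs["DZ"], "DZ pairs\n")
  cat(sprintf("  logLik = %.3f, parameters = %d\n", x$loglik, x$n_par))
  print(round(rbind(h2 = x$h2), 3))
  invisible(x)
}

#' Tidy a biometric twin fit
#'
#' @param x A `swb_twin_fit`.
#' @param ... Unused.
#' @return One row per trait with `h2`, `d2`, and the implied MZ and DZ
#'   cross-twin correlations.
#' @method tidy swb_twin_fit
#' @export
tidy.swb_twin_fit <- function(x, ...) {
  p <- length(x$traits)
  mz <- expected_twin_cov(x$sigma_a, x$sigma_d, x$sigma_e, "MZ")
  dz <- expected_twin_cov(x$sigma_a, x$sigma_d, x$sigma_e, "DZ")
  tibble::tibble(
    trait = x$traits,
    h2 = unname(x$h2), d2 = unname(x$d2),
    r_mz = vapply(seq_len(p), function(t) mz[t, p + t] / mz[t, t], numeric(1)),
    r_dz = vapply(seq_len(p), function(t) dz[t, p + t] / dz[t, t], numeric(1))
  )
}

#' @method glance swb_twin_fit
#' @export
glance.swb_twin_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$loglik, n_par = x$n_par,
                 AIC = -2 * x$loglik + 2 * x$n_par,
                 n_mz = x$n_pairs[["MZ"]], n_dz = x$n_pairs[["DZ"]],
                 convergence = x$convergence)
}
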