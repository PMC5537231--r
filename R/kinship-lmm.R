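#' Z-score a numeric vector
#'
#' Standardizes by subtracting the mean and dividing by the sample standard
#' deviation (n - 1 denominator), the descriptive transform applied to the
#' subcortical volumes before entering linear and quadratic terms. Missing
#' values are ignored in the moments and passed through.
#'
#' @param x Numeric vector with at least two distinct non-missing values.
#' @return A standardized vector with mean 0 and SD 1.
#' @export
#' @examples
#' zscore(c(1, 2, 3))
zscore <- function(x) {
  m <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-score a constant vector (zero standard deviation)",
         call. = FALSE)
  }
  (x - m) / s
}

#' Build the genetic-relatedness (kinship) matrix of a cohort
#'
#' Block-diagonal over families in cohort row order: 1 on the diagonal and
#' between MZ co-twins, 0.5 between DZ co-twins and between siblings (and
#' between a twin and a sibling), 0 across families.
#'
#' @param cohort Tibble with `person_id`, `family_id`, `zygosity_role`.
#' @return A symmetric matrix of class `swb_kinship` with person ids as
#'   dimnames.
#' @export
#' @examples
#' mz <- tibble::tibble(person_id = c("a", "b"), family_id = "f1",
#'                      zygosity_role = c("MZ1", "MZ2"))
#' build_kinship(mz)
build_kinship <- function(cohort) {
  if (anyDuplicated(cohort$person_id)) {
    dup <- unique(cohort$person_id[duplicated(cohort$person_id)])
    stop("person(s) appearing more than once (possibly in two families): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  n <- nrow(cohort)
  K <- matrix(0, n, n, dimnames = list(cohort$person_id, cohort$person_id))
  for (f in unique(cohort$family_id)) {
    rows <- which(cohort$family_id == f)
    K[rows, rows] <- 0.5
    mz <- rows[cohort$zygosity_role[rows] %in% c("MZ1", "MZ2")]
    if (length(mz) == 2) K[mz, mz] <- 1
    diag(K)[rows] <- 1
  }
  structure(K, class = c("swb_kinship", "matrix", "array"))
}

#' Precompute the eigendecomposition of a kinship matrix
#'
#' The mixed-model fit only needs the eigenvectors and eigenvalues of `K`;
#' when many models are fit on the same pedigree (an association scan,
#' replicate simulations) decomposing once saves most of the cost.
#'
#' @param K Kinship matrix.
#' @return List of class `swb_kinship_eigen` with `vectors`, `values`, `n`.
#' @export
kinship_decompose <- function(K) {
  K <- unclass(K)
  if (max(abs(K - t(K))) > 1e-8) stop("kinship matrix is not symmetric", call. = FALSE)
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(abs(e$values))) {
    stop("kinship matrix is not positive semi-definite", call. = FALSE)
  }
  structure(list(vectors = e$vectors, values = pmax(e$values, 0), n = nrow(K)),
            class = "swb_kinship_eigen")
}

#' Identity kinship for samples of unrelated persons
#'
#' A lightweight stand-in for `kinship_decompose(diag(n))`: no matrix is
#' formed and the mixed model collapses to (generalized) least squares.
#'
#' @param n Number of persons.
#' @return An object usable wherever a kinship decomposition is accepted.
#' @export
identity_kinship <- function(n) {
  structure(list(identity = TRUE, n = n, values = rep(1, n)),
            class = "swb_kinship_eigen")
}

#' Fit a linear mixed model with a kinship-structured random effect
#'
#' Maximizes the Gaussian likelihood of `y ~ N(X beta, sigma_g^2 K +
#' sigma_e^2 I)` where `K` is the genetic-relatedness matrix (1 between MZ
#' co-twins, 0.5 between DZ co-twins and siblings). The variance ratio
#' `sigma_g^2 / sigma_e^2` is profiled by a bounded one-dimensional search
#' after rotating into the eigenbasis of `K`; fixed effects are the
#' generalized-least-squares solution at the maximizing components.
#' Rows with missing values in any model variable are dropped listwise and
#' counted in the fit record.
#'
#' @param data Data frame with the model variables (and pedigree columns if
#'   `kinship` is not supplied).
#' @param formula Model formula for the fixed effects.
#' @param kinship Kinship matrix over the rows of `data`, or a
#'   [kinship_decompose()] object; default builds it from the pedigree
#'   columns of `data`.
#' @param reml Use REML instead of ML (default `FALSE`, i.e. ML).
#' @return Object of class `kinship_lmm` with elements `beta`, `se`,
#'   `vcov`, `sigma2_g`, `sigma2_e`, `loglik`, `fitted`, `residuals`,
#'   `n`, `n_dropped`, and internals used by [test_fixed_term()].
#' @export
fit_kinship_lmm <- function(data, formula, kinship = NULL, reml = FALSE) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  keep <- stats::complete.cases(mf)
  n_dropped <- sum(!keep)
  mf <- mf[keep, , drop = FALSE]
  y <- stats::model.response(mf)
  X <- stats::model.matrix(stats::terms(mf), mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  if (is.null(kinship)) kinship <- build_kinship(data)
  if (inherits(kinship, "swb_kinship_eigen")) {
    if (kinship$n != nrow(data)) {
      stop("kinship decomposition does not match data rows", call. = FALSE)
    }
    if (isTRUE(kinship$identity)) {
      ed <- identity_kinship(sum(keep))
    } else if (all(keep)) {
      ed <- kinship
    } else {
      stop("precomputed kinship eigen requires complete data", call. = FALSE)
    }
  } else {
    K <- unclass(kinship)[keep, keep, drop = FALSE]
    ed <- kinship_decompose(K)
  }
  fit <- kinship_lmm_engine(y, X, ed, reml = reml)
  fit$n_dropped <- n_dropped
  fit$formula <- formula
  fit$keep <- keep
  fit
}

kinship_lmm_engine <- function(y, X, ed, reml = FALSE) {
  n <- length(y)
  p <- ncol(X)
  if (isTRUE(ed$identity)) {
    ys <- matrix(y, ncol = 1)
    Xs <- X
    d <- rep(1, n)
  } else {
    U <- ed$vectors
    d <- ed$values
    ys <- crossprod(U, y)
    Xs <- crossprod(U, X)
  }
  # column scaling keeps ill-conditioned designs (raw volumes and their
  # squares) numerically solvable; estimates are unscaled on exit
  xsc <- sqrt(colMeans(Xs^2))
  xsc[xsc == 0] <- 1
  Xs <- sweep(Xs, 2, xsc, "/")

  prof <- function(log_gamma) {
    g <- exp(log_gamma)
    w <- 1 / (g * d + 1)
    XtWX <- crossprod(Xs, Xs * w)
    beta <- solve(XtWX, crossprod(Xs, ys * w))
    r <- ys - Xs %*% beta
    rss <- sum(w * r^2)
    if (reml) {
      s2 <- rss / (n - p)
      ll <- -0.5 * ((n - p) * log(2 * pi * s2) + (n - p) -
                      sum(log(w)) + determinant(XtWX)$modulus[1])
    } else {
      s2 <- rss / n
      ll <- -0.5 * (n * log(2 * pi * s2) + n - sum(log(w)))
    }
    list(ll = ll, beta = beta, s2 = s2, gamma = g, w = w, XtWX = XtWX)
  }
  obj <- function(lg) -prof(lg)$ll
  opt <- stats::optimize(obj, interval = c(-14, 14), tol = 1e-10)
  cands <- list(prof(opt$minimum), prof(-30))  # interior vs ~zero ratio
  best <- cands[[which.max(vapply(cands, `[[`, numeric(1), "ll"))]]
  if (best$gamma < 1.5e-13) best$gamma <- 0

  sigma2_e <- best$s2
  sigma2_g <- best$gamma * sigma2_e
  vv <- sigma2_g * d + sigma2_e
  XtVX <- crossprod(Xs, Xs / vv)
  Vb <- solve(XtVX)
  beta_sc <- drop(Vb %*% crossprod(Xs, ys / vv))
  # back to the original column scale
  beta <- beta_sc / xsc
  Vb <- Vb / outer(xsc, xsc)
  Xs <- sweep(Xs, 2, xsc, "*")
  names(beta) <- colnames(X)
  se <- sqrt(diag(Vb))
  fitted <- drop(X %*% beta)
  structure(list(
    beta = beta, se = se, vcov = Vb,
    sigma2_g = sigma2_g, sigma2_e = sigma2_e,
    loglik = best$ll, n = n, p = p, reml = reml,
    fitted = fitted, residuals = y - fitted,
    Xs = Xs, d = d, vv = vv, coef_names = colnames(X)
  ), class = "kinship_lmm")
}

# Satterthwaite denominator df for the variance of a contrast c'beta.
# theta = (sigma_g^2, sigma_e^2); expected ML information
# I_jk = 0.5 * tr(V^-1 V_j V^-1 V_k) with V_1 = K, V_2 = I.
satterthwaite_df <- function(fit, cvec) {
  d <- fit$d
  vv <- fit$vv
  Xs <- fit$Xs
  Vb <- fit$vcov
  f <- drop(t(cvec) %*% Vb %*% cvec)
  grad <- vapply(list(d, rep(1, length(d))), function(m) {
    Mk <- crossprod(Xs, Xs * (m / vv^2))
    drop(t(cvec) %*% Vb %*% Mk %*% Vb %*% cvec)
  }, numeric(1))
  info <- 0.5 * matrix(c(sum(d^2 / vv^2), sum(d / vv^2),
                         sum(d / vv^2), sum(1 / vv^2)), 2, 2)
  A <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(A)) return(fit$n - fit$p)
  denom <- drop(t(grad) %*% A %*% grad)
  if (!is.finite(denom) || denom <= 0) return(fit$n - fit$p)
  df <- 2 * f^2 / denom
  min(max(df, 1), 10 * fit$n)
}

#' Test fixed-effect terms of a kinship mixed model
#'
#' Single-coefficient tests use the squared Wald ratio as an F statistic
#' with Satterthwaite-approximated denominator degrees of freedom (the
#' `"residual"` method uses `n - p` instead). A character vector of several
#' coefficients, or a contrast matrix `L`, gives the omnibus Wald F with the
#' mean of the per-contrast Satterthwaite dfs as denominator df.
#'
#' @param fit A [fit_kinship_lmm()] object.
#' @param term Coefficient name(s), or a numeric contrast matrix with one
#'   row per contrast over the coefficient vector.
#' @param ddf_method `"satterthwaite"` (default) or `"residual"`.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic` (F),
#'   `df` (denominator), `p.value`.
#' @export
test_fixed_term <- function(fit, term, ddf_method = c("satterthwaite", "residual")) {
  ddf_method <- match.arg(ddf_method)
  nm <- fit$coef_names
  if (is.character(term)) {
    bad <- setdiff(term, nm)
    if (length(bad)) {
      stop("unknown term(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    L <- matrix(0, length(term), length(nm), dimnames = list(term, nm))
    L[cbind(seq_along(term), match(term, nm))] <- 1
  } else {
    L <- rbind(term)
    if (ncol(L) != length(nm)) stop("contrast matrix has wrong width", call. = FALSE)
  }
  q <- nrow(L)
  est <- as.numeric(L %*% fit$beta)
  Vc <- L %*% fit$vcov %*% t(L)
  dfs <- vapply(seq_len(q), function(i) {
    if (ddf_method == "residual") fit$n - fit$p else satterthwaite_df(fit, L[i, ])
  }, numeric(1))
  if (q == 1) {
    se <- as.numeric(sqrt(diag(Vc)))
    F_ <- (est / se)^2
    tibble::tibble(term = rownames(L) %||% "contrast", estimate = est,
                   std.error = se, statistic = F_, df = dfs,
                   p.value = stats::pf(F_, 1, dfs, lower.tail = FALSE))
  } else {
    F_ <- drop(t(est) %*% solve(Vc, est)) / q
    df <- mean(dfs)
    tibble::tibble(term = paste(rownames(L), collapse = " + "),
                   estimate = NA_real_, std.error = NA_real_,
                   statistic = F_, df = df,
                   p.value = stats::pf(F_, q, df, lower.tail = FALSE))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.kinship_lmm <- function(x, ...) {
  cat("Kinship linear mixed model (", if (x$reml) "REML" else "ML", ")\n", sep = "")
  cat(sprintf("  n = %d (dropped %d), logLik = %.3f\n", x$n,
              x$n_dropped %||% 0, x$loglik))
  cat(sprintf("  sigma^2_g = %.4f, sigma^2_e = %.4f\n", x$sigma2_g, x$sigma2_e))
  print(round(rbind(estimate = x$beta, se = x$se), 4))
  invisible(x)
}

#' Tidy a kinship mixed-model fit
#'
#' @param x A `kinship_lmm` object.
#' @param ddf_method Denominator-df method, see [test_fixed_term()].
#' @param ... Unused.
#' @return One row per fixed-effect coefficient with F statistic,
#'   Satterthwaite df and p-value.
#' @method tidy kinship_lmm
#' @export
tidy.kinship_lmm <- function(x, ddf_method = "satterthwaite", ...) {
  purrr::map_dfr(x$coef_names, function(nm) test_fixed_term(x, nm, ddf_method))
}

#' @method glance kinship_lmm
#' @export
glance.kinship_lmm <- function(x, ...) {
  tibble::tibble(sigma2_g = x$sigma2_g, sigma2_e = x$sigma2_e,
                 logLik = x$loglik, nobs = x$n,
                 n_dropped = x$n_dropped %||% 0L, reml = x$reml)
}
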