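#' Fit the covariate-only null logistic model
#'
#' Maximum-likelihood logistic regression of the binary trait on an
#' intercept plus the covariates (no CNV term), fitted by iteratively
#' reweighted least squares. With no covariates the fitted probability is
#' the sample mean of `y` for every subject.
#'
#' @param y binary 0/1 vector, non-constant.
#' @param Z numeric covariate matrix with `length(y)` rows; `NULL` or a
#'   zero-column matrix for an intercept-only null.
#' @return object of class `"mckat_null"`: list with `beta0`, `beta`,
#'   `yhat` (fitted probabilities), `v` (IRLS weights `yhat * (1 - yhat)`),
#'   `Z`, `converged`, `iterations`.
#' @export
fit_null_model <- function(y, Z = NULL) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  n <- length(y)
  if (length(unique(y)) < 2L)
    stop("constant y: degenerate null model", call. = FALSE)
  if (is.null(Z)) Z <- matrix(numeric(0), nrow = n, ncol = 0)
  Z <- as.matrix(Z)
  storage.mode(Z) <- "numeric"
  if (nrow(Z) != n) stop("Z must have length(y) rows", call. = FALSE)
  c_ <- ncol(Z)
  if (n <= c_ + 1L)
    stop("need n > ncol(Z) + 1 observations", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, Z)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient covariate matrix", call. = FALSE)
  fit <- suppressWarnings(
    stats::glm.fit(x = X, y = y, family = stats::binomial()))
  yhat <- fit$fitted.values
  eps <- 1e-10
  if (!fit$converged || any(yhat < eps) || any(yhat > 1 - eps))
    stop("null logistic model did not converge (possible complete separation)",
         call. = FALSE)
  structure(list(beta0 = unname(fit$coefficients[1]),
                 beta = unname(fit$coefficients[-1]),
                 yhat = unname(yhat),
                 v = unname(yhat * (1 - yhat)),
                 Z = Z,
                 converged = fit$converged,
                 iterations = fit$iter),
            class = "mckat_null")
}

#' @export
print.mckat_null <- function(x, ...) {
  cat(sprintf("<mckat_null> n=%d, %d covariate(s), beta0=%.4f, %d IRLS iteration(s)\n",
              length(x$yhat), ncol(x$Z), x$beta0, x$iterations))
  invisible(x)
}

as_kernel_mat <- function(K) {
  if (inherits(K, "kernel_matrix")) K$K else as.matrix(K)
}

#' Variance-component score statistic
#'
#' `Q = (y - yhat)' K (y - yhat)`, the score statistic for H0: tau = 0 in
#' the logistic mixed model with random effect f ~ N(0, tau K). No variance
#' rescaling is applied.
#'
#' @param y binary 0/1 vector.
#' @param null a fitted [fit_null_model()].
#' @param K a `"kernel_matrix"` or plain symmetric matrix.
#' @return non-negative real (when K is positive semi-definite).
#' @export
score_statistic <- function(y, null, K) {
  stopifnot(inherits(null, "mckat_null"))
  Km <- as_kernel_mat(K)
  r <- as.numeric(y) - null$yhat
  if (length(r) != nrow(Km)) stop("dimension mismatch", call. = FALSE)
  drop(crossprod(r, Km %*% r))
}

#' Mixture weights for the null distribution of Q
#'
#' Under H0 the score statistic is asymptotically a weighted sum of
#' chi-square(1) variables with weights the eigenvalues of
#' `P0^{1/2} K P0^{1/2}`, where `P0 = V - V Zt (Zt' V Zt)^-1 Zt' V`,
#' `V = diag(yhat * (1 - yhat))` and `Zt = [1 | Z]` — the projected variance
#' of the null residuals. Eigenvalues below `tol * max(eigenvalue)` are
#' dropped; the result is sorted descending.
#'
#' @param K a `"kernel_matrix"` or symmetric PSD matrix.
#' @param null a fitted [fit_null_model()].
#' @param tol relative eigenvalue retention threshold (default 1e-10).
#' @return object of class `"mixture_weights"`: list with `lambdas`
#'   (possibly empty: a degenerate test, p = 1) and `trace` (= tr(P0 K)).
#' @export
mixture_weights <- function(K, null, tol = 1e-10) {
  stopifnot(inherits(null, "mckat_null"))
  Km <- as_kernel_mat(K)
  n <- length(null$yhat)
  if (nrow(Km) != n) stop("dimension mismatch", call. = FALSE)
  v <- null$v
  if (ncol(null$Z) == 0L) {
    # intercept-only: yhat is constant, so V = v I and
    # P0 = v (I - J/n); its square root is sqrt(v) (I - J/n), hence
    # P0^{1/2} K P0^{1/2} = v * (doubly centered K)
    B <- v[1] * sweep(sweep(Km, 1, colMeans(Km)), 2, rowMeans(Km) - mean(Km))
    tr <- sum(diag(B))
  } else {
    Zt <- cbind(1, null$Z)
    WZ <- v * Zt                                 # V %*% Zt
    P0 <- diag(v, n) - WZ %*% solve(crossprod(Zt, WZ), t(WZ))
    P0 <- (P0 + t(P0)) / 2
    ep <- eigen(P0, symmetric = TRUE)
    dv <- pmax(ep$values, 0)
    P0h <- ep$vectors %*% (sqrt(dv) * t(ep$vectors))
    B <- P0h %*% Km %*% P0h
    tr <- sum(P0 * Km)                           # tr(P0 K), P0 symmetric
  }
  B <- (B + t(B)) / 2
  lam <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  lmax <- max(lam, 0)
  lam <- lam[lam > tol * lmax & lam > 0]
  structure(list(lambdas = sort(lam, decreasing = TRUE), trace = tr),
            class = "mixture_weights")
}

#' Tail p-value of a chi-square mixture
#'
#' `P(sum_i lambda_i chi2_1 >= Q)` by numerical inversion of the
#' characteristic function (Davies-type computation) at the requested
#' absolute accuracy, falling back to a moment-matching (Liu-type)
#' approximation when the inversion faults or returns a value outside
#' \[0, 1\]. The returned p is clamped to \[1e-300, 1\]; a p at the floor is
#' flagged `below_resolution`.
#'
#' @param Q non-negative score statistic (non-finite values are an error).
#' @param w a [mixture_weights()] or numeric vector of positive weights.
#' @param accuracy absolute accuracy of the inversion (default 1e-9).
#' @return list with `p` in \[1e-300, 1\], `method` ("davies",
#'   "moment_fallback" or "degenerate"), and `below_resolution` flag.
#' @export
mixture_pvalue <- function(Q, w, accuracy = 1e-9) {
  if (!is.finite(Q)) stop("non-finite Q statistic", call. = FALSE)
  lambdas <- if (inherits(w, "mixture_weights")) w$lambdas else as.numeric(w)
  lambdas <- lambdas[lambdas > 0]
  if (length(lambdas) == 0L)
    return(list(p = 1, method = "degenerate", below_resolution = FALSE))
  dv <- davies_pvalue(Q, lambdas, accuracy = accuracy)
  slack <- max(accuracy, 1e-12)
  if (dv$ifault == 0L && is.finite(dv$p) && dv$p >= -slack && dv$p <= 1 + slack) {
    p <- dv$p
    method <- "davies"
  } else {
    p <- liu_pvalue(Q, lambdas)
    method <- "moment_fallback"
  }
  below <- p < 1e-300
  list(p = min(max(p, 1e-300), 1), method = method, below_resolution = below)
}

#' Kernel association test for one genomic region
#'
#' Composes the kernel matrix, null logistic fit, score statistic, mixture
#' weights and mixture p-value into one association result. A region in
#' which no cohort CNVs fall (all-zero kernel) yields Q = 0, p = 1 with a
#' degeneracy note rather than an error.
#'
#' @param profiles a [cnv_profile_set()] aligned with `pheno`.
#' @param pheno a [phenotype_table()] in the same subject order.
#' @param region chromosome label, `list(chrom =, start =, end =)`, or NULL
#'   (all chromosomes, summed kernel).
#' @param cfg a [kernel_config()].
#' @param accuracy p-value inversion accuracy.
#' @return object of class `"mckat_result"`: list with `region`, `n_cnvs`,
#'   `Q`, `p_value`, `method`, `significant` (NA until a threshold is
#'   applied by a scan), `note`.
#' @export
test_region <- function(profiles, pheno, region = NULL, cfg = kernel_config(),
                        accuracy = 1e-9) {
  stopifnot(inherits(profiles, "cnv_profile_set"),
            inherits(pheno, "phenotype_table"))
  if (!identical(profiles$subjects, pheno$subjects))
    stop("profiles and pheno are not aligned; use align_cohort()", call. = FALSE)
  rr <- resolve_region(region)
  n_cnvs <- sum(region_rows(profiles$cnv, rr))
  km <- kernel_matrix(profiles, region, cfg)
  null <- fit_null_model(pheno$y, if (ncol(pheno$Z)) pheno$Z else NULL)
  Q <- score_statistic(pheno$y, null, km)
  if (all(km$K == 0)) {
    res <- list(p = 1, method = "degenerate", below_resolution = FALSE)
    note <- "no CNVs in region: degenerate test"
  } else {
    w <- mixture_weights(km, null)
    res <- mixture_pvalue(Q, w, accuracy = accuracy)
    note <- if (res$method == "degenerate")
      "kernel orthogonal to residual space: degenerate test" else
        if (res$below_resolution) "p below numerical resolution" else ""
  }
  structure(list(region = rr$label, n_cnvs = n_cnvs, Q = Q,
                 p_value = res$p, method = res$method,
                 significant = NA, note = note),
            class = "mckat_result")
}

#' @export
print.mckat_result <- function(x, ...) {
  cat(sprintf("<mckat_result> %s: %d CNVs, Q = %.4g, p = %.4g (%s)%s\n",
              x$region, x$n_cnvs, x$Q, x$p_value, x$method,
              if (nzchar(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}
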