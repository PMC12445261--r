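#' Specify a single-trait animal mixed model
#'
#' Builds the response, the fixed-effect design (intercept, sex, birth type,
#' parity and the first two genomic principal components, when present) and
#' the list of random-effect relationship matrices for one trait. Constant
#' or collinear columns are dropped so X is full column rank.
#'
#' @param traits a trait table (from [simulate_traits()] or a CSV with an
#'   `id` column).
#' @param trait name of the response column.
#' @param K named list of `relmat` objects (e.g. `list(G = ..., D = ...)` or
#'   `list(A = ..., Dp = ...)`); all are subset to the analysis animals.
#' @param covariates character vector of factor covariates present in
#'   `traits` (default sex, birth type, parity when available).
#' @param qcovar character vector of numeric covariates (e.g. PC columns).
#' @param pcs optional matrix of PC scores (rownames = ids); its first
#'   `n_pcs` columns are appended as numeric covariates.
#' @param n_pcs number of PCs taken from `pcs` (default 2).
#' @param scale trait scale tag: `"gaussian"`, `"count-as-gaussian"` or
#'   `"binary-observed"`; guessed from the data when `NULL`.
#' @return an object of class `mm_spec` with elements `y`, `X`, `K`, `ids`,
#'   `scale`, `trait`.
#' @export
mm_spec <- function(traits, trait, K, covariates = NULL, qcovar = character(0),
                    pcs = NULL, n_pcs = 2L, scale = NULL) {
  stopifnot(trait %in% names(traits), is.list(K), length(K) >= 1)
  if (is.null(covariates))
    covariates <- intersect(c("sex", "birth_type", "parity"), names(traits))
  ids <- as.character(traits$id)
  keep <- !is.na(traits[[trait]])
  kids <- rownames(K[[1]])
  keep <- keep & ids %in% kids
  df <- traits[keep, , drop = FALSE]
  ids <- ids[keep]
  y <- as.numeric(df[[trait]])
  cols <- list(`(Intercept)` = rep(1, length(y)))
  for (cv in covariates) {
    v <- df[[cv]]
    f <- factor(v)
    if (nlevels(f) < 2L) next
    mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(mm) <- paste0(cv, levels(f)[-1])
    for (j in seq_len(ncol(mm))) cols[[colnames(mm)[j]]] <- mm[, j]
  }
  for (qv in qcovar) cols[[qv]] <- as.numeric(df[[qv]])
  if (!is.null(pcs)) {
    sc <- pcs[ids, seq_len(n_pcs), drop = FALSE]
    for (j in seq_len(ncol(sc))) cols[[colnames(sc)[j]]] <- sc[, j]
  }
  X <- do.call(cbind, cols)
  rownames(X) <- ids
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  Ksub <- lapply(K, function(k) {
    kk <- unclass(k)[ids, ids, drop = FALSE]
    attr(kk, "kind") <- attr(k, "kind")
    kk
  })
  if (is.null(scale)) {
    uy <- unique(y)
    scale <- if (all(uy %in% c(0, 1))) "binary-observed"
             else if (all(y == round(y))) "count-as-gaussian" else "gaussian"
  }
  structure(list(y = y, X = X, K = Ksub, ids = ids, scale = scale,
                 trait = trait),
            class = "mm_spec")
}

# restricted log-likelihood pieces for given variance components
reml_eval <- function(theta, y, X, Ks) {
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (k in seq_along(Ks)) V <- V + theta[k] * Ks[[k]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- chol(V + diag(1e-6 * mean(diag(V)), n))
  }
  Vi <- chol2inv(ch)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  XtViX_ch <- chol((XtViX + t(XtViX)) / 2)
  Viy <- Vi %*% y
  beta <- backsolve(XtViX_ch, forwardsolve(t(XtViX_ch), crossprod(X, Viy)))
  Py <- Viy - ViX %*% beta
  logdetV <- 2 * sum(log(diag(ch)))
  logdetXVX <- 2 * sum(log(diag(XtViX_ch)))
  ll <- -0.5 * (logdetV + logdetXVX + sum(y * Py))
  list(ll = ll, Vi = Vi, ViX = ViX, XtViX_ch = XtViX_ch, Py = as.numeric(Py),
       beta = as.numeric(beta))
}

# P %*% v without forming P
apply_P <- function(st, v) {
  as.numeric(st$Vi %*% v - st$ViX %*%
               backsolve(st$XtViX_ch,
                         forwardsolve(t(st$XtViX_ch), crossprod(st$ViX, v))))
}

# tr(P K) using symmetry: tr(Vi K) - tr((X'ViX)^-1 X'Vi K Vi X)
trace_PK <- function(st, K) {
  t1 <- sum(st$Vi * K)
  B <- K %*% st$ViX
  M <- backsolve(st$XtViX_ch,
                 forwardsolve(t(st$XtViX_ch), crossprod(st$ViX, B)))
  t1 - sum(diag(M))
}

#' REML variance components by average information with EM fallback
#'
#' Fits `y = Xb + sum_k u_k + e` with `u_k ~ N(0, K_k sigma_k^2)` and
#' `e ~ N(0, I sigma_e^2)` by restricted maximum likelihood. Steps use the
#' average-information (AI) update with step-halving; when an AI step fails
#' to increase the restricted log-likelihood (or the AI matrix is singular)
#' an EM step is taken instead. Components are constrained to at least
#' `1e-8 * var(y)`; estimates at that bound are flagged (the analog of a
#' printed "<0.00"). Standard errors come from the inverse AI matrix.
#'
#' @param spec an [mm_spec()].
#' @param max_iter maximum iterations (default 100).
#' @param tol convergence tolerance on the relative parameter change and
#'   log-likelihood change (default 1e-8).
#' @param algorithm `"AI"`, `"EM"`, or `"AI-with-EM-fallback"` (default).
#' @param prevalence population prevalence K for binary traits; enables the
#'   liability-scale heritability in the result.
#' @param verbose print per-iteration log-likelihoods.
#' @return object of class `varcomp_result`: `estimates` (named, including
#'   `sigma_e2`), `se`, `sigma_p2`, `h2`, `h2_se`, `d2` (when a dominance
#'   matrix is present), `loglik`, `converged`, `n_iter`, `at_bound`,
#'   `h2_liability` (when binary + prevalence), `beta`, `spec`, `ai_inv`.
#' @export
reml_fit <- function(spec, max_iter = 100L, tol = 1e-8,
                     algorithm = c("AI-with-EM-fallback", "AI", "EM"),
                     prevalence = NULL, verbose = FALSE) {
  algorithm <- match.arg(algorithm)
  y <- spec$y; X <- spec$X; Ks <- spec$K
  n <- length(y)
  nk <- length(Ks) + 1L
  vy <- stats::var(y)
  lower <- 1e-8 * vy
  theta <- rep(vy / nk, nk)
  names(theta) <- c(paste0("sigma_", names(Ks), "2"), "sigma_e2")
  st <- reml_eval(theta, y, X, Ks)
  ll <- st$ll
  converged <- FALSE
  AI <- NULL
  iter <- 0L

  em_step <- function(theta, st) {
    newt <- theta
    for (k in seq_len(nk)) {
      Kk <- if (k < nk) Ks[[k]] else diag(1, n)
      KPy <- if (k < nk) as.numeric(Kk %*% st$Py) else st$Py
      yPKPy <- sum(st$Py * KPy)
      trPK <- if (k < nk) trace_PK(st, Kk) else
        sum(diag(st$Vi)) - sum(st$ViX *
          t(backsolve(st$XtViX_ch,
                      forwardsolve(t(st$XtViX_ch), t(st$ViX)))))
      newt[k] <- theta[k] + theta[k]^2 * (yPKPy - trPK) / n
    }
    pmax(newt, lower)
  }

  for (iter in seq_len(max_iter)) {
    # score vector and AI matrix at current theta
    KPy <- vector("list", nk)
    trPKs <- numeric(nk)
    for (k in seq_len(nk)) {
      if (k < nk) {
        KPy[[k]] <- as.numeric(Ks[[k]] %*% st$Py)
        trPKs[k] <- trace_PK(st, Ks[[k]])
      } else {
        KPy[[k]] <- st$Py
        PtX <- backsolve(st$XtViX_ch,
                         forwardsolve(t(st$XtViX_ch), t(st$ViX)))
        trPKs[k] <- sum(diag(st$Vi)) - sum(st$ViX * t(PtX))
      }
    }
    score <- vapply(seq_len(nk), function(k)
      -0.5 * (trPKs[k] - sum(st$Py * KPy[[k]])), numeric(1))
    PKPy <- lapply(KPy, function(v) apply_P(st, v))
    AI <- matrix(0, nk, nk)
    for (k in seq_len(nk)) for (l in k:nk) {
      AI[k, l] <- 0.5 * sum(KPy[[k]] * PKPy[[l]])
      AI[l, k] <- AI[k, l]
    }

    use_em <- algorithm == "EM" || (iter == 1L && algorithm != "AI")
    new_theta <- NULL
    if (!use_em) {
      # active-set AI: components pinned at the bound with a negative score
      # stay fixed; the Newton step is taken in the free subspace
      free <- !(theta <= lower * (1 + 1e-6) & score < 0)
      if (!any(free)) { converged <- TRUE; break }
      delta <- tryCatch({
        d <- rep(0, nk)
        d[free] <- solve(AI[free, free, drop = FALSE], score[free])
        d
      }, error = function(e) NULL)
      if (is.null(delta)) {
        use_em <- algorithm == "AI-with-EM-fallback"
        if (!use_em) stop("singular AI matrix in pure AI algorithm")
      } else {
        # step-halving until the restricted log-likelihood does not decrease
        stepsize <- 1
        for (tryi in 1:8) {
          cand <- pmax(theta + stepsize * delta, lower)
          st_c <- reml_eval(cand, y, X, Ks)
          if (st_c$ll >= ll - 1e-10) { new_theta <- cand; st_new <- st_c; break }
          stepsize <- stepsize / 2
        }
        if (is.null(new_theta)) use_em <- algorithm == "AI-with-EM-fallback"
      }
    }
    if (use_em) {
      new_theta <- em_step(theta, st)
      st_new <- reml_eval(new_theta, y, X, Ks)
    }
    if (is.null(new_theta)) { converged <- FALSE; break }
    dpar <- max(abs(new_theta - theta) / (abs(theta) + 1e-12))
    # absolute criterion keeps components pinned at the bound (where EM
    # moves at rate theta^2) from stalling formal convergence
    dabs <- max(abs(new_theta - theta)) / vy
    dll <- st_new$ll - ll
    theta <- new_theta; st <- st_new; ll <- st$ll
    if (verbose) cat(sprintf("iter %d  ll %.6f  dpar %.3e\n", iter, ll, dpar))
    if (dpar < tol || dabs < tol || abs(dll) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("REML did not converge in ", max_iter,
            " iterations; returning last iterate")

  ai_inv <- tryCatch(solve(AI), error = function(e)
    matrix(NA_real_, nk, nk))
  se <- sqrt(pmax(diag(ai_inv), 0))
  names(se) <- names(theta)
  sigma_p2 <- sum(theta)
  # delta-method SE of h2 = theta_g / sum(theta)
  h2_grad <- rep(-theta[1] / sigma_p2^2, nk)
  h2_grad[1] <- (sigma_p2 - theta[1]) / sigma_p2^2
  h2_se <- sqrt(max(0, as.numeric(t(h2_grad) %*% ai_inv %*% h2_grad)))
  res <- list(estimates = theta, se = se, sigma_p2 = sigma_p2,
              h2 = as.numeric(theta[1] / sigma_p2), h2_se = h2_se,
              loglik = ll, converged = converged, n_iter = iter,
              at_bound = theta <= lower * (1 + 1e-6),
              beta = st$beta, ai_inv = ai_inv, spec = spec)
  dk <- grep("^sigma_(D|Dp|d)2$", names(theta))
  if (length(dk) == 1L) res$d2 <- as.numeric(theta[dk] / sigma_p2)
  if (identical(spec$scale, "binary-observed") && !is.null(prevalence)) {
    P <- mean(y)
    res$prevalence <- prevalence
    res$case_proportion <- P
    res$h2_liability <- liability_transform(res$h2, prevalence, P)
  }
  class(res) <- "varcomp_result"
  res
}

#' @export
print.varcomp_result <- function(x, ...) {
  est <- x$estimates
  cat("REML variance components (", if (x$converged) "converged" else
    "NOT converged", ", ", x$n_iter, " iterations)\n", sep = "")
  for (k in seq_along(est)) {
    lbl <- if (x$at_bound[k]) "<0.00 (at bound)" else sprintf("%.4f", est[k])
    cat(sprintf("  %-10s %s (%.4f)\n", names(est)[k], lbl, x$se[k]))
  }
  cat(sprintf("  sigma_p2   %.4f\n  h2         %.4f (%.4f)\n",
              x$sigma_p2, x$h2, x$h2_se))
  if (!is.null(x$d2)) cat(sprintf("  d2         %.4f\n", x$d2))
  if (!is.null(x$h2_liability))
    cat(sprintf("  h2 (liability, K=%.4f) %.4f\n", x$prevalence,
                x$h2_liability))
  invisible(x)
}

#' Heritability from variance components
#'
#' `h2 = sigma_g2 / sigma_p2` where `sigma_p2` is the sum of all fitted
#' components; SE by the delta method on the component covariance matrix.
#' Also callable on raw numbers for worked examples.
#'
#' @param result a `varcomp_result`, or a numeric `sigma_g2` when
#'   `sigma_p2` is given.
#' @param sigma_p2 optional phenotypic variance (for the two-number form;
#'   SE is then `NA`).
#' @return list with `h2` and `se`.
#' @export
heritability <- function(result, sigma_p2 = NULL) {
  if (is.numeric(result) && !is.null(sigma_p2)) {
    if (sigma_p2 <= 0) stop("sigma_p2 must be positive")
    return(list(h2 = result / sigma_p2, se = NA_real_))
  }
  stopifnot(inherits(result, "varcomp_result"))
  if (result$sigma_p2 <= 0) stop("sigma_p2 must be positive")
  list(h2 = result$h2, se = result$h2_se)
}

#' Dominance fraction of phenotypic variance
#'
#' `d2 = sigma_d2 / sigma_p2`, returned as a percentage.
#'
#' @param result a `varcomp_result` from a fit including a dominance
#'   matrix, or a numeric `sigma_d2` when `sigma_p2` is given.
#' @param sigma_p2 optional phenotypic variance for the two-number form.
#' @return percentage of phenotypic variance explained by dominance.
#' @export
dominance_fraction <- function(result, sigma_p2 = NULL) {
  if (is.numeric(result) && !is.null(sigma_p2))
    return(100 * result / sigma_p2)
  stopifnot(inherits(result, "varcomp_result"))
  if (is.null(result$d2)) stop("fit has no dominance component")
  100 * result$d2
}

#' Observed-scale to liability-scale heritability
#'
#' Case-control transformation:
#' `h2_l = h2_obs * K(1-K)/z^2 * K(1-K) / (P(1-P))` with `z` the standard
#' normal density at the threshold `qnorm(1-K)`. With `P = K` this reduces
#' to `h2_obs * K(1-K)/z^2`.
#'
#' @param h2_observed observed-scale (0/1) heritability.
#' @param K population prevalence in (0,1).
#' @param P case proportion in the sample, in (0,1); defaults to `K`.
#' @return liability-scale heritability.
#' @export
liability_transform <- function(h2_observed, K, P = K) {
  if (K <= 0 || K >= 1 || P <= 0 || P >= 1)
    stop("K and P must lie strictly within (0, 1)")
  z <- stats::dnorm(stats::qnorm(1 - K))
  h2_observed * (K * (1 - K) / z^2) * (K * (1 - K) / (P * (1 - P)))
}
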