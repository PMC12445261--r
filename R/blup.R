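#' BLUP breeding values at the REML estimates
#'
#' Solves the mixed-model equations implicitly through the GLS identities:
#' `b_hat = (X'V^-1 X)^-1 X'V^-1 y` and
#' `g_hat = sigma_g2 * K[, pheno] V^-1 (y - X b_hat)`, where `V` is built
#' from the fitted components. Animals present in the relationship matrix
#' but without phenotypes receive predictions through their relationships.
#'
#' @param spec the [mm_spec()] used in the fit.
#' @param fit a `varcomp_result` from [reml_fit()].
#' @param K_full optional relationship matrix covering extra animals
#'   (defaults to the spec's first matrix, i.e. phenotyped animals only).
#' @return data.frame (class `ebv_table`) with `id` and `ebv`.
#' @export
blup_solve <- function(spec, fit, K_full = NULL) {
  y <- spec$y; X <- spec$X; Ks <- spec$K
  theta <- fit$estimates
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (k in seq_along(Ks)) V <- V + theta[k] * Ks[[k]]
  ch <- tryCatch(chol(V), error = function(e)
    stop("singular phenotypic covariance; condition number too large ",
         "(rcond = ", format(rcond(V)), ")"))
  Vi <- chol2inv(ch)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  beta <- solve(XtViX, crossprod(X, Vi %*% y))
  resid <- as.numeric(y - X %*% beta)
  Vir <- as.numeric(Vi %*% resid)
  Kg <- if (is.null(K_full)) Ks[[1]] else unclass(K_full)
  if (is.null(K_full)) {
    ebv <- theta[1] * as.numeric(Kg %*% Vir)
    ids <- spec$ids
  } else {
    ids <- rownames(Kg)
    ebv <- theta[1] * as.numeric(Kg[, spec$ids, drop = FALSE] %*% Vir)
  }
  out <- data.frame(id = ids, ebv = ebv, stringsAsFactors = FALSE)
  class(out) <- c("ebv_table", "data.frame")
  out
}

star_label <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
                                   ifelse(p <= 0.05, "*", "")))
}

#' Pearson correlations among EBV vectors
#'
#' Pairwise-complete Pearson correlations across traits, with a two-sided
#' t-test (n - 2 df) against zero and significance stars at
#' p <= 0.05 / 0.01 / 0.001.
#'
#' @param ebvs data.frame with an `id` column and one EBV column per trait,
#'   or a named list of `ebv_table`s (merged on id).
#' @param animals optional ids to restrict to (e.g. phenotyped lambs).
#' @return list of trait x trait matrices `r`, `p`, `stars`, `n`.
#' @export
ebv_correlations <- function(ebvs, animals = NULL) {
  if (is.list(ebvs) && !is.data.frame(ebvs)) {
    stopifnot(!is.null(names(ebvs)))
    df <- NULL
    for (tr in names(ebvs)) {
      tab <- ebvs[[tr]]
      colnames(tab)[colnames(tab) == "ebv"] <- tr
      df <- if (is.null(df)) tab else merge(df, tab, by = "id", all = TRUE)
    }
    ebvs <- df
  }
  if (!is.null(animals)) ebvs <- ebvs[ebvs$id %in% animals, , drop = FALSE]
  traits <- setdiff(names(ebvs), "id")
  k <- length(traits)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    x <- ebvs[[traits[i]]]; y <- ebvs[[traits[j]]]
    ok <- !is.na(x) & !is.na(y)
    nn <- sum(ok)
    if (nn < 3L) next
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warning("zero-variance EBV vector for pair ", traits[i], "/", traits[j],
              "; correlation undefined")
      next
    }
    rr <- stats::cor(x[ok], y[ok])
    tt <- rr * sqrt((nn - 2) / max(1 - rr^2, 1e-300))
    pp <- 2 * stats::pt(abs(tt), nn - 2, lower.tail = FALSE)
    r[i, j] <- r[j, i] <- rr
    p[i, j] <- p[j, i] <- pp
    nmat[i, j] <- nmat[j, i] <- nn
  }
  list(r = r, p = p, stars = matrix(star_label(p), k, k,
                                    dimnames = dimnames(p)), n = nmat)
}

#' Format an EBV correlation table as upper-triangle text with stars
#' @param ct result of [ebv_correlations()].
#' @return character matrix (upper triangle filled, e.g. `"0.60***"`).
#' @export
format_correlation_table <- function(ct) {
  k <- nrow(ct$r)
  out <- matrix("", k, k, dimnames = dimnames(ct$r))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    if (is.na(ct$r[i, j])) next
    out[i, j] <- paste0(sprintf("%.2f", ct$r[i, j]), ct$stars[i, j])
  }
  out[, -1, drop = FALSE][seq_len(k - 1), , drop = FALSE]
}

#' Descriptive statistics per trait and group
#'
#' Mean, SD, min, max and CV = SD/mean for each trait column, optionally
#' split by a grouping column. A zero mean yields `NA` CV with a warning;
#' a constant trait yields SD = 0 and CV = 0.
#'
#' @param traits trait table with an `id` column.
#' @param trait_cols columns to summarize (default: all numeric non-id).
#' @param group optional name of a grouping column.
#' @return data.frame with trait, group, n, mean, sd, min, max, cv.
#' @export
descriptive_stats <- function(traits, trait_cols = NULL, group = NULL) {
  if (is.null(trait_cols))
    trait_cols <- names(traits)[vapply(traits, is.numeric, logical(1))]
  trait_cols <- setdiff(trait_cols, c("parity"))
  groups <- if (is.null(group)) list(all = rep(TRUE, nrow(traits)))
            else split(seq_len(nrow(traits)), traits[[group]])
  rows <- list()
  for (gn in names(groups)) {
    idx <- groups[[gn]]
    for (tc in trait_cols) {
      v <- traits[[tc]][idx]
      v <- v[!is.na(v)]
      if (length(v) == 0L) next
      m <- mean(v); s <- stats::sd(v)
      cv <- if (m == 0) {
        if (s == 0) 0 else { warning("mean 0 for ", tc, "; CV undefined"); NA_real_ }
      } else s / m
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tc, group = gn, n = length(v), mean = m, sd = s,
        min = min(v), max = max(v), cv = cv, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
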