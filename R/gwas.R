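#' Single-variant scan for additive and dominance effects
#'
#' For each variant, fits by generalized least squares the model
#' `y = X b + x_a b_a + x_d b_d + (polygenic) + e` with covariance
#' `V = G sigma_g2 + I sigma_e2` held fixed at the null-model REML
#' estimates. The additive covariate is the centred dosage
#' `(0, 1, 2) - 2p`; the dominance covariate takes `(-2p^2, 2pq, -2q^2)`.
#' Test statistics are `chi2 = (estimate / SE)^2` on 1 df.
#'
#' When a genotype class is absent the dominance covariate is collinear
#' with the additive one plus the intercept; the dominance effect is then
#' reported missing and the additive effect is tested alone. Variants
#' monomorphic in the analysed animals are skipped (all-NA row).
#'
#' @param y response vector (named by animal id, or aligned with `X`).
#' @param X fixed-effect design including intercept and PCs (rownames =
#'   ids).
#' @param geno a `genotypes` object containing the analysed animals.
#' @param G additive relationship matrix used for the polygenic term.
#' @param sigma_g2,sigma_e2 null-model variance components (e.g. from
#'   [reml_fit()]).
#' @param method `"spectral"` (one-time eigendecomposition of G, default)
#'   or `"direct"` (full V inversion); the two agree to numerical
#'   precision.
#' @return data.frame of class `assoc_result`: chr, pos, id, freq, beta_a,
#'   se_a, chi2_a, p_a, beta_d, se_d, chi2_d, p_d.
#' @export
assoc_scan <- function(y, X, geno, G, sigma_g2, sigma_e2,
                       method = c("spectral", "direct")) {
  method <- match.arg(method)
  ids <- rownames(X)
  if (is.null(ids)) ids <- geno$ids[seq_along(y)]
  dos <- geno$dosages[ids, , drop = FALSE]
  p <- colMeans(dos, na.rm = TRUE) / 2
  n <- length(y)
  m <- ncol(dos)
  Gm <- unclass(G)[ids, ids, drop = FALSE]

  if (method == "spectral") {
    eg <- eigen((Gm + t(Gm)) / 2, symmetric = TRUE)
    w <- 1 / (sigma_g2 * pmax(eg$values, 0) + sigma_e2)
    U <- eg$vectors
    yr <- as.numeric(crossprod(U, y))
    Xr <- crossprod(U, X)
    rotate <- function(M) crossprod(U, M)
  } else {
    V <- sigma_g2 * Gm + diag(sigma_e2, n)
    Vi <- chol2inv(chol(V))
  }

  res <- data.frame(chr = geno$map$chr, pos = geno$map$pos, id = geno$map$id,
                    freq = as.numeric(p),
                    beta_a = NA_real_, se_a = NA_real_, chi2_a = NA_real_,
                    p_a = NA_real_,
                    beta_d = NA_real_, se_d = NA_real_, chi2_d = NA_real_,
                    p_d = NA_real_, stringsAsFactors = FALSE)

  px <- ncol(X)
  gls_fit <- function(C) {
    # returns list(beta, cov) for GLS with fixed V
    if (method == "spectral") {
      Cw <- C * w
      A <- crossprod(C, Cw)
      b <- crossprod(Cw, yr)
    } else {
      ViC <- Vi %*% C
      A <- crossprod(C, ViC)
      b <- crossprod(ViC, y)
    }
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    if (min(diag(ch))^2 < 1e-10 * max(diag(A))) return(NULL)
    cov <- chol2inv(ch)
    list(beta = as.numeric(cov %*% b), cov = cov)
  }

  for (j in seq_len(m)) {
    d <- dos[, j]
    if (anyNA(d)) d[is.na(d)] <- 2 * p[j]
    if (stats::var(d) == 0) next
    xa <- d - 2 * p[j]
    q <- 1 - p[j]
    xd <- ifelse(d == 0, -2 * p[j]^2, ifelse(d == 1, 2 * p[j] * q, -2 * q^2))
    if (method == "spectral") {
      xa_u <- as.numeric(crossprod(U, xa))
      xd_u <- as.numeric(crossprod(U, xd))
      Cfull <- cbind(Xr, xa_u, xd_u)
    } else {
      Cfull <- cbind(X, xa, xd)
    }
    fit <- gls_fit(Cfull)
    if (!is.null(fit)) {
      ia <- px + 1L; idd <- px + 2L
      res$beta_a[j] <- fit$beta[ia]
      res$se_a[j] <- sqrt(fit$cov[ia, ia])
      res$beta_d[j] <- fit$beta[idd]
      res$se_d[j] <- sqrt(fit$cov[idd, idd])
    } else {
      # dominance collinear: additive-only model
      fit <- gls_fit(Cfull[, seq_len(px + 1L), drop = FALSE])
      if (is.null(fit)) next
      ia <- px + 1L
      res$beta_a[j] <- fit$beta[ia]
      res$se_a[j] <- sqrt(fit$cov[ia, ia])
    }
    res$chi2_a[j] <- (res$beta_a[j] / res$se_a[j])^2
    res$p_a[j] <- stats::pchisq(res$chi2_a[j], 1, lower.tail = FALSE)
    if (!is.na(res$beta_d[j])) {
      res$chi2_d[j] <- (res$beta_d[j] / res$se_d[j])^2
      res$p_d[j] <- stats::pchisq(res$chi2_d[j], 1, lower.tail = FALSE)
    }
  }
  class(res) <- c("assoc_result", "data.frame")
  res
}

#' Genomic inflation factor
#'
#' `lambda = median(chi2) / qchisq(0.5, 1)`; the denominator is the 0.4549
#' constant (median of the 1-df chi-squared distribution).
#'
#' @param chisq vector of 1-df chi-squared statistics (NAs dropped).
#' @return the inflation factor.
#' @export
inflation_factor <- function(chisq) {
  chisq <- chisq[!is.na(chisq)]
  if (length(chisq) == 0L) stop("no test statistics supplied")
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Significance thresholds from the effective number of independent tests
#'
#' Bonferroni threshold `alpha / Meff` and suggestive threshold `1 / Meff`,
#' with their -log10 forms.
#'
#' @param meff effective number of independent variants (>= 1).
#' @param alpha genome-wide error rate (default 0.05).
#' @return list with `meff`, `p_bonf`, `p_sug`, `mlog10_bonf`,
#'   `mlog10_sug`.
#' @export
thresholds_from_meff <- function(meff, alpha = 0.05) {
  if (meff < 1) stop("meff must be at least 1")
  p_bonf <- alpha / meff
  p_sug <- 1 / meff
  list(meff = meff, p_bonf = p_bonf, p_sug = p_sug,
       mlog10_bonf = -log10(p_bonf), mlog10_sug = -log10(p_sug))
}

tier_of <- function(p, thr) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < thr$p_bonf, "bonferroni",
                ifelse(p < thr$p_sug, "suggestive", "none")))
}

#' Manhattan plot data with significance tiers
#'
#' Adds a cumulative genome coordinate and -log10 p-values for the additive
#' and dominance components, and classifies each variant against the
#' Bonferroni and suggestive thresholds (`bonferroni` strictly below
#' `p_bonf`, `suggestive` strictly below `p_sug`).
#'
#' @param assoc an `assoc_result`.
#' @param thresholds from [thresholds_from_meff()].
#' @return data.frame with `chr`, `pos`, `cum_pos`, `mlog10_a`, `mlog10_d`,
#'   `tier_a`, `tier_d` plus threshold attributes.
#' @export
manhattan_export <- function(assoc, thresholds) {
  chrs <- unique(assoc$chr)
  offset <- 0
  cum <- numeric(nrow(assoc))
  for (c in chrs) {
    idx <- which(assoc$chr == c)
    cum[idx] <- assoc$pos[idx] + offset
    offset <- offset + max(assoc$pos[idx])
  }
  out <- data.frame(chr = assoc$chr, pos = assoc$pos, cum_pos = cum,
                    mlog10_a = -log10(assoc$p_a),
                    mlog10_d = -log10(assoc$p_d),
                    tier_a = tier_of(assoc$p_a, thresholds),
                    tier_d = tier_of(assoc$p_d, thresholds),
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thresholds
  out
}

#' Write a two-panel Manhattan plot
#'
#' Additive (a) and dominance (b) panels with horizontal lines at the
#' Bonferroni (solid) and suggestive (dotted) thresholds.
#'
#' @param mh output of [manhattan_export()].
#' @param path output file (".png" or ".svg").
#' @param width,height device size in inches.
#' @return `path`, invisibly.
#' @export
manhattan_plot <- function(mh, path, width = 9, height = 6) {
  thr <- attr(mh, "thresholds")
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") grDevices::svg(path, width = width, height = height)
  else grDevices::png(path, width = width * 100, height = height * 100)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  cols <- 1 + (as.integer(factor(mh$chr, levels = unique(mh$chr))) %% 2)
  for (panel in c("a", "d")) {
    v <- if (panel == "a") mh$mlog10_a else mh$mlog10_d
    ymax <- max(c(v, thr$mlog10_bonf), na.rm = TRUE) * 1.05
    graphics::plot(mh$cum_pos, v, pch = 20, cex = 0.4,
                   col = c("grey30", "steelblue")[cols],
                   xlab = "genome position", ylab = "-log10(p)",
                   main = if (panel == "a") "(a) additive" else "(b) dominance",
                   ylim = c(0, ymax))
    graphics::abline(h = thr$mlog10_bonf, col = "red", lty = 1)
    graphics::abline(h = thr$mlog10_sug, col = "red", lty = 3)
  }
  invisible(path)
}
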