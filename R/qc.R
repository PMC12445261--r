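#' Hardy-Weinberg exact test
#'
#' Two-sided conditional exact test: given the allele counts, sums the
#' probabilities of all heterozygote configurations whose conditional
#' probability does not exceed that of the observed one (no mid-p).
#' Probabilities are computed by the stable ratio recurrence over
#' heterozygote counts.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total > 0).
#' @return the exact p-value. Invariant under swapping `n_AA` and `n_aa`.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n <= 0) stop("total genotype count must be positive")
  r <- 2 * min(n_AA, n_aa) + n_Aa   # minor allele count
  if (r == 0 || r == 2 * n) return(1)
  h_max <- min(r, 2 * n - r)
  hs <- seq(r %% 2, h_max, by = 2)
  # unnormalized probabilities via recurrence:
  # P(h+2)/P(h) = 4 * hom_r(h) * hom_c(h) / ((h+2)(h+1))
  probs <- numeric(length(hs))
  probs[1] <- 1
  if (length(hs) > 1) {
    for (i in seq_len(length(hs) - 1)) {
      h <- hs[i]
      hom_r <- (r - h) / 2
      hom_c <- (2 * n - r - h) / 2
      probs[i + 1] <- probs[i] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  obs <- n_Aa
  p_obs <- probs[match(obs, hs)]
  if (is.na(p_obs)) stop("observed heterozygote count has wrong parity")
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

#' Apply the study's variant filters
#'
#' Keeps variants with call rate strictly above `call_rate_min`, minor
#' allele frequency strictly above `maf_min`, and Hardy-Weinberg exact-test
#' p-value at or above `hwe_p_min`. Monomorphic variants fail the MAF
#' filter. Filters are evaluated on the input (not sequentially re-computed),
#' and a variant is attributed to the first filter it fails, in the order
#' call rate, MAF, HWE.
#'
#' @param geno a `genotypes` object.
#' @param call_rate_min,maf_min,hwe_p_min thresholds (defaults 0.95, 0.05,
#'   1e-6).
#' @return list with `genotypes` (retained variants, frequencies
#'   recomputed) and `report` (counts per filter, retained, per-animal call
#'   rate).
#' @export
filter_variants <- function(geno, call_rate_min = 0.95, maf_min = 0.05,
                            hwe_p_min = 1e-6) {
  dos <- geno$dosages
  m <- ncol(dos)
  call_rate <- colMeans(!is.na(dos))
  p <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  fail_cr <- call_rate <= call_rate_min
  fail_maf <- !fail_cr & maf <= maf_min
  hwe_p <- rep(1, m)
  need_hwe <- which(!fail_cr & !fail_maf)
  for (j in need_hwe) {
    d <- dos[, j]
    hwe_p[j] <- hwe_exact_test(sum(d == 0, na.rm = TRUE),
                               sum(d == 1, na.rm = TRUE),
                               sum(d == 2, na.rm = TRUE))
  }
  fail_hwe <- !fail_cr & !fail_maf & hwe_p < hwe_p_min
  keep <- !(fail_cr | fail_maf | fail_hwe)
  if (!any(keep))
    warning("all variants removed by QC filters; returning empty genotype set")
  report <- list(n_input = m,
                 removed_call_rate = sum(fail_cr),
                 removed_maf = sum(fail_maf),
                 removed_hwe = sum(fail_hwe),
                 retained = sum(keep),
                 animal_call_rate = rowMeans(!is.na(dos)))
  list(genotypes = subset_genotypes(geno, variants = which(keep)),
       report = report)
}

#' Principal components from a relationship matrix
#'
#' Eigendecomposition of a (symmetric) genomic relationship matrix; scores
#' are eigenvectors scaled by the square root of their eigenvalues, variance
#' explained is eigenvalue over trace.
#'
#' @param G symmetric relationship matrix.
#' @param n_components number of leading components (default 20, capped at
#'   the matrix order).
#' @return list with `scores` (n x k, columns PC1..), and
#'   `variance_explained` (length-n fractions summing to 1).
#' @export
pca_from_grm <- function(G, n_components = 20L) {
  n <- nrow(G)
  if (n_components > n)
    stop("n_components (", n_components, ") exceeds matrix order (", n, ")")
  if (max(abs(G - t(G))) > 1e-8 * max(1, max(abs(G))))
    stop("G must be symmetric")
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  lam <- eg$values
  k <- seq_len(n_components)
  scores <- eg$vectors[, k, drop = FALSE] %*% diag(sqrt(pmax(lam[k], 0)), n_components)
  dimnames(scores) <- list(rownames(G), paste0("PC", k))
  list(scores = scores, variance_explained = lam / sum(lam))
}

# squared correlation between dosage columns, pairwise-complete if needed
r2_matrix <- function(dos) {
  if (anyNA(dos)) {
    suppressWarnings(stats::cor(dos, use = "pairwise.complete.obs"))^2
  } else {
    suppressWarnings(stats::cor(dos))^2
  }
}

#' Effective number of independent variants by LD pruning
#'
#' Greedy within-window pairwise pruning on squared genotype correlation, in
#' the style of plink's `--indep-pairwise`: within each window, pairs of
#' still-kept variants are visited in index order and, when r-squared
#' exceeds `r2_max`, the variant with the lower MAF is dropped (ties: the
#' later index). The window then slides by `step` variants. Windows never
#' span chromosomes. The count of surviving variants is Meff.
#'
#' @param geno a (QC-filtered) `genotypes` object.
#' @param r2_max prune threshold on squared correlation (default 0.5;
#'   pruning acts on r-squared strictly greater than this).
#' @param window window size in variants (default 5000).
#' @param step slide in variants (default 500).
#' @return list with `meff` (count), `kept` (logical per variant).
#' @export
effective_n_variants <- function(geno, r2_max = 0.5, window = 5000L,
                                 step = 500L) {
  if (window < step) stop("window must be >= step")
  dos <- geno$dosages
  m <- ncol(dos)
  p <- geno$map$freq
  maf <- pmin(p, 1 - p)
  keep <- rep(TRUE, m)
  for (chr in unique(geno$map$chr)) {
    idx <- which(geno$map$chr == chr)
    start <- 1L
    repeat {
      win <- idx[seq(start, min(start + window - 1L, length(idx)))]
      win_keep <- win[keep[win]]
      if (length(win_keep) > 1L) {
        r2 <- r2_matrix(dos[, win_keep, drop = FALSE])
        r2[!is.finite(r2)] <- 0
        hits <- which(upper.tri(r2) & r2 > r2_max, arr.ind = TRUE)
        if (nrow(hits) > 0L) {
          hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
          alive <- rep(TRUE, length(win_keep))
          for (h in seq_len(nrow(hits))) {
            i <- hits[h, 1]; j <- hits[h, 2]
            if (!alive[i] || !alive[j]) next
            vi <- win_keep[i]; vj <- win_keep[j]
            drop <- if (maf[vi] < maf[vj]) i
                    else if (maf[vj] < maf[vi]) j
                    else max(i, j)
            alive[drop] <- FALSE
          }
          keep[win_keep[!alive]] <- FALSE
        }
      }
      if (start + window - 1L >= length(idx)) break
      start <- start + step
    }
  }
  list(meff = sum(keep), kept = keep)
}
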