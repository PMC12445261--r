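#' Construct a relationship matrix object
#'
#' @param K symmetric numeric matrix with animal-id dimnames.
#' @param kind one of `"G_additive"`, `"D_dominance"`, `"A_pedigree"`,
#'   `"D_pedigree"`.
#' @param ids animal ids (defaults to rownames).
#' @return a `relmat` (matrix subclass with `kind` attribute).
#' @export
new_relmat <- function(K, kind, ids = rownames(K)) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  kind <- match.arg(kind, c("G_additive", "D_dominance",
                            "A_pedigree", "D_pedigree"))
  dimnames(K) <- list(ids, ids)
  structure(K, kind = kind, class = c("relmat", "matrix", "array"))
}

#' @export
print.relmat <- function(x, ...) {
  cat("relmat [", attr(x, "kind"), "] order", nrow(x),
      " mean diag", sprintf("%.3f", mean(diag(x))), "\n")
  invisible(x)
}

check_polymorphic <- function(p) {
  if (any(p <= 0 | p >= 1))
    stop("monomorphic variants present (p = 0 or 1); run filter_variants() first")
}

#' Genomic additive relationship matrix (GRM)
#'
#' Standard variant-based additive relationship matrix from centred,
#' standardized dosages, with the distinct diagonal form
#' `1 + (1/m) sum_i (x^2 - (1+2p)x + 2p^2) / (2pq)`. Missing dosages are
#' mean-imputed with `2p` per variant.
#'
#' @param geno a QC-passed `genotypes` object (genotyped animals only are
#'   used).
#' @return a `relmat` of kind `G_additive` with attribute `n_variants`.
#' @export
grm_additive <- function(geno) {
  g <- subset_genotyped(geno)
  dos <- g$dosages
  p <- g$map$freq
  check_polymorphic(p)
  m <- length(p)
  for (j in which(colSums(is.na(dos)) > 0L)) dos[is.na(dos[, j]), j] <- 2 * p[j]
  denom <- 2 * p * (1 - p)
  W <- sweep(dos, 2L, 2 * p)
  W <- sweep(W, 2L, sqrt(denom), "/")
  G <- tcrossprod(W) / m
  dd <- numeric(nrow(dos))
  for (j in seq_len(m)) {
    x <- dos[, j]
    dd <- dd + (x^2 - (1 + 2 * p[j]) * x + 2 * p[j]^2) / denom[j]
  }
  diag(G) <- 1 + dd / m
  out <- new_relmat(G, "G_additive")
  attr(out, "n_variants") <- m
  out
}

#' Genomic dominance relationship matrix
#'
#' Per-variant dominance covariate `w` with values `(-2p^2, 2pq, -2q^2)` for
#' dosages (0, 1, 2); `D = W W' / sum_i (2 p_i q_i)^2`. Missing dosages
#' contribute the HWE expectation of `w` (zero).
#'
#' @param geno a QC-passed `genotypes` object.
#' @return a `relmat` of kind `D_dominance` with attribute `n_variants`.
#' @export
grm_dominance <- function(geno) {
  g <- subset_genotyped(geno)
  dos <- g$dosages
  p <- g$map$freq
  check_polymorphic(p)
  W <- dom_code(dos, p)
  W[is.na(W)] <- 0
  denom <- sum((2 * p * (1 - p))^2)
  D <- tcrossprod(W) / denom
  out <- new_relmat(D, "D_dominance")
  attr(out, "n_variants") <- length(p)
  out
}

# topological order with cycle detection; returns permutation of row indices
pedigree_order <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- idx[ped$sire]; di <- idx[ped$dam]
  depth <- rep(NA_integer_, n)
  compute_depth <- function(i, stack = integer(0)) {
    if (!is.na(depth[i])) return(depth[i])
    if (i %in% stack)
      stop("pedigree cycle detected involving animal ", ped$id[i])
    stack <- c(stack, i)
    ds <- if (is.na(si[i])) 0L else compute_depth(si[i], stack) + 1L
    dd <- if (is.na(di[i])) 0L else compute_depth(di[i], stack) + 1L
    depth[i] <<- max(ds, dd)
    depth[i]
  }
  for (i in seq_len(n)) compute_depth(i)
  order(depth)
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Wright's numerator relationship matrix with inbreeding:
#' `a_jj = 1 + F_j = 1 + 0.5 a_{sire,dam}`, off-diagonals by the classic
#' recursion. Unknown parents contribute zero.
#'
#' @param ped a `pedigree` data.frame (columns `id`, `sire`, `dam`; parents
#'   may appear in any row order; cycles raise an error naming an animal).
#' @return a `relmat` of kind `A_pedigree` ordered as the input rows.
#' @export
pedigree_additive <- function(ped) {
  n <- nrow(ped)
  ord <- pedigree_order(ped)
  ids <- ped$id[ord]
  idx <- stats::setNames(seq_len(n), ids)
  si <- idx[ped$sire[ord]]; di <- idx[ped$dam[ord]]
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (j in seq_len(n)) {
    s <- si[j]; d <- di[j]
    if (j > 1L) {
      ks <- seq_len(j - 1L)
      as_ <- if (!is.na(s)) A[ks, s] else 0
      ad_ <- if (!is.na(d)) A[ks, d] else 0
      A[ks, j] <- 0.5 * (as_ + ad_)
      A[j, ks] <- A[ks, j]
    }
    A[j, j] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  back <- match(ped$id, ids)
  new_relmat(A[back, back, drop = FALSE], "A_pedigree")
}

#' Pedigree dominance relationship matrix
#'
#' Non-inbred approximation
#' `d_jk = 0.25 (a_{sj,sk} a_{dj,dk} + a_{sj,dk} a_{dj,sk})` for pairs with
#' both parents known; pairs involving founders or half-known parents get 0
#' off-diagonal; diagonal is 1.
#'
#' @param ped a `pedigree` data.frame.
#' @param A matching numerator relationship matrix from
#'   [pedigree_additive()] (computed if missing).
#' @return a `relmat` of kind `D_pedigree` in pedigree row order.
#' @export
pedigree_dominance <- function(ped, A = NULL) {
  if (is.null(A)) A <- pedigree_additive(ped)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- idx[ped$sire]; di <- idx[ped$dam]
  D <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  known <- which(!is.na(si) & !is.na(di))
  for (aj in known) {
    for (ak in known) {
      if (ak > aj) next
      if (aj == ak) next
      D[aj, ak] <- 0.25 * (A[si[aj], si[ak]] * A[di[aj], di[ak]] +
                           A[si[aj], di[ak]] * A[di[aj], si[ak]])
      D[ak, aj] <- D[aj, ak]
    }
  }
  diag(D) <- 1
  new_relmat(D, "D_pedigree")
}
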