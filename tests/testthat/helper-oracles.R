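# Independent oracles used to freeze expected values. These deliberately use
# different algorithms from the package code paths they check.

# HWE exact test by direct enumeration with log-factorials:
# P(h | r, n) = C(n; hom_r, h, hom_c) 2^h / C(2n, r)
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  r <- 2 * min(n_AA, n_aa) + n_Aa
  if (r == 0 || r == 2 * n) return(1)
  hs <- seq(r %% 2, min(r, 2 * n - r), by = 2)
  logp <- vapply(hs, function(h) {
    hom_r <- (r - h) / 2
    hom_c <- n - hom_r - h
    lfactorial(n) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c) +
      h * log(2) - (lfactorial(2 * n) - lfactorial(r) - lfactorial(2 * n - r))
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hs)]
  sum(p[p <= obs * (1 + 1e-12)])
}

# pedigree additive relationship by the recursive kinship definition
# f(i,j) = coancestry; a(i,j) = 2 f(i,j). Memoized on id pairs.
ped_a_oracle <- function(ped) {
  idx <- setNames(seq_len(nrow(ped)), ped$id)
  si <- idx[ped$sire]; di <- idx[ped$dam]
  memo <- new.env(hash = TRUE)
  f <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- paste(min(i, j), max(i, j))
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (i == j) {
      0.5 * (1 + f(si[i], di[i]))
    } else if (i < j) {
      # recurse on the later animal (parents have smaller depth by order here)
      jj <- max(i, j); ii <- min(i, j)
      0.5 * (f(ii, si[jj]) + f(ii, di[jj]))
    } else {
      f(j, i)
    }
    memo[[key]] <- val
    val
  }
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) {
    A[i, j] <- A[j, i] <- 2 * f(i, j)
  }
  A
}

# greedy LD pruning oracle on an explicit r2 matrix: pairs in index order,
# drop lower MAF (tie -> later index)
prune_oracle <- function(r2, maf, r2_max = 0.5) {
  m <- nrow(r2)
  alive <- rep(TRUE, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (!alive[i] || !alive[j]) next
    if (r2[i, j] > r2_max) {
      drop <- if (maf[i] < maf[j]) i else if (maf[j] < maf[i]) j else j
      alive[drop] <- FALSE
    }
  }
  alive
}

# all-pairs gene annotation oracle
annotate_oracle <- function(variants, genes, flank = 1000L) {
  hits <- list()
  for (i in seq_len(nrow(variants))) for (j in seq_len(nrow(genes))) {
    if (variants$chr[i] != genes$chr[j]) next
    if (variants$pos[i] >= genes$start[j] - flank &&
        variants$pos[i] <= genes$end[j] + flank) {
      hits[[length(hits) + 1L]] <- data.frame(
        variant = variants$id[i], gene = genes$gene[j],
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(variant = character(0), gene = character(0)))
  do.call(rbind, hits)
}

# small random pedigree: founders then offspring of random earlier animals
random_pedigree <- function(n, n_founders = 10L, seed = 1L) {
  set.seed(seed)
  id <- sprintf("A%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  sex <- c(rep(c("M", "F"), length.out = n_founders),
           sample(c("M", "F"), n - n_founders, replace = TRUE))
  for (i in (n_founders + 1L):n) {
    males <- which(sex[seq_len(i - 1L)] == "M")
    females <- which(sex[seq_len(i - 1L)] == "F")
    sire[i] <- id[sample(males, 1L)]
    dam[i] <- id[sample(females, 1L)]
  }
  structure(data.frame(id = id, sire = sire, dam = dam, sex = sex,
                       stringsAsFactors = FALSE),
            class = c("pedigree", "data.frame"))
}

# genotypes object from a raw dosage matrix on one chromosome
toy_genotypes <- function(dos, chr = "1") {
  m <- ncol(dos)
  map <- data.frame(chr = rep(chr, length.out = m),
                    pos = seq(1000L, by = 1000L, length.out = m),
                    id = sprintf("v%03d", seq_len(m)),
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  new_genotypes(dos, map)
}
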