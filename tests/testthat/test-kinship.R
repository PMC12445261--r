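founder_geno <- function(n, m, p_range = c(0.1, 0.5), seed = 1L) {
  set.seed(seed)
  p <- runif(m, p_range[1], p_range[2])
  dos <- vapply(p, function(pp) rbinom(n, 2, pp), numeric(n))
  rownames(dos) <- sprintf("F%04d", seq_len(n))
  toy_genotypes(dos)
}

test_that("genomic G has unit-mean diagonal and null off-diagonal on founders", {
  geno <- founder_geno(200, 10000, seed = 3L)
  G <- grm_additive(geno)
  expect_lt(max(abs(G - t(G))), 1e-12)
  expect_lt(abs(mean(diag(G)) - 1), 0.02)
  expect_lt(abs(mean(G[upper.tri(G)])), 0.01)
  # dominance analogue
  D <- grm_dominance(geno)
  expect_lt(max(abs(D - t(D))), 1e-12)
  expect_lt(abs(mean(D[upper.tri(D)])), 0.01)
  expect_lt(abs(mean(diag(D)) - 1), 0.05)
})

test_that("dominance coding and single-variant identities", {
  # p = 0.5: w = (-0.5, 0.5, -0.5); het pair centred additive term is 0
  dos <- matrix(c(0, 1, 2, 1), nrow = 4, ncol = 1,
                dimnames = list(c("a", "b", "c", "d"), NULL))
  geno <- toy_genotypes(dos)
  expect_equal(geno$map$freq, 0.5)
  W <- adgreml:::dom_code(dos, 0.5)
  expect_equal(as.numeric(W), c(-0.5, 0.5, -0.5, 0.5))
  G <- grm_additive(geno)
  expect_equal(G["b", "d"], 0)  # (1-2p)(1-2p)/2pq with p=.5 -> 0

  # algebraic null: E[w] over HWE genotypes is 0 for any p
  for (p in c(0.1, 0.3, 0.5)) {
    q <- 1 - p
    expect_equal(q^2 * (-2 * p^2) + 2 * p * q * (2 * p * q) + p^2 * (-2 * q^2), 0)
  }
})

test_that("genomic and pedigree expectations agree for full sibs", {
  # 250 full-sib pairs via gene dropping
  cfg <- cohort_config(n_sires = 0L, n_ewes = 0L, n_lambs = 0L,
                       group_sizes = integer(0),
                       n_contemporaries_ungenotyped = 0L,
                       n_variants = 3000L, selection_differential = 0,
                       target_h2 = c(TL = 0.5), target_d2 = c(TL = 0),
                       trait_means = c(TL = 0), trait_sds = c(TL = 1),
                       seed = 31L)
  npair <- 250L
  set.seed(31)
  m <- cfg$n_variants
  p <- runif(m, 0.2, 0.5)
  chr_index <- rep(1L, m)
  ids <- c(sprintf("P%03da", seq_len(npair)), sprintf("P%03db", seq_len(npair)))
  dos <- matrix(0, 2L * npair, m, dimnames = list(ids, NULL))
  for (k in seq_len(npair)) {
    hs <- matrix(rbinom(2 * m, 1, rep(p, each = 2)), nrow = 2)
    hd <- matrix(rbinom(2 * m, 1, rep(p, each = 2)), nrow = 2)
    for (sib in 1:2) {
      g1 <- adgreml:::make_gamete(hs[1, ], hs[2, ], chr_index, 0.01)
      g2 <- adgreml:::make_gamete(hd[1, ], hd[2, ], chr_index, 0.01)
      dos[(sib - 1L) * npair + k, ] <- g1 + g2
    }
  }
  geno <- toy_genotypes(dos)
  G <- grm_additive(geno)
  D <- grm_dominance(geno)
  sib_g <- vapply(seq_len(npair), function(k) G[k, npair + k], numeric(1))
  sib_d <- vapply(seq_len(npair), function(k) D[k, npair + k], numeric(1))
  expect_lt(abs(mean(sib_g) - 0.5), 0.05)
  expect_lt(abs(mean(sib_d) - 0.25), 0.05)
})

test_that("G and D are invariant to allele relabeling", {
  geno <- founder_geno(80, 400, seed = 5L)
  G1 <- grm_additive(geno); D1 <- grm_dominance(geno)
  flipped <- toy_genotypes(2 - geno$dosages)
  G2 <- grm_additive(flipped); D2 <- grm_dominance(flipped)
  expect_equal(unclass(G1), unclass(G2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(unclass(D1), unclass(D2), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("monomorphic variants are rejected with guidance", {
  dos <- cbind(rbinom(30, 2, 0.4), rep(2, 30))
  rownames(dos) <- sprintf("S%02d", 1:30)
  expect_error(grm_additive(toy_genotypes(dos)), "filter_variants")
  expect_error(grm_dominance(toy_genotypes(dos)), "filter_variants")
})

test_that("pedigree A reproduces classical values and the recursive oracle", {
  ped <- structure(data.frame(
    id = c("s", "d", "o1", "o2", "x"),
    sire = c(NA, NA, "s", "s", "o1"),
    dam = c(NA, NA, "d", "d", "d"),
    stringsAsFactors = FALSE), class = c("pedigree", "data.frame"))
  A <- pedigree_additive(ped)
  expect_equal(A["s", "o1"], 0.5)       # parent-offspring
  expect_equal(A["o1", "o2"], 0.5)      # full sibs
  # x = offspring of o1 and its dam d (parent-offspring mating): F = 0.25
  expect_equal(A["x", "x"], 1.25)
  expect_equal(diag(A) >= 1, rep(TRUE, 5), ignore_attr = TRUE)

  # random 50-animal pedigree, entrywise against the recursive oracle
  rp <- random_pedigree(50, n_founders = 8L, seed = 6L)
  expect_equal(unclass(pedigree_additive(rp)), ped_a_oracle(rp),
               tolerance = 1e-12, ignore_attr = TRUE)

  cyc <- structure(data.frame(id = c("a", "b"), sire = c("b", "a"),
                              dam = c(NA, NA), stringsAsFactors = FALSE),
                   class = c("pedigree", "data.frame"))
  expect_error(pedigree_additive(cyc), "cycle")
})

test_that("pedigree dominance matrix gives the classical coefficients", {
  ped <- structure(data.frame(
    id = c("s1", "s2", "d1", "d2", "fs1", "fs2", "hs1", "hs2", "u"),
    sire = c(NA, NA, NA, NA, "s1", "s1", "s1", "s1", NA),
    dam = c(NA, NA, NA, NA, "d1", "d1", "d1", "d2", NA),
    stringsAsFactors = FALSE), class = c("pedigree", "data.frame"))
  A <- pedigree_additive(ped)
  D <- pedigree_dominance(ped, A)
  expect_equal(D["fs1", "fs2"], 0.25)   # full sibs
  expect_equal(D["hs1", "hs2"], 0)      # half sibs (shared sire only)
  expect_equal(D["fs1", "u"], 0)        # unrelated
  expect_equal(diag(D), setNames(rep(1, 9), ped$id))
  expect_equal(unclass(D), unclass(t(D)), ignore_attr = TRUE)
})

test_that("relationship matrices round-trip through TSV and GCTA layout", {
  geno <- founder_geno(25, 200, seed = 7L)
  G <- grm_additive(geno)
  tsv <- tempfile(fileext = ".tsv")
  write_grm_tsv(G, tsv)
  G2 <- read_grm_tsv(tsv)
  expect_equal(unclass(G2), unclass(G), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rownames(G2), rownames(G))

  pre <- tempfile()
  write_grm_gcta(G, pre)
  G3 <- read_grm_gcta(pre)
  # float stream -> 1e-6 relative precision
  expect_equal(unclass(G3), unclass(G), tolerance = 1e-5, ignore_attr = TRUE)
})
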