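test_that("default pedigree reproduces the mating-experiment layout", {
  cfg <- cohort_config(n_variants = 100L, seed = 1L)
  ped <- simulate_pedigree(cfg)
  lambs <- ped[ped$role == "lamb" & ped$group != "CON", ]
  expect_equal(nrow(lambs), 254L)
  counts <- as.integer(table(lambs$sire)[sprintf("SIRE%02d", 1:4)])
  expect_equal(counts, c(62L, 65L, 64L, 63L))
  expect_setequal(unique(lambs$group), c("ST1", "ST2", "LT1", "LT2"))
  cons <- ped[ped$group %in% "CON", ]
  expect_equal(nrow(cons), 38L)
  expect_false(any(cons$genotyped))
  expect_true(all(lambs$litter_size %in% 1:3))
  expect_true(all(lambs$parity %in% 1:4))
})

test_that("pedigree edge cases: founders only, referential integrity", {
  cfg0 <- cohort_config(n_lambs = 0L, group_sizes = integer(0),
                        n_contemporaries_ungenotyped = 0L,
                        n_variants = 50L, seed = 2L)
  ped0 <- simulate_pedigree(cfg0)
  expect_true(all(is.na(ped0$sire) & is.na(ped0$dam)))
  expect_equal(nrow(ped0), cfg0$n_sires + cfg0$n_ewes)

  for (seed in c(3L, 17L)) {
    ped <- simulate_pedigree(cohort_config(n_variants = 50L, seed = seed))
    offs <- ped[!is.na(ped$sire), ]
    expect_true(all(offs$sire %in% ped$id))
    expect_true(all(offs$dam %in% ped$id))
  }
  expect_error(cohort_config(n_lambs = 100L, group_sizes = c(10L, 10L, 10L, 10L)),
               "group_sizes")
  expect_error(cohort_config(n_variants = 10L, n_qtl_additive = 20L),
               "n_qtl")
  expect_error(cohort_config(target_h2 = c(TL = 0.9), target_d2 = c(TL = 0.2)),
               "infeasible")
})

test_that("gene dropping respects HWE, Mendelian transmission and frequency", {
  cfg <- cohort_config(n_sires = 0L, n_ewes = 2000L, n_lambs = 0L,
                       group_sizes = integer(0),
                       n_contemporaries_ungenotyped = 0L,
                       n_variants = 60L, n_qtl_additive = 10L,
                       n_qtl_dominance = 5L,
                       maf_range = c(0.3, 0.3), selection_differential = 0,
                       trait_means = c(TL = 0), trait_sds = c(TL = 1),
                       target_h2 = c(TL = 0.5), target_d2 = c(TL = 0),
                       seed = 4L)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  # observed founder frequency within 3 binomial SE of 0.3 (single-variant
  # example); across 60 variants allow 5 SE
  se <- sqrt(0.3 * 0.7 / (2 * 2000))
  expect_lt(abs(geno$map$freq[1] - 0.3), 3 * se)
  expect_lt(max(abs(geno$map$freq - 0.3)), 5 * se)
  # HWE genotype proportions at p ~ 0.3 pooled over variants
  pooled <- table(factor(geno$dosages, levels = 0:2)) / length(geno$dosages)
  expect_equal(as.numeric(pooled), c(0.49, 0.42, 0.09), tolerance = 0.03)

  # Mendelian: both parents dosage 0 at a variant -> offspring 0
  cfg2 <- cohort_config(n_variants = 200L, n_qtl_additive = 20L,
                        n_qtl_dominance = 5L, seed = 5L)
  ch <- simulate_cohort(cfg2)
  ped2 <- ch$pedigree
  dos <- ch$genotypes$dosages
  lambs <- ped2[ped2$role == "lamb", ][1:50, ]
  for (i in seq_len(nrow(lambs))) {
    both0 <- dos[lambs$sire[i], ] == 0 & dos[lambs$dam[i], ] == 0
    expect_true(all(dos[lambs$id[i], both0] == 0))
    both2 <- dos[lambs$sire[i], ] == 2 & dos[lambs$dam[i], ] == 2
    expect_true(all(dos[lambs$id[i], both2] == 2))
  }
  # allele frequencies conserved founders -> offspring in expectation
  founders <- ped2$id[is.na(ped2$sire)]
  offs <- ped2$id[!is.na(ped2$sire)]
  pf <- colMeans(dos[founders, ]) / 2
  po <- colMeans(dos[offs, ]) / 2
  expect_lt(mean(abs(pf - po)), 0.08)
})

test_that("trait generation hits its stated world", {
  ch <- simulate_founder_cohort(n = 4000, m = 400, h2 = 0.8, d2 = 0,
                                n_qtl = 60L, seed = 6L)
  tt <- ch$traits
  # prevalence of the binary trait within 3 binomial SE
  K <- 0.15
  expect_lt(abs(mean(tt$AXISD) - K), 3 * sqrt(K * (1 - K) / nrow(tt)))
  # breeder's-equation oracle: slope of TBV on phenotype ~ h2
  tbv <- ch$true_params$tbv[tt$id, "TL"]
  slope <- coef(lm(tbv ~ tt$TL))[2]
  expect_equal(unname(slope), 0.8, tolerance = 0.05)
  # d2 = 0 -> no dominance deviations
  expect_equal(var(ch$true_params$dominance_deviation[, "TL"]), 0)

  # realized variance decomposition matches targets (ANOVA against truth)
  ch2 <- simulate_founder_cohort(n = 5000, m = 300, h2 = 0.6, d2 = 0.15,
                                 n_qtl = 60L, n_qtl_dom = 30L, seed = 7L)
  tp <- ch2$true_params$per_trait$TL
  u <- ch2$true_params$tbv[, "TL"]
  v <- ch2$true_params$dominance_deviation[, "TL"]
  y <- ch2$traits$TL
  fit <- lm(y ~ u + v)
  expect_equal(unname(coef(fit)[2:3]), c(1, 1), tolerance = 0.05)
  expect_equal(var(u), tp$sigma_g2, tolerance = 1e-8)
  expect_equal(var(v), tp$sigma_d2, tolerance = 1e-8)
  expect_equal(sum(resid(fit)^2) / df.residual(fit), tp$sigma_e2,
               tolerance = 0.1)
})

test_that("same seed gives bit-identical cohorts; selection diverges groups", {
  cfg <- cohort_config(n_variants = 300L, n_qtl_additive = 50L,
                       n_qtl_dominance = 10L, seed = 8L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$traits, b$traits)
  # divergent selection: LT lambs longer-tailed than ST lambs
  tl <- tapply(a$traits$TL, substr(a$traits$group, 1, 2), mean)
  expect_gt(tl[["LT"]] - tl[["ST"]], 1)
  expect_gt(a$true_params$realized_selection_differential, 1)
})

test_that("genetic correlation between traits is controllable", {
  cfg <- cohort_config(n_sires = 0L, n_ewes = 1500L, n_lambs = 0L,
                       group_sizes = integer(0),
                       n_contemporaries_ungenotyped = 0L,
                       n_variants = 900L, n_qtl_additive = 300L,
                       n_qtl_dominance = 10L, selection_differential = 0,
                       target_h2 = c(TL = 0.6, TC = 0.6),
                       target_d2 = c(TL = 0, TC = 0),
                       trait_means = c(TL = 0, TC = 0),
                       trait_sds = c(TL = 1, TC = 1),
                       qtl_effect_cor = c(TC = 0.6), seed = 9L)
  ch <- simulate_cohort(cfg)
  gc <- cor(ch$true_params$tbv[, "TL"], ch$true_params$tbv[, "TC"])
  expect_equal(gc, 0.6, tolerance = 0.15)
})
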