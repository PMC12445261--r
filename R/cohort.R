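#' Configuration for a synthetic divergent-selection cohort
#'
#' Captures the design of a selection and mating experiment: a handful of
#' extreme-EBV sires mated to extreme-EBV ewes in "short x short" (ST) and
#' "long x long" (LT) groups, plus a set of ungenotyped herd contemporaries.
#' Defaults reproduce the cohort layout the package emulates: 4 sires,
#' 142 ewes, 254 lambs split 62/65/64/63 over the four mating groups, and
#' 38 contemporaries with phenotypes and pedigree links but no genotypes.
#'
#' @param n_sires number of sires (half assigned to ST, half to LT).
#' @param n_ewes number of mated ewes.
#' @param n_lambs total number of lambs across the mating groups.
#' @param group_sizes integer vector of lambs per sire group summing to
#'   `n_lambs`; defaults to 62/65/64/63 when the defaults are kept, otherwise
#'   an even split.
#' @param n_contemporaries_ungenotyped phenotyped but ungenotyped lambs from
#'   further matings.
#' @param n_variants number of biallelic autosomal variants.
#' @param n_chromosomes autosomes the variants are spread over (default 26).
#' @param maf_range founder minor-allele-frequency range, within (0, 0.5].
#' @param n_qtl_additive,n_qtl_dominance number of causal variants; dominance
#'   QTLs are a subset of the additive ones.
#' @param target_h2 named fractions of phenotypic variance that are additive,
#'   per trait.
#' @param target_d2 named dominance fractions per trait.
#' @param binary_prevalences named prevalences in (0,1) for binary traits.
#' @param selection_differential separation, in genetic-SD units, between the
#'   ST and LT parent groups on the focal trait's genetic score.
#' @param recomb_rate per-adjacent-variant recombination probability used in
#'   gene dropping (uniform within chromosome).
#' @param missing_rate proportion of dosages set missing (for QC testing).
#' @param fst two-deme founder differentiation (Balding-Nichols); 0 disables.
#' @param focal_trait trait whose genetic score drives parent selection.
#' @param qtl_effect_cor named vector: correlation of a trait's QTL effect
#'   sizes with the focal trait's (traits share QTL positions, so this is
#'   approximately the genetic correlation); unnamed traits get independent
#'   effects.
#' @param trait_means,trait_sds named phenotypic means/SDs on the recorded
#'   scale for the Gaussian and count traits.
#' @param seed integer seed; all randomness derives from it.
#'
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_sires = 4L,
                          n_ewes = 142L,
                          n_lambs = 254L,
                          group_sizes = NULL,
                          n_contemporaries_ungenotyped = 38L,
                          n_variants = 5000L,
                          n_chromosomes = 26L,
                          maf_range = c(0.05, 0.5),
                          n_qtl_additive = NULL,
                          n_qtl_dominance = NULL,
                          target_h2 = c(TL = 0.80, TC = 0.21, BL = 0.85,
                                        BW = 0.85, nVERT = 0.29,
                                        AXISD = 0.10, BLCKV = 0.10,
                                        WDGV = 0.10, FRC = 0.10),
                          target_d2 = c(TL = 0.15, TC = 0, BL = 0.15,
                                        BW = 0, nVERT = 0,
                                        AXISD = 0, BLCKV = 0,
                                        WDGV = 0, FRC = 0),
                          binary_prevalences = c(AXISD = 0.1528,
                                                 BLCKV = 0.1289,
                                                 WDGV = 0.0833,
                                                 FRC = 0.2773),
                          selection_differential = 2.0,
                          recomb_rate = NULL,
                          missing_rate = 0,
                          fst = 0,
                          focal_trait = "TL",
                          qtl_effect_cor = NULL,
                          trait_means = c(TL = 22.54, TC = 6.54, BL = 32.73,
                                          BW = 5.43, nVERT = 20.35),
                          trait_sds = c(TL = 2.29, TC = 0.50, BL = 2.37,
                                        BW = 0.95, nVERT = 1.63),
                          seed = 2021L) {
  if (n_sires > 0L && is.null(group_sizes)) {
    if (n_sires == 4L && n_lambs == 254L) {
      group_sizes <- c(62L, 65L, 64L, 63L)
    } else {
      base <- n_lambs %/% max(n_sires, 1L)
      group_sizes <- rep(base, n_sires)
      extra <- n_lambs - sum(group_sizes)
      if (extra > 0L) group_sizes[seq_len(extra)] <- group_sizes[seq_len(extra)] + 1L
    }
  }
  if (is.null(n_qtl_additive))
    n_qtl_additive <- max(1L, min(300L, n_variants %/% 10L))
  if (is.null(n_qtl_dominance))
    n_qtl_dominance <- max(1L, n_qtl_additive %/% 3L)
  if (n_sires > 0L && sum(group_sizes) != n_lambs)
    stop("group_sizes must sum to n_lambs (", sum(group_sizes), " != ", n_lambs, ")")
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be within (0, 0.5] with lower <= upper")
  traits <- union(names(target_h2), names(target_d2))
  for (tr in traits) {
    h2 <- if (tr %in% names(target_h2)) target_h2[[tr]] else 0
    d2 <- if (tr %in% names(target_d2)) target_d2[[tr]] else 0
    if (h2 < 0 || d2 < 0 || h2 + d2 > 1)
      stop("infeasible variance targets for trait ", tr, ": h2 + d2 must lie in [0, 1]")
  }
  if (any(binary_prevalences <= 0 | binary_prevalences >= 1))
    stop("binary prevalences must lie in (0, 1)")
  if (n_qtl_dominance > n_qtl_additive)
    stop("n_qtl_dominance cannot exceed n_qtl_additive")
  if (n_variants < n_qtl_additive)
    stop("n_variants (", n_variants, ") < n_qtl_additive (", n_qtl_additive, ")")
  if (is.null(recomb_rate)) {
    # ~1 Morgan per chromosome spread over its variants
    recomb_rate <- min(0.5, n_chromosomes / max(n_variants, 1L))
  }
  cfg <- list(n_sires = as.integer(n_sires), n_ewes = as.integer(n_ewes),
              n_lambs = as.integer(n_lambs),
              group_sizes = as.integer(group_sizes),
              n_contemporaries_ungenotyped = as.integer(n_contemporaries_ungenotyped),
              n_variants = as.integer(n_variants),
              n_chromosomes = as.integer(n_chromosomes),
              maf_range = maf_range,
              n_qtl_additive = as.integer(n_qtl_additive),
              n_qtl_dominance = as.integer(n_qtl_dominance),
              target_h2 = target_h2, target_d2 = target_d2,
              binary_prevalences = binary_prevalences,
              selection_differential = selection_differential,
              recomb_rate = recomb_rate, missing_rate = missing_rate,
              fst = fst, focal_trait = focal_trait,
              qtl_effect_cor = qtl_effect_cor,
              trait_means = trait_means, trait_sds = trait_sds,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

gaussian_traits <- function(config) {
  setdiff(names(config$trait_means), "nVERT")
}

all_trait_names <- function(config) {
  c(names(config$trait_means), names(config$binary_prevalences))
}

#' Simulate the mating-experiment pedigree
#'
#' Founder sires and ewes plus lambs allocated to sire groups; litter size
#' (single/twin/triplet) and dam parity (1-4) are assigned and recorded as
#' covariates. Ungenotyped contemporaries descend from separate founder
#' matings. With `n_lambs = 0` only founders are returned.
#'
#' @param config a [cohort_config()].
#' @return a `data.frame` of class `pedigree` with columns `id`, `sire`,
#'   `dam`, `sex`, `birth_year`, `group`, `role`, `litter_size`, `parity`,
#'   `genotyped` (unknown parents are `NA`).
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_sires <- config$n_sires
  half <- n_sires %/% 2L
  sire_ids <- if (n_sires > 0L) sprintf("SIRE%02d", seq_len(n_sires)) else character(0)
  sire_grp <- if (n_sires > 0L)
    c(rep("ST", half), rep("LT", n_sires - half)) else character(0)
  ewe_ids <- if (config$n_ewes > 0L) sprintf("EWE%04d", seq_len(config$n_ewes)) else character(0)

  founders <- data.frame(
    id = c(sire_ids, ewe_ids),
    sire = NA_character_, dam = NA_character_,
    sex = c(rep("M", length(sire_ids)), rep("F", length(ewe_ids))),
    birth_year = 2019L,
    group = c(sire_grp, rep(NA_character_, length(ewe_ids))),
    role = c(rep("sire", length(sire_ids)), rep("ewe", length(ewe_ids))),
    litter_size = NA_integer_, parity = NA_integer_,
    # only the experiment's lambs are sequenced; in founder-only cohorts the
    # founders themselves are the study animals
    genotyped = config$n_lambs == 0L,
    stringsAsFactors = FALSE)

  lambs <- NULL
  if (config$n_lambs > 0L) {
    if (n_sires < 1L) stop("lambs requested but no sires configured")
    # ewes split evenly over sire groups, in id order; group label ST/LT by sire half
    ewe_group_of <- rep(seq_len(n_sires), length.out = config$n_ewes)
    ewe_group_of <- sort(ewe_group_of)
    lamb_rows <- vector("list", n_sires)
    lamb_counter <- 0L
    for (g in seq_len(n_sires)) {
      n_g <- config$group_sizes[g]
      ewes_g <- ewe_ids[ewe_group_of == g]
      if (length(ewes_g) == 0L) stop("no ewes allocated to sire group ", g)
      # litters of 1-3 lambs until the group quota is met
      dams <- character(0); litters <- integer(0)
      remaining <- n_g; k <- 1L
      while (remaining > 0L) {
        ls <- sample(1:3, 1L, prob = c(0.35, 0.5, 0.15))
        ls <- min(ls, remaining)
        dam <- ewes_g[((k - 1L) %% length(ewes_g)) + 1L]
        dams <- c(dams, rep(dam, ls)); litters <- c(litters, rep(ls, ls))
        remaining <- remaining - ls; k <- k + 1L
      }
      ids <- sprintf("LAMB%04d", lamb_counter + seq_len(n_g))
      lamb_counter <- lamb_counter + n_g
      lamb_rows[[g]] <- data.frame(
        id = ids, sire = sire_ids[g], dam = dams,
        sex = sample(c("M", "F"), n_g, replace = TRUE),
        birth_year = 2021L,
        group = paste0(sire_grp[g], ((g - 1L) %% max(half, 1L)) + 1L),
        role = "lamb",
        litter_size = litters,
        parity = NA_integer_,
        genotyped = TRUE, stringsAsFactors = FALSE)
    }
    lambs <- do.call(rbind, lamb_rows)
    # parity is a dam covariate shared within litter
    dam_parity <- stats::setNames(sample(1:4, config$n_ewes, replace = TRUE), ewe_ids)
    lambs$parity <- dam_parity[lambs$dam]
  }

  cons <- NULL
  if (config$n_contemporaries_ungenotyped > 0L) {
    n_c <- config$n_contemporaries_ungenotyped
    con_sires <- sprintf("CSIRE%02d", seq_len(2L))
    con_dams <- sprintf("CEWE%03d", seq_len(n_c))
    con_founders <- data.frame(
      id = c(con_sires, con_dams),
      sire = NA_character_, dam = NA_character_,
      sex = c(rep("M", 2L), rep("F", n_c)),
      birth_year = 2019L, group = NA_character_,
      role = c(rep("sire", 2L), rep("ewe", n_c)),
      litter_size = NA_integer_, parity = NA_integer_,
      genotyped = FALSE, stringsAsFactors = FALSE)
    cons <- data.frame(
      id = sprintf("CON%03d", seq_len(n_c)),
      sire = sample(con_sires, n_c, replace = TRUE),
      dam = con_dams,
      sex = sample(c("M", "F"), n_c, replace = TRUE),
      birth_year = 2021L, group = "CON", role = "lamb",
      litter_size = sample(1:3, n_c, replace = TRUE, prob = c(0.35, 0.5, 0.15)),
      parity = sample(1:4, n_c, replace = TRUE),
      genotyped = FALSE, stringsAsFactors = FALSE)
    cons <- rbind(con_founders, cons)
  }

  ped <- rbind(founders, cons[cons$role != "lamb", , drop = FALSE],
               lambs, cons[cons$role == "lamb", , drop = FALSE])
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  attr(ped, "config_seed") <- config$seed
  ped
}

# deterministic variant map: variants spread evenly over autosomes
variant_map <- function(config) {
  m <- config$n_variants
  chr <- sort(rep_len(seq_len(config$n_chromosomes), m))
  pos <- integer(m)
  for (c in unique(chr)) {
    idx <- which(chr == c)
    pos[idx] <- seq(10000L, by = 5000L, length.out = length(idx))
  }
  data.frame(chr = as.character(chr), pos = pos,
             id = sprintf("var%06d", seq_len(m)),
             ref = "A", alt = "G", stringsAsFactors = FALSE)
}

# one gamete from a parent's two haplotypes, recombining within chromosomes
make_gamete <- function(h1, h2, chr_index, recomb_rate) {
  m <- length(h1)
  switches <- stats::runif(m) < recomb_rate
  # independent chromosome starts
  new_chr <- c(TRUE, chr_index[-1] != chr_index[-m])
  switches[new_chr] <- stats::runif(sum(new_chr)) < 0.5
  phase <- cumsum(switches) %% 2L
  ifelse(phase == 0L, h1, h2)
}

#' Simulate genotypes by gene dropping through the pedigree
#'
#' Founder haplotypes are drawn at per-variant allele frequencies in
#' Hardy-Weinberg proportions; offspring genotypes arise by Mendelian
#' transmission with recombination within chromosomes. Parent selection on a
#' QTL-based genetic score reproduces the divergent ST/LT design: a candidate
#' founder pool is simulated and the extremes (at a truncation solved from
#' `selection_differential`) become the experiment's sires and ewes.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param config the same [cohort_config()].
#' @return an object of class `genotypes`: list with `dosages` (animals x
#'   variants, values 0/1/2/NA), `map` (chr, pos, id, ref, alt, freq), `ids`,
#'   `genotyped` flag vector, and a `qtl` attribute holding causal indices
#'   and raw effect draws reused by [simulate_traits()].
#' @export
simulate_genotypes <- function(ped, config) {
  stopifnot(inherits(ped, "pedigree"), inherits(config, "cohort_config"))
  set.seed(config$seed + 1L)
  m <- config$n_variants
  map <- variant_map(config)
  chr_index <- as.integer(map$chr)
  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])

  # causal architecture fixed here so parent selection can use it
  qtl_idx <- sort(sample.int(m, config$n_qtl_additive))
  qtl_dom <- sort(sample(qtl_idx, config$n_qtl_dominance))
  a_raw <- stats::rnorm(config$n_qtl_additive)
  k_dom <- stats::rnorm(config$n_qtl_dominance, mean = 1, sd = 0.5)

  founders <- ped$id[is.na(ped$sire) & is.na(ped$dam)]
  sel_sires <- ped$id[ped$role == "sire" & grepl("^SIRE", ped$id)]
  sel_ewes <- ped$id[ped$role == "ewe" & grepl("^EWE", ped$id)]
  n_need <- length(sel_sires) + length(sel_ewes)
  do_selection <- config$n_lambs > 0L && n_need > 0L &&
    config$selection_differential > 0

  draw_haps <- function(n, freq) {
    matrix(stats::rbinom(2L * n * m, 1L, rep(freq, each = 2L * n)),
           nrow = 2L * n, ncol = m)
  }

  hap <- list()  # per animal: 2 x m matrix
  if (do_selection) {
    # truncation fraction f with selected-tail mean phi(z)/f = d/2
    d <- config$selection_differential
    f <- tryCatch(stats::uniroot(function(f) {
      z <- stats::qnorm(1 - f); stats::dnorm(z) / f - d / 2
    }, c(1e-4, 0.999))$root, error = function(e) 0.5)
    pool_mult <- max(2L, min(25L, ceiling(1 / (2 * f))))
    for (role in c("sire", "ewe")) {
      ids <- if (role == "sire") sel_sires else sel_ewes
      if (length(ids) == 0L) next
      n_pool <- length(ids) * 2L * pool_mult %/% 2L
      n_pool <- max(length(ids) * 2L, length(ids) * pool_mult)
      freq <- p
      H <- draw_haps(n_pool, freq)
      dos <- H[seq(1, 2L * n_pool, 2L), qtl_idx, drop = FALSE] +
        H[seq(2, 2L * n_pool, 2L), qtl_idx, drop = FALSE]
      score <- as.numeric(dos %*% a_raw)
      ord <- order(score)
      n_low <- ceiling(length(ids) / 2); n_high <- length(ids) - n_low
      pick <- c(ord[seq_len(n_low)],
                if (n_high > 0) rev(ord)[seq_len(n_high)] else integer(0))
      # low scores -> ST side (first half of ids), high -> LT side
      for (i in seq_along(ids)) {
        r <- pick[i]
        hap[[ids[i]]] <- H[c(2L * r - 1L, 2L * r), , drop = FALSE]
      }
    }
  }
  # remaining founders (contemporary parents, or everyone when no selection)
  rest <- setdiff(founders, names(hap))
  if (length(rest) > 0L) {
    two_deme <- config$fst > 0
    if (two_deme) {
      th <- (1 - config$fst) / config$fst
      p1 <- stats::rbeta(m, p * th, (1 - p) * th)
      p2 <- stats::rbeta(m, p * th, (1 - p) * th)
      deme_of <- rep_len(c(1L, 2L), length(rest))
    }
    for (i in seq_along(rest)) {
      freq <- if (two_deme) (if (deme_of[i] == 1L) p1 else p2) else p
      hap[[rest[i]]] <- matrix(stats::rbinom(2L * m, 1L, rep(freq, each = 2L)),
                               nrow = 2L, ncol = m)
    }
  }

  # gene dropping in pedigree order (parents precede offspring)
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    if (!is.null(hap[[id]])) next
    s <- ped$sire[i]; dm <- ped$dam[i]
    if (is.na(s) || is.na(dm) || is.null(hap[[s]]) || is.null(hap[[dm]]))
      stop("parents of ", id, " not simulated before offspring")
    g1 <- make_gamete(hap[[s]][1, ], hap[[s]][2, ], chr_index, config$recomb_rate)
    g2 <- make_gamete(hap[[dm]][1, ], hap[[dm]][2, ], chr_index, config$recomb_rate)
    hap[[id]] <- rbind(g1, g2)
  }

  ids <- ped$id
  dos <- matrix(0L, nrow = length(ids), ncol = m,
                dimnames = list(ids, map$id))
  for (i in seq_along(ids)) dos[i, ] <- hap[[ids[i]]][1, ] + hap[[ids[i]]][2, ]
  storage.mode(dos) <- "double"
  if (config$missing_rate > 0) {
    nmiss <- round(config$missing_rate * length(dos))
    dos[sample.int(length(dos), nmiss)] <- NA_real_
  }
  geno <- new_genotypes(dos, map, genotyped = stats::setNames(ped$genotyped, ids))
  attr(geno, "qtl") <- list(idx = qtl_idx, dom_idx = qtl_dom,
                            a_raw = a_raw, k_dom = k_dom)
  attr(geno, "seed") <- config$seed
  geno
}

#' Construct a genotypes object
#'
#' @param dosages numeric matrix (animals x variants) with values in
#'   {0, 1, 2, NA}; rownames are animal ids, colnames variant ids.
#' @param map data.frame with columns `chr`, `pos`, `id`, `ref`, `alt`.
#' @param genotyped optional named logical; defaults to all TRUE.
#' @return object of class `genotypes` with per-variant allele frequency of
#'   the counted (alt) allele computed from non-missing calls.
#' @export
new_genotypes <- function(dosages, map, genotyped = NULL) {
  stopifnot(is.matrix(dosages), nrow(map) == ncol(dosages))
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("ID%04d", seq_len(nrow(dosages)))
  if (is.null(map$id)) map$id <- sprintf("var%06d", seq_len(nrow(map)))
  colnames(dosages) <- map$id
  if (is.null(genotyped))
    genotyped <- stats::setNames(rep(TRUE, nrow(dosages)), rownames(dosages))
  map$freq <- colMeans(dosages, na.rm = TRUE) / 2
  structure(list(dosages = dosages, map = map, ids = rownames(dosages),
                 genotyped = genotyped),
            class = "genotypes")
}

#' Subset a genotypes object
#' @param geno a `genotypes` object.
#' @param animals,variants indices, ids or logical masks (default: keep all).
#' @param recompute_freq recompute allele frequencies on the subset.
#' @return a `genotypes` object.
#' @export
subset_genotypes <- function(geno, animals = NULL, variants = NULL,
                             recompute_freq = TRUE) {
  dos <- geno$dosages
  if (!is.null(animals)) dos <- dos[animals, , drop = FALSE]
  map <- geno$map
  if (!is.null(variants)) {
    dos <- dos[, variants, drop = FALSE]
    map <- map[variants, , drop = FALSE]
  }
  out <- new_genotypes(dos, map, genotyped = geno$genotyped[rownames(dos)])
  if (!recompute_freq) out$map$freq <- map$freq
  for (a in c("qtl", "seed")) attr(out, a) <- attr(geno, a)
  out
}

#' Keep only genotyped animals
#' @param geno a `genotypes` object.
#' @return a `genotypes` object restricted to animals flagged genotyped.
#' @export
subset_genotyped <- function(geno) {
  subset_genotypes(geno, animals = which(geno$genotyped[geno$ids]))
}

#' @export
print.genotypes <- function(x, ...) {
  cat("genotypes:", nrow(x$dosages), "animals x", ncol(x$dosages), "variants\n")
  cat("  chromosomes:", length(unique(x$map$chr)),
      " missing:", sprintf("%.3f", mean(is.na(x$dosages))), "\n")
  invisible(x)
}

# dominance-deviation covariate: (-2p^2, 2pq, -2q^2) for dosage (0, 1, 2)
dom_code <- function(dos, p) {
  q <- 1 - p
  w <- matrix(NA_real_, nrow = nrow(dos), ncol = ncol(dos),
              dimnames = dimnames(dos))
  for (v in c(0, 1, 2)) {
    idx <- which(dos == v)
    if (length(idx) == 0L) next
    col <- ((idx - 1L) %/% nrow(dos)) + 1L
    w[idx] <- switch(as.character(v),
                     "0" = -2 * p[col]^2,
                     "1" = 2 * p[col] * q[col],
                     "2" = -2 * q[col]^2)
  }
  w
}

#' Simulate phenotypes with additive and dominance architecture
#'
#' Each trait is built as mean + fixed effects (sex, birth type, parity) +
#' QTL breeding values + QTL dominance deviations + Gaussian residual, with
#' the QTL effect vectors rescaled so the realized additive and dominance
#' variance fractions hit the configured targets on the simulated cohort.
#' The count trait (nVERT) is a rounded latent Gaussian; each binary trait is
#' an indicator of a standardized liability exceeding the normal quantile of
#' its prevalence. Per-QTL dominance deviations use `d_i = k_i * a_i` with
#' `k_i ~ N(1, 0.5)`, then one global rescale.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param geno genotypes from [simulate_genotypes()] covering all animals in
#'   `ped` (including ungenotyped contemporaries, whose genotypes are used
#'   only to generate their phenotypes).
#' @param config the same [cohort_config()].
#' @return list with `traits` (a `data.frame` with id, covariates, and one
#'   column per trait) and `true_params` (per-trait variance components,
#'   per-QTL effects, per-animal true breeding values and dominance
#'   deviations, realized selection differential).
#' @export
simulate_traits <- function(ped, geno, config) {
  stopifnot(inherits(ped, "pedigree"), inherits(geno, "genotypes"))
  set.seed(config$seed + 2L)
  qtl <- attr(geno, "qtl")
  if (is.null(qtl)) stop("geno lacks QTL metadata; use simulate_genotypes()")
  lamb_rows <- ped$role == "lamb"
  if (!any(lamb_rows)) lamb_rows <- rep(TRUE, nrow(ped))  # founder-only cohorts
  ids <- ped$id[lamb_rows]
  n <- length(ids)
  dosQ <- geno$dosages[ids, qtl$idx, drop = FALSE]
  dosQ[is.na(dosQ)] <- 0
  pQ <- geno$map$freq[qtl$idx]
  Xa <- sweep(dosQ, 2L, 2 * pQ)                       # centred dosage
  dom_pos <- match(qtl$dom_idx, qtl$idx)
  Wd <- dom_code(dosQ[, dom_pos, drop = FALSE], pQ[dom_pos])

  # covariates
  sex <- ped$sex[lamb_rows]
  btype <- ped$litter_size[lamb_rows]; btype[is.na(btype)] <- 1L
  parity <- ped$parity[lamb_rows]; parity[is.na(parity)] <- 1L
  btype_lab <- c("single", "twin", "triplet")[pmin(btype, 3L)]

  trait_names <- all_trait_names(config)
  traits <- data.frame(id = ids, sex = sex, birth_type = btype_lab,
                       parity = as.integer(parity),
                       group = ped$group[lamb_rows],
                       genotyped = ped$genotyped[lamb_rows],
                       stringsAsFactors = FALSE)

  tp <- list(seed = config$seed, per_trait = list(),
             qtl_idx = qtl$idx, dom_idx = qtl$dom_idx)
  tbv_mat <- matrix(0, n, length(trait_names),
                    dimnames = list(ids, trait_names))
  dd_mat <- tbv_mat

  for (tr in trait_names) {
    h2 <- if (tr %in% names(config$target_h2)) config$target_h2[[tr]] else 0
    d2 <- if (tr %in% names(config$target_d2)) config$target_d2[[tr]] else 0
    binary <- tr %in% names(config$binary_prevalences)
    # focal trait reuses the selection-score effects so divergence is genetic
    a <- if (identical(tr, config$focal_trait)) {
      qtl$a_raw
    } else if (!is.null(config$qtl_effect_cor) &&
               tr %in% names(config$qtl_effect_cor)) {
      rho <- config$qtl_effect_cor[[tr]]
      rho * qtl$a_raw + sqrt(max(0, 1 - rho^2)) * stats::rnorm(length(qtl$idx))
    } else {
      stats::rnorm(length(qtl$idx))
    }
    u <- as.numeric(Xa %*% a)
    vu <- stats::var(u)
    scale_a <- if (vu > 0 && h2 > 0) sqrt(h2 / vu) else 0
    u <- u * scale_a
    d_eff <- qtl$k_dom * a[dom_pos]
    v <- as.numeric(Wd %*% d_eff)
    vv <- stats::var(v)
    scale_d <- if (vv > 0 && d2 > 0) sqrt(d2 / vv) else 0
    v <- v * scale_d
    e <- stats::rnorm(n, 0, sqrt(max(1 - h2 - d2, 1e-12)))
    liab <- u + v + e    # unit-variance scale by construction

    # small fixed effects (<= 0.5 SD) on the recorded scale
    fe <- 0.3 * (sex == "M") +
      c(single = 0, twin = -0.25, triplet = -0.45)[btype_lab] +
      0.08 * (parity - 2.5)
    if (binary) {
      K <- config$binary_prevalences[[tr]]
      thr <- stats::qnorm(1 - K)
      y <- as.integer(liab > thr)
      mu <- NA_real_; sd_t <- 1
    } else {
      mu <- config$trait_means[[tr]]; sd_t <- config$trait_sds[[tr]]
      y <- mu + sd_t * (liab + fe)
      if (tr == "nVERT") y <- round(y)
    }
    traits[[tr]] <- y
    tbv_mat[, tr] <- u * sd_t
    dd_mat[, tr] <- v * sd_t
    tp$per_trait[[tr]] <- list(
      sigma_g2 = h2 * sd_t^2, sigma_d2 = d2 * sd_t^2,
      sigma_e2 = (1 - h2 - d2) * sd_t^2,
      a = a * scale_a * sd_t, d = d_eff * scale_d * sd_t,
      binary = binary,
      prevalence = if (binary) config$binary_prevalences[[tr]] else NA_real_)
  }
  tp$tbv <- tbv_mat
  tp$dominance_deviation <- dd_mat
  grp <- ped$group[lamb_rows]
  if (any(grepl("^ST", grp)) && any(grepl("^LT", grp))) {
    u_f <- tbv_mat[, config$focal_trait]
    sg <- stats::sd(u_f)
    tp$realized_selection_differential <-
      if (sg > 0) (mean(u_f[grepl("^LT", grp)]) - mean(u_f[grepl("^ST", grp)])) / sg
      else NA_real_
  }
  class(traits) <- c("trait_table", "data.frame")
  list(traits = traits, true_params = tp)
}

#' Simulate a full cohort (pedigree + genotypes + traits)
#'
#' @param config a [cohort_config()].
#' @return list with `pedigree`, `genotypes`, `traits`, `true_params`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  ped <- simulate_pedigree(config)
  geno <- simulate_genotypes(ped, config)
  tt <- simulate_traits(ped, geno, config)
  list(pedigree = ped, genotypes = geno,
       traits = tt$traits, true_params = tt$true_params)
}

#' Founder-only cohort for calibration studies
#'
#' Convenience wrapper: `n` unrelated, unselected animals with `m` variants
#' and the requested architecture for one focal trait. Used by the recovery
#' and calibration tests.
#'
#' @param n animals; @param m variants; @param h2,d2 focal-trait targets;
#' @param n_qtl,n_qtl_dom causal counts; @param seed integer seed;
#' @param ... forwarded to [cohort_config()].
#' @return as [simulate_cohort()].
#' @export
simulate_founder_cohort <- function(n, m, h2 = 0.5, d2 = 0, n_qtl = 200L,
                                    n_qtl_dom = max(1L, n_qtl %/% 3L),
                                    seed = 1L, ...) {
  config <- cohort_config(
    n_sires = 0L, n_ewes = n, n_lambs = 0L,
    n_contemporaries_ungenotyped = 0L, n_variants = m,
    n_qtl_additive = n_qtl, n_qtl_dominance = n_qtl_dom,
    target_h2 = c(TL = h2), target_d2 = c(TL = d2),
    binary_prevalences = c(AXISD = 0.15),
    trait_means = c(TL = 0), trait_sds = c(TL = 1),
    selection_differential = 0, seed = seed, ...)
  simulate_cohort(config)
}
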