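#' Write genotypes to VCF
#'
#' Plain-text VCFv4.2 with declared contigs and a GT FORMAT field; positions
#' are 1-based. Only animals flagged genotyped are written unless
#' `all_animals = TRUE`.
#'
#' @param geno a `genotypes` object.
#' @param path output path (".vcf"; not compressed).
#' @param all_animals include ungenotyped animals too.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path, all_animals = FALSE) {
  g <- if (all_animals) geno else subset_genotyped(geno)
  dos <- g$dosages
  map <- g$map
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=adgreml", con)
  for (chr in unique(map$chr))
    writeLines(sprintf("##contig=<ID=%s>", chr), con)
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">', con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(dos)), collapse = "\t"), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(dos))) {
    d <- dos[, j]
    gt <- ifelse(is.na(d), "./.", gt_codes[d + 1L])
    writeLines(paste(c(map$chr[j], map$pos[j], map$id[j], map$ref[j],
                       map$alt[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Parses biallelic sites via VariantAnnotation; dosages count the ALT
#' allele. Half-calls and missing GT become `NA`.
#'
#' @param path a VCF file (optionally bgzipped).
#' @return a `genotypes` object.
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf_genotypes requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  ref <- as.character(VariantAnnotation::ref(vcf))
  rr <- SummarizedExperiment::rowRanges(vcf)
  dos <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), rownames(gt)))
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_real_, length(x))
    out[x %in% c("0/0")] <- 0
    out[x %in% c("0/1", "1/0")] <- 1
    out[x %in% c("1/1")] <- 2
    out
  }
  for (j in seq_len(nrow(gt))) dos[, j] <- code(gt[j, ])
  map <- data.frame(chr = as.character(GenomicRanges::seqnames(rr)),
                    pos = GenomicRanges::start(rr),
                    id = rownames(gt), ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
  new_genotypes(dos, map)
}

#' Write genotypes as PLINK-dialect .bed/.bim/.fam
#'
#' SNP-major .bed (magic bytes 0x6c 0x1b 0x01) with the usual two-bit
#' genotype codes; A1 in the .bim is the counted (alt) allele.
#'
#' @details PLINK two-bit codes per genotype: 00 homozygous A1, 01 missing,
#'   10 heterozygous, 11 homozygous A2. We write A1 = alt (counted) allele,
#'   so dosage 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01.
#' @param geno a `genotypes` object.
#' @param prefix output path prefix.
#' @param all_animals include ungenotyped animals too.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(geno, prefix, all_animals = FALSE) {
  g <- if (all_animals) geno else subset_genotyped(geno)
  dos <- g$dosages
  map <- g$map
  n <- nrow(dos); m <- ncol(dos)
  fam <- data.frame(fid = rownames(dos), iid = rownames(dos),
                    pat = 0L, mat = 0L, sex = 0L, pheno = -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chr = map$chr, id = map$id, cm = 0L, pos = map$pos,
                    a1 = map$alt, a2 = map$ref)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  codes <- c("0" = 3L, "1" = 2L, "2" = 0L)  # two-bit value per dosage; NA -> 1
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  bytes_per_snp <- ceiling(n / 4)
  for (j in seq_len(m)) {
    d <- dos[, j]
    two <- ifelse(is.na(d), 1L, codes[as.character(d)])
    length(two) <- bytes_per_snp * 4L
    two[is.na(two)] <- 0L
    mat <- matrix(two, nrow = 4L)
    byte <- mat[1, ] + mat[2, ] * 4L + mat[3, ] * 16L + mat[4, ] * 64L
    writeBin(as.raw(byte), con)
  }
  invisible(prefix)
}

#' Read PLINK-dialect .bed/.bim/.fam genotypes
#'
#' @param prefix path prefix of the trio.
#' @return a `genotypes` object; dosages count the A1 (.bim column 5) allele.
#' @export
read_plink <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"),
                           col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
                           colClasses = "character")
  bim <- utils::read.table(paste0(prefix, ".bim"),
                           col.names = c("chr", "id", "cm", "pos", "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3L + ceiling(n / 4) * m)
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK .bed file")
  body <- as.integer(raw[-(1:3)])
  bytes_per_snp <- ceiling(n / 4)
  # decode all two-bit fields at once
  b <- matrix(body, nrow = bytes_per_snp, ncol = m)
  two <- array(0L, dim = c(4L, bytes_per_snp, m))
  two[1, , ] <- b %% 4L
  two[2, , ] <- (b %/% 4L) %% 4L
  two[3, , ] <- (b %/% 16L) %% 4L
  two[4, , ] <- (b %/% 64L) %% 4L
  dim(two) <- c(4L * bytes_per_snp, m)
  two <- two[seq_len(n), , drop = FALSE]
  dos <- matrix(NA_real_, n, m)
  dos[two == 0L] <- 2
  dos[two == 2L] <- 1
  dos[two == 3L] <- 0
  dimnames(dos) <- list(fam$iid, bim$id)
  map <- data.frame(chr = bim$chr, pos = bim$pos, id = bim$id,
                    ref = bim$a2, alt = bim$a1, stringsAsFactors = FALSE)
  new_genotypes(dos, map)
}

#' Write a cohort to plain-text files
#'
#' Pedigree and trait tables as headered CSV, genotypes as VCF and PLINK
#' trio, true simulation parameters as JSON.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(cohort$pedigree),
                   file.path(dir, "pedigree.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(cohort$traits),
                   file.path(dir, "traits.csv"), row.names = FALSE)
  write_vcf(cohort$genotypes, file.path(dir, "genotypes.vcf"))
  write_plink(cohort$genotypes, file.path(dir, "genotypes"))
  tp <- cohort$true_params
  tp$tbv <- NULL; tp$dominance_deviation <- NULL  # keep JSON small
  jsonlite::write_json(tp, file.path(dir, "true_params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a relationship matrix as TSV
#'
#' Full square matrix with an ID header column/row.
#' @param K a `relmat` (or plain symmetric matrix with dimnames).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grm_tsv <- function(K, path) {
  df <- data.frame(id = rownames(K), unclass(K), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a relationship matrix from TSV
#' @param path file written by [write_grm_tsv()].
#' @param kind kind tag to attach.
#' @return a `relmat`.
#' @export
read_grm_tsv <- function(path, kind = "G_additive") {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df$id
  new_relmat(K, kind = kind, ids = df$id)
}

#' Write a relationship matrix in GCTA-GRM binary layout
#'
#' Lower triangle (including diagonal) as a little-endian float stream in
#' `prefix.grm.bin`, pair counts in `prefix.grm.N.bin`, ids in
#' `prefix.grm.id`.
#'
#' @param K a `relmat`; @param prefix path prefix; @param n_variants number
#'   of variants used (written as the N stream).
#' @return `prefix`, invisibly.
#' @export
write_grm_gcta <- function(K, prefix, n_variants = attr(K, "n_variants")) {
  n <- nrow(K)
  ids <- rownames(K)
  utils::write.table(data.frame(ids, ids), paste0(prefix, ".grm.id"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  lower <- K[upper.tri(K, diag = TRUE)]  # column-major upper == row-major lower
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lower), con, size = 4L, endian = "little")
  close(con)
  if (is.null(n_variants)) n_variants <- 0
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(n_variants), length(lower)), con, size = 4L,
           endian = "little")
  close(con)
  invisible(prefix)
}

#' Read a GCTA-layout binary relationship matrix
#' @param prefix path prefix; @param kind kind tag.
#' @return a `relmat`.
#' @export
read_grm_gcta <- function(prefix, kind = "G_additive") {
  idf <- utils::read.table(paste0(prefix, ".grm.id"),
                           colClasses = "character")
  ids <- idf[[2]]
  n <- length(ids)
  nval <- n * (n + 1) / 2
  vals <- readBin(paste0(prefix, ".grm.bin"), "numeric", n = nval,
                  size = 4L, endian = "little")
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  K[upper.tri(K, diag = TRUE)] <- vals
  K <- K + t(K) - diag(diag(K))
  new_relmat(K, kind = kind, ids = ids)
}
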