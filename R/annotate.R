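#' Read a gene coordinate table from GFF3 or BED
#'
#' GFF3 gene-type features are used as-is (1-based inclusive); BED intervals
#' (0-based half-open) are converted to 1-based inclusive coordinates.
#'
#' @param path a `.gff`/`.gff3` or `.bed` file.
#' @param feature_type GFF3 feature type to keep (default `"gene"`).
#' @return data.frame with `gene`, `chr`, `start`, `end`, `strand`.
#' @export
read_gene_table <- function(path, feature_type = "gene") {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[S4Vectors::mcols(gr)$type == feature_type]
    nm <- S4Vectors::mcols(gr)$Name
    if (is.null(nm)) nm <- S4Vectors::mcols(gr)$ID
    data.frame(gene = as.character(nm),
               chr = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               stringsAsFactors = FALSE)
  } else if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    data.frame(gene = as.character(S4Vectors::mcols(gr)$name),
               chr = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),  # rtracklayer converts to 1-based
               end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               stringsAsFactors = FALSE)
  } else {
    stop("unsupported gene table format: .", ext)
  }
}

#' Annotate significant variants to candidate genes
#'
#' A variant is annotated to a gene when its position lies within the gene
#' span extended by `flank` bp on both sides (strand-agnostic, 1-based
#' inclusive endpoints). All qualifying genes are reported for each
#' variant, with the relation (`genic`, `upstream-flank`,
#' `downstream-flank` relative to the + coordinate direction) and the
#' distance to the gene span (0 when genic).
#'
#' @param variants data.frame with `chr`, `pos` (and optionally `id`);
#'   typically the suggestive-or-better rows of an `assoc_result`.
#' @param genes gene table from [read_gene_table()] or equivalent.
#' @param flank flanking distance in bp (default 1000).
#' @return data.frame with `variant`, `chr`, `pos`, `gene`, `relation`,
#'   `distance` (zero rows when nothing qualifies).
#' @export
annotate_variants <- function(variants, genes, flank = 1000L) {
  if (nrow(variants) > 0 && !any(variants$chr %in% genes$chr)) {
    stop("no shared chromosome names between variants and genes; ",
         "unmatched: ", paste(unique(variants$chr), collapse = ", "))
  }
  if (is.null(variants$id))
    variants$id <- paste0(variants$chr, ":", variants$pos)
  empty <- data.frame(variant = character(0), chr = character(0),
                      pos = integer(0), gene = character(0),
                      relation = character(0), distance = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(variants) == 0L || nrow(genes) == 0L) return(empty)
  lvls <- union(unique(variants$chr), unique(genes$chr))
  vgr <- GenomicRanges::GRanges(factor(variants$chr, levels = lvls),
                                IRanges::IRanges(variants$pos, variants$pos))
  ggr <- GenomicRanges::GRanges(factor(genes$chr, levels = lvls),
                                IRanges::IRanges(pmax(1L, genes$start - flank),
                                                 genes$end + flank))
  hits <- GenomicRanges::findOverlaps(vgr, ggr)
  if (length(hits) == 0L) return(empty)
  vi <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
  pos <- variants$pos[vi]
  gs <- genes$start[gi]; ge <- genes$end[gi]
  relation <- ifelse(pos < gs, "upstream-flank",
                     ifelse(pos > ge, "downstream-flank", "genic"))
  distance <- pmax(0L, pmax(gs - pos, pos - ge))
  data.frame(variant = variants$id[vi], chr = variants$chr[vi], pos = pos,
             gene = genes$gene[gi], relation = relation,
             distance = as.integer(distance), stringsAsFactors = FALSE)
}

#' Summarize candidate genes per component
#'
#' Counts suggestive and Bonferroni variants and distinct candidate genes,
#' overall and per chromosome, for the additive and dominance components of
#' one scan.
#'
#' @param assoc an `assoc_result`.
#' @param thresholds from [thresholds_from_meff()].
#' @param genes gene table; annotation is run on the suggestive-or-better
#'   variants of each component.
#' @param flank flank in bp (default 1000).
#' @return list with `summary` (one row per component) and `per_chr`
#'   (counts per chromosome) and `annotation` (the per-variant gene hits).
#' @export
summarize_candidates <- function(assoc, thresholds, genes, flank = 1000L) {
  comps <- c(additive = "p_a", dominance = "p_d")
  rows <- list(); per_chr <- list(); ann_all <- list()
  for (cn in names(comps)) {
    p <- assoc[[comps[[cn]]]]
    sig <- !is.na(p) & p < thresholds$p_sug
    bonf <- !is.na(p) & p < thresholds$p_bonf
    vs <- assoc[sig, c("chr", "pos", "id"), drop = FALSE]
    ann <- if (nrow(vs) > 0) annotate_variants(vs, genes, flank) else
      annotate_variants(vs[0, , drop = FALSE], genes, flank)
    rows[[cn]] <- data.frame(component = cn,
                             n_suggestive = sum(sig), n_bonferroni = sum(bonf),
                             n_candidate_genes = length(unique(ann$gene)),
                             stringsAsFactors = FALSE)
    if (sum(sig) > 0) {
      tab <- table(assoc$chr[sig])
      per_chr[[cn]] <- data.frame(component = cn, chr = names(tab),
                                  n_suggestive = as.integer(tab),
                                  stringsAsFactors = FALSE)
    }
    if (nrow(ann) > 0) ann$component <- cn
    ann_all[[cn]] <- ann
  }
  list(summary = do.call(rbind, rows),
       per_chr = if (length(per_chr)) do.call(rbind, per_chr) else NULL,
       annotation = do.call(rbind, ann_all))
}
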