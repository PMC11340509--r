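REGION_LEVELS <- c("exonic_cds", "UTR_or_exon_noncds", "intronic",
                   "upstream", "downstream", "intergenic")
EFFECT_LEVELS <- c("synonymous", "nonsynonymous", "stop_gain", "stop_loss",
                   "not_coding")

#' Classify SNP loci into genomic region classes
#'
#' Assigns each locus exactly one label with precedence
#' exonic_cds > UTR_or_exon_noncds > intronic > upstream > downstream >
#' intergenic. Upstream/downstream windows (default 2 kb, the "gene
#' regulatory region") are strand-aware: upstream of a minus-strand gene lies
#' at larger coordinates.
#'
#' @param x a \linkS4class{SnpGenotypes} or \code{GRanges} of SNP positions.
#' @param models gene models from \code{\link{readGeneModels}} or
#'   \code{\link{simulateReference}}.
#' @param regulatory_window bp of regulatory flank on each side of a gene.
#' @return factor of region labels, one per locus.
#' @export
classifyRegion <- function(x, models, regulatory_window = 2000L) {
  gr <- if (is(x, "GRanges")) x else SummarizedExperiment::rowRanges(x)
  gr <- GenomicRanges::granges(gr)
  GenomicRanges::strand(gr) <- "*"
  lab <- rep("intergenic", length(gr))
  genes <- models$genes
  if (length(genes)) {
    hit <- function(subject) {
      IRanges::overlapsAny(gr, subject, ignore.strand = TRUE)
    }
    down <- GenomicRanges::flank(genes, regulatory_window, start = FALSE)
    down <- GenomicRanges::trim(down)
    up <- GenomicRanges::flank(genes, regulatory_window, start = TRUE)
    up <- GenomicRanges::trim(up)
    lab[hit(down)] <- "downstream"
    lab[hit(up)] <- "upstream"
    lab[hit(genes)] <- "intronic"
    lab[hit(unlist(models$exons))] <- "UTR_or_exon_noncds"
    lab[hit(unlist(models$cds))] <- "exonic_cds"
  }
  factor(lab, levels = REGION_LEVELS)
}

# genomic positions of a gene's CDS bases in translation order
cdsPositionMap <- function(cds_gr) {
  str <- as.character(GenomicRanges::strand(cds_gr))[1]
  segs <- lapply(seq_along(cds_gr), function(i) {
    s <- GenomicRanges::start(cds_gr)[i]; e <- GenomicRanges::end(cds_gr)[i]
    if (str == "-") seq(e, s) else seq(s, e)
  })
  unlist(segs)
}

#' Classify the coding effect of SNP substitutions
#'
#' For loci inside a CDS, substitutes the (first) alternate base into its
#' codon -- reverse-complemented for minus-strand genes -- translates with the
#' standard genetic code, and labels the change synonymous, nonsynonymous,
#' stop_gain (new termination codon) or stop_loss (lost termination codon).
#' Loci outside any CDS are \code{not_coding}. When several genes' CDS
#' contain a locus, the lexicographically smallest gene id wins. Gene models
#' whose CDS length is not divisible by 3 are skipped with a warning.
#'
#' @inheritParams classifyRegion
#' @param genome a \link[Biostrings]{DNAStringSet}.
#' @return factor of effect labels, one per locus.
#' @export
classifyCodingEffect <- function(x, models, genome) {
  gr <- if (is(x, "GRanges")) x else SummarizedExperiment::rowRanges(x)
  mc <- S4Vectors::mcols(gr)
  alt1 <- vapply(strsplit(as.character(mc$alt), ","), `[`, "", 1L)
  refb <- as.character(mc$ref)
  out <- rep("not_coding", length(gr))
  code <- Biostrings::GENETIC_CODE

  cds_list <- models$cds
  bad <- names(cds_list)[vapply(cds_list, function(z)
    sum(GenomicRanges::width(z)) %% 3L != 0L, logical(1))]
  if (length(bad)) {
    warning("skipping gene models with CDS length not divisible by 3: ",
            paste(bad, collapse = ", "))
    cds_list <- cds_list[setdiff(names(cds_list), bad)]
  }
  if (!length(cds_list)) return(factor(out, levels = EFFECT_LEVELS))

  cds_flat <- unlist(GenomicRanges::GRangesList(lapply(cds_list, sort)))
  cds_gene <- rep(names(cds_list),
                  vapply(cds_list, length, integer(1)))
  q <- GenomicRanges::granges(gr); GenomicRanges::strand(q) <- "*"
  ov <- GenomicRanges::findOverlaps(q, cds_flat, ignore.strand = TRUE)
  if (!length(ov)) return(factor(out, levels = EFFECT_LEVELS))
  gene_of <- tapply(cds_gene[S4Vectors::subjectHits(ov)],
                    S4Vectors::queryHits(ov), function(g) sort(g)[1])
  posmap_cache <- new.env()
  for (qi in as.integer(names(gene_of))) {
    g <- gene_of[[as.character(qi)]]
    if (is.null(posmap_cache[[g]]))
      posmap_cache[[g]] <- cdsPositionMap(cds_list[[g]])
    pm <- posmap_cache[[g]]
    str <- as.character(GenomicRanges::strand(cds_list[[g]]))[1]
    pos <- GenomicRanges::start(gr)[qi]
    off <- match(pos, pm)
    if (is.na(off)) next
    codon_i <- (off - 1L) %/% 3L
    cpos <- pm[codon_i * 3L + 1:3]
    ctg <- as.character(GenomeInfoDb::seqnames(gr))[qi]
    bases <- vapply(cpos, function(p)
      as.character(Biostrings::subseq(genome[[ctg]], p, p)), character(1))
    if (str == "-") bases <- compBase(bases)
    ref_codon <- paste(bases, collapse = "")
    within <- off - codon_i * 3L
    sub_base <- if (str == "-") compBase(alt1[qi]) else alt1[qi]
    alt_bases <- bases; alt_bases[within] <- sub_base
    alt_codon <- paste(alt_bases, collapse = "")
    ref_aa <- code[[ref_codon]]; alt_aa <- code[[alt_codon]]
    out[qi] <- if (ref_aa == alt_aa) "synonymous"
      else if (alt_aa == "*") "stop_gain"
      else if (ref_aa == "*") "stop_loss"
      else "nonsynonymous"
  }
  factor(out, levels = EFFECT_LEVELS)
}

#' Substitution spectrum, Ts/Tv and het/hom counts
#'
#' Tallies the 12 directed ref-to-alt substitution types over biallelic loci,
#' the transition (A<->G, C<->T) and transversion totals and their ratio, and
#' the number of heterozygous/homozygous non-missing calls that carry an
#' alternate allele. When no transversions are present the ratio is
#' undefined (\code{NA}) and flagged.
#'
#' @param x a \linkS4class{SnpGenotypes}; multiallelic loci are excluded.
#' @return list with \code{type_counts} (named 12-type table),
#'   \code{transitions}, \code{transversions}, \code{ts_tv},
#'   \code{ts_tv_undefined}, \code{het_count}, \code{hom_count},
#'   \code{n_loci}.
#' @export
substitutionSpectrum <- function(x) {
  bi <- !isMultiallelic(x) & lengths(altAlleles(x)) == 1L
  xb <- x[bi, ]
  refb <- refAlleles(xb)
  altb <- vapply(altAlleles(xb), `[`, "", 1L)
  types <- paste0(refb, ">", altb)
  all_types <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                               paste, sep = ">"))
  all_types <- all_types[substr(all_types, 1, 1) != substr(all_types, 3, 3)]
  tc <- table(factor(types, levels = sort(all_types)))
  is_ts <- types %in% c("A>G", "G>A", "C>T", "T>C")
  ts <- sum(is_ts); tv <- sum(!is_ts)
  cc <- alleleCodes(xb)
  carries_alt <- !is.na(cc$a1) & (cc$a1 > 0L | cc$a2 > 0L)
  het <- sum(carries_alt & cc$a1 != cc$a2)
  hom <- sum(carries_alt & cc$a1 == cc$a2)
  list(type_counts = tc, transitions = ts, transversions = tv,
       ts_tv = if (tv > 0) ts / tv else NA_real_,
       ts_tv_undefined = tv == 0, het_count = het, hom_count = hom,
       n_loci = nrow(xb))
}
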