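#' Read a multi-sample VCF into a SnpGenotypes object
#'
#' Parses a VCF 4.x file (via \pkg{VariantAnnotation}) into the internal
#' genotype container. Per-sample GT is required and parsed into unordered
#' allele pairs; \code{"./."} and \code{"."} become missing calls. Multiallelic
#' records are retained and flagged. \code{mean_depth} and \code{mean_gq} are
#' the means of FORMAT \code{DP}/\code{GQ} over non-missing samples when those
#' fields are present (falling back to the INFO fields \code{DPM}/\code{GQM}
#' that \code{\link{writeVariants}} emits). INFO \code{QD}, \code{MQ},
#' \code{FS}, \code{MQRankSum} and \code{ReadPosRankSum} are honored when
#' present; absent fields stay \code{NA} and are never imputed.
#'
#' @param vcf_path path to an uncompressed or bgzipped VCF file.
#' @return A \linkS4class{SnpGenotypes} object.
#' @export
readVariants <- function(vcf_path) {
  if (!file.exists(vcf_path)) stop("VCF file not found: ", vcf_path)
  vcf <- tryCatch(
    VariantAnnotation::readVcf(vcf_path, genome = "unknown"),
    error = function(e) stop("failed to parse VCF header/body of '",
                             vcf_path, "': ", conditionMessage(e)))
  gt <- tryCatch(VariantAnnotation::geno(vcf)$GT, error = function(e) NULL)
  if (is.null(gt)) stop("FORMAT field GT is absent in ", vcf_path)

  n_loci <- nrow(gt); samples <- colnames(gt)
  a1 <- matrix(NA_integer_, n_loci, length(samples))
  a2 <- matrix(NA_integer_, n_loci, length(samples))
  gtv <- as.character(gt)
  miss <- gtv %in% c(".", "./.", ".|.") | is.na(gtv)
  parts <- strsplit(gtv[!miss], "[/|]")
  p1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  p2 <- suppressWarnings(as.integer(vapply(parts, function(z)
    if (length(z) > 1L) z[2L] else z[1L], "")))
  a1[!miss] <- p1
  a2[!miss] <- p2
  half <- is.na(a1) != is.na(a2)   # half-calls like ./1 -> missing
  a1[half] <- NA_integer_; a2[half] <- NA_integer_

  rr <- SummarizedExperiment::rowRanges(vcf)
  alt_list <- VariantAnnotation::alt(vcf)
  alt_chr <- vapply(as.list(alt_list), function(z)
    paste(as.character(z), collapse = ","), character(1))
  gr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(rr),
                               IRanges::IRanges(GenomicRanges::start(rr), width = 1L))
  mc <- S4Vectors::DataFrame(
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt_chr)
  info <- VariantAnnotation::info(vcf)
  pick <- function(nm) {
    if (nm %in% colnames(info)) as.numeric(info[[nm]]) else rep(NA_real_, n_loci)
  }
  mc$qd <- pick("QD"); mc$mq <- pick("MQ"); mc$fs <- pick("FS")
  mc$mq_rank_sum <- pick("MQRankSum"); mc$read_pos_rank_sum <- pick("ReadPosRankSum")
  mc$site_quality <- as.numeric(VariantAnnotation::qual(vcf))

  meanFmt <- function(nm, fallback) {
    m <- tryCatch(VariantAnnotation::geno(vcf)[[nm]], error = function(e) NULL)
    if (!is.null(m)) {
      storage.mode(m) <- "numeric"
      rowMeans(m, na.rm = TRUE)
    } else pick(fallback)
  }
  mc$mean_depth <- meanFmt("DP", "DPM")
  mc$mean_gq <- meanFmt("GQ", "GQM")
  mc$mean_depth[is.nan(mc$mean_depth)] <- NA_real_
  mc$mean_gq[is.nan(mc$mean_gq)] <- NA_real_
  S4Vectors::mcols(gr) <- mc
  names(gr) <- paste0(GenomeInfoDb::seqnames(gr), "_", GenomicRanges::start(gr))
  SnpGenotypes(a1, a2, gr, samples)
}

#' Write a SnpGenotypes object back to VCF
#'
#' Emits a minimal deterministic VCF 4.2 with per-sample GT and the site QC
#' fields as INFO (including \code{DPM}/\code{GQM} carrying the mean depth and
#' mean genotype quality so that \code{\link{readVariants}} round-trips them).
#' Writing then re-reading reproduces calls and the missing mask exactly.
#'
#' @param x a \linkS4class{SnpGenotypes}.
#' @param path output file path.
#' @param contig_lengths optional named integer vector for \code{##contig}
#'   header lines.
#' @return \code{path}, invisibly.
#' @export
writeVariants <- function(x, path, contig_lengths = NULL) {
  rr <- SummarizedExperiment::rowRanges(x)
  cc <- alleleCodes(x)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=kaspanel")
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  hdr <- c(hdr,
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand bias">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="Mapping quality rank sum">',
    '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Read position rank sum">',
    '##INFO=<ID=DPM,Number=1,Type=Float,Description="Mean sample depth">',
    '##INFO=<ID=GQM,Number=1,Type=Float,Description="Mean sample genotype quality">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", accessionIds(x)), collapse = "\t"))
  infoStr <- function(i) {
    f <- c(QD = qcField(x, "qd")[i], MQ = qcField(x, "mq")[i],
           FS = qcField(x, "fs")[i], MQRankSum = qcField(x, "mq_rank_sum")[i],
           ReadPosRankSum = qcField(x, "read_pos_rank_sum")[i],
           DPM = qcField(x, "mean_depth")[i], GQM = qcField(x, "mean_gq")[i])
    f <- f[!is.na(f)]
    if (!length(f)) return(".")
    paste(paste0(names(f), "=", fmtNum(unname(f))), collapse = ";")
  }
  lines <- vapply(seq_len(nrow(x)), function(i) {
    g <- ifelse(is.na(cc$a1[i, ]), "./.",
                paste0(cc$a1[i, ], "/", cc$a2[i, ]))
    paste(c(as.character(GenomeInfoDb::seqnames(rr))[i],
            GenomicRanges::start(rr)[i], ".",
            as.character(S4Vectors::mcols(rr)$ref)[i],
            as.character(S4Vectors::mcols(rr)$alt)[i],
            fmtNum(S4Vectors::mcols(rr)$site_quality[i]), ".",
            infoStr(i), "GT", g), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a reference genome FASTA
#'
#' @param fasta_path path to a FASTA file with at least one record.
#' @return A \link[Biostrings]{DNAStringSet}, sequences uppercased. Contig
#'   identifiers are the first whitespace-delimited token of each header and
#'   must be unique.
#' @export
readReference <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  dna <- Biostrings::readDNAStringSet(fasta_path)
  if (length(dna) == 0L) stop("empty FASTA: ", fasta_path)
  names(dna) <- sub("\\s.*$", "", names(dna))
  if (anyDuplicated(names(dna)))
    stop("duplicate contig ids in FASTA: ",
         paste(unique(names(dna)[duplicated(names(dna))]), collapse = ", "))
  # normalize case (lowercase soft-masked input is accepted)
  Biostrings::DNAStringSet(toupper(as.character(dna)))
}

#' Read gene models from GFF3
#'
#' Imports gene/mRNA/exon/CDS features (via \pkg{rtracklayer}) and assembles
#' per-gene exon and CDS interval lists. CDS intervals are stored in
#' translation order (ascending coordinates for + strand genes, descending
#' for - strand genes).
#'
#' @param gff_path path to a GFF3 file.
#' @return A list with elements \code{genes} (named \code{GRanges}),
#'   \code{exons} and \code{cds} (named \code{GRangesList} keyed by gene id).
#' @export
readGeneModels <- function(gff_path) {
  if (!file.exists(gff_path)) stop("GFF3 file not found: ", gff_path)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  buildGeneModels(gr)
}

# assemble the gene/exon/CDS structure from a raw GFF3 GRanges
buildGeneModels <- function(gr) {
  typ <- as.character(gr$type)
  genes <- gr[typ == "gene"]
  names(genes) <- genes$ID
  tx <- gr[typ == "mRNA"]
  tx2gene <- setNames(vapply(tx$Parent, `[`, "", 1L), tx$ID)
  featGene <- function(feat) {
    par <- vapply(feat$Parent, `[`, "", 1L)
    g <- ifelse(par %in% names(tx2gene), tx2gene[par], par)
    sp <- split(feat, g)
    lapply(sp, function(z) GenomicRanges::reduce(z))
  }
  exons <- featGene(gr[typ == "exon"])
  cds_raw <- featGene(gr[typ == "CDS"])
  cds <- lapply(names(cds_raw), function(g) {
    z <- sort(cds_raw[[g]])
    if (as.character(GenomicRanges::strand(genes[g])) == "-") z <- rev(z)
    z
  })
  names(cds) <- names(cds_raw)
  list(genes = genes,
       exons = GenomicRanges::GRangesList(exons),
       cds = GenomicRanges::GRangesList(cds))
}

#' Extract the flanking window around a genomic position
#'
#' Returns the window \code{[pos - width, pos + width]} intersected with the
#' contig, as a character string plus its 1-based closed interval. The base at
#' the center of the (untruncated) window corresponds to \code{pos}.
#'
#' @param genome a \link[Biostrings]{DNAStringSet}.
#' @param contig contig identifier.
#' @param pos 1-based position on the contig.
#' @param width flank width in bp on each side.
#' @return list with \code{seq}, \code{start}, \code{end}, and \code{offset}
#'   (position of \code{pos} within \code{seq}).
#' @export
extractFlank <- function(genome, contig, pos, width) {
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  len <- Biostrings::width(genome[contig])
  if (pos < 1L || pos > len)
    stop("position ", pos, " out of range for contig ", contig,
         " (length ", len, ")")
  s <- max(1L, pos - width)
  e <- min(len, pos + width)
  list(seq = as.character(Biostrings::subseq(genome[[contig]], s, e)),
       start = s, end = e, offset = pos - s + 1L)
}

#' Write a genome to FASTA
#' @param genome a \link[Biostrings]{DNAStringSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeReference <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 80L)
  invisible(path)
}

#' Write gene models to GFF3
#' @param models a gene-model list as returned by \code{\link{readGeneModels}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneModels <- function(models, path) {
  rows <- list()
  for (g in names(models$genes)) {
    gene <- models$genes[g]
    ex <- sort(models$exons[[g]])
    cds <- sort(models$cds[[g]])
    str <- as.character(GenomicRanges::strand(gene))
    mk <- function(gr2, type, id, parent) {
      S4Vectors::DataFrame(
        seqnames = as.character(GenomeInfoDb::seqnames(gr2)),
        start = GenomicRanges::start(gr2), end = GenomicRanges::end(gr2),
        type = type, strand = str,
        id = id, parent = parent, phase = NA_integer_)
    }
    mid <- paste0(g, ".t1")
    rows[[length(rows) + 1L]] <- mk(gene, "gene", g, NA_character_)
    rows[[length(rows) + 1L]] <- mk(gene, "mRNA", mid, g)
    rows[[length(rows) + 1L]] <- mk(ex, "exon",
                                    paste0(mid, ".exon", seq_along(ex)), mid)
    # CDS phase in translation order
    tr <- if (str == "-") rev(cds) else cds
    w <- GenomicRanges::width(tr)
    ph <- (3L - (cumsum(c(0L, w[-length(w)])) %% 3L)) %% 3L
    cdf <- mk(tr, "CDS", paste0(mid, ".cds", seq_along(tr)), mid)
    cdf$phase <- ph
    rows[[length(rows) + 1L]] <- cdf
  }
  df <- do.call(rbind, rows)
  attr_col <- ifelse(is.na(df$parent), paste0("ID=", df$id),
                     paste0("ID=", df$id, ";Parent=", df$parent))
  lines <- paste(df$seqnames, "kaspanel", df$type, df$start, df$end, ".",
                 df$strand, ifelse(is.na(df$phase), ".", df$phase),
                 attr_col, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
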