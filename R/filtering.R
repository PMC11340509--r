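#' Filter thresholds for the SNP screening cascade
#'
#' Defaults follow the standard GATK hard-filter recommendations and the
#' high-quality / KASP-eligibility criteria used for the *G. frondosa* panel:
#' sites are removed when QD < 2.0, MQ < 40.0, FS > 60.0, MQRankSum < -12.5 or
#' ReadPosRankSum < -8.0; high-quality loci require mean depth > 5x,
#' MAF > 0.05, AverageQ > 30 and call rate ("integrity") > 0.9; KASP
#' candidates must be variant-free within 50 bp on each side, unique-mapping
#' over a +/-100 bp flank, biallelic, and have PIC > 0.2. All comparators are
#' strict, exactly as printed.
#'
#' @param qd_min,mq_min,fs_max,mqrs_min,rprs_min GATK-style hard-filter
#'   bounds.
#' @param depth_min minimum mean coverage depth (x).
#' @param maf_min minimum minor allele frequency.
#' @param avgq_min minimum AverageQ.
#' @param integrity_min minimum call rate.
#' @param conservation_window bp of variant-free flank required on each side.
#' @param uniqueness_flank bp of flank mapped back to the genome.
#' @param uniq_min_identity,uniq_min_length secondary-match identity/length
#'   that disqualifies a locus.
#' @param uniq_seed_k exact seed length for the uniqueness scan.
#' @param pic_min minimum polymorphic information content.
#' @param avgq_source \code{"auto"} uses mean per-sample GQ when present and
#'   falls back to site QUAL; \code{"gq"} or \code{"qual"} force one source.
#' @return list of class \code{FilterThresholds}.
#' @export
filterThresholds <- function(qd_min = 2.0, mq_min = 40.0, fs_max = 60.0,
                             mqrs_min = -12.5, rprs_min = -8.0,
                             depth_min = 5.0, maf_min = 0.05, avgq_min = 30.0,
                             integrity_min = 0.90,
                             conservation_window = 50L,
                             uniqueness_flank = 100L,
                             uniq_min_identity = 0.90, uniq_min_length = 100L,
                             uniq_seed_k = 31L,
                             pic_min = 0.20, avgq_source = "auto") {
  t <- list(qd_min = qd_min, mq_min = mq_min, fs_max = fs_max,
            mqrs_min = mqrs_min, rprs_min = rprs_min, depth_min = depth_min,
            maf_min = maf_min, avgq_min = avgq_min,
            integrity_min = integrity_min,
            conservation_window = as.integer(conservation_window),
            uniqueness_flank = as.integer(uniqueness_flank),
            uniq_min_identity = uniq_min_identity,
            uniq_min_length = as.integer(uniq_min_length),
            uniq_seed_k = as.integer(uniq_seed_k),
            pic_min = pic_min, avgq_source = avgq_source)
  stopifnot(all(vapply(t[1:9], is.finite, TRUE)),
            t$conservation_window > 0L, t$uniqueness_flank > 0L)
  class(t) <- "FilterThresholds"
  t
}

mkReport <- function(stage, keep, ids) {
  FilterReport(
    data.frame(stage = stage, input = length(keep),
               removed = sum(!keep), surviving = sum(keep)),
    setNames(ifelse(keep, NA_character_, stage), ids))
}

#' GATK-style hard filter
#'
#' A locus is removed iff any *present* QC field violates its bound
#' (QD < qd_min, MQ < mq_min, FS > fs_max, MQRankSum < mqrs_min,
#' ReadPosRankSum < rprs_min). Absent (\code{NA}) fields never trigger
#' removal.
#'
#' @param x a \linkS4class{SnpGenotypes}.
#' @param thresholds a \code{\link{filterThresholds}} list.
#' @return list with \code{genotypes} (survivors) and \code{report}
#'   (\linkS4class{FilterReport}).
#' @export
hardFilter <- function(x, thresholds = filterThresholds()) {
  keep <- hardFilterKeep(x, thresholds)
  list(genotypes = x[keep, ], report = mkReport("hard_filter", keep, lociIds(x)))
}

hardFilterKeep <- function(x, t) {
  viol <- function(v, bad) !is.na(v) & bad(v)
  fail <- viol(qcField(x, "qd"), function(v) v < t$qd_min) |
    viol(qcField(x, "mq"), function(v) v < t$mq_min) |
    viol(qcField(x, "fs"), function(v) v > t$fs_max) |
    viol(qcField(x, "mq_rank_sum"), function(v) v < t$mqrs_min) |
    viol(qcField(x, "read_pos_rank_sum"), function(v) v < t$rprs_min)
  !fail
}

#' High-quality SNP filter
#'
#' Keeps loci with mean depth > depth_min, MAF > maf_min (frequency of the
#' second-most-frequent allele over non-missing calls), AverageQ > avgq_min
#' and call rate > integrity_min. Absent depth/quality fields do not trigger
#' removal (same policy as \code{\link{hardFilter}}).
#'
#' @inheritParams hardFilter
#' @return list with \code{genotypes} and \code{report}.
#' @export
qualityFilter <- function(x, thresholds = filterThresholds()) {
  keep <- qualityFilterKeep(x, thresholds)
  list(genotypes = x[keep, ],
       report = mkReport("quality_filter", keep, lociIds(x)))
}

qualityFilterKeep <- function(x, t) {
  st <- locusStats(x)
  avgq <- switch(t$avgq_source,
                 gq = qcField(x, "mean_gq"),
                 qual = qcField(x, "site_quality"),
                 { v <- qcField(x, "mean_gq")
                   ifelse(is.na(v), qcField(x, "site_quality"), v) })
  passNA <- function(v, ok) is.na(v) | ok(v)
  passNA(qcField(x, "mean_depth"), function(v) v > t$depth_min) &
    (!is.na(st$maf) & st$maf > t$maf_min) &
    passNA(avgq, function(v) v > t$avgq_min) &
    callRate(x) > t$integrity_min
}

#' Flank-conservation filter
#'
#' A locus survives iff no other variant lies within \code{window} bp on the
#' same contig ("conserved in sequences greater than 50 bp on each side").
#' The test is made against \code{all_loci} -- by default the loci of
#' \code{x} itself, but in a cascade the full pre-filter variant set should be
#' supplied, since primer-binding regions must be variant-free regardless of
#' the neighbours' quality.
#'
#' @inheritParams hardFilter
#' @param all_loci a \code{GRanges} (or \linkS4class{SnpGenotypes}) holding
#'   every called variant position.
#' @param window flank width in bp.
#' @return list with \code{genotypes} and \code{report}.
#' @export
conservationFilter <- function(x, all_loci = NULL, window = 50L) {
  keep <- conservationKeep(x, all_loci, window)
  list(genotypes = x[keep, ],
       report = mkReport("conservation_filter", keep, lociIds(x)))
}

conservationKeep <- function(x, all_loci = NULL, window = 50L) {
  if (is.null(all_loci)) all_loci <- x
  if (is(all_loci, "SnpGenotypes"))
    all_loci <- SummarizedExperiment::rowRanges(all_loci)
  qc <- as.character(GenomeInfoDb::seqnames(SummarizedExperiment::rowRanges(x)))
  qp <- GenomicRanges::start(SummarizedExperiment::rowRanges(x))
  ac <- as.character(GenomeInfoDb::seqnames(all_loci))
  ap <- GenomicRanges::start(all_loci)
  vapply(seq_along(qp), function(i) {
    p <- ap[ac == qc[i]]
    d <- abs(p - qp[i])
    # ignore exactly one copy of the query itself
    if (any(d == 0L)) d <- d[-match(0L, d)]
    !any(d <= window)
  }, logical(1))
}

#' Flank-uniqueness filter
#'
#' Extracts the +/-\code{flank} window around each SNP and removes the locus
#' when that window (or its reverse complement) has a secondary match
#' elsewhere in the genome with at least \code{uniq_min_identity} identity
#' over at least \code{uniq_min_length} bp. Matches are found by an exact
#' k-mer seed scan over both strands followed by anchored ungapped extension.
#'
#' @inheritParams hardFilter
#' @param genome a \link[Biostrings]{DNAStringSet}.
#' @return list with \code{genotypes} and \code{report}.
#' @export
uniquenessFilter <- function(x, genome, thresholds = filterThresholds()) {
  keep <- uniquenessKeep(x, genome, thresholds)
  list(genotypes = x[keep, ],
       report = mkReport("uniqueness_filter", keep, lociIds(x)))
}

uniquenessKeep <- function(x, genome, t = filterThresholds()) {
  rr <- SummarizedExperiment::rowRanges(x)
  qc <- as.character(GenomeInfoDb::seqnames(rr))
  if (!all(qc %in% names(genome)))
    stop("SNP contig absent from genome: ",
         paste(setdiff(unique(qc), names(genome)), collapse = ", "))
  k <- t$uniq_seed_k
  seqs <- as.character(genome)
  # k-mer catalogue over both strands, hashed once
  kmersOf <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  }
  plus <- lapply(seqs, kmersOf)
  minus <- lapply(seqs, function(s) kmersOf(revcomp(s)))
  all_k <- c(unlist(plus, use.names = FALSE), unlist(minus, use.names = FALSE))
  repeated <- duplicated(all_k) | duplicated(all_k, fromLast = TRUE)
  # index ranges of each contig's plus-strand k-mers within all_k
  off <- cumsum(c(0L, lengths(plus)))
  contig_idx <- setNames(seq_along(seqs), names(genome))

  # location of every occurrence, for extension checks (built lazily)
  kmer_loc <- NULL
  buildLoc <- function() {
    if (!is.null(kmer_loc)) return(kmer_loc)
    locs <- data.frame(
      kmer = all_k,
      contig = c(rep(names(genome), lengths(plus)),
                 rep(names(genome), lengths(minus))),
      strand = rep(c("+", "-"), c(sum(lengths(plus)), sum(lengths(minus)))),
      pos = c(unlist(lapply(plus, seq_along), use.names = FALSE),
              unlist(lapply(minus, seq_along), use.names = FALSE)))
    kmer_loc <<- locs[repeated, , drop = FALSE]
    kmer_loc
  }

  pos_v <- GenomicRanges::start(rr)
  vapply(seq_along(pos_v), function(i) {
    fl <- extractFlank(genome, qc[i], pos_v[i], t$uniqueness_flank)
    ws <- fl$start; we <- fl$end
    if (we - ws + 1L < k) return(TRUE)
    ci <- contig_idx[[qc[i]]]
    kidx <- off[ci] + (ws:(we - k + 1L))
    hot <- which(repeated[kidx])
    if (!length(hot)) return(TRUE)
    locs <- buildLoc()
    win <- fl$seq
    for (h in hot) {
      seed_pos <- ws + h - 1L                      # genomic pos of seed start
      seed <- substring(seqs[[ci]], seed_pos, seed_pos + k - 1L)
      cand <- locs[locs$kmer == seed, , drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        hc <- cand$contig[r]; hs <- cand$pos[r]; hstr <- cand$strand[r]
        if (hstr == "+" && hc == qc[i] && hs == seed_pos) next  # home hit
        # anchored ungapped alignment of the whole window at this hit
        subj <- if (hstr == "+") seqs[[which(names(genome) == hc)]]
                else revcomp(seqs[[which(names(genome) == hc)]])
        a_start <- hs - (seed_pos - ws)
        a_end <- a_start + nchar(win) - 1L
        lo <- max(1L, a_start); hi2 <- min(nchar(subj), a_end)
        if (hi2 - lo + 1L < t$uniq_min_length) next
        wseg <- substring(win, lo - a_start + 1L, hi2 - a_start + 1L)
        sseg <- substring(subj, lo, hi2)
        m <- sum(strsplit(wseg, "")[[1]] == strsplit(sseg, "")[[1]])
        if (m / nchar(wseg) >= t$uniq_min_identity &&
            nchar(wseg) >= t$uniq_min_length)
          return(FALSE)
      }
    }
    TRUE
  }, logical(1))
}

#' KASP-eligibility filter
#'
#' Keeps loci that are biallelic and have PIC > pic_min (default 0.2).
#'
#' @inheritParams hardFilter
#' @param stats optional precomputed \code{\link{locusStats}} table for
#'   \code{x}.
#' @return list with \code{genotypes} and \code{report}.
#' @export
kaspEligibilityFilter <- function(x, stats = NULL,
                                  thresholds = filterThresholds()) {
  keep <- kaspEligKeep(x, stats, thresholds)
  list(genotypes = x[keep, ],
       report = mkReport("kasp_eligibility", keep, lociIds(x)))
}

kaspEligKeep <- function(x, stats = NULL, t = filterThresholds()) {
  if (is.null(stats)) stats <- locusStats(x)
  !isMultiallelic(x) & lengths(altAlleles(x)) == 1L &
    !is.na(stats$pic) & stats$pic > t$pic_min
}

#' Run the full filter cascade
#'
#' Applies hard filter, high-quality filter, flank conservation (judged
#' against the complete input variant set), flank uniqueness and KASP
#' eligibility, in that order. Because every stage is a per-locus predicate,
#' the surviving set is invariant to stage order; the per-stage counts of the
#' report reflect the order used here.
#'
#' @inheritParams uniquenessFilter
#' @return list with \code{genotypes} (final survivors) and \code{report}
#'   (telescoping \linkS4class{FilterReport} whose \code{firstFail} labels
#'   every input locus).
#' @export
filterCascade <- function(x, genome = NULL, thresholds = filterThresholds()) {
  ids <- lociIds(x)
  keeps <- list(
    hard_filter = hardFilterKeep(x, thresholds),
    quality_filter = qualityFilterKeep(x, thresholds),
    conservation_filter = conservationKeep(x, NULL,
                                           thresholds$conservation_window))
  if (!is.null(genome))
    keeps$uniqueness_filter <- uniquenessKeep(x, genome, thresholds)
  keeps$kasp_eligibility <- kaspEligKeep(x, NULL, thresholds)

  firstFail <- rep(NA_character_, length(ids))
  alive <- rep(TRUE, length(ids))
  stages <- data.frame(stage = character(0), input = integer(0),
                       removed = integer(0), surviving = integer(0))
  for (s in names(keeps)) {
    inp <- sum(alive)
    newly <- alive & !keeps[[s]]
    firstFail[newly] <- s
    alive <- alive & keeps[[s]]
    stages <- rbind(stages, data.frame(stage = s, input = inp,
                                       removed = sum(newly),
                                       surviving = sum(alive)))
  }
  list(genotypes = x[alive, ],
       report = FilterReport(stages, setNames(firstFail, ids)))
}
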