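#' Simulation configuration for a structured germplasm panel
#'
#' Defaults emulate the shape of a 60-strain *Grifola frondosa* resequencing
#' panel: 60 accessions in 5 subpopulations with marked differentiation
#' (Fst 0.3), 5,000 biallelic SNPs on 3 contigs, 2% missing calls and two
#' duplicated accession pairs (clonal re-deposits are common in mushroom
#' culture collections). Allele frequencies follow the Balding-Nichols
#' F-model: per-locus ancestral frequency p ~ Uniform(freq_range), then
#' subpopulation frequency ~ Beta(p(1-F)/F, (1-p)(1-F)/F) with F = fst, and
#' diploid genotypes are drawn binomially within subpopulations.
#'
#' @param seed root random seed (stage seeds are derived from it).
#' @param n_accessions,n_subpops panel size and number of subpopulations.
#' @param fst differentiation parameter F in [0, 1).
#' @param n_snps number of biallelic SNP loci.
#' @param contig_lengths integer vector of contig lengths (bp, each >= 1000).
#' @param missing_rate per-call missing probability.
#' @param n_duplicates number of accessions cloned from another accession
#'   (creates that many indistinguishable pairs).
#' @param frac_fail fraction of loci deliberately injected with one failing
#'   GATK-style hard-filter field.
#' @param frac_multiallelic fraction of loci given a second alternate allele.
#' @param mean_depth Poisson mean of per-sample read depth.
#' @param freq_range range of the ancestral alternate-allele frequency.
#' @param ts_prob probability that a simulated substitution is a transition.
#' @param qc_field_ranges list with \code{pass} and \code{fail} per-field
#'   numeric ranges for QD/MQ/FS/MQRankSum/ReadPosRankSum.
#' @return A validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L, n_accessions = 60L, n_subpops = 5L,
                             fst = 0.3, n_snps = 5000L,
                             contig_lengths = c(150000L, 120000L, 90000L),
                             missing_rate = 0.02, n_duplicates = 2L,
                             frac_fail = 0.05, frac_multiallelic = 0.01,
                             mean_depth = 30, freq_range = c(0.05, 0.5),
                             ts_prob = 0.65,
                             qc_field_ranges = NULL) {
  if (is.null(qc_field_ranges)) qc_field_ranges <- list(
    pass = list(QD = c(2.5, 35), MQ = c(45, 60), FS = c(0, 30),
                MQRankSum = c(-3, 3), ReadPosRankSum = c(-3, 3)),
    fail = list(QD = c(0, 1.9), MQ = c(10, 39), FS = c(61, 120),
                MQRankSum = c(-20, -13), ReadPosRankSum = c(-15, -8.5)))
  cfg <- list(seed = as.integer(seed), n_accessions = as.integer(n_accessions),
              n_subpops = as.integer(n_subpops), fst = fst,
              n_snps = as.integer(n_snps),
              contig_lengths = as.integer(contig_lengths),
              missing_rate = missing_rate,
              n_duplicates = as.integer(n_duplicates),
              frac_fail = frac_fail, frac_multiallelic = frac_multiallelic,
              mean_depth = mean_depth, freq_range = freq_range,
              ts_prob = ts_prob, qc_field_ranges = qc_field_ranges)
  stopifnot(cfg$n_duplicates < cfg$n_accessions,
            cfg$n_subpops <= cfg$n_accessions,
            cfg$fst >= 0, cfg$fst < 1,
            cfg$missing_rate >= 0, cfg$missing_rate < 1)
  if (length(cfg$contig_lengths) == 0L) stop("at least one contig is required")
  if (any(cfg$contig_lengths < 1000L)) stop("contig lengths must be >= 1000 bp")
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate a reference genome with gene models
#'
#' Generates random DNA contigs and tiles roughly 40% of each contig with
#' multi-exon protein-coding genes on both strands. Every gene carries short
#' terminal UTRs and a CDS whose total length is divisible by 3.
#' Deterministic for a fixed config seed.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{genome} (\link[Biostrings]{DNAStringSet}) and
#'   \code{models} (gene-model list as from \code{\link{readGeneModels}}).
#' @export
simulateReference <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(deriveSeed(config$seed, "reference"))
  lens <- config$contig_lengths
  contigs <- paste0("ctg", seq_along(lens))
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  genome <- Biostrings::DNAStringSet(setNames(seqs, contigs))

  genes <- list(); exons <- list(); cds <- list()
  for (ci in seq_along(contigs)) {
    L <- lens[ci]; pos <- sample(500:1500, 1L); gi <- 0L
    while (TRUE) {
      glen <- sample(1500:3000, 1L)
      if (pos + glen + 500L > L) break
      gi <- gi + 1L
      gid <- sprintf("g%02d_%03d", ci, gi)
      strand <- sample(c("+", "-"), 1L)
      n_ex <- sample(2:4, 1L)
      introns <- if (n_ex > 1L) sample(100:300, n_ex - 1L, replace = TRUE)
                 else integer(0)
      ex_total <- glen - sum(introns)
      # exon lengths: 200 bp floor, remainder spread at random
      extra <- ex_total - 200L * n_ex
      splits <- if (n_ex > 1L) sort(sample(0:extra, n_ex - 1L, replace = TRUE))
                else integer(0)
      ex_len <- diff(c(0L, splits, extra)) + 200L
      ex_start <- pos + cumsum(c(0L, head(ex_len, -1L) + introns))
      ex_end <- ex_start + ex_len - 1L
      gstart <- pos; gend <- ex_end[n_ex]
      # exonic base positions in ascending genomic order
      exonic <- unlist(mapply(seq, ex_start, ex_end, SIMPLIFY = FALSE))
      tot <- length(exonic)
      utr5 <- 60L; utr3 <- 60L
      cds_len <- tot - utr5 - utr3
      utr3 <- utr3 + (cds_len %% 3L)   # keep CDS length divisible by 3
      if (strand == "+") {
        cL <- exonic[utr5 + 1L]; cR <- exonic[tot - utr3]
      } else {
        cR <- exonic[tot - utr5]; cL <- exonic[utr3 + 1L]
      }
      gr_ex <- GenomicRanges::GRanges(contigs[ci],
        IRanges::IRanges(ex_start, ex_end), strand = strand)
      gr_cds <- GenomicRanges::restrict(gr_ex, cL, cR)
      gr_cds <- gr_cds[GenomicRanges::width(gr_cds) > 0L]
      gr_cds <- sort(gr_cds)
      if (strand == "-") gr_cds <- rev(gr_cds)   # translation order
      genes[[gid]] <- GenomicRanges::GRanges(contigs[ci],
        IRanges::IRanges(gstart, gend), strand = strand)
      exons[[gid]] <- gr_ex
      cds[[gid]] <- gr_cds
      pos <- gend + sample(2000:5000, 1L)
    }
  }
  gg <- unlist(GenomicRanges::GRangesList(genes))
  names(gg) <- names(genes)
  gg$ID <- names(gg)
  models <- list(genes = gg,
                 exons = GenomicRanges::GRangesList(exons),
                 cds = GenomicRanges::GRangesList(cds))
  list(genome = genome, models = models)
}

#' Simulate a structured multi-accession SNP panel
#'
#' Draws SNP positions on the simulated genome, Balding-Nichols subpopulation
#' allele frequencies, binomial diploid genotypes, duplicated accessions,
#' injected hard-filter-failing sites, multiallelic spike-ins, per-sample
#' depth/quality fields and uniform missingness. Deterministic for a fixed
#' config seed; duplicated accessions are exact genotype copies before
#' missingness is applied.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param reference output of \code{\link{simulateReference}} (or a list with
#'   a \code{genome} element).
#' @return list with \code{genotypes} (\linkS4class{SnpGenotypes}),
#'   \code{truth} (latent values: subpopulation labels, ancestral and
#'   subpopulation allele frequencies, duplicate pairs, injected failing
#'   sites, multiallelic loci) and per-sample \code{depth}/\code{gq} matrices.
#' @export
simulatePopulation <- function(config, reference) {
  stopifnot(inherits(config, "SimulationConfig"))
  genome <- reference$genome
  set.seed(deriveSeed(config$seed, "population"))
  lens <- Biostrings::width(genome)
  contigs <- names(genome)
  n <- config$n_accessions; K <- config$n_subpops; M <- config$n_snps
  if (M > floor(sum(lens) * 0.5))
    stop("n_snps exceeds available distinct positions")

  # positions: allocated to contigs proportionally to length
  alloc <- floor(M * lens / sum(lens))
  alloc[1L] <- alloc[1L] + (M - sum(alloc))
  pos_l <- lapply(seq_along(contigs), function(ci)
    sort(sample.int(lens[ci], alloc[ci])))
  contig_v <- rep(contigs, lengths(pos_l))
  pos_v <- unlist(pos_l)

  refb <- vapply(seq_len(M), function(i)
    as.character(Biostrings::subseq(genome[[contig_v[i]]], pos_v[i], pos_v[i])),
    character(1))
  altb <- vapply(refb, function(r) {
    ts <- c(A = "G", G = "A", C = "T", T = "C")[r]
    if (runif(1) < config$ts_prob) unname(ts)
    else sample(setdiff(c("A", "C", "G", "T"), c(r, ts)), 1L)
  }, character(1), USE.NAMES = FALSE)

  n_multi <- round(config$frac_multiallelic * M)
  multi_idx <- if (n_multi > 0) sort(sample.int(M, n_multi)) else integer(0)
  alt2 <- rep(NA_character_, M)
  for (i in multi_idx)
    alt2[i] <- sample(setdiff(c("A", "C", "G", "T"), c(refb[i], altb[i])), 1L)

  p_anc <- runif(M, config$freq_range[1], config$freq_range[2])
  if (config$fst < 1e-9) {
    p_sub <- matrix(rep(p_anc, K), ncol = K)
  } else {
    a <- p_anc * (1 - config$fst) / config$fst
    b <- (1 - p_anc) * (1 - config$fst) / config$fst
    p_sub <- matrix(rbeta(M * K, rep(a, K), rep(b, K)), ncol = K)
  }
  subpop_of <- sort(rep_len(seq_len(K), n))

  dosage <- matrix(0L, M, n)
  for (j in seq_len(n))
    dosage[, j] <- rbinom(M, 2L, p_sub[, subpop_of[j]])
  a1 <- matrix(0L, M, n); a2 <- matrix(0L, M, n)
  a1[dosage == 2L] <- 1L
  a2[dosage >= 1L] <- 1L
  # multiallelic spike-ins: each allele copy switches to alt2 at low frequency
  for (i in multi_idx) {
    q2 <- runif(1, 0.05, 0.15)
    sw1 <- runif(n) < q2; sw2 <- runif(n) < q2
    a1[i, sw1] <- 2L; a2[i, sw2] <- 2L
    lo <- pmin(a1[i, ], a2[i, ]); hi <- pmax(a1[i, ], a2[i, ])
    a1[i, ] <- lo; a2[i, ] <- hi
  }

  acc <- sprintf("Acc%02d", seq_len(n))
  dup_pairs <- NULL
  if (config$n_duplicates > 0L) {
    src <- seq_len(config$n_duplicates)
    clone <- n - config$n_duplicates + src
    for (k in seq_along(src)) {
      a1[, clone[k]] <- a1[, src[k]]
      a2[, clone[k]] <- a2[, src[k]]
      subpop_of[clone[k]] <- subpop_of[src[k]]
    }
    dup_pairs <- data.frame(source = acc[src], clone = acc[clone])
  }

  # site QC fields: passing ranges everywhere, then targeted failing draws
  rng <- config$qc_field_ranges
  drawField <- function(f, kind)
    runif(M, rng[[kind]][[f]][1], rng[[kind]][[f]][2])
  fields <- c("QD", "MQ", "FS", "MQRankSum", "ReadPosRankSum")
  qc <- lapply(setNames(fields, fields), drawField, kind = "pass")
  n_fail <- round(config$frac_fail * M)
  fail_idx <- if (n_fail > 0) sort(sample.int(M, n_fail)) else integer(0)
  fail_field <- character(0)
  if (n_fail > 0) {
    fail_field <- sample(fields, n_fail, replace = TRUE)
    for (k in seq_len(n_fail)) {
      f <- fail_field[k]
      qc[[f]][fail_idx[k]] <- runif(1, rng$fail[[f]][1], rng$fail[[f]][2])
    }
  }

  depth <- matrix(rpois(M * n, config$mean_depth), M, n)
  gq <- matrix(sample(40:90, M * n, replace = TRUE), M, n)
  miss <- matrix(runif(M * n) < config$missing_rate, M, n)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_

  gr <- GenomicRanges::GRanges(contig_v, IRanges::IRanges(pos_v, width = 1L))
  GenomeInfoDb::seqlengths(gr) <- setNames(lens, contigs)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    ref = refb,
    alt = ifelse(is.na(alt2), altb, paste0(altb, ",", alt2)),
    qd = round(qc$QD, 2), mq = round(qc$MQ, 2), fs = round(qc$FS, 2),
    mq_rank_sum = round(qc$MQRankSum, 2),
    read_pos_rank_sum = round(qc$ReadPosRankSum, 2),
    site_quality = round(runif(M, 500, 2000), 1),
    mean_depth = round(rowMeans(depth), 2),
    mean_gq = round(rowMeans(gq), 2))
  names(gr) <- paste0(contig_v, "_", pos_v)
  gt <- SnpGenotypes(a1, a2, gr, acc)

  truth <- list(
    subpop_of = setNames(subpop_of, acc),
    ancestral_freq = setNames(p_anc, names(gr)),
    subpop_freq = `dimnames<-`(p_sub,
      list(names(gr), paste0("subpop", seq_len(K)))),
    duplicate_pairs = dup_pairs,
    failing = data.frame(id = names(gr)[fail_idx], field = fail_field),
    multiallelic = names(gr)[multi_idx])
  list(genotypes = gt, truth = truth, depth = depth, gq = gq)
}

# deterministic VCF emission with per-sample GT:DP:GQ
writePopulationVcf <- function(sim, genome, path) {
  x <- sim$genotypes
  rr <- SummarizedExperiment::rowRanges(x)
  cc <- alleleCodes(x)
  hdr <- c("##fileformat=VCFv4.2", "##source=kaspanel-simulate",
    sprintf("##contig=<ID=%s,length=%d>", names(genome),
            Biostrings::width(genome)),
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand bias">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="Mapping quality rank sum">',
    '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Read position rank sum">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", accessionIds(x)), collapse = "\t"))
  mc <- S4Vectors::mcols(rr)
  info <- sprintf("QD=%s;MQ=%s;FS=%s;MQRankSum=%s;ReadPosRankSum=%s",
                  fmtNum(mc$qd), fmtNum(mc$mq), fmtNum(mc$fs),
                  fmtNum(mc$mq_rank_sum), fmtNum(mc$read_pos_rank_sum))
  lines <- vapply(seq_len(nrow(x)), function(i) {
    g <- ifelse(is.na(cc$a1[i, ]), "./.", paste0(cc$a1[i, ], "/", cc$a2[i, ]))
    samp <- paste0(g, ":", sim$depth[i, ], ":", sim$gq[i, ])
    paste(c(as.character(GenomeInfoDb::seqnames(rr))[i],
            GenomicRanges::start(rr)[i], ".", mc$ref[i], mc$alt[i],
            fmtNum(mc$site_quality[i], 1), ".", info[i], "GT:DP:GQ", samp),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Generate the full default fixture on disk
#'
#' One-call wrapper: simulates the reference genome, gene models and
#' population, and writes \code{reference.fa}, \code{genes.gff3},
#' \code{population.vcf} and \code{truth.json} into \code{dir}. Same seed
#' gives byte-identical files.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param dir output directory (created if needed).
#' @return list with file \code{paths} plus the in-memory \code{genome},
#'   \code{models}, \code{genotypes} and \code{truth}.
#' @export
simulateFixture <- function(config = simulationConfig(), dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulateReference(config)
  sim <- simulatePopulation(config, ref)
  paths <- list(fasta = file.path(dir, "reference.fa"),
                gff = file.path(dir, "genes.gff3"),
                vcf = file.path(dir, "population.vcf"),
                truth = file.path(dir, "truth.json"))
  writeReference(ref$genome, paths$fasta)
  writeGeneModels(ref$models, paths$gff)
  writePopulationVcf(sim, ref$genome, paths$vcf)
  tr <- sim$truth
  writeJson(list(subpop_of = as.list(tr$subpop_of),
                 duplicate_pairs = tr$duplicate_pairs,
                 failing = tr$failing,
                 multiallelic = tr$multiallelic,
                 ancestral_freq = unname(tr$ancestral_freq)), paths$truth)
  list(paths = paths, genome = ref$genome, models = ref$models,
       genotypes = sim$genotypes, truth = tr)
}
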