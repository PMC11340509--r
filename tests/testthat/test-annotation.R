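# hand-drawn toy models: one gene per strand on a 20 kb contig
toyModels <- function() {
  # plus-strand gene: exons [5000,5399] and [5600,5999]; CDS [5100,5399]+[5600,5899]
  gp <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, 5999), strand = "+")
  exp_ <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(5000, 5600), c(5399, 5999)), strand = "+")
  cdsp <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(5100, 5600), c(5399, 5899)), strand = "+")
  # minus-strand gene at [12000,12999], single exon, CDS [12100,12899] read rightwards-to-left
  gm <- GenomicRanges::GRanges("chr1", IRanges::IRanges(12000, 12999), strand = "-")
  exm <- GenomicRanges::GRanges("chr1", IRanges::IRanges(12000, 12999), strand = "-")
  cdsm <- GenomicRanges::GRanges("chr1", IRanges::IRanges(12100, 12899), strand = "-")
  genes <- c(gp, gm); names(genes) <- c("gA", "gB")
  list(genes = genes,
       exons = GenomicRanges::GRangesList(gA = exp_, gB = exm),
       cds = GenomicRanges::GRangesList(gA = cdsp, gB = cdsm))
}

snpAt <- function(pos, ref = "A", alt = "G")
  makeGt(matrix(paste0(ref, alt), length(pos), 1),
         ref = rep(ref, length(pos)), alt = rep(alt, length(pos)), pos = pos)

test_that("region classification follows the documented precedence", {
  m <- toyModels()
  got <- classifyRegion(snpAt(c(5200, 5050, 5450, 4500, 6500, 9000,
                                12950, 13500, 11500)), m)
  expect_equal(as.character(got),
               c("exonic_cds",          # inside CDS
                 "UTR_or_exon_noncds",  # exon before CDS start
                 "intronic",            # between the two exons
                 "upstream",            # 500 bp 5' of + strand gene
                 "downstream",          # 3' of + strand gene
                 "intergenic",
                 "UTR_or_exon_noncds", # exon of the - strand gene, past its CDS
                 "upstream",            # 500 bp beyond END of - strand gene
                 "downstream"))         # below start of - strand gene
})

test_that("region labels partition all loci", {
  fx <- smallFixture()
  lab <- classifyRegion(fx$sim$genotypes, fx$ref$models)
  expect_false(any(is.na(lab)))
  expect_equal(length(lab), nrow(fx$sim$genotypes))
})

test_that("coding effects on hand-built codons", {
  # genome with known codons in the CDS of a + strand gene
  s <- paste(rep("T", 3000), collapse = "")
  # gene gX: CDS [1001,1150] on + strand (150 bp, divisible by 3)
  substring(s, 1001, 1009) <- "ATGGGAGAT"          # M G D ...
  substring(s, 1148, 1150) <- "TAA"                # terminal stop codon
  genome <- Biostrings::DNAStringSet(c(chr1 = s))
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1150), strand = "+")
  genes <- g; names(genes) <- "gX"
  m <- list(genes = genes,
            exons = GenomicRanges::GRangesList(gX = g),
            cds = GenomicRanges::GRangesList(gX = g))
  # GGA -> GGG (Gly/Gly): synonymous; third base of codon 2 is pos 1006
  x1 <- snpAt(1006, ref = "A", alt = "G")
  expect_equal(as.character(classifyCodingEffect(x1, m, genome)), "synonymous")
  # GAT -> TAT (Asp -> Tyr): nonsynonymous at pos 1007
  x2 <- snpAt(1007, ref = "G", alt = "T")
  expect_equal(as.character(classifyCodingEffect(x2, m, genome)),
               "nonsynonymous")
  # TTT -> TTA? no: make a stop gain: TTA = Leu. Use TAA: pos 1011 T->A then
  # codon 4 (1010..1012) TTT -> TAT is Tyr; instead mutate codon to TAA:
  # set positions 1010..1012 already TTT; ref T at 1011 -> A gives TAT (Tyr).
  # Proper stop gain: TGC-like site; craft TAC -> TAA at codon 5
  s2 <- s; substring(s2, 1013, 1015) <- "TAC"
  genome2 <- Biostrings::DNAStringSet(c(chr1 = s2))
  x3 <- snpAt(1015, ref = "C", alt = "A")
  expect_equal(as.character(classifyCodingEffect(x3, m, genome2)), "stop_gain")
  # stop loss at the terminal codon TAA -> CAA
  x4 <- snpAt(1148, ref = "T", alt = "C")
  expect_equal(as.character(classifyCodingEffect(x4, m, genome)), "stop_loss")
  # CDS not divisible by 3 -> warning, effect not_coding
  gBad <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1151), strand = "+")
  mBad <- list(genes = setNames(gBad, "gX"),
               exons = GenomicRanges::GRangesList(gX = gBad),
               cds = GenomicRanges::GRangesList(gX = gBad))
  expect_warning(e <- classifyCodingEffect(x1, mBad, genome), "divisible")
  expect_equal(as.character(e), "not_coding")
})

test_that("coding effects agree with full-protein retranslation on the fixture", {
  fx <- smallFixture()
  x <- fx$sim$genotypes
  bi <- x[!isMultiallelic(x), ]
  lab <- classifyRegion(bi, fx$ref$models)
  eff <- classifyCodingEffect(bi, fx$ref$models, fx$ref$genome)
  idx <- which(lab == "exonic_cds")
  expect_gt(length(idx), 10)
  rr <- SummarizedExperiment::rowRanges(bi)
  cds_flat <- unlist(GenomicRanges::GRangesList(lapply(fx$ref$models$cds, sort)))
  gene_names <- rep(names(fx$ref$models$cds),
                    lengths(fx$ref$models$cds))
  for (i in idx) {
    ctg <- as.character(GenomeInfoDb::seqnames(rr))[i]
    pos <- GenomicRanges::start(rr)[i]
    ov <- which(as.character(GenomeInfoDb::seqnames(cds_flat)) == ctg &
                GenomicRanges::start(cds_flat) <= pos &
                GenomicRanges::end(cds_flat) >= pos)
    gene <- sort(gene_names[ov])[1]
    want <- oracleCodingEffect(ctg, pos, refAlleles(bi)[i],
                               altAlleles(bi)[[i]][1], gene,
                               fx$ref$models, fx$ref$genome)
    expect_equal(as.character(eff[i]), want,
                 label = paste("locus", lociIds(bi)[i]))
  }
  # one-directional invariant: coding effect only inside CDS regions
  expect_true(all(eff[lab != "exonic_cds"] == "not_coding"))
})

test_that("substitution spectrum counts transitions and transversions", {
  g <- makeGt(matrix(c("CT", "AG", "AC"), 3, 1),
              ref = c("C", "A", "A"), alt = c("T", "G", "C"),
              pos = c(100, 600, 1100))
  sp <- substitutionSpectrum(g)
  expect_equal(sp$transitions, 2L)
  expect_equal(sp$transversions, 1L)
  expect_equal(sp$ts_tv, 2.0)
  expect_false(sp$ts_tv_undefined)
  expect_equal(unname(sp$type_counts[c("C>T", "A>G", "A>C")]), rep(1L, 3),
               ignore_attr = TRUE)
  # transition-only set: the ratio is undefined and flagged
  g2 <- makeGt(matrix("AG", 1, 1), ref = "A", alt = "G")
  sp2 <- substitutionSpectrum(g2)
  expect_true(sp2$ts_tv_undefined)
  expect_true(is.na(sp2$ts_tv))
  # transversion-only set: ratio 0, defined
  g3 <- makeGt(matrix("AC", 1, 1), ref = "A", alt = "C")
  expect_equal(substitutionSpectrum(g3)$ts_tv, 0)
})

test_that("het/hom counts cover calls carrying an alternate allele", {
  g <- makeGt(matrix(c("AG", "GG", "AA", NA), 1), ref = "A", alt = "G")
  sp <- substitutionSpectrum(g)
  expect_equal(sp$het_count, 1L)
  expect_equal(sp$hom_count, 1L)   # the AA call carries no alt; NA is missing
})
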