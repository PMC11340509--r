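# two-locus helper with controllable QC fields
qcGt <- function(qd = NA, mq = NA, fs = NA, mqrs = NA, rprs = NA,
                 depth = 20, gq = 60) {
  makeGt(matrix(c("AG", "AA", "GG", "AG"), 2, 2, byrow = TRUE),
         ref = c("A", "A"), alt = c("G", "G"),
         qc = list(qd = c(qd, 10), mq = c(mq, 50), fs = c(fs, 5),
                   mq_rank_sum = c(mqrs, 0), read_pos_rank_sum = c(rprs, 0),
                   mean_depth = c(depth, depth), mean_gq = c(gq, gq),
                   site_quality = c(1000, 1000)))
}

test_that("hard filter applies strict printed inequalities per present field", {
  r <- hardFilter(qcGt(qd = 1.5))
  expect_equal(nrow(r$genotypes), 1L)
  expect_equal(unname(firstFailingStage(r$report)[1]), "hard_filter")
  # boundary: FS = 60.0 exactly is retained (removal requires > 60)
  expect_equal(nrow(hardFilter(qcGt(fs = 60.0))$genotypes), 2L)
  expect_equal(nrow(hardFilter(qcGt(fs = 60.01))$genotypes), 1L)
  expect_equal(nrow(hardFilter(qcGt(qd = 2.0))$genotypes), 2L)
  expect_equal(nrow(hardFilter(qcGt(mq = 39.9))$genotypes), 1L)
  expect_equal(nrow(hardFilter(qcGt(mqrs = -13))$genotypes), 1L)
  expect_equal(nrow(hardFilter(qcGt(rprs = -8.5))$genotypes), 1L)
  # absent fields never trigger removal
  expect_equal(nrow(hardFilter(qcGt())$genotypes), 2L)
})

test_that("quality filter enforces MAF, integrity, depth and AverageQ", {
  # MAF exactly 0.05: 9 x AA + 1 x AG over 10 samples -> removed (strict >)
  g <- makeGt(matrix(c(rep("AA", 9), "AG"), 1), ref = "A", alt = "G",
              qc = list(mean_depth = 20, mean_gq = 60))
  expect_equal(nrow(qualityFilter(g)$genotypes), 0L)
  # call rate 0.8 -> removed by integrity
  g2 <- makeGt(matrix(c(rep("AG", 8), NA, NA), 1), ref = "A", alt = "G",
               qc = list(mean_depth = 20, mean_gq = 60))
  expect_equal(nrow(qualityFilter(g2)$genotypes), 0L)
  # all criteria passing -> retained
  g3 <- makeGt(matrix(rep(c("AA", "AG"), 5), 1), ref = "A", alt = "G",
               qc = list(mean_depth = 10, mean_gq = 40))
  expect_equal(nrow(qualityFilter(g3)$genotypes), 1L)
  # depth 5 exactly fails (strict), 5.1 passes
  g4 <- makeGt(matrix(rep(c("AA", "AG"), 5), 1), ref = "A", alt = "G",
               qc = list(mean_depth = 5, mean_gq = 40))
  expect_equal(nrow(qualityFilter(g4)$genotypes), 0L)
})

test_that("MAF of a multiallelic locus is the second-most-frequent allele", {
  g <- makeGt(matrix(c("AA", "AG", "AT", "AA", "AA"), 1),
              ref = "A", alt = "G,T")
  st <- locusStats(g)
  # freqs: A 0.8, G 0.1, T 0.1 -> MAF 0.1
  expect_equal(unname(st$maf), 0.1)
})

test_that("conservation filter uses pairwise distance on the same contig", {
  mk <- function(pos) makeGt(matrix("AG", length(pos), 1),
                             ref = rep("A", length(pos)),
                             alt = rep("G", length(pos)), pos = pos)
  # 40 bp apart: both removed
  expect_equal(nrow(conservationFilter(mk(c(1000, 1040)))$genotypes), 0L)
  # 51 bp apart: both retained ("greater than 50 bp" passes)
  expect_equal(nrow(conservationFilter(mk(c(1000, 1051)))$genotypes), 2L)
  # exactly 50 bp apart: removed
  expect_equal(nrow(conservationFilter(mk(c(1000, 1050)))$genotypes), 0L)
  # singleton on its own contig: retained
  g3 <- makeGt(matrix("AG", 2, 1), ref = c("A", "A"), alt = c("G", "G"),
               contig = c("chr1", "chr2"), pos = c(1000, 1030))
  expect_equal(nrow(conservationFilter(g3)$genotypes), 2L)
})

test_that("conservation is judged against the full pre-filter variant set", {
  all <- makeGt(matrix("AG", 3, 1), ref = rep("A", 3), alt = rep("G", 3),
                pos = c(1000, 1030, 5000))
  # query only the first locus; its neighbour at 1030 still disqualifies it
  q <- all[1, ]
  expect_equal(nrow(conservationFilter(q, all)$genotypes), 0L)
  expect_equal(nrow(conservationFilter(all[3, ], all)$genotypes), 1L)
})

test_that("uniqueness filter removes loci inside duplicated segments", {
  set.seed(99)
  base <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE),
                collapse = "")
  seg <- substring(base, 1000, 1400)   # 401 bp duplicated verbatim
  genome <- Biostrings::DNAStringSet(c(
    chr1 = base, chr2 = paste0(substring(base, 4500, 5000), seg)))
  g <- makeGt(matrix("AG", 2, 1), ref = c("A", "A"), alt = c("G", "G"),
              pos = c(1200, 3000))
  r <- uniquenessFilter(g, genome)
  expect_equal(lociIds(r$genotypes), "chr1_3000")
  expect_equal(unname(firstFailingStage(r$report)["chr1_1200"]),
               "uniqueness_filter")
})

test_that("uniqueness keeps all loci of a non-repetitive genome (exhaustive scan)", {
  set.seed(7)
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 10000, replace = TRUE), collapse = "")))
  pos <- seq(300, 9700, by = 450)
  g <- makeGt(matrix("AG", length(pos), 1), ref = rep("A", length(pos)),
              alt = rep("G", length(pos)), pos = pos)
  keep <- uniquenessFilter(g, genome)$genotypes
  expect_equal(nrow(keep), length(pos))
  # oracle: every +/-100 bp window occurs exactly once in the genome
  for (p in sample(pos, 5)) {
    fl <- extractFlank(genome, "chr1", p, 100)
    expect_equal(countOccurrences(genome, fl$seq), 1L)
  }
})

test_that("reverse-complement duplications are also detected", {
  set.seed(17)
  base <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                collapse = "")
  seg <- substring(base, 2000, 2300)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seg)))
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(base, rc)))
  g <- makeGt(matrix("AG", 1, 1), ref = "A", alt = "G", pos = 2150)
  expect_equal(nrow(uniquenessFilter(g, genome)$genotypes), 0L)
})

test_that("KASP eligibility needs biallelic loci with PIC above 0.2", {
  # triallelic with high PIC -> removed
  tri <- makeGt(matrix(c("AG", "AT", "GT", "AA", "GG", "TT"), 1),
                ref = "A", alt = "G,T")
  expect_gt(locusStats(tri)$pic, 0.2)
  expect_equal(nrow(kaspEligibilityFilter(tri)$genotypes), 0L)
  # biallelic 0.9/0.1 -> PIC 0.1638 -> removed
  lo <- makeGt(matrix(c(rep("AA", 8), "AG", "AG"), 1), ref = "A", alt = "G")
  expect_equal(unname(locusStats(lo)$pic), 1 - 0.82 - 2 * 0.81 * 0.01,
               tolerance = 1e-12)
  expect_equal(nrow(kaspEligibilityFilter(lo)$genotypes), 0L)
  # biallelic 0.5/0.5 -> PIC 0.375 -> retained
  hi <- makeGt(matrix(rep("AG", 10), 1), ref = "A", alt = "G")
  expect_equal(nrow(kaspEligibilityFilter(hi)$genotypes), 1L)
})

test_that("cascade survivors are invariant to stage order", {
  fx <- smallFixture()
  x <- fx$sim$genotypes
  genome <- fx$ref$genome
  t <- filterThresholds()
  full <- SummarizedExperiment::rowRanges(x)
  ordA <- filterCascade(x, genome, t)$genotypes
  # apply the same predicates in a different order, conservation still
  # judged against the full input set
  s1 <- kaspEligibilityFilter(x, thresholds = t)$genotypes
  s2 <- conservationFilter(s1, full, t$conservation_window)$genotypes
  s3 <- qualityFilter(s2, t)$genotypes
  s4 <- uniquenessFilter(s3, genome, t)$genotypes
  ordB <- hardFilter(s4, t)$genotypes
  expect_setequal(lociIds(ordA), lociIds(ordB))
})

test_that("filter report counts telescope and label first failures", {
  fx <- smallFixture()
  casc <- filterCascade(fx$sim$genotypes, fx$ref$genome)
  st <- filterStages(casc$report)
  expect_equal(st$surviving, st$input - st$removed)
  expect_equal(st$input[-1], st$surviving[-nrow(st)])
  expect_equal(st$input[1], nrow(fx$sim$genotypes))
  ff <- firstFailingStage(casc$report)
  expect_equal(sum(is.na(ff)), nrow(casc$genotypes))
  expect_equal(as.integer(table(ff)[st$stage[st$removed > 0]]),
               st$removed[st$removed > 0])
})

test_that("injected failing sites are exactly the hard-filter removals", {
  fx <- smallFixture()
  x <- fx$sim$genotypes
  r <- hardFilter(x)
  removed <- setdiff(lociIds(x), lociIds(r$genotypes))
  expect_setequal(removed, fx$sim$truth$failing$id)
})
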