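# Build a SnpGenotypes object from human-readable genotype strings.
# geno: character matrix (loci x accessions) with entries like "AA", "AG",
# or NA for missing. ref/alt give the per-locus alleles (alt comma-separated
# for multiallelic loci).
makeGt <- function(geno, ref, alt, contig = "chr1", pos = NULL, acc = NULL,
                   qc = list()) {
  geno <- as.matrix(geno)
  L <- nrow(geno); n <- ncol(geno)
  if (is.null(pos)) pos <- seq(100L, by = 500L, length.out = L)
  if (length(contig) == 1L) contig <- rep(contig, L)
  if (is.null(acc)) acc <- sprintf("S%02d", seq_len(n))
  a1 <- matrix(NA_integer_, L, n); a2 <- matrix(NA_integer_, L, n)
  for (i in seq_len(L)) {
    alleles <- c(ref[i], strsplit(alt[i], ",")[[1]])
    for (j in seq_len(n)) {
      g <- geno[i, j]
      if (is.na(g)) next
      b <- strsplit(g, "")[[1]]
      code <- match(b, alleles) - 1L
      if (any(is.na(code))) stop("genotype uses unknown allele: ", g)
      a1[i, j] <- min(code); a2[i, j] <- max(code)
    }
  }
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, width = 1L))
  mc <- S4Vectors::DataFrame(ref = ref, alt = alt)
  for (f in names(qc)) mc[[f]] <- qc[[f]]
  S4Vectors::mcols(gr) <- mc
  SnpGenotypes(a1, a2, gr, acc)
}

# small simulated fixture shared by several tests (cheap: ~1 s)
smallFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulationConfig(seed = 42L, n_snps = 400L, n_accessions = 24L,
                              n_subpops = 3L, contig_lengths = c(30000L, 20000L))
      ref <- simulateReference(cfg)
      sim <- simulatePopulation(cfg, ref)
      cache <<- list(cfg = cfg, ref = ref, sim = sim)
    }
    cache
  }
})
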