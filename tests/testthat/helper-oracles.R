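# Independent oracles used to verify the implementation.

# Full-protein retranslation oracle for coding effects: rebuild the entire
# CDS sequence, substitute the variant base genomically, translate both
# proteins and classify the difference.
oracleCodingEffect <- function(contig, pos, refb, altb, gene, models, genome) {
  cds <- models$cds[[gene]]
  str <- as.character(GenomicRanges::strand(cds))[1]
  getCds <- function(gnm) {
    cds2 <- sort(cds)
    segs <- vapply(seq_along(cds2), function(k)
      as.character(Biostrings::subseq(gnm[[contig]],
                                      GenomicRanges::start(cds2)[k],
                                      GenomicRanges::end(cds2)[k])),
      character(1))
    s <- paste(segs, collapse = "")
    if (str == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }
  mutate <- function(gnm) {
    s <- as.character(gnm[[contig]])
    stopifnot(substring(s, pos, pos) == refb)
    substring(s, pos, pos) <- altb
    out <- gnm
    out[[contig]] <- Biostrings::DNAString(s)
    out
  }
  tr <- function(s) as.character(Biostrings::translate(Biostrings::DNAString(s),
                                                       no.init.codon = TRUE))
  p0 <- tr(getCds(genome)); p1 <- tr(getCds(mutate(genome)))
  if (p0 == p1) return("synonymous")
  d <- which(strsplit(p0, "")[[1]] != strsplit(p1, "")[[1]])[1]
  a0 <- substring(p0, d, d); a1 <- substring(p1, d, d)
  if (a1 == "*") "stop_gain" else if (a0 == "*") "stop_loss" else "nonsynonymous"
}

# Exhaustive minimal fully-discriminating marker-set search over all subsets.
# gmat: accessions x markers matrix of genotype codes (NA = missing).
bruteMarkerCover <- function(gmat) {
  n <- nrow(gmat); M <- ncol(gmat)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  resolves <- sapply(seq_len(M), function(m) {
    g <- gmat[, m]
    apply(pairs, 1, function(pr) {
      a <- g[pr[1]]; b <- g[pr[2]]
      !is.na(a) && !is.na(b) && a != b
    })
  })
  if (is.null(dim(resolves))) resolves <- matrix(resolves, ncol = M)
  best_cov <- 0; best_size <- 0L   # the empty set covers zero pairs
  for (mask in seq_len(2^M - 1L)) {
    mem <- which(bitwAnd(mask, 2^(seq_len(M) - 1L)) > 0)
    cov <- sum(Reduce(`|`, lapply(mem, function(m) resolves[, m])))
    if (cov > best_cov) { best_cov <- cov; best_size <- length(mem) }
    else if (cov == best_cov && length(mem) < best_size) best_size <- length(mem)
  }
  list(max_covered = best_cov, min_size = best_size,
       n_pairs = nrow(pairs))
}

# Exhaustive entry-to-nearest-entry optimum over all k-subsets.
bruteCoreOptimum <- function(D, k) {
  n <- nrow(D)
  best <- -Inf
  for (sel in combn(n, k, simplify = FALSE)) {
    sub <- D[sel, sel, drop = FALSE]; diag(sub) <- Inf
    v <- mean(apply(sub, 1, min))
    if (v > best) best <- v
  }
  best
}

# Random additive (tree-metric) distance matrix from a random binary tree
# with positive branch lengths; returns the generating ape tree + distances.
randomAdditiveTree <- function(n) {
  tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
  D <- ape::cophenetic.phylo(tr)
  D <- D[order(rownames(D)), order(colnames(D))]
  list(tree = tr, D = D)
}

# topology equality of two unrooted trees (Robinson-Foulds distance 0)
sameTopology <- function(newick, ref_tree) {
  t1 <- ape::unroot(ape::read.tree(text = newick))
  t2 <- ape::unroot(ref_tree)
  ape::dist.topo(t1, t2) == 0
}

# exhaustive substring-occurrence scan: counts occurrences of `pat` in the
# genome on both strands (overlapping)
countOccurrences <- function(genome, pat) {
  cnt <- 0L
  for (ctg in names(genome)) {
    s <- as.character(genome[[ctg]])
    rc <- as.character(Biostrings::reverseComplement(genome[[ctg]]))
    for (subj in c(s, rc)) {
      hits <- gregexpr(pat, subj, fixed = TRUE)[[1]]
      cnt <- cnt + sum(hits > 0)
    }
  }
  cnt
}

# bitmask variant of the exhaustive cover search (n*(n-1)/2 <= 30 pairs):
# gmat is accessions x markers of genotype codes with NA for missing.
bruteMarkerCoverFast <- function(gmat) {
  n <- nrow(gmat); M <- ncol(gmat)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  np <- nrow(pairs)
  stopifnot(np <= 30)
  colmask <- vapply(seq_len(M), function(m) {
    g <- gmat[, m]
    ok <- !is.na(g[pairs[, 1]]) & !is.na(g[pairs[, 2]]) &
      g[pairs[, 1]] != g[pairs[, 2]]
    v <- 0L
    for (b in which(ok)) v <- bitwOr(v, bitwShiftL(1L, b - 1L))
    v
  }, integer(1))
  popcount <- function(v) sum(bitwAnd(bitwShiftR(v, 0:29), 1L))
  best_cov <- 0L; best_size <- 0L
  for (mask in seq_len(2^M - 1L)) {
    v <- 0L
    mm <- mask; i <- 1L
    while (mm > 0L) {
      if (bitwAnd(mm, 1L)) v <- bitwOr(v, colmask[i])
      mm <- bitwShiftR(mm, 1L); i <- i + 1L
    }
    cov <- popcount(v)
    sz <- popcount(mask)
    if (cov > best_cov || (cov == best_cov && sz < best_size)) {
      best_cov <- cov; best_size <- sz
    }
  }
  list(max_covered = best_cov, min_size = best_size, n_pairs = np)
}
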