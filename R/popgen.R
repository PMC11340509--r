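#' Polymorphic information content (PIC)
#'
#' Botstein's marker informativeness,
#' \deqn{PIC = 1 - \sum_i P_i^2 - \sum_{i<j} 2 P_i^2 P_j^2,}
#' where the \eqn{P_i} are the allele frequencies at the locus and the sums
#' run over the \eqn{l} observed alleles. For a biallelic locus it is maximal
#' (0.375) at equal frequencies.
#'
#' @param allele_freqs numeric vector of allele frequencies summing to 1
#'   (tolerance 1e-6).
#' @return PIC value in [0, 1).
#' @examples
#' pic(c(0.5, 0.5))    # 0.375
#' pic(c(0.8, 0.2))    # 0.2688
#' @export
pic <- function(allele_freqs) {
  p <- as.numeric(allele_freqs)
  if (any(is.na(p)) || abs(sum(p) - 1) > 1e-6)
    stop("allele frequencies must sum to 1 (tolerance 1e-6)")
  s2 <- sum(p^2); s4 <- sum(p^4)
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  1 - s2 - (s2^2 - s4)
}

#' Per-locus diversity statistics
#'
#' Computes, from non-missing calls at every locus: minor allele frequency
#' (frequency of the second-most-frequent allele), observed allele count Na,
#' effective allele count Ne = 1/sum(p^2), observed heterozygosity Ho,
#' expected heterozygosity He = 1 - sum(p^2) (uncorrected, identical to Nei's
#' gene diversity H), Shannon's index I = -sum(p log p), PIC, and the missing
#' rate. Loci with no called genotype are flagged undefined (\code{NA}
#' statistics).
#'
#' @param x a \linkS4class{SnpGenotypes}.
#' @return a \link[S4Vectors]{DataFrame} with one row per locus (columns
#'   \code{id, contig, pos, maf, na, ne, ho, he, shannon_i, nei_h, pic,
#'   missing_rate, defined}).
#' @export
locusStats <- function(x) {
  cnt <- alleleCountMatrix(x)
  tot <- rowSums(cnt)
  p <- cnt / ifelse(tot == 0, NA_real_, tot)
  s2 <- rowSums(p^2, na.rm = TRUE)
  s4 <- rowSums(p^4, na.rm = TRUE)
  he <- ifelse(tot == 0, NA_real_, 1 - s2)
  plog <- p * log(p)
  plog[!is.finite(plog)] <- 0
  shannon <- ifelse(tot == 0, NA_real_, -rowSums(plog, na.rm = TRUE))
  picv <- ifelse(tot == 0, NA_real_, 1 - s2 - (s2^2 - s4))
  na_cnt <- rowSums(cnt > 0)
  maf <- apply(p, 1, function(z) {
    z <- z[!is.na(z)]
    if (!length(z)) return(NA_real_)
    s <- sort(z, decreasing = TRUE)
    if (length(s) >= 2L) s[2] else 0
  })
  cc <- alleleCodes(x)
  called <- rowSums(!is.na(cc$a1))
  het <- rowSums(cc$a1 != cc$a2, na.rm = TRUE)
  rr <- SummarizedExperiment::rowRanges(x)
  S4Vectors::DataFrame(
    id = lociIds(x),
    contig = as.character(GenomeInfoDb::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    maf = maf,
    na = ifelse(tot == 0, NA_integer_, na_cnt),
    ne = ifelse(tot == 0, NA_real_, 1 / s2),
    ho = ifelse(called == 0, NA_real_, het / called),
    he = he,
    shannon_i = shannon,
    nei_h = he,
    pic = picv,
    missing_rate = 1 - called / ncol(x),
    defined = tot > 0)
}

#' Pairwise allele-sharing distance matrix
#'
#' d(a, b) = 1 - mean over comparable loci of (shared alleles / 2), where the
#' shared-allele count compares unordered genotype pairs (0, 1 or 2 alleles
#' in common). Loci with a missing call in either accession are excluded
#' pairwise; a pair with zero comparable loci is an error.
#'
#' @param x a \linkS4class{SnpGenotypes} with >= 2 accessions.
#' @return symmetric numeric matrix with zero diagonal and a
#'   \code{"pairwise_n"} attribute giving the loci used per pair.
#' @export
distanceMatrix <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop("need at least 2 accessions")
  cc <- alleleCodes(x)
  ids <- accessionIds(x)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  N <- matrix(nrow(x), n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    ai <- cc$a1[, i]; bi <- cc$a2[, i]
    for (j in (i + 1L):n) {
      aj <- cc$a1[, j]; bj <- cc$a2[, j]
      ok <- !is.na(ai) & !is.na(aj)
      if (!any(ok))
        stop("no comparable loci for pair ", ids[i], " / ", ids[j])
      shared <- pmax((ai[ok] == aj[ok]) + (bi[ok] == bj[ok]),
                     (ai[ok] == bj[ok]) + (bi[ok] == aj[ok]))
      d <- 1 - mean(shared) / 2
      D[i, j] <- D[j, i] <- d
      N[i, j] <- N[j, i] <- sum(ok)
    }
  }
  attr(D, "pairwise_n") <- N
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration with the usual branch-length updates.
#' Negative branch lengths are clamped to zero with the deficit transferred
#' to the sister edge (preserving the joined pair's distance). Ties in the
#' Q-criterion are broken by row/column order for determinism. The unrooted
#' tree is returned as a Newick string.
#'
#' @param d symmetric numeric distance matrix with row/column names.
#' @return Newick string (terminated by ";").
#' @export
njTree <- function(d) {
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 taxa")
  labs <- rownames(d) %||% paste0("t", seq_len(n))
  fmt <- function(v) sprintf("%.10g", max(v, 0))
  node <- labs
  D <- as.matrix(d)
  while (length(node) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    k <- which(Q == min(Q), arr.ind = TRUE)
    k <- k[order(k[, 1], k[, 2]), , drop = FALSE][1, ]
    i <- min(k); j <- max(k)
    dij <- D[i, j]
    bi <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- dij - bi
    if (bi < 0) { bi <- 0; bj <- dij }
    if (bj < 0) { bj <- 0; bi <- dij }
    newlab <- sprintf("(%s:%s,%s:%s)", node[i], fmt(bi), node[j], fmt(bj))
    du <- (D[i, ] + D[j, ] - dij) / 2
    du <- du[-c(i, j)]
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, du), c(du, 0))
    node <- c(node[-c(i, j)], newlab)
  }
  if (length(node) == 2L) {
    b <- D[1, 2] / 2
    return(sprintf("(%s:%s,%s:%s);", node[1], fmt(b), node[2], fmt(b)))
  }
  ba <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  bb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  bc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  sprintf("(%s:%s,%s:%s,%s:%s);",
          node[1], fmt(ba), node[2], fmt(bb), node[3], fmt(bc))
}

#' Principal component analysis of a genotype matrix
#'
#' Genotypes are encoded as non-reference allele dosage (0/1/2), missing
#' dosages are imputed to the locus mean, loci are mean-centered, and the
#' sample covariance is eigendecomposed (via \code{prcomp}). Components are
#' ordered by decreasing explained variance.
#'
#' @param x a \linkS4class{SnpGenotypes} with >= 2 accessions and >= 1
#'   polymorphic locus.
#' @return list with \code{coordinates} (accessions x components) and
#'   \code{variance_fraction} (per component, summing to 1).
#' @export
pcaGenotypes <- function(x) {
  if (ncol(x) < 2L) stop("need at least 2 accessions")
  d <- dosageMatrix(x)
  mu <- rowMeans(d, na.rm = TRUE)
  for (i in seq_len(nrow(d))) d[i, is.na(d[i, ])] <- mu[i]
  v <- apply(d, 1, stats::var)
  d <- d[v > 0, , drop = FALSE]
  if (nrow(d) == 0L) stop("no polymorphic loci")
  X <- t(d)
  X <- sweep(X, 2, colMeans(X))
  pr <- prcomp(X, center = FALSE, scale. = FALSE)
  vf <- pr$sdev^2 / sum(pr$sdev^2)
  rownames(pr$x) <- accessionIds(x)
  list(coordinates = pr$x, variance_fraction = vf)
}
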