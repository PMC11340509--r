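#' Accessors for SnpGenotypes
#'
#' Small helpers around the \linkS4class{SnpGenotypes} container. All of them
#' are plain functions (no slot access is needed by user code).
#'
#' @param x a \linkS4class{SnpGenotypes} object.
#' @name snp-accessors
NULL

#' @describeIn snp-accessors accession identifiers (column names).
#' @export
accessionIds <- function(x) colnames(x)

#' @describeIn snp-accessors locus identifiers (\code{"<contig>_<pos>"}).
#' @export
lociIds <- function(x) rownames(x)

#' @describeIn snp-accessors reference alleles, one per locus.
#' @export
refAlleles <- function(x)
  as.character(S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$ref)

#' @describeIn snp-accessors list of alternate-allele vectors, one per locus.
#' @export
altAlleles <- function(x)
  strsplit(as.character(S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$alt), ",")

#' @describeIn snp-accessors list of full allele vectors (ref first).
#' @export
lociAlleles <- function(x) mapply(c, refAlleles(x), altAlleles(x),
                                  SIMPLIFY = FALSE, USE.NAMES = FALSE)

#' @describeIn snp-accessors logical: locus has more than one alternate allele.
#' @export
isMultiallelic <- function(x)
  S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$multiallelic

#' @describeIn snp-accessors per-locus fraction of non-missing calls
#'   (the "integrity" of a locus).
#' @export
callRate <- function(x)
  rowMeans(!is.na(SummarizedExperiment::assay(x, "allele1")))

#' @describeIn snp-accessors the two allele-code matrices as a list.
#' @export
alleleCodes <- function(x)
  list(a1 = SummarizedExperiment::assay(x, "allele1"),
       a2 = SummarizedExperiment::assay(x, "allele2"))

#' @describeIn snp-accessors loci x accessions matrix counting non-reference
#'   alleles per call (0/1/2, \code{NA} for missing) -- the dosage encoding
#'   used for PCA.
#' @export
dosageMatrix <- function(x) {
  cc <- alleleCodes(x)
  d <- (cc$a1 != 0L) + (cc$a2 != 0L)
  storage.mode(d) <- "integer"
  d
}

#' @describeIn snp-accessors loci x accessions character matrix of genotype
#'   strings such as \code{"A/G"} (alphabetical within the pair), \code{NA}
#'   when missing.
#' @export
genotypeStrings <- function(x) {
  cc <- alleleCodes(x)
  alle <- lociAlleles(x)
  out <- matrix(NA_character_, nrow(x), ncol(x), dimnames = dimnames(cc$a1))
  for (i in seq_len(nrow(x))) {
    ok <- !is.na(cc$a1[i, ])
    if (!any(ok)) next
    b1 <- alle[[i]][cc$a1[i, ok] + 1L]
    b2 <- alle[[i]][cc$a2[i, ok] + 1L]
    lo <- pmin(b1, b2); hi <- pmax(b1, b2)
    out[i, ok] <- paste0(lo, "/", hi)
  }
  out
}

# per-locus allele counts over called genotypes: loci x (max allele code + 1)
alleleCountMatrix <- function(x) {
  cc <- alleleCodes(x)
  kmax <- suppressWarnings(max(cc$a2, na.rm = TRUE))
  if (!is.finite(kmax)) kmax <- 0L
  cnt <- sapply(0:kmax, function(k)
    rowSums(cc$a1 == k, na.rm = TRUE) + rowSums(cc$a2 == k, na.rm = TRUE))
  if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = nrow(x))
  colnames(cnt) <- as.character(0:kmax)
  rownames(cnt) <- rownames(x)
  cnt
}

#' @describeIn snp-accessors per-locus allele frequency vectors (named by
#'   allele base), computed from non-missing calls.
#' @export
alleleFreqs <- function(x) {
  cnt <- alleleCountMatrix(x)
  tot <- rowSums(cnt)
  alle <- lociAlleles(x)
  lapply(seq_len(nrow(cnt)), function(i) {
    k <- length(alle[[i]])
    v <- cnt[i, seq_len(min(k, ncol(cnt)))]
    if (tot[i] == 0) return(setNames(rep(NA_real_, k), alle[[i]]))
    setNames(as.numeric(v) / tot[i], alle[[i]][seq_along(v)])
  })
}

#' @describeIn snp-accessors one site QC column (\code{"qd"}, \code{"mq"},
#'   \code{"fs"}, \code{"mq_rank_sum"}, \code{"read_pos_rank_sum"},
#'   \code{"site_quality"}, \code{"mean_depth"} or \code{"mean_gq"}).
#' @param f QC field name.
#' @export
qcField <- function(x, f)
  S4Vectors::mcols(SummarizedExperiment::rowRanges(x))[[f]]
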