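#' SnpGenotypes: diploid genotype calls at SNP loci
#'
#' The central container of the pipeline: an accessions-by-loci table of
#' unordered diploid allele pairs together with the per-locus variant record
#' (position, ref/alt alleles, site QC fields). It extends
#' \linkS4class{RangedSummarizedExperiment}: loci are rows (with a
#' \link[GenomicRanges]{GRanges} of width-1 positions), accessions are columns,
#' and the two assays \code{allele1}/\code{allele2} hold integer allele codes
#' (0 = ref, 1.. = alternate alleles in ALT order, \code{NA} = missing call).
#' Calls are stored unordered with \code{allele1 <= allele2}; phase is
#' discarded, consistent with genotyping dikaryotic strains diploid-like.
#'
#' Row metadata columns: \code{ref}, \code{alt} (comma-separated),
#' \code{multiallelic}, and the site QC fields \code{qd}, \code{mq}, \code{fs},
#' \code{mq_rank_sum}, \code{read_pos_rank_sum}, \code{site_quality},
#' \code{mean_depth}, \code{mean_gq} (absent fields are \code{NA}, never
#' imputed).
#'
#' @aliases SnpGenotypes-class
#' @exportClass SnpGenotypes
setClass("SnpGenotypes", contains = "RangedSummarizedExperiment")

setValidity("SnpGenotypes", function(object) {
  msg <- character(0)
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("allele1", "allele2") %in% an))
    msg <- c(msg, "assays 'allele1' and 'allele2' are required")
  else {
    a1 <- SummarizedExperiment::assay(object, "allele1")
    a2 <- SummarizedExperiment::assay(object, "allele2")
    if (!is.integer(a1) || !is.integer(a2))
      msg <- c(msg, "allele assays must be integer matrices")
    if (any(is.na(a1) != is.na(a2)))
      msg <- c(msg, "allele1/allele2 must be missing together")
    ok <- !is.na(a1)
    if (any(a1[ok] > a2[ok]))
      msg <- c(msg, "calls must be stored unordered with allele1 <= allele2")
    if (any(a1[ok] < 0L))
      msg <- c(msg, "allele codes must be >= 0")
    mc <- S4Vectors::mcols(SummarizedExperiment::rowRanges(object))
    need <- c("ref", "alt")
    if (!all(need %in% colnames(mc)))
      msg <- c(msg, "rowRanges mcols must contain 'ref' and 'alt'")
    else {
      nall <- 1L + lengths(strsplit(as.character(mc$alt), ","))
      bad <- which(apply(a2, 1, function(z) suppressWarnings(max(z, na.rm = TRUE))) >=
                     nall & rowSums(!is.na(a2)) > 0)
      if (length(bad))
        msg <- c(msg, sprintf("allele codes exceed allele count at %d loci",
                              length(bad)))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SnpGenotypes object
#'
#' @param allele1,allele2 integer matrices (loci x accessions) of allele codes
#'   with \code{NA} for missing calls; pairs are reordered so that
#'   \code{allele1 <= allele2}.
#' @param loci a \link[GenomicRanges]{GRanges} of width-1 SNP positions with
#'   metadata columns \code{ref} and \code{alt} (comma-separated alternate
#'   alleles); QC columns are added as \code{NA} when absent.
#' @param accessions character vector of accession identifiers.
#' @return A \linkS4class{SnpGenotypes} object. Locus names default to
#'   \code{"<contig>_<pos>"}.
#' @export
SnpGenotypes <- function(allele1, allele2, loci, accessions) {
  stopifnot(is.matrix(allele1), is.matrix(allele2),
            all(dim(allele1) == dim(allele2)),
            length(loci) == nrow(allele1),
            length(accessions) == ncol(allele1))
  storage.mode(allele1) <- "integer"
  storage.mode(allele2) <- "integer"
  lo <- pmin(allele1, allele2)
  hi <- pmax(allele1, allele2)
  mc <- S4Vectors::mcols(loci)
  for (f in c("qd", "mq", "fs", "mq_rank_sum", "read_pos_rank_sum",
              "site_quality", "mean_depth", "mean_gq")) {
    if (is.null(mc[[f]])) mc[[f]] <- rep(NA_real_, length(loci))
  }
  if (is.null(mc$multiallelic))
    mc$multiallelic <- lengths(strsplit(as.character(mc$alt), ",")) > 1L
  S4Vectors::mcols(loci) <- mc
  if (is.null(names(loci)))
    names(loci) <- paste0(GenomeInfoDb::seqnames(loci), "_",
                          GenomicRanges::start(loci))
  dimnames(lo) <- dimnames(hi) <- list(names(loci), accessions)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(allele1 = lo, allele2 = hi), rowRanges = loci)
  new("SnpGenotypes", se)
}

setMethod("show", "SnpGenotypes", function(object) {
  cat(sprintf("SnpGenotypes: %d loci x %d accessions\n",
              nrow(object), ncol(object)))
  cat(sprintf("  multiallelic loci: %d | missing calls: %.2f%%\n",
              sum(isMultiallelic(object)),
              100 * mean(is.na(SummarizedExperiment::assay(object, "allele1")))))
  contigs <- unique(as.character(GenomeInfoDb::seqnames(
    SummarizedExperiment::rowRanges(object))))
  cat("  contigs:", paste(head(contigs, 5), collapse = ", "),
      if (length(contigs) > 5) "..." else "", "\n")
})

#' FilterReport: per-stage accounting of a filter cascade
#'
#' Records, for each filter stage in order, the number of loci entering,
#' removed and surviving, plus (optionally) the first failing stage per locus.
#' Counts telescope: each stage's survivors are the next stage's input.
#'
#' @aliases FilterReport-class
#' @exportClass FilterReport
setClass("FilterReport",
         representation(stages = "data.frame", firstFail = "character"))

setValidity("FilterReport", function(object) {
  s <- object@stages
  if (!all(c("stage", "input", "removed", "surviving") %in% colnames(s)))
    return("stages needs columns stage/input/removed/surviving")
  if (any(s$surviving != s$input - s$removed))
    return("surviving must equal input - removed at every stage")
  if (nrow(s) > 1 && any(s$input[-1] != s$surviving[-nrow(s)]))
    return("stage counts must telescope")
  TRUE
})

FilterReport <- function(stages, firstFail = character(0)) {
  new("FilterReport", stages = stages, firstFail = firstFail)
}

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport:\n")
  print(object@stages, row.names = FALSE)
})

#' @describeIn filterCascade stage table of a \linkS4class{FilterReport}.
#' @param report a \linkS4class{FilterReport}.
#' @export
filterStages <- function(report) report@stages

#' @describeIn filterCascade named character vector giving each input locus's
#'   first failing stage (\code{NA} for survivors).
#' @export
firstFailingStage <- function(report) report@firstFail

#' CoreSet: a selected core collection
#'
#' @aliases CoreSet-class
#' @exportClass CoreSet
setClass("CoreSet", representation(ids = "character", ratio = "numeric",
                                   objective = "numeric", seed = "integer"))

setMethod("show", "CoreSet", function(object) {
  cat(sprintf("CoreSet: %d accessions (ratio %.2f), E-NE objective %.4f\n",
              length(object@ids), object@ratio, object@objective))
})

#' @describeIn selectCore accession identifiers of a \linkS4class{CoreSet}.
#' @export
coreIds <- function(core) core@ids

#' @describeIn selectCore entry-to-nearest-entry objective value of a
#'   \linkS4class{CoreSet}.
#' @export
coreObjective <- function(core) core@objective
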