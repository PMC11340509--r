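#' Screening criteria for candidate core markers
#'
#' Candidate core SNPs are picked from designed, exonic KASP markers by
#' missing rate, MAF and PIC (preferring PIC >= pic_min, relaxing to
#' pic_fallback when too few markers qualify), with a minimum physical
#' spacing between accepted markers and an optional per-contig cap.
#'
#' @param missing_max maximum per-locus missing rate.
#' @param pic_min preferred PIC floor.
#' @param pic_fallback PIC floor used when the preferred one yields fewer
#'   than \code{target_count} markers.
#' @param maf_min minimum minor allele frequency.
#' @param min_spacing minimum bp between accepted markers on a contig.
#' @param max_per_contig maximum markers accepted per contig.
#' @param target_count number of candidates to return.
#' @param region genomic region class required (default exonic CDS).
#' @return list of class \code{CandidateScreenCriteria}.
#' @export
candidateScreenCriteria <- function(missing_max = 0.10, pic_min = 0.30,
                                    pic_fallback = 0.20, maf_min = 0.20,
                                    min_spacing = 1000L,
                                    max_per_contig = Inf,
                                    target_count = 50L,
                                    region = "exonic_cds") {
  stopifnot(missing_max >= 0, missing_max <= 1, target_count >= 1L)
  structure(list(missing_max = missing_max, pic_min = pic_min,
                 pic_fallback = pic_fallback, maf_min = maf_min,
                 min_spacing = as.integer(min_spacing),
                 max_per_contig = max_per_contig,
                 target_count = as.integer(target_count), region = region),
            class = "CandidateScreenCriteria")
}

#' Screen candidate core markers
#'
#' Filters per-locus statistics by design status, region class, missing rate,
#' MAF and PIC, ranks by PIC (descending, ties by contig then position),
#' enforces the spacing and per-contig caps in rank order, and truncates to
#' \code{target_count}. Returns all survivors with a warning when fewer than
#' \code{target_count} remain.
#'
#' @param stats \code{\link{locusStats}} table (needs id/contig/pos/maf/pic/
#'   missing_rate).
#' @param regions factor of \code{\link{classifyRegion}} labels aligned with
#'   \code{stats}.
#' @param panel KASP design table aligned by \code{marker_id} (only rows with
#'   status \code{"designed"} are eligible); pass \code{NULL} to skip the
#'   design requirement.
#' @param criteria a \code{\link{candidateScreenCriteria}} list.
#' @return character vector of marker ids, ranked.
#' @export
screenCandidates <- function(stats, regions = NULL, panel = NULL,
                             criteria = candidateScreenCriteria()) {
  df <- as.data.frame(stats[, c("id", "contig", "pos", "maf", "pic",
                                "missing_rate")])
  ok <- rep(TRUE, nrow(df))
  if (!is.null(panel)) {
    designed <- panel$marker_id[panel$status == "designed"]
    ok <- ok & df$id %in% designed
  }
  if (!is.null(regions) && !is.null(criteria$region))
    ok <- ok & as.character(regions) == criteria$region
  ok <- ok & !is.na(df$missing_rate) & df$missing_rate <= criteria$missing_max
  ok <- ok & !is.na(df$maf) & df$maf >= criteria$maf_min
  base <- ok & !is.na(df$pic)
  pref <- base & df$pic >= criteria$pic_min
  use <- if (sum(pref) >= criteria$target_count) pref
         else base & df$pic >= criteria$pic_fallback
  cand <- df[use, , drop = FALSE]
  cand <- cand[order(-cand$pic, cand$contig, cand$pos), , drop = FALSE]
  sel <- character(0); sel_contig <- character(0); sel_pos <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ctg <- cand$contig[i]; p <- cand$pos[i]
    if (sum(sel_contig == ctg) >= criteria$max_per_contig) next
    near <- sel_contig == ctg & abs(sel_pos - p) < criteria$min_spacing
    if (any(near)) next
    sel <- c(sel, cand$id[i])
    sel_contig <- c(sel_contig, ctg); sel_pos <- c(sel_pos, p)
    if (length(sel) >= criteria$target_count) break
  }
  if (length(sel) < criteria$target_count)
    warning("only ", length(sel), " candidate markers pass the screen ",
            "(target ", criteria$target_count, ")")
  sel
}

# per-marker resolved accession-pair logical matrix utilities
pairIndex <- function(n) {
  ut <- which(upper.tri(matrix(0, n, n)))
  list(idx = ut, n = n)
}

markerResolves <- function(x, marker) {
  cc <- alleleCodes(x)
  i <- if (is.character(marker)) match(marker, lociIds(x)) else marker
  if (is.na(i)) stop("marker not found: ", marker)
  g <- ifelse(is.na(cc$a1[i, ]), NA_integer_,
              cc$a1[i, ] * 16L + cc$a2[i, ])
  m <- outer(g, g, "!=") & !is.na(outer(g, g, function(a, b) a + b))
  m[upper.tri(m)]
}

#' Identification efficiency of a marker set
#'
#' Fraction of all accession pairs distinguished by at least one marker of
#' the set; a pair with a missing call at a marker is not distinguished by
#' that marker.
#'
#' @param x a \linkS4class{SnpGenotypes}.
#' @param markers character vector of marker (locus) ids, or indices.
#' @return efficiency in [0, 1].
#' @export
identificationEfficiency <- function(x, markers) {
  n <- ncol(x)
  if (n < 2L) stop("need at least 2 accessions")
  if (!length(markers)) return(0)
  resolved <- rep(FALSE, n * (n - 1L) / 2L)
  for (m in markers) resolved <- resolved | markerResolves(x, m)
  mean(resolved)
}

#' Select a minimal fully-discriminating core marker set
#'
#' Greedy maximum-coverage set cover over accession pairs: repeatedly add the
#' candidate resolving the most currently-unresolved pairs (ties broken by
#' higher PIC, then contig/position order), stopping when every resolvable
#' pair is covered or no candidate adds coverage; then prune any selected
#' marker whose removal keeps the achieved efficiency (yielding a
#' superset-minimal core). Pairs no candidate resolves (e.g. duplicated
#' accessions) are reported, not fatal.
#'
#' @param x a \linkS4class{SnpGenotypes}.
#' @param candidates character vector of candidate marker ids (the screening
#'   order is irrelevant).
#' @param stats optional \code{\link{locusStats}} table for PIC tie-breaks.
#' @return list with \code{core_markers}, \code{efficiency},
#'   \code{saturation} (data.frame of the greedy order and cumulative
#'   efficiency) and \code{unresolved_pairs} (data.frame, possibly empty).
#' @export
selectCoreMarkers <- function(x, candidates, stats = NULL) {
  if (!length(candidates)) stop("no candidate markers")
  if (is.null(stats)) stats <- locusStats(x[candidates, ])
  sdf <- as.data.frame(stats[, c("id", "contig", "pos", "pic")])
  sdf <- sdf[match(candidates, sdf$id), ]
  n <- ncol(x)
  npair <- n * (n - 1L) / 2L
  res_m <- vapply(candidates, function(m) markerResolves(x, m),
                  logical(npair))
  if (is.null(dim(res_m))) res_m <- matrix(res_m, nrow = npair)
  resolvable <- rowSums(res_m) > 0
  resolved <- rep(FALSE, npair)
  order_key <- order(-sdf$pic, sdf$contig, sdf$pos)
  rank_of <- integer(length(candidates)); rank_of[order_key] <- seq_along(order_key)
  chosen <- integer(0)
  curve <- data.frame(marker = character(0), efficiency = numeric(0))
  repeat {
    gains <- colSums(res_m & !resolved)
    gains[chosen] <- -1
    if (max(gains) <= 0) break
    best <- which(gains == max(gains))
    best <- best[order(rank_of[best])][1]
    chosen <- c(chosen, best)
    resolved <- resolved | res_m[, best]
    curve <- rbind(curve, data.frame(marker = candidates[best],
                                     efficiency = mean(resolved)))
    if (all(resolved)) break
  }
  achieved <- mean(resolved)
  # prune in reverse greedy order until superset-minimal
  repeat {
    dropped <- FALSE
    for (ci in rev(seq_along(chosen))) {
      keep <- chosen[-ci]
      eff <- if (length(keep))
        mean(Reduce(`|`, lapply(keep, function(b) res_m[, b]))) else 0
      if (eff >= achieved - 1e-12) {
        chosen <- keep; dropped <- TRUE; break
      }
    }
    if (!dropped) break
  }
  un <- which(!resolvable)
  pair_ids <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  unresolved <- which(!resolved)
  acc <- accessionIds(x)
  up <- pair_ids[unresolved, , drop = FALSE]
  list(core_markers = candidates[chosen],
       efficiency = achieved,
       saturation = curve,
       unresolved_pairs = data.frame(acc1 = acc[up[, 1]], acc2 = acc[up[, 2]]))
}

#' Build a DNA fingerprint table
#'
#' Accessions x core-marker genotype codes: homozygous calls as
#' \code{"A/A"}-style pure genotypes, heterozygous calls as the sorted allele
#' pair, missing calls as \code{"./."}. The uniqueness report lists every
#' accession pair that the marker set fails to distinguish (same semantics as
#' \code{\link{identificationEfficiency}}: a missing call never
#' distinguishes), so all rows are unique exactly when the set's
#' identification efficiency is 1.
#'
#' @param x a \linkS4class{SnpGenotypes}.
#' @param core_markers character vector of marker ids (non-empty).
#' @return list with \code{table} (character matrix accessions x markers),
#'   \code{classes} (\code{"hom"}/\code{"het"}/\code{"missing"} matrix),
#'   \code{indistinguishable_pairs} (data.frame) and \code{efficiency}.
#' @export
buildFingerprint <- function(x, core_markers) {
  if (!length(core_markers)) stop("empty core marker list")
  xs <- x[core_markers, ]
  gs <- t(genotypeStrings(xs))   # accessions x markers
  cls <- gs
  cc <- alleleCodes(xs)
  het <- t(cc$a1 != cc$a2)
  cls[!is.na(gs)] <- ifelse(het[!is.na(gs)], "het", "hom")
  cls[is.na(gs)] <- "missing"
  gs[is.na(gs)] <- "./."
  eff <- identificationEfficiency(x, core_markers)
  n <- ncol(x)
  resolved <- rep(FALSE, n * (n - 1L) / 2L)
  for (m in core_markers) resolved <- resolved | markerResolves(x, m)
  pair_ids <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  up <- pair_ids[!resolved, , drop = FALSE]
  acc <- accessionIds(x)
  list(table = gs, classes = cls,
       indistinguishable_pairs = data.frame(acc1 = acc[up[, 1]],
                                            acc2 = acc[up[, 2]]),
       efficiency = eff)
}
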