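# entry-to-nearest-entry objective: mean over selected accessions of the
# distance to the closest other selected accession (maximized)
eneObjective <- function(D, sel) {
  if (length(sel) < 2L) return(0)
  sub <- D[sel, sel, drop = FALSE]
  diag(sub) <- Inf
  mean(apply(sub, 1, min))
}

#' Select a core collection of accessions
#'
#' Picks \code{round(ratio * n)} accessions (minimum 2) maximizing the mean
#' entry-to-nearest-entry (E-NE) distance, one of the standard Core Hunter
#' objectives: greedy seeding (start from the most distant pair, repeatedly
#' add the accession whose distance to its nearest selected neighbour is
#' largest), followed by steepest-ascent swap local search until no swap
#' improves the objective. Fully deterministic; ties are broken by accession
#' order.
#'
#' @param x a \linkS4class{SnpGenotypes} or a symmetric distance matrix.
#' @param ratio sampling ratio in (0, 1].
#' @param seed integer recorded in the result (the search itself is
#'   deterministic).
#' @return a \linkS4class{CoreSet}.
#' @export
selectCore <- function(x, ratio, seed = 1L) {
  D <- if (is.matrix(x)) x else distanceMatrix(x)
  n <- nrow(D)
  ids <- rownames(D)
  if (ratio <= 0 || ratio > 1) stop("ratio must be in (0, 1]")
  k <- round(ratio * n)
  if (k < 2L) stop("ratio ", ratio, " yields fewer than 2 accessions")
  if (k >= n) {
    return(new("CoreSet", ids = ids, ratio = ratio,
               objective = eneObjective(D, seq_len(n)),
               seed = as.integer(seed)))
  }
  grow <- function(sel) {
    while (length(sel) < k) {
      cand <- setdiff(seq_len(n), sel)
      nn <- vapply(cand, function(c) min(D[c, sel]), numeric(1))
      sel <- sort(c(sel, cand[which.max(nn)]))
    }
    sel
  }
  polish <- function(sel) {
    repeat {
      cur <- eneObjective(D, sel)
      best <- cur; best_swap <- NULL
      for (s in sel) for (u in setdiff(seq_len(n), sel)) {
        val <- eneObjective(D, c(setdiff(sel, s), u))
        if (val > best + 1e-12) { best <- val; best_swap <- c(s, u) }
      }
      if (is.null(best_swap)) break
      sel <- sort(c(setdiff(sel, best_swap[1]), best_swap[2]))
    }
    sel
  }
  # deterministic multi-start: greedy seeding from each of the most distant
  # pairs plus, for every accession, the pair it forms with its farthest
  # partner (the swap neighbourhood has local optima; restarts escape them)
  Dz <- D; diag(Dz) <- -Inf
  ut <- which(upper.tri(Dz), arr.ind = TRUE)
  ord <- order(-Dz[ut], ut[, 1], ut[, 2])
  seeds <- lapply(head(ord, 10L), function(s) sort(as.integer(ut[s, ])))
  far <- max.col(Dz, ties.method = "first")
  seeds <- c(seeds, lapply(seq_len(n), function(i) sort(c(i, far[i]))))
  seeds <- unique(seeds)
  best_sel <- NULL; best_val <- -Inf
  for (sd in seeds) {
    sel <- polish(grow(sd))
    val <- eneObjective(D, sel)
    if (val > best_val + 1e-12) { best_val <- val; best_sel <- sel }
  }
  new("CoreSet", ids = ids[best_sel], ratio = ratio,
      objective = best_val, seed = as.integer(seed))
}

#' Evaluate the representativeness of a core collection
#'
#' Computes allele coverage (fraction of the alleles observed in the full
#' panel, pooled over loci, that are retained in the core) and the mean
#' diversity indices (Na, Ne, I, Ho, He, PIC, Nei's H) for the core and the
#' full set, with their core/full ratios. Evaluating the full set gives
#' coverage 1 and ratios 1.
#'
#' @param x a \linkS4class{SnpGenotypes}.
#' @param core a \linkS4class{CoreSet} or character vector of accession ids.
#' @return list with \code{allele_coverage}, \code{core_indices},
#'   \code{full_indices}, \code{index_ratios}, \code{n_core}, \code{n_full}.
#' @export
evaluateCore <- function(x, core) {
  ids <- if (is(core, "CoreSet")) coreIds(core) else as.character(core)
  if (!length(ids)) stop("empty core")
  if (!all(ids %in% accessionIds(x)))
    stop("core accessions absent from matrix: ",
         paste(setdiff(ids, accessionIds(x)), collapse = ", "))
  xc <- x[, ids]
  full_cnt <- alleleCountMatrix(x) > 0
  core_cnt <- alleleCountMatrix(xc) > 0
  if (ncol(core_cnt) < ncol(full_cnt))
    core_cnt <- cbind(core_cnt,
                      matrix(FALSE, nrow(core_cnt),
                             ncol(full_cnt) - ncol(core_cnt)))
  coverage <- sum(core_cnt & full_cnt) / sum(full_cnt)
  idx <- function(st) {
    ok <- st$defined
    c(na = mean(st$na[ok]), ne = mean(st$ne[ok]),
      shannon_i = mean(st$shannon_i[ok]), ho = mean(st$ho[ok]),
      he = mean(st$he[ok]), pic = mean(st$pic[ok]),
      nei_h = mean(st$nei_h[ok]))
  }
  ci <- idx(locusStats(xc)); fi <- idx(locusStats(x))
  list(allele_coverage = coverage, core_indices = ci, full_indices = fi,
       index_ratios = ci / fi, n_core = ncol(xc), n_full = ncol(x))
}

#' Sweep core-collection sampling ratios
#'
#' Runs \code{\link{selectCore}} + \code{\link{evaluateCore}} over a grid of
#' sampling ratios (default 5\%..95\% in steps of 5\%).
#'
#' @inheritParams evaluateCore
#' @param ratios numeric vector of sampling ratios.
#' @param seed integer seed recorded in each core set.
#' @return data.frame with one row per ratio (size, objective, allele
#'   coverage and mean index ratios).
#' @export
coreSweep <- function(x, ratios = seq(0.05, 0.95, by = 0.05), seed = 1L) {
  D <- distanceMatrix(x)
  rows <- lapply(ratios, function(r) {
    k <- round(r * nrow(D))
    if (k < 2L) return(NULL)
    cs <- selectCore(D, r, seed)
    ev <- evaluateCore(x, cs)
    data.frame(ratio = r, size = length(coreIds(cs)),
               objective = coreObjective(cs),
               allele_coverage = ev$allele_coverage,
               he_ratio = unname(ev$index_ratios["he"]),
               pic_ratio = unname(ev$index_ratios["pic"]),
               shannon_ratio = unname(ev$index_ratios["shannon_i"]),
               ids = paste(coreIds(cs), collapse = ","))
  })
  do.call(rbind, rows)
}
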