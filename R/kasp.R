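#' Universal KASP tail sequences
#'
#' The FAM and VIC universal 5' tails prepended verbatim to the two
#' allele-specific forward primers.
#'
#' @return named character vector with elements \code{FAM} and \code{VIC}.
#' @export
kaspTails <- function() {
  c(FAM = "GAAGGTGACCAAGTTCATGCT", VIC = "GAAGGTCGGAGTCAACGGATT")
}

#' KASP primer design constraints
#'
#' Thermodynamic and structural constraints applied to the *untailed* primer
#' cores: GC content below \code{gc_max} percent, melting temperature within
#' [\code{tm_min}, \code{tm_max}] degrees C, PCR product at most
#' \code{product_max} bp, primer length within \code{primer_len}, and
#' (optionally) no other known variant under any primer footprint.
#'
#' @param gc_max maximum GC percent (exclusive).
#' @param tm_min,tm_max allowed melting-temperature window, degrees C.
#' @param product_max maximum amplicon length, bp.
#' @param primer_len integer length range of the untailed primer core, nt.
#' @param forbid_variants reject candidates whose footprint overlaps another
#'   known variant.
#' @return list of class \code{DesignConstraints}.
#' @export
designConstraints <- function(gc_max = 60, tm_min = 55, tm_max = 61,
                              product_max = 120L, primer_len = c(18L, 30L),
                              forbid_variants = TRUE) {
  stopifnot(tm_min < tm_max, length(primer_len) == 2L)
  structure(list(gc_max = gc_max, tm_min = tm_min, tm_max = tm_max,
                 product_max = as.integer(product_max),
                 primer_len = as.integer(primer_len),
                 forbid_variants = isTRUE(forbid_variants)),
            class = "DesignConstraints")
}

#' GC content of a DNA sequence
#'
#' @param seq non-empty DNA string over A/C/G/T.
#' @return percent, 100 * (G + C) / length.
#' @export
gcContent <- function(seq) {
  s <- toupper(seq)
  if (!nzchar(s)) stop("empty sequence")
  b <- strsplit(s, "")[[1]]
  if (!all(b %in% c("A", "C", "G", "T")))
    stop("non-ACGT characters in sequence")
  100 * sum(b %in% c("G", "C")) / length(b)
}

# unified nearest-neighbor parameters (dH kcal/mol, dS cal/mol/K)
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
           GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
           TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
           GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           CC = -19.9)
NN_INIT_DH <- c(GC = 0.1, AT = 2.3)   # per terminal base pair
NN_INIT_DS <- c(GC = -2.8, AT = 4.1)

#' Melting temperature by nearest-neighbor thermodynamics
#'
#' Duplex Tm from the unified nearest-neighbor dH/dS parameter set with
#' terminal initiation terms, the entropic salt correction
#' 0.368 (N-1) ln[Na+], and the total-strand-concentration term
#' R ln(CT/4) for non-self-complementary duplexes (CT for self-complementary
#' ones, which also receive the symmetry entropy penalty). Deterministic
#' given the parameter table; defaults are 50 mM monovalent salt and 200 nM
#' primer.
#'
#' @param seq DNA string, length >= 8 nt.
#' @param Na monovalent cation concentration, mol/L.
#' @param primer_conc total primer concentration, mol/L.
#' @return Tm in degrees C.
#' @export
meltingTemp <- function(seq, Na = 0.05, primer_conc = 200e-9) {
  s <- toupper(seq)
  n <- nchar(s)
  if (n < 8L) stop("sequence too short for nearest-neighbor Tm (need >= 8 nt)")
  b <- strsplit(s, "")[[1]]
  if (!all(b %in% c("A", "C", "G", "T")))
    stop("non-ACGT characters in sequence")
  dinuc <- paste0(b[-n], b[-1L])
  dH <- sum(NN_DH[dinuc])
  dS <- sum(NN_DS[dinuc])
  termClass <- function(base) if (base %in% c("G", "C")) "GC" else "AT"
  dH <- dH + NN_INIT_DH[termClass(b[1L])] + NN_INIT_DH[termClass(b[n])]
  dS <- dS + NN_INIT_DS[termClass(b[1L])] + NN_INIT_DS[termClass(b[n])]
  selfcomp <- identical(s, revcomp(s))
  if (selfcomp) dS <- dS - 1.4
  dS <- dS + 0.368 * (n - 1L) * log(Na)
  x <- if (selfcomp) 1 else 4
  unname(1000 * dH / (dS + 1.987 * log(primer_conc / x)) - 273.15)
}

# first primer-core length whose untailed Tm/GC pass, or NA (with reason)
pickPrimerLen <- function(seqFor, lens, c) {
  reason <- "no_tm_window"
  for (L in lens) {
    s <- seqFor(L)
    if (is.null(s)) next
    if (gcContent(s) >= c$gc_max) { reason <- "gc_out_of_range"; next }
    tm <- meltingTemp(s)
    if (tm >= c$tm_min && tm <= c$tm_max)
      return(list(len = L, seq = s, tm = tm, gc = gcContent(s)))
  }
  list(len = NA_integer_, reason = reason)
}

failRow <- function(id, chrpos, alleles, reason) {
  data.frame(marker_id = id, chr_position = chrpos, allele_pair = alleles,
             f1 = NA_character_, f2 = NA_character_, r = NA_character_,
             strand = NA_character_, product_len = NA_integer_,
             f1_tm = NA_real_, f2_tm = NA_real_, r_tm = NA_real_,
             f1_gc = NA_real_, f2_gc = NA_real_, r_gc = NA_real_,
             status = paste0("failed(", reason, ")"),
             stringsAsFactors = FALSE)
}

#' Design a KASP assay for one biallelic SNP
#'
#' Builds the two allele-specific forward primers (3' base = each SNP allele,
#' 5' length adjusted independently within the allowed range until the
#' untailed core's Tm falls in the constraint window) plus a common reverse
#' primer on the opposite strand, scanning outward from the SNP and taking
#' the first window satisfying all constraints (deterministic). If no
#' combination works on the plus strand the design is retried with the
#' primers on the minus strand. Any primer footprint overlapping another
#' known variant is rejected when \code{forbid_variants} is set. The FAM/VIC
#' tails are prepended verbatim to the two forwards.
#'
#' @param x a \linkS4class{SnpGenotypes} (for the locus record), or a one-row
#'   \code{GRanges} with \code{ref}/\code{alt} metadata.
#' @param locus locus identifier (rowname) or index in \code{x}.
#' @param genome a \link[Biostrings]{DNAStringSet}.
#' @param variant_positions optional data.frame with columns
#'   \code{contig}/\code{pos} of every known variant (defaults to the loci of
#'   \code{x}); the target SNP itself is always allowed under the forwards.
#' @param constraints a \code{\link{designConstraints}} list.
#' @return one-row data.frame (primer sequences, Tm/GC of the untailed cores,
#'   product length, design strand, and \code{status} "designed" or
#'   "failed(reason)").
#' @export
designKasp <- function(x, locus, genome, variant_positions = NULL,
                       constraints = designConstraints()) {
  if (is(x, "SnpGenotypes")) {
    rr <- SummarizedExperiment::rowRanges(x)
    if (is.null(variant_positions))
      variant_positions <- data.frame(
        contig = as.character(GenomeInfoDb::seqnames(rr)),
        pos = GenomicRanges::start(rr))
    i <- if (is.character(locus)) match(locus, lociIds(x)) else as.integer(locus)
    if (is.na(i)) stop("locus not found: ", locus)
    rec <- rr[i]
  } else rec <- x
  alts <- strsplit(as.character(S4Vectors::mcols(rec)$alt), ",")[[1]]
  if (length(alts) != 1L) stop("KASP design requires a biallelic SNP")
  refb <- as.character(S4Vectors::mcols(rec)$ref)
  contig <- as.character(GenomeInfoDb::seqnames(rec))
  pos <- GenomicRanges::start(rec)
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  clen <- Biostrings::width(genome[contig])
  id <- names(rec) %||% paste0(contig, "_", pos)
  chrpos <- paste0(contig, "_", pos)
  alleles <- paste0(refb, "/", alts)
  c <- constraints
  vp <- variant_positions
  other <- if (!is.null(vp)) vp$pos[vp$contig == contig & vp$pos != pos]
           else integer(0)
  hasVar <- function(a, b) c$forbid_variants && any(other >= a & other <= b)
  gseq <- genome[[contig]]
  lens <- seq(c$primer_len[1], c$primer_len[2])
  tails <- kaspTails()

  tryStrand <- function(strand) {
    # forward cores, one per allele, 3' terminating at the SNP
    mkFor <- function(allele) {
      pickPrimerLen(function(L) {
        if (strand == "+") {
          a <- pos - L + 1L
          if (a < 1L) return(NULL)
          if (hasVar(a, pos - 1L)) return(NULL)
          paste0(as.character(Biostrings::subseq(gseq, a, pos - 1L)), allele)
        } else {
          b <- pos + L - 1L
          if (b > clen) return(NULL)
          if (hasVar(pos + 1L, b)) return(NULL)
          revcomp(paste0(allele,
                         as.character(Biostrings::subseq(gseq, pos + 1L, b))))
        }
      }, lens, c)
    }
    f1 <- mkFor(refb); f2 <- mkFor(alts)
    if (is.na(f1$len) || is.na(f2$len)) {
      # distinguish a variant blockade from a thermodynamic failure
      blocked <- if (strand == "+") hasVar(pos - c$primer_len[1] + 1L, pos - 1L)
                 else hasVar(pos + 1L, pos + c$primer_len[1] - 1L)
      return(list(ok = FALSE,
                  reason = if (blocked) "variant_under_primer"
                           else (f1$reason %||% f2$reason)))
    }
    lf <- max(f1$len, f2$len)
    # reverse primer on the opposite side, first acceptable window outward
    found <- NULL; saw_site <- FALSE
    if (strand == "+") {
      amp_start <- pos - lf + 1L
      if (pos + 1L > clen) return(list(ok = FALSE, reason = "edge"))
      for (q in (pos + 1L):min(clen, pos + c$product_max)) {
        for (Lr in lens) {
          e <- q + Lr - 1L
          if (e > clen) break
          plen <- e - amp_start + 1L
          if (plen > c$product_max) break
          saw_site <- TRUE
          if (hasVar(q, e)) next
          rseq <- revcomp(as.character(Biostrings::subseq(gseq, q, e)))
          if (gcContent(rseq) >= c$gc_max) next
          tm <- meltingTemp(rseq)
          if (tm < c$tm_min || tm > c$tm_max) next
          found <- list(seq = rseq, tm = tm, plen = plen); break
        }
        if (!is.null(found)) break
      }
    } else {
      amp_end <- pos + lf - 1L
      if (pos - 1L < 1L) return(list(ok = FALSE, reason = "edge"))
      for (q in (pos - 1L):max(1L, pos - c$product_max)) {
        for (Lr in lens) {
          a <- q - Lr + 1L
          if (a < 1L) break
          plen <- amp_end - a + 1L
          if (plen > c$product_max) break
          saw_site <- TRUE
          if (hasVar(a, q)) next
          rseq <- as.character(Biostrings::subseq(gseq, a, q))
          if (gcContent(rseq) >= c$gc_max) next
          tm <- meltingTemp(rseq)
          if (tm < c$tm_min || tm > c$tm_max) next
          found <- list(seq = rseq, tm = tm, plen = plen); break
        }
        if (!is.null(found)) break
      }
    }
    if (is.null(found))
      return(list(ok = FALSE,
                  reason = if (saw_site) "no_reverse_primer" else "no_reverse_site"))
    list(ok = TRUE, f1 = f1, f2 = f2, r = found, strand = strand)
  }

  res <- tryStrand("+")
  if (!res$ok) {
    res2 <- tryStrand("-")
    if (res2$ok) res <- res2
  }
  if (!res$ok) return(failRow(id, chrpos, alleles, res$reason))
  data.frame(marker_id = id, chr_position = chrpos, allele_pair = alleles,
             f1 = paste0(tails["FAM"], res$f1$seq),
             f2 = paste0(tails["VIC"], res$f2$seq),
             r = res$r$seq, strand = res$strand,
             product_len = res$r$plen,
             f1_tm = res$f1$tm, f2_tm = res$f2$tm, r_tm = res$r$tm,
             f1_gc = res$f1$gc, f2_gc = res$f2$gc,
             r_gc = gcContent(res$r$seq),
             status = "designed", stringsAsFactors = FALSE)
}

#' Design KASP assays for every locus of a panel
#'
#' @inheritParams designKasp
#' @return data.frame with one row per locus (see \code{\link{designKasp}}).
#' @export
designKaspPanel <- function(x, genome, variant_positions = NULL,
                            constraints = designConstraints()) {
  rr <- SummarizedExperiment::rowRanges(x)
  if (is.null(variant_positions))
    variant_positions <- data.frame(
      contig = as.character(GenomeInfoDb::seqnames(rr)),
      pos = GenomicRanges::start(rr))
  rows <- lapply(seq_len(nrow(x)), function(i)
    designKasp(x, i, genome, variant_positions, constraints))
  do.call(rbind, rows)
}

#' KASP conversion (transformation) rate
#'
#' @param panel data.frame from \code{\link{designKaspPanel}} (needs a
#'   \code{status} column).
#' @return percent of assays with status \code{"designed"}.
#' @export
conversionRate <- function(panel) {
  if (is.null(panel) || nrow(panel) == 0L) stop("empty panel")
  100 * mean(panel$status == "designed")
}

#' Structural validation of KASP primer sets
#'
#' Checks, for each assay: the FAM/VIC universal tails are verbatim 5'
#' prefixes of the two forwards; the untailed forwards 3'-terminate in the
#' listed allele pair (directly, or as its complement when the assay was
#' designed on the minus strand -- consistently across both primers); and the
#' two untailed cores are identical over their 3'-proximal overlap except
#' the terminal allele base and any 5' length adjustment.
#'
#' @param panel data.frame with columns \code{f1}, \code{f2} (tailed
#'   forwards), \code{allele_pair} (e.g. \code{"A/G"}) and optionally
#'   \code{marker_id}.
#' @return data.frame of per-assay logical checks plus an overall \code{pass}.
#' @export
validateKaspStructure <- function(panel) {
  tails <- kaspTails()
  res <- lapply(seq_len(nrow(panel)), function(i) {
    f1 <- panel$f1[i]; f2 <- panel$f2[i]
    al <- strsplit(panel$allele_pair[i], "/")[[1]]
    tail_ok <- startsWith(f1, tails["FAM"]) && startsWith(f2, tails["VIC"])
    c1 <- substring(f1, nchar(tails["FAM"]) + 1L)
    c2 <- substring(f2, nchar(tails["VIC"]) + 1L)
    e1 <- substring(c1, nchar(c1)); e2 <- substring(c2, nchar(c2))
    allele_ok <- (e1 == al[1] && e2 == al[2]) ||
      (e1 == compBase(al[1]) && e2 == compBase(al[2]))
    b1 <- substring(c1, 1, nchar(c1) - 1L)
    b2 <- substring(c2, 1, nchar(c2) - 1L)
    k <- min(nchar(b1), nchar(b2))
    core_ok <- substring(b1, nchar(b1) - k + 1L) ==
      substring(b2, nchar(b2) - k + 1L)
    data.frame(marker_id = panel$marker_id[i] %||% i,
               tails_verbatim = tail_ok, terminal_allele = allele_ok,
               shared_core = core_ok,
               pass = tail_ok && allele_ok && core_ok)
  })
  do.call(rbind, res)
}
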