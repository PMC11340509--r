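#' Pipeline run configuration
#'
#' Exactly one of \code{vcf}/\code{fasta}(/\code{gff}) input paths or a
#' \code{simulate} block must be given. One root seed is propagated to every
#' stochastic step through \code{\link{deriveSeed}}.
#'
#' @param vcf,fasta,gff input file paths (multi-sample VCF, reference FASTA,
#'   gene-model GFF3). \code{gff} is optional (annotation is skipped without
#'   it).
#' @param simulate a \code{\link{simulationConfig}} to generate the inputs
#'   instead.
#' @param thresholds a \code{\link{filterThresholds}} list.
#' @param constraints a \code{\link{designConstraints}} list.
#' @param screen a \code{\link{candidateScreenCriteria}} list.
#' @param core_ratio core-collection sampling ratio (single value) used for
#'   the main run; use \code{\link{coreSweep}} for the full grid.
#' @param outdir output directory.
#' @param seed root seed.
#' @return list of class \code{RunConfig}.
#' @export
pipelineConfig <- function(vcf = NULL, fasta = NULL, gff = NULL,
                           simulate = NULL,
                           thresholds = filterThresholds(),
                           constraints = designConstraints(),
                           screen = candidateScreenCriteria(),
                           core_ratio = 0.3,
                           outdir = tempfile("kaspanel_run_"),
                           seed = 1L) {
  has_paths <- !is.null(vcf) || !is.null(fasta)
  if (has_paths == !is.null(simulate))
    stop("exactly one of input paths (vcf + fasta) or a simulate block ",
         "must be provided")
  if (has_paths) {
    if (is.null(vcf) || is.null(fasta))
      stop("both vcf and fasta paths are required")
    for (p in c(vcf, fasta, if (!is.null(gff)) gff))
      if (!file.exists(p)) stop("input file not found: ", p)
  }
  structure(list(vcf = vcf, fasta = fasta, gff = gff, simulate = simulate,
                 thresholds = thresholds, constraints = constraints,
                 screen = screen, core_ratio = core_ratio,
                 outdir = outdir, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Run the full identification pipeline
#'
#' Executes, in dependency order: (optional) simulation of the fixture,
#' variant reading, the filter cascade, annotation, per-locus statistics,
#' distance/NJ tree/PCA, core-collection selection, KASP design, candidate
#' screening, core-marker selection with its saturation curve, and
#' fingerprint construction. All artifacts are written under
#' \code{config$outdir}; a manifest JSON lists every emitted file with its
#' MD5 checksum, so two runs with the same config and seed are byte-identical.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return the manifest, invisibly (list with \code{files} and
#'   \code{counts}).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  emitted <- character(0)
  emit <- function(p) { emitted <<- c(emitted, p); p }

  if (!is.null(config$simulate)) {
    cfg <- config$simulate
    cfg$seed <- deriveSeed(config$seed, "simulate")
    fx <- simulateFixture(cfg, file.path(out, "fixture"))
    vcf_path <- fx$paths$vcf; fasta_path <- fx$paths$fasta
    gff_path <- fx$paths$gff
    for (p in unlist(fx$paths)) emit(p)
  } else {
    vcf_path <- config$vcf; fasta_path <- config$fasta
    gff_path <- config$gff
  }

  genome <- readReference(fasta_path)
  models <- if (!is.null(gff_path)) readGeneModels(gff_path) else NULL
  x <- readVariants(vcf_path)

  casc <- filterCascade(x, genome, config$thresholds)
  surv <- casc$genotypes
  writeTsv(filterStages(casc$report), emit(file.path(out, "filter_report.tsv")))
  writeJson(list(stages = filterStages(casc$report)),
            emit(file.path(out, "filter_report.json")))
  writeVariants(surv, emit(file.path(out, "survivors.vcf")),
                setNames(Biostrings::width(genome), names(genome)))

  # high-quality set for population genetics: hard + quality predicates only
  hq_keep <- hardFilterKeep(x, config$thresholds) &
    qualityFilterKeep(x, config$thresholds)
  hq <- x[hq_keep, ]

  spec <- substitutionSpectrum(hq)
  writeJson(list(transitions = spec$transitions,
                 transversions = spec$transversions,
                 ts_tv = spec$ts_tv, het_count = spec$het_count,
                 hom_count = spec$hom_count, n_loci = spec$n_loci,
                 type_counts = as.list(spec$type_counts)),
            emit(file.path(out, "spectrum.json")))

  ann_df <- NULL
  if (!is.null(models)) {
    regions <- classifyRegion(hq, models)
    effects <- classifyCodingEffect(hq, models, genome)
    ann_df <- data.frame(id = lociIds(hq), region = as.character(regions),
                         effect = as.character(effects))
    writeTsv(ann_df, emit(file.path(out, "annotation.tsv")))
  }

  st <- locusStats(hq)
  writeTsv(as.data.frame(st), emit(file.path(out, "locus_stats.tsv")))

  D <- distanceMatrix(hq)
  writeTsv(data.frame(accession = rownames(D), as.data.frame(D)),
           emit(file.path(out, "distance.tsv")))
  writeLines(njTree(D), emit(file.path(out, "nj_tree.nwk")))

  pca <- pcaGenotypes(hq)
  writeTsv(data.frame(accession = rownames(pca$coordinates),
                      round(pca$coordinates[, seq_len(min(10, ncol(pca$coordinates))),
                                            drop = FALSE], 6)),
           emit(file.path(out, "pca_coords.tsv")))
  writeTsv(data.frame(component = seq_along(pca$variance_fraction),
                      variance_fraction = round(pca$variance_fraction, 6)),
           emit(file.path(out, "pca_variance.tsv")))

  core <- selectCore(D, config$core_ratio, deriveSeed(config$seed, "core"))
  ev <- evaluateCore(hq, core)
  writeTsv(data.frame(accession = coreIds(core)),
           emit(file.path(out, "core_collection.tsv")))
  writeJson(list(ratio = core@ratio, objective = coreObjective(core),
                 allele_coverage = ev$allele_coverage,
                 core_indices = as.list(ev$core_indices),
                 full_indices = as.list(ev$full_indices),
                 index_ratios = as.list(ev$index_ratios)),
            emit(file.path(out, "core_evaluation.json")))

  panel <- designKaspPanel(surv, genome,
                           variant_positions = data.frame(
                             contig = as.character(GenomeInfoDb::seqnames(
                               SummarizedExperiment::rowRanges(x))),
                             pos = GenomicRanges::start(
                               SummarizedExperiment::rowRanges(x))),
                           constraints = config$constraints)
  writeTsv(panel, emit(file.path(out, "kasp_panel.tsv")))
  writeJson(list(designed = sum(panel$status == "designed"),
                 total = nrow(panel),
                 conversion_rate = conversionRate(panel)),
            emit(file.path(out, "kasp_conversion.json")))

  surv_st <- st[match(lociIds(surv), st$id), ]
  surv_regions <- if (!is.null(ann_df))
    ann_df$region[match(lociIds(surv), ann_df$id)] else NULL
  cand <- withCallingHandlers(
    screenCandidates(surv_st, surv_regions, panel, config$screen),
    warning = function(w) invokeRestart("muffleWarning"))
  writeTsv(data.frame(marker_id = cand),
           emit(file.path(out, "candidate_markers.tsv")))

  counts <- list(
    input_loci = nrow(x), survivors = nrow(surv),
    high_quality = nrow(hq), designed = sum(panel$status == "designed"),
    candidates = length(cand))

  if (length(cand)) {
    sel <- selectCoreMarkers(x, cand, stats = st[match(cand, st$id), ])
    writeTsv(sel$saturation, emit(file.path(out, "saturation_curve.tsv")))
    writeTsv(data.frame(marker_id = sel$core_markers),
             emit(file.path(out, "core_markers.tsv")))
    fp <- buildFingerprint(x, sel$core_markers)
    writeTsv(data.frame(accession = rownames(fp$table), fp$table,
                        check.names = FALSE),
             emit(file.path(out, "fingerprint.tsv")))
    writeJson(list(core_markers = sel$core_markers,
                   efficiency = sel$efficiency,
                   indistinguishable_pairs = fp$indistinguishable_pairs),
              emit(file.path(out, "fingerprint.json")))
    counts$core_markers <- length(sel$core_markers)
    counts$identification_efficiency <- sel$efficiency
  }

  rel <- ifelse(startsWith(emitted, paste0(out, "/")),
                substring(emitted, nchar(out) + 2L), basename(emitted))
  manifest <- list(
    files = data.frame(file = rel, md5 = unname(tools::md5sum(emitted))),
    counts = counts, seed = config$seed)
  writeJson(manifest, file.path(out, "manifest.json"))
  invisible(manifest)
}
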