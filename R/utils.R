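#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowRanges
#' @importFrom S4Vectors mcols DataFrame
#' @importFrom stats prcomp rbeta rbinom rpois runif setNames var
#' @importFrom utils write.table read.delim combn head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific random seed from a root seed
#'
#' Stage seeds are derived by stable hashing of the stage name so that adding
#' pipeline stages never perturbs the randomness consumed by earlier ones.
#' Results stay below 2^31 - 1.
#'
#' @param seed integer root seed.
#' @param stage character stage name.
#' @return An integer seed.
#' @export
deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147480009
  as.integer((as.numeric(seed) + h) %% 2147480009 + 1)
}

COMP_BASE <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(s) {
  vapply(s, function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  }, character(1), USE.NAMES = FALSE)
}

compBase <- function(b) unname(COMP_BASE[toupper(b)])

writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# numeric formatting for VCF emission: plain decimal, no scientific notation
fmtNum <- function(x, digits = 2) {
  ifelse(is.na(x), ".", formatC(round(x, digits), format = "f", digits = digits))
}
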