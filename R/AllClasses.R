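#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand
NULL

#' Simulation configuration for synthetic nanopore reads
#'
#' Holds every tunable parameter of the read simulator: the toy transcriptome
#' geometry, background and modified-site error rates, the geometric 5'
#' truncation probability that produces 3' coverage bias, the chimera
#' fraction, the cDNA-mode strand bias, and the pass/fail mean-quality mixture.
#'
#' @slot n_transcripts number of transcripts to place on the toy genome.
#' @slot len_min,len_max,len_mean transcript length distribution (bases);
#'   lengths are drawn from a gamma distribution with mean `len_mean` and
#'   clamped to `[len_min, len_max]`.
#' @slot coverage_per_transcript mean number of reads per transcript
#'   (Poisson-distributed, scaled by the transcript's relative abundance).
#' @slot abundance_sdlog log-normal sd of per-transcript relative abundance
#'   (mean 1); default 1, about one decade of spread between lowly and
#'   highly expressed transcripts. 0 gives uniform expression.
#' @slot p_err_bg per-base background error probability (default 0.12,
#'   matching the ~88% read identity regime of nanopore RNA reads).
#' @slot p_err_mod per-base error probability at modified sites; must exceed
#'   `p_err_bg`.
#' @slot err_split length-3 probability vector splitting errors into
#'   substitution / insertion / deletion (default 0.6/0.2/0.2).
#' @slot mods_per_kb expected planted modification sites per kilobase.
#' @slot truncation_p per-base probability that the molecule is lost from the
#'   5' end: read length back from the 3' anchor is geometric with this
#'   parameter, censored at the transcript length. 0 disables truncation.
#' @slot chimera_frac probability a read is emitted as a chimeric
#'   primary + supplementary pair.
#' @slot fwd_strand_frac cdna mode only: probability a read reports the
#'   forward (first-strand) orientation.
#' @slot q_pass_frac fraction of reads drawn with mean quality >= 7.
#' @slot min_read_len floor on simulated read length (default 50, below the
#'   200-base QC cutoff so the length filter is exercised).
#' @slot seed integer RNG seed; recorded in output headers.
#' @slot mode `"rna"` (3'-anchored, strand follows the transcript) or
#'   `"cdna"` (orientation drawn with `fwd_strand_frac`).
#'
#' @seealso [simulationConfig()], [simulateReads()]
#' @export
setClass("SimulationConfig",
  representation(
    n_transcripts = "integer",
    len_min = "integer", len_max = "integer", len_mean = "numeric",
    coverage_per_transcript = "numeric",
    abundance_sdlog = "numeric",
    p_err_bg = "numeric", p_err_mod = "numeric",
    err_split = "numeric",
    mods_per_kb = "numeric",
    truncation_p = "numeric",
    chimera_frac = "numeric",
    fwd_strand_frac = "numeric",
    q_pass_frac = "numeric",
    min_read_len = "integer",
    seed = "integer",
    mode = "character"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  probs <- c(
    p_err_bg = object@p_err_bg, p_err_mod = object@p_err_mod,
    truncation_p = object@truncation_p, chimera_frac = object@chimera_frac,
    fwd_strand_frac = object@fwd_strand_frac, q_pass_frac = object@q_pass_frac
  )
  bad <- probs < 0 | probs > 1 | !is.finite(probs)
  if (any(bad))
    msg <- c(msg, paste0("probabilities outside [0,1]: ",
                         paste(names(probs)[bad], collapse = ", ")))
  if (object@p_err_mod <= object@p_err_bg)
    msg <- c(msg, "p_err_mod must exceed p_err_bg")
  if (object@n_transcripts < 1L)
    msg <- c(msg, "n_transcripts must be >= 1")
  if (length(object@err_split) != 3L || any(object@err_split < 0) ||
      abs(sum(object@err_split) - 1) > 1e-8)
    msg <- c(msg, "err_split must be 3 non-negative values summing to 1")
  if (object@len_min < 1L || object@len_max < object@len_min ||
      object@len_mean < object@len_min || object@len_mean > object@len_max)
    msg <- c(msg, "need len_min <= len_mean <= len_max with len_min >= 1")
  if (!object@mode %in% c("rna", "cdna"))
    msg <- c(msg, "mode must be 'rna' or 'cdna'")
  if (object@mods_per_kb < 0)
    msg <- c(msg, "mods_per_kb must be non-negative")
  if (object@abundance_sdlog < 0)
    msg <- c(msg, "abundance_sdlog must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimulationConfig compact parameter listing.
#' @param object a `SimulationConfig`.
#' @export
setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig (", object@mode, " mode, seed ", object@seed, ")\n",
      sep = "")
  cat("  transcripts: ", object@n_transcripts, " of ", object@len_min, "-",
      object@len_max, " b (mean ", object@len_mean, "), coverage ",
      object@coverage_per_transcript, "x\n", sep = "")
  cat("  errors: bg ", object@p_err_bg, ", mod ", object@p_err_mod,
      " (sub/ins/del ", paste(object@err_split, collapse = "/"), "), ",
      object@mods_per_kb, " mod sites/kb\n", sep = "")
  cat("  truncation_p ", object@truncation_p, ", chimera_frac ",
      object@chimera_frac, ", fwd_strand_frac ", object@fwd_strand_frac,
      ", q_pass_frac ", object@q_pass_frac, "\n", sep = "")
})

#' Background error model for the site test
#'
#' The null model of the per-site modification test: the error probability
#' expected at a position absent modification. Three modes are supported:
#' `"constant"` (one genome-wide rate `p0`), `"context"` (a 5-mer table of
#' rates, with a `"default"` fallback entry), and `"paired_control"` (error
#' counts taken from a matched control pileup at the same site, mirroring a
#' direct ESB-vs-ESB comparison design).
#'
#' @slot mode one of `"constant"`, `"context"`, `"paired_control"`.
#' @slot p0 background error probability (constant mode).
#' @slot context_table named numeric vector mapping 5-mers to probabilities;
#'   a `"default"` entry supplies the fallback for missing contexts.
#' @slot control a site pileup `GRanges` (see [computePileup()]) used as the
#'   paired control.
#'
#' @seealso [backgroundModel()], [testSites()]
#' @export
setClass("BackgroundModel",
  representation(
    mode = "character",
    p0 = "numeric",
    context_table = "numeric",
    control = "ANY"
  )
)

setValidity("BackgroundModel", function(object) {
  msg <- character()
  if (!object@mode %in% c("constant", "context", "paired_control"))
    msg <- c(msg, "mode must be constant, context or paired_control")
  if (object@mode == "constant" &&
      (length(object@p0) != 1L || object@p0 <= 0 || object@p0 >= 1))
    msg <- c(msg, "p0 must be a single probability in (0,1)")
  if (object@mode == "context") {
    tb <- object@context_table
    if (!length(tb) || is.null(names(tb)))
      msg <- c(msg, "context mode needs a named context_table")
    else if (any(tb <= 0 | tb >= 1))
      msg <- c(msg, "context_table probabilities must lie in (0,1)")
    else if (length(tb) < 1024L && !"default" %in% names(tb))
      msg <- c(msg, "context_table must cover all 1024 5-mers or supply a 'default' fallback")
  }
  if (object@mode == "paired_control" && !is(object@control, "GRanges"))
    msg <- c(msg, "paired_control mode needs a control pileup GRanges")
  if (length(msg)) msg else TRUE
})

#' @describeIn BackgroundModel one-line description of the model.
#' @param object a `BackgroundModel`.
#' @export
setMethod("show", "BackgroundModel", function(object) {
  cat("BackgroundModel, mode:", object@mode)
  if (object@mode == "constant") cat(" (p0 =", object@p0, ")")
  if (object@mode == "context")
    cat(" (", length(object@context_table), "contexts )")
  if (object@mode == "paired_control")
    cat(" (", length(object@control), "control sites )")
  cat("\n")
})

#' Per-read alignment records
#'
#' A thin container around a `DataFrame` of SAM-level read records carrying
#' exactly the fields the QC and pileup layers need: flags, position, CIGAR,
#' sequence, per-read mean quality, edit distance (NM) and the supplementary
#' alignment tag (SA). Unmapped reads are retained (with NA position fields)
#' so that read classification can account for every read name.
#'
#' The per-read mean quality is the standard per-read Q: Phred scores are
#' converted to error probabilities, averaged, and converted back, i.e.
#' `-10*log10(mean(10^(-q/10)))`.
#'
#' @slot records a `DataFrame` with columns `read_id`, `flag`, `ref`, `pos`,
#'   `mapq`, `cigar`, `seq`, `qual`, `nm`, `sa`, `read_length`, `mean_q`,
#'   `strand`.
#'
#' @seealso [readAlignmentRecords()], [classifyReads()], [summarizeQc()]
#' @export
setClass("ReadRecords", representation(records = "DataFrame"))

.readrec_cols <- c("read_id", "flag", "ref", "pos", "mapq", "cigar", "seq",
                   "qual", "nm", "sa", "read_length", "mean_q", "strand")

setValidity("ReadRecords", function(object) {
  df <- object@records
  miss <- setdiff(.readrec_cols, colnames(df))
  if (length(miss))
    return(paste("missing record columns:", paste(miss, collapse = ", ")))
  if (nrow(df)) {
    if (any(!is.na(df$nm) & df$nm < 0)) return("NM must be >= 0")
    if (any(!is.na(df$mean_q) & df$mean_q < 0)) return("mean_q must be >= 0")
    mapped <- !bitwAnd(df$flag, 0x4)
    if (any(mapped & (is.na(df$cigar) | df$cigar == "*")))
      return("mapped records must have a CIGAR")
  }
  TRUE
})

#' @describeIn ReadRecords number of records (alignment lines, not read names).
#' @param x a `ReadRecords`.
#' @export
setMethod("length", "ReadRecords", function(x) nrow(x@records))

#' @describeIn ReadRecords summary of the container.
#' @param object a `ReadRecords`.
#' @export
setMethod("show", "ReadRecords", function(object) {
  df <- object@records
  cat("ReadRecords:", nrow(df), "records,",
      length(unique(df$read_id)), "read names\n")
  if (nrow(df)) {
    fl <- df$flag
    cat("  unmapped:", sum(bitwAnd(fl, 0x4) > 0),
        " secondary:", sum(bitwAnd(fl, 0x100) > 0),
        " supplementary:", sum(bitwAnd(fl, 0x800) > 0), "\n")
  }
})

#' Extract the record table
#'
#' @param x a `ReadRecords` object.
#' @return the underlying `DataFrame` of SAM-level records.
#' @export
readRecords <- function(x) {
  stopifnot(is(x, "ReadRecords"))
  x@records
}

#' Construct ReadRecords from a record table
#'
#' @param records a `DataFrame` or `data.frame` with the columns documented
#'   in [ReadRecords-class].
#' @return a `ReadRecords` object.
#' @export
ReadRecords <- function(records) {
  new("ReadRecords", records = as(records, "DataFrame"))
}

#' Stratified 2x2 error tables for differential testing
#'
#' For each candidate site, K replicate-paired 2x2 tables comparing error /
#' non-error counts between condition A and condition B; the input of the
#' Cochran-Mantel-Haenszel test. Cells are stored as site-by-stratum
#' matrices: `a` = errors in A, `b` = non-errors in A, `c` = errors in B,
#' `d` = non-errors in B.
#'
#' @slot sites a `GRanges` of site keys (position and strand).
#' @slot a,b,c,d numeric matrices, sites x strata.
#'
#' @seealso [buildStrata()], [cmhTest()], [mhCommonOR()]
#' @export
setClass("StratifiedTables",
  representation(sites = "GRanges",
                 a = "matrix", b = "matrix", c = "matrix", d = "matrix")
)

setValidity("StratifiedTables", function(object) {
  dims <- vapply(list(object@a, object@b, object@c, object@d), dim,
                 integer(2))
  if (any(dims[1, ] != length(object@sites)))
    return("cell matrices must have one row per site")
  if (length(unique(dims[2, ])) != 1L)
    return("cell matrices must agree on the number of strata")
  if (ncol(object@a) < 1L) return("need at least one stratum (K >= 1)")
  if (any(c(object@a, object@b, object@c, object@d) < 0))
    return("all cells must be non-negative")
  TRUE
})

#' @describeIn StratifiedTables number of sites.
#' @param x a `StratifiedTables`.
#' @export
setMethod("length", "StratifiedTables", function(x) length(x@sites))

#' @describeIn StratifiedTables summary of sites and strata.
#' @param object a `StratifiedTables`.
#' @export
setMethod("show", "StratifiedTables", function(object) {
  cat("StratifiedTables:", length(object@sites), "sites x",
      ncol(object@a), "strata (replicate pairs)\n")
})

#' Number of strata (replicate pairs)
#'
#' @param x a `StratifiedTables` object.
#' @return integer K, the number of replicate pairs.
#' @export
nStrata <- function(x) {
  stopifnot(is(x, "StratifiedTables"))
  ncol(x@a)
}

#' Site keys of a StratifiedTables object
#'
#' @param x a `StratifiedTables` object.
#' @return the `GRanges` of site keys.
#' @export
strataSites <- function(x) {
  stopifnot(is(x, "StratifiedTables"))
  x@sites
}
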