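#' @importFrom Rsamtools asBam scanBam ScanBamParam scanBamFlag
#' @importFrom GenomicAlignments cigarOpTable cigarWidthAlongQuerySpace
#'   cigarWidthAlongReferenceSpace
#' @importFrom utils head write.table
NULL

#' Read SAM/BAM alignment records
#'
#' Loads all records (including unmapped, secondary and supplementary) from
#' a SAM or BAM file into a [ReadRecords-class]. Per-read mean quality is
#' computed the standard way: Phred scores are converted to error
#' probabilities, averaged over the read, and converted back to the Phred
#' scale.
#'
#' @param file path to a SAM or BAM file (SAM is converted on the fly).
#' @return a [ReadRecords-class].
#' @export
readAlignmentRecords <- function(file) {
  if (grepl("\\.sam$", file, ignore.case = TRUE))
    file <- asBam(file, destination = tempfile(), overwrite = TRUE,
                  indexDestination = FALSE)
  p <- ScanBamParam(what = c("qname", "flag", "rname", "pos", "mapq",
                             "cigar", "seq", "qual"),
                    tag = c("NM", "SA"))
  x <- scanBam(file, param = p)[[1]]
  ql <- as(x$qual, "IntegerList")
  n_b <- S4Vectors::elementNROWS(ql)
  perr <- sum(methods::as(10^(-methods::as(ql, "NumericList") / 10),
                          "NumericList"))
  ## rounded beyond Phred resolution so constant-quality reads land exactly
  ## on their nominal score (the pass cutoff at 7 is inclusive)
  mean_q <- ifelse(n_b > 0,
                   round(-10 * log10(perr / pmax(n_b, 1L)), 6L), NA_real_)
  seqc <- as.character(x$seq)
  rl <- Biostrings::width(x$seq)
  unmapped <- bitwAnd(x$flag, 0x4) > 0L
  df <- DataFrame(
    read_id = x$qname,
    flag = x$flag,
    ref = ifelse(unmapped, NA_character_, as.character(x$rname)),
    pos = ifelse(unmapped, NA_integer_, x$pos),
    mapq = x$mapq,
    cigar = ifelse(unmapped, NA_character_, x$cigar),
    seq = seqc,
    qual = as.character(x$qual),
    nm = if (is.null(x$tag$NM)) NA_integer_ else x$tag$NM,
    sa = if (is.null(x$tag$SA)) NA_character_ else x$tag$SA,
    read_length = rl,
    mean_q = mean_q,
    strand = ifelse(unmapped, "*",
                    ifelse(bitwAnd(x$flag, 0x10) > 0L, "-", "+")))
  ReadRecords(df)
}

#' Classify read names into mapped / unmapped / chimeric / other
#'
#' Applies the CIGAR/flag-based read classification: a read name is
#' `unmapped` if its primary record carries the unmapped flag (0x4);
#' `chimeric` if any of its records is supplementary (0x800) or its primary
#' record carries an `SA` supplementary-alignment tag; `other` if it has
#' only secondary records, no primary record at all, or a primary CIGAR
#' whose consumed query length disagrees with the stored sequence length;
#' and `mapped` otherwise. Every read name receives exactly one category.
#'
#' @param records a [ReadRecords-class].
#' @return a data.frame with columns `read_id` and `category` (factor with
#'   levels mapped, unmapped, chimeric, other), one row per read name.
#' @export
classifyReads <- function(records) {
  stopifnot(is(records, "ReadRecords"))
  df <- readRecords(records)
  ids <- unique(df$read_id)
  if (!length(ids))
    return(data.frame(read_id = character(),
                      category = factor(levels = .qc_categories)))
  is_secondary <- bitwAnd(df$flag, 0x100) > 0L
  is_supp <- bitwAnd(df$flag, 0x800) > 0L
  is_primary <- !is_secondary & !is_supp
  is_unmapped <- bitwAnd(df$flag, 0x4) > 0L

  f <- factor(df$read_id, levels = ids)
  any_supp <- tapply(is_supp, f, any)
  has_primary <- tapply(is_primary, f, any)

  prim <- which(is_primary)
  prim <- prim[!duplicated(df$read_id[prim])]
  pi <- match(ids, df$read_id[prim])
  prim_row <- prim[pi]

  prim_unmapped <- rep(FALSE, length(ids))
  prim_sa <- rep(FALSE, length(ids))
  cigar_bad <- rep(FALSE, length(ids))
  ok <- !is.na(prim_row)
  if (any(ok)) {
    pr <- prim_row[ok]
    prim_unmapped[ok] <- is_unmapped[pr]
    prim_sa[ok] <- !is.na(df$sa[pr])
    mp <- ok & !prim_unmapped
    if (any(mp)) {
      pr2 <- prim_row[mp]
      qw <- cigarWidthAlongQuerySpace(df$cigar[pr2],
                                      after.soft.clipping = FALSE)
      cigar_bad[mp] <- qw != nchar(df$seq[pr2])
    }
  }
  no_primary <- !has_primary
  if (any(no_primary & !any_supp))
    warning(sum(no_primary & !any_supp),
            " read name(s) with no primary and no unmapped record;",
            " classified as 'other'")
  category <- rep("mapped", length(ids))
  category[cigar_bad | no_primary] <- "other"
  category[any_supp | prim_sa] <- "chimeric"
  category[prim_unmapped] <- "unmapped"
  data.frame(read_id = ids,
             category = factor(category, levels = .qc_categories))
}

.qc_categories <- c("mapped", "unmapped", "chimeric", "other")

#' Pass/fail quality filter
#'
#' The base-caller-style read filter: a read passes when its mean quality
#' is at least `min_q` (inclusive) and its length strictly exceeds
#' `min_len` bases (a 200-base read fails at the default cutoff).
#'
#' @param x a [ReadRecords-class], or a numeric vector of per-read mean
#'   qualities.
#' @param read_length read lengths (bases) when `x` is numeric.
#' @param min_q mean-quality cutoff (default 7, inclusive).
#' @param min_len length cutoff in bases (default 200, strict).
#' @return logical vector, one element per record (or per `x` element).
#' @examples
#' qcPass(c(7, 6.9, 12), c(201, 10000, 200))  # TRUE FALSE FALSE
#' @export
qcPass <- function(x, read_length = NULL, min_q = 7, min_len = 200) {
  if (is(x, "ReadRecords")) {
    df <- readRecords(x)
    mean_q <- df$mean_q
    read_length <- df$read_length
  } else {
    mean_q <- x
    stopifnot(length(read_length) == length(mean_q))
  }
  mean_q >= min_q & read_length > min_len
}

#' Percent read identity
#'
#' Identity of a mapped record from its CIGAR and edit distance:
#' `100 * (aligned_columns - NM) / aligned_columns`, where aligned columns
#' count matched, mismatched, inserted and deleted bases (M/=/X/I/D ops).
#' Returns `NA` for unmapped records, records without an NM tag, and
#' zero-column alignments (which are excluded from summaries).
#'
#' @param records a [ReadRecords-class].
#' @return numeric vector of percent identities, one per record.
#' @examples
#' # CIGAR 100M with NM=12 gives 88% identity
#' @export
readIdentity <- function(records) {
  stopifnot(is(records, "ReadRecords"))
  df <- readRecords(records)
  out <- rep(NA_real_, nrow(df))
  mapped <- bitwAnd(df$flag, 0x4) == 0L & !is.na(df$cigar) & !is.na(df$nm)
  if (any(mapped)) {
    ops <- cigarOpTable(df$cigar[mapped])
    cols <- rowSums(ops[, c("M", "I", "D", "=", "X"), drop = FALSE])
    id <- 100 * (cols - df$nm[mapped]) / cols
    id[cols == 0] <- NA_real_
    out[mapped] <- id
  }
  out
}

#' Fraction of primary mapped records on the forward strand
#'
#' @param records a [ReadRecords-class] with at least one primary mapped
#'   record.
#' @return fraction in `[0, 1]`.
#' @export
strandFraction <- function(records) {
  stopifnot(is(records, "ReadRecords"))
  df <- readRecords(records)
  prim <- bitwAnd(df$flag, 0x904) == 0L
  if (!any(prim)) stop("no primary mapped records; strand fraction undefined")
  mean(df$strand[prim] == "+")
}

#' Summarize read-level QC
#'
#' Computes the read-characteristics battery: category counts (mapped /
#' unmapped / chimeric / other), pass/fail counts at the quality and length
#' cutoffs, a percent-identity summary over mapped primary records, read
#' length histograms for all reads and after removing chimeric read names,
#' and forward/reverse strand counts of primary mapped records.
#'
#' @param records a [ReadRecords-class].
#' @param min_q,min_len pass/fail cutoffs (see [qcPass()]).
#' @param bin_width length-histogram bin width in bases (default 100).
#' @return an object of class `QcSummary`: a list with elements
#'   `categories` (per-read-name table with pass flag), `category_counts`,
#'   `pass_counts`, `identity` (summary stats), `length_hist` (data.frame
#'   with counts for all and non-chimeric reads), `strand_counts`, and
#'   `n_reads`.
#' @export
summarizeQc <- function(records, min_q = 7, min_len = 200, bin_width = 100) {
  stopifnot(is(records, "ReadRecords"))
  df <- readRecords(records)
  cls <- classifyReads(records)
  prim <- bitwAnd(df$flag, 0x900) == 0L
  ## per read name: take the primary record (or first record if none)
  first_of <- function(idx) idx[!duplicated(df$read_id[idx])]
  pr <- first_of(which(prim))
  rows <- pr[match(cls$read_id, df$read_id[pr])]
  fallback <- match(cls$read_id, df$read_id)
  rows[is.na(rows)] <- fallback[is.na(rows)]
  pass <- qcPass(df$mean_q[rows], df$read_length[rows], min_q, min_len)
  pass[is.na(pass)] <- FALSE
  cls$pass <- pass

  cat_counts <- table(cls$category)
  pass_counts <- c(pass = sum(pass), fail = sum(!pass))

  id <- readIdentity(records)[prim & bitwAnd(df$flag, 0x4) == 0L]
  id <- id[!is.na(id)]
  id_summary <- if (length(id))
    c(n = length(id), mean = mean(id), median = median(id),
      q25 = unname(stats::quantile(id, 0.25)),
      q75 = unname(stats::quantile(id, 0.75)))
  else c(n = 0, mean = NA, median = NA, q25 = NA, q75 = NA)

  lens <- df$read_length[rows]
  keep <- cls$category != "chimeric"
  maxlen <- max(c(lens, bin_width), na.rm = TRUE)
  breaks <- seq(0, ceiling(maxlen / bin_width) * bin_width, by = bin_width)
  hall <- if (length(lens)) hist_counts(lens, breaks) else integer(length(breaks) - 1L)
  hnoc <- if (any(keep)) hist_counts(lens[keep], breaks) else integer(length(breaks) - 1L)
  length_hist <- data.frame(bin_start = head(breaks, -1L),
                            bin_end = breaks[-1L],
                            all_reads = hall, non_chimeric = hnoc)

  pm <- prim & bitwAnd(df$flag, 0x4) == 0L
  strand_counts <- c(forward = sum(df$strand[pm] == "+"),
                     reverse = sum(df$strand[pm] == "-"))

  structure(list(categories = cls,
                 category_counts = cat_counts,
                 pass_counts = pass_counts,
                 identity = id_summary,
                 length_hist = length_hist,
                 strand_counts = strand_counts,
                 n_reads = nrow(cls)),
            class = "QcSummary")
}

hist_counts <- function(x, breaks) {
  x <- x[!is.na(x)]
  as.integer(table(cut(x, breaks = breaks, include.lowest = TRUE,
                       right = TRUE)))
}

#' @export
print.QcSummary <- function(x, ...) {
  cat("QcSummary over", x$n_reads, "read names\n")
  cat("  categories:",
      paste(names(x$category_counts), x$category_counts, collapse = ", "),
      "\n")
  cat("  pass/fail:", x$pass_counts["pass"], "/", x$pass_counts["fail"], "\n")
  if (x$identity["n"] > 0)
    cat(sprintf("  identity: mean %.2f%%, median %.2f%% (n=%d)\n",
                x$identity["mean"], x$identity["median"],
                as.integer(x$identity["n"])))
  cat("  strand (fwd/rev):", x$strand_counts["forward"], "/",
      x$strand_counts["reverse"], "\n")
  invisible(x)
}

#' Write QC summary tables
#'
#' Writes `qc_summary.tsv` (one metric per row), `categories.tsv`
#' (read_id, category, pass) and `length_hist.tsv`.
#'
#' @param summary a `QcSummary` from [summarizeQc()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
writeQcSummary <- function(summary, outdir) {
  stopifnot(inherits(summary, "QcSummary"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  metrics <- data.frame(
    metric = c(paste0("n_", names(summary$category_counts)),
               "n_pass", "n_fail",
               paste0("identity_", names(summary$identity)),
               "n_forward", "n_reverse"),
    value = c(as.numeric(summary$category_counts),
              as.numeric(summary$pass_counts),
              as.numeric(summary$identity),
              as.numeric(summary$strand_counts)))
  write.table(metrics, file.path(outdir, "qc_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(summary$categories, file.path(outdir, "categories.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(summary$length_hist, file.path(outdir, "length_hist.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
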