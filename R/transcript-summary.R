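#' @importFrom GenomicRanges countOverlaps findOverlaps granges
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#' @importFrom stats cor setNames
NULL

## Genomic spans of primary, mapped, non-chimeric records as a GRanges.
.read_spans <- function(records) {
  df <- readRecords(records)
  use <- bitwAnd(df$flag, 0x904) == 0L & is.na(df$sa)
  df <- df[use, , drop = FALSE]
  w <- GenomicAlignments::cigarWidthAlongReferenceSpace(df$cigar)
  GRanges(df$ref, IRanges(df$pos, width = w), strand = df$strand,
          read_id = df$read_id)
}

#' Count reads per transcript
#'
#' A primary, mapped, non-chimeric read increments every transcript whose
#' interval it overlaps by at least one base on the matching strand
#' (the multicov-style overlap rule).
#'
#' @param records a [ReadRecords-class].
#' @param transcripts transcript `GRanges` with a `transcript_id` column.
#' @return named integer vector of counts, one per transcript (in
#'   coordinate-sorted annotation order).
#' @export
countReads <- function(records, transcripts) {
  stopifnot(is(records, "ReadRecords"), is(transcripts, "GRanges"))
  o <- order(as.factor(seqnames(transcripts)), start(transcripts),
             end(transcripts))
  if (!identical(o, seq_along(transcripts))) {
    warning("transcript annotation not coordinate-sorted; sorting internally")
    transcripts <- transcripts[o]
  }
  reads <- .read_spans(records)
  setNames(countOverlaps(transcripts, reads, minoverlap = 1L,
                         ignore.strand = FALSE),
           transcripts$transcript_id)
}

#' Build a transcript-by-sample count table
#'
#' Assembles per-sample [countReads()] columns into a
#' `SummarizedExperiment` (assay `"counts"`, transcripts as rows).
#'
#' @param record_list named list of [ReadRecords-class], one per sample.
#' @param transcripts transcript `GRanges`.
#' @param col_data optional `DataFrame` of sample annotations (condition,
#'   replicate, library type), one row per sample.
#' @return a `SummarizedExperiment`.
#' @export
buildCountTable <- function(record_list, transcripts, col_data = NULL) {
  transcripts <- sort(transcripts, ignore.strand = TRUE)
  counts <- vapply(record_list, countReads, integer(length(transcripts)),
                   transcripts = transcripts)
  if (is.null(col_data))
    col_data <- DataFrame(sample = colnames(counts))
  SummarizedExperiment(assays = list(counts = counts),
                       rowRanges = transcripts, colData = col_data)
}

#' Pairwise replicate correlations of a count table
#'
#' Pearson correlation between `log10(count + 1)`-transformed sample
#' columns, the standard replicate-concordance summary for long-read
#' count tables.
#'
#' @param x a `SummarizedExperiment` from [buildCountTable()], or a counts
#'   matrix.
#' @return symmetric correlation matrix with unit diagonal; columns with
#'   zero variance give `NA` entries (with a warning).
#' @export
correlateCounts <- function(x) {
  m <- if (is(x, "SummarizedExperiment")) assay(x, "counts") else as.matrix(x)
  if (ncol(m) < 2L) stop("need at least two samples")
  lm <- log10(m + 1)
  v <- apply(lm, 2L, stats::var)
  if (any(v == 0))
    warning("zero-variance column(s): ",
            paste(colnames(m)[v == 0], collapse = ", "),
            "; correlations undefined")
  r <- suppressWarnings(cor(lm, method = "pearson"))
  diag(r) <- 1
  r
}

#' Sites per transcript
#'
#' Assigns every called site to each transcript containing it on the same
#' strand (a site inside two overlapping transcripts counts in both) and
#' returns the per-transcript distribution including zero-site
#' transcripts.
#'
#' @param sites width-1 `GRanges` of called sites.
#' @param transcripts transcript `GRanges` with `transcript_id`.
#' @return list with `counts` (named integer vector over all transcripts)
#'   and `median`.
#' @export
sitesPerTranscript <- function(sites, transcripts) {
  stopifnot(is(sites, "GRanges"), is(transcripts, "GRanges"))
  counts <- setNames(countOverlaps(transcripts, sites,
                                   ignore.strand = FALSE),
                     transcripts$transcript_id)
  list(counts = counts, median = median(counts))
}

#' Per-transcript Jaccard commonality of two site sets
#'
#' For each transcript, the Jaccard index `|A n B| / |A u B|` of the two
#' conditions' called sites restricted to the transcript interval (sites
#' keyed by position and strand). Transcripts with no site in either
#' condition (0/0) are excluded. With `window > 0`, a site in A is counted
#' as common when a B site lies within `window` bases.
#'
#' @param sites_a,sites_b width-1 `GRanges` of called sites per condition.
#' @param transcripts transcript `GRanges` with `transcript_id`.
#' @param window matching tolerance in bases (default 0 = exact position).
#' @return data.frame with `transcript_id`, `n_a`, `n_b`, `n_common`,
#'   `jaccard`, one row per transcript with a non-empty union.
#' @export
jaccardPerTranscript <- function(sites_a, sites_b, transcripts, window = 0) {
  stopifnot(is(sites_a, "GRanges"), is(sites_b, "GRanges"),
            is(transcripts, "GRanges"))
  res <- lapply(seq_along(transcripts), function(i) {
    tx <- transcripts[i]
    A <- sites_a[countOverlaps(sites_a, tx, ignore.strand = FALSE) > 0]
    B <- sites_b[countOverlaps(sites_b, tx, ignore.strand = FALSE) > 0]
    na <- length(A); nb <- length(B)
    if (na + nb == 0L) return(NULL)
    if (window == 0) {
      ka <- paste(start(A), strand(A)); kb <- paste(start(B), strand(B))
      ncom <- length(intersect(unique(ka), unique(kb)))
      nuni <- length(union(unique(ka), unique(kb)))
    } else {
      hit <- countOverlaps(A, B + window, ignore.strand = FALSE) > 0
      ncom <- sum(hit)
      nuni <- na + nb - ncom
    }
    data.frame(transcript_id = tx$transcript_id, n_a = na, n_b = nb,
               n_common = ncom, jaccard = ncom / nuni)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(transcript_id = character(), n_a = integer(),
                      n_b = integer(), n_common = integer(),
                      jaccard = numeric())
  out
}

#' Correlate two per-position tracks
#'
#' Pearson correlation between two per-position value tracks (e.g. two
#' odds-ratio tracks, or an odds-ratio track against an external
#' accessibility score), inner-joined on positions carrying a value in
#' both.
#'
#' @param track_a,track_b data.frames with columns `ref`, `pos`, `value`
#'   (or named numeric vectors keyed by position).
#' @return list with `r` (Pearson correlation; `NA` with a warning when
#'   fewer than 3 joined positions) and `n` (number of joined positions).
#' @export
correlateTracks <- function(track_a, track_b) {
  tok <- function(t) {
    if (is.data.frame(t))
      list(key = paste(t$ref, t$pos), value = t$value)
    else
      list(key = names(t), value = unname(t))
  }
  A <- tok(track_a); B <- tok(track_b)
  mi <- match(A$key, B$key)
  ok <- !is.na(mi) & !is.na(A$value) & !is.na(B$value[ifelse(is.na(mi), 1L, mi)])
  n <- sum(ok)
  if (n < 3L) {
    warning("fewer than 3 joined positions; correlation undefined")
    return(list(r = NA_real_, n = n))
  }
  list(r = cor(A$value[ok], B$value[mi[ok]]), n = n)
}
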