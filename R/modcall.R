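#' @importFrom stats phyper pchisq p.adjust
#' @importFrom Biostrings getSeq
NULL

#' Construct a background error model
#'
#' @param mode `"constant"`, `"context"` or `"paired_control"`.
#' @param p0 background error probability (constant mode; default 0.12,
#'   the typical nanopore RNA background).
#' @param context_table named numeric vector of 5-mer error probabilities
#'   (context mode); must cover all 1024 5-mers or include a `"default"`
#'   fallback entry.
#' @param control a control pileup `GRanges` (paired_control mode), e.g. an
#'   unmodified in-vitro-transcribed or cDNA run piled up over the same
#'   regions.
#' @return a validated [BackgroundModel-class].
#' @export
backgroundModel <- function(mode = c("constant", "context", "paired_control"),
                            p0 = 0.12, context_table = numeric(),
                            control = NULL) {
  mode <- match.arg(mode)
  new("BackgroundModel", mode = mode, p0 = as.numeric(p0),
      context_table = context_table, control = control)
}

## One-sided Fisher p for 2x2 tables [a, b; c, d], alternative: the test
## sample's error rate exceeds the background. Hypergeometric tail with the
## observed margins (vectorized).
.fisher_one_sided <- function(a, b, c, d) {
  phyper(a - 1, m = a + c, n = b + d, k = a + b, lower.tail = FALSE)
}

## Haldane-corrected cross-product odds ratio.
.haldane_or <- function(a, b, c, d) {
  ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
}

#' Test sites against a background error model
#'
#' For every pileup site with sufficient coverage, builds the 2x2 table
#' `[n_error, coverage - n_error; e0, n0 - e0]`, where the background
#' counts `(e0, n0)` come from the paired control pileup (paired_control
#' mode) or from a pseudo-sample `(round(p0_site * pseudo_n), pseudo_n)`
#' (constant and context modes). The p-value is the one-sided Fisher exact
#' test for the site's error rate exceeding the background; the odds ratio
#' is the Haldane-corrected cross-product. Adjusted p-values are
#' Benjamini-Hochberg over all tested sites.
#'
#' @param pileup pileup `GRanges` from [computePileup()].
#' @param bg a [BackgroundModel-class].
#' @param reference named `DNAStringSet`; required in context mode for
#'   5-mer lookup.
#' @param pseudo_n pseudo-sample size for model-mode backgrounds
#'   (default 1000).
#' @param min_coverage minimum site coverage (default 20); lower-coverage
#'   sites are excluded and reported in the skip table.
#' @return a `GRanges` of tested sites with metadata columns `coverage`,
#'   `n_error`, `esb_test`, `esb_bg`, `odds_ratio`, `pval`, `adj_pval`.
#'   Skipped sites (with a `reason`) are attached as
#'   `metadata(mcols(result))$skipped`.
#' @export
testSites <- function(pileup, bg, reference = NULL, pseudo_n = 1000,
                      min_coverage = 20) {
  stopifnot(is(pileup, "GRanges"), is(bg, "BackgroundModel"))
  validObject(bg)
  keep <- pileup$coverage >= min_coverage
  skipped <- pileup[!keep]
  if (length(skipped)) skipped$reason <- "low_coverage"
  x <- pileup[keep]

  if (bg@mode == "paired_control") {
    key <- function(g) paste(seqnames(g), start(g), strand(g))
    ctl <- bg@control
    mi <- match(key(x), key(ctl))
    ctl_ok <- !is.na(mi) & ctl$coverage[ifelse(is.na(mi), 1L, mi)] >=
      min_coverage
    if (any(!ctl_ok)) {
      sk <- x[!ctl_ok]
      sk$reason <- "control_missing_or_low"
      skipped <- c(skipped, sk)
      x <- x[ctl_ok]; mi <- mi[ctl_ok]
    }
    e0 <- ctl$n_error[mi]
    n0 <- ctl$coverage[mi]
  } else {
    p0 <- if (bg@mode == "constant") {
      rep(bg@p0, length(x))
    } else {
      if (is.null(reference))
        stop("context mode requires the reference sequence")
      ctx <- .site_context(x, reference, k = 5L)
      hit <- bg@context_table[ctx]
      fb <- bg@context_table["default"]
      ifelse(is.na(hit), unname(fb), unname(hit))
    }
    if (anyNA(p0)) stop("context table has no entry (and no default) for some sites")
    e0 <- round(p0 * pseudo_n)
    n0 <- rep(as.integer(pseudo_n), length(x))
  }

  a <- x$n_error; b <- x$coverage - x$n_error
  cc <- e0; dd <- n0 - e0
  x$esb_test <- ifelse(x$coverage > 0, a / x$coverage, NA_real_)
  x$esb_bg <- cc / n0
  x$odds_ratio <- .haldane_or(a, b, cc, dd)
  x$pval <- .fisher_one_sided(a, b, cc, dd)
  x$adj_pval <- adjustPvalues(x$pval)
  S4Vectors::metadata(mcols(x))$skipped <- skipped
  x
}

## k-mer context centred on each site, on the site strand
.site_context <- function(sites, reference, k = 5L) {
  half <- (k - 1L) %/% 2L
  ch <- as.character(seqnames(sites))
  lo <- pmax(start(sites) - half, 1L)
  chrlen <- width(reference)[match(ch, names(reference))]
  hi <- pmin(start(sites) + half, chrlen)
  minus <- as.character(strand(sites)) == "-"
  vapply(seq_along(sites), function(i) {
    s <- subseq(reference[[ch[i]]], lo[i], hi[i])
    if (minus[i]) s <- reverseComplement(s)
    as.character(s)
  }, "")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment over the tested family (all sites in a run).
#' Thin, named wrapper so the multiple-testing family and procedure are
#' explicit at the call sites.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order as `pvals`.
#' @export
adjustPvalues <- function(pvals) {
  if (!length(pvals)) return(numeric())
  stopifnot(all(is.finite(pvals)), all(pvals >= 0 & pvals <= 1))
  p.adjust(pvals, method = "BH")
}

#' Apply the profiling call thresholds
#'
#' Flags sites passing the modification-profiling cutoffs: odds ratio at
#' least `min_or` and adjusted p-value below `max_adjp`. The headline
#' thresholds are OR >= 3 with adjP < 1e-50 at production sequencing depth;
#' at desk-scale coverage a surrogate such as `max_adjp = 1e-6` is
#' appropriate.
#'
#' @param calls `GRanges` from [testSites()].
#' @param min_or odds-ratio cutoff (default 3, inclusive).
#' @param max_adjp adjusted-p cutoff (default 1e-50, strict).
#' @return `calls` with a logical `passed` metadata column.
#' @export
callProfile <- function(calls, min_or = 3, max_adjp = 1e-50) {
  stopifnot(is(calls, "GRanges"),
            all(c("odds_ratio", "adj_pval") %in% colnames(mcols(calls))))
  calls$passed <- calls$odds_ratio >= min_or & calls$adj_pval < max_adjp
  calls
}

#' Write called sites as BED6+2
#'
#' BED6 (0-based half-open; score column holds the odds ratio capped at
#' 1000) with the odds ratio and adjusted p-value appended as columns 7-8.
#' Only sites with `passed == TRUE` are written unless `passed_only` is
#' `FALSE`.
#'
#' @param calls `GRanges` from [callProfile()].
#' @param path output BED path.
#' @param passed_only write only passing sites (default TRUE).
#' @return `path`, invisibly.
#' @export
writeCallsBed <- function(calls, path, passed_only = TRUE) {
  x <- if (passed_only && "passed" %in% colnames(mcols(calls)))
    calls[calls$passed] else calls
  df <- data.frame(chrom = as.character(seqnames(x)),
                   start = start(x) - 1L, end = end(x),
                   name = sprintf("site%06d", seq_along(x)),
                   score = pmin(round(x$odds_ratio, 2), 1000),
                   strand = as.character(strand(x)),
                   odds_ratio = x$odds_ratio, adj_pval = x$adj_pval)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' One-shot modification-profile calling
#'
#' Pipeline convenience: pileup, test against the background model, apply
#' the profiling thresholds.
#'
#' @param records a [ReadRecords-class].
#' @param reference named `DNAStringSet`.
#' @param regions transcript/region `GRanges`.
#' @param bg a [BackgroundModel-class].
#' @param min_or,max_adjp call thresholds (see [callProfile()]).
#' @param min_coverage site coverage floor (see [testSites()]).
#' @param ... passed to [computePileup()].
#' @return `GRanges` of tested sites with test columns and `passed` flag.
#' @export
modCall <- function(records, reference, regions, bg,
                    min_or = 3, max_adjp = 1e-50, min_coverage = 20, ...) {
  pu <- computePileup(records, reference, regions, ...)
  tst <- testSites(pu, bg, reference = reference,
                   min_coverage = min_coverage)
  callProfile(tst, min_or = min_or, max_adjp = max_adjp)
}
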