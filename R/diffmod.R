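#' Build replicate-stratified 2x2 tables
#'
#' Pairs replicate k of condition A with replicate k of condition B
#' (index-based pairing) and, for every site, assembles the K 2x2
#' error/non-error tables that feed the Cochran-Mantel-Haenszel test.
#' Sites are retained only if every replicate of both conditions meets the
#' coverage floor at the site; excluded sites are recorded in the result's
#' metadata.
#'
#' @param pileups_a,pileups_b lists of K pileup `GRanges`
#'   (see [computePileup()]), one per biological replicate.
#' @param min_coverage per-replicate coverage floor (default 20).
#' @return a [StratifiedTables-class] over the retained sites.
#' @export
buildStrata <- function(pileups_a, pileups_b, min_coverage = 20) {
  if (length(pileups_a) != length(pileups_b))
    stop("conditions must have the same number of replicates (got ",
         length(pileups_a), " vs ", length(pileups_b), ")")
  K <- length(pileups_a)
  if (K < 1L) stop("need at least one replicate pair")
  all_p <- c(pileups_a, pileups_b)
  key <- function(g) paste(seqnames(g), start(g), strand(g))
  k0 <- key(all_p[[1L]])
  idx <- lapply(all_p, function(g) match(k0, key(g)))
  present <- Reduce(`&`, lapply(idx, function(i) !is.na(i)))
  covok <- present
  for (j in seq_along(all_p)) {
    cv <- rep(0L, length(k0))
    cv[present] <- all_p[[j]]$coverage[idx[[j]][present]]
    covok <- covok & cv >= min_coverage
  }
  sites <- GenomicRanges::granges(all_p[[1L]])[covok]
  n <- sum(covok)
  cell <- function(plist, what) {
    m <- matrix(0, n, K)
    for (k in seq_len(K)) {
      i <- idx[[if (identical(plist, "a")) k else K + k]][covok]
      g <- all_p[[if (identical(plist, "a")) k else K + k]]
      m[, k] <- if (what == "err") g$n_error[i]
                else g$coverage[i] - g$n_error[i]
    }
    m
  }
  new("StratifiedTables", sites = sites,
      a = cell("a", "err"), b = cell("a", "non"),
      c = cell("b", "err"), d = cell("b", "non"))
}

#' Construct StratifiedTables from cell matrices
#'
#' Lower-level constructor for testing and for table-level simulation:
#' supply the four site-by-stratum cell matrices directly.
#'
#' @param a,b,c,d numeric matrices (sites x strata): errors / non-errors in
#'   condition A, errors / non-errors in condition B.
#' @param sites optional `GRanges` of site keys; defaults to dummy
#'   positions 1..n on a placeholder sequence.
#' @return a [StratifiedTables-class].
#' @export
stratifiedTables <- function(a, b, c, d, sites = NULL) {
  a <- as.matrix(a); b <- as.matrix(b); c <- as.matrix(c); d <- as.matrix(d)
  if (is.null(sites))
    sites <- GRanges("site", IRanges(seq_len(nrow(a)), width = 1L), "+")
  new("StratifiedTables", sites = sites, a = a, b = b, c = c, d = d)
}

#' Cochran-Mantel-Haenszel test over replicate strata
#'
#' For each site the CMH chi-square statistic
#' \deqn{(|\sum_k (a_k - E[a_k])| - c/2)^2 / \sum_k Var(a_k)}
#' with hypergeometric expectation and variance per stratum (`c` is 1 with
#' the continuity correction, 0 without), referred to a chi-square
#' distribution with 1 df. Strata with a zero row or column margin carry no
#' information and contribute 0 to both sums; a site whose strata are all
#' degenerate is reported with `pval = 1` and `degenerate = TRUE`.
#'
#' @param st a [StratifiedTables-class].
#' @param continuity apply the 0.5 continuity correction (default TRUE,
#'   matching the common default of stratified-test implementations).
#' @return a `DataFrame` with `cmh_statistic`, `pval`, `degenerate`, one
#'   row per site.
#' @export
cmhTest <- function(st, continuity = TRUE) {
  stopifnot(is(st, "StratifiedTables"))
  a <- st@a; b <- st@b; cc <- st@c; dd <- st@d
  n <- a + b + cc + dd
  r1 <- a + b; r2 <- cc + dd; c1 <- a + cc; c2 <- b + dd
  valid <- r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0 & n >= 2
  E <- ifelse(valid, r1 * c1 / pmax(n, 1), 0)
  V <- ifelse(valid, r1 * r2 * c1 * c2 / (pmax(n, 2)^2 * pmax(n - 1, 1)), 0)
  dev <- ifelse(valid, a - E, 0)
  sumdev <- rowSums(dev)
  sumV <- rowSums(V)
  degenerate <- sumV <= 0
  ## the 0.5 correction is only applied when |sum dev| >= 0.5, matching
  ## standard CMH implementations; otherwise the uncorrected quadratic form
  yates <- ifelse(continuity & abs(sumdev) >= 0.5, 0.5, 0)
  num <- (abs(sumdev) - yates)^2
  stat <- ifelse(degenerate, 0, num / ifelse(degenerate, 1, sumV))
  pval <- ifelse(degenerate, 1, pchisq(stat, df = 1, lower.tail = FALSE))
  DataFrame(cmh_statistic = stat, pval = pval, degenerate = degenerate)
}

#' Mantel-Haenszel common odds ratio
#'
#' The pooled odds-ratio estimator
#' \deqn{\sum_k a_k d_k / n_k \; / \; \sum_k b_k c_k / n_k .}
#' Any stratum containing a zero cell receives a Haldane +0.5 on all four
#' of its cells before entering the sums; a site whose denominator is
#' still zero is returned as `NA` (undefined estimate).
#'
#' @param st a [StratifiedTables-class].
#' @return numeric vector of common odds ratios (`NA` where undefined).
#' @export
mhCommonOR <- function(st) {
  stopifnot(is(st, "StratifiedTables"))
  a <- st@a; b <- st@b; cc <- st@c; dd <- st@d
  zero <- a == 0 | b == 0 | cc == 0 | dd == 0
  a <- a + 0.5 * zero; b <- b + 0.5 * zero
  cc <- cc + 0.5 * zero; dd <- dd + 0.5 * zero
  n <- a + b + cc + dd
  num <- rowSums(a * dd / n)
  den <- rowSums(b * cc / n)
  ifelse(den > 0, num / den, NA_real_)
}

#' Differential modification testing between two conditions
#'
#' Runs the stratified CMH test and the Mantel-Haenszel common odds ratio
#' over all retained sites, applies Benjamini-Hochberg adjustment across
#' the tested family, and flags sites passing the differential thresholds.
#'
#' @param pileups_a,pileups_b per-replicate pileup lists (condition A and
#'   B), or a pre-built [StratifiedTables-class] passed as `pileups_a`.
#' @param min_coverage per-replicate coverage floor (see [buildStrata()]).
#' @param continuity CMH continuity correction (see [cmhTest()]).
#' @param min_or,max_adjp call thresholds (see [callDifferential()]).
#' @return a `GRanges` of tested sites with metadata columns
#'   `cmh_statistic`, `pval`, `adj_pval`, `or_mh`, `direction`,
#'   `degenerate`, `passed`.
#' @export
diffModCall <- function(pileups_a, pileups_b = NULL, min_coverage = 20,
                        continuity = TRUE, min_or = 1.5, max_adjp = 0.01) {
  st <- if (is(pileups_a, "StratifiedTables")) pileups_a
        else buildStrata(pileups_a, pileups_b, min_coverage)
  res <- cmhTest(st, continuity = continuity)
  out <- strataSites(st)
  out$cmh_statistic <- res$cmh_statistic
  out$pval <- res$pval
  out$degenerate <- res$degenerate
  out$adj_pval <- adjustPvalues(res$pval)
  out$or_mh <- mhCommonOR(st)
  callDifferential(out, min_or = min_or, max_adjp = max_adjp)
}

#' Apply the differential call thresholds
#'
#' A site is called differential when its common odds ratio is at least
#' `min_or` in either direction (`or_mh >= min_or` or
#' `or_mh <= 1/min_or`) and its adjusted p-value is below `max_adjp`.
#' Direction is assigned by the odds ratio relative to 1: `A_higher` for
#' `or_mh > 1`, `B_higher` for `or_mh < 1`.
#'
#' @param calls `GRanges` with `or_mh` and `adj_pval` columns.
#' @param min_or odds-ratio cutoff (default 1.5, inclusive).
#' @param max_adjp adjusted-p cutoff (default 0.01, strict).
#' @return `calls` with `direction` and logical `passed` columns.
#' @export
callDifferential <- function(calls, min_or = 1.5, max_adjp = 0.01) {
  stopifnot(is(calls, "GRanges"),
            all(c("or_mh", "adj_pval") %in% colnames(mcols(calls))))
  or <- calls$or_mh
  calls$direction <- factor(ifelse(is.na(or) | or == 1, NA,
                                   ifelse(or > 1, "A_higher", "B_higher")),
                            levels = c("A_higher", "B_higher"))
  calls$passed <- !is.na(or) & (or >= min_or | or <= 1 / min_or) &
    calls$adj_pval < max_adjp
  calls
}

#' Write differential calls
#'
#' Writes `diff_calls.tsv` (all tested sites) plus `a_higher.bed` and
#' `b_higher.bed` (BED6 of passing sites split by direction).
#'
#' @param calls `GRanges` from [diffModCall()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
writeDiffCalls <- function(calls, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(ref = as.character(seqnames(calls)),
                   pos = start(calls) - 1L,
                   strand = as.character(strand(calls)),
                   cmh_statistic = calls$cmh_statistic, pval = calls$pval,
                   adj_pval = calls$adj_pval, or_mh = calls$or_mh,
                   direction = as.character(calls$direction),
                   passed = calls$passed)
  write.table(df, file.path(outdir, "diff_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (dir in c("A_higher", "B_higher")) {
    x <- calls[calls$passed & !is.na(calls$direction) &
                 calls$direction == dir]
    bed <- data.frame(chrom = as.character(seqnames(x)),
                      start = start(x) - 1L, end = end(x),
                      name = sprintf("diff%06d", seq_along(x)),
                      score = pmin(round(ifelse(x$or_mh < 1, 1 / x$or_mh,
                                                x$or_mh), 2), 1000),
                      strand = as.character(strand(x)))
    write.table(bed, file.path(outdir, paste0(tolower(substr(dir, 1, 1)),
                                              "_higher.bed")),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(outdir)
}
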