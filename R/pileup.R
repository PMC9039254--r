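#' @importFrom GenomicAlignments explodeCigarOps explodeCigarOpLengths
#' @importFrom IRanges IRanges coverage
NULL

#' Per-base error pileup
#'
#' Builds the site-level error profile that houses the ESB (error at
#' specific base). For every reference position inside `regions`, counts
#' the reads covering the position and the reads showing an error there. A
#' read contributes at most one error per position: a substitution at the
#' position, a deletion spanning it, or an insertion immediately following
#' it (insertions attach to the preceding reference base). Only primary,
#' mapped, non-chimeric and (by default) QC-passing records are used.
#'
#' @param records a [ReadRecords-class] (e.g. from [readAlignmentRecords()]
#'   or the simulator).
#' @param reference named `DNAStringSet` matching the alignment targets.
#' @param regions `GRanges` of intervals to pile up (typically the
#'   transcript annotation); reported sites inherit the region strand.
#' @param min_q,min_len QC cutoffs applied to reads (see [qcPass()]);
#'   set `apply_qc = FALSE` to disable.
#' @param apply_qc whether to drop QC-failing reads (default TRUE).
#' @return a width-1 `GRanges` with metadata columns `coverage`, `n_error`,
#'   `n_mismatch`, `n_del`, `n_ins`.
#' @export
computePileup <- function(records, reference, regions,
                          min_q = 7, min_len = 200, apply_qc = TRUE) {
  stopifnot(is(records, "ReadRecords"), is(reference, "DNAStringSet"),
            is(regions, "GRanges"))
  if (!all(as.character(seqnames(regions)) %in% names(reference)))
    stop("regions reference chromosomes absent from the reference")
  if (any(end(regions) > width(reference)[match(
        as.character(seqnames(regions)), names(reference))]))
    stop("regions exceed reference bounds")
  df <- readRecords(records)
  use <- bitwAnd(df$flag, 0x904) == 0L & is.na(df$sa)
  if (apply_qc) use <- use & qcPass(df$mean_q, df$read_length, min_q, min_len)
  df <- df[use, , drop = FALSE]

  chroms <- as.character(unique(seqnames(regions)))
  clen <- stats::setNames(width(reference)[match(chroms, names(reference))],
                          chroms)
  acc <- lapply(chroms, function(ch)
    list(cov = integer(clen[ch]), mm = integer(), del = integer(),
         ins = integer(), err = integer()))
  names(acc) <- chroms
  refraw <- lapply(chroms, function(ch)
    charToRaw(as.character(reference[[ch]])))
  names(refraw) <- chroms

  if (nrow(df)) {
    ops_all <- explodeCigarOps(df$cigar)
    lens_all <- explodeCigarOpLengths(df$cigar)
    ref_v <- df$ref; pos_v <- df$pos; seq_v <- df$seq
    for (ch in chroms) {
      rows <- which(ref_v == ch)
      if (!length(rows)) next
      mm_l <- del_l <- ins_l <- err_l <- vector("list", length(rows))
      spans_s <- integer(length(rows)); spans_e <- integer(length(rows))
      rw <- refraw[[ch]]
      for (j in seq_along(rows)) {
        r <- rows[j]
        ops <- ops_all[[r]]; lens <- lens_all[[r]]
        refc <- ops %in% c("M", "=", "X", "D", "N")
        qryc <- ops %in% c("M", "=", "X", "I", "S")
        refstart <- pos_v[r] + cumsum(c(0L, lens * refc))[seq_along(lens)]
        qstart <- 1L + cumsum(c(0L, lens * qryc))[seq_along(lens)]
        spans_s[j] <- pos_v[r]
        spans_e[j] <- pos_v[r] + sum(lens[refc]) - 1L
        iD <- which(ops %in% c("D", "N"))
        dpos <- if (length(iD)) sequence(lens[iD], from = refstart[iD])
                else integer()
        iI <- which(ops == "I")
        ipos <- refstart[iI] - 1L
        ipos <- ipos[ipos >= spans_s[j]]
        iM <- which(ops %in% c("M", "=", "X"))
        mpos <- integer()
        if (length(iM)) {
          qidx <- sequence(lens[iM], from = qstart[iM])
          ridx <- sequence(lens[iM], from = refstart[iM])
          qraw <- charToRaw(seq_v[r])
          mpos <- ridx[qraw[qidx] != rw[ridx]]
        }
        mm_l[[j]] <- mpos; del_l[[j]] <- dpos; ins_l[[j]] <- ipos
        err_l[[j]] <- unique(c(mpos, dpos, ipos))
      }
      cv <- coverage(IRanges(spans_s, spans_e), width = clen[ch])
      acc[[ch]]$cov <- as.integer(cv)
      acc[[ch]]$mm <- unlist(mm_l); acc[[ch]]$del <- unlist(del_l)
      acc[[ch]]$ins <- unlist(ins_l); acc[[ch]]$err <- unlist(err_l)
    }
  }

  pos_l <- vector("list", length(regions))
  for (g in seq_along(regions)) pos_l[[g]] <- start(regions)[g]:end(regions)[g]
  npos <- lengths(pos_l)
  pos <- unlist(pos_l)
  ch_v <- rep(as.character(seqnames(regions)), npos)
  st_v <- rep(as.character(strand(regions)), npos)
  cov <- n_mm <- n_del <- n_ins <- n_err <- integer(length(pos))
  for (ch in chroms) {
    w <- which(ch_v == ch)
    if (!length(w)) next
    a <- acc[[ch]]
    cov[w] <- a$cov[pos[w]]
    n_mm[w] <- tabulate(a$mm, clen[ch])[pos[w]]
    n_del[w] <- tabulate(a$del, clen[ch])[pos[w]]
    n_ins[w] <- tabulate(a$ins, clen[ch])[pos[w]]
    n_err[w] <- tabulate(a$err, clen[ch])[pos[w]]
  }
  GRanges(ch_v, IRanges(pos, width = 1L), strand = st_v,
          coverage = cov, n_error = n_err, n_mismatch = n_mm,
          n_del = n_del, n_ins = n_ins,
          seqinfo = GenomeInfoDb::Seqinfo(names(reference),
                                          width(reference)))
}

#' Error at specific base (ESB)
#'
#' The per-site error fraction `n_error / coverage`. Sites with zero
#' coverage have no ESB and return `NA` (they are skipped by the callers).
#'
#' @param pileup a pileup `GRanges` from [computePileup()].
#' @return numeric vector of error fractions in `[0, 1]` (NA where
#'   coverage is 0).
#' @export
esb <- function(pileup) {
  stopifnot(is(pileup, "GRanges"),
            all(c("coverage", "n_error") %in% colnames(mcols(pileup))))
  ifelse(pileup$coverage > 0, pileup$n_error / pileup$coverage, NA_real_)
}

#' Write a pileup as TSV
#'
#' Columns: ref, pos (0-based), strand, coverage, n_error, n_mismatch,
#' n_del, n_ins.
#'
#' @param pileup pileup `GRanges`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePileup <- function(pileup, path) {
  df <- data.frame(ref = as.character(seqnames(pileup)),
                   pos = start(pileup) - 1L,
                   strand = as.character(strand(pileup)),
                   coverage = pileup$coverage, n_error = pileup$n_error,
                   n_mismatch = pileup$n_mismatch, n_del = pileup$n_del,
                   n_ins = pileup$n_ins)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pileup TSV
#'
#' @param path file written by [writePileup()].
#' @return a pileup `GRanges`.
#' @export
readPileup <- function(path) {
  df <- utils::read.delim(path)
  GRanges(df$ref, IRanges(df$pos + 1L, width = 1L), strand = df$strand,
          coverage = df$coverage, n_error = df$n_error,
          n_mismatch = df$n_mismatch, n_del = df$n_del, n_ins = df$n_ins)
}
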