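#' @importFrom stats rpois rgeom runif rbinom rnorm pnorm qnorm rgamma median
#' @importFrom Biostrings DNAStringSet writeXStringSet subseq
#'   reverseComplement DNAString
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

#' Create a simulation configuration
#'
#' Builds a validated [SimulationConfig-class] with mode-aware defaults.
#' The defaults emulate the observed behaviour of matched nanopore runs on
#' yeast poly-A RNA: a ~12% per-base background error (about 88% read
#' identity), elevated error at modified sites, 3'-anchored reads with
#' geometric 5' truncation in `rna` mode, and a pass fraction at mean
#' quality 7 of about 85% for native RNA reads versus about 50% for direct
#' cDNA reads, where chimeric pairs are also much more common (15-20%) and
#' a strong one-strand bias is seen.
#'
#' @param mode `"rna"` or `"cdna"`.
#' @param n_transcripts number of transcripts in the toy transcriptome.
#' @param len_min,len_max,len_mean transcript length distribution (bases).
#' @param coverage_per_transcript mean reads per transcript.
#' @param abundance_sdlog log-normal spread of per-transcript relative
#'   abundance (mean 1); 0 gives uniform expression.
#' @param p_err_bg background per-base error probability.
#' @param p_err_mod per-base error probability at modified sites.
#' @param err_split substitution/insertion/deletion split of errors.
#' @param mods_per_kb planted modification sites per kilobase.
#' @param truncation_p geometric per-base 5'-loss probability (0 = none).
#' @param chimera_frac probability a read is emitted as a chimeric pair.
#' @param fwd_strand_frac cdna mode: probability of forward orientation.
#' @param q_pass_frac fraction of reads with mean quality >= 7.
#' @param min_read_len floor on read length (bases).
#' @param seed integer RNG seed.
#' @return a validated `SimulationConfig`.
#' @examples
#' cfg <- simulationConfig("rna", n_transcripts = 5, seed = 1)
#' cfg
#' @export
simulationConfig <- function(mode = c("rna", "cdna"),
                             n_transcripts = 50L,
                             len_min = 200L, len_max = 4000L, len_mean = 1500,
                             coverage_per_transcript = 50,
                             abundance_sdlog = 1,
                             p_err_bg = 0.12,
                             p_err_mod = 0.30,
                             err_split = c(0.6, 0.2, 0.2),
                             mods_per_kb = 10,
                             truncation_p = if (mode == "rna") 0.001 else 0,
                             chimera_frac = if (mode == "rna") 0.02 else 0.18,
                             fwd_strand_frac = if (mode == "rna") 0.5 else 0.9,
                             q_pass_frac = if (mode == "rna") 0.85 else 0.50,
                             min_read_len = 50L,
                             seed = 1L) {
  mode <- match.arg(mode)
  new("SimulationConfig",
      n_transcripts = as.integer(n_transcripts),
      len_min = as.integer(len_min), len_max = as.integer(len_max),
      len_mean = as.numeric(len_mean),
      coverage_per_transcript = as.numeric(coverage_per_transcript),
      abundance_sdlog = as.numeric(abundance_sdlog),
      p_err_bg = as.numeric(p_err_bg), p_err_mod = as.numeric(p_err_mod),
      err_split = as.numeric(err_split),
      mods_per_kb = as.numeric(mods_per_kb),
      truncation_p = as.numeric(truncation_p),
      chimera_frac = as.numeric(chimera_frac),
      fwd_strand_frac = as.numeric(fwd_strand_frac),
      q_pass_frac = as.numeric(q_pass_frac),
      min_read_len = as.integer(min_read_len),
      seed = as.integer(seed),
      mode = mode)
}

.config_fields <- function() {
  c("n_transcripts", "len_min", "len_max", "len_mean",
    "coverage_per_transcript", "abundance_sdlog", "p_err_bg", "p_err_mod", "err_split",
    "mods_per_kb", "truncation_p", "chimera_frac", "fwd_strand_frac",
    "q_pass_frac", "min_read_len", "seed", "mode")
}

#' Write a simulation configuration to YAML
#'
#' @param config a [SimulationConfig-class].
#' @param path output YAML file path.
#' @return `path`, invisibly.
#' @seealso [readSimConfig()] for the lossless inverse.
#' @export
writeSimConfig <- function(config, path) {
  stopifnot(is(config, "SimulationConfig"))
  x <- lapply(.config_fields(), function(f) slot(config, f))
  names(x) <- .config_fields()
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file written by [writeSimConfig()] (or hand-written with
#'   the same fields; missing fields fall back to the constructor defaults).
#' @return a validated [SimulationConfig-class].
#' @export
readSimConfig <- function(path) {
  x <- yaml::read_yaml(path)
  known <- intersect(names(x), .config_fields())
  do.call(simulationConfig, c(list(mode = x$mode %||% "rna"),
                              x[setdiff(known, "mode")]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a toy reference transcriptome
#'
#' Draws transcript lengths from a gamma distribution (mean `len_mean`,
#' clamped to `[len_min, len_max]`), lays the transcripts end-to-end with
#' 100-base spacers on a single linear chromosome, assigns strands at
#' random, and fills the chromosome with uniform random bases. Deterministic
#' given `config@seed`.
#'
#' @param config a [SimulationConfig-class].
#' @param chrom_len optional fixed chromosome length; an error is raised if
#'   the drawn transcripts cannot fit.
#' @return a list with `reference` (a named `DNAStringSet`) and
#'   `transcripts` (a `GRanges` with a `transcript_id` metadata column).
#' @export
generateTranscriptome <- function(config, chrom_len = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  n <- config@n_transcripts
  shape <- 4
  lens <- as.integer(round(rgamma(n, shape = shape,
                                  scale = config@len_mean / shape)))
  lens <- pmin(pmax(lens, config@len_min), config@len_max)
  spacer <- 100L
  starts <- spacer + cumsum(c(0L, head(lens, -1L) + spacer)) + 1L
  ends <- starts + lens - 1L
  total <- ends[n] + spacer
  if (!is.null(chrom_len)) {
    if (total > chrom_len)
      stop("transcripts (", total, " b) do not fit the requested chromosome (",
           chrom_len, " b)")
    total <- as.integer(chrom_len)
  }
  chrom <- "chrS"
  seq <- DNAStringSet(paste(sample(c("A", "C", "G", "T"), total,
                                   replace = TRUE), collapse = ""))
  names(seq) <- chrom
  ids <- sprintf("TX%04d", seq_len(n))
  sdl <- config@abundance_sdlog
  abundance <- if (sdl > 0) stats::rlnorm(n, -sdl^2 / 2, sdl) else rep(1, n)
  tx <- GRanges(chrom, IRanges(starts, ends),
                strand = sample(c("+", "-"), n, replace = TRUE),
                transcript_id = ids, abundance = abundance,
                seqlengths = stats::setNames(total, chrom))
  names(tx) <- ids
  list(reference = seq, transcripts = tx)
}

#' Plant ground-truth modification sites
#'
#' Draws for each transcript a Poisson number of sites with mean
#' `length/1000 * mods_per_kb` and places them uniformly (without
#' replacement) within the transcript interval, on the transcript strand.
#'
#' @param config a [SimulationConfig-class].
#' @param transcripts transcript `GRanges` from [generateTranscriptome()].
#' @return a width-1 `GRanges` of modified positions with a `transcript_id`
#'   metadata column.
#' @export
plantModifications <- function(config, transcripts) {
  stopifnot(is(config, "SimulationConfig"), is(transcripts, "GRanges"))
  if (!length(transcripts)) stop("empty transcript annotation")
  set.seed(config@seed + 1L)
  lens <- width(transcripts)
  nsites <- rpois(length(transcripts), lens / 1000 * config@mods_per_kb)
  nsites <- pmin(nsites, lens)
  pos <- unlist(lapply(seq_along(transcripts), function(i) {
    if (nsites[i] == 0L) return(integer())
    sort(start(transcripts)[i] - 1L + sample.int(lens[i], nsites[i]))
  }))
  GRanges(rep(as.character(seqnames(transcripts)), nsites),
          IRanges(pos, width = 1L),
          strand = rep(as.character(strand(transcripts)), nsites),
          transcript_id = rep(transcripts$transcript_id, nsites),
          seqinfo = GenomeInfoDb::seqinfo(transcripts))
}

## Truncated-normal draw via inverse CDF
.rtnorm <- function(n, mean, sd, lo, hi) {
  qnorm(runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd)), mean, sd)
}

## Simulate one aligned segment on transcript ti spanning genomic
## [gstart, gend]: per-base errors at p_err_bg (p_err_mod at mod sites),
## split sub/ins/del, insertions attached after their reference base.
.sim_segment <- function(ti, gstart, gend, txenv, config) {
  chars <- txenv$chars[[ti]]
  idx <- (gstart:gend) - txenv$gstart[ti] + 1L
  L <- length(idx)
  base <- chars[idx]
  p <- rep(config@p_err_bg, L)
  mod_rel <- txenv$mods[[ti]] - gstart + 1L
  mod_rel <- mod_rel[mod_rel >= 1L & mod_rel <= L]
  p[mod_rel] <- config@p_err_mod
  err <- runif(L) < p
  nerr <- sum(err)
  op <- rep("M", L)
  ins <- character(L); ins[] <- ""
  nm <- 0L
  if (nerr) {
    type <- sample(c("S", "I", "D"), nerr, replace = TRUE,
                   prob = config@err_split)
    wh <- which(err)
    sub_i <- wh[type == "S"]; ins_i <- wh[type == "I"]; del_i <- wh[type == "D"]
    if (length(sub_i)) {
      alt <- c("A", "C", "G", "T")
      ## cycle the base by a random non-zero offset in ACGT order
      off <- sample.int(3L, length(sub_i), replace = TRUE)
      idx <- match(base[sub_i], alt)
      idx[is.na(idx)] <- 1L
      base[sub_i] <- alt[((idx - 1L + off) %% 4L) + 1L]
    }
    if (length(ins_i))
      ins[ins_i] <- sample(c("A", "C", "G", "T"), length(ins_i),
                           replace = TRUE)
    op[del_i] <- "D"
    base[del_i] <- ""
    nm <- length(sub_i) + length(ins_i) + length(del_i)
  }
  seq <- paste0(paste0(base, ins), collapse = "")
  opchars <- paste0(op, ifelse(nzchar(ins), "I", ""))
  r <- rle(strsplit(paste0(opchars, collapse = ""), "", fixed = TRUE)[[1]])
  list(seq = seq,
       cigar = paste0(r$lengths, r$values, collapse = ""),
       nm = nm, qlen = nchar(seq))
}

## Draw 3'-anchored genomic spans for n reads on transcript ti.
.draw_spans <- function(n, ti, txenv, config) {
  len <- txenv$len[ti]
  if (config@truncation_p > 0) {
    L <- 1L + rgeom(n, config@truncation_p)
  } else {
    L <- rep(len, n)
  }
  L <- pmin(len, pmax(L, min(config@min_read_len, len)))
  if (txenv$strand[ti] == "+") {
    gend <- rep(txenv$gend[ti], n); gstart <- gend - L + 1L
  } else {
    gstart <- rep(txenv$gstart[ti], n); gend <- gstart + L - 1L
  }
  data.frame(gstart = gstart, gend = gend)
}

#' Simulate aligned nanopore-style reads
#'
#' Draws a Poisson number of reads per transcript and emits SAM-level
#' records. In `rna` mode every read is anchored at its transcript's 3'
#' terminus and its 5' start is truncated geometrically (`truncation_p`),
#' reproducing the 3' coverage bias of native-RNA sequencing; the alignment
#' strand follows the transcript. In `cdna` mode the reported orientation is
#' drawn with `fwd_strand_frac`. Per covered base an error occurs with
#' probability `p_err_bg` (`p_err_mod` at planted sites) and is realised as
#' a substitution, 1-base insertion (attached after its reference base) or
#' 1-base deletion per `err_split`. With probability `chimera_frac` a read
#' is chimeric: a primary segment plus a supplementary segment on another
#' transcript, soft-clipped and cross-linked through the `SA` tag. Per-read
#' mean quality is drawn from a two-component truncated-normal mixture so
#' that a fraction `q_pass_frac` has mean Q >= 7; per-base qualities are
#' constant within a read.
#'
#' @param config a [SimulationConfig-class].
#' @param reference named `DNAStringSet` from [generateTranscriptome()].
#' @param transcripts transcript `GRanges`.
#' @param mod_sites planted sites from [plantModifications()] (may be empty).
#' @return a list with `records` (a [ReadRecords-class], coordinate-sorted)
#'   and `truth` (per-read data.frame: `read_id`, `transcript_id`, `start`,
#'   `end`, `strand`, `is_chimera`, `mean_q`).
#' @export
simulateReads <- function(config, reference, transcripts, mod_sites) {
  stopifnot(is(config, "SimulationConfig"), is(reference, "DNAStringSet"),
            is(transcripts, "GRanges"))
  validObject(config)
  chroms <- as.character(unique(seqnames(transcripts)))
  if (!all(chroms %in% names(reference)))
    stop("annotation references chromosomes absent from the reference")
  if (any(end(transcripts) > width(reference)[match(
        as.character(seqnames(transcripts)), names(reference))]))
    stop("transcript intervals exceed reference bounds")
  set.seed(config@seed + 2L)

  ntx <- length(transcripts)
  txenv <- new.env(parent = emptyenv())
  txenv$gstart <- start(transcripts)
  txenv$gend <- end(transcripts)
  txenv$len <- width(transcripts)
  txenv$strand <- as.character(strand(transcripts))
  txenv$chrom <- as.character(seqnames(transcripts))
  txenv$chars <- lapply(seq_len(ntx), function(i) {
    strsplit(as.character(subseq(reference[[txenv$chrom[i]]],
                                 txenv$gstart[i], txenv$gend[i])),
             "", fixed = TRUE)[[1]]
  })
  msl <- split(start(mod_sites),
               factor(mod_sites$transcript_id,
                      levels = transcripts$transcript_id))
  txenv$mods <- lapply(msl, as.integer)

  ab <- if (!is.null(transcripts$abundance)) transcripts$abundance
        else rep(1, ntx)
  nreads <- rpois(ntx, config@coverage_per_transcript * ab)
  ti <- rep(seq_len(ntx), nreads)
  n <- length(ti)
  if (n == 0L) stop("no reads drawn; increase coverage_per_transcript")
  read_id <- sprintf("read%06d", seq_len(n))

  ## orientation of the reported alignment
  if (config@mode == "rna") {
    rev_flag <- txenv$strand[ti] == "-"
  } else {
    rev_flag <- runif(n) >= config@fwd_strand_frac
  }
  ## per-read mean quality (two-component truncated normal mixture)
  is_pass <- runif(n) < config@q_pass_frac
  q <- numeric(n)
  q[is_pass] <- .rtnorm(sum(is_pass), 9.5, 1.5, 7, 41)
  q[!is_pass] <- .rtnorm(sum(!is_pass), 5, 1, 1, 6.5)
  q_int <- pmax(1L, pmin(41L, as.integer(round(q))))

  chim <- runif(n) < config@chimera_frac & ntx > 1L
  ti2 <- integer(n)
  if (any(chim))
    ti2[chim] <- vapply(ti[chim], function(i)
      sample(setdiff(seq_len(ntx), i), 1L), 1L)

  spans <- matrix(0L, n, 2L)
  for (i in seq_len(ntx)) {
    w <- which(ti == i)
    if (length(w)) {
      sp <- .draw_spans(length(w), i, txenv, config)
      spans[w, 1L] <- sp$gstart; spans[w, 2L] <- sp$gend
    }
  }

  rec <- vector("list", n + sum(chim))
  k <- 0L
  for (r in seq_len(n)) {
    seg1 <- .sim_segment(ti[r], spans[r, 1L], spans[r, 2L], txenv, config)
    st1 <- if (rev_flag[r]) "-" else "+"
    flag1 <- if (rev_flag[r]) 16L else 0L
    if (!chim[r]) {
      k <- k + 1L
      rec[[k]] <- list(read_id = read_id[r], flag = flag1,
                       ref = txenv$chrom[ti[r]], pos = spans[r, 1L],
                       cigar = seg1$cigar, seq = seg1$seq, nm = seg1$nm,
                       sa = NA_character_, qlen = seg1$qlen, q = q_int[r],
                       strand = st1)
    } else {
      sp2 <- .draw_spans(1L, ti2[r], txenv, config)
      seg2 <- .sim_segment(ti2[r], sp2$gstart, sp2$gend, txenv, config)
      fullseq <- paste0(seg1$seq, seg2$seq)
      cig1 <- paste0(seg1$cigar, seg2$qlen, "S")
      cig2 <- paste0(seg1$qlen, "S", seg2$cigar)
      sa1 <- sprintf("%s,%d,%s,%s,60,%d;", txenv$chrom[ti2[r]], sp2$gstart,
                     st1, cig2, seg2$nm)
      sa2 <- sprintf("%s,%d,%s,%s,60,%d;", txenv$chrom[ti[r]], spans[r, 1L],
                     st1, cig1, seg1$nm)
      k <- k + 1L
      rec[[k]] <- list(read_id = read_id[r], flag = flag1,
                       ref = txenv$chrom[ti[r]], pos = spans[r, 1L],
                       cigar = cig1, seq = fullseq, nm = seg1$nm,
                       sa = sa1, qlen = nchar(fullseq), q = q_int[r],
                       strand = st1)
      k <- k + 1L
      rec[[k]] <- list(read_id = read_id[r], flag = flag1 + 2048L,
                       ref = txenv$chrom[ti2[r]], pos = sp2$gstart,
                       cigar = cig2, seq = fullseq, nm = seg2$nm,
                       sa = sa2, qlen = nchar(fullseq), q = q_int[r],
                       strand = st1)
    }
  }
  df <- DataFrame(
    read_id = vapply(rec, `[[`, "", "read_id"),
    flag = vapply(rec, `[[`, 0L, "flag"),
    ref = vapply(rec, `[[`, "", "ref"),
    pos = vapply(rec, `[[`, 0L, "pos"),
    mapq = 60L,
    cigar = vapply(rec, `[[`, "", "cigar"),
    seq = vapply(rec, `[[`, "", "seq"),
    qual = NA_character_,
    nm = vapply(rec, `[[`, 0L, "nm"),
    sa = vapply(rec, `[[`, NA_character_, "sa"),
    read_length = vapply(rec, `[[`, 0L, "qlen"),
    mean_q = as.numeric(vapply(rec, `[[`, 0L, "q")),
    strand = vapply(rec, `[[`, "", "strand"))
  df$qual <- strrep(vapply(df$mean_q + 33L, function(x) rawToChar(as.raw(x)),
                           ""),
                    df$read_length)
  df <- df[order(df$ref, df$pos, df$read_id, df$flag), , drop = FALSE]
  records <- ReadRecords(df)
  metadata(records@records)$seqlengths <-
    stats::setNames(width(reference), names(reference))
  metadata(records@records)$seed <- config@seed

  truth <- data.frame(
    read_id = read_id,
    transcript_id = transcripts$transcript_id[ti],
    start = spans[, 1L], end = spans[, 2L],
    strand = ifelse(rev_flag, "-", "+"),
    is_chimera = chim,
    mean_q = as.numeric(q_int))
  list(records = records, truth = truth)
}

#' Run the full simulator
#'
#' Convenience wrapper: generates the transcriptome, plants modification
#' sites, simulates reads and (optionally) writes all standard-format
#' outputs to a directory.
#'
#' @param config a [SimulationConfig-class].
#' @param outdir optional output directory; see [writeSimulation()].
#' @return a list: `config`, `reference`, `transcripts`, `mod_sites`,
#'   `reads` ([ReadRecords-class]) and `truth` (per-read data.frame).
#' @examples
#' sim <- simulateRun(simulationConfig("rna", n_transcripts = 3,
#'                                     coverage_per_transcript = 10,
#'                                     seed = 7))
#' sim$reads
#' @export
simulateRun <- function(config, outdir = NULL) {
  txome <- generateTranscriptome(config)
  mods <- plantModifications(config, txome$transcripts)
  rd <- simulateReads(config, txome$reference, txome$transcripts, mods)
  res <- list(config = config, reference = txome$reference,
              transcripts = txome$transcripts, mod_sites = mods,
              reads = rd$records, truth = rd$truth)
  if (!is.null(outdir)) writeSimulation(res, outdir)
  res
}

#' Write simulated data as standard-format files
#'
#' Writes `ref.fa` (FASTA), `transcripts.bed` and `mod_sites.bed` (BED6,
#' 0-based half-open), `reads.sam` (coordinate-sorted, with `NM` and `SA`
#' tags), `reads.fastq` (Phred+33; reverse-flag reads are
#' reverse-complemented back to read orientation), `read_truth.tsv` and
#' `config.yaml`. Output bytes are fully determined by the configuration.
#'
#' @param sim result of [simulateRun()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
writeSimulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  writeXStringSet(sim$reference, file.path(outdir, "ref.fa"))
  .write_bed6(sim$transcripts, sim$transcripts$transcript_id,
              file.path(outdir, "transcripts.bed"))
  .write_bed6(sim$mod_sites, sim$mod_sites$transcript_id,
              file.path(outdir, "mod_sites.bed"))
  writeSam(sim$reads, file.path(outdir, "reads.sam"),
           seed = sim$config@seed)
  df <- readRecords(sim$reads)
  prim <- df[bitwAnd(df$flag, 0x900) == 0L, , drop = FALSE]
  sq <- DNAStringSet(prim$seq)
  rev <- bitwAnd(prim$flag, 0x10) > 0L
  sq[rev] <- reverseComplement(sq[rev])
  qv <- vapply(prim$qual, function(x) x, "")
  qv[rev] <- vapply(qv[rev], function(x)
    intToUtf8(rev(utf8ToInt(x))), "")
  fq <- file.path(outdir, "reads.fastq")
  writeLines(paste0("@", prim$read_id, "\n", as.character(sq), "\n+\n", qv),
             fq)
  utils::write.table(sim$truth, file.path(outdir, "read_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeSimConfig(sim$config, file.path(outdir, "config.yaml"))
  invisible(outdir)
}

.write_bed6 <- function(gr, names, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = names, score = 0L,
                   strand = as.character(strand(gr)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Write ReadRecords as a SAM file
#'
#' Emits a coordinate-sorted SAM with `@HD`/`@SQ`/`@PG` headers, `NM` edit
#' distance and `SA` supplementary-linkage tags. The RNG seed is recorded in
#' a `@CO` line; no timestamps are written, so output is byte-reproducible.
#'
#' @param records a [ReadRecords-class]; sequence lengths are taken from its
#'   metadata or from `seqlengths`.
#' @param path output SAM path.
#' @param seqlengths named integer vector of reference lengths (optional if
#'   present in the records' metadata).
#' @param seed integer recorded in the header comment, or `NULL`.
#' @return `path`, invisibly.
#' @export
writeSam <- function(records, path, seqlengths = NULL, seed = NULL) {
  stopifnot(is(records, "ReadRecords"))
  df <- readRecords(records)
  if (is.null(seqlengths))
    seqlengths <- metadata(df)$seqlengths
  if (is.null(seqlengths))
    stop("seqlengths not supplied and absent from records metadata")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   as.integer(seqlengths)),
           "@PG\tID:nanomod\tPN:nanomod")
  if (!is.null(seed)) hdr <- c(hdr, sprintf("@CO\tseed:%d", as.integer(seed)))
  unmapped <- bitwAnd(df$flag, 0x4) > 0L
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d",
                  df$read_id, df$flag,
                  ifelse(unmapped, "*", df$ref),
                  ifelse(unmapped, 0L, df$pos),
                  ifelse(unmapped, 0L, df$mapq),
                  ifelse(unmapped, "*", df$cigar),
                  df$seq, df$qual, ifelse(is.na(df$nm), 0L, df$nm))
  has_sa <- !is.na(df$sa)
  body[has_sa] <- paste0(body[has_sa], "\tSA:Z:", df$sa[has_sa])
  writeLines(c(hdr, body), path)
  invisible(path)
}
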