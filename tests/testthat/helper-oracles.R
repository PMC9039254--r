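## Shared helpers: independent oracles and hand-built fixtures.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
  library(Biostrings)
})

site_key <- function(g) paste(seqnames(g), start(g), strand(g))

## Brute-force one-sided Fisher p for the 2x2 table [a,b; c,d]: explicit
## enumeration of the hypergeometric point masses over the fixed margins,
## independent of any distribution-function implementation.
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; m <- a + c; N <- r1 + r2
  xs <- max(0, m - r2):min(m, r1)
  logp <- lchoose(r1, xs) + lchoose(r2, m - xs) - lchoose(N, m)
  w <- exp(logp - max(logp))
  sum(w[xs >= a]) / sum(w)
}

## CMH statistic/p via stats::mantelhaen.test on one K-stratum site.
cmh_reference <- function(a, b, c, d, correct = TRUE) {
  K <- length(a)
  tb <- array(0, c(2, 2, K))
  for (k in seq_len(K))
    tb[, , k] <- matrix(c(a[k], c[k], b[k], d[k]), 2, 2)
  mt <- stats::mantelhaen.test(tb, correct = correct, exact = FALSE)
  list(stat = unname(mt$statistic), p = mt$p.value,
       or = unname(mt$estimate))
}

## Build a ReadRecords object from minimal per-record fields; fills in
## constant-quality strings so mean_q round-trips exactly.
make_records <- function(read_id, flag, ref, pos, cigar, seq,
                         nm = 0L, sa = NA_character_, mean_q = 20,
                         strand = NULL) {
  n <- length(read_id)
  flag <- rep_len(flag, n); nm <- rep_len(as.integer(nm), n)
  sa <- rep_len(sa, n); mean_q <- rep_len(mean_q, n)
  if (is.null(strand))
    strand <- ifelse(bitwAnd(flag, 0x4) > 0L, "*",
                     ifelse(bitwAnd(flag, 0x10) > 0L, "-", "+"))
  qual <- strrep(vapply(as.integer(round(mean_q)) + 33L,
                        function(x) rawToChar(as.raw(x)), ""), nchar(seq))
  ReadRecords(DataFrame(
    read_id = read_id, flag = as.integer(flag),
    ref = rep_len(ref, n), pos = as.integer(rep_len(pos, n)),
    mapq = rep_len(60L, n), cigar = cigar, seq = seq, qual = qual,
    nm = nm, sa = sa, read_length = nchar(seq),
    mean_q = as.numeric(mean_q), strand = strand))
}

## Hand-written six-record SAM: 2 mapped, 1 unmapped, 1 chimeric pair
## (2 records), 1 secondary-only. Returns the file path.
write_six_read_sam <- function(path = tempfile(fileext = ".sam")) {
  qs <- function(q, n) strrep(rawToChar(as.raw(q + 33L)), n)
  A <- function(n) strrep("A", n)
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:ref\tLN:1000",
    paste("m1", 0, "ref", 1, 60, "300M", "*", 0, 0, A(300), qs(10, 300),
          "NM:i:0", sep = "\t"),
    paste("s1", 256, "ref", 10, 0, "50M", "*", 0, 0, A(50), qs(8, 50),
          "NM:i:0", sep = "\t"),
    paste("c1", 0, "ref", 50, 60, "100M200S", "*", 0, 0, A(300), qs(9, 300),
          "NM:i:0", "SA:Z:ref,600,+,100S200M,60,0;", sep = "\t"),
    paste("m2", 0, "ref", 400, 60, "201M", "*", 0, 0, A(201), qs(7, 201),
          "NM:i:0", sep = "\t"),
    paste("c1", 2048, "ref", 600, 60, "100S200M", "*", 0, 0, A(300),
          qs(9, 300), "NM:i:0", "SA:Z:ref,50,+,100M200S,60,0;", sep = "\t"),
    paste("u1", 4, "*", 0, 0, "*", "*", 0, 0, A(250), qs(6, 250),
          sep = "\t"))
  writeLines(lines, path)
  path
}

## Small, fast simulation presets used across tests.
quick_config <- function(seed, ...) {
  args <- list(mode = "rna", n_transcripts = 5L,
               len_min = 300L, len_mean = 600, len_max = 1200L,
               coverage_per_transcript = 40, abundance_sdlog = 0,
               p_err_bg = 0.05, p_err_mod = 0.30, truncation_p = 0,
               chimera_frac = 0, q_pass_frac = 1, seed = as.integer(seed))
  args[names(list(...))] <- list(...)
  do.call(simulationConfig, args)
}
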