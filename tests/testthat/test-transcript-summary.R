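test_that("read counting matches brute-force overlap counting", {
  set.seed(13)
  tx <- GRanges("chrS", IRanges(c(1, 101, 301, 501), width = c(100, 150, 100, 200)),
                c("+", "-", "+", "+"),
                transcript_id = paste0("T", 1:4))
  n <- 20
  starts <- sample(1:650, n, replace = TRUE)
  widths <- sample(20:120, n, replace = TRUE)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  rec <- make_records(sprintf("r%02d", 1:n), ifelse(strands == "-", 16L, 0L),
                      "chrS", starts, paste0(widths, "M"),
                      strrep("A", widths), strand = strands)
  counts <- countReads(rec, tx)
  ## brute force: nested loops over reads x transcripts
  brute <- integer(length(tx))
  for (i in seq_along(tx)) for (r in seq_len(n)) {
    ov <- min(end(tx)[i], starts[r] + widths[r] - 1) >=
      max(start(tx)[i], starts[r])
    if (ov && strands[r] == as.character(strand(tx))[i])
      brute[i] <- brute[i] + 1L
  }
  expect_equal(unname(counts), brute)
})

test_that("a read spanning two adjacent same-strand transcripts counts in both", {
  tx <- GRanges("chrS", IRanges(c(1, 120), width = 100), "+",
                transcript_id = c("T1", "T2"))
  rec <- make_records("r1", 0L, "chrS", 90L, "40M", strrep("A", 40))
  expect_equal(unname(countReads(rec, tx)), c(1L, 1L))
})

test_that("unsorted annotation triggers a warning and internal sorting", {
  tx <- GRanges("chrS", IRanges(c(200, 1), width = 50), "+",
                transcript_id = c("T2", "T1"))
  rec <- make_records("r1", 0L, "chrS", 10L, "20M", strrep("A", 20))
  expect_warning(cnt <- countReads(rec, tx), "sort")
  expect_equal(cnt, c(T1 = 1L, T2 = 0L))
})

test_that("count correlations have unit diagonal, symmetry, exact cases", {
  m <- cbind(s1 = c(10, 100, 1000, 20), s2 = c(10, 100, 1000, 20) * 3,
             s3 = c(5, 80, 900, 400))
  r <- correlateCounts(m)
  expect_equal(diag(r), c(s1 = 1, s2 = 1, s3 = 1))
  expect_equal(r, t(r))
  expect_gt(r["s1", "s2"], 0.999)  # scalar multiples, counts >= 10
  expect_warning(correlateCounts(cbind(a = c(1, 1), b = c(1, 2))),
                 "zero-variance")
})

test_that("independent simulated replicates correlate strongly", {
  cfg <- simulationConfig("rna", n_transcripts = 200L,
                          coverage_per_transcript = 50,
                          len_min = 200L, len_mean = 400, len_max = 800L,
                          p_err_bg = 0.05, p_err_mod = 0.3, truncation_p = 0,
                          chimera_frac = 0, q_pass_frac = 1, seed = 21L)
  txo <- generateTranscriptome(cfg)
  mods <- plantModifications(cfg, txo$transcripts)
  mk <- function(s) {
    c2 <- cfg; c2@seed <- as.integer(s)
    simulateReads(c2, txo$reference, txo$transcripts, mods)$records
  }
  se <- buildCountTable(list(rep1 = mk(121), rep2 = mk(221)),
                        txo$transcripts,
                        col_data = S4Vectors::DataFrame(
                          condition = c("glu", "glu"), replicate = 1:2))
  r <- correlateCounts(se)
  expect_gt(r["rep1", "rep2"], 0.9)
  ## per-transcript counts recover the expected depth
  counts <- SummarizedExperiment::assay(se, "counts")
  mu <- 50 * txo$transcripts$abundance
  pooled <- rowSums(counts)
  expect_lt(abs(sum(pooled) / 2 - sum(mu)) / sum(mu), 0.1)
})

test_that("sites per transcript include zeros and honor overlaps", {
  tx <- GRanges("chrS", IRanges(c(1, 50, 200), width = c(100, 100, 50)),
                "+", transcript_id = c("T1", "T2", "T3"))
  empty <- sitesPerTranscript(GRanges(), tx)
  expect_equal(unname(empty$counts), c(0L, 0L, 0L))
  expect_equal(empty$median, 0)

  sites <- GRanges("chrS", IRanges(c(60, 70, 210), width = 1), "+")
  sp <- sitesPerTranscript(sites, tx)
  expect_equal(unname(sp$counts), c(2L, 2L, 1L))  # 60,70 in both T1 and T2
  ## conservation: sum of per-transcript counts >= number of sites
  expect_gte(sum(sp$counts), length(sites))
})

test_that("sites-per-transcript density tracks the generator truth", {
  cfg <- quick_config(29, n_transcripts = 30L, mods_per_kb = 10,
                      len_min = 1500L, len_mean = 2000, len_max = 2500L,
                      coverage_per_transcript = 1)
  txo <- generateTranscriptome(cfg)
  mods <- plantModifications(cfg, txo$transcripts)
  sp <- sitesPerTranscript(mods, txo$transcripts)
  ## ~2 kb at 10/kb: median around 20
  expect_lt(abs(sp$median - 20), 5)
})

test_that("Jaccard index matches hand counts and satisfies its bounds", {
  tx <- GRanges("chrS", IRanges(1, 100), "+", transcript_id = "T1")
  g <- function(p) GRanges("chrS", IRanges(p, width = 1), "+")
  expect_equal(jaccardPerTranscript(g(c(3, 7, 9)), g(c(7, 9, 15)), tx)$jaccard,
               0.5)
  expect_equal(jaccardPerTranscript(g(1:4), g(1:4), tx)$jaccard, 1.0)
  expect_equal(jaccardPerTranscript(g(1:3), g(5:8), tx)$jaccard, 0.0)
  ## empty union excluded
  expect_equal(nrow(jaccardPerTranscript(GRanges(), GRanges(), tx)), 0L)
  ## symmetry
  set.seed(14)
  A <- g(sample(1:100, 20)); B <- g(sample(1:100, 25))
  jab <- jaccardPerTranscript(A, B, tx)$jaccard
  jba <- jaccardPerTranscript(B, A, tx)$jaccard
  expect_equal(jab, jba)
  expect_true(jab >= 0 && jab <= 1)
  ## windowed matching
  jw <- jaccardPerTranscript(g(10), g(12), tx, window = 2)
  expect_equal(jw$jaccard, 1.0)
})

test_that("track correlation joins on positions and flags tiny overlaps", {
  tA <- data.frame(ref = "c", pos = 1:10, value = (1:10)^2)
  expect_equal(correlateTracks(tA, tA)$r, 1.0)
  tB <- tA; tB$value <- -tB$value
  expect_equal(correlateTracks(tA, tB)$r, -1.0)
  tC <- data.frame(ref = "c", pos = 11:12, value = 1:2)
  expect_warning(res <- correlateTracks(tA, tC), "fewer than 3")
  expect_true(is.na(res$r))
  expect_equal(res$n, 0L)
})
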