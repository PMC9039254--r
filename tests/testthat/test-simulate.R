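test_that("configuration validates its parameter space and round-trips YAML", {
  expect_error(simulationConfig("rna", p_err_bg = 0.3, p_err_mod = 0.1),
               "p_err_mod")
  expect_error(simulationConfig("rna", chimera_frac = 1.5), "\\[0,1\\]")
  expect_error(simulationConfig("rna", n_transcripts = 0), "n_transcripts")
  expect_error(simulationConfig("rna", err_split = c(1, 1, 1)), "err_split")

  cfg <- simulationConfig("cdna", n_transcripts = 7L, p_err_bg = 0.08,
                          p_err_mod = 0.25, seed = 42L,
                          err_split = c(0.5, 0.25, 0.25))
  f <- tempfile(fileext = ".yaml")
  writeSimConfig(cfg, f)
  cfg2 <- readSimConfig(f)
  for (s in slotNames(cfg))
    expect_equal(slot(cfg2, s), slot(cfg, s), info = s)
})

test_that("transcriptome generation is deterministic and respects geometry", {
  cfg <- simulationConfig("rna", n_transcripts = 1L, len_min = 1000L,
                          len_mean = 1000, len_max = 1000L, seed = 3L)
  tx <- generateTranscriptome(cfg)
  expect_length(tx$reference, 1L)
  expect_length(tx$transcripts, 1L)
  expect_equal(width(tx$transcripts), 1000L)

  cfg2 <- simulationConfig("rna", n_transcripts = 100L, seed = 9L)
  a <- generateTranscriptome(cfg2)
  b <- generateTranscriptome(cfg2)
  expect_identical(as.character(a$reference), as.character(b$reference))
  expect_identical(start(a$transcripts), start(b$transcripts))
  ## total annotated bases close to n * len_mean (gamma clamping allows slack)
  expect_lt(abs(sum(width(a$transcripts)) - 150000) / 150000, 0.2)
  ## non-overlapping intervals
  expect_true(all(start(a$transcripts)[-1] >
                    head(end(a$transcripts), -1)))
  expect_error(generateTranscriptome(cfg2, chrom_len = 1000), "fit")
})

test_that("planted modification sites follow the Poisson density and lie in transcripts", {
  tx <- GRanges("chrS", IRanges(101, 2100), "+", transcript_id = "TX0001",
                seqlengths = c(chrS = 2300L))
  cfg0 <- simulationConfig("rna", mods_per_kb = 0, seed = 1L)
  expect_length(plantModifications(cfg0, tx), 0L)

  counts <- vapply(1:200, function(s) {
    cfg <- simulationConfig("rna", mods_per_kb = 10, seed = as.integer(s))
    length(plantModifications(cfg, tx))
  }, 1L)
  ## 2 kb at 10 sites/kb: mean 20, Poisson SE over 200 draws
  se <- sqrt(20 / 200)
  expect_lt(abs(mean(counts) - 20), 3 * se)

  cfg <- simulationConfig("rna", mods_per_kb = 10, seed = 5L)
  sites <- plantModifications(cfg, tx)
  expect_true(all(start(sites) >= start(tx) & start(sites) <= end(tx)))
  expect_true(all(as.character(strand(sites)) == "+"))
})

test_that("error-free limit yields exact full-length matches", {
  cfg <- quick_config(11, p_err_bg = 0, p_err_mod = 1e-6)
  sim <- simulateRun(cfg)
  df <- readRecords(sim$reads)
  expect_true(all(grepl("^[0-9]+M$", df$cigar)))
  expect_true(all(df$nm == 0L))
  expect_true(all(readIdentity(sim$reads) == 100))
})

test_that("simulator output is byte-identical under a fixed seed", {
  cfg <- quick_config(17, n_transcripts = 3L, chimera_frac = 0.2,
                      truncation_p = 0.002, q_pass_frac = 0.8)
  d1 <- tempfile(); d2 <- tempfile()
  simulateRun(cfg, outdir = d1)
  simulateRun(cfg, outdir = d2)
  for (f in c("ref.fa", "transcripts.bed", "mod_sites.bed", "reads.sam",
              "reads.fastq", "read_truth.tsv", "config.yaml"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
})

test_that("reads are 3'-anchored in rna mode", {
  cfg <- quick_config(23, truncation_p = 0.005)
  sim <- simulateRun(cfg)
  df <- readRecords(sim$reads)
  prim <- df[bitwAnd(df$flag, 0x900) == 0L & is.na(df$sa), , drop = FALSE]
  tx <- sim$transcripts
  w <- GenomicAlignments::cigarWidthAlongReferenceSpace(prim$cigar)
  ends <- prim$pos + w - 1L
  ti <- match(sim$truth$transcript_id[match(prim$read_id,
                                            sim$truth$read_id)],
              tx$transcript_id)
  plus <- as.character(strand(tx))[ti] == "+"
  expect_true(all(ends[plus] == end(tx)[ti[plus]]))
  expect_true(all(prim$pos[!plus] == start(tx)[ti[!plus]]))
})

test_that("empirical error rates recover the configured probabilities", {
  cfg <- quick_config(31, n_transcripts = 8L, coverage_per_transcript = 60,
                      mods_per_kb = 5)
  sim <- simulateRun(cfg)
  pu <- computePileup(sim$reads, sim$reference, sim$transcripts,
                      apply_qc = FALSE)
  ismod <- site_key(pu) %in% site_key(sim$mod_sites)
  n_bg <- sum(pu$coverage[!ismod]); e_bg <- sum(pu$n_error[!ismod])
  n_md <- sum(pu$coverage[ismod]); e_md <- sum(pu$n_error[ismod])
  expect_lt(abs(e_bg / n_bg - 0.05), 3 * sqrt(0.05 * 0.95 / n_bg))
  expect_lt(abs(e_md / n_md - 0.30), 3 * sqrt(0.30 * 0.70 / n_md))
})

test_that("chimera fraction and pass fraction are recovered within 3 SE", {
  cfg <- quick_config(37, n_transcripts = 10L, coverage_per_transcript = 80,
                      chimera_frac = 0.18, q_pass_frac = 0.7)
  sim <- simulateRun(cfg)
  df <- readRecords(sim$reads)
  ids <- unique(df$read_id)
  n <- length(ids)
  supp <- unique(df$read_id[bitwAnd(df$flag, 0x800) > 0L])
  expect_lt(abs(length(supp) / n - 0.18), 3 * sqrt(0.18 * 0.82 / n))
  prim <- df[bitwAnd(df$flag, 0x900) == 0L, , drop = FALSE]
  frac_pass <- mean(prim$mean_q >= 7)
  expect_lt(abs(frac_pass - 0.7), 3 * sqrt(0.7 * 0.3 / n))
})

test_that("geometric truncation matches its closed-form survival curve", {
  ## one transcript, deep coverage; read lengths back from the 3' anchor
  ## should follow S(d) = (1-p)^d (censored at the transcript length)
  p <- 0.002
  cfg <- simulationConfig("rna", n_transcripts = 1L, len_min = 2000L,
                          len_mean = 2000, len_max = 2000L,
                          coverage_per_transcript = 500,
                          abundance_sdlog = 0,
                          p_err_bg = 0, p_err_mod = 1e-6,
                          truncation_p = p, chimera_frac = 0,
                          q_pass_frac = 1, min_read_len = 1L, seed = 41L)
  sim <- simulateRun(cfg)
  L <- sim$truth$end - sim$truth$start + 1L
  d <- 0:1999
  s_theory <- (1 - p)^d
  s_emp <- vapply(d, function(x) mean(L > x), 1)
  ## censoring at the 3' anchor: both curves live on [0, len)
  expect_lt(max(abs(s_emp - s_theory)), 0.05)
  ## pooled coverage non-increasing from the 3' end (in expectation):
  ## check monotonicity of the theoretical curve against binned empirical
  pu <- computePileup(sim$reads, sim$reference, sim$transcripts,
                      apply_qc = FALSE)
  ## order coverage by distance from the 3' terminus
  cov_by_d <- if (as.character(strand(sim$transcripts)) == "+")
    rev(pu$coverage) else pu$coverage
  bins <- split(cov_by_d, rep(1:20, each = 100))
  mb <- vapply(bins, mean, 1)
  expect_true(all(diff(mb) <= 0 | abs(diff(mb)) < 15))
})

test_that("simulateReads rejects inconsistent annotation", {
  cfg <- quick_config(43)
  tx <- generateTranscriptome(cfg)
  bad <- suppressWarnings(GenomicRanges::shift(tx$transcripts, 1e6))
  expect_error(suppressWarnings(simulateReads(cfg, tx$reference, bad,
                                              GRanges())), "bounds|absent")
})
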