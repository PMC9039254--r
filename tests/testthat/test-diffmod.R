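random_strata <- function(n, K = 3, cov = c(30, 150), p = c(0.02, 0.3)) {
  cov_a <- matrix(sample(cov[1]:cov[2], n * K, TRUE), n, K)
  cov_b <- matrix(sample(cov[1]:cov[2], n * K, TRUE), n, K)
  pa <- matrix(runif(n * K, p[1], p[2]), n, K)
  pb <- matrix(runif(n * K, p[1], p[2]), n, K)
  a <- matrix(rbinom(n * K, cov_a, pa), n, K)
  c_ <- matrix(rbinom(n * K, cov_b, pb), n, K)
  stratifiedTables(a, cov_a - a, c_, cov_b - c_)
}

test_that("CMH statistic and p agree with the stock stratified test", {
  set.seed(8)
  st <- random_strata(300)
  for (correct in c(TRUE, FALSE)) {
    res <- cmhTest(st, continuity = correct)
    for (i in seq_len(50)) {
      ref <- cmh_reference(st@a[i, ], st@b[i, ], st@c[i, ], st@d[i, ],
                           correct = correct)
      expect_lt(abs(res$cmh_statistic[i] - ref$stat), 1e-8)
      expect_lt(abs(res$pval[i] - ref$p), 1e-8)
    }
  }
})

test_that("Mantel-Haenszel common OR matches the stock estimator and examples", {
  set.seed(9)
  st <- random_strata(100)
  or <- mhCommonOR(st)
  nz <- which(apply(st@a > 0 & st@b > 0 & st@c > 0 & st@d > 0, 1, all))
  for (i in nz[1:20]) {
    ref <- cmh_reference(st@a[i, ], st@b[i, ], st@c[i, ], st@d[i, ])
    expect_equal(or[i], ref$or, tolerance = 1e-12)
  }
  ## identical proportions across strata
  st1 <- stratifiedTables(matrix(10, 1, 3), matrix(90, 1, 3),
                          matrix(10, 1, 3), matrix(90, 1, 3))
  expect_equal(mhCommonOR(st1), 1.0)
  ## single-stratum cross-product
  st2 <- stratifiedTables(20, 80, 10, 90)
  expect_equal(mhCommonOR(st2), 2.25)
})

test_that("single-stratum CMH equals the ordinary 2x2 score chi-square", {
  a <- 25; b <- 75; c <- 5; d <- 95
  st <- stratifiedTables(a, b, c, d)
  res <- cmhTest(st, continuity = FALSE)
  n <- a + b + c + d
  chi <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  ## CMH variance uses n-1; the score statistic uses n
  expect_equal(res$cmh_statistic * n / (n - 1), chi, tolerance = 1e-12)
})

test_that("null tables give zero statistic and degenerate strata are handled", {
  st <- stratifiedTables(matrix(c(10, 20), 1, 2), matrix(c(90, 80), 1, 2),
                         matrix(c(10, 20), 1, 2), matrix(c(90, 80), 1, 2))
  res <- cmhTest(st, continuity = FALSE)
  expect_equal(res$cmh_statistic, 0)
  expect_equal(res$pval, 1)

  ## all-degenerate site: zero column margins
  st0 <- stratifiedTables(0, 50, 0, 50)
  res0 <- cmhTest(st0)
  expect_true(res0$degenerate)
  expect_equal(res0$pval, 1)
})

test_that("condition swap inverts the OR, flips direction, keeps p", {
  set.seed(10)
  st <- random_strata(200)
  sw <- stratifiedTables(st@c, st@d, st@a, st@b, sites = strataSites(st))
  r1 <- diffModCall(st); r2 <- diffModCall(sw)
  expect_equal(r2$pval, r1$pval, tolerance = 1e-12)
  expect_equal(r2$or_mh, 1 / r1$or_mh, tolerance = 1e-12)
  expect_equal(r2$passed, r1$passed)
  flip <- !is.na(r1$direction)
  expect_equal(as.character(r2$direction[flip]),
               ifelse(r1$direction[flip] == "A_higher",
                      "B_higher", "A_higher"))
})

test_that("reordering replicate strata leaves all outputs unchanged", {
  set.seed(11)
  st <- random_strata(100, K = 4)
  perm <- c(3, 1, 4, 2)
  stp <- stratifiedTables(st@a[, perm], st@b[, perm], st@c[, perm],
                          st@d[, perm], sites = strataSites(st))
  expect_equal(cmhTest(st), cmhTest(stp))
  expect_equal(mhCommonOR(st), mhCommonOR(stp))
})

test_that("identical strata collapse to the single-table cross-product OR", {
  a <- 18; b <- 82; c <- 6; d <- 94
  st <- stratifiedTables(matrix(a, 1, 3), matrix(b, 1, 3),
                         matrix(c, 1, 3), matrix(d, 1, 3))
  expect_equal(mhCommonOR(st), a * d / (b * c))
})

test_that("strata construction pairs replicates and filters on joint coverage", {
  mkp <- function(cov, err) GRanges("ref", IRanges(seq_along(cov), width = 1),
                                    "+", coverage = as.integer(cov),
                                    n_error = as.integer(err),
                                    n_mismatch = 0L, n_del = 0L, n_ins = 0L)
  pa <- list(mkp(c(100, 100, 5), c(1, 2, 0)),
             mkp(c(100, 100, 100), c(3, 4, 1)),
             mkp(c(100, 50), c(5, 6)))
  pb <- list(mkp(c(100, 100, 100), c(7, 8, 2)),
             mkp(c(100, 100, 100), c(9, 10, 3)),
             mkp(c(100, 100, 100), c(11, 12, 4)))
  st <- buildStrata(pa, pb, min_coverage = 20)
  ## site 1: full margins everywhere; site 2: covered in A reps 1-2 only;
  ## site 3: coverage 5 in A rep 1
  expect_equal(length(st), 2L)
  expect_equal(nStrata(st), 3L)
  expect_equal(st@a[1, ], c(1, 3, 5))
  expect_equal(st@c[1, ], c(7, 9, 11))
  expect_equal(st@a[1, ] + st@b[1, ], c(100, 100, 100))
  expect_error(buildStrata(pa[1:2], pb), "replicates")
})

test_that("differential thresholds apply at their quoted boundaries", {
  calls <- GRanges("ref", IRanges(1:4, width = 1), "+",
                   or_mh = c(1.5, 1.4, 1 / 1.6, 3),
                   adj_pval = c(0.009, 1e-10, 0.001, 0.5))
  out <- callDifferential(calls)
  expect_equal(out$passed, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(as.character(out$direction),
               c("A_higher", "A_higher", "B_higher", "A_higher"))
})

test_that("differential power run calls planted sites and spares nulls", {
  set.seed(12)
  n <- 600; K <- 3; cov <- 150
  is_mod <- seq_len(n) <= 60
  pA <- ifelse(is_mod, 0.20, 0.05)
  a <- matrix(rbinom(n * K, cov, pA), n, K)
  c_ <- matrix(rbinom(n * K, cov, 0.05), n, K)
  st <- stratifiedTables(a, cov - a, c_, cov - c_)
  calls <- diffModCall(st)
  power <- mean(calls$passed[is_mod])
  fpr <- mean(calls$passed[!is_mod])
  expect_gte(power, 0.8)
  expect_lte(fpr, 0.02)
  expect_true(all(calls$direction[calls$passed & is_mod] == "A_higher"))
  d <- tempfile()
  writeDiffCalls(calls, d)
  expect_true(file.exists(file.path(d, "diff_calls.tsv")))
  expect_gt(length(readLines(file.path(d, "a_higher.bed"))), 0)
})
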