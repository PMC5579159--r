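cond22 <- c("sham", "sham", "irradiated", "irradiated")

test_that("region-set merging coalesces across libraries", {
  r1 <- structure(data.frame(chrom = "chr1", start = 0L, end = 1000L),
                  class = c("enriched_regions", "data.frame"), mark = "5mC")
  r2 <- structure(data.frame(chrom = "chr1", start = 500L, end = 1500L),
                  class = c("enriched_regions", "data.frame"), mark = "5mC")
  m <- merge_region_sets(list(r1, r2))
  expect_equal(m, data.frame(chrom = "chr1", start = 0L, end = 1500L))

  # identity for a single set
  expect_equal(merge_region_sets(list(r1))[1, ],
               data.frame(chrom = "chr1", start = 0L, end = 1000L))

  # disjoint sets of m and n intervals give m + n intervals
  r3 <- structure(data.frame(chrom = c("chr1", "chr2"),
                             start = c(5000L, 0L), end = c(6000L, 800L)),
                  class = c("enriched_regions", "data.frame"), mark = "5mC")
  expect_equal(nrow(merge_region_sets(list(r1, r3))), 3)

  # mixed marks refused
  r4 <- structure(data.frame(chrom = "chr1", start = 0L, end = 10L),
                  class = c("enriched_regions", "data.frame"), mark = "5hmC")
  expect_error(merge_region_sets(list(r1, r4)), "per mark")
})

test_that("tag counting per region matches membership", {
  genome <- c(chr1 = 10000)
  regions <- data.frame(chrom = "chr1", start = c(1000L, 5000L),
                        end = c(2000L, 6000L))
  t1 <- mk_tags(c(1000:1006, 50), chrom_len = 10000, library_id = "A")
  t2 <- mk_tags(c(5999, 6000), chrom_len = 10000, library_id = "B")
  rc <- count_tags_in_regions(list(t1, t2), regions)
  expect_equal(rc$counts[, 1], c(7L, 0L))   # 7 tags inside region 1
  expect_equal(rc$counts[, 2], c(0L, 1L))   # 6000 is outside [5000,6000)
  # conservation bound
  expect_true(all(colSums(rc$counts) <= c(8, 2)))
  # overlapping regions refused
  bad <- data.frame(chrom = "chr1", start = c(0L, 500L), end = c(1000L, 1500L))
  expect_error(count_tags_in_regions(list(t1), bad), "non-overlapping")
})

test_that("size factors follow the median-of-ratios closed form", {
  m <- matrix(rpois(400, 50), ncol = 4)
  expect_equal(estimate_size_factors(cbind(m[, 1], m[, 1])), c(1, 1))
  # library B = 2x library A -> factor ratio 2, geometric mean 1
  sf <- estimate_size_factors(cbind(m[, 1], m[, 1] * 2L))
  expect_equal(sf[2] / sf[1], 2, tolerance = 1e-12)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)
  # global rescaling leaves ratios unchanged
  sf3 <- estimate_size_factors(m * 3L)
  expect_equal(sf3 / estimate_size_factors(m), rep(1, 4), tolerance = 1e-12)
  # fallback when no region is positive everywhere
  mz <- rbind(c(10L, 0L), c(0L, 20L))
  expect_warning(sfz <- estimate_size_factors(mz), "total-count")
  expect_equal(sfz[2] / sfz[1], 2, tolerance = 1e-12)
})

test_that("the NB test is symmetric under the null and rejects bad input", {
  m <- cbind(c(30L, 10L), c(40L, 12L), c(30L, 10L), c(40L, 12L))
  rc <- mk_region_counts(m, cond22)
  res <- nb_test(rc, size_factors = rep(1, 4))
  expect_equal(res$log2fc, c(0, 0))
  expect_true(all(res$p > 0.5))
  expect_true(all(res$q >= res$p))
  expect_true(all((res$log2fc >= 0) == (res$direction == "up")))

  expect_error(nb_test(mk_region_counts(m, rep("sham", 4))), "two conditions")
  rc_neg <- mk_region_counts(m, cond22); rc_neg$counts[1, 1] <- -1L
  expect_error(nb_test(rc_neg), "negative")

  # all-zero regions dropped and reported
  m2 <- rbind(m, c(0L, 0L, 0L, 0L))
  res2 <- nb_test(mk_region_counts(m2, cond22), size_factors = rep(1, 4))
  expect_equal(nrow(res2), 2)
  expect_equal(nrow(attr(res2, "dropped")), 1)
})

test_that("in the Poisson limit the Wald p agrees with the exact conditional binomial", {
  set.seed(42)
  n <- 200
  mu <- runif(n, 20, 80)
  m <- cbind(rpois(n, mu), rpois(n, mu),
             rpois(n, mu * runif(n, 0.5, 2)), rpois(n, mu * runif(n, 0.5, 2)))
  res <- nb_test(mk_region_counts(m, cond22), size_factors = rep(1, 4),
                 dispersion = 0)
  # oracle: conditional on the total, the treatment sum is binomial with
  # success probability from the (here equal) size factors
  p_oracle <- vapply(seq_len(n), function(i) {
    binom.test(m[i, 3] + m[i, 4], sum(m[i, ]), 0.5)$p.value
  }, numeric(1))
  expect_lte(max(abs(res$p - p_oracle)), 0.02)
})

test_that("type-I error is near nominal on null NB counts", {
  set.seed(9)
  n <- 2500
  mu <- runif(n, 30, 200)
  m <- sapply(1:4, function(j) rnbinom(n, mu = mu, size = 10))  # dispersion 0.1
  res <- nb_test(mk_region_counts(m, cond22), size_factors = rep(1, 4))
  frac <- mean(res$p <= 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("planted fold-changes are recovered with the expected sensitivity and FDR", {
  set.seed(5)
  ntrue <- 300; nnull <- 2700; n <- ntrue + nnull
  mu <- c(runif(ntrue, 50, 150), runif(nnull, 30, 200))
  fold <- c(rep(4, ntrue), rep(1, nnull))
  m <- cbind(rnbinom(n, mu = mu, size = 20), rnbinom(n, mu = mu, size = 20),
             rnbinom(n, mu = mu * fold, size = 20),
             rnbinom(n, mu = mu * fold, size = 20))
  res <- nb_test(mk_region_counts(m, cond22), size_factors = rep(1, 4))
  sens <- mean(res$q[1:ntrue] < 0.01)
  n_called <- sum(res$q < 0.01)
  fdr <- sum(res$q[(ntrue + 1):n] < 0.01) / max(n_called, 1)
  expect_gte(sens, 0.8)
  expect_lte(fdr, 0.05)
  # direction matches the planted sign for essentially all true positives
  tp_dir <- res$direction[1:ntrue][res$q[1:ntrue] < 0.01]
  expect_gte(mean(tp_dir == "up"), 0.99)
})

test_that("NB test ranks regions like an established NB implementation", {
  set.seed(11)
  n <- 400
  mu <- runif(n, 30, 150)
  fold <- ifelse(seq_len(n) <= 50, 3, 1)
  m <- cbind(rnbinom(n, mu = mu, size = 15), rnbinom(n, mu = mu, size = 15),
             rnbinom(n, mu = mu * fold, size = 15),
             rnbinom(n, mu = mu * fold, size = 15))
  res <- nb_test(mk_region_counts(m, cond22), size_factors = rep(1, 4))
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      countData = m,
      colData = data.frame(condition = factor(cond22,
                                              levels = c("sham", "irradiated"))),
      design = ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    dres <- DESeq2::results(dds)
  })
  keep <- !is.na(dres$pvalue)
  expect_gte(cor(-log10(res$p[keep] + 1e-300),
                 -log10(dres$pvalue[keep] + 1e-300),
                 method = "spearman"), 0.9)
  sign_ok <- sign(res$log2fc[keep]) == sign(dres$log2FoldChange[keep])
  expect_gte(mean(sign_ok[abs(dres$log2FoldChange[keep]) > 0.5]), 0.95)
})

test_that("BH adjustment matches hand computation and edge cases", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.01, 0.2, 0.9)
  expect_true(all(bh_adjust(p) >= p))
  # order invariance (up to permutation)
  o <- c(3, 1, 4, 2)
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
})

test_that("Storey q-values estimate pi0 and reduce to BH when pi0 = 1", {
  set.seed(31)
  p_unif <- runif(5000)
  # uniform nulls can push the raw estimate just above 1 (clipped, warns)
  st <- suppressWarnings(storey_qvalue(p_unif))
  expect_gte(st$pi0, 0.9)
  expect_lte(st$pi0, 1.0)

  # all signal: pi0 near 0, q near 0
  p_sig <- rbeta(2000, 0.05, 10)
  st_sig <- storey_qvalue(p_sig)
  expect_lt(st_sig$pi0, 0.3)
  expect_lt(median(st_sig$q), 0.01)

  # algebraic identity with pi0 fixed at 1
  p_mix <- c(runif(900), rbeta(100, 0.1, 10))
  expect_equal(storey_qvalue(p_mix, pi0 = 1)$q, bh_adjust(p_mix))

  # order invariance
  o <- sample(length(p_mix))
  expect_equal(storey_qvalue(p_mix)$q[o], storey_qvalue(p_mix[o])$q)
})

test_that("significant regions partition by direction at the q threshold", {
  d <- data.frame(q = c(0.001, 0.5, 0.004, 0.02),
                  direction = c("up", "up", "down", "down"))
  s <- call_significant(d, 0.01)
  expect_equal(nrow(s$up), 1)
  expect_equal(nrow(s$down), 1)
  s0 <- call_significant(d[0, ], 0.01)
  expect_equal(nrow(s0$up), 0)
  expect_equal(nrow(s0$down), 0)
  sall <- call_significant(d, 1.0)
  expect_equal(nrow(sall$up) + nrow(sall$down), 4)
})
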