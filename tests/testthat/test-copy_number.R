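make_grid <- function(n, bin = 5e4) {
  lay <- tiny_layout(c(A = n * bin))
  list(lay = lay, grid = tile_genome(lay, bin))
}

test_that("scale_library: identity, factor 0.5, sort-median oracle", {
  g <- make_grid(200)
  ref_med <- rep(100, 200)
  bc <- binned_counts(g$grid, rep(100, 200))
  expect_equal(scale_library(bc, ref_med)$counts, rep(100, 200))
  expect_equal(attr(scale_library(bc, ref_med), "scale_factor"), 1)

  bc2 <- binned_counts(g$grid, rep(200, 200))
  expect_equal(attr(scale_library(bc2, ref_med), "scale_factor"), 0.5)

  set.seed(8)
  counts <- rpois(200, 150)
  ref <- rpois(200, 120) + 1
  bc3 <- binned_counts(g$grid, counts)
  use <- counts > 0
  oracle_s <- sort_median(ref[use] / counts[use])
  expect_equal(attr(scale_library(bc3, ref), "scale_factor"), oracle_s)

  expect_error(scale_library(binned_counts(g$grid, rep(0, 200)), ref_med),
               "cannot scale")
})

test_that("gc_correct flattens bias and leaves constant inputs alone", {
  g <- make_grid(2000)
  set.seed(5)
  gc <- runif(2000, 0.25, 0.75)
  # constant counts, varying gc -> output constant
  bc <- binned_counts(g$grid, rep(500, 2000), gc = gc)
  expect_equal(gc_correct(bc)$counts, rep(500, 2000))
  # deterministic monotone bias, no noise -> constant away from strata edges
  bias <- exp(1.2 * (gc - 0.5))
  bc2 <- binned_counts(g$grid, 500 * bias, gc = gc)
  corr <- gc_correct(bc2)$counts
  # interior of each stratum: relative spread collapses vs the raw 1.8x
  stratum <- floor(gc / 0.02)
  interior <- abs(gc / 0.02 - stratum - 0.5) < 0.3
  spread <- diff(range(corr[interior])) / median(corr[interior])
  expect_lt(spread, 0.05)
  expect_gt(diff(range(500 * bias)) / 500, 0.5)

  expect_error(gc_correct(binned_counts(g$grid, rep(0, 2000), gc = gc)),
               "all-zero")
  expect_error(gc_correct(binned_counts(g$grid, rep(5, 2000))), "no gc")
  gc_sparse <- gc; gc_sparse[1:500] <- NA
  expect_error(gc_correct(binned_counts(g$grid, rep(5, 2000),
                                        gc = gc_sparse)), "need >=")
})

test_that("build_reference equals the brute-force median/MAD oracle", {
  g <- make_grid(50)
  # 3 identical samples -> sd all 0
  same <- lapply(1:3, function(i) binned_counts(g$grid, rep(7, 50),
                                                sample_id = paste0("s", i)))
  ref <- build_reference(same)
  expect_true(all(ref$ref_sd == 0))
  expect_equal(ref$n_samples, 3)
  expect_equal(ref$member_ids, c("s1", "s2", "s3"))

  # bin values {1..5} across 5 samples: median 3, MAD 1 -> sd 1.4826.
  # a cyclic latin square, so every sample holds each value equally often
  # and the one-pass cohort normalisation is exactly the identity
  vals <- outer(seq_len(50), 1:5, function(i, j) ((i + j) %% 5) + 1)
  samples <- lapply(1:5, function(j) binned_counts(g$grid, vals[, j]))
  ref2 <- build_reference(samples)
  expect_equal(unique(ref2$ref_median), 3)
  expect_equal(unique(ref2$ref_sd), 1.4826)

  # random cohort vs oracle, exact equality
  set.seed(13)
  m <- matrix(rpois(50 * 8, 300), nrow = 50)
  cohort <- lapply(seq_len(8), function(j) binned_counts(g$grid, m[, j]))
  ref3 <- build_reference(cohort)
  oracle <- oracle_reference(m)
  expect_identical(ref3$ref_median, oracle$median)
  expect_identical(ref3$ref_sd, oracle$sd)

  g2 <- make_grid(40)
  expect_error(build_reference(cohort, g2$grid), "grid mismatch")
  expect_error(build_reference(list()), "at least one")
})

test_that("reference is robust to tumour contamination (seed 7)", {
  g <- make_grid(500)
  set.seed(7)
  gcv <- runif(500, 0.3, 0.7)
  normals <- lapply(1:20, function(i)
    poisson_sample(g$grid, gcv, 500, 1, sprintf("n%02d", i)))
  # 5 tumours with planted CNVs over 30% of bins
  tumours <- lapply(1:5, function(i) {
    cn <- rep(2, 500)
    cn[sample(500, 150)] <- sample(c(1, 3, 4), 150, replace = TRUE)
    mu <- 500 * (cn / 2) * exp(gcv - 0.5)
    binned_counts(g$grid, rpois(500, mu), gc = gcv,
                  sample_id = sprintf("t%02d", i))
  })
  ref_all <- build_reference(c(normals, tumours))
  ref_norm <- build_reference(normals)
  rel <- abs(ref_all$ref_median - ref_norm$ref_median) /
    ref_norm$ref_median
  expect_gte(mean(rel < 0.02), 0.99)
})

test_that("estimate_cn: identity, halving, monotonicity, low_ref flag", {
  g <- make_grid(100)
  refm <- structure(list(grid = g$grid, ref_median = rep(400, 100),
                         ref_sd = rep(20, 100), n_samples = 10,
                         member_ids = paste0("r", 1:10)),
                    class = "reference_model")
  bc <- binned_counts(g$grid, rep(400, 100))
  cn <- estimate_cn(bc, refm)
  expect_equal(cn$cn, rep(2, 100))
  expect_equal(cn$sd, rep(2 * 20 / 400, 100))

  # heterozygous-deletion signature: x = ref/2 -> CN 1
  x <- rep(400, 100); x[40:50] <- 200
  cn2 <- estimate_cn(binned_counts(g$grid, x), refm)
  expect_equal(unique(cn2$cn[40:50]), 1)

  # monotonicity: scaling a region's counts by k scales cn by exactly k
  x3 <- x; x3[10:20] <- x[10:20] * 1.7
  cn3 <- estimate_cn(binned_counts(g$grid, x3), refm)
  expect_equal(cn3$cn[10:20], cn2$cn[10:20] * 1.7)

  # low reference bins are flagged and NA
  refm2 <- refm; refm2$ref_median[5] <- 3   # below max(10, 1% of 400)
  cn4 <- estimate_cn(bc, refm2)
  expect_true(cn4$flags$low_ref[5])
  expect_true(is.na(cn4$cn[5]))
  expect_false(any(cn4$flags$low_ref[-5]))

  # per-chromosome ploidy override
  cn5 <- estimate_cn(bc, refm, ploidy = c(2, A = 1))
  expect_equal(unique(cn5$cn), 1)

  g2 <- make_grid(50)
  expect_error(estimate_cn(binned_counts(g2$grid, rep(1, 50)), refm),
               "grid mismatch")
})

test_that("reference of n=1 leaves sd missing but CN computable", {
  g <- make_grid(30)
  ref1 <- build_reference(list(binned_counts(g$grid, rep(100, 30))))
  expect_true(all(is.na(ref1$ref_sd)))
  cn <- estimate_cn(binned_counts(g$grid, rep(150, 30)), ref1)
  expect_equal(unique(cn$cn), 3)
  expect_true(all(is.na(cn$sd)))
})

test_that("ratio_mode: identity, CN ratio, floors, count tracks", {
  g <- make_grid(60)
  refm <- build_reference(lapply(1:4, function(i)
    binned_counts(g$grid, rep(300, 60))))
  a <- estimate_cn(binned_counts(g$grid, rep(600, 60)), refm)
  b <- estimate_cn(binned_counts(g$grid, rep(300, 60)), refm)
  # a vs a is 1 on all non-missing support
  raa <- ratio_mode(a, a)
  expect_true(all(raa$ratio[!raa$missing] == 1))
  expect_false(any(raa$missing))
  # CN 4 over CN 2 -> 2
  expect_true(all(ratio_mode(a, b)$ratio == 2))
  # denominator floor -> missing
  b2 <- b; b2$cn[3] <- 0.1
  expect_true(ratio_mode(a, b2)$missing[3])
  # count tracks: denominator is rescaled to the numerator first
  ca <- binned_counts(g$grid, rpois(60, 1000) + 1)
  cb <- binned_counts(g$grid, (rpois(60, 1000) + 1) * 3)
  rc <- ratio_mode(ca, cb)
  expect_equal(median(rc$ratio, na.rm = TRUE), 1, tolerance = 0.05)
  g2 <- make_grid(10)
  expect_error(ratio_mode(a, estimate_cn(binned_counts(g2$grid,
                                                       rep(300, 10)),
                                         build_reference(list(
                                           binned_counts(g2$grid,
                                                         rep(300, 10)))))),
               "grid mismatch")
})

test_that("qc_summary computes robust CVs with target split", {
  g <- make_grid(100)
  refm <- build_reference(lapply(1:4, function(i)
    binned_counts(g$grid, rep(300, 100))))
  # constant vector -> CV 0
  bc <- binned_counts(g$grid, rep(300, 100))
  cn <- estimate_cn(bc, refm)
  qc <- qc_summary(bc, bc, cn)
  expect_true(all(qc$cv == 0))
  # {1,2,3,4,5} repeated -> CV = 1.4826 * 1 / 3
  v <- rep(1:5, 20)
  bc2 <- binned_counts(g$grid, v)
  qc2 <- qc_summary(bc2, bc2, cn)
  expect_equal(qc2$cv[qc2$metric == "cv_raw"], 1.4826 / 3)
  # targeted / untargeted split
  targets <- data.frame(chrom = "A", start = 0, end = 10 * 5e4)
  qc3 <- qc_summary(bc2, bc2, cn, targets)
  expect_setequal(unique(qc3$subset), c("all", "target", "offtarget"))
  expect_equal(qc3$n_bins[qc3$metric == "cv_raw" & qc3$subset == "target"],
               10)
})

test_that("GC-biased sample: correction reduces the robust CV", {
  g <- make_grid(2000)
  set.seed(42)
  gcv <- runif(2000, 0.25, 0.75)
  raw <- poisson_sample(g$grid, gcv, 500, 1.5)
  corr <- gc_correct(raw)
  refm <- build_reference(lapply(1:4, function(i)
    gc_correct(poisson_sample(g$grid, gcv, 500, 1.5, paste0("r", i)))))
  cn <- estimate_cn(scale_library(corr, refm), refm)
  qc <- qc_summary(raw, corr, cn)
  expect_lt(qc$cv[qc$metric == "cv_gc"], qc$cv[qc$metric == "cv_raw"])
})
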