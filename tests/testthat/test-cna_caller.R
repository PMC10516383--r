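b <- test_bundle()

test_that("per-target depth is overlap-aware aligned-base arithmetic", {
  tg <- data.frame(chrom = "chrZ", start = 0L, end = 1000L, label = "t1",
                   stringsAsFactors = FALSE)
  recs <- do.call(rbind, lapply(1:10, function(i)
    make_record("chrZ", 100L + i, "100M", strrep("A", 100),
                qname = paste0("r", i))))
  d <- compute_depths(recs, tg)
  expect_equal(d$depth, 1.0)

  # read half-overlapping the target contributes only overlapping bases
  half <- make_record("chrZ", 950L, "100M", strrep("A", 100))
  expect_equal(compute_depths(half, tg)$depth, 50 / 1000)

  # soft-clipped bases never consume reference
  clip <- make_record("chrZ", 100L, "50M50S", strrep("A", 100))
  expect_equal(compute_depths(clip, tg)$depth, 50 / 1000)

  # duplicates and low-mapq reads are excluded
  dup <- make_record("chrZ", 100L, "100M", strrep("A", 100), flag = 1024L)
  expect_equal(compute_depths(dup, tg)$depth, 0)
  lowq <- make_record("chrZ", 100L, "100M", strrep("A", 100), mapq = 5L)
  expect_equal(compute_depths(lowq, tg)$depth, 0)

  expect_equal(compute_depths(recs[0, ], tg)$depth, 0)
  expect_error(compute_depths(recs, data.frame(chrom = "chrZ", start = 5L,
                                               end = 5L, label = "z")),
               "zero-length")
})

test_that("a flat profile normalizes to all-zero log2 with passing QC", {
  p <- simulate_cna_profile(b, noise_cv = 0, seed = 1)
  n <- normalize_coverage(p, b)
  expect_true(all(abs(n$log2) < 1e-9))
  expect_equal(n$uniformity_iqr, 0)
  expect_true(n$qc_pass)
  # backbone median is exactly zero after normalization
  expect_lt(abs(median(n$log2[n$backbone_labels])), 1e-9)

  calls <- call_cnas(n, b)
  expect_true(all(calls$calls$state == "neutral"))
})

test_that("noiseless lesions give closed-form log2 ratios and clonal fractions", {
  p <- simulate_cna_profile(b, list(del17p = 1.0), noise_cv = 0, seed = 1)
  res <- call_cnas(normalize_coverage(p, b), b)$calls
  d17 <- res[res$region == "del17p", ]
  expect_equal(d17$state, "deletion")
  expect_equal(d17$median_log2, -1)
  expect_equal(d17$clonal_fraction, 1)

  p <- simulate_cna_profile(b, list(del13q = 0.4), noise_cv = 0, seed = 1)
  res <- call_cnas(normalize_coverage(p, b), b)$calls
  d13 <- res[res$region == "del13q", ]
  expect_equal(d13$median_log2, log2(0.8), tolerance = 1e-12)
  expect_equal(d13$clonal_fraction, 0.4, tolerance = 1e-12)

  p <- simulate_cna_profile(b, list(tri12 = 1.0), noise_cv = 0, seed = 1)
  res <- call_cnas(normalize_coverage(p, b), b)$calls
  t12 <- res[res$region == "tri12", ]
  expect_equal(t12$state, "gain")
  expect_equal(t12$median_log2, log2(1.5), tolerance = 1e-12)
  expect_equal(t12$clonal_fraction, 1, tolerance = 1e-12)
})

test_that("panel-of-normals mode divides per-target and masks zero-median targets", {
  normals <- test_normals()
  p <- simulate_cna_profile(b, list(del11q = 0.5), noise_cv = 0.1, seed = 5)
  n <- normalize_coverage(p, b, normals)
  expect_equal(n$mode, "panel_of_normals")
  expect_length(n$masked, 0L)
  res <- call_cnas(n, b)$calls
  expect_equal(res$state[res$region == "del11q"], "deletion")

  # a target with zero depth across all normals is masked, not fatal
  broken <- lapply(normals, function(np) {
    np$depth[np$label == "del11q_bin_0001"] <- 0
    np
  })
  n2 <- normalize_coverage(p, b, broken)
  expect_true("del11q_bin_0001" %in% n2$masked)
  res2 <- call_cnas(n2, b)$calls
  expect_equal(res2$n_targets[res2$region == "del11q"],
               length(b$cna_regions$del11q) - 1L)
})

test_that("heavy multiplicative noise trips the uniformity QC gate", {
  fails <- 0L
  for (i in 1:20) {
    p <- simulate_cna_profile(b, noise_cv = 0.6, seed = 700 + i)
    n <- normalize_coverage(p, b)
    if (!n$qc_pass) fails <- fails + 1L
  }
  expect_gte(fails, 19L)
  # QC failure blocks calling entirely
  p <- simulate_cna_profile(b, list(del17p = 1), noise_cv = 0.6, seed = 701)
  out <- call_cnas(normalize_coverage(p, b), b)
  expect_false(out$qc_pass)
  expect_null(out$calls)
})

test_that("direction gates hold over random noisy profiles", {
  for (i in 1:25) {
    lesions <- list()
    if (i %% 3 == 0) lesions$tri12 <- runif(1)
    if (i %% 3 == 1) lesions$del17p <- runif(1)
    p <- simulate_cna_profile(b, lesions, noise_cv = 0.15, seed = 800 + i)
    res <- call_cnas(normalize_coverage(p, b), b)
    if (is.null(res$calls)) next
    expect_false(any(res$calls$state == "deletion" &
                       res$calls$region == "tri12"))
    expect_false(any(res$calls$state == "gain" &
                       res$calls$region != "tri12"))
  }
})

test_that("regions with too few informative targets are uncallable", {
  p <- simulate_cna_profile(b, noise_cv = 0, seed = 1)
  n <- normalize_coverage(p, b)
  n$masked <- utils::head(b$cna_regions$del13q,
                          length(b$cna_regions$del13q) - 2L)
  res <- call_cnas(n, b)$calls
  expect_equal(res$state[res$region == "del13q"], "uncallable")
})
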