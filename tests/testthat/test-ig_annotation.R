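b <- test_bundle()

test_that("an exact germline V reports 100.00 identity and the right allele", {
  tr <- simulate_rearrangement(
    b, "IGH", list(v_name = "IGHV3-21*01", j_name = "IGHJ4*01",
                   shm_target_identity = 1.0), seed = 1)
  v <- assign_v_gene(tr$truth_sequence, b, "IGH")
  expect_equal(v$segment_name, "IGHV3-21*01")
  expect_equal(v$identity_pct, 100)
  expect_equal(v$mismatches, 0L)
})

test_that("annotated identity equals simulator truth across SHM levels", {
  for (i in 1:25) {
    tr <- simulate_rearrangement(
      b, "IGH", list(shm_target_identity = 0.90 + 0.01 * (i %% 11)),
      seed = 400 + i)
    v <- assign_v_gene(tr$truth_sequence, b, "IGH")
    expect_equal(v$segment_name, tr$v_name, label = paste("seed", i))
    expect_equal(v$identity_pct, tr$truth_v_identity,
                 label = paste("seed", i))
  }
})

test_that("equal-scoring alleles resolve to the lexicographically smaller name", {
  segs <- tiny_segments()
  v1 <- segs$v
  v2 <- v1; v2$name <- "IGHV9-2*01"; v2$start <- 600L; v2$end <- 660L
  tg <- data.frame(chrom = "chrT", start = 0L, end = 1000L, label = "ig_all",
                   role = "ig", stringsAsFactors = FALSE)
  bb <- ig_bundle(list(v1, v2, segs$j), tg, list())
  seq <- paste0(v1$sequence, strrep("ACGTAC", 4), segs$j$sequence)
  v <- assign_v_gene(seq, bb, "IGH", config = list(min_v_span = 50L))
  expect_equal(v$segment_name, "IGHV9-1*01")
})

test_that("J assignment is 3'-anchored and reflects germline trimming", {
  segj <- b$segments[["IGHJ6*01"]]
  segv <- b$segments[["IGHV1-2*01"]]
  # junction bases chosen to mismatch the trimmed J head, so the trim
  # boundary is unambiguous
  head5 <- strsplit(substr(segj$sequence, 1L, 5L), "")[[1]]
  jnk <- vapply(head5, function(x) setdiff(c("A", "C", "G", "T"), x)[1], "")
  seq <- paste0(segv$sequence, paste(jnk, collapse = ""),
                substr(segj$sequence, 6L, nchar(segj$sequence)))
  j <- assign_j_gene(seq, b, "IGH")
  expect_equal(j$segment_name, "IGHJ6*01")
  expect_equal(j$identity_pct, 100)
  expect_equal(j$s_first, 5L)  # alignment starts at germline offset 5
})

test_that("sequences unrelated to any germline fail with an explicit error", {
  set.seed(1)
  junk <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
  expect_error(assign_v_gene(junk, b, "IGH"), "no V assignment")
  expect_error(assign_j_gene(junk, b, "IGH"), "no J assignment")
  expect_error(assign_v_gene("ACGT", b, "IGH"), "100 nt")
})

test_that("D assignment finds cores, honors thresholds and prefers longer matches", {
  d <- b$segments[["IGHD3-10*01"]]$sequence
  core12 <- substr(d, 4L, 15L)
  hit <- assign_d_gene(paste0("ACGT", core12, "TTAA"), b)
  expect_equal(hit$segment_name, "IGHD3-10*01")
  expect_gte(hit$match_len, 12L)

  expect_null(assign_d_gene("ACGT", b))          # below minimum length
  set.seed(2)

  # 8-nt match from one D beats a 6-nt match from another
  d2 <- b$segments[["IGHD6-19*01"]]$sequence
  jnt <- paste0("CC", substr(d, 1L, 8L), "CC")
  hit2 <- assign_d_gene(jnt, b)
  expect_equal(hit2$segment_name, "IGHD3-10*01")
})

test_that("SHM classification applies the 98% cutoff and the borderline band", {
  r <- classify_shm(98.00)
  expect_equal(r$status, "unmutated"); expect_false(r$borderline)
  r <- classify_shm(97.50)
  expect_equal(r$status, "mutated"); expect_true(r$borderline)
  r <- classify_shm(100)
  expect_equal(r$status, "unmutated"); expect_false(r$borderline)
  # rounding half-up happens before classification
  expect_equal(classify_shm(97.995)$status, "unmutated")
  expect_equal(classify_shm(97.994)$status, "mutated")
  expect_true(classify_shm(97.994)$borderline)
  expect_error(classify_shm(101), "0, 100")
  expect_error(classify_shm(-1), "0, 100")

  # dense grid: unmutated if and only if identity >= 98.00
  grid <- seq(0, 100, by = 0.01)
  st <- vapply(grid, function(x) classify_shm(x)$status, "")
  expect_identical(st == "unmutated", round_half_up(grid, 2) >= 98)
  bl <- vapply(grid, function(x) classify_shm(x)$borderline, TRUE)
  expect_identical(bl, round_half_up(grid, 2) >= 97 &
                     round_half_up(grid, 2) <= 97.99)
})

test_that("CDR3 extraction matches truth and detects anchor loss", {
  tr <- simulate_rearrangement(b, "IGH", list(shm_target_identity = 0.97),
                               seed = 5)
  ann <- annotate_rearrangement(tr$truth_sequence, b, "IGH")
  expect_true(ann$productive)
  expect_equal(ann$cdr3$junction_aa, tr$truth_junction_aa)
  expect_equal(oracle_translate(ann$cdr3$junction_nt), tr$truth_junction_aa)
  # junction/CDR3 length relation with intact anchors
  expect_equal(nchar(ann$cdr3$junction_aa), nchar(ann$cdr3$aa_sequence) + 2L)
  expect_match(ann$cdr3$junction_aa, "^C.*[WF]$")

  # mutate the V anchor TGT -> TAT (C -> Y)
  s <- tr$truth_sequence
  av <- tr$anchor_v_pos
  stopifnot(substr(s, av + 1L, av + 3L) == "TGT")
  substr(s, av + 2L, av + 2L) <- "A"
  ann2 <- annotate_rearrangement(s, b, "IGH")
  expect_false(ann2$productive)
  expect_equal(ann2$failure_reason, "missing_anchor")
})

test_that("frame and stop-codon defects are classified and CDR3 nt still reported", {
  tr <- simulate_rearrangement(b, "IGH", list(shm_target_identity = 1.0),
                               seed = 6)
  # insert one junction base: out of frame
  s <- tr$truth_sequence
  cut <- tr$junction_start + 2L
  s_oof <- paste0(substr(s, 1L, cut), "A", substr(s, cut + 1L, nchar(s)))
  ann <- annotate_rearrangement(s_oof, b, "IGH")
  expect_false(ann$productive)
  expect_equal(ann$failure_reason, "out_of_frame")
  expect_gt(nchar(ann$cdr3$nt_sequence), 0L)

  # introduce TAG inside FR3: stop codon
  s2 <- tr$truth_sequence
  pos <- 240L - (240L %% 3L)  # codon boundary inside FR3
  substr(s2, pos + 1L, pos + 3L) <- "TAG"
  ann2 <- annotate_rearrangement(s2, b, "IGH")
  expect_false(ann2$productive)
  expect_equal(ann2$failure_reason, "stop_codon")
})

test_that("assign_v_gene identity agrees with an independent NW oracle", {
  segv <- b$segments[["IGHV3-23*01"]]
  span <- segv$region_bounds[6]
  set.seed(77)
  for (i in 1:40) {
    k <- sample(0:30, 1)
    mut <- strsplit(segv$sequence, "")[[1]]
    if (k > 0) {
      at <- sample(seq_len(span), k)   # SHM lands in FR1..FR3
      mut[at] <- vapply(mut[at], function(x)
        sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    }
    mutated <- paste(mut, collapse = "")
    v <- assign_v_gene(mutated, b, "IGH")
    oracle <- nw_identity_oracle(segv$sequence, mutated, span)
    expect_equal(v$identity_pct, oracle, tolerance = 1e-9,
                 label = paste("pair", i))
  }
})
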