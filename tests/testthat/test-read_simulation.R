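b <- test_bundle()

test_that("with no trimming, no N bases and no SHM the truth is the exact V+D+J concatenation", {
  cfg <- list(v_trim_range = c(0L, 0L), d_trim_range = c(0L, 0L),
              j_trim_range = c(0L, 0L), n_range = c(0L, 0L),
              shm_target_identity = 1.0, force_productive = FALSE,
              v_name = "IGHV1-2*01", d_name = "IGHD2-2*01",
              j_name = "IGHJ4*01")
  tr <- simulate_rearrangement(b, "IGH", cfg, seed = 1)
  expected <- paste0(b$segments[["IGHV1-2*01"]]$sequence,
                     b$segments[["IGHD2-2*01"]]$sequence,
                     b$segments[["IGHJ4*01"]]$sequence)
  expect_identical(tr$truth_sequence, expected)
  expect_equal(tr$truth_v_identity, 100)
  expect_null(tr$truth_mutations)
})

test_that("SHM hits the closest achievable identity at or above the target", {
  segv <- b$segments[["IGHV3-21*01"]]
  span <- segv$region_bounds[6]
  for (target in c(0.98, 0.935, 0.90)) {
    tr <- simulate_rearrangement(
      b, "IGH", list(v_name = "IGHV3-21*01",
                     shm_target_identity = target,
                     force_productive = FALSE), seed = 5)
    n_mut <- floor(span * (1 - target) + 1e-9)
    expect_equal(nrow(tr$truth_mutations), n_mut)
    expect_equal(tr$truth_v_identity,
                 round_half_up(100 * (span - n_mut) / span, 2))
    expect_gte(tr$truth_v_identity, 100 * target - 1e-9)
    # every mutation lies inside the identity-evaluation span and matches
    # the germline reference it claims to replace
    expect_true(all(tr$truth_mutations$offset < span))
    gl <- strsplit(segv$sequence, "")[[1]]
    expect_identical(tr$truth_mutations$ref,
                     gl[tr$truth_mutations$offset + 1L])
    expect_true(all(tr$truth_mutations$ref != tr$truth_mutations$alt))
  }
})

test_that("force_productive yields stop-free in-frame junctions (independent translation)", {
  for (i in 1:30) {
    tr <- simulate_rearrangement(b, "IGH",
                                 list(shm_target_identity = 0.92),
                                 seed = 100 + i)
    expect_true(tr$productive_truth)
    frame <- b$segments[[tr$v_name]]$anchor_codon %% 3L
    aa <- oracle_translate(substr(tr$truth_sequence, frame + 1L,
                                  nchar(tr$truth_sequence)))
    aa <- substr(aa, 1L, nchar(aa))
    expect_false(grepl("*", aa, fixed = TRUE), label = paste("seed", i))
    expect_equal((tr$anchor_j_pos - tr$anchor_v_pos) %% 3L, 0L)
  }
})

test_that("identical seed and config give byte-identical SAM; different seeds differ", {
  tr <- simulate_rearrangement(b, "IGH", list(), seed = 7)
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.sam"); f2 <- file.path(dir, "b.sam")
  f3 <- file.path(dir, "c.sam")
  write_sam(simulate_reads(tr, b, list(depth = 50), seed = 11), f1, b)
  write_sam(simulate_reads(tr, b, list(depth = 50), seed = 11), f2, b)
  write_sam(simulate_reads(tr, b, list(depth = 50), seed = 12), f3, b)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("at error rate 0 every soft-clip is a substring of the truth sequence", {
  tr <- simulate_rearrangement(b, "IGH", list(shm_target_identity = 0.95),
                               seed = 8)
  rs <- simulate_reads(tr, b, list(depth = 80, error_rate = 0), seed = 9)
  clipped <- rs$records[grepl("S", rs$records$cigar), ]
  expect_gt(nrow(clipped), 0L)
  for (i in seq_len(nrow(clipped))) {
    cg <- clipped$cigar[i]
    lead <- if (grepl("^[0-9]+S", cg))
      as.integer(sub("^([0-9]+)S.*", "\\1", cg)) else 0L
    trail <- if (grepl("[0-9]+S$", cg))
      as.integer(sub("^.*?([0-9]+)S$", "\\1", cg)) else 0L
    sq <- clipped$seq[i]
    if (lead > 0L)
      expect_true(grepl(substr(sq, 1L, lead), tr$truth_sequence,
                        fixed = TRUE))
    if (trail > 0L)
      expect_true(grepl(substr(sq, nchar(sq) - trail + 1L, nchar(sq)),
                        tr$truth_sequence, fixed = TRUE))
  }
})

test_that("realized mean depth tracks the request within 15%", {
  tr <- simulate_rearrangement(b, "IGH", list(), seed = 13)
  rs <- simulate_reads(tr, b, list(depth = 200, error_rate = 0.001),
                       seed = 14)
  span <- nchar(tr$truth_sequence)
  aligned <- sum(vapply(rs$records$cigar, function(cg) {
    m <- regmatches(cg, gregexpr("[0-9]+(?=M)", cg, perl = TRUE))[[1]]
    sum(as.integer(m))
  }, 0))
  clip <- sum(vapply(rs$records$cigar, function(cg) {
    m <- regmatches(cg, gregexpr("[0-9]+(?=S)", cg, perl = TRUE))[[1]]
    sum(as.integer(m))
  }, 0))
  mean_depth <- (aligned + clip) / span
  expect_gte(mean_depth, 170)
  expect_lte(mean_depth, 230)
})

test_that("read_len above the fragment length and non-positive depth error", {
  tr <- simulate_rearrangement(b, "IGH", list(), seed = 7)
  expect_error(simulate_reads(tr, b, list(read_len = 600, frag_mean = 500),
                              seed = 1), "fragment")
  expect_error(simulate_reads(tr, b, list(depth = 0), seed = 1), "depth")
})

test_that("CNA profile multipliers follow the closed forms", {
  p <- simulate_cna_profile(b, list(del17p = 1.0), noise_cv = 0, seed = 1)
  d17 <- p$depth[p$label %in% b$cna_regions$del17p]
  expect_true(all(d17 == 750))
  other <- p$depth[!p$label %in% b$cna_regions$del17p]
  expect_true(all(other == 1500))

  p <- simulate_cna_profile(b, list(del13q = 0.4), noise_cv = 0, seed = 1)
  expect_true(all(p$depth[p$label %in% b$cna_regions$del13q] == 1500 * 0.8))

  p <- simulate_cna_profile(b, list(tri12 = 1.0), noise_cv = 0, seed = 1)
  expect_true(all(p$depth[p$label %in% b$cna_regions$tri12] == 2250))

  expect_error(simulate_cna_profile(b, list(del9q = 0.5), seed = 1),
               "unknown CNA region")
})

test_that("spiked variants behave binomially and edit CIGARs correctly", {
  rs <- simulate_target_reads(b, "TP53", depth = 1200, seed = 21)
  tg <- b$targets[b$targets$label == "TP53", ]
  gseq <- as.character(b$genome[[tg$chrom]])
  pos <- tg$start + 200L
  ref <- substr(gseq, pos + 1L, pos + 1L)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]

  # vaf = 1: every overlapping read carries the alternate
  rs1 <- spike_variant(rs, tg$chrom, pos, ref, alt, vaf = 1.0, seed = 22)
  sp <- rs1$spikes[[1]]
  expect_equal(sp$realized_alt, sp$overlapping)

  # small vaf: realized count within the exact binomial 99% interval
  rs2 <- spike_variant(rs, tg$chrom, pos, ref, alt, vaf = 0.0092, seed = 23)
  sp2 <- rs2$spikes[[1]]
  ci <- binom_interval(sp2$overlapping, 0.0092)
  expect_gte(sp2$realized_alt, ci[1])
  expect_lte(sp2$realized_alt, ci[2])

  # insertion spikes appear as I operations with longer sequences
  rs3 <- spike_variant(rs, tg$chrom, pos, ref, "+AT", vaf = 0.5, seed = 24)
  edited <- grepl("I", rs3$records$cigar)
  expect_gt(sum(edited), 0L)
  expect_true(all(grepl("^[0-9]+M2I([0-9]+M)?$", rs3$records$cigar[edited])))
  expect_true(all(nchar(rs3$records$seq[edited]) ==
                    cigar_ref_len(rs3$records$cigar[edited]) + 2L))

  # wrong reference base is a hard error
  expect_error(spike_variant(rs, tg$chrom, pos, alt, ref, 0.5, seed = 25),
               "mismatch")
})

test_that("emitted SAM is readable by samtools and by read_sam", {
  tr <- simulate_rearrangement(b, "IGH", list(), seed = 30)
  rs <- simulate_reads(tr, b, list(depth = 40), seed = 31)
  f <- file.path(withr::local_tempdir(), "x.sam")
  write_sam(rs, f, b)
  n <- suppressWarnings(
    as.integer(system2("samtools", c("view", "-c", f), stdout = TRUE)))
  expect_equal(n, nrow(rs$records))
  back <- read_sam(f)
  expect_equal(back$pos0, rs$records$pos0)
  expect_equal(back$cigar, rs$records$cigar)
  expect_equal(back$seq, rs$records$seq)
})
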