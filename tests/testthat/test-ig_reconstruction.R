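b <- test_bundle()

test_that("junction evidence has correct segment-local coordinates", {
  segj <- b$segments[["IGHJ4*01"]]
  # read aligned to the J with a 40-nt left soft-clip at J offset 7
  rec <- make_record(segj$chrom, segj$start + 7L, "40S60M",
                     strrep("A", 100))
  ev <- collect_junction_evidence(rec, b)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$segment, "IGHJ4*01")
  expect_equal(ev$breakpoint, 7L)
  expect_equal(ev$clip_side, "left")
  expect_equal(nchar(ev$clip_seq), 40L)

  # fully aligned read inside a V: no evidence
  segv <- b$segments[["IGHV1-2*01"]]
  rec2 <- make_record(segv$chrom, segv$start, "100M", strrep("A", 100))
  expect_equal(nrow(collect_junction_evidence(rec2, b)), 0L)

  # below min_clip or below min_mapq: no evidence
  rec3 <- make_record(segj$chrom, segj$start + 7L, "5S60M", strrep("A", 65))
  expect_equal(nrow(collect_junction_evidence(rec3, b)), 0L)
  rec4 <- make_record(segj$chrom, segj$start + 7L, "40S60M",
                      strrep("A", 100), mapq = 10L)
  expect_equal(nrow(collect_junction_evidence(rec4, b)), 0L)
})

test_that("minus-strand segments flip clip side, offset and orientation", {
  # same J content presented on the minus genomic strand
  j_reading <- paste0("GCTACG", "TGG", "GTCAAGGAACCA")
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  v <- gene_segment("IGHV9-1*01", "IGH", "V", "chrM", 100L, 160L, "+",
                    paste0(strrep("ACG", 18), "TGT", "GCA"),
                    region_bounds = c(0L, 10L, 20L, 30L, 40L, 54L),
                    anchor_codon = 54L)
  jp <- gene_segment("IGHJ9*01", "IGH", "J", "chrM", 400L, 421L, "+",
                     j_reading, anchor_codon = 6L)
  jm <- gene_segment("IGHJ9*01", "IGH", "J", "chrM", 400L, 421L, "-",
                     j_reading, anchor_codon = 6L)
  tg <- data.frame(chrom = "chrM", start = c(90L, 390L), end = c(170L, 431L),
                   label = c("ig_V", "ig_J"), role = "ig",
                   stringsAsFactors = FALSE)
  bp_plus <- ig_bundle(list(v, jp), tg, list())
  bp_minus <- ig_bundle(list(v, jm), tg, list())

  clip <- "ACGTACGTACGTACG"  # 15 nt of junction-side bases
  # plus strand: left clip at genomic 407 = reading offset 7
  rec_p <- make_record("chrM", 407L, "15S14M",
                       paste0(clip, substr(j_reading, 8L, 21L)))
  ev_p <- collect_junction_evidence(rec_p, bp_plus)
  # minus strand: reading offsets [7, 21) map to genomic [400, 414) and the
  # reading-left clip attaches on the genomic right at 414; the SAM SEQ is
  # the reverse complement of the reading-direction read
  rec_m <- make_record("chrM", 400L, "14M15S",
                       paste0(rc(substr(j_reading, 8L, 21L)), rc(clip)))
  ev_m <- collect_junction_evidence(rec_m, bp_minus)
  expect_equal(ev_m$segment, ev_p$segment)
  expect_equal(ev_m$clip_side, "left")
  expect_equal(ev_m$breakpoint, 7L)
  expect_equal(ev_m$clip_seq, ev_p$clip_seq)
})

test_that("breakpoint clustering matches a brute-force single-linkage oracle", {
  mk <- function(bps) data.frame(
    segment = rep("IGHV1-2*01", length(bps)), breakpoint = bps,
    clip_side = rep("right", length(bps)),
    clip_seq = rep(strrep("A", 20), length(bps)),
    read_name = paste0("r", seq_along(bps)),
    mapq = rep(60L, length(bps)), stringsAsFactors = FALSE)

  ev <- mk(c(100L, 100L, 101L, 100L, 250L))
  cl <- cluster_junctions(ev, list(window = 5, min_support = 3))
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$breakpoint, 100L)
  expect_equal(cl[[1]]$support, 4L)

  empty_ev <- mk(c(1L))[0, , drop = FALSE]
  expect_length(cluster_junctions(empty_ev), 0L)

  # two items at 100 and 104: one group at window 5, two at window 3;
  # both below min_support = 3 either way
  expect_length(cluster_junctions(mk(c(100L, 104L)),
                                  list(window = 5, min_support = 3)), 0L)
  expect_length(cluster_junctions(mk(c(100L, 104L)),
                                  list(window = 5, min_support = 2)), 1L)
  expect_length(cluster_junctions(mk(c(100L, 104L)),
                                  list(window = 3, min_support = 2)), 0L)

  # randomized agreement with the oracle on group count and sizes
  set.seed(99)
  for (rep in 1:20) {
    bps <- sample(0:60, sample(3:12, 1), replace = TRUE)
    got <- cluster_junctions(mk(bps), list(window = 4, min_support = 1))
    want <- brute_cluster(sort(bps), 4)
    expect_equal(length(got), length(unique(want)))
    expect_setequal(vapply(got, `[[`, 0L, "support"),
                    as.integer(table(want)))
  }
})

test_that("modal breakpoint ties resolve to the smallest offset", {
  ev <- data.frame(segment = "IGHV1-2*01",
                   breakpoint = c(101L, 101L, 99L, 99L),
                   clip_side = "right", clip_seq = strrep("A", 20),
                   read_name = paste0("r", 1:4), mapq = 60L,
                   stringsAsFactors = FALSE)
  cl <- cluster_junctions(ev, list(window = 5, min_support = 3))
  expect_equal(cl[[1]]$breakpoint, 99L)
})

test_that("error-free assembly reproduces the truth including SHM bases", {
  tr <- simulate_rearrangement(b, "IGH", list(shm_target_identity = 0.95),
                               seed = 51)
  rs <- simulate_reads(tr, b, list(depth = 100), seed = 52)
  rec <- reconstruct_ig(rs$records, b, "IGH")
  expect_gte(length(rec$candidates), 1L)
  top <- rec$candidates[[1]]
  expect_identical(top$sequence, tr$truth_sequence)
  expect_equal(length(top$per_base_support), nchar(top$sequence))
  # all mutated bases present in the assembly
  got <- strsplit(top$sequence, "")[[1]]
  expect_identical(got[tr$truth_mutations$offset + 1L],
                   tr$truth_mutations$alt)
})

test_that("unjoinable cluster pairs return no candidate", {
  tr <- simulate_rearrangement(b, "IGH", list(), seed = 53)
  rs <- simulate_reads(tr, b, list(depth = 60), seed = 54)
  ev <- collect_junction_evidence(rs$records, b)
  cl <- cluster_junctions(ev)
  is_v <- vapply(cl, function(x)
    b$segments[[x$segment]]$segment_class == "V", TRUE)
  vcl <- cl[is_v][[1]]; jcl <- cl[!is_v][[1]]
  expect_null(assemble_candidate(vcl, jcl, rs$records, b,
                                 list(min_overlap = 10000L)))
})

test_that("a read set with no soft-clips over IG targets yields no candidates", {
  segv <- b$segments[["IGHV1-2*01"]]
  recs <- do.call(rbind, lapply(1:10, function(i)
    make_record(segv$chrom, segv$start, "100M", strrep("A", 100),
                qname = paste0("r", i))))
  out <- reconstruct_ig(recs, b, "IGH")
  expect_length(out$candidates, 0L)
})

test_that("ranking follows score with deterministic name tie-breaks", {
  mk <- function(v, j, support, len, mapq) {
    structure(list(locus = "IGH", sequence = strrep("A", len),
                   v_segment = v, j_segment = j, support = support,
                   mean_mapq = mapq,
                   score = support * log2(1 + len) * mapq / 60),
              class = "rearrangement_candidate")
  }
  # score spot check: support 10, length 511, mapq 60 -> 10 * 9 = 90
  expect_equal(mk("V", "J", 10, 511, 60)$score, 90)
  # monotone in support
  r <- rank_candidates(list(mk("a", "j", 3, 400, 60),
                            mk("b", "j", 50, 400, 60)))
  expect_equal(r[[1]]$v_segment, "b")
  # identical metrics: lexicographically smaller V name first
  r2 <- rank_candidates(list(mk("IGHV3-21*01", "j", 5, 400, 60),
                             mk("IGHV1-2*01", "j", 5, 400, 60)))
  expect_equal(r2[[1]]$v_segment, "IGHV1-2*01")
  # adding supporting reads never lowers the score
  s1 <- mk("V", "J", 10, 400, 60)$score
  s2 <- mk("V", "J", 11, 400, 60)$score
  expect_gt(s2, s1)
})
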