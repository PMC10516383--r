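# Shared fixtures, built in code. The full synthetic bundle is expensive
# enough to build once and reuse across test files.

.fixture_env <- new.env(parent = emptyenv())

test_bundle <- function() {
  if (is.null(.fixture_env$bundle))
    .fixture_env$bundle <- simulate_reference_bundle(seed = 42)
  .fixture_env$bundle
}

test_normals <- function(n = 10, noise_cv = 0.1) {
  key <- paste0("normals_", n, "_", noise_cv)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- lapply(seq_len(n), function(i)
      simulate_cna_profile(test_bundle(), noise_cv = noise_cv,
                           seed = 90000 + i))
  .fixture_env[[key]]
}

test_subsets <- function() {
  read_subset_definitions(system.file("extdata",
                                      "subset_definitions_synthetic.tsv",
                                      package = "cllpanel"))
}

# a tiny hand-written bundle: one V, one D, one J on a plus-strand contig
tiny_segments <- function() {
  v_seq <- paste0(strrep("ACG", 18), "TGT", "GCA")  # 60 nt, Cys at offset 54
  j_seq <- paste0("GCTACG", "TGG", "GTCAAGGAACCA")  # 21 nt, Trp at offset 6
  d_seq <- "GGTATAGCAGCT"                           # 12 nt
  list(
    v = gene_segment("IGHV9-1*01", "IGH", "V", "chrT", 100L, 160L, "+",
                     v_seq, region_bounds = c(0L, 10L, 20L, 30L, 40L, 54L),
                     anchor_codon = 54L),
    d = gene_segment("IGHD9-9*01", "IGH", "D", "chrT", 300L, 312L, "+", d_seq),
    j = gene_segment("IGHJ9*01", "IGH", "J", "chrT", 400L, 421L, "+",
                     j_seq, anchor_codon = 6L))
}

tiny_bundle <- function() {
  segs <- tiny_segments()
  targets <- data.frame(
    chrom = "chrT", start = c(90L, 290L, 390L), end = c(170L, 322L, 431L),
    label = c("ig_V", "ig_D", "ig_J"), role = "ig", stringsAsFactors = FALSE)
  ig_bundle(unname(segs), targets, cna_regions = list())
}

# write a bundle's files into a fresh temp dir; returns the three paths
write_tiny_bundle_files <- function(bundle = tiny_bundle(), dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("bundle")
    dir.create(dir)
  }
  fa <- file.path(dir, "segments.fasta")
  tsv <- file.path(dir, "segments.tsv")
  bed <- file.path(dir, "targets.bed")
  write_reference_bundle(bundle, fa, tsv, bed)
  list(fasta = fa, tsv = tsv, bed = bed, dir = dir)
}

# one fully aligned alignment record
make_record <- function(rname, pos0, cigar, seq, qname = "r1", flag = 0L,
                        mapq = 60L) {
  data.frame(qname = qname, flag = flag, rname = rname, pos0 = pos0,
             mapq = mapq, cigar = cigar, rnext = "*", pnext = 0L, tlen = 0L,
             seq = seq, qual = strrep("?", nchar(seq)),
             stringsAsFactors = FALSE)
}
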