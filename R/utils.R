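# Internal helpers shared across modules. All coordinates are 0-based
# half-open unless a function name says otherwise; 1-based coordinates are
# produced only at report/SAM boundaries.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Classification boundaries (e.g. the 98.00 identity cutoff) require
#' deterministic half-up rounding; base `round()` rounds half to even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  floor(x * f + 0.5 + 1e-9) / f
}

#' Reverse complement of nucleotide strings
#'
#' @param x character vector of ACGTN strings.
#' @return character vector, reverse-complemented.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate a nucleotide string
#'
#' Translates in frame 0 after truncating to a whole number of codons.
#' Ambiguous codons (containing N) become `X`; stops are `*`.
#'
#' @param nt nucleotide string.
#' @return amino-acid string (possibly empty).
#' @export
translate_dna <- function(nt) {
  n <- nchar(nt)
  if (n < 3L) return("")
  n <- n - n %% 3L
  codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"   # ambiguous codons (N)
  paste(aa, collapse = "")
}

# random DNA of length n from the generator's RNG stream
random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  if (n <= 0L) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# codons that never encode a stop, used to build synthetic in-frame segments
.safe_codons <- local({
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

random_orf <- function(n_codons) {
  paste(sample(.safe_codons, n_codons, replace = TRUE), collapse = "")
}

# ---- CIGAR helpers ------------------------------------------------------

# parse one CIGAR string into a data.frame(op, len)
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || cigar == "") {
    return(data.frame(op = character(), len = integer()))
  }
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  stopifnot(length(lens) == length(ops))
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

# reference-consuming length of a CIGAR (M, D, N, =, X); vectorized
cigar_ref_len <- function(cigar) {
  if (length(cigar) == 0L) return(integer(0))
  lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))
  mapply(function(l, o) {
    if (length(l) == 0L) return(0L)
    sum(as.integer(l)[o %in% c("M", "D", "N", "=", "X")])
  }, lens, ops, USE.NAMES = FALSE)
}

# build a CIGAR string from op/len vectors, merging zero-length ops away
make_cigar <- function(ops, lens) {
  keep <- lens > 0L
  paste0(lens[keep], ops[keep], collapse = "")
}

# split a string into single characters
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# draw one integer uniformly from [lo, hi] (safe against R's sample(n, 1)
# scalar expansion when lo == hi)
draw_int <- function(lo, hi) {
  if (hi <= lo) return(as.integer(lo))
  as.integer(lo) + sample.int(hi - lo + 1L, 1L) - 1L
}

# majority vote over a 4xN (or 5xN) count matrix of A,C,G,T(,N) rows.
# Ties resolved by base priority A < C < G < T; returns list(base, tied).
vote_bases <- function(counts) {
  bases <- rownames(counts)
  idx <- apply(counts, 2, which.max) # which.max takes first on ties => priority
  tied <- apply(counts, 2, function(col) sum(col == max(col)) > 1L && max(col) > 0L)
  list(base = bases[idx], tied = tied, depth = colSums(counts))
}

# stable md5 of an R object's canonical JSON serialization (content-addressed,
# independent of file paths)
content_md5 <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"), tf)
  unname(tools::md5sum(tf))
}
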