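#' @title Germline IG reference bundle
#'
#' @description
#' The reference bundle is the single object every analysis module consumes:
#' a set of germline immunoglobulin gene segments (V, D, J alleles with
#' IMGT-style framework/CDR region bounds and conserved anchor codons), the
#' capture-panel target intervals, and the grouping of coverage targets into
#' the four recurrent CLL copy-number regions (del17p, del11q, del13q, tri12).
#'
#' Segments are stored in *reading orientation* (5'->3' of the coding strand)
#' regardless of their genomic strand, so downstream alignment and annotation
#' are strand-free; the flip happens once at load time.
#'
#' @name reference_model
NULL

.valid_loci <- c("IGH", "IGL", "IGK")
.valid_classes <- c("V", "D", "J")
.valid_roles <- c("ig", "driver", "cna_backbone")
.cna_region_names <- c("del17p", "del11q", "del13q", "tri12")
.region_names5 <- c("FR1", "CDR1", "FR2", "CDR2", "FR3")

#' Construct a single germline gene segment
#'
#' @param name allele identifier, e.g. `"IGHV3-21*01"`.
#' @param locus one of `"IGH"`, `"IGL"`, `"IGK"`.
#' @param segment_class one of `"V"`, `"D"`, `"J"`.
#' @param chrom contig name.
#' @param start,end 0-based half-open genomic interval.
#' @param strand `"+"` or `"-"` (genomic strand of the coding sequence).
#' @param sequence coding-strand nucleotides in reading orientation.
#' @param region_bounds for V segments, a numeric vector of 6 ascending
#'   offsets delimiting FR1/CDR1/FR2/CDR2/FR3 as 0-based half-open windows
#'   within `sequence`; `NULL` otherwise.
#' @param anchor_codon 0-based offset of the conserved anchor codon
#'   (Cys-104 for V, Trp/Phe-118 for J); `NA` for D segments.
#' @param aux_codon optional 0-based offset of an additional annotated codon
#'   (used to carry the IMGT position-110 codon of IGLV3-21 alleles).
#' @return an object of class `gene_segment`.
#' @export
gene_segment <- function(name, locus, segment_class, chrom, start, end, strand,
                         sequence, region_bounds = NULL, anchor_codon = NA_integer_,
                         aux_codon = NA_integer_) {
  seg <- structure(list(
    name = name, locus = locus, segment_class = segment_class,
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    strand = strand, sequence = toupper(sequence),
    region_bounds = if (is.null(region_bounds)) NULL else as.integer(region_bounds),
    anchor_codon = as.integer(anchor_codon),
    aux_codon = as.integer(aux_codon)
  ), class = "gene_segment")
  validate_gene_segment(seg)
  seg
}

validate_gene_segment <- function(seg) {
  n <- nchar(seg$sequence)
  if (!seg$locus %in% .valid_loci)
    stop("segment '", seg$name, "': unknown locus '", seg$locus, "'")
  if (!seg$segment_class %in% .valid_classes)
    stop("segment '", seg$name, "': unknown class '", seg$segment_class, "'")
  if (!seg$strand %in% c("+", "-"))
    stop("segment '", seg$name, "': strand must be '+' or '-'")
  if (seg$end - seg$start != n)
    stop("segment '", seg$name, "': genomic interval width (", seg$end - seg$start,
         ") does not match sequence length (", n, ")")
  if (grepl("[^ACGTN]", seg$sequence))
    stop("segment '", seg$name, "': sequence contains characters outside ACGTN")
  if (!is.na(seg$anchor_codon) && seg$anchor_codon + 3L > n)
    stop("segment '", seg$name, "': anchor codon at offset ", seg$anchor_codon,
         " extends past sequence end (length ", n, ")")
  if (seg$segment_class == "V") {
    rb <- seg$region_bounds
    if (is.null(rb) || length(rb) != 6L)
      stop("segment '", seg$name, "': V segments need 6 region boundary offsets")
    if (any(diff(rb) <= 0L) || rb[1] < 0L || rb[6] > n)
      stop("segment '", seg$name, "': region bounds must be ascending within [0, ",
           n, ")")
    if (is.na(seg$anchor_codon))
      stop("segment '", seg$name, "': V segment requires an anchor codon offset")
    if (seg$anchor_codon < rb[6])
      stop("segment '", seg$name, "': V anchor (", seg$anchor_codon,
           ") must lie at or after the FR3 end boundary (", rb[6], ")")
  }
  if (seg$segment_class == "J" && is.na(seg$anchor_codon))
    stop("segment '", seg$name, "': J segment requires an anchor codon offset")
  if (!is.na(seg$aux_codon) && seg$aux_codon + 3L > n)
    stop("segment '", seg$name, "': auxiliary codon extends past sequence end")
  invisible(seg)
}

# FR3 end boundary (the 3' limit of the identity-evaluation span) of a V segment
fr3_end <- function(seg) {
  stopifnot(seg$segment_class == "V")
  seg$region_bounds[6]
}

#' Construct a validated reference bundle
#'
#' @param segments list of [gene_segment()] objects.
#' @param targets data.frame with columns `chrom`, `start`, `end`, `label`,
#'   `role` (0-based half-open intervals).
#' @param cna_regions named list mapping each of `del17p`, `del11q`, `del13q`,
#'   `tri12` to a character vector of target labels.
#' @param genome optional named [Biostrings::DNAStringSet] of contig sequences
#'   (used by the simulator and the pileup caller).
#' @return an object of class `ig_bundle`.
#' @export
ig_bundle <- function(segments, targets, cna_regions, genome = NULL) {
  names(segments) <- vapply(segments, `[[`, "", "name")
  bundle <- structure(list(segments = segments, targets = targets,
                           cna_regions = cna_regions, genome = genome),
                      class = "ig_bundle")
  validate_bundle(bundle)
  bundle
}

validate_bundle <- function(bundle) {
  for (seg in bundle$segments) validate_gene_segment(seg)
  tg <- bundle$targets
  need <- c("chrom", "start", "end", "label", "role")
  if (!all(need %in% names(tg)))
    stop("targets must have columns: ", paste(need, collapse = ", "))
  if (any(!nzchar(tg$label))) stop("every target label must be non-empty")
  if (any(duplicated(tg$label))) stop("target labels must be unique")
  if (any(!tg$role %in% .valid_roles))
    stop("unknown target role(s): ",
         paste(unique(tg$role[!tg$role %in% .valid_roles]), collapse = ", "))
  if (any(tg$end <= tg$start)) stop("zero or negative length target interval")
  # cna_backbone targets on one chromosome must not overlap
  bb <- tg[tg$role == "cna_backbone", , drop = FALSE]
  for (ch in unique(bb$chrom)) {
    b <- bb[bb$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    if (nrow(b) > 1L && any(b$start[-1] < b$end[-nrow(b)]))
      stop("overlapping cna_backbone targets on ", ch)
  }
  for (rn in names(bundle$cna_regions)) {
    if (!rn %in% .cna_region_names)
      stop("unknown CNA region '", rn, "'")
    missing <- setdiff(bundle$cna_regions[[rn]], tg$label)
    if (length(missing))
      stop("CNA region '", rn, "' references unknown target label(s): ",
           paste(utils::head(missing, 3), collapse = ", "))
  }
  # every locus present must carry at least one V and one J
  loci <- unique(vapply(bundle$segments, `[[`, "", "locus"))
  for (lc in loci) {
    cls <- vapply(bundle$segments, function(s)
      if (s$locus == lc) s$segment_class else "", "")
    if (!"V" %in% cls || !"J" %in% cls)
      stop("locus ", lc, " must contain at least one V and one J segment")
  }
  invisible(bundle)
}

#' Load a germline IG reference bundle from disk
#'
#' Reads germline segments from a FASTA file, their annotations from a
#' tab-separated sidecar, and panel targets from a BED3+2 file. Minus-strand
#' segments (the FASTA is assumed to hold the genomic/plus-strand sequence)
#' are reverse-complemented into reading orientation at load time.
#'
#' The annotation TSV has columns `name`, `locus`, `class`, `chrom`, `start`,
#' `end`, `strand`, `region_bounds` (six comma-separated offsets for V, empty
#' otherwise), `anchor` and `aux_codon` (integer offsets or empty). The BED
#' file has columns chrom, start, end, label, role with role in
#' `ig`/`driver`/`cna_backbone`. Targets whose label starts with a CNA region
#' name (`del17p`, `del11q`, `del13q`, `tri12`) are grouped into that region.
#'
#' @param fasta_path path to the germline segment FASTA.
#' @param annotation_path path to the annotation TSV.
#' @param bed_path path to the panel BED file.
#' @param genome_fasta optional path to a contig-level FASTA (for pileups and
#'   read simulation over driver targets).
#' @return a validated [ig_bundle()].
#' @export
load_reference_bundle <- function(fasta_path, annotation_path, bed_path,
                                  genome_fasta = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("name", "locus", "class", "chrom", "start", "end", "strand",
            "region_bounds", "anchor", "aux_codon")
  if (!all(need %in% names(ann)))
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  segments <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    nm <- names(seqs)[i]
    row <- ann[ann$name == nm, , drop = FALSE]
    if (nrow(row) == 0L)
      stop("FASTA record '", nm, "' has no annotation row")
    row <- row[1L, ]
    sq <- as.character(seqs[[i]])
    if (row$strand == "-") sq <- revcomp(sq)
    rb <- NULL
    if (nzchar(row$region_bounds))
      rb <- as.integer(strsplit(row$region_bounds, ",", fixed = TRUE)[[1]])
    segments[[i]] <- gene_segment(
      name = nm, locus = row$locus, segment_class = row$class,
      chrom = row$chrom, start = as.integer(row$start), end = as.integer(row$end),
      strand = row$strand, sequence = sq, region_bounds = rb,
      anchor_codon = if (nzchar(row$anchor)) as.integer(row$anchor) else NA_integer_,
      aux_codon = if (nzchar(row$aux_codon)) as.integer(row$aux_codon) else NA_integer_)
  }
  targets <- read_bed_targets(bed_path)
  cna_regions <- derive_cna_regions(targets)
  genome <- if (!is.null(genome_fasta)) Biostrings::readDNAStringSet(genome_fasta)
  bundle <- ig_bundle(segments, targets, cna_regions, genome = genome)
  validate_aux_codons(bundle)
  bundle
}

read_bed_targets <- function(bed_path) {
  lines <- readLines(bed_path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(rows, length, 0L) < 3L)
  if (length(bad))
    stop("malformed BED line ", bad[1], ": fewer than 3 columns")
  df <- data.frame(
    chrom = vapply(rows, `[`, "", 1L),
    start = suppressWarnings(as.integer(vapply(rows, `[`, "", 2L))),
    end = suppressWarnings(as.integer(vapply(rows, `[`, "", 3L))),
    label = vapply(rows, function(r) if (length(r) >= 4L) r[4L] else "", ""),
    role = vapply(rows, function(r) if (length(r) >= 5L) r[5L] else "driver", ""),
    stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$end)) {
    bad <- which(is.na(df$start) | is.na(df$end))[1]
    stop("malformed BED line ", bad, ": non-integer coordinates")
  }
  df$label[!nzchar(df$label)] <- paste0(df$chrom, ":", df$start, "-", df$end)[!nzchar(df$label)]
  df
}

derive_cna_regions <- function(targets) {
  regions <- lapply(.cna_region_names, function(rn)
    targets$label[startsWith(targets$label, rn)])
  names(regions) <- .cna_region_names
  regions[vapply(regions, length, 0L) > 0L]
}

# an annotated auxiliary codon must translate to a residue (not a stop) in the
# germline: it marks a genuine codon of interest (e.g. IGLV3-21 position 110)
validate_aux_codons <- function(bundle) {
  for (seg in bundle$segments) {
    if (!is.na(seg$aux_codon)) {
      aa <- translate_dna(substr(seg$sequence, seg$aux_codon + 1L, seg$aux_codon + 3L))
      if (aa == "*")
        stop("segment '", seg$name, "': auxiliary codon is a stop in the germline")
    }
  }
  invisible(bundle)
}

#' Write a reference bundle back to FASTA + TSV + BED
#'
#' Inverse of [load_reference_bundle()]; round-tripping preserves sequences,
#' bounds and targets exactly. Minus-strand segments are written back as
#' genomic (plus-strand) FASTA sequences.
#'
#' @param bundle an [ig_bundle()].
#' @param fasta_path,annotation_path,bed_path output paths.
#' @return invisibly, the bundle.
#' @export
write_reference_bundle <- function(bundle, fasta_path, annotation_path, bed_path) {
  seqs <- vapply(bundle$segments, function(s)
    if (s$strand == "-") revcomp(s$sequence) else s$sequence, "")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta_path)
  ann <- do.call(rbind, lapply(bundle$segments, function(s) data.frame(
    name = s$name, locus = s$locus, class = s$segment_class, chrom = s$chrom,
    start = s$start, end = s$end, strand = s$strand,
    region_bounds = if (is.null(s$region_bounds)) "" else
      paste(s$region_bounds, collapse = ","),
    anchor = if (is.na(s$anchor_codon)) "" else as.character(s$anchor_codon),
    aux_codon = if (is.na(s$aux_codon)) "" else as.character(s$aux_codon),
    stringsAsFactors = FALSE)))
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tg <- bundle$targets
  utils::write.table(tg[, c("chrom", "start", "end", "label", "role")],
                     bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(bundle)
}

#' Retrieve segments of a given locus and class in deterministic order
#'
#' Ordering is lexicographic by allele name (C locale), which downstream
#' tie-breaking relies on for reproducibility.
#'
#' @param bundle an [ig_bundle()].
#' @param locus `"IGH"`, `"IGL"` or `"IGK"`.
#' @param cls `"V"`, `"D"` or `"J"`.
#' @return (possibly empty) list of `gene_segment` objects.
#' @export
segments_by_class <- function(bundle, locus, cls) {
  keep <- vapply(bundle$segments, function(s)
    s$locus == locus && s$segment_class == cls, TRUE)
  segs <- bundle$segments[keep]
  segs[order(names(segs), method = "radix")]
}

# locate the segment containing a genomic position (0-based), or NULL
segment_at <- function(bundle, chrom, gpos) {
  for (seg in bundle$segments) {
    if (seg$chrom == chrom && gpos >= seg$start && gpos <= seg$end) return(seg)
  }
  NULL
}
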