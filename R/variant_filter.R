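#' @title Pileup variant calling and VAF-tier filtering
#'
#' @description
#' A reference pileup caller over driver-gene targets plus the panel's
#' variant-allele-fraction tiers: calls below 2% VAF are filtered out,
#' calls between 2% and 3% are retained as low-confidence (reproducibility
#' across independent runs is only guaranteed from 3% upward), and calls
#' at or above 3% pass. The pileup caller is deliberately simple — its
#' role is to make the filter tiers and the end-to-end pipeline testable —
#' and externally produced VCFs can be fed straight into the filter
#' instead.
#'
#' @name variant_filter
NULL

default_variant_config <- function() {
  list(min_base_q = 20L, min_mapq = 20L, min_depth = 100L, min_alt_reads = 5L,
       vaf_cutoff = 0.02, high_confidence_vaf = 0.03)
}

# per-position base counts and indel events over one target window
.target_pileup <- function(aln, ref_seq, t_start, t_end, cfg) {
  n <- t_end - t_start
  counts <- matrix(0L, nrow = 4L, ncol = n,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  indels <- list()
  minq <- cfg$min_base_q + 33L
  for (i in seq_len(nrow(aln))) {
    rec <- aln[i, ]
    ops <- parse_cigar(rec$cigar)
    g <- rec$pos0; q <- 0L
    for (k in seq_len(nrow(ops))) {
      op <- ops$op[k]; len <- ops$len[k]
      if (op %in% c("M", "=", "X")) {
        lo <- max(g, t_start); hi <- min(g + len, t_end)
        if (hi > lo) {
          qoff <- (lo - g) + q
          bases <- chars(substr(rec$seq, qoff + 1L, qoff + (hi - lo)))
          quals <- utf8ToInt(substr(rec$qual, qoff + 1L, qoff + (hi - lo)))
          bi <- match(bases, c("A", "C", "G", "T"))
          ok <- !is.na(bi) & quals >= minq
          if (any(ok)) {
            off <- (lo:(hi - 1L) - t_start)[ok]
            tab <- tabulate(off * 4L + bi[ok], nbins = 4L * n)
            counts <- counts + matrix(tab, nrow = 4L)
          }
        }
        g <- g + len; q <- q + len
      } else if (op == "I") {
        # insertion anchored on the preceding reference base
        p <- g - 1L
        if (p >= t_start && p < t_end)
          indels[[length(indels) + 1L]] <- list(
            pos = p, type = "ins", seq = substr(rec$seq, q + 1L, q + len))
        q <- q + len
      } else if (op == "D") {
        p <- g - 1L
        if (p >= t_start && p < t_end)
          indels[[length(indels) + 1L]] <- list(
            pos = p, type = "del",
            seq = substr(ref_seq, g - t_start + 1L, g - t_start + len))
        g <- g + len
      } else if (op %in% c("N")) {
        g <- g + len
      } else if (op == "S") {
        q <- q + len
      }
    }
  }
  list(counts = counts, indels = indels)
}

#' Call SNVs and simple indels by reference pileup over driver targets
#'
#' Per-position allele counts from quality-filtered bases; an alternate
#' allele is emitted when supported by at least `min_alt_reads` reads.
#' Insertions and deletions are taken from CIGAR I/D blocks, anchored on
#' the preceding reference base (VCF convention). Multiple alternates at
#' one site yield separate records. Exported positions are 1-based.
#'
#' @param alignments records data frame.
#' @param bundle an [ig_bundle()] with a `genome` slot (the pileup
#'   reference).
#' @param targets optional target subset (default: all driver-role
#'   targets).
#' @param config see [default_variant_config()].
#' @return data frame of calls: `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `depth`, `alt_count`, `vaf`, `gene`. Zero rows when nothing is found.
#' @export
pileup_call <- function(alignments, bundle, targets = NULL, config = list()) {
  cfg <- utils::modifyList(default_variant_config(), config)
  if (is.null(bundle$genome)) stop("bundle has no genome reference")
  if (is.null(targets))
    targets <- bundle$targets[bundle$targets$role == "driver", , drop = FALSE]
  keep <- alignments$mapq >= cfg$min_mapq &
    bitwAnd(alignments$flag, 1024L) == 0L
  aln0 <- alignments[keep, , drop = FALSE]
  aend <- aln0$pos0 + cigar_ref_len(aln0$cigar)
  out <- list()
  for (t in seq_len(nrow(targets))) {
    ch <- targets$chrom[t]
    if (!ch %in% names(bundle$genome)) next
    t0 <- targets$start[t]; t1 <- targets$end[t]
    on <- which(aln0$rname == ch & aln0$pos0 < t1 & aend > t0)
    if (!length(on)) next
    ref_seq <- substr(as.character(bundle$genome[[ch]]), t0 + 1L, t1)
    pp <- .target_pileup(aln0[on, , drop = FALSE], ref_seq, t0, t1, cfg)
    depth <- colSums(pp$counts)
    refb <- chars(ref_seq)
    ref_idx <- match(refb, c("A", "C", "G", "T"))
    for (b in 1:4) {
      alt_base <- c("A", "C", "G", "T")[b]
      ac <- pp$counts[b, ]
      hit <- which(ac >= cfg$min_alt_reads & ref_idx != b & depth > 0L)
      for (p in hit) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, pos = t0 + p, ref = refb[p], alt = alt_base,
          depth = as.integer(depth[p]), alt_count = as.integer(ac[p]),
          vaf = ac[p] / depth[p], gene = targets$label[t],
          stringsAsFactors = FALSE)
      }
    }
    if (length(pp$indels)) {
      key <- vapply(pp$indels, function(e)
        paste(e$pos, e$type, e$seq, sep = "\r"), "")
      for (k in unique(key)) {
        e <- pp$indels[[match(k, key)]]
        cnt <- sum(key == k)
        if (cnt < cfg$min_alt_reads) next
        p <- e$pos - t0 + 1L
        dp <- as.integer(depth[p])
        anchor <- refb[p]
        if (e$type == "ins") { ref <- anchor; alt <- paste0(anchor, e$seq) }
        else { ref <- paste0(anchor, e$seq); alt <- anchor }
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, pos = e$pos + 1L, ref = ref, alt = alt,
          depth = dp, alt_count = cnt, vaf = cnt / dp,
          gene = targets$label[t], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), depth = integer(),
                      alt_count = integer(), vaf = numeric(),
                      gene = character(), stringsAsFactors = FALSE))
  calls <- do.call(rbind, out)
  calls[order(calls$chrom, calls$pos, calls$alt, method = "radix"), ,
        drop = FALSE]
}

#' Apply the VAF filter tiers to variant calls
#'
#' Tiers: `vaf < vaf_cutoff` (default 2%) is filtered out
#' (`below_vaf_cutoff`); `vaf_cutoff <= vaf < high_confidence_vaf`
#' (default 3%) is retained as low-confidence; `vaf >= high_confidence_vaf`
#' passes. Calls below `min_depth` are filtered as `low_depth` regardless
#' of VAF.
#'
#' @param calls data frame from [pileup_call()] (or any table with `vaf`
#'   and `depth` columns).
#' @param config list overriding `vaf_cutoff = 0.02`,
#'   `high_confidence_vaf = 0.03`, `min_depth = 100`.
#' @return the same table with `filters` (comma-joined flags) and `status`
#'   (`"pass"`, `"low_confidence"`, `"filtered"`) columns.
#' @export
apply_vaf_filters <- function(calls, config = list()) {
  cfg <- utils::modifyList(default_variant_config(), config)
  n <- nrow(calls)
  filters <- character(n)
  status <- character(n)
  for (i in seq_len(n)) {
    fl <- character()
    if (calls$depth[i] < cfg$min_depth) fl <- c(fl, "low_depth")
    if (calls$vaf[i] < cfg$vaf_cutoff) fl <- c(fl, "below_vaf_cutoff")
    else if (calls$vaf[i] < cfg$high_confidence_vaf)
      fl <- c(fl, "low_confidence_vaf")
    status[i] <- if ("below_vaf_cutoff" %in% fl || "low_depth" %in% fl)
      "filtered" else if ("low_confidence_vaf" %in% fl) "low_confidence"
    else "pass"
    filters[i] <- paste(fl, collapse = ",")
  }
  calls$filters <- filters
  calls$status <- status
  calls
}

#' Write variant calls as VCF
#'
#' FILTER is `PASS`, `lowConf`, `vafCutoff` or `lowDepth`; INFO carries
#' `VAF`, `ALTC` and `GENE`.
#'
#' @param calls filtered calls from [apply_vaf_filters()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_variants_vcf <- function(calls, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
           "##INFO=<ID=ALTC,Number=1,Type=Integer,Description=\"Alternate read count\">",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Target gene\">",
           "##FILTER=<ID=lowConf,Description=\"VAF below high-confidence tier\">",
           "##FILTER=<ID=vafCutoff,Description=\"VAF below 2% cutoff\">",
           "##FILTER=<ID=lowDepth,Description=\"Depth below minimum\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  filt <- vapply(seq_len(nrow(calls)), function(i) {
    fl <- strsplit(calls$filters[i], ",", fixed = TRUE)[[1]]
    if ("low_depth" %in% fl) "lowDepth"
    else if ("below_vaf_cutoff" %in% fl) "vafCutoff"
    else if ("low_confidence_vaf" %in% fl) "lowConf"
    else "PASS"
  }, "")
  body <- if (nrow(calls)) sprintf(
    "%s\t%d\t.\t%s\t%s\t.\t%s\tVAF=%.6g;ALTC=%d;GENE=%s",
    calls$chrom, calls$pos, calls$ref, calls$alt, filt, calls$vaf,
    calls$alt_count, calls$gene) else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read variant calls from a VCF into the filter input format
#'
#' Alternative input path for externally called variants: only
#' [apply_vaf_filters()] runs on these. Requires the `vcfR` package.
#'
#' @param path VCF path.
#' @return calls data frame (`chrom`, `pos`, `ref`, `alt`, `depth`,
#'   `alt_count`, `vaf`, `gene`).
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCFs requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- t(fx)   # single-record VCFs drop dimensions
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  info <- vcfR::extract.info(v, "VAF")
  altc <- vcfR::extract.info(v, "ALTC")
  gene <- vcfR::extract.info(v, "GENE")
  vaf <- suppressWarnings(as.numeric(info))
  ac <- suppressWarnings(as.integer(altc))
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
             alt = fix$ALT,
             depth = ifelse(is.na(ac) | is.na(vaf) | vaf == 0, NA_integer_,
                            as.integer(round(ac / vaf))),
             alt_count = ac, vaf = vaf,
             gene = ifelse(is.na(gene), "", gene), stringsAsFactors = FALSE)
}
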