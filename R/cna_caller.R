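#' @title Copy-number calling from panel coverage
#'
#' @description
#' Calls the four recurrent CLL copy-number alterations — del(17p),
#' del(11q), del(13q) and trisomy 12 — from per-target mean depths using
#' the standard log2-ratio formulation: depths are optionally divided by
#' the per-target median of a panel of normals, recentred on the sample's
#' median backbone ratio, and log2-transformed. A coverage-uniformity QC
#' gate (interquartile range of backbone log2 ratios) must pass before any
#' call is made; samples failing it are reported as QC-failed with no
#' calls. The backbone used for centring and QC consists of the
#' `cna_backbone` targets that do not belong to a recurrent CNA region, so
#' a real lesion cannot bias its own reference. Clonal fractions are
#' estimated by inverting the expected ratio: `f = 2(1 - 2^m)` for
#' deletions and `f = 2(2^m - 1)` for trisomy, clipped to `[0, 1]`.
#'
#' @name cna_caller
NULL

default_cna_config <- function() {
  list(del_threshold = -0.2, gain_threshold = 0.15, min_targets = 3L,
       qc_iqr_threshold = 0.5, min_mapq = 20L)
}

#' Compute per-target mean depths from aligned reads
#'
#' Mean depth is the number of aligned bases falling inside the target
#' divided by the target length; duplicate-flagged reads and reads below
#' `min_mapq` are excluded. Soft-clipped and inserted bases do not consume
#' reference and never count.
#'
#' @param alignments records data frame.
#' @param targets target data frame (`chrom`, `start`, `end`, `label`).
#' @param config list overriding `min_mapq = 20`.
#' @return depth table data frame (`label`, `chrom`, `start`, `end`,
#'   `depth`).
#' @export
compute_depths <- function(alignments, targets, config = list()) {
  cfg <- utils::modifyList(default_cna_config(), config)
  if (any(targets$end <= targets$start)) stop("zero-length target")
  keep <- alignments$mapq >= cfg$min_mapq &
    bitwAnd(alignments$flag, 1024L) == 0L
  aln <- alignments[keep, , drop = FALSE]
  astart <- aln$pos0
  aend <- aln$pos0 + cigar_ref_len(aln$cigar)
  depth <- numeric(nrow(targets))
  for (i in seq_len(nrow(targets))) {
    on <- which(aln$rname == targets$chrom[i] &
                  astart < targets$end[i] & aend > targets$start[i])
    if (length(on)) {
      ov <- pmin(aend[on], targets$end[i]) - pmax(astart[on], targets$start[i])
      depth[i] <- sum(ov) / (targets$end[i] - targets$start[i])
    }
  }
  data.frame(label = targets$label, chrom = targets$chrom,
             start = targets$start, end = targets$end, depth = depth,
             stringsAsFactors = FALSE)
}

#' Normalize a coverage profile to log2 ratios with a QC gate
#'
#' With a panel of normals, each target's depth is divided by its median
#' depth across the normals; otherwise raw depths are used. All ratios are
#' then divided by the sample's median backbone ratio and log2-transformed,
#' so the backbone median log2 ratio is exactly 0. Targets whose normal
#' median is 0 are masked and counted. The uniformity metric is the IQR of
#' backbone log2 ratios; `qc_pass` requires it at or below
#' `qc_iqr_threshold` (default 0.5).
#'
#' @param profile depth table for the sample.
#' @param bundle an [ig_bundle()] (supplies target roles and CNA regions).
#' @param normals optional list of depth tables from non-tumor samples.
#' @param config list overriding `qc_iqr_threshold`.
#' @return a `normalized_profile`: list with `log2` (named vector),
#'   `masked` labels, `mode`, `uniformity_iqr`, `qc_pass`.
#' @export
normalize_coverage <- function(profile, bundle, normals = NULL,
                               config = list()) {
  cfg <- utils::modifyList(default_cna_config(), config)
  tg <- bundle$targets
  labels <- tg$label[tg$role == "cna_backbone"]
  region_labels <- unique(unlist(bundle$cna_regions))
  backbone_labels <- setdiff(labels, region_labels)
  depth <- profile$depth[match(labels, profile$label)]
  if (anyNA(depth))
    stop("profile is missing cna_backbone target(s): ",
         paste(utils::head(labels[is.na(depth)], 3), collapse = ", "))
  masked <- character()
  if (!is.null(normals) && length(normals)) {
    nm <- vapply(normals, function(np) np$depth[match(labels, np$label)],
                 numeric(length(labels)))
    med <- apply(as.matrix(nm), 1L, stats::median)
    masked <- labels[med <= 0 | is.na(med)]
    ratio <- ifelse(med > 0, depth / med, NA_real_)
    mode <- "panel_of_normals"
  } else {
    ratio <- depth
    mode <- "median_center"
  }
  bb <- match(backbone_labels, labels)
  center <- stats::median(ratio[bb], na.rm = TRUE)
  if (!is.finite(center) || center <= 0)
    stop("cannot centre profile: non-positive median backbone ratio")
  l2 <- log2(ratio / center)
  names(l2) <- labels
  iqr <- stats::IQR(l2[bb], na.rm = TRUE)
  structure(list(log2 = l2, masked = masked, mode = mode,
                 backbone_labels = backbone_labels,
                 uniformity_iqr = iqr,
                 qc_pass = iqr <= cfg$qc_iqr_threshold),
            class = "normalized_profile")
}

#' Call the four recurrent CNAs from a normalized profile
#'
#' Per region, the median log2 ratio over its unmasked targets drives the
#' call: deletion when at or below `del_threshold` (del17p/del11q/del13q
#' only), gain when at or above `gain_threshold` (tri12 only) — the
#' region-specific direction gate means e.g. trisomy 12 can never be
#' reported as a deletion. Regions with fewer than `min_targets` informative
#' targets are `uncallable`. When the profile failed the uniformity QC no
#' calls are made and a QC-failed marker is returned instead.
#'
#' @param norm a `normalized_profile`.
#' @param bundle an [ig_bundle()].
#' @param config list overriding `del_threshold = -0.2`,
#'   `gain_threshold = 0.15`, `min_targets = 3`.
#' @return list with `qc_pass`, `uniformity_iqr` and `calls` (data frame:
#'   `region`, `state`, `median_log2`, `n_targets`, `clonal_fraction`; NULL
#'   when QC failed).
#' @export
call_cnas <- function(norm, bundle, config = list()) {
  cfg <- utils::modifyList(default_cna_config(), config)
  if (!isTRUE(norm$qc_pass))
    return(list(qc_pass = FALSE, uniformity_iqr = norm$uniformity_iqr,
                calls = NULL))
  rows <- lapply(names(bundle$cna_regions), function(rn) {
    labs <- setdiff(bundle$cna_regions[[rn]], norm$masked)
    vals <- norm$log2[labs]
    vals <- vals[is.finite(vals)]
    n <- length(vals)
    if (n < cfg$min_targets)
      return(data.frame(region = rn, state = "uncallable",
                        median_log2 = NA_real_, n_targets = n,
                        clonal_fraction = NA_real_, stringsAsFactors = FALSE))
    m <- stats::median(vals)
    if (rn == "tri12") {
      state <- if (m >= cfg$gain_threshold) "gain" else "neutral"
      f <- if (state == "gain") min(1, max(0, 2 * (2^m - 1))) else NA_real_
    } else {
      state <- if (m <= cfg$del_threshold) "deletion" else "neutral"
      f <- if (state == "deletion") min(1, max(0, 2 * (1 - 2^m))) else NA_real_
    }
    data.frame(region = rn, state = state, median_log2 = m, n_targets = n,
               clonal_fraction = f, stringsAsFactors = FALSE)
  })
  list(qc_pass = TRUE, uniformity_iqr = norm$uniformity_iqr,
       calls = do.call(rbind, rows))
}
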