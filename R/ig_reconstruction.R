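#' @title Rearrangement reconstruction from soft-clipped reads
#'
#' @description
#' Capture panels tile both sides of a V(D)J junction deeply, so a read
#' aligner leaves the partner-segment bases of every junction-spanning read
#' as a soft-clip at the breakpoint. This module harvests those clips over
#' IG targets, clusters them per anchor segment and breakpoint, and joins
#' the V-side and J-side consensus sequences into a full-length rearranged
#' sequence (FR1 through FR4). The V body upstream of the breakpoint is
#' taken from the read consensus where covered — so somatic hypermutation is
#' captured — and from germline where uncovered (flagged via per-base
#' support).
#'
#' @name ig_reconstruction
NULL

default_reconstruction_config <- function() {
  list(min_clip = 10L, min_mapq = 20L, window = 5L, min_support = 3L,
       min_overlap = 20L, max_mismatch_rate = 0.05)
}

#' Collect soft-clip junction evidence over IG targets
#'
#' One evidence item is emitted per soft-clip of length >= `min_clip` on a
#' read with mapping quality >= `min_mapq` whose alignment overlaps an
#' ig-role target. Clip coordinates are converted to segment-local offsets
#' in reading orientation; for minus-strand segments the clip side flips
#' and the clipped bases are reverse-complemented.
#'
#' @param alignments records data frame (see [read_sam()]).
#' @param bundle an [ig_bundle()].
#' @param config list overriding `min_clip = 10`, `min_mapq = 20`.
#' @return data.frame with columns `segment`, `breakpoint` (segment-local,
#'   reading orientation), `clip_side` (`"left"`/`"right"`), `clip_seq`,
#'   `read_name`, `mapq`; attribute `n_skipped_contigs` counts reads on
#'   contigs absent from the bundle.
#' @export
collect_junction_evidence <- function(alignments, bundle, config = list()) {
  cfg <- utils::modifyList(default_reconstruction_config(), config)
  ig_tg <- bundle$targets[bundle$targets$role == "ig", , drop = FALSE]
  known_chroms <- unique(vapply(bundle$segments, `[[`, "", "chrom"))
  empty <- data.frame(segment = character(), breakpoint = integer(),
                      clip_side = character(), clip_seq = character(),
                      read_name = character(), mapq = integer(),
                      stringsAsFactors = FALSE)
  skipped <- 0L
  if (nrow(alignments) == 0L) {
    attr(empty, "n_skipped_contigs") <- 0L
    return(empty)
  }
  has_clip <- grepl("S", alignments$cigar, fixed = TRUE)
  unknown <- !(alignments$rname %in% known_chroms)
  skipped <- sum(has_clip & unknown & !(alignments$rname %in% ig_tg$chrom))
  cand <- which(alignments$mapq >= cfg$min_mapq & has_clip & !unknown)
  out_seg <- out_side <- out_clip <- out_name <- character()
  out_bp <- out_mapq <- integer()
  if (length(cand)) {
    sub <- alignments[cand, , drop = FALSE]
    rlen <- cigar_ref_len(sub$cigar)
    astart <- sub$pos0
    aend <- sub$pos0 + rlen
    lead <- suppressWarnings(
      as.integer(sub("^([0-9]+)S.*$", "\\1", sub$cigar)))
    lead[!grepl("^[0-9]+S", sub$cigar)] <- 0L
    trail <- suppressWarnings(
      as.integer(sub("^.*?([0-9]+)S$", "\\1", sub$cigar)))
    trail[!grepl("S$", sub$cigar)] <- 0L
    # overlap with an ig-role target
    on_ig <- vapply(seq_len(nrow(sub)), function(i)
      any(ig_tg$chrom == sub$rname[i] & ig_tg$start < aend[i] &
            ig_tg$end > astart[i]), TRUE)
    add <- function(i, gpos, genomic_side, clip_seq) {
      seg <- segment_at(bundle, sub$rname[i], gpos)
      if (is.null(seg)) return()
      if (seg$strand == "+") {
        side <- genomic_side; off <- gpos - seg$start; cs <- clip_seq
      } else {
        side <- if (genomic_side == "left") "right" else "left"
        off <- seg$end - gpos; cs <- revcomp(clip_seq)
      }
      out_seg[length(out_seg) + 1L] <<- seg$name
      out_bp[length(out_bp) + 1L] <<- off
      out_side[length(out_side) + 1L] <<- side
      out_clip[length(out_clip) + 1L] <<- cs
      out_name[length(out_name) + 1L] <<- sub$qname[i]
      out_mapq[length(out_mapq) + 1L] <<- sub$mapq[i]
    }
    for (i in which(on_ig)) {
      if (lead[i] >= cfg$min_clip)
        add(i, astart[i], "left", substr(sub$seq[i], 1L, lead[i]))
      if (trail[i] >= cfg$min_clip)
        add(i, aend[i], "right",
            substr(sub$seq[i], nchar(sub$seq[i]) - trail[i] + 1L,
                   nchar(sub$seq[i])))
    }
  }
  ev <- if (length(out_seg)) data.frame(
    segment = out_seg, breakpoint = out_bp, clip_side = out_side,
    clip_seq = out_clip, read_name = out_name, mapq = out_mapq,
    stringsAsFactors = FALSE) else empty
  attr(ev, "n_skipped_contigs") <- skipped
  ev
}

#' Cluster junction evidence by breakpoint
#'
#' Single-linkage clustering of evidence items sharing anchor segment and
#' clip side whose breakpoints lie within `window` of each other; clusters
#' with fewer than `min_support` members are discarded. The cluster
#' breakpoint is the modal offset (ties resolved toward the smallest).
#'
#' @param evidence output of [collect_junction_evidence()].
#' @param config list overriding `window = 5`, `min_support = 3`.
#' @return list of clusters, each a list with `segment`, `clip_side`,
#'   `breakpoint`, `support`, `members` (evidence rows).
#' @export
cluster_junctions <- function(evidence, config = list()) {
  cfg <- utils::modifyList(default_reconstruction_config(), config)
  clusters <- list()
  if (nrow(evidence) == 0L) return(clusters)
  keys <- split(seq_len(nrow(evidence)),
                paste(evidence$segment, evidence$clip_side, sep = "\r"))
  for (key in sort(names(keys))) {
    idx <- keys[[key]]
    bp <- evidence$breakpoint[idx]
    o <- order(bp)
    idx <- idx[o]; bp <- bp[o]
    grp <- cumsum(c(1L, as.integer(diff(bp) > cfg$window)))
    for (g in unique(grp)) {
      gi <- idx[grp == g]
      if (length(gi) < cfg$min_support) next
      tb <- table(evidence$breakpoint[gi])
      modal <- as.integer(names(tb)[which.max(tb)])  # first max = smallest
      clusters[[length(clusters) + 1L]] <- list(
        segment = evidence$segment[gi[1]],
        clip_side = evidence$clip_side[gi[1]],
        breakpoint = modal, support = length(gi),
        members = evidence[gi, , drop = FALSE])
    }
  }
  clusters
}

# consensus over reads aligned to one segment, in reading orientation;
# returns list(base = character vec len(seg), depth = integer vec, tied)
segment_pileup <- function(alignments, seg) {
  n <- nchar(seg$sequence)
  rel <- alignments[alignments$rname == seg$chrom &
                      alignments$pos0 < seg$end, , drop = FALSE]
  all_lin <- vector("list", nrow(rel))
  for (i in seq_len(nrow(rel))) {
    cg <- rel$cigar[i]
    ops <- parse_cigar(cg)
    g <- rel$pos0[i]
    q <- 0L
    for (k in seq_len(nrow(ops))) {
      op <- ops$op[k]; len <- ops$len[k]
      if (op %in% c("M", "=", "X")) {
        lo <- max(g, seg$start); hi <- min(g + len, seg$end)
        if (hi > lo) {
          qoff <- (lo - g) + q
          bases <- chars(substr(rel$seq[i], qoff + 1L, qoff + (hi - lo)))
          goff <- lo:(hi - 1L)
          if (seg$strand == "+") {
            off <- goff - seg$start
          } else {
            off <- rev(seg$end - 1L - goff)
            bases <- chars(revcomp(paste(bases, collapse = "")))
          }
          bi <- match(bases, c("A", "C", "G", "T"))
          ok <- !is.na(bi)
          if (any(ok))
            all_lin[[i]] <- c(all_lin[[i]], off[ok] * 4L + bi[ok])
        }
        g <- g + len; q <- q + len
      } else if (op %in% c("D", "N")) {
        g <- g + len
      } else if (op %in% c("I", "S")) {
        q <- q + len
      }
    }
  }
  lin <- unlist(all_lin)
  counts <- matrix(if (length(lin)) tabulate(lin, nbins = 4L * n) else
    integer(4L * n), nrow = 4L,
    dimnames = list(c("A", "C", "G", "T"), NULL))
  vote_bases(counts)
}

# columnar consensus over a list of (start_col, string) fragments; columns
# with no votes get NA. Returns list(base, depth, tied, offset) where
# `offset` is the column index of the first element.
column_consensus <- function(starts, seqs) {
  if (length(seqs) == 0L)
    return(list(base = character(), depth = integer(), tied = logical(),
                offset = 0L))
  ends <- starts + nchar(seqs)
  lo <- min(starts); hi <- max(ends)
  n <- hi - lo
  counts <- matrix(0L, nrow = 4L, ncol = n,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_along(seqs)) {
    b <- chars(seqs[i])
    off <- (starts[i] - lo) + seq_along(b) - 1L
    bi <- match(b, c("A", "C", "G", "T"))
    ok <- !is.na(bi)
    if (any(ok)) {
      tab <- tabulate(off[ok] * 4L + bi[ok], nbins = 4L * n)
      counts <- counts + matrix(tab, nrow = 4L)
    }
  }
  v <- vote_bases(counts)
  v$offset <- lo
  v
}

#' Assemble a rearrangement candidate from a V and a J junction cluster
#'
#' Builds the candidate as: read-consensus V body up to the V breakpoint
#' (germline where uncovered), the right-clip consensus, joined by overlap
#' to the left-clip consensus plus the J body from the J breakpoint onward.
#' Returns `NULL` when the V-side and J-side consensi share no overlap of at
#' least `min_overlap` bases at mismatch rate <= `max_mismatch_rate`.
#' Equal-count consensus ties are resolved by base priority A<C<G<T and
#' flagged in the candidate metadata.
#'
#' @param v_cluster,j_cluster clusters from [cluster_junctions()], anchored
#'   on a V ("right" side) and J ("left" side) segment of the same locus.
#' @param alignments records data frame (for the body pileups).
#' @param bundle an [ig_bundle()].
#' @param config list overriding `min_overlap = 20`,
#'   `max_mismatch_rate = 0.05`.
#' @return a `rearrangement_candidate` (list with `locus`, `sequence`,
#'   `support`, `score`, `per_base_support`, cluster references, tie flag)
#'   or `NULL`.
#' @export
assemble_candidate <- function(v_cluster, j_cluster, alignments, bundle,
                               config = list()) {
  cfg <- utils::modifyList(default_reconstruction_config(), config)
  segv <- bundle$segments[[v_cluster$segment]]
  segj <- bundle$segments[[j_cluster$segment]]
  stopifnot(segv$segment_class == "V", segj$segment_class == "J")
  if (segv$locus != segj$locus) return(NULL)
  bv <- v_cluster$breakpoint
  bj <- j_cluster$breakpoint

  # V side: body consensus [0, bv) + right-clip consensus
  vp <- segment_pileup(alignments, segv)
  germv <- chars(segv$sequence)
  vbody <- ifelse(vp$depth[seq_len(bv)] > 0L, vp$base[seq_len(bv)],
                  germv[seq_len(bv)])
  vbody_dep <- vp$depth[seq_len(bv)]
  vm <- v_cluster$members
  vc <- column_consensus(vm$breakpoint - bv, vm$clip_seq)
  # keep columns at/after the modal breakpoint
  keep <- seq_along(vc$base) + vc$offset - 1L >= 0L
  vclip <- vc$base[keep]; vclip_dep <- vc$depth[keep]
  vclip_tied <- any(vc$tied[keep] & vclip_dep > 0L)
  covered <- !is.na(vclip) & vclip_dep > 0L
  vclip <- vclip[covered]; vclip_dep <- vclip_dep[covered]
  sv <- c(vbody, vclip)
  sv_dep <- c(vbody_dep, vclip_dep)

  # J side: left-clip consensus + body consensus [bj, len)
  jp <- segment_pileup(alignments, segj)
  germj <- chars(segj$sequence)
  lj <- nchar(segj$sequence)
  jbody_idx <- if (bj < lj) (bj + 1L):lj else integer()
  jbody <- ifelse(jp$depth[jbody_idx] > 0L, jp$base[jbody_idx], germj[jbody_idx])
  jbody_dep <- jp$depth[jbody_idx]
  jm <- j_cluster$members
  # clips are right-justified at their breakpoints: last clip base abuts the
  # first aligned J base; column 0 is the J start
  jc <- column_consensus((jm$breakpoint - bj) - nchar(jm$clip_seq), jm$clip_seq)
  keepj <- seq_along(jc$base) + jc$offset - 1L < 0L
  jclip <- jc$base[keepj]; jclip_dep <- jc$depth[keepj]
  jclip_tied <- any(jc$tied[keepj] & jclip_dep > 0L)
  coveredj <- !is.na(jclip) & jclip_dep > 0L
  jclip <- jclip[coveredj]; jclip_dep <- jclip_dep[coveredj]
  sj <- c(jclip, jbody)
  sj_dep <- c(jclip_dep, jbody_dep)

  # join by best suffix(sv)/prefix(sj) overlap
  max_o <- min(length(sv), length(sj))
  if (max_o < cfg$min_overlap) return(NULL)
  best <- NULL
  for (o in seq(max_o, cfg$min_overlap)) {
    a <- sv[(length(sv) - o + 1L):length(sv)]
    b <- sj[seq_len(o)]
    mm <- sum(a != b)
    if (mm / o <= cfg$max_mismatch_rate) {
      score <- (o - mm) - 4L * mm
      if (is.null(best) || score > best$score) best <- list(o = o, score = score)
    }
  }
  if (is.null(best)) return(NULL)
  o <- best$o
  sj_tail <- if (o < length(sj)) (o + 1L):length(sj) else integer()
  sequence <- paste(c(sv, sj[sj_tail]), collapse = "")
  support_vec <- c(sv_dep, sj_dep[sj_tail])
  ov_idx <- (length(sv) - o + 1L):length(sv)
  support_vec[ov_idx] <- support_vec[ov_idx] + sj_dep[seq_len(o)]

  mean_mapq <- mean(c(vm$mapq, jm$mapq))
  support <- min(v_cluster$support, j_cluster$support)
  structure(list(
    locus = segv$locus, sequence = sequence,
    v_segment = segv$name, j_segment = segj$name,
    v_breakpoint = bv, j_breakpoint = bj,
    v_cluster = v_cluster, j_cluster = j_cluster,
    support = support, mean_mapq = mean_mapq,
    per_base_support = as.integer(support_vec),
    consensus_tie = isTRUE(vclip_tied) || isTRUE(jclip_tied),
    score = candidate_score(support, nchar(sequence), mean_mapq)),
    class = "rearrangement_candidate")
}

candidate_score <- function(support, len, mean_mapq) {
  support * log2(1 + len) * mean_mapq / 60
}

#' Rank rearrangement candidates
#'
#' Descending by score `support * log2(1 + length) * mean_mapq / 60`; ties
#' broken lexicographically by (V segment name, J segment name). The first
#' candidate is reported as the clonal rearrangement.
#'
#' @param candidates list of `rearrangement_candidate` objects.
#' @return the same list, ordered.
#' @export
rank_candidates <- function(candidates) {
  if (length(candidates) <= 1L) return(candidates)
  sc <- vapply(candidates, `[[`, 0, "score")
  vn <- vapply(candidates, `[[`, "", "v_segment")
  jn <- vapply(candidates, `[[`, "", "j_segment")
  candidates[order(-sc, vn, jn, method = "radix")]
}

#' Reconstruct rearrangements for one locus
#'
#' End-to-end reconstruction: evidence collection, clustering, pairwise
#' V x J assembly, ranking. Clusters that cannot be paired into a joinable
#' candidate are reported as incomplete (never as the clonal result).
#'
#' @param alignments records data frame.
#' @param bundle an [ig_bundle()].
#' @param locus `"IGH"` or `"IGL"`.
#' @param config reconstruction parameters (see
#'   [default_reconstruction_config()]).
#' @return list with `candidates` (ranked), `incomplete` (unpaired
#'   clusters), `n_evidence`.
#' @export
reconstruct_ig <- function(alignments, bundle, locus = "IGH", config = list()) {
  ev <- collect_junction_evidence(alignments, bundle, config)
  loc <- vapply(ev$segment, function(nm) bundle$segments[[nm]]$locus, "",
                USE.NAMES = FALSE)
  ev <- ev[loc == locus, , drop = FALSE]
  clusters <- cluster_junctions(ev, config)
  is_v <- vapply(clusters, function(cl)
    bundle$segments[[cl$segment]]$segment_class == "V" &&
      cl$clip_side == "right", TRUE)
  is_j <- vapply(clusters, function(cl)
    bundle$segments[[cl$segment]]$segment_class == "J" &&
      cl$clip_side == "left", TRUE)
  vcl <- clusters[is_v]; jcl <- clusters[is_j]
  cands <- list()
  used_v <- rep(FALSE, length(vcl)); used_j <- rep(FALSE, length(jcl))
  for (a in seq_along(vcl)) for (b in seq_along(jcl)) {
    cand <- assemble_candidate(vcl[[a]], jcl[[b]], alignments, bundle, config)
    if (!is.null(cand)) {
      cands[[length(cands) + 1L]] <- cand
      used_v[a] <- TRUE; used_j[b] <- TRUE
    }
  }
  list(candidates = rank_candidates(cands),
       incomplete = c(vcl[!used_v], jcl[!used_j],
                      clusters[!(is_v | is_j)]),
       n_evidence = nrow(ev))
}
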