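#' @title Germline annotation of assembled rearrangements
#'
#' @description
#' Assigns germline V, D and J genes to an assembled rearranged sequence by
#' affine-gap ends-free alignment against every allele of the locus, computes
#' the germline identity of the V gene over its FR1-FR3 span, classifies the
#' somatic hypermutation (SHM) status with the clinical 98% cutoff (97.00 to
#' 97.99% flagged as borderline), extracts the CDR3/junction between the
#' conserved Cys-104 and Trp/Phe-118 anchors, and checks productivity
#' (in-frame junction, intact anchors, no stop codons).
#'
#' Identity is the IMGT-style quantity 100 * matches / (matches + mismatches
#' + gap columns) over evaluated germline-V columns, each indel column
#' counting once. The evaluated span runs from the first aligned V position
#' (positions clipped by the ends-free alignment at the 5' terminus are
#' paired back and counted as mismatches) to the FR3 end boundary: junction
#' and germline-CDR3 bases never enter the identity.
#'
#' @name ig_annotation
NULL

default_annotation_config <- function() {
  list(match = 1, mismatch = -2, gap_open = 6, gap_extend = 1,
       min_identity = 60, min_v_span = 100L, min_j_span = 20L,
       d_min_len = 5L, d_min_ident = 0.80)
}

.sub_matrix <- function(match = 1, mismatch = -2) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", ] <- mismatch; m[, "N"] <- mismatch
  m
}

# ends-free alignment of germline segments (patterns) against one candidate
# sequence (subject); one vectorized call, a list of per-segment results
align_segments <- function(seg_seqs, sequence, cfg) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(seg_seqs), Biostrings::DNAString(sequence),
    type = "local", substitutionMatrix = .sub_matrix(cfg$match, cfg$mismatch),
    gapOpening = cfg$gap_open, gapExtension = cfg$gap_extend)
  pgs <- as.character(Biostrings::alignedPattern(pa))
  sgs <- as.character(Biostrings::alignedSubject(pa))
  p1s <- BiocGenerics::start(Biostrings::pattern(pa))   # 1-based, ungapped
  q1s <- BiocGenerics::start(Biostrings::subject(pa))
  scores <- Biostrings::score(pa)
  lapply(seq_along(seg_seqs), function(i)
    .alignment_bookkeeping(pgs[i], sgs[i], p1s[i], q1s[i],
                           nchar(seg_seqs[i]), nchar(sequence), scores[i]))
}

.alignment_bookkeeping <- function(pg_s, sg_s, p1, q1, plen, qlen, score) {
  pg <- chars(pg_s)
  sg <- chars(sg_s)
  pcons <- pg != "-"
  qcons <- sg != "-"
  # 0-based offset consumed at each column (gap columns inherit the offset
  # of the next consumed position)
  soff <- (p1 - 1L) + cumsum(pcons) - ifelse(pcons, 1L, 0L)
  qoff <- (q1 - 1L) + cumsum(qcons) - ifelse(qcons, 1L, 0L)
  both <- pcons & qcons
  # gapless blocks
  blocks <- NULL
  if (any(both)) {
    bi <- which(both)
    newblk <- c(TRUE, diff(soff[bi]) != 1L | diff(qoff[bi]) != 1L)
    grp <- cumsum(newblk)
    blocks <- data.frame(
      q0 = tapply(qoff[bi], grp, min),
      s0 = tapply(soff[bi], grp, min),
      len = as.integer(table(grp)))
    rownames(blocks) <- NULL
  }
  list(pg = pg, sg = sg, soff = soff, qoff = qoff, pcons = pcons,
       qcons = qcons, p1 = p1, q1 = q1,
       s_first = soff[which(pcons)[1]], s_last = soff[rev(which(pcons))[1]],
       q_first = qoff[which(qcons)[1]], q_last = qoff[rev(which(qcons))[1]],
       blocks = blocks, plen = plen, qlen = qlen, score = score)
}

# single-segment convenience wrapper
align_segment <- function(seg_seq, sequence, cfg) {
  align_segments(seg_seq, sequence, cfg)[[1]]
}

# identity over an inclusion mask of alignment columns, with terminal
# columns clipped by the local alignment paired back in as
# `extra_match` matches plus `extra_mm` mismatches
.identity_counts <- function(al, include, extra_match = 0L, extra_mm = 0L) {
  pg <- al$pg[include]; sg <- al$sg[include]
  matches <- sum(pg == sg & pg != "-") + extra_match
  mism <- sum(pg != sg & pg != "-" & sg != "-") + extra_mm
  ins <- sum(pg == "-")
  del <- sum(sg == "-")
  denom <- matches + mism + ins + del
  list(matches = matches, mismatches = mism, insertions = ins,
       deletions = del,
       identity_pct = if (denom == 0L) 0 else
         round_half_up(100 * matches / denom, 2))
}

new_gene_assignment <- function(name, al, counts, extra = list()) {
  structure(c(list(
    segment_name = name, blocks = al$blocks,
    matches = counts$matches, mismatches = counts$mismatches,
    insertions = counts$insertions, deletions = counts$deletions,
    identity_pct = counts$identity_pct,
    s_first = al$s_first, s_last = al$s_last,
    q_first = al$q_first, q_last = al$q_last,
    qlen = al$qlen), extra), class = "gene_assignment")
}

#' Assign the germline V gene of a rearranged sequence
#'
#' Every V allele of the locus is aligned ends-free against the sequence;
#' the best assignment maximizes identity over the evaluated V span
#' (FR1 start through the FR3 end boundary, never past the V breakpoint or
#' into untemplated bases). Ties prefer fewer gap columns, then the
#' lexicographically smaller allele name.
#'
#' @param sequence assembled rearranged nucleotides (reading orientation),
#'   length >= 100.
#' @param bundle an [ig_bundle()].
#' @param locus `"IGH"` or `"IGL"`.
#' @param config see [default_annotation_config()].
#' @return a `gene_assignment` with `identity_pct`, counts, aligned blocks
#'   and breakpoint bookkeeping.
#' @export
assign_v_gene <- function(sequence, bundle, locus = "IGH", config = list()) {
  cfg <- utils::modifyList(default_annotation_config(), config)
  if (nchar(sequence) < 100L) stop("sequence shorter than 100 nt")
  alleles <- segments_by_class(bundle, locus, "V")
  if (length(alleles) == 0L) stop("no V alleles for locus ", locus)
  als <- align_segments(vapply(alleles, `[[`, "", "sequence"), sequence, cfg)
  best <- NULL
  for (ai in seq_along(alleles)) {
    seg <- alleles[[ai]]
    al <- als[[ai]]
    if (is.null(al$blocks)) next
    f3 <- fr3_end(seg)
    # pair clipped 5'-terminal bases back in one-to-one and compare them
    lead <- min(al$p1 - 1L, al$q1 - 1L)
    lead_match <- 0L
    if (lead > 0L) {
      pl <- chars(substr(seg$sequence, al$p1 - lead, al$p1 - 1L))
      ql <- chars(substr(sequence, al$q1 - lead, al$q1 - 1L))
      lead_match <- sum(pl == ql)
    }
    include <- al$soff < f3
    counts <- .identity_counts(al, include, extra_match = lead_match,
                               extra_mm = lead - lead_match)
    span <- counts$matches + counts$mismatches + counts$insertions +
      counts$deletions
    if (span < cfg$min_v_span) next  # spurious short local hit
    gaps <- counts$insertions + counts$deletions
    cand <- new_gene_assignment(seg$name, al, counts,
                                extra = list(fr3_end = f3, lead = lead,
                                             eval_span = span,
                                             span_short = span < 150L))
    if (is.null(best) ||
        cand$identity_pct > best$identity_pct ||
        (cand$identity_pct == best$identity_pct &&
           (gaps < best$.gaps ||
              (gaps == best$.gaps && cand$segment_name < best$segment_name)))) {
      cand$.gaps <- gaps
      best <- cand
    }
  }
  if (is.null(best) || best$identity_pct < cfg$min_identity)
    stop("no V assignment: no allele reaches ", cfg$min_identity, "% identity")
  best$.gaps <- NULL
  best
}

#' Assign the germline J gene of a rearranged sequence
#'
#' Symmetric to [assign_v_gene()] but anchored at the 3' end: identity is
#' evaluated from the first aligned J position to the J 3' terminus
#' (terminal columns clipped by the ends-free alignment are paired back as
#' mismatches), requiring an evaluated span of at least `min_j_span`.
#'
#' @inheritParams assign_v_gene
#' @return a `gene_assignment`.
#' @export
assign_j_gene <- function(sequence, bundle, locus = "IGH", config = list()) {
  cfg <- utils::modifyList(default_annotation_config(), config)
  alleles <- segments_by_class(bundle, locus, "J")
  if (length(alleles) == 0L) stop("no J alleles for locus ", locus)
  als <- align_segments(vapply(alleles, `[[`, "", "sequence"), sequence, cfg)
  best <- NULL
  for (ai in seq_along(alleles)) {
    seg <- alleles[[ai]]
    al <- als[[ai]]
    if (is.null(al$blocks)) next
    # pair clipped 3'-terminal bases back in one-to-one and compare them
    tail <- min(al$plen - 1L - al$s_last, al$qlen - 1L - al$q_last)
    tail_match <- 0L
    if (tail > 0L) {
      pt <- chars(substr(seg$sequence, al$s_last + 2L, al$s_last + 1L + tail))
      qt <- chars(substr(sequence, al$q_last + 2L, al$q_last + 1L + tail))
      tail_match <- sum(pt == qt)
    }
    counts <- .identity_counts(al, rep(TRUE, length(al$pg)),
                               extra_match = tail_match,
                               extra_mm = tail - tail_match)
    span <- counts$matches + counts$mismatches + counts$insertions +
      counts$deletions
    if (span < cfg$min_j_span) next
    gaps <- counts$insertions + counts$deletions
    cand <- new_gene_assignment(seg$name, al, counts)
    if (is.null(best) ||
        cand$identity_pct > best$identity_pct ||
        (cand$identity_pct == best$identity_pct &&
           (gaps < best$.gaps ||
              (gaps == best$.gaps && cand$segment_name < best$segment_name)))) {
      cand$.gaps <- gaps
      best <- cand
    }
  }
  if (is.null(best) || best$identity_pct < cfg$min_identity)
    stop("no J assignment: no allele reaches ", cfg$min_identity,
         "% identity over >= ", cfg$min_j_span, " nt")
  best$.gaps <- NULL
  best
}

# best ungapped local match of a short pattern inside a window; two-pointer
# per diagonal, mismatch budget from the identity floor
best_ungapped_match <- function(pattern, subject, min_len, min_ident) {
  pl <- nchar(pattern); sl <- nchar(subject)
  if (pl == 0L || sl == 0L) return(NULL)
  p <- chars(pattern); s <- chars(subject)
  best <- NULL
  for (off in (-(pl - 1L)):(sl - 1L)) {
    i0 <- max(1L, 1L - off); i1 <- min(pl, sl - off)
    if (i1 - i0 + 1L < min_len) next
    mm <- p[i0:i1] != s[(i0:i1) + off]
    lo <- i0
    nmm <- 0L
    for (hi in i0:i1) {
      nmm <- nmm + as.integer(mm[hi - i0 + 1L])
      while (nmm > floor((hi - lo + 1L) * (1 - min_ident))) {
        nmm <- nmm - as.integer(mm[lo - i0 + 1L])
        lo <- lo + 1L
      }
      len <- hi - lo + 1L
      ident <- (len - nmm) / len
      if (len >= min_len && ident >= min_ident &&
          (is.null(best) || len > best$len ||
             (len == best$len && ident > best$ident))) {
        best <- list(len = len, ident = ident, p_off = lo - 1L,
                     s_off = lo - 1L + off, mismatches = nmm)
      }
    }
  }
  best
}

#' Assign the D gene within a junction
#'
#' Best ungapped local match of any D allele (either orientation) inside the
#' junction nucleotides; reported only when the match spans at least
#' `d_min_len` nt at `d_min_ident` identity or better. Ties prefer the
#' longer match, then the lexicographically smaller allele name. Absence of
#' a D call is a valid outcome (`NULL`).
#'
#' @param junction_nt bases between the V and J breakpoints.
#' @param bundle an [ig_bundle()].
#' @param locus locus whose D alleles to search (default `"IGH"`).
#' @param config see [default_annotation_config()].
#' @return a list (`segment_name`, `match_len`, `identity_pct`,
#'   `orientation`) or `NULL`.
#' @export
assign_d_gene <- function(junction_nt, bundle, locus = "IGH", config = list()) {
  cfg <- utils::modifyList(default_annotation_config(), config)
  ds <- segments_by_class(bundle, locus, "D")
  if (length(ds) == 0L || nchar(junction_nt) < cfg$d_min_len) return(NULL)
  best <- NULL
  for (seg in ds) {
    for (ori in c("+", "-")) {
      pat <- if (ori == "+") seg$sequence else revcomp(seg$sequence)
      m <- best_ungapped_match(pat, junction_nt, cfg$d_min_len, cfg$d_min_ident)
      if (is.null(m)) next
      if (is.null(best) || m$len > best$match_len ||
          (m$len == best$match_len && seg$name < best$segment_name)) {
        best <- list(segment_name = seg$name, match_len = m$len,
                     identity_pct = round_half_up(100 * m$ident, 2),
                     orientation = ori, junction_offset = m$s_off)
      }
    }
  }
  best
}

#' Classify somatic hypermutation status from germline identity
#'
#' Identity is rounded half-up to two decimals before the cutoff is
#' applied: >= 98.00 is unmutated, below is mutated; 97.00-97.99 is flagged
#' borderline.
#'
#' @param identity_pct percent identity in `[0, 100]`.
#' @return list with `identity_pct` (rounded), `status`
#'   (`"mutated"`/`"unmutated"`), `borderline`.
#' @export
classify_shm <- function(identity_pct) {
  if (is.na(identity_pct) || identity_pct < 0 || identity_pct > 100)
    stop("identity_pct must be in [0, 100]")
  id <- round_half_up(identity_pct, 2)
  list(identity_pct = id,
       status = if (id >= 98.00) "unmutated" else "mutated",
       borderline = id >= 97.00 && id <= 97.99)
}

# map a segment offset to a query offset through an assignment's blocks;
# gapless extrapolation past the aligned ends, NA when unmappable
map_to_query <- function(assign, seg_off) {
  bl <- assign$blocks
  for (i in seq_len(nrow(bl))) {
    if (seg_off >= bl$s0[i] && seg_off < bl$s0[i] + bl$len[i])
      return(bl$q0[i] + (seg_off - bl$s0[i]))
  }
  if (seg_off > assign$s_last) {
    q <- assign$q_last + (seg_off - assign$s_last)
    if (q <= assign$qlen - 1L) return(q) else return(NA_integer_)
  }
  if (seg_off < assign$s_first) {
    q <- assign$q_first - (assign$s_first - seg_off)
    if (q >= 0L) return(q) else return(NA_integer_)
  }
  NA_integer_  # inside an alignment gap
}

#' Extract the CDR3 and junction between the conserved anchors
#'
#' Locates the Cys-104 codon through the V alignment and the Trp/Phe-118
#' codon through the J alignment; the junction is anchor-to-anchor
#' inclusive, the CDR3 is the junction minus both anchor codons, translated
#' in the V reading frame. An anchor falling in an alignment gap, beyond
#' the assembly, or mutated to a non-anchor residue yields
#' `failure_reason = "missing_anchor"`.
#'
#' @param sequence assembled rearranged nucleotides.
#' @param v_assign,j_assign assignments from [assign_v_gene()] /
#'   [assign_j_gene()].
#' @param bundle an [ig_bundle()].
#' @return list with `nt_sequence`, `aa_sequence`, `junction_nt`,
#'   `junction_aa`, `frame_offset`, `anchors_intact`, `v_anchor_q`,
#'   `j_anchor_q`; or `failure_reason`.
#' @export
extract_cdr3 <- function(sequence, v_assign, j_assign, bundle) {
  segv <- bundle$segments[[v_assign$segment_name]]
  segj <- bundle$segments[[j_assign$segment_name]]
  qa_v <- map_to_query(v_assign, segv$anchor_codon)
  qa_j <- map_to_query(j_assign, segj$anchor_codon)
  if (is.na(qa_v) || is.na(qa_j) || qa_j + 3L > nchar(sequence) ||
      qa_j <= qa_v)
    return(list(failure_reason = "missing_anchor"))
  junction_nt <- substr(sequence, qa_v + 1L, qa_j + 3L)
  cdr3_nt <- substr(sequence, qa_v + 4L, qa_j)
  in_frame <- nchar(junction_nt) %% 3L == 0L
  junction_aa <- if (in_frame) translate_dna(junction_nt) else NA_character_
  cdr3_aa <- if (in_frame) translate_dna(cdr3_nt) else NA_character_
  first_aa <- translate_dna(substr(sequence, qa_v + 1L, qa_v + 3L))
  last_aa <- translate_dna(substr(sequence, qa_j + 1L, qa_j + 3L))
  anchors_intact <- identical(first_aa, "C") && last_aa %in% c("W", "F")
  res <- list(nt_sequence = cdr3_nt, aa_sequence = cdr3_aa,
              junction_nt = junction_nt, junction_aa = junction_aa,
              frame_offset = qa_v %% 3L, anchors_intact = anchors_intact,
              v_anchor_q = qa_v, j_anchor_q = qa_j)
  if (!anchors_intact) res$failure_reason <- "missing_anchor"
  res
}

#' Check productivity of an annotated rearrangement
#'
#' Productive means: the junction preserves the V reading frame into J
#' (anchor-to-anchor nucleotide distance is a codon multiple), both anchors
#' are intact, and the translated V-through-J sequence contains no stop
#' codon.
#'
#' @param sequence assembled nucleotides.
#' @param cdr3 result of [extract_cdr3()].
#' @param j_assign the J assignment (for the 3' translation limit).
#' @return list with `productive` and `failure_reason`
#'   (`NA`, `"missing_anchor"`, `"out_of_frame"` or `"stop_codon"`).
#' @export
check_productivity <- function(sequence, cdr3, j_assign) {
  if (!is.null(cdr3$failure_reason) &&
      identical(cdr3$failure_reason, "missing_anchor"))
    return(list(productive = FALSE, failure_reason = "missing_anchor"))
  in_frame <- (cdr3$j_anchor_q - cdr3$v_anchor_q) %% 3L == 0L
  if (!in_frame)
    return(list(productive = FALSE, failure_reason = "out_of_frame"))
  frame <- cdr3$v_anchor_q %% 3L
  aa <- translate_dna(substr(sequence, frame + 1L,
                             min(nchar(sequence), j_assign$q_last + 1L)))
  if (grepl("*", aa, fixed = TRUE))
    return(list(productive = FALSE, failure_reason = "stop_codon"))
  list(productive = TRUE, failure_reason = NA_character_)
}

#' Annotate an assembled rearrangement end to end
#'
#' Runs V, J and (for IGH) D assignment, SHM classification, CDR3
#' extraction and the productivity check on a candidate (or bare sequence).
#'
#' @param candidate a `rearrangement_candidate` or a nucleotide string.
#' @param bundle an [ig_bundle()].
#' @param locus `"IGH"` or `"IGL"`.
#' @param config see [default_annotation_config()].
#' @return an `annotated_rearrangement`: list with `sequence`, `v`, `d`,
#'   `j`, `shm`, `cdr3`, `productive`, `failure_reason`, `candidate`.
#' @export
annotate_rearrangement <- function(candidate, bundle, locus = "IGH",
                                   config = list()) {
  sequence <- if (inherits(candidate, "rearrangement_candidate"))
    candidate$sequence else candidate
  v <- assign_v_gene(sequence, bundle, locus, config)
  j <- assign_j_gene(sequence, bundle, locus, config)
  junction_nt <- if (j$q_first > v$q_last + 1L)
    substr(sequence, v$q_last + 2L, j$q_first) else ""
  d <- if (locus == "IGH") assign_d_gene(junction_nt, bundle, locus, config)
  cdr3 <- extract_cdr3(sequence, v, j, bundle)
  prod <- check_productivity(sequence, cdr3, j)
  structure(list(
    sequence = sequence, locus = locus,
    v = v, d = d, j = j,
    shm = classify_shm(v$identity_pct),
    cdr3 = if (is.null(cdr3$failure_reason) || !is.null(cdr3$nt_sequence))
      cdr3 else NULL,
    productive = prod$productive,
    failure_reason = prod$failure_reason,
    candidate = if (inherits(candidate, "rearrangement_candidate"))
      candidate else NULL),
    class = "annotated_rearrangement")
}

#' Write annotated rearrangements as an AIRR-style rearrangement TSV
#'
#' One row per annotated rearrangement with the community column names
#' (`v_call`, `d_call`, `j_call`, `junction_aa`, `v_identity`,
#' `productive`, ...).
#'
#' @param annotated list of `annotated_rearrangement` objects.
#' @param path output TSV path.
#' @param ids optional sequence identifiers.
#' @return invisibly, the data frame written.
#' @export
write_airr <- function(annotated, path, ids = NULL) {
  if (inherits(annotated, "annotated_rearrangement")) annotated <- list(annotated)
  rows <- lapply(seq_along(annotated), function(i) {
    a <- annotated[[i]]
    data.frame(
      sequence_id = if (is.null(ids)) sprintf("seq%03d", i) else ids[i],
      sequence = a$sequence,
      v_call = a$v$segment_name,
      d_call = if (is.null(a$d)) "" else a$d$segment_name,
      j_call = a$j$segment_name,
      junction = if (is.null(a$cdr3)) "" else a$cdr3$junction_nt,
      junction_aa = if (is.null(a$cdr3) || is.na(a$cdr3$junction_aa)) "" else
        a$cdr3$junction_aa,
      cdr3_aa = if (is.null(a$cdr3) || is.na(a$cdr3$aa_sequence)) "" else
        a$cdr3$aa_sequence,
      v_identity = a$v$identity_pct,
      shm_status = a$shm$status,
      shm_borderline = a$shm$borderline,
      productive = a$productive,
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
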