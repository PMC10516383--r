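#' @title Seeded capture-read simulator
#'
#' @description
#' Generates the synthetic study material used to exercise the whole
#' pipeline: a germline reference bundle with realistic segment geometry,
#' recombined and somatically hypermutated V(D)J rearrangements with full
#' truth records, reference-aligned capture reads whose junction-spanning
#' members carry soft-clips (mimicking aligner output without requiring an
#' aligner), CNA-scaled per-target depth tables, and spiked point
#' mutations/indels at specified allele fractions. Identical seed and
#' configuration always produce byte-identical output.
#'
#' @name read_simulation
NULL

# run expr under a private RNG state seeded with `seed`; the caller's RNG
# stream is untouched
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# ---- synthetic germline bundle -----------------------------------------

.driver_genes <- data.frame(
  gene = c("TP53", "NOTCH1", "SF3B1", "ATM", "BIRC3", "EGR2", "FBXW7",
           "NFKBIE", "POT1", "XPO1", "KRAS", "MYD88", "CXCR4", "BTK",
           "PLCG2", "BCL2"),
  chrom = c("chr17", "chr9", "chr2", "chr11", "chr11", "chr10", "chr4",
            "chr6", "chr7", "chr2", "chr12", "chr3", "chr2", "chrX",
            "chr16", "chr18"),
  stringsAsFactors = FALSE)

# build one synthetic V allele: 96 codons of FR1..FR3, the conserved Cys
# anchor (TGT), then a germline CDR3 stub. Optionally extended to carry an
# annotated position-110 codon (lambda V genes reach position ~110).
.make_v_sequence <- function(with_aux = FALSE, aux_base_codon = "GGG") {
  body <- random_orf(96L)                       # offsets [0, 288)
  if (with_aux) {
    tail <- paste0(random_orf(5L), aux_base_codon, random_orf(1L)) # 306 aux
    list(seq = paste0(body, "TGT", tail), anchor = 288L, aux = 306L, len = 312L)
  } else {
    list(seq = paste0(body, "TGT", random_orf(3L)), anchor = 288L,
         aux = NA_integer_, len = 300L)
  }
}

.v_region_bounds <- c(0L, 78L, 102L, 153L, 177L, 288L)

#' Generate the default synthetic reference bundle
#'
#' Creates a fully synthetic germline bundle shaped like the real panel:
#' IGH V/D/J and IGL V/J alleles with IMGT-style region bounds and anchor
#' codons (V alleles ~300 nt, D 12-22 nt, J 39-48 nt), IGLV3-21 alleles
#' carrying an annotated position-110 codon (germline glycine, GGG), one
#' capture target per segment, one 420-nt target per driver gene, and
#' coverage bins for CNA calling: `n_region_bins` 120-nt bins per recurrent
#' region (del17p, del11q, del13q, tri12) plus `n_backbone_bins` neutral
#' backbone bins. All sequences are synthetic; no licensed germline database
#' content is reproduced.
#'
#' @param seed integer seed; the bundle is a pure function of it.
#' @param n_region_bins coverage bins per CNA region.
#' @param n_backbone_bins neutral backbone coverage bins.
#' @return an [ig_bundle()] with a `genome` slot covering IG and driver loci.
#' @export
simulate_reference_bundle <- function(seed = 1L, n_region_bins = 250L,
                                      n_backbone_bins = 500L) {
  with_seed(seed, {
    segments <- list()
    add_seg <- function(s) segments[[length(segments) + 1L]] <<- s

    # --- IGH on chr14 ---
    pos <- 1000L
    igh_v <- c("IGHV1-2*01", "IGHV1-69*01", "IGHV3-21*01", "IGHV3-23*01",
               "IGHV4-34*01")
    for (nm in igh_v) {
      v <- .make_v_sequence()
      add_seg(gene_segment(nm, "IGH", "V", "chr14", pos, pos + v$len, "+",
                           v$seq, .v_region_bounds, v$anchor))
      pos <- pos + v$len + 500L
    }
    igh_d <- c("IGHD2-2*01" = 16L, "IGHD3-10*01" = 22L, "IGHD6-19*01" = 12L)
    for (nm in names(igh_d)) {
      dn <- igh_d[[nm]]
      add_seg(gene_segment(nm, "IGH", "D", "chr14", pos, pos + dn, "+",
                           random_dna(dn)))
      pos <- pos + dn + 500L
    }
    for (nm in c("IGHJ4*01", "IGHJ5*01", "IGHJ6*01")) {
      jseq <- paste0(random_dna(9L), "TGG", random_orf(12L))  # 48 nt, anchor 9
      add_seg(gene_segment(nm, "IGH", "J", "chr14", pos, pos + 48L, "+",
                           jseq, anchor_codon = 9L))
      pos <- pos + 48L + 500L
    }
    chr14_len <- pos + 1000L

    # --- IGL on chr22: *04 is the base allele, *02 differs at two
    # diagnostic positions, *01 at four others ---
    pos <- 1000L
    v04 <- .make_v_sequence(with_aux = TRUE)
    subst_codon <- function(seq, codon_start) {
      old <- substr(seq, codon_start + 1L, codon_start + 3L)
      new <- sample(setdiff(.safe_codons, old), 1L)
      paste0(substr(seq, 1L, codon_start), new,
             substr(seq, codon_start + 4L, nchar(seq)))
    }
    s02 <- subst_codon(subst_codon(v04$seq, 60L), 150L)
    s01 <- Reduce(subst_codon, c(30L, 90L, 120L, 210L), accumulate = FALSE,
                  init = v04$seq)
    v214 <- .make_v_sequence(with_aux = TRUE)
    for (nm_seq in list(c("IGLV3-21*01", s01), c("IGLV3-21*02", s02),
                        c("IGLV3-21*04", v04$seq), c("IGLV2-14*01", v214$seq))) {
      add_seg(gene_segment(nm_seq[1], "IGL", "V", "chr22", pos,
                           pos + v04$len, "+", nm_seq[2], .v_region_bounds,
                           v04$anchor, aux_codon = v04$aux))
      pos <- pos + v04$len + 500L
    }
    for (nm in c("IGLJ2*01", "IGLJ3*02")) {
      jseq <- paste0(random_dna(6L), "TTC", random_orf(10L))  # 39 nt, anchor 6
      add_seg(gene_segment(nm, "IGL", "J", "chr22", pos, pos + 39L, "+",
                           jseq, anchor_codon = 6L))
      pos <- pos + 39L + 500L
    }
    chr22_len <- pos + 1000L

    # --- panel targets ---
    tg <- list()
    for (s in segments)
      tg[[length(tg) + 1L]] <- data.frame(
        chrom = s$chrom, start = max(0L, s$start - 50L), end = s$end + 50L,
        label = paste0("ig_", s$name), role = "ig", stringsAsFactors = FALSE)
    seen <- integer(0)
    for (i in seq_len(nrow(.driver_genes))) {
      ch <- .driver_genes$chrom[i]
      k <- if (ch %in% names(seen)) seen[[ch]] + 1L else 0L
      seen[ch] <- k
      dpos <- 10000L + 1000L * k
      tg[[length(tg) + 1L]] <- data.frame(
        chrom = ch, start = dpos, end = dpos + 420L,
        label = .driver_genes$gene[i], role = "driver", stringsAsFactors = FALSE)
    }
    region_chrom <- c(del17p = "chr17", del11q = "chr11", del13q = "chr13",
                      tri12 = "chr12")
    for (rn in names(region_chrom)) {
      st <- 1000000L + 500L * (seq_len(n_region_bins) - 1L)
      tg[[length(tg) + 1L]] <- data.frame(
        chrom = region_chrom[[rn]], start = st, end = st + 120L,
        label = sprintf("%s_bin_%04d", rn, seq_len(n_region_bins)),
        role = "cna_backbone", stringsAsFactors = FALSE)
    }
    bb_chroms <- c("chr1", "chr3", "chr5", "chr6", "chr8")
    per <- ceiling(n_backbone_bins / length(bb_chroms))
    bbl <- 0L
    for (ch in bb_chroms) {
      k <- min(per, n_backbone_bins - bbl)
      if (k <= 0L) break
      st <- 1000000L + 500L * (seq_len(k) - 1L)
      tg[[length(tg) + 1L]] <- data.frame(
        chrom = ch, start = st, end = st + 120L,
        label = sprintf("backbone_bin_%04d", bbl + seq_len(k)),
        role = "cna_backbone", stringsAsFactors = FALSE)
      bbl <- bbl + k
    }
    targets <- do.call(rbind, tg)
    rownames(targets) <- NULL

    # --- genome contigs: IG loci embed the germline segments; driver
    # contigs get random sequence under their targets (CNA bins are depth
    # bookkeeping only and need no sequence) ---
    genome_chrs <- list(chr14 = chr14_len, chr22 = chr22_len)
    for (ch in unique(.driver_genes$chrom)) genome_chrs[[ch]] <- 14000L
    genome <- lapply(names(genome_chrs), function(ch)
      random_dna(genome_chrs[[ch]]))
    names(genome) <- names(genome_chrs)
    for (s in segments) {
      sq <- if (s$strand == "-") revcomp(s$sequence) else s$sequence
      substr(genome[[s$chrom]], s$start + 1L, s$end) <- sq
    }
    genome <- Biostrings::DNAStringSet(unlist(genome))

    cna_regions <- derive_cna_regions(targets)
    ig_bundle(segments, targets, cna_regions, genome = genome)
  })
}

# ---- rearrangement simulation ------------------------------------------

#' Simulate one V(D)J rearrangement with somatic hypermutation
#'
#' Builds a rearranged sequence as trimmed germline V + untemplated N1 +
#' trimmed D (IGH only) + untemplated N2 + trimmed germline J, then applies
#' SHM point mutations uniformly over the V identity-evaluation span
#' (FR1 through FR3) until the germline identity equals the closest
#' achievable value at or above `shm_target_identity`. Trims never remove an
#' anchor codon (or the annotated auxiliary codon, when present).
#'
#' @param bundle an [ig_bundle()].
#' @param locus `"IGH"` or `"IGL"`.
#' @param config list overriding defaults: `v_name`, `d_name`, `j_name`
#'   (default: drawn at random), `v_trim_range`, `d_trim_range`,
#'   `j_trim_range`, `n_range` (length ranges for N1/N2),
#'   `shm_target_identity` (fraction in (0.8, 1]), `force_productive`
#'   (default `TRUE`), `force_mutations` (list of `list(offset, alt)`
#'   applied to the kept V portion after SHM, e.g. to spike R110),
#'   `max_attempts` for the productivity redraw loop.
#' @param seed integer seed.
#' @return a `sim_rearrangement` object carrying the truth sequence,
#'   mutation list, truth identity, junction geometry and productivity.
#' @export
simulate_rearrangement <- function(bundle, locus = "IGH", config = list(),
                                   seed = 1L) {
  cfg <- utils::modifyList(list(
    v_name = NULL, d_name = NULL, j_name = NULL,
    v_trim_range = c(0L, 4L), d_trim_range = c(0L, 4L),
    j_trim_range = c(0L, 4L), n_range = c(2L, 8L),
    shm_target_identity = 1.0, force_productive = TRUE,
    force_mutations = NULL, max_attempts = 50L), config)
  stopifnot(cfg$shm_target_identity > 0.8, cfg$shm_target_identity <= 1)

  vs <- segments_by_class(bundle, locus, "V")
  js <- segments_by_class(bundle, locus, "J")
  ds <- segments_by_class(bundle, locus, "D")
  if (length(vs) == 0L || length(js) == 0L)
    stop("bundle has no V or no J segments for locus ", locus)

  with_seed(seed, {
    # one attempt: draw segments (unless fixed), geometry (trims, N
    # lengths), pad N2 into frame if forcing productivity, then apply SHM
    # and untemplated bases. Re-drawing segments across attempts matters:
    # a D core can carry stop codons in every reading frame, making some
    # fixed V/D/J combinations unable to ever satisfy productivity.
    build <- function() {
      segv <- if (is.null(cfg$v_name)) vs[[sample(length(vs), 1L)]] else
        bundle$segments[[cfg$v_name]]
      segj <- if (is.null(cfg$j_name)) js[[sample(length(js), 1L)]] else
        bundle$segments[[cfg$j_name]]
      segd <- NULL
      if (length(ds) > 0L)
        segd <- if (is.null(cfg$d_name)) ds[[sample(length(ds), 1L)]] else
          bundle$segments[[cfg$d_name]]
      lv <- nchar(segv$sequence)
      keep_until <- if (!is.na(segv$aux_codon)) segv$aux_codon + 3L else
        segv$anchor_codon + 3L
      span <- fr3_end(segv)
      n_mut <- floor(span * (1 - cfg$shm_target_identity) + 1e-9)
      vt_max <- min(cfg$v_trim_range[2], lv - keep_until)
      v_trim <- draw_int(cfg$v_trim_range[1], max(cfg$v_trim_range[1], vt_max))
      jt_max <- min(cfg$j_trim_range[2], segj$anchor_codon)
      j_trim <- draw_int(cfg$j_trim_range[1], max(cfg$j_trim_range[1], jt_max))
      d_kept <- ""
      d_trim_l <- d_trim_r <- 0L
      if (!is.null(segd)) {
        ld <- nchar(segd$sequence)
        d_trim_l <- draw_int(cfg$d_trim_range[1], min(cfg$d_trim_range[2], ld %/% 3L))
        d_trim_r <- draw_int(cfg$d_trim_range[1], min(cfg$d_trim_range[2], ld %/% 3L))
        d_kept <- substr(segd$sequence, d_trim_l + 1L, ld - d_trim_r)
      }
      n1_len <- draw_int(cfg$n_range[1], cfg$n_range[2])
      n2_len <- draw_int(cfg$n_range[1], cfg$n_range[2])
      kept_v_len <- lv - v_trim
      anchor_j_in_kept <- segj$anchor_codon - j_trim
      if (cfg$force_productive) {
        jl <- n1_len + nchar(d_kept) + n2_len
        dist <- (kept_v_len - segv$anchor_codon) + jl + anchor_j_in_kept
        n2_len <- n2_len + (3L - dist %% 3L) %% 3L
      }
      kept_j <- substr(segj$sequence, j_trim + 1L, nchar(segj$sequence))
      n1 <- random_dna(n1_len)
      n2 <- random_dna(n2_len)
      vkept <- chars(substr(segv$sequence, 1L, kept_v_len))
      muts <- NULL
      if (n_mut > 0L) {
        offs <- sort(sample(seq_len(span) - 1L, n_mut))
        refs <- vkept[offs + 1L]
        alts <- vapply(refs, function(b) sample(setdiff(c("A","C","G","T"), b), 1L), "")
        vkept[offs + 1L] <- alts
        muts <- data.frame(offset = offs, ref = refs, alt = unname(alts),
                           stringsAsFactors = FALSE)
      }
      if (!is.null(cfg$force_mutations)) {
        for (fm in cfg$force_mutations) {
          o <- fm$offset
          stopifnot(o >= 0L, o < kept_v_len)
          muts <- rbind(muts, data.frame(offset = o, ref = vkept[o + 1L],
                                         alt = fm$alt, stringsAsFactors = FALSE))
          vkept[o + 1L] <- fm$alt
        }
      }
      jstart <- kept_v_len + n1_len + nchar(d_kept) + n2_len
      list(seq = paste0(paste(vkept, collapse = ""), n1, d_kept, n2, kept_j),
           n1 = n1, n2 = n2, muts = muts, v_trim = v_trim, j_trim = j_trim,
           d_trim_l = d_trim_l, d_trim_r = d_trim_r,
           kept_v_len = kept_v_len, jstart = jstart,
           qa_v = segv$anchor_codon, qa_j = jstart + anchor_j_in_kept,
           frame = segv$anchor_codon %% 3L, span = span, n_mut = n_mut,
           segv = segv, segj = segj, segd = segd)
    }

    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      b <- build()
      aa <- translate_dna(substr(b$seq, b$frame + 1L, nchar(b$seq)))
      in_frame <- (b$qa_j - b$qa_v) %% 3L == 0L
      anchors_ok <- translate_dna(substr(b$seq, b$qa_v + 1L, b$qa_v + 3L)) == "C" &&
        translate_dna(substr(b$seq, b$qa_j + 1L, b$qa_j + 3L)) %in% c("W", "F")
      productive <- in_frame && anchors_ok && !grepl("*", aa, fixed = TRUE)
      if (!cfg$force_productive || productive) break
      if (attempt >= cfg$max_attempts)
        stop("could not satisfy productivity after ", attempt, " attempts")
    }

    structure(list(
      locus = locus, v_name = b$segv$name,
      d_name = if (is.null(b$segd)) NA_character_ else b$segd$name,
      j_name = b$segj$name,
      v_trim = b$v_trim, d_trim_left = b$d_trim_l, d_trim_right = b$d_trim_r,
      j_trim = b$j_trim, n1 = b$n1, n2 = b$n2,
      shm_target_identity = cfg$shm_target_identity,
      truth_sequence = b$seq, truth_mutations = b$muts,
      truth_v_identity = round_half_up(100 * (b$span - b$n_mut) / b$span, 2),
      productive_truth = productive,
      kept_v_len = b$kept_v_len, junction_start = b$kept_v_len,
      j_start = b$jstart,
      anchor_v_pos = b$qa_v, anchor_j_pos = b$qa_j,
      truth_junction_aa = if (productive)
        translate_dna(substr(b$seq, b$qa_v + 1L, b$qa_j + 3L)) else
          NA_character_,
      seed = seed), class = "sim_rearrangement")
  })
}

# ---- read generation ----------------------------------------------------

empty_records <- function() {
  data.frame(qname = character(), flag = integer(), rname = character(),
             pos0 = integer(), mapq = integer(), cigar = character(),
             rnext = character(), pnext = integer(), tlen = integer(),
             seq = character(), qual = character(), stringsAsFactors = FALSE)
}

apply_seq_errors <- function(bases, error_rate) {
  if (error_rate <= 0) return(bases)
  hit <- which(stats::runif(length(bases)) < error_rate)
  if (length(hit))
    bases[hit] <- vapply(bases[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  bases
}

#' Simulate aligned capture reads over a rearranged IG locus
#'
#' Emits paired 2x`read_len` reads as reference-aligned records: portions
#' falling inside the kept germline V or J are aligned (CIGAR M, carrying
#' any SHM bases as mismatches); portions crossing the junction are
#' soft-clipped at the breakpoint with the clipped bases taken from the
#' rearranged side, reproducing what a read aligner does at a V(D)J
#' junction. Reads falling entirely inside the junction are dropped
#' (unmappable). Base qualities are constant Q30.
#'
#' @param truth a `sim_rearrangement` from [simulate_rearrangement()].
#' @param bundle the bundle the truth was generated from.
#' @param config list overriding defaults `read_len = 300`,
#'   `frag_mean = 500`, `frag_sd = 60`, `error_rate = 0`, `depth = 100`,
#'   `min_portion = 30`, `min_anchor = 15`, `prefix = "sim"`.
#' @param seed integer seed.
#' @return a `sim_read_set`: list with `records` (alignment data frame,
#'   0-based positions), `truth`, `seed`, `config`.
#' @export
simulate_reads <- function(truth, bundle, config = list(), seed = 1L) {
  cfg <- utils::modifyList(list(read_len = 300L, frag_mean = 500L,
                                frag_sd = 60L, error_rate = 0, depth = 100,
                                min_portion = 30L, min_anchor = 15L,
                                prefix = "sim"), config)
  if (cfg$depth <= 0) stop("depth must be > 0")
  if (cfg$read_len > cfg$frag_mean)
    stop("read_len (", cfg$read_len, ") exceeds mean fragment length (",
         cfg$frag_mean, ")")
  segv <- bundle$segments[[truth$v_name]]
  segj <- bundle$segments[[truth$j_name]]
  span <- nchar(truth$truth_sequence)
  keptV <- truth$kept_v_len
  jstart <- truth$j_start
  tbases <- chars(truth$truth_sequence)

  with_seed(seed, {
    nfrag <- max(1L, ceiling(cfg$depth * (span + cfg$frag_mean - 1) /
                               (2 * cfg$read_len)))
    fl <- pmax(cfg$read_len,
               as.integer(round(stats::rnorm(nfrag, cfg$frag_mean, cfg$frag_sd))))
    fs <- as.integer(floor(stats::runif(nfrag, -fl + 1, span)))
    nmax <- 2L * nfrag
    frag_i <- mate_i <- pos0 <- pnext <- flag <- integer(nmax)
    rname <- cigar <- seqv <- rnm <- character(nmax)
    k <- 0L
    for (i in seq_len(nfrag)) {
      mates <- list(c(fs[i], fs[i] + cfg$read_len),
                    c(fs[i] + fl[i] - cfg$read_len, fs[i] + fl[i]))
      got <- c(NA_integer_, NA_integer_)
      for (m in 1:2) {
        s <- max(0L, mates[[m]][1]); e <- min(span, mates[[m]][2])
        if (e - s < cfg$min_portion) next
        bases <- apply_seq_errors(tbases[(s + 1L):e], cfg$error_rate)
        v_aln <- max(0L, min(e, keptV) - s)
        j_aln <- max(0L, e - max(s, jstart))
        if (max(v_aln, j_aln) < cfg$min_anchor) next
        k <- k + 1L
        got[m] <- k
        if (v_aln >= j_aln) {
          rname[k] <- segv$chrom
          pos0[k] <- segv$start + s
          cigar[k] <- make_cigar(c("M", "S"), c(v_aln, e - min(e, keptV)))
        } else {
          jo <- truth$j_trim + (max(s, jstart) - jstart)
          rname[k] <- segj$chrom
          pos0[k] <- segj$start + jo
          cigar[k] <- make_cigar(c("S", "M"), c(max(s, jstart) - s, j_aln))
        }
        seqv[k] <- paste(bases, collapse = "")
        frag_i[k] <- i
        mate_i[k] <- m
      }
      paired <- !anyNA(got)
      for (m in 1:2) {
        kk <- got[m]
        if (is.na(kk)) next
        flag[kk] <- if (!paired) 0L else if (m == 1L) 99L else 147L
        if (paired) {
          om <- got[if (m == 1L) 2L else 1L]
          rnm[kk] <- if (rname[om] == rname[kk]) "=" else rname[om]
          pnext[kk] <- pos0[om]
        } else {
          rnm[kk] <- "*"
          pnext[kk] <- 0L
        }
      }
    }
    idx <- seq_len(k)
    records <- if (k > 0L) data.frame(
      qname = sprintf("%s_f%06d", cfg$prefix, frag_i[idx]), flag = flag[idx],
      rname = rname[idx], pos0 = pos0[idx], mapq = 60L, cigar = cigar[idx],
      rnext = rnm[idx], pnext = pnext[idx], tlen = 0L, seq = seqv[idx],
      qual = strrep("?", nchar(seqv[idx])), stringsAsFactors = FALSE)
    else empty_records()
    structure(list(records = records, truth = truth, seed = seed,
                   config = cfg, spikes = list()),
              class = "sim_read_set")
  })
}

#' Simulate fully aligned reads over panel targets
#'
#' Uniform read placement over each named target (reads may extend slightly
#' past the target edges into flanking contig sequence). Used to exercise
#' coverage computation and the pileup variant caller.
#'
#' @param bundle an [ig_bundle()] with a `genome` slot.
#' @param labels character vector of target labels to cover.
#' @param depth requested mean depth over each target.
#' @param config list overriding `read_len = 300`, `error_rate = 0`,
#'   `prefix = "cov"`.
#' @param seed integer seed.
#' @return a `sim_read_set` (truth is the requested depth per target).
#' @export
simulate_target_reads <- function(bundle, labels, depth, config = list(),
                                  seed = 1L) {
  cfg <- utils::modifyList(list(read_len = 300L, error_rate = 0,
                                prefix = "cov"), config)
  if (depth <= 0) stop("depth must be > 0")
  if (is.null(bundle$genome)) stop("bundle has no genome sequences")
  tg <- bundle$targets[bundle$targets$label %in% labels, , drop = FALSE]
  if (nrow(tg) == 0L) stop("no matching targets: ", paste(labels, collapse = ", "))
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(tg))) {
      ch <- tg$chrom[i]
      if (!ch %in% names(bundle$genome))
        stop("no genome sequence for contig ", ch)
      clen <- Biostrings::width(bundle$genome[ch])
      rl <- min(cfg$read_len, clen)
      w0 <- max(0L, tg$start[i] - rl + 50L)
      w1 <- min(clen - rl, tg$end[i] - 50L)
      if (w1 < w0) { w0 <- max(0L, tg$start[i]); w1 <- max(w0, min(clen - rl, tg$end[i] - rl)) }
      n <- max(1L, ceiling(depth * (w1 - w0 + 1) / rl))
      st <- as.integer(floor(stats::runif(n, w0, w1 + 1)))
      seqs <- substring(as.character(bundle$genome[[ch]]), st + 1L, st + rl)
      if (cfg$error_rate > 0)
        seqs <- vapply(seqs, function(s)
          paste(apply_seq_errors(chars(s), cfg$error_rate), collapse = ""), "",
          USE.NAMES = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        qname = sprintf("%s_%s_%06d", cfg$prefix, tg$label[i], seq_len(n)),
        flag = 0L, rname = ch, pos0 = st, mapq = 60L,
        cigar = sprintf("%dM", rl), rnext = "*", pnext = 0L, tlen = 0L,
        seq = seqs, qual = strrep("?", rl), stringsAsFactors = FALSE)
    }
    structure(list(records = do.call(rbind, rows), truth = list(depth = depth,
                   labels = labels), seed = seed, config = cfg,
                   spikes = list()), class = "sim_read_set")
  })
}

#' Combine simulated read sets into one
#'
#' @param ... `sim_read_set` objects.
#' @return a `sim_read_set` whose records are the row-bound inputs.
#' @export
combine_read_sets <- function(...) {
  sets <- list(...)
  structure(list(records = do.call(rbind, lapply(sets, `[[`, "records")),
                 truth = lapply(sets, `[[`, "truth"),
                 seed = vapply(sets, function(s) as.integer(s$seed[1]), 0L),
                 config = lapply(sets, `[[`, "config"),
                 spikes = do.call(c, lapply(sets, `[[`, "spikes"))),
            class = "sim_read_set")
}

# ---- CNA profile simulation --------------------------------------------

#' Simulate a CNA-scaled per-target depth table
#'
#' Expected depth multiplier is `1 - f/2` for deletions and `1 + f/2` for
#' trisomy 12, where `f` is the clonal fraction of the lesion; all other
#' targets stay at multiplier 1. Multiplicative noise is mean-one lognormal
#' with coefficient of variation `noise_cv`.
#'
#' @param bundle an [ig_bundle()].
#' @param lesions named list/vector mapping region names (`del17p`,
#'   `del11q`, `del13q`, `tri12`) to clonal fractions in `[0, 1]`.
#' @param base_depth neutral-state mean depth (default 1500, the panel's
#'   working coverage).
#' @param noise_cv per-target multiplicative noise CV (0 = deterministic).
#' @param seed integer seed.
#' @return data.frame with columns `label`, `chrom`, `start`, `end`, `depth`.
#' @export
simulate_cna_profile <- function(bundle, lesions = list(), base_depth = 1500,
                                 noise_cv = 0.1, seed = 1L) {
  tg <- bundle$targets
  mult <- rep(1, nrow(tg))
  for (rn in names(lesions)) {
    if (!rn %in% names(bundle$cna_regions))
      stop("unknown CNA region '", rn, "'")
    f <- lesions[[rn]]
    stopifnot(f >= 0, f <= 1)
    idx <- tg$label %in% bundle$cna_regions[[rn]]
    mult[idx] <- if (rn == "tri12") 1 + f / 2 else 1 - f / 2
  }
  with_seed(seed, {
    noise <- if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      stats::rlnorm(nrow(tg), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, nrow(tg))
    data.frame(label = tg$label, chrom = tg$chrom, start = tg$start,
               end = tg$end, depth = base_depth * mult * noise,
               stringsAsFactors = FALSE)
  })
}

# ---- variant spiking ----------------------------------------------------

# aligned read offset of reference position `pos` for a pure-M record, or NA
.pure_m_offset <- function(rec, pos) {
  if (!grepl("^[0-9]+M$", rec$cigar)) return(NA_integer_)
  off <- pos - rec$pos0
  if (off < 0L || off >= nchar(rec$seq)) return(NA_integer_)
  off
}

#' Spike a variant into overlapping reads at a given allele fraction
#'
#' Each read whose aligned span fully contains the edited bases
#' independently carries the alternate allele with probability `vaf`.
#' SNVs substitute one base; insertions (`alt = "+SEQ"`) insert SEQ after
#' `pos` and split the CIGAR M block with an I op; deletions
#' (`alt = "-SEQ"`) remove the bases following `pos` and insert a D op.
#' Only fully aligned (pure M) records are edited.
#'
#' @param read_set a `sim_read_set`.
#' @param chrom contig name.
#' @param pos 0-based reference position of the ref base.
#' @param ref reference base at `pos` (validated against the read consensus).
#' @param alt alternate allele: a single base, `"+SEQ"` or `"-SEQ"`.
#' @param vaf target allele fraction in (0, 1].
#' @param seed integer seed.
#' @return the read set with edited records; the realized alternate count is
#'   appended to `$spikes`.
#' @export
spike_variant <- function(read_set, chrom, pos, ref, alt, vaf, seed = 1L) {
  stopifnot(inherits(read_set, "sim_read_set"), vaf > 0, vaf <= 1)
  rec <- read_set$records
  is_ins <- startsWith(alt, "+")
  is_del <- startsWith(alt, "-")
  indel_seq <- if (is_ins || is_del) substr(alt, 2L, nchar(alt)) else ""
  need_span <- if (is_del) nchar(indel_seq) + 1L else 1L

  cand <- which(rec$rname == chrom &
                  rec$pos0 <= pos &
                  rec$pos0 + cigar_ref_len(rec$cigar) >= pos + need_span &
                  grepl("^[0-9]+M$", rec$cigar))
  if (length(cand) == 0L) stop("position ", chrom, ":", pos, " not covered")
  obs <- vapply(cand, function(i)
    substr(rec$seq[i], pos - rec$pos0[i] + 1L, pos - rec$pos0[i] + 1L), "")
  consensus <- names(sort(table(obs), decreasing = TRUE))[1]
  if (consensus != ref)
    stop("reference mismatch at ", chrom, ":", pos, ": expected ", ref,
         " but reads show ", consensus)

  with_seed(seed, {
    take <- cand[stats::runif(length(cand)) < vaf]
    for (i in take) {
      off <- pos - rec$pos0[i]          # 0-based offset of ref base in read
      s <- rec$seq[i]; n <- nchar(s)
      if (is_ins) {
        rec$seq[i] <- paste0(substr(s, 1L, off + 1L), indel_seq,
                             substr(s, off + 2L, n))
        rec$cigar[i] <- make_cigar(c("M", "I", "M"),
                                   c(off + 1L, nchar(indel_seq), n - off - 1L))
        rec$qual[i] <- strrep("?", nchar(rec$seq[i]))
      } else if (is_del) {
        dl <- nchar(indel_seq)
        rec$seq[i] <- paste0(substr(s, 1L, off + 1L), substr(s, off + 2L + dl, n))
        rec$cigar[i] <- make_cigar(c("M", "D", "M"),
                                   c(off + 1L, dl, n - off - 1L - dl))
        rec$qual[i] <- strrep("?", nchar(rec$seq[i]))
      } else {
        substr(rec$seq[i], off + 1L, off + 1L) <- alt
      }
    }
    read_set$records <- rec
    read_set$spikes[[length(read_set$spikes) + 1L]] <- list(
      chrom = chrom, pos = pos, ref = ref, alt = alt, vaf = vaf,
      realized_alt = length(take), overlapping = length(cand))
    read_set
  })
}

# ---- SAM text I/O -------------------------------------------------------

#' Write alignment records as SAM text
#'
#' Produces standard SAM readable by samtools. Internal 0-based positions
#' are converted to SAM's 1-based convention here and only here.
#'
#' @param x a `sim_read_set` or a records data frame.
#' @param path output path.
#' @param bundle bundle used for the `@SQ` header lines.
#' @return invisibly, `path`.
#' @export
write_sam <- function(x, path, bundle) {
  rec <- if (inherits(x, "sim_read_set")) x$records else x
  contigs <- unique(c(names(bundle$genome), bundle$targets$chrom))
  lens <- vapply(contigs, function(ch) {
    gl <- if (!is.null(bundle$genome) && ch %in% names(bundle$genome))
      Biostrings::width(bundle$genome[ch]) else 0L
    tl <- bundle$targets$end[bundle$targets$chrom == ch]
    max(c(gl, tl, 1L)) + 1000L
  }, 0L)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", contigs, lens))
  pnext1 <- ifelse(rec$rnext == "*", 0L, rec$pnext + 1L)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  rec$qname, rec$flag, rec$rname, rec$pos0 + 1L, rec$mapq,
                  rec$cigar, rec$rnext, pnext1, rec$tlen, rec$seq,
                  rec$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read SAM text into an alignment records data frame
#'
#' Minimal reader for the simulator's exchange format (and any standard SAM
#' with mapped reads). Positions are converted to the package's internal
#' 0-based convention.
#'
#' @param path SAM file path.
#' @return records data frame (`qname`, `flag`, `rname`, `pos0`, `mapq`,
#'   `cigar`, `rnext`, `pnext`, `tlen`, `seq`, `qual`).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) return(empty_records())
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    qname = vapply(f, `[`, "", 1L),
    flag = as.integer(vapply(f, `[`, "", 2L)),
    rname = vapply(f, `[`, "", 3L),
    pos0 = as.integer(vapply(f, `[`, "", 4L)) - 1L,
    mapq = as.integer(vapply(f, `[`, "", 5L)),
    cigar = vapply(f, `[`, "", 6L),
    rnext = vapply(f, `[`, "", 7L),
    pnext = as.integer(vapply(f, `[`, "", 8L)) - 1L,
    tlen = as.integer(vapply(f, `[`, "", 9L)),
    seq = vapply(f, `[`, "", 10L),
    qual = vapply(f, `[`, "", 11L),
    stringsAsFactors = FALSE)
}

#' Write / read per-target depth tables
#'
#' @param depths data.frame as returned by [simulate_cna_profile()] or
#'   [compute_depths()].
#' @param path TSV path.
#' @return `write_depth_tsv`: invisibly, `path`; `read_depth_tsv`: the table.
#' @export
write_depth_tsv <- function(depths, path) {
  utils::write.table(depths, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_tsv
#' @export
read_depth_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
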