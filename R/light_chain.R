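#' @title IGLV3-21 light-chain analysis and R110 status
#'
#' @description
#' A point mutation creating an arginine at IMGT position 110 of the
#' lambda IGLV3-21 V-J junction (IGLV3-21 R110) enables autonomous B-cell
#' receptor signaling and is prognostically adverse in CLL. This module
#' reuses the reconstruction machinery over IGL targets, determines the
#' IGLV3-21 allele (*01/*02/*04 in the bundled synthetic set), and reads
#' out the position-110 codon from the assembled sequence. The position-110
#' codon is carried as an annotated offset on the germline allele (validated
#' at load time) rather than computed by full IMGT numbering.
#'
#' @name light_chain
NULL

#' Call the IGLV allele of an assembled light-chain sequence
#'
#' Best-identity assignment among all IGL V alleles; IGLV3-21 alleles
#' compete with the rest of the locus as rejectors. When the best hit is
#' not an IGLV3-21 allele, R110 analysis is skipped.
#'
#' @param sequence assembled IGL candidate nucleotides.
#' @param bundle an [ig_bundle()].
#' @param config see [default_annotation_config()].
#' @return the winning `gene_assignment`.
#' @export
call_iglv_allele <- function(sequence, bundle, config = list()) {
  assign_v_gene(sequence, bundle, locus = "IGL", config = config)
}

#' Determine R110 status from an assembled IGLV3-21 rearrangement
#'
#' Maps the annotated position-110 codon of the assigned allele through the
#' alignment, translates it in the V reading frame, and reports arginine
#' status. A codon falling in an alignment gap, truncated from the
#' assembly, or supported by fewer than `min_support` reads is reported as
#' indeterminate — never as a negative call.
#'
#' @param sequence assembled nucleotides.
#' @param v_assign `gene_assignment` for an IGLV3-21 allele.
#' @param bundle an [ig_bundle()].
#' @param per_base_support optional per-base read support vector of
#'   `sequence` (from the assembler).
#' @param min_support minimum reads across the codon for a call
#'   (default 10).
#' @return list with `iglv_allele`, `status`
#'   (`"positive"`/`"negative"`/`"indeterminate"`/`"not_IGLV3-21"`),
#'   `position110_codon`, `position110_aa`, `r110`, `supporting_reads`.
#' @export
detect_r110 <- function(sequence, v_assign, bundle, per_base_support = NULL,
                        min_support = 10L) {
  allele <- v_assign$segment_name
  if (!startsWith(strip_allele(allele), "IGLV3-21"))
    return(list(iglv_allele = allele, status = "not_IGLV3-21",
                position110_codon = NA_character_,
                position110_aa = NA_character_, r110 = NA,
                supporting_reads = NA_integer_))
  seg <- bundle$segments[[allele]]
  if (is.na(seg$aux_codon))
    stop("allele ", allele, " carries no annotated position-110 codon")
  q <- vapply(seg$aux_codon + 0:2, function(o) map_to_query(v_assign, o), 0L)
  indeterminate <- list(iglv_allele = allele, status = "indeterminate",
                        position110_codon = NA_character_,
                        position110_aa = NA_character_, r110 = NA,
                        supporting_reads = 0L)
  if (anyNA(q) || any(diff(q) != 1L) || q[3] + 1L > nchar(sequence))
    return(indeterminate)
  support <- NA_integer_
  if (!is.null(per_base_support)) {
    support <- min(per_base_support[q + 1L])
    if (support < min_support) return(indeterminate)
  }
  codon <- substr(sequence, q[1] + 1L, q[3] + 1L)
  aa <- translate_dna(codon)
  list(iglv_allele = allele,
       status = if (identical(aa, "R")) "positive" else "negative",
       position110_codon = codon, position110_aa = aa,
       r110 = identical(aa, "R"),
       supporting_reads = support)
}

#' Light-chain analysis over aligned reads
#'
#' Reconstructs IGL rearrangements, takes the top-ranked candidate, calls
#' the IGLV allele and — when it is IGLV3-21 — the R110 status from the
#' assembly.
#'
#' @param alignments records data frame.
#' @param bundle an [ig_bundle()].
#' @param config reconstruction/annotation parameters.
#' @param min_support R110 read-support gate (default 10).
#' @return list with `status` (adds `"no_rearrangement"`), `iglv_allele`,
#'   `identity_pct`, `r110` fields, and the `candidate`.
#' @export
analyze_light_chain <- function(alignments, bundle, config = list(),
                                min_support = 10L) {
  rec <- reconstruct_ig(alignments, bundle, locus = "IGL", config = config)
  if (length(rec$candidates) == 0L)
    return(list(status = "no_rearrangement", iglv_allele = NA_character_,
                identity_pct = NA_real_, position110_codon = NA_character_,
                position110_aa = NA_character_, r110 = NA,
                supporting_reads = NA_integer_, candidate = NULL))
  cand <- rec$candidates[[1]]
  v <- call_iglv_allele(cand$sequence, bundle, config)
  res <- detect_r110(cand$sequence, v, bundle,
                     per_base_support = cand$per_base_support,
                     min_support = min_support)
  c(res[c("status", "iglv_allele", "position110_codon", "position110_aa",
          "r110", "supporting_reads")],
    list(identity_pct = v$identity_pct, candidate = cand))
}
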