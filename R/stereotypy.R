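#' @title Stereotyped subset assignment
#'
#' @description
#' Recurrent, quasi-identical B-cell receptor configurations ("stereotyped
#' subsets", e.g. subset #2) are shared across CLL patients and carry
#' prognostic weight. Assignment here is resource-driven: a definitions
#' table supplies, per subset, the allowed V genes (allele-agnostic), the
#' exact CDR3 amino-acid length, a position-indexed motif with wildcards
#' and per-position allowed residue sets, and a mismatch budget. Matching
#' is positionwise over the CDR3 — a deliberate, reproducible
#' simplification relative to profile-based assigners — and the resource
#' file records a version string that is echoed into reports.
#'
#' @name stereotypy
NULL

# motif syntax: one token per CDR3 position; `X` or `.` = wildcard,
# `[ABC]` = allowed set, a plain letter = that residue
parse_motif <- function(motif) {
  tokens <- list()
  i <- 1L
  n <- nchar(motif)
  while (i <= n) {
    ch <- substr(motif, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(motif, i, n), fixed = TRUE)
      if (j < 0L) stop("unterminated [ ] set in motif: ", motif)
      tokens[[length(tokens) + 1L]] <- chars(substr(motif, i + 1L, i + j - 2L))
      i <- i + j
    } else {
      # a NULL token is a wildcard; assign via list() so the slot is kept
      tokens[length(tokens) + 1L] <- if (ch %in% c("X", ".")) list(NULL) else
        list(ch)
      i <- i + 1L
    }
  }
  tokens
}

#' Load stereotyped subset definitions
#'
#' Reads a TSV with columns `subset_id`, `v_genes` (comma-separated gene
#' names, allele-agnostic), `cdr3_length_aa`, `motif`, `max_mismatches`.
#' A leading `# version:` comment line is captured and echoed into reports.
#' Definition invariants (motif length equals CDR3 length, mismatch budget
#' below CDR3 length) are enforced at load time.
#'
#' @param path definitions TSV.
#' @return list with `definitions` (list of parsed definitions) and
#'   `version`.
#' @export
read_subset_definitions <- function(path) {
  lines <- readLines(path)
  version <- "unversioned"
  vline <- grep("^#\\s*version:", lines, value = TRUE)
  if (length(vline))
    version <- trimws(sub("^#\\s*version:", "", vline[1]))
  lines <- lines[!startsWith(lines, "#")]
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE)
  need <- c("subset_id", "v_genes", "cdr3_length_aa", "motif", "max_mismatches")
  if (!all(need %in% names(df)))
    stop("subset definitions need columns: ", paste(need, collapse = ", "))
  defs <- lapply(seq_len(nrow(df)), function(i) {
    tokens <- parse_motif(df$motif[i])
    len <- as.integer(df$cdr3_length_aa[i])
    mm <- as.integer(df$max_mismatches[i])
    if (length(tokens) != len)
      stop("subset ", df$subset_id[i], ": motif length ", length(tokens),
           " != cdr3_length_aa ", len)
    if (mm >= len)
      stop("subset ", df$subset_id[i], ": max_mismatches must be < CDR3 length")
    list(subset_id = df$subset_id[i],
         allowed_v_genes = trimws(strsplit(df$v_genes[i], ",")[[1]]),
         cdr3_length_aa = len, motif = tokens, max_mismatches = mm)
  })
  list(definitions = defs, version = version)
}

# gene name without the allele suffix: "IGHV3-21*01" -> "IGHV3-21"
strip_allele <- function(name) sub("\\*.*$", "", name)

#' Assign a rearrangement to a stereotyped subset
#'
#' Gates first on exact CDR3 amino-acid length and V-gene membership, then
#' counts positionwise motif mismatches; the best subset is the one with
#' fewest mismatches within its budget (ties resolved by lexicographic
#' subset id). Non-productive rearrangements or missing CDR3s are
#' unassigned.
#'
#' @param annotated an `annotated_rearrangement`.
#' @param definitions result of [read_subset_definitions()].
#' @return list with `subset_id` (`"unassigned"` when no subset fits),
#'   `mismatches`, `definition`.
#' @export
assign_subset <- function(annotated, definitions) {
  unassigned <- list(subset_id = "unassigned", mismatches = NA_integer_,
                     definition = NULL)
  if (!isTRUE(annotated$productive) || is.null(annotated$cdr3) ||
      is.na(annotated$cdr3$aa_sequence))
    return(unassigned)
  cdr3 <- chars(annotated$cdr3$aa_sequence)
  vgene <- strip_allele(annotated$v$segment_name)
  best <- NULL
  for (def in definitions$definitions) {
    if (length(cdr3) != def$cdr3_length_aa) next
    if (!vgene %in% def$allowed_v_genes) next
    mm <- 0L
    for (p in seq_along(def$motif)) {
      tok <- def$motif[[p]]
      if (is.null(tok)) next
      if (!cdr3[p] %in% tok) mm <- mm + 1L
    }
    if (mm > def$max_mismatches) next
    if (is.null(best) || mm < best$mismatches ||
        (mm == best$mismatches && def$subset_id < best$subset_id))
      best <- list(subset_id = def$subset_id, mismatches = mm,
                   definition = def)
  }
  if (is.null(best)) unassigned else best
}
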