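# Independent oracles: these never call the code paths they check.

# Global Needleman-Wunsch with linear gap penalties, row-vectorized.
# The per-gap cost of 7 equals the affine cost of a length-1 gap under the
# annotation scoring (open 6 + extend 1), so both engines prefer the same
# alignment class on substitution-dominated pairs.
# Returns the per-column alignment as vectors of 0-based offsets (NA = gap).
nw_align <- function(a, b, match = 1, mismatch = -2, gap = -7) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1L, m + 1L)
  H[1L, ] <- gap * (0:m)
  H[, 1L] <- gap * (0:n)
  for (i in seq_len(n)) {
    s <- ifelse(av[i] == bv, match, mismatch)
    diag_up <- pmax(H[i, 1:m] + s, H[i, 2:(m + 1L)] + gap)
    # resolve the within-row (left) dependency with a cummax trick:
    # H[i+1, j] = max_k<=j ( t[k] - (j - k) * |gap| )
    cand <- c(H[i + 1L, 1L], diag_up) - gap * (0:m)
    H[i + 1L, ] <- cummax(cand) + gap * (0:m)
  }
  # traceback
  ai <- integer(0); bi <- integer(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        H[i + 1L, j + 1L] ==
          H[i, j] + (if (av[i] == bv[j]) match else mismatch)) {
      ai <- c(i - 1L, ai); bi <- c(j - 1L, bi); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && H[i + 1L, j + 1L] == H[i, j + 1L] + gap) {
      ai <- c(i - 1L, ai); bi <- c(NA_integer_, bi); i <- i - 1L
    } else {
      ai <- c(NA_integer_, ai); bi <- c(j - 1L, bi); j <- j - 1L
    }
  }
  list(a_off = ai, b_off = bi, a = av, b = bv)
}

# identity (%) over germline columns with offset < span_end, per the
# matches / (matches + mismatches + gap columns) convention
nw_identity_oracle <- function(germline, mutated, span_end) {
  al <- nw_align(germline, mutated)
  # attribute each column a germline offset; gap-in-germline columns take
  # the offset of the next consumed germline position
  att <- al$a_off
  for (k in rev(seq_along(att)))
    if (is.na(att[k])) att[k] <- if (k == length(att)) Inf else att[k + 1L]
  inc <- att < span_end
  a <- al$a_off[inc]; b <- al$b_off[inc]
  ok <- !is.na(a) & !is.na(b)
  matches <- sum(al$a[a[ok] + 1L] == al$b[b[ok] + 1L])
  round_half_up(100 * matches / sum(inc), 2)
}

# brute-force single-linkage clustering of breakpoints within a window
brute_cluster <- function(breakpoints, window) {
  n <- length(breakpoints)
  if (n == 0L) return(integer(0))
  adj <- abs(outer(breakpoints, breakpoints, "-")) <= window
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && grp[j] != grp[i]) {
        grp[grp == grp[j]] <- grp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(grp, unique(grp))
}

# independent translation (seqinr)
oracle_translate <- function(nt) {
  paste(seqinr::translate(strsplit(tolower(nt), "")[[1]]), collapse = "")
}

# exact binomial central interval bounds
binom_interval <- function(n, p, conf = 0.99) {
  a <- (1 - conf) / 2
  c(stats::qbinom(a, n, p), stats::qbinom(1 - a, n, p))
}
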