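# Profile-HMM construction: match-column assignment, sequence weighting,
# parameter estimation, consensus, single-sequence profiles, and the
# local-alignment search configuration.

TRANS_NAMES <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")

# Prior-shaped transition pseudocount pattern (total mass 1 per source state).
# A symmetric Laplace prior on transitions would put ~1/6 of the mass on gap
# opening at desk-scale row counts; profile search expects indels to be rare,
# so the pseudocount mass follows the usual strong match-match prior.
TRANS_PRIOR <- c(MM = 0.90, MI = 0.05, MD = 0.05,
                 IM = 0.80, II = 0.20,
                 DM = 0.80, DD = 0.20)

#' Assign match columns of an alignment
#'
#' A column becomes a match (consensus) column when the fraction of non-gap
#' symbols is at least `gap_threshold`; ties resolve to match. Remaining
#' columns are treated as insertions.
#'
#' @param aln An [msa] object.
#' @param gap_threshold Minimum non-gap fraction, in (0, 1].
#' @return Logical vector of length `aln$n_columns`.
#' @export
assign_match_columns <- function(aln, gap_threshold = 0.5) {
  stopifnot(inherits(aln, "msa"), gap_threshold > 0, gap_threshold <= 1)
  m <- msa_matrix(aln)
  frac <- colMeans(m != "-")
  mask <- frac >= gap_threshold
  if (!any(mask)) {
    stop("no consensus columns: every column fails the gap threshold",
         call. = FALSE)
  }
  mask
}

#' Henikoff position-based sequence weights
#'
#' Each residue cell contributes `1 / (r * s)` to its row, where `r` is the
#' number of distinct residue types in the column and `s` the count of that
#' residue; gap cells contribute nothing. Row totals are normalized to sum to
#' the number of rows.
#'
#' @param aln An [msa] object.
#' @return Numeric vector of per-row weights, all positive, summing to
#'   `nrow`.
#' @export
sequence_weights <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  m <- msa_matrix(aln)
  n <- nrow(m)
  if (n == 1L) return(1.0)
  w <- numeric(n)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    res <- col != "-"
    if (!any(res)) next
    tab <- table(col[res])
    r <- length(tab)
    contrib <- 1 / (r * as.numeric(tab[col[res]]))
    w[res] <- w[res] + contrib
  }
  if (any(w == 0)) w[w == 0] <- min(w[w > 0]) * 1e-3  # all-gap rows, degenerate
  w * n / sum(w)
}

# Fractional residue counts for one cell over A,C,G,T; degenerate codes are
# spread uniformly across their compatible nucleotides.
residue_counts <- function(ch) {
  set <- IUPAC_SETS[[ch]]
  cnt <- c(A = 0, C = 0, G = 0, T = 0)
  cnt[set] <- 1 / length(set)
  cnt
}

#' Build a profile HMM from a weighted alignment
#'
#' Match emissions are weighted observed counts plus a Laplace
#' `pseudocount` per nucleotide, normalized. Insert emissions are fixed to
#' the background distribution. Transitions are weighted counts of the
#' observed per-row state paths plus a match-favoring pseudocount of total
#' mass `pseudocount` per source state. Degenerate residues count
#' fractionally across their compatible nucleotides.
#'
#' @param aln An [msa] object.
#' @param mask Match-column mask from [assign_match_columns()]; defaults to
#'   calling it with its default threshold.
#' @param weights Row weights from [sequence_weights()]; defaults likewise.
#' @param pseudocount Positive pseudocount (default 1, Laplace).
#' @param null1 Background nucleotide frequencies (default uniform).
#' @param name Model name.
#' @return An object of class `profile_hmm`.
#' @export
build_profile <- function(aln, mask = NULL, weights = NULL, pseudocount = 1,
                          null1 = rep(0.25, 4), name = "profile") {
  stopifnot(inherits(aln, "msa"), pseudocount > 0)
  if (is.null(mask)) mask <- assign_match_columns(aln)
  if (is.null(weights)) weights <- sequence_weights(aln)
  if (length(mask) != aln$n_columns) {
    stop("mask length does not match alignment columns", call. = FALSE)
  }
  null1 <- null1 / sum(null1)
  m <- msa_matrix(aln)
  n_rows <- nrow(m)
  M <- sum(mask)
  node_of <- cumsum(mask)  # column -> match node index (0 before first)

  match_counts <- matrix(0, M, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  trans_counts <- matrix(0, M, 7, dimnames = list(NULL, TRANS_NAMES))

  for (r in seq_len(n_rows)) {
    w <- weights[r]
    row <- m[r, ]
    state <- "B"; node <- 0L  # begin
    for (j in seq_len(aln$n_columns)) {
      ch <- row[j]
      if (mask[j]) {
        k <- node_of[j]
        new_state <- if (ch == "-") "D" else "M"
        if (ch != "-") match_counts[k, ] <- match_counts[k, ] +
            w * residue_counts(ch)
        if (node >= 1L) {
          tn <- paste0(state, new_state)
          if (tn %in% TRANS_NAMES) {
            trans_counts[node, tn] <- trans_counts[node, tn] + w
          }
        }
        state <- new_state; node <- k
      } else if (ch != "-") {
        # insert residue after node `node` (inserts before node 1 fold into
        # the local entry and are not modeled)
        if (node >= 1L && node < M) {
          tn <- paste0(state, "I")
          if (tn %in% TRANS_NAMES) {
            trans_counts[node, tn] <- trans_counts[node, tn] + w
          }
          state <- "I"
        }
      }
    }
  }

  match_emit <- (match_counts + pseudocount)
  match_emit <- match_emit / rowSums(match_emit)
  insert_emit <- matrix(null1, M, 4, byrow = TRUE,
                        dimnames = list(NULL, c("A", "C", "G", "T")))

  transitions <- matrix(0, M, 7, dimnames = list(NULL, TRANS_NAMES))
  for (grp in list(c("MM", "MI", "MD"), c("IM", "II"), c("DM", "DD"))) {
    cnt <- trans_counts[, grp, drop = FALSE] +
      matrix(TRANS_PRIOR[grp] * pseudocount, M, length(grp), byrow = TRUE)
    transitions[, grp] <- cnt / rowSums(cnt)
  }
  # node M: no onward core states; by convention all mass to the (implicit)
  # exit and none to I_M
  transitions[M, ] <- c(1, 0, 0, 1, 0, 1, 0)

  consensus <- consensus_from_msa(aln, mask, weights)$residues

  structure(
    list(name = name, M = M, match_emit = match_emit,
         insert_emit = insert_emit, transitions = transitions,
         null1 = stats::setNames(null1, c("A", "C", "G", "T")),
         consensus = consensus),
    class = "profile_hmm"
  )
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile_hmm '%s': %d match states\nconsensus: %s%s\n",
              x$name, x$M, substr(x$consensus, 1, 60),
              if (x$M > 60) "..." else ""))
  invisible(x)
}

#' Majority-rule consensus sequence of an alignment
#'
#' One residue per match column: the (weighted) plurality nucleotide, ties
#' broken alphabetically. Degenerate codes contribute fractional counts.
#'
#' @inheritParams build_profile
#' @return A [seq_record] of length equal to the number of match columns.
#' @export
consensus_from_msa <- function(aln, mask = NULL, weights = NULL) {
  stopifnot(inherits(aln, "msa"))
  if (is.null(mask)) mask <- assign_match_columns(aln)
  if (is.null(weights)) weights <- sequence_weights(aln)
  m <- msa_matrix(aln)
  out <- character(sum(mask))
  k <- 0L
  for (j in which(mask)) {
    k <- k + 1L
    cnt <- c(A = 0, C = 0, G = 0, T = 0)
    for (r in seq_len(nrow(m))) {
      if (m[r, j] != "-") cnt <- cnt + weights[r] * residue_counts(m[r, j])
    }
    # which.max takes the first maximum; names are alphabetical already
    out[k] <- if (all(cnt == 0)) "A" else names(cnt)[which.max(cnt)]
  }
  seq_record(paste0(attr(aln, "name") %||% "consensus"),
             paste(out, collapse = ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Profile HMM from a single query sequence
#'
#' Each position emits its own residue with probability `match_prob`, the
#' other three nucleotides sharing the remainder; transitions are
#' position-independent. A degenerate query residue splits `match_prob`
#' across its compatible nucleotides.
#'
#' @param seq A [seq_record] (gap-free).
#' @param match_prob Probability of the query residue at its own position.
#' @param gap_open Probability of opening an insertion or deletion.
#' @param gap_extend Probability of extending one.
#' @param null1 Background frequencies.
#' @return A `profile_hmm`.
#' @export
profile_from_single_sequence <- function(seq, match_prob = 0.85,
                                         gap_open = 0.02, gap_extend = 0.4,
                                         null1 = rep(0.25, 4)) {
  stopifnot(inherits(seq, "seq_record"), nchar(seq$residues) >= 1,
            match_prob > 0, match_prob < 1,
            gap_open > 0, 2 * gap_open < 1, gap_extend > 0, gap_extend < 1)
  null1 <- null1 / sum(null1)
  chars <- strsplit(seq$residues, "")[[1]]
  M <- length(chars)
  match_emit <- matrix(0, M, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  cons <- character(M)
  for (k in seq_len(M)) {
    set <- IUPAC_SETS[[chars[k]]]
    e <- c(A = 0, C = 0, G = 0, T = 0)
    rest <- setdiff(c("A", "C", "G", "T"), set)
    if (length(rest)) {
      e[set] <- match_prob / length(set)
      e[rest] <- (1 - match_prob) / length(rest)
    } else {
      e[set] <- 1 / length(set)   # fully degenerate position (N)
    }
    match_emit[k, ] <- e
    cons[k] <- names(e)[which.max(e)]
  }
  transitions <- matrix(rep(c(1 - 2 * gap_open, gap_open, gap_open,
                              1 - gap_extend, gap_extend,
                              1 - gap_extend, gap_extend), each = M),
                        M, 7, dimnames = list(NULL, TRANS_NAMES))
  transitions[M, ] <- c(1, 0, 0, 1, 0, 1, 0)
  structure(
    list(name = seq$id, M = M, match_emit = match_emit,
         insert_emit = matrix(null1, M, 4, byrow = TRUE,
                              dimnames = list(NULL, c("A", "C", "G", "T"))),
         transitions = transitions,
         null1 = stats::setNames(null1, c("A", "C", "G", "T")),
         consensus = paste(cons, collapse = "")),
    class = "profile_hmm"
  )
}

# Log-odds emission table over the full 15-code IUPAC alphabet (natural log).
# A degenerate target residue scores as the background-weighted average over
# its compatible nucleotides: log( sum_e(a) / sum_f(a) ).
lod_table_nat <- function(match_emit, null1) {
  M <- nrow(match_emit)
  out <- matrix(0, M, 15, dimnames = list(NULL, IUPAC_CODES))
  for (ci in seq_along(IUPAC_CODES)) {
    set <- IUPAC_SETS[[IUPAC_CODES[ci]]]
    num <- rowSums(match_emit[, set, drop = FALSE])
    den <- sum(null1[set])
    out[, ci] <- log(num / den)
  }
  out
}

#' Configure a profile for local search
#'
#' Produces the log-odds-configured, unihit local form of a profile: uniform
#' fragment entry over match states (`entry_k` proportional to `M - k + 1`),
#' exit allowed from every match state, and precomputed log-odds tables over
#' the full degenerate target alphabet. Multiple hits on one target arise
#' from multiple windows, not from a multi-hit model.
#'
#' @param hmm A `profile_hmm`.
#' @param calibration Optional calibration parameter list (see
#'   [calibrate()]).
#' @return An object of class `search_profile`.
#' @export
configure_local <- function(hmm, calibration = NULL) {
  stopifnot(inherits(hmm, "profile_hmm"))
  M <- hmm$M
  entry <- 2 * (M - seq_len(M) + 1) / (M * (M + 1))
  lodn <- lod_table_nat(hmm$match_emit, hmm$null1)
  comp <- t(vapply(IUPAC_SETS, function(set) {
    as.integer(c("A", "C", "G", "T") %in% set)
  }, integer(4)))
  structure(
    list(hmm = hmm, mode = "local-unihit",
         entry = entry, exit = rep(1, M),
         match_lod = lodn / log(2),     # bits, M x 15
         lodn = lodn,                   # natural log, for Viterbi
         ol = exp(lodn),                # linear odds, for Forward/Backward
         tr = hmm$transitions,          # linear
         ltr = log(hmm$transitions),    # natural log (-Inf where 0)
         lentry = log(entry),
         comp = comp,                   # 15 x 4 IUPAC membership
         calibration = calibration,
         max_dp_length = 32768L),
    class = "search_profile"
  )
}

#' @export
print.search_profile <- function(x, ...) {
  cat(sprintf("search_profile '%s': M = %d, mode = %s, %s\n",
              x$hmm$name, x$hmm$M, x$mode,
              if (is.null(x$calibration)) "uncalibrated" else "calibrated"))
  invisible(x)
}
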