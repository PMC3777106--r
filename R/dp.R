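# R-level interface to the DP kernels, plus the exhaustive path-enumeration
# oracle used to validate them on small instances.

check_dp_input <- function(sp, seq) {
  stopifnot(inherits(sp, "search_profile"))
  res <- if (inherits(seq, "seq_record")) seq$residues else sanitize_dna(seq)
  if (nchar(res) > sp$max_dp_length) {
    stop(sprintf(paste0("target length %d exceeds the dynamic-programming ",
                        "window cap (%d); use search() which windows long ",
                        "targets"), nchar(res), sp$max_dp_length),
         call. = FALSE)
  }
  res
}

#' Single-segment ungapped Viterbi (SSV) scan
#'
#' For every diagonal offset between model and target, finds the
#' maximal-scoring single contiguous segment of match log-odds cells (no
#' gaps, no restarts; transition terms are not scored). Segments scoring at
#' least `min_score` bits are returned.
#'
#' @param sp A [configure_local()] search profile.
#' @param seq A [seq_record] or DNA string.
#' @param min_score Reporting threshold in bits.
#' @return A data frame with columns `target_start`, `target_end` (0-based
#'   half-open), `model_start` (1-based node), `score` (bits); attribute
#'   `best` holds the best segment score over all diagonals.
#' @export
ssv_scan <- function(sp, seq, min_score) {
  res <- if (inherits(seq, "seq_record")) seq$residues else sanitize_dna(seq)
  x <- encode_dna(res)
  out <- cpp_ssv(sp$match_lod, x, min_score)
  df <- data.frame(target_start = out$target_start,
                   target_end = out$target_end,
                   model_start = out$model_start,
                   score = out$score)
  attr(df, "best") <- out$best
  df
}

#' Viterbi alignment score and path
#'
#' Log-odds (bits) of the single best begin-to-end path under the unihit
#' local configuration, with the path recovered by traceback.
#'
#' @inheritParams ssv_scan
#' @return List with `score` (bits), `path` (character vector of states,
#'   e.g. `c("B","M1","M2","E")`), and 0-based half-open `ali_start`/
#'   `ali_end` target coordinates plus `hmm_start`/`hmm_end` model nodes
#'   (all `NA` when the best path skips the model entirely).
#' @export
viterbi <- function(sp, seq) {
  res <- check_dp_input(sp, seq)
  x <- encode_dna(res)
  out <- cpp_viterbi(sp$lodn, sp$ltr, sp$lentry, x, TRUE)
  ops <- strsplit(out$ops, "")[[1]]
  if (length(ops) == 0L) {
    path <- c("B", "E")
    ali <- list(ali_start = NA_integer_, ali_end = NA_integer_,
                hmm_start = NA_integer_, hmm_end = NA_integer_)
  } else {
    k <- out$k_start
    labs <- character(length(ops))
    for (j in seq_along(ops)) {
      labs[j] <- paste0(ops[j], k)
      if (j < length(ops) && ops[j + 1] != "I") k <- k + 1L
    }
    path <- c("B", labs, "E")
    ali <- list(ali_start = out$i_start - 1L, ali_end = out$i_end,
                hmm_start = out$k_start, hmm_end = out$k_end)
  }
  c(list(score = out$score, path = path, ops = out$ops), ali)
}

# score-only Viterbi (filter stage)
viterbi_score <- function(sp, x_codes) {
  cpp_viterbi(sp$lodn, sp$ltr, sp$lentry, x_codes, FALSE)$score
}

#' Forward score
#'
#' Log2 odds of the sequence under the profile (all alignments summed,
#' including the no-alignment path) versus the iid background.
#'
#' @inheritParams ssv_scan
#' @return Score in bits.
#' @export
forward <- function(sp, seq) {
  res <- check_dp_input(sp, seq)
  cpp_forward_score(sp$ol, sp$tr, sp$entry, encode_dna(res))
}

#' Backward score
#'
#' Same quantity as [forward()], computed by the reverse recursion; the two
#' agree to numerical tolerance.
#'
#' @inheritParams ssv_scan
#' @return Score in bits.
#' @export
backward <- function(sp, seq) {
  res <- check_dp_input(sp, seq)
  cpp_backward_mat(sp$ol, sp$tr, sp$entry, encode_dna(res))$score
}

#' Forward dynamic-programming matrix
#' @inheritParams ssv_scan
#' @return A `dp_matrix` list of row-scaled state matrices (for
#'   [posterior_decode()]); element `score` is the Forward score in bits.
#' @export
forward_matrix <- function(sp, seq) {
  res <- check_dp_input(sp, seq)
  out <- cpp_forward_mat(sp$ol, sp$tr, sp$entry, encode_dna(res))
  structure(out, class = "dp_matrix", kind = "forward")
}

#' Backward dynamic-programming matrix
#' @inheritParams ssv_scan
#' @return A `dp_matrix`; element `score` is the Backward score in bits.
#' @export
backward_matrix <- function(sp, seq) {
  res <- check_dp_input(sp, seq)
  out <- cpp_backward_mat(sp$ol, sp$tr, sp$entry, encode_dna(res))
  structure(out, class = "dp_matrix", kind = "backward")
}

#' Posterior decoding
#'
#' Per-target-position posterior probability that each emitting state (match
#' and insert states plus the N/C flanks) emitted that residue, given the
#' whole sequence. Each row sums to 1. The aligned-state mass (sum over
#' match and insert columns) is attached as attribute `aligned`.
#'
#' @param sp Search profile used for both matrices.
#' @param seq The sequence both matrices were computed for.
#' @param fwd Result of [forward_matrix()].
#' @param bwd Result of [backward_matrix()].
#' @return Matrix with L rows and columns `M1..MM, I1..IM, N, C`.
#' @export
posterior_decode <- function(sp, seq, fwd, bwd) {
  stopifnot(inherits(fwd, "dp_matrix"), inherits(bwd, "dp_matrix"))
  if (fwd$L != bwd$L || ncol(fwd$M) != ncol(bwd$M)) {
    stop("forward and backward matrices do not match", call. = FALSE)
  }
  M <- ncol(fwd$M)
  post <- cpp_posterior(fwd, bwd, fwd$score)
  colnames(post) <- c(paste0("M", seq_len(M)), paste0("I", seq_len(M)),
                      "N", "C")
  attr(post, "aligned") <- rowSums(post[, seq_len(2 * M), drop = FALSE])
  post
}

#' Exhaustive path enumeration (test oracle)
#'
#' Explicitly enumerates every legal state path of the unihit local model for
#' a small profile/sequence pair and returns exact sums and maxima. Only
#' intended as an independent check of the DP kernels; guarded to `M <= 6`
#' and `L <= 8`.
#'
#' @inheritParams ssv_scan
#' @return List with `total` (log2 of summed path odds, the Forward
#'   quantity), `best` (log2 of the best path odds, the Viterbi quantity),
#'   `best_path` (state labels), `n_paths`, and `posterior` (L x 2M+2 matrix
#'   in the [posterior_decode()] layout).
#' @export
enumerate_paths <- function(sp, seq) {
  res <- if (inherits(seq, "seq_record")) seq$residues else sanitize_dna(seq)
  x <- encode_dna(res)
  M <- sp$hmm$M; L <- length(x)
  if (M > 6 || L > 8) {
    stop("enumerate_paths is an oracle for tiny instances (M <= 6, L <= 8)",
         call. = FALSE)
  }
  eta <- if (L > 0) L / (L + 2) else 0
  l1 <- 1 - eta
  ol <- sp$ol; tr <- sp$tr; entry <- sp$entry
  env <- new.env()
  env$total <- 0; env$best <- -Inf; env$best_path <- NULL; env$n <- 0L
  env$post <- matrix(0, nrow = max(L, 1L), ncol = 2 * M + 2)

  finish <- function(w, path, emits) {
    env$total <- env$total + w
    env$n <- env$n + 1L
    if (w > env$best) { env$best <- w; env$best_path <- path }
    if (L > 0) {
      for (i in seq_len(L)) {
        env$post[i, emits[i]] <- env$post[i, emits[i]] + w
      }
    }
  }
  # emission column ids: M_k = k, I_k = M + k, N = 2M+1, C = 2M+2
  rec <- function(state, k, i, w, path, emits) {
    if (state == "N") {
      if (i < L) {
        e2 <- emits; e2[i + 1] <- 2L * M + 1L
        rec("N", 0L, i + 1L, w * eta, c(path, "N"), e2)
      }
      rec("B", 0L, i, w * l1, c(path, "B"), emits)
    } else if (state == "B") {
      rec("E", 0L, i, w, c(path, "E"), emits)  # no-alignment path
      if (i < L) {
        for (kk in seq_len(M)) {
          e2 <- emits; e2[i + 1] <- kk
          rec("M", kk, i + 1L, w * entry[kk] * ol[kk, x[i + 1]],
              c(path, paste0("M", kk)), e2)
        }
      }
    } else if (state == "M") {
      rec("E", 0L, i, w, c(path, "E"), emits)  # local exit
      if (k < M && i < L) {
        e2 <- emits; e2[i + 1] <- k + 1L
        rec("M", k + 1L, i + 1L, w * tr[k, "MM"] * ol[k + 1L, x[i + 1]],
            c(path, paste0("M", k + 1L)), e2)
      }
      if (k < M && i < L) {
        e2 <- emits; e2[i + 1] <- M + k
        rec("I", k, i + 1L, w * tr[k, "MI"], c(path, paste0("I", k)), e2)
      }
      if (k < M) {
        rec("D", k + 1L, i, w * tr[k, "MD"], c(path, paste0("D", k + 1L)),
            emits)
      }
    } else if (state == "I") {
      if (i < L) {
        e2 <- emits; e2[i + 1] <- k + 1L
        rec("M", k + 1L, i + 1L, w * tr[k, "IM"] * ol[k + 1L, x[i + 1]],
            c(path, paste0("M", k + 1L)), e2)
        e2 <- emits; e2[i + 1] <- M + k
        rec("I", k, i + 1L, w * tr[k, "II"], c(path, paste0("I", k)), e2)
      }
    } else if (state == "D") {
      if (k < M && i < L) {
        e2 <- emits; e2[i + 1] <- k + 1L
        rec("M", k + 1L, i + 1L, w * tr[k, "DM"] * ol[k + 1L, x[i + 1]],
            c(path, paste0("M", k + 1L)), e2)
      }
      if (k < M) {
        rec("D", k + 1L, i, w * tr[k, "DD"], c(path, paste0("D", k + 1L)),
            emits)
      }
    } else if (state == "E") {
      # E -> C; C loops emitting, then C -> T at i == L
      ci <- i
      wc <- w
      ce <- emits
      repeat {
        if (ci == L) {
          finish(wc * l1, path, ce)
          break
        }
        ce[ci + 1] <- 2L * M + 2L
        wc <- wc * eta
        ci <- ci + 1L
      }
    }
  }
  rec("N", 0L, 0L, 1, "N", integer(max(L, 1L)))
  post <- env$post / env$total
  colnames(post) <- c(paste0("M", seq_len(M)), paste0("I", seq_len(M)),
                      "N", "C")
  list(total = unname(log2(env$total)), best = unname(log2(env$best)),
       best_path = env$best_path, n_paths = env$n,
       posterior = if (L > 0) post else post[0, , drop = FALSE])
}
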