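# Score-distribution calibration by simulation, and score -> P-value ->
# E-value conversion.
#
# SSV and window-Viterbi maxima over a null target follow a Gumbel law
# (extreme-value statistics of optimal alignment scores); the Forward score,
# a sum over alignments, has an exponential right tail with lambda fixed at
# 1 per bit. Calibration simulates null targets of length calib_L, runs the
# same seeding/windowing machinery the search pipeline uses, and fits these
# laws; P-values are per calib_L scanned residues and E-values rescale
# linearly to the searched database size.

#' Sample i.i.d. null targets
#'
#' @param null1 Background nucleotide frequencies (A, C, G, T).
#' @param n Number of targets.
#' @param L Length of each.
#' @param seed RNG seed (deterministic output).
#' @return List of [seq_record]s named `null1..nulln`.
#' @export
sample_null_targets <- function(null1, n, L, seed = 42L) {
  stopifnot(n >= 1, L >= 1)
  null1 <- null1 / sum(null1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  lapply(seq_len(n), function(i) {
    seq_record(sprintf("null%d", i),
               paste(sample(bases, L, replace = TRUE, prob = null1),
                     collapse = ""))
  })
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Maximum-likelihood Gumbel fit
#'
#' Fits location/scale of the extreme-value law
#' `P(S >= x) = 1 - exp(-exp(-lambda (x - mu)))`.
#'
#' @param scores Numeric score sample (bits).
#' @return List with `mu` and `lambda`.
#' @export
fit_gumbel <- function(scores) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 2 || stats::sd(scores) == 0) {
    stop("degenerate score sample: cannot fit a Gumbel", call. = FALSE)
  }
  x <- scores
  xbar <- mean(x)
  # profile likelihood in lambda: 1/lambda - xbar + A(lambda) = 0
  A <- function(lam) {
    z <- -lam * (x - min(x))
    w <- exp(z - max(z))
    sum(x * w) / sum(w)
  }
  h <- function(lam) 1 / lam - xbar + A(lam)
  lam0 <- pi / (stats::sd(x) * sqrt(6))
  lo <- lam0 / 200; hi <- lam0 * 200
  # widen until bracketed (h decreasing: +inf at 0+, negative at infinity)
  while (h(hi) > 0) hi <- hi * 10
  lambda <- stats::uniroot(h, c(lo, hi), tol = 1e-10)$root
  z <- -lambda * x
  mu <- -(max(z) + log(mean(exp(z - max(z))))) / lambda
  list(mu = mu, lambda = lambda)
}

#' Exponential-tail fit for Forward scores
#'
#' `tau` is the `1 - tailmass` empirical quantile; the tail is modeled as
#' `P(S >= x) = tailmass * 2^-(x - tau)` for `x >= tau` (lambda fixed at one
#' per bit).
#'
#' @param scores Numeric score sample (bits).
#' @param tailmass Fraction of the distribution modeled as tail.
#' @return List with `tau`, `lambda` (always 1) and `tailmass`.
#' @export
fit_exp_tail <- function(scores, tailmass = 0.04) {
  scores <- scores[is.finite(scores)]
  stopifnot(tailmass > 0, tailmass < 1)
  if (length(scores) < 2 || stats::sd(scores) == 0) {
    stop("degenerate score sample: cannot fit an exponential tail",
         call. = FALSE)
  }
  tau <- stats::quantile(scores, 1 - tailmass, names = FALSE)
  list(tau = tau, lambda = 1, tailmass = tailmass)
}

# Forward-stage P-value: exponential law above tau, empirical calibration
# body below it (linear interpolation on the stored quantile grid), so that
# null P-values are uniform over the whole (0, 1) range, not only the tail.
fwd_pvalue <- function(x, params) {
  tail_p <- params$fwd_tailmass * 2^(-(x - params$fwd_tau))
  if (is.null(params$fwd_qx)) return(pmin(1, tail_p))  # tail-only fallback
  body_p <- 1 - stats::approx(params$fwd_qx, params$fwd_qp, xout = x,
                              rule = 2, ties = max)$y
  # the grid's last point is tau itself, so the two pieces join at tailmass
  pmin(1, ifelse(x >= params$fwd_tau, tail_p, body_p))
}

# Gumbel helpers
gumbel_pvalue <- function(x, mu, lambda) {
  -expm1(-exp(-lambda * (x - mu)))
}
gumbel_quantile <- function(p, mu, lambda) {
  # x such that P(S >= x) = p
  mu - log(-log1p(-p)) / lambda
}

#' Calibrate a search profile by null simulation
#'
#' Simulates `n` null targets of length `L`, records for each the best SSV
#' diagonal-segment score, then (seeding windows exactly as the search
#' pipeline does, with a permissive seed floor) the best window Viterbi and
#' window Forward scores. Gumbel laws are fitted to the SSV and Viterbi
#' maxima and an exponential tail to the Forward scores.
#'
#' @param sp A search profile.
#' @param null1 Background frequencies used for the simulation.
#' @param n Number of null targets (warning recorded when below 100).
#' @param L Length of each null target.
#' @param seed RNG seed.
#' @param tailmass Forward tail mass.
#' @param pad_factor Window padding (in model lengths), as in the pipeline.
#' @return A `calibration_params` list; attach it with
#'   `sp$calibration <- calibrate(...)` or build profiles through
#'   [build_search_profile()].
#' @export
calibrate <- function(sp, null1 = sp$hmm$null1, n = 200L, L = 10000L,
                      seed = 42L, tailmass = 0.04, pad_factor = 2) {
  stopifnot(inherits(sp, "search_profile"))
  targets <- sample_null_targets(null1, n, L, seed)
  M <- sp$hmm$M
  codes <- lapply(targets, function(t) encode_dna(t$residues))

  ssv_best <- vapply(codes, function(x)
    cpp_ssv(sp$match_lod, x, Inf)$best, 0.0)
  g_ssv <- fit_gumbel(ssv_best)
  floor0 <- gumbel_quantile(0.999, g_ssv$mu, g_ssv$lambda)

  vit_best <- rep(NA_real_, n)
  fwd_best <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    x <- codes[[i]]
    seeds <- cpp_ssv(sp$match_lod, x, floor0)
    if (length(seeds$target_start) == 0L) next
    win <- merge_windows(data.frame(start = seeds$target_start,
                                    end = seeds$target_end),
                         M, L, pad_factor)
    vs <- -Inf; fs <- -Inf
    for (w in seq_len(nrow(win))) {
      xw <- x[(win$start[w] + 1):win$end[w]]
      vs <- max(vs, cpp_viterbi(sp$lodn, sp$ltr, sp$lentry, xw, FALSE)$score)
      # bias-corrected Forward, the same quantity the pipeline reports
      ws <- cpp_window_stats(sp$ol, sp$tr, sp$entry, sp$hmm$match_emit,
                             sp$hmm$null1, sp$comp, xw, FALSE)
      fs <- max(fs, ws$score - ws$bias)
    }
    vit_best[i] <- vs; fwd_best[i] <- fs
  }
  keep <- is.finite(vit_best)
  g_vit <- fit_gumbel(vit_best[keep])
  t_fwd <- fit_exp_tail(fwd_best[keep], tailmass)
  # empirical body of the Forward null: quantile grid below tau, so that
  # P-values are honest over the whole score range (the exponential law only
  # models the top tailmass of the distribution)
  qp <- c(0, seq(0.02, 1 - tailmass, by = 0.02))
  qx <- stats::quantile(fwd_best[keep], qp, names = FALSE)

  params <- list(ssv_mu = g_ssv$mu, ssv_lambda = g_ssv$lambda,
                 vit_mu = g_vit$mu, vit_lambda = g_vit$lambda,
                 fwd_tau = t_fwd$tau, fwd_lambda = 1,
                 fwd_tailmass = tailmass,
                 fwd_qp = qp, fwd_qx = qx,
                 calib_L = as.integer(L), calib_N = as.integer(n),
                 seed = as.integer(seed),
                 n_uncensored = sum(keep))
  if (n < 100) {
    params$warning <- sprintf("calibration used only %d null targets", n)
  }
  class(params) <- "calibration_params"
  params
}

#' @export
print.calibration_params <- function(x, ...) {
  cat(sprintf(paste0("calibration: SSV Gumbel(mu=%.2f, lambda=%.3f), ",
                     "Viterbi Gumbel(mu=%.2f, lambda=%.3f),\n  Forward tail",
                     " (tau=%.2f, tailmass=%.3g); n=%d targets of %d nt, ",
                     "seed %d\n"),
              x$ssv_mu, x$ssv_lambda, x$vit_mu, x$vit_lambda,
              x$fwd_tau, x$fwd_tailmass, x$calib_N, x$calib_L, x$seed))
  if (!is.null(x$warning)) cat("warning:", x$warning, "\n")
  invisible(x)
}

#' Convert a score to a P-value and E-value
#'
#' The P-value comes from the stage's fitted null law (per `calib_L` scanned
#' residues); the E-value rescales linearly to the total number of residues
#' searched (both strands).
#'
#' @param score Score(s) in bits.
#' @param stage One of `"ssv"`, `"vit"`, `"fwd"`.
#' @param params A `calibration_params` object.
#' @param searched_residues Total nucleotides scanned.
#' @return List with vectors `pvalue` and `evalue`.
#' @export
score_to_evalue <- function(score, stage, params, searched_residues) {
  stopifnot(inherits(params, "calibration_params"))
  p <- switch(stage,
    ssv = gumbel_pvalue(score, params$ssv_mu, params$ssv_lambda),
    vit = gumbel_pvalue(score, params$vit_mu, params$vit_lambda),
    fwd = fwd_pvalue(score, params),
    stop("unknown stage tag '", stage, "'", call. = FALSE)
  )
  list(pvalue = p, evalue = p * searched_residues / params$calib_L)
}

#' Forward-stage scores of a target, without filtering
#'
#' Seeds and windows a target exactly as [calibrate()] does (permissive seed
#' floor, same padding and merging), scores every window at the Forward
#' stage with the composition-bias correction, and returns the
#' per-window scores with P- and E-values. This is the E-value
#' self-consistency diagnostic: on null targets of length `calib_L`, the
#' per-target best-window P-values are uniform and the expected number of
#' windows with E below a cutoff equals the cutoff (per search).
#'
#' @param sp Calibrated search profile.
#' @param targets A [seq_record] or list of them.
#' @param both_strands Scan the reverse complement too (default `TRUE`).
#' @param pad_factor Window padding, as in the pipeline.
#' @return Data frame with one row per window: `target_id`, `strand`,
#'   `start`, `end`, `raw_score`, `bias`, `score`, `pvalue`, `evalue`.
#' @export
forward_stage_hits <- function(sp, targets, both_strands = TRUE,
                               pad_factor = 2) {
  if (inherits(targets, "seq_record")) targets <- list(targets)
  cal <- sp$calibration
  if (is.null(cal)) stop("profile is not calibrated", call. = FALSE)
  M <- sp$hmm$M
  floor0 <- gumbel_quantile(0.999, cal$ssv_mu, cal$ssv_lambda)
  strands <- if (both_strands) c("+", "-") else "+"
  searched <- (if (both_strands) 2 else 1) *
    sum(vapply(targets, function(t) nchar(t$residues), 0L))
  rows <- list()
  for (tg in targets) {
    for (strand in strands) {
      res <- if (strand == "+") tg$residues else revcomp(tg$residues)
      x <- encode_dna(res)
      seeds <- cpp_ssv(sp$match_lod, x, floor0)
      if (!length(seeds$target_start)) next
      win <- merge_windows(data.frame(start = seeds$target_start,
                                      end = seeds$target_end),
                           M, length(x), pad_factor)
      for (w in seq_len(nrow(win))) {
        a <- win$start[w]; b <- win$end[w]
        xw <- x[(a + 1):b]
        ws <- cpp_window_stats(sp$ol, sp$tr, sp$entry, sp$hmm$match_emit,
                               sp$hmm$null1, sp$comp, xw, FALSE)
        sc <- ws$score - ws$bias
        pe <- score_to_evalue(sc, "fwd", cal, searched)
        rows[[length(rows) + 1L]] <- data.frame(
          target_id = tg$id, strand = strand, start = a, end = b,
          raw_score = ws$score, bias = ws$bias, score = sc,
          pvalue = pe$pvalue, evalue = pe$evalue,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(target_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      raw_score = numeric(0), bias = numeric(0),
                      score = numeric(0), pvalue = numeric(0),
                      evalue = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Build and calibrate a search profile in one step
#'
#' Convenience constructor: [configure_local()] followed by [calibrate()].
#'
#' @param hmm A `profile_hmm`.
#' @param n,L,seed,tailmass Calibration settings (see [calibrate()]).
#' @return A calibrated `search_profile`.
#' @export
build_search_profile <- function(hmm, n = 200L, L = 10000L, seed = 42L,
                                 tailmass = 0.04) {
  sp <- configure_local(hmm)
  sp$calibration <- calibrate(sp, n = n, L = L, seed = seed,
                              tailmass = tailmass)
  sp
}
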