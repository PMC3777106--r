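# Plain-text profile file format (loosely modeled on the tool family's ASCII
# profile layout): header lines, one probability line per node, optional
# calibration block, END terminator.
#
#   PROFSCAN 1.0
#   NAME  <name>
#   LENG  <M>
#   ALPH  DNA
#   NULL  <4 background frequencies>
#   CONS  <consensus string>
#   CALIB <ssv_mu ssv_lambda vit_mu vit_lambda fwd_tau fwd_tailmass
#          calib_L calib_N seed>            (only when calibrated)
#   NODE  <k>  <4 match emissions> <4 insert emissions> <7 transitions>
#   END

#' Write a profile HMM (and its calibration, if any) to a text file
#'
#' @param hmm A `profile_hmm`, or a `search_profile` whose underlying model
#'   and calibration should be serialized.
#' @param path Output path.
#' @export
write_profile <- function(hmm, path) {
  calibration <- NULL
  if (inherits(hmm, "search_profile")) {
    calibration <- hmm$calibration
    hmm <- hmm$hmm
  }
  stopifnot(inherits(hmm, "profile_hmm"))
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) paste(sprintf("%.8e", x), collapse = " ")
  writeLines(c("PROFSCAN 1.0",
               paste("NAME", hmm$name),
               paste("LENG", hmm$M),
               "ALPH DNA",
               paste("NULL", num(hmm$null1)),
               paste("CONS", hmm$consensus)), con)
  if (!is.null(calibration)) {
    cl <- calibration
    writeLines(paste("CALIB", num(c(cl$ssv_mu, cl$ssv_lambda, cl$vit_mu,
                                    cl$vit_lambda, cl$fwd_tau,
                                    cl$fwd_tailmass)),
                     cl$calib_L, cl$calib_N, cl$seed), con)
    if (!is.null(cl$fwd_qx)) {
      writeLines(paste("CALIBQP", num(cl$fwd_qp)), con)
      writeLines(paste("CALIBQX", num(cl$fwd_qx)), con)
    }
  }
  for (k in seq_len(hmm$M)) {
    writeLines(paste("NODE", k, num(hmm$match_emit[k, ]),
                     num(hmm$insert_emit[k, ]), num(hmm$transitions[k, ])),
               con)
  }
  writeLines("END", con)
  invisible(NULL)
}

#' Read a profile HMM text file
#'
#' Reproduces all parameters written by [write_profile()] to within 1e-5.
#'
#' @param path Input path.
#' @param configure If `TRUE` (default) return a ready
#'   [configure_local()] `search_profile` (with the stored calibration, if
#'   present); otherwise return the bare `profile_hmm`.
#' @return A `search_profile` or `profile_hmm`.
#' @export
read_profile <- function(path, configure = TRUE) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^PROFSCAN", lines[1])) {
    stop("not a profile file (missing PROFSCAN header): ", path,
         call. = FALSE)
  }
  field <- function(tag) {
    ln <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
    if (!length(ln)) stop("profile file missing ", tag, " line",
                          call. = FALSE)
    sub(paste0("^", tag, "\\s+"), "", ln[1])
  }
  name <- field("NAME")
  M <- as.integer(field("LENG"))
  alph <- field("ALPH")
  if (!identical(alph, "DNA")) {
    stop("alphabet mismatch: expected DNA, found ", alph, call. = FALSE)
  }
  null1 <- as.numeric(strsplit(field("NULL"), "\\s+")[[1]])
  cons <- field("CONS")
  match_emit <- matrix(NA_real_, M, 4,
                       dimnames = list(NULL, c("A", "C", "G", "T")))
  insert_emit <- match_emit
  transitions <- matrix(NA_real_, M, 7, dimnames = list(NULL, TRANS_NAMES))
  node_lines <- grep("^NODE\\s", lines, value = TRUE)
  for (ln in node_lines) {
    v <- strsplit(sub("^NODE\\s+", "", ln), "\\s+")[[1]]
    k <- as.integer(v[1])
    if (is.na(k) || k < 1 || k > M || length(v) != 16L) {
      stop("profile parse error at node ", v[1], call. = FALSE)
    }
    vals <- as.numeric(v[-1])
    match_emit[k, ] <- vals[1:4]
    insert_emit[k, ] <- vals[5:8]
    transitions[k, ] <- vals[9:15]
  }
  bad <- which(!stats::complete.cases(match_emit))
  if (length(bad)) {
    stop("truncated profile file: node ", bad[1], " missing", call. = FALSE)
  }
  if (!any(grepl("^END", lines))) {
    stop("truncated profile file: END marker missing", call. = FALSE)
  }
  hmm <- structure(
    list(name = name, M = M, match_emit = match_emit,
         insert_emit = insert_emit, transitions = transitions,
         null1 = stats::setNames(null1, c("A", "C", "G", "T")),
         consensus = cons),
    class = "profile_hmm")
  calibration <- NULL
  cl <- grep("^CALIB\\s", lines, value = TRUE)
  if (length(cl)) {
    v <- as.numeric(strsplit(sub("^CALIB\\s+", "", cl[1]), "\\s+")[[1]])
    numline <- function(tag) {
      ln <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
      if (!length(ln)) return(NULL)
      as.numeric(strsplit(sub(paste0("^", tag, "\\s+"), "", ln[1]),
                          "\\s+")[[1]])
    }
    calibration <- structure(
      list(ssv_mu = v[1], ssv_lambda = v[2], vit_mu = v[3],
           vit_lambda = v[4], fwd_tau = v[5], fwd_lambda = 1,
           fwd_tailmass = v[6], fwd_qp = numline("CALIBQP"),
           fwd_qx = numline("CALIBQX"), calib_L = as.integer(v[7]),
           calib_N = as.integer(v[8]), seed = as.integer(v[9])),
      class = "calibration_params")
  }
  if (!configure) return(hmm)
  configure_local(hmm, calibration = calibration)
}
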