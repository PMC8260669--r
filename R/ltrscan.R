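# Structural detection of intact LTR retrotransposon candidates: exact
# k-mer seed pairs at plausible separations, ungapped X-drop extension into
# a direct-repeat candidate, boundary refinement on insertion hallmarks
# (target site duplication, TG...CA termini), then a gapped global alignment
# of the two repeats to score identity. A deliberate simplification of the
# suffix-array maximal-repeat strategy of the standard tools, adequate at
# the scale this package targets.

#' Scan a genome for paired direct repeats (intact LTR-RT candidates)
#'
#' @param genome named character vector of sequences (ACGT + IUPAC codes;
#'   non-ACGT bases never seed matches).
#' @param min_ltr,max_ltr allowed LTR length range in bp.
#' @param min_sep,max_sep allowed separation between the 5' and 3' LTR start
#'   positions in bp.
#' @param min_identity minimum gapped alignment identity between the two
#'   repeats, in (0, 1].
#' @param k exact seed length in bp (k <= min_ltr).
#' @param xdrop ungapped extension stops once the running score falls this
#'   far below its maximum (match +1, mismatch -2).
#' @param snap_window bp searched around the extended bounds for TSD and
#'   TG...CA hallmarks.
#' @param max_occ k-mers occurring more often than this are not used as
#'   seeds.
#' @param cluster_gap seed runs on one diagonal are split into separate
#'   candidates at gaps larger than this (bp).
#' @return A data.frame of candidates (one per element) with 1-based
#'   inclusive coordinates: `element_id`, `seq_id`, `start`, `end`,
#'   `ltr5_start/end`, `ltr3_start/end`, `tsd`, `has_tg_ca`, `identity`,
#'   `score`, sorted by (seq_id, start). Overlapping candidates are resolved
#'   greedily by score = identity x length, ties by leftmost start.
#' @export
scan_ltr_pairs <- function(genome,
                           min_ltr = 100L, max_ltr = 3500L,
                           min_sep = 1000L, max_sep = 15000L,
                           min_identity = 0.8, k = 20L,
                           xdrop = 12, snap_window = 25L,
                           max_occ = 100L, cluster_gap = 150L) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  if (k > min_ltr)
    pe_error("seed length k must not exceed min_ltr", "paleoevo_parameter_error")
  if (min_ltr > max_ltr || min_sep > max_sep || min_identity <= 0 ||
      min_identity > 1)
    pe_error("inconsistent scan thresholds", "paleoevo_parameter_error")
  bad <- vapply(genome, function(s)
    grepl(sprintf("[^%s]", paste(IUPAC_CHARS, collapse = "")), s),
    logical(1))
  if (any(bad))
    pe_error("sequences contain non-IUPAC characters", "paleoevo_input_error")

  out <- lapply(names(genome), function(sid)
    scan_one_sequence(toupper(genome[[sid]]), sid, min_ltr, max_ltr,
                      min_sep, max_sep, min_identity, k, xdrop,
                      snap_window, max_occ, cluster_gap))
  out <- do.call(rbind, c(out, list(NULL)))
  if (is.null(out) || nrow(out) == 0) return(empty_scan_table())
  out <- out[order(out$seq_id, out$start), ]
  out$element_id <- sprintf("cand%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[c("element_id", "seq_id", "start", "end", "ltr5_start", "ltr5_end",
        "ltr3_start", "ltr3_end", "tsd", "has_tg_ca", "identity", "score")]
}

empty_scan_table <- function() {
  data.frame(element_id = character(), seq_id = character(),
             start = integer(), end = integer(),
             ltr5_start = integer(), ltr5_end = integer(),
             ltr3_start = integer(), ltr3_end = integer(),
             tsd = character(), has_tg_ca = logical(),
             identity = numeric(), score = numeric(),
             stringsAsFactors = FALSE)
}

scan_one_sequence <- function(seq, sid, min_ltr, max_ltr, min_sep, max_sep,
                              min_identity, k, xdrop, snap_window, max_occ,
                              cluster_gap) {
  seeds <- seed_pairs_cpp(seq, k, min_sep, max_sep, max_occ)
  if (nrow(seeds) == 0) return(NULL)
  sep <- seeds[, 2] - seeds[, 1]
  cand <- list()
  for (d in unique(sep)) {
    ii <- sort(seeds[sep == d, 1])
    # split runs on the same diagonal into clusters
    brk <- c(0L, which(diff(ii) > cluster_gap), length(ii))
    for (b in seq_len(length(brk) - 1)) {
      lo <- ii[brk[b] + 1L]
      hi <- ii[brk[b + 1]] + k - 1L
      if (hi - lo + 1L > max_ltr + 2L * snap_window) next
      ext <- extend_seed_cpp(seq, lo, hi, d, 1, -2, xdrop, max_ltr + 2L * snap_window)
      sn <- snap_bounds_cpp(seq, ext[1], ext[2], d, 4L, 6L, snap_window, 6)
      s <- sn$s; e <- sn$e
      len <- e - s + 1L
      if (len < min_ltr || len > max_ltr || e >= s + d) next
      # cheap ungapped pre-filter before the gapped alignment
      if (ungapped_identity_cpp(seq, s, e, d) < min_identity - 0.05) next
      a <- substring(seq, s + 1L, e + 1L)
      b2 <- substring(seq, s + d + 1L, e + d + 1L)
      aln <- nw_align_cpp(a, b2, 1, -1, -2)
      cols <- strsplit(aln$a, "")[[1]]
      colb <- strsplit(aln$b, "")[[1]]
      ident <- sum(cols == colb) / length(cols)
      if (ident < min_identity) next
      cand[[length(cand) + 1]] <- data.frame(
        seq_id = sid,
        start = s + 1L, end = e + d + 1L,
        ltr5_start = s + 1L, ltr5_end = e + 1L,
        ltr3_start = s + d + 1L, ltr3_end = e + d + 1L,
        tsd = sn$tsd, has_tg_ca = sn$has_tg && sn$has_ca,
        identity = ident,
        score = ident * len * (if (nchar(sn$tsd) > 0) 1 else 0.9),
        stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0) return(NULL)
  cand <- do.call(rbind, cand)
  resolve_overlaps(cand)
}

# greedy conflict resolution: best score first, ties by leftmost start
resolve_overlaps <- function(cand) {
  ord <- order(-cand$score, cand$start)
  cand <- cand[ord, ]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(cand)) > i)
    if (!length(later)) next
    ov <- cand$start[later] <= cand$end[i] & cand$end[later] >= cand$start[i]
    keep[later[ov]] <- FALSE
  }
  cand[keep, ]
}

#' Match detected candidates against a planted truth table
#'
#' A detection counts as a recovery of a planted element when both lie on
#' the same sequence and the reciprocal overlap of the element intervals is
#' at least `min_overlap`.
#'
#' @param detected,truth element tables with `seq_id`, `start`, `end`.
#' @param min_overlap reciprocal-overlap threshold.
#' @return Data.frame pairing each truth row with its matching detected row
#'   index (`NA` when missed), plus the recall as an attribute.
#' @export
match_elements <- function(detected, truth, min_overlap = 0.9) {
  hit <- rep(NA_integer_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    same <- which(detected$seq_id == truth$seq_id[i])
    if (!length(same)) next
    ov_s <- pmax(detected$start[same], truth$start[i])
    ov_e <- pmin(detected$end[same], truth$end[i])
    ov <- pmax(0, ov_e - ov_s + 1)
    rec <- pmin(ov / (detected$end[same] - detected$start[same] + 1),
                ov / (truth$end[i] - truth$start[i] + 1))
    j <- which.max(rec)
    if (length(j) && rec[j] >= min_overlap) hit[i] <- same[j]
  }
  out <- data.frame(truth_row = seq_len(nrow(truth)), detected_row = hit)
  attr(out, "recall") <- mean(!is.na(hit))
  out
}
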