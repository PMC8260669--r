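# Synonymous/nonsynonymous divergence (Nei-Gojobori pathway counting with
# Jukes-Cantor correction) and the fourfold-degenerate transversion
# proportion (4dTv) for paralog pairs, plus kernel-density peak detection
# over their distributions. The modes of the Ks and 4dTv distributions of
# paralogous blocks mark whole-genome duplication events.

#' Codon-aware alignment of two CDS
#'
#' Translates both CDS, aligns the proteins globally (match 2, mismatch -1,
#' gap -4 by default), and back-translates the alignment so gaps are whole
#' codons. Ungapped columns carry the original codons verbatim.
#'
#' @param cds_a,cds_b nucleotide strings; length divisible by 3, no internal
#'   stop codons (a trailing stop is trimmed from both before alignment).
#' @param match,mismatch,gap protein alignment scores.
#' @return Object of class `codon_alignment`: list with `codons_a`,
#'   `codons_b` (equal-length codon vectors, `"---"` for gaps).
#' @export
codon_align <- function(cds_a, cds_b, match = 2, mismatch = -1, gap = -4) {
  ca <- split_codons(toupper(cds_a))
  cb <- split_codons(toupper(cds_b))
  aa_a <- translate_codons(ca)
  aa_b <- translate_codons(cb)
  # trailing stops are allowed and trimmed; internal stops are an error
  if (length(aa_a) && !is.na(aa_a[length(aa_a)]) && aa_a[length(aa_a)] == "*") {
    ca <- ca[-length(ca)]; aa_a <- aa_a[-length(aa_a)]
  }
  if (length(aa_b) && !is.na(aa_b[length(aa_b)]) && aa_b[length(aa_b)] == "*") {
    cb <- cb[-length(cb)]; aa_b <- aa_b[-length(aa_b)]
  }
  if (any(aa_a == "*", na.rm = TRUE) || any(aa_b == "*", na.rm = TRUE))
    pe_error("internal stop codon", "paleoevo_input_error")
  if (length(ca) == 0 || length(cb) == 0)
    pe_error("empty CDS", "paleoevo_input_error")
  aa_a[is.na(aa_a)] <- "X"
  aa_b[is.na(aa_b)] <- "X"
  aln <- nw_align_cpp(paste(aa_a, collapse = ""), paste(aa_b, collapse = ""),
                      match, mismatch, gap)
  pa <- strsplit(aln$a, "")[[1]]
  pb <- strsplit(aln$b, "")[[1]]
  out_a <- character(length(pa)); out_b <- character(length(pb))
  i <- 0L; j <- 0L
  for (k in seq_along(pa)) {
    if (pa[k] == "-") out_a[k] <- "---" else { i <- i + 1L; out_a[k] <- ca[i] }
    if (pb[k] == "-") out_b[k] <- "---" else { j <- j + 1L; out_b[k] <- cb[j] }
  }
  structure(list(codons_a = out_a, codons_b = out_b),
            class = "codon_alignment")
}

# core NG counts on equal-length, gap-free codon vectors
ng_core <- function(ca, cb) {
  tab <- ng_tables()
  ia <- match(ca, tab$codons)
  ib <- match(cb, tab$codons)
  ok <- !is.na(ia) & !is.na(ib)
  ia <- ia[ok]; ib <- ib[ok]
  syn_sites <- (sum(tab$syn_sites[ia]) + sum(tab$syn_sites[ib])) / 2
  nonsyn_sites <- 3 * length(ia) - syn_sites
  sd <- sum(tab$sd[cbind(ia, ib)])
  nd <- sum(tab$nd[cbind(ia, ib)])
  pS <- if (syn_sites > 0) sd / syn_sites else NA_real_
  pN <- if (nonsyn_sites > 0) nd / nonsyn_sites else NA_real_
  jc <- function(p) {
    if (is.na(p) || p >= 0.75 - 1e-5) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  }
  list(codons = length(ia), syn_sites = syn_sites, nonsyn_sites = nonsyn_sites,
       syn_diffs = sd, nonsyn_diffs = nd, pS = pS, pN = pN,
       Ks = jc(pS), Ka = jc(pN))
}

#' Nei-Gojobori synonymous/nonsynonymous distances for a codon alignment
#'
#' Pathway-counting estimator: per-codon synonymous site fractions from the
#' standard genetic code averaged over the two sequences, differences in
#' multi-substitution codons averaged over all minimal mutational pathways
#' (pathways through stop codons excluded), and a Jukes-Cantor style
#' correction `Ks = -3/4 ln(1 - 4 pS / 3)` (Ka analogous).
#'
#' @param alignment a `codon_alignment`.
#' @param min_codons fewer analyzable codons than this yields status
#'   `too_short`.
#' @param max_ambiguous maximum tolerated fraction of codons with ambiguity
#'   codes (excluded from counts) before an input error is raised.
#' @return Object of class `codon_pair_stats`: list with site/difference
#'   counts, `pS`, `pN`, `Ks`, `Ka`, fourfold-site summaries (`fourfold_sites`,
#'   `fourfold_tv`, `fdtv`) and `status` (`ok`, `saturated`, `too_short`).
#' @export
ng_distance <- function(alignment, min_codons = 30L, max_ambiguous = 0.05) {
  stopifnot(inherits(alignment, "codon_alignment"))
  ca <- alignment$codons_a
  cb <- alignment$codons_b
  keep <- ca != "---" & cb != "---"
  ca <- ca[keep]; cb <- cb[keep]
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  if (length(ca) > 0 && mean(!clean) > max_ambiguous)
    pe_error("too many ambiguous codons", "paleoevo_input_error")
  st <- ng_core(ca[clean], cb[clean])
  fd <- fourfold_core(ca[clean], cb[clean])
  status <- if (st$codons < min_codons) "too_short"
  else if (!is.na(st$pS) && st$pS >= 0.75 - 1e-5) "saturated"
  else "ok"
  structure(c(st, fd, list(status = status)), class = "codon_pair_stats")
}

#' @export
print.codon_pair_stats <- function(x, ...) {
  cat(sprintf(paste0("<codon_pair_stats> %d codons [%s]\n",
                     "  pS=%.4f pN=%.4f Ks=%.4f Ka=%.4f 4dTv=%s (%d sites)\n"),
              x$codons, x$status, x$pS, x$pN,
              ifelse(is.na(x$Ks), NA, x$Ks), ifelse(is.na(x$Ka), NA, x$Ka),
              format(x$fdtv, digits = 4), x$fourfold_sites))
  invisible(x)
}

# fourfold-degenerate transversion counts on gap-free codon vectors:
# a column counts iff the first two codon positions are identical in both
# sequences and that prefix makes position 3 fourfold degenerate
fourfold_core <- function(ca, cb) {
  pa <- substr(ca, 1, 2)
  pb <- substr(cb, 1, 2)
  four <- pa == pb & pa %in% FOURFOLD_PREFIXES
  n4 <- sum(four)
  b3a <- substr(ca[four], 3, 3)
  b3b <- substr(cb[four], 3, 3)
  tv <- sum(b3a != b3b & !is_transition(b3a, b3b))
  list(fourfold_sites = as.integer(n4), fourfold_tv = as.integer(tv),
       fdtv = if (n4 > 0) tv / n4 else NA_real_)
}

#' Fourfold-degenerate transversion proportion (4dTv)
#'
#' The raw (uncorrected) fraction of fourfold-degenerate third positions at
#' which the two sequences differ by a transversion. Columns qualify only
#' when both sequences share an identical fourfold-degenerate codon prefix.
#'
#' @param alignment a `codon_alignment`.
#' @return List `fourfold_sites`, `fourfold_tv`, `fdtv` (`NA` and flagged
#'   via `undefined = TRUE` when there are no fourfold sites).
#' @export
four_dtv <- function(alignment) {
  stopifnot(inherits(alignment, "codon_alignment"))
  keep <- alignment$codons_a != "---" & alignment$codons_b != "---"
  ca <- alignment$codons_a[keep]
  cb <- alignment$codons_b[keep]
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  out <- fourfold_core(ca[clean], cb[clean])
  out$undefined <- out$fourfold_sites == 0
  out
}

#' Per-block median Ks and 4dTv
#'
#' @param blocks a `synteny_blocks` object.
#' @param stats data.frame keyed by `gene_a`, `gene_b` with columns `Ks`,
#'   `fdtv`, `status` (one row per anchor pair, e.g. assembled from
#'   [ng_distance()] results).
#' @return Data.frame `block_id`, `n_pairs`, `n_ok`, `median_ks`,
#'   `median_fdtv`, `low_support` (fewer than 3 usable pairs). Medians are
#'   taken over `status == "ok"` pairs only.
#' @export
block_median_distances <- function(blocks, stats) {
  key <- function(a, b) paste(a, b, sep = "\r")
  sk <- key(stats$gene_a, stats$gene_b)
  out <- lapply(split(blocks$pairs, blocks$pairs$block_id), function(p) {
    m <- match(key(p$gene_a, p$gene_b), sk)
    s <- stats[m[!is.na(m)], , drop = FALSE]
    ok <- s[!is.na(s$status) & s$status == "ok", , drop = FALSE]
    data.frame(block_id = p$block_id[1], n_pairs = nrow(p), n_ok = nrow(ok),
               median_ks = if (nrow(ok)) stats::median(ok$Ks) else NA_real_,
               median_fdtv = if (nrow(ok)) stats::median(ok$fdtv) else NA_real_,
               low_support = nrow(ok) < 3)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect peaks in a distance distribution
#'
#' Gaussian kernel density estimate on `[0, max(values)]`; peaks are strict
#' local maxima of the estimate whose topographic prominence is at least
#' `prominence` times the global maximum, reported in ascending position
#' order.
#'
#' @param values numeric distances (Ks or 4dTv); at least 50 required.
#' @param bandwidth kernel bandwidth, or `"auto"` for Silverman's
#'   rule-of-thumb.
#' @param prominence prominence threshold as a fraction of the global
#'   density maximum.
#' @param n_grid density grid size.
#' @return Object of class `peak_call`: list `positions`, `heights`,
#'   `bandwidth`, `n_values`.
#' @export
detect_peaks <- function(values, bandwidth = "auto", prominence = 0.05,
                         n_grid = 512L) {
  values <- values[!is.na(values)]
  if (length(values) < 50)
    pe_error("need at least 50 values for peak detection",
             "paleoevo_insufficient_data")
  bw <- if (identical(bandwidth, "auto")) stats::bw.nrd0(values) else bandwidth
  # distances live on [0, Inf): reflection at zero removes the kernel
  # rolloff at the support boundary, and the grid extends past the data
  # maximum so a mode near the top of the range stays an interior maximum
  den <- stats::density(c(values, -values), bw = bw,
                        from = 0, to = max(values) + 4 * bw, n = n_grid)
  y <- den$y; x <- den$x
  n <- length(y)
  gmax <- max(y)
  # prominence of a strict local maximum = drop to the higher of its two
  # nearest flanking local minima (grid boundary value when no minimum
  # intervenes); small wiggles on a plateau or shoulder thus never qualify
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n], FALSE)
  is_min <- c(FALSE, y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] < y[3:n], FALSE)
  min_idx <- which(is_min)
  pos <- numeric(0); hts <- numeric(0)
  for (i in which(is_max)) {
    left <- min_idx[min_idx < i]
    right <- min_idx[min_idx > i]
    base_l <- if (length(left)) y[max(left)] else y[1]
    base_r <- if (length(right)) y[min(right)] else y[n]
    if (y[i] - max(base_l, base_r) >= prominence * gmax) {
      pos <- c(pos, x[i]); hts <- c(hts, y[i])
    }
  }
  structure(list(positions = pos, heights = hts, bandwidth = bw,
                 n_values = length(values)),
            class = "peak_call")
}

#' @export
print.peak_call <- function(x, ...) {
  cat(sprintf("<peak_call> %d peak(s) from %d values (bw=%.4g)\n",
              length(x$positions), x$n_values, x$bandwidth))
  if (length(x$positions))
    cat("  at:", paste(sprintf("%.3f", x$positions), collapse = ", "), "\n")
  invisible(x)
}

#' Combine syntenic depth and distance peaks into a duplication-event call
#'
#' Declarative rules, all echoed into the report: a modal syntenic depth of
#' 2 together with the youngest distance peak calls a recent WGD at that
#' distance; every additional older peak is reported as an older shared
#' event; no peaks with modal depth <= 1 is "no duplication signal".
#'
#' @param depth_summary result of [depth_ratio_test()], or `NULL`.
#' @param peaks a `peak_call`, or `NULL`.
#' @return List with `events` (data.frame `event`, `distance`), `rules`
#'   (character log of rule firings), `gaps` (inputs that were missing).
#' @export
wgd_report <- function(depth_summary, peaks) {
  rules <- character(0)
  gaps <- character(0)
  events <- data.frame(event = character(), distance = numeric(),
                       stringsAsFactors = FALSE)
  if (is.null(depth_summary)) gaps <- c(gaps, "depth_summary")
  if (is.null(peaks)) gaps <- c(gaps, "peaks")
  have_peaks <- !is.null(peaks) && length(peaks$positions) > 0
  modal <- if (!is.null(depth_summary)) depth_summary$modal_depth else NA_integer_
  if (!is.null(depth_summary))
    rules <- c(rules, sprintf("modal syntenic depth = %d (%s)", modal,
                              depth_summary$call))
  if (!have_peaks && !is.na(modal) && modal <= 1) {
    rules <- c(rules, "no peaks and modal depth <= 1 -> no duplication signal")
    return(list(events = events, rules = rules, gaps = gaps,
                call = "no duplication signal"))
  }
  if (have_peaks) {
    p <- sort(peaks$positions)
    if (!is.na(modal) && modal == 2) {
      rules <- c(rules, sprintf(
        "modal depth 2 + youngest peak -> recent WGD at distance %.3f", p[1]))
      events <- rbind(events, data.frame(event = "recent WGD", distance = p[1]))
    } else {
      rules <- c(rules, sprintf(
        "youngest peak at %.3f without 1:2 depth support", p[1]))
      events <- rbind(events,
                      data.frame(event = "duplication (unsupported depth)",
                                 distance = p[1]))
    }
    if (length(p) > 1) {
      for (q in p[-1]) {
        rules <- c(rules, sprintf("additional older peak -> older shared event at %.3f", q))
        events <- rbind(events, data.frame(event = "older shared event",
                                           distance = q))
      }
    }
  }
  call <- if (nrow(events) == 0) "no duplication signal" else
    paste(events$event, collapse = " + ")
  list(events = events, rules = rules, gaps = gaps, call = call)
}
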