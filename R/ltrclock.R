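# Dating intact LTR retrotransposons from the divergence of their two
# terminal repeats. The two LTRs are identical at insertion; each then
# accumulates neutral substitutions at rate r per site per year, so the
# observed mismatch proportion lambda, corrected for multiple hits with the
# Jukes-Cantor transform K = -3/4 ln(1 - 4 lambda / 3), estimates 2 r T and
# the insertion time is T = K / (2 r).

#' Globally align the two LTRs of an element
#'
#' Needleman-Wunsch global alignment with linear gap penalties and a
#' deterministic traceback (diagonal preferred, then gap in the second
#' sequence, then gap in the first).
#'
#' @param ltr5,ltr3 nucleotide strings (non-empty).
#' @param match,mismatch,gap alignment scores.
#' @return An object of class `pairwise_alignment`: list with aligned
#'   strings `a`, `b` and the optimal `score`.
#' @examples
#' align_ltrs("ACGT", "ACT")
#' @export
align_ltrs <- function(ltr5, ltr3, match = 1, mismatch = -1, gap = -2) {
  if (!nzchar(ltr5) || !nzchar(ltr3))
    pe_error("empty sequence", "paleoevo_input_error")
  aln <- nw_align_cpp(toupper(ltr5), toupper(ltr3), match, mismatch, gap)
  structure(aln, class = "pairwise_alignment")
}

#' Observed divergence of an alignment
#'
#' lambda is the mismatch proportion over columns where both bases are
#' unambiguous nucleotides; gap and ambiguity columns are excluded from
#' numerator and denominator alike.
#'
#' @param alignment a `pairwise_alignment`.
#' @return List with `lambda`, `aligned_sites`, `mismatches`.
#' @export
compute_lambda <- function(alignment) {
  a <- strsplit(alignment$a, "")[[1]]
  b <- strsplit(alignment$b, "")[[1]]
  usable <- a %in% BASES & b %in% BASES
  n <- sum(usable)
  if (n == 0)
    pe_error("no usable (gap-free, unambiguous) columns",
             "paleoevo_too_short")
  mm <- sum(a[usable] != b[usable])
  list(lambda = mm / n, aligned_sites = n, mismatches = mm)
}

#' Jukes-Cantor corrected genetic distance
#'
#' `K = -3/4 ln(1 - 4 lambda / 3)`, the expected substitutions per site
#' implied by an observed divergence `lambda` under JC69. Undefined at and
#' beyond saturation (`lambda >= 0.75`), where a classed saturation error is
#' raised; such elements are excluded from dating rather than assigned a
#' time.
#'
#' @param lambda observed divergence in `[0, 0.75)` (vectorized).
#' @return K, substitutions per site; always `>= lambda`.
#' @examples
#' jc_distance(0.05)  # 0.0517447
#' @export
jc_distance <- function(lambda) {
  if (!is.numeric(lambda) || any(is.na(lambda)) || any(lambda < 0))
    pe_error("lambda must be in [0, 0.75)", "paleoevo_parameter_error")
  if (any(lambda >= 0.75))
    pe_error("lambda >= 0.75: divergence is saturated, K undefined",
             "paleoevo_saturation_error")
  -0.75 * log(1 - 4 * lambda / 3)
}

#' Insertion time from genetic distance
#'
#' `T = K / (2 r)`: each LTR accumulates `K/2` substitutions per site since
#' insertion when the pairwise distance is K.
#'
#' @param K Jukes-Cantor distance(s), substitutions per site.
#' @param r substitution rate per site per year (default 7.0e-9).
#' @return Insertion time in years.
#' @examples
#' insertion_time(0.014, r = 7e-9)  # 1e6 years
#' @export
insertion_time <- function(K, r = 7.0e-9) {
  if (!is.numeric(r) || length(r) != 1 || r <= 0)
    pe_error("rate r must be > 0", "paleoevo_parameter_error")
  if (any(K < 0)) pe_error("K must be >= 0", "paleoevo_parameter_error")
  K / (2 * r)
}

#' Date every element of a detection (or truth) table
#'
#' Extracts the two LTR sequences of each element, aligns them, computes
#' lambda, K and T, and records a status: `ok`, `saturated`
#' (lambda >= 0.75), or `too_short` (fewer than `min_sites` usable columns).
#' K and T are reported only for `ok` elements.
#'
#' @param elements data.frame with `element_id`, `seq_id`, `ltr5_start`,
#'   `ltr5_end`, `ltr3_start`, `ltr3_end` (1-based inclusive).
#' @param genome named character vector of sequences.
#' @param r substitution rate per site per year.
#' @param min_sites minimum usable alignment columns.
#' @param match,mismatch,gap alignment scores.
#' @return A data.frame of divergence records: `element_id`,
#'   `aligned_sites`, `mismatches`, `lambda`, `K`, `T_years`, `status`.
#' @export
date_elements <- function(elements, genome, r = 7.0e-9, min_sites = 50L,
                          match = 1, mismatch = -1, gap = -2) {
  n <- nrow(elements)
  if (n == 0)
    return(data.frame(element_id = character(), aligned_sites = integer(),
                      mismatches = integer(), lambda = numeric(),
                      K = numeric(), T_years = numeric(),
                      status = character(), stringsAsFactors = FALSE))
  out <- data.frame(element_id = elements$element_id,
                    aligned_sites = NA_integer_, mismatches = NA_integer_,
                    lambda = NA_real_, K = NA_real_, T_years = NA_real_,
                    status = "ok", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    s <- genome[[elements$seq_id[i]]]
    l5 <- substring(s, elements$ltr5_start[i], elements$ltr5_end[i])
    l3 <- substring(s, elements$ltr3_start[i], elements$ltr3_end[i])
    lam <- tryCatch(compute_lambda(align_ltrs(l5, l3, match, mismatch, gap)),
                    paleoevo_too_short = function(e) NULL)
    if (is.null(lam)) {
      out$status[i] <- "too_short"
      next
    }
    out$aligned_sites[i] <- lam$aligned_sites
    out$mismatches[i] <- lam$mismatches
    out$lambda[i] <- lam$lambda
    if (lam$aligned_sites < min_sites) {
      out$status[i] <- "too_short"
    } else if (lam$lambda >= 0.75) {
      out$status[i] <- "saturated"
    } else {
      out$K[i] <- jc_distance(lam$lambda)
      out$T_years[i] <- insertion_time(out$K[i], r)
    }
  }
  out
}

#' Classify one element's superfamily from its protein-domain order
#'
#' Integrase strictly before reverse transcriptase marks Ty1/copia; RT (and
#' RH when present) strictly before INT marks Ty3/gypsy; a missing INT or
#' RT, or interleaved order, yields `unknown`.
#'
#' @param hits data.frame of domain hits for a single element: columns
#'   `domain` (GAG/PR/INT/RT/RH), `start`, `end` (bp within the element).
#' @return `"Ty1/copia"`, `"Ty3/gypsy"`, or `"unknown"`.
#' @export
classify_superfamily <- function(hits) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0) return("unknown")
  if (!all(hits$domain %in% names(DOMAIN_MOTIFS)))
    pe_error("unknown domain type", "paleoevo_input_error")
  if (any(hits$start >= hits$end))
    pe_error("domain hit with start >= end", "paleoevo_input_error")
  if (anyDuplicated(hits$domain))
    pe_error("duplicate domain types within one element",
             "paleoevo_ambiguity_error")
  int <- hits[hits$domain == "INT", ]
  rt <- hits[hits$domain == "RT", ]
  if (nrow(int) == 0 || nrow(rt) == 0) return("unknown")
  if (int$end < rt$start) return("Ty1/copia")
  if (rt$end < int$start) {
    rh <- hits[hits$domain == "RH", ]
    if (nrow(rh) == 1 && !(rh$end < int$start)) return("unknown")
    return("Ty3/gypsy")
  }
  "unknown"
}

#' Histogram of insertion times
#'
#' Bins `ok` records into half-open intervals `[i w, (i+1) w)`; saturated
#' and too-short records are tallied separately in the summary attribute.
#'
#' @param records divergence records from [date_elements()].
#' @param bin_width bin width in years (> 0).
#' @return Data.frame `bin_start`, `bin_end`, `count` with a `summary`
#'   attribute (`n_ok`, `n_saturated`, `n_too_short`).
#' @export
age_distribution <- function(records, bin_width = 5e5) {
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width <= 0)
    pe_error("bin_width must be > 0", "paleoevo_parameter_error")
  ok <- records[records$status == "ok", ]
  summ <- c(n_ok = nrow(ok),
            n_saturated = sum(records$status == "saturated"),
            n_too_short = sum(records$status == "too_short"))
  if (nrow(ok) == 0) {
    out <- data.frame(bin_start = numeric(), bin_end = numeric(),
                      count = integer())
    attr(out, "summary") <- summ
    return(out)
  }
  idx <- floor(ok$T_years / bin_width)
  tab <- table(factor(idx, levels = 0:max(idx)))
  out <- data.frame(bin_start = as.numeric(names(tab)) * bin_width,
                    bin_end = (as.numeric(names(tab)) + 1) * bin_width,
                    count = as.integer(tab))
  attr(out, "summary") <- summ
  out
}
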