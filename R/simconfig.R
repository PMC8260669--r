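#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-genome simulator. A fixed `seed`
#' makes all simulator outputs byte-identical across runs.
#'
#' @param seed integer seed governing all randomness derived from this
#'   configuration.
#' @param r neutral nucleotide substitution rate in substitutions per site
#'   per year. The default 7.0e-9 is the rate commonly applied to plant
#'   LTR retrotransposons.
#' @param ltr_length length of each long terminal repeat in bp.
#' @param internal_length length of the internal (coding) region in bp;
#'   must hold the five 30-bp domain marker motifs (>= 180 bp).
#' @param tsd_length target site duplication length in bp (4-6 typical).
#' @param background_gc GC fraction of background sequence.
#' @param ks_target planted synonymous divergence (substitutions per
#'   synonymous site) for duplicated gene copies.
#' @param transversion_fraction fraction of planted synonymous changes at
#'   fourfold-degenerate sites that are transversions, in `[0, 1]`.
#' @param loss_rate independent probability that a duplicated gene copy is
#'   lost, in `[0, 1]`.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, ltr_length = 300)
#' cfg$r
#' @export
sim_config <- function(seed = 1L,
                       r = 7.0e-9,
                       ltr_length = 300L,
                       internal_length = 1000L,
                       tsd_length = 5L,
                       background_gc = 0.4,
                       ks_target = 0.3,
                       transversion_fraction = 0.5,
                       loss_rate = 0) {
  stopifnot(is_count(seed))
  if (!is.numeric(r) || length(r) != 1 || r <= 0)
    pe_error("substitution rate r must be > 0", "paleoevo_parameter_error")
  if (!is_count(ltr_length) || ltr_length <= 0 ||
      !is_count(internal_length) || internal_length < 180 ||
      !is_count(tsd_length) || tsd_length <= 0)
    pe_error("lengths must be positive (internal_length >= 180)",
             "paleoevo_parameter_error")
  for (f in c(background_gc, transversion_fraction, loss_rate))
    if (!is.numeric(f) || length(f) != 1 || f < 0 || f > 1)
      pe_error("fractions must lie in [0, 1]", "paleoevo_parameter_error")
  if (!is.numeric(ks_target) || any(ks_target < 0))
    pe_error("ks_target must be >= 0", "paleoevo_parameter_error")
  structure(list(seed = as.integer(seed), r = r,
                 ltr_length = as.integer(ltr_length),
                 internal_length = as.integer(internal_length),
                 tsd_length = as.integer(tsd_length),
                 background_gc = background_gc,
                 ks_target = ks_target,
                 transversion_fraction = transversion_fraction,
                 loss_rate = loss_rate),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}
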