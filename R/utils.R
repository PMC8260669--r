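# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# string <-> 0-based integer codes (NA for non-ACGT)
seq_to_codes <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], BASES) - 1L
}

codes_to_seq <- function(codes) {
  paste(BASES[codes + 1L], collapse = "")
}

#' Derive a stage-specific random seed from a global seed
#'
#' One global seed governs every stochastic stage of a run; each stage
#' re-seeds from a stable hash of (global seed, stage name) so stages are
#' reproducible in isolation and insensitive to execution order.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * (seq_along(utf8ToInt(stage)) %% 97 + 1))
  as.integer((abs(seed) %% 50021) * 40503 + (h * 2654435) %% 1048573) %% 2147483629L
}

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate an i.i.d. random nucleotide sequence
#'
#' @param n sequence length in bp.
#' @param gc GC fraction in `[0, 1]`; A/T and G/C are split evenly.
#' @return A single character string over ACGT.
#' @export
random_sequence <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

# classed conditions
pe_error <- function(msg, class) {
  stop(structure(class = c(class, "paleoevo_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x == floor(x)

# split a CDS string into codon triplets
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3 != 0) pe_error("CDS length not divisible by 3", "paleoevo_input_error")
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}

# IUPAC nucleotide alphabet accepted in FASTA input
IUPAC_CHARS <- c(BASES, "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
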