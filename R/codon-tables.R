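# Standard genetic code and precomputed Nei-Gojobori codon tables.
#
# Site counts follow the classic pathway-counting convention: at each codon
# position the synonymous-site fraction is (number of the 3 possible single-
# base changes that preserve the amino acid) / 3, with changes that create a
# stop codon counted as nonsynonymous, so syn + nonsyn sites always sum to 3
# per codon. Differences between codons differing at >1 position are averaged
# over all minimal mutational pathways; pathways passing through a stop codon
# are excluded (all pathways are used if none avoids a stop).

# Standard genetic code (codon -> one-letter amino acid, "*" = stop).
standard_genetic_code <- function() {
  b <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0)))
  # amino acids in TCAG x TCAG x TCAG order
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aas, codons)
}

GENETIC_CODE_STD <- standard_genetic_code()

# codon prefixes whose third position is fourfold degenerate
FOURFOLD_PREFIXES <- c("TC", "CT", "CC", "CG", "AC", "GT", "GC", "GG")

is_transition <- function(x, y) {
  (x == "A" & y == "G") | (x == "G" & y == "A") |
  (x == "C" & y == "T") | (x == "T" & y == "C")
}

translate_codons <- function(codons) {
  aa <- GENETIC_CODE_STD[codons]
  unname(aa)
}

# package-local cache
.pe_cache <- new.env(parent = emptyenv())

# Enumerate all minimal mutational pathways between two codons and return
# the pathway-averaged (syn_diffs, nonsyn_diffs). Used to build the 64x64
# lookup tables once per session.
codon_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(0, 0))
  p1 <- strsplit(c1, "")[[1]]
  p2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(p1 != p2)
  perms <- switch(as.character(length(diff_pos)),
    "1" = list(diff_pos),
    "2" = list(diff_pos, rev(diff_pos)),
    "3" = {
      p <- diff_pos
      list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
           p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
    })
  path_counts <- list()
  for (ord in perms) {
    cur <- p1
    sd <- 0; nd <- 0; valid <- TRUE
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- p2[pos]
      aa_cur <- GENETIC_CODE_STD[[paste(cur, collapse = "")]]
      aa_nxt <- GENETIC_CODE_STD[[paste(nxt, collapse = "")]]
      if (aa_nxt == "*" && paste(nxt, collapse = "") != c2) valid <- FALSE
      if (aa_cur == aa_nxt) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    path_counts[[length(path_counts) + 1]] <- list(sd = sd, nd = nd, valid = valid)
  }
  ok <- Filter(function(p) p$valid, path_counts)
  if (length(ok) == 0) ok <- path_counts
  c(mean(vapply(ok, `[[`, numeric(1), "sd")),
    mean(vapply(ok, `[[`, numeric(1), "nd")))
}

# Per-codon synonymous site count (sum over 3 positions of synonymous
# fraction among the 3 alternative bases; stop-creating changes nonsyn).
codon_syn_sites <- function(codon) {
  p <- strsplit(codon, "")[[1]]
  aa <- GENETIC_CODE_STD[codon]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(BASES, p[pos])) {
      alt <- p
      alt[pos] <- b
      alt_aa <- GENETIC_CODE_STD[paste(alt, collapse = "")]
      if (alt_aa != "*" && alt_aa == aa) s <- s + 1 / 3
    }
  }
  s
}

ng_tables <- function() {
  if (!is.null(.pe_cache$ng)) return(.pe_cache$ng)
  codons <- names(GENETIC_CODE_STD)
  n <- length(codons)
  syn_sites <- vapply(codons, codon_syn_sites, numeric(1))
  sd_mat <- matrix(0, n, n, dimnames = list(codons, codons))
  nd_mat <- matrix(0, n, n, dimnames = list(codons, codons))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- codon_pair_diffs(codons[i], codons[j])
      sd_mat[i, j] <- d[1]
      nd_mat[i, j] <- d[2]
    }
  }
  .pe_cache$ng <- list(codons = codons, syn_sites = syn_sites,
                       sd = sd_mat, nd = nd_mat)
  .pe_cache$ng
}
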