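# Independent brute-force oracles used to validate the package's dynamic
# programming and counting code. Each is written as a direct enumeration,
# sharing no code path with the implementation it checks.

# --- exhaustive global alignment score (tiny strings only) -----------------
# Enumerates all alignments recursively; returns the optimal score.
brute_force_align_score <- function(a, b, match, mismatch, gap) {
  na <- nchar(a); nb <- nchar(b)
  rec <- function(i, j) {
    if (i > na && j > nb) return(0)
    best <- -Inf
    if (i <= na && j <= nb) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1))
    }
    if (i <= na) best <- max(best, gap + rec(i + 1, j))
    if (j <= nb) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# --- Nei-Gojobori by direct enumeration ------------------------------------
# Site counts and pathway-averaged difference counts computed from scratch,
# one codon pair at a time.
oracle_translate <- function(codon) {
  # independent translation via amino-acid lookup assembled from the
  # reverse (amino acid -> codons) listing of the standard code
  aa2cod <- list(
    F = c("TTT", "TTC"), L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
    I = c("ATT", "ATC", "ATA"), M = "ATG",
    V = c("GTT", "GTC", "GTA", "GTG"),
    S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
    P = c("CCT", "CCC", "CCA", "CCG"), T = c("ACT", "ACC", "ACA", "ACG"),
    A = c("GCT", "GCC", "GCA", "GCG"), Y = c("TAT", "TAC"),
    H = c("CAT", "CAC"), Q = c("CAA", "CAG"), N = c("AAT", "AAC"),
    K = c("AAA", "AAG"), D = c("GAT", "GAC"), E = c("GAA", "GAG"),
    C = c("TGT", "TGC"), W = "TGG",
    R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
    G = c("GGT", "GGC", "GGA", "GGG"), `*` = c("TAA", "TAG", "TGA"))
  for (aa in names(aa2cod)) if (codon %in% aa2cod[[aa]]) return(aa)
  stop("bad codon: ", codon)
}

oracle_syn_sites <- function(codon) {
  p <- strsplit(codon, "")[[1]]
  aa <- oracle_translate(codon)
  total <- 0
  for (pos in 1:3) for (b in setdiff(c("A", "C", "G", "T"), p[pos])) {
    q <- p; q[pos] <- b
    alt <- oracle_translate(paste(q, collapse = ""))
    if (alt != "*" && alt == aa) total <- total + 1 / 3
  }
  total
}

# all permutations of a short vector (n <= 3)
oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (k in seq_along(v)) for (rest in oracle_perms(v[-k]))
    out[[length(out) + 1]] <- c(v[k], rest)
  out
}

oracle_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(syn = 0, nonsyn = 0))
  p1 <- strsplit(c1, "")[[1]]; p2 <- strsplit(c2, "")[[1]]
  dpos <- which(p1 != p2)
  res <- list()
  for (ord in oracle_perms(dpos)) {
    cur <- p1; sd <- 0; nd <- 0; through_stop <- FALSE
    for (pos in ord) {
      prev_aa <- oracle_translate(paste(cur, collapse = ""))
      cur[pos] <- p2[pos]
      cod <- paste(cur, collapse = "")
      aa <- oracle_translate(cod)
      if (aa == "*" && cod != c2) through_stop <- TRUE
      if (aa == prev_aa) sd <- sd + 1 else nd <- nd + 1
    }
    res[[length(res) + 1]] <- c(sd, nd, through_stop)
  }
  m <- do.call(rbind, res)
  ok <- m[m[, 3] == 0, , drop = FALSE]
  if (nrow(ok) == 0) ok <- m
  c(syn = mean(ok[, 1]), nonsyn = mean(ok[, 2]))
}

# full oracle over two gap-free codon vectors: returns pS, pN, Ks, Ka
oracle_ng <- function(ca, cb) {
  S <- (sum(vapply(ca, oracle_syn_sites, 0)) +
        sum(vapply(cb, oracle_syn_sites, 0))) / 2
  N <- 3 * length(ca) - S
  d <- rowSums(vapply(seq_along(ca),
                      function(k) oracle_pair_diffs(ca[k], cb[k]),
                      c(syn = 0, nonsyn = 0)))
  pS <- d[["syn"]] / S; pN <- d[["nonsyn"]] / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(syn_sites = S, nonsyn_sites = N, syn_diffs = d[["syn"]],
       nonsyn_diffs = d[["nonsyn"]], pS = pS, pN = pN,
       Ks = jc(pS), Ka = jc(pN))
}

# random stop-free codon vector
random_codons <- function(n) {
  sense <- setdiff(
    as.vector(outer(c("T", "C", "A", "G"),
                    outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                          paste0), paste0)),
    c("TAA", "TAG", "TGA"))
  sample(sense, n, replace = TRUE)
}

# --- exhaustive chain enumeration ------------------------------------------
# Best monotone chain score by depth-first enumeration of every chain, with
# the same scoring contract as chain_anchors: consecutive anchors must step
# 1..max_gap ranks on both genomes (descending on b for inverted), scored
# sum(anchor scores) - gap_penalty * sum(skipped ranks).
oracle_best_chain_score <- function(ra, rb, sc, orient, max_gap, gap_penalty) {
  n <- length(ra)
  best <- -Inf
  extend <- function(i, total) {
    best <<- max(best, total)
    for (j in seq_len(n)) {
      da <- ra[j] - ra[i]
      db <- if (orient == "same") rb[j] - rb[i] else rb[i] - rb[j]
      if (da >= 1 && da <= max_gap && db >= 1 && db <= max_gap)
        extend(j, total + sc[j] - gap_penalty * ((da - 1) + (db - 1)))
    }
  }
  for (i in seq_len(n)) extend(i, sc[i])
  best
}
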