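# Collinear (syntenic) block detection by dynamic-programming anchor
# chaining in gene-rank coordinates, and syntenic-depth summaries: the
# number of blocks of one genome covering each gene of a reference genome.
# A modal depth of 2 with a sharp decline beyond marks a 1:2 copy ratio,
# the classic footprint of one extra whole-genome duplication.

#' Chain homolog anchor pairs into collinear blocks
#'
#' Within each chromosome pair and orientation, anchors sorted by rank on
#' the first genome are chained by dynamic programming with
#' `score(chain) = sum(anchor scores) - gap_penalty * sum(skipped ranks)`,
#' allowing at most `max_gap` rank steps between consecutive anchors on
#' both genomes. Chains are extracted greedily by score (used anchors
#' removed, ties by `(chrom_a, chrom_b, first rank_a)`); chains with fewer
#' than `min_pairs` anchors are discarded.
#'
#' @param anchors data.frame `gene_a`, `gene_b`, `score`.
#' @param loci_a,loci_b gene locus tables (`gene_id`, `seq_id`, `rank`, ...)
#'   as built by [simulate_genes()] or [gene_loci()].
#' @param max_gap maximum rank step between consecutive anchors (>= 1).
#' @param min_pairs minimum anchors per reported block. The field convention
#'   for "more than 5 gene pairs" is a >= 5 cutoff, the default here.
#' @param gap_penalty score penalty per skipped rank.
#' @param drop_self drop trivial self-pairs (`gene_a == gene_b`) and, after
#'   chaining, mirror-duplicate blocks; use for self-comparisons.
#' @return An object of class `synteny_blocks`: list with `blocks`
#'   (block_id, chrom_a, chrom_b, orientation, n_pairs, score, rank_a_min,
#'   rank_a_max) and `pairs` (block_id, gene_a, gene_b, rank_a, rank_b).
#' @export
chain_anchors <- function(anchors, loci_a, loci_b, max_gap = 25L,
                          min_pairs = 5L, gap_penalty = 1,
                          drop_self = FALSE) {
  if (max_gap < 1 || min_pairs < 2)
    pe_error("max_gap must be >= 1 and min_pairs >= 2",
             "paleoevo_parameter_error")
  if (nrow(anchors) > 0 &&
      (!all(anchors$gene_a %in% loci_a$gene_id) ||
       !all(anchors$gene_b %in% loci_b$gene_id)))
    pe_error("anchor references unknown gene", "paleoevo_input_error")
  if (drop_self) anchors <- anchors[anchors$gene_a != anchors$gene_b, , drop = FALSE]

  ia <- match(anchors$gene_a, loci_a$gene_id)
  ib <- match(anchors$gene_b, loci_b$gene_id)
  tab <- data.frame(gene_a = anchors$gene_a, gene_b = anchors$gene_b,
                    score = anchors$score,
                    chrom_a = loci_a$seq_id[ia], rank_a = loci_a$rank[ia],
                    chrom_b = loci_b$seq_id[ib], rank_b = loci_b$rank[ib],
                    stringsAsFactors = FALSE)
  # deterministic base order regardless of input permutation
  tab <- tab[order(tab$chrom_a, tab$chrom_b, tab$rank_a, tab$rank_b), ]

  blocks <- list(); pairs <- list()
  for (grp in split(tab, list(tab$chrom_a, tab$chrom_b), drop = TRUE)) {
    sub <- grp
    # anchors are single-use: both orientations draw from one pool, the
    # higher-scoring chain wins each round
    while (nrow(sub) >= 1) {
      ch_s <- best_chain(sub, "same", max_gap, gap_penalty)
      ch_i <- best_chain(sub, "inverted", max_gap, gap_penalty)
      take_same <- ch_i$score < ch_s$score ||
        (ch_i$score == ch_s$score)     # prefer "same" on exact ties
      ch <- if (take_same) ch_s else ch_i
      orient <- if (take_same) "same" else "inverted"
      used <- sub[ch$idx, ]
      if (length(ch$idx) >= min_pairs) {
        blocks[[length(blocks) + 1]] <- data.frame(
          chrom_a = used$chrom_a[1], chrom_b = used$chrom_b[1],
          orientation = orient, n_pairs = nrow(used), score = ch$score,
          rank_a_min = min(used$rank_a), rank_a_max = max(used$rank_a),
          first_rank_a = used$rank_a[1], stringsAsFactors = FALSE)
        pairs[[length(pairs) + 1]] <- used[c("gene_a", "gene_b",
                                             "rank_a", "rank_b")]
      }
      sub <- sub[-ch$idx, , drop = FALSE]
      if (max(0, nrow(sub)) < min_pairs) break
    }
  }
  if (length(blocks) == 0) {
    return(structure(list(blocks = empty_block_table(),
                          pairs = data.frame(block_id = integer(),
                                             gene_a = character(),
                                             gene_b = character(),
                                             rank_a = integer(),
                                             rank_b = integer())),
                     class = "synteny_blocks"))
  }
  bl <- do.call(rbind, blocks)
  ord <- order(-bl$score, bl$chrom_a, bl$chrom_b, bl$first_rank_a)
  bl <- bl[ord, ]; pairs <- pairs[ord]
  if (drop_self) {
    sig <- vapply(pairs, function(p) {
      keys <- apply(cbind(pmin(p$gene_a, p$gene_b), pmax(p$gene_a, p$gene_b)),
                    1, paste, collapse = "\r")
      paste(sort(keys), collapse = "\n")
    }, character(1))
    keep <- !duplicated(sig)
    bl <- bl[keep, ]; pairs <- pairs[keep]
  }
  bl$block_id <- seq_len(nrow(bl))
  bl$first_rank_a <- NULL
  rownames(bl) <- NULL
  pr <- do.call(rbind, lapply(seq_along(pairs), function(k)
    cbind(block_id = k, pairs[[k]])))
  rownames(pr) <- NULL
  structure(list(blocks = bl[c("block_id", "chrom_a", "chrom_b",
                               "orientation", "n_pairs", "score",
                               "rank_a_min", "rank_a_max")],
                 pairs = pr),
            class = "synteny_blocks")
}

empty_block_table <- function() {
  data.frame(block_id = integer(), chrom_a = character(),
             chrom_b = character(), orientation = character(),
             n_pairs = integer(), score = numeric(),
             rank_a_min = integer(), rank_a_max = integer(),
             stringsAsFactors = FALSE)
}

# best-scoring monotone chain among anchors of one chromosome pair
best_chain <- function(sub, orient, max_gap, gap_penalty) {
  n <- nrow(sub)
  if (n == 0) return(NULL)
  ra <- sub$rank_a; rb <- sub$rank_b
  sc <- sub$score
  best <- sc; prev <- rep(0L, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1)) {
      da <- ra[j] - ra[i]
      db <- if (orient == "same") rb[j] - rb[i] else rb[i] - rb[j]
      if (da < 1 || da > max_gap || db < 1 || db > max_gap) next
      cand <- best[i] + sc[j] - gap_penalty * ((da - 1) + (db - 1))
      if (cand > best[j]) { best[j] <- cand; prev[j] <- i }
    }
  }
  j <- which.max(best)   # ties: first (lowest rank_a) wins
  idx <- integer(0)
  while (j != 0) { idx <- c(j, idx); j <- prev[j] }
  list(idx = idx, score = best[idx[length(idx)]])
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat(sprintf("<synteny_blocks> %d block(s), %d anchor pair(s)\n",
              nrow(x$blocks), nrow(x$pairs)))
  if (nrow(x$blocks)) print(utils::head(x$blocks, 10))
  invisible(x)
}

#' Syntenic depth of each reference gene
#'
#' `depth(g)` is the number of distinct blocks whose span of first-genome
#' ranks (on g's chromosome) contains g's rank.
#'
#' @param blocks a `synteny_blocks` object (reference genome on side a).
#' @param ref_loci reference gene locus table.
#' @return List with `depth` (gene_id, depth) and `histogram`
#'   (depth, count, fraction).
#' @export
syntenic_depth <- function(blocks, ref_loci) {
  bl <- blocks$blocks
  depth <- integer(nrow(ref_loci))
  for (k in seq_len(nrow(bl))) {
    inblk <- ref_loci$seq_id == bl$chrom_a[k] &
      ref_loci$rank >= bl$rank_a_min[k] & ref_loci$rank <= bl$rank_a_max[k]
    depth <- depth + inblk
  }
  tab <- table(depth)
  hist <- data.frame(depth = as.integer(names(tab)),
                     count = as.integer(tab),
                     fraction = as.numeric(tab) / nrow(ref_loci))
  list(depth = data.frame(gene_id = ref_loci$gene_id, depth = depth,
                          stringsAsFactors = FALSE),
       histogram = hist)
}

#' Ploidy-ratio call from a syntenic-depth histogram
#'
#' Reports the modal nonzero depth and calls "duplication consistent" (a
#' 1:2 copy ratio, i.e. one extra WGD in the second genome) when the modal
#' depth is 2 and the fraction of genes at depth >= 3 is below
#' `max_frac_deeper` - the "depth declines sharply beyond 2x" pattern.
#'
#' @param histogram depth histogram from [syntenic_depth()].
#' @param max_frac_deeper threshold on the fraction at depth >= 3.
#' @return List `modal_depth`, `fraction_le_modal`, `fraction_ge3`, `call`
#'   (one of `"duplication consistent"`, `"not consistent"`,
#'   `"no signal"`).
#' @export
depth_ratio_test <- function(histogram, max_frac_deeper = 0.1) {
  if (nrow(histogram) == 0)
    pe_error("empty depth histogram", "paleoevo_input_error")
  nz <- histogram[histogram$depth > 0, , drop = FALSE]
  if (nrow(nz) == 0 || sum(nz$count) == 0) {
    return(list(modal_depth = 0L, fraction_le_modal = 1,
                fraction_ge3 = 0, call = "no signal"))
  }
  modal <- nz$depth[which.max(nz$count)]
  frac_le <- sum(histogram$fraction[histogram$depth <= modal])
  frac_ge3 <- sum(histogram$fraction[histogram$depth >= 3])
  call <- if (modal == 2 && frac_ge3 < max_frac_deeper)
    "duplication consistent" else "not consistent"
  list(modal_depth = as.integer(modal), fraction_le_modal = frac_le,
       fraction_ge3 = frac_ge3, call = call)
}

#' Build a gene locus table from a GFF3 feature table
#'
#' Keeps `gene` features and assigns each chromosome a dense 0-based rank
#' by start coordinate.
#'
#' @param gff a GFF3 feature table from [read_gff3()].
#' @param type feature type to keep.
#' @return Locus table `gene_id`, `seq_id`, `start`, `end`, `strand`, `rank`.
#' @export
gene_loci <- function(gff, type = "gene") {
  g <- gff[gff$type == type, , drop = FALSE]
  g <- g[order(g$seqid, g$start), ]
  ids <- vapply(g$attr, function(a) unname(a["ID"]), character(1))
  rank <- stats::ave(seq_len(nrow(g)), g$seqid, FUN = seq_along) - 1L
  data.frame(gene_id = ids, seq_id = g$seqid, start = g$start, end = g$end,
             strand = g$strand, rank = as.integer(rank),
             stringsAsFactors = FALSE)
}
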