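# Neighbor-joining trees from distance matrices, and lineage assignment of
# reverse-transcriptase sequences by nearest reference leaf on the tree.
# Trees are built from uncorrected p-distances, the convention for LTR-RT
# lineage phylogenies.

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration. Negative branch lengths are clamped
#' to zero with the deficit transferred to the sister branch; ties in the
#' Q criterion are broken by label order, so output is deterministic. Exact
#' on additive distance matrices.
#'
#' @param d symmetric numeric matrix with zero diagonal, non-negative
#'   off-diagonal entries, labelled dimnames, size >= 3.
#' @return An unrooted `phylo` tree (ape).
#' @examples
#' d <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' nj_tree(d)
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d) || nrow(d) < 3)
    pe_error("distance matrix must be square with >= 3 taxa",
             "paleoevo_input_error")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  if (max(abs(d - t(d))) > 1e-9 || any(abs(diag(d)) > 1e-12) || any(d < 0))
    pe_error("matrix must be symmetric, zero-diagonal and non-negative",
             "paleoevo_input_error")

  labels <- rownames(d)
  newick <- labels          # growing subtree strings
  tiebk <- labels           # smallest leaf label per subtree, for ties
  D <- d
  fmt <- function(x) sprintf("%.12g", x)
  while (nrow(D) > 3) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) {
      p <- sort(c(tiebk[ij[1]], tiebk[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key, method = "radix")[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    new_nwk <- sprintf("(%s:%s,%s:%s)", newick[i], fmt(vi), newick[j], fmt(vj))
    new_tb <- min(tiebk[i], tiebk[j])
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    newick <- c(newick[keep], new_nwk)
    tiebk <- c(tiebk[keep], new_tb)
  }
  # final three-way join at an unrooted root
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- c(v1, v2, v3)
  if (any(v < 0)) {
    deficit <- sum(v[v < 0])
    v[v < 0] <- 0
    imax <- which.max(v)
    v[imax] <- max(0, v[imax] + deficit)
  }
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 newick[1], fmt(v[1]), newick[2], fmt(v[2]),
                 newick[3], fmt(v[3]))
  ape::read.tree(text = txt)
}

# copia and gypsy lineage names used for reference exemplars
COPIA_LINEAGES <- c("Angela", "Ale", "Bianca", "Ivana", "Maximus", "TAR")
GYPSY_LINEAGES <- c("Tekay", "Galadriel", "CRM", "Reina", "Athila", "Tat")

#' Simulate reference reverse-transcriptase exemplars per lineage
#'
#' One random RT exemplar per copia and gypsy lineage, for use as the
#' labelled reference set of [assign_lineage()] and in recovery tests where
#' queries are mutated copies of an exemplar.
#'
#' @param cfg a [sim_config()].
#' @param length exemplar length in bp.
#' @return Data.frame `id`, `lineage`, `superfamily`, `seq`.
#' @export
simulate_lineage_refs <- function(cfg = sim_config(), length = 300L) {
  with_seed(derive_seed(cfg$seed, "lineage_refs"), {
    lin <- c(COPIA_LINEAGES, GYPSY_LINEAGES)
    data.frame(
      id = paste0(lin, "_ref"),
      lineage = lin,
      superfamily = rep(c("Ty1/copia", "Ty3/gypsy"), each = 6),
      seq = vapply(lin, function(x) random_sequence(length, cfg$background_gc),
                   character(1)),
      stringsAsFactors = FALSE)
  })
}

# uncorrected p-distance between two sequences via global alignment
p_distance <- function(a, b) {
  compute_lambda(align_ltrs(a, b))$lambda
}

#' Assign an RT sequence to a lineage
#'
#' Joins the query to a neighbor-joining tree built from uncorrected
#' p-distances of the query plus all reference exemplars, then labels it
#' with the lineage of the nearest reference leaf by path length. An exact
#' tie between different lineages yields `"unknown"`.
#'
#' @param rt_seq query nucleotide string.
#' @param references data.frame with columns `id`, `lineage`, `seq`
#'   (at least one exemplar per lineage).
#' @param min_length minimum query length in bp.
#' @return The lineage label, or `"unknown"` on a tie.
#' @export
assign_lineage <- function(rt_seq, references, min_length = 100L) {
  if (nchar(rt_seq) < min_length)
    pe_error("query RT sequence shorter than minimum length",
             "paleoevo_too_short")
  stopifnot(all(c("id", "lineage", "seq") %in% names(references)),
            nrow(references) >= 2)
  seqs <- c(query = rt_seq, stats::setNames(references$seq, references$id))
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- p_distance(seqs[[i]], seqs[[j]])
  tr <- nj_tree(D)
  pd <- ape::cophenetic.phylo(tr)
  dq <- pd["query", references$id]
  best <- min(dq)
  hits <- references$lineage[dq <= best + 1e-12]
  if (length(unique(hits)) > 1) return("unknown")
  unique(hits)
}
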