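# Anchor chaining, syntenic depth, and the ploidy-ratio call.

# small helper: locus tables with ranks 0..n-1 on one chromosome each
mk_loci <- function(ids, chrom = "c1") {
  data.frame(gene_id = ids, seq_id = chrom,
             start = seq_along(ids) * 1000L,
             end = seq_along(ids) * 1000L + 500L,
             strand = "+", rank = seq_along(ids) - 1L,
             stringsAsFactors = FALSE)
}

test_that("a perfect diagonal chains into a single block", {
  la <- mk_loci(paste0("a", 1:6)); lb <- mk_loci(paste0("b", 1:6), "c2")
  anch <- data.frame(gene_a = la$gene_id, gene_b = lb$gene_id, score = 1)
  res <- chain_anchors(anch, la, lb, min_pairs = 5)
  expect_identical(nrow(res$blocks), 1L)
  expect_identical(res$blocks$n_pairs, 6L)
  expect_identical(res$blocks$orientation, "same")

  # below the pair threshold: no blocks
  res4 <- chain_anchors(anch[1:4, ], la, lb, min_pairs = 5)
  expect_identical(nrow(res4$blocks), 0L)

  # inverted diagonal
  anch_inv <- data.frame(gene_a = la$gene_id, gene_b = rev(lb$gene_id),
                         score = 1)
  resi <- chain_anchors(anch_inv, la, lb, min_pairs = 5)
  expect_identical(resi$blocks$orientation, "inverted")
  expect_identical(resi$blocks$n_pairs, 6L)
})

test_that("chained blocks satisfy strict monotonicity in both genomes", {
  set.seed(61)
  la <- mk_loci(paste0("a", 1:40)); lb <- mk_loci(paste0("b", 1:40), "c2")
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    anch <- data.frame(gene_a = sample(la$gene_id, n),
                       gene_b = sample(lb$gene_id, n), score = 1)
    res <- chain_anchors(anch, la, lb, max_gap = 10, min_pairs = 2)
    for (bid in res$blocks$block_id) {
      p <- res$pairs[res$pairs$block_id == bid, ]
      expect_true(all(diff(p$rank_a) >= 1))
      o <- res$blocks$orientation[res$blocks$block_id == bid]
      if (o == "same") expect_true(all(diff(p$rank_b) >= 1))
      else expect_true(all(diff(p$rank_b) <= -1))
    }
  }
})

test_that("DP chain score equals exhaustive chain enumeration", {
  set.seed(62)
  la <- mk_loci(paste0("a", 1:15)); lb <- mk_loci(paste0("b", 1:15), "c2")
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    anch <- unique(data.frame(gene_a = sample(la$gene_id, n, replace = TRUE),
                              gene_b = sample(lb$gene_id, n, replace = TRUE),
                              score = sample(1:3, n, replace = TRUE)))
    ra <- la$rank[match(anch$gene_a, la$gene_id)]
    rb <- lb$rank[match(anch$gene_b, lb$gene_id)]
    max_gap <- sample(2:6, 1)
    want <- max(
      oracle_best_chain_score(ra, rb, anch$score, "same", max_gap, 1),
      oracle_best_chain_score(ra, rb, anch$score, "inverted", max_gap, 1))
    res <- chain_anchors(anch, la, lb, max_gap = max_gap, min_pairs = 2,
                         gap_penalty = 1)
    got <- if (nrow(res$blocks)) max(res$blocks$score) else -Inf
    # the DP's best extracted chain must attain the oracle optimum; when the
    # optimum is a single anchor (never reported as a block) the singleton
    # score stands in
    expect_identical(max(got, max(anch$score)), want)
  }
})

test_that("chaining is invariant to anchor input order", {
  set.seed(63)
  la <- mk_loci(paste0("a", 1:30)); lb <- mk_loci(paste0("b", 1:30), "c2")
  anch <- data.frame(gene_a = la$gene_id[c(1:10, 15:24)],
                     gene_b = lb$gene_id[c(1:10, 24:15)], score = 1)
  r1 <- chain_anchors(anch, la, lb, min_pairs = 5)
  r2 <- chain_anchors(anch[sample(nrow(anch)), ], la, lb, min_pairs = 5)
  expect_identical(r1$blocks, r2$blocks)
  expect_identical(r1$pairs, r2$pairs)
})

test_that("anchors naming unknown genes are rejected", {
  la <- mk_loci("a1")
  expect_error(chain_anchors(data.frame(gene_a = "zz", gene_b = "a1",
                                        score = 1), la, la),
               class = "paleoevo_input_error")
})

test_that("syntenic depth counts covering blocks and double-counts add up", {
  cfg <- sim_config(seed = 64, ks_target = 0.2, loss_rate = 0)
  genes <- simulate_genes(40, cfg, codon_range = c(60L, 90L))
  w <- simulate_wgd(genes, cfg)
  blocks <- chain_anchors(w$anchors, genes$loci, w$genes$loci)
  dep <- syntenic_depth(blocks, genes$loci)
  # clean WGD: every reference gene at depth exactly 2
  expect_true(all(dep$depth$depth == 2L))
  # sum over genes of depth = sum over blocks of rank-span length
  spans <- with(blocks$blocks, rank_a_max - rank_a_min + 1)
  expect_identical(sum(dep$depth$depth), as.integer(sum(spans)))
  # no blocks: all depths zero
  none <- chain_anchors(w$anchors[0, ], genes$loci, w$genes$loci)
  expect_true(all(syntenic_depth(none, genes$loci)$depth$depth == 0L))
})

test_that("depth_ratio_test calls ploidy patterns as specified", {
  cfg <- sim_config(seed = 65, ks_target = 0.2, loss_rate = 0)
  genes <- simulate_genes(30, cfg, codon_range = c(60L, 90L))

  w <- simulate_wgd(genes, cfg)
  dep <- syntenic_depth(chain_anchors(w$anchors, genes$loci, w$genes$loci),
                        genes$loci)
  expect_identical(depth_ratio_test(dep$histogram)$call,
                   "duplication consistent")
  expect_identical(depth_ratio_test(dep$histogram)$modal_depth, 2L)

  # unduplicated self-comparison (self pairs dropped): no signal
  self_anch <- data.frame(gene_a = genes$loci$gene_id,
                          gene_b = genes$loci$gene_id, score = 1)
  bl <- chain_anchors(self_anch, genes$loci, genes$loci, drop_self = TRUE)
  dep0 <- syntenic_depth(bl, genes$loci)
  r0 <- depth_ratio_test(dep0$histogram)
  expect_lte(r0$modal_depth, 1L)
  expect_false(r0$call == "duplication consistent")

  # two duplication rounds: modal depth 3, not a 1:2 pattern
  w3 <- simulate_wgd(genes, cfg, copies = 2)
  dep3 <- syntenic_depth(chain_anchors(w3$anchors, genes$loci, w3$genes$loci),
                         genes$loci)
  r3 <- depth_ratio_test(dep3$histogram)
  expect_identical(r3$modal_depth, 3L)
  expect_identical(r3$call, "not consistent")
})
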