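# Codon alignment, Nei-Gojobori distances, 4dTv, and peak detection.

test_that("codon alignment back-translates verbatim with codon gaps", {
  cds <- paste(random_codons(40), collapse = "")
  al <- codon_align(cds, cds)
  expect_identical(al$codons_a, al$codons_b)
  expect_false(any(al$codons_a == "---"))

  # one whole-codon deletion -> exactly one codon gap column
  cod <- random_codons(40)
  al2 <- codon_align(paste(cod, collapse = ""),
                     paste(cod[-20], collapse = ""))
  expect_identical(sum(al2$codons_b == "---"), 1L)
  expect_identical(sum(al2$codons_a == "---"), 0L)
  # ungapped columns carry the original codons verbatim
  expect_identical(al2$codons_a[al2$codons_b != "---"][1:19], cod[1:19])

  expect_error(codon_align("ACGTA", "ACGTAA"), class = "paleoevo_input_error")
  expect_error(codon_align("ATGTAAAAA", "ATGTAAAAA"),
               class = "paleoevo_input_error")  # internal stop
})

test_that("the worked NG example and symmetry hold exactly", {
  st <- ng_distance(codon_align("GGTGATCAT", "GGCGATCAT"), min_codons = 1L)
  expect_equal(st$syn_sites, 5 / 3)
  expect_equal(st$nonsyn_sites, 22 / 3)
  expect_identical(st$syn_diffs, 1)
  expect_equal(st$pS, 0.6)
  expect_lt(abs(st$Ks - (-0.75 * log(0.2))), 1e-9)
  expect_identical(st$Ka, 0)

  # identical sequences
  cds <- paste(random_codons(50), collapse = "")
  st0 <- ng_distance(codon_align(cds, cds))
  expect_identical(st0$Ks, 0)
  expect_identical(st0$Ka, 0)

  # swapping the pair changes nothing
  a <- paste(random_codons(60), collapse = "")
  b <- mutate_jc(a, 0.1, seed = 4)
  s1 <- ng_distance(codon_align(a, b))
  s2 <- ng_distance(codon_align(b, a))
  expect_equal(s1[setdiff(names(s1), "status")],
               s2[setdiff(names(s2), "status")])
})

test_that("ng_distance matches the minimal-pathway brute-force oracle", {
  set.seed(71)
  for (rep in 1:60) {
    ca <- random_codons(60)
    # perturb some codons arbitrarily (keeping stop-free)
    cb <- ca
    idx <- sample(60, 25)
    cb[idx] <- random_codons(25)
    aln <- structure(list(codons_a = ca, codons_b = cb),
                     class = "codon_alignment")
    got <- ng_distance(aln)
    want <- oracle_ng(ca, cb)
    expect_equal(got$syn_sites, want$syn_sites, tolerance = 1e-12)
    expect_equal(got$syn_diffs, want$syn_diffs, tolerance = 1e-12)
    expect_equal(got$nonsyn_diffs, want$nonsyn_diffs, tolerance = 1e-12)
    expect_equal(got$pS, want$pS, tolerance = 1e-12)
    if (!is.na(want$Ks)) expect_equal(got$Ks, want$Ks, tolerance = 1e-12)
  }
})

test_that("the package genetic code table matches the Biostrings reference", {
  skip_if_not_installed("Biostrings")
  ref <- Biostrings::GENETIC_CODE
  mine <- paleoevo:::GENETIC_CODE_STD
  expect_identical(unname(mine[names(ref)]), unname(as.character(ref)))
})

test_that("too-short and saturated pairs are flagged, not dated", {
  short <- structure(list(codons_a = random_codons(10),
                          codons_b = random_codons(10)),
                     class = "codon_alignment")
  expect_identical(ng_distance(short)$status, "too_short")

  a <- random_codons(100)
  b <- a
  # scramble third positions hard at fourfold sites to push pS high
  four <- substr(a, 1, 2) %in% paleoevo:::FOURFOLD_PREFIXES
  b[four] <- paste0(substr(a[four], 1, 2),
                    chartr("ACGT", "CATG", substr(a[four], 3, 3)))
  st <- ng_distance(structure(list(codons_a = a, codons_b = b),
                              class = "codon_alignment"))
  expect_true(st$status %in% c("ok", "saturated"))  # depends on draw
  expect_true(st$pS <= 1)
})

test_that("4dTv counts transversions at shared fourfold prefixes only", {
  cds <- paste(random_codons(80), collapse = "")
  expect_identical(four_dtv(codon_align(cds, cds))$fdtv, 0)

  # transitions at fourfold sites do not move 4dTv
  ca <- rep("GGT", 100)
  cb <- rep("GGC", 100)  # T->C transition at a fourfold site
  aln <- structure(list(codons_a = ca, codons_b = cb),
                   class = "codon_alignment")
  expect_identical(four_dtv(aln)$fdtv, 0)
  expect_identical(four_dtv(aln)$fourfold_sites, 100L)

  # one transversion among 100 fourfold sites -> 0.01
  cb2 <- cb; cb2[1] <- "GGA"  # T->A transversion
  aln2 <- structure(list(codons_a = ca, codons_b = cb2),
                    class = "codon_alignment")
  expect_identical(four_dtv(aln2)$fdtv, 0.01)

  # no fourfold sites -> flagged undefined
  none <- structure(list(codons_a = rep("AAA", 40), codons_b = rep("AAA", 40)),
                    class = "codon_alignment")
  expect_true(four_dtv(none)$undefined)
})

test_that("block medians exclude non-ok pairs and flag low support", {
  blocks <- structure(list(
    blocks = data.frame(block_id = 1:2, chrom_a = "c1", chrom_b = "c2",
                        orientation = "same", n_pairs = c(3L, 2L),
                        score = 1, rank_a_min = 0L, rank_a_max = 5L),
    pairs = data.frame(block_id = c(1L, 1L, 1L, 2L, 2L),
                       gene_a = paste0("a", 1:5), gene_b = paste0("b", 1:5),
                       rank_a = 0:4, rank_b = 0:4)),
    class = "synteny_blocks")
  stats <- data.frame(gene_a = paste0("a", 1:5), gene_b = paste0("b", 1:5),
                      Ks = c(0.1, 0.2, 0.9, 0.3, 0.3),
                      fdtv = c(0.1, 0.2, 0.3, 0.2, 0.2),
                      status = c("ok", "ok", "saturated", "ok", "ok"))
  bm <- block_median_distances(blocks, stats)
  expect_equal(bm$median_ks[bm$block_id == 1], 0.15)  # saturated excluded
  expect_true(bm$low_support[bm$block_id == 1])       # 2 ok pairs < 3
  expect_equal(bm$median_ks[bm$block_id == 2], 0.3)
})

test_that("peak detection finds planted modes and ignores noise", {
  set.seed(72)
  # near-point mass at 0.3
  v <- 0.3 + rnorm(200, 0, 0.005)
  pk <- detect_peaks(v)
  expect_identical(length(pk$positions), 1L)
  expect_lt(abs(pk$positions - 0.3), 0.02)

  # bimodal mixture echoing a two-event Ks/4dTv distribution
  v2 <- c(rnorm(1000, 0.3, 0.05), rnorm(1000, 0.7, 0.05))
  pk2 <- detect_peaks(v2)
  expect_identical(length(pk2$positions), 2L)
  expect_lt(abs(pk2$positions[1] - 0.3), 0.05)
  expect_lt(abs(pk2$positions[2] - 0.7), 0.05)
  expect_false(is.unsorted(pk2$positions))

  # invariant to ordering and (at fixed bandwidth) duplication of the input
  pk3 <- detect_peaks(sample(v2))
  expect_identical(pk2$positions, pk3$positions)
  pk4 <- detect_peaks(c(v2, v2), bandwidth = pk2$bandwidth)
  expect_identical(detect_peaks(v2, bandwidth = pk2$bandwidth)$positions,
                   pk4$positions)

  expect_error(detect_peaks(runif(10)),
               class = "paleoevo_insufficient_data")
})

test_that("uniform draws rarely produce a prominent peak", {
  # at sample sizes where kernel wiggle noise sits below the prominence
  # threshold, a featureless distribution must yield no peaks
  set.seed(73)
  n_peaky <- sum(vapply(1:10, function(i) {
    length(detect_peaks(runif(50000))$positions) > 0
  }, logical(1)))
  expect_lte(n_peaky, 1)
})

test_that("wgd_report fires the declarative rules", {
  depth2 <- list(modal_depth = 2L, fraction_le_modal = 0.9,
                 fraction_ge3 = 0.02, call = "duplication consistent")
  pk <- structure(list(positions = c(0.3, 0.7), heights = c(2, 1),
                       bandwidth = 0.03, n_values = 200),
                  class = "peak_call")
  rep2 <- wgd_report(depth2, pk)
  expect_identical(rep2$events$event, c("recent WGD", "older shared event"))
  expect_equal(rep2$events$distance, c(0.3, 0.7))

  none <- wgd_report(list(modal_depth = 1L, call = "not consistent"),
                     structure(list(positions = numeric(0)),
                               class = "peak_call"))
  expect_identical(none$call, "no duplication signal")

  partial <- wgd_report(NULL, pk)
  expect_identical(partial$gaps, "depth_summary")
})
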