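# Simulator: JC mutation process, planted elements, WGD planting, truth.

test_that("mutate_jc honors the JC site-change probability", {
  s <- random_sequence(200, 0.5)
  expect_identical(mutate_jc(s, 0), s)

  # saturation: expected mismatch fraction tends to 0.75
  big <- mutate_jc(strrep("A", 20000), 50, seed = 1)
  mm <- mean(strsplit(big, "")[[1]] != "A")
  expect_lt(abs(mm - 0.75), 0.02)

  # closed-form expectation at d = 0.10 over replicate seeds
  d <- 0.10
  p_expect <- 0.75 * (1 - exp(-4 * d / 3))
  base <- random_sequence(10000, 0.5)
  obs <- vapply(1:100, function(sd) {
    m <- mutate_jc(base, d, seed = sd)
    mean(strsplit(m, "")[[1]] != strsplit(base, "")[[1]])
  }, numeric(1))
  se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - p_expect), 3 * se)

  expect_error(mutate_jc("ACGT", -1), class = "paleoevo_parameter_error")
  expect_error(mutate_jc("ACGN", 0.1), class = "paleoevo_input_error")
})

test_that("simulated elements carry the planted structure", {
  cfg <- sim_config(seed = 2, ltr_length = 300, internal_length = 1000)
  set.seed(1)
  el0 <- simulate_ltr_element(0, cfg, "copia")
  expect_identical(el0$ltr5, el0$ltr3)
  expect_identical(substr(el0$ltr5, 1, 2), "TG")
  expect_identical(substr(el0$ltr5, 299, 300), "CA")
  expect_identical(nchar(el0$seq), 2L * 300L + 1000L + 2L * 5L)

  # gypsy: RT motif placed before INT in the truth record
  elg <- simulate_ltr_element(1e6, cfg, "gypsy")
  d <- elg$domains
  expect_lt(d$start[d$domain == "RT"], d$start[d$domain == "INT"])
  elc <- simulate_ltr_element(1e6, cfg, "copia")
  d <- elc$domains
  expect_lt(d$start[d$domain == "INT"], d$start[d$domain == "RT"])

  # pairwise LTR mismatch over replicates matches 3/4 (1 - exp(-8 r T / 3))
  set.seed(42)
  T_years <- 2e6
  expect_mm <- 0.75 * (1 - exp(-8 * cfg$r * T_years / 3))
  mm <- vapply(1:100, function(i) {
    el <- simulate_ltr_element(T_years, cfg)
    mean(strsplit(el$ltr5, "")[[1]] != strsplit(el$ltr3, "")[[1]])
  }, numeric(1))
  se <- sqrt(expect_mm * (1 - expect_mm) / (300 * 100))
  expect_lt(abs(mean(mm) - expect_mm), 3.5 * se)
})

test_that("insert_elements places and reports exact coordinates", {
  cfg <- sim_config(seed = 3)
  genome <- c(chrT = strrep("ACGT", 2500))

  # empty element list: genome unchanged, empty truth
  res0 <- insert_elements(genome, list(), cfg = cfg)
  expect_identical(res0$genome, genome)
  expect_identical(nrow(res0$gff), 0L)

  # single element: downstream sequence shifted by the element length
  set.seed(7)
  el <- simulate_ltr_element(1e6, cfg)
  res <- insert_elements(genome, list(el),
                         positions = data.frame(seq_id = "chrT", pos = 1000L))
  expect_identical(substr(res$genome[["chrT"]], 1, 1000),
                   substr(genome[["chrT"]], 1, 1000))
  expect_identical(nchar(res$genome[["chrT"]]),
                   nchar(genome[["chrT"]]) + nchar(el$seq))
  expect_identical(substring(res$genome[["chrT"]], 1001 + nchar(el$seq)),
                   substring(genome[["chrT"]], 1001))

  # truth coordinates address the planted LTR copies exactly
  e <- res$elements
  expect_identical(substring(res$genome[["chrT"]], e$ltr5_start, e$ltr5_end),
                   el$ltr5)
  expect_identical(substring(res$genome[["chrT"]], e$ltr3_start, e$ltr3_end),
                   el$ltr3)

  expect_error(
    insert_elements(genome, list(el, el),
                    positions = data.frame(seq_id = "chrT", pos = c(5L, 5L))),
    class = "paleoevo_placement_error")
})

test_that("simulator output is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 123)
  s1 <- simulate_ltr_genome(cfg, ages = c(0, 1e6), n_per_age = 5)
  s2 <- simulate_ltr_genome(cfg, ages = c(0, 1e6), n_per_age = 5)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$elements, s2$elements)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(s1$genome, f1); write_fasta(s2$genome, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(f1, f2))
})

test_that("truth GFF3 round-trips and re-extracts the planted sequences", {
  cfg <- sim_config(seed = 5)
  sim <- simulate_ltr_genome(cfg, ages = c(0, 3e6), n_per_age = 4)
  path <- tempfile(fileext = ".gff3")
  write_gff3(sim$gff, path)
  gff <- read_gff3(path)
  ltrs <- gff[gff$type == "long_terminal_repeat", ]
  for (i in seq_len(nrow(sim$elements))) {
    e <- sim$elements[i, ]
    mine <- ltrs[vapply(ltrs$attr, function(a)
      identical(unname(a["Parent"]), e$element_id), logical(1)), ]
    expect_identical(nrow(mine), 2L)
    got <- substring(sim$genome[[e$seq_id]], mine$start, mine$end)
    want <- substring(sim$genome[[e$seq_id]],
                      c(e$ltr5_start, e$ltr3_start), c(e$ltr5_end, e$ltr3_end))
    expect_identical(sort(got), sort(want))
  }
  unlink(path)
})

test_that("simulate_wgd plants Ks on target with synonymous-only changes", {
  cfg0 <- sim_config(seed = 8, ks_target = 0, loss_rate = 0)
  genes <- simulate_genes(12, cfg0)
  w0 <- simulate_wgd(genes, cfg0)
  # ks 0, loss 0: duplicates identical, truth blocks cover every gene
  expect_identical(unname(w0$genes$cds[paste0(genes$loci$gene_id, "_wgd1")]),
                   unname(genes$cds[genes$loci$gene_id]))
  expect_setequal(
    w0$truth$blocks$gene_a[w0$truth$blocks$chrom_b == "chrA01_wgd1"],
    genes$loci$gene_id)
  expect_true(all(w0$truth$pairs$ks_true == 0))

  # planted Ks lands within 0.02 of target, Ka is exactly 0
  cfg <- sim_config(seed = 9, ks_target = 0.3, loss_rate = 0)
  w <- simulate_wgd(simulate_genes(30, cfg), cfg)
  expect_true(all(abs(w$truth$pairs$ks_true - 0.3) <= 0.02))
  ka <- vapply(seq_len(nrow(w$truth$pairs)), function(k) {
    ng_distance(codon_align(w$genes$cds[[w$truth$pairs$gene_a[k]]],
                            w$genes$cds[[w$truth$pairs$gene_b[k]]]))$Ka
  }, numeric(1))
  expect_true(all(ka == 0))

  # transversion_fraction 0: planted 4dTv identically 0
  cfgtv <- sim_config(seed = 10, ks_target = 0.3, transversion_fraction = 0)
  wtv <- simulate_wgd(simulate_genes(15, cfgtv), cfgtv)
  expect_true(all(wtv$truth$pairs$fdtv_true == 0))

  # internal stop is rejected
  bad <- list(loci = data.frame(gene_id = "x", seq_id = "c", start = 1,
                                end = 6, strand = "+", rank = 0),
              cds = c(x = "ATGTAAGGG"))
  expect_error(simulate_wgd(bad, cfg), class = "paleoevo_input_error")
})

test_that("gene loss thins duplicated blocks at the configured rate", {
  cfg <- sim_config(seed = 21, ks_target = 0.1, loss_rate = 0.3)
  genes <- simulate_genes(120, cfg, codon_range = c(60L, 90L))
  w <- simulate_wgd(genes, cfg)
  surv <- nrow(w$truth$pairs)
  # binomial(120, 0.7): allow 4 sd
  expect_lt(abs(surv - 120 * 0.7), 4 * sqrt(120 * 0.7 * 0.3))
  # duplicate ranks stay dense
  dup <- w$genes$loci[w$genes$loci$seq_id == "chrA01_wgd1", ]
  expect_identical(sort(dup$rank), seq_len(nrow(dup)) - 1L)
})
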