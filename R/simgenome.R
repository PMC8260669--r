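# Synthetic-genome simulator: LTR elements of known age, WGD paralog sets of
# known Ks/4dTv, and the ground truth every downstream estimator is tested
# against. The mutation model is deliberately site-independent Jukes-Cantor
# with no indels, so the JC correction applied downstream is exactly the
# right estimator for the planted divergences.

# 30-bp marker motifs standing in for retroviral protein domains; ordering
# within the internal region encodes the superfamily (integrase before
# reverse transcriptase = Ty1/copia, after = Ty3/gypsy).
DOMAIN_MOTIFS <- c(
  GAG = "ATGGGACAGACTTGGAAGCCTAGGACTTCA",
  PR  = "TGCCTGACGATATTCCGGTTAAGCACTGAC",
  INT = "GATTACGGCATCAAGTGGCCGAACTTCGTA",
  RT  = "CCATGTCGAATGGCTTCGTACAGGATTGAC",
  RH  = "TTGACCGTAGCATCCGGATAACGTGCTTCA")

SUPERFAMILY_DOMAIN_ORDER <- list(
  copia = c("GAG", "PR", "INT", "RT", "RH"),
  gypsy = c("GAG", "PR", "RT", "RH", "INT"))

#' Mutate a sequence under the Jukes-Cantor model
#'
#' Each site is independently substituted with probability
#' `p = 3/4 (1 - exp(-4 d / 3))` to a uniformly chosen different base,
#' the site-wise change probability implied by an expected divergence of
#' `d` substitutions per site under JC69.
#'
#' @param seq nucleotide string over ACGT.
#' @param d expected substitutions per site (>= 0).
#' @param seed optional integer seed; when given the caller's RNG state is
#'   left untouched.
#' @return The mutated sequence (same length).
#' @examples
#' mutate_jc("ACGTACGT", 0)      # identity
#' nchar(mutate_jc(random_sequence(100, 0.5), 0.1, seed = 1))
#' @export
mutate_jc <- function(seq, d, seed = NULL) {
  if (!is.numeric(d) || length(d) != 1 || is.na(d) || d < 0)
    pe_error("divergence d must be a single number >= 0",
             "paleoevo_parameter_error")
  codes <- seq_to_codes(seq)
  if (anyNA(codes))
    pe_error("sequence must contain only A, C, G, T", "paleoevo_input_error")
  run <- function() {
    p <- 0.75 * (1 - exp(-4 * d / 3))
    hit <- which(stats::runif(length(codes)) < p)
    if (length(hit)) {
      off <- sample.int(3L, length(hit), replace = TRUE)
      codes[hit] <- (codes[hit] + off) %% 4L
    }
    codes_to_seq(codes)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate one intact LTR retrotransposon of known age
#'
#' Draws an ancestral LTR (forced to begin `TG` and end `CA`), mutates two
#' copies independently with `d = r * age_years` each (total pairwise
#' divergence `2 r T`, matching the `T = K / 2r` dating convention), places
#' ordered domain marker motifs in the internal region according to the
#' requested superfamily, and flanks the element with identical target site
#' duplications.
#'
#' @param age_years planted insertion age in years (>= 0).
#' @param cfg a [sim_config()].
#' @param superfamily `"copia"` (INT before RT) or `"gypsy"` (RT before INT).
#' @return A list with the full insertable string (`seq`, including both
#'   TSDs), the component sequences, and element-relative truth coordinates
#'   (`domains` as a data.frame of 1-based positions within the element).
#' @export
simulate_ltr_element <- function(age_years, cfg = sim_config(),
                                 superfamily = c("copia", "gypsy")) {
  superfamily <- match.arg(superfamily)
  if (!is.numeric(age_years) || length(age_years) != 1 || age_years < 0)
    pe_error("age_years must be >= 0", "paleoevo_parameter_error")
  L <- cfg$ltr_length
  I <- cfg$internal_length
  anc <- random_sequence(L, cfg$background_gc)
  substr(anc, 1, 2) <- "TG"
  substr(anc, L - 1, L) <- "CA"
  d <- cfg$r * age_years
  ltr5 <- mutate_jc(anc, d)
  ltr3 <- mutate_jc(anc, d)
  internal <- random_sequence(I, cfg$background_gc)
  ord <- SUPERFAMILY_DOMAIN_ORDER[[superfamily]]
  offs <- floor(seq(1, I - 29, length.out = length(ord)))
  for (k in seq_along(ord))
    substr(internal, offs[k], offs[k] + 29) <- DOMAIN_MOTIFS[[ord[k]]]
  tsd <- random_sequence(cfg$tsd_length, cfg$background_gc)
  list(seq = paste0(tsd, ltr5, internal, ltr3, tsd),
       ltr5 = ltr5, ltr3 = ltr3, tsd = tsd,
       age_years = age_years, superfamily = superfamily,
       ltr_length = L, internal_length = I, tsd_length = cfg$tsd_length,
       # positions relative to the element (ltr5 start = 1)
       domains = data.frame(domain = ord,
                            start = L + offs,
                            end = L + offs + 29L,
                            stringsAsFactors = FALSE))
}

#' Insert simulated elements into a genome
#'
#' Splices element strings into host sequences at the given (or sampled)
#' points and returns the modified genome together with a truth annotation
#' whose 1-based inclusive coordinates exactly address the inserted copies.
#'
#' @param genome named character vector of host sequences.
#' @param elements list of elements from [simulate_ltr_element()].
#' @param positions data.frame with columns `seq_id` and `pos` (insertion
#'   after base `pos`, 0 = before the sequence), one row per element, or
#'   `NULL` to sample uniform distinct points.
#' @param cfg a [sim_config()] (used only when sampling positions).
#' @return A list: `genome` (modified sequences), `elements` (truth table,
#'   one row per element), `domains` (element-relative domain hits), and
#'   `gff` (truth features: `LTR_retrotransposon`, `long_terminal_repeat`,
#'   `target_site_duplication`).
#' @export
insert_elements <- function(genome, elements, positions = NULL,
                            cfg = sim_config()) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  m <- length(elements)
  if (m == 0) {
    return(list(genome = genome,
                elements = empty_element_table(),
                domains = data.frame(element_id = character(), domain = character(),
                                     start = integer(), end = integer()),
                gff = empty_gff()))
  }
  if (is.null(positions)) {
    lens <- nchar(genome)
    sid <- sample(names(genome), m, replace = TRUE, prob = lens)
    pos <- vapply(sid, function(s) sample.int(nchar(genome[[s]]) - 1L, 1L),
                  integer(1))
    positions <- data.frame(seq_id = sid, pos = pos, stringsAsFactors = FALSE)
  }
  stopifnot(nrow(positions) == m)
  if (anyDuplicated(positions[c("seq_id", "pos")]))
    pe_error("overlapping insertion points", "paleoevo_placement_error")
  bad <- positions$pos < 0 | positions$pos > nchar(genome)[positions$seq_id]
  if (any(bad))
    pe_error("insertion point outside sequence bounds",
             "paleoevo_placement_error")

  out_genome <- genome
  rows <- vector("list", m)
  dom_rows <- vector("list", m)
  eid <- sprintf("elt%04d", seq_len(m))
  for (sid in unique(positions$seq_id)) {
    idx <- which(positions$seq_id == sid)
    idx <- idx[order(positions$pos[idx])]
    src <- genome[[sid]]
    pieces <- character(0)
    cursor <- 0L
    offset <- 0L
    for (k in idx) {
      p <- positions$pos[k]
      el <- elements[[k]]
      pieces <- c(pieces, substring(src, cursor + 1L, p), el$seq)
      cursor <- p
      t <- el$tsd_length; L <- el$ltr_length; I <- el$internal_length
      s5 <- p + offset + t + 1L
      rows[[k]] <- data.frame(
        element_id = eid[k], seq_id = sid,
        start = s5, end = s5 + 2L * L + I - 1L,
        ltr5_start = s5, ltr5_end = s5 + L - 1L,
        ltr3_start = s5 + L + I, ltr3_end = s5 + 2L * L + I - 1L,
        tsd = el$tsd, age_years = el$age_years,
        superfamily = el$superfamily, stringsAsFactors = FALSE)
      dom_rows[[k]] <- data.frame(element_id = eid[k], domain = el$domains$domain,
                                  start = el$domains$start, end = el$domains$end,
                                  stringsAsFactors = FALSE)
      offset <- offset + nchar(el$seq)
    }
    pieces <- c(pieces, substring(src, cursor + 1L, nchar(src)))
    out_genome[[sid]] <- paste(pieces, collapse = "")
  }
  elements_df <- do.call(rbind, rows)
  elements_df <- elements_df[order(elements_df$seq_id, elements_df$start), ]
  rownames(elements_df) <- NULL
  domains_df <- do.call(rbind, dom_rows)
  list(genome = out_genome, elements = elements_df, domains = domains_df,
       gff = element_truth_gff(elements_df))
}

empty_element_table <- function() {
  data.frame(element_id = character(), seq_id = character(),
             start = integer(), end = integer(),
             ltr5_start = integer(), ltr5_end = integer(),
             ltr3_start = integer(), ltr3_end = integer(),
             tsd = character(), age_years = numeric(),
             superfamily = character(), stringsAsFactors = FALSE)
}

# truth GFF3 rows for a planted-element table
element_truth_gff <- function(el) {
  if (nrow(el) == 0) return(empty_gff())
  per <- lapply(seq_len(nrow(el)), function(i) {
    e <- el[i, ]
    t <- nchar(e$tsd)
    data.frame(
      seqid = e$seq_id, source = "paleoevo_sim",
      type = c("LTR_retrotransposon", "long_terminal_repeat",
               "long_terminal_repeat", "target_site_duplication",
               "target_site_duplication"),
      start = c(e$start, e$ltr5_start, e$ltr3_start, e$start - t, e$end + 1L),
      end = c(e$end, e$ltr5_end, e$ltr3_end, e$start - 1L, e$end + t),
      score = ".", strand = "+", phase = ".",
      attr = I(list(
        c(ID = e$element_id, age_years = format(e$age_years, scientific = FALSE),
          superfamily = e$superfamily),
        c(ID = paste0(e$element_id, "_ltr5"), Parent = e$element_id),
        c(ID = paste0(e$element_id, "_ltr3"), Parent = e$element_id),
        c(ID = paste0(e$element_id, "_tsd5"), Parent = e$element_id),
        c(ID = paste0(e$element_id, "_tsd3"), Parent = e$element_id))),
      stringsAsFactors = FALSE)
  })
  g <- do.call(rbind, per)
  g[order(g$seqid, g$start), ]
}

#' Simulate a genome populated with LTR elements of known ages
#'
#' Convenience wrapper around [simulate_ltr_element()] and
#' [insert_elements()]: elements are planted at regular spacings on as many
#' chromosomes as needed, with `spacer` bp of background between inserts.
#'
#' @param cfg a [sim_config()]; `cfg$seed` governs all randomness here.
#' @param ages vector of planted ages in years, one value per age class.
#' @param n_per_age elements planted per age class.
#' @param superfamilies recycled over elements.
#' @param spacer background bp between consecutive insertion points.
#' @param elements_per_chrom maximum elements per chromosome.
#' @return As [insert_elements()], plus `cfg`.
#' @export
simulate_ltr_genome <- function(cfg = sim_config(), ages = c(5e5, 2e6, 5e6),
                                n_per_age = 10,
                                superfamilies = c("copia", "gypsy"),
                                spacer = 600L, elements_per_chrom = 250L) {
  with_seed(derive_seed(cfg$seed, "ltr_genome"), {
    age_vec <- rep(ages, each = n_per_age)
    m <- length(age_vec)
    sf <- rep_len(superfamilies, m)
    n_chrom <- ceiling(m / elements_per_chrom)
    chrom_of <- rep(seq_len(n_chrom), each = elements_per_chrom)[seq_len(m)]
    genome <- character(0)
    positions <- NULL
    elements <- vector("list", m)
    for (k in seq_len(m))
      elements[[k]] <- simulate_ltr_element(age_vec[k], cfg, sf[k])
    for (cc in seq_len(n_chrom)) {
      idx <- which(chrom_of == cc)
      genome[[sprintf("chr%02d", cc)]] <-
        random_sequence((length(idx) + 1L) * spacer, cfg$background_gc)
      positions <- rbind(positions, data.frame(
        seq_id = sprintf("chr%02d", cc),
        pos = seq_along(idx) * spacer, stringsAsFactors = FALSE))
    }
    # reorder elements so positions data.frame rows align
    ord <- order(chrom_of)
    res <- insert_elements(genome, elements[ord], positions, cfg)
    # carry planted ages in the same order as the truth table
    res$cfg <- cfg
    res
  })
}

#' Simulate a set of protein-coding genes with chromosomal order
#'
#' Generates random stop-free CDS (first codon ATG) laid out sequentially
#' along one or more chromosomes, the input expected by [simulate_wgd()].
#'
#' @param n_genes number of genes.
#' @param cfg a [sim_config()].
#' @param n_chrom number of chromosomes to spread genes over.
#' @param codon_range inclusive range of gene lengths in codons.
#' @param intergenic bp between consecutive genes.
#' @return A gene set: list with `loci` (gene_id, seq_id, start, end,
#'   strand, rank) and `cds` (named character vector).
#' @export
simulate_genes <- function(n_genes, cfg = sim_config(), n_chrom = 1L,
                           codon_range = c(350L, 550L), intergenic = 200L) {
  with_seed(derive_seed(cfg$seed, "genes"), {
    sense <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD != "*"]
    per_chrom <- ceiling(n_genes / n_chrom)
    gid <- sprintf("g%04d", seq_len(n_genes))
    chrom <- sprintf("chrA%02d", rep(seq_len(n_chrom), each = per_chrom)[seq_len(n_genes)])
    cds <- character(n_genes)
    for (i in seq_len(n_genes)) {
      nc <- sample(codon_range[1]:codon_range[2], 1L)
      cds[i] <- paste(c("ATG", sample(sense, nc - 1L, replace = TRUE)),
                      collapse = "")
    }
    names(cds) <- gid
    loci <- do.call(rbind, lapply(unique(chrom), function(ch) {
      idx <- which(chrom == ch)
      lens <- nchar(cds[idx])
      starts <- cumsum(c(1L, utils::head(lens, -1) + intergenic))
      data.frame(gene_id = gid[idx], seq_id = ch,
                 start = starts, end = starts + lens - 1L,
                 strand = "+", rank = seq_along(idx) - 1L,
                 stringsAsFactors = FALSE)
    }))
    rownames(loci) <- NULL
    list(loci = loci, cds = cds)
  })
}

#' Simulate whole-genome duplication with planted synonymous divergence
#'
#' Appends duplicated chromosome copies that preserve gene order. Each
#' surviving duplicate accumulates strictly synonymous third-position
#' substitutions (proposal/rejection: a proposed change is kept only if the
#' amino acid is unchanged, so Ka = 0 by construction) until the realized
#' Nei-Gojobori Ks of the pair - measured by this package's own estimator on
#' the true, gap-free alignment - is within 0.02 of `ks_target`.
#' `cfg$transversion_fraction` sets the transversion share of proposals at
#' fourfold-degenerate sites; `cfg$loss_rate` drops duplicates independently.
#'
#' @param genes a gene set from [simulate_genes()].
#' @param cfg a [sim_config()].
#' @param copies number of duplicated copies to append (1 = WGD-like 1:2
#'   layout, 2 = triplication-like 1:3 layout).
#' @param ks_target planted Ks per copy (recycled); defaults to
#'   `cfg$ks_target`.
#' @return A list: `genes` (original + duplicated gene set), `anchors`
#'   (homolog pairs, score 1 each), and `truth` with `pairs` (gene_a,
#'   gene_b, ks_true, fourfold_sites, fourfold_tv, fdtv_true) and `blocks`
#'   (planted collinear layout).
#' @export
simulate_wgd <- function(genes, cfg = sim_config(), copies = 1L,
                         ks_target = NULL) {
  if (is.null(ks_target)) ks_target <- cfg$ks_target
  ks_target <- rep_len(ks_target, copies)
  loci <- genes$loci
  cds <- genes$cds
  for (g in names(cds)) {
    cod <- split_codons(cds[[g]])
    aa <- translate_codons(cod)
    if (any(aa[-length(aa)] == "*"))
      pe_error(sprintf("internal stop codon in %s", g), "paleoevo_input_error")
  }
  with_seed(derive_seed(cfg$seed, "wgd"), {
    new_loci <- list(loci)
    new_cds <- cds
    pair_rows <- list()
    block_rows <- list()
    for (cc in seq_len(copies)) {
      for (ch in unique(loci$seq_id)) {
        sub <- loci[loci$seq_id == ch, ]
        sub <- sub[order(sub$rank), ]
        keep <- stats::runif(nrow(sub)) >= cfg$loss_rate
        sub <- sub[keep, , drop = FALSE]
        if (nrow(sub) == 0) next
        dch <- sprintf("%s_wgd%d", ch, cc)
        did <- sprintf("%s_wgd%d", sub$gene_id, cc)
        dup_seq <- character(nrow(sub))
        ks_real <- numeric(nrow(sub))
        ff <- integer(nrow(sub)); fftv <- integer(nrow(sub))
        for (i in seq_len(nrow(sub))) {
          res <- mutate_synonymous(cds[[sub$gene_id[i]]], ks_target[cc],
                                   cfg$transversion_fraction)
          dup_seq[i] <- res$seq
          ks_real[i] <- res$ks_real
          fd <- fourfold_core(split_codons(cds[[sub$gene_id[i]]]),
                              split_codons(res$seq))
          ff[i] <- fd$fourfold_sites; fftv[i] <- fd$fourfold_tv
        }
        lens <- nchar(dup_seq)
        starts <- cumsum(c(1L, utils::head(lens, -1) + 200L))
        new_loci[[length(new_loci) + 1]] <- data.frame(
          gene_id = did, seq_id = dch, start = starts,
          end = starts + lens - 1L, strand = "+",
          rank = seq_len(nrow(sub)) - 1L, stringsAsFactors = FALSE)
        names(dup_seq) <- did
        new_cds <- c(new_cds, dup_seq)
        pair_rows[[length(pair_rows) + 1]] <- data.frame(
          gene_a = sub$gene_id, gene_b = did, ks_true = ks_real,
          fourfold_sites = ff, fourfold_tv = fftv,
          fdtv_true = ifelse(ff > 0, fftv / ff, NA_real_),
          stringsAsFactors = FALSE)
        block_rows[[length(block_rows) + 1]] <- data.frame(
          chrom_a = ch, chrom_b = dch, gene_a = sub$gene_id, gene_b = did,
          order = seq_len(nrow(sub)), stringsAsFactors = FALSE)
      }
    }
    pairs <- do.call(rbind, c(pair_rows, list(NULL)))
    blocks <- do.call(rbind, c(block_rows, list(NULL)))
    # identity anchors: every original gene also matches the untouched copy
    # retained in the duplicated genome (the reference-vs-query homologs
    # that make a clean WGD read as syntenic depth 2)
    ident_blocks <- do.call(rbind, lapply(unique(loci$seq_id), function(ch) {
      sub <- loci[loci$seq_id == ch, ]
      sub <- sub[order(sub$rank), ]
      data.frame(chrom_a = ch, chrom_b = ch, gene_a = sub$gene_id,
                 gene_b = sub$gene_id, order = seq_len(nrow(sub)),
                 stringsAsFactors = FALSE)
    }))
    blocks <- rbind(ident_blocks, blocks)
    paralog_anchors <- if (is.null(pairs)) NULL else
      data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b, score = 1,
                 stringsAsFactors = FALSE)
    anchors <- rbind(
      data.frame(gene_a = loci$gene_id, gene_b = loci$gene_id, score = 1,
                 stringsAsFactors = FALSE),
      paralog_anchors)
    list(genes = list(loci = do.call(rbind, new_loci), cds = new_cds),
         anchors = anchors,
         truth = list(pairs = pairs, blocks = blocks),
         ks_target = ks_target)
  })
}

# Accumulate synonymous substitutions in one CDS until the realized NG Ks
# against the original is as close as achievable to ks_target (closest
# single-step state kept; genes of a few hundred codons land within ~0.02).
mutate_synonymous <- function(cds, ks_target, tv_frac, max_rounds = 500L) {
  codons <- split_codons(cds)
  aa <- translate_codons(codons)
  if (any(aa[-length(aa)] == "*"))
    pe_error("internal stop codon", "paleoevo_input_error")
  mut_idx <- which(aa != "*")
  if (ks_target <= 0)
    return(list(seq = cds, ks_real = 0))
  tab <- ng_tables()
  S <- sum(tab$syn_sites[match(codons, tab$codons)])
  pS_t <- 0.75 * (1 - exp(-4 * ks_target / 3))
  cur <- codons
  prev <- NULL; prev_ks <- -Inf
  for (round in seq_len(max_rounds)) {
    st <- ng_core(codons, cur)
    ks_now <- if (is.na(st$Ks)) Inf else st$Ks
    if (abs(ks_now - ks_target) <= 0.005) break
    if (ks_now > ks_target) {
      if (!is.null(prev) && abs(prev_ks - ks_target) < abs(ks_now - ks_target))
        cur <- prev
      break
    }
    need <- max(1L, floor(S * (pS_t - st$pS) * 0.4))
    prev <- cur; prev_ks <- ks_now
    cur <- apply_syn_mutations(cur, need, tv_frac, mut_idx)
  }
  st <- ng_core(codons, cur)
  list(seq = paste(cur, collapse = ""), ks_real = st$Ks)
}

# n accepted synonymous third-position substitutions across codons[mut_idx]
apply_syn_mutations <- function(codons, n, tv_frac, mut_idx) {
  count <- 0L
  guard <- 0L
  while (count < n && guard < 100L * n + 1000L) {
    guard <- guard + 1L
    i <- mut_idx[sample.int(length(mut_idx), 1L)]
    cd <- codons[i]
    prefix <- substr(cd, 1, 2)
    b3 <- substr(cd, 3, 3)
    aa0 <- GENETIC_CODE_STD[[cd]]
    alts <- setdiff(BASES, b3)
    syn <- alts[vapply(alts, function(b)
      GENETIC_CODE_STD[[paste0(prefix, b)]] == aa0, logical(1))]
    if (!length(syn)) next
    ts <- syn[is_transition(b3, syn)]
    tv <- syn[!is_transition(b3, syn)]
    pick_tv <- length(tv) > 0 &&
      (length(ts) == 0 || stats::runif(1) < tv_frac)
    b <- if (pick_tv) tv[sample.int(length(tv), 1L)] else ts[sample.int(length(ts), 1L)]
    codons[i] <- paste0(prefix, b)
    count <- count + 1L
  }
  codons
}
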