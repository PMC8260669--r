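# Readers and writers for the on-disk formats. All file coordinates are
# 1-based inclusive (FASTA/GFF3 convention); any 0-based arithmetic is
# internal and converted at this boundary. Tables are tab-delimited with a
# single header row.

#' Read a FASTA file
#'
#' Case-insensitive parse (sequences uppercased), CRLF tolerated, the
#' record id is the first whitespace-delimited token after `>`.
#'
#' @param path file path.
#' @return Named character vector of sequences (possibly empty, with a
#'   warning for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    pe_error(sprintf("file not found: %s", path), "paleoevo_input_error")
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  if (length(lines) == 0 || all(!nzchar(lines))) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  hdr <- grepl("^>", lines)
  if (!hdr[match(TRUE, nzchar(lines))])
    pe_error("FASTA must start with a '>' header", "paleoevo_input_error")
  rec <- cumsum(hdr)
  ids <- sub("^>(\\S*).*$", "\\1", lines[hdr])
  if (anyDuplicated(ids))
    pe_error(sprintf("duplicate FASTA id: %s", ids[duplicated(ids)][1]),
             "paleoevo_input_error")
  body <- !hdr & nzchar(lines)
  bad <- body & grepl(sprintf("[^%s]", paste(c(IUPAC_CHARS, tolower(IUPAC_CHARS)),
                                             collapse = "")), lines)
  if (any(bad))
    pe_error(sprintf("non-IUPAC character at line %d", which(bad)[1]),
             "paleoevo_input_error")
  seqs <- vapply(seq_along(ids), function(k)
    toupper(paste(lines[body & rec == k], collapse = "")), character(1))
  stats::setNames(seqs, ids)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    n <- nchar(s)
    if (n > 0)
      writeLines(substring(s, seq(1, n, width),
                           pmin(seq(1, n, width) + width - 1, n)), con)
  }
  invisible(path)
}

# percent-encoding for GFF3 attribute values
gff_encode <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

gff_decode <- function(x) {
  vapply(x, utils::URLdecode, character(1), USE.NAMES = FALSE)
}

empty_gff <- function() {
  data.frame(seqid = character(), source = character(), type = character(),
             start = integer(), end = integer(), score = character(),
             strand = character(), phase = character(),
             attr = I(list()), stringsAsFactors = FALSE)
}

#' Read a GFF3 file
#'
#' @param path file path (must carry a `##gff-version 3` header).
#' @return Data.frame with columns `seqid`, `source`, `type`, `start`,
#'   `end`, `score`, `strand`, `phase` and a list-column `attr` of named
#'   character vectors (percent-decoded). Coordinates are 1-based
#'   inclusive, preserved verbatim.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path))
    pe_error(sprintf("file not found: %s", path), "paleoevo_input_error")
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  if (length(lines) == 0 || !grepl("^##gff-version\\s+3", lines[1]))
    pe_error("missing ##gff-version 3 header", "paleoevo_input_error")
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) return(empty_gff())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 9))
    pe_error("GFF3 rows must have 9 tab-separated columns",
             "paleoevo_input_error")
  m <- do.call(rbind, fields)
  start <- as.integer(m[, 4]); end <- as.integer(m[, 5])
  if (anyNA(start) || anyNA(end))
    pe_error("non-numeric GFF3 coordinates", "paleoevo_input_error")
  if (any(end < start))
    pe_error("GFF3 feature with end < start", "paleoevo_input_error")
  attr_col <- lapply(m[, 9], function(a) {
    if (a == "." || !nzchar(a)) return(stats::setNames(character(0), character(0)))
    kv <- strsplit(strsplit(a, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    stats::setNames(gff_decode(vapply(kv, function(p)
      if (length(p) > 1) p[2] else "", character(1))),
      gff_decode(vapply(kv, `[`, character(1), 1)))
  })
  data.frame(seqid = m[, 1], source = m[, 2], type = m[, 3],
             start = start, end = end, score = m[, 6], strand = m[, 7],
             phase = m[, 8], attr = I(attr_col), stringsAsFactors = FALSE)
}

#' Write a GFF3 file
#'
#' Features are sorted by (seqid, start) on write; attribute values are
#' percent-encoded symmetrically to [read_gff3()], so a read/write cycle is
#' byte-identical for sorted input. Unknown feature types pass through
#' verbatim.
#'
#' @param features data.frame as returned by [read_gff3()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  f <- features[order(features$seqid, features$start), , drop = FALSE]
  attr_str <- vapply(f$attr, function(a) {
    if (length(a) == 0) return(".")
    paste(paste0(gff_encode(names(a)), "=", gff_encode(unname(a))),
          collapse = ";")
  }, character(1))
  lines <- c("##gff-version 3",
             if (nrow(f)) paste(f$seqid, f$source, f$type, f$start, f$end,
                                f$score, f$strand, f$phase, attr_str,
                                sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write/read a tab-delimited table with a single header row
#'
#' @param x data.frame (list-columns are not supported).
#' @param path file path.
#' @return `path` invisibly for the writer; a data.frame for the reader.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "")
}

#' Write/read synteny blocks in the block-file format
#'
#' Each block is a header line `#block <id> <chrom_a> <chrom_b>
#' <orientation> <n_pairs> <score>` followed by one tab-separated line per
#' anchor pair (`gene_a`, `gene_b`, `rank_a`, `rank_b`).
#'
#' @param blocks a `synteny_blocks` object.
#' @param path file path.
#' @return `path` invisibly for the writer; a `synteny_blocks` for the
#'   reader.
#' @export
write_blocks <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(blocks$blocks))) {
    b <- blocks$blocks[k, ]
    writeLines(sprintf("#block %d %s %s %s %d %.6g", b$block_id, b$chrom_a,
                       b$chrom_b, b$orientation, b$n_pairs, b$score), con)
    p <- blocks$pairs[blocks$pairs$block_id == b$block_id, ]
    writeLines(paste(p$gene_a, p$gene_b, p$rank_a, p$rank_b, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_blocks
#' @export
read_blocks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^#block ", lines)
  blocks <- list(); pairs <- list()
  bounds <- c(hdr_idx, length(lines) + 1L)
  for (k in seq_along(hdr_idx)) {
    h <- strsplit(lines[hdr_idx[k]], " ", fixed = TRUE)[[1]]
    bid <- as.integer(h[2])
    blocks[[k]] <- data.frame(
      block_id = bid, chrom_a = h[3], chrom_b = h[4], orientation = h[5],
      n_pairs = as.integer(h[6]), score = as.numeric(h[7]),
      stringsAsFactors = FALSE)
    body <- lines[seq(hdr_idx[k] + 1L, bounds[k + 1] - 1L)]
    body <- body[nzchar(body)]
    m <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    pairs[[k]] <- data.frame(block_id = bid, gene_a = m[, 1], gene_b = m[, 2],
                             rank_a = as.integer(m[, 3]),
                             rank_b = as.integer(m[, 4]),
                             stringsAsFactors = FALSE)
  }
  bl <- do.call(rbind, c(blocks, list(NULL)))
  pr <- do.call(rbind, c(pairs, list(NULL)))
  if (is.null(bl)) {
    bl <- data.frame(block_id = integer(), chrom_a = character(),
                     chrom_b = character(), orientation = character(),
                     n_pairs = integer(), score = numeric())
    pr <- data.frame(block_id = integer(), gene_a = character(),
                     gene_b = character(), rank_a = integer(),
                     rank_b = integer())
  } else {
    rka <- tapply(pr$rank_a, pr$block_id, range)
    bl$rank_a_min <- vapply(rka[as.character(bl$block_id)], `[`, numeric(1), 1)
    bl$rank_a_max <- vapply(rka[as.character(bl$block_id)], `[`, numeric(1), 2)
  }
  structure(list(blocks = bl, pairs = pr), class = "synteny_blocks")
}

#' Convert a gene locus table to GFF3 features
#'
#' @param loci locus table (`gene_id`, `seq_id`, `start`, `end`, `strand`).
#' @param source source column value.
#' @return GFF3 feature data.frame suitable for [write_gff3()].
#' @export
loci_to_gff <- function(loci, source = "paleoevo") {
  data.frame(seqid = loci$seq_id, source = source, type = "gene",
             start = loci$start, end = loci$end, score = ".",
             strand = loci$strand, phase = ".",
             attr = I(lapply(loci$gene_id, function(g) c(ID = g))),
             stringsAsFactors = FALSE)
}
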