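# Readers and writers for the standard formats the pipeline consumes:
# FASTA transcripts and miRNAs, GFF3 intervals, TSV expression matrices,
# and SIF/TSV network exports.

#' Read a FASTA file of transcripts
#'
#' Sequences are whitespace-stripped and upper-cased; with `to_rna = TRUE`
#' (default) T is normalized to U so all downstream code sees RNA.
#'
#' @param path path to a FASTA file.
#' @param to_rna normalize T to U (default `TRUE`).
#' @param biotype optional biotype tag (`"lincRNA"` or `"mRNA"`) attached to
#'   every record.
#' @return a `data.frame` with columns `id`, `sequence` and, when `biotype`
#'   is given, `biotype`, one row per record in file order.
#' @export
read_fasta <- function(path, to_rna = TRUE, biotype = NULL) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) stopf("empty FASTA file: %s", path)
  if (!startsWith(trimws(lines[nonempty[1]]), ">"))
    stopf("malformed FASTA: line %d of %s does not start a record",
          nonempty[1], path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stopf("duplicate FASTA id(s): %s", paste(unique(dup), collapse = ", "))
  seqs <- toupper(gsub("[[:space:]]", "", as.character(set)))
  if (to_rna) seqs <- chartr("T", "U", seqs)
  if (any(!nzchar(seqs)))
    stopf("empty sequence for record(s): %s",
          paste(ids[!nzchar(seqs)], collapse = ", "))
  out <- data.frame(id = ids, sequence = unname(seqs),
                    stringsAsFactors = FALSE)
  if (!is.null(biotype)) {
    biotype <- match.arg(biotype, c("lincRNA", "mRNA"))
    out$biotype <- biotype
  }
  out
}

#' Write transcripts to FASTA
#'
#' @param x data.frame with columns `id` and `sequence`.
#' @param path output path.
#' @param width line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(paste0(">", x$id[i]), con)
    s <- x$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Load mature miRNAs and merge identical sequences
#'
#' Reads a miRBase-style mature FASTA, keeps entries whose id starts with
#' `species_prefix`, and merges records that share the same sequence into a
#' single entry whose id is the sorted original ids joined by `":"` (the
#' colon-joined ids seen in published target tables). Merging is idempotent.
#'
#' @param path mature miRNA FASTA (miRBase dialect; headers may carry
#'   accession/description after the id).
#' @param species_prefix id prefix to retain, e.g. `"zma-"`.
#' @return data.frame with columns `id`, `sequence`, `n_members`; attributes
#'   `n_extracted` (records matching the prefix) and `n_merged` (rows).
#' @export
load_and_merge_mirnas <- function(path, species_prefix) {
  recs <- read_fasta(path, to_rna = TRUE)
  keep <- startsWith(recs$id, species_prefix)
  if (!any(keep))
    stopf("no miRNA ids start with prefix '%s' in %s", species_prefix, path)
  recs <- recs[keep, , drop = FALSE]
  check_rna(recs$sequence, "miRNA sequence")
  len <- nchar(recs$sequence)
  if (any(len < 18L | len > 26L))
    warning(sprintf("%d mature sequence(s) outside the expected 18-26 nt range",
                    sum(len < 18L | len > 26L)))
  groups <- split(recs$id, recs$sequence)
  merged <- data.frame(
    id = vapply(groups, function(ids) paste(sort(ids), collapse = ":"),
                character(1)),
    sequence = names(groups),
    n_members = lengths(groups),
    stringsAsFactors = FALSE, row.names = NULL
  )
  merged <- merged[order(merged$id), , drop = FALSE]
  rownames(merged) <- NULL
  structure(merged, n_extracted = nrow(recs), n_merged = nrow(merged))
}

#' Construct a set of genomic intervals
#'
#' Coordinates are 1-based inclusive throughout the package.
#'
#' @param chrom chromosome names.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"`, `"-"` or `"."` (default).
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)))
    stopf("non-integer interval coordinates")
  if (any(start > end))
    stopf("invalid interval(s): start > end at row %s",
          paste(which(start > end), collapse = ", "))
  if (any(start < 1L)) stopf("interval start must be >= 1")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             strand = rep_len(as.character(strand), length(chrom)),
             stringsAsFactors = FALSE)
}

#' Read intervals from a GFF3 file
#'
#' Only seqid, start, end and strand are consumed; the attribute column is
#' ignored (full GFF3 attribute parsing is out of scope).
#'
#' @param path GFF3 file.
#' @param feature_types optional character vector; keep only these values of
#'   the `type` column (e.g. `"gene"`, `"miRNA_primary_transcript"`).
#' @return interval data.frame as from [genomic_intervals()].
#' @export
read_gff_intervals <- function(path, feature_types = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (!is.null(feature_types))
    gr <- gr[as.character(gr$type) %in% feature_types]
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  genomic_intervals(as.character(GenomicRanges::seqnames(gr)),
                    BiocGenerics::start(gr), BiocGenerics::end(gr), strand)
}

intervals_to_granges <- function(iv) {
  GenomicRanges::GRanges(iv$chrom,
                         IRanges::IRanges(iv$start, iv$end))
}

#' Keep lincRNAs that are truly intergenic
#'
#' Drops every lincRNA whose genomic interval shares at least one base with
#' any annotated gene or any miRNA hairpin (small RNA precursor) interval,
#' strand-agnostically. Survivors are returned in input order.
#'
#' @param lincs data.frame of lincRNA transcripts (columns `id`, `sequence`).
#' @param linc_intervals interval data.frame aligned row-by-row with `lincs`.
#' @param genes,hairpins interval data.frames of annotated genes and miRNA
#'   hairpins (either may have zero rows).
#' @return the subset of `lincs` with no overlap, original order preserved.
#' @export
filter_intergenic_lincrnas <- function(lincs, linc_intervals, genes, hairpins) {
  if (nrow(lincs) != nrow(linc_intervals))
    stopf("lincs and linc_intervals must align row-by-row")
  if (nrow(lincs) == 0L) return(lincs)
  blocked <- rbind(genes[, c("chrom", "start", "end", "strand")],
                   hairpins[, c("chrom", "start", "end", "strand")])
  if (nrow(blocked) == 0L) return(lincs)
  ql <- intervals_to_granges(linc_intervals)
  bl <- intervals_to_granges(blocked)
  hit <- IRanges::overlapsAny(ql, bl, minoverlap = 1L)
  lincs[!hit, , drop = FALSE]
}

#' Read a genes-by-samples expression matrix from TSV
#'
#' First column holds gene ids, the header row holds sample ids. Values must
#' be numeric and non-negative (FPKM-like).
#'
#' @param path TSV file.
#' @return numeric matrix, genes in rows, samples in columns, in file order.
#' @export
read_expression_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stopf("expression TSV needs a header and >= 1 row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  samples <- header[-1]
  ncol_expected <- length(header)
  rows <- cells[-1]
  genes <- character(length(rows))
  mat <- matrix(NA_real_, nrow = length(rows), ncol = length(samples))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != ncol_expected)
      stopf("ragged expression TSV: row %d has %d fields, expected %d",
            i + 1L, length(r), ncol_expected)
    genes[i] <- r[1]
    vals <- suppressWarnings(as.numeric(r[-1]))
    if (anyNA(vals))
      stopf("non-numeric expression value in row %d (gene %s)", i + 1L, r[1])
    mat[i, ] <- vals
  }
  if (anyDuplicated(genes))
    stopf("duplicate gene id(s) in expression matrix: %s",
          paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (any(mat < 0)) stopf("negative expression values are not allowed")
  dimnames(mat) <- list(genes, samples)
  mat
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]; round-trips preserve content.
#'
#' @param mat numeric matrix with gene row names and sample column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export network edges for external viewers
#'
#' Writes one edge per line, either as a Cytoscape SIF triple
#' (`source interaction target`) or as a headered TSV, plus a node-attribute
#' side file (`<path>.nodes.tsv`) carrying each node's kind and roles.
#'
#' @param network a [build_network()] result.
#' @param path output path for the edge file.
#' @param dialect `"SIF"` or `"TSV"`.
#' @return `path`, invisibly.
#' @export
export_network_edges <- function(network, path, dialect = c("SIF", "TSV")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(network, "regulatory_network"))
  ed <- network$edges
  if (dialect == "SIF") {
    lines <- if (nrow(ed)) sprintf("%s %s %s", ed$mirna, ed$role, ed$partner)
             else character(0)
    writeLines(lines, path)
  } else {
    write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  nodes <- network$nodes
  nodes$roles <- vapply(seq_len(nrow(nodes)), function(i) {
    paste(c(if (nodes$role_target[i]) "target",
            if (nodes$role_decoy[i]) "decoy"), collapse = ",")
  }, character(1))
  write.table(nodes[, c("id", "kind", "roles")],
              paste0(path, ".nodes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
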