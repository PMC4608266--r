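# Cross-species conservation of miRNA-pairing regions: window extraction,
# seed-and-extend homology search with Karlin-Altschul E-values, progressive
# multiple alignment, and >80% site-identity calls.

#' Extract a fixed-width window around a binding site
#'
#' Centers a `total_len` window on the site (left flank = floor of the
#' remainder / 2, right = ceiling). If the window runs off a transcript end
#' it is shifted to keep its full length when possible; the unrecoverable
#' deficit (transcript shorter than `total_len`) is reported.
#'
#' @param transcript one-row transcript record (`id`, `sequence`).
#' @param site_start,site_end 1-based inclusive site coordinates.
#' @param total_len window length (default 100).
#' @return list with `window` (sequence), `window_start`, `window_end`
#'   (transcript coords), `site_offsets` (site start/end within the window),
#'   `deficit`, and `site_truncated` flag (site longer than `total_len`).
#' @export
extract_site_window <- function(transcript, site_start, site_end,
                                total_len = 100L) {
  tlen <- nchar(transcript$sequence)
  if (site_start < 1L || site_end > tlen || site_start > site_end)
    stopf("site outside transcript")
  site_len <- site_end - site_start + 1L
  if (site_len > total_len) {
    warning("site longer than window; returning the site itself")
    return(list(window = substring(transcript$sequence, site_start, site_end),
                window_start = site_start, window_end = site_end,
                site_offsets = c(1L, site_len), deficit = 0L,
                site_truncated = TRUE))
  }
  rem <- total_len - site_len
  ws <- site_start - rem %/% 2L
  we <- site_end + (rem - rem %/% 2L)
  if (ws < 1L) { we <- we + (1L - ws); ws <- 1L }
  if (we > tlen) { ws <- ws - (we - tlen); we <- tlen }
  ws <- max(ws, 1L)
  deficit <- total_len - (we - ws + 1L)
  list(window = substring(transcript$sequence, ws, we),
       window_start = ws, window_end = we,
       site_offsets = c(site_start - ws + 1L, site_end - ws + 1L),
       deficit = as.integer(deficit), site_truncated = FALSE)
}

.seed_positions <- function(query, subject, word = 7L) {
  # (query offset, subject offset) pairs of exact word matches
  qlen <- nchar(query)
  hits_i <- integer(0); hits_j <- integer(0)
  subj <- Biostrings::BString(subject)
  for (i in seq_len(qlen - word + 1L)) {
    w <- substring(query, i, i + word - 1L)
    m <- Biostrings::matchPattern(Biostrings::BString(w), subj)
    if (length(m)) {
      js <- BiocGenerics::start(m)
      hits_i <- c(hits_i, rep.int(i, length(js)))
      hits_j <- c(hits_j, js)
    }
  }
  cbind(i = hits_i, j = hits_j)
}

.best_seeded_segment <- function(scores, seed_starts, word = 7L) {
  # optimal-scoring contiguous segment that fully contains >= 1 seed word
  n <- length(scores)
  cs <- c(0, cumsum(scores))
  best <- NULL
  for (t in seed_starts) {
    lo <- t; hi <- t + word - 1L
    # best extension left of lo and right of hi (may be empty)
    left_scores <- cs[lo] - cs[seq_len(lo)]          # start a = 1..lo
    a <- which.max(left_scores)
    right_scores <- cs[(hi:n) + 1L] - cs[hi + 1L]    # end b = hi..n
    b <- hi + which.max(right_scores) - 1L
    sc <- cs[b + 1L] - cs[a]
    if (is.null(best) || sc > best$score)
      best <- list(start = a, end = b, score = sc)
  }
  best
}

#' Seed-and-extend homology search
#'
#' Exact 7-mer seeds on both strands are extended ungapped (match +1,
#' mismatch -2) to the optimal segment on the seed diagonal; the raw score S
#' is converted to an E-value with the Karlin-Altschul formula
#' `E = K * m * n * exp(-lambda * S)` using published ungapped DNA constants
#' (lambda = 1.28, K = 0.46 for +1/-2 scoring). Hits with `E < evalue_cutoff`
#' are returned sorted by E ascending.
#'
#' @param query query sequence (>= 11 nt).
#' @param subject subject sequence (genome or window); empty gives no hits.
#' @param evalue_cutoff report hits with E below this (default 0.1).
#' @param word seed word size (default 7).
#' @param lambda,K Karlin-Altschul constants.
#' @return data.frame of hits: `subject_start`, `subject_end` (1-based on the
#'   forward subject), `strand`, `score`, `identity`, `evalue`,
#'   `query_start`, `query_end`.
#' @export
homology_search <- function(query, subject, evalue_cutoff = 0.1, word = 7L,
                            lambda = 1.28, K = 0.46) {
  query <- as_rna(query); subject <- as_rna(subject)
  if (nchar(query) < 11L) stopf("query must be >= 11 nt")
  if (!nzchar(subject)) {
    return(data.frame(subject_start = integer(0), subject_end = integer(0),
                      strand = character(0), score = numeric(0),
                      identity = numeric(0), evalue = numeric(0),
                      query_start = integer(0), query_end = integer(0)))
  }
  m <- nchar(query); n <- nchar(subject)
  qc <- strsplit(query, "")[[1]]
  out <- list()
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") subject else rna_revcomp(subject)
    sc <- strsplit(subj, "")[[1]]
    seeds <- .seed_positions(query, subj, word)
    if (nrow(seeds) == 0L) next
    diags <- unique(seeds[, "j"] - seeds[, "i"])
    for (d in diags) {
      i0 <- max(1L, 1L - d); i1 <- min(m, n - d)
      idx <- i0:i1
      match_vec <- qc[idx] == sc[idx + d]
      scores <- ifelse(match_vec, 1, -2)
      seed_i <- seeds[seeds[, "j"] - seeds[, "i"] == d, "i"]
      seg <- .best_seeded_segment(scores, seed_i - i0 + 1L, word)
      if (is.null(seg)) next
      E <- K * m * n * exp(-lambda * seg$score)
      if (E >= evalue_cutoff) next
      qs <- i0 + seg$start - 1L; qe <- i0 + seg$end - 1L
      ss <- qs + d; se <- qe + d
      if (strand == "-") { tmp <- ss; ss <- n - se + 1L; se <- n - tmp + 1L }
      out[[length(out) + 1L]] <- data.frame(
        subject_start = ss, subject_end = se, strand = strand,
        score = seg$score,
        identity = mean(match_vec[seg$start:seg$end]),
        evalue = E, query_start = qs, query_end = qe,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(homology_search(query, "", evalue_cutoff))
  hits <- do.call(rbind, out)
  hits[order(hits$evalue, hits$subject_start), , drop = FALSE]
}

.nw_pair <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  # global alignment of two character vectors, linear gap penalty
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1L, m + 1L)
  P <- matrix(0L, n + 1L, m + 1L)      # 1 diag, 2 up (gap in b), 3 left
  S[, 1] <- gap * (0:n); S[1, ] <- gap * (0:m)
  P[, 1] <- 2L; P[1, ] <- 3L; P[1, 1] <- 0L
  for (i in seq_len(n)) {
    sub <- ifelse(a[i] == b, match, mismatch)
    for (j in seq_len(m)) {
      d <- S[i, j] + sub[j]; u <- S[i, j + 1L] + gap; l <- S[i + 1L, j] + gap
      if (d >= u && d >= l) { S[i + 1L, j + 1L] <- d; P[i + 1L, j + 1L] <- 1L }
      else if (u >= l)      { S[i + 1L, j + 1L] <- u; P[i + 1L, j + 1L] <- 2L }
      else                  { S[i + 1L, j + 1L] <- l; P[i + 1L, j + 1L] <- 3L }
    }
  }
  ai <- character(0); bi <- character(0)
  i <- n + 1L; j <- m + 1L
  while (i > 1L || j > 1L) {
    p <- P[i, j]
    if (p == 1L) { ai <- c(a[i - 1L], ai); bi <- c(b[j - 1L], bi); i <- i - 1L; j <- j - 1L }
    else if (p == 2L) { ai <- c(a[i - 1L], ai); bi <- c("-", bi); i <- i - 1L }
    else { ai <- c("-", ai); bi <- c(b[j - 1L], bi); j <- j - 1L }
  }
  list(a = ai, b = bi, score = S[n + 1L, m + 1L])
}

.profile_align <- function(rows, seq_chars, match = 1, mismatch = -1, gap = -2) {
  # align one sequence against a profile (list of equal-length char vectors)
  ncol_prof <- length(rows[[1]])
  prof <- do.call(rbind, rows)
  m <- length(seq_chars)
  colscore <- matrix(0, ncol_prof, m)
  for (j in seq_len(m)) {
    eq <- prof == seq_chars[j]
    colscore[, j] <- colMeans(ifelse(eq, match, mismatch))
  }
  S <- matrix(0, ncol_prof + 1L, m + 1L)
  P <- matrix(0L, ncol_prof + 1L, m + 1L)
  S[, 1] <- gap * (0:ncol_prof); S[1, ] <- gap * (0:m)
  P[, 1] <- 2L; P[1, ] <- 3L; P[1, 1] <- 0L
  for (i in seq_len(ncol_prof)) {
    for (j in seq_len(m)) {
      d <- S[i, j] + colscore[i, j]; u <- S[i, j + 1L] + gap; l <- S[i + 1L, j] + gap
      if (d >= u && d >= l) { S[i + 1L, j + 1L] <- d; P[i + 1L, j + 1L] <- 1L }
      else if (u >= l)      { S[i + 1L, j + 1L] <- u; P[i + 1L, j + 1L] <- 2L }
      else                  { S[i + 1L, j + 1L] <- l; P[i + 1L, j + 1L] <- 3L }
    }
  }
  keep_col <- integer(0)   # for each output column: profile column index or 0
  new_row <- character(0)
  i <- ncol_prof + 1L; j <- m + 1L
  while (i > 1L || j > 1L) {
    p <- P[i, j]
    if (p == 1L) { keep_col <- c(i - 1L, keep_col); new_row <- c(seq_chars[j - 1L], new_row); i <- i - 1L; j <- j - 1L }
    else if (p == 2L) { keep_col <- c(i - 1L, keep_col); new_row <- c("-", new_row); i <- i - 1L }
    else { keep_col <- c(0L, keep_col); new_row <- c(seq_chars[j - 1L], new_row); j <- j - 1L }
  }
  rows_out <- lapply(rows, function(r)
    ifelse(keep_col > 0L, r[pmax(keep_col, 1L)], "-"))
  c(rows_out, list(new_row))
}

#' Progressive multiple alignment of a site window and its homologs
#'
#' Internal progressive global aligner (match +1, mismatch -1, gap -2),
#' joining sequences in order of decreasing pairwise identity to the
#' reference; alternatively parses the output of an external aligner command
#' (e.g. MAFFT) when `external` is given. The reference (first input) row
#' comes first in the block and the site offsets are mapped through any
#' reference gaps.
#'
#' @param sequences named character vector, reference first (>= 2 sequences).
#' @param site_offsets optional `c(start, end)` of the miRNA-pairing site in
#'   reference coordinates; mapped to block columns.
#' @param external optional external aligner command template; must contain
#'   `%s` for the input FASTA path and print aligned FASTA on stdout
#'   (e.g. `"mafft --maxiterate 1000 --localpair --quiet %s"`).
#' @return a `site_alignment_block`: list with `rows` (named, gapped, equal
#'   length), `site_columns`, `column_frequencies` (A/C/G/U/- counts per
#'   column).
#' @export
multiple_align <- function(sequences, site_offsets = NULL, external = NULL) {
  if (length(sequences) < 2L) stopf("multiple_align needs >= 2 sequences")
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  sequences <- as_rna(sequences)
  if (!is.null(external)) {
    fa <- tempfile(fileext = ".fa")
    write_fasta(data.frame(id = names(sequences), sequence = sequences), fa)
    alnfa <- tempfile(fileext = ".fa")
    system(sprintf(paste(external, "> %s"), fa, alnfa))
    parsed <- read_fasta(alnfa, to_rna = FALSE)
    rows_chr <- setNames(chartr("T", "U", toupper(parsed$sequence)), parsed$id)
    rows_chr <- rows_chr[names(sequences)]
  } else {
    chars <- lapply(strsplit(sequences, ""), identity)
    ref <- chars[[1]]
    idents <- vapply(chars[-1], function(s) {
      al <- .nw_pair(ref, s)
      mean(al$a == al$b & al$a != "-")
    }, numeric(1))
    ord <- order(-idents)
    rows <- list(ref)
    for (k in ord) rows <- .profile_align(rows, chars[-1][[k]])
    # restore input order of non-reference rows
    rows_named <- vector("list", length(sequences))
    rows_named[[1]] <- rows[[1]]
    for (pos in seq_along(ord)) rows_named[[1L + ord[pos]]] <- rows[[1L + pos]]
    rows_chr <- setNames(vapply(rows_named, paste, character(1), collapse = ""),
                         names(sequences))
  }
  rowmat <- do.call(rbind, strsplit(unname(rows_chr), ""))
  rownames(rowmat) <- names(rows_chr)
  site_columns <- integer(0)
  if (!is.null(site_offsets)) {
    ref_pos <- cumsum(rowmat[1, ] != "-")
    site_columns <- which(rowmat[1, ] != "-" &
                          ref_pos >= site_offsets[1] & ref_pos <= site_offsets[2])
  }
  freq <- apply(rowmat, 2, function(col)
    table(factor(col, levels = c("A", "C", "G", "U", "-"))))
  structure(list(rows = rows_chr, site_columns = site_columns,
                 column_frequencies = freq),
            class = "site_alignment_block")
}

#' Site conservation report
#'
#' Per-column identity is the fraction of non-reference rows matching the
#' reference base (a gap never matches). `site_identity` is the mean over the
#' site columns; the site is conserved when it exceeds `threshold`.
#' `flank_identity` is computed identically over the remaining columns.
#'
#' @param block a `site_alignment_block` with non-empty `site_columns`.
#' @param threshold conservation threshold on the mean site identity
#'   (default 0.80, strict inequality).
#' @return a `conservation_report` list with `site_identity`,
#'   `flank_identity`, `conserved`, `n_species`, `column_identity`.
#' @export
site_conservation <- function(block, threshold = 0.80) {
  if (length(block$rows) < 2L) stopf("block needs >= 2 rows")
  if (length(block$site_columns) == 0L) stopf("empty site_columns")
  rowmat <- do.call(rbind, strsplit(unname(block$rows), ""))
  ref <- rowmat[1, ]
  others <- rowmat[-1, , drop = FALSE]
  col_id <- colMeans(sweep(others, 2, ref, "==") & ref[col(others)] != "-" &
                     others != "-")
  site_id <- mean(col_id[block$site_columns])
  flank_cols <- setdiff(seq_along(ref), block$site_columns)
  flank_id <- if (length(flank_cols)) mean(col_id[flank_cols]) else NA_real_
  structure(list(site_identity = site_id, flank_identity = flank_id,
                 conserved = site_id > threshold,
                 n_species = nrow(rowmat) - 1L,
                 column_identity = col_id),
            class = "conservation_report")
}
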