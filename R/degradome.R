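# Degradome (PARE) processing: read preprocessing, 5'-end mapping onto
# transcripts, t-plot profiles, and cleavage category / empirical p-value at
# predicted cleavage positions.

#' Read degradome reads from FASTA or FASTQ
#'
#' @param path input file; format auto-detected from the first character
#'   (`>` FASTA, `@` FASTQ) unless given.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return character vector of reads, T normalized to U.
#' @export
read_degradome_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- substr(readLines(path, n = 1L), 1, 1)
    format <- if (identical(first, "@")) "fastq" else "fasta"
  }
  set <- Biostrings::readBStringSet(path, format = format)
  unname(as_rna(as.character(set)))
}

#' Preprocess degradome reads into a deduplicated library
#'
#' Clips the 3' adapter at the first exact occurrence of its first 8 nt,
#' drops reads shorter than `min_len` after clipping or with an N fraction
#' above `max_n_frac`, and merges redundant reads into unique sequences with
#' counts.
#'
#' @param reads character vector of raw reads (RNA or DNA; normalized).
#' @param adapter 3' adapter sequence, or `""` for none.
#' @param min_len minimum read length after clipping (default 18).
#' @param max_n_frac maximum tolerated fraction of N bases (default 0.1).
#' @param library_id identifier carried on the result.
#' @return a `degradome_library`: list with `library_id` and `unique_reads`
#'   (named integer vector, names are read sequences).
#' @export
preprocess_degradome <- function(reads, adapter = "", min_len = 18L,
                                 max_n_frac = 0.1, library_id = "lib1") {
  if (min_len < 1L) stopf("min_len must be >= 1")
  reads <- as_rna(reads)
  if (nzchar(adapter)) {
    key <- substr(as_rna(adapter), 1L, 8L)
    hit <- regexpr(key, reads, fixed = TRUE)
    clip <- hit > 0L
    reads[clip] <- substr(reads[clip], 1L, hit[clip] - 1L)
  }
  n_frac <- nchar(gsub("[^N]", "", reads)) / pmax(nchar(reads), 1L)
  reads <- reads[nchar(reads) >= min_len & n_frac <= max_n_frac]
  counts <- table(reads)
  structure(list(library_id = library_id,
                 unique_reads = setNames(as.integer(counts), names(counts))),
            class = "degradome_library")
}

#' Map degradome 5' ends onto a transcript
#'
#' Every exact full-length occurrence of each unique read contributes the
#' read's count at the occurrence's 5' position (multi-mapping reads count at
#' every occurrence).
#'
#' @param library a `degradome_library`.
#' @param transcript one-row transcript record (`id`, `sequence`).
#' @return a `degradome_profile`: list with `transcript_id`, `length`, and
#'   `abundance` (named integer vector position -> summed count; only
#'   occupied positions present).
#' @export
map_five_prime_ends <- function(library, transcript) {
  tseq <- as_rna(transcript$sequence)
  if (!nzchar(tseq)) stopf("empty transcript")
  n <- nchar(tseq)
  abundance <- integer(0)
  # prefix index: all occurrences (overlapping included) of every 12-mer
  w0 <- 12L
  index <- if (n >= w0) {
    kmers <- substring(tseq, seq_len(n - w0 + 1L), seq_len(n - w0 + 1L) + w0 - 1L)
    split(seq_len(n - w0 + 1L), kmers)
  } else list()
  for (read in names(library$unique_reads)) {
    w <- nchar(read)
    if (w > n) next
    starts <- if (w >= w0) {
      cand <- index[[substr(read, 1L, w0)]] %||% integer(0)
      cand <- cand[cand + w - 1L <= n]
      if (length(cand) == 0L) integer(0)
      else cand[substring(tseq, cand, cand + w - 1L) == read]
    } else {
      BiocGenerics::start(Biostrings::matchPattern(read, tseq))
    }
    for (s in as.character(starts)) {
      abundance[s] <- (if (s %in% names(abundance)) abundance[[s]] else 0L) +
        library$unique_reads[[read]]
    }
  }
  pos <- as.integer(names(abundance))
  o <- order(pos)
  structure(list(transcript_id = transcript$id, length = nchar(tseq),
                 abundance = setNames(as.integer(abundance[o]),
                                      names(abundance)[o])),
            class = "degradome_profile")
}

#' Predicted cleavage position of a duplex alignment
#'
#' miRNA-guided cleavage leaves a 3' fragment whose 5' end sits on the
#' transcript base opposite miRNA position 10; for a perfect site at
#' `[s, e]` that is `e - 9`. With `window = TRUE` the transcript coordinates
#' opposite miRNA positions 9-12 are returned (the acceptance window used
#' when position 10 itself is unpaired).
#'
#' @param alignment a `duplex_alignment`.
#' @param window return the 9-12 window instead of the single canonical
#'   position.
#' @return integer position (or sorted vector of window positions).
#' @export
predicted_cleavage_site <- function(alignment, window = FALSE) {
  co <- alignment$columns
  if (window) {
    pos <- co$t_pos[co$mirna_pos %in% 9:12 & co$t_pos > 0]
    if (length(pos) == 0L) stopf("miRNA positions 9-12 all unpaired")
    return(sort(unique(pos)))
  }
  hit <- co$t_pos[co$mirna_pos == 10L]
  if (length(hit) != 1L || hit == 0L)
    stopf("miRNA position 10 is unpaired; use window = TRUE as fallback")
  hit
}

#' Cleavage category of a degradome signal at a position
#'
#' With `a` the abundance at the queried position, `M` the maximum and `med`
#' the median abundance over occupied positions: `a == 1` is category 4;
#' `a > 1` and the unique maximum is 0; a tied maximum is 1; above the median
#' but below the maximum is 2; at or below the median is 3. A position with
#' no reads yields no category (`NA`).
#'
#' @param profile a `degradome_profile` with at least one occupied position.
#' @param position 1-based transcript coordinate.
#' @return integer category 0-4, or `NA` if the position is unoccupied.
#' @export
assign_category <- function(profile, position) {
  ab <- profile$abundance
  if (length(ab) == 0L) stopf("empty degradome profile")
  if (position < 1L || position > profile$length)
    stopf("position outside transcript")
  a <- if (as.character(position) %in% names(ab)) ab[[as.character(position)]] else 0L
  if (a == 0L) return(NA_integer_)
  if (a == 1L) return(4L)
  M <- max(ab)
  med <- median(ab)
  if (a == M) {
    if (sum(ab == M) == 1L) 0L else 1L
  } else if (a > med) 2L else 3L
}

#' Empirical positional p-value of a cleavage signal
#'
#' The fraction of transcript positions whose category would be at least as
#' good (numerically `<=`) as the observed category; unoccupied positions
#' never qualify. A transparent positional-empirical scheme, not a
#' CleaveLand4 reproduction.
#'
#' @param profile a `degradome_profile`.
#' @param position queried transcript coordinate (must be occupied).
#' @param transcript_length denominator; defaults to the profile's length.
#' @return p-value in (0, 1].
#' @export
cleavage_pvalue <- function(profile, position,
                            transcript_length = profile$length) {
  if (transcript_length < 1L) stopf("transcript_length must be >= 1")
  obs <- assign_category(profile, position)
  if (is.na(obs)) stopf("no degradome signal at position %d", position)
  cats <- vapply(as.integer(names(profile$abundance)),
                 function(p) assign_category(profile, p), integer(1))
  sum(cats <= obs) / transcript_length
}

#' Validate target calls against degradome libraries
#'
#' For each target-verdict call and each library, maps the library onto the
#' transcript and emits cleavage evidence whenever the predicted cleavage
#' position (canonical position opposite miRNA position 10, with a 9-12
#' window fallback) carries at least one read. Evidence is kept separate per
#' library.
#'
#' @param calls list of `interaction_call` objects (verdict `"target"`
#'   entries are validated; others are ignored).
#' @param libraries list of `degradome_library` objects.
#' @param transcripts data.frame of transcript records (`id`, `sequence`).
#' @param use_window fall back to the positions opposite miRNA positions
#'   9-12 when position 10 is unpaired or silent (default `TRUE`).
#' @return data.frame of cleavage evidence (miRNA, transcript, position,
#'   category, p-value, library), plus a `profiles` attribute keyed by
#'   `library_id:transcript_id` holding the t-plot profiles.
#' @export
validate_interactions <- function(calls, libraries, transcripts,
                                  use_window = TRUE) {
  targets <- Filter(function(cl) cl$verdict == "target", calls)
  rows <- list()
  profiles <- list()
  for (cl in targets) {
    a <- cl$alignment
    idx <- match(a$transcript_id, transcripts$id)
    if (is.na(idx)) stopf("transcript %s referenced by a call but absent",
                          a$transcript_id)
    tr <- transcripts[idx, , drop = FALSE]
    for (lib in libraries) {
      key <- paste(lib$library_id, a$transcript_id, sep = ":")
      if (is.null(profiles[[key]]))
        profiles[[key]] <- map_five_prime_ends(lib, tr)
      prof <- profiles[[key]]
      if (length(prof$abundance) == 0L) next
      canonical <- tryCatch(predicted_cleavage_site(a), error = function(e) NA)
      pos <- NA_integer_
      if (!is.na(canonical) && !is.na(assign_category(prof, canonical))) {
        pos <- canonical
      } else if (use_window) {
        win <- predicted_cleavage_site(a, window = TRUE)
        occ <- win[vapply(win, function(p) !is.na(assign_category(prof, p)),
                          logical(1))]
        if (length(occ)) {
          ab <- vapply(occ, function(p)
            prof$abundance[[as.character(p)]], integer(1))
          pos <- occ[which.max(ab)]
        }
      }
      if (is.na(pos)) next
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = a$mirna_id, transcript_id = a$transcript_id,
        site_start = a$site_start, site_end = a$site_end,
        mfe_ratio = a$mfe_ratio,
        cleavage_position = pos,
        category = assign_category(prof, pos),
        p_value = cleavage_pvalue(prof, pos),
        library_id = lib$library_id, stringsAsFactors = FALSE)
    }
  }
  ev <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(0), transcript_id = character(0),
               site_start = integer(0), site_end = integer(0),
               mfe_ratio = numeric(0), cleavage_position = integer(0),
               category = integer(0), p_value = numeric(0),
               library_id = character(0))
  attr(ev, "profiles") <- profiles
  ev
}

#' Export a t-plot profile as a two-column table
#'
#' @param profile a `degradome_profile`.
#' @param mark optional position to flag in a third column.
#' @return data.frame with `position`, `abundance` (all transcript positions,
#'   zeros included) and `marked`.
#' @export
tplot_data <- function(profile, mark = NULL) {
  ab <- integer(profile$length)
  ab[as.integer(names(profile$abundance))] <- profile$abundance
  out <- data.frame(position = seq_len(profile$length), abundance = ab)
  out$marked <- if (is.null(mark)) FALSE else out$position %in% mark
  out
}
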