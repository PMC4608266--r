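# Candidate-site discovery: align the miRNA antiparallel against each
# transcript (semi-global affine DP in C++), derive per-column pair states,
# score each retained site with MFEsite/MFEperfect/MFEratio.

#' Scanning parameters
#'
#' @param mfe_ratio_cutoff minimum MFEratio retained (default 0.65; the
#'   smallest ratio in the published maize target/decoy tables is 0.6506).
#' @param max_defects_total pre-filter on total mismatches plus indels in a
#'   candidate alignment (default 10).
#' @param gu_counts_as_pair treat G:U wobbles as pairs in rule counting
#'   (default `TRUE`, the plant-target-prediction convention).
#' @param report_overlapping keep overlapping sites instead of collapsing to
#'   the best MFEratio per region (default `FALSE`).
#' @param min_score_frac alignment-score floor as a fraction of the miRNA
#'   length, used to prune DP end points before energy scoring (default 0.45).
#' @return a `scan_params` list.
#' @export
scan_params <- function(mfe_ratio_cutoff = 0.65, max_defects_total = 10L,
                        gu_counts_as_pair = TRUE, report_overlapping = FALSE,
                        min_score_frac = 0.45) {
  if (!(mfe_ratio_cutoff > 0 && mfe_ratio_cutoff <= 1))
    stopf("mfe_ratio_cutoff must be in (0, 1]")
  structure(list(mfe_ratio_cutoff = mfe_ratio_cutoff,
                 max_defects_total = as.integer(max_defects_total),
                 gu_counts_as_pair = isTRUE(gu_counts_as_pair),
                 report_overlapping = isTRUE(report_overlapping),
                 min_score_frac = min_score_frac),
            class = "scan_params")
}

new_duplex_alignment <- function(mirna_id, transcript_id, site_start, site_end,
                                 columns, mfe_site, mfe_perfect, score = NA_real_) {
  structure(list(mirna_id = mirna_id, transcript_id = transcript_id,
                 site_start = site_start, site_end = site_end,
                 columns = columns, mfe_site = mfe_site,
                 mfe_perfect = mfe_perfect,
                 mfe_ratio = mfe_ratio(mfe_site, mfe_perfect),
                 score = score),
            class = "duplex_alignment")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat(sprintf("%s ~ %s [%d-%d]  MFEsite %.2f  MFEperfect %.2f  MFEratio %.4f\n",
              x$mirna_id, x$transcript_id, x$site_start, x$site_end,
              x$mfe_site, x$mfe_perfect, x$mfe_ratio))
  cat(format_duplex_alignment(x), sep = "\n")
  invisible(x)
}

#' Render a duplex alignment as three text lines
#'
#' Target 5'->3' on top, pairing symbols (`|` Watson-Crick, `o` G:U) in the
#' middle, miRNA 3'->5' at the bottom.
#'
#' @param aln a `duplex_alignment`.
#' @return character vector of three lines.
#' @export
format_duplex_alignment <- function(aln) {
  co <- aln$columns
  top <- ifelse(co$t_pos > 0, co$t_base, "-")
  bot <- ifelse(co$mirna_pos > 0, co$mirna_base, "-")
  mid <- ifelse(co$state == "WC", "|", ifelse(co$state == "GU", "o", " "))
  c(paste0("5' ", paste(top, collapse = ""), " 3' (target)"),
    paste0("   ", paste(mid, collapse = "")),
    paste0("3' ", paste(bot, collapse = ""), " 5' (miRNA)"))
}

.make_columns <- function(mirna_seq, transcript_seq, mirna_pos, t_pos) {
  mb <- ifelse(mirna_pos > 0,
               substring(mirna_seq, mirna_pos, mirna_pos), "-")
  tb <- ifelse(t_pos > 0, substring(transcript_seq, t_pos, t_pos), "-")
  state <- character(length(mirna_pos))
  both <- mirna_pos > 0 & t_pos > 0
  state[both] <- pair_state(mb[both], tb[both])
  state[mirna_pos > 0 & t_pos == 0] <- "BULGE_MIRNA"
  state[mirna_pos == 0 & t_pos > 0] <- "BULGE_TARGET"
  data.frame(mirna_pos = mirna_pos, t_pos = t_pos, state = state,
             mirna_base = mb, t_base = tb, stringsAsFactors = FALSE)
}

.count_defects <- function(columns, gu_counts_as_pair = TRUE) {
  pair_states <- if (gu_counts_as_pair) c("WC", "GU") else "WC"
  sum(!(columns$state %in% pair_states))
}

#' Scan one transcript for candidate miRNA binding sites
#'
#' Aligns the miRNA antiparallel against the transcript (match +1, G:U +0.5,
#' mismatch -1, gap open/extend -2/-1), keeping alignments that cover every
#' miRNA position. Each candidate is scored with `hybrid_mfe()` and its
#' MFEratio; sites below `mfe_ratio_cutoff` are discarded and overlapping
#' sites are collapsed to the best ratio unless `report_overlapping`.
#'
#' @param mirna one-row miRNA record (`id`, `sequence`) or a list with those
#'   fields.
#' @param transcript one-row transcript record (`id`, `sequence`).
#' @param params a [scan_params()] object.
#' @return list of `duplex_alignment` objects sorted by MFEratio descending,
#'   ties broken by `site_start` ascending.
#' @export
scan_candidate_sites <- function(mirna, transcript, params = scan_params()) {
  mseq <- as_rna(mirna$sequence); tseq <- as_rna(transcript$sequence)
  if (!nzchar(mseq) || !nzchar(tseq)) stopf("empty sequence")
  check_rna(mseq, "miRNA"); check_rna(tseq, "transcript")
  L <- nchar(mseq)
  if (nchar(tseq) < L) stopf("transcript %s shorter than miRNA %s",
                             transcript$id, mirna$id)
  cands <- .duplex_align_cpp(mseq, tseq, 1.0, 0.5, -1.0, -2.0, -1.0,
                             params$min_score_frac * L)
  mfe_perf <- perfect_mfe(mseq)
  out <- list()
  for (cand in cands) {
    co <- .make_columns(mseq, tseq, cand$mirna_pos, cand$t_pos)
    if (.count_defects(co, params$gu_counts_as_pair) > params$max_defects_total)
      next
    if (!any(co$state %in% c("WC", "GU"))) next
    site_seq <- substring(tseq, cand$site_start, cand$site_end)
    mfe_site <- hybrid_mfe(co, mseq, site_seq, site_offset = cand$site_start)
    if (mfe_site > 0) next
    ratio <- mfe_ratio(mfe_site, mfe_perf)
    if (ratio < params$mfe_ratio_cutoff) next
    out[[length(out) + 1L]] <- new_duplex_alignment(
      mirna$id, transcript$id, cand$site_start, cand$site_end, co,
      mfe_site, mfe_perf, score = cand$score)
  }
  if (length(out) == 0L) return(out)
  ord <- order(-vapply(out, `[[`, numeric(1), "mfe_ratio"),
               vapply(out, `[[`, integer(1), "site_start"))
  out <- out[ord]
  if (!params$report_overlapping) {
    kept <- list()
    for (aln in out) {
      overlaps <- any(vapply(kept, function(k)
        aln$site_start <= k$site_end && k$site_start <= aln$site_end,
        logical(1)))
      if (!overlaps) kept[[length(kept) + 1L]] <- aln
    }
    out <- kept
  }
  out
}

#' Scan every miRNA against every transcript
#'
#' @param mirnas data.frame of miRNA records (`id`, `sequence`).
#' @param transcripts data.frame of transcript records (`id`, `sequence`,
#'   optional `biotype`).
#' @param params a [scan_params()] object.
#' @return flat list of `duplex_alignment` objects; each carries the
#'   transcript biotype in `$biotype` when provided.
#' @export
scan_transcriptome <- function(mirnas, transcripts, params = scan_params()) {
  out <- list()
  for (i in seq_len(nrow(mirnas))) {
    mi <- mirnas[i, , drop = FALSE]
    if (nchar(mi$sequence) < 1L) stopf("empty miRNA sequence: %s", mi$id)
    for (j in seq_len(nrow(transcripts))) {
      tr <- transcripts[j, , drop = FALSE]
      if (nchar(tr$sequence) < nchar(mi$sequence)) next
      alns <- scan_candidate_sites(mi, tr, params)
      for (a in alns) {
        if (!is.null(transcripts$biotype)) a$biotype <- tr$biotype
        out[[length(out) + 1L]] <- a
      }
    }
  }
  out
}

#' Tabulate duplex alignments
#'
#' One row per alignment, mirroring the published target/decoy table columns.
#'
#' @param alignments list of `duplex_alignment` objects.
#' @return data.frame with miRNA id, transcript id, site, MFE columns and the
#'   rendered alignment string.
#' @export
alignment_table <- function(alignments) {
  if (length(alignments) == 0L)
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      site_start = integer(0), site_end = integer(0),
                      mfe_perfect = numeric(0), mfe_site = numeric(0),
                      mfe_ratio = numeric(0), alignment = character(0)))
  do.call(rbind, lapply(alignments, function(a) data.frame(
    mirna_id = a$mirna_id, transcript_id = a$transcript_id,
    site_start = a$site_start, site_end = a$site_end,
    mfe_perfect = a$mfe_perfect, mfe_site = a$mfe_site,
    mfe_ratio = a$mfe_ratio,
    alignment = paste(format_duplex_alignment(a), collapse = " / "),
    stringsAsFactors = FALSE)))
}
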