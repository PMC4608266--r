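# Target/decoy rule engine. A duplex alignment is classified from region
# diagnostics over miRNA positions (position 1 = miRNA 5' end):
#   target: <= 1 mismatch/indel at positions 9-12, <= 4 defects elsewhere,
#           no two consecutive mismatch columns anywhere;
#   decoy:  2-5 mismatches/indels at positions 9-12, perfect pairing at
#           positions 2-8 with no adjacent indel, <= 4 defects at positions
#           1 and 13..L.

#' Region diagnostics of a duplex alignment
#'
#' Assigns every defect column to a miRNA-position region. A mismatch or
#' bulged miRNA base at position i belongs to the region containing i; an
#' unpaired transcript base between miRNA positions i and i+1 belongs to the
#' region containing i (the 5'-ward flank).
#'
#' @param alignment a `duplex_alignment`.
#' @param gu_counts_as_pair treat G:U as a pair (default `TRUE`); otherwise
#'   wobble columns count as mismatches everywhere, including run length.
#' @return a `region_diagnostics` list with `defects_9_12`, `perfect_2_8`,
#'   `defects_other_target`, `defects_other_decoy`, `max_mismatch_run`.
#' @export
region_diagnostics <- function(alignment, gu_counts_as_pair = TRUE) {
  co <- alignment$columns
  L <- max(co$mirna_pos)
  state <- co$state
  if (!gu_counts_as_pair) state[state == "GU"] <- "MISMATCH"
  # assigned miRNA position per column; bulged transcript bases take the
  # 5'-ward flanking position (the smaller of the two neighbors)
  assigned <- co$mirna_pos
  n <- length(assigned)
  for (k in which(assigned == 0L)) {
    right <- k + 1L
    while (right <= n && assigned[right] == 0L) right <- right + 1L
    if (right <= n) assigned[k] <- assigned[right]       # transcript-ascending
    else {
      left <- k - 1L
      while (left >= 1L && assigned[left] == 0L) left <- left - 1L
      assigned[k] <- max(assigned[left] - 1L, 1L)
    }
  }
  defect <- state %in% c("MISMATCH", "BULGE_MIRNA", "BULGE_TARGET")
  central <- assigned >= 9L & assigned <= 12L
  d912 <- sum(defect & central)
  other_t <- sum(defect & !central)
  other_d <- sum(defect & (assigned == 1L | assigned >= 13L))
  p28 <- !any(defect & state != "BULGE_TARGET" & assigned >= 2L & assigned <= 8L) &&
         !any(state == "BULGE_TARGET" & assigned >= 1L & assigned <= 8L)
  runs <- rle(state == "MISMATCH")
  max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  structure(list(defects_9_12 = d912, perfect_2_8 = p28,
                 defects_other_target = other_t,
                 defects_other_decoy = other_d,
                 max_mismatch_run = as.integer(max_run)),
            class = "region_diagnostics")
}

#' Classify a duplex as miRNA target, decoy, or neither
#'
#' Pure function of the diagnostics; target and decoy are disjoint because of
#' the central-defect thresholds (<= 1 vs >= 2).
#'
#' @param diag a [region_diagnostics()] result.
#' @return an `interaction_call` with `verdict` in
#'   `c("target", "decoy", "none")` and the diagnostics attached.
#' @export
classify_interaction <- function(diag) {
  verdict <- if (diag$defects_9_12 <= 1L &&
                 diag$defects_other_target <= 4L &&
                 diag$max_mismatch_run <= 1L) "target"
  else if (diag$defects_9_12 >= 2L && diag$defects_9_12 <= 5L &&
           isTRUE(diag$perfect_2_8) &&
           diag$defects_other_decoy <= 4L) "decoy"
  else "none"
  structure(list(verdict = verdict, diagnostics = diag),
            class = "interaction_call")
}

#' Classify a list of scanned alignments
#'
#' @param alignments list of `duplex_alignment` objects (e.g. from
#'   [scan_transcriptome()]).
#' @param gu_counts_as_pair passed to [region_diagnostics()].
#' @param drop_none drop alignments classified as neither (default `TRUE`).
#' @return list of `interaction_call` objects, each carrying `$alignment` and
#'   `$biotype` (when present on the alignment).
#' @export
classify_alignments <- function(alignments, gu_counts_as_pair = TRUE,
                                drop_none = TRUE) {
  calls <- lapply(alignments, function(a) {
    call <- classify_interaction(region_diagnostics(a, gu_counts_as_pair))
    call$alignment <- a
    call$biotype <- a$biotype %||% NA_character_
    call
  })
  if (drop_none)
    calls <- Filter(function(cl) cl$verdict != "none", calls)
  calls
}

#' Tabulate interaction calls
#'
#' @param calls list of `interaction_call` objects with attached alignments.
#' @return data.frame of verdicts and diagnostics, one row per call.
#' @export
call_table <- function(calls) {
  if (length(calls) == 0L)
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      site_start = integer(0), site_end = integer(0),
                      verdict = character(0), defects_9_12 = integer(0),
                      defects_other = integer(0), max_mismatch_run = integer(0),
                      mfe_ratio = numeric(0)))
  do.call(rbind, lapply(calls, function(cl) {
    a <- cl$alignment; d <- cl$diagnostics
    data.frame(mirna_id = a$mirna_id, transcript_id = a$transcript_id,
               site_start = a$site_start, site_end = a$site_end,
               verdict = cl$verdict, defects_9_12 = d$defects_9_12,
               defects_other = if (cl$verdict == "decoy") d$defects_other_decoy
                               else d$defects_other_target,
               max_mismatch_run = d$max_mismatch_run,
               mfe_ratio = a$mfe_ratio, stringsAsFactors = FALSE)
  }))
}

#' Exhaustive defect-placement rule table
#'
#' Enumerates every placement of up to `max_defects` defects (mismatch,
#' bulged miRNA base, bulged transcript base; one per miRNA position) on an
#' `L`-nt duplex and returns the distinct region-diagnostics tuples with an
#' independently coded clause-checker verdict and the number of placements
#' mapping to each tuple. Used by the acceptance suite to prove rule-engine
#' equivalence over the full enumeration.
#'
#' @param L miRNA length (default 21).
#' @param max_defects maximum number of defects (default 6).
#' @return data.frame of distinct tuples with `oracle_target`,
#'   `oracle_decoy` and `count` columns.
#' @export
enumerate_defect_rules <- function(L = 21L, max_defects = 6L) {
  .enum_defect_rule_table_cpp(as.integer(L), as.integer(max_defects))
}
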