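# Nearest-neighbor RNA/RNA hybridization energy for miRNA-transcript duplexes.
#
# Stacking terms are Turner-lineage RNA/RNA free energies at 37 C (Watson-Crick
# stacks after Xia et al. 1998, wobble-containing stacks after Mathews et al.
# 1999); the two destabilizing wobble-wobble motifs are clamped to zero so
# that removing a stack can never lower the duplex energy. Loop penalties are
# simplified length-dependent terms (see the methods vignette). Exact equality
# with RNAhybrid output is explicitly not a goal; the MFEratio arithmetic and
# ordering properties are.

PAIR_LEVELS <- c("AU", "UA", "CG", "GC", "GU", "UG")

.stack_table <- local({
  st <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_LEVELS, PAIR_LEVELS))
  # 5'-XY-3' / 3'-WZ-5' stack = st["XW", "YZ"]
  vals <- c(
    "AU AU -0.93", "AU UA -1.10", "UA AU -1.33", "UA UA -0.93",
    "CG AU -2.11", "CG UA -2.08", "GC AU -2.35", "GC UA -2.24",
    "AU CG -2.24", "AU GC -2.08", "UA CG -2.35", "UA GC -2.11",
    "CG CG -3.26", "CG GC -2.36", "GC CG -3.42", "GC GC -3.26",
    "AU GU -0.55", "AU UG -1.36", "CG GU -1.41", "CG UG -2.11",
    "GC GU -1.53", "GC UG -2.51", "UA GU -1.27", "UA UG -1.00",
    "GU AU -1.00", "GU UA -1.36", "GU CG -2.51", "GU GC -2.11",
    "UG AU -1.27", "UG UA -0.55", "UG CG -1.53", "UG GC -1.41",
    "GU GU  0.00", "UG UG  0.00", "GU UG -0.50", "UG GU  0.00"
  )
  for (v in vals) {
    f <- strsplit(v, " +")[[1]]
    st[f[1], f[2]] <- as.numeric(f[3])
  }
  st
})

DUPLEX_INIT <- 4.09       # duplex initiation, kcal/mol
TERMINAL_AU <- 0.45       # per terminal A:U or G:U closing pair

.bulge_penalty <- function(len) {
  base <- c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4)
  if (len <= 6L) base[len] else base[6] + 1.75 * log(len / 6)
}

.internal_penalty <- function(side1, side2) {
  s <- side1 + side2
  base <- c(1.5, 1.9, 2.2, 2.5, 2.8)     # sizes 2..6
  init <- if (s <= 6L) base[s - 1L] else base[5] + 1.75 * log(s / 6)
  init + 0.5 * min(abs(side1 - side2), 3L)
}

.pair_key <- function(mirna_base, target_base) paste0(mirna_base, target_base)

#' Nearest-neighbor hybridization free energy of a duplex alignment
#'
#' Sums stacking terms over adjacent paired columns (Watson-Crick and G:U),
#' adds the duplex initiation penalty, terminal A:U/G:U penalties, and
#' length-dependent penalties for mismatches, internal loops and bulges.
#' More negative values mean a more stable duplex. Deterministic.
#'
#' @param columns alignment column data.frame with `mirna_pos`, `t_pos`,
#'   `state` (as stored in a `duplex_alignment`), ordered 5'->3' along the
#'   transcript.
#' @param mirna_seq miRNA sequence 5'->3' (RNA).
#' @param site_seq transcript site sequence 5'->3' (RNA), covering the
#'   transcript positions referenced by `columns`.
#' @param site_offset transcript coordinate of the first base of `site_seq`
#'   (defaults to the smallest `t_pos` in `columns`).
#' @return free energy in kcal/mol.
#' @export
hybrid_mfe <- function(columns, mirna_seq, site_seq, site_offset = NULL) {
  if (is.null(site_offset)) site_offset <- min(columns$t_pos[columns$t_pos > 0])
  # walk in miRNA 5'->3' order (reverse of transcript order)
  cols <- columns[rev(seq_len(nrow(columns))), , drop = FALSE]
  mb <- ifelse(cols$mirna_pos > 0,
               substring(mirna_seq, cols$mirna_pos, cols$mirna_pos), "")
  tb <- ifelse(cols$t_pos > 0,
               substring(site_seq, cols$t_pos - site_offset + 1L,
                         cols$t_pos - site_offset + 1L), "")
  paired <- which(cols$state %in% c("WC", "GU"))
  if (length(paired) == 0L) stopf("alignment has no paired columns")
  e <- DUPLEX_INIT
  keys <- .pair_key(mb[paired], tb[paired])
  for (k in keys[c(1, length(keys))])
    if (k %in% c("AU", "UA", "GU", "UG")) e <- e + TERMINAL_AU
  if (length(paired) > 1L) {
    for (idx in seq_len(length(paired) - 1L)) {
      i <- paired[idx]; k <- paired[idx + 1L]
      if (k == i + 1L) {
        e <- e + .stack_table[keys[idx], keys[idx + 1L]]
      } else {
        between <- cols$state[(i + 1L):(k - 1L)]
        n_mm <- sum(between == "MISMATCH")
        n_bm <- sum(between == "BULGE_MIRNA")
        n_bt <- sum(between == "BULGE_TARGET")
        side_m <- n_mm + n_bm
        side_t <- n_mm + n_bt
        e <- e + if (side_m == 0L || side_t == 0L)
          .bulge_penalty(max(side_m, side_t))
        else
          .internal_penalty(side_m, side_t)
      }
    }
  }
  e
}

#' Free energy of a perfectly matched site (MFEperfect)
#'
#' The hybridization energy of a miRNA against its exact reverse complement:
#' the denominator of the MFEratio. Strictly negative for valid miRNAs.
#'
#' @param mirna_seq miRNA sequence 5'->3' (RNA), or a one-row miRNA record.
#' @return free energy in kcal/mol (< 0).
#' @export
perfect_mfe <- function(mirna_seq) {
  if (is.list(mirna_seq)) mirna_seq <- mirna_seq$sequence
  check_rna(mirna_seq, "miRNA sequence")
  L <- nchar(mirna_seq)
  cols <- data.frame(mirna_pos = L:1, t_pos = seq_len(L),
                     state = "WC", stringsAsFactors = FALSE)
  site <- rna_revcomp(mirna_seq)
  e <- hybrid_mfe(cols, mirna_seq, site, site_offset = 1L)
  if (e >= 0) stopf("perfect-site energy is non-negative; sequence too short?")
  e
}

#' MFEratio of a binding site
#'
#' `MFEsite / MFEperfect`, the site-quality statistic printed in published
#' target and decoy tables. Full floating precision is retained.
#'
#' @param mfe_site site hybridization energy (kcal/mol, <= 0).
#' @param mfe_perfect perfect-site energy (kcal/mol, < 0).
#' @return dimensionless ratio in (0, 1] for admissible sites.
#' @export
mfe_ratio <- function(mfe_site, mfe_perfect) {
  if (any(mfe_perfect >= 0)) stopf("mfe_perfect must be negative")
  if (any(mfe_site > 0)) stopf("mfe_site must be <= 0")
  mfe_site / mfe_perfect
}
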