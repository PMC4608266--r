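# Shared fixture builders. Everything is generated in code; no stored data.

fixture_mirna <- function(seq = "UGGAAGCUGUGAAGCUGCCUG", id = "miR-fix") {
  list(id = id, sequence = seq)
}

# transcript with the miRNA's perfect site implanted at a known position
fixture_perfect_transcript <- function(mirna, at = 50L, len = 200L,
                                       seed = 7L, id = "tx-fix") {
  bg <- with_seed(seed, paste(sample(c("A", "C", "G", "U"), len, TRUE),
                              collapse = ""))
  imp <- implant_site(bg, mirna, NULL, at, transcript_id = id)
  list(transcript = list(id = id, sequence = imp$sequence),
       truth = imp$truth)
}

# build a duplex_alignment directly from a defect placement on a perfect
# duplex (no scanning involved) -- used to unit-test the rule engine
fixture_alignment_from_spec <- function(mirna_seq, defect_spec, bg_seed = 101L) {
  mirna <- list(id = "m", sequence = mirna_seq)
  bg <- random_rna_string(60L, bg_seed)
  imp <- implant_site(bg, mirna, defect_spec, position = 20L,
                      transcript_id = "t")
  tr <- list(id = "t", sequence = imp$sequence)
  alns <- scan_candidate_sites(mirna, tr,
                               scan_params(mfe_ratio_cutoff = 0.05,
                                           report_overlapping = TRUE))
  stopifnot(length(alns) >= 1L)
  starts <- vapply(alns, `[[`, integer(1), "site_start")
  alns[[which.min(abs(starts - imp$truth$site_start))]]
}

# naive affine-gap global alignment score of pattern vs window (oracle)
oracle_nw_affine <- function(pat, win, match = 1, gu = 0.5, mismatch = -1,
                             gap_open = -2, gap_ext = -1) {
  # pat: miRNA positions L..1 along the window (antiparallel)
  m <- length(pat); n <- length(win)
  NEG <- -1e9
  M <- matrix(NEG, m + 1L, n + 1L)
  X <- matrix(NEG, m + 1L, n + 1L)   # gap in pattern (target bulge)
  Y <- matrix(NEG, m + 1L, n + 1L)   # gap in window (miRNA bulge)
  M[1, 1] <- 0
  for (i in 1:(m + 1L)) for (j in 1:(n + 1L)) {
    if (i > 1L && j > 1L) {
      s <- pair_state(pat[i - 1L], win[j - 1L])
      sc <- if (s == "WC") match else if (s == "GU") gu else mismatch
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + sc
    }
    if (j > 1L)
      X[i, j] <- max(M[i, j - 1L] + gap_open, X[i, j - 1L] + gap_ext,
                     Y[i, j - 1L] + gap_open)
    if (i > 1L)
      Y[i, j] <- max(M[i - 1L, j] + gap_open, Y[i - 1L, j] + gap_ext,
                     X[i - 1L, j] + gap_open)
  }
  # the window's terminal bases must be aligned (no terminal target bulge)
  max(M[m + 1L, n + 1L], Y[m + 1L, n + 1L])
}

# best site score over all windows: oracle for the semi-global scan DP
oracle_best_window <- function(mirna_seq, transcript_seq, slack = 4L) {
  mb <- rev(strsplit(mirna_seq, "")[[1]])   # positions L..1 along transcript
  tb <- strsplit(transcript_seq, "")[[1]]
  L <- length(mb); n <- length(tb)
  best <- -Inf; best_win <- c(NA, NA)
  for (w in max(1L, L - slack):(L + slack)) {
    if (w > n) next
    for (s in 1:(n - w + 1L)) {
      sc <- oracle_nw_affine(mb, tb[s:(s + w - 1L)])
      if (sc > best) { best <- sc; best_win <- c(s, s + w - 1L) }
    }
  }
  list(score = best, site = best_win)
}

random_rna_string <- function(n, seed) {
  with_seed(seed, paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = ""))
}
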