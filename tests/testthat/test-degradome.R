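test_that("preprocessing clips adapters, filters, and deduplicates", {
  read20 <- random_rna_string(20, 1)
  lib <- preprocess_degradome(c(rep(read20, 3), random_rna_string(10, 2)))
  expect_length(lib$unique_reads, 1L)
  expect_equal(unname(lib$unique_reads[read20]), 3L)

  # 30-nt read = 20-nt insert + adapter; clipped at the adapter prefix
  adapter <- "UCGUAUGCCGUCUUCUGCUUG"
  insert <- random_rna_string(20, 3)
  raw <- paste0(insert, substr(adapter, 1, 10))
  lib2 <- preprocess_degradome(raw, adapter = adapter)
  expect_equal(names(lib2$unique_reads), insert)

  expect_length(preprocess_degradome(character(0))$unique_reads, 0L)
  expect_error(preprocess_degradome("ACGU", min_len = 0), "min_len")

  # N-fraction filter
  noisy <- paste0(substr(read20, 1, 15), "NNNNN")   # 25% N
  expect_length(preprocess_degradome(c(read20, noisy))$unique_reads, 1L)
})

test_that("FASTA and FASTQ degradome reads load identically", {
  reads <- vapply(1:5, function(i) random_rna_string(20, i), character(1))
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(as.vector(rbind(paste0(">r", 1:5), chartr("U", "T", reads))), fa)
  fq <- withr::local_tempfile(fileext = ".fq")
  writeLines(as.vector(rbind(paste0("@r", 1:5), chartr("U", "T", reads), "+",
                             strrep("I", 20))), fq)
  expect_equal(sort(read_degradome_reads(fa)), sort(reads))
  expect_equal(sort(read_degradome_reads(fq)), sort(reads))
})

test_that("5'-end mapping counts every exact occurrence", {
  tx <- list(id = "t", sequence = random_rna_string(300, 10))
  read <- substr(tx$sequence, 61, 80)
  lib <- preprocess_degradome(rep(read, 5))
  prof <- map_five_prime_ends(lib, tx)
  expect_equal(unname(prof$abundance[["61"]]), 5L)

  # multi-mapping read counted at each occurrence; conservation of mass
  for (seed in 1:4) {
    tx2 <- list(id = "t2",
                sequence = paste0(random_rna_string(60, seed),
                                  strrep(substr(random_rna_string(40, seed + 50),
                                                1, 25), 2)))
    reads <- c(substr(tx2$sequence, 61, 80), substr(tx2$sequence, 10, 29),
               random_rna_string(20, seed + 99))
    lib2 <- preprocess_degradome(rep(reads, times = c(4, 2, 1)))
    prof2 <- map_five_prime_ends(lib2, tx2)
    # oracle: quadratic all-positions substring scan
    want <- integer(0)
    for (r in names(lib2$unique_reads)) {
      w <- nchar(r)
      for (p in seq_len(nchar(tx2$sequence) - w + 1L)) {
        if (substr(tx2$sequence, p, p + w - 1L) == r) {
          key <- as.character(p)
          want[key] <- (if (key %in% names(want)) want[[key]] else 0L) +
            lib2$unique_reads[[r]]
        }
      }
    }
    want <- want[order(as.integer(names(want)))]
    expect_identical(prof2$abundance, want)
    expect_equal(sum(prof2$abundance),
                 sum(vapply(names(lib2$unique_reads), function(r) {
                   hits <- length(Biostrings::matchPattern(r, tx2$sequence))
                   hits * lib2$unique_reads[[r]]
                 }, integer(1))))
  }
})

test_that("predicted cleavage position reads off the paired coordinate", {
  mir21 <- fixture_mirna()
  fix <- fixture_perfect_transcript(mir21, at = 50L)
  a <- scan_candidate_sites(mir21, fix$transcript)[[1]]
  expect_equal(predicted_cleavage_site(a), a$site_end - 9L)   # 61
  expect_equal(predicted_cleavage_site(a, window = TRUE), 59:62)

  # 22-nt miRNA, perfect site at 100-121 -> 112
  mir22 <- list(id = "m22", sequence = paste0(mir21$sequence, "A"))
  bg <- random_rna_string(300, 21)
  imp <- implant_site(bg, mir22, NULL, 100L, "t")
  a22 <- scan_candidate_sites(mir22, list(id = "t", sequence = imp$sequence))[[1]]
  expect_equal(a22$site_start, 100L)
  expect_equal(predicted_cleavage_site(a22), 112L)

  # a target bulge 5' of position 10 shifts the coordinate by one,
  # matching a direct column walk
  spec <- data.frame(pos = 12L, type = "BULGE_TARGET")
  imp2 <- implant_site(bg, mir21, spec, 100L, "t")
  ab <- scan_candidate_sites(mir21, list(id = "t", sequence = imp2$sequence),
                             scan_params(report_overlapping = TRUE))
  starts <- vapply(ab, `[[`, integer(1), "site_start")
  a2 <- ab[[which(starts == 100L)[1]]]
  col_walk <- a2$columns$t_pos[a2$columns$mirna_pos == 10L]
  expect_equal(predicted_cleavage_site(a2), col_walk)
  expect_equal(predicted_cleavage_site(a2), 112L)  # one more than 100-120 site

  # unpaired position 10 errors and suggests the window
  a3 <- list(columns = data.frame(mirna_pos = c(11L, 10L, 9L),
                                  t_pos = c(30L, 0L, 31L),
                                  state = c("WC", "BULGE_MIRNA", "WC")))
  expect_error(predicted_cleavage_site(a3), "window")
  expect_equal(predicted_cleavage_site(a3, window = TRUE), c(30L, 31L))
})

test_that("categories follow the definition (with a literal oracle)", {
  mkprof <- function(ab, len = 100L)
    structure(list(transcript_id = "t", length = len,
                   abundance = setNames(as.integer(ab), names(ab))),
              class = "degradome_profile")
  expect_equal(assign_category(mkprof(c("61" = 1)), 61), 4L)
  expect_equal(assign_category(mkprof(c("61" = 5, "20" = 3, "90" = 1)), 61), 0L)
  p <- mkprof(c("61" = 3, "20" = 3, "90" = 1))
  expect_equal(assign_category(p, 61), 1L)
  expect_equal(assign_category(p, 90), 4L)
  expect_true(is.na(assign_category(p, 50)))
  expect_error(assign_category(mkprof(integer(0)), 10), "empty")

  oracle_cat <- function(ab, pos) {
    a <- if (as.character(pos) %in% names(ab)) ab[[as.character(pos)]] else 0L
    if (a == 0) return(NA_integer_)
    if (a == 1) return(4L)
    M <- max(ab); med <- median(ab)
    if (a == M && sum(ab == M) == 1) 0L
    else if (a == M) 1L
    else if (a > med) 2L else 3L
  }
  set.seed(77)
  for (rep in 1:200) {
    k <- sample(1:12, 1)
    ab <- setNames(sample(1:9, k, TRUE), sample(100, k))
    prof <- mkprof(ab)
    pos <- sample(100, 1)
    expect_identical(assign_category(prof, pos), oracle_cat(ab, pos))
  }
})

test_that("empirical p-values are positional fractions and monotone", {
  mkprof <- function(ab, len = 100L)
    structure(list(transcript_id = "t", length = len,
                   abundance = setNames(as.integer(ab), names(ab))),
              class = "degradome_profile")
  # all reads at one position, length 100, category 0 -> 1/100
  expect_equal(cleavage_pvalue(mkprof(c("61" = 8)), 61), 0.01)
  # every position holds exactly one read -> category 4 everywhere, p = 1
  full <- mkprof(setNames(rep(1L, 50), 1:50), len = 50L)
  expect_equal(cleavage_pvalue(full, 25), 1.0)
  # monotone: better category never has a larger qualifying count
  p <- mkprof(c("10" = 6, "20" = 3, "30" = 3, "40" = 1))
  cats <- c(`10` = 0L, `20` = 2L, `30` = 2L, `40` = 4L)
  qual <- vapply(c(10, 20, 30, 40), function(pos)
    cleavage_pvalue(p, pos) * p$length, numeric(1))
  expect_true(all(diff(qual[order(cats)]) >= 0))
  expect_error(cleavage_pvalue(p, 10, transcript_length = 0), ">= 1")
  expect_error(cleavage_pvalue(p, 55), "no degradome signal")
})

test_that("validate_interactions emits per-library evidence at planted peaks", {
  mirs <- gen_mirnas(4, seed = 21)
  sim <- gen_transcriptome(4, 2, mirs, n_target = 3, n_decoy = 0, seed = 22)
  calls <- classify_alignments(scan_transcriptome(mirs, sim$transcripts))
  libA <- gen_degradome(sim$truths, sim$transcripts, seed = 23,
                        library_id = "libA")
  ev <- validate_interactions(calls, list(libA), sim$transcripts)
  planted <- Filter(function(t) t$kind == "target_site", sim$truths)
  for (t in planted) {
    row <- ev[ev$mirna_id == t$mirna_id & ev$transcript_id == t$transcript_id, ]
    expect_equal(nrow(row), 1L)
    expect_equal(row$cleavage_position, t$cleavage_position)
    expect_equal(row$category, 0L)
    expect_equal(row$library_id, "libA")
  }
  # a library with no reads on these transcripts yields no evidence
  libB <- preprocess_degradome(random_rna_string(20, 999), library_id = "libB")
  ev2 <- validate_interactions(calls, list(libA, libB), sim$transcripts)
  expect_true(all(ev2$library_id == "libA"))
  # missing transcript errors
  expect_error(validate_interactions(calls, list(libA),
                                     sim$transcripts[0, ]), "absent")
  # t-plot export covers the whole transcript
  prof <- attr(ev, "profiles")[[1]]
  tp <- tplot_data(prof, mark = 5L)
  expect_equal(nrow(tp), prof$length)
  expect_equal(sum(tp$abundance), sum(prof$abundance))
})
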