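test_that("miRNA generation is deterministic with valid lengths and ids", {
  a <- gen_mirnas(10, seed = 5)
  b <- gen_mirnas(10, seed = 5)
  expect_identical(a, b)
  expect_equal(anyDuplicated(a$id), 0L)
  lens <- nchar(gen_mirnas(300, seed = 6)$sequence)
  expect_true(all(lens >= 20 & lens <= 22))
  expect_error(gen_mirnas(0), ">= 1")
  expect_error(gen_mirnas(3, length_range = c(25, 20)), "length_range")
})

test_that("implant_site constructs rule-conformant sites with truth", {
  mir <- fixture_mirna()
  bg <- random_rna_string(200, 44)

  # 0-defect implant scans and classifies as target
  imp <- implant_site(bg, mir, NULL, 80L, "t")
  expect_equal(imp$truth$verdict, "target")
  expect_equal(imp$truth$cleavage_position, imp$truth$site_end - 9L)
  a <- scan_candidate_sites(mir, list(id = "t", sequence = imp$sequence))[[1]]
  expect_equal(a$site_start, imp$truth$site_start)

  # central mismatches at 10 and 11 with untouched 2-8 give a decoy
  imp2 <- implant_site(bg, mir, data.frame(pos = c(10L, 11L),
                                           type = "MISMATCH"), 80L, "t")
  expect_equal(imp2$truth$verdict, "decoy")

  # a 3-nt bulge at one junction is three central defects
  imp3 <- implant_site(bg, mir, data.frame(pos = rep(10L, 3),
                                           type = "BULGE_TARGET"), 80L, "t")
  expect_equal(imp3$truth$verdict, "decoy")
  expect_equal(imp3$truth$site_end - imp3$truth$site_start + 1L,
               nchar(mir$sequence) + 3L)

  expect_error(implant_site(bg, mir, data.frame(pos = c(5L, 5L),
                                                type = c("MISMATCH",
                                                         "BULGE_MIRNA")), 10),
               "conflicting")
  expect_error(implant_site(bg, mir, data.frame(pos = 21L,
                                                type = "BULGE_TARGET"), 10),
               "3'")
})

test_that("random rule-conformant implants are recovered end-to-end", {
  n_ok <- 0L; n_all <- 0L
  for (seed in 1:3) {
    mirs <- gen_mirnas(6, seed = seed * 7)
    sim <- gen_transcriptome(8, 8, mirs, n_target = 5, n_decoy = 5,
                             seed = seed * 7 + 1)
    calls <- classify_alignments(scan_transcriptome(mirs, sim$transcripts))
    tab <- call_table(calls)
    for (t in sim$truths) {
      n_all <- n_all + 1L
      hit <- tab[tab$mirna_id == t$mirna_id &
                 tab$transcript_id == t$transcript_id &
                 tab$site_start == t$site_start &
                 tab$site_end == t$site_end &
                 tab$verdict == t$verdict, ]
      n_ok <- n_ok + (nrow(hit) == 1L)
    }
  }
  expect_equal(n_ok, n_all)
})

test_that("transcriptome generation is deterministic and capacity-checked", {
  mirs <- gen_mirnas(3, seed = 1)
  s1 <- gen_transcriptome(5, 5, mirs, n_target = 2, n_decoy = 2, seed = 9)
  s2 <- gen_transcriptome(5, 5, mirs, n_target = 2, n_decoy = 2, seed = 9)
  expect_identical(s1$transcripts, s2$transcripts)
  expect_equal(length(s1$truths), 4L)
  expect_error(gen_transcriptome(2, 2, mirs, n_target = 3, n_decoy = 3),
               "capacity")
  # background-only transcripts carry no accidental site at the 0.65 floor
  s3 <- gen_transcriptome(6, 6, mirs, seed = 10)
  alns <- scan_transcriptome(mirs, s3$transcripts)
  expect_length(alns, 0L)
})

test_that("degradome generation plants dominant peaks", {
  mirs <- gen_mirnas(4, seed = 2)
  sim <- gen_transcriptome(6, 6, mirs, n_target = 4, n_decoy = 0, seed = 3)
  lib <- gen_degradome(sim$truths, sim$transcripts, peak_reads = 10,
                       seed = 4)
  lib_b <- gen_degradome(sim$truths, sim$transcripts, peak_reads = 10,
                         seed = 4)
  expect_identical(lib$unique_reads, lib_b$unique_reads)
  for (t in Filter(function(x) x$kind == "target_site", sim$truths)) {
    tr <- sim$transcripts[match(t$transcript_id, sim$transcripts$id), ]
    prof <- map_five_prime_ends(lib, tr)
    key <- as.character(t$cleavage_position)
    expect_gte(prof$abundance[[key]], 10L)
    expect_equal(assign_category(prof, t$cleavage_position), 0L)
  }
  expect_error(gen_degradome(list(), sim$transcripts), "no target_site")
})

test_that("expression modules hit the requested correlation", {
  modules <- list(m1 = paste0("a", 1:6), m2 = paste0("b", 1:6))
  ex <- gen_expression_with_modules(300, 30, modules, r_target = 0.9,
                                    seed = 15)
  expect_identical(ex$matrix,
                   gen_expression_with_modules(300, 30, modules,
                                               r_target = 0.9,
                                               seed = 15)$matrix)
  expect_true(all(ex$matrix >= 0))
  cors <- cor(t(ex$matrix[paste0("a", 1:6), ]))
  within <- cors[upper.tri(cors)]
  expect_lt(abs(mean(within) - 0.9), 0.1)
  cross <- cor(t(ex$matrix[c(paste0("a", 1:3), paste0("b", 1:3)), ]))
  expect_lt(abs(mean(cross[1:3, 4:6])), 0.35)
  expect_error(gen_expression_with_modules(10, 3), ">= 4")
  expect_error(gen_expression_with_modules(10, 30,
                                           list(x = "g1", y = "g1")),
               "disjoint")
})

test_that("GO annotation generation marks modules and respects rates", {
  genes <- paste0("g", 1:500)
  anno <- gen_go_annotations(genes,
                             module_genes = list(m = genes[1:10]),
                             module_terms = c(m = "GO:M"),
                             background_rate = 0.02, seed = 16)
  expect_true(all(vapply(genes[1:10], function(g)
    "GO:M" %in% anno$gene_terms[[g]], logical(1))))
  # background term rate within loose binomial bounds
  bg_hits <- sum(vapply(anno$gene_terms, function(t)
    "GO:BG0001" %in% t, logical(1)))
  expect_true(bg_hits >= 1 && bg_hits <= 30)
  expect_identical(anno$universe,
                   gen_go_annotations(genes,
                                      module_genes = list(m = genes[1:10]),
                                      module_terms = c(m = "GO:M"),
                                      seed = 16)$universe)
  expect_error(gen_go_annotations(genes,
                                  module_genes = list(a = "g1", b = "g2"),
                                  module_terms = c(a = "GO:X", b = "GO:X")),
               "collision")
})

test_that("ortholog windows diverge at the requested rates", {
  win <- random_rna_string(100, 17)
  orth <- gen_ortholog_windows(win, 8, c(40, 60), seed = 18)
  expect_identical(orth, gen_ortholog_windows(win, 8, c(40, 60), seed = 18))
  site_ident <- vapply(orth[-1], function(s) {
    a <- strsplit(s, "")[[1]][40:60]
    b <- strsplit(win, "")[[1]][40:60]
    mean(a == b)
  }, numeric(1))
  flank_ident <- vapply(orth[-1], function(s) {
    a <- strsplit(s, "")[[1]][-(40:60)]
    b <- strsplit(win, "")[[1]][-(40:60)]
    mean(a == b)
  }, numeric(1))
  expect_gt(mean(site_ident), 0.9)     # 1 - 0.05, binomial noise allowed
  expect_lt(mean(flank_ident), 0.7)    # 1 - 0.40
  expect_error(gen_ortholog_windows(win, 2, c(0, 10)), "offsets")
  expect_error(gen_ortholog_windows(win, 2, c(10, 20), site_divergence = 2),
               "\\[0, 1\\]")
})
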