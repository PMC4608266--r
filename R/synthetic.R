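# Synthetic-data generators: fully self-contained inputs with known truth for
# every pipeline stage. All generators are pure functions of (parameters,
# seed); backgrounds are uniform over {A,C,G,U} (no GC-skew modeling), which
# is sufficient for rule and statistics testing.

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so generators are pure
#' functions of (parameters, seed).
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

.random_rna <- function(n_bases) {
  paste(sample(RNA_BASES, n_bases, replace = TRUE), collapse = "")
}

#' Generate synthetic mature miRNAs
#'
#' Uniform random RNA sequences with ids `syn-miR-0001`, ... Deterministic
#' given the seed.
#'
#' @param n number of miRNAs (>= 1).
#' @param length_range inclusive length range, default `c(20, 22)`.
#' @param seed RNG seed.
#' @return miRNA data.frame (`id`, `sequence`).
#' @export
gen_mirnas <- function(n, length_range = c(20L, 22L), seed = 1L) {
  if (n < 1L) stopf("n must be >= 1")
  if (length(length_range) != 2L || length_range[1] > length_range[2] ||
      length_range[1] < 18L)
    stopf("invalid length_range")
  with_seed(seed, {
    lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
    data.frame(id = sprintf("syn-miR-%04d", seq_len(n)),
               sequence = vapply(lens, .random_rna, character(1)),
               stringsAsFactors = FALSE)
  })
}

.intended_verdict <- function(defect_spec, L) {
  pos <- defect_spec$pos; type <- defect_spec$type
  d912 <- sum(pos >= 9L & pos <= 12L)
  other_t <- sum(pos < 9L | pos > 12L)
  other_d <- sum(pos == 1L | pos >= 13L)
  p28 <- !any(type %in% c("MISMATCH", "BULGE_MIRNA") & pos >= 2L & pos <= 8L) &&
         !any(type == "BULGE_TARGET" & pos >= 1L & pos <= 8L)
  mm_pos <- sort(pos[type == "MISMATCH"])
  run <- if (length(mm_pos)) {
    r <- rle(diff(mm_pos) == 1L)
    if (any(r$values)) max(r$lengths[r$values]) + 1L else 1L
  } else 0L
  if (d912 <= 1L && other_t <= 4L && run <= 1L) "target"
  else if (d912 >= 2L && d912 <= 5L && p28 && other_d <= 4L) "decoy"
  else "none"
}

.nonpairing_base <- function(mirna_base) mirna_base  # b:b is never WC nor G:U

#' Implant a miRNA binding site into a background transcript
#'
#' Constructs the site as the reverse complement of the miRNA, applies each
#' defect (mismatch: substitute the opposing base with one pairing neither
#' Watson-Crick nor G:U; bulged miRNA base: delete the opposing base; bulged
#' transcript base: insert a non-pairing base between the bases opposite
#' positions i and i+1), and splices the site into the background at
#' `position`.
#'
#' @param background background transcript sequence (RNA string).
#' @param mirna one-row miRNA record (`id`, `sequence`).
#' @param defect_spec data.frame with columns `pos` (miRNA position) and
#'   `type` (`"MISMATCH"`, `"BULGE_MIRNA"`, `"BULGE_TARGET"`); at most one
#'   defect per position, bulged transcript bases only at positions 1..L-1.
#' @param position 1-based insertion point in the background.
#' @param transcript_id id recorded in the truth record.
#' @return list with `sequence` (background with the site spliced in) and
#'   `truth` (kind, ids, site coordinates, predicted cleavage position,
#'   intended verdict, the defect spec).
#' @export
implant_site <- function(background, mirna, defect_spec = NULL, position = 1L,
                         transcript_id = "synthetic") {
  mseq <- as_rna(mirna$sequence)
  L <- nchar(mseq)
  if (is.null(defect_spec))
    defect_spec <- data.frame(pos = integer(0), type = character(0))
  # a repeated position is only meaningful as a multi-nucleotide target
  # bulge (several insertions at one junction); anything else conflicts
  dup <- unique(defect_spec$pos[duplicated(defect_spec$pos)])
  for (p in dup)
    if (!all(defect_spec$type[defect_spec$pos == p] == "BULGE_TARGET"))
      stopf("conflicting defects at position %d", p)
  if (any(defect_spec$pos < 1L | defect_spec$pos > L))
    stopf("defect position outside miRNA")
  if (any(defect_spec$type == "BULGE_TARGET" & defect_spec$pos == L))
    stopf("bulged transcript base undefined 3' of the last miRNA position")
  if (position < 1L || position > nchar(background) + 1L)
    stopf("invalid implant position")
  mb <- strsplit(mseq, "")[[1]]
  dtype <- setNames(rep("", L), seq_len(L))
  not_bt <- defect_spec$type != "BULGE_TARGET"
  dtype[defect_spec$pos[not_bt]] <- defect_spec$type[not_bt]
  bt_count <- tabulate(defect_spec$pos[!not_bt], nbins = L)
  site <- character(0)
  cleavage_idx <- NA_integer_
  # transcript 5'->3' corresponds to miRNA positions L..1; a bulged
  # transcript base at junction p sits between the columns of p+1 and p
  for (p in L:1) {
    if (bt_count[p] > 0L) {
      allowed <- Filter(function(b)
        pair_state(mb[p], b) == "MISMATCH" &&
        pair_state(mb[p + 1L], b) == "MISMATCH", RNA_BASES)
      if (length(allowed) == 0L)
        allowed <- Filter(function(b)
          !(pair_state(mb[p], b) == "WC" || pair_state(mb[p + 1L], b) == "WC"),
          RNA_BASES)
      site <- c(site, rep(allowed[[1]], bt_count[p]))
    }
    if (dtype[[p]] == "BULGE_MIRNA") {
      # opposing base deleted: no transcript base for this position
    } else if (dtype[[p]] == "MISMATCH") {
      site <- c(site, .nonpairing_base(mb[p]))
      if (p == 10L) cleavage_idx <- length(site)
    } else {
      site <- c(site, rna_complement_base(mb[p]))
      if (p == 10L) cleavage_idx <- length(site)
    }
  }
  site_seq <- paste(site, collapse = "")
  seq_out <- paste0(substring(background, 1L, position - 1L), site_seq,
                    substring(background, position, nchar(background)))
  verdict <- .intended_verdict(defect_spec, L)
  truth <- list(kind = if (verdict == "decoy") "decoy_site" else "target_site",
                mirna_id = mirna$id, transcript_id = transcript_id,
                site_start = position,
                site_end = position + nchar(site_seq) - 1L,
                cleavage_position = if (is.na(cleavage_idx)) NA_integer_
                                    else position + cleavage_idx - 1L,
                verdict = verdict,
                defect_spec = defect_spec)
  list(sequence = seq_out, truth = truth)
}

.implant_mfe_ratio <- function(mirna, spec) {
  # MFEratio the scan will assign to the bare implanted site
  site <- implant_site("", mirna, spec, 1L, "probe")$sequence
  alns <- scan_candidate_sites(mirna, list(id = "probe", sequence = site),
                               scan_params(mfe_ratio_cutoff = 0.05,
                                           report_overlapping = TRUE))
  if (length(alns) == 0L) return(0)
  max(vapply(alns, `[[`, numeric(1), "mfe_ratio"))
}

.decoy_spec <- function(mirna_seq) {
  # Rule-conformant decoy structures that a GSTAr-like scan retains at the
  # 0.65 MFEratio floor (published decoys are above the floor by
  # construction): either a contiguous 2-3 nt bulged-target insertion at a
  # central junction (the classic eTM structure) or two adjacent central
  # mismatches. Junctions whose flanking miRNA bases are {G,U} admit no
  # strictly non-pairing insert and are avoided.
  mb <- strsplit(mirna_seq, "")[[1]]
  junctions <- Filter(function(j)
    any(vapply(RNA_BASES, function(b)
      pair_state(mb[j], b) == "MISMATCH" &&
      pair_state(mb[j + 1L], b) == "MISMATCH", logical(1))), 9:11)
  use_bulge <- length(junctions) > 0L && runif(1) < 0.5
  if (use_bulge) {
    j <- if (length(junctions) == 1L) junctions else sample(junctions, 1L)
    k <- sample(2:3, 1L)
    data.frame(pos = rep(j, k), type = "BULGE_TARGET",
               stringsAsFactors = FALSE)
  } else {
    start <- sample(9:11, 1L)
    data.frame(pos = c(start, start + 1L), type = "MISMATCH",
               stringsAsFactors = FALSE)
  }
}

#' Generate a synthetic transcriptome with implanted sites
#'
#' Random backgrounds (uniform base composition, geometric-ish lengths around
#' `mean_len`) receive at most one implanted site each, following `site_plan`.
#' By default the plan implants `n_target` perfect (0-defect) target sites
#' and `n_decoy` rule-conformant decoy sites (a contiguous 2-3 nt central
#' bulged-target insertion, the classic eTM structure, or two adjacent
#' central mismatches), each
#' for a random miRNA on its own transcript.
#'
#' @param n_linc,n_mrna numbers of lincRNA and mRNA transcripts.
#' @param mirnas miRNA data.frame from [gen_mirnas()].
#' @param n_target,n_decoy numbers of implanted target / decoy sites
#'   (together at most `n_linc + n_mrna`).
#' @param mean_len mean background length (default 500; minimum 200).
#' @param seed RNG seed.
#' @return list with `transcripts` (data.frame `id`, `sequence`, `biotype`)
#'   and `truths` (list of truth records).
#' @export
gen_transcriptome <- function(n_linc, n_mrna, mirnas, n_target = 0L,
                              n_decoy = 0L, mean_len = 500L, seed = 1L) {
  n <- n_linc + n_mrna
  if (n_target + n_decoy > n)
    stopf("site plan exceeds transcript capacity (one site per transcript)")
  with_seed(seed, {
    lens <- pmax(200L, 200L + stats::rgeom(n, 1 / max(mean_len - 200L, 1L)))
    ids <- c(sprintf("syn-linc-%04d", seq_len(n_linc)),
             sprintf("syn-mrna-%04d", seq_len(n_mrna)))
    biotype <- c(rep("lincRNA", n_linc), rep("mRNA", n_mrna))
    seqs <- vapply(lens, .random_rna, character(1))
    truths <- list()
    carriers <- sample(n, n_target + n_decoy)
    kinds <- c(rep("target", n_target), rep("decoy", n_decoy))
    for (k in seq_along(carriers)) {
      i <- carriers[k]
      if (kinds[k] == "target") {
        mi <- mirnas[sample(nrow(mirnas), 1L), , drop = FALSE]
        spec <- data.frame(pos = integer(0), type = character(0))
      } else {
        # decoys are, by definition, sites the scan retains at the MFEratio
        # floor; verify at construction (with a 0.03 margin) and redraw the
        # miRNA/defect pattern otherwise
        for (attempt in 1:30) {
          mi <- mirnas[sample(nrow(mirnas), 1L), , drop = FALSE]
          spec <- .decoy_spec(mi$sequence)
          if (.implant_mfe_ratio(mi, spec) >= 0.68) break
        }
      }
      pos <- sample(seq(50L, nchar(seqs[i]) - 50L), 1L)
      imp <- implant_site(seqs[i], mi, spec, pos, transcript_id = ids[i])
      seqs[i] <- imp$sequence
      truths[[length(truths) + 1L]] <- imp$truth
    }
    list(transcripts = data.frame(id = ids, sequence = seqs,
                                  biotype = biotype, stringsAsFactors = FALSE),
         truths = truths)
  })
}

#' Generate a synthetic degradome library
#'
#' For every target-site truth record, `peak_reads` reads start exactly at
#' the predicted cleavage position (the transcript base opposite miRNA
#' position 10); `noise_reads` reads per carrying transcript start at
#' uniform-random other positions. All reads are exact transcript substrings
#' of `read_len` (clipped at the transcript end).
#'
#' @param truths truth list from [gen_transcriptome()].
#' @param transcripts transcript data.frame.
#' @param peak_reads reads planted at each cleavage position (default 10).
#' @param noise_reads background reads per carrying transcript (default 20).
#' @param read_len read length (default 20).
#' @param seed RNG seed.
#' @param library_id id of the resulting library.
#' @return a `degradome_library`.
#' @export
gen_degradome <- function(truths, transcripts, peak_reads = 10L,
                          noise_reads = 20L, read_len = 20L, seed = 1L,
                          library_id = "synthetic-degradome") {
  targets <- Filter(function(tr) tr$kind == "target_site" &&
                      !is.na(tr$cleavage_position), truths)
  if (length(targets) == 0L) stopf("no target_site truth records")
  with_seed(seed, {
    reads <- character(0)
    for (tr in targets) {
      seq <- transcripts$sequence[match(tr$transcript_id, transcripts$id)]
      tlen <- nchar(seq)
      peak <- substring(seq, tr$cleavage_position,
                        min(tr$cleavage_position + read_len - 1L, tlen))
      reads <- c(reads, rep(peak, peak_reads))
      others <- setdiff(seq_len(tlen - read_len + 1L), tr$cleavage_position)
      starts <- sample(others, min(noise_reads, length(others)))
      reads <- c(reads, substring(seq, starts, starts + read_len - 1L))
    }
    counts <- table(reads)
    structure(list(library_id = library_id,
                   unique_reads = setNames(as.integer(counts), names(counts))),
              class = "degradome_library")
  })
}

#' Generate an expression matrix with planted co-expression modules
#'
#' Module members share a latent factor with loading `sqrt(r_target)` so the
#' expected pairwise correlation within a module is `r_target`; remaining
#' genes are independent noise. Values are shifted to a non-negative
#' FPKM-like scale (50 + 10 z, clamped at 0), which preserves Pearson
#' correlations exactly up to the (negligible) clamping.
#'
#' @param n_genes total number of genes including module members (ignored
#'   when `gene_ids` is given).
#' @param n_samples number of samples (>= 4; default 30).
#' @param modules named list: module name -> character vector of gene ids
#'   (disjoint).
#' @param r_target expected within-module correlation (default 0.9).
#' @param seed RNG seed.
#' @param gene_ids optional explicit gene ids for every row; must contain
#'   all module members. Without it, non-module genes are named
#'   `syn-noise-*`.
#' @param module_scale amplitude multiplier for module genes (default 1.25),
#'   so co-regulated genes rank above independent noise in a variance
#'   filter; scaling leaves Pearson correlations unchanged.
#' @return list with `matrix` (genes x samples) and `truths` (data.frame
#'   `module`, `gene`).
#' @export
gen_expression_with_modules <- function(n_genes = NULL, n_samples = 30L,
                                        modules = list(), r_target = 0.9,
                                        seed = 1L, gene_ids = NULL,
                                        module_scale = 1.25) {
  if (n_samples < 4L) stopf("n_samples must be >= 4")
  module_genes <- unlist(modules, use.names = FALSE)
  if (anyDuplicated(module_genes)) stopf("module members must be disjoint")
  if (is.null(gene_ids)) {
    if (is.null(n_genes)) stopf("give n_genes or gene_ids")
    n_noise <- n_genes - length(module_genes)
    if (n_noise < 0L) stopf("n_genes smaller than the module membership")
    genes <- c(module_genes, sprintf("syn-noise-%05d", seq_len(n_noise)))
  } else {
    if (!all(module_genes %in% gene_ids))
      stopf("module members missing from gene_ids")
    if (anyDuplicated(gene_ids)) stopf("duplicate gene_ids")
    genes <- gene_ids
  }
  with_seed(seed, {
    mat <- matrix(rnorm(length(genes) * n_samples), length(genes), n_samples)
    for (m in names(modules)) {
      f <- rnorm(n_samples)
      idx <- match(modules[[m]], genes)
      mat[idx, ] <- module_scale *
        (sqrt(r_target) * matrix(f, length(idx), n_samples, byrow = TRUE) +
         sqrt(1 - r_target) * mat[idx, , drop = FALSE])
    }
    fpkm <- pmax(50 + 10 * mat, 0)
    dimnames(fpkm) <- list(genes, sprintf("sample_%02d", seq_len(n_samples)))
    truths <- if (length(modules))
      data.frame(module = rep(names(modules), lengths(modules)),
                 gene = module_genes, stringsAsFactors = FALSE)
    else data.frame(module = character(0), gene = character(0))
    list(matrix = fpkm, truths = truths)
  })
}

#' Generate GO annotations with one enriched term per module
#'
#' Every gene of a module carries that module's designated term; background
#' terms are assigned to random genes at a low uniform rate.
#'
#' @param genes all gene ids.
#' @param module_genes named list: module name -> gene ids (subsets of
#'   `genes`).
#' @param module_terms named character: module name -> GO term id (distinct
#'   across modules).
#' @param n_background_terms number of background terms (default 20).
#' @param background_rate per-gene probability of carrying each background
#'   term (default 0.02).
#' @param seed RNG seed.
#' @return a `go_annotation`.
#' @export
gen_go_annotations <- function(genes, module_genes = list(),
                               module_terms = character(0),
                               n_background_terms = 20L,
                               background_rate = 0.02, seed = 1L) {
  if (anyDuplicated(unname(module_terms)))
    stopf("term collision across modules")
  if (!all(names(module_genes) %in% names(module_terms)) && length(module_genes))
    stopf("every module needs a designated term")
  bad <- setdiff(unlist(module_genes, use.names = FALSE), genes)
  if (length(bad)) stopf("module gene(s) outside the gene universe")
  with_seed(seed, {
    gene_terms <- setNames(vector("list", length(genes)), genes)
    bg_terms <- sprintf("GO:BG%04d", seq_len(n_background_terms))
    for (tm in bg_terms) {
      carriers <- genes[runif(length(genes)) < background_rate]
      for (g in carriers) gene_terms[[g]] <- c(gene_terms[[g]], tm)
    }
    for (m in names(module_genes))
      for (g in module_genes[[m]])
        gene_terms[[g]] <- c(gene_terms[[g]], module_terms[[m]])
    # every gene carries at least one term so the background is well-defined
    orphan <- names(gene_terms)[lengths(gene_terms) == 0L]
    for (g in orphan) gene_terms[[g]] <- "GO:BG0000"
    go_annotation(gene_terms)
  })
}

#' Generate ortholog windows with conserved sites and divergent flanks
#'
#' Each species copy of the window mutates site columns at `site_divergence`
#' and flank columns at `flank_divergence` (uniform substitutions to a
#' different base).
#'
#' @param window reference window sequence.
#' @param n_species number of ortholog copies.
#' @param site_offsets `c(start, end)` of the site within the window.
#' @param site_divergence,flank_divergence per-base substitution rates in
#'   `[0, 1]` (defaults 0.05 and 0.40).
#' @param seed RNG seed.
#' @return named character vector: reference first (`ref`), then
#'   `species_1`, ...
#' @export
gen_ortholog_windows <- function(window, n_species, site_offsets,
                                 site_divergence = 0.05,
                                 flank_divergence = 0.40, seed = 1L) {
  window <- as_rna(window)
  wlen <- nchar(window)
  if (any(site_offsets < 1L) || any(site_offsets > wlen) ||
      site_offsets[1] > site_offsets[2])
    stopf("invalid site offsets")
  if (any(c(site_divergence, flank_divergence) < 0) ||
      any(c(site_divergence, flank_divergence) > 1))
    stopf("divergence rates must lie in [0, 1]")
  ref <- strsplit(window, "")[[1]]
  is_site <- seq_len(wlen) >= site_offsets[1] & seq_len(wlen) <= site_offsets[2]
  rate <- ifelse(is_site, site_divergence, flank_divergence)
  with_seed(seed, {
    out <- setNames(character(n_species + 1L),
                    c("ref", sprintf("species_%d", seq_len(n_species))))
    out[1] <- window
    for (s in seq_len(n_species)) {
      mut <- ref
      flip <- runif(wlen) < rate
      for (i in which(flip))
        mut[i] <- sample(setdiff(RNA_BASES, ref[i]), 1L)
      out[s + 1L] <- paste(mut, collapse = "")
    }
    out
  })
}
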