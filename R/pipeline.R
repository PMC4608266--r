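# Pipeline orchestration: configuration, stage dependency order, artifact
# writing, and a run manifest. The command-line entry point in inst/cli/
# is a thin wrapper over run_pipeline().

#' Pipeline stage names in dependency order
#' @export
PIPELINE_STAGES <- c("simulate", "scan", "classify", "validate", "conserve",
                     "network", "coexpress", "annotate")

#' Build a pipeline run configuration
#'
#' Paths may be `NULL` when the `simulate` stage generates them.
#'
#' @param out_dir output directory (created if missing).
#' @param seed RNG seed for every stochastic stage.
#' @param mirna_fasta,lincrna_fasta,mrna_fasta,degradome_fasta input paths.
#' @param expression_tsv,go_tsv expression matrix and GO annotation paths.
#' @param params a [scan_params()] object.
#' @param alpha,tail_fraction co-expression thresholds.
#' @param conservation_threshold site-identity threshold.
#' @param n_mirnas,n_linc,n_mrna,n_target,n_decoy simulate-stage sizes.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir = "lincmir-out", seed = 1L,
                       mirna_fasta = NULL, lincrna_fasta = NULL,
                       mrna_fasta = NULL, degradome_fasta = NULL,
                       expression_tsv = NULL, go_tsv = NULL,
                       params = scan_params(), alpha = 0.05,
                       tail_fraction = 0.05, conservation_threshold = 0.80,
                       n_mirnas = 10L, n_linc = 20L, n_mrna = 20L,
                       n_target = 8L, n_decoy = 8L) {
  for (p in c(mirna_fasta, lincrna_fasta, mrna_fasta, degradome_fasta,
              expression_tsv, go_tsv))
    if (!is.null(p) && !file.exists(p)) stopf("input path does not exist: %s", p)
  suppressWarnings(rm(p))
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from a key-value file
#'
#' One `key = value` pair per line (TOML-style scalars: quoted strings, bare
#' numbers, true/false); `#` comments and section headers are ignored.
#' `overrides` (e.g. parsed command-line flags) take precedence.
#'
#' @param path config file.
#' @param overrides named list merged over the file's values.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  vals <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stopf("malformed config line: %s", ln)
    key <- trimws(kv[1]); raw <- trimws(paste(kv[-1], collapse = "="))
    vals[[key]] <- if (grepl('^".*"$', raw)) gsub('^"|"$', "", raw)
    else if (raw %in% c("true", "false")) raw == "true"
    else if (grepl("^-?[0-9.eE+]+$", raw)) as.numeric(raw)
    else raw
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

.log <- function(level, fmt, ...) {
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Run the discovery pipeline
#'
#' Executes the requested stages in dependency order (simulate -> scan ->
#' classify -> validate -> conserve -> network -> coexpress -> annotate),
#' writing one artifact per stage into `config$out_dir` plus a run manifest
#' (package version, parameters, input digests). Deterministic for a fixed
#' seed and config.
#'
#' @param config a [run_config()].
#' @param stages subset of the stage names; defaults to all.
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES) {
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad))
    stopf("unknown stage(s): %s (valid: %s)",
          paste(bad, collapse = ", "), paste(PIPELINE_STAGES, collapse = ", "))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- new.env(parent = emptyenv())
  outputs <- character(0)
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    outputs <<- c(outputs, path)
    path
  }

  for (stage in stages) {
    .log("INFO", "stage %s", stage)
    switch(stage,
      simulate = {
        st$mirnas <- gen_mirnas(config$n_mirnas, seed = config$seed)
        sim <- gen_transcriptome(config$n_linc, config$n_mrna, st$mirnas,
                                 n_target = config$n_target,
                                 n_decoy = config$n_decoy,
                                 seed = config$seed + 1L)
        st$transcripts <- sim$transcripts
        st$truths <- sim$truths
        st$library <- gen_degradome(sim$truths, sim$transcripts,
                                    seed = config$seed + 2L)
        emit("mirnas.fa", function(p) write_fasta(st$mirnas, p))
        emit("transcripts.fa", function(p) write_fasta(st$transcripts, p))
        emit("truth.jsonl", function(p)
          writeLines(vapply(st$truths, function(tr)
            jsonlite::toJSON(tr, auto_unbox = TRUE, digits = NA,
                             dataframe = "columns"), character(1)), p))
      },
      scan = {
        if (is.null(st$mirnas)) {
          if (is.null(config$mirna_fasta))
            stopf("stage scan needs the simulate stage or mirna_fasta")
          st$mirnas <- read_fasta(config$mirna_fasta)
          st$transcripts <- rbind(
            read_fasta(config$lincrna_fasta, biotype = "lincRNA"),
            read_fasta(config$mrna_fasta, biotype = "mRNA"))
        }
        st$alignments <- scan_transcriptome(st$mirnas, st$transcripts,
                                            config$params)
        emit("alignments.tsv", function(p)
          write.table(alignment_table(st$alignments), p, sep = "\t",
                      quote = FALSE, row.names = FALSE))
      },
      classify = {
        if (is.null(st$alignments))
          stopf("stage classify needs the scan stage output")
        st$calls <- classify_alignments(st$alignments)
        emit("verdicts.tsv", function(p)
          write.table(call_table(st$calls), p, sep = "\t", quote = FALSE,
                      row.names = FALSE))
      },
      validate = {
        if (is.null(st$calls))
          stopf("stage validate needs the classify stage output")
        libs <- if (!is.null(st$library)) list(st$library)
        else if (!is.null(config$degradome_fasta))
          list(preprocess_degradome(
            read_degradome_reads(config$degradome_fasta)))
        else stopf("stage validate needs a degradome library")
        st$evidence <- validate_interactions(st$calls, libs, st$transcripts)
        emit("evidence.tsv", function(p)
          write.table(st$evidence, p, sep = "\t", quote = FALSE,
                      row.names = FALSE))
      },
      conserve = {
        if (is.null(st$calls))
          stopf("stage conserve needs the classify stage output")
        reports <- list()
        for (cl in head(st$calls, 5L)) {
          a <- cl$alignment
          tr <- st$transcripts[match(a$transcript_id, st$transcripts$id), ]
          win <- extract_site_window(tr, a$site_start, a$site_end)
          orth <- gen_ortholog_windows(win$window, 4L, win$site_offsets,
                                       seed = config$seed + 3L)
          block <- multiple_align(orth, win$site_offsets)
          rep <- site_conservation(block, config$conservation_threshold)
          reports[[length(reports) + 1L]] <- data.frame(
            mirna_id = a$mirna_id, transcript_id = a$transcript_id,
            site_identity = rep$site_identity,
            flank_identity = rep$flank_identity,
            conserved = rep$conserved, stringsAsFactors = FALSE)
        }
        st$conservation <- if (length(reports)) do.call(rbind, reports)
                           else data.frame()
        emit("conservation.tsv", function(p)
          write.table(st$conservation, p, sep = "\t", quote = FALSE,
                      row.names = FALSE))
      },
      network = {
        if (is.null(st$calls))
          stopf("stage network needs the classify stage output")
        st$network <- build_network(st$calls)
        emit("network.sif", function(p)
          export_network_edges(st$network, p, "SIF"))
      },
      coexpress = {
        if (is.null(st$expression)) {
          if (!is.null(config$expression_tsv)) {
            st$expression <- read_expression_matrix(config$expression_tsv)
          } else {
            if (is.null(st$transcripts))
              stopf("stage coexpress needs simulate or expression_tsv")
            lincs <- st$transcripts$id[st$transcripts$biotype == "lincRNA"]
            mrnas <- st$transcripts$id[st$transcripts$biotype == "mRNA"]
            modules <- list(module_1 = c(lincs[1], head(mrnas, 4L)))
            ex <- gen_expression_with_modules(
              modules = modules, seed = config$seed + 4L,
              gene_ids = c(st$transcripts$id,
                           sprintf("syn-noise-%05d", seq_len(100L))))
            st$expression <- ex$matrix
            st$modules <- modules
          }
        }
        lincs <- intersect(st$transcripts$id[st$transcripts$biotype == "lincRNA"],
                           rownames(st$expression))
        mrnas <- intersect(st$transcripts$id[st$transcripts$biotype == "mRNA"],
                           rownames(st$expression))
        filtered <- variance_filter(st$expression)
        lincs <- intersect(lincs, rownames(filtered))
        mrnas <- intersect(mrnas, rownames(filtered))
        st$coexpression <- select_coexpression_edges(
          filtered, lincs, mrnas, alpha = config$alpha,
          tail_fraction = config$tail_fraction)
        emit("coexpression.tsv", function(p)
          write.table(st$coexpression, p, sep = "\t", quote = FALSE,
                      row.names = FALSE))
      },
      annotate = {
        if (is.null(st$coexpression) || is.null(st$network))
          stopf("stage annotate needs the coexpress and network stages")
        anno <- if (!is.null(config$go_tsv)) read_go_annotation(config$go_tsv)
        else gen_go_annotations(
          rownames(st$expression),
          module_genes = lapply(st$modules %||% list(),
                                function(g) g[-1]),
          module_terms = setNames(sprintf("GO:MOD%04d",
                                          seq_along(st$modules %||% list())),
                                  names(st$modules %||% list())),
          seed = config$seed + 5L)
        rows <- list()
        for (l in unique(st$coexpression$lincrna_id)) {
          enr <- annotate_lincrna_targets(l, st$coexpression, anno)
          if (nrow(enr)) rows[[length(rows) + 1L]] <-
              data.frame(lincrna_id = l, mode = "coexpression", enr,
                         stringsAsFactors = FALSE)
        }
        decoys <- st$network$nodes$id[st$network$nodes$kind == "lincRNA" &
                                      st$network$nodes$role_decoy]
        for (l in decoys) {
          enr <- tryCatch(annotate_lincrna_decoys(l, st$network, anno),
                          error = function(e) NULL, warning = function(w) NULL)
          if (!is.null(enr) && nrow(enr)) rows[[length(rows) + 1L]] <-
              data.frame(lincrna_id = l, mode = "ceRNA", enr,
                         stringsAsFactors = FALSE)
        }
        st$annotation <- if (length(rows)) do.call(rbind, rows)
                         else data.frame()
        emit("annotation.tsv", function(p)
          write.table(st$annotation, p, sep = "\t", quote = FALSE,
                      row.names = FALSE))
      })
  }
  manifest <- list(
    package = "lincmir",
    version = as.character(utils::packageVersion("lincmir")),
    seed = config$seed,
    stages = stages,
    params = unclass(config$params),
    outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                               basename(outputs))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  .log("INFO", "done; %d artifact(s) in %s", length(outputs), config$out_dir)
  invisible(as.list(st))
}
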