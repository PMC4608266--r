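# LincRNA-mRNA co-expression and function transfer: variance filter, Pearson
# correlation with the Fisher z-transform asymptotic p-value, Bonferroni,
# top/bottom-5% edge selection, Fisher-exact GO over-representation, and the
# ceRNA rule for decoy annotation.

#' Keep the most variable genes
#'
#' Retains the `ceil(keep_fraction * n_genes)` genes with the largest sample
#' variance; ties are broken by input order.
#'
#' @param mat genes-by-samples numeric matrix (>= 2 samples).
#' @param keep_fraction fraction of genes kept (default 0.75).
#' @return the filtered matrix, rows in original relative order.
#' @export
variance_filter <- function(mat, keep_fraction = 0.75) {
  if (!(keep_fraction > 0 && keep_fraction <= 1))
    stopf("keep_fraction must be in (0, 1]")
  if (ncol(mat) < 2L) stopf("need >= 2 samples")
  v <- apply(mat, 1, var)
  k <- ceiling(keep_fraction * nrow(mat))
  keep <- order(-v, seq_along(v))[seq_len(k)]   # stable: ties by input order
  mat[sort(keep), , drop = FALSE]
}

#' Pearson correlation with Fisher's asymptotic p-value
#'
#' `p = 2 * (1 - Phi(|z|))` with `z = atanh(r) * sqrt(n - 3)`; r is clamped
#' to +/-(1 - 1e-15) before the transform so perfect correlations yield a
#' finite z.
#'
#' @param x,y numeric vectors of equal length `n >= 4` with non-zero
#'   variance.
#' @return list with `pcc` and `p_raw`.
#' @export
correlation_pvalue <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stopf("x and y must have equal length")
  if (n < 4L) stopf("need n >= 4 samples")
  if (var(x) == 0 || var(y) == 0) stopf("zero variance")
  r <- cor(x, y)
  list(pcc = r, p_raw = .fisher_z_p(r, n))
}

.fisher_z_p <- function(r, n) {
  rc <- pmin(pmax(r, -(1 - 1e-15)), 1 - 1e-15)
  z <- atanh(rc) * sqrt(n - 3)
  2 * pnorm(abs(z), lower.tail = FALSE)
}

#' Bonferroni adjustment
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param m number of tests (default `length(p)`).
#' @return `pmin(1, m * p)`.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  pmin(1, m * p)
}

#' Select lincRNA-mRNA co-expression edges
#'
#' Computes the Pearson correlation and Fisher asymptotic p-value for every
#' lincRNA-mRNA pair in an (already variance-filtered) matrix, Bonferroni-
#' adjusts over the number of pairs computed, and retains pairs with
#' `p_adj < alpha` whose correlation lies in the top or bottom
#' `tail_fraction` of the computed correlation distribution.
#'
#' @param mat genes-by-samples matrix containing all ids.
#' @param lincrna_ids,mrna_ids disjoint gene-id sets present in `mat`.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param tail_fraction correlation tail fraction (default 0.05).
#' @return data.frame of edges: `lincrna_id`, `mrna_id`, `pcc`, `p_raw`,
#'   `p_adj`.
#' @export
select_coexpression_edges <- function(mat, lincrna_ids, mrna_ids,
                                      alpha = 0.05, tail_fraction = 0.05) {
  if (length(lincrna_ids) == 0L || length(mrna_ids) == 0L)
    stopf("empty id set")
  if (length(intersect(lincrna_ids, mrna_ids)))
    stopf("lincRNA and mRNA id sets must be disjoint")
  missing <- setdiff(c(lincrna_ids, mrna_ids), rownames(mat))
  if (length(missing))
    stopf("ids absent from matrix: %s",
          paste(head(missing, 3), collapse = ", "))
  n <- ncol(mat)
  if (n < 4L) stopf("need >= 4 samples")
  cc <- cor(t(mat[lincrna_ids, , drop = FALSE]),
            t(mat[mrna_ids, , drop = FALSE]))
  pairs <- expand.grid(lincrna_id = lincrna_ids, mrna_id = mrna_ids,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pcc <- as.vector(cc)                      # column-major matches expand.grid
  p_raw <- .fisher_z_p(pcc, n)
  m <- length(pcc)
  p_adj <- bonferroni_adjust(p_raw, m)
  hi <- quantile(pcc, 1 - tail_fraction, names = FALSE)
  lo <- quantile(pcc, tail_fraction, names = FALSE)
  keep <- p_adj < alpha & (pcc >= hi | pcc <= lo)
  out <- data.frame(pairs[keep, , drop = FALSE],
                    pcc = pcc[keep], p_raw = p_raw[keep], p_adj = p_adj[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a gene-to-GO annotation table
#'
#' Two-column TSV, one (gene, term) pair per line, no header required.
#'
#' @param path TSV file.
#' @return a `go_annotation`: list with `gene_terms` (named list gene ->
#'   character vector of terms) and `universe` (all terms).
#' @export
read_go_annotation <- function(path) {
  df <- read.delim(path, header = FALSE, col.names = c("gene", "term"),
                   stringsAsFactors = FALSE)
  go_annotation(split(df$term, df$gene))
}

#' Construct a GO annotation object
#'
#' @param gene_terms named list mapping gene id to a character vector of GO
#'   term ids.
#' @return a `go_annotation` list with `gene_terms` and `universe`.
#' @export
go_annotation <- function(gene_terms) {
  gene_terms <- lapply(gene_terms, unique)
  structure(list(gene_terms = gene_terms,
                 universe = sort(unique(unlist(gene_terms, use.names = FALSE)))),
            class = "go_annotation")
}

#' One-sided Fisher exact (over-representation) p-value
#'
#' Upper hypergeometric tail for a 2x2 table with `k` query hits, query size
#' `n`, `K` background hits, background size `N`. This is the p-value
#' [go_enrichment()] assigns to every term.
#'
#' @param k,K,n,N table margins (vectorized).
#' @return p-values in (0, 1].
#' @export
fisher_overrep_p <- function(k, K, n, N) {
  phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' GO term over-representation by Fisher's exact test
#'
#' For each term with at least one query hit, the one-sided (upper tail)
#' Fisher exact p-value of the 2x2 table (query hits, query misses,
#' background hits outside the query, the rest), Bonferroni-adjusted over the
#' number of terms tested.
#'
#' @param query character vector of query gene ids (subset of the annotated
#'   background).
#' @param annotation a `go_annotation`.
#' @param alpha report terms with `p_adj < alpha` (default 0.05); use 1 to
#'   keep everything tested.
#' @return data.frame sorted by `p_adj`: `term`, `k` (query hits), `n`
#'   (query size), `K` (background hits), `N` (background size), `p_raw`,
#'   `p_adj`.
#' @export
go_enrichment <- function(query, annotation, alpha = 0.05) {
  if (length(query) == 0L) stopf("empty query")
  background <- names(annotation$gene_terms)
  query <- unique(query)
  outside <- setdiff(query, background)
  if (length(outside))
    stopf("query gene(s) not in annotated background: %s",
          paste(head(outside, 3), collapse = ", "))
  N <- length(background); n <- length(query)
  term_genes <- list()
  for (g in background)
    for (tm in annotation$gene_terms[[g]])
      term_genes[[tm]] <- c(term_genes[[tm]], g)
  rows <- list()
  tested <- 0L
  for (tm in names(term_genes)) {
    K <- length(term_genes[[tm]])
    k <- length(intersect(term_genes[[tm]], query))
    if (k == 0L) next
    tested <- tested + 1L
    p <- fisher_overrep_p(k, K, n, N)
    rows[[length(rows) + 1L]] <- data.frame(
      term = tm, k = k, n = n, K = K, N = N, p_raw = p,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p_raw = numeric(0),
                      p_adj = numeric(0)))
  res <- do.call(rbind, rows)
  res$p_adj <- bonferroni_adjust(res$p_raw, tested)
  res <- res[res$p_adj < alpha, , drop = FALSE]
  res <- res[order(res$p_adj, res$p_raw, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate a lincRNA target via its co-expressed mRNAs
#'
#' GO enrichment of the mRNAs co-expressed with the lincRNA, against the full
#' annotated background.
#'
#' @param lincrna_id lincRNA of interest.
#' @param edges co-expression edges from [select_coexpression_edges()].
#' @param annotation a `go_annotation`.
#' @param alpha passed to [go_enrichment()].
#' @return enrichment data.frame (empty, with a warning, if the lincRNA has
#'   no edges).
#' @export
annotate_lincrna_targets <- function(lincrna_id, edges, annotation,
                                     alpha = 0.05) {
  partners <- unique(edges$mrna_id[edges$lincrna_id == lincrna_id])
  if (length(partners) == 0L) {
    warning(sprintf("lincRNA %s has no co-expression edges", lincrna_id))
    return(go_enrichment(names(annotation$gene_terms)[1], annotation,
                         alpha = 0)[0, ])
  }
  go_enrichment(partners, annotation, alpha = alpha)
}

#' Annotate a lincRNA decoy via the ceRNA rule
#'
#' The partner set is every mRNA holding a target edge to any miRNA that has
#' a decoy edge to this lincRNA; the decoy's function is inferred from the
#' mRNAs it de-represses.
#'
#' @param lincrna_id lincRNA holding a decoy role in the network.
#' @param network a `regulatory_network`.
#' @param annotation a `go_annotation`.
#' @param alpha passed to [go_enrichment()].
#' @return enrichment data.frame over the ceRNA partner set.
#' @export
annotate_lincrna_decoys <- function(lincrna_id, network, annotation,
                                    alpha = 0.05) {
  nd <- network$nodes; ed <- network$edges
  row <- nd[nd$id == lincrna_id, , drop = FALSE]
  if (nrow(row) == 0L || !row$role_decoy)
    stopf("%s does not hold a decoy role in the network", lincrna_id)
  mirnas <- unique(ed$mirna[ed$partner == lincrna_id & ed$role == "decoy"])
  mrna_ids <- nd$id[nd$kind == "mRNA"]
  partners <- unique(ed$partner[ed$mirna %in% mirnas & ed$role == "target" &
                                ed$partner %in% mrna_ids])
  if (length(partners) == 0L) {
    warning(sprintf("no mRNA targets behind the miRNAs decoyed by %s",
                    lincrna_id))
    return(go_enrichment(names(annotation$gene_terms)[1], annotation,
                         alpha = 0)[0, ])
  }
  go_enrichment(partners, annotation, alpha = alpha)
}
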