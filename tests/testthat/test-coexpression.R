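test_that("variance filter keeps the top-variance genes with stable ties", {
  m <- matrix(c(1, 1, 1, 1,
                1, 2, 3, 4,
                0, 5, 0, 5,
                10, 10, 10, 11), 4, 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  kept <- variance_filter(m, 0.75)
  expect_equal(nrow(kept), 3L)     # ceil(0.75 * 4)
  expect_false("g1" %in% rownames(kept))   # the constant gene goes

  flat <- matrix(5, 10, 4, dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  expect_equal(rownames(variance_filter(flat, 0.75)), paste0("g", 1:8))

  # random matrices agree with a sort-and-slice oracle
  for (seed in 1:4) {
    set.seed(seed)
    r <- matrix(abs(rnorm(200)), 20, 10,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
    kept <- variance_filter(r, 0.6)
    v <- apply(r, 1, var)
    want <- sort(names(sort(v, decreasing = TRUE)[1:ceiling(0.6 * 20)]))
    expect_setequal(rownames(kept), want)
    expect_equal(rownames(kept),
                 rownames(r)[rownames(r) %in% want])   # input order kept
  }
  expect_error(variance_filter(m, 0), "keep_fraction")
  expect_error(variance_filter(m[, 1, drop = FALSE]), ">= 2")
})

test_that("correlation p-values match an independent normal-CDF oracle", {
  # oracle: numerically integrate the standard normal density
  oracle_p <- function(r, n) {
    z <- abs(atanh(min(max(r, -(1 - 1e-15)), 1 - 1e-15)) * sqrt(n - 3))
    2 * stats::integrate(stats::dnorm, z, Inf, rel.tol = 1e-12,
                         abs.tol = 0)$value
  }
  x <- seq_len(10)
  res <- correlation_pvalue(x, x)
  expect_equal(res$pcc, 1)
  expect_lt(res$p_raw, 1e-200)

  # r = 0 exactly -> p = 1
  x0 <- c(1, -1, 1, -1, 1, -1); y0 <- c(1, 1, -1, -1, 1, 1)
  expect_equal(correlation_pvalue(x0, y0)$p_raw, 1)

  # worked value: r = 0.5, n = 30
  expect_equal(2 * pnorm(atanh(0.5) * sqrt(27), lower.tail = FALSE),
               oracle_p(0.5, 30), tolerance = 1e-9)

  for (r in c(-0.95, -0.5, -0.1, 0.1, 0.3, 0.8)) {
    for (n in c(5, 10, 30, 100)) {
      set.seed(1)
      expect_equal(unname(2 * pnorm(abs(atanh(r) * sqrt(n - 3)),
                                    lower.tail = FALSE)),
                   oracle_p(r, n), tolerance = 1e-9)
      # symmetry p(r) = p(-r)
      expect_equal(oracle_p(r, n), oracle_p(-r, n), tolerance = 1e-12)
    }
  }
  expect_error(correlation_pvalue(1:3, 1:3), "n >= 4")
  expect_error(correlation_pvalue(rep(1, 5), 1:5), "variance")
})

test_that("bonferroni adjustment scales and caps", {
  expect_equal(bonferroni_adjust(0.02, 10), 0.2)
  expect_equal(bonferroni_adjust(0.5, 10), 1.0)
  p <- c(0.001, 0.2, 0.9)
  expect_equal(bonferroni_adjust(p, 7),
               vapply(p, bonferroni_adjust, numeric(1), m = 7))
  expect_true(all(bonferroni_adjust(p) >= p))
  expect_error(bonferroni_adjust(1.2), "\\[0, 1\\]")
})

test_that("edge selection keeps planted pairs and rejects noise", {
  modules <- list(mod1 = c("lincA", paste0("m", 1:3)))
  ex <- gen_expression_with_modules(120, 30, modules, r_target = 0.95,
                                    seed = 91)
  lincs <- c("lincA", grep("syn-noise", rownames(ex$matrix),
                           value = TRUE)[1:9])
  mrnas <- setdiff(rownames(ex$matrix), lincs)
  edges <- select_coexpression_edges(ex$matrix, lincs, mrnas)
  got <- paste(edges$lincrna_id, edges$mrna_id)
  expect_true(all(paste("lincA", paste0("m", 1:3)) %in% got))

  # independent noise only: nothing survives Bonferroni
  noise <- gen_expression_with_modules(40, 30, list(), seed = 92)
  e0 <- select_coexpression_edges(noise$matrix, rownames(noise$matrix)[1:10],
                                  rownames(noise$matrix)[11:40])
  expect_equal(nrow(e0), 0L)

  # degenerate thresholds retain every pair
  eall <- select_coexpression_edges(noise$matrix, rownames(noise$matrix)[1:5],
                                    rownames(noise$matrix)[6:15],
                                    alpha = 1.0000001, tail_fraction = 1)
  expect_equal(nrow(eall), 50L)
  expect_true(all(eall$p_raw <= eall$p_adj))
  expect_true(all(abs(eall$pcc) <= 1))

  expect_error(select_coexpression_edges(noise$matrix, character(0), "x"),
               "empty")
  expect_error(select_coexpression_edges(noise$matrix,
                                         rownames(noise$matrix)[1:2],
                                         rownames(noise$matrix)[2:4]),
               "disjoint")
})

test_that("GO enrichment matches the hypergeometric tail and spec examples", {
  # background of 100 genes, term A on 10; query of 10 with 5 hits
  genes <- paste0("g", 1:100)
  gt <- setNames(rep(list("GO:OTHER"), 100), genes)
  for (g in genes[1:10]) gt[[g]] <- c(gt[[g]], "GO:A")
  anno <- go_annotation(gt)
  query <- c(genes[1:5], genes[21:25])
  res <- go_enrichment(query, anno, alpha = 1.0000001)
  pA <- res$p_raw[res$term == "GO:A"]
  want <- sum(vapply(5:10, function(j)
    choose(10, j) * choose(90, 10 - j) / choose(100, 10), numeric(1)))
  expect_equal(pA, want, tolerance = 1e-12)

  # query = whole background: p_raw = 1 everywhere
  resall <- go_enrichment(genes, anno, alpha = 2)
  expect_true(all(resall$p_raw == 1))

  expect_error(go_enrichment(character(0), anno), "empty")
  expect_error(go_enrichment("nope", anno), "background")
})

test_that("function transfer recovers planted modules (targets and decoys)", {
  modules <- list(mod1 = c("lincA", paste0("mt", 1:4)),
                  mod2 = c("lincB", paste0("mu", 1:4)))
  ex <- gen_expression_with_modules(400, 30, modules, seed = 93)
  lincs <- c("lincA", "lincB")
  mrnas <- setdiff(rownames(ex$matrix), lincs)
  edges <- select_coexpression_edges(ex$matrix, lincs, mrnas)
  anno <- gen_go_annotations(mrnas,
                             module_genes = list(mod1 = paste0("mt", 1:4),
                                                 mod2 = paste0("mu", 1:4)),
                             module_terms = c(mod1 = "GO:MOD1",
                                              mod2 = "GO:MOD2"),
                             seed = 94)
  enrA <- annotate_lincrna_targets("lincA", edges, anno)
  expect_equal(enrA$term[1], "GO:MOD1")
  # invariant to edge order
  enrA2 <- annotate_lincrna_targets("lincA", edges[rev(seq_len(nrow(edges))), ],
                                    anno)
  expect_equal(enrA, enrA2)
  expect_warning(res0 <- annotate_lincrna_targets("lincZ", edges, anno),
                 "no co-expression")
  expect_equal(nrow(res0), 0L)

  # ceRNA rule: decoy inherits the targets of its miRNAs
  calls <- list()
  add <- function(m, p, r, kind) {
    cl <- structure(list(verdict = r, biotype = kind,
                         alignment = list(mirna_id = m, transcript_id = p)),
                    class = "interaction_call")
    calls[[length(calls) + 1L]] <<- cl
  }
  add("miR1", "lincD", "decoy", "lincRNA")
  add("miR2", "lincD", "decoy", "lincRNA")
  for (g in paste0("mt", 1:4)) add("miR1", g, "target", "mRNA")
  add("miR2", "mu1", "target", "mRNA")
  add("miR3", "mu2", "target", "mRNA")   # not decoyed: must not contribute
  net <- build_network(calls)
  enrD <- annotate_lincrna_decoys("lincD", net, anno)
  expect_equal(enrD$term[1], "GO:MOD1")
  # partner set is the deduplicated union over both miRNAs
  expect_equal(enrD$n[1], 5L)            # mt1..mt4 + mu1, not mu2
  expect_error(annotate_lincrna_decoys("mt1", net, anno), "decoy role")
})
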