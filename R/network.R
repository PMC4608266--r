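# miRNA-lincRNA-mRNA regulatory network: typed nodes with role sets
# (a transcript can be a target of one miRNA and a decoy of another),
# role-labeled edges, summaries, and connected components.

#' Build the regulatory network from interaction calls
#'
#' One node per distinct miRNA or transcript and one edge per distinct
#' (miRNA, transcript, verdict) triple. Transcripts appearing with both
#' verdicts hold both roles.
#'
#' @param calls list of `interaction_call` objects with verdict `"target"`
#'   or `"decoy"` (verdict `"none"` is rejected).
#' @return a `regulatory_network`: list with `nodes` (id, kind, role_target,
#'   role_decoy) and `edges` (mirna, partner, role) data.frames.
#' @export
build_network <- function(calls) {
  if (any(vapply(calls, function(cl) cl$verdict == "none", logical(1))))
    stopf("calls with verdict 'none' cannot enter the network")
  ed <- if (length(calls)) unique(do.call(rbind, lapply(calls, function(cl)
    data.frame(mirna = cl$alignment$mirna_id,
               partner = cl$alignment$transcript_id,
               role = cl$verdict,
               partner_kind = cl$biotype %||% NA_character_,
               stringsAsFactors = FALSE))))
  else data.frame(mirna = character(0), partner = character(0),
                  role = character(0), partner_kind = character(0))
  mirnas <- unique(ed$mirna)
  partners <- unique(ed[, c("partner", "partner_kind")])
  nodes <- rbind(
    data.frame(id = mirnas, kind = rep("miRNA", length(mirnas)),
               role_target = rep(FALSE, length(mirnas)),
               role_decoy = rep(FALSE, length(mirnas)),
               stringsAsFactors = FALSE),
    data.frame(id = partners$partner,
               kind = ifelse(is.na(partners$partner_kind), "mRNA",
                             partners$partner_kind),
               role_target = vapply(partners$partner, function(p)
                 any(ed$partner == p & ed$role == "target"), logical(1)),
               role_decoy = vapply(partners$partner, function(p)
                 any(ed$partner == p & ed$role == "decoy"), logical(1)),
               stringsAsFactors = FALSE))
  rownames(nodes) <- NULL
  structure(list(nodes = nodes,
                 edges = ed[, c("mirna", "partner", "role")]),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  s <- summarize_network(x)
  cat(sprintf("regulatory network: %d nodes, %d edges\n",
              s$total_nodes, s$total_edges))
  cat(sprintf("  miRNAs %d | lincRNA targets %d | lincRNA decoys %d | mRNA targets %d | mRNA decoys %d\n",
              s$n_mirnas, s$n_lincrna_targets, s$n_lincrna_decoys,
              s$n_mrna_targets, s$n_mrna_decoys))
  invisible(x)
}

#' Summarize a regulatory network
#'
#' Per-class node counts with dual-role transcripts counted once per role,
#' plus per-miRNA counts of the four partner types.
#'
#' @param net a `regulatory_network`.
#' @return a `network_summary` list; `$per_mirna` is a data.frame with one
#'   row per miRNA and columns for each partner type.
#' @export
summarize_network <- function(net) {
  nd <- net$nodes; ed <- net$edges
  is_linc <- nd$kind == "lincRNA"; is_mrna <- nd$kind == "mRNA"
  mirnas <- nd$id[nd$kind == "miRNA"]
  per <- do.call(rbind, lapply(mirnas, function(m) {
    sub <- ed[ed$mirna == m, , drop = FALSE]
    kind <- nd$kind[match(sub$partner, nd$id)]
    data.frame(mirna = m,
               lincrna_targets = sum(kind == "lincRNA" & sub$role == "target"),
               lincrna_decoys = sum(kind == "lincRNA" & sub$role == "decoy"),
               mrna_targets = sum(kind == "mRNA" & sub$role == "target"),
               mrna_decoys = sum(kind == "mRNA" & sub$role == "decoy"),
               stringsAsFactors = FALSE)
  }))
  structure(list(
    n_mirnas = length(mirnas),
    n_lincrna_targets = sum(is_linc & nd$role_target),
    n_lincrna_decoys = sum(is_linc & nd$role_decoy),
    n_mrna_targets = sum(is_mrna & nd$role_target),
    n_mrna_decoys = sum(is_mrna & nd$role_decoy),
    total_nodes = nrow(nd),
    total_edges = nrow(ed),
    per_mirna = per %||% data.frame()),
    class = "network_summary")
}

#' Connected components of the network
#'
#' Components of the undirected edge set, sorted by node count descending;
#' a miRNA whose partners are all private forms its own component.
#'
#' @param net a `regulatory_network`.
#' @return list of character vectors of node ids, largest first.
#' @export
find_subnetworks <- function(net) {
  if (nrow(net$edges) == 0L)
    return(lapply(net$nodes$id, identity))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("mirna", "partner")], directed = FALSE,
    vertices = net$nodes$id)
  comp <- igraph::components(g)
  comps <- split(names(comp$membership), comp$membership)
  comps <- comps[order(-lengths(comps))]
  unname(lapply(comps, as.character))
}
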