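#' Build cooperative metabolic route networks
#'
#' Tripartite species-KO-pathway graph. Species-KO edges of type `"protein"`
#' come from key proteins (the species expresses a key protein under that
#' KO). KO-pathway edges record membership of targeted KOs in enriched
#' pathways. An abundant species (taxon-level p_adj < 0.05, log2FC > 0)
#' lacking any key protein is attached to a KO by a `"taxon"`-evidence edge
#' when it has nonzero expression of some protein under that KO and the KO is
#' already anchored by a key protein of another species; this keeps evidence
#' provenance explicit while admitting taxon-level-only species into routes.
#' The per-pathway group is the sorted set of species attached to any of the
#' pathway's KOs.
#'
#' @param abundant_species character vector of positively associated species
#'   (taxon stage, p_adj < 0.05).
#' @param key_proteins key-protein table from [targeted_kos()].
#' @param catalog,maps catalog and function maps.
#' @param enriched_pathways enriched pathway IDs.
#' @param pel optional PEL matrix used to check expression for
#'   taxon-evidence edges; when `NULL` no taxon-evidence edges are added.
#' @return list of class `mp_routes` with `nodes` (id, type), `edges`
#'   (from, to, type, evidence), `groups` (pathway_id, species).
#' @export
build_routes <- function(abundant_species, key_proteins, catalog, maps,
                         enriched_pathways, pel = NULL) {
  empty <- list(
    nodes = data.frame(id = character(), type = character(),
                       stringsAsFactors = FALSE),
    edges = data.frame(from = character(), to = character(),
                       type = character(), evidence = character(),
                       stringsAsFactors = FALSE),
    groups = data.frame(pathway_id = character(), species = character(),
                        stringsAsFactors = FALSE))
  class(empty) <- "mp_routes"
  if (is.null(key_proteins) || nrow(key_proteins) == 0) {
    warning("empty key-protein set; returning empty route graph")
    return(empty)
  }
  kp <- maps$ko_pathway
  ## species-KO edges from key proteins
  sk <- unique(key_proteins[, c("species", "ko_id")])
  sk$evidence <- "protein"
  ## KO-pathway edges (targeted KOs restricted to enriched pathways)
  kos <- sort(unique(sk$ko_id))
  kpw <- unique(kp[kp$ko_id %in% kos & kp$pathway_id %in% enriched_pathways,
                   c("ko_id", "pathway_id")])
  ## taxon-evidence edges
  if (!is.null(pel) && length(abundant_species)) {
    lacking <- setdiff(abundant_species, unique(key_proteins$species))
    expr_sp <- rowSums(pel) > 0
    det <- catalog[match(rownames(pel)[expr_sp], catalog$protein_id),
                   c("species", "ko_id")]
    det <- det[!is.na(det$ko_id) & det$ko_id %in% kos, ]
    for (s in lacking) {
      kos_s <- unique(det$ko_id[det$species == s])
      for (k in kos_s) {
        anchored <- any(sk$ko_id == k & sk$species != s & sk$evidence == "protein")
        if (anchored)
          sk <- rbind(sk, data.frame(species = s, ko_id = k,
                                     evidence = "taxon",
                                     stringsAsFactors = FALSE))
      }
    }
  }
  sk <- unique(sk)
  sk <- sk[order(sk$species, sk$ko_id), ]

  nodes <- rbind(
    data.frame(id = sort(unique(sk$species)), type = "species",
               stringsAsFactors = FALSE),
    data.frame(id = sort(unique(c(sk$ko_id, kpw$ko_id))), type = "ko",
               stringsAsFactors = FALSE),
    data.frame(id = sort(unique(kpw$pathway_id)), type = "pathway",
               stringsAsFactors = FALSE))
  edges <- rbind(
    data.frame(from = sk$species, to = sk$ko_id, type = "species-ko",
               evidence = sk$evidence, stringsAsFactors = FALSE),
    data.frame(from = kpw$ko_id, to = kpw$pathway_id, type = "ko-pathway",
               evidence = "membership", stringsAsFactors = FALSE))
  edges <- edges[order(edges$type, edges$from, edges$to), ]
  rownames(edges) <- NULL
  ## drop orphan KO nodes (no pathway in the enriched set)
  linked_kos <- unique(kpw$ko_id)
  edges <- edges[!(edges$type == "species-ko" & !(edges$to %in% linked_kos)), ]
  used <- unique(c(edges$from, edges$to))
  nodes <- nodes[nodes$id %in% used, ]
  rownames(nodes) <- NULL

  groups <- do.call(rbind, lapply(sort(unique(kpw$pathway_id)), function(p) {
    k <- kpw$ko_id[kpw$pathway_id == p]
    sp <- sort(unique(sk$species[sk$ko_id %in% k]))
    if (!length(sp)) return(NULL)
    data.frame(pathway_id = p, species = sp, stringsAsFactors = FALSE)
  }))
  groups <- groups %||% empty$groups
  out <- list(nodes = nodes, edges = edges, groups = groups)
  class(out) <- "mp_routes"
  out
}

#' @export
print.mp_routes <- function(x, ...) {
  cat(sprintf("Route graph: %d species, %d KOs, %d pathways; %d edges\n",
              sum(x$nodes$type == "species"), sum(x$nodes$type == "ko"),
              sum(x$nodes$type == "pathway"), nrow(x$edges)))
  invisible(x)
}

#' Convert a route graph to igraph
#'
#' @param routes `mp_routes`.
#' @return igraph object with `type` node attribute and `evidence` edge
#'   attribute.
#' @export
routes_igraph <- function(routes) {
  igraph::graph_from_data_frame(
    routes$edges[, c("from", "to", "type", "evidence")],
    directed = FALSE, vertices = routes$nodes)
}

#' Export a route graph
#'
#' Writes GraphML plus an edge-list TSV and the per-pathway group table.
#'
#' @param routes `mp_routes`.
#' @param graphml_path,edges_path,groups_path output paths (NULL to skip).
#' @return invisibly, the written paths.
#' @export
write_routes <- function(routes, graphml_path = NULL, edges_path = NULL,
                         groups_path = NULL) {
  written <- character()
  if (!is.null(graphml_path)) {
    if (nrow(routes$edges)) {
      igraph::write_graph(routes_igraph(routes), graphml_path,
                          format = "graphml")
    } else {
      writeLines("<graphml/>", graphml_path)
    }
    written <- c(written, graphml_path)
  }
  if (!is.null(edges_path))
    written <- c(written, write_tsv(routes$edges, edges_path))
  if (!is.null(groups_path))
    written <- c(written, write_tsv(routes$groups, groups_path))
  invisible(written)
}

#' Group-mean PELs of key proteins (bubble table)
#'
#' Long table of protein x group mean PEL. Zeros are explicit: a protein
#' undetected in every sample of a group has mean 0 ("no bubble").
#'
#' @param protein_ids key protein IDs (must be rows of `pel`).
#' @param pel PEL matrix.
#' @param metadata sample metadata with `sample`, `group`.
#' @return data.frame `protein_id`, `group`, `mean_pel`.
#' @export
bubble_table <- function(protein_ids, pel, metadata) {
  miss <- setdiff(protein_ids, rownames(pel))
  if (length(miss)) stop("key protein absent from PEL matrix: ", miss[1])
  grp <- metadata$group[match(colnames(pel), metadata$sample)]
  sub <- pel[protein_ids, , drop = FALSE]
  means <- t(apply(sub, 1, function(r) tapply(r, grp, mean)))
  out <- data.frame(
    protein_id = rep(rownames(means), ncol(means)),
    group = rep(colnames(means), each = nrow(means)),
    mean_pel = as.vector(means), stringsAsFactors = FALSE)
  out[order(out$protein_id, out$group), ]
}
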