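#' Normalise a node symbol
#'
#' Uppercases, strips surrounding whitespace, converts internal whitespace
#' to underscores, and removes compartment suffixes of the form
#' `@compartment` (HGNC-style matching across sources requires exact
#' symbols). Idempotent.
#'
#' @param raw character vector of raw labels.
#' @return character vector of canonical symbols.
#' @export
normalize_symbol <- function(raw) {
  s <- trimws(raw)
  s <- sub("@.*$", "", s)
  s <- trimws(s)
  s <- gsub("[ \t]+", "_", s)
  s <- toupper(s)
  if (any(!nzchar(s))) stop("symbol empty after normalisation")
  s
}

#' Normalise all symbols in a network
#' @param net a [signed_network()].
#' @return a [signed_network()] with canonical ids (duplicates merged).
#' @export
normalize_network <- function(net) {
  nodes <- net$nodes
  edges <- net$edges
  nodes$id <- normalize_symbol(nodes$id)
  if (nrow(edges)) {
    edges$source <- normalize_symbol(edges$source)
    edges$target <- normalize_symbol(edges$target)
  }
  signed_network(nodes, edges)
}

#' Recreate the reactants of complex nodes
#'
#' Signalling maps often collapse a protein complex into a single node.
#' For each complex `C` with members `m1..mk`, member nodes are added (if
#' absent) and each member gets an `ACTIVATION` edge `mi -> C`, so that
#' overlays landing on members stay connected to the complex's targets.
#' All pre-existing edges are preserved.
#'
#' @param net a [signed_network()].
#' @param membership named list: complex node id -> character vector of
#'   member symbols. Every name must be a node of kind `COMPLEX`.
#' @return a [signed_network()].
#' @export
expand_complexes <- function(net, membership) {
  if (length(membership) == 0) return(net)
  complexes <- net$nodes$id[net$nodes$kind == "COMPLEX"]
  bad <- setdiff(names(membership), complexes)
  if (length(bad)) {
    stop("membership references non-complex node(s): ",
         paste(bad, collapse = ", "))
  }
  if (any(lengths(membership) == 0)) stop("empty member list in membership")
  new_members <- setdiff(unique(unlist(membership)), net$nodes$id)
  nodes <- net$nodes
  if (length(new_members)) {
    nodes <- rbind(nodes, data.frame(
      id = new_members, label = new_members, kind = "PROTEIN",
      origin = "MAP", stringsAsFactors = FALSE))
  }
  add <- do.call(rbind, lapply(names(membership), function(cx) {
    data.frame(source = membership[[cx]], target = cx, sign = "ACTIVATION",
               provenance = "complex_member", stringsAsFactors = FALSE)
  }))
  signed_network(nodes, rbind(net$edges, add))
}

#' Collapse duplicated entities onto one representative
#'
#' Maps (e.g. CellDesigner exports) often carry the same biological entity
#' several times, as a gene, an mRNA, and a protein. Each alias group is
#' collapsed onto its lexicographically smallest member; edges are
#' re-targeted, parallel duplicates merged, and self-edges arising purely
#' from the collapse dropped.
#'
#' @param net a [signed_network()].
#' @param alias_groups list of character vectors (pairwise disjoint).
#' @return a [signed_network()].
#' @export
deduplicate_entities <- function(net, alias_groups) {
  if (length(alias_groups) == 0) return(net)
  all_ids <- unlist(alias_groups)
  if (anyDuplicated(all_ids)) stop("alias groups must be pairwise disjoint")
  unknown <- setdiff(all_ids, net$nodes$id)
  if (length(unknown)) {
    stop("alias group references unknown id(s): ",
         paste(unknown, collapse = ", "))
  }
  remap <- setNames(net$nodes$id, net$nodes$id)
  for (grp in alias_groups) {
    rep_id <- min(grp)
    remap[grp] <- rep_id
  }
  nodes <- net$nodes[net$nodes$id %in% unique(remap), , drop = FALSE]
  edges <- net$edges
  if (nrow(edges)) {
    edges$source <- unname(remap[edges$source])
    edges$target <- unname(remap[edges$target])
    collapsed_self <- edges$source == edges$target &
      !(net$edges$source == net$edges$target)
    edges <- edges[!collapsed_self, , drop = FALSE]
  }
  signed_network(nodes, edges)
}

#' Exact intersection of TF symbol sets
#'
#' The interface between the co-regulatory network and the signalling map:
#' TFs present in both (after [normalize_symbol()]) seed the integration.
#' @param coreg_tfs,map_nodes character vectors of canonical symbols.
#' @return sorted character vector.
#' @export
match_tfs <- function(coreg_tfs, map_nodes) {
  sort(intersect(coreg_tfs, map_nodes))
}

#' Merge two signed networks into a global network
#'
#' Node set is the union keyed by id (origin becomes `BOTH` for shared
#' nodes; the first network's kind wins on conflict); the edge multiset is
#' the deduplicated union. A merge summary with per-sign counts is
#' attached as attribute `summary`.
#'
#' @param coreg,signalling [signed_network()] objects with normalised
#'   symbols.
#' @return a [signed_network()] with attribute `summary`.
#' @export
merge_networks <- function(coreg, signalling) {
  shared <- intersect(coreg$nodes$id, signalling$nodes$id)
  nodes <- rbind(coreg$nodes,
                 signalling$nodes[!signalling$nodes$id %in% coreg$nodes$id, ,
                                  drop = FALSE])
  nodes$origin[nodes$id %in% shared] <- "BOTH"
  merged <- signed_network(nodes, rbind(coreg$edges, signalling$edges))
  sgn <- table(factor(merged$edges$sign, levels = RALOGIC_SIGNS))
  attr(merged, "summary") <- list(
    n_nodes = nrow(merged$nodes),
    n_edges = nrow(merged$edges),
    n_activation = unname(sgn[["ACTIVATION"]]),
    n_inhibition = unname(sgn[["INHIBITION"]]),
    n_coregulation = unname(sgn[["COREGULATION"]]),
    shared_nodes = sort(shared))
  merged
}

# Directed adjacency (successor or predecessor lists) over
# activation/inhibition edges; co-regulation is non-directional evidence
# and is never traversed.
directed_adjacency <- function(net, mode = c("out", "in")) {
  mode <- match.arg(mode)
  e <- net$edges[net$edges$sign != "COREGULATION", , drop = FALSE]
  key <- if (mode == "out") e$source else e$target
  val <- if (mode == "out") e$target else e$source
  split(val, factor(key, levels = net$nodes$id))
}

induced_subnetwork <- function(net, keep_ids) {
  nodes <- net$nodes[net$nodes$id %in% keep_ids, , drop = FALSE]
  edges <- net$edges[net$edges$source %in% keep_ids &
                     net$edges$target %in% keep_ids, , drop = FALSE]
  signed_network(nodes, edges)
}

check_seeds <- function(net, seeds) {
  unknown <- setdiff(seeds, net$nodes$id)
  if (length(unknown)) {
    stop("unknown seed node(s): ", paste(unknown, collapse = ", "))
  }
}

#' Extract the upstream subnetwork of a set of seeds
#'
#' Induced subnetwork on all nodes with a directed path *to* a seed
#' (reverse reachability over activation and inhibition edges), seeds
#' included.
#'
#' @param net a [signed_network()].
#' @param seeds character vector of node ids.
#' @return a [signed_network()].
#' @export
extract_upstream <- function(net, seeds) {
  check_seeds(net, seeds)
  pred <- directed_adjacency(net, "in")
  visited <- unique(seeds)
  frontier <- visited
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(pred[frontier], use.names = FALSE)), visited)
    visited <- c(visited, nxt)
    frontier <- nxt
  }
  induced_subnetwork(net, visited)
}

#' Extract downstream cascades up to the first transcription factor
#'
#' Forward traversal from each seed over activation/inhibition edges. TF
#' nodes are absorbing: they are included when reached but their
#' successors are not expanded, yielding the cascade "up to the first
#' affected TF(s)". Edges among collected nodes are retained (induced
#' subnetwork).
#'
#' @param net a [signed_network()].
#' @param seeds character vector of node ids.
#' @param tf_set character vector of TF symbols (absorbing nodes).
#' @return a [signed_network()].
#' @export
extract_downstream_to_first_tf <- function(net, seeds, tf_set) {
  check_seeds(net, seeds)
  succ <- directed_adjacency(net, "out")
  visited <- unique(seeds)
  # seeds that are themselves TFs are kept but not expanded
  frontier <- setdiff(visited, tf_set)
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(succ[frontier], use.names = FALSE)), visited)
    visited <- c(visited, nxt)
    frontier <- setdiff(nxt, tf_set)
  }
  induced_subnetwork(net, visited)
}

#' Select differentially expressed genes at an FDR threshold
#'
#' Genes with FDR strictly below the threshold (default 0.1).
#' @param table an overlay table of kind `DEG`.
#' @param fdr_threshold numeric scalar.
#' @return sorted character vector of gene symbols.
#' @export
select_degs <- function(table, fdr_threshold = 0.1) {
  stopifnot(identical(attr(table, "kind"), "DEG"))
  sort(unique(as.character(table$gene[table$fdr < fdr_threshold])))
}

#' Filter disease variants by association and evidence scores
#'
#' Keeps rows with variant-disease-association (VDA) and evidence index
#' (EI) both at or above the thresholds (default 0.7; rows *lower than*
#' the threshold are removed, so the boundary is inclusive).
#'
#' @param table an overlay table of kind `VARIANT`.
#' @param vda_min,ei_min numeric thresholds.
#' @return list with `rows` (kept rows) and `genes` (distinct gene
#'   symbols of kept rows, sorted).
#' @export
filter_variants <- function(table, vda_min = 0.7, ei_min = 0.7) {
  stopifnot(identical(attr(table, "kind"), "VARIANT"))
  keep <- table$vda >= vda_min & table$ei >= ei_min
  rows <- as.data.frame(table)[keep, , drop = FALSE]
  rownames(rows) <- NULL
  list(rows = rows, genes = sort(unique(as.character(rows$gene))))
}

#' Project marker sets onto a network
#'
#' Keeps only symbols present in the network; non-matching symbols are
#' allowed and counted. Idempotent: projecting a projection changes
#' nothing.
#'
#' @param net a [signed_network()].
#' @param marker_sets named list: marker name (e.g. `DEG_RESPONSE`,
#'   `DEG_TREATMENT`, `VARIANT_CARRIER`) -> character vector of symbols.
#' @return object of class `network_overlay`: list with `markers` (named
#'   list of matched symbol vectors) and `report` (data frame of
#'   matched/unmatched counts per marker).
#' @export
project_overlay <- function(net, marker_sets) {
  ids <- net$nodes$id
  markers <- lapply(marker_sets, function(s) sort(intersect(unique(s), ids)))
  report <- data.frame(
    marker = names(marker_sets),
    matched = vapply(names(marker_sets), function(m)
      length(markers[[m]]), integer(1)),
    unmatched = vapply(names(marker_sets), function(m)
      length(setdiff(unique(marker_sets[[m]]), ids)), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(markers = markers, report = report),
            class = "network_overlay")
}
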