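#' Build the reaction graph of a model
#'
#' Reactions are nodes; a directed edge runs from reaction A to reaction B
#' when some product species of A is a substrate species of B. Currency
#' metabolites (ubiquitous cofactors) are excluded from edge induction,
#' otherwise they connect nearly everything to nearly everything and every
#' metric degenerates; the default list is explicit configuration and can
#' be overridden. Self-loops are dropped.
#'
#' The default exclusion list covers energy and redox carriers, water,
#' phosphate and photons. CO2 and O2 are deliberately kept: in a
#' photosynthetic network they are the substrates whose routing the
#' analysis is about (the CO2-concentrating shuttle is a CO2 path), not
#' bookkeeping cofactors.
#'
#' @param model A `stoich_model`.
#' @param currency_exclusions Character vector of metabolite base names or
#'   full ids excluded from edge induction.
#' @return A `reaction_graph`: list with `graph` (directed igraph object)
#'   and `currency_exclusions`.
#' @export
build_graph <- function(model,
                        currency_exclusions = c("atp", "adp", "amp", "nadp",
                                                "nadph", "nad", "nadh", "h",
                                                "h2o", "pi", "ppi",
                                                "photon")) {
  sto <- model$stoichiometry
  base <- sub("_[^_]*$", "", sto$metabolite_id)
  sto <- sto[!(base %in% currency_exclusions |
                 sto$metabolite_id %in% currency_exclusions), ]
  # a reversible reaction runs both ways, so each of its species is both
  # a substrate and a product for edge induction
  rev_ids <- model$reactions$id[model$reactions$lower_bound < 0]
  is_rev <- sto$reaction_id %in% rev_ids
  prod <- sto[sto$coefficient > 0 | is_rev, c("reaction_id", "metabolite_id")]
  subs <- sto[sto$coefficient < 0 | is_rev, c("reaction_id", "metabolite_id")]
  edges <- dplyr::inner_join(prod, subs, by = "metabolite_id",
                             suffix = c("_from", "_to"),
                             relationship = "many-to-many")
  edges <- unique(edges[edges$reaction_id_from != edges$reaction_id_to,
                        c("reaction_id_from", "reaction_id_to")])
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = sort(model$reactions$id)))
  structure(list(graph = g, currency_exclusions = currency_exclusions),
            class = "reaction_graph")
}

#' @export
print.reaction_graph <- function(x, ...) {
  cat(sprintf("<reaction_graph>  %d nodes, %d directed edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Topology metric panel of a reaction graph
#'
#' Computes the comparative topology panel: average degree and Freeman
#' degree centralization on the undirected view, average local clustering
#' coefficient (undirected), Freeman betweenness centralization (directed),
#' average and maximum directed shortest-path distance on the largest
#' strongly connected component, and the transitive-reduction redundancy of
#' [redundancy_score()]. Graphs with fewer than 3 nodes report
#' centralizations of 0 with a `small_graph` flag.
#'
#' @param graph A `reaction_graph` (or bare igraph object).
#' @return One-row tibble: `n_nodes`, `n_edges`, `average_degree`,
#'   `degree_centralization`, `average_clustering`,
#'   `betweenness_centralization`, `average_distance`, `maximum_distance`,
#'   `redundancy`, `small_graph`.
#' @export
metric_panel <- function(graph) {
  g <- if (inherits(graph, "reaction_graph")) graph$graph else graph
  n <- igraph::vcount(g)
  gu <- igraph::as_undirected(g, mode = "collapse")
  small <- n < 3
  avg_deg <- if (n) mean(igraph::degree(gu)) else NA_real_
  cent_deg <- if (small) 0 else
    igraph::centr_degree(gu, loops = FALSE)$centralization
  clus <- if (n) {
    tr <- igraph::transitivity(gu, type = "localundirected", isolates = "zero")
    mean(tr)
  } else NA_real_
  cent_btw <- if (small) 0 else
    igraph::centr_betw(g)$centralization
  # distances on the largest strongly connected component
  comp <- if (n) igraph::components(g, mode = "strong") else NULL
  if (!is.null(comp) && comp$no >= 1 && max(comp$csize) >= 2) {
    big <- which.max(comp$csize)
    sub <- igraph::induced_subgraph(g, which(comp$membership == big))
    D <- igraph::distances(sub, mode = "out")
    finite <- D[is.finite(D) & D > 0]
    avg_dist <- mean(finite)
    max_dist <- max(finite)
  } else {
    avg_dist <- NA_real_
    max_dist <- NA_real_
  }
  tibble::tibble(n_nodes = n, n_edges = igraph::ecount(g),
                 average_degree = avg_deg,
                 degree_centralization = cent_deg,
                 average_clustering = clus,
                 betweenness_centralization = cent_btw,
                 average_distance = avg_dist,
                 maximum_distance = max_dist,
                 redundancy = redundancy_score(graph),
                 small_graph = small)
}

#' Redundancy of a directed graph
#'
#' The share of edges that are redundant for reachability:
#' \eqn{1 - |E_{tr}| / |E|}, where \eqn{E_{tr}} is the transitive reduction
#' of the condensation of the graph (cycles are contracted to single nodes
#' first, so the reduction is well defined). Trees score 0; densely
#' shortcut networks approach 1.
#'
#' @param graph A `reaction_graph` or igraph object.
#' @return A number in \[0, 1); 0 for an empty edge set.
#' @export
redundancy_score <- function(graph) {
  g <- if (inherits(graph, "reaction_graph")) graph$graph else graph
  m <- igraph::ecount(g)
  if (m == 0) return(0)
  comp <- igraph::components(g, mode = "strong")
  el_full <- igraph::as_edgelist(g, names = FALSE)
  memb <- comp$membership
  intra_m <- sum(memb[el_full[, 1]] == memb[el_full[, 2]])
  # a strongly connected block of k >= 2 nodes needs k edges (one cycle)
  needed_intra <- sum(comp$csize[comp$csize >= 2])
  cond <- igraph::contract(g, memb)
  cond <- igraph::simplify(cond, remove.loops = TRUE, remove.multiple = TRUE)
  m_cond <- igraph::ecount(cond)
  inter_m <- m - intra_m
  intra <- max(0, intra_m - needed_intra) + (inter_m - m_cond)
  # transitive reduction of the DAG: edge (u,v) is redundant iff v is
  # reachable from u on a path of length >= 2
  el <- igraph::as_edgelist(cond, names = FALSE)
  redundant <- 0L
  if (nrow(el)) {
    adj <- lapply(igraph::V(cond), function(v)
      as.integer(igraph::neighbors(cond, v, mode = "out")))
    nv <- igraph::vcount(cond)
    reach2 <- function(u, v) {          # path u -> v of length >= 2?
      start <- setdiff(adj[[u]], v)
      if (!length(start)) return(FALSE)
      seen <- logical(nv)
      stack <- start
      while (length(stack)) {
        w <- stack[length(stack)]
        stack <- stack[-length(stack)]
        if (w == v) return(TRUE)
        if (!seen[w]) {
          seen[w] <- TRUE
          stack <- c(stack, adj[[w]])
        }
      }
      FALSE
    }
    for (i in seq_len(nrow(el))) {
      if (reach2(el[i, 1], el[i, 2])) redundant <- redundant + 1L
    }
  }
  (intra + redundant) / m
}
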