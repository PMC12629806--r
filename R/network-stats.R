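#' Construct a cell-type-specific gene network object
#'
#' Light container around a weighted undirected edge list, as produced by
#' reference-interactome-guided network inference run per patient or per
#' response group. Self-loops are dropped; isolated nodes may be supplied via
#' `nodes`.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `weight`.
#' @param id Network identifier (e.g. patient ID).
#' @param group Optional group label (e.g. `"R"` / `"NR"`).
#' @param nodes Optional character vector of node names; defaults to the
#'   genes appearing in `edges`.
#' @return A `gene_network` object.
#' @export
gene_network <- function(edges, id = "net", group = NA_character_,
                         nodes = NULL) {
  stopifnot(all(c("gene_a", "gene_b", "weight") %in% names(edges)))
  edges <- tibble::as_tibble(edges)[, c("gene_a", "gene_b", "weight")]
  edges <- edges[edges$gene_a != edges$gene_b, ]
  if (any(edges$weight < 0)) abort("edge weights must be nonnegative")
  nodes <- sort(unique(c(nodes, edges$gene_a, edges$gene_b)))
  if (length(nodes) == 0L) abort("network has no nodes")
  structure(list(id = id, group = group, nodes = nodes, edges = edges),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("Gene network '%s' (%s): %d nodes, %d edges\n",
              x$id, x$group, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$edges$gene_a, to = net$edges$gene_b,
               weight = net$edges$weight),
    directed = FALSE,
    vertices = data.frame(name = net$nodes))
  g
}

#' Binary node-membership profiles over a network union space
#'
#' Each network becomes a binary vector over the union of all node sets:
#' 1 when the gene was modeled in that network, 0 when it was not.
#'
#' @param nets List of `gene_network` objects (at least 2).
#' @return Binary matrix, networks x union genes, with network IDs as row
#'   names.
#' @export
node_profiles <- function(nets) {
  stopifnot(length(nets) >= 2L)
  universe <- sort(unique(unlist(lapply(nets, `[[`, "nodes"))))
  m <- t(vapply(nets, function(n) as.integer(universe %in% n$nodes),
                integer(length(universe))))
  dimnames(m) <- list(vapply(nets, `[[`, character(1), "id"), universe)
  m
}

#' Pairwise Euclidean distance between node profiles
#'
#' On binary membership rows this equals the square root of the Hamming
#' distance. Set `use_adjacency = TRUE` to compare flattened weighted
#' adjacency matrices over the union gene space instead of membership
#' vectors.
#'
#' @param x A binary profile matrix from [node_profiles()], or (with
#'   `use_adjacency`) a list of `gene_network`s.
#' @param use_adjacency Compare upper-triangle adjacency vectors instead of
#'   node-membership vectors.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
pairwise_profile_distance <- function(x, use_adjacency = FALSE) {
  if (use_adjacency) {
    stopifnot(is.list(x))
    universe <- sort(unique(unlist(lapply(x, `[[`, "nodes"))))
    rows <- t(vapply(x, function(n) {
      a <- matrix(0, length(universe), length(universe),
                  dimnames = list(universe, universe))
      a[cbind(n$edges$gene_a, n$edges$gene_b)] <- n$edges$weight
      a[cbind(n$edges$gene_b, n$edges$gene_a)] <- n$edges$weight
      a[upper.tri(a)]
    }, numeric(length(universe) * (length(universe) - 1L) / 2L)))
    rownames(rows) <- vapply(x, `[[`, character(1), "id")
    x <- rows
  }
  stopifnot(is.matrix(x), nrow(x) >= 2L)
  as.matrix(stats::dist(x, method = "euclidean"))
}

#' Compare within-group network similarity between two groups
#'
#' Pools the within-group pairwise profile distances of each group and
#' contrasts them with a two-sided t test (location) and a Fligner-Killeen
#' test (spread); together they ask whether one group's networks are more
#' homogeneous than the other's.
#'
#' @param d Distance matrix from [pairwise_profile_distance()].
#' @param groups Named vector or factor mapping network IDs (rownames of `d`)
#'   to exactly two group labels.
#' @return Tibble with `t_statistic`, `t_p.value`, `fk_statistic`,
#'   `fk_p.value` and per-group mean distances.
#' @export
group_similarity_tests <- function(d, groups) {
  ids <- rownames(d)
  g <- groups[ids]
  lv <- unique(stats::na.omit(g))
  if (length(lv) != 2L) abort("exactly two groups required")
  pool <- function(lab) {
    sub <- d[g == lab, g == lab, drop = FALSE]
    if (nrow(sub) < 2L) abort(sprintf("group '%s' has < 2 networks", lab))
    sub[upper.tri(sub)]
  }
  da <- pool(lv[1]); db <- pool(lv[2])
  tt <- t.test(da, db)
  fk <- fligner.test(list(da, db))
  tibble::tibble(
    group_a = as.character(lv[1]), group_b = as.character(lv[2]),
    mean_dist_a = mean(da), mean_dist_b = mean(db),
    t_statistic = unname(tt$statistic), t_p.value = tt$p.value,
    fk_statistic = unname(fk$statistic), fk_p.value = fk$p.value)
}

#' Percentile-rank degree centrality
#'
#' Weighted degree (strength) converted to a percentile rank in `(0, 1]`
#' (average rank for ties, divided by node count). Percentile ranks make
#' centralities comparable between networks of different sizes.
#'
#' @param net A `gene_network`.
#' @return Named numeric vector, one percentile per node.
#' @export
percentile_centrality <- function(net) {
  g <- as_igraph(net)
  s <- igraph::strength(g)
  setNames(rank(s, ties.method = "average") / length(s), names(s))
}

#' Louvain subcommunities of a gene network
#'
#' @param net A `gene_network`.
#' @param resolution Louvain resolution parameter.
#' @param seed Integer seed (vertex-order randomization).
#' @return Tibble with `gene`, `community` (communities numbered by
#'   decreasing size).
#' @export
detect_communities <- function(net, resolution = 1, seed = 1L) {
  g <- as_igraph(net)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(cl)
  ord <- order(-as.vector(table(memb)[as.character(sort(unique(memb)))]),
               sort(unique(memb)))
  relabel <- setNames(seq_along(ord), sort(unique(memb))[ord])
  tibble::tibble(gene = names(memb),
                 community = as.integer(relabel[as.character(memb)]))
}

#' Differential-hub signature between two networks
#'
#' Within a subcommunity of interest of network A, finds the genes modeled in
#' both networks whose percentile-rank centrality is strictly higher in A
#' than in B, ranks them by centrality in A, and keeps the top `top_n` -- the
#' procedure that turns "hubbier in responders" into a gene signature.
#'
#' @param net_a,net_b `gene_network`s to contrast (A = reference, e.g.
#'   responders).
#' @param community Character vector of genes, a subset of `net_a`'s nodes.
#' @param top_n Signature size cap (default 30).
#' @return A `hub_signature` tibble: `gene`, `centrality_a`, `centrality_b`,
#'   ordered by decreasing `centrality_a`.
#' @export
differential_hub_signature <- function(net_a, net_b, community, top_n = 30) {
  missing <- setdiff(community, net_a$nodes)
  if (length(missing)) {
    abort(paste0("community genes absent from net_a: ",
                 paste(missing, collapse = ", ")))
  }
  pa <- percentile_centrality(net_a)
  pb <- percentile_centrality(net_b)
  cand <- intersect(community, net_b$nodes)
  cand <- cand[pa[cand] > pb[cand]]
  if (length(cand) == 0L) {
    warn("no gene has strictly higher centrality in net_a; empty signature")
  }
  out <- tibble::tibble(gene = cand,
                        centrality_a = unname(pa[cand]),
                        centrality_b = unname(pb[cand]))
  out <- dplyr::arrange(out, dplyr::desc(.data$centrality_a), .data$gene)
  out <- head(out, top_n)
  class(out) <- c("hub_signature", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.hub_signature <- function(object, ...) {
  d <- tidyr::pivot_longer(tibble::as_tibble(object),
                           dplyr::starts_with("centrality_"),
                           names_to = "network", values_to = "percentile",
                           names_prefix = "centrality_")
  d$gene <- factor(d$gene, levels = rev(object$gene))
  ggplot2::ggplot(d, ggplot2::aes(.data$percentile, .data$gene,
                                  colour = .data$network)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "percentile-rank centrality", y = NULL) +
    ggplot2::theme_minimal()
}
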