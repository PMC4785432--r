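#' First-neighbour PPI subnetwork around seed genes
#'
#' Nodes are the seeds plus their direct neighbours in the parental
#' network; retained edges are the parental edges with at least one seed
#' endpoint (neighbour--neighbour edges are excluded by default). Seeds
#' absent from the parent are kept as isolated nodes with a warning.
#'
#' @param ppi parental [igraph::graph] with named vertices.
#' @param seeds seed gene ids.
#' @param include_neighbor_edges also keep neighbour--neighbour edges.
#' @return the subnetwork as an igraph graph.
#' @export
first_neighbor_subnetwork <- function(ppi, seeds,
                                      include_neighbor_edges = FALSE) {
  seeds <- unique(seeds)
  missing <- setdiff(seeds, igraph::V(ppi)$name)
  if (length(missing) > 0)
    warning(length(missing),
            " seed(s) absent from the parental network; kept isolated")
  present <- setdiff(seeds, missing)
  if (length(present) == 0) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    return(igraph::add_vertices(g, length(missing), name = missing))
  }
  nbrs <- unique(unlist(lapply(igraph::adjacent_vertices(ppi, present),
                               names)))
  nodes <- union(present, nbrs)
  sub <- igraph::induced_subgraph(ppi, nodes)
  if (!include_neighbor_edges) {
    el <- igraph::as_edgelist(sub)
    drop <- !(el[, 1] %in% present) & !(el[, 2] %in% present)
    sub <- igraph::delete_edges(sub, which(drop))
  }
  if (length(missing) > 0)
    sub <- igraph::add_vertices(sub, length(missing), name = missing)
  sub
}

#' Topology summary of a network
#'
#' Reports the degree distribution P(k) (number of nodes of each degree),
#' the mean local clustering coefficient (nodes of degree < 2 contribute
#' 0), the mean neighbourhood connectivity (average over nodes of the
#' mean degree of their neighbours; isolated nodes excluded), the
#' diameter of the largest connected component, the edge density, the
#' Freeman degree centralization and the degree heterogeneity
#' (coefficient of variation of the degrees, population SD).
#'
#' @param g an igraph graph (non-empty).
#' @return list(degree_distribution (data.frame k, count),
#'   mean_clustering, mean_neighborhood_connectivity, diameter, density,
#'   centralization, heterogeneity).
#' @export
topology_summary <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0) stop("empty graph")
  deg <- igraph::degree(g)
  dd <- as.data.frame(table(deg), stringsAsFactors = FALSE)
  names(dd) <- c("k", "count")
  dd$k <- as.integer(dd$k)

  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[deg < 2] <- 0

  nbc <- vapply(seq_len(n), function(v) {
    nb <- igraph::neighbors(g, v)
    if (length(nb) == 0) NA_real_ else mean(deg[as.integer(nb)])
  }, numeric(1))

  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  diam <- igraph::diameter(
    igraph::induced_subgraph(g, which(comp$membership == big)),
    unconnected = FALSE)

  centralization <- if (n > 2)
    sum(max(deg) - deg) / ((n - 1) * (n - 2)) else 0
  mu <- mean(deg)
  het <- if (mu > 0) sqrt(mean((deg - mu)^2)) / mu else 0

  list(degree_distribution = dd,
       mean_clustering = mean(cc),
       mean_neighborhood_connectivity = mean(nbc, na.rm = TRUE),
       diameter = diam,
       density = igraph::edge_density(g),
       centralization = centralization,
       heterogeneity = het)
}

#' Fit a power law to a degree distribution
#'
#' Least-squares line on (log10 k, log10 P(k)) for the positive
#' coordinates (k = 0 and zero counts are excluded), giving
#' `P(k) = beta * k^a`. The fit's R-squared measures the log--log
#' linearity.
#'
#' @param dd data.frame with columns k and count.
#' @return list(beta, a, r_squared, n_points).
#' @export
fit_power_law <- function(dd) {
  dd <- dd[dd$k > 0 & dd$count > 0, , drop = FALSE]
  if (nrow(dd) < 2)
    stop("need at least 2 positive-degree points for the power-law fit")
  fit <- stats::lm(log10(count) ~ log10(k), data = dd)
  y <- log10(dd$count)
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sstot
  list(beta = 10^unname(coef(fit)[1]), a = unname(coef(fit)[2]),
       r_squared = r2, n_points = nrow(dd))
}
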