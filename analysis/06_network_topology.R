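#!/usr/bin/env Rscript
# Stage 6 -- PPI first-neighbour subnetwork and topology of the
# regulated genes.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_config.R"))

inp <- read_study_inputs(INPUTS)
seeds <- readLines(file.path(RESULTS, "regulated_genes.txt"))

sub <- suppressWarnings(first_neighbor_subnetwork(inp$ppi, seeds))
write_sif(sub, file.path(RESULTS, "subnetwork.sif"))
ts <- topology_summary(sub)
rep <- data.frame(
  statistic = c("nodes", "edges", "diameter", "density",
                "mean_clustering", "mean_neighborhood_connectivity",
                "centralization", "heterogeneity"),
  value = c(igraph::vcount(sub), igraph::ecount(sub), ts$diameter,
            ts$density, ts$mean_clustering,
            ts$mean_neighborhood_connectivity, ts$centralization,
            ts$heterogeneity))
write.table(rep, file.path(RESULTS, "topology.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ts$degree_distribution,
            file.path(RESULTS, "degree_distribution.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

msg("subnetwork: %d nodes, %d edges, diameter %d",
    igraph::vcount(sub), igraph::ecount(sub), ts$diameter)
dd <- ts$degree_distribution
if (sum(dd$k > 0 & dd$count > 0) >= 2) {
  pl <- fit_power_law(dd)
  msg("degree distribution P(k) ~ %.2f * k^%.2f (R2 = %.2f)",
      pl$beta, pl$a, pl$r_squared)
} else {
  msg("degree distribution too degenerate for a power-law fit")
}
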