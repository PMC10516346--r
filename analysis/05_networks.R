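#!/usr/bin/env Rscript
# Stage 5: competitive networks.
#
# Builds the directed networks per pH -- single-control and SvS-control
# rate-ratio networks and the EoC-wins network -- and exports each as JSON
# plus an edge-list CSV. Prints each species' out-width sum (node size), the
# ranking the network plots encode.

suppressPackageStartupMessages(library(fungalcompete))

fits <- utils::read.csv("results/growth_fits.csv")
svs_fits <- utils::read.csv("results/svs_fits.csv")
eoc <- utils::read.csv("results/eoc.csv")

for (ph in sort(unique(fits$ph))) {
  nets <- list(
    single_control = build_control_network(fits, ph, "single"),
    svs_control = build_control_network(svs_fits, ph, "svs"),
    eoc_wins = build_eoc_network(eoc, ph)
  )
  cat(sprintf("\n== pH %s ==\n", ph))
  for (metric in names(nets)) {
    net <- nets[[metric]]
    export_network(net,
                   sprintf("results/network_%s_ph%s.json", metric, ph),
                   sprintf("results/network_%s_ph%s.csv", metric, ph))
    ranked <- net$nodes[order(-net$nodes$size), ]
    cat(sprintf("%-15s top: %s (%.1f), weakest: %s (%.1f)\n", metric,
                ranked$id[1], ranked$size[1],
                ranked$id[nrow(ranked)], ranked$size[nrow(ranked)]))
  }
}

cat("\nnetworks exported under results/\n")
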