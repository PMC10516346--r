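#!/usr/bin/env Rscript
# Stage 3: competition metrics.
#
# Computes the effect-of-competition (EoC) ratio for every competition plug
# against its pH-matched SvS baseline, the per-pH growth-rate distance
# matrices, and the patristic distance matrix from the phylogeny; then tests
# for identity-by-pH interactions with the factorial linear model.

suppressPackageStartupMessages(library(fungalcompete))

fits <- utils::read.csv("results/growth_fits.csv")
svs_fits <- utils::read.csv("results/svs_fits.csv")
comp_fits <- fits[fits$treatment == "competition", ]

eoc <- compute_eoc(comp_fits, svs_fits, response = "growth_rate")
utils::write.csv(eoc, "results/eoc.csv", row.names = FALSE)
cat(sprintf("EoC computed for %d competition plugs; %d (%.0f%%) below 1\n",
            nrow(eoc), sum(eoc$eoc < 1), 100 * mean(eoc$eoc < 1)))

tree <- read_newick("results/tree.nwk")
species <- sort(unique(fits$focal))
patristic <- patristic_distances(tree, species)
write_dist_matrix(patristic, "results/dist_patristic.csv")

for (ph in sort(unique(fits$ph))) {
  gd <- growth_distance(svs_fits, ph, response = "growth_rate")
  write_dist_matrix(gd, sprintf("results/dist_growth_ph%s.csv", ph))
}

ilm <- fit_interaction_lm(eoc)
cat(sprintf(
  "EoC ~ focal x opponent x pH: F_%d,%d = %.2f, p = %.3g, adj R2 = %.3f\n",
  ilm$df_num, ilm$df_den, ilm$f_stat, ilm$p_value, ilm$adj_r_squared))
if (length(ilm$aliased)) {
  cat(sprintf("  %d coefficients aliased by the incomplete focal/opponent crossing\n",
              length(ilm$aliased)))
}
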