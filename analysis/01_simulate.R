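#!/usr/bin/env Rscript
# Stage 1: generate the in-silico experiment.
#
# Reproduces the design of the plate assay: 5 ectomycorrhizal species, media
# at pH 5.6 and 7.0, single / self-vs-self (SvS) / pairwise competition
# treatments, 10 replicates each (400 plates), ~8% attrition. Writes the
# plate table, the simulated phylogeny and the generative ground truth under
# results/.

suppressPackageStartupMessages(library(fungalcompete))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cfg <- sim_config(tree_seed = 101, noise_seed = 202)
sim <- simulate_experiment(cfg)

write_plates(sim$plates, file.path(out_dir, "plates.csv"))
writeLines(sim$truth$tree, file.path(out_dir, "tree.nwk"))
jsonlite::write_json(
  list(coefficients = as.list(sim$truth$coefficients),
       rate_table = sim$truth$rate_table,
       eoc_table = sim$truth$eoc_table),
  file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)

meta <- unique(sim$plates[c("plate_id", "treatment", "excluded")])
cat(sprintf("simulated %d plates (%d single, %d SvS, %d competition)\n",
            nrow(meta), sum(meta$treatment == "single"),
            sum(meta$treatment == "SvS"),
            sum(meta$treatment == "competition")))
cat(sprintf("%d plates (%.1f%%) flagged excluded\n", sum(meta$excluded),
            100 * mean(meta$excluded)))
cat(sprintf("true log-EoC model: beta0 = %.3f, beta_dist = %.3f, beta_ph = %.3f\n",
            cfg$beta0, cfg$beta_dist, cfg$beta_ph))
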