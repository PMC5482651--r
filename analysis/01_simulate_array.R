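#!/usr/bin/env Rscript
# Generates the synthetic two-channel array experiment used by the array
# analysis: a desk-scale pan-pathogen array (2,000 non-human probes, 100
# human reference probes) over 20 cancer, 10 matched-control and 10
# non-matched-control samples, with a handful of planted taxa emulating
# the kind of structure the screen is designed to detect: cancer-specific
# taxa at varying prevalence, one control-specific taxon, and one taxon
# shared between cancer and the matched controls.
library(pathosig)

outdir <- "results/sim_array"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

taxa <- data.frame(
  name = c("Shewanella", "Pediococcus", "Cladosporium", "Morganella",
           "Geotrichum"),
  family = c("Shewanellaceae", "Lactobacillaceae", "Cladosporiaceae",
             "Morganellaceae", "Dipodascaceae"),
  group = c("Proteobacteria", "Firmicutes", "Dothideomycetes",
            "Proteobacteria", "Saccharomycetes"),
  kingdom = c("bacteria", "bacteria", "fungus", "bacteria", "fungus"),
  n_probes = c(12, 12, 8, 8, 8),
  planted_group = c("cancer", "cancer", "cancer", "matched_control",
                    "cancer"),
  effect_size = c(3, 2.5, 3, 3, 2.5),
  prevalence_target = c(0.9, 0.6, 1, 1, 1))
# Geotrichum is also planted in both control groups (shared signature)
taxa <- rbind(taxa,
              within(taxa[5, ], planted_group <- "matched_control"),
              within(taxa[5, ], planted_group <- "nonmatched_control"))
taxa$effect_size[6:7] <- 4  # stronger in controls than in cancer

cfg <- array_sim_config(taxa = taxa, seed = 20260301)
sim <- simulate_array(cfg)

write_signal_table(sim$experiment,
                   file.path(outdir, "green.tsv"),
                   file.path(outdir, "red.tsv"),
                   file.path(outdir, "groups.tsv"))
write_probe_annotation(sim$annotation, file.path(outdir, "annotation.tsv"))
write.table(sim$truth, file.path(outdir, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Simulated", nrow(sim$experiment$green), "probes x",
    ncol(sim$experiment$green), "samples;", nrow(sim$truth),
    "planted taxon/group effects.\n")
cat("Inputs written under", outdir, "\n")
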