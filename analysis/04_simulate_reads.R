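#!/usr/bin/env Rscript
# Generates the capture-sequencing inputs for the integration analysis:
# a 3-virus metagenome, a 2-chromosome host genome with gene models and
# capture-probe regions, and 250-nt single-end reads containing chimeric
# virus-host junction reads for five planted integrations among pure-host
# and pure-virus (capture-enriched) background.
library(pathosig)

outdir <- "results/sim_reads"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

base_cfg <- read_sim_config(seed = 20260302)
refs <- simulate_references(base_cfg)
set.seed(20260303)
ints <- sample_integration_sites(refs, 5,
                                 n_spanning_reads = c(12, 8, 8, 6, 5))
cfg <- read_sim_config(seed = 20260304, integrations = ints,
                       n_background_host = 400, n_background_virus = 400,
                       substitution_rate = 0.002)
rs <- simulate_reads(refs, cfg)

write_sequences(refs$viral, file.path(outdir, "viral.fasta"))
write_sequences(refs$host, file.path(outdir, "host.fasta"))
write_gene_models_gff3(refs$genes, file.path(outdir, "genes.gff3"))
write_regions_bed(refs$capture, file.path(outdir, "capture.bed"))
write_sequences(rs$reads, file.path(outdir, "reads.fastq"))
write.table(rs$truth, file.path(outdir, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Planted", nrow(ints), "integrations:\n")
print(ints)
cat("Emitted", length(rs$reads), "reads (",
    sum(ints$n_spanning_reads), "junction-spanning ) under", outdir, "\n")
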