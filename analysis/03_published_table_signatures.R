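#!/usr/bin/env Rscript
# Recomputes, from the packaged transcription of the published signature
# membership table, the quantities printed in the study: the per-kingdom
# unique/shared partition counts, the phylum distribution of the
# cancer-detected bacterial genera, and the tumorigenic fraction of the
# cancer-detected viral families.
library(pathosig)

outdir <- "results/table1"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

fix <- load_table1_fixture()
rows <- list()
for (k in names(fix)) {
  d <- membership_detected_sets(fix, k)
  cmp <- compare_sets(d$cancer, d$mc, d$nc)
  write_set_comparison(cmp, file.path(outdir, paste0("partition_", k, ".tsv")),
                       kingdom = k)
  rows[[k]] <- data.frame(kingdom = k, t(cmp$counts))
}
counts <- do.call(rbind, rows)
write.table(counts, file.path(outdir, "partition_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(counts)

bact <- membership_detected_sets(fix, "bacteria")
dist <- phylum_distribution(compare_sets(bact$cancer, bact$mc, bact$nc),
                            attr(fix, "phylum_of"))
write.table(data.frame(phylum = names(dist), percent = unname(dist)),
            file.path(outdir, "phylum_distribution.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nPhylum distribution of cancer-detected bacterial genera (%):\n")
print(dist)

vir <- membership_detected_sets(fix, "virus")
tf <- tumorigenic_fraction(compare_sets(vir$cancer, vir$mc, vir$nc))
cat("\nTumorigenic viral families among cancer-detected families:",
    tf, "%\n")
write.table(data.frame(quantity = "tumorigenic_viral_fraction_percent",
                       value = tf),
            file.path(outdir, "tumorigenic_fraction.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Outputs written under", outdir, "\n")
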