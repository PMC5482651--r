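# small in-code fixtures shared across test files

tiny_annotation <- function() {
  probe_annotation(
    probe_id = c("P1", "P2", "P3", "P4", "H1"),
    target_accession = c("A1", "A1", "A2", "A3", "HS"),
    taxon = c("Shewanella", "Shewanella", "Pediococcus", "Geotrichum", "Homo"),
    family = c("Shewanellaceae", "Shewanellaceae", "Lactobacillaceae",
               "Dipodascaceae", "Hominidae"),
    group = c("Proteobacteria", "Proteobacteria", "Firmicutes",
              "Saccharomycetes", "human reference"),
    kingdom = c("bacteria", "bacteria", "bacteria", "fungus", "human"),
    probe_class = c("specific", "conserved", "specific", "specific",
                    "human_reference"),
    metagenome_chrom = "meta1",
    start = c(100, 200, 300, 400, 500),
    end = c(159, 259, 359, 459, 559))
}

tiny_experiment <- function(green, red,
                            groups = c(S1 = "cancer", S2 = "matched_control")) {
  array_experiment(green, red, groups)
}

# normalized_matrix built directly from a signal matrix
as_norm <- function(n, groups) {
  structure(list(n = n,
                 scale_factors = stats::setNames(rep(1, ncol(n)), colnames(n)),
                 groups = groups[colnames(n)]),
            class = "normalized_matrix")
}

random_seqs <- function(n, len, prefix = "s") {
  stats::setNames(
    vapply(seq_len(n),
           function(i) paste(sample(c("A", "C", "G", "T"), len, TRUE),
                             collapse = ""),
           character(1)),
    paste0(prefix, seq_len(n)))
}
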