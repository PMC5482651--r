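#' Gene model sets
#'
#' Internal container for host gene models used to annotate integration
#' breakpoints: a `genes` table (gene_id, chrom, strand, start, end) and an
#' `exons` table (gene_id, start, end). All coordinates are 1-based
#' inclusive; conversion from 0-based half-open BED happens at the format
#' boundary only.
#'
#' @param genes data.frame with columns gene_id, chrom, strand, start, end.
#' @param exons data.frame with columns gene_id, start, end.
#' @return An object of class `gene_model_set`.
#' @export
gene_model_set <- function(genes, exons) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  if (nrow(genes) > 0) {
    if (any(genes$start > genes$end)) stop("gene with start > end")
    if (any(duplicated(genes$gene_id))) stop("duplicate gene_id")
    if (!all(genes$strand %in% c("+", "-"))) stop("strand must be + or -")
  }
  if (nrow(exons) > 0) {
    span <- genes[match(exons$gene_id, genes$gene_id), ]
    if (any(is.na(span$gene_id))) stop("exon with unknown gene_id")
    outside <- exons$start < span$start | exons$end > span$end
    if (any(outside)) {
      stop("exon outside gene span for gene: ",
           paste(unique(exons$gene_id[outside]), collapse = ", "))
    }
    # sort and check per-gene non-overlap
    exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ]
    for (g in unique(exons$gene_id)) {
      e <- exons[exons$gene_id == g, ]
      if (nrow(e) > 1 && any(e$start[-1] <= e$end[-nrow(e)])) {
        stop("overlapping exons in gene: ", g)
      }
    }
  }
  structure(list(genes = genes, exons = exons), class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat("gene_model_set:", nrow(x$genes), "genes,", nrow(x$exons), "exons\n")
  invisible(x)
}

empty_gene_model_set <- function() {
  gene_model_set(
    data.frame(gene_id = character(), chrom = character(),
               strand = character(), start = integer(), end = integer()),
    data.frame(gene_id = character(), start = integer(), end = integer()))
}

#' Read gene models from GFF3 or BED12
#'
#' GFF3 input uses `gene` features (with `ID`) and `exon` features (with
#' `Parent`); BED12 input takes each line as one gene whose blocks are its
#' exons. Both converge on identical 1-based inclusive internal
#' coordinates.
#'
#' @param path a `.gff3`/`.gff` or `.bed` file.
#' @return A [gene_model_set()].
#' @export
read_gene_models <- function(path) {
  if (length(readLines(path, warn = FALSE)) == 0) return(empty_gene_model_set())
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    if (length(gr) == 0) return(empty_gene_model_set())
    genes <- data.frame(
      gene_id = gr$name,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE)
    if (!is.null(gr$blocks)) {
      rel <- gr$blocks  # block positions relative to gene start (1-based)
      n_per <- S4Vectors::elementNROWS(rel)
      flat <- unlist(rel, use.names = FALSE)
      off <- rep(genes$start, n_per) - 1L
      exons <- data.frame(
        gene_id = rep(genes$gene_id, n_per),
        start = IRanges::start(flat) + off,
        end = IRanges::end(flat) + off,
        stringsAsFactors = FALSE)
    } else {
      exons <- data.frame(gene_id = genes$gene_id, start = genes$start,
                          end = genes$end, stringsAsFactors = FALSE)
    }
    return(gene_model_set(genes, exons))
  }
  gr <- rtracklayer::import(path, format = "GFF3")
  is_gene <- gr$type == "gene"
  is_exon <- gr$type == "exon"
  if (!any(is_gene)) return(empty_gene_model_set())
  gg <- gr[is_gene]
  genes <- data.frame(
    gene_id = gg$ID,
    chrom = as.character(GenomicRanges::seqnames(gg)),
    strand = as.character(GenomicRanges::strand(gg)),
    start = GenomicRanges::start(gg),
    end = GenomicRanges::end(gg),
    stringsAsFactors = FALSE)
  ge <- gr[is_exon]
  parent <- vapply(as.list(ge$Parent), function(p) p[1], character(1))
  exons <- data.frame(
    gene_id = parent,
    start = GenomicRanges::start(ge),
    end = GenomicRanges::end(ge),
    stringsAsFactors = FALSE)
  gene_model_set(genes, exons)
}

#' Write gene models as GFF3
#'
#' @param models a [gene_model_set()].
#' @param path output path.
#' @export
write_gene_models_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(models$genes))) {
    g <- models$genes[i, ]
    writeLines(sprintf("%s\tpathosig\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, g$start, g$end, g$strand, g$gene_id), con)
    e <- models$exons[models$exons$gene_id == g$gene_id, ]
    if (nrow(e) > 0) {
      writeLines(sprintf("%s\tpathosig\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                         g$chrom, e$start, e$end, g$strand, g$gene_id,
                         seq_len(nrow(e)), g$gene_id), con)
    }
  }
  invisible(path)
}
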