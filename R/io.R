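#' Probe annotation tables
#'
#' A probe annotation maps each array probe to its target taxon, family,
#' higher group (e.g. "dsDNA virus" or a bacterial phylum), kingdom,
#' probe class and metagenome coordinates. Human reference probes
#' (`probe_class == "human_reference"`) carry `kingdom == "human"` and are
#' used only for scale-factor computation.
#'
#' @param probe_id,target_accession,taxon,family,group character vectors.
#' @param kingdom character vector over `c("virus","bacteria","fungus",
#'   "parasite","human")`.
#' @param probe_class character vector over `c("conserved","specific",
#'   "human_reference")`.
#' @param metagenome_chrom character vector of target reference names.
#' @param start,end 1-based inclusive integer coordinates on the target.
#' @return A `data.frame` of class `probe_annotation`, one row per probe.
#' @export
probe_annotation <- function(probe_id, target_accession, taxon, family, group,
                             kingdom, probe_class, metagenome_chrom,
                             start, end) {
  ann <- data.frame(
    probe_id = as.character(probe_id),
    target_accession = as.character(target_accession),
    taxon = as.character(taxon),
    family = as.character(family),
    group = as.character(group),
    kingdom = as.character(kingdom),
    probe_class = as.character(probe_class),
    metagenome_chrom = as.character(metagenome_chrom),
    start = as.integer(start),
    end = as.integer(end),
    stringsAsFactors = FALSE
  )
  class(ann) <- c("probe_annotation", "data.frame")
  validate_probe_annotation(ann)
}

kingdom_levels <- c("virus", "bacteria", "fungus", "parasite", "human")
probe_class_levels <- c("conserved", "specific", "human_reference")

validate_probe_annotation <- function(ann) {
  dup <- ann$probe_id[duplicated(ann$probe_id)]
  if (length(dup) > 0) {
    stop("duplicate probe_id: ", paste(unique(dup), collapse = ", "))
  }
  bad_k <- setdiff(unique(ann$kingdom), kingdom_levels)
  if (length(bad_k) > 0) {
    stop("unknown kingdom value: ", paste(bad_k, collapse = ", "))
  }
  bad_c <- setdiff(unique(ann$probe_class), probe_class_levels)
  if (length(bad_c) > 0) {
    stop("unknown probe_class value: ", paste(bad_c, collapse = ", "))
  }
  if (any(ann$start > ann$end)) {
    stop("probe with start > end: ",
         paste(ann$probe_id[ann$start > ann$end], collapse = ", "))
  }
  human_mismatch <- xor(ann$probe_class == "human_reference",
                        ann$kingdom == "human")
  if (any(human_mismatch)) {
    stop("probe_class 'human_reference' and kingdom 'human' must coincide: ",
         paste(ann$probe_id[human_mismatch], collapse = ", "))
  }
  nonhuman <- ann$kingdom != "human"
  empty <- nonhuman & (is.na(ann$taxon) | ann$taxon == "" |
                         is.na(ann$family) | ann$family == "")
  if (any(empty)) {
    stop("non-human probe lacking taxon/family: ",
         paste(ann$probe_id[empty], collapse = ", "))
  }
  ann
}

#' Read / write a probe annotation table
#'
#' Tab-separated with a header line naming the `probe_annotation()` fields.
#'
#' @param path file path.
#' @return [read_probe_annotation()] returns a validated `probe_annotation`;
#'   [write_probe_annotation()] returns `path` invisibly.
#' @export
read_probe_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  needed <- c("probe_id", "target_accession", "taxon", "family", "group",
              "kingdom", "probe_class", "metagenome_chrom", "start", "end")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0) {
    stop("annotation file lacks columns: ", paste(missing, collapse = ", "))
  }
  probe_annotation(tab$probe_id, tab$target_accession, tab$taxon, tab$family,
                   tab$group, tab$kingdom, tab$probe_class,
                   tab$metagenome_chrom, as.integer(tab$start),
                   as.integer(tab$end))
}

#' @rdname read_probe_annotation
#' @param annotation a `probe_annotation`.
#' @export
write_probe_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Two-channel array experiments
#'
#' Container for raw probe-level two-channel intensities: a green (sample,
#' Cy3) and a red (reference, Cy5) matrix of shape probes x samples, plus a
#' group label per sample.
#'
#' @param green,red numeric matrices, probes x samples, with identical
#'   dimnames; intensities must be non-negative.
#' @param groups named character vector mapping every sample to one of
#'   `c("cancer","matched_control","nonmatched_control")`.
#' @return An object of class `array_experiment`.
#' @export
array_experiment <- function(green, red, groups) {
  green <- as.matrix(green)
  red <- as.matrix(red)
  if (!identical(dim(green), dim(red)) ||
      !identical(dimnames(green), dimnames(red))) {
    stop("green and red matrices must share probes and samples ",
         "(axis mismatch: green ", nrow(green), "x", ncol(green),
         ", red ", nrow(red), "x", ncol(red), ")")
  }
  if (is.null(rownames(green)) || is.null(colnames(green))) {
    stop("intensity matrices need probe rownames and sample colnames")
  }
  if (any(green < 0) || any(red < 0)) stop("negative intensity")
  groups <- groups[colnames(green)]
  if (any(is.na(groups))) {
    stop("sample lacking a group label: ",
         paste(colnames(green)[is.na(groups)], collapse = ", "))
  }
  bad <- setdiff(unique(groups), group_levels)
  if (length(bad) > 0) stop("unknown group label: ", paste(bad, collapse = ", "))
  structure(list(green = green, red = red,
                 groups = stats::setNames(as.character(groups),
                                          colnames(green))),
            class = "array_experiment")
}

group_levels <- c("cancer", "matched_control", "nonmatched_control")

#' @export
print.array_experiment <- function(x, ...) {
  cat("array_experiment:", nrow(x$green), "probes x", ncol(x$green),
      "samples\n")
  print(table(x$groups))
  invisible(x)
}

#' Read a two-channel signal table pair
#'
#' Reads the green and red probe x sample intensity matrices (TSV, probe ids
#' in the first column, sample ids in the header) together with a two-column
#' sample-to-group table (`sample`, `group`).
#'
#' @param green_path,red_path,groups_path file paths.
#' @return An [array_experiment()].
#' @export
read_signal_table <- function(green_path, red_path, groups_path) {
  g <- read_matrix_tsv(green_path)
  r <- read_matrix_tsv(red_path)
  if (!identical(dimnames(g), dimnames(r))) {
    stop("axis mismatch between green (", nrow(g), "x", ncol(g),
         ") and red (", nrow(r), "x", ncol(r), ") signal tables")
  }
  gr <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(gr))) {
    stop("groups file needs columns 'sample' and 'group'")
  }
  array_experiment(g, r, stats::setNames(gr$group, gr$sample))
}

#' Write an array experiment as its three TSV files
#'
#' @param experiment an [array_experiment()].
#' @param green_path,red_path,groups_path output file paths.
#' @export
write_signal_table <- function(experiment, green_path, red_path, groups_path) {
  write_matrix_tsv(experiment$green, green_path)
  write_matrix_tsv(experiment$red, red_path)
  utils::write.table(
    data.frame(sample = names(experiment$groups),
               group = unname(experiment$groups)),
    groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

read_matrix_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  storage.mode(m) <- "double"
  m
}

write_matrix_tsv <- function(m, path, id_col = "probe_id") {
  tab <- data.frame(rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(tab)[1] <- id_col
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
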