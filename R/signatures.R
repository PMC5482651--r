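#' Seven-way partition of detected signature sets
#'
#' Partitions the signatures detected in cancer, matched control (MC) and
#' non-matched control (NC) samples into the seven disjoint regions of the
#' three-set Venn diagram. Inputs are treated as sets (duplicates and order
#' ignored); names are matched case-insensitively after trimming but stored
#' as given.
#'
#' @param detected_cancer,detected_mc,detected_nc character vectors of
#'   signature names.
#' @return An object of class `signature_set_comparison`: list with `sets`
#'   (the seven membership vectors) and `counts` (named integer vector).
#' @export
compare_sets <- function(detected_cancer, detected_mc, detected_nc) {
  canon <- function(x) tolower(trimws(x))
  uniq <- function(x) x[!duplicated(canon(x))]
  ca <- uniq(as.character(detected_cancer))
  mc <- uniq(as.character(detected_mc))
  nc <- uniq(as.character(detected_nc))
  universe <- uniq(c(ca, mc, nc))
  in_ca <- canon(universe) %in% canon(ca)
  in_mc <- canon(universe) %in% canon(mc)
  in_nc <- canon(universe) %in% canon(nc)
  sets <- list(
    only_cancer = universe[in_ca & !in_mc & !in_nc],
    only_mc     = universe[!in_ca & in_mc & !in_nc],
    only_nc     = universe[!in_ca & !in_mc & in_nc],
    cancer_mc   = universe[in_ca & in_mc & !in_nc],
    cancer_nc   = universe[in_ca & !in_mc & in_nc],
    mc_nc       = universe[!in_ca & in_mc & in_nc],
    all_three   = universe[in_ca & in_mc & in_nc])
  stopifnot(sum(lengths(sets)) == length(universe))
  structure(list(sets = sets,
                 counts = vapply(sets, length, integer(1)),
                 detected = list(cancer = ca, mc = mc, nc = nc)),
            class = "signature_set_comparison")
}

#' @export
print.signature_set_comparison <- function(x, ...) {
  cat("signature_set_comparison\n")
  print(x$counts)
  invisible(x)
}

cancer_detected_names <- function(comparison) {
  with(comparison$sets,
       c(only_cancer, cancer_mc, cancer_nc, all_three))
}

#' Phylum distribution of cancer-detected signatures
#'
#' Integer percentages of each phylum among everything detected in the
#' cancer samples (cancer-only plus all regions shared with cancer).
#' Percentages round half away from zero.
#'
#' @param comparison a [compare_sets()] result (typically bacteria).
#' @param phylum_of named character vector mapping signature name to phylum.
#' @return named integer vector, phylum -> percent, descending.
#' @export
phylum_distribution <- function(comparison, phylum_of) {
  cancer <- cancer_detected_names(comparison)
  phyla <- phylum_of[cancer]
  if (any(is.na(phyla) | phyla == "")) {
    stop("no phylum mapping for: ",
         paste(cancer[is.na(phyla) | phyla == ""], collapse = ", "))
  }
  counts <- table(phyla)
  pct <- vapply(counts, function(k) {
    as.integer(round_half_up(100 * k / length(cancer)))
  }, integer(1))
  sort(pct, decreasing = TRUE)
}

#' Fraction of cancer-detected viral families that are tumorigenic
#'
#' @param comparison a [compare_sets()] result over viral families.
#' @param tumorigenic character vector of tumorigenic family names
#'   (default [tumorigenic_viral_families()]).
#' @return integer percent.
#' @export
tumorigenic_fraction <- function(comparison,
                                 tumorigenic = tumorigenic_viral_families()) {
  cancer <- cancer_detected_names(comparison)
  if (length(cancer) == 0) stop("no cancer-detected families")
  hit <- tolower(trimws(cancer)) %in% tolower(trimws(tumorigenic))
  as.integer(round_half_up(100 * sum(hit) / length(cancer)))
}

#' Write a set comparison as a tidy TSV
#'
#' @param comparison a [compare_sets()] result.
#' @param path output path.
#' @param kingdom optional kingdom label column.
#' @export
write_set_comparison <- function(comparison, path, kingdom = NA_character_) {
  tab <- do.call(rbind, lapply(names(comparison$sets), function(p) {
    members <- comparison$sets[[p]]
    data.frame(kingdom = kingdom, partition = p,
               count = length(members),
               members = paste(members, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
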