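#' Published signature membership table
#'
#' Loads the packaged transcription of the published table of microbial
#' signatures detected in ovarian cancer, matched control (MC) and
#' non-matched control (NC) samples: for each kingdom, the disjoint
#' membership lists (cancer-only, MC-only, NC-only, cancer+MC, cancer+NC,
#' MC+NC, all three). Names are stored as printed; bacterial genera carry
#' their printed phylum. One duplication in the printed table (a genus
#' listed under both the cancer-only and NC-only columns) is resolved in
#' favour of the cancer-only column, which keeps the membership lists
#' disjoint and matches the printed partition counts.
#'
#' @return A `signature_membership` object: a list with one element per
#'   kingdom, each a named list of the seven membership character vectors,
#'   plus a `phylum_of` lookup for bacterial genera.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_signatures.tsv",
                      package = "pathosig", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  memberships <- c("cancer_only", "mc_only", "nc_only",
                   "cancer_mc", "cancer_nc", "mc_nc", "all_three")
  out <- lapply(split(tab, tab$kingdom), function(k) {
    sets <- lapply(memberships, function(m) k$name[k$membership == m])
    names(sets) <- memberships
    sets
  })
  for (k in names(out)) {
    all_names <- unlist(out[[k]], use.names = FALSE)
    if (anyDuplicated(all_names)) {
      stop("fixture membership lists not disjoint in kingdom ", k, ": ",
           paste(unique(all_names[duplicated(all_names)]), collapse = ", "))
    }
  }
  bact <- tab[tab$kingdom == "bacteria", ]
  attr(out, "phylum_of") <- stats::setNames(bact$phylum_or_group, bact$name)
  class(out) <- "signature_membership"
  out
}

#' Detected-set view of a signature membership table
#'
#' Reassembles, for one kingdom, the three per-group detected sets from the
#' seven-way membership partition (e.g. detected-in-cancer = cancer-only +
#' cancer+MC + cancer+NC + all-three).
#'
#' @param membership a `signature_membership` from [load_table1_fixture()].
#' @param kingdom one of `"virus"`, `"bacteria"`, `"fungus"`, `"parasite"`.
#' @return list with character vectors `cancer`, `mc`, `nc`.
#' @export
membership_detected_sets <- function(membership, kingdom) {
  m <- membership[[kingdom]]
  if (is.null(m)) stop("no such kingdom in fixture: ", kingdom)
  list(
    cancer = c(m$cancer_only, m$cancer_mc, m$cancer_nc, m$all_three),
    mc = c(m$mc_only, m$cancer_mc, m$mc_nc, m$all_three),
    nc = c(m$nc_only, m$cancer_nc, m$mc_nc, m$all_three))
}

#' Tumorigenic viral families
#'
#' The six virus families treated as tumorigenic when summarising the viral
#' signature set.
#'
#' @return character vector of family names.
#' @export
tumorigenic_viral_families <- function() {
  c("Retroviridae", "Hepadnaviridae", "Papillomaviridae",
    "Flaviviridae", "Polyomaviridae", "Herpesviridae")
}
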