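#' Default alignment scoring
#'
#' Match +1, mismatch -2, gap open -3, gap extension -1; a gap of length L
#' costs `gap_open + L * gap_ext`.
#' @return named list of scoring parameters.
#' @export
alignment_scoring <- function(match = 1L, mismatch = -2L, gap_open = 3L,
                              gap_ext = 1L) {
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap_open = as.integer(gap_open), gap_ext = as.integer(gap_ext))
}

as_sequence_character <- function(x) {
  if (is.character(x)) {
    if (length(x) > 0 && is.null(names(x))) {
      names(x) <- paste0("seq", seq_along(x))
    }
    return(toupper(x))
  }
  out <- as.character(x)
  names(out) <- names(x)
  toupper(out)
}

#' Smith-Waterman local alignment of a read against reference sequences
#'
#' Aligns one read against every reference (both strands by default) and
#' returns the best local alignment, with unaligned read ends reported as
#' soft clips. References are scanned with a k-mer seed index and the
#' dynamic programme is evaluated in windows around seed diagonals; an
#' exhaustive quadratic reference is used in the test suite to check the
#' scores. Returns `NULL` when no alignment reaches `min_score`.
#'
#' @param read a character scalar (or single `DNAStringSet` element).
#' @param references named character vector or `DNAStringSet`.
#' @param min_score minimum local alignment score (default 30).
#' @param scoring from [alignment_scoring()].
#' @param seed_k k-mer size for seeding (default 13).
#' @param both_strands search the reverse complement too (default TRUE).
#' @return list of class `alignment`: read_id, ref, strand, score,
#'   ref_start/ref_end (1-based), read_start/read_end (on the aligned
#'   orientation of the read), cigar (full-read, with terminal `S`),
#'   n_match, n_mismatch, n_gap, second_score, read_seq (aligned
#'   orientation).
#' @export
local_align <- function(read, references, min_score = 30,
                        scoring = alignment_scoring(), seed_k = 13,
                        both_strands = TRUE) {
  reads <- as_sequence_character(read)
  if (length(reads) != 1) stop("local_align takes a single read")
  hits <- align_reads(reads, references, min_score = min_score,
                      scoring = scoring, seed_k = seed_k,
                      both_strands = both_strands)
  if (!hits$found[1]) return(NULL)
  alignment_from_row(hits[1, ], reads[[1]])
}

#' Batch seeded alignment of reads against reference sequences
#'
#' @param reads named character vector or `DNAStringSet`.
#' @inheritParams local_align
#' @return data.frame, one row per read (see [local_align()] fields);
#'   `found` is `FALSE` where no alignment reached `min_score`.
#' @export
align_reads <- function(reads, references, min_score = 30,
                        scoring = alignment_scoring(), seed_k = 13,
                        both_strands = TRUE) {
  reads <- as_sequence_character(reads)
  refs <- as_sequence_character(references)
  if (length(refs) == 0) stop("empty reference set")
  align_reads_cpp(names(reads), unname(reads), names(refs), unname(refs),
                  as.integer(seed_k), as.integer(min_score),
                  scoring$match, scoring$mismatch, scoring$gap_open,
                  scoring$gap_ext, both_strands)
}

# build an alignment record (incl. soft-clipped full-read CIGAR) from one
# align_reads() row
alignment_from_row <- function(row, read_seq) {
  seq_aln <- if (identical(row$strand, "-")) revcomp(read_seq) else read_seq
  len <- nchar(seq_aln)
  lead <- row$read_start - 1L
  trail <- len - row$read_end
  cigar <- paste0(if (lead > 0) paste0(lead, "S") else "",
                  row$cigar,
                  if (trail > 0) paste0(trail, "S") else "")
  structure(list(read_id = row$read_id, ref = row$ref, strand = row$strand,
                 score = row$score, ref_start = row$ref_start,
                 ref_end = row$ref_end, read_start = row$read_start,
                 read_end = row$read_end, cigar = cigar,
                 n_match = row$n_match, n_mismatch = row$n_mismatch,
                 n_gap = row$n_gap, second_score = row$second_score,
                 read_seq = seq_aln),
            class = "alignment")
}

#' Reverse complement of a DNA string
#' @param x character scalar.
#' @return character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Exact Smith-Waterman alignment of two sequences
#'
#' Full quadratic dynamic programme with traceback (no seeding); used for
#' clip remapping and as the alignment core. 1-based coordinates.
#'
#' @param a,b character scalars (a is the read/query).
#' @param scoring from [alignment_scoring()].
#' @return list: score, a_start, a_end, b_start, b_end, n_match,
#'   n_mismatch, n_gap, cigar (M/I/D w.r.t. `a`).
#' @export
sw_align <- function(a, b, scoring = alignment_scoring()) {
  sw_align_pair_cpp(toupper(a), toupper(b), scoring$match, scoring$mismatch,
                    scoring$gap_open, scoring$gap_ext)
}
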