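#' Read and write sequence sets
#'
#' FASTA files are read into a [Biostrings::DNAStringSet]; FASTQ files into
#' a [Biostrings::QualityScaledDNAStringSet] so per-base qualities survive a
#' round trip. Sequences are upper-cased on input. FASTQ records are
#' structurally validated first so that a malformed record (for instance a
#' quality string whose length differs from the sequence) raises an error
#' naming the offending record.
#'
#' @param path file path; format is inferred from the extension
#'   (`.fq`/`.fastq` = FASTQ, anything else FASTA) unless `format` is given.
#' @param format `"fasta"`, `"fastq"` or `NULL` (infer).
#' @return A `DNAStringSet` (FASTA) or `QualityScaledDNAStringSet` (FASTQ).
#' @export
read_sequences <- function(path, format = NULL) {
  format <- format %||% infer_seq_format(path)
  if (format == "fastq") {
    validate_fastq(path)
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    quals <- Biostrings::PhredQuality(S4Vectors::mcols(x)$qualities)
    S4Vectors::mcols(x) <- NULL
    Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(toupper(x)), quals)
  } else {
    x <- Biostrings::readDNAStringSet(path)
    names(x) <- sub("\\s.*$", "", names(x))
    Biostrings::DNAStringSet(toupper(x))
  }
}

#' @rdname read_sequences
#' @param seqs a `DNAStringSet` (written as FASTA), a
#'   `QualityScaledDNAStringSet` (written as FASTQ), or a named character
#'   vector (written as FASTA).
#' @export
write_sequences <- function(seqs, path, format = NULL) {
  format <- format %||% infer_seq_format(path)
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (format == "fastq") {
    if (!methods::is(seqs, "QualityScaledDNAStringSet")) {
      stop("FASTQ output requires a QualityScaledDNAStringSet")
    }
    Biostrings::writeQualityScaledXStringSet(seqs, path)
  } else {
    Biostrings::writeXStringSet(seqs, path)
  }
  invisible(path)
}

infer_seq_format <- function(path) {
  if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) "fastq" else "fasta"
}

validate_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) return(invisible(TRUE))
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ '", path, "': line count not a multiple of 4")
  }
  heads <- lines[seq(1, length(lines), by = 4)]
  seqs <- lines[seq(2, length(lines), by = 4)]
  plus <- lines[seq(3, length(lines), by = 4)]
  quals <- lines[seq(4, length(lines), by = 4)]
  ids <- sub("^@", "", sub("\\s.*$", "", heads))
  bad <- !startsWith(heads, "@")
  if (any(bad)) stop("malformed FASTQ record (missing '@'): ", ids[which(bad)[1]])
  bad <- !startsWith(plus, "+")
  if (any(bad)) stop("malformed FASTQ record (missing '+'): ", ids[which(bad)[1]])
  bad <- nchar(seqs) != nchar(quals)
  if (any(bad)) {
    stop("malformed FASTQ record (sequence/quality length mismatch): ",
         ids[which(bad)[1]])
  }
  invisible(TRUE)
}
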