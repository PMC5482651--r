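#' Extract terminal soft clips from an alignment
#'
#' Returns one record per terminal soft-clipped segment of length at least
#' `min_clip`, together with the reference coordinate of the aligned base
#' adjacent to the clip (the virus-side breakpoint anchor): the first
#' aligned base for a left clip, the last aligned base for a right clip.
#' Clip sequences are reported in the alignment orientation of the read.
#'
#' @param alignment an `alignment` (from [local_align()] or
#'   [sam_to_alignments()]).
#' @param min_clip minimum clip length (default 20).
#' @return data.frame: read_id, side (`"left"`/`"right"`), clip_seq,
#'   anchor_ref_coord. Zero rows when no clip qualifies.
#' @export
extract_soft_clips <- function(alignment, min_clip = 20) {
  len <- nchar(alignment$read_seq)
  lead <- alignment$read_start - 1L
  trail <- len - alignment$read_end
  out <- list()
  if (lead >= min_clip) {
    out[[length(out) + 1]] <- data.frame(
      read_id = alignment$read_id, side = "left",
      clip_seq = substr(alignment$read_seq, 1, lead),
      anchor_ref_coord = alignment$ref_start, stringsAsFactors = FALSE)
  }
  if (trail >= min_clip) {
    out[[length(out) + 1]] <- data.frame(
      read_id = alignment$read_id, side = "right",
      clip_seq = substr(alignment$read_seq, alignment$read_end + 1, len),
      anchor_ref_coord = alignment$ref_end, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(read_id = character(), side = character(),
                      clip_seq = character(), anchor_ref_coord = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Map a soft-clipped segment to the host genome
#'
#' Best local alignment of the clip against the host genome (both
#' strands). The mapping is rejected (`NULL`, with a `reason` attribute)
#' when the alignment covers less than `min_cover` of the clip, when
#' identity over the aligned columns falls below `min_identity`, or when a
#' second locus scores within `ambiguity_margin` of the best (multi-mapping
#' clips cannot support a single-base breakpoint).
#'
#' @param clip_seq character scalar (>= 20 bp recommended).
#' @param host_genome named character vector or `DNAStringSet`.
#' @param min_identity minimum identity over aligned columns (default 0.95).
#' @param min_cover minimum aligned fraction of the clip (default 0.9).
#' @param ambiguity_margin score margin defining a multi-mapping clip
#'   (default 2).
#' @param scoring from [alignment_scoring()].
#' @return list: chrom, start, end, strand, score, read_start, read_end,
#'   identity; or `NULL`.
#' @export
map_clip_to_host <- function(clip_seq, host_genome, min_identity = 0.95,
                             min_cover = 0.9, ambiguity_margin = 2,
                             scoring = alignment_scoring()) {
  res <- map_clip_detail(clip_seq, host_genome, min_identity, min_cover,
                         ambiguity_margin, scoring)
  if (!res$ok) return(NULL)
  res$locus
}

map_clip_detail <- function(clip_seq, host_genome, min_identity, min_cover,
                            ambiguity_margin, scoring) {
  len <- nchar(clip_seq)
  hits <- align_reads(stats::setNames(clip_seq, "clip"), host_genome,
                      min_score = max(10L, as.integer(floor(len / 2))),
                      scoring = scoring)
  reject <- function(reason) list(ok = FALSE, reason = reason, locus = NULL)
  if (!hits$found[1]) return(reject("no_host_hit"))
  h <- hits[1, ]
  if (h$second_score >= h$score - ambiguity_margin) {
    return(reject("ambiguous_host_mapping"))
  }
  cover <- (h$read_end - h$read_start + 1) / len
  if (cover < min_cover) return(reject("low_coverage"))
  ident <- h$n_match / (h$n_match + h$n_mismatch + h$n_gap)
  if (ident < min_identity) return(reject("low_identity"))
  list(ok = TRUE, reason = NA_character_,
       locus = list(chrom = h$ref, start = h$ref_start, end = h$ref_end,
                    strand = h$strand, score = h$score,
                    read_start = h$read_start, read_end = h$read_end,
                    identity = ident))
}

# host coordinate of clip base `clip_base` (1-based in the clip's given
# orientation), extrapolated linearly from the mapping when an edge base
# was trimmed
clip_base_host_coord <- function(mapping, clip_base, clip_len) {
  q <- if (mapping$strand == "+") clip_base else clip_len - clip_base + 1
  as.integer(mapping$start + q - mapping$read_start)
}

#' Call viral integration breakpoints from soft-clipped reads
#'
#' The virus-fusion pipeline: reads are aligned to the viral metagenome
#' first (the virus genome is the primary alignment target); terminal
#' soft-clipped segments of mapped reads are extracted and remapped to the
#' host genome; each uniquely mapped clip yields one breakpoint pair — the
#' terminal virus-aligned base and the host base adjacent to the junction —
#' at single-base resolution. Calls identical in (virus, virus breakpoint,
#' host chromosome, host breakpoint) within `merge_radius` are merged with
#' support summed.
#'
#' @param reads named character vector, `DNAStringSet`, or
#'   `QualityScaledDNAStringSet` of sequencing reads. Alternatively pass
#'   pre-computed viral alignments via `alignments` (see
#'   [sam_to_alignments()]) and leave `reads` `NULL`.
#' @param viral_refs,host_genome named character vectors or `DNAStringSet`.
#' @param alignments optional list of `alignment` objects against
#'   `viral_refs`, bypassing the built-in aligner.
#' @param min_score minimum viral alignment score (default 30).
#' @param min_clip minimum soft-clip length (default 20).
#' @param merge_radius breakpoint merge radius in bp (default 5).
#' @param min_identity,min_cover,ambiguity_margin clip remapping filters,
#'   see [map_clip_to_host()].
#' @param scoring from [alignment_scoring()].
#' @return data.frame of class `integration_calls`: virus, virus_bp,
#'   chrom, host_bp, orientation, support. Suppressed reads are logged in
#'   attribute `"log"` (read_id, reason).
#' @export
call_integrations <- function(reads = NULL, viral_refs, host_genome,
                              alignments = NULL, min_score = 30,
                              min_clip = 20, merge_radius = 5,
                              min_identity = 0.95, min_cover = 0.9,
                              ambiguity_margin = 2,
                              scoring = alignment_scoring()) {
  if (is.null(alignments)) {
    if (is.null(reads)) stop("supply reads or alignments")
    reads <- as_sequence_character(reads)
    if (length(reads) == 0) {
      return(empty_integration_calls(log = data.frame(
        read_id = character(), reason = character())))
    }
    hits <- align_reads(reads, viral_refs, min_score = min_score,
                        scoring = scoring)
    alignments <- lapply(which(hits$found), function(i) {
      alignment_from_row(hits[i, ], reads[[i]])
    })
    log <- data.frame(read_id = hits$read_id[!hits$found],
                      reason = rep("unaligned_to_virus", sum(!hits$found)),
                      stringsAsFactors = FALSE)
  } else {
    log <- data.frame(read_id = character(), reason = character(),
                      stringsAsFactors = FALSE)
  }
  raw <- list()
  for (aln in alignments) {
    clips <- extract_soft_clips(aln, min_clip = min_clip)
    if (nrow(clips) == 0) {
      log <- rbind(log, data.frame(read_id = aln$read_id,
                                   reason = "no_qualifying_clip"))
      next
    }
    for (ci in seq_len(nrow(clips))) {
      clip <- clips[ci, ]
      detail <- map_clip_detail(clip$clip_seq, host_genome,
                                min_identity = min_identity,
                                min_cover = min_cover,
                                ambiguity_margin = ambiguity_margin,
                                scoring = scoring)
      if (!detail$ok) {
        log <- rbind(log, data.frame(read_id = aln$read_id,
                                     reason = detail$reason))
        next
      }
      mapping <- detail$locus
      clip_len <- nchar(clip$clip_seq)
      junction_base <- if (clip$side == "right") 1L else clip_len
      raw[[length(raw) + 1]] <- data.frame(
        virus = aln$ref,
        virus_bp = as.integer(clip$anchor_ref_coord),
        chrom = mapping$chrom,
        host_bp = clip_base_host_coord(mapping, junction_base, clip_len),
        orientation = if (clip$side == "right") "virus_left_host_right"
                      else "host_left_virus_right",
        stringsAsFactors = FALSE)
    }
  }
  if (length(raw) == 0) return(empty_integration_calls(log = log))
  raw <- do.call(rbind, raw)
  calls <- merge_breakpoints(raw, merge_radius)
  attr(calls, "log") <- log
  class(calls) <- c("integration_calls", "data.frame")
  calls
}

empty_integration_calls <- function(log) {
  calls <- data.frame(virus = character(), virus_bp = integer(),
                      chrom = character(), host_bp = integer(),
                      orientation = character(), support = integer(),
                      stringsAsFactors = FALSE)
  attr(calls, "log") <- log
  class(calls) <- c("integration_calls", "data.frame")
  calls
}

# greedy single-linkage merge of per-read breakpoint pairs within radius
merge_breakpoints <- function(raw, merge_radius) {
  out <- list()
  for (key in unique(paste(raw$virus, raw$chrom, raw$orientation, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- raw[raw$virus == parts[1] & raw$chrom == parts[2] &
                 raw$orientation == parts[3], , drop = FALSE]
    sub <- sub[order(sub$virus_bp, sub$host_bp), , drop = FALSE]
    clusters <- list()
    for (i in seq_len(nrow(sub))) {
      placed <- FALSE
      for (ci in seq_along(clusters)) {
        cl <- clusters[[ci]]
        if (abs(sub$virus_bp[i] - cl$virus_bp0) <= merge_radius &&
            abs(sub$host_bp[i] - cl$host_bp0) <= merge_radius) {
          clusters[[ci]]$virus_bp <- c(cl$virus_bp, sub$virus_bp[i])
          clusters[[ci]]$host_bp <- c(cl$host_bp, sub$host_bp[i])
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        clusters[[length(clusters) + 1]] <- list(
          virus_bp0 = sub$virus_bp[i], host_bp0 = sub$host_bp[i],
          virus_bp = sub$virus_bp[i], host_bp = sub$host_bp[i])
      }
    }
    for (cl in clusters) {
      out[[length(out) + 1]] <- data.frame(
        virus = parts[1],
        virus_bp = consensus_coord(cl$virus_bp),
        chrom = parts[2],
        host_bp = consensus_coord(cl$host_bp),
        orientation = parts[3],
        support = length(cl$virus_bp), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(-out$support, out$virus, out$virus_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# modal coordinate of a merged cluster (smallest on ties)
consensus_coord <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

#' Annotate an integration breakpoint with its gene context
#'
#' A breakpoint inside an exon is `exonic`; inside a gene span but no exon,
#' `intronic`; otherwise the nearest gene within `window` bp classifies it
#' as `upstream` (5' of the transcription start, strand-aware) or
#' `downstream` (3' of the gene end), with the distance to the gene
#' boundary; beyond the window it is `intergenic`.
#'
#' @param chrom,host_bp breakpoint location.
#' @param genes a [gene_model_set()].
#' @param window search window in bp (default 100000).
#' @return list: relation, gene_id (`NA` for intergenic), distance (bp; 0
#'   for exonic/intronic).
#' @export
annotate_breakpoint <- function(chrom, host_bp, genes, window = 100000) {
  g <- genes$genes[genes$genes$chrom == chrom, , drop = FALSE]
  inside <- g[g$start <= host_bp & host_bp <= g$end, , drop = FALSE]
  if (nrow(inside) > 0) {
    inside <- inside[order(inside$gene_id), , drop = FALSE]
    gid <- inside$gene_id[1]
    ex <- genes$exons[genes$exons$gene_id == gid, , drop = FALSE]
    exonic <- any(ex$start <= host_bp & host_bp <= ex$end)
    return(list(relation = if (exonic) "exonic" else "intronic",
                gene_id = gid, distance = 0L))
  }
  if (nrow(g) == 0) {
    return(list(relation = "intergenic", gene_id = NA_character_,
                distance = NA_integer_))
  }
  dist_start <- g$start - host_bp  # positive when breakpoint left of gene
  dist_end <- host_bp - g$end      # positive when breakpoint right of gene
  dist <- pmax(dist_start, dist_end)
  relation <- ifelse(dist_start > 0,
                     ifelse(g$strand == "+", "upstream", "downstream"),
                     ifelse(g$strand == "+", "downstream", "upstream"))
  ok <- dist <= window
  if (!any(ok)) {
    return(list(relation = "intergenic", gene_id = NA_character_,
                distance = NA_integer_))
  }
  cand <- order(dist, g$gene_id)[1]
  if (!ok[cand]) cand <- which(ok)[order(dist[ok], g$gene_id[ok])][1]
  list(relation = relation[cand], gene_id = g$gene_id[cand],
       distance = as.integer(dist[cand]))
}

#' Annotate a table of integration calls
#'
#' @param calls an `integration_calls` data.frame.
#' @param genes a [gene_model_set()].
#' @param window see [annotate_breakpoint()].
#' @return `calls` with added columns relation, gene_id, distance.
#' @export
annotate_calls <- function(calls, genes, window = 100000) {
  ann <- lapply(seq_len(nrow(calls)), function(i) {
    annotate_breakpoint(calls$chrom[i], calls$host_bp[i], genes, window)
  })
  calls$relation <- vapply(ann, `[[`, character(1), "relation")
  calls$gene_id <- vapply(ann, `[[`, character(1), "gene_id")
  calls$distance <- vapply(ann, `[[`, integer(1), "distance")
  calls
}

#' Per-chromosome insertion tally
#'
#' @param calls an `integration_calls` data.frame.
#' @return data.frame: chrom, n_insertions (descending).
#' @export
tally_by_chromosome <- function(calls) {
  if (nrow(calls) == 0) {
    return(data.frame(chrom = character(), n_insertions = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(calls$chrom)
  out <- data.frame(chrom = names(tab), n_insertions = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_insertions, out$chrom), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count aligned reads over capture-probe regions
#'
#' A read counts for a region when its aligned reference span overlaps the
#' region by at least 1 bp; each read counts for at most one region — the
#' one with the largest overlap, ties broken by the lowest region start.
#'
#' @param alignments data.frame from [align_reads()] (rows with
#'   `found == TRUE` are used), with columns ref, ref_start, ref_end.
#' @param regions data.frame with columns chrom, start, end and optionally
#'   name (1-based inclusive), or a path to a BED file.
#' @param ref_names reference names the alignments were computed against;
#'   a region on any other reference is an error.
#' @return data.frame: region name, chrom, start, end, count.
#' @export
count_reads_in_regions <- function(alignments, regions, ref_names = NULL) {
  if (is.character(regions) && length(regions) == 1) {
    regions <- read_regions_bed(regions)
  }
  if (is.null(regions$name)) {
    regions$name <- paste0(regions$chrom, ":", regions$start, "-", regions$end)
  }
  if (!is.null(ref_names)) {
    bad <- setdiff(unique(regions$chrom), ref_names)
    if (length(bad) > 0) {
      stop("region on unknown reference: ", paste(bad, collapse = ", "))
    }
  }
  aln <- alignments[alignments$found %||% rep(TRUE, nrow(alignments)), ,
                    drop = FALSE]
  counts <- integer(nrow(regions))
  if (nrow(aln) > 0) {
    reg_gr <- GenomicRanges::GRanges(
      regions$chrom, IRanges::IRanges(regions$start, regions$end))
    aln_gr <- GenomicRanges::GRanges(
      aln$ref, IRanges::IRanges(aln$ref_start, aln$ref_end))
    ov <- GenomicRanges::findOverlaps(aln_gr, reg_gr)
    if (length(ov) > 0) {
      qh <- S4Vectors::queryHits(ov)
      sh <- S4Vectors::subjectHits(ov)
      width <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(aln_gr)[qh], IRanges::ranges(reg_gr)[sh]))
      # per read: largest overlap, ties -> lowest region start
      ord <- order(qh, -width, regions$start[sh], sh)
      keep <- !duplicated(qh[ord])
      chosen <- sh[ord][keep]
      tab <- table(chosen)
      counts[as.integer(names(tab))] <- as.integer(tab)
    }
  }
  data.frame(name = regions$name, chrom = regions$chrom,
             start = regions$start, end = regions$end, count = counts,
             stringsAsFactors = FALSE)
}

#' Read BED intervals into a 1-based regions table
#'
#' @param path BED file (0-based half-open on disk).
#' @return data.frame: chrom, start, end, name (1-based inclusive).
#' @export
read_regions_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             name = if (is.null(gr$name)) NA_character_ else gr$name,
             stringsAsFactors = FALSE)
}

#' Import externally produced viral alignments from SAM
#'
#' Reads a SAM file (e.g. produced by an external aligner against the
#' viral metagenome) and converts each mapped record into the `alignment`
#' structure consumed by [extract_soft_clips()] and [call_integrations()].
#' Only M/S/I/D CIGAR operations are interpreted; clips must be terminal.
#'
#' @param path SAM file path.
#' @return list of `alignment` objects.
#' @export
sam_to_alignments <- function(path) {
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  rec <- Rsamtools::scanBam(bam)[[1]]
  keep <- !is.na(rec$pos)
  lapply(which(keep), function(i) {
    cigar <- rec$cigar[i]
    ops <- parse_cigar(cigar)
    read_len <- sum(ops$len[ops$op %in% c("M", "I", "S")])
    lead <- if (ops$op[1] == "S") ops$len[1] else 0L
    trail <- if (ops$op[nrow(ops)] == "S") ops$len[nrow(ops)] else 0L
    ref_span <- sum(ops$len[ops$op %in% c("M", "D")])
    structure(list(
      read_id = rec$qname[i], ref = as.character(rec$rname[i]),
      strand = as.character(rec$strand[i]),
      score = NA_integer_,
      ref_start = rec$pos[i], ref_end = rec$pos[i] + ref_span - 1L,
      read_start = lead + 1L, read_end = read_len - trail,
      cigar = cigar, n_match = NA_integer_, n_mismatch = NA_integer_,
      n_gap = sum(ops$len[ops$op %in% c("I", "D")]),
      second_score = NA_integer_,
      read_seq = as.character(rec$seq[i])), class = "alignment")
  })
}

parse_cigar <- function(cigar) {
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  data.frame(len = len, op = op, stringsAsFactors = FALSE)
}

#' Write a 1-based regions table as BED
#'
#' @param regions data.frame with chrom, start, end and optionally name
#'   (1-based inclusive).
#' @param path output path (0-based half-open on disk).
#' @export
write_regions_bed <- function(regions, path) {
  name <- regions$name %||% paste0("region", seq_len(nrow(regions)))
  writeLines(sprintf("%s\t%d\t%d\t%s", regions$chrom,
                     regions$start - 1L, regions$end, name), path)
  invisible(path)
}
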