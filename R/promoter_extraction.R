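# Strand-aware extraction of the intergenic region upstream of an operon
# head gene — the operational promoter definition: the ORF-free span between
# the head gene's transcription-start side and the nearest annotated gene on
# either strand.

#' Extract the upstream intergenic region of a gene
#'
#' For a forward-strand gene the region ends at `start - 1` and reaches back
#' to one base past the nearest gene end on its left; for a reverse-strand
#' gene it starts at `end + 1` and reaches to one base before the nearest
#' gene start on its right, and the sequence is reverse-complemented so it
#' always reads 5'-3' in the gene's orientation. Regions longer than
#' `max_len` are truncated to the `max_len` bases proximal to the gene and
#' flagged; regions shorter than `min_len` are flagged, not rejected. On a
#' replicon declared circular the span may wrap the origin.
#'
#' @param gene_id head gene id.
#' @param annotation annotation data.frame (`gene_id`, `replicon`, `start`,
#'   `end`, `strand`).
#' @param genome named `DNAStringSet` (or character vector) of replicon
#'   sequences.
#' @param min_len flag threshold in bp (default 20).
#' @param max_len truncation cap in bp (default 1000).
#' @param circular logical: treat the gene's replicon as circular.
#' @param candidate_id optional label (e.g. `"PS01"`) carried into the
#'   output.
#' @return a one-row `promoter_region` data.frame: `candidate_id`,
#'   `head_gene`, `replicon`, `start`, `end` (1-based closed, genomic),
#'   `strand`, `length`, `sequence`, `truncated_by_cap`, `shorter_than_min`,
#'   `wraps_origin`.
#' @export
extract_upstream_region <- function(gene_id, annotation, genome,
                                    min_len = 20L, max_len = 1000L,
                                    circular = FALSE,
                                    candidate_id = gene_id) {
  i <- match(gene_id, annotation$gene_id)
  stop_if(is.na(i), "gene %s not found in annotation", gene_id)
  repl <- annotation$replicon[i]
  seq_full <- as.character(genome[[repl]])
  stop_if(is.null(seq_full), "no genome sequence for replicon %s", repl)
  L <- nchar(seq_full)
  others <- annotation[annotation$replicon == repl &
                         annotation$gene_id != gene_id, , drop = FALSE]
  strand <- annotation$strand[i]
  gstart <- annotation$start[i]; gend <- annotation$end[i]
  wraps <- FALSE

  if (strand == "+") {
    # overlap across the gene start leaves no intergenic space
    stop_if(any(others$start < gstart & others$end >= gstart),
            "no upstream region for %s: neighbouring gene overlaps its start",
            gene_id)
    left_ends <- others$end[others$end < gstart]
    if (length(left_ends) > 0) {
      rstart <- max(left_ends) + 1L
      rend <- gstart - 1L
    } else if (circular) {
      rstart <- if (nrow(others)) max(others$end) + 1L else gend + 1L
      rend <- gstart - 1L
      wraps <- rstart > L || rend < 1L || rstart > rend
    } else {
      rstart <- 1L
      rend <- gstart - 1L
    }
  } else {
    stop_if(any(others$start <= gend & others$end > gend),
            "no upstream region for %s: neighbouring gene overlaps its start",
            gene_id)
    right_starts <- others$start[others$start > gend]
    if (length(right_starts) > 0) {
      rstart <- gend + 1L
      rend <- min(right_starts) - 1L
    } else if (circular) {
      rstart <- gend + 1L
      rend <- if (nrow(others)) min(others$start) - 1L else gstart - 1L
      wraps <- rend < rstart
    } else {
      rstart <- gend + 1L
      rend <- L
    }
  }

  raw_len <- if (!wraps) rend - rstart + 1L else (L - rstart + 1L) + rend
  stop_if(raw_len <= 0, "no upstream region for %s: zero intergenic bases",
          gene_id)

  truncated <- raw_len > max_len
  if (truncated) {
    # keep the max_len bases proximal to the gene's transcription start
    if (strand == "+") {
      # proximal side is rend; move rstart forward
      if (!wraps) {
        rstart <- rend - max_len + 1L
      } else {
        if (rend >= max_len) { rstart <- rend - max_len + 1L; wraps <- FALSE }
        else rstart <- L - (max_len - rend) + 1L
      }
    } else {
      if (!wraps) {
        rend <- rstart + max_len - 1L
      } else {
        if (L - rstart + 1L >= max_len) {
          rend <- rstart + max_len - 1L; wraps <- FALSE
        } else rend <- max_len - (L - rstart + 1L)
      }
    }
    raw_len <- max_len
  }

  seq_out <- if (!wraps) substr(seq_full, rstart, rend) else
    paste0(substr(seq_full, rstart, L), substr(seq_full, 1, rend))
  if (strand == "-") {
    seq_out <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seq_out)))
  }

  out <- data.frame(
    candidate_id = candidate_id, head_gene = gene_id, replicon = repl,
    start = rstart, end = rend, strand = strand, length = raw_len,
    sequence = seq_out, truncated_by_cap = truncated,
    shorter_than_min = raw_len < min_len, wraps_origin = wraps,
    stringsAsFactors = FALSE)
  class(out) <- c("promoter_region", "data.frame")
  out
}

#' Extract upstream regions for a whole candidate set
#'
#' Assigns candidate ids `"<prefix>01"`, `"<prefix>02"`, ... in rank order
#' and extracts each head gene's upstream region. Heads whose extraction
#' fails (no intergenic space) are dropped with a warning.
#'
#' @param candidates a `candidate_set` (or data.frame with `head_gene`).
#' @param annotation,genome,min_len,max_len,circular see
#'   [extract_upstream_region()].
#' @param prefix candidate-id prefix, e.g. `"PS"` for specific and `"PC"`
#'   for constitutive candidates.
#' @return `promoter_region` data.frame, one row per extractable candidate.
#' @export
extract_promoters <- function(candidates, annotation, genome,
                              min_len = 20L, max_len = 1000L,
                              circular = FALSE, prefix = "PS") {
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    id <- sprintf("%s%02d", prefix, i)
    reg <- tryCatch(
      extract_upstream_region(candidates$head_gene[i], annotation, genome,
                              min_len = min_len, max_len = max_len,
                              circular = circular, candidate_id = id),
      error = function(e) {
        warning(sprintf("skipping %s: %s", candidates$head_gene[i],
                        conditionMessage(e)))
        NULL
      })
    rows[[length(rows) + 1L]] <- reg
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- extract_empty_regions()
  }
  rownames(out) <- NULL
  class(out) <- c("promoter_region", "data.frame")
  out
}

extract_empty_regions <- function() {
  data.frame(candidate_id = character(), head_gene = character(),
             replicon = character(), start = integer(), end = integer(),
             strand = character(), length = integer(), sequence = character(),
             truncated_by_cap = logical(), shorter_than_min = logical(),
             wraps_origin = logical(), stringsAsFactors = FALSE)
}

#' Write promoter regions as FASTA
#'
#' One record per region, 60-column wrapped, with header
#' `>{candidate_id} {replicon}:{start}-{end}({strand}) head={gene_id}`.
#'
#' @param regions `promoter_region` data.frame.
#' @param path output path.
#' @export
write_promoter_fasta <- function(regions, path) {
  stop_if(anyDuplicated(regions$candidate_id) > 0,
          "duplicate candidate ids")
  seqs <- Biostrings::DNAStringSet(regions$sequence)
  names(seqs) <- sprintf("%s %s:%d-%d(%s) head=%s",
                         regions$candidate_id, regions$replicon,
                         regions$start, regions$end, regions$strand,
                         regions$head_gene)
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Write promoter regions as BED (0-based half-open)
#'
#' @param regions `promoter_region` data.frame; wrapped regions are split
#'   into their two genomic arms sharing one name.
#' @param path output path.
#' @export
write_promoter_bed <- function(regions, path) {
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    if (!r$wraps_origin) {
      data.frame(chrom = r$replicon, start = r$start - 1L, end = r$end,
                 name = r$candidate_id, score = 0L, strand = r$strand)
    } else {
      # two arms: [start, L] and [1, end]; replicon length is unknown here,
      # so the first arm is written with its genomic start and open end at
      # the region length boundary computed from the record
      arm1_len <- r$length - r$end
      data.frame(chrom = r$replicon,
                 start = c(r$start - 1L, 0L),
                 end = c(r$start - 1L + arm1_len, r$end),
                 name = r$candidate_id, score = 0L, strand = r$strand)
    }
  })
  bed <- do.call(rbind, rows)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
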