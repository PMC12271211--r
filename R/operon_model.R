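# Operon inference by the classic intergenic-distance heuristic, and
# resolution of any gene to its operon's first-transcribed gene (the gene
# whose upstream region carries the operon promoter).

#' Cluster genes into putative operons
#'
#' Greedy scan per replicon over coordinate-sorted genes: consecutive
#' same-strand genes whose intergenic gap (`next.start - prev.end - 1`,
#' so adjacent genes have gap 0) is at most `max_gap`, with no intervening
#' opposite-strand gene, join one cluster. Overlapping same-strand genes
#' (common in bacteria) always join, with a warning. Every gene belongs to
#' exactly one cluster; singletons are allowed.
#'
#' Optionally, when a TPM matrix is supplied, adjacent genes must in
#' addition have a Pearson correlation of expression profiles of at least
#' `min_cor` to join — a co-expression refinement of the distance rule.
#'
#' @param annotation data.frame with `gene_id`, `replicon`, `start`, `end`,
#'   `strand` (1-based closed coordinates).
#' @param max_gap maximum intergenic distance in bp (default 50).
#' @param tpm optional TPM matrix (genes x samples) for the co-expression
#'   refinement.
#' @param min_cor minimum adjacent-gene correlation when `tpm` is given.
#' @return object of class `operon_set`: data.frame with `gene_id`,
#'   `operon_id`, `replicon`, `strand`, `head_gene`, ordered by replicon and
#'   coordinate.
#' @examples
#' ann <- data.frame(gene_id = c("a", "b"), replicon = "chr",
#'                   start = c(1, 131), end = c(100, 230), strand = "+")
#' infer_operons(ann, max_gap = 50)
#' @export
infer_operons <- function(annotation, max_gap = 50, tpm = NULL,
                          min_cor = 0.8) {
  stop_if(max_gap < 0, "max_gap must be >= 0")
  ann <- annotation[order(annotation$replicon, annotation$start,
                          annotation$end), , drop = FALSE]
  n <- nrow(ann)
  cluster <- integer(n)
  cid <- 0L
  warned_overlap <- FALSE
  prev_end <- -Inf
  for (i in seq_len(n)) {
    new_cluster <- TRUE
    if (i > 1L && ann$replicon[i] == ann$replicon[i - 1L]) {
      gap <- ann$start[i] - prev_end - 1L
      if (ann$strand[i] == ann$strand[i - 1L] && gap <= max_gap) {
        joined <- TRUE
        if (!is.null(tpm)) {
          r <- suppressWarnings(
            stats::cor(tpm[ann$gene_id[i], ], tpm[ann$gene_id[i - 1L], ]))
          joined <- !is.na(r) && r >= min_cor
        }
        if (joined && gap < 0L && !warned_overlap) {
          warning("overlapping same-strand genes merged into one operon")
          warned_overlap <- TRUE
        }
        new_cluster <- !joined
      }
    }
    if (new_cluster) {
      cid <- cid + 1L
      prev_end <- ann$end[i]
    } else {
      prev_end <- max(prev_end, ann$end[i])
    }
    cluster[i] <- cid
  }
  # head = first-transcribed member: leftmost on +, rightmost on -
  head_gene <- character(n)
  for (k in unique(cluster)) {
    members <- which(cluster == k)
    h <- if (ann$strand[members[1]] == "+") members[1] else
      members[which.max(ann$end[members])]
    head_gene[members] <- ann$gene_id[h]
  }
  out <- data.frame(
    gene_id = ann$gene_id,
    operon_id = sprintf("operon_%04d", cluster),
    replicon = ann$replicon,
    strand = ann$strand,
    head_gene = head_gene,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("operon_set", "data.frame")
  out
}

#' First-transcribed gene of a gene's operon
#'
#' @param gene_id gene id(s) to resolve.
#' @param operons an `operon_set` from [infer_operons()].
#' @return character vector of head gene ids (the gene itself for
#'   singletons).
#' @export
operon_head <- function(gene_id, operons) {
  idx <- match(gene_id, operons$gene_id)
  stop_if(anyNA(idx), "unknown gene id(s): %s",
          paste(gene_id[is.na(idx)], collapse = ", "))
  operons$head_gene[idx]
}

#' Write the operon table as TSV
#'
#' One row per operon: id, replicon, strand, head gene and comma-separated
#' member list in transcription order.
#'
#' @param operons an `operon_set`.
#' @param path output path.
#' @export
write_operons_tsv <- function(operons, path) {
  per_op <- split(seq_len(nrow(operons)), operons$operon_id)
  rows <- lapply(per_op, function(ix) {
    members <- operons$gene_id[ix]
    if (operons$strand[ix[1]] == "-") members <- rev(members)
    data.frame(operon_id = operons$operon_id[ix[1]],
               replicon = operons$replicon[ix[1]],
               strand = operons$strand[ix[1]],
               head_gene = operons$head_gene[ix[1]],
               members = paste(members, collapse = ","),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$operon_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
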