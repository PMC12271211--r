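# Candidate promoter selection: the dual top-k procedure for
# autotroph-specific genes, quantile-stratified selection of constitutive
# genes across the expression range, operon-head resolution, and
# deduplication of near-identical paralogous operons by global-alignment
# identity of their upstream sequences.

#' Selection configuration
#'
#' Thresholds of the two selection procedures. The significance set uses
#' strict inequalities (`L2FC > 2`, `p < 0.01`, `TPM > 100`); the
#' constitutive band is inclusive (`|L2FC| <= 0.3`).
#'
#' @param l2fc_min_sig,p_max,tpm_min significance-set thresholds.
#' @param k_by_l2fc size of the top-L2FC stage (stage 1).
#' @param k_by_tpm size of the top-TPM stage (stage 2).
#' @param l2fc_min_for_tpm_rank L2FC floor for stage-2 eligibility.
#' @param constitutive_band half-width of the constitutive |L2FC| band.
#' @param k_constitutive number of constitutive candidates / expression
#'   strata.
#' @param identity_dedup_threshold pairwise upstream-sequence identity at or
#'   above which candidates are treated as paralog copies.
#' @param exclude_operon_mates if `TRUE` (default), stage 2 also excludes
#'   genes sharing an operon with a stage-1 pick, not only the picked genes
#'   themselves.
#' @return list of class `selection_config`.
#' @export
selection_config <- function(l2fc_min_sig = 2, p_max = 0.01, tpm_min = 100,
                             k_by_l2fc = 6L, k_by_tpm = 6L,
                             l2fc_min_for_tpm_rank = 3,
                             constitutive_band = 0.3,
                             k_constitutive = 7L,
                             identity_dedup_threshold = 0.95,
                             exclude_operon_mates = TRUE) {
  stop_if(k_by_l2fc < 0 || k_by_tpm < 0 || k_constitutive < 0,
          "k parameters must be >= 0")
  stop_if(constitutive_band < 0, "constitutive_band must be >= 0")
  stop_if(identity_dedup_threshold <= 0 || identity_dedup_threshold > 1,
          "identity_dedup_threshold must be in (0, 1]")
  structure(list(
    l2fc_min_sig = l2fc_min_sig, p_max = p_max, tpm_min = tpm_min,
    k_by_l2fc = as.integer(k_by_l2fc), k_by_tpm = as.integer(k_by_tpm),
    l2fc_min_for_tpm_rank = l2fc_min_for_tpm_rank,
    constitutive_band = constitutive_band,
    k_constitutive = as.integer(k_constitutive),
    identity_dedup_threshold = identity_dedup_threshold,
    exclude_operon_mates = exclude_operon_mates
  ), class = "selection_config")
}

# Walk a ranked gene list, resolving each pick to its operon head and
# promoting the next-ranked gene whenever a head (or excluded operon) repeats.
pick_heads <- function(ranked_ids, k, operons, route, diff,
                       taken_heads = character()) {
  if (k <= 0) return(NULL)
  heads <- character(0); src <- character(0)
  for (g in ranked_ids) {
    h <- operon_head(g, operons)
    if (h %in% c(taken_heads, heads)) next
    heads <- c(heads, h); src <- c(src, g)
    if (length(heads) == k) break
  }
  if (length(heads) == 0) return(NULL)
  idx <- match(heads, diff$gene_id)
  data.frame(route = route, head_gene = heads, source_gene = src,
             l2fc = diff$l2fc[match(src, diff$gene_id)],
             mean_tpm = diff$mean_a[match(src, diff$gene_id)],
             operon_id = operons$operon_id[match(heads, operons$gene_id)],
             stringsAsFactors = FALSE)
}

finish_candidates <- function(parts, config) {
  out <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(route = character(), head_gene = character(),
                      source_gene = character(), l2fc = numeric(),
                      mean_tpm = numeric(), operon_id = character(),
                      stringsAsFactors = FALSE)
  }
  out$rank <- seq_len(nrow(out))
  out <- out[, c("rank", "route", "head_gene", "source_gene", "l2fc",
                 "mean_tpm", "operon_id")]
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' Select condition-specific promoter candidates
#'
#' Two-stage procedure on a differential result for the autotrophic vs
#' heterotrophic pair. Stage 1: among genes with `mean_tpm_a > tpm_min`,
#' take the top `k_by_l2fc` by L2FC. Stage 2: among genes with
#' `l2fc > l2fc_min_for_tpm_rank`, excluding stage-1 picks (and, by default,
#' their operon mates), take the top `k_by_tpm` by autotrophic TPM. Every
#' pick is replaced by its operon's first gene; when two picks resolve to
#' the same head the next-ranked gene is promoted. Ties break on gene id,
#' so the output is fully deterministic.
#'
#' @param diff [differential_stats()] result (condition A = autotrophic).
#' @param operons `operon_set` from [infer_operons()].
#' @param config a [selection_config()].
#' @return `candidate_set` data.frame (`rank`, `route`, `head_gene`,
#'   `source_gene`, `l2fc`, `mean_tpm`, `operon_id`).
#' @export
select_condition_specific <- function(diff, operons,
                                      config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  # stage 1: highest L2FC among well-expressed genes
  e1 <- diff[diff$mean_a > config$tpm_min & is.finite(diff$l2fc), ,
             drop = FALSE]
  r1 <- e1$gene_id[order(-e1$l2fc, e1$gene_id)]
  s1 <- pick_heads(r1, config$k_by_l2fc, operons, "by_l2fc", diff)
  s1_heads <- if (is.null(s1)) character() else s1$head_gene
  s1_src <- if (is.null(s1)) character() else s1$source_gene

  # stage 2: highest TPM among strongly upregulated genes
  e2 <- diff[diff$l2fc > config$l2fc_min_for_tpm_rank, , drop = FALSE]
  excluded <- s1_src
  if (config$exclude_operon_mates && length(s1_heads)) {
    mates <- operons$gene_id[operons$operon_id %in%
                               operons$operon_id[match(s1_heads,
                                                       operons$gene_id)]]
    excluded <- union(excluded, mates)
  }
  e2 <- e2[!e2$gene_id %in% excluded, , drop = FALSE]
  r2 <- e2$gene_id[order(-e2$mean_a, e2$gene_id)]
  s2 <- pick_heads(r2, config$k_by_tpm, operons, "by_tpm", diff,
                   taken_heads = s1_heads)

  got <- NROW(s1) + NROW(s2)
  if (got < config$k_by_l2fc + config$k_by_tpm) {
    warning(sprintf("only %d of %d condition-specific candidates found",
                    got, config$k_by_l2fc + config$k_by_tpm))
  }
  finish_candidates(list(s1, s2), config)
}

#' Select constitutive promoter candidates across the expression range
#'
#' Eligible genes have `|L2FC| <= constitutive_band` (inclusive band around
#' 0). To spread candidates over "various" expression levels, eligible genes
#' are binned into `k_constitutive` quantile strata of log10 autotrophic
#' TPM and, within each stratum, the gene with |L2FC| closest to 0 is picked
#' (gene-id tie-break), then resolved to its operon head.
#'
#' @inheritParams select_condition_specific
#' @return `candidate_set` with route `"constitutive"`.
#' @export
select_constitutive <- function(diff, operons, config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  e <- diff[abs(diff$l2fc) <= config$constitutive_band & diff$mean_a > 0, ,
            drop = FALSE]
  if (nrow(e) == 0 || config$k_constitutive == 0) {
    warning("no eligible constitutive genes")
    return(finish_candidates(list(), config))
  }
  lx <- log10(e$mean_a)
  breaks <- unique(stats::quantile(lx, probs = seq(0, 1,
                                                   length.out = config$k_constitutive + 1)))
  if (length(breaks) < config$k_constitutive + 1) {
    warning("expression strata collapsed; returning fewer constitutive candidates")
  }
  if (length(breaks) == 1) breaks <- c(breaks - 1e-9, breaks + 1e-9)
  stratum <- cut(lx, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  heads <- character(0); src <- character(0)
  for (k in sort(unique(stratum))) {
    members <- e[stratum == k, , drop = FALSE]
    ranked <- members$gene_id[order(abs(members$l2fc), members$gene_id)]
    for (g in ranked) {
      h <- operon_head(g, operons)
      if (h %in% heads) next
      heads <- c(heads, h); src <- c(src, g)
      break
    }
  }
  if (length(heads) < config$k_constitutive) {
    warning(sprintf("only %d of %d constitutive candidates found",
                    length(heads), config$k_constitutive))
  }
  part <- if (length(heads)) {
    data.frame(route = "constitutive", head_gene = heads, source_gene = src,
               l2fc = diff$l2fc[match(src, diff$gene_id)],
               mean_tpm = diff$mean_a[match(src, diff$gene_id)],
               operon_id = operons$operon_id[match(heads, operons$gene_id)],
               stringsAsFactors = FALSE)
  } else NULL
  finish_candidates(list(part), config)
}

#' Global-alignment identity of two sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0 and free
#' gaps (full dynamic programming via [Biostrings::pairwiseAlignment()]);
#' identity = matched positions / alignment columns. Symmetric, and equal
#' to 1 iff the sequences are identical.
#'
#' @param a,b character or `DNAString` sequences.
#' @return identity in \[0, 1\].
#' @export
alignment_identity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  stop_if(nchar(a) == 0 || nchar(b) == 0, "empty sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 0)
  matches <- Biostrings::nmatch(aln)
  alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
  matches / alen
}

#' Drop duplicate candidates from near-identical paralogous operons
#'
#' Bacterial genomes can carry near-identical copies of an operon on
#' different replicons (the motivating case: duplicated CO2-fixation
#' operons on chromosome and megaplasmid). Candidates whose extracted
#' upstream sequences align at or above `threshold` identity are merged,
#' keeping the copy on the highest-priority replicon (gene-id tie-break).
#'
#' @param candidates a `candidate_set`.
#' @param upstream_seqs named character vector or `DNAStringSet` of upstream
#'   sequences, named by `head_gene`.
#' @param threshold identity threshold (default from the candidate set's
#'   config, 0.95).
#' @param replicon_priority character vector of replicon names, highest
#'   priority first; replicons not listed rank last.
#' @param replicons named character vector mapping head gene ids to replicon
#'   names (used with `replicon_priority` to choose which copy to keep).
#' @return the deduplicated `candidate_set`, re-ranked.
#' @export
deduplicate_paralogous <- function(candidates, upstream_seqs,
                                   threshold = NULL,
                                   replicon_priority = character(),
                                   replicons = NULL) {
  config <- attr(candidates, "config")
  threshold <- threshold %||% config$identity_dedup_threshold %||% 0.95
  seqs <- stats::setNames(as.character(upstream_seqs), names(upstream_seqs))
  n <- nrow(candidates)
  if (n <= 1) return(candidates)
  s <- seqs[candidates$head_gene]
  usable <- !is.na(s) & nzchar(s)
  if (any(!usable)) {
    warning(sprintf("candidate(s) without upstream sequence skipped in dedup: %s",
                    paste(candidates$head_gene[!usable], collapse = ", ")))
  }
  # union-find over pairs above threshold
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (!usable[i] || !usable[j]) next
    if (alignment_identity(s[i], s[j]) >= threshold) {
      parent[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  repl <- if (is.null(replicons)) rep(NA_character_, n) else
    unname(replicons[candidates$head_gene])
  rank_repl <- match(repl, replicon_priority)
  rank_repl[is.na(rank_repl)] <- length(replicon_priority) + 1L
  keep <- vapply(unique(roots), function(r) {
    members <- which(roots == r)
    members[order(rank_repl[members], candidates$head_gene[members])][1]
  }, integer(1))
  out <- candidates[sort(keep), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' Write candidates as TSV with a JSON provenance block
#'
#' @param candidates a `candidate_set`.
#' @param path output TSV path; provenance JSON goes to
#'   `paste0(path, ".json")`.
#' @export
write_candidates_tsv <- function(candidates, path) {
  utils::write.table(as.data.frame(candidates), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  config <- attr(candidates, "config")
  jsonlite::write_json(
    list(n_candidates = nrow(candidates),
         config = unclass(config) %||% list()),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
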