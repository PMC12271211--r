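# Relative quantification of qRT-PCR Ct values against a housekeeping
# reference gene (Livak delta-Ct method, amplification efficiency fixed at
# 2.0 per cycle), and comparison of exogenous vs endogenous genes sharing a
# promoter.

#' Relative expression from Ct values (delta-Ct / Livak method)
#'
#' Pairs each gene's Ct with the reference gene's Ct from the same
#' replicate: `delta_Ct = Ct_gene - Ct_reference`, `fold = 2^(-delta_Ct)`,
#' `log2_fold = -delta_Ct`. Summaries (mean, sd) are over biological
#' replicates.
#'
#' @param records data.frame with columns `gene`, `role` (`endogenous`,
#'   `exogenous` or `reference`), `replicate`, `ct` (cycles, > 0).
#' @param reference_gene id of the housekeeping reference; must be measured
#'   in every replicate in which any target gene is measured.
#' @return object of class `relative_expression`: list with `per_replicate`
#'   (data.frame `gene`, `replicate`, `delta_ct`, `fold`, `log2_fold`) and
#'   `summary` (data.frame `gene`, `role`, `n`, `mean_fold`,
#'   `mean_log2_fold`, `sd_log2_fold`).
#' @examples
#' ct <- data.frame(gene = rep(c("gyrB", "cbbL"), each = 3),
#'                  role = rep(c("reference", "endogenous"), each = 3),
#'                  replicate = rep(1:3, 2),
#'                  ct = c(21.0, 21.1, 20.9, 20.0, 20.1, 19.9))
#' relative_expression(ct, "gyrB")$summary
#' @export
relative_expression <- function(records, reference_gene) {
  need <- c("gene", "role", "replicate", "ct")
  stop_if(!all(need %in% names(records)),
          "records must have columns %s", paste(need, collapse = ", "))
  stop_if(any(records$ct <= 0), "Ct values must be positive")
  ref <- records[records$gene == reference_gene, , drop = FALSE]
  stop_if(nrow(ref) == 0, "reference gene %s not found", reference_gene)
  ref_ct <- stats::setNames(ref$ct, ref$replicate)
  targets <- records[records$gene != reference_gene, , drop = FALSE]
  missing <- setdiff(unique(targets$replicate), names(ref_ct))
  stop_if(length(missing) > 0,
          "missing reference Ct for replicate(s): %s",
          paste(missing, collapse = ", "))
  per <- data.frame(
    gene = targets$gene,
    replicate = targets$replicate,
    delta_ct = targets$ct - ref_ct[as.character(targets$replicate)],
    stringsAsFactors = FALSE)
  per$fold <- 2^(-per$delta_ct)
  per$log2_fold <- -per$delta_ct
  rownames(per) <- NULL
  summ <- do.call(rbind, lapply(split(per, per$gene), function(d) {
    data.frame(gene = d$gene[1],
               role = targets$role[match(d$gene[1], targets$gene)],
               n = nrow(d),
               mean_fold = mean(d$fold),
               mean_log2_fold = mean(d$log2_fold),
               sd_log2_fold = if (nrow(d) > 1) stats::sd(d$log2_fold) else
                 NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(per_replicate = per, summary = summ),
            class = "relative_expression")
}

#' Compare an exogenous gene with the endogenous gene sharing its promoter
#'
#' Ratio of mean folds (exogenous over endogenous) plus a pooled-variance
#' Student's t-test on the per-replicate log2 folds. A ratio near 1 with a
#' non-significant p indicates the promoter drives the exogenous gene as it
#' drives its native operon.
#'
#' @param rel a [relative_expression()] result.
#' @param exo_gene,endo_gene gene ids; both must be measured in the same
#'   replicates.
#' @return list with `ratio`, `t`, `df`, `p`.
#' @export
promoter_pair_comparison <- function(rel, exo_gene, endo_gene) {
  stopifnot(inherits(rel, "relative_expression"))
  per <- rel$per_replicate
  e <- per[per$gene == exo_gene, , drop = FALSE]
  n <- per[per$gene == endo_gene, , drop = FALSE]
  stop_if(nrow(e) == 0 || nrow(n) == 0, "gene not found in Ct records")
  stop_if(!setequal(e$replicate, n$replicate),
          "replicate mismatch between %s and %s", exo_gene, endo_gene)
  tt <- two_sample_ttest(e$log2_fold, n$log2_fold, variant = "student")
  list(ratio = mean(e$fold) / mean(n$fold), t = tt$t, df = tt$df, p = tt$p)
}

#' Read a Ct table from TSV
#'
#' @param path TSV with columns `gene`, `role`, `replicate`, `ct`.
#' @export
read_ct_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a relative-expression summary as TSV
#'
#' @param rel a [relative_expression()] result.
#' @param path output path.
#' @export
write_relative_expression_tsv <- function(rel, path) {
  utils::write.table(rel$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
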