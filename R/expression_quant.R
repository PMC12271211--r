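# Expression quantification: TPM normalization, per-condition summaries,
# pairwise differential statistics (log2 fold change + replicate t-test),
# threshold filtering and the cross-comparison regression.

#' Transcripts per million from raw counts
#'
#' `tpm(g, s) = 1e6 * (count(g, s) / length(g)) / sum_g'(count(g', s) /
#' length(g'))`. Gene length is the annotated gene span in bp (no isoform
#' model; bacterial ORFs). A sample with all-zero counts yields all-zero TPM
#' with a warning.
#'
#' @param counts non-negative matrix (genes x samples) with gene ids as
#'   rownames.
#' @param lengths named numeric vector of gene lengths in bp covering every
#'   gene in `counts`.
#' @return TPM matrix with the same dimnames; each non-degenerate sample
#'   column sums to 1e6.
#' @examples
#' counts <- matrix(c(10, 20, 30), dimnames = list(c("a", "b", "c"), "s1"))
#' compute_tpm(counts, c(a = 100, b = 200, c = 300))
#' @export
compute_tpm <- function(counts, lengths) {
  stop_if(is.null(rownames(counts)), "counts must have gene ids as rownames")
  stop_if(anyDuplicated(rownames(counts)) > 0, "duplicate gene ids in counts")
  stop_if(any(counts < 0), "counts must be non-negative")
  missing <- setdiff(rownames(counts), names(lengths))
  stop_if(length(missing) > 0, "missing gene length(s): %s",
          paste(utils::head(missing, 5), collapse = ", "))
  len <- lengths[rownames(counts)]
  stop_if(any(len <= 0), "gene lengths must be positive")
  rate <- counts / len
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    warning(sprintf("sample(s) with all-zero counts: %s",
                    paste(colnames(counts)[zero], collapse = ", ")))
    denom[zero] <- 1  # leaves the column all-zero
  }
  sweep(rate, 2, denom, "/") * 1e6
}

#' Pairwise differential statistics between two conditions
#'
#' For every gene computes the arithmetic mean (and sd) of replicate TPMs in
#' each condition, the log2 fold change
#' `log2((mean_a + pseudocount) / (mean_b + pseudocount))`, and a two-sample
#' t-test p-value on `log2(TPM + pseudocount)` replicate values (Welch by
#' default; pooled-variance Student available).
#'
#' @param tpm TPM matrix (genes x samples).
#' @param design data.frame with columns `sample`, `condition`.
#' @param pair character(2): condition A (numerator) and condition B
#'   (denominator); both need >= 2 replicates.
#' @param pseudocount added inside both the fold change and the log transform;
#'   keeps L2FC finite for silent genes. Default 1 TPM.
#' @param test `"welch"` (default) or `"student"`.
#' @return data.frame (`gene_id`, `mean_a`, `mean_b`, `sd_a`, `sd_b`,
#'   `l2fc`, `p_value`) with attributes `pair`, `pseudocount`, `test`.
#' @export
differential_stats <- function(tpm, design, pair, pseudocount = 1,
                               test = c("welch", "student")) {
  test <- match.arg(test)
  stop_if(length(pair) != 2, "pair must name two conditions")
  for (cond in pair) {
    stop_if(!cond %in% design$condition, "unknown condition label: %s", cond)
    stop_if(sum(design$condition == cond) < 2,
            "condition %s has fewer than 2 replicates", cond)
  }
  sa <- design$sample[design$condition == pair[1]]
  sb <- design$sample[design$condition == pair[2]]
  stop_if(!all(c(sa, sb) %in% colnames(tpm)),
          "design samples missing from the TPM matrix")
  A <- tpm[, sa, drop = FALSE]
  B <- tpm[, sb, drop = FALSE]
  mean_a <- rowMeans(A); mean_b <- rowMeans(B)
  sd_a <- apply(A, 1, stats::sd); sd_b <- apply(B, 1, stats::sd)
  l2fc <- log2((mean_a + pseudocount) / (mean_b + pseudocount))

  la <- log2(A + pseudocount); lb <- log2(B + pseudocount)
  na <- ncol(la); nb <- ncol(lb)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- rowSums((la - ma)^2) / (na - 1)
  vb <- rowSums((lb - mb)^2) / (nb - 1)
  if (test == "welch") {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- na + nb - 2
  }
  tstat <- (ma - mb) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate variance guard: identical replicate sets give p = 1,
  # zero-variance separation gives p = 0
  degen <- se2 == 0 | !is.finite(p)
  p[degen] <- ifelse(abs(ma - mb)[degen] < .Machine$double.eps^0.5, 1, 0)

  out <- data.frame(gene_id = rownames(tpm), mean_a = mean_a, mean_b = mean_b,
                    sd_a = sd_a, sd_b = sd_b, l2fc = l2fc, p_value = p,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "pair") <- pair
  attr(out, "pseudocount") <- pseudocount
  attr(out, "test") <- test
  out
}

#' Genes significantly upregulated in condition A
#'
#' Applies the three filters with strict inequalities: `l2fc > l2fc_min`,
#' `p_value < p_max` and `mean_a > tpm_a_min`; exact-boundary genes are
#' excluded. Tightening any threshold can only shrink the set.
#'
#' @param diff a [differential_stats()] result.
#' @param l2fc_min,p_max,tpm_a_min thresholds (defaults: 2, 0.01, 100).
#' @param fdr if `TRUE`, filter on Benjamini-Hochberg adjusted p-values
#'   instead of raw p-values (off by default; the selection procedure this
#'   package implements filters on raw p).
#' @return character vector of gene ids in descending-L2FC order, ties broken
#'   by gene id.
#' @export
upregulated_set <- function(diff, l2fc_min = 2, p_max = 0.01,
                            tpm_a_min = 100, fdr = FALSE) {
  stop_if(!all(is.finite(c(l2fc_min, p_max, tpm_a_min))),
          "thresholds must be finite")
  p <- if (fdr) stats::p.adjust(diff$p_value, method = "BH") else diff$p_value
  keep <- diff$l2fc > l2fc_min & p < p_max & diff$mean_a > tpm_a_min
  keep[is.na(keep)] <- FALSE
  sel <- diff[keep, , drop = FALSE]
  sel$gene_id[order(-sel$l2fc, sel$gene_id)]
}

#' Genes upregulated against both heterotrophic comparisons
#'
#' @param set_frc,set_ace gene-id vectors from [upregulated_set()].
#' @return intersection, ordered by gene id.
#' @export
common_upregulated <- function(set_frc, set_ace) {
  sort(intersect(set_frc, set_ace))
}

#' Cross-comparison regression of per-gene log2 fold changes
#'
#' Ordinary least squares of `y = L2FC(A/C)` on `x = L2FC(A/B)` over the
#' shared gene universe, plus the Pearson correlation — the standard check
#' that two heterotrophic baselines give a consistent picture of
#' autotroph-specific regulation. Non-finite pairs are dropped and counted.
#'
#' @param diff_frc,diff_ace two [differential_stats()] results over the same
#'   genes (x and y respectively).
#' @return object of class `cross_regression`: list with `slope`,
#'   `intercept`, `r`, `n`, `n_dropped`.
#' @export
cross_condition_regression <- function(diff_frc, diff_ace) {
  stop_if(!setequal(diff_frc$gene_id, diff_ace$gene_id),
          "both results must cover the same gene universe")
  x <- diff_frc$l2fc
  y <- diff_ace$l2fc[match(diff_frc$gene_id, diff_ace$gene_id)]
  ok <- is.finite(x) & is.finite(y)
  stop_if(sum(ok) < 3, "fewer than 3 finite L2FC pairs")
  fit <- stats::lm.fit(cbind(1, x[ok]), y[ok])
  structure(list(
    slope = unname(fit$coefficients[2]),
    intercept = unname(fit$coefficients[1]),
    r = stats::cor(x[ok], y[ok]),
    n = sum(ok),
    n_dropped = sum(!ok)
  ), class = "cross_regression")
}

#' @export
print.cross_regression <- function(x, ...) {
  cat(sprintf("Cross-comparison regression: y = %.3fx %+.3f, r = %.3f (n = %d, dropped %d)\n",
              x$slope, x$intercept, x$r, x$n, x$n_dropped))
  invisible(x)
}
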