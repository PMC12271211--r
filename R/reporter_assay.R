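# Reporter-assay arithmetic: per-promoter activity summaries, the
# autotrophic/heterotrophic fold ratio, a two-sample t-test, and
# classification of promoters as condition-specific, constitutive, or
# inactive.

#' Summarize reporter activities per promoter and condition
#'
#' @param table data.frame with columns `promoter`, `condition`,
#'   `replicate`, `activity` (mU per microgram protein, non-negative).
#' @return data.frame with `promoter`, `condition`, `mean`, `sd` (sample sd,
#'   n-1 denominator; `NA` for a single replicate), `n`.
#' @examples
#' tab <- data.frame(promoter = "P", condition = "autotrophic",
#'                   replicate = 1:3, activity = c(100, 105, 110))
#' summarize_assay(tab)
#' @export
summarize_assay <- function(table) {
  need <- c("promoter", "condition", "replicate", "activity")
  stop_if(!all(need %in% names(table)),
          "assay table must have columns %s", paste(need, collapse = ", "))
  stop_if(any(table$activity < 0), "activities must be non-negative")
  key <- paste(table$promoter, table$condition, sep = "\r")
  groups <- split(table$activity, key)
  keys <- strsplit(names(groups), "\r", fixed = TRUE)
  out <- data.frame(
    promoter = vapply(keys, `[[`, character(1), 1),
    condition = vapply(keys, `[[`, character(1), 2),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, function(x) if (length(x) > 1) stats::sd(x) else
      NA_real_, numeric(1)),
    n = vapply(groups, length, integer(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$promoter, out$condition), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Autotrophic / heterotrophic activity fold ratio
#'
#' @param summary a [summarize_assay()] result.
#' @param promoter promoter id.
#' @return the ratio `mean_autotrophic / mean_heterotrophic`; `Inf` (with
#'   attribute `flag = "infinite_ratio"`) when the heterotrophic mean is 0
#'   and the autotrophic mean is positive; `NaN` when both are 0.
#' @examples
#' s <- data.frame(promoter = "PS01",
#'                 condition = c("autotrophic", "heterotrophic"),
#'                 mean = c(104.8, 3.0), sd = c(5.9, 1.2), n = 3L)
#' round(fold_ratio(s, "PS01"), 1)
#' @export
fold_ratio <- function(summary, promoter) {
  rows <- summary[summary$promoter == promoter, , drop = FALSE]
  m_auto <- rows$mean[rows$condition == "autotrophic"]
  m_het <- rows$mean[rows$condition == "heterotrophic"]
  stop_if(length(m_auto) != 1 || length(m_het) != 1,
          "promoter %s needs one autotrophic and one heterotrophic summary",
          promoter)
  if (m_het == 0) {
    ratio <- if (m_auto > 0) Inf else NaN
    attr(ratio, "flag") <- "infinite_ratio"
    return(ratio)
  }
  m_auto / m_het
}

#' Two-sample t-test on replicate values
#'
#' Pooled-variance Student's test by default (the convention for triplicate
#' reporter assays); Welch's unequal-variance variant available. Degenerate
#' zero-variance groups are guarded: identical groups give p = 1, separated
#' zero-variance groups give p = 0.
#'
#' @param a,b numeric replicate vectors (each n >= 2).
#' @param variant `"student"` or `"welch"`.
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_ttest <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  stop_if(length(a) < 2 || length(b) < 2, "each group needs n >= 2")
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (variant == "student") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- na + nb - 2
  } else {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  if (se2 == 0) {
    same <- abs(ma - mb) < .Machine$double.eps^0.5
    return(list(t = if (same) 0 else sign(ma - mb) * Inf,
                df = df, p = if (same) 1 else 0))
  }
  t <- (ma - mb) / sqrt(se2)
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Assay classification configuration
#'
#' @param activity_floor activity (mU per microgram protein) below which a
#'   promoter is considered inactive in a condition; 1.1 by default, the
#'   conventional negligible-activity cutoff for this reporter system.
#' @param specific_ratio_min minimum autotrophic/heterotrophic fold ratio
#'   for a condition-specific call (default 3).
#' @param constitutive_band two-sided fold-ratio band for a constitutive
#'   call (default \[0.5, 2\], a superset of the 0.8-1.6 range typical of
#'   validated constitutive promoters).
#' @param alpha significance level of the t-test backing a
#'   condition-specific call.
#' @param test `"student"` (default) or `"welch"`.
#' @return list of class `assay_config`.
#' @export
assay_config <- function(activity_floor = 1.1, specific_ratio_min = 3.0,
                         constitutive_band = c(0.5, 2.0), alpha = 0.05,
                         test = c("student", "welch")) {
  structure(list(activity_floor = activity_floor,
                 specific_ratio_min = specific_ratio_min,
                 constitutive_band = constitutive_band,
                 alpha = alpha, test = match.arg(test)),
            class = "assay_config")
}

#' Classify promoters from replicate reporter activities
#'
#' Calls each promoter, with precedence: `inactive` when every condition
#' mean is below the activity floor; else `condition_specific` when the
#' fold ratio is at least `specific_ratio_min` and the between-condition
#' t-test gives p below `alpha`; else `constitutive` when the fold ratio
#' lies inside the constitutive band and both means clear the floor;
#' otherwise `ambiguous`. Exactly one label per promoter.
#'
#' @param table replicate-level assay data.frame (`promoter`, `condition`,
#'   `replicate`, `activity`) with conditions `autotrophic` and
#'   `heterotrophic`.
#' @param config an [assay_config()].
#' @return data.frame (`promoter`, `mean_auto`, `sd_auto`, `n_auto`,
#'   `mean_het`, `sd_het`, `n_het`, `fold_ratio`, `p_value`, `call`) with
#'   the config as attribute.
#' @export
classify_promoters <- function(table, config = assay_config()) {
  stopifnot(inherits(config, "assay_config"))
  summary <- summarize_assay(table)
  out <- lapply(unique(summary$promoter), function(p) {
    rows <- summary[summary$promoter == p, ]
    a <- table$activity[table$promoter == p & table$condition == "autotrophic"]
    b <- table$activity[table$promoter == p & table$condition == "heterotrophic"]
    m_auto <- rows$mean[rows$condition == "autotrophic"]
    m_het <- rows$mean[rows$condition == "heterotrophic"]
    ratio <- as.numeric(fold_ratio(summary, p))
    p_val <- if (length(a) >= 2 && length(b) >= 2)
      two_sample_ttest(a, b, config$test)$p else NA_real_
    call <- if (max(m_auto, m_het) < config$activity_floor) {
      "inactive"
    } else if (is.finite(ratio) && ratio >= config$specific_ratio_min &&
               !is.na(p_val) && p_val < config$alpha) {
      "condition_specific"
    } else if (!is.finite(ratio) && ratio > 0 && !is.na(p_val) &&
               p_val < config$alpha) {
      # infinite ratio (het mean 0) with a significant contrast
      "condition_specific"
    } else if (is.finite(ratio) &&
               ratio >= config$constitutive_band[1] &&
               ratio <= config$constitutive_band[2] &&
               min(m_auto, m_het) >= config$activity_floor) {
      "constitutive"
    } else {
      "ambiguous"
    }
    data.frame(promoter = p,
               mean_auto = m_auto,
               sd_auto = rows$sd[rows$condition == "autotrophic"],
               n_auto = rows$n[rows$condition == "autotrophic"],
               mean_het = m_het,
               sd_het = rows$sd[rows$condition == "heterotrophic"],
               n_het = rows$n[rows$condition == "heterotrophic"],
               fold_ratio = ratio, p_value = p_val, call = call,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "config") <- config
  out
}

#' Read a replicate-level assay table from TSV
#'
#' @param path TSV with columns `promoter`, `condition`, `replicate`,
#'   `activity`.
#' @export
read_assay_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write promoter calls (with summary statistics) as TSV
#'
#' @param calls a [classify_promoters()] result.
#' @param path output path.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
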