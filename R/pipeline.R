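# End-to-end orchestration behind one configuration object: quantify ->
# differential -> operons -> select -> extract -> (assay, qPCR) -> report.
# Re-running with identical inputs reproduces identical outputs byte for
# byte (no timestamps in any artifact).

#' Pipeline configuration
#'
#' Collects input paths and stage parameters, validating that every
#' referenced input exists before any stage runs.
#'
#' @param counts,design,gff,genome input paths (counts TSV, design TSV,
#'   GFF3 annotation, genome FASTA). `genome` may be `NULL` to skip
#'   promoter extraction.
#' @param assay,qpcr optional paths to a replicate-level assay TSV and a Ct
#'   TSV; the corresponding stages run only when given.
#' @param out_dir output directory (created if needed).
#' @param condition_auto autotrophic condition label in the design.
#' @param condition_het heterotrophic condition labels (first is the
#'   primary comparison used for selection).
#' @param selection a [selection_config()].
#' @param assay_cfg an [assay_config()].
#' @param max_gap operon-inference gap cap in bp.
#' @param min_len,max_len promoter extraction caps in bp.
#' @param pseudocount TPM pseudocount for differential statistics.
#' @param reference_gene qPCR housekeeping reference gene id.
#' @param replicon_priority replicon order used for paralog dedup.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, design, gff, genome = NULL,
                            assay = NULL, qpcr = NULL, out_dir,
                            condition_auto = "H2CO2",
                            condition_het = c("fructose", "acetate"),
                            selection = selection_config(),
                            assay_cfg = assay_config(),
                            max_gap = 50, min_len = 20L, max_len = 1000L,
                            pseudocount = 1,
                            reference_gene = "gyrB",
                            replicon_priority = character()) {
  paths <- list(counts = counts, design = design, gff = gff,
                genome = genome, assay = assay, qpcr = qpcr)
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!is.null(p)) stop_if(!file.exists(p),
                             "config error: %s file not found: %s", nm, p)
  }
  structure(list(paths = paths, out_dir = out_dir,
                 condition_auto = condition_auto,
                 condition_het = condition_het,
                 selection = selection, assay_cfg = assay_cfg,
                 max_gap = max_gap, min_len = min_len, max_len = max_len,
                 pseudocount = pseudocount,
                 reference_gene = reference_gene,
                 replicon_priority = replicon_priority),
            class = "pipeline_config")
}

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Run the full promoter-mining pipeline
#'
#' Executes, in order: TPM quantification, differential statistics of the
#' autotrophic condition against each heterotrophic condition, operon
#' inference, condition-specific and constitutive candidate selection
#' (with paralog dedup when a genome is available), upstream-region
#' extraction, and — when their inputs are configured — reporter-assay
#' classification and qPCR relative quantification. All stage outputs are
#' written under `config$out_dir`; any stage error aborts with the stage
#' name.
#'
#' @param config a [pipeline_config()].
#' @return a `run_report` list: per-stage record counts, candidate and call
#'   tables, config echo + hash, package version and input checksums.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  report <- list(version = as.character(utils::packageVersion("promscreen")),
                 config_hash = config_hash(config),
                 config = unclass_deep(config),
                 input_checksums = as.list(
                   tools::md5sum(unlist(Filter(Negate(is.null),
                                               config$paths)))),
                 stages = list())
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # quantify
  counts <- run_stage("quantify", read_counts_tsv(config$paths$counts))
  design <- run_stage("quantify", read_design_tsv(config$paths$design))
  ann <- run_stage("quantify", read_annotation_gff3(config$paths$gff))
  lengths <- stats::setNames(ann$length, ann$gene_id)
  tpm <- run_stage("quantify", compute_tpm(counts, lengths))
  utils::write.table(
    data.frame(gene_id = rownames(tpm), round(tpm, 4), check.names = FALSE),
    out("tpm.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  report$stages$quantify <- list(n_genes = nrow(tpm), n_samples = ncol(tpm))
  stage_msg("quantify", "%d genes x %d samples", nrow(tpm), ncol(tpm))

  # differential: autotrophic vs each heterotrophic condition
  diffs <- list()
  for (het in config$condition_het) {
    d <- run_stage("differential",
                   differential_stats(tpm, design,
                                      c(config$condition_auto, het),
                                      pseudocount = config$pseudocount))
    diffs[[het]] <- d
    utils::write.table(d, out(sprintf("differential_%s.tsv", het)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  primary <- diffs[[config$condition_het[1]]]
  report$stages$differential <- list(pairs = length(diffs))

  sets <- lapply(diffs, upregulated_set,
                 l2fc_min = config$selection$l2fc_min_sig,
                 p_max = config$selection$p_max,
                 tpm_a_min = config$selection$tpm_min)
  common <- if (length(sets) >= 2) common_upregulated(sets[[1]], sets[[2]])
  else sets[[1]]
  report$stages$upregulated <- c(lapply(sets, length),
                                 list(common = length(common)))
  if (length(diffs) >= 2) {
    reg <- run_stage("differential",
                     cross_condition_regression(diffs[[1]], diffs[[2]]))
    report$stages$regression <- unclass(reg)
  }

  # operons
  operons <- run_stage("operons", infer_operons(ann, config$max_gap))
  write_operons_tsv(operons, out("operons.tsv"))
  report$stages$operons <- list(n_operons = length(unique(operons$operon_id)))
  stage_msg("operons", "%d operons", length(unique(operons$operon_id)))

  # select
  specific <- run_stage("select",
                        select_condition_specific(primary, operons,
                                                  config$selection))
  constitutive <- run_stage("select",
                            select_constitutive(primary, operons,
                                                config$selection))

  # extract (+ dedup of specific candidates) when a genome is available
  regions <- NULL
  if (!is.null(config$paths$genome)) {
    genome <- run_stage("extract",
                        Biostrings::readDNAStringSet(config$paths$genome))
    names(genome) <- sub("\\s.*$", "", names(genome))
    reg_s <- run_stage("extract",
                       extract_promoters(specific, ann, genome,
                                         min_len = config$min_len,
                                         max_len = config$max_len,
                                         prefix = "PS"))
    seqs <- stats::setNames(reg_s$sequence, reg_s$head_gene)
    repl <- stats::setNames(reg_s$replicon, reg_s$head_gene)
    specific <- run_stage("select",
                          deduplicate_paralogous(
                            specific[specific$head_gene %in% reg_s$head_gene, ],
                            seqs,
                            replicon_priority = config$replicon_priority,
                            replicons = repl))
    reg_s <- reg_s[reg_s$head_gene %in% specific$head_gene, , drop = FALSE]
    reg_s$candidate_id <- sprintf("PS%02d", seq_len(nrow(reg_s)))
    reg_c <- run_stage("extract",
                       extract_promoters(constitutive, ann, genome,
                                         min_len = config$min_len,
                                         max_len = config$max_len,
                                         prefix = "PC"))
    regions <- rbind(reg_s, reg_c)
    write_promoter_fasta(regions, out("promoters.fasta"))
    write_promoter_bed(regions, out("promoters.bed"))
    report$stages$extract <- list(n_regions = nrow(regions))
    stage_msg("extract", "%d promoter regions", nrow(regions))
  }
  write_candidates_tsv(specific, out("candidates_specific.tsv"))
  write_candidates_tsv(constitutive, out("candidates_constitutive.tsv"))
  report$stages$select <- list(n_specific = nrow(specific),
                               n_constitutive = nrow(constitutive))
  stage_msg("select", "%d specific + %d constitutive candidates",
            nrow(specific), nrow(constitutive))
  report$candidates <- list(specific = as.data.frame(specific),
                            constitutive = as.data.frame(constitutive))

  # assay
  if (!is.null(config$paths$assay)) {
    tab <- run_stage("assay", read_assay_tsv(config$paths$assay))
    calls <- run_stage("assay", classify_promoters(tab, config$assay_cfg))
    write_calls_tsv(calls, out("assay_calls.tsv"))
    report$stages$assay <- list(n_promoters = nrow(calls))
    report$calls <- calls
    stage_msg("assay", "%d promoters classified", nrow(calls))
  }

  # qPCR
  if (!is.null(config$paths$qpcr)) {
    ct <- run_stage("qpcr", read_ct_tsv(config$paths$qpcr))
    rel <- run_stage("qpcr",
                     relative_expression(ct, config$reference_gene))
    write_relative_expression_tsv(rel, out("qpcr_relative_expression.tsv"))
    report$stages$qpcr <- list(n_genes = nrow(rel$summary))
    report$qpcr <- rel$summary
  }

  class(report) <- "run_report"
  report
}

#' Render a run report as markdown + JSON
#'
#' The JSON round-trips losslessly through [jsonlite]; the markdown carries
#' the per-stage counts and candidate / call tables, plus the config hash
#' that reproduces the run.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param path output markdown path; JSON is written alongside with
#'   extension `.json`.
#' @return invisibly, the markdown path.
#' @export
render_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  json_path <- sub("\\.md$", "", path)
  json_path <- paste0(json_path, ".json")
  jsonlite::write_json(unclass_deep(unclass(report)), json_path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  lines <- c(
    "# Promoter screen run report",
    "",
    sprintf("- package version: %s", report$version),
    sprintf("- config hash: %s", report$config_hash),
    "",
    "## Stage record counts", "")
  for (nm in names(report$stages)) {
    vals <- unlist(report$stages[[nm]])
    lines <- c(lines, sprintf("- %s: %s", nm,
                              paste(sprintf("%s=%s", names(vals), vals),
                                    collapse = ", ")))
  }
  md_table <- function(df) {
    if (is.null(df) || nrow(df) == 0) return("(none)")
    hdr <- paste(names(df), collapse = " | ")
    sep <- paste(rep("---", ncol(df)), collapse = " | ")
    body <- apply(df, 1, function(r) paste(r, collapse = " | "))
    c(paste("|", hdr, "|"), paste("|", sep, "|"),
      paste("|", body, "|"))
  }
  lines <- c(lines, "", "## Condition-specific candidates", "",
             md_table(report$candidates$specific),
             "", "## Constitutive candidates", "",
             md_table(report$candidates$constitutive))
  if (!is.null(report$calls)) {
    lines <- c(lines, "", "## Promoter calls", "", md_table(report$calls))
  }
  writeLines(lines, path)
  invisible(path)
}
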