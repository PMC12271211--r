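# Shared fixture builders. Everything is generated in code; no data files.

# Minimal annotation data.frame from parallel vectors.
toy_annotation <- function(start, end, strand, replicon = "chr",
                           gene_id = sprintf("g%02d", seq_along(start))) {
  data.frame(gene_id = gene_id, replicon = replicon,
             start = as.integer(start), end = as.integer(end),
             strand = strand, length = as.integer(end - start + 1),
             stringsAsFactors = FALSE)
}

# Random annotation of <= max_genes genes on one replicon, for property tests.
random_annotation <- function(n_genes, replicon_len = 30000L,
                              replicon = "chr") {
  pos <- 1L
  starts <- integer(n_genes); ends <- integer(n_genes)
  for (i in seq_len(n_genes)) {
    pos <- pos + sample(10:200, 1)
    len <- sample(100:600, 1)
    starts[i] <- pos; ends[i] <- pos + len - 1L
    pos <- ends[i] + 1L
  }
  stopifnot(max(ends) <= replicon_len)
  toy_annotation(starts, ends, sample(c("+", "-"), n_genes, replace = TRUE),
                 replicon = replicon)
}

random_genome <- function(annotation, pad = 500L) {
  L <- max(annotation$end) + pad
  s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  Biostrings::DNAStringSet(stats::setNames(s, annotation$replicon[1]))
}

# Brute-force operon oracle: transitive closure of the pairwise join
# relation (same replicon + strand, intergenic gap <= max_gap, and no gene
# strictly between the pair).
oracle_operons <- function(annotation, max_gap) {
  ann <- annotation[order(annotation$replicon, annotation$start,
                          annotation$end), ]
  n <- nrow(ann)
  joined <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (ann$replicon[i] != ann$replicon[j]) next
    if (ann$strand[i] != ann$strand[j]) next
    lo <- min(i, j); hi <- max(i, j)
    if (hi - lo != 1) next  # only coordinate-adjacent genes can join directly
    gap <- ann$start[hi] - max(ann$end[lo:(hi - 1)]) - 1L
    if (gap <= max_gap) joined[i, j] <- TRUE
  }
  # transitive closure (Floyd-Warshall on the boolean relation)
  reach <- joined | diag(n) > 0
  for (k in seq_len(n)) {
    reach <- reach | (reach[, k] %o% reach[k, ]) > 0
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[reach[i, ] & reach[, i]] <- cid
    }
  }
  split(ann$gene_id, comp)
}

# Tiny hand-made differential table.
toy_diff <- function(gene_id, l2fc, p_value = 0.001, mean_a = 500,
                     mean_b = 50) {
  n <- length(gene_id)
  data.frame(gene_id = gene_id,
             mean_a = rep_len(mean_a, n), mean_b = rep_len(mean_b, n),
             sd_a = rep_len(1, n), sd_b = rep_len(1, n),
             l2fc = l2fc, p_value = rep_len(p_value, n),
             stringsAsFactors = FALSE)
}

# Singleton operon set in which every gene is its own head.
singleton_operons <- function(gene_ids, replicon = "chr", strand = "+") {
  out <- data.frame(gene_id = gene_ids,
                    operon_id = sprintf("operon_%04d", seq_along(gene_ids)),
                    replicon = rep_len(replicon, length(gene_ids)),
                    strand = rep_len(strand, length(gene_ids)),
                    head_gene = gene_ids, stringsAsFactors = FALSE)
  class(out) <- c("operon_set", "data.frame")
  out
}

# Small benchmark dataset shared by selection tests (cached per session).
bench_dataset <- local({
  cache <- NULL
  function(seed = 2, dispersion = 0.01) {
    key <- paste(seed, dispersion)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$value)
    # full-scale gene universe: with ~2000 genes the planted high-abundance
    # operons stay a small fraction of each library, so the TPM denominator
    # (and hence every L2FC) is only marginally perturbed by the planting
    spec <- synthetic_genome_spec(seed = seed)
    gen <- generate_annotation(spec, genome = FALSE)
    program <- expression_program(gen$annotation, nb_dispersion = dispersion,
                                  seed = seed + 1)
    sim <- simulate_counts(gen$annotation, program, seed = seed + 2)
    value <- list(annotation = gen$annotation, counts = sim$counts,
                  design = sim$design, truth = sim$truth)
    cache <<- list(key = key, value = value)
    value
  }
})
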