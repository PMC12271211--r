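# Synthetic benchmark data: an annotated multi-replicon bacterial genome with
# operon structure, a planted expression program over three growth conditions
# (H2/CO2 autotrophy vs fructose / acetate heterotrophy), negative-binomial
# read counts, and reporter-assay fixtures. Every generator is seeded and
# deterministic, and the planted truth is returned alongside the data so that
# downstream selection stages can be scored against it.

#' Describe a synthetic multi-replicon genome
#'
#' Builds the parameter object consumed by [generate_annotation()]. The
#' defaults emulate a bacterium with a large chromosome, a secondary
#' chromosome and a megaplasmid, carrying on the order of two thousand genes
#' organised into operons of one to twelve genes.
#'
#' @param replicons named numeric vector of replicon lengths in bp.
#' @param n_operons total number of operons to place (allocated across
#'   replicons proportionally to length).
#' @param operon_size_probs named numeric vector: probability of each operon
#'   size; names are integer sizes.
#' @param gene_length_range integer range (bp) genes are drawn from, uniform.
#' @param intra_operon_gap integer range (bp) for gaps between genes of one
#'   operon. Must lie strictly below `inter_operon_gap` so that distance-based
#'   operon inference is well-posed on the synthetic truth.
#' @param inter_operon_gap integer range (bp) for gaps between operons.
#' @param strand_flip_prob probability that each new operon switches strand
#'   relative to the previous one; the first operon of a replicon is always
#'   on the forward strand, so `strand_flip_prob = 0` yields an all-forward
#'   genome.
#' @param seed integer seed.
#' @return an object of class `synthetic_genome_spec`.
#' @examples
#' spec <- synthetic_genome_spec(replicons = c(chr = 50000), n_operons = 10)
#' ann <- generate_annotation(spec)
#' head(ann$annotation)
#' @export
synthetic_genome_spec <- function(replicons = c(chromosome1 = 1.9e6,
                                                chromosome2 = 1.1e6,
                                                megaplasmid = 4.5e5),
                                  n_operons = 940,
                                  operon_size_probs = c(
                                    "1" = 0.45, "2" = 0.20, "3" = 0.12,
                                    "4" = 0.08, "5" = 0.06, "6" = 0.04,
                                    "7" = 0.02, "8" = 0.010, "9" = 0.008,
                                    "10" = 0.006, "11" = 0.004, "12" = 0.002),
                                  gene_length_range = c(200L, 1800L),
                                  intra_operon_gap = c(0L, 40L),
                                  inter_operon_gap = c(60L, 600L),
                                  strand_flip_prob = 0.5,
                                  seed = 1L) {
  stop_if(is.null(names(replicons)) || any(!nzchar(names(replicons))),
          "replicons must be a named vector of lengths")
  stop_if(any(replicons <= 0), "replicon lengths must be positive")
  stop_if(n_operons < 1, "n_operons must be >= 1")
  stop_if(is.null(names(operon_size_probs)),
          "operon_size_probs must be named by operon size")
  stop_if(any(operon_size_probs < 0) || sum(operon_size_probs) <= 0,
          "operon_size_probs must be non-negative and sum > 0")
  stop_if(gene_length_range[1] < 1 || diff(gene_length_range) < 0,
          "invalid gene_length_range")
  stop_if(max(intra_operon_gap) >= min(inter_operon_gap),
          "intra-operon gaps must be strictly smaller than inter-operon gaps")
  stop_if(strand_flip_prob < 0 || strand_flip_prob > 1,
          "strand_flip_prob must be in [0, 1]")
  structure(list(
    replicons = replicons,
    n_operons = as.integer(n_operons),
    operon_size_probs = operon_size_probs / sum(operon_size_probs),
    gene_length_range = as.integer(gene_length_range),
    intra_operon_gap = as.integer(intra_operon_gap),
    inter_operon_gap = as.integer(inter_operon_gap),
    strand_flip_prob = strand_flip_prob,
    seed = as.integer(seed)
  ), class = "synthetic_genome_spec")
}

#' Generate a synthetic genome annotation (and optionally its sequence)
#'
#' Places operons of same-strand genes along each replicon with small
#' intra-operon and larger inter-operon gaps. Genes never overlap and always
#' lie wholly within their replicon; output is deterministic for a fixed
#' spec + seed. The returned annotation records the true operon membership
#' and the true operon head (first-transcribed gene), which downstream tests
#' use as ground truth.
#'
#' @param spec a [synthetic_genome_spec()].
#' @param genome logical; also generate uniform-random A/C/G/T replicon
#'   sequences (as a [Biostrings::DNAStringSet]). Sequence generation uses a
#'   seed derived from `spec$seed`, so annotations are identical whether or
#'   not sequences are requested.
#' @return list with `annotation` (data.frame: `gene_id`, `replicon`,
#'   `start`, `end`, `strand`, `length`, `operon_id`, `is_head`; 1-based
#'   closed coordinates, coordinate-sorted within replicon) and `genome`
#'   (`DNAStringSet` or `NULL`).
#' @export
generate_annotation <- function(spec, genome = TRUE) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  sizes <- as.integer(names(spec$operon_size_probs))

  # allocate operons across replicons proportional to length (largest share
  # absorbs the rounding remainder)
  share <- spec$replicons / sum(spec$replicons)
  n_rep <- floor(share * spec$n_operons)
  n_rep[which.max(share)] <- n_rep[which.max(share)] +
    spec$n_operons - sum(n_rep)

  ann <- with_seed(spec$seed, {
    rows <- vector("list", spec$n_operons)
    op_counter <- 0L
    for (rep_i in seq_along(spec$replicons)) {
      rep_name <- names(spec$replicons)[rep_i]
      rep_len <- spec$replicons[[rep_i]]
      pos <- 1L
      strand <- "+"
      gene_counter <- 0L
      n_here <- n_rep[[rep_i]]
      if (n_here == 0L) next
      for (op_j in seq_len(n_here)) {
        gap <- sample_from(spec$inter_operon_gap[1]:spec$inter_operon_gap[2], 1)
        pos <- pos + gap
        if (op_j > 1L && stats::runif(1) < spec$strand_flip_prob) {
          strand <- if (strand == "+") "-" else "+"
        }
        size <- sample_from(sizes, 1, prob = spec$operon_size_probs)
        op_counter <- op_counter + 1L
        op_id <- sprintf("op%04d", op_counter)
        starts <- integer(size); ends <- integer(size)
        for (g in seq_len(size)) {
          len <- sample_from(spec$gene_length_range[1]:spec$gene_length_range[2], 1)
          starts[g] <- pos
          ends[g] <- pos + len - 1L
          pos <- ends[g] + 1L
          if (g < size) {
            pos <- pos + sample_from(spec$intra_operon_gap[1]:spec$intra_operon_gap[2], 1)
          }
        }
        stop_if(ends[size] > rep_len,
                "replicon %s (length %d) cannot accommodate operon %d: need up to position %d",
                rep_name, as.integer(rep_len), op_j, ends[size])
        ids <- sprintf("%s_%04d", rep_name, gene_counter + seq_len(size))
        gene_counter <- gene_counter + size
        # head = first-transcribed gene: leftmost on +, rightmost on -
        head_idx <- if (strand == "+") 1L else size
        rows[[op_counter]] <- data.frame(
          gene_id = ids, replicon = rep_name, start = starts, end = ends,
          strand = strand, length = ends - starts + 1L, operon_id = op_id,
          is_head = seq_len(size) == head_idx,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows[seq_len(op_counter)])
  })
  rownames(ann) <- NULL

  seqs <- NULL
  if (genome) {
    seqs <- with_seed(spec$seed + 777L, {
      s <- vapply(spec$replicons, function(L) {
        paste(sample_from(c("A", "C", "G", "T"), as.integer(L), replace = TRUE),
              collapse = "")
      }, character(1))
      Biostrings::DNAStringSet(s)
    })
  }
  list(annotation = ann, genome = seqs)
}

#' Define a planted expression program over the synthetic operons
#'
#' Assigns each operon a class and an effect size. Classes follow the biology
#' being emulated: `specific_up` operons (e.g. CO2-fixation and hydrogenase
#' clusters) are upregulated under autotrophy by a planted log2 fold change
#' in \[3, 7\]; `het_specific_down` operons (e.g. fructose catabolism) carry a
#' planted L2FC in \[-6, -4\]; `constitutive` operons have identical expected
#' expression in all conditions; all remaining `baseline` operons get a
#' moderate condition effect of random sign (magnitude drawn from
#' `baseline_effect_range`), representing ordinary condition-dependent genes
#' that are neither strongly specific nor strictly flat. The two heterotrophic
#' conditions (fructose, acetate) share their generative means.
#'
#' @param annotation annotation data.frame from [generate_annotation()].
#' @param n_specific,n_het_down,n_constitutive number of operons per planted
#'   class; the remainder are `baseline`.
#' @param specific_l2fc_range,het_down_l2fc_range uniform ranges for planted
#'   log2 fold changes (autotrophic over heterotrophic).
#' @param specific_base_log10_range uniform range of log10 heterotrophic
#'   expression for `specific_up` genes, placed high enough that their
#'   autotrophic TPM clears typical expression filters.
#' @param baseline_log10_mean,baseline_log10_sd normal parameters of log10
#'   base expression for all other genes.
#' @param baseline_effect_range magnitude range (log2) of the baseline
#'   condition effect.
#' @param nb_dispersion negative-binomial dispersion of simulated counts
#'   (variance = mu + dispersion * mu^2); must be > 0.
#' @param library_size expected reads per sample (scalar or one per sample).
#' @param seed integer seed for the class assignment and effect draws.
#' @return object of class `expression_program` with a per-operon table
#'   (`operon_id`, `class`, `planted_l2fc`).
#' @export
expression_program <- function(annotation,
                               n_specific = 12L,
                               n_het_down = 6L,
                               n_constitutive = 30L,
                               specific_l2fc_range = c(3, 7),
                               het_down_l2fc_range = c(-6, -4),
                               specific_base_log10_range = c(1.3, 2.3),
                               baseline_log10_mean = 2,
                               baseline_log10_sd = 0.7,
                               baseline_effect_range = c(1.2, 2.2),
                               nb_dispersion = 0.1,
                               library_size = 5e6,
                               seed = 1L) {
  stop_if(nb_dispersion <= 0, "nb_dispersion must be > 0")
  ops <- unique(annotation$operon_id)
  n_planted <- n_specific + n_het_down + n_constitutive
  stop_if(n_planted > length(ops),
          "cannot plant %d operons: only %d available", n_planted, length(ops))
  tab <- with_seed(seed, {
    picked <- sample_from(ops, n_planted)
    cls <- rep("baseline", length(ops))
    names(cls) <- ops
    cls[picked[seq_len(n_specific)]] <- "specific_up"
    if (n_het_down > 0)
      cls[picked[n_specific + seq_len(n_het_down)]] <- "het_specific_down"
    if (n_constitutive > 0)
      cls[picked[n_specific + n_het_down + seq_len(n_constitutive)]] <- "constitutive"
    l2fc <- numeric(length(ops))
    l2fc[cls == "specific_up"] <-
      stats::runif(sum(cls == "specific_up"),
                   specific_l2fc_range[1], specific_l2fc_range[2])
    l2fc[cls == "het_specific_down"] <-
      stats::runif(sum(cls == "het_specific_down"),
                   het_down_l2fc_range[1], het_down_l2fc_range[2])
    nb <- sum(cls == "baseline")
    l2fc[cls == "baseline"] <-
      sample_from(c(-1, 1), nb, replace = TRUE) *
      stats::runif(nb, baseline_effect_range[1], baseline_effect_range[2])
    data.frame(operon_id = ops, class = unname(cls), planted_l2fc = l2fc,
               stringsAsFactors = FALSE)
  })
  structure(list(
    operons = tab,
    specific_base_log10_range = specific_base_log10_range,
    baseline_log10_mean = baseline_log10_mean,
    baseline_log10_sd = baseline_log10_sd,
    nb_dispersion = nb_dispersion,
    library_size = library_size,
    seed = as.integer(seed)
  ), class = "expression_program")
}

#' Conditions and replicate layout of the synthetic experiment
#'
#' Three conditions (autotrophic H2/CO2, heterotrophic fructose and acetate)
#' with `n_replicates` biological replicates each, mirroring the triplicated
#' comparative design the benchmark emulates.
#'
#' @param n_replicates replicates per condition.
#' @return design data.frame with columns `sample`, `condition`, `replicate`.
#' @export
default_design <- function(n_replicates = 3L) {
  conditions <- c("H2CO2", "fructose", "acetate")
  data.frame(
    sample = paste0(rep(conditions, each = n_replicates), "_",
                    rep(seq_len(n_replicates), times = length(conditions))),
    condition = rep(conditions, each = n_replicates),
    replicate = rep(seq_len(n_replicates), times = length(conditions)),
    stringsAsFactors = FALSE)
}

#' Simulate negative-binomial read counts under a planted program
#'
#' Each gene inherits its operon's class and planted effect. Per condition,
#' the gene's expected relative transcript abundance is its base level times
#' `2^effect` in the autotrophic condition (effect 0 for constitutive genes
#' and for both heterotrophic conditions). Expected counts are proportional
#' to abundance times gene length, scaled to the sample library size, and
#' counts are drawn from a negative binomial with the program's dispersion,
#' so the expected TPM ratio between conditions equals `2^planted_l2fc` up
#' to the (small) compositional shift of the TPM denominator.
#'
#' @param annotation annotation data.frame from [generate_annotation()].
#' @param program an [expression_program()].
#' @param design design data.frame (default [default_design()]); condition
#'   labels must be `H2CO2`, `fructose`, `acetate`.
#' @param seed integer seed for base-level and count draws.
#' @return list with `counts` (integer matrix genes x samples), `design`,
#'   and `truth` (per-gene data.frame: `gene_id`, `operon_id`, `class`,
#'   `planted_l2fc`, `is_head`).
#' @export
simulate_counts <- function(annotation, program, design = default_design(),
                            seed = 1L) {
  stopifnot(inherits(program, "expression_program"))
  known <- c("H2CO2", "fructose", "acetate")
  bad <- setdiff(unique(design$condition), known)
  stop_if(length(bad) > 0, "unknown condition label(s): %s",
          paste(bad, collapse = ", "))

  op <- program$operons
  idx <- match(annotation$operon_id, op$operon_id)
  stop_if(anyNA(idx), "annotation contains operons missing from the program")
  cls <- op$class[idx]
  eff <- op$planted_l2fc[idx]
  n_genes <- nrow(annotation)
  libs <- rep_len(program$library_size, nrow(design))

  out <- with_seed(seed, {
    base <- numeric(n_genes)
    sp <- cls == "specific_up"
    base[!sp] <- 10^stats::rnorm(sum(!sp), program$baseline_log10_mean,
                                 program$baseline_log10_sd)
    base[sp] <- 10^stats::runif(sum(sp),
                                program$specific_base_log10_range[1],
                                program$specific_base_log10_range[2])
    # relative abundance per condition; heterotrophic conditions share means.
    # Baseline effects are split half on each side (H2 x 2^(e/2), het x
    # 2^(-e/2)): the planted L2FC is unchanged but the per-condition
    # abundance sums stay balanced in expectation, so planting thousands of
    # sign-symmetric baseline effects does not shift the TPM denominator.
    half <- cls == "baseline"
    h2_mult <- ifelse(cls == "constitutive", 1,
                      2^ifelse(half, eff / 2, eff))
    het_mult <- ifelse(half, 2^(-eff / 2), 1)
    abundance <- cbind(
      H2CO2 = base * h2_mult,
      fructose = base * het_mult,
      acetate = base * het_mult)
    counts <- matrix(0L, n_genes, nrow(design),
                     dimnames = list(annotation$gene_id, design$sample))
    size <- 1 / program$nb_dispersion
    for (s in seq_len(nrow(design))) {
      a <- abundance[, design$condition[s]]
      p <- a * annotation$length
      mu <- libs[s] * p / sum(p)
      counts[, s] <- stats::rnbinom(n_genes, mu = mu, size = size)
    }
    counts
  })

  truth <- data.frame(
    gene_id = annotation$gene_id, operon_id = annotation$operon_id,
    class = cls, planted_l2fc = ifelse(cls == "constitutive", 0, eff),
    is_head = annotation$is_head, stringsAsFactors = FALSE)
  list(counts = out, design = design, truth = truth)
}

#' One-call synthetic dataset
#'
#' Convenience wrapper chaining [generate_annotation()],
#' [expression_program()] and [simulate_counts()] under one seed.
#'
#' @param spec a [synthetic_genome_spec()]; defaults to the package's
#'   standard benchmark genome.
#' @param seed master seed; the annotation, program and counts use seeds
#'   derived from it.
#' @param genome logical, generate replicon sequences.
#' @param ... passed to [expression_program()].
#' @return list with `annotation`, `genome`, `counts`, `design`, `truth`,
#'   `program`.
#' @export
simulate_dataset <- function(spec = NULL, seed = 1L, genome = FALSE, ...) {
  if (is.null(spec)) spec <- synthetic_genome_spec(seed = seed)
  gen <- generate_annotation(spec, genome = genome)
  program <- expression_program(gen$annotation, seed = seed + 1L, ...)
  sim <- simulate_counts(gen$annotation, program, seed = seed + 2L)
  list(annotation = gen$annotation, genome = gen$genome,
       counts = sim$counts, design = sim$design, truth = sim$truth,
       program = program)
}

#' Generate a synthetic reporter-assay table
#'
#' Produces triplicate (by default) enzyme activities per promoter under the
#' autotrophic and heterotrophic conditions, with Gaussian noise at a fixed
#' coefficient of variation. Each truth row gives the promoter's class, its
#' mean autotrophic activity (mU per microgram protein) and its target
#' autotrophic/heterotrophic fold ratio.
#'
#' @param truth data.frame with columns `promoter`, `class`
#'   (`condition_specific`, `constitutive` or `inactive`), `auto_mean`,
#'   `ratio`.
#' @param cv coefficient of variation of the Gaussian noise; `cv = 0` yields
#'   activities exactly equal to the class means.
#' @param n_replicates replicates per promoter and condition.
#' @param seed integer seed.
#' @return data.frame with columns `promoter`, `condition`
#'   (`autotrophic` / `heterotrophic`), `replicate`, `activity`; negative
#'   noise draws are clamped at 0.
#' @export
generate_assay_fixture <- function(truth, cv = 0.05, n_replicates = 3L,
                                   seed = 1L) {
  need <- c("promoter", "class", "auto_mean", "ratio")
  stop_if(!all(need %in% names(truth)),
          "truth must have columns %s", paste(need, collapse = ", "))
  stop_if(any(truth$auto_mean < 0), "negative target activity")
  stop_if(any(truth$ratio <= 0), "target ratio must be positive")
  stop_if(cv < 0, "cv must be non-negative")
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      means <- c(autotrophic = truth$auto_mean[i],
                 heterotrophic = truth$auto_mean[i] / truth$ratio[i])
      do.call(rbind, lapply(names(means), function(cond) {
        m <- means[[cond]]
        act <- if (cv == 0) rep(m, n_replicates) else
          pmax(0, stats::rnorm(n_replicates, m, cv * m))
        data.frame(promoter = truth$promoter[i], condition = cond,
                   replicate = seq_len(n_replicates), activity = act,
                   stringsAsFactors = FALSE)
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

## ---- plain-text serialization ------------------------------------------

#' Write / read the synthetic fixtures as plain-text files
#'
#' GFF3 carries `gene` features with `ID` and `locus_tag` attributes in
#' 1-based closed coordinates; FASTA holds one record per replicon; counts,
#' design and truth are tab-separated. These are the on-disk interfaces the
#' pipeline consumes.
#'
#' @param annotation annotation data.frame.
#' @param replicon_lengths named lengths (bp) used for GFF3 sequence regions.
#' @param path output file path.
#' @name synthetic_io
NULL

#' @rdname synthetic_io
#' @export
write_annotation_gff3 <- function(annotation, replicon_lengths, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$replicon,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$source <- "promscreen"
  S4Vectors::mcols(gr)$ID <- annotation$gene_id
  S4Vectors::mcols(gr)$locus_tag <- annotation$gene_id
  GenomeInfoDb::seqlengths(gr) <-
    as.integer(replicon_lengths[GenomeInfoDb::seqlevels(gr)])
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname synthetic_io
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  ids <- S4Vectors::mcols(gr)$locus_tag
  if (is.null(ids)) ids <- S4Vectors::mcols(gr)$ID
  ann <- data.frame(
    gene_id = as.character(ids),
    replicon = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    stringsAsFactors = FALSE)
  stop_if(any(!ann$strand %in% c("+", "-")),
          "GFF3 gene features must be stranded")
  ann$length <- ann$end - ann$start + 1L
  ann <- ann[order(ann$replicon, ann$start, ann$end), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' @rdname synthetic_io
#' @param genome a `DNAStringSet`.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 60L)
  invisible(path)
}

#' @rdname synthetic_io
#' @param counts integer matrix (genes x samples).
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname synthetic_io
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname synthetic_io
#' @param design design data.frame.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname synthetic_io
#' @export
read_design_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname synthetic_io
#' @param truth per-gene truth data.frame.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
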