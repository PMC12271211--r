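test_that("annotation generation is deterministic and respects geometry", {
  spec <- synthetic_genome_spec(replicons = c(chr = 10000), n_operons = 2,
                                operon_size_probs = c("2" = 1), seed = 7)
  a1 <- generate_annotation(spec)
  a2 <- generate_annotation(spec)
  expect_identical(a1$annotation, a2$annotation)
  expect_identical(as.character(a1$genome), as.character(a2$genome))
  ann <- a1$annotation
  expect_equal(nrow(ann), 4L)
  # coordinate-sorted, non-overlapping, inside the replicon
  expect_true(all(diff(ann$start) > 0))
  expect_true(all(ann$start[-1] > ann$end[-nrow(ann)]))
  expect_true(all(ann$start >= 1 & ann$end <= 10000))
  expect_equal(Biostrings::width(a1$genome), 10000)
})

test_that("strand_flip_prob 0 keeps every gene on the forward strand", {
  spec <- synthetic_genome_spec(replicons = c(chr = 50000), n_operons = 12,
                                strand_flip_prob = 0, seed = 3)
  ann <- generate_annotation(spec, genome = FALSE)$annotation
  expect_true(all(ann$strand == "+"))
})

test_that("impossible placement raises a capacity error", {
  spec <- synthetic_genome_spec(replicons = c(chr = 3000), n_operons = 10,
                                operon_size_probs = c("4" = 1), seed = 1)
  expect_error(generate_annotation(spec), "cannot accommodate")
})

test_that("geometric invariants hold across random specs", {
  for (seed in 1:10) {
    spec <- synthetic_genome_spec(
      replicons = c(r1 = 60000, r2 = 40000), n_operons = 15,
      strand_flip_prob = stats::runif(1), seed = seed)
    ann <- generate_annotation(spec, genome = FALSE)$annotation
    for (r in unique(ann$replicon)) {
      a <- ann[ann$replicon == r, ]
      expect_true(all(a$start[-1] > a$end[-nrow(a)]))
    }
    # operons are same-strand blocks with exactly one head each
    heads <- tapply(ann$is_head, ann$operon_id, sum)
    expect_true(all(heads == 1))
    strands <- tapply(ann$strand, ann$operon_id,
                      function(s) length(unique(s)))
    expect_true(all(strands == 1))
    # intra-operon gaps stay below the inter-operon minimum by construction
    for (op in unique(ann$operon_id)) {
      a <- ann[ann$operon_id == op, ]
      if (nrow(a) > 1) {
        gaps <- a$start[-1] - a$end[-nrow(a)] - 1L
        expect_true(all(gaps <= max(spec$intra_operon_gap)))
      }
    }
  }
})

test_that("near-zero dispersion gives equal TPM across conditions for constitutive genes", {
  spec <- synthetic_genome_spec(replicons = c(chr = 1.6e6), n_operons = 500,
                                seed = 5)
  gen <- generate_annotation(spec, genome = FALSE)
  program <- expression_program(gen$annotation, n_specific = 0,
                                n_het_down = 0, n_constitutive = 500,
                                nb_dispersion = 1e-6, library_size = 1e8,
                                seed = 6)
  sim <- simulate_counts(gen$annotation, program, seed = 7)
  lengths <- stats::setNames(gen$annotation$length, gen$annotation$gene_id)
  tpm <- compute_tpm(sim$counts, lengths)
  m <- sapply(unique(sim$design$condition), function(cond) {
    rowMeans(tpm[, sim$design$sample[sim$design$condition == cond]])
  })
  # all genes constitutive -> per-condition means agree within 1 % once the
  # residual Poisson counting error is small (deeply sequenced genes)
  expressed <- rowMeans(m) > 1000
  rel_spread <- apply(m[expressed, ], 1, function(x) diff(range(x)) / mean(x))
  expect_lt(stats::quantile(rel_spread, 0.95), 0.01)
})

test_that("planted fold changes are recovered in the low-noise limit", {
  spec <- synthetic_genome_spec(replicons = c(chr = 1.6e6), n_operons = 500,
                                seed = 11)
  gen <- generate_annotation(spec, genome = FALSE)
  errs <- sapply(1:10, function(s) {
    program <- expression_program(gen$annotation, n_specific = 8,
                                  specific_l2fc_range = c(4, 4),
                                  nb_dispersion = 0.01, seed = s)
    sim <- simulate_counts(gen$annotation, program, seed = s + 100)
    lengths <- stats::setNames(gen$annotation$length, gen$annotation$gene_id)
    tpm <- compute_tpm(sim$counts, lengths)
    d <- differential_stats(tpm, sim$design, c("H2CO2", "fructose"),
                            pseudocount = 0)
    sp <- sim$truth$gene_id[sim$truth$class == "specific_up"]
    mean(d$l2fc[match(sp, d$gene_id)])
  })
  expect_true(all(abs(errs - 4) < 0.5))
})

test_that("generative L2FC converges to the planted value as dispersion shrinks", {
  spec <- synthetic_genome_spec(replicons = c(chr = 1.6e6), n_operons = 500,
                                seed = 21)
  gen <- generate_annotation(spec, genome = FALSE)
  spread <- sapply(c(0.5, 0.1, 0.001), function(disp) {
    program <- expression_program(gen$annotation, n_specific = 8,
                                  specific_l2fc_range = c(5, 5),
                                  nb_dispersion = disp, seed = 22)
    sim <- simulate_counts(gen$annotation, program, seed = 23)
    lengths <- stats::setNames(gen$annotation$length, gen$annotation$gene_id)
    tpm <- compute_tpm(sim$counts, lengths)
    d <- differential_stats(tpm, sim$design, c("H2CO2", "fructose"),
                            pseudocount = 0)
    sp <- sim$truth$gene_id[sim$truth$class == "specific_up"]
    stats::sd(d$l2fc[match(sp, d$gene_id)])
  })
  expect_true(all(diff(spread) < 0))
  expect_lt(spread[3], 0.1)
})

test_that("doubling a library size leaves expected TPM unchanged", {
  spec <- synthetic_genome_spec(replicons = c(chr = 2e5), n_operons = 60,
                                seed = 9)
  gen <- generate_annotation(spec, genome = FALSE)
  base <- expression_program(gen$annotation, n_specific = 0, n_het_down = 0,
                             n_constitutive = 0, nb_dispersion = 0.001,
                             library_size = 2e6, seed = 10)
  doubled <- base
  doubled$library_size <- c(4e6, rep(2e6, 8))
  lengths <- stats::setNames(gen$annotation$length, gen$annotation$gene_id)
  t1 <- compute_tpm(simulate_counts(gen$annotation, base, seed = 1)$counts,
                    lengths)
  t2 <- compute_tpm(simulate_counts(gen$annotation, doubled, seed = 1)$counts,
                    lengths)
  # sample 1 belongs to the same condition as sample 2: its expected TPM
  # profile is unaffected by the sequencing depth
  ratio <- (t2[, 1] + 1) / (t2[, 2] + 1)
  expect_lt(abs(median(log2(ratio))), 0.1)
  expect_equal(colnames(t1), colnames(t2))
})

test_that("class planting matches the configured counts", {
  ds <- bench_dataset()
  per_operon <- unique(ds$truth[, c("operon_id", "class")])
  expect_equal(sum(per_operon$class == "specific_up"), 12)
  expect_equal(sum(per_operon$class == "het_specific_down"), 6)
  expect_equal(sum(per_operon$class == "constitutive"), 30)
  expect_true(all(table(ds$truth$gene_id) == 1))
})

test_that("assay fixture honours class means, noise level and the floor", {
  truth <- data.frame(promoter = c("PS01", "PC01", "PX01"),
                      class = c("condition_specific", "constitutive",
                                "inactive"),
                      auto_mean = c(105, 50, 0.3),
                      ratio = c(35, 1, 1))
  exact <- generate_assay_fixture(truth, cv = 0, seed = 1)
  expect_equal(exact$activity[exact$promoter == "PS01" &
                                exact$condition == "autotrophic"],
               rep(105, 3))
  expect_equal(exact$activity[exact$promoter == "PS01" &
                                exact$condition == "heterotrophic"],
               rep(3, 3))

  ratios <- sapply(1:100, function(s) {
    tab <- generate_assay_fixture(truth[1, ], cv = 0.05, seed = s)
    s_ <- summarize_assay(tab)
    fold_ratio(s_, "PS01")
  })
  expect_gte(mean(ratios >= 25 & ratios <= 45), 0.95)

  floors <- sapply(1:100, function(s) {
    tab <- generate_assay_fixture(truth[3, ], cv = 0.2, seed = s)
    all(tab$activity < 1.1)
  })
  expect_gte(mean(floors), 0.90)

  expect_error(generate_assay_fixture(transform(truth, auto_mean = -1)),
               "negative")
})

test_that("fixtures round-trip through their plain-text formats", {
  spec <- synthetic_genome_spec(replicons = c(chrA = 30000, chrB = 20000),
                                n_operons = 8, seed = 13)
  gen <- generate_annotation(spec)
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "ann.gff3")
  write_annotation_gff3(gen$annotation, spec$replicons, gff)
  back <- read_annotation_gff3(gff)
  expect_equal(back$gene_id, gen$annotation$gene_id)
  expect_equal(back$start, gen$annotation$start)
  expect_equal(back$end, gen$annotation$end)
  expect_equal(back$strand, gen$annotation$strand)

  fa <- file.path(dir, "genome.fasta")
  write_genome_fasta(gen$genome, fa)
  g2 <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(g2), as.character(gen$genome))

  program <- expression_program(gen$annotation, n_specific = 2,
                                n_het_down = 1, n_constitutive = 2,
                                seed = 14)
  sim <- simulate_counts(gen$annotation, program, seed = 15)
  cf <- file.path(dir, "counts.tsv"); df <- file.path(dir, "design.tsv")
  write_counts_tsv(sim$counts, cf)
  write_design_tsv(sim$design, df)
  expect_equal(read_counts_tsv(cf), sim$counts + 0)
  expect_equal(read_design_tsv(df), sim$design)
})
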