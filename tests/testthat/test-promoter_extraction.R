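genome_from <- function(seq, name = "chr") {
  Biostrings::DNAStringSet(stats::setNames(seq, name))
}

test_that("forward-strand extraction takes the span left of the gene", {
  set.seed(1)
  gseq <- paste(sample(c("A", "C", "G", "T"), 2500, replace = TRUE),
                collapse = "")
  ann <- toy_annotation(c(1, 1001), c(800, 2000), c("+", "+"),
                        gene_id = c("up", "head"))
  reg <- extract_upstream_region("head", ann, genome_from(gseq))
  expect_equal(reg$start, 801)
  expect_equal(reg$end, 1000)
  expect_equal(reg$length, 200)
  expect_equal(reg$sequence, substr(gseq, 801, 1000))
  expect_equal(reg$length, nchar(reg$sequence))
  expect_equal(reg$length, reg$end - reg$start + 1)
  expect_false(reg$truncated_by_cap)
  expect_false(reg$shorter_than_min)
})

test_that("reverse-strand extraction reverse-complements the right flank", {
  set.seed(2)
  gseq <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                collapse = "")
  ann <- toy_annotation(c(1001, 2301), c(2000, 2900), c("-", "+"),
                        gene_id = c("head", "down"))
  reg <- extract_upstream_region("head", ann, genome_from(gseq))
  expect_equal(reg$start, 2001)
  expect_equal(reg$end, 2300)
  expect_equal(reg$length, 300)
  want <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(gseq, 2001, 2300))))
  expect_equal(reg$sequence, want)
})

test_that("long spans are truncated to the gene-proximal cap", {
  set.seed(3)
  gseq <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
                collapse = "")
  ann <- toy_annotation(c(1, 2001), c(400, 3000), c("+", "+"),
                        gene_id = c("up", "head"))  # intergenic 401..2000
  reg <- extract_upstream_region("head", ann, genome_from(gseq),
                                 max_len = 1000)
  expect_true(reg$truncated_by_cap)
  expect_equal(reg$length, 1000)
  expect_equal(reg$start, 1001)  # proximal 1000 bases kept
  expect_equal(reg$end, 2000)

  # minus strand: proximal side is the gene end
  ann2 <- toy_annotation(c(101, 2001), c(300, 2500), c("-", "+"),
                         gene_id = c("head", "down"))  # intergenic 301..2000
  reg2 <- extract_upstream_region("head", ann2, genome_from(gseq),
                                  max_len = 500)
  expect_equal(reg2$start, 301)
  expect_equal(reg2$end, 800)
})

test_that("short regions are flagged, absent regions are errors", {
  set.seed(4)
  gseq <- paste(sample(c("A", "C", "G", "T"), 1200, replace = TRUE),
                collapse = "")
  ann <- toy_annotation(c(1, 111), c(100, 300), c("+", "+"),
                        gene_id = c("up", "head"))
  reg <- extract_upstream_region("head", ann, genome_from(gseq),
                                 min_len = 20)
  expect_true(reg$shorter_than_min)
  expect_equal(reg$length, 10)

  # gene starting at base 1 has no upstream bases on a linear replicon
  ann2 <- toy_annotation(1, 100, "+", gene_id = "edge")
  expect_error(extract_upstream_region("edge", ann2, genome_from(gseq)),
               "no upstream region")
  # adjacent upstream gene leaves zero intergenic bases
  ann3 <- toy_annotation(c(1, 101), c(100, 300), c("+", "+"),
                         gene_id = c("up", "head"))
  expect_error(extract_upstream_region("head", ann3, genome_from(gseq)),
               "no upstream region")
})

test_that("circular replicons may wrap the origin", {
  gseq <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")  # 100 bp
  ann <- toy_annotation(c(21, 61), c(40, 90), c("+", "+"),
                        gene_id = c("head", "other"))
  # upstream of head on a circle: 91..100 then 1..20
  reg <- extract_upstream_region("head", ann, genome_from(gseq),
                                 circular = TRUE)
  expect_true(reg$wraps_origin)
  expect_equal(reg$length, 30)
  expect_equal(reg$sequence,
               paste0(substr(gseq, 91, 100), substr(gseq, 1, 20)))
})

test_that("extracted regions never overlap annotated genes", {
  set.seed(19)
  for (i in 1:20) {
    ann <- random_annotation(sample(4:20, 1))
    genome <- random_genome(ann)
    heads <- unique(infer_operons(ann, 120)$head_gene)
    for (h in heads) {
      reg <- tryCatch(extract_upstream_region(h, ann, genome),
                      error = function(e) NULL)
      if (is.null(reg)) next
      overlaps <- ann$start <= reg$end & ann$end >= reg$start
      expect_false(any(overlaps),
                   info = sprintf("iteration %d head %s", i, h))
      expect_equal(nchar(reg$sequence), reg$length)
    }
  }
})

test_that("mirroring the replicon preserves the oriented promoter sequence", {
  set.seed(29)
  for (i in 1:10) {
    ann <- random_annotation(sample(4:15, 1))
    genome <- random_genome(ann, pad = 200L)
    L <- Biostrings::width(genome)[1]
    mir_ann <- ann
    mir_ann$start <- L - ann$end + 1L
    mir_ann$end <- L - ann$start + 1L
    mir_ann$strand <- ifelse(ann$strand == "+", "-", "+")
    mir_genome <- Biostrings::reverseComplement(genome)
    names(mir_genome) <- names(genome)
    for (g in ann$gene_id) {
      r1 <- tryCatch(extract_upstream_region(g, ann, genome),
                     error = function(e) NULL)
      r2 <- tryCatch(extract_upstream_region(g, mir_ann, mir_genome),
                     error = function(e) NULL)
      expect_equal(is.null(r1), is.null(r2))
      if (!is.null(r1)) expect_equal(r2$sequence, r1$sequence)
    }
  }
})

test_that("FASTA output wraps at 60 columns and round-trips", {
  set.seed(8)
  seqs <- c(paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                  collapse = ""),
            paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                  collapse = ""))
  regions <- data.frame(
    candidate_id = c("PS01", "PC01"), head_gene = c("gA", "gB"),
    replicon = "chr", start = c(100, 900), end = c(299, 959),
    strand = c("+", "-"), length = c(200L, 60L), sequence = seqs,
    truncated_by_cap = FALSE, shorter_than_min = FALSE,
    wraps_origin = FALSE, stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_promoter_fasta(regions, path)
  lines <- readLines(path)
  expect_equal(lines[1], ">PS01 chr:100-299(+) head=gA")
  # 200 bp -> 60 + 60 + 60 + 20
  expect_equal(nchar(lines[2:5]), c(60, 60, 60, 20))
  back <- Biostrings::readDNAStringSet(path)
  expect_equal(unname(as.character(back)), seqs)

  dup <- regions; dup$candidate_id <- c("PS01", "PS01")
  expect_error(write_promoter_fasta(dup, path), "duplicate")

  # empty set still writes a valid (empty) file
  write_promoter_fasta(regions[0, ], path)
  expect_equal(length(Biostrings::readDNAStringSet(path)), 0L)
})

test_that("BED output uses 0-based half-open coordinates", {
  regions <- data.frame(
    candidate_id = "PS01", head_gene = "gA", replicon = "chr",
    start = 801L, end = 1000L, strand = "+", length = 200L,
    sequence = strrep("A", 200), truncated_by_cap = FALSE,
    shorter_than_min = FALSE, wraps_origin = FALSE,
    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".bed")
  write_promoter_bed(regions, path)
  bed <- read.delim(path, header = FALSE)
  expect_equal(bed$V2, 800)   # 1-based closed 801 -> 0-based half-open 800
  expect_equal(bed$V3, 1000)
  expect_equal(bed$V3 - bed$V2, regions$length)
  expect_equal(bed$V6, "+")
})

test_that("extract_promoters labels candidates and skips failures", {
  set.seed(9)
  gseq <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                collapse = "")
  ann <- toy_annotation(c(1, 501, 1001), c(400, 900, 2000),
                        c("+", "+", "+"),
                        gene_id = c("edge", "mid", "late"))
  cand <- data.frame(head_gene = c("edge", "mid", "late"))
  expect_warning(
    regs <- extract_promoters(cand, ann, genome_from(gseq), prefix = "PS"),
    "skipping edge")
  expect_equal(regs$candidate_id, c("PS02", "PS03"))
  expect_equal(regs$head_gene, c("mid", "late"))
})
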