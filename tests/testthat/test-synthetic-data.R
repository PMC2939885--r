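# The generator's own contracts: quadripartite geometry, planted-feature
# bookkeeping, read error model, heteroplasmy injection, determinism.

test_that("simulated genome satisfies the quadripartite invariants", {
  sp <- genome_spec(lsc_len = 2000, ssc_len = 600, ir_len = 800, n_genes = 1,
                    seed = 3)
  g <- simulate_genome(sp)
  expect_equal(g$length, 2000 + 600 + 2 * 800)
  irb <- substr(g$sequence, g$layout$irb[1], g$layout$irb[2])
  ira <- substr(g$sequence, g$layout$ira[1], g$layout$ira[2])
  expect_identical(ira, revcomp(irb))
  expect_equal(g$layout$lsc_len + g$layout$ssc_len + 2 * g$layout$ir_len,
               g$length)
})

test_that("realized A+T content tracks the requested fraction", {
  sp <- genome_spec(lsc_len = 40000, ssc_len = 4000, ir_len = 3000,
                    at_fraction = 0.63, seed = 11)
  g <- simulate_genome(sp)
  at <- sum(strsplit(g$sequence, "")[[1]] %in% c("A", "T")) / g$length
  expect_lt(abs(at - 0.63), 0.01)
})

test_that("generator output is byte-identical for a fixed seed", {
  sp <- genome_spec(lsc_len = 1500, ssc_len = 500, ir_len = 600, n_genes = 2,
                    homopolymer_plants = data.frame(base = "A", length = 8),
                    seed = 42)
  g1 <- simulate_genome(sp)
  g2 <- simulate_genome(sp)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$annotation, g2$annotation)
  cfg <- read_sim_config(depth = 5, seed = 7)
  r1 <- simulate_reads(g1, cfg)
  r2 <- simulate_reads(g1, cfg)
  expect_identical(r1$seq, r2$seq)
  expect_identical(r1$qual, r2$qual)
})

test_that("explicitly placed features that overlap are rejected", {
  sp <- genome_spec(lsc_len = 3000, ssc_len = 600, ir_len = 700,
                    homopolymer_plants = data.frame(
                      base = c("A", "T"), length = c(9, 9),
                      start = c(500, 503)),
                    seed = 5)
  expect_error(simulate_genome(sp), "overlap")
})

test_that("error-free reads are exact substrings of the doubled genome", {
  sp <- genome_spec(lsc_len = 2500, ssc_len = 600, ir_len = 700, seed = 8)
  g <- simulate_genome(sp)
  cfg <- read_sim_config(depth = 8, hp_error_rate = 0, sub_error_rate = 0,
                         seed = 9)
  rs <- simulate_reads(g, cfg)
  d2 <- paste0(g$sequence, g$sequence)
  ok <- vapply(rs$seq, function(r)
    grepl(r, d2, fixed = TRUE) || grepl(revcomp(r), d2, fixed = TRUE),
    logical(1))
  expect_true(all(ok))
})

test_that("read count and realized depth follow the coverage request", {
  sp <- genome_spec(lsc_len = 2500, ssc_len = 600, ir_len = 450, seed = 8)
  g <- simulate_genome(sp)   # 4000 bp
  cfg <- read_sim_config(mean_len = 400, len_sd = 20, depth = 100, seed = 2)
  rs <- simulate_reads(g, cfg)
  expect_equal(length(rs$seq), round(100 * g$length / 400))
  realized <- sum(nchar(rs$seq)) / g$length
  expect_lt(abs(realized - 100), 10)
  expect_error(simulate_reads(g, read_sim_config(depth = 1e-9, seed = 1)),
               "zero reads")
})

complement_dna_test <- function(x) chartr("ACGT", "TGCA", x)

test_that("heteroplasmic minor fractions converge to the specification", {
  sp <- genome_spec(lsc_len = 1500, ssc_len = 400, ir_len = 300, seed = 21)
  g <- simulate_genome(sp)
  pos <- 700L
  major <- substr(g$sequence, pos, pos)
  minor <- setdiff(c("A", "C", "G", "T"), major)[1]
  het <- heteroplasmy_spec(sites = data.frame(pos = pos, major = major,
                                              minor = minor,
                                              fraction = 0.125))
  cfg <- read_sim_config(depth = 1000, hp_error_rate = 0, sub_error_rate = 0,
                         seed = 4)
  rs <- simulate_reads(g, cfg, het)
  # count reads carrying the minor base at the site
  hitn <- 0L; covn <- 0L
  G <- g$length
  for (i in seq_along(rs$seq)) {
    st <- rs$truth$start[i]; len <- nchar(rs$seq[i])
    off <- ((pos - st) %% G) + 1L
    if (off > len) next
    covn <- covn + 1L
    b <- if (rs$truth$strand[i] == "+") substr(rs$seq[i], off, off) else
      complement_dna_test(substr(rs$seq[i], len - off + 1L, len - off + 1L))
    if (b == minor) hitn <- hitn + 1L
  }
  sd3 <- 3 * sqrt(0.125 * 0.875 / covn)
  expect_lt(abs(hitn / covn - 0.125), sd3)
})

test_that("heteroplasmy validation rejects inconsistent specifications", {
  expect_error(heteroplasmy_spec(sites = data.frame(
    pos = 1, major = "A", minor = "A", fraction = 0.2)))
  expect_error(heteroplasmy_spec(sites = data.frame(
    pos = 1, major = "A", minor = "C", fraction = 0.7)))
})

test_that("cDNA reads respect abundance, units and the polyA artifact", {
  ops <- list(list(genes = c("g1", "g2", "g3"), strand = "+", spacer = 60))
  sp <- genome_spec(lsc_len = 6000, ssc_len = 800, ir_len = 700,
                    operon_specs = ops,
                    gene_specs = list(
                      list(name = "solo", n_codons = 120, strand = "+"),
                      list(name = "silent", n_codons = 120, strand = "+")),
                    seed = 31)
  g <- simulate_genome(sp)
  expr <- c(g1 = 5, g2 = 5, g3 = 5, solo = 5, silent = 0)
  cd <- simulate_cdna(g, expr, n_reads = 600, seed = 13)
  counts <- cd$truth$gene_counts
  expect_equal(unname(counts[["silent"]]), 0)
  # reads from the operon span member-gene junctions
  spans <- cd$truth$reads$unit[cd$truth$reads$gene %in% c("g1", "g2", "g3")]
  expect_true(length(unique(spans)) == 1)
  expect_error(simulate_cdna(g, c(nosuch = 1), n_reads = 10, seed = 1),
               "unknown gene")
})

test_that("a planted upstream A-run enriches its downstream gene", {
  # gene at a fixed spot; 22-bp A-run ending 57 bp upstream of its start
  gene_start <- 2000L
  sp <- genome_spec(lsc_len = 6000, ssc_len = 800, ir_len = 700,
                    gene_specs = list(
                      list(name = "hot", n_codons = 100, strand = "+",
                           start = gene_start),
                      list(name = "cold1", n_codons = 100, strand = "+"),
                      list(name = "cold2", n_codons = 100, strand = "+"),
                      list(name = "cold3", n_codons = 100, strand = "+")),
                    homopolymer_plants = data.frame(
                      base = "A", length = 22,
                      start = gene_start - 57L - 22L),
                    seed = 77)
  g <- simulate_genome(sp)
  expr <- c(hot = 1, cold1 = 1, cold2 = 1, cold3 = 1)
  cd <- simulate_cdna(g, expr, n_reads = 1200, enrichment = 50,
                      enrich_min_a = 15, seed = 3)
  counts <- cd$truth$gene_counts
  expect_gte(counts[["hot"]], 10 * stats::median(counts[c("cold1", "cold2", "cold3")]))
})

test_that("FASTA, GFF3 and FASTQ round-trip through the standard writers", {
  sp <- genome_spec(lsc_len = 1500, ssc_len = 400, ir_len = 300,
                    gene_specs = list(list(name = "two", n_codons = 60,
                                           exons = 2, strand = "-")),
                    seed = 71)
  g <- simulate_genome(sp)
  fa <- tempfile(fileext = ".fasta")
  write_genome_fasta(g, fa)
  expect_identical(read_genome_fasta(fa), g$sequence)
  gff <- tempfile(fileext = ".gff3")
  write_annotation_gff3(g$annotation, gff)
  back <- read_annotation_gff3(gff)
  o <- order(back$gene, back$rank)
  o0 <- order(g$annotation$gene, g$annotation$rank)
  expect_equal(back[o, ], g$annotation[o0, ], ignore_attr = TRUE)
  fq <- tempfile(fileext = ".fastq")
  rs <- simulate_reads(g, read_sim_config(depth = 2, seed = 1))
  write_fastq(rs, fq)
  back_rs <- read_fastq(fq)
  expect_identical(back_rs$seq, rs$seq)
  expect_equal(back_rs$qual, lapply(rs$qual, function(v) round(v)))
})
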