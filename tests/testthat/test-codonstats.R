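# CDS extraction, codon counting, RSCU, compositions, start-codon audit.

mini_genome_with <- function(plus_cds, minus_cds = NULL, pad = 200) {
  # build a small genome carrying the given CDS payloads with annotation
  set.seed(123)
  left <- rand_dna(pad)
  mid <- rand_dna(pad)
  right <- rand_dna(pad)
  seqs <- left
  ann <- empty_annotation()
  st <- nchar(left) + 1L
  seqs <- paste0(seqs, plus_cds)
  ann <- rbind(ann, data.frame(gene = "plus", type = "CDS", start = st,
                               end = st + nchar(plus_cds) - 1L, strand = "+",
                               rank = 1L, pseudo = FALSE))
  seqs <- paste0(seqs, mid)
  if (!is.null(minus_cds)) {
    st2 <- nchar(seqs) + 1L
    seqs <- paste0(seqs, revcomp(minus_cds))
    ann <- rbind(ann, data.frame(gene = "minus", type = "CDS", start = st2,
                                 end = st2 + nchar(minus_cds) - 1L,
                                 strand = "-", rank = 1L, pseudo = FALSE))
  }
  list(seq = paste0(seqs, right), ann = ann)
}

test_that("CDS extraction honours strand, rank order and trans-splicing", {
  mg <- mini_genome_with("ATGAAATAA", "ATGCCCGGGTAA")
  cds <- extract_cds(mg$seq, mg$ann)
  by_gene <- stats::setNames(cds, vapply(cds, function(x) x$gene, character(1)))
  expect_equal(by_gene[["plus"]]$sequence, "ATGAAATAA")
  expect_equal(by_gene[["minus"]]$sequence, "ATGCCCGGGTAA")
  # generator round-trip: multi-exon minus-strand and 3-part trans-spliced
  sp <- genome_spec(lsc_len = 6000, ssc_len = 800, ir_len = 700,
                    gene_specs = list(
                      list(name = "twoexon", n_codons = 80, strand = "-",
                           exons = 2),
                      list(name = "transg", n_codons = 90, exons = 3,
                           trans = TRUE)),
                    seed = 17)
  g <- simulate_genome(sp)
  cds2 <- extract_cds(g)
  by_gene2 <- stats::setNames(cds2,
                              vapply(cds2, function(x) x$gene, character(1)))
  expect_equal(by_gene2[["twoexon"]]$sequence, g$truth$cds[["twoexon"]])
  expect_equal(by_gene2[["transg"]]$sequence, g$truth$cds[["transg"]])
  # pseudogenes are excluded; out-of-bounds exons are an error
  annp <- mg$ann; annp$pseudo[1] <- TRUE
  expect_false("plus" %in% vapply(extract_cds(mg$seq, annp),
                                  function(x) x$gene, character(1)))
  annb <- mg$ann; annb$end[1] <- nchar(mg$seq) + 50L
  expect_error(extract_cds(mg$seq, annb), "plus")
})

test_that("codon counting matches direct cases and flags ambiguity", {
  ct <- count_codons(list("ATGAAATAA"))
  expect_equal(unname(ct[["ATG"]]), 1L)
  expect_equal(unname(ct[["AAA"]]), 1L)
  expect_equal(unname(ct[["TAA"]]), 1L)
  expect_equal(attr(ct, "total"), 3L)
  ctn <- count_codons(list("ATGNNNTAA"))
  expect_equal(attr(ctn, "ambiguous"), 1L)
  expect_equal(attr(ctn, "total"), 2L)
})

test_that("published codon counts reproduce the printed statistics", {
  fx <- datepalm_codon_usage()
  expect_equal(attr(fx$table, "total"), 22950L)
  # Ile and Cys totals and percentages
  ac <- aa_composition(fx$table)
  expect_equal(ac$count[ac$aa == "I"], 2001L)
  expect_equal(ac$percent[ac$aa == "I"], 8.72)
  expect_equal(ac$count[ac$aa == "C"], 271L)
  expect_equal(ac$percent[ac$aa == "C"], 1.18)
  r <- rscu(fx$table)
  expect_equal(unname(r[["TTT"]]), 1.29)
  expect_equal(unname(r[["TTA"]]), 1.89)
  expect_equal(unname(r[["AGA"]]), 1.92)
  expect_equal(unname(r[["TGG"]]), 1)       # single-codon family
  expect_equal(unname(r[["TAA"]]), 0)       # stops render as 0
  # every printed sense-codon RSCU agrees to 2 decimals
  sense <- names(Biostrings::getGeneticCode("11"))[
    Biostrings::getGeneticCode("11") != "*"]
  d <- fx$data
  d$dna <- chartr("U", "T", d$codon)
  d <- d[d$dna %in% sense, ]
  expect_true(all(abs(r[d$dna] - d$rscu_printed) < 0.005 + 1e-9))
  expect_equal(positional_base_composition(fx$table), c(54.4, 61.8, 70.6))
})

test_that("RSCU sums to the family size and is 1 under uniform use", {
  set.seed(3)
  counts <- stats::setNames(sample(0:500, 64, TRUE),
                            chartr("T", "U", names(datepalm_codon_usage()$table)))
  ct <- codon_table(counts)
  r <- rscu(ct, digits = NULL)
  fams <- split(names(Biostrings::getGeneticCode("11")),
                Biostrings::getGeneticCode("11"))
  fams <- fams[names(fams) != "*"]
  for (f in fams) {
    if (sum(ct[f]) > 0) expect_equal(sum(r[f]), length(f))
  }
  uni <- codon_table(stats::setNames(rep(10, 64), names(ct)))
  ru <- rscu(uni, digits = NULL)
  sense <- unlist(fams)
  expect_true(all(abs(ru[sense] - 1) < 1e-12))
  expect_equal(positional_base_composition(uni), c(50, 50, 50))
})

test_that("codon totals and compositions agree with raw-CDS recomputation", {
  sp <- genome_spec(lsc_len = 8000, ssc_len = 900, ir_len = 800, n_genes = 6,
                    seed = 19)
  g <- simulate_genome(sp)
  cds <- extract_cds(g)
  ct <- count_codons(cds)
  lens <- vapply(cds, function(x) nchar(x$sequence), integer(1))
  expect_equal(3L * attr(ct, "total"), sum(lens))
  # brute-force positional composition from the raw strings
  raw <- paste(vapply(cds, function(x) x$sequence, character(1)),
               collapse = "")
  ch <- strsplit(raw, "")[[1]]
  for (p in 1:3) {
    frac <- 100 * mean(ch[seq(p, length(ch), by = 3)] %in% c("A", "T"))
    expect_lt(abs(positional_base_composition(ct)[p] - frac), 0.05 + 1e-9)
  }
})

test_that("single-codon table yields 100 percent for its amino acid", {
  ct <- codon_table(c(AUG = 5))
  ac <- aa_composition(ct)
  expect_equal(ac$percent[ac$aa == "M"], 100)
  expect_equal(positional_base_composition(ct), c(100, 100, 0))
})

test_that("start-codon audit flags non-canonical starts and upstream stops", {
  mg <- mini_genome_with("ATGAAATAA")
  cds <- extract_cds(mg$seq, mg$ann)
  a <- audit_start_codons(cds, mg$seq)
  expect_true(a$canonical[a$gene == "plus"])
  # planted ACG start via the generator
  sp <- genome_spec(lsc_len = 5000, ssc_len = 700, ir_len = 600,
                    gene_specs = list(list(name = "acgGene", n_codons = 60,
                                           start_codon = "ACG")),
                    seed = 29)
  g <- simulate_genome(sp)
  a2 <- audit_start_codons(extract_cds(g), g)
  row <- a2[a2$gene == "acgGene", ]
  expect_false(row$canonical)
  expect_equal(row$start_codon, "ACG")
  # upstream in-frame TAG 12 bp before the start is reported
  up <- paste0(rand_dna(30), "TAG", "CAAGCATTA")   # TAG at -12..-10
  body <- "ATGGTTCATTAA"
  s <- paste0(up, body, rand_dna(30))
  ann <- data.frame(gene = "amb", type = "CDS", start = nchar(up) + 1L,
                    end = nchar(up) + nchar(body), strand = "+",
                    rank = 1L, pseudo = FALSE)
  a3 <- audit_start_codons(extract_cds(s, ann), s)
  expect_equal(a3$upstream_stop_at, 12L)
  expect_match(a3$note, "12 bp upstream")
})
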