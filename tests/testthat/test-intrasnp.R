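# Pileup construction, the four filtering rules, codon-effect annotation,
# indel calls, and the major/minor swap comparison.

# a pileup built directly from counts, bypassing alignment
fake_pileup <- function(counts_list, G = 1000L) {
  counts <- matrix(0L, nrow = G, ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  for (p in names(counts_list)) {
    v <- counts_list[[p]]
    counts[as.integer(p), names(v)] <- as.integer(v)
  }
  structure(list(counts = counts, gap_reads = integer(G),
                 depth_q = as.integer(rowSums(counts)),
                 insertions = data.frame(pos = integer(0),
                                         inserted = character(0),
                                         read_id = character(0)),
                 min_qual = 20, genome_length = G),
            class = "pileup")
}

new_read_set_test <- function(id, seq, qual)
  structure(list(id = id, seq = seq, qual = qual, truth = NULL),
            class = "read_set")

plastid_sense_codons <- function() {
  gc <- Biostrings::getGeneticCode("11")
  names(gc)[gc != "*"]
}

test_that("pileup counts identical reads and separates gapped reads", {
  set.seed(33)
  s <- rand_dna(600)
  reads <- rep(substr(s, 101, 400), 10)
  names(reads) <- sprintf("r%02d", 1:10)
  aln <- map_reads(reads, s, circular = FALSE)
  pu <- build_pileup(aln, s)
  expect_equal(unname(pu$depth_q[250]), 10L)
  base250 <- substr(s, 250, 250)
  expect_equal(unname(pu$counts[250, base250]), 10L)
  expect_equal(sum(pu$gap_reads), 0L)
  # a read with an internal deletion registers a gap, not a base
  del_read <- paste0(substr(s, 101, 249), substr(s, 251, 400))
  aln2 <- map_reads(c(reads, del = del_read), s, circular = FALSE)
  pu2 <- build_pileup(aln2, s)
  expect_equal(unname(pu2$gap_reads[250]), 1L)
  expect_equal(unname(pu2$counts[250, base250]), 10L)
})

test_that("bases at or below the quality threshold are excluded", {
  s <- strrep("ACGT", 100)
  rs <- new_read_set_test(
    id = c("hi", "lo"),
    seq = rep(substr(s, 1, 100), 2),
    qual = list(rep(30, 100), rep(15, 100)))
  aln <- map_reads(rs, s, circular = FALSE)
  pu <- build_pileup(aln, s, min_qual = 20)
  expect_equal(unname(pu$depth_q[50]), 1L)
  pu2 <- build_pileup(aln, s, min_qual = 10)
  expect_equal(unname(pu2$depth_q[50]), 2L)
})

test_that("the four filtering rules gate calls as printed arithmetic", {
  set.seed(2)
  g <- rand_dna(1000)
  pu <- fake_pileup(list(
    `100` = c(C = 863, T = 124),     # psbA-style site
    `200` = c(A = 30, C = 21),       # depth 51 > 50: qualifies
    `300` = c(A = 30, C = 20),       # depth 50 exactly: excluded (strict)
    `400` = c(A = 950, C = 50),      # minor 5%: excluded
    `500` = c(G = 450, T = 50),      # minor exactly 10%: excluded (strict)
    `600` = c(A = 60, G = 60)))      # tie
  calls <- call_intrasnps(pu, g, hp_mask = integer(0))
  expect_setequal(calls$position, c(100, 200, 600))
  r100 <- calls[calls$position == 100, ]
  expect_equal(r100$major, "C"); expect_equal(r100$minor, "T")
  expect_equal(r100$major_pct, 87.4)
  expect_equal(r100$minor_pct, 12.6)
  expect_equal(r100$mutation_class, "transition")
  r600 <- calls[calls$position == 600, ]
  expect_equal(r600$major, "A")     # lexicographic tie-break
  expect_true(r600$ambiguous)
})

test_that("no call is ever emitted inside a masked homopolymer run", {
  # a 9-A run with an artifact-like C pileup at its edge
  set.seed(6)
  s <- paste0(rand_dna(300), strrep("A", 9), rand_dna(300))
  pu <- fake_pileup(list(`309` = c(A = 700, C = 150),    # inside the run
                         `150` = c(A = 500, G = 100)),   # clean site
                    G = nchar(s))
  calls <- call_intrasnps(pu, s)
  expect_equal(calls$position, 150)
  mask <- homopolymer_mask(find_homopolymers(s, 5), flank = 1,
                           genome_length = nchar(s))
  expect_false(any(calls$position %in% mask))
})

test_that("codon effects reproduce the printed classification logic", {
  # minus-strand gene: CDS position 858 is a C->T third-position change
  n_codons <- 300
  set.seed(41)
  body <- c("ATG", sample(setdiff(plastid_sense_codons(), "ACC"),
                          n_codons - 2, TRUE), "TAA")
  # codon index for CDS pos 858: ceiling(858/3) = 286; plant ACC there
  body[286] <- "ACC"
  cds <- paste(body, collapse = "")
  left <- rand_dna(120); right <- rand_dna(120)
  s <- paste0(left, revcomp(cds), right)
  ann <- data.frame(gene = "psbA", type = "CDS", start = nchar(left) + 1L,
                    end = nchar(left) + nchar(cds), strand = "-",
                    rank = 1L, pseudo = FALSE)
  # genome position of CDS offset 858 on the minus strand
  gpos <- ann$end - 858L + 1L
  # the genome (plus-strand) base there is complement of CDS base C -> G
  expect_equal(substr(s, gpos, gpos), "G")
  calls <- data.frame(position = gpos, major = "G", minor = "A",
                      major_n = 863L, minor_n = 124L, major_pct = 87.4,
                      minor_pct = 12.6,
                      mutation_class = mutation_class("G", "A"),
                      ambiguous = FALSE)
  cl <- classify_snps(calls, ann, s)
  expect_equal(cl$context, "CDS")
  expect_equal(cl$cds_pos, 858L)
  expect_equal(cl$major_codon, "acC")
  expect_equal(cl$minor_codon, "acT")
  expect_equal(cl$effect, "synonymous")
  expect_equal(cl$mutation_class, "transition")
})

test_that("nonsense and intergenic classifications behave", {
  # plus-strand gene with codon TTA; minor makes TGA (stop)
  set.seed(43)
  body <- c("ATG", rep("GGT", 20), "TTA", rep("CAT", 20), "TAA")
  cds <- paste(body, collapse = "")
  left <- rand_dna(100)
  s <- paste0(left, cds, rand_dna(100))
  ann <- data.frame(gene = "rpoC2", type = "CDS", start = nchar(left) + 1L,
                    end = nchar(left) + nchar(cds), strand = "+",
                    rank = 1L, pseudo = FALSE)
  gpos <- ann$start - 1L + 3L * 21L + 2L     # middle base of the TTA codon
  calls <- data.frame(position = gpos, major = "T", minor = "G",
                      major_n = 789L, minor_n = 99L, major_pct = 88.9,
                      minor_pct = 11.1,
                      mutation_class = mutation_class("T", "G"),
                      ambiguous = FALSE)
  cl <- classify_snps(calls, ann, s)
  expect_equal(cl$major_codon, "tTa")
  expect_equal(cl$minor_codon, "tGa")
  expect_equal(cl$effect, "nonsense")
  expect_equal(cl$mutation_class, "transversion")
  # intergenic site
  calls2 <- calls; calls2$position <- 10L
  cl2 <- classify_snps(calls2, ann, s)
  expect_equal(cl2$context, "intergenic")
})

test_that("published SNP table arithmetic is self-consistent", {
  sn <- datepalm_intrasnps()
  expect_equal(nrow(sn), 62)
  ok <- !is.na(sn$major_n)
  expect_equal(sum(!ok), 1)          # the codon-sharing row carries NA counts
  recomputed <- round(100 * sn$major_n[ok] / (sn$major_n[ok] + sn$minor_n[ok]), 1)
  expect_equal(recomputed, sn$major_pct[ok])
  expect_true(all(sn$major_n[ok] >= sn$minor_n[ok]))
  # transition/transversion classes partition the records
  cls <- mutation_class(sn$major, sn$minor)
  expect_true(all(cls %in% c("transition", "transversion")))
  expect_equal(sum(sn$oilpalm_swap), 19)
})

test_that("intravarietal insertions report carrier fractions", {
  set.seed(51)
  s <- rand_dna(800)
  base <- substr(s, 201, 500)
  with_ins <- paste0(substr(s, 201, 350), "TAGA", substr(s, 351, 500))
  reads <- c(rep(base, 18), rep(with_ins, 7))
  names(reads) <- sprintf("r%02d", seq_along(reads))
  aln <- map_reads(reads, s, circular = FALSE)
  pu <- build_pileup(aln, s)
  ind <- call_intra_indels(pu)
  expect_equal(nrow(ind), 1)
  expect_equal(ind$inserted, "TAGA")
  expect_equal(ind$with_n, 7L)
  expect_true(ind$minor)
  expect_lt(abs(ind$fraction - 7 / 25), 0.05)
  # unanimous insertion is not heteroplasmic
  aln2 <- map_reads(stats::setNames(rep(with_ins, 5), paste0("u", 1:5)), s,
                    circular = FALSE)
  ind2 <- call_intra_indels(build_pileup(aln2, s))
  expect_false(ind2$minor[1])
})

test_that("genotype swaps against an ortholog set are counted exactly", {
  set.seed(61)
  n <- 60
  codons <- c("ATG", sample(plastid_sense_codons(), 120, TRUE), "TAA")
  own <- paste(codons, collapse = "")
  own_rec <- structure(list(gene = "orth", sequence = own, strand = "+",
                            parts = data.frame(gene = "orth", type = "CDS",
                                               start = 1,
                                               end = nchar(own),
                                               strand = "+", rank = 1,
                                               pseudo = FALSE),
                            in_frame = TRUE), class = "cds_record")
  # calls at 60 third-codon positions, minor differing from major
  pos <- 3L * (2:(n + 1))
  majors <- substring(own, pos, pos)
  minors <- vapply(majors, function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                   character(1))
  calls <- data.frame(position = pos, major = majors, minor = minors,
                      gene = "orth", cds_pos = pos, strand = "+")
  # comparator: flip 19 sites to the minor allele
  oth <- strsplit(own, "")[[1]]
  flip <- sample(n, 19)
  oth[pos[flip]] <- minors[flip]
  res <- compare_genotypes(calls, list(own_rec),
                           c(orth = paste(oth, collapse = "")))
  expect_equal(sum(res$status == "swap"), 19)
  expect_equal(sum(res$status == "no_swap"), n - 19)
  # identical orthologs: zero swaps
  res2 <- compare_genotypes(calls, list(own_rec), c(orth = own))
  expect_equal(sum(res2$status == "swap"), 0)
})
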