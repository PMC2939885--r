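# Quadripartite detection, junction context, repeats, small inversions.

test_that("quadripartite detection recovers planted region lengths exactly", {
  sp <- genome_spec(lsc_len = 2000, ssc_len = 600, ir_len = 800, seed = 51)
  g <- simulate_genome(sp)
  lay <- detect_quadripartite(g, min_ir_len = 300)
  expect_true(lay$found)
  expect_equal(lay$lsc_len, 2000)
  expect_equal(lay$ssc_len, 600)
  expect_equal(lay$ir_len, 800)
})

test_that("a random sequence has no quadripartite structure", {
  set.seed(4)
  lay <- detect_quadripartite(rand_dna(10000), min_ir_len = 1000)
  expect_false(lay$found)
  expect_match(lay$reason, "no quadripartite")
})

test_that("detection is rotation-invariant on the circle", {
  sp <- genome_spec(lsc_len = 2400, ssc_len = 700, ir_len = 600, seed = 52)
  g <- simulate_genome(sp)
  set.seed(8)
  for (rot in sample(g$length, 4)) {
    s <- paste0(substr(g$sequence, rot + 1, g$length),
                substr(g$sequence, 1, rot))
    lay <- detect_quadripartite(s, min_ir_len = 300)
    expect_true(lay$found)
    expect_equal(c(lay$lsc_len, lay$ssc_len, lay$ir_len), c(2400, 700, 600))
  }
})

test_that("junction context reports distances, spans and overlaps", {
  sp <- genome_spec(lsc_len = 2000, ssc_len = 600, ir_len = 800, seed = 53)
  g <- simulate_genome(sp)
  jlb <- g$layout$junctions[["JLB"]]
  jsb <- g$layout$junctions[["JSB"]]
  ann <- data.frame(
    gene = c("endsAtJLB", "spansJSB", "farGene"),
    type = "CDS",
    start = c(jlb - 299L, jsb - 244L, 100L),
    end = c(jlb, jsb + 55L, 400L),       # 55 bp past JSB into the SSC
    strand = c("+", "-", "+"), rank = 1L, pseudo = FALSE)
  rep <- junction_report(g$layout, ann)
  row_jlb <- rep[rep$junction == "JLB", ]
  expect_equal(row_jlb$left_gene, "endsAtJLB")
  expect_equal(row_jlb$left_dist, 0L)
  expect_true(is.na(row_jlb$spanning_gene))
  row_jsb <- rep[rep$junction == "JSB", ]
  expect_equal(row_jsb$spanning_gene, "spansJSB")
  expect_equal(row_jsb$overlap, 55L)
  expect_warning(junction_report(g$layout, empty_annotation()), "empty")
})

test_that("junction context matches a brute-force interval scan", {
  sp <- genome_spec(lsc_len = 2000, ssc_len = 600, ir_len = 800, seed = 54)
  g <- simulate_genome(sp)
  G <- g$length
  set.seed(12)
  for (case in 1:5) {
    st <- sort(sample(seq(50, G - 400, by = 13), 8))
    ann <- data.frame(gene = sprintf("g%02d", 1:8), type = "CDS",
                      start = st, end = st + sample(100:350, 8),
                      strand = sample(c("+", "-"), 8, TRUE),
                      rank = 1L, pseudo = FALSE)
    rep <- junction_report(g$layout, ann)
    for (j in seq_len(nrow(rep))) {
      b <- rep$pos[j]
      spanning <- ann$gene[ann$start <= b & ann$end > b]
      if (length(spanning)) {
        expect_equal(rep$spanning_gene[j], spanning[1])
      } else {
        expect_true(is.na(rep$spanning_gene[j]))
        dl <- (b - ann$end) %% G
        expect_equal(rep$left_gene[j], ann$gene[which.min(dl)])
        expect_equal(rep$left_dist[j], min(dl))
      }
    }
  }
})

test_that("repeat finder handles planted exact and mismatched pairs", {
  rp <- data.frame(unit_len = c(30, 39, 35), mismatches = c(0, 3, 2),
                   type = c("F", "F", "I"))
  sp <- genome_spec(lsc_len = 9000, ssc_len = 900, ir_len = 900,
                    repeat_plants = rp, seed = 61)
  g <- simulate_genome(sp)
  # pad the IR exclusion: under the mismatch budget the genome-scale IR
  # pair is maximal a few bases beyond the exact IR boundaries
  ex <- data.frame(start = c(g$layout$irb[1], g$layout$ira[1]) - 12L,
                   end = c(g$layout$irb[2], g$layout$ira[2]) + 12L)
  hits <- find_repeats(g, min_len = 30, max_mismatch = 3, exclude = ex)
  truth <- g$truth$repeats
  for (i in seq_len(nrow(truth))) {
    m <- hits[hits$start1 == truth$start1[i] & hits$start2 == truth$start2[i], ]
    expect_equal(nrow(m), 1)
    expect_equal(m$unit_len, truth$unit_len[i])
    expect_equal(m$mismatches, truth$mismatches[i])
    expect_equal(m$type, truth$type[i])
  }
  expect_equal(nrow(hits), nrow(truth))    # exclusion removed the IR itself
})

test_that("repeat location classes resolve against the annotation", {
  sp <- genome_spec(lsc_len = 9000, ssc_len = 900, ir_len = 900,
                    n_genes = 2,
                    repeat_plants = data.frame(unit_len = 32, mismatches = 0,
                                               type = "F"),
                    seed = 63)
  g <- simulate_genome(sp)
  ex <- data.frame(start = c(g$layout$irb[1], g$layout$ira[1]),
                   end = c(g$layout$irb[2], g$layout$ira[2]))
  hits <- find_repeats(g, exclude = ex)
  expect_true(all(grepl("^(IGS\\(|intron\\(|gene)", hits$location1)))
})

test_that("seeded repeat finder equals the brute-force oracle", {
  set.seed(71)
  for (case in 1:8) {
    n <- sample(300:700, 1)
    s <- rand_dna(n)
    ml <- sample(10:14, 1); mm <- sample(0:3, 1)
    got <- find_repeats(s, min_len = ml, max_mismatch = mm)
    exp <- oracle_repeats(s, ml, mm)
    expect_equal(got[c("unit_len", "start1", "start2", "type", "mismatches")],
                 exp, ignore_attr = TRUE)
  }
})

test_that("hairpin score follows its closed form and orderings", {
  stem <- strrep("G", 13)
  cand <- paste0(stem, "TTTT", revcomp(stem))
  expect_equal(hairpin_score(cand, 13), -39)
  expect_equal(hairpin_score(cand, 13), hairpin_score(cand, 13))
  # broken stem beyond budget is rejected
  bad <- paste0("AAAAAAAAAAAAA", "TTTT", "AAAAAAAAAAAAA")
  expect_equal(hairpin_score(bad, 13), Inf)
  # longer loops are penalized
  cand2 <- paste0(stem, strrep("T", 30), revcomp(stem))
  expect_gt(hairpin_score(cand2, 13), hairpin_score(cand, 13))
  # the date-palm psaB stem-loop is more stable than the Acorus variant,
  # matching the published free-energy ordering
  si <- datepalm_si_alignment()
  phx <- si$sequence[si$taxon == "Phoenix"]
  aco <- si$sequence[si$taxon == "Acorus.ame"]
  expect_lt(hairpin_score(phx, 13),
            hairpin_score(aco, 13, max_mismatch = 3))
})

test_that("small inversions satisfy their geometry and round-trip the plant", {
  sp <- genome_spec(lsc_len = 6000, ssc_len = 800, ir_len = 700,
                    si_plants = data.frame(stem = c(13, 11, 18),
                                           loop = c(37, 20, 8)),
                    seed = 81)
  g <- simulate_genome(sp)
  res <- find_small_inversions(g)
  all_hits <- rbind(res$confirmed, res$putative)
  expect_equal(all_hits$end - all_hits$start + 1L,
               2L * all_hits$stem_len + all_hits$loop_len)
  truth <- g$truth$small_inversions
  for (i in seq_len(nrow(truth))) {
    m <- all_hits[all_hits$start == truth$start[i], ]
    expect_equal(nrow(m), 1)
    expect_equal(m$stem_len, truth$stem[i])
    expect_equal(m$loop_len, truth$loop[i])
  }
})

test_that("comparator homology separates confirmed from putative SIs", {
  sp <- genome_spec(lsc_len = 6000, ssc_len = 800, ir_len = 700,
                    si_plants = data.frame(stem = c(13, 14, 12),
                                           loop = c(37, 25, 30)),
                    seed = 82)
  g <- simulate_genome(sp)
  truth <- g$truth$small_inversions
  # comparator contains homologous spans for the first two SIs only
  set.seed(1)
  spans <- vapply(1:2, function(i)
    substr(g$sequence, truth$start[i], truth$end[i]), character(1))
  comparator <- paste0(rand_dna(300), spans[1], rand_dna(300), spans[2],
                       rand_dna(300))
  res <- find_small_inversions(g, comparators = c(monocot = comparator))
  expect_equal(sort(res$confirmed$start), sort(truth$start[1:2]))
  expect_equal(res$putative$start, truth$start[3])
  expect_true(all(grepl("monocot", res$confirmed$support)))
  # no comparators: everything stable is putative
  res0 <- find_small_inversions(g)
  expect_equal(nrow(res0$confirmed), 0)
  expect_equal(nrow(res0$putative), 3)
})

test_that("a sequence without qualifying inverted repeats yields nothing", {
  expect_equal(nrow(find_small_inversions(strrep("ACGT", 50))$putative), 0)
})
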