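#!/usr/bin/env Rscript
# Build the synthetic study genome: a circular quadripartite chloroplast
# genome at the published region sizes (LSC 86,198 / SSC 17,712 / IR
# 27,276 bp; A+T 0.63), with planted genes, operons, homopolymer runs,
# dispersed repeats and stem-loop small inversions. Writes the genome,
# its annotation and the planted-feature truth tables.

suppressPackageStartupMessages(library(plastidkit))
dir.create("results", showWarnings = FALSE)

ops <- list(
  list(genes = c("rps2", "atpI", "atpH", "atpF", "atpA"), strand = "-",
       spacer = 80, n_codons = 140),
  list(genes = c("psbB", "psbT", "psbN", "psbH"), strand = "+",
       spacer = 70, n_codons = 120))
hp <- data.frame(base = rep(c("A", "T", "C"), c(6, 5, 1)),
                 length = c(7, 7, 8, 9, 10, 12, 7, 8, 8, 9, 11, 13))
rp <- data.frame(unit_len = c(30, 35, 39, 31), mismatches = c(0, 1, 3, 2),
                 type = c("F", "F", "F", "I"))
si <- data.frame(stem = c(13, 11, 16), loop = c(37, 24, 12))

spec <- genome_spec(lsc_len = 86198L, ssc_len = 17712L, ir_len = 27276L,
                    at_fraction = 0.63, n_genes = 12,
                    operon_specs = ops, homopolymer_plants = hp,
                    repeat_plants = rp, si_plants = si, seed = 20100915)
genome <- simulate_genome(spec)
print(genome)

write_genome_fasta(genome, "results/synthetic_genome.fasta",
                   name = "synthetic_cp")
write_annotation_gff3(genome$annotation, "results/synthetic_genome.gff3",
                      seqid = "synthetic_cp")

runs <- find_homopolymers(genome, 7)
write.table(runs, "results/homopolymer_inventory.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
counts <- attr(runs, "counts")
cat(sprintf("homopolymer runs >= 7 bp: %d at exactly 7, %d longer\n",
            counts[["at_min"]], counts[["above_min"]]))

win <- validation_windows(runs, genome, flank = 300)
write.table(win, "results/validation_windows.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("validation windows covering all runs: %d (<= %d runs)\n",
            nrow(win), nrow(runs)))

at <- mean(strsplit(genome$sequence, "")[[1]] %in% c("A", "T"))
cat(sprintf("genome %d bp, realized A+T %.4f\n", genome$length, at))
# later steps rebuild this genome deterministically from the same spec
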