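#!/usr/bin/env Rscript
# Codon-usage statistics: recompute RSCU, amino-acid composition and
# positional base composition from the published date-palm chloroplast
# codon counts, and audit start codons on a simulated genome carrying
# non-canonical starts.

suppressPackageStartupMessages(library(plastidkit))
dir.create("results", showWarnings = FALSE)

usage <- datepalm_codon_usage()
r <- rscu(usage$table)
comp <- aa_composition(usage$table)
pos <- positional_base_composition(usage$table)

out <- usage$data
out$rscu_recomputed <- unname(r[chartr("U", "T", out$codon)])
write.table(out, "results/codon_usage_rscu.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(comp, "results/aa_composition.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("total codons: %d\n", attr(usage$table, "total")))
cat(sprintf("most frequent amino acid: Ile %d (%.2f%%); least: Cys %d (%.2f%%)\n",
            comp$count[comp$aa == "I"], comp$percent[comp$aa == "I"],
            comp$count[comp$aa == "C"], comp$percent[comp$aa == "C"]))
cat(sprintf("positional A+T%%: %.1f / %.1f / %.1f\n", pos[1], pos[2], pos[3]))
cat(sprintf("RSCU examples: UUU %.2f, UUA %.2f, AGA %.2f\n",
            r[["TTT"]], r[["TTA"]], r[["AGA"]]))
agree <- abs(out$rscu_recomputed - out$rscu_printed) < 0.005 + 1e-9
sense <- chartr("U", "T", out$codon) %in%
  names(Biostrings::getGeneticCode("11"))[Biostrings::getGeneticCode("11") != "*"]
cat(sprintf("printed RSCU values reproduced (sense codons): %d/%d\n",
            sum(agree & sense), sum(sense)))

# start-codon audit on a genome with planted ACG/GTG starts and an
# ambiguous gene with an upstream in-frame stop
spec <- genome_spec(lsc_len = 8000L, ssc_len = 900L, ir_len = 900L,
                    gene_specs = list(
                      list(name = "rpl2like", n_codons = 90,
                           start_codon = "ACG"),
                      list(name = "rps19like", n_codons = 80,
                           start_codon = "GTG", strand = "-"),
                      list(name = "ordinary", n_codons = 100)),
                    seed = 77)
g <- simulate_genome(spec)
audit <- audit_start_codons(extract_cds(g), g)
write.table(audit, "results/start_codon_audit.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("start-codon audit: %d/%d non-canonical\n",
            sum(!audit$canonical), nrow(audit)))
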