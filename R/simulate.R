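# Synthetic data: circular quadripartite genomes with planted features,
# pyrosequencing-style reads with homopolymer-length miscalls and
# heteroplasmic minor alleles, and polyT-primed cDNA libraries.
#
# The generator is truth-carrying: every planted feature is recorded at its
# final coordinates so downstream detectors can be scored exactly.

#' Specification of a synthetic quadripartite genome
#'
#' Region lengths default to the published date-palm chloroplast values
#' (LSC 86,198 / SSC 17,712 / IR 27,276 bp) and the genome-wide A+T
#' fraction to 0.63. Planted features are placed in the LSC, mutually
#' non-overlapping; explicit `start` coordinates are honoured and checked.
#'
#' @param lsc_len,ssc_len,ir_len Region lengths in bp; the genome length is
#'   `lsc_len + ssc_len + 2 * ir_len` and `ir_len < lsc_len` is required.
#' @param at_fraction Target A+T proportion of the background sequence.
#' @param n_genes Number of additional unnamed single-exon genes to plant.
#' @param gene_specs List of gene descriptions: `list(name, n_codons,
#'   strand, exons, trans, start_codon, intron_len, start)`; multi-exon
#'   genes are split by introns, `trans = TRUE` places each exon part
#'   independently (possibly on both strands) to emulate trans-splicing.
#' @param operon_specs List of `list(genes = c(...), strand, spacer,
#'   n_codons)` polycistronic units; member genes are contiguous with
#'   `spacer` bp between them.
#' @param homopolymer_plants Data frame (`base`, `length`, optional `start`)
#'   of runs to plant; background runs are capped below the inventory
#'   threshold so these are the only long runs.
#' @param repeat_plants Data frame (`unit_len`, `mismatches`, `type` =
#'   "F"/"I", optional `start1`, `start2`) of dispersed repeat pairs.
#' @param si_plants Data frame (`stem`, `loop`, optional `start`) of
#'   stem-loop small inversions (perfect stems).
#' @param max_background_run Longest background single-base run left intact.
#' @param seed Integer seed; required (all generator draws come from it).
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(lsc_len = 86198L, ssc_len = 17712L, ir_len = 27276L,
                        at_fraction = 0.63, n_genes = 0L, gene_specs = list(),
                        operon_specs = list(),
                        homopolymer_plants = NULL, repeat_plants = NULL,
                        si_plants = NULL, max_background_run = 6L, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(lsc_len > 0, ssc_len > 0, ir_len > 0)
  if (ir_len >= lsc_len)
    stop("ir_len must be smaller than lsc_len", call. = FALSE)
  if (at_fraction < 0 || at_fraction > 1)
    stop("at_fraction must lie in [0, 1]", call. = FALSE)
  if (!is.null(si_plants)) {
    if (any(si_plants$stem < 5 | si_plants$stem > 50))
      stop("si stem lengths must lie in [5, 50]", call. = FALSE)
  }
  structure(list(lsc_len = as.integer(lsc_len), ssc_len = as.integer(ssc_len),
                 ir_len = as.integer(ir_len), at_fraction = at_fraction,
                 n_genes = as.integer(n_genes), gene_specs = gene_specs,
                 operon_specs = operon_specs,
                 homopolymer_plants = homopolymer_plants,
                 repeat_plants = repeat_plants, si_plants = si_plants,
                 max_background_run = as.integer(max_background_run),
                 seed = as.integer(seed)),
            class = "genome_spec")
}

# sense (non-stop) codons of the plastid/bacterial code, DNA alphabet
sense_codons <- function() {
  gc <- Biostrings::getGeneticCode("11")
  names(gc)[gc != "*"]
}

# a CDS payload: start codon + random sense codons + TAA, no run >= 7
random_cds <- function(n_codons, start_codon = "ATG") {
  stopifnot(n_codons >= 2)
  repeat {
    body <- sample(sense_codons(), n_codons - 2L, replace = TRUE)
    s <- paste0(start_codon, paste(body, collapse = ""), "TAA")
    if (max(base_runs(s)$length) < 7L) return(s)
  }
}

# place `len`-bp features without overlap inside [lo, hi]; `fixed` entries
# carry their own start. Returns integer starts. Buffer keeps features and
# their flank adjustments apart.
place_features <- function(lens, fixed_starts, lo, hi, occupied, buffer = 10L) {
  starts <- integer(length(lens))
  occ <- occupied            # data.frame(start, end)
  claim <- function(s, e) occ <<- rbind(occ, data.frame(start = s, end = e))
  overlaps <- function(s, e)
    nrow(occ) > 0L && any(occ$start <= e + buffer & occ$end >= s - buffer)
  for (i in seq_along(lens)) {
    if (!is.na(fixed_starts[i])) {
      s <- fixed_starts[i]; e <- s + lens[i] - 1L
      if (s < lo || e > hi)
        stop("planted feature lies outside the placement region", call. = FALSE)
      if (overlaps(s, e))
        stop(sprintf(
          "planted features overlap: feature at %d..%d collides with an existing feature",
          s, e), call. = FALSE)
    } else {
      ok <- FALSE
      for (try in 1:2000) {
        s <- sample(lo:(hi - lens[i] + 1L), 1L)
        e <- s + lens[i] - 1L
        if (!overlaps(s, e)) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place planted features without overlap; ",
                    "region too crowded", call. = FALSE)
    }
    starts[i] <- s
    claim(s, e)
  }
  list(starts = starts, occupied = occ)
}

#' Simulate an annotated quadripartite genome
#'
#' The genome is stored linearized at the IRa->LSC junction (LSC first), as
#' `LSC | IRb | SSC | IRa` with IRa the exact reverse complement of IRb.
#' All planted features land in the LSC so the IR identity holds exactly.
#'
#' @param spec A [genome_spec()].
#' @return An [annotated_genome()] carrying layout, annotation, operons and
#'   truth tables for every planted feature.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, simulate_genome_impl(spec))
}

simulate_genome_impl <- function(spec) {
  G <- spec$lsc_len + spec$ssc_len + 2L * spec$ir_len
  lsc <- seq_chars(random_dna(spec$lsc_len, spec$at_fraction,
                              spec$max_background_run))
  irb <- random_dna(spec$ir_len, spec$at_fraction, spec$max_background_run)
  ssc <- random_dna(spec$ssc_len, spec$at_fraction, spec$max_background_run)

  margin <- min(60L, spec$lsc_len %/% 20L)
  lo <- 1L + margin
  hi <- spec$lsc_len - margin
  occupied <- data.frame(start = integer(0), end = integer(0))

  ann <- empty_annotation()
  truth <- list(cds = list())
  operons <- list()

  # ---- gene payloads (operon members + standalone) -------------------------
  gene_specs <- spec$gene_specs
  if (spec$n_genes > 0L) {
    auto <- lapply(seq_len(spec$n_genes), function(i)
      list(name = sprintf("gene%02d", i),
           n_codons = sample(80:250, 1L),
           strand = sample(c("+", "-"), 1L)))
    gene_specs <- c(gene_specs, auto)
  }
  norm_gene <- function(g) {
    # exact [[ ]] indexing: `$` would partially match start -> start_codon
    g$n_codons <- if (is.null(g[["n_codons"]])) 150L else as.integer(g[["n_codons"]])
    g$strand <- if (is.null(g[["strand"]])) "+" else g[["strand"]]
    g$exons <- if (is.null(g[["exons"]])) 1L else as.integer(g[["exons"]])
    g$trans <- isTRUE(g[["trans"]])
    g$start_codon <- if (is.null(g[["start_codon"]])) "ATG" else g[["start_codon"]]
    g$intron_len <- if (is.null(g[["intron_len"]])) 120L else as.integer(g[["intron_len"]])
    g$start <- if (is.null(g[["start"]])) NA_integer_ else as.integer(g[["start"]])
    g
  }
  gene_specs <- lapply(gene_specs, norm_gene)

  plant_gene_block <- function(gspec) {
    # returns list(payload chars, relative annotation rows, spliced cds)
    cds <- random_cds(gspec$n_codons, gspec$start_codon)
    L <- nchar(cds)
    if (gspec$exons <= 1L) {
      seqs <- cds
    } else {
      cuts <- sort(sample(seq(3L, L - 3L, by = 3L), gspec$exons - 1L))
      seqs <- substring(cds, c(1L, cuts + 1L), c(cuts, L))
    }
    list(cds = cds, exon_seqs = seqs)
  }

  # operons: one contiguous block each
  for (oi in seq_along(spec$operon_specs)) {
    op <- spec$operon_specs[[oi]]
    strand <- if (is.null(op$strand)) "+" else op$strand
    spacer <- if (is.null(op$spacer)) 80L else as.integer(op$spacer)
    ncod <- if (is.null(op$n_codons)) 120L else as.integer(op$n_codons)
    members <- op$genes
    cdss <- lapply(members, function(g) random_cds(ncod))
    spacers <- vapply(seq_along(members), function(i)
      random_dna(spacer, spec$at_fraction, spec$max_background_run),
      character(1))
    block <- character(0)
    rel <- integer(0)
    for (i in seq_along(members)) {
      rel[i] <- sum(nchar(block)) + 1L
      block <- c(block, cdss[[i]], if (i < length(members)) spacers[i])
    }
    payload <- paste(block, collapse = "")
    if (strand == "-") {
      # rev-comp the whole block; member order reverses on the plus strand
      payload_rc <- revcomp(payload)
      pl <- nchar(payload)
      rel_rc <- pl - (rel + nchar(vapply(cdss, identity, character(1))) - 1L) + 1L
      placement <- place_features(nchar(payload), NA_integer_, lo, hi, occupied)
      occupied <- placement$occupied
      s0 <- placement$starts[1]
      for (i in seq_along(members)) {
        ann <- rbind(ann, data.frame(
          gene = members[i], type = "CDS",
          start = s0 + rel_rc[i] - 1L,
          end = s0 + rel_rc[i] + nchar(cdss[[i]]) - 2L,
          strand = "-", rank = 1L, pseudo = FALSE, stringsAsFactors = FALSE))
        truth$cds[[members[i]]] <- cdss[[i]]
      }
      lsc[placement$starts[1]:(placement$starts[1] + nchar(payload) - 1L)] <-
        seq_chars(payload_rc)
      operons[[length(operons) + 1L]] <- list(genes = members, strand = "-")
    } else {
      placement <- place_features(nchar(payload), NA_integer_, lo, hi, occupied)
      occupied <- placement$occupied
      s0 <- placement$starts[1]
      for (i in seq_along(members)) {
        ann <- rbind(ann, data.frame(
          gene = members[i], type = "CDS",
          start = s0 + rel[i] - 1L,
          end = s0 + rel[i] + nchar(cdss[[i]]) - 2L,
          strand = "+", rank = 1L, pseudo = FALSE, stringsAsFactors = FALSE))
        truth$cds[[members[i]]] <- cdss[[i]]
      }
      lsc[s0:(s0 + nchar(payload) - 1L)] <- seq_chars(payload)
      operons[[length(operons) + 1L]] <- list(genes = members, strand = "+")
    }
  }

  # standalone genes (possibly multi-exon or trans-spliced)
  for (g in gene_specs) {
    blk <- plant_gene_block(g)
    nexon <- length(blk$exon_seqs)
    if (g$trans && nexon > 1L) {
      # each exon part placed independently; strand alternates to exercise
      # mixed-strand trans-splicing
      for (i in seq_len(nexon)) {
        part_strand <- if (i %% 2L == 1L) g$strand else
          setdiff(c("+", "-"), g$strand)
        pseq <- blk$exon_seqs[i]
        placed <- if (part_strand == "-") revcomp(pseq) else pseq
        placement <- place_features(nchar(pseq), NA_integer_, lo, hi, occupied)
        occupied <- placement$occupied
        s0 <- placement$starts[1]
        lsc[s0:(s0 + nchar(pseq) - 1L)] <- seq_chars(placed)
        ann <- rbind(ann, data.frame(
          gene = g$name, type = "CDS", start = s0,
          end = s0 + nchar(pseq) - 1L, strand = part_strand, rank = i,
          pseudo = FALSE, stringsAsFactors = FALSE))
      }
    } else {
      intr <- if (nexon > 1L)
        vapply(seq_len(nexon - 1L), function(i)
          random_dna(g$intron_len, spec$at_fraction, spec$max_background_run),
          character(1)) else character(0)
      parts <- character(0)
      rel <- integer(nexon)
      for (i in seq_len(nexon)) {
        rel[i] <- sum(nchar(parts)) + 1L
        parts <- c(parts, blk$exon_seqs[i], if (i < nexon) intr[i])
      }
      payload <- paste(parts, collapse = "")
      placed <- if (g$strand == "-") revcomp(payload) else payload
      placement <- place_features(nchar(payload), g$start, lo, hi, occupied)
      occupied <- placement$occupied
      s0 <- placement$starts[1]
      lsc[s0:(s0 + nchar(payload) - 1L)] <- seq_chars(placed)
      for (i in seq_len(nexon)) {
        if (g$strand == "+") {
          st <- s0 + rel[i] - 1L
          en <- st + nchar(blk$exon_seqs[i]) - 1L
        } else {
          en <- s0 + nchar(payload) - 1L - (rel[i] - 1L)
          st <- en - nchar(blk$exon_seqs[i]) + 1L
        }
        ann <- rbind(ann, data.frame(
          gene = g$name, type = "CDS", start = st, end = en,
          strand = g$strand, rank = i, pseudo = FALSE,
          stringsAsFactors = FALSE))
      }
    }
    truth$cds[[g$name]] <- blk$cds
  }

  # ---- homopolymer runs ----------------------------------------------------
  hp_truth <- NULL
  hp <- spec$homopolymer_plants
  if (!is.null(hp) && nrow(hp)) {
    fixed <- if ("start" %in% names(hp)) as.integer(hp$start) else
      rep(NA_integer_, nrow(hp))
    placement <- place_features(as.integer(hp$length), fixed, lo, hi, occupied)
    occupied <- placement$occupied
    alt <- c(A = "C", C = "A", G = "T", T = "G")
    for (i in seq_len(nrow(hp))) {
      s0 <- placement$starts[i]; L <- as.integer(hp$length[i])
      b <- toupper(hp$base[i])
      lsc[s0:(s0 + L - 1L)] <- b
      # runs must be maximal: force differing neighbours
      if (s0 > 1L && lsc[s0 - 1L] == b) lsc[s0 - 1L] <- alt[[b]]
      if (s0 + L <= length(lsc) && lsc[s0 + L] == b) lsc[s0 + L] <- alt[[b]]
    }
    hp_truth <- data.frame(base = toupper(hp$base), start = placement$starts,
                           length = as.integer(hp$length),
                           stringsAsFactors = FALSE)
  }

  # ---- dispersed repeats ---------------------------------------------------
  rep_truth <- NULL
  rp <- spec$repeat_plants
  if (!is.null(rp) && nrow(rp)) {
    starts1 <- integer(nrow(rp)); starts2 <- integer(nrow(rp))
    for (i in seq_len(nrow(rp))) {
      L <- as.integer(rp$unit_len[i])
      mm <- as.integer(rp$mismatches[i])
      type <- toupper(substr(rp$type[i], 1, 1))
      unit <- random_dna(L, spec$at_fraction, spec$max_background_run)
      copy2 <- if (type == "I") revcomp(unit) else unit
      if (mm > 0L) {
        pos <- sample(2:(L - 1L), mm)      # interior, so the hit is not trimmed
        c2 <- seq_chars(copy2)
        for (p in pos) c2[p] <- sample(setdiff(c("A", "C", "G", "T"), c2[p]), 1L)
        copy2 <- paste(c2, collapse = "")
      }
      f1 <- if ("start1" %in% names(rp)) as.integer(rp$start1[i]) else NA_integer_
      f2 <- if ("start2" %in% names(rp)) as.integer(rp$start2[i]) else NA_integer_
      placement <- place_features(c(L + 8L, L + 8L), c(f1, f2), lo, hi, occupied)
      occupied <- placement$occupied
      s1 <- placement$starts[1] + 4L
      s2 <- placement$starts[2] + 4L
      if (s2 < s1) { tmp <- s1; s1 <- s2; s2 <- tmp }
      lsc[s1:(s1 + L - 1L)] <- seq_chars(unit)
      lsc[s2:(s2 + L - 1L)] <- seq_chars(copy2)
      # dense mismatching flanks (4 bp each side) pin down maximality
      u <- seq_chars(unit); c2 <- seq_chars(copy2)
      anti <- function(b) c(A = "C", C = "A", G = "T", T = "G")[[b]]
      for (d in 1:4) {
        # flank of copy2 must mismatch the extension of copy1 (and vice versa)
        if (type == "F") {
          if (s1 - d >= 1L) lsc[s2 - d] <- anti(lsc[s1 - d])
          if (s1 + L - 1L + d <= length(lsc)) lsc[s2 + L - 1L + d] <-
              anti(lsc[s1 + L - 1L + d])
        } else {
          # inverted: left flank of copy1 pairs with right flank of copy2
          if (s2 + L - 1L + d <= length(lsc) && s1 - d >= 1L)
            lsc[s2 + L - 1L + d] <- anti(complement_dna(lsc[s1 - d]))
          if (s1 + L - 1L + d <= length(lsc) && s2 - d >= 1L)
            lsc[s2 - d] <- anti(complement_dna(lsc[s1 + L - 1L + d]))
        }
      }
      starts1[i] <- s1; starts2[i] <- s2
    }
    rep_truth <- data.frame(unit_len = as.integer(rp$unit_len),
                            mismatches = as.integer(rp$mismatches),
                            type = toupper(substr(rp$type, 1, 1)),
                            start1 = starts1, start2 = starts2,
                            stringsAsFactors = FALSE)
  }

  # ---- small inversions (perfect stems) ------------------------------------
  si_truth <- NULL
  si <- spec$si_plants
  if (!is.null(si) && nrow(si)) {
    starts <- integer(nrow(si))
    comp1 <- c(A = "T", T = "A", C = "G", G = "C")
    for (i in seq_len(nrow(si))) {
      st <- as.integer(si$stem[i]); lp <- as.integer(si$loop[i])
      repeat {
        stem <- random_dna(st, spec$at_fraction, spec$max_background_run)
        loop <- random_dna(lp, spec$at_fraction, spec$max_background_run)
        # loop must not extend the stem inward, and the stem must not be
        # extendible by loop/flank symmetry
        if (lp >= 2L &&
            substr(loop, 1, 1) == comp1[[substr(loop, lp, lp)]]) next
        if (lp == 1L) break
        break
      }
      payload <- paste0(stem, loop, revcomp(stem))
      fixed <- if ("start" %in% names(si)) as.integer(si$start[i]) else NA_integer_
      placement <- place_features(nchar(payload) + 2L, fixed, lo, hi, occupied)
      occupied <- placement$occupied
      s0 <- placement$starts[1] + 1L
      lsc[s0:(s0 + nchar(payload) - 1L)] <- seq_chars(payload)
      # outward maximality: flanking bases must not pair
      if (s0 > 1L && s0 + nchar(payload) <= length(lsc)) {
        b_after <- lsc[s0 + nchar(payload)]
        if (lsc[s0 - 1L] == comp1[[b_after]])
          lsc[s0 - 1L] <- setdiff(c("A", "C", "G", "T"),
                                  c(comp1[[b_after]]))[1]
      }
      starts[i] <- s0
    }
    si_truth <- data.frame(start = starts,
                           end = starts + 2L * as.integer(si$stem) +
                             as.integer(si$loop) - 1L,
                           stem = as.integer(si$stem),
                           loop = as.integer(si$loop), stringsAsFactors = FALSE)
  }

  # ---- assemble and sanitise accidental long runs --------------------------
  lsc_s <- paste(lsc, collapse = "")
  seqn <- paste0(lsc_s, irb, ssc, revcomp(irb))
  # break accidental runs >= 7 created at payload boundaries, outside
  # planted/annotated features
  runs <- base_runs(seqn)
  long <- runs[runs$length >= 7L, , drop = FALSE]
  if (nrow(long)) {
    chars <- seq_chars(seqn)
    protected <- occupied
    if (nrow(ann))
      protected <- rbind(protected,
                         data.frame(start = ann$start, end = ann$end))
    is_planted_run <- function(s, L) {
      !is.null(hp_truth) && any(hp_truth$start == s & hp_truth$length == L)
    }
    in_protected <- function(p)
      nrow(protected) > 0L &&
        any(protected$start - 1L <= p & protected$end + 1L >= p)
    alt <- c(A = "C", C = "A", G = "T", T = "G")
    for (i in seq_len(nrow(long))) {
      if (is_planted_run(long$start[i], long$length[i])) next
      cand <- c(long$start[i], long$start[i] + long$length[i] - 1L,
                long$start[i] + 3L)
      cand <- cand[cand <= spec$lsc_len]     # only touch the LSC copy
      cand <- cand[!vapply(cand, in_protected, logical(1))]
      if (length(cand)) chars[cand[1]] <- alt[[long$base[i]]]
    }
    # keep IRa == revcomp(IRb) exact after edits inside IRb (none expected,
    # edits are LSC-only) and rebuild
    seqn <- paste(chars, collapse = "")
  }

  # pin the IR junctions: the planted IR pair must not be extendible by
  # chance complementarity of the flanking bases, or detected region
  # lengths would drift off the requested sizes
  {
    chars <- seq_chars(seqn)
    comp1 <- c(A = "T", T = "A", C = "G", G = "C")
    fix_pair <- function(i, j) {
      # ensure chars[i] != comp(chars[j]); i is a background position
      if (chars[i] == comp1[[chars[j]]])
        chars[i] <<- setdiff(c("A", "C", "G", "T"),
                             c(comp1[[chars[j]]], chars[i]))[1]
    }
    lsc_end <- spec$lsc_len
    irb_end <- spec$lsc_len + spec$ir_len
    ssc_end <- irb_end + spec$ssc_len
    fix_pair(lsc_end, 1L)                 # leftward extension of IRb vs IRa
    fix_pair(irb_end + 1L, ssc_end)       # rightward ext: SSC first vs last
    seqn <- paste(chars, collapse = "")
  }

  layout <- list(found = TRUE,
                 lsc = c(1L, spec$lsc_len),
                 irb = c(spec$lsc_len + 1L, spec$lsc_len + spec$ir_len),
                 ssc = c(spec$lsc_len + spec$ir_len + 1L,
                         spec$lsc_len + spec$ir_len + spec$ssc_len),
                 ira = c(spec$lsc_len + spec$ir_len + spec$ssc_len + 1L, G),
                 lsc_len = spec$lsc_len, ssc_len = spec$ssc_len,
                 ir_len = spec$ir_len,
                 junctions = c(JLB = spec$lsc_len,
                               JSB = spec$lsc_len + spec$ir_len,
                               JSA = spec$lsc_len + spec$ir_len + spec$ssc_len,
                               JLA = G))
  class(layout) <- "quadripartite_layout"

  truth$homopolymers <- hp_truth
  truth$repeats <- rep_truth
  truth$small_inversions <- si_truth

  annotated_genome(seqn, annotation = ann, layout = layout,
                   operons = operons, truth = truth, circular = TRUE)
}

#' Read-simulation configuration
#'
#' Defaults emulate GS FLX pyrosequencing: ~380 bp reads, per-run
#' homopolymer length-miscall probability growing with run length
#' (`min(0.9, rate * (L - 3))` for a run of length `L`), a small per-base
#' substitution rate, and Phred qualities around Q30 decaying along the
#' read.
#'
#' @param mean_len,len_sd Read length distribution (bp).
#' @param depth Fold coverage; required (> 0).
#' @param hp_error_rate Rate `r` of the run-length miscall model.
#' @param sub_error_rate Per-base substitution probability.
#' @param hp_min_run Shortest run subject to length miscalls.
#' @param qual_mean,qual_decay Mean Phred at the 5' end and total linear
#'   drop across the read.
#' @param seed Integer seed; required.
#' @return A `read_sim_config` list.
#' @export
read_sim_config <- function(mean_len = 380, len_sd = 40, depth,
                            hp_error_rate = 0.02, sub_error_rate = 0.002,
                            hp_min_run = 4L, qual_mean = 30, qual_decay = 5,
                            seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (missing(depth) || depth <= 0) stop("`depth` must be > 0", call. = FALSE)
  stopifnot(hp_error_rate >= 0, hp_error_rate <= 1,
            sub_error_rate >= 0, sub_error_rate <= 1)
  structure(list(mean_len = mean_len, len_sd = len_sd, depth = depth,
                 hp_error_rate = hp_error_rate,
                 sub_error_rate = sub_error_rate,
                 hp_min_run = as.integer(hp_min_run), qual_mean = qual_mean,
                 qual_decay = qual_decay, seed = as.integer(seed)),
            class = "read_sim_config")
}

#' Heteroplasmy specification
#'
#' @param sites Data frame with columns `pos` (1-based genome position),
#'   `major`, `minor` (bases) and `fraction` (minor fraction in (0, 0.5]).
#' @param indels Data frame with columns `pos` (insertion after this
#'   position), `inserted` (string) and `fraction`.
#' @return A `heteroplasmy_spec` list.
#' @export
heteroplasmy_spec <- function(sites = NULL, indels = NULL) {
  if (!is.null(sites) && nrow(sites)) {
    stopifnot(all(sites$fraction > 0), all(sites$fraction <= 0.5),
              all(sites$major != sites$minor))
  }
  if (!is.null(indels) && nrow(indels))
    stopifnot(all(indels$fraction > 0), all(indels$fraction <= 0.5))
  structure(list(sites = sites, indels = indels), class = "heteroplasmy_spec")
}

#' Simulate pyrosequencing reads from a circular genome
#'
#' Reads are sampled uniformly over the circle (wrapping across the origin),
#' on either strand. Heteroplasmic minor alleles are injected per covering
#' read with the specified fraction, homopolymer-length miscalls only inside
#' runs of at least `cfg$hp_min_run` bases, then uniform substitution
#' errors. The returned truth table records each read's origin.
#'
#' @param genome An [annotated_genome()] (or DNA string).
#' @param cfg A [read_sim_config()].
#' @param het Optional [heteroplasmy_spec()].
#' @return A `read_set` with elements `id`, `seq`, `qual` (numeric Phred
#'   vectors) and `truth` (data frame: id, start, strand, length).
#' @export
simulate_reads <- function(genome, cfg, het = NULL) {
  stopifnot(inherits(cfg, "read_sim_config"))
  s <- if (inherits(genome, "annotated_genome")) genome$sequence else genome
  if (nchar(s) == 0L) stop("genome is empty", call. = FALSE)
  with_seed(cfg$seed, simulate_reads_impl(s, cfg, het))
}

simulate_reads_impl <- function(s, cfg, het) {
  G <- nchar(s)
  n_reads <- round(cfg$depth * G / cfg$mean_len)
  if (n_reads < 1L) stop("depth too low: zero reads", call. = FALSE)
  if (!is.null(het) && !is.null(het$sites) && nrow(het$sites)) {
    ref_at <- substring(s, het$sites$pos, het$sites$pos)
    if (any(ref_at != het$sites$major))
      stop("heteroplasmy major base disagrees with the genome", call. = FALSE)
  }
  doubled <- paste0(s, s)
  starts <- sample.int(G, n_reads, replace = TRUE)
  lens <- pmax(30L, round(stats::rnorm(n_reads, cfg$mean_len, cfg$len_sd)))
  lens <- pmin(lens, G)
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  seqs <- character(n_reads)
  quals <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    chars <- seq_chars(substr(doubled, starts[i], starts[i] + lens[i] - 1L))
    # heteroplasmic SNVs (defined on the plus strand)
    if (!is.null(het) && !is.null(het$sites) && nrow(het$sites)) {
      off <- ((het$sites$pos - starts[i]) %% G) + 1L
      cov <- off >= 1L & off <= lens[i]
      for (j in which(cov)) {
        if (stats::runif(1) < het$sites$fraction[j])
          chars[off[j]] <- het$sites$minor[j]
      }
    }
    # heteroplasmic insertions
    if (!is.null(het) && !is.null(het$indels) && nrow(het$indels)) {
      off <- ((het$indels$pos - starts[i]) %% G) + 1L
      cov <- off >= 1L & off < lens[i]
      ins_at <- which(cov)
      if (length(ins_at)) {
        for (j in rev(ins_at)) {       # right-to-left keeps offsets valid
          if (stats::runif(1) < het$indels$fraction[j]) {
            chars <- append(chars, seq_chars(het$indels$inserted[j]),
                            after = off[j])
          }
        }
      }
    }
    # homopolymer length miscalls
    if (cfg$hp_error_rate > 0) {
      r <- rle(chars)
      hp_runs <- which(r$lengths >= cfg$hp_min_run)
      if (length(hp_runs)) {
        ends <- cumsum(r$lengths)
        del <- integer(0); ins_pos <- integer(0); ins_base <- character(0)
        for (k in hp_runs) {
          p_err <- min(0.9, cfg$hp_error_rate * (r$lengths[k] - 3L))
          if (stats::runif(1) < p_err) {
            if (stats::runif(1) < 0.5) del <- c(del, ends[k])
            else { ins_pos <- c(ins_pos, ends[k]); ins_base <- c(ins_base, r$values[k]) }
          }
        }
        if (length(del)) chars <- chars[-del]
        if (length(ins_pos)) {
          for (k in order(ins_pos, decreasing = TRUE))
            chars <- append(chars, ins_base[k], after = ins_pos[k])
        }
      }
    }
    # substitution errors
    if (cfg$sub_error_rate > 0) {
      hit <- which(stats::runif(length(chars)) < cfg$sub_error_rate)
      for (p in hit)
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    }
    L <- length(chars)
    q <- cfg$qual_mean - cfg$qual_decay * (seq_len(L) - 1L) / max(1L, L - 1L) +
      stats::rnorm(L, 0, 2)
    q <- pmin(40, pmax(2, q))
    if (strands[i] == "-") {
      seqs[i] <- revcomp(paste(chars, collapse = ""))
      quals[[i]] <- rev(q)
    } else {
      seqs[i] <- paste(chars, collapse = "")
      quals[[i]] <- q
    }
  }
  ids <- sprintf("read%06d", seq_len(n_reads))
  new_read_set(id = ids, seq = seqs, qual = quals,
               truth = data.frame(id = ids, start = starts, strand = strands,
                                  length = lens, stringsAsFactors = FALSE))
}

#' Simulate a polyT-primed cDNA library
#'
#' Reads derive from transcription units (planted operons plus singleton
#' genes): a gene is drawn by abundance, then a read overlapping that gene
#' is sampled from the unit's genomic span, so reads cross gene junctions
#' inside a unit. Genes with a genomic A-run of at least `enrich_min_a`
#' bases within `enrich_window` bp upstream (in transcription orientation)
#' are over-sampled by `enrichment`, reproducing the polyT priming artifact.
#'
#' @param genome An [annotated_genome()] with operons defined.
#' @param expression Named numeric vector: gene -> relative abundance.
#'   Unknown gene names are an error.
#' @param adaptor Adaptor sequence appended to a fraction of reads.
#' @param n_reads Total reads to draw.
#' @param mean_len,len_sd Read length distribution.
#' @param enrich_min_a,enrich_window,enrichment PolyA-track enrichment model.
#' @param adaptor_prob Fraction of reads carrying the adaptor.
#' @param sub_error_rate Per-base substitution rate.
#' @param seed Integer seed; required.
#' @return A `read_set`; its `truth` records the source gene and unit of
#'   every read and the per-gene effective sampling weights.
#' @export
simulate_cdna <- function(genome, expression, adaptor = "", n_reads = 2000L,
                          mean_len = 300, len_sd = 30, enrich_min_a = 15L,
                          enrich_window = 200L, enrichment = 50,
                          adaptor_prob = 0.7, sub_error_rate = 0, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(inherits(genome, "annotated_genome"))
  genes <- unique(genome$annotation$gene)
  unknown <- setdiff(names(expression), genes)
  if (length(unknown))
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  with_seed(seed, simulate_cdna_impl(genome, expression, adaptor, n_reads,
                                     mean_len, len_sd, enrich_min_a,
                                     enrich_window, enrichment, adaptor_prob,
                                     sub_error_rate))
}

simulate_cdna_impl <- function(genome, expression, adaptor, n_reads, mean_len,
                               len_sd, enrich_min_a, enrich_window, enrichment,
                               adaptor_prob, sub_error_rate) {
  ann <- genome$annotation
  s <- genome$sequence
  genes <- unique(ann$gene)
  gspan <- t(vapply(genes, function(g) {
    r <- gene_rows(ann, g)
    c(min(r$start), max(r$end))
  }, integer(2)))
  gstrand <- vapply(genes, function(g) gene_rows(ann, g)$strand[1], character(1))

  # unit membership: operon genes share a unit; others are singletons
  unit_of <- stats::setNames(rep(NA_integer_, length(genes)), genes)
  units <- list()
  for (op in genome$operons) {
    units[[length(units) + 1L]] <- op$genes
    unit_of[op$genes] <- length(units)
  }
  for (g in genes[is.na(unit_of[genes])]) {
    units[[length(units) + 1L]] <- g
    unit_of[g] <- length(units)
  }
  uspan <- t(vapply(units, function(m)
    c(min(gspan[m, 1]), max(gspan[m, 2])), integer(2)))

  # effective per-gene weights: abundance x polyA-track enrichment
  ab <- stats::setNames(rep(0, length(genes)), genes)
  ab[names(expression)] <- expression
  runs <- base_runs(s)
  enriched <- vapply(genes, function(g) {
    i <- match(g, genes)
    if (gstrand[g] == "+") {
      win <- c(max(1L, gspan[i, 1] - enrich_window), gspan[i, 1] - 1L)
      hit <- runs$base == "A" & runs$length >= enrich_min_a &
        runs$start <= win[2] & (runs$start + runs$length - 1L) >= win[1]
    } else {
      win <- c(gspan[i, 2] + 1L, min(nchar(s), gspan[i, 2] + enrich_window))
      hit <- runs$base == "T" & runs$length >= enrich_min_a &
        runs$start <= win[2] & (runs$start + runs$length - 1L) >= win[1]
    }
    any(hit)
  }, logical(1))
  w <- ab * ifelse(enriched, enrichment, 1)
  if (sum(w) <= 0) stop("all gene abundances are zero", call. = FALSE)

  pick <- sample(genes, n_reads, replace = TRUE, prob = w)
  lens <- pmax(40L, round(stats::rnorm(n_reads, mean_len, len_sd)))
  seqs <- character(n_reads); quals <- vector("list", n_reads)
  src_unit <- integer(n_reads)
  for (i in seq_len(n_reads)) {
    g <- pick[i]
    u <- unit_of[[g]]
    gi <- match(g, genes)
    lo <- max(uspan[u, 1], gspan[gi, 1] - lens[i] + 1L)
    hi <- min(uspan[u, 2], gspan[gi, 2])
    st <- if (hi <= lo) lo else sample(lo:hi, 1L)
    en <- min(st + lens[i] - 1L, uspan[u, 2])
    frag <- substr(s, st, en)
    if (gstrand[g] == "-") frag <- revcomp(frag)
    if (sub_error_rate > 0) {
      chars <- seq_chars(frag)
      hit <- which(stats::runif(length(chars)) < sub_error_rate)
      for (p in hit)
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
      frag <- paste(chars, collapse = "")
    }
    if (nzchar(adaptor) && stats::runif(1) < adaptor_prob)
      frag <- paste0(frag, adaptor)
    seqs[i] <- frag
    quals[[i]] <- rep(30, nchar(frag))
    src_unit[i] <- u
  }
  ids <- sprintf("cdna%06d", seq_len(n_reads))
  new_read_set(id = ids, seq = seqs, qual = quals,
               truth = list(reads = data.frame(id = ids, gene = pick,
                                               unit = src_unit,
                                               stringsAsFactors = FALSE),
                            weights = w, units = units,
                            gene_counts = table(factor(pick, levels = genes))))
}
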