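# Intravarietal (heteroplasmic) SNP and indel calling from quality-filtered
# pileups, with four filtering rules: (1) quality-passing depth above the
# minimum (strict), (2) the largest minor genotype above the minimum
# percentage (strict), (3) reads gapped at the locus removed before the
# depth check, and (4) loci overlapping homopolymer runs masked.

#' Positions masked by homopolymer runs
#'
#' @param runs Data frame from [find_homopolymers()] (typically at
#'   `min_len = 5`).
#' @param flank Flanking bases masked on each side of a run (default 1).
#' @param genome_length Circle length for clipping.
#' @return Integer vector of masked positions.
#' @export
homopolymer_mask <- function(runs, flank = 1L, genome_length = NULL) {
  if (is.null(runs) || nrow(runs) == 0L) return(integer(0))
  pos <- unlist(lapply(seq_len(nrow(runs)), function(i)
    (runs$start[i] - flank):(runs$start[i] + runs$length[i] - 1L + flank)))
  pos <- pos[pos >= 1L]
  if (!is.null(genome_length)) pos <- pos[pos <= genome_length]
  unique(sort(pos))
}

#' Call intravarietal SNPs from a pileup
#'
#' A call is emitted iff, at a locus: the quality-passing depth after
#' gap-read removal exceeds `min_depth` (strict); at least two genotypes
#' are observed; the largest minor genotype exceeds `min_minor_pct`
#' percent (strict) of the two reported genotypes; and the locus does not
#' overlap the homopolymer mask. Percentages are computed over the two
#' reported genotypes only. Count ties are resolved to the
#' lexicographically smaller base as major and flagged ambiguous.
#'
#' @param pileup A `pileup` from [build_pileup()].
#' @param genome [annotated_genome()] or DNA string (consensus context).
#' @param min_depth Strict depth threshold (default 50).
#' @param min_minor_pct Strict minor-percentage threshold (default 10).
#' @param hp_mask Integer positions to mask (from [homopolymer_mask()]),
#'   or `NULL` to derive it from the genome at run length >= 5.
#' @param hp_min_run Run length for the derived mask.
#' @param hp_flank Mask flank in bp.
#' @return Data frame of calls: `position`, `major`, `minor`, `major_n`,
#'   `minor_n`, `major_pct`, `minor_pct`, `mutation_class`, `ambiguous`.
#' @export
call_intrasnps <- function(pileup, genome, min_depth = 50L,
                           min_minor_pct = 10, hp_mask = NULL,
                           hp_min_run = 5L, hp_flank = 1L) {
  stopifnot(inherits(pileup, "pileup"))
  s <- if (inherits(genome, "annotated_genome")) genome$sequence else genome
  if (is.null(hp_mask))
    hp_mask <- homopolymer_mask(find_homopolymers(s, hp_min_run),
                                flank = hp_flank, genome_length = nchar(s))
  counts <- pileup$counts
  depth <- pileup$depth_q
  cand <- which(depth > min_depth & rowSums(counts > 0L) >= 2L)
  cand <- setdiff(cand, hp_mask)
  rows <- lapply(cand, function(p) {
    v <- counts[p, ]
    o <- order(-v, names(v))           # ties -> lexicographically smaller
    major <- names(v)[o[1]]; minor <- names(v)[o[2]]
    mn <- v[[o[1]]]; nn <- v[[o[2]]]
    pct_minor <- 100 * nn / (mn + nn)
    if (pct_minor <= min_minor_pct) return(NULL)
    data.frame(position = p, major = major, minor = minor,
               major_n = mn, minor_n = nn,
               major_pct = round_half_up(100 * mn / (mn + nn), 1),
               minor_pct = round_half_up(pct_minor, 1),
               mutation_class = mutation_class(major, minor),
               ambiguous = mn == nn, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(position = integer(0), major = character(0),
                      minor = character(0), major_n = integer(0),
                      minor_n = integer(0), major_pct = numeric(0),
                      minor_pct = numeric(0), mutation_class = character(0),
                      ambiguous = logical(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Transition / transversion classification
#' @param a,b The two bases.
#' @return "transition" for purine-purine or pyrimidine-pyrimidine pairs,
#'   else "transversion".
#' @export
mutation_class <- function(a, b) {
  pur <- c("A", "G")
  ifelse((a %in% pur) == (b %in% pur), "transition", "transversion")
}

#' Annotate SNP calls with their codon context
#'
#' For calls inside a CDS the codon is reconstructed on the coding strand
#' at the CDS offset; the effect is synonymous (same amino acid), nonsense
#' (minor codon is a stop) or nonsynonymous. Codons are rendered with the
#' variant position in upper case (e.g. `acC`/`acT`). A call inside two
#' overlapping genes yields one row per gene.
#'
#' @param calls Data frame from [call_intrasnps()].
#' @param annotation Annotation data frame.
#' @param genome DNA string or [annotated_genome()].
#' @return The calls with columns `context`, `gene`, `cds_pos`, `strand`,
#'   `major_codon`, `minor_codon`, `major_aa`, `minor_aa`, `effect` added.
#' @export
classify_snps <- function(calls, annotation, genome) {
  s <- if (inherits(genome, "annotated_genome")) genome$sequence else genome
  if (is.null(annotation) && inherits(genome, "annotated_genome"))
    annotation <- genome$annotation
  annotation <- validate_annotation(annotation)
  gc11 <- plastid_code()
  out <- lapply(seq_len(nrow(calls)), function(i) {
    call <- calls[i, , drop = FALSE]
    p <- call$position
    hits <- annotation[annotation$start <= p & annotation$end >= p &
                         !annotation$pseudo & annotation$type == "CDS", ,
                       drop = FALSE]
    if (nrow(hits) == 0L) {
      spans_genes <- unique(annotation$gene[
        vapply(unique(annotation$gene), function(g) {
          r <- annotation[annotation$gene == g, , drop = FALSE]
          min(r$start) <= p && max(r$end) >= p
        }, logical(1))])
      call$context <- if (length(spans_genes))
        sprintf("intron(%s)", spans_genes[1]) else "intergenic"
      call$gene <- NA_character_; call$cds_pos <- NA_integer_
      call$strand <- NA_character_
      call$major_codon <- NA_character_; call$minor_codon <- NA_character_
      call$major_aa <- NA_character_; call$minor_aa <- NA_character_
      call$effect <- NA_character_
      return(call)
    }
    do.call(rbind, lapply(unique(hits$gene), function(g) {
      rows <- annotation[annotation$gene == g & annotation$type == "CDS", ,
                         drop = FALSE]
      rows <- rows[order(rows$rank), , drop = FALSE]
      cds_pos <- 0L
      for (j in seq_len(nrow(rows))) {
        w <- rows$end[j] - rows$start[j] + 1L
        if (p >= rows$start[j] && p <= rows$end[j]) {
          off <- if (rows$strand[j] == "+") p - rows$start[j] + 1L else
            rows$end[j] - p + 1L
          cds_pos <- cds_pos + off
          break
        }
        cds_pos <- cds_pos + w
      }
      cds <- extract_cds(s, rows)[[1]]$sequence
      strand <- rows$strand[1]
      major_c <- if (strand == "+") call$major else complement_dna(call$major)
      minor_c <- if (strand == "+") call$minor else complement_dna(call$minor)
      ci <- (cds_pos - 1L) %/% 3L
      within <- cds_pos - 3L * ci
      codon <- substr(cds, 3L * ci + 1L, 3L * ci + 3L)
      maj_cod <- codon; substr(maj_cod, within, within) <- major_c
      min_cod <- codon; substr(min_cod, within, within) <- minor_c
      render <- function(cod) {
        r <- tolower(cod)
        substr(r, within, within) <- toupper(substr(cod, within, within))
        r
      }
      maj_aa <- unname(gc11[maj_cod]); min_aa <- unname(gc11[min_cod])
      call2 <- call
      call2$context <- "CDS"
      call2$gene <- g
      call2$cds_pos <- cds_pos
      call2$strand <- strand
      call2$major_codon <- render(maj_cod)
      call2$minor_codon <- render(min_cod)
      call2$major_aa <- maj_aa
      call2$minor_aa <- min_aa
      call2$effect <- if (min_aa == "*") "nonsense"
        else if (maj_aa == min_aa) "synonymous" else "nonsynonymous"
      call2
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call intravarietal insertions
#'
#' At loci where an identical insertion string is seen in at least
#' `min_reads` reads, the insertion is reported with carrier and
#' non-carrier counts over the quality-passing covering reads; `minor` is
#' set when fewer reads carry it than not.
#'
#' @param pileup A `pileup` (carries the insertion records).
#' @param min_reads Minimum carrier reads (default 2).
#' @return Data frame: `pos`, `inserted`, `with_n`, `without_n`,
#'   `fraction`, `minor`.
#' @export
call_intra_indels <- function(pileup, min_reads = 2L) {
  stopifnot(inherits(pileup, "pileup"))
  ins <- pileup$insertions
  if (nrow(ins) == 0L)
    return(data.frame(pos = integer(0), inserted = character(0),
                      with_n = integer(0), without_n = integer(0),
                      fraction = numeric(0), minor = logical(0),
                      stringsAsFactors = FALSE))
  key <- paste(ins$pos, ins$inserted)
  tt <- table(key)
  keep <- names(tt)[tt >= min_reads]
  rows <- lapply(keep, function(k) {
    sel <- ins[key == k, , drop = FALSE]
    p <- sel$pos[1]
    with_n <- nrow(sel)
    depth <- pileup$depth_q[p]
    without_n <- max(0L, depth - with_n)
    data.frame(pos = p, inserted = sel$inserted[1], with_n = with_n,
               without_n = without_n,
               fraction = with_n / max(1L, with_n + without_n),
               minor = with_n < without_n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare major/minor genotypes against an orthologous CDS set
#'
#' Each CDS call is mapped through a global pairwise alignment of the two
#' orthologous coding sequences; the comparator's base at the aligned
#' position is reported as a swap (equals the minor genotype), no swap
#' (equals the major) or a third state. Ortholog pairs aligning below 60%
#' identity are skipped with a warning.
#'
#' @param calls Classified calls (from [classify_snps()], CDS rows).
#' @param own_cds List of `cds_record`s of this genome.
#' @param other_cds Named character vector of orthologous CDS (by gene).
#' @return Data frame: `position`, `gene`, `cds_pos`, `comparator_base`,
#'   `status` (swap / no_swap / third / unaligned).
#' @export
compare_genotypes <- function(calls, own_cds, other_cds) {
  cds_by_gene <- stats::setNames(
    lapply(own_cds, function(x) x$sequence),
    vapply(own_cds, function(x) x$gene, character(1)))
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    call <- calls[i, , drop = FALSE]
    if (is.na(call$gene) || !call$gene %in% names(other_cds)) return(NULL)
    own <- cds_by_gene[[call$gene]]
    oth <- other_cds[[call$gene]]
    pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(own),
                                        Biostrings::DNAString(oth),
                                        type = "global", substitutionMatrix = dna_submat(),
                                        gapOpening = 4, gapExtension = 2)
    p <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
    q <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
    ident <- sum(p == q & p != "-") / max(nchar(own), nchar(oth))
    if (ident < 0.6) {
      warning(sprintf("ortholog pair for %s below 60%% identity; skipped",
                      call$gene))
      return(NULL)
    }
    own_pos <- cumsum(p != "-")
    col <- match(call$cds_pos, own_pos)
    cb <- if (is.na(col)) NA_character_ else q[col]
    # genotypes are reported in genome (plus-strand) bases; the CDS is in
    # coding orientation
    major_c <- if (call$strand == "+") call$major else
      complement_dna(call$major)
    minor_c <- if (call$strand == "+") call$minor else
      complement_dna(call$minor)
    status <- if (is.na(cb) || cb == "-") "unaligned"
      else if (cb == minor_c) "swap"
      else if (cb == major_c) "no_swap" else "third"
    data.frame(position = call$position, gene = call$gene,
               cds_pos = call$cds_pos, comparator_base = cb,
               status = status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(position = integer(0), gene = character(0),
                      cds_pos = integer(0), comparator_base = character(0),
                      status = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
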