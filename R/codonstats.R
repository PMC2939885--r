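# Codon usage statistics: CDS extraction (introns, strand, trans-splicing),
# codon counting under the plastid/bacterial genetic code (table 11), RSCU,
# amino-acid and positional base composition, and a start-codon audit.

plastid_code <- function() Biostrings::getGeneticCode("11")

# Table-1-style rendering: DNA codon -> RNA codon
codon_rna <- function(x) chartr("T", "U", x)
codon_dna <- function(x) chartr("U", "T", x)

all_codons <- function() {
  b <- c("T", "C", "A", "G")
  eg <- expand.grid(p3 = b, p2 = b, p1 = b, stringsAsFactors = FALSE)
  paste0(eg$p1, eg$p2, eg$p3)
}

#' Extract spliced coding sequences
#'
#' Exons are concatenated in `rank` order (which for trans-spliced genes
#' need not be genomic order and may mix strands), each part
#' reverse-complemented on the minus strand. Pseudogenes are excluded.
#' Records whose spliced length is not divisible by 3 are flagged, not
#' dropped.
#'
#' @param genome DNA string or [annotated_genome()].
#' @param annotation Annotation data frame (defaults to the genome's own).
#' @return List of `cds_record`s: `gene`, `sequence`, `strand`, `parts`
#'   (the exon rows), `in_frame` (length divisible by 3).
#' @export
extract_cds <- function(genome, annotation = NULL) {
  s <- if (inherits(genome, "annotated_genome")) genome$sequence else genome
  if (is.null(annotation) && inherits(genome, "annotated_genome"))
    annotation <- genome$annotation
  annotation <- validate_annotation(annotation, nchar(s))
  annotation <- annotation[annotation$type %in% c("CDS", "gene"), , drop = FALSE]
  genes <- unique(annotation$gene[!annotation$pseudo])
  lapply(genes, function(g) {
    rows <- annotation[annotation$gene == g & !annotation$pseudo, , drop = FALSE]
    rows <- rows[order(rows$rank), , drop = FALSE]
    parts <- vapply(seq_len(nrow(rows)), function(i) {
      p <- substr(s, rows$start[i], rows$end[i])
      if (rows$strand[i] == "-") revcomp(p) else p
    }, character(1))
    spliced <- paste(parts, collapse = "")
    structure(list(gene = g, sequence = spliced, strand = rows$strand[1],
                   parts = rows, in_frame = nchar(spliced) %% 3L == 0L),
              class = "cds_record")
  })
}

#' Count codons over a CDS set
#'
#' Stop codons are counted; codons containing ambiguity characters are
#' skipped and tallied separately.
#'
#' @param cds_list List of `cds_record`s (or plain character CDS strings).
#' @param code_id NCBI genetic code id (default "11", plastid/bacterial).
#' @return A `codon_table`: named integer vector of the 64 codon counts
#'   (DNA alphabet), with attributes `total`, `ambiguous`, `code_id`.
#' @export
count_codons <- function(cds_list, code_id = "11") {
  seqs <- vapply(cds_list, function(x)
    if (inherits(x, "cds_record")) x$sequence else as.character(x),
    character(1))
  bad <- which(nchar(seqs) %% 3L != 0L)
  if (length(bad))
    warning(sprintf("%d CDS record(s) not divisible by 3; trailing bases dropped",
                    length(bad)))
  counts <- stats::setNames(integer(64), all_codons())
  ambiguous <- 0L
  for (s in seqs) {
    n3 <- nchar(s) %/% 3L
    if (n3 == 0L) next
    cods <- substring(s, 3L * seq_len(n3) - 2L, 3L * seq_len(n3))
    known <- cods %in% names(counts)
    ambiguous <- ambiguous + sum(!known)
    t <- table(cods[known])
    counts[names(t)] <- counts[names(t)] + as.integer(t)
  }
  codon_table(counts, code_id = code_id, ambiguous = ambiguous)
}

#' Construct a codon table from counts
#'
#' @param counts Named numeric vector; names are codons in DNA or RNA
#'   alphabet, missing codons count 0.
#' @param code_id Genetic code id.
#' @param ambiguous Ambiguous-codon tally.
#' @return A `codon_table`.
#' @export
codon_table <- function(counts, code_id = "11", ambiguous = 0L) {
  full <- stats::setNames(integer(64), all_codons())
  nm <- codon_dna(toupper(names(counts)))
  if (any(!nm %in% names(full)))
    stop("unknown codon(s): ", paste(nm[!nm %in% names(full)], collapse = ", "),
         call. = FALSE)
  full[nm] <- as.integer(counts)
  structure(full, total = sum(full), ambiguous = as.integer(ambiguous),
            code_id = code_id, class = "codon_table")
}

#' @export
print.codon_table <- function(x, ...) {
  cat(sprintf("<codon_table> %d codons (%d ambiguous skipped), code %s\n",
              attr(x, "total"), attr(x, "ambiguous"), attr(x, "code_id")))
  invisible(x)
}

# synonymous families of sense codons: list aa -> codon vector
codon_families <- function(code_id = "11") {
  gc <- Biostrings::getGeneticCode(code_id)
  sense <- gc[gc != "*"]
  split(names(sense), unname(sense))
}

#' Relative synonymous codon usage
#'
#' For sense codon `c` of amino acid `a` with family size `k`:
#' `RSCU = n_c * k / sum(n_c' for c' in a)`. Stop codons are reported as 0
#' by convention; a family with zero total yields 0 for all members.
#' Single-codon families (Met, Trp in code 11) give RSCU 1 when present.
#'
#' @param table A `codon_table`.
#' @param digits Rounding (half-up) applied to the result; `NULL` for
#'   unrounded values.
#' @return Named numeric vector over all 64 codons (DNA alphabet).
#' @export
rscu <- function(table, digits = 2) {
  stopifnot(inherits(table, "codon_table"))
  if (attr(table, "total") <= 0) stop("empty codon table", call. = FALSE)
  fams <- codon_families(attr(table, "code_id"))
  out <- stats::setNames(numeric(64), names(table))
  for (f in fams) {
    tot <- sum(table[f])
    if (tot > 0) out[f] <- as.numeric(table[f]) * length(f) / tot
  }
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

#' Amino-acid composition
#'
#' Percentages use the full codon total (stop codons included in the
#' denominator).
#'
#' @param table A `codon_table`.
#' @return Data frame (`aa`, `count`, `percent`), stops under `*`.
#' @export
aa_composition <- function(table) {
  stopifnot(inherits(table, "codon_table"))
  total <- attr(table, "total")
  if (total <= 0) stop("empty codon table", call. = FALSE)
  gc <- Biostrings::getGeneticCode(attr(table, "code_id"))
  aa <- unname(gc[names(table)])
  agg <- tapply(as.integer(table), aa, sum)
  data.frame(aa = names(agg), count = as.integer(agg),
             percent = round_half_up(100 * as.integer(agg) / total, 2),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' A+T fraction at each codon position
#'
#' @param table A `codon_table`.
#' @param digits Rounding of the percentages.
#' @return Numeric vector of length 3: percent A+T (A+U) at codon
#'   positions 1..3, weighted by codon counts.
#' @export
positional_base_composition <- function(table, digits = 1) {
  stopifnot(inherits(table, "codon_table"))
  total <- attr(table, "total")
  if (total <= 0) stop("empty codon table", call. = FALSE)
  vapply(1:3, function(p) {
    b <- substr(names(table), p, p)
    round_half_up(100 * sum(table[b %in% c("A", "T")]) / total, digits)
  }, numeric(1))
}

#' Audit start codons of a CDS set
#'
#' Every CDS's first codon is reported and flagged when not ATG. With the
#' genome available, the upstream sequence (in coding orientation) is
#' scanned for in-frame stop codons within `upstream_codons` codons; a hit
#' is reported as an ambiguity note, flagging genes whose start assignment
#' is questionable.
#'
#' @param cds_list List of `cds_record`s.
#' @param genome Optional genome (DNA string or [annotated_genome()]) for
#'   the upstream scan.
#' @param upstream_codons Codons scanned upstream of the start.
#' @return Data frame (`gene`, `start_codon`, `canonical`,
#'   `upstream_stop_at` - offset in bp of the nearest upstream in-frame
#'   stop, NA when none or no genome, `note`).
#' @export
audit_start_codons <- function(cds_list, genome = NULL,
                               upstream_codons = 10L) {
  s <- if (inherits(genome, "annotated_genome")) genome$sequence else genome
  rows <- lapply(cds_list, function(r) {
    start <- substr(r$sequence, 1, 3)
    canonical <- identical(start, "ATG")
    up_at <- NA_integer_
    if (!is.null(s)) {
      first <- r$parts[order(r$parts$rank), , drop = FALSE][1, ]
      W <- 3L * upstream_codons
      if (first$strand == "+") {
        from <- max(1L, first$start - W)
        up <- substr(s, from, first$start - 1L)
      } else {
        to <- min(nchar(s), first$end + W)
        up <- revcomp(substr(s, first$end + 1L, to))
      }
      L <- nchar(up)
      if (L >= 3L) {
        n3 <- L %/% 3L
        offs <- L - 3L * seq_len(n3) + 1L     # in-frame, nearest first
        cods <- substring(up, offs, offs + 2L)
        stop_hit <- which(cods %in% c("TAA", "TAG", "TGA"))
        if (length(stop_hit)) up_at <- 3L * stop_hit[1]
      }
    }
    note <- if (!canonical && !is.na(up_at))
      sprintf("non-canonical start %s with in-frame stop %d bp upstream",
              start, up_at)
    else if (!canonical) sprintf("non-canonical start %s", start)
    else if (!is.na(up_at))
      sprintf("in-frame stop %d bp upstream of the start", up_at)
    else ""
    data.frame(gene = r$gene, start_codon = start, canonical = canonical,
               upstream_stop_at = up_at, note = note, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
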