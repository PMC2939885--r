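# The central container: a circular genome sequence plus its gene models,
# quadripartite layout and (for simulated genomes) planted ground truth.

#' Construct an annotated (chloroplast) genome
#'
#' @param sequence Single DNA string; the circle is stored linearized with
#'   its origin at the IRa -> LSC junction (LSC first).
#' @param annotation Data frame of gene parts, one row per exon, with
#'   columns `gene`, `type` (CDS/tRNA/rRNA), `start`, `end` (1-based
#'   inclusive), `strand` (+/-), `rank` (exon order within the spliced
#'   product), `pseudo` (logical).
#' @param layout Optional quadripartite layout (see
#'   [detect_quadripartite()]), as recorded by the simulator.
#' @param operons Optional list of character vectors: ordered gene names of
#'   each planted polycistronic unit.
#' @param truth Optional list of planted-feature tables (homopolymers,
#'   repeats, small inversions, CDS sequences) kept for round-trip tests.
#' @param circular Logical; chloroplast genomes are circular.
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(sequence, annotation = empty_annotation(),
                             layout = NULL, operons = list(), truth = list(),
                             circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("genome sequence contains non-ACGTN characters", call. = FALSE)
  annotation <- validate_annotation(annotation, nchar(sequence))
  structure(list(sequence = sequence, length = nchar(sequence),
                 annotation = annotation, layout = layout, operons = operons,
                 truth = truth, circular = circular),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s bp (%s), %d gene(s), %d operon(s)\n",
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear",
              length(unique(x$annotation$gene)), length(x$operons)))
  if (!is.null(x$layout) && isTRUE(x$layout$found))
    cat(sprintf("  LSC %d / IRb %d / SSC %d / IRa %d bp\n",
                x$layout$lsc_len, x$layout$ir_len, x$layout$ssc_len,
                x$layout$ir_len))
  invisible(x)
}

#' @rdname annotated_genome
#' @export
empty_annotation <- function() {
  data.frame(gene = character(0), type = character(0), start = integer(0),
             end = integer(0), strand = character(0), rank = integer(0),
             pseudo = logical(0), stringsAsFactors = FALSE)
}

validate_annotation <- function(ann, genome_len = NULL) {
  need <- c("gene", "type", "start", "end", "strand", "rank", "pseudo")
  if (is.null(ann)) ann <- empty_annotation()
  miss <- setdiff(need, names(ann))
  if ("rank" %in% miss) ann$rank <- 1L
  if ("pseudo" %in% miss) ann$pseudo <- FALSE
  if ("type" %in% miss) ann$type <- "CDS"
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(ann)) {
    ann$start <- as.integer(ann$start)
    ann$end <- as.integer(ann$end)
    ann$rank <- as.integer(ann$rank)
    if (any(ann$end < ann$start))
      stop("annotation has end < start", call. = FALSE)
    if (!all(ann$strand %in% c("+", "-")))
      stop("annotation strand must be '+' or '-'", call. = FALSE)
    if (!is.null(genome_len) && any(ann$start < 1L | ann$end > genome_len)) {
      bad <- ann$gene[ann$start < 1L | ann$end > genome_len][1]
      stop(sprintf("exon of gene '%s' lies outside the genome", bad),
           call. = FALSE)
    }
  }
  ann[need]
}

# the spliced span (all exon rows) of one gene
gene_rows <- function(ann, gene) ann[ann$gene == gene, , drop = FALSE]

#' Classify a genomic interval against the annotation
#'
#' Mirrors the location labels of repeat tables: an interval overlapping an
#' exon is labelled with the gene name; one inside a gene span but not in an
#' exon is `intron(gene)`; otherwise `IGS(left - right)` with the flanking
#' gene names.
#'
#' @param ann Annotation data frame.
#' @param start,end 1-based inclusive interval.
#' @param genome_len Genome length (for the flanking-gene search on the
#'   circle).
#' @return A single character label.
#' @export
locate_interval <- function(ann, start, end, genome_len = NA_integer_) {
  if (nrow(ann) == 0L) return("IGS(? - ?)")
  hit <- ann$start <= end & ann$end >= start
  if (any(hit)) return(unique(ann$gene[hit])[1])
  gs <- vapply(unique(ann$gene), function(g) min(ann$start[ann$gene == g]),
               integer(1))
  ge <- vapply(unique(ann$gene), function(g) max(ann$end[ann$gene == g]),
               integer(1))
  within <- gs <= start & ge >= end
  if (any(within)) return(sprintf("intron(%s)", names(gs)[within][1]))
  lefts <- ge[ge < start]
  rights <- gs[gs > end]
  left <- if (length(lefts)) names(lefts)[which.max(lefts)] else
    names(ge)[which.max(ge)]        # wraps the origin
  right <- if (length(rights)) names(rights)[which.min(rights)] else
    names(gs)[which.min(gs)]
  sprintf("IGS(%s - %s)", left, right)
}

# ---- standard-format I/O (Biostrings-backed) --------------------------------

#' Read / write genome FASTA
#' @param x An `annotated_genome` (or DNA string) to write.
#' @param file Path.
#' @param name Sequence name used in the FASTA header.
#' @return `read_genome_fasta` returns the first sequence as a string.
#' @export
write_genome_fasta <- function(x, file, name = "genome") {
  s <- if (inherits(x, "annotated_genome")) x$sequence else x
  ss <- Biostrings::DNAStringSet(s)
  names(ss) <- name
  Biostrings::writeXStringSet(ss, filepath = file)
  invisible(file)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(file) {
  ss <- Biostrings::readDNAStringSet(file)
  as.character(ss[[1]])
}

#' Write / read the annotation as GFF3
#'
#' One feature per exon part (rtracklayer-backed); `type` is the feature
#' type, attributes carry `ID=` (gene name), `rank=` and `pseudo=`.
#' Coordinates are 1-based inclusive, as GFF3 requires.
#'
#' @param ann Annotation data frame.
#' @param file Path.
#' @param seqid Sequence name used in the GFF3.
#' @export
write_annotation_gff3 <- function(ann, file, seqid = "genome") {
  ann <- validate_annotation(ann)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(seqid, nrow(ann)),
    ranges = IRanges::IRanges(start = ann$start, end = ann$end),
    strand = ann$strand)
  S4Vectors::mcols(gr)$source <- "plastidkit"
  S4Vectors::mcols(gr)$type <- ann$type
  S4Vectors::mcols(gr)$ID <- ann$gene
  S4Vectors::mcols(gr)$rank <- ann$rank
  S4Vectors::mcols(gr)$pseudo <- ifelse(ann$pseudo, "true", "false")
  # CDS phase: offset of the first complete codon within each exon part
  phase <- integer(nrow(ann))
  for (g in unique(ann$gene)) {
    idx <- which(ann$gene == g)
    idx <- idx[order(ann$rank[idx])]
    cum <- 0L
    for (i in idx) {
      phase[i] <- (3L - cum %% 3L) %% 3L
      cum <- cum + ann$end[i] - ann$start[i] + 1L
    }
  }
  S4Vectors::mcols(gr)$phase <- ifelse(ann$type == "CDS", phase, NA_integer_)
  rtracklayer::export(gr, file, format = "gff3")
  invisible(file)
}

#' @rdname write_annotation_gff3
#' @export
read_annotation_gff3 <- function(file) {
  gr <- rtracklayer::import(file, format = "gff3")
  if (!length(gr)) return(empty_annotation())
  mc <- S4Vectors::mcols(gr)
  getcol <- function(nm, default) {
    if (nm %in% names(mc)) as.vector(mc[[nm]]) else
      rep(default, length(gr))
  }
  rank <- suppressWarnings(as.integer(getcol("rank", 1L)))
  rank[is.na(rank)] <- 1L
  out <- data.frame(
    gene = as.character(getcol("ID", NA_character_)),
    type = as.character(getcol("type", "CDS")),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    rank = rank,
    pseudo = tolower(as.character(getcol("pseudo", "false"))) == "true",
    stringsAsFactors = FALSE)
  validate_annotation(out)
}

#' Write / read FASTQ read sets
#'
#' @param reads A `read_set` (see [simulate_reads()]) or a character vector
#'   of sequences plus a list of numeric Phred qualities.
#' @param file Path.
#' @export
write_fastq <- function(reads, file) {
  seqs <- reads$seq
  quals <- reads$qual
  ids <- reads$id
  q <- Biostrings::PhredQuality(vapply(quals, function(v)
    rawToChar(as.raw(pmin(93, pmax(0, round(v))) + 33L)), character(1)))
  x <- Biostrings::QualityScaledDNAStringSet(Biostrings::DNAStringSet(seqs), q)
  names(x) <- ids
  Biostrings::writeQualityScaledXStringSet(x, filepath = file)
  invisible(file)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(file) {
  # metadata-column note from Biostrings is expected: FASTQ carries none
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(file))
  qual <- lapply(as.character(Biostrings::quality(x)), function(s)
    as.numeric(charToRaw(s)) - 33)
  new_read_set(id = names(x), seq = as.character(x), qual = qual,
               truth = NULL)
}

new_read_set <- function(id, seq, qual, truth = NULL) {
  structure(list(id = id, seq = unname(seq), qual = unname(qual),
                 truth = truth),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads, mean length %.0f bp\n",
              length(x$seq), mean(nchar(x$seq))))
  invisible(x)
}

#' @export
length.read_set <- function(x) length(x$seq)
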