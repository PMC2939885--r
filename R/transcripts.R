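# cDNA mapping, poly/monocistronic transcription-unit assignment, the
# per-tissue expression matrix, and detection of genomic polyA-like tracks
# that bias polyT-primed libraries.

#' Map cDNA reads and tally per-gene support
#'
#' Reads are adaptor-trimmed, then aligned to the genome on either strand.
#' Per gene: the supporting read count (reads overlapping its exons at
#' `min_identity` or better) and the percent of its exonic length covered
#' by at least one read. A gene is detected iff coverage exceeds
#' `min_cov_pct` percent (strict) and identity is at least `min_identity`.
#'
#' @param reads A `read_set` (cDNA) or character vector.
#' @param genome An [annotated_genome()].
#' @param adaptor Adaptor sequence to trim (may be "").
#' @param min_identity Identity threshold (default 0.99).
#' @param min_cov_pct Coverage threshold in percent, strict (default 80).
#' @return A list: `alignments` (an `alignment_set`), `tally` data frame
#'   (`gene`, `strand`, `reads`, `coverage`, `detected`).
#' @export
map_cdna <- function(reads, genome, adaptor = "", min_identity = 0.99,
                     min_cov_pct = 80) {
  stopifnot(inherits(genome, "annotated_genome"))
  rs <- as_read_set(reads)
  if (nzchar(adaptor)) {
    rs <- trim_adaptor(rs, adaptor)
  }
  aln <- map_reads(rs, genome, min_identity = min_identity)
  tab <- aln$table
  ann <- genome$annotation
  genes <- unique(ann$gene)
  G <- genome$length
  # read intervals on the genome
  ok <- which(tab$mapped & tab$identity >= min_identity)
  starts <- tab$ref_start[ok]
  lens <- vapply(ok, function(i)
    sum(seq_chars(aln$ref_aln[[i]]) != "-"), integer(1))
  ends <- starts + lens - 1L           # may exceed G (wrap)
  rows <- lapply(genes, function(g) {
    gr <- ann[ann$gene == g, , drop = FALSE]
    exon_len <- sum(gr$end - gr$start + 1L)
    covered <- logical(exon_len)
    nreads <- 0L
    off <- 0L
    hit_read <- rep(FALSE, length(ok))
    for (j in seq_len(nrow(gr))) {
      w <- gr$end[j] - gr$start[j] + 1L
      ov_s <- pmax(starts, gr$start[j])
      ov_e <- pmin(ends, gr$end[j])
      hit <- ov_s <= ov_e
      hit_read <- hit_read | hit
      for (r in which(hit))
        covered[(off + ov_s[r] - gr$start[j] + 1L):(off + ov_e[r] - gr$start[j] + 1L)] <- TRUE
      off <- off + w
    }
    cov_pct <- 100 * sum(covered) / exon_len
    data.frame(gene = g, strand = gr$strand[1], reads = sum(hit_read),
               coverage = round_half_up(cov_pct, 1),
               detected = cov_pct > min_cov_pct & sum(hit_read) > 0L,
               stringsAsFactors = FALSE)
  })
  list(alignments = aln, tally = do.call(rbind, rows))
}

# remove the adaptor (and anything after it) from read 3' ends; also strip
# a leading adaptor remnant
trim_adaptor <- function(rs, adaptor, min_match = 10L) {
  probe <- substr(adaptor, 1L, min(nchar(adaptor), 20L))
  seqs <- rs$seq
  quals <- rs$qual
  for (i in seq_along(seqs)) {
    hit <- regexpr(probe, seqs[i], fixed = TRUE)
    if (hit > 0) {
      seqs[i] <- substr(seqs[i], 1L, hit - 1L)
      if (!is.null(quals)) quals[[i]] <- quals[[i]][seq_len(hit - 1L)]
    }
  }
  keep <- nchar(seqs) >= 30L
  new_read_set(rs$id[keep], seqs[keep],
               if (!is.null(quals)) quals[keep] else NULL, truth = rs$truth)
}

#' Assign poly- and monocistronic transcription units
#'
#' Mapped reads are assembled into transcript contigs per strand (interval
#' merge with at least `min_overlap` bp shared); a contig gap lying wholly
#' inside an annotated intron does not split a unit. Genes whose exons are
#' covered by one contig on one strand form one unit, ordered in
#' transcription direction; a unit is polycistronic iff it holds two or
#' more genes.
#'
#' @param alignments An `alignment_set` of cDNA reads (strand-resolved).
#' @param annotation Annotation data frame.
#' @param min_overlap Minimum read overlap to merge (default 40 bp).
#' @param min_gene_cov Fraction of a gene's exonic length a contig must
#'   cover to claim the gene (default 0.8, strict).
#' @return List of `transcription_unit`s: `genes` (transcription order),
#'   `strand`, `kind`, `span`.
#' @export
assign_transcription_units <- function(alignments, annotation,
                                       min_overlap = 40L,
                                       min_gene_cov = 0.8) {
  annotation <- validate_annotation(annotation)
  tab <- alignments$table
  ok <- which(tab$mapped)
  if (!length(ok)) return(list())
  starts <- tab$ref_start[ok]
  lens <- vapply(ok, function(i)
    sum(seq_chars(alignments$ref_aln[[i]]) != "-"), integer(1))
  ends <- starts + lens - 1L
  strands <- tab$strand[ok]
  # annotated introns: gaps between consecutive exons of one gene
  introns <- do.call(rbind, lapply(unique(annotation$gene), function(g) {
    r <- annotation[annotation$gene == g, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) < 2L) return(NULL)
    data.frame(start = r$end[-nrow(r)] + 1L, end = r$start[-1] - 1L)
  }))
  units <- list()
  for (std in c("+", "-")) {
    sel <- strands == std
    if (!any(sel)) next
    iv <- data.frame(start = starts[sel], end = ends[sel])
    iv <- iv[order(iv$start), , drop = FALSE]
    # merge with required overlap
    cs <- iv$start[1]; ce <- iv$end[1]
    contigs <- NULL
    flush <- function(s, e) rbind(contigs, data.frame(start = s, end = e))
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv$start[i] <= ce - min_overlap + 1L) {
        ce <- max(ce, iv$end[i])
      } else {
        contigs <- flush(cs, ce)
        cs <- iv$start[i]; ce <- iv$end[i]
      }
    }
    contigs <- flush(cs, ce)
    # bridge contig gaps that lie wholly inside an annotated intron
    if (!is.null(introns) && nrow(contigs) > 1L) {
      i <- 1L
      while (i < nrow(contigs)) {
        gap_s <- contigs$end[i] + 1L; gap_e <- contigs$start[i + 1L] - 1L
        if (gap_s <= gap_e &&
            any(introns$start <= gap_s & introns$end >= gap_e)) {
          contigs$end[i] <- contigs$end[i + 1L]
          contigs <- contigs[-(i + 1L), , drop = FALSE]
        } else i <- i + 1L
      }
    }
    # claim genes per contig
    genes <- unique(annotation$gene[annotation$strand == std])
    for (ci in seq_len(nrow(contigs))) {
      claimed <- character(0)
      for (g in genes) {
        gr <- annotation[annotation$gene == g, , drop = FALSE]
        exon_len <- sum(gr$end - gr$start + 1L)
        cov <- sum(pmax(0L, pmin(gr$end, contigs$end[ci]) -
                          pmax(gr$start, contigs$start[ci]) + 1L))
        if (cov / exon_len > min_gene_cov) claimed <- c(claimed, g)
      }
      if (!length(claimed)) next
      gs <- vapply(claimed, function(g)
        min(annotation$start[annotation$gene == g]), integer(1))
      ordg <- claimed[order(gs, decreasing = (std == "-"))]
      units[[length(units) + 1L]] <- structure(
        list(genes = ordg, strand = std,
             kind = if (length(ordg) >= 2L) "polycistronic" else
               "monocistronic",
             span = c(contigs$start[ci], contigs$end[ci])),
        class = "transcription_unit")
    }
  }
  units
}

#' @export
print.transcription_unit <- function(x, ...) {
  cat(sprintf("<transcription_unit> %s (%s, %s)\n",
              paste(x$genes, collapse = "-"), x$strand, x$kind))
  invisible(x)
}

#' Per-tissue expression matrix
#'
#' @param tallies Named list: tissue -> tally data frame from [map_cdna()].
#' @param tissues Tissue order for the columns (defaults to the list
#'   names).
#' @return Data frame: `gene`, `strand`, then per tissue `<t>_reads` and
#'   `<t>_coverage`.
#' @export
expression_table <- function(tallies, tissues = names(tallies)) {
  if (!length(tissues)) stop("at least one tissue required", call. = FALSE)
  base <- tallies[[tissues[1]]][, c("gene", "strand")]
  for (t in tissues) {
    tt <- tallies[[t]]
    m <- match(base$gene, tt$gene)
    base[[paste0(t, "_reads")]] <- tt$reads[m]
    base[[paste0(t, "_coverage")]] <- tt$coverage[m]
  }
  base
}

#' Write / read the expression matrix in the published table style
#'
#' Cells are rendered `reads(coverage)`, genes with zero reads as "-".
#' The writer and parser round-trip bit-identically.
#'
#' @param tab Data frame from [expression_table()] (or parsed back).
#' @param file Path.
#' @param tissues Tissue names (inferred from columns when `NULL`).
#' @export
write_expression_tsv <- function(tab, file, tissues = NULL) {
  if (is.null(tissues))
    tissues <- sub("_reads$", "", grep("_reads$", names(tab), value = TRUE))
  out <- data.frame(gene = tab$gene, strand = tab$strand,
                    stringsAsFactors = FALSE)
  for (t in tissues) {
    r <- tab[[paste0(t, "_reads")]]
    cv <- tab[[paste0(t, "_coverage")]]
    out[[t]] <- ifelse(is.na(r) | r == 0L, "-",
                       sprintf("%d(%s)", r, format_num(cv)))
  }
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

format_num <- function(x) {
  ifelse(x == round(x), sprintf("%d", as.integer(round(x))),
         sub("0+$", "", sprintf("%.1f", x)))
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(file) {
  raw <- utils::read.table(file, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  tissues <- setdiff(names(raw), c("gene", "strand"))
  out <- raw[, c("gene", "strand")]
  for (t in tissues) {
    cell <- raw[[t]]
    m <- regmatches(cell, regexec("^([0-9]+)\\(([0-9.]+)\\)$", cell))
    out[[paste0(t, "_reads")]] <- vapply(m, function(v)
      if (length(v) == 3L) as.integer(v[2]) else 0L, integer(1))
    out[[paste0(t, "_coverage")]] <- vapply(m, function(v)
      if (length(v) == 3L) as.numeric(v[3]) else NA_real_, numeric(1))
  }
  out
}

#' Detect polyA-like genomic tracks
#'
#' Maximal A-rich (or T-rich, for the minus strand) windows with purity at
#' least `min_purity` and length at least `min_len`: pure runs are found
#' first, then nearby runs of the same base are chained while the combined
#' window keeps the purity. Each track is linked to the nearest gene start
#' downstream in its strand orientation within `window` bp.
#'
#' @param genome An [annotated_genome()] or DNA string (with `annotation`).
#' @param min_len Minimum track length (default 10).
#' @param min_purity Minimum A fraction (default 0.8).
#' @param window Search range for the downstream gene (default 200 bp).
#' @param annotation Optional annotation when `genome` is a string.
#' @return Data frame: `start`, `length`, `purity`, `strand`,
#'   `nearest_downstream_gene`, `distance`.
#' @export
detect_polyA_tracks <- function(genome, min_len = 10L, min_purity = 0.8,
                                window = 200L, annotation = NULL) {
  s <- if (inherits(genome, "annotated_genome")) genome$sequence else genome
  if (is.null(annotation) && inherits(genome, "annotated_genome"))
    annotation <- genome$annotation
  if (!is.null(annotation)) annotation <- validate_annotation(annotation)
  find_tracks <- function(base) {
    ch <- seq_chars(s)
    isb <- ch == base
    runs <- base_runs(paste(ifelse(isb, "A", "x"), collapse = ""))
    runs <- runs[runs$base == "A", , drop = FALSE]
    if (!nrow(runs)) return(NULL)
    # chain neighbouring runs while purity holds
    tracks <- NULL
    i <- 1L
    while (i <= nrow(runs)) {
      st <- runs$start[i]; en <- st + runs$length[i] - 1L
      nb <- sum(runs$length[i])
      j <- i + 1L
      while (j <= nrow(runs)) {
        en2 <- runs$start[j] + runs$length[j] - 1L
        nb2 <- nb + runs$length[j]
        if (nb2 / (en2 - st + 1L) >= min_purity) {
          en <- en2; nb <- nb2; j <- j + 1L
        } else break
      }
      tracks <- rbind(tracks, data.frame(start = st, length = en - st + 1L,
                                         purity = nb / (en - st + 1L)))
      i <- j
    }
    tracks[tracks$length >= min_len & tracks$purity >= min_purity, ,
           drop = FALSE]
  }
  res <- NULL
  for (std in c("+", "-")) {
    tr <- find_tracks(if (std == "+") "A" else "T")
    if (is.null(tr) || !nrow(tr)) next
    tr$strand <- std
    tr$nearest_downstream_gene <- NA_character_
    tr$distance <- NA_integer_
    if (!is.null(annotation) && nrow(annotation)) {
      genes <- unique(annotation$gene[annotation$strand == std])
      if (length(genes)) {
        gs <- vapply(genes, function(g) {
          r <- annotation[annotation$gene == g, , drop = FALSE]
          if (std == "+") min(r$start) else max(r$end)
        }, integer(1))
        for (k in seq_len(nrow(tr))) {
          if (std == "+") {
            d <- gs - (tr$start[k] + tr$length[k] - 1L) - 1L
          } else {
            d <- tr$start[k] - gs - 1L
          }
          d[d < 0L] <- NA_integer_
          if (all(is.na(d)) || min(d, na.rm = TRUE) > window) next
          hit <- which.min(d)
          tr$nearest_downstream_gene[k] <- genes[hit]
          tr$distance[k] <- d[hit]
        }
      }
    }
    res <- rbind(res, tr)
  }
  if (is.null(res))
    res <- data.frame(start = integer(0), length = integer(0),
                      purity = numeric(0), strand = character(0),
                      nearest_downstream_gene = character(0),
                      distance = integer(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
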