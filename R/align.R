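# Seed-and-extend read mapping against a (circular) genome. The fast path
# is a gapless placement from exact k-mer seeds; reads whose gapless
# identity is poor (homopolymer length miscalls shift the frame) fall back
# to a windowed Needleman-Wunsch via Biostrings::pairwiseAlignment.

#' Map reads to a genome
#'
#' @param reads A `read_set` or character vector of read sequences.
#' @param genome An [annotated_genome()] or DNA string.
#' @param min_identity Minimum alignment identity to report a hit.
#' @param k Seed k-mer length.
#' @param circular Wrap alignments across the origin.
#' @return An `alignment_set`: data frame with one row per read
#'   (`id`, `mapped`, `strand`, `ref_start`, `identity`, `read_cov`) plus
#'   parallel lists `ref_aln`, `read_aln`, `qual_aln` of aligned strings /
#'   quality vectors (gaps as "-", quality `NA` at read gaps).
#' @export
map_reads <- function(reads, genome, min_identity = 0.8, k = 15L,
                      circular = TRUE) {
  s <- if (inherits(genome, "annotated_genome")) genome$sequence else genome
  rs <- as_read_set(reads)
  G <- nchar(s)
  maxlen <- max(nchar(rs$seq), 0L)
  ext <- if (circular) paste0(s, substr(s, 1L, min(G, maxlen + 50L))) else s
  idx <- kmer_index(ext, k)
  ext_int <- seq_ints(ext)
  n <- length(rs$seq)
  out <- data.frame(id = rs$id, mapped = logical(n), strand = NA_character_,
                    ref_start = NA_integer_, identity = NA_real_,
                    read_cov = NA_real_, stringsAsFactors = FALSE)
  ref_aln <- vector("list", n); read_aln <- vector("list", n)
  qual_aln <- vector("list", n)
  for (i in seq_len(n)) {
    hit <- locate_read(rs$seq[i], ext, ext_int, idx, k, min_identity)
    if (is.null(hit)) next
    q <- if (!is.null(rs$qual)) rs$qual[[i]] else rep(30, nchar(rs$seq[i]))
    if (hit$strand == "-") q <- rev(q)
    qa <- rep(NA_real_, nchar(hit$read_aln))
    qa[seq_chars(hit$read_aln) != "-"] <- q
    st <- hit$ref_start
    if (circular) st <- ((st - 1L) %% G) + 1L
    out$mapped[i] <- TRUE
    out$strand[i] <- hit$strand
    out$ref_start[i] <- st
    out$identity[i] <- hit$identity
    out$read_cov[i] <- hit$read_cov
    ref_aln[[i]] <- hit$ref_aln
    read_aln[[i]] <- hit$read_aln
    qual_aln[[i]] <- qa
  }
  structure(list(table = out, ref_aln = ref_aln, read_aln = read_aln,
                 qual_aln = qual_aln, genome_length = G, circular = circular),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("<alignment_set> %d/%d reads mapped (genome %d bp)\n",
              sum(x$table$mapped), nrow(x$table), x$genome_length))
  invisible(x)
}

as_read_set <- function(reads) {
  if (inherits(reads, "read_set")) return(reads)
  if (is.character(reads))
    return(new_read_set(id = if (!is.null(names(reads))) names(reads) else
      sprintf("read%06d", seq_along(reads)),
      seq = unname(reads), qual = NULL))
  stop("reads must be a read_set or character vector", call. = FALSE)
}

# best placement of one read on ext (forward orientation of ext only;
# the read is tried on both strands). Returns NULL if nothing qualifies.
locate_read <- function(read, ext, ext_int, idx, k, min_identity) {
  best <- NULL
  for (strand in c("+", "-")) {
    rseq <- if (strand == "-") revcomp(read) else read
    L <- nchar(rseq)
    if (L < k) next
    offs <- unique(pmax(1L, pmin(L - k + 1L,
                                 round(seq(1L, L - k + 1L, length.out = 5L)))))
    cand <- integer(0)
    for (o in offs) {
      pos <- kmer_lookup(idx, substr(rseq, o, o + k - 1L))
      if (length(pos)) cand <- c(cand, pos - o + 1L)
    }
    if (!length(cand)) next
    tt <- sort(table(cand), decreasing = TRUE)
    starts <- as.integer(names(tt))[seq_len(min(3L, length(tt)))]
    ri <- seq_ints(rseq)
    for (st in starts) {
      if (st < 1L || st + L - 1L > nchar(ext)) next
      # gapless fast path
      ident <- 1 - sum(ri != ext_int[st:(st + L - 1L)]) / L
      if (ident >= max(0.95, min_identity)) {
        h <- list(strand = strand, ref_start = st, identity = ident,
                  read_cov = 1, ref_aln = substr(ext, st, st + L - 1L),
                  read_aln = rseq)
        if (is.null(best) || ident > best$identity) best <- h
        next
      }
      # stepwise indel-aware extension (handles the isolated +/-1
      # homopolymer length miscalls of pyrosequencing in O(L))
      h <- step_align(ri, ext_int, st)
      if (!is.null(h) && h$identity >= min_identity) {
        h$strand <- strand; h$read_cov <- 1
        if (is.null(best) || h$identity > best$identity) best <- h
        next
      }
      # full dynamic-programming fallback on a padded window
      pad <- 15L
      ws <- max(1L, st - pad)
      we <- min(nchar(ext), st + L - 1L + pad)
      win <- substr(ext, ws, we)
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(rseq), Biostrings::DNAString(win),
        type = "global-local", substitutionMatrix = dna_submat(),
        gapOpening = 4, gapExtension = 2)
      p_aln <- as.character(Biostrings::aligned(Biostrings::pattern(pa)))
      s_aln <- as.character(Biostrings::aligned(Biostrings::subject(pa)))
      cols <- nchar(p_aln)
      m <- sum(seq_chars(p_aln) == seq_chars(s_aln))
      ident <- m / cols
      if (ident >= min_identity) {
        sub_start <- ws + Biostrings::start(Biostrings::subject(pa)@range) - 1L
        h <- list(strand = strand, ref_start = sub_start, identity = ident,
                  read_cov = 1, ref_aln = s_aln, read_aln = p_aln)
        if (is.null(best) || ident > best$identity) best <- h
      }
    }
  }
  best
}

# greedy columnwise alignment of a read (int codes) to the reference from
# position `st`: on a mismatch, a 12-bp lookahead decides between a
# substitution, a 1-bp deletion or a 1-bp insertion; at most `max_events`
# indel decisions. Returns NULL when the model does not fit.
step_align <- function(ri, gi, st, max_events = 12L, lookahead = 12L) {
  L <- length(ri); GL <- length(gi)
  out_r <- integer(0); out_g <- integer(0)
  pr <- 1L; pg <- st; events <- 0L
  gap <- 45L                     # "-"
  while (pr <= L) {
    n <- min(L - pr, GL - pg) + 1L
    if (n <= 0L) return(NULL)
    a <- ri[pr:(pr + n - 1L)]; b <- gi[pg:(pg + n - 1L)]
    d <- which(a != b)
    if (!length(d)) {
      out_r <- c(out_r, a); out_g <- c(out_g, b)
      pr <- pr + n; pg <- pg + n
      break
    }
    f <- d[1L]
    if (f > 1L) {
      out_r <- c(out_r, a[seq_len(f - 1L)])
      out_g <- c(out_g, b[seq_len(f - 1L)])
      pr <- pr + f - 1L; pg <- pg + f - 1L
    }
    la <- function(dr, dg) {
      i1 <- pr + dr; j1 <- pg + dg
      n2 <- min(lookahead, L - i1 + 1L, GL - j1 + 1L)
      if (n2 <= 0L) return(1)          # at the end: any option closes
      sum(ri[i1:(i1 + n2 - 1L)] == gi[j1:(j1 + n2 - 1L)]) / n2
    }
    ss <- la(1L, 1L); dd <- la(0L, 1L); ii <- la(1L, 0L)
    if (ss >= dd && ss >= ii) {        # substitution
      out_r <- c(out_r, ri[pr]); out_g <- c(out_g, gi[pg])
      pr <- pr + 1L; pg <- pg + 1L
    } else {
      events <- events + 1L
      if (events > max_events) return(NULL)
      if (dd >= ii) {                  # deletion in the read
        out_r <- c(out_r, gap); out_g <- c(out_g, gi[pg])
        pg <- pg + 1L
      } else {                         # insertion in the read
        out_r <- c(out_r, ri[pr]); out_g <- c(out_g, gap)
        pr <- pr + 1L
      }
    }
  }
  if (pr <= L) return(NULL)
  ident <- sum(out_r == out_g) / length(out_r)
  list(ref_start = st, identity = ident,
       ref_aln = intToUtf8(out_g), read_aln = intToUtf8(out_r))
}

#' Build a quality-filtered pileup from read alignments
#'
#' One column per genome position. Bases with Phred quality not above
#' `min_qual` are excluded from the base counts; reads carrying an
#' alignment gap (deletion) at a locus are tallied in `gap_reads` and do
#' not contribute a base there. Insertions are collected separately with
#' their anchor position (insertion after that base).
#'
#' @param alignments An `alignment_set` from [map_reads()].
#' @param genome Genome (for its length).
#' @param min_qual Strict Phred threshold (base kept iff quality > min_qual).
#' @return A `pileup` object: `counts` (genome x ACGT matrix), `gap_reads`,
#'   `depth_q` vectors, and `insertions` data frame (`pos`, `inserted`,
#'   `read_id`).
#' @export
build_pileup <- function(alignments, genome, min_qual = 20) {
  stopifnot(inherits(alignments, "alignment_set"))
  s <- if (inherits(genome, "annotated_genome")) genome$sequence else genome
  G <- nchar(s)
  base_idx <- vector("list", nrow(alignments$table))
  gap_idx <- vector("list", nrow(alignments$table))
  ins_pos <- integer(0); ins_seq <- character(0); ins_read <- character(0)
  tab <- alignments$table
  for (i in which(tab$mapped)) {
    ra <- seq_chars(alignments$ref_aln[[i]])
    da <- seq_chars(alignments$read_aln[[i]])
    qa <- alignments$qual_aln[[i]]
    if (!alignments$circular &&
        tab$ref_start[i] + sum(ra != "-") - 1L > G)
      stop("alignment extends past the genome end", call. = FALSE)
    rp <- tab$ref_start[i] - 1L + cumsum(ra != "-")
    rp <- ((rp - 1L) %% G) + 1L
    is_ins <- ra == "-"
    is_del <- da == "-"
    base_col <- !is_ins & !is_del
    keep <- base_col & !is.na(qa) & qa > min_qual & da %in% c("A", "C", "G", "T")
    if (any(keep))
      base_idx[[i]] <- rp[keep] + (match(da[keep], c("A", "C", "G", "T")) - 1L) * G
    if (any(is_del))
      gap_idx[[i]] <- unique(rp[is_del])
    if (any(is_ins)) {
      # group consecutive insertion columns into one event
      runs <- rle(is_ins)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (j in which(runs$values)) {
        anchor <- if (starts[j] > 1L) rp[starts[j] - 1L] else rp[1L] - 1L
        ins <- paste(da[starts[j]:ends[j]], collapse = "")
        # left-normalize: an insertion is ambiguous when its last base
        # matches the reference at the anchor; shift to the leftmost
        # equivalent placement so identical events group together
        w <- nchar(ins)
        while (anchor >= 1L && substr(s, anchor, anchor) == substr(ins, w, w)) {
          ins <- paste0(substr(ins, w, w), substr(ins, 1L, w - 1L))
          anchor <- anchor - 1L
        }
        ins_pos <- c(ins_pos, anchor)
        ins_seq <- c(ins_seq, ins)
        ins_read <- c(ins_read, tab$id[i])
      }
    }
  }
  bi <- unlist(base_idx); if (is.null(bi)) bi <- integer(0)
  gi <- unlist(gap_idx); if (is.null(gi)) gi <- integer(0)
  counts <- matrix(tabulate(bi, nbins = 4L * G), nrow = G,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  gaps <- tabulate(gi, nbins = G)
  structure(list(counts = counts, gap_reads = gaps,
                 depth_q = as.integer(rowSums(counts)),
                 insertions = data.frame(pos = ins_pos, inserted = ins_seq,
                                         read_id = ins_read,
                                         stringsAsFactors = FALSE),
                 min_qual = min_qual, genome_length = G),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %d positions, median quality-filtered depth %d\n",
              x$genome_length, stats::median(x$depth_q)))
  invisible(x)
}
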