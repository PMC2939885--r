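# Read screening, iterative end-anchored contig elongation, and the
# homopolymer-run inventory used to target validation experiments.

#' Screen chloroplast-derived reads from a mixed pool
#'
#' A read is kept iff its best seeded alignment to any reference genome
#' (either strand) reaches `min_identity` over at least `min_cov` of the
#' read. The partition is exhaustive and disjoint.
#'
#' @param reads A `read_set` or character vector.
#' @param references Character vector (or list) of reference genome
#'   sequences, or a single [annotated_genome()].
#' @param min_identity Minimum alignment identity (default 0.90).
#' @param min_cov Minimum fraction of the read aligned (default 0.80).
#' @return A list with `kept` and `discarded` read-id vectors and `report`,
#'   a data frame (id, best_reference, identity, coverage, kept).
#' @export
screen_cp_reads <- function(reads, references, min_identity = 0.90,
                            min_cov = 0.80) {
  rs <- as_read_set(reads)
  if (inherits(references, "annotated_genome"))
    references <- references$sequence
  references <- vapply(references, function(r)
    if (inherits(r, "annotated_genome")) r$sequence else r, character(1))
  if (!length(references)) stop("references must be nonempty", call. = FALSE)
  if (is.null(names(references)) || any(!nzchar(names(references))))
    names(references) <- sprintf("ref%d", seq_along(references))
  if (!length(rs$seq)) {
    warning("empty read set; nothing to screen")
    return(list(kept = character(0), discarded = character(0),
                report = data.frame(id = character(0),
                                    best_reference = character(0),
                                    identity = numeric(0),
                                    coverage = numeric(0), kept = logical(0))))
  }
  n <- length(rs$seq)
  best_id <- rep(NA_real_, n); best_cov <- rep(NA_real_, n)
  best_ref <- rep(NA_character_, n)
  for (rn in names(references)) {
    aln <- map_reads(rs, references[[rn]], min_identity = min_identity,
                     circular = TRUE)
    hit <- aln$table$mapped
    better <- hit & (is.na(best_id) | aln$table$identity > best_id)
    best_id[better] <- aln$table$identity[better]
    best_cov[better] <- aln$table$read_cov[better]
    best_ref[better] <- rn
  }
  kept <- !is.na(best_id) & best_id >= min_identity & best_cov >= min_cov
  list(kept = rs$id[kept], discarded = rs$id[!kept],
       report = data.frame(id = rs$id, best_reference = best_ref,
                           identity = best_id, coverage = best_cov,
                           kept = kept, stringsAsFactors = FALSE))
}

#' Subset a read set by id
#' @param reads A `read_set`.
#' @param ids Ids to keep.
#' @return A `read_set`.
#' @export
subset_reads <- function(reads, ids) {
  keep <- reads$id %in% ids
  new_read_set(reads$id[keep], reads$seq[keep],
               if (!is.null(reads$qual)) reads$qual[keep] else NULL,
               truth = if (is.data.frame(reads$truth))
                 reads$truth[keep, , drop = FALSE] else reads$truth)
}

#' Iterative end-anchored contig elongation
#'
#' Each round, reads anchored to a contig end by `min_overlap` identical
#' bases vote per position on the extension; the consensus is appended
#' while at least `min_support` reads cover a position and agree by
#' majority. Contigs whose ends mutually overlap are merged, and a contig
#' whose own two ends overlap by at least `min_overlap` is marked closed
#' (circular) and trimmed. Iteration stops at a fixed point.
#'
#' @param contigs Character vector of seed contig sequences.
#' @param reads A `read_set` or character vector of reads.
#' @param min_overlap Anchor length in bp (>= 20).
#' @param min_support Minimum agreeing reads per extended position.
#' @param min_identity Identity required over a merge overlap.
#' @param max_rounds Safety cap on elongation rounds.
#' @return A list of contig records: `sequence`, `closed`, plus an
#'   `ambiguities` attribute logging halted ends.
#' @export
elongate_contigs <- function(contigs, reads, min_overlap = 40L,
                             min_support = 3L, min_identity = 0.98,
                             max_rounds = 200L) {
  if (min_overlap < 20L) stop("min_overlap must be >= 20", call. = FALSE)
  rs <- as_read_set(reads)
  pool <- c(rs$seq, revcomp(rs$seq))
  # one concatenated haystack with separators: gregexpr is far cheaper per
  # anchor search than per-read pattern matching
  big <- paste(pool, collapse = "#")
  bstarts <- cumsum(c(1L, nchar(pool[-length(pool)]) + 1L))
  bends <- bstarts + nchar(pool) - 1L
  ambig <- character(0)
  note_ambig <- function(msg) ambig <<- c(ambig, msg)

  extend_right <- function(seq) {
    # returns the extension string ("" if none)
    anchor <- substr(seq, nchar(seq) - min_overlap + 1L, nchar(seq))
    m <- gregexpr(anchor, big, fixed = TRUE)[[1]]
    ext <- character(0)
    if (m[1] != -1L) {
      ridx <- findInterval(m, bstarts)
      ends_in_read <- as.integer(m) + min_overlap - 1L
      ok <- ends_in_read <= bends[ridx]        # match not crossing separator
      for (j in which(ok)) {
        e <- ends_in_read[j]
        if (e < bends[ridx[j]])
          ext <- c(ext, substr(big, e + 1L, bends[ridx[j]]))
      }
    }
    if (length(ext) < min_support) return("")
    maxl <- max(nchar(ext))
    cons <- character(0)
    mat <- matrix("", nrow = length(ext), ncol = maxl)
    for (i in seq_along(ext)) {
      ch <- seq_chars(ext[i])
      mat[i, seq_along(ch)] <- ch
    }
    # deep columns only: at the chunk tip just the few longest extensions
    # vote, and with indel-bearing reads a tiny shifted family could reach
    # unanimity by chance
    min_cov <- max(min_support, ceiling(0.3 * length(ext)))
    for (p in seq_len(maxl)) {
      col <- mat[, p]
      col <- col[nzchar(col)]
      if (length(col) < min_cov) break
      tt <- sort(table(col), decreasing = TRUE)
      if (length(tt) > 1L && tt[1] == tt[2]) {
        note_ambig(sprintf("tie at extension offset %d", p))
        break
      }
      # near-unanimity is required: at the exit of a large repeat (the IR)
      # the anchored reads split between the two copies and a bare majority
      # would walk a chimeric path; a split vote halts the end instead
      if (tt[1] < min_support || tt[1] / length(col) < 0.9) {
        if (tt[1] / length(col) <= 0.75)
          note_ambig(sprintf("split vote (%.2f) at extension offset %d",
                             tt[1] / length(col), p))
        break
      }
      cons <- c(cons, names(tt)[1])
    }
    paste(cons, collapse = "")
  }

  # overlap of a's suffix with b's prefix, anchored by an exact min_overlap
  # seed; returns overlap length or 0
  suffix_prefix_overlap <- function(a, b) {
    anchor <- substr(a, nchar(a) - min_overlap + 1L, nchar(a))
    m <- gregexpr(anchor, b, fixed = TRUE)[[1]]
    if (m[1] == -1L) return(0L)
    for (j in seq_along(m)) {
      ov <- as.integer(m[j]) + min_overlap - 1L   # b[1..ov] vs a's suffix
      if (ov > nchar(a)) next
      ident <- hamming_identity(substr(a, nchar(a) - ov + 1L, nchar(a)),
                                substr(b, 1L, ov))
      if (!is.na(ident) && ident >= min_identity) return(ov)
    }
    0L
  }

  recs <- lapply(contigs, function(s) list(sequence = s, closed = FALSE))
  for (round in seq_len(max_rounds)) {
    changed <- FALSE
    # 1) merge contigs with mutually overlapping ends
    repeat {
      merged <- FALSE
      nrec <- length(recs)
      if (nrec < 2L) break
      for (i in seq_len(nrec - 1L)) {
        if (merged) break
        for (j in (i + 1L):nrec) {
          if (recs[[i]]$closed || recs[[j]]$closed) next
          a <- recs[[i]]$sequence
          for (b_orient in c("+", "-")) {
            b <- if (b_orient == "+") recs[[j]]$sequence else
              revcomp(recs[[j]]$sequence)
            ov_ab <- suffix_prefix_overlap(a, b)
            ov_ba <- suffix_prefix_overlap(b, a)
            if (ov_ab >= min_overlap && ov_ab >= ov_ba) {
              recs[[i]]$sequence <- paste0(a, substr(b, ov_ab + 1L, nchar(b)))
              recs[[j]] <- NULL
              merged <- TRUE; changed <- TRUE
              break
            } else if (ov_ba >= min_overlap) {
              recs[[i]]$sequence <- paste0(b, substr(a, ov_ba + 1L, nchar(a)))
              recs[[j]] <- NULL
              merged <- TRUE; changed <- TRUE
              break
            }
          }
          if (merged) break
        }
      }
      if (!merged) break
    }
    # 2) close circles: a contig whose two ends overlap each other
    for (i in seq_along(recs)) {
      if (recs[[i]]$closed) next
      s <- recs[[i]]$sequence
      if (nchar(s) < 3L * min_overlap) next
      anchor <- substr(s, nchar(s) - min_overlap + 1L, nchar(s))
      m <- gregexpr(anchor, substr(s, 1L, nchar(s) - min_overlap), fixed = TRUE)[[1]]
      if (m[1] != -1L) {
        e <- as.integer(m[1]) + min_overlap - 1L
        # verify a bounded window around the anchor: over a long duplicated
        # stretch consensus indels would throw a full-length Hamming
        # comparison out of register
        w <- min(e, 3L * min_overlap)
        ident <- hamming_identity(substr(s, nchar(s) - w + 1L, nchar(s)),
                                  substr(s, e - w + 1L, e))
        if (!is.na(ident) && ident >= min_identity) {
          recs[[i]]$sequence <- substr(s, 1L, nchar(s) - e)
          recs[[i]]$closed <- TRUE
          changed <- TRUE
        }
      }
    }

    # 3) extend both ends of every open contig
    for (i in seq_along(recs)) {
      if (recs[[i]]$closed) next
      s <- recs[[i]]$sequence
      er <- extend_right(s)
      if (nzchar(er)) { s <- paste0(s, er); changed <- TRUE }
      el <- extend_right(revcomp(s))
      if (nzchar(el)) { s <- paste0(revcomp(el), s); changed <- TRUE }
      recs[[i]]$sequence <- s
    }
    if (!changed) break
  }
  attr(recs, "ambiguities") <- ambig
  recs
}

#' Canonicalize a closed circular contig
#'
#' Rotation and strand are normalized: with a reference, the strand and
#' rotation matching the reference start are chosen; otherwise the
#' lexicographically minimal rotation over both strands.
#'
#' @param seq Circular contig sequence.
#' @param reference Optional reference genome string.
#' @return The canonical rotation.
#' @export
canonical_rotation <- function(seq, reference = NULL) {
  rots_of <- function(s) {
    n <- nchar(s)
    d <- paste0(s, s)
    substring(d, 1:n, n:(2L * n - 1L))
  }
  if (!is.null(reference)) {
    probe <- substr(reference, 1L, min(40L, nchar(reference)))
    for (s in c(seq, revcomp(seq))) {
      hit <- regexpr(probe, paste0(s, s), fixed = TRUE)
      if (hit > 0) {
        n <- nchar(s)
        st <- ((hit - 1L) %% n) + 1L
        return(circular_substr(s, st, n))
      }
    }
  }
  cand <- c(rots_of(seq), rots_of(revcomp(seq)))
  sort(cand)[1]
}

#' Inventory maximal homopolymer runs
#'
#' @param seq DNA string (or [annotated_genome()]).
#' @param min_len Minimum run length (>= 2).
#' @return Data frame (`base`, `start`, `length`) of maximal runs, sorted
#'   by position, with a `counts` attribute splitting runs at exactly
#'   `min_len` from longer ones.
#' @export
find_homopolymers <- function(seq, min_len = 7L) {
  if (inherits(seq, "annotated_genome")) seq <- seq$sequence
  if (min_len < 2L) stop("min_len must be >= 2", call. = FALSE)
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0)
    stop(sprintf("non-ACGT character at position %d", as.integer(bad)),
         call. = FALSE)
  runs <- base_runs(seq)
  out <- runs[runs$length >= min_len, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- c(at_min = sum(out$length == min_len),
                           above_min = sum(out$length > min_len))
  out
}

#' Minimal validation windows covering homopolymer runs
#'
#' Each run is expanded by `flank` bp on both sides; overlapping windows
#' are merged, so the result is the minimal window set covering every run.
#'
#' @param runs Data frame from [find_homopolymers()].
#' @param genome Genome (bounds for clipping), or its length.
#' @param flank Flank size in bp (>= 50).
#' @return Data frame (`start`, `end`) of merged windows.
#' @export
validation_windows <- function(runs, genome, flank = 300L) {
  if (flank < 50L) stop("flank must be >= 50", call. = FALSE)
  G <- if (inherits(genome, "annotated_genome")) genome$length else
    if (is.character(genome)) nchar(genome) else as.integer(genome)
  if (is.null(runs) || nrow(runs) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  st <- pmax(1L, runs$start - flank)
  en <- pmin(G, runs$start + runs$length - 1L + flank)
  merge_intervals(st, en)
}
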