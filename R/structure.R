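# Quadripartite architecture, dispersed repeats and small inversions.
#
# The repeat machinery works diagonal-wise: for two sequences laid against
# each other at a fixed offset, mismatch positions along the diagonal are
# computed in one vectorized comparison, and the maximal intervals holding
# at most `max_mm` mismatches are enumerated from the mismatch positions
# alone. Maximal means: extending the interval either way hits a sequence
# boundary or would exceed the mismatch budget; terminal mismatches are
# trimmed so a hit never starts or ends on a mismatch.

# maximal <=max_mm-mismatch windows from a logical mismatch vector
mismatch_windows <- function(neq, max_mm, min_len) {
  len <- length(neq)
  if (len < min_len) return(NULL)
  mpos <- which(neq)
  M <- length(mpos)
  b <- c(0L, mpos, len + 1L)            # bounding sentinels
  if (M <= max_mm) {
    starts <- 1L; ends <- len
  } else {
    a <- 0:(M - max_mm)
    starts <- b[a + 1L] + 1L            # just past the left bounding mismatch
    ends <- b[pmin(M + 2L, a + max_mm + 2L)] - 1L   # right bound or sequence end
  }
  # trim terminal mismatches
  match_pos <- which(!neq)
  if (!length(match_pos)) return(NULL)
  si <- findInterval(starts - 1L, match_pos) + 1L   # first match >= start
  ei <- findInterval(ends, match_pos)               # last match <= end
  ok <- si <= length(match_pos) & ei >= 1L & si <= ei
  starts <- match_pos[si[ok]]; ends <- match_pos[ei[ok]]
  keep <- (ends - starts + 1L) >= min_len
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) return(NULL)
  # drop containment-redundant windows (possible after trimming)
  o <- order(starts, -ends)
  starts <- starts[o]; ends <- ends[o]
  keep <- rep(TRUE, length(starts))
  max_end <- -1L
  for (i in seq_along(starts)) {
    if (ends[i] <= max_end) keep[i] <- FALSE else max_end <- ends[i]
  }
  starts <- starts[keep]; ends <- ends[keep]
  mm <- vapply(seq_along(starts), function(i)
    sum(neq[starts[i]:ends[i]]), integer(1))
  data.frame(start = starts, end = ends, mm = mm)
}

# maximal matches between strings a and b along the given diagonal offsets
# (offset d: a[i] vs b[i + d]); returns data.frame(ia, ib, len, mm)
diag_matches <- function(ai, bi, offsets, max_mm, min_len) {
  na <- length(ai); nb <- length(bi)
  res <- list()
  for (d in offsets) {
    i1 <- max(1L, 1L - d); i2 <- min(na, nb - d)
    if (i2 - i1 + 1L < min_len) next
    neq <- ai[i1:i2] != bi[(i1 + d):(i2 + d)]
    w <- mismatch_windows(neq, max_mm, min_len)
    if (is.null(w)) next
    res[[length(res) + 1L]] <-
      data.frame(ia = w$start + i1 - 1L, ib = w$start + i1 - 1L + d,
                 len = w$end - w$start + 1L, mm = w$mm)
  }
  if (!length(res)) return(data.frame(ia = integer(0), ib = integer(0),
                                      len = integer(0), mm = integer(0)))
  unique(do.call(rbind, res))
}

# q-gram filtering: candidate diagonal segments sharing enough exact
# k-mers between a and b. Pigeonhole: a hit of length >= min_len with
# <= max_mm mismatches contains, inside any min_len window, at least
# t_req = (min_len - max_mm) - (max_mm + 1)(k - 1) exact k-mer seeds on
# its diagonal, so it is enough to scan bounded regions around diagonal
# positions where t_req seeds cluster within min_len. Returns
# data.frame(d, lo, hi) in a-coordinates, or NULL when the guarantee is
# too weak (caller scans everything).
seed_regions <- function(a, b, min_len, max_mm, self = FALSE) {
  k <- min(ceiling((min_len - max_mm) / (max_mm + 1L)), 24L)
  if (k < 5L) return(NULL)
  t_req <- max(1L, (min_len - max_mm) - (max_mm + 1L) * (k - 1L))
  na <- nchar(a); nb <- nchar(b)
  empty <- data.frame(d = integer(0), lo = integer(0), hi = integer(0))
  if (na < k || nb < k) return(empty)
  kms_a <- substring(a, 1:(na - k + 1L), k:na)
  grp_a <- split(seq_along(kms_a), kms_a)
  grp_b <- if (self) grp_a else
    split(seq_len(nb - k + 1L), substring(b, 1:(nb - k + 1L), k:nb))
  common <- if (self) names(grp_a) else
    intersect(names(grp_a), names(grp_b))
  if (!length(common)) return(empty)
  ga <- grp_a[common]; gb <- grp_b[common]     # positional access below
  dl <- vector("list", length(common)); il <- vector("list", length(common))
  j <- 0L
  for (g in seq_along(common)) {
    pa <- ga[[g]]; pb <- gb[[g]]
    if (self && length(pa) < 2L) next
    d <- rep(pb, each = length(pa)) - rep.int(pa, length(pb))
    i <- rep.int(pa, length(pb))
    if (self) { keep <- d > 0L; d <- d[keep]; i <- i[keep] }
    if (!length(d)) next
    j <- j + 1L
    dl[[j]] <- d; il[[j]] <- i
  }
  if (j == 0L) return(empty)
  d <- unlist(dl[seq_len(j)]); i <- unlist(il[seq_len(j)])
  o <- order(d, i)
  d <- d[o]; i <- i[o]
  # within each diagonal, t_req seeds spread over at most min_len - k;
  # vectorized across the sorted (d, i) pairs: a window of t_req
  # consecutive entries must share the diagonal and stay within the spread
  np <- length(d)
  if (np < t_req) return(empty)
  hd <- seq_len(np - t_req + 1L)
  tl <- hd + t_req - 1L
  ok <- which(d[hd] == d[tl] & (i[tl] - i[hd]) <= min_len - k)
  if (!length(ok)) return(empty)
  cand <- data.frame(d = d[ok], lo = i[ok], hi = i[ok + t_req - 1L] + k - 1L)
  # merge overlapping candidate windows per diagonal
  out <- lapply(split(cand, cand$d), function(cc) {
    iv <- merge_intervals(cc$lo, cc$hi)
    data.frame(d = cc$d[1], lo = iv$start, hi = iv$end)
  })
  do.call(rbind, out)
}

# maximal matches restricted to candidate regions; slices are widened
# until no reported window is truncated at a slice edge
scan_regions <- function(ai, bi, regions, max_mm, min_len) {
  na <- length(ai); nb <- length(bi)
  res <- list()
  for (r in seq_len(nrow(regions))) {
    dd <- regions$d[r]
    i1 <- max(1L, 1L - dd); i2 <- min(na, nb - dd)
    pad <- 4L * min_len + 50L
    repeat {
      lo <- max(i1, regions$lo[r] - pad)
      hi <- min(i2, regions$hi[r] + pad)
      if (hi - lo + 1L < min_len) break
      neq <- ai[lo:hi] != bi[(lo + dd):(hi + dd)]
      w <- mismatch_windows(neq, max_mm, min_len)
      if (is.null(w)) break
      abs_s <- w$start + lo - 1L; abs_e <- w$end + lo - 1L
      truncated <- any((abs_s - min_len < lo & lo > i1) |
                         (abs_e + min_len > hi & hi < i2))
      if (!truncated || (lo == i1 && hi == i2)) {
        res[[length(res) + 1L]] <-
          data.frame(ia = abs_s, ib = abs_s + dd,
                     len = abs_e - abs_s + 1L, mm = w$mm)
        break
      }
      pad <- pad * 4L
    }
  }
  if (!length(res)) return(data.frame(ia = integer(0), ib = integer(0),
                                      len = integer(0), mm = integer(0)))
  unique(do.call(rbind, res))
}

# all maximal forward repeat pairs within s (i < j); exhaustive if
# `all_diagonals`, else q-gram-filtered
self_forward_matches <- function(s, min_len, max_mm, all_diagonals = FALSE) {
  si <- seq_ints(s)
  n <- length(si)
  reg <- if (all_diagonals) NULL else seed_regions(s, s, min_len, max_mm,
                                                   self = TRUE)
  m <- if (is.null(reg))
    diag_matches(si, si, seq_len(n - min_len), max_mm, min_len)
  else scan_regions(si, si, reg, max_mm, min_len)
  data.frame(start1 = m$ia, start2 = m$ib, len = m$len, mm = m$mm)
}

# all maximal inverted repeat pairs within s (disjoint copies, start1 <
# start2): forward matches between s and revcomp(s), mapped back
self_inverted_matches <- function(s, min_len, max_mm, all_diagonals = FALSE) {
  t <- revcomp(s)
  si <- seq_ints(s); ti <- seq_ints(t)
  n <- length(si)
  reg <- if (all_diagonals) NULL else seed_regions(s, t, min_len, max_mm)
  m <- if (is.null(reg))
    diag_matches(si, ti, seq(-(n - min_len), n - min_len), max_mm, min_len)
  else scan_regions(si, ti, reg, max_mm, min_len)
  if (!nrow(m)) return(data.frame(start1 = integer(0), start2 = integer(0),
                                  len = integer(0), mm = integer(0)))
  # s[ia..ia+len-1] matches t[ib..]; t position q corresponds to s position
  # n - q + 1, so copy2 spans s[n - (ib + len - 1) + 1 .. n - ib + 1]
  s2 <- n - (m$ib + m$len - 1L) + 1L
  a <- pmin(m$ia, s2); b <- pmax(m$ia, s2)
  out <- data.frame(start1 = a, start2 = b, len = m$len, mm = m$mm)
  out <- out[out$start2 >= out$start1 + out$len, , drop = FALSE]  # disjoint
  unique(out)
}

#' Find dispersed repeats (forward and inverted)
#'
#' Reports all maximal repeat pairs of at least `min_len` bp with at most
#' `max_mismatch` substitutions (REPuter-style Hamming matches; no indels).
#' Pairs with both copies inside `exclude` intervals are suppressed - used
#' to mask the genome-scale IR duplication itself. Pad the exclusion by a
#' few bases: with a mismatch budget the maximal IR-pair hit runs slightly
#' past the exact IR boundaries.
#'
#' @param genome DNA string or [annotated_genome()].
#' @param min_len Minimum unit length (default 30, >= 10).
#' @param max_mismatch Mismatch budget (default 3).
#' @param exclude Optional data frame (`start`, `end`) of intervals.
#' @param annotation Optional annotation for location labels.
#' @param all_diagonals Use the exhaustive scan instead of seeding.
#' @return Data frame: `unit_len`, `start1`, `start2`, `type` ("F"/"I"),
#'   `mismatches`, `location1`, `location2`.
#' @export
find_repeats <- function(genome, min_len = 30L, max_mismatch = 3L,
                         exclude = NULL, annotation = NULL,
                         all_diagonals = FALSE) {
  if (min_len < 10L) stop("min_len must be >= 10", call. = FALSE)
  s <- if (inherits(genome, "annotated_genome")) genome$sequence else genome
  if (is.null(annotation) && inherits(genome, "annotated_genome"))
    annotation <- genome$annotation
  fw <- self_forward_matches(s, min_len, max_mismatch, all_diagonals)
  iv <- self_inverted_matches(s, min_len, max_mismatch, all_diagonals)
  hits <- rbind(
    if (nrow(fw)) cbind(fw, type = "F") else NULL,
    if (nrow(iv)) cbind(iv, type = "I") else NULL)
  if (is.null(hits) || !nrow(hits))
    return(data.frame(unit_len = integer(0), start1 = integer(0),
                      start2 = integer(0), type = character(0),
                      mismatches = integer(0), location1 = character(0),
                      location2 = character(0), stringsAsFactors = FALSE))
  if (!is.null(exclude) && nrow(exclude)) {
    inside <- function(st, en) {
      vapply(seq_along(st), function(i)
        any(exclude$start <= st[i] & exclude$end >= en[i]), logical(1))
    }
    drop <- inside(hits$start1, hits$start1 + hits$len - 1L) &
      inside(hits$start2, hits$start2 + hits$len - 1L)
    hits <- hits[!drop, , drop = FALSE]
  }
  loc <- function(st, len) {
    if (is.null(annotation) || !nrow(annotation))
      return(rep(NA_character_, length(st)))
    vapply(seq_along(st), function(i)
      locate_interval(annotation, st[i], st[i] + len[i] - 1L), character(1))
  }
  out <- data.frame(unit_len = hits$len, start1 = hits$start1,
                    start2 = hits$start2, type = hits$type,
                    mismatches = hits$mm,
                    location1 = loc(hits$start1, hits$len),
                    location2 = loc(hits$start2, hits$len),
                    stringsAsFactors = FALSE)
  out <- out[order(out$type, out$start1, out$start2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect the quadripartite LSC / IRb / SSC / IRa architecture
#'
#' Finds the maximal-length exact inverted repeat pair of at least
#' `min_ir_len` bp on the circle; the larger single-copy gap is labelled
#' LSC. IRb is the IR copy first encountered downstream of the LSC end.
#' Junction positions (JLB, JSB, JSA, JLA) are the last base of LSC, IRb,
#' SSC and IRa respectively, in the input's own coordinates.
#'
#' @param genome DNA string or [annotated_genome()] (>= 1 kb).
#' @param min_ir_len Minimum IR length to qualify (default 1000 bp).
#' @return A `quadripartite_layout`; if no IR qualifies, a layout with
#'   `found = FALSE` (not an error).
#' @export
detect_quadripartite <- function(genome, min_ir_len = 1000L) {
  s <- if (inherits(genome, "annotated_genome")) genome$sequence else genome
  n <- nchar(s)
  if (n < 1000L) stop("genome must be at least 1 kb", call. = FALSE)
  s2 <- paste0(s, s)                     # catch IRs crossing the origin
  hits <- self_inverted_matches(s2, min_ir_len, 0L)
  hits <- hits[hits$len <= n, , drop = FALSE]
  if (!nrow(hits))
    return(structure(list(found = FALSE,
                          reason = "no quadripartite structure"),
                     class = "quadripartite_layout"))
  # reduce to circle coordinates and deduplicate doubled-sequence copies
  a <- ((hits$start1 - 1L) %% n) + 1L
  b <- ((hits$start2 - 1L) %% n) + 1L
  key <- paste(pmin(a, b), pmax(a, b), hits$len)
  hits <- hits[!duplicated(key), , drop = FALSE]
  hits <- hits[order(-hits$len), , drop = FALSE]
  h <- hits[1, ]
  L <- h$len
  a <- ((h$start1 - 1L) %% n) + 1L
  b <- ((h$start2 - 1L) %% n) + 1L
  ea <- a + L - 1L; eb <- b + L - 1L     # may exceed n (wrapping)
  gap1 <- (b - ea - 1L) %% n             # gap downstream of copy A
  gap2 <- (a - eb - 1L) %% n             # gap downstream of copy B
  if (gap1 + gap2 + 2L * L != n)
    return(structure(list(found = FALSE,
                          reason = "inverted match inconsistent with a quadripartite circle"),
                     class = "quadripartite_layout"))
  # LSC = larger gap; IRb = copy right after LSC
  if (gap1 >= gap2) {
    # gap after copy A is the SSC or LSC? gap1 lies between copyA and copyB
    lsc_len <- gap1; ssc_len <- gap2
    irb_start <- b                       # copy after the larger gap
    lsc_start <- (ea %% n) + 1L
  } else {
    lsc_len <- gap2; ssc_len <- gap1
    irb_start <- a
    lsc_start <- (eb %% n) + 1L
  }
  jlb <- ((lsc_start + lsc_len - 2L) %% n) + 1L
  jsb <- ((jlb + L - 1L) %% n) + 1L
  jsa <- ((jsb + ssc_len - 1L) %% n) + 1L
  jla <- ((jsa + L - 1L) %% n) + 1L
  structure(list(found = TRUE,
                 lsc = c(lsc_start, jlb), irb = c((jlb %% n) + 1L, jsb),
                 ssc = c((jsb %% n) + 1L, jsa), ira = c((jsa %% n) + 1L, jla),
                 lsc_len = lsc_len, ssc_len = ssc_len, ir_len = L,
                 junctions = c(JLB = jlb, JSB = jsb, JSA = jsa, JLA = jla)),
            class = "quadripartite_layout")
}

#' @export
print.quadripartite_layout <- function(x, ...) {
  if (!isTRUE(x$found)) {
    cat("<quadripartite_layout> not found:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<quadripartite_layout> LSC %s / IRb %s / SSC %s / IRa %s bp (total %s)\n",
    format(x$lsc_len, big.mark = ","), format(x$ir_len, big.mark = ","),
    format(x$ssc_len, big.mark = ","), format(x$ir_len, big.mark = ","),
    format(x$lsc_len + x$ssc_len + 2L * x$ir_len, big.mark = ",")))
  cat("  junctions:", paste(names(x$junctions), x$junctions, sep = "=",
                            collapse = "  "), "\n")
  invisible(x)
}

#' Gene context of the four quadripartite junctions
#'
#' For each of JLB, JSB, JSA and JLA: the nearest gene on each side with
#' its distance, and any gene spanning the junction with the overlap
#' length (how far it reaches past the junction into the downstream
#' region). Distances are measured on the circle.
#'
#' @param layout A found `quadripartite_layout`.
#' @param annotation Annotation data frame in the same coordinates.
#' @param genome_length Circle length (needed for wrap-around distances);
#'   defaults to the layout total.
#' @return Data frame with one row per junction.
#' @export
junction_report <- function(layout, annotation, genome_length = NULL) {
  stopifnot(inherits(layout, "quadripartite_layout"), isTRUE(layout$found))
  G <- if (is.null(genome_length))
    layout$lsc_len + layout$ssc_len + 2L * layout$ir_len else genome_length
  if (!is.null(annotation) && nrow(annotation))
    annotation <- validate_annotation(annotation)
  if (is.null(annotation) || nrow(annotation) == 0L) {
    warning("empty annotation: junction contexts are empty")
    return(data.frame(junction = names(layout$junctions),
                      pos = unname(layout$junctions),
                      left_gene = NA_character_, left_dist = NA_integer_,
                      right_gene = NA_character_, right_dist = NA_integer_,
                      spanning_gene = NA_character_, overlap = NA_integer_,
                      spanning_strand = NA_character_,
                      stringsAsFactors = FALSE))
  }
  genes <- unique(annotation$gene)
  gs <- vapply(genes, function(g) min(annotation$start[annotation$gene == g]),
               integer(1))
  ge <- vapply(genes, function(g) max(annotation$end[annotation$gene == g]),
               integer(1))
  gstr <- vapply(genes, function(g)
    annotation$strand[annotation$gene == g][1], character(1))
  rows <- lapply(seq_along(layout$junctions), function(i) {
    b <- unname(layout$junctions[i])
    spanning <- which(gs <= b & ge > b)
    sp_gene <- if (length(spanning)) genes[spanning[1]] else NA_character_
    ovl <- if (length(spanning)) ge[spanning[1]] - b else NA_integer_
    non_span <- setdiff(seq_along(genes), spanning)
    dl <- (b - ge[non_span]) %% G
    dr <- (gs[non_span] - b - 1L) %% G
    li <- non_span[which.min(dl)]
    ri <- non_span[which.min(dr)]
    data.frame(junction = names(layout$junctions)[i], pos = b,
               left_gene = genes[li], left_dist = as.integer(min(dl)),
               right_gene = genes[ri], right_dist = as.integer(min(dr)),
               spanning_gene = sp_gene, overlap = ovl,
               spanning_strand = if (length(spanning))
                 gstr[spanning[1]] else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Stability score of a stem-loop candidate
#'
#' A simplified hairpin score standing in for a folding free energy:
#' `-(3 x GC pairs + 2 x AT pairs) + lambda x max(0, loop - 4)`. More
#' negative is more stable. Stems with more than `max_mismatch`
#' non-complementary columns score `+Inf` (rejected).
#'
#' @param candidate The full stem-loop sequence (5' stem + loop + 3' stem).
#' @param stem_len Stem length in bp.
#' @param lambda Loop-length penalty per base beyond 4 (default 0.5).
#' @param max_mismatch Allowed non-pairing stem columns (default 0).
#' @return A single numeric score (dimensionless).
#' @export
hairpin_score <- function(candidate, stem_len, lambda = 0.5,
                          max_mismatch = 0L) {
  n <- nchar(candidate)
  loop_len <- n - 2L * stem_len
  if (loop_len < 0L) stop("candidate shorter than twice the stem", call. = FALSE)
  ch <- seq_chars(toupper(candidate))
  left <- ch[seq_len(stem_len)]
  right <- ch[seq(n, n - stem_len + 1L)]      # reversed 3' stem
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  paired <- left == unname(comp[right])
  if (sum(!paired) > max_mismatch) return(Inf)
  gc <- sum(paired & left %in% c("G", "C"))
  at <- sum(paired & left %in% c("A", "T"))
  -(3 * gc + 2 * at) + lambda * max(0, loop_len - 4L)
}

#' Find small inversions (short stem-loops)
#'
#' Three filters in order: (i) maximal perfect (or
#' `max_stem_mismatch`-tolerant) inverted-repeat pairs with stem length in
#' `stem_range` and loop shorter than `max_loop`; (ii) hairpin stability,
#' [hairpin_score()] at most `score_threshold`; (iii) homology - the SI
#' span must align to at least one comparator genome at `min_homology`
#' identity, with the loop orientation (same or inverted) recorded per
#' comparator. Candidates passing (ii) but failing (iii) are returned as
#' putative, not dropped.
#'
#' @param genome DNA string or [annotated_genome()].
#' @param stem_range Stem length bounds (within `[5, 50]`).
#' @param max_loop Loop must be shorter than this (default 50).
#' @param comparators Named character vector of comparator sequences
#'   (genomes or orthologous regions); `NULL` means all stable candidates
#'   are putative.
#' @param min_homology Identity threshold over the SI span (default 0.90).
#' @param max_stem_mismatch Stem mismatch budget (default 0, perfect stems).
#' @param score_threshold Hairpin score cutoff (default -10).
#' @param lambda Loop penalty of the score.
#' @return List with data frames `confirmed` and `putative` (columns
#'   `start`, `end`, `stem_len`, `loop_len`, `score`, `support` - a
#'   semicolon-joined `comparator:identity:orientation` string).
#' @export
find_small_inversions <- function(genome, stem_range = c(11L, 24L),
                                  max_loop = 50L, comparators = NULL,
                                  min_homology = 0.90,
                                  max_stem_mismatch = 0L,
                                  score_threshold = -10, lambda = 0.5) {
  if (stem_range[1] < 5L || stem_range[2] > 50L)
    stop("stem_range must lie within [5, 50]", call. = FALSE)
  s <- if (inherits(genome, "annotated_genome")) genome$sequence else genome
  empty <- data.frame(start = integer(0), end = integer(0),
                      stem_len = integer(0), loop_len = integer(0),
                      score = numeric(0), support = character(0),
                      stringsAsFactors = FALSE)
  iv <- self_inverted_matches(s, stem_range[1], max_stem_mismatch)
  if (!nrow(iv)) return(list(confirmed = empty, putative = empty))
  loop <- iv$start2 - (iv$start1 + iv$len)
  keep <- iv$len >= stem_range[1] & iv$len <= stem_range[2] &
    loop >= 0L & loop < max_loop
  iv <- iv[keep, , drop = FALSE]; loop <- loop[keep]
  if (!nrow(iv)) return(list(confirmed = empty, putative = empty))
  cand <- data.frame(start = iv$start1, end = iv$start2 + iv$len - 1L,
                     stem_len = iv$len, loop_len = loop,
                     stringsAsFactors = FALSE)
  cand$score <- vapply(seq_len(nrow(cand)), function(i)
    hairpin_score(substr(s, cand$start[i], cand$end[i]), cand$stem_len[i],
                  lambda = lambda, max_mismatch = max_stem_mismatch),
    numeric(1))
  cand <- cand[cand$score <= score_threshold, , drop = FALSE]
  if (!nrow(cand)) return(list(confirmed = empty, putative = empty))
  cand$support <- ""
  if (!is.null(comparators) && length(comparators)) {
    if (is.null(names(comparators)))
      names(comparators) <- sprintf("comparator%d", seq_along(comparators))
    for (i in seq_len(nrow(cand))) {
      span <- substr(s, cand$start[i], cand$end[i])
      sup <- character(0)
      for (cn in names(comparators)) {
        h <- si_homology(span, comparators[[cn]], cand$stem_len[i],
                         cand$loop_len[i])
        if (!is.null(h) && h$identity >= min_homology)
          sup <- c(sup, sprintf("%s:%.3f:%s", cn, h$identity, h$orientation))
      }
      cand$support[i] <- paste(sup, collapse = ";")
    }
  }
  rownames(cand) <- NULL
  list(confirmed = cand[nzchar(cand$support), , drop = FALSE],
       putative = cand[!nzchar(cand$support), , drop = FALSE])
}

# identity of an SI span against a comparator, plus loop orientation
si_homology <- function(span, comparator, stem_len, loop_len) {
  if (nchar(comparator) < nchar(span) * 0.5) return(NULL)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(span), Biostrings::DNAString(comparator),
    type = "global-local", substitutionMatrix = dna_submat(),
        gapOpening = 4, gapExtension = 2)
  p <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
  q <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
  ident <- sum(p == q & p != "-") / nchar(span)
  # loop orientation: compare the comparator's loop segment to the span's
  # loop, forward vs reverse-complement
  pat_pos <- cumsum(p != "-")
  loop_cols <- pat_pos > stem_len & pat_pos <= stem_len + loop_len & p != "-"
  sub_loop <- paste(q[loop_cols & q != "-"], collapse = "")
  span_loop <- substr(span, stem_len + 1L, stem_len + loop_len)
  fwd <- align_identity(span_loop, sub_loop)
  rev_ <- align_identity(span_loop, revcomp(sub_loop))
  list(identity = ident,
       orientation = if (!is.na(fwd) && (is.na(rev_) || fwd >= rev_))
         "same" else "inverted")
}

align_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) return(NA_real_)
  if (nchar(a) == nchar(b)) return(hamming_identity(a, b))
  pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                      Biostrings::DNAString(b),
                                      type = "global", substitutionMatrix = dna_submat(),
                                        gapOpening = 4, gapExtension = 2)
  p <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
  q <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
  sum(p == q & p != "-") / max(nchar(a), nchar(b))
}
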