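# Low-level sequence helpers shared across modules. All public coordinates
# are 1-based inclusive; wrapping on the circle is handled by the callers.

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (ACGTN).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Complement (no reversal) of DNA strings
#' @param x Character vector.
#' @return Character vector.
#' @keywords internal
complement_dna <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

# split a string into single characters
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# integer codes for fast comparison (utf8 of A,C,G,T)
seq_ints <- function(s) utf8ToInt(s)

# run a block with a private RNG stream; the caller's .Random.seed is
# untouched, and a given `seed` always yields the same draws
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Random DNA with a target A+T fraction
#'
#' Bases are drawn i.i.d. with P(A) = P(T) = at_fraction/2 and
#' P(C) = P(G) = (1 - at_fraction)/2. Runs of a single base at least
#' `max_run + 1` long are broken by substituting a base of the other class,
#' so that planted homopolymers are the only runs reaching the inventory
#' threshold.
#'
#' @param n Length in bp.
#' @param at_fraction Target A+T proportion in `[0, 1]`.
#' @param max_run Longest run of one base left intact (default 6).
#' @return A single DNA string of length `n`.
#' @keywords internal
random_dna <- function(n, at_fraction = 0.63, max_run = 6L) {
  if (n <= 0) return("")
  p <- c(A = at_fraction / 2, T = at_fraction / 2,
         C = (1 - at_fraction) / 2, G = (1 - at_fraction) / 2)
  b <- sample(names(p), n, replace = TRUE, prob = p)
  b <- break_runs(b, max_run)
  paste(b, collapse = "")
}

# substitute every (max_run+1)-th base of a run so no run exceeds max_run
break_runs <- function(chars, max_run = 6L) {
  r <- rle(chars)
  if (!any(r$lengths > max_run)) return(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  alt <- c(A = "C", C = "A", G = "T", T = "G", N = "A")
  for (i in which(r$lengths > max_run)) {
    off <- seq(max_run, r$lengths[i] - 1L, by = max_run)
    pos <- starts[i] + off
    chars[pos] <- alt[[r$values[i]]]
  }
  chars
}

# maximal single-base runs in a character string; returns data.frame
base_runs <- function(s) {
  chars <- seq_chars(s)
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  data.frame(base = r$values, start = ends - r$lengths + 1L,
             length = r$lengths, stringsAsFactors = FALSE)
}

# substring on a circular sequence (1-based start, may wrap past the end)
circular_substr <- function(s, start, len) {
  n <- nchar(s)
  start <- ((start - 1L) %% n) + 1L
  if (start + len - 1L <= n) return(substr(s, start, start + len - 1L))
  paste0(substr(s, start, n), substr(strrep(s, ceiling(len / n)), 1L, start + len - 1L - n))
}

# exact k-mer index of a string: environment mapping k-mer -> start positions
kmer_index <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(list2env(list(), hash = TRUE))
  km <- substring(s, 1:(n - k + 1L), k:n)
  list2env(split(seq_len(n - k + 1L), km), hash = TRUE)
}

kmer_lookup <- function(idx, kmer) {
  v <- idx[[kmer]]
  if (is.null(v)) integer(0) else v
}

# hamming identity of two equal-length strings (NA-safe, 0-length -> NA)
hamming_identity <- function(a, b) {
  if (nchar(a) == 0L || nchar(a) != nchar(b)) return(NA_real_)
  1 - sum(seq_ints(a) != seq_ints(b)) / nchar(a)
}

# round half away from zero (printed tables use commercial rounding;
# base round() would give 0.5 -> 0)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# cached nucleotide substitution matrix: pairwiseAlignment otherwise
# rebuilds quality-based matrices on every call, dominating runtime
.pk_cache <- new.env(parent = emptyenv())
dna_submat <- function() {
  if (is.null(.pk_cache$submat))
    .pk_cache$submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1.5, baseOnly = TRUE)
  .pk_cache$submat
}

# merge 1-based inclusive intervals given as a two-column matrix/data.frame,
# returning a data.frame(start, end) of the union
merge_intervals <- function(start, end) {
  if (length(start) == 0L) return(data.frame(start = integer(0), end = integer(0)))
  ir <- IRanges::reduce(IRanges::IRanges(start = start, end = end))
  data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
}
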