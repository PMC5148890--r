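# Local alignment kernel.
#
# All clustering decisions in this package rest on one fixed-parameter
# Smith-Waterman kernel (match +2, mismatch -3, gap open -5, gap extend -2;
# N never matches anything, including another N), mirroring the local
# (-G 0) identity convention of CD-HIT-EST: identity is identical columns
# divided by alignment columns, with gap positions counting as columns.

#' Best local alignment between two nucleotide sequences
#'
#' Computes the best-scoring Smith-Waterman local alignment under the
#' package's fixed scoring scheme and summarizes it as the quantities
#' thresholded by clustering: alignment identity, and the aligned fraction
#' of the shorter and of the longer sequence.  With `both_strands = TRUE`
#' the better of the forward and reverse-complement orientations of `b`
#' is used (ties go to the forward strand).
#'
#' @param a,b nucleotide strings (or single-row record data.frames).
#' @param both_strands consider the reverse complement of `b` as well.
#' @return A list with `identity`, `cov_short`, `cov_long`, `strand`
#'   (`"+"`/`"-"`), `score`, and the 0-based half-open alignment spans
#'   `a_start`, `a_end`, `b_start`, `b_end` (always reported on the
#'   forward strand of each input).
#' @export
local_align <- function(a, b, both_strands = TRUE) {
  a <- one_seq(a); b <- one_seq(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  fwd <- .sw_align_cpp(a, b)
  best <- fwd; strand <- "+"
  if (both_strands) {
    rc <- .sw_align_cpp(a, .revcomp_cpp(b))
    if (rc$score > fwd$score) { best <- rc; strand <- "-" }
  }
  la <- nchar(a); lb <- nchar(b)
  bs <- best$b_start; be <- best$b_end
  if (strand == "-") { tmp <- bs; bs <- lb - be; be <- lb - tmp }
  span_a <- best$a_end - best$a_start
  span_b <- be - bs
  cov_a <- span_a / la
  cov_b <- span_b / lb
  shorter_is_a <- la <= lb
  list(identity = if (best$columns > 0) best$matches / best$columns else 0,
       cov_short = if (shorter_is_a) cov_a else cov_b,
       cov_long = if (shorter_is_a) cov_b else cov_a,
       strand = strand,
       score = best$score,
       a_start = best$a_start, a_end = best$a_end,
       b_start = bs, b_end = be)
}

one_seq <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    return(x$seq)
  }
  stopifnot(is.character(x), length(x) == 1L)
  x
}

# Smallest guaranteed exact-match run (over {A,C,G,T}) implied by an
# alignment at identity >= c whose span on the shorter sequence is at
# least min_span columns.  Used to size the k-mer prescreen so that it can
# never discard a pair the thresholds would accept.
guaranteed_run <- function(c, min_span) {
  min_span <- max(1L, as.integer(ceiling(min_span)))
  if (c >= 1) return(min_span)
  max(0L, as.integer(floor(c * min_span / ((1 - c) * min_span + 1))))
}

# TRUE when the pair can be skipped without aligning: no shared k-mer of
# the guaranteed length exists on either strand.  k is capped at 24 so the
# screen stays byte-cheap; pairs below a usable run length are never
# screened out.
prescreen_skip <- function(a, b, c, aS, both_strands) {
  ls <- min(nchar(a), nchar(b))
  g <- guaranteed_run(c, aS * ls)
  k <- min(24L, g)
  if (k < 4L) return(FALSE)
  if (.kmer_share_cpp(a, b, k)) return(FALSE)
  if (both_strands && .kmer_share_cpp(a, .revcomp_cpp(b), k)) return(FALSE)
  TRUE
}
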