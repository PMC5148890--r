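# Greedy incremental clustering with CD-HIT-EST identity/coverage
# semantics: a candidate joins the first existing cluster (in creation
# order) whose representative it matches at identity >= c, aligned
# fraction of the shorter sequence >= aS and aligned fraction of the
# longer sequence >= aL; otherwise it founds a new cluster.  Records are
# processed longest-first (ties by id), so every representative is a
# longest member of its cluster and the result is independent of input
# order.

# tolerance for comparing rational alignment fractions against thresholds
EPS <- 1e-9

#' Clustering thresholds
#'
#' @param c minimum alignment identity, in (0, 1].
#' @param aS minimum aligned fraction of the shorter sequence, in (0, 1].
#' @param aL minimum aligned fraction of the longer sequence, in (0, 1].
#' @param both_strands consider reverse-complement matches (CD-HIT-EST's
#'   default behaviour for nucleotide input).
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(c = 1.0, aS = 1.0, aL = 0.005,
                           both_strands = TRUE) {
  stopifnot(c > 0, c <= 1, aS > 0, aS <= 1, aL > 0, aL <= 1)
  structure(list(c = c, aS = aS, aL = aL, both_strands = both_strands),
            class = "cluster_params")
}

new_cluster_set <- function(members, params) {
  structure(list(members = members, params = params), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters, %d members\n",
              length(unique(x$members$cluster)), nrow(x$members)))
  invisible(x)
}

#' Greedy incremental clustering of nucleotide sequences
#'
#' @param records a record data.frame (see [seq_records()]).
#' @param params a [cluster_params()] object.
#' @return A `cluster_set`: a list with `members` (data.frame with columns
#'   `cluster` (0-based), `id`, `length`, `is_rep`, `identity`, `strand`,
#'   `cov_short`, `cov_long`) and `params`.
#' @export
greedy_cluster <- function(records, params = cluster_params()) {
  if (nrow(records) == 0L) stop("no sequences")
  if (anyDuplicated(records$id)) {
    stop("duplicate id: ", records$id[duplicated(records$id)][[1L]])
  }
  len <- nchar(records$seq)
  ord <- order(-len, records$id, method = "radix")
  ids <- records$id[ord]; seqs <- records$seq[ord]; len <- len[ord]

  rep_seq <- character(0L); rep_len <- integer(0L)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    joined <- FALSE
    for (cl in seq_along(rep_seq)) {
      hit <- try_member(seqs[[i]], len[[i]], rep_seq[[cl]], rep_len[[cl]],
                        params)
      if (!is.null(hit)) {
        out[[i]] <- data.frame(cluster = cl - 1L, id = ids[[i]],
                               length = len[[i]], is_rep = FALSE,
                               identity = hit$identity, strand = hit$strand,
                               cov_short = hit$cov_short,
                               cov_long = hit$cov_long,
                               stringsAsFactors = FALSE)
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      rep_seq <- c(rep_seq, seqs[[i]]); rep_len <- c(rep_len, len[[i]])
      out[[i]] <- data.frame(cluster = length(rep_seq) - 1L, id = ids[[i]],
                             length = len[[i]], is_rep = TRUE,
                             identity = NA_real_, strand = "+",
                             cov_short = NA_real_, cov_long = NA_real_,
                             stringsAsFactors = FALSE)
    }
  }
  members <- do.call(rbind, out)
  members <- members[order(members$cluster, !members$is_rep, members$id), ]
  rownames(members) <- NULL
  new_cluster_set(members, params)
}

# alignment summary if (member, rep) passes all thresholds, else NULL
try_member <- function(seq, len, rseq, rlen, params) {
  if (prescreen_skip(seq, rseq, params$c, params$aS, params$both_strands)) {
    return(NULL)
  }
  al <- local_align(seq, rseq, both_strands = params$both_strands)
  if (al$identity + EPS >= params$c &&
      al$cov_short + EPS >= params$aS &&
      al$cov_long + EPS >= params$aL) al else NULL
}

#' Remove strictly redundant transcripts within one assembly
#'
#' Greedy clustering at 100% local identity over 100% of the shorter
#' sequence (`c = 1.0, aS = 1.0, aL = 0.005`, both strands): a transcript
#' is removed exactly when it, or its reverse complement, occurs as an
#' exact substring of a retained longer (or equal-length, smaller-id)
#' transcript.
#'
#' @param records records from a single assembly.
#' @return A list with `retained` (representatives, longest first) and
#'   `clusters` (the underlying `cluster_set`).
#' @export
dedup_exact <- function(records) {
  cs <- greedy_cluster(records, cluster_params(c = 1.0, aS = 1.0,
                                               aL = 0.005,
                                               both_strands = TRUE))
  reps <- cs$members$id[cs$members$is_rep]
  reps <- reps[order(match(reps, cs$members$id[cs$members$is_rep]))]
  retained <- records[match(reps, records$id), , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, clusters = cs)
}

#' Cluster counts per representative
#'
#' @param clusters a `cluster_set`.
#' @return data.frame with one row per cluster: `cluster`, `rep_id`,
#'   `n_members`.
#' @export
cluster_summary <- function(clusters) {
  m <- clusters$members
  reps <- m[m$is_rep, c("cluster", "id")]
  names(reps)[2L] <- "rep_id"
  cnt <- as.data.frame(table(cluster = m$cluster), stringsAsFactors = FALSE)
  cnt$cluster <- as.integer(cnt$cluster)
  out <- merge(reps, cnt, by = "cluster")
  names(out)[3L] <- "n_members"
  out[order(out$cluster), ]
}
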