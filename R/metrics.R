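# Assembly statistics, annotatability metrics from tabular
# similarity-search hits, the aS sweep, and reference-recovery
# comparison.

#' N50 of a set of sequence lengths
#'
#' The length at which the cumulative sum of lengths, sorted descending,
#' first reaches at least half of the total.
#'
#' @param lengths integer vector of sequence lengths.
#' @return The N50 length.
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) stop("empty length list")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[[which(cumsum(s) >= sum(s) / 2)[[1L]]]]
}

#' Standard assembly statistics
#'
#' @param records a record data.frame, or an integer vector of lengths.
#' @return data.frame with `n_transcripts`, `smallest`, `largest`,
#'   `median`, `total_size`, `n50`.
#' @export
assembly_stats <- function(records) {
  lengths <- if (is.data.frame(records)) nchar(records$seq)
             else as.integer(records)
  if (!length(lengths)) stop("empty length list")
  data.frame(n_transcripts = length(lengths),
             smallest = min(lengths),
             largest = max(lengths),
             median = stats::median(lengths),
             total_size = sum(lengths),
             n50 = n50(lengths))
}

#' Read a 12-column tabular similarity-search hit file
#'
#' The BLAST tabular dialect: qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore.
#'
#' @param path path to the hit file (TSV, no header).
#' @return data.frame with the 12 standard columns.
#' @export
read_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) != 12L) stop("expected 12 tab-separated columns, got ",
                            ncol(df))
  names(df) <- cols
  df
}

#' Annotatability counts from a hit table
#'
#' Counts queries with at least one qualifying hit (each query counts
#' once however many hits it has) and the number of distinct subjects
#' over qualifying hits.  A hit is qualifying when its e-value is at or
#' below `max_evalue`.
#'
#' @param hits a hit data.frame (see [read_hits()]).
#' @param query_ids the full set of query ids (e.g. uniCDS ids); hits
#'   referencing unknown queries are dropped with a warning.
#' @param max_evalue inclusive e-value threshold (default 1e-3).
#' @return list with `n_queries_with_hit`, `n_unique_subjects`.
#' @export
annotatability <- function(hits, query_ids, max_evalue = 1e-3) {
  unknown <- !(hits$qseqid %in% query_ids)
  if (any(unknown)) {
    warning(sum(unknown), " hit(s) referencing unknown queries excluded")
    hits <- hits[!unknown, , drop = FALSE]
  }
  ok <- hits$evalue <= max_evalue
  list(n_queries_with_hit = length(unique(hits$qseqid[ok])),
       n_unique_subjects = length(unique(hits$sseqid[ok])))
}

#' Sweep the aS coverage ratio of the CDS clustering pass
#'
#' Re-clusters the pooled CDS set once per aS value and reports the
#' uniCDS count (and, when a hit table is given, the annotatability of
#' the representatives).  The largest aS below 1.00 at which the number
#' of unique subjects drops under the aS = 1.00 baseline is flagged as
#' the information-loss onset.
#'
#' @param cds a CDS data.frame from [extract_cds()].
#' @param aS_values coverage ratios to sweep; 1.0 is added when missing
#'   (it is the baseline).
#' @param params a [consensus_params()] object supplying identity/aL.
#' @param hits optional hit data.frame with CDS ids as queries.
#' @param max_evalue e-value threshold for the annotatability counts.
#' @return data.frame with one row per aS value (descending): `aS`,
#'   `n_uniCDS`, and with hits `n_queries_with_hit`, `n_unique_subjects`.
#'   Attributes: `loss_onset_aS` (`NA` when no loss is seen) and
#'   `uniCDS_monotone` (`FALSE` when the uniCDS count increased while aS
#'   decreased, which is reported rather than silently accepted).
#' @export
as_sweep <- function(cds, aS_values = c(1.00, 0.99, 0.98, 0.97, 0.96,
                                        0.95, 0.90, 0.85, 0.80, 0.75),
                     params = consensus_params(), hits = NULL,
                     max_evalue = 1e-3) {
  stopifnot(all(aS_values > 0), all(aS_values <= 1))
  aS_values <- sort(unique(c(1.0, aS_values)), decreasing = TRUE)
  recs <- data.frame(id = cds$cds_id, source = cds$source,
                     seq = cds$nt_seq, stringsAsFactors = FALSE)
  rows <- lapply(aS_values, function(aS) {
    cs <- greedy_cluster(recs, cluster_params(
      c = params$cds_identity, aS = aS, aL = params$cds_aL,
      both_strands = params$cds_both_strands))
    reps <- cs$members$id[cs$members$is_rep]
    row <- data.frame(aS = aS, n_uniCDS = length(reps))
    if (!is.null(hits)) {
      ann <- annotatability(hits[hits$qseqid %in% reps, , drop = FALSE],
                            query_ids = reps, max_evalue = max_evalue)
      row$n_queries_with_hit <- ann$n_queries_with_hit
      row$n_unique_subjects <- ann$n_unique_subjects
    }
    row
  })
  out <- do.call(rbind, rows)
  loss <- NA_real_
  if (!is.null(hits)) {
    baseline <- out$n_unique_subjects[out$aS == 1.0][[1L]]
    below <- out$aS[out$aS < 1.0 & out$n_unique_subjects < baseline]
    if (length(below)) loss <- max(below)
  }
  attr(out, "loss_onset_aS") <- loss
  attr(out, "uniCDS_monotone") <- !is.unsorted(rev(out$n_uniCDS))
  out
}

#' Compare assembled transcripts against a reference transcriptome
#'
#' An original is recovered when some assembled transcript aligns to it
#' at identity at least `min_identity` over at least
#' `min_cov_of_original` of the original's length; an assembled
#' transcript qualifying against no original is an invented
#' (bioinformatic artifact) transcript.  When a hit table is supplied
#' (queries = assembled, subjects = originals) the rule is applied to
#' its rows; otherwise the built-in local-alignment kernel is used.
#'
#' @param assembled,originals record data.frames.
#' @param min_identity minimum nucleotide identity (default 0.98).
#' @param min_cov_of_original minimum covered fraction of the original
#'   transcript (default 0.5); coverage is the single best alignment's
#'   span on the original (no chaining of disjoint fragments).
#' @param hits optional hit data.frame.
#' @return A list of class `recovery_report`: `n_original`,
#'   `n_assembled`, `missing_original_ids`, `invented_assembled_ids`,
#'   `n_missing`, `n_invented`, and the rule parameters.
#' @export
compare_to_reference <- function(assembled, originals,
                                 min_identity = 0.98,
                                 min_cov_of_original = 0.5,
                                 hits = NULL) {
  stopifnot(nrow(assembled) > 0, nrow(originals) > 0)
  olen <- stats::setNames(nchar(originals$seq), originals$id)
  recovered <- character(0L)
  qualifying_assembled <- character(0L)
  if (!is.null(hits)) {
    need <- olen[hits$sseqid]
    ok <- !is.na(need) &
      hits$pident >= 100 * min_identity - 100 * EPS &
      hits$length >= min_cov_of_original * need - EPS
    recovered <- unique(hits$sseqid[ok])
    qualifying_assembled <- unique(hits$qseqid[ok])
  } else {
    for (i in seq_len(nrow(assembled))) {
      a <- assembled$seq[[i]]
      for (j in seq_len(nrow(originals))) {
        o <- originals$seq[[j]]
        need_span <- min_cov_of_original * nchar(o)
        if (prescreen_skip(a, o, min_identity,
                           min(1, need_span / min(nchar(a), nchar(o))),
                           both_strands = TRUE)) next
        al <- local_align(a, o, both_strands = TRUE)
        if (al$identity + EPS >= min_identity &&
            (al$b_end - al$b_start) + EPS >= need_span) {
          recovered <- c(recovered, originals$id[[j]])
          qualifying_assembled <- c(qualifying_assembled, assembled$id[[i]])
        }
      }
    }
    recovered <- unique(recovered)
    qualifying_assembled <- unique(qualifying_assembled)
  }
  structure(list(
    n_original = nrow(originals),
    n_assembled = nrow(assembled),
    missing_original_ids = setdiff(originals$id, recovered),
    invented_assembled_ids = setdiff(assembled$id, qualifying_assembled),
    n_missing = nrow(originals) - length(recovered),
    n_invented = nrow(assembled) - length(qualifying_assembled),
    min_identity = min_identity,
    min_cov_of_original = min_cov_of_original),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "recovery_report: %d/%d originals missing, %d/%d assembled invented\n",
    x$n_missing, x$n_original, x$n_invented, x$n_assembled))
  invisible(x)
}

#' Bin a recovery report by read coverage of the originals
#'
#' @param report a `recovery_report`.
#' @param coverage named numeric vector: original id -> fold coverage
#'   (every original in the report must be present).
#' @param threshold fold-coverage cutoff (default 10).
#' @param original_ids the full set of original ids the report was
#'   computed over; defaults to the union of missing ids and `coverage`
#'   names restricted to the report.
#' @return list with `frac_missing_below` (fraction of missing originals
#'   with coverage < threshold; `NA` when nothing is missing) and
#'   `frac_recovered_at_or_above` (fraction of recovered originals with
#'   coverage >= threshold; `NA` when nothing is recovered).
#' @export
coverage_binned_recovery <- function(report, coverage, threshold = 10,
                                     original_ids = names(coverage)) {
  missing <- report$missing_original_ids
  recovered <- setdiff(original_ids, missing)
  need <- union(missing, recovered)
  absent <- setdiff(need, names(coverage))
  if (length(absent)) stop("no coverage entry for: ", absent[[1L]])
  list(frac_missing_below = if (length(missing))
         mean(coverage[missing] < threshold) else NA_real_,
       frac_recovered_at_or_above = if (length(recovered))
         mean(coverage[recovered] >= threshold) else NA_real_)
}
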