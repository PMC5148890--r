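# Six-frame ORF detection and CDS extraction.
#
# For each of the six reading frames the maximal stop-free codon
# stretches are enumerated.  A stretch is reported from its first ATG
# when one exists (completeness "complete" when a stop follows,
# "3prime_partial" when the stretch runs off the sequence end); a stretch
# without an ATG is reported only when it abuts the 5' end of its reading
# direction with no upstream stop ("5prime_partial", or "internal" when
# it runs off both ends).  Codons containing N translate to X and never
# count as stops.  The stop codon is excluded from the reported sequence
# and coordinates.  Only the single longest qualifying ORF per stretch is
# reported (no nested sub-ORFs at internal ATGs).

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Detect open reading frames in one transcript
#'
#' @param record a single-row record data.frame, or a nucleotide string.
#' @param min_aa minimum ORF length in amino acids, inclusive (default
#'   100, the TransDecoder-style floor).
#' @param id,source record id / assembly label when `record` is a bare
#'   string.
#' @return A data.frame of CDS records with columns `transcript_id`,
#'   `source`, `strand`, `frame`, `start`, `end` (0-based half-open on
#'   the forward strand of the transcript), `aa_len`, `nt_seq`
#'   (strand-adjusted, 5'->3'), `completeness`; sorted by `aa_len`
#'   descending, then strand (`+` first), then `start`.  Zero rows when
#'   no ORF qualifies.
#' @export
find_orfs <- function(record, min_aa = 100L, id = NULL, source = NA_character_) {
  stopifnot(min_aa >= 1L)
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    id <- record$id; source <- record$source; s <- record$seq
  } else {
    s <- clean_seq(record)
    if (is.null(id)) id <- "seq"
  }
  L <- nchar(s)
  hits <- list()
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") s else .revcomp_cpp(s)
    for (f in 0:2) {
      ncod <- (L - f) %/% 3L
      if (ncod < 1L) next
      starts <- f + 1L + 3L * (0:(ncod - 1L))
      codons <- substring(ss, starts, starts + 2L)
      stop_idx <- which(codons %in% STOP_CODONS)
      bounds <- c(0L, stop_idx, ncod + 1L)
      for (b in seq_len(length(bounds) - 1L)) {
        i1 <- bounds[[b]] + 1L
        i2 <- bounds[[b + 1L]] - 1L
        if (i2 < i1) next
        has_stop_after <- bounds[[b + 1L]] <= ncod
        atg <- which(codons[i1:i2] == "ATG")
        if (length(atg)) {
          o1 <- i1 + atg[[1L]] - 1L
          completeness <- if (has_stop_after) "complete" else "3prime_partial"
        } else if (i1 == 1L) {
          # stretch abuts the 5' end of this reading direction, no
          # upstream stop
          o1 <- i1
          completeness <- if (has_stop_after) "5prime_partial" else "internal"
        } else {
          next
        }
        aa <- i2 - o1 + 1L
        if (aa < min_aa) next
        s0 <- f + (o1 - 1L) * 3L        # 0-based on ss
        e0 <- f + i2 * 3L
        if (strand == "+") { st <- s0; en <- e0 }
        else { st <- L - e0; en <- L - s0 }
        hits[[length(hits) + 1L]] <- data.frame(
          transcript_id = id, source = source, strand = strand,
          frame = f, start = st, end = en, aa_len = aa,
          nt_seq = substr(ss, s0 + 1L, e0),
          completeness = completeness, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(empty_cds())
  out <- do.call(rbind, hits)
  out <- out[order(-out$aa_len, out$strand, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_cds <- function() {
  data.frame(transcript_id = character(0), source = character(0),
             strand = character(0), frame = integer(0), start = integer(0),
             end = integer(0), aa_len = integer(0), nt_seq = character(0),
             completeness = character(0), stringsAsFactors = FALSE)
}

#' Extract all qualifying CDSs from a set of transcripts
#'
#' Runs [find_orfs()] on every record and numbers the CDSs per transcript
#' in output order: `<transcript id><sep>cds<k>`.
#'
#' @param records a record data.frame.
#' @param min_aa minimum ORF length in amino acids.
#' @param sep separator used to build CDS ids.
#' @return A data.frame of CDS records with a leading `cds_id` column.
#' @export
extract_cds <- function(records, min_aa = 100L, sep = "|") {
  if (anyDuplicated(records$id)) {
    stop("duplicate id: ", records$id[duplicated(records$id)][[1L]])
  }
  parts <- lapply(seq_len(nrow(records)), function(i) {
    orfs <- find_orfs(records[i, , drop = FALSE], min_aa = min_aa)
    if (nrow(orfs)) {
      orfs$cds_id <- paste0(orfs$transcript_id, sep, "cds", seq_len(nrow(orfs)))
    } else {
      orfs$cds_id <- character(0)
    }
    orfs
  })
  out <- do.call(rbind, parts)
  out <- out[, c("cds_id", "transcript_id", "source", "strand", "frame",
                 "start", "end", "aa_len", "nt_seq", "completeness")]
  rownames(out) <- NULL
  out
}

#' Per-transcript CDS counts
#'
#' @param cds a CDS data.frame from [extract_cds()].
#' @return data.frame with columns `transcript_id`, `n_cds`.
#' @export
cds_counts <- function(cds) {
  tab <- table(cds$transcript_id)
  data.frame(transcript_id = names(tab), n_cds = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Write CDS records as a nucleotide FASTA
#'
#' The description field carries strand, 1-based inclusive coordinates on
#' the source transcript, and completeness.
#'
#' @param cds a CDS data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path) {
  hdr <- sprintf("%s %s:%d-%d(%s) %s", cds$cds_id, cds$transcript_id,
                 cds$start + 1L, cds$end, cds$strand, cds$completeness)
  x <- Biostrings::DNAStringSet(stats::setNames(cds$nt_seq, hdr))
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}
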