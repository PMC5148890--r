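#' @useDynLib transcat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# Internal canonical representation of a set of sequence records: a
# data.frame with columns id (unique), source (assembly label) and seq
# (uppercase nucleotides over A/C/G/T/N).

AMBIGUITY_FROM <- "RYSWKMBDHVryswkmbdhv"
AMBIGUITY_TO   <- "NNNNNNNNNNNNNNNNNNNN"

#' Construct a set of sequence records
#'
#' @param id character vector of unique identifiers.
#' @param seq character vector of nucleotide sequences.
#' @param source assembly label(s), recycled to the number of records.
#' @return A data.frame with columns `id`, `source`, `seq`.
#' @export
seq_records <- function(id, seq, source = NA_character_) {
  stopifnot(length(id) == length(seq))
  df <- data.frame(id = as.character(id),
                   source = rep_len(as.character(source), length(id)),
                   seq = clean_seq(seq),
                   stringsAsFactors = FALSE)
  validate_records(df)
  df
}

clean_seq <- function(seq) {
  chartr(AMBIGUITY_FROM, AMBIGUITY_TO, toupper(as.character(seq)))
}

validate_records <- function(df) {
  if (nrow(df) == 0L) stop("no sequences")
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) stop("duplicate id: ", dup[[1L]])
  if (any(!nzchar(df$seq))) {
    stop("empty sequence for id: ", df$id[!nzchar(df$seq)][[1L]])
  }
  bad <- regexpr("[^ACGTN]", df$seq)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[[1L]]
    stop(sprintf("non-nucleotide residue '%s' at position %d in '%s'",
                 substr(df$seq[i], bad[i], bad[i]), bad[i], df$id[i]))
  }
  invisible(df)
}

#' Read a FASTA file into sequence records
#'
#' Headers are truncated at the first whitespace to give the record id,
#' sequences are uppercased and IUPAC ambiguity codes other than N are
#' mapped to N.
#'
#' @param path path to a FASTA file.
#' @param source assembly label stored on every record (default `NA`).
#' @return A data.frame of records in file order (columns `id`, `source`,
#'   `seq`).
#' @export
read_fasta <- function(path, source = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("no sequences in ", path)
  ids <- sub("\\s.*$", "", names(x))
  seq_records(ids, as.character(x), source = source)
}

#' Write sequence records to FASTA
#'
#' Sequences are wrapped at 80 columns; ids are written verbatim.
#'
#' @param records a record data.frame (see [seq_records()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(records$seq, records$id))
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Prefix record ids with their assembly label
#'
#' Every id is rewritten as `<label><sep><original id>` and the `source`
#' field is set to the label, so the assembler of origin of each sequence
#' in a concatenated assembly stays traceable.
#'
#' @param records a record data.frame.
#' @param label assembly label; must be non-empty and contain neither
#'   whitespace nor `sep`.
#' @param sep provenance separator (default `"|"`).
#' @return A list with `records` (renamed) and `map` (data.frame with
#'   columns `old`, `new`).
#' @export
harmonize_names <- function(records, label, sep = "|") {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop("label must be a non-empty string")
  }
  if (grepl("\\s", label) || grepl(sep, label, fixed = TRUE)) {
    stop("label must not contain whitespace or the separator '", sep, "'")
  }
  new <- paste0(label, sep, records$id)
  if (anyDuplicated(new)) {
    stop("id collision after renaming: ", new[duplicated(new)][[1L]])
  }
  out <- records
  out$id <- new
  out$source <- label
  list(records = out, map = data.frame(old = records$id, new = new,
                                       stringsAsFactors = FALSE))
}

#' Split harmonized ids back into (label, original id)
#'
#' @param id character vector of harmonized ids.
#' @param sep provenance separator.
#' @return data.frame with columns `label`, `original`.
#' @export
split_harmonized <- function(id, sep = "|") {
  pos <- regexpr(sep, id, fixed = TRUE)
  if (any(pos < 0L)) stop("id without separator: ", id[pos < 0L][[1L]])
  data.frame(label = substr(id, 1L, pos - 1L),
             original = substr(id, pos + nchar(sep), nchar(id)),
             stringsAsFactors = FALSE)
}

#' Write a cluster set in the CD-HIT .clstr dialect
#'
#' Each cluster gets a `>Cluster N` header; member lines carry the member
#' length, id, and either `*` (representative) or `at <strand>/<pct>%`.
#'
#' @param clusters a `cluster_set` (see [greedy_cluster()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clstr <- function(clusters, path) {
  stopifnot(inherits(clusters, "cluster_set"))
  m <- clusters$members
  lines <- character(0L)
  for (cl in sort(unique(m$cluster))) {
    sub <- m[m$cluster == cl, , drop = FALSE]
    lines <- c(lines, sprintf(">Cluster %d", cl))
    tail <- ifelse(sub$is_rep, "*",
                   sprintf("at %s/%.2f%%", sub$strand, 100 * sub$identity))
    lines <- c(lines, sprintf("%d\t%dnt, >%s... %s",
                              seq_len(nrow(sub)) - 1L, sub$length, sub$id,
                              tail))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse a CD-HIT-style .clstr file
#'
#' Round-trips the structural fields written by [write_clstr()]: ids,
#' lengths, representative flags, strands, and identities to two decimal
#' places.  Alignment coverages are not stored in this format and come
#' back as `NA`.
#'
#' @param path path to a .clstr file.
#' @return A `cluster_set`.
#' @export
parse_clstr <- function(path) {
  lines <- readLines(path)
  cluster <- integer(0); id <- character(0); len <- integer(0)
  is_rep <- logical(0); identity <- numeric(0); strand <- character(0)
  cur <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln)) next
    if (startsWith(ln, ">Cluster")) {
      cur <- as.integer(sub("^>Cluster\\s+(\\d+)\\s*$", "\\1", ln))
      if (is.na(cur)) stop("malformed cluster header at line ", i)
      next
    }
    m <- regmatches(ln, regexec(
      "^\\d+\\t(\\d+)nt, >(.*)\\.\\.\\. (\\*|at ([+-])/([0-9.]+)%)\\s*$", ln))[[1L]]
    if (length(m) == 0L || is.na(cur)) stop("malformed member line at line ", i)
    cluster <- c(cluster, cur)
    len <- c(len, as.integer(m[[2L]]))
    id <- c(id, m[[3L]])
    rep <- identical(m[[4L]], "*")
    is_rep <- c(is_rep, rep)
    identity <- c(identity, if (rep) NA_real_ else as.numeric(m[[6L]]) / 100)
    strand <- c(strand, if (rep) "+" else m[[5L]])
  }
  if (length(cluster) == 0L) stop("no clusters in ", path)
  members <- data.frame(cluster = cluster, id = id, length = len,
                        is_rep = is_rep, identity = identity,
                        strand = strand,
                        cov_short = NA_real_, cov_long = NA_real_,
                        stringsAsFactors = FALSE)
  bad <- tapply(members$is_rep, members$cluster, sum)
  if (any(bad != 1L)) stop("cluster without exactly one representative: ",
                           names(bad)[bad != 1L][[1L]])
  new_cluster_set(members, params = list())
}

#' Reverse complement of nucleotide strings
#'
#' @param seq character vector over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  vapply(seq, .revcomp_cpp, character(1L), USE.NAMES = FALSE)
}
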