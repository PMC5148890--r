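# The consensus pipeline: per-assembly exact deduplication, pooling with
# provenance, CDS extraction, inter-assembly CDS clustering, provenance
# categories, extension statistics, and the final coding transcriptome.

#' Parameters of the consensus pipeline
#'
#' Defaults reproduce the published two-pass procedure: intra-assembly
#' deduplication at 100% identity over the full shorter sequence, then
#' CDS clustering at 98% identity (one point below typical Illumina
#' error), aS = 1.00 and aL = 0.005, with a 100-amino-acid ORF floor.
#'
#' @param cds_identity identity threshold for the CDS clustering pass.
#' @param cds_aS minimum aligned fraction of the shorter CDS.
#' @param cds_aL minimum aligned fraction of the longer CDS.
#' @param min_aa minimum ORF length in amino acids.
#' @param cds_both_strands whether the CDS pass considers reverse
#'   complements; CDSs are already strand-adjusted, so the default is
#'   `FALSE`.
#' @param sep provenance separator used in harmonized ids.
#' @param category_map optional named integer vector overriding the
#'   default subset-to-category mapping (names are sorted member label
#'   sets joined with `"+"`).
#' @return A `consensus_params` list.
#' @export
consensus_params <- function(cds_identity = 0.98, cds_aS = 1.00,
                             cds_aL = 0.005, min_aa = 100L,
                             cds_both_strands = FALSE, sep = "|",
                             category_map = NULL) {
  stopifnot(cds_identity > 0, cds_identity <= 1,
            cds_aS > 0, cds_aS <= 1, cds_aL > 0, cds_aL <= 1, min_aa >= 1)
  structure(list(cds_identity = cds_identity, cds_aS = cds_aS,
                 cds_aL = cds_aL, min_aa = as.integer(min_aa),
                 cds_both_strands = cds_both_strands, sep = sep,
                 category_map = category_map),
            class = "consensus_params")
}

#' Map a cluster's member label set to its provenance category
#'
#' With the canonical three assemblers (`CLC`, `IDBA_tran`, `Trinity`)
#' the seven non-empty subsets map to categories 1-7: 1 = all three,
#' 2 = CLC+IDBA_tran, 3 = CLC+Trinity, 4 = IDBA_tran+Trinity, 5 = CLC
#' only, 6 = Trinity only, 7 = IDBA_tran only.  For other assembler
#' counts the non-empty subsets are numbered by decreasing subset size,
#' then by label order.
#'
#' @param member_labels a character vector of member labels (one cluster),
#'   or a list of such vectors.
#' @param labels the ordered assembler labels.
#' @param category_map optional named integer vector overriding the
#'   default mapping; names are sorted-by-`labels` subsets joined with
#'   `"+"`.
#' @return Integer category (or vector of categories for a list input).
#' @export
assign_categories <- function(member_labels,
                              labels = c("CLC", "IDBA_tran", "Trinity"),
                              category_map = NULL) {
  if (is.null(category_map)) category_map <- default_category_map(labels)
  one <- function(m) {
    m <- unique(m)
    if (!length(m)) stop("empty member label set")
    bad <- setdiff(m, labels)
    if (length(bad)) stop("unknown label: ", bad[[1L]])
    key <- paste(labels[sort(match(m, labels))], collapse = "+")
    unname(category_map[[key]])
  }
  if (is.list(member_labels)) vapply(member_labels, one, integer(1L))
  else one(member_labels)
}

default_category_map <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 1L)
  if (n == 3L) {
    keys <- c(paste(labels, collapse = "+"),
              paste(labels[c(1, 2)], collapse = "+"),
              paste(labels[c(1, 3)], collapse = "+"),
              paste(labels[c(2, 3)], collapse = "+"),
              labels[[1L]], labels[[3L]], labels[[2L]])
    return(stats::setNames(1:7, keys))
  }
  keys <- character(0L)
  for (k in rev(seq_len(n))) {
    cmb <- utils::combn(n, k)
    keys <- c(keys, apply(cmb, 2L, function(ix)
      paste(labels[ix], collapse = "+")))
  }
  stats::setNames(seq_along(keys), keys)
}

#' Per-assembler CDS extension statistics
#'
#' For each cluster, each assembler that contributed at least one member
#' CDS is compared to the cluster representative: when its longest
#' contributed CDS is strictly shorter, that assembler is counted as
#' extended in this cluster, by the length difference in bp.
#'
#' @param step8_clusters the CDS-level `cluster_set`.
#' @param cds the CDS data.frame (for id-to-source/length lookup).
#' @param rep_ids named character vector: cluster (as character) ->
#'   representative cds_id.  Defaults to the cluster-set representatives.
#' @param labels ordered assembler labels.
#' @return data.frame with one row per assembler: `label`,
#'   `n_clusters_present`, `n_extended`, `pct_extended`,
#'   `cumulated_extension_bp`, `mean_extension_bp`.
#' @export
compute_extensions <- function(step8_clusters, cds,
                               rep_ids = NULL,
                               labels = NULL) {
  m <- step8_clusters$members
  src <- cds$source[match(m$id, cds$cds_id)]
  if (anyNA(src)) stop("cluster member without CDS record: ",
                       m$id[is.na(src)][[1L]])
  if (is.null(labels)) labels <- sort(unique(src))
  if (is.null(rep_ids)) {
    reps <- m[m$is_rep, ]
    rep_ids <- stats::setNames(reps$id, as.character(reps$cluster))
  }
  rep_len <- stats::setNames(
    nchar(cds$nt_seq[match(rep_ids, cds$cds_id)]), names(rep_ids))
  out <- lapply(labels, function(lab) {
    sel <- m[src == lab, , drop = FALSE]
    if (!nrow(sel)) {
      return(data.frame(label = lab, n_clusters_present = 0L,
                        n_extended = 0L, pct_extended = NA_real_,
                        cumulated_extension_bp = 0L,
                        mean_extension_bp = NA_real_,
                        stringsAsFactors = FALSE))
    }
    longest <- tapply(sel$length, as.character(sel$cluster), max)
    rl <- rep_len[names(longest)]
    ext <- rl - longest
    extended <- ext > 0L
    data.frame(label = lab,
               n_clusters_present = length(longest),
               n_extended = sum(extended),
               pct_extended = 100 * sum(extended) / length(longest),
               cumulated_extension_bp = as.integer(sum(ext[extended])),
               mean_extension_bp = if (any(extended))
                 sum(ext[extended]) / sum(extended) else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Final transcript selection and redundancy bookkeeping
#'
#' Final transcripts are the owners of at least one representative CDS,
#' kept with UTRs intact.  A final transcript carrying more than one CDS
#' is counted multi-CDS; CDSs on final transcripts that are cluster
#' members but not representatives are the redundant CDSs retained in
#' the final assembly.
#'
#' @param rep_cds_ids cds_ids of the cluster representatives.
#' @param all_cds the full CDS data.frame.
#' @param transcripts the pooled transcript records.
#' @return list with `final_transcripts` (records), `n_multi_cds`,
#'   `n_total_cds_on_final`, `n_redundant_cds`.
#' @export
finalize_transcripts <- function(rep_cds_ids, all_cds, transcripts) {
  owners <- all_cds$transcript_id[match(rep_cds_ids, all_cds$cds_id)]
  if (anyNA(owners)) stop("representative with no owning transcript: ",
                          rep_cds_ids[is.na(owners)][[1L]])
  final_ids <- unique(owners)
  missing <- setdiff(final_ids, transcripts$id)
  if (length(missing)) stop("representative with no owning transcript: ",
                            missing[[1L]])
  final <- transcripts[transcripts$id %in% final_ids, , drop = FALSE]
  rownames(final) <- NULL
  on_final <- all_cds[all_cds$transcript_id %in% final_ids, , drop = FALSE]
  per <- table(on_final$transcript_id)
  list(final_transcripts = final,
       n_multi_cds = sum(per > 1L),
       n_total_cds_on_final = nrow(on_final),
       n_redundant_cds = sum(!(on_final$cds_id %in% rep_cds_ids)))
}

#' Run the consensus pipeline end to end
#'
#' Executes, in order: name harmonization per assembly, exact
#' intra-assembly deduplication, pooling, ORF/CDS extraction,
#' inter-assembly CDS clustering, representative designation (longest
#' CDS; ties broken by assembler-label order, then id), provenance
#' categories, extension statistics, and final transcript selection.
#'
#' @param assemblies named list of record data.frames, one per assembler
#'   (names are the assembler labels, in order).
#' @param params a [consensus_params()] object.
#' @param threads worker processes for the per-assembly deduplication
#'   stage; results are identical for any value.
#' @param quiet suppress per-stage progress messages.
#' @return A `consensus_result`: list with `uniCDS` (representative CDS
#'   records with their cluster), `final_transcripts`, `categories`
#'   (per-cluster table), `cds`, `concatenated`, `step5_clusters` (named
#'   list), `step8_clusters`, `extensions`, `stats`, `params`, `labels`.
#' @export
run_consensus <- function(assemblies, params = consensus_params(),
                          threads = 1L, quiet = FALSE) {
  if (!is.list(assemblies) || is.null(names(assemblies)) ||
      any(!nzchar(names(assemblies)))) {
    stop("assemblies must be a named list of record data.frames")
  }
  labels <- names(assemblies)
  if (anyDuplicated(labels)) stop("duplicate assembly labels")
  if (length(labels) < 2L) {
    warning("fewer than 2 assemblies: consensus is degenerate")
  }
  say <- function(...) if (!quiet) message(...)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # (a) harmonize names per assembly
  harm <- stage("harmonize", lapply(labels, function(lab)
    harmonize_names(assemblies[[lab]], lab, sep = params$sep)$records))
  names(harm) <- labels

  # (b) exact deduplication per assembly
  dedup_one <- function(lab) dedup_exact(harm[[lab]])
  dedups <- stage("dedup", {
    if (threads > 1L && .Platform$OS.type == "unix") {
      parallel::mclapply(labels, dedup_one, mc.cores = threads)
    } else {
      lapply(labels, dedup_one)
    }
  })
  names(dedups) <- labels
  step5 <- lapply(dedups, `[[`, "clusters")
  dedup_stats <- data.frame(
    label = labels,
    n_input = vapply(harm, nrow, integer(1L)),
    n_retained = vapply(dedups, function(d) nrow(d$retained), integer(1L)),
    stringsAsFactors = FALSE)
  dedup_stats$redundancy_pct <-
    100 * (dedup_stats$n_input - dedup_stats$n_retained) / dedup_stats$n_input
  for (i in seq_len(nrow(dedup_stats))) {
    say(sprintf("step 5 [%s]: %d -> %d transcripts (%.2f%% redundant)",
                dedup_stats$label[i], dedup_stats$n_input[i],
                dedup_stats$n_retained[i], dedup_stats$redundancy_pct[i]))
  }

  # (c) concatenate survivors
  concatenated <- stage("concatenate",
                        do.call(rbind, lapply(dedups, `[[`, "retained")))
  rownames(concatenated) <- NULL
  say(sprintf("step 6: %d concatenated transcripts", nrow(concatenated)))

  # (d) CDS extraction
  cds <- stage("extract_cds",
               extract_cds(concatenated, min_aa = params$min_aa,
                           sep = params$sep))
  say(sprintf("step 7: %d CDSs (>= %d aa)", nrow(cds), params$min_aa))
  if (nrow(cds) == 0L) stop("stage 'extract_cds' failed: no CDS detected")

  # (e) inter-assembly CDS clustering
  cds_recs <- data.frame(id = cds$cds_id, source = cds$source,
                         seq = cds$nt_seq, stringsAsFactors = FALSE)
  step8 <- stage("cds_cluster", greedy_cluster(
    cds_recs, cluster_params(c = params$cds_identity, aS = params$cds_aS,
                             aL = params$cds_aL,
                             both_strands = params$cds_both_strands)))
  m <- step8$members
  n_clusters <- length(unique(m$cluster))
  say(sprintf("step 8: %d uniCDS clusters", n_clusters))

  # (f) representative = longest CDS; ties by assembler-label order, then id
  rep_ids <- designate_reps(m, cds, labels)

  # (g) provenance categories
  member_labels <- split(cds$source[match(m$id, cds$cds_id)],
                         as.character(m$cluster))
  cl_order <- as.character(sort(unique(m$cluster)))
  member_labels <- member_labels[cl_order]
  cats <- assign_categories(member_labels, labels = labels,
                            category_map = params$category_map)
  categories <- data.frame(
    cluster = as.integer(cl_order),
    category = cats,
    members = vapply(member_labels, function(x)
      paste(labels[sort(unique(match(x, labels)))], collapse = "+"),
      character(1L)),
    rep_cds = unname(rep_ids[cl_order]),
    stringsAsFactors = FALSE)
  categories$rep_transcript <-
    cds$transcript_id[match(categories$rep_cds, cds$cds_id)]

  # (h) extension statistics
  extensions <- stage("extensions",
                      compute_extensions(step8, cds, rep_ids = rep_ids,
                                         labels = labels))

  # (i) final transcripts
  fin <- stage("finalize",
               finalize_transcripts(unname(rep_ids), cds, concatenated))
  say(sprintf("step 9: %d final transcripts", nrow(fin$final_transcripts)))

  uniCDS <- cds[match(unname(rep_ids[cl_order]), cds$cds_id), , drop = FALSE]
  uniCDS$cluster <- as.integer(cl_order)
  rownames(uniCDS) <- NULL

  stats <- list(
    dedup = dedup_stats,
    n_concatenated_transcripts = nrow(concatenated),
    n_cds = nrow(cds),
    n_uniCDS = n_clusters,
    step8_redundancy_pct = 100 * (nrow(cds) - n_clusters) / nrow(cds),
    n_final_transcripts = nrow(fin$final_transcripts),
    n_total_cds_on_final_transcripts = fin$n_total_cds_on_final,
    n_multi_cds_transcripts = fin$n_multi_cds,
    n_redundant_cds = fin$n_redundant_cds,
    redundant_cds_pct = if (fin$n_total_cds_on_final > 0)
      100 * fin$n_redundant_cds / fin$n_total_cds_on_final else NA_real_,
    category_counts = table(factor(categories$category)))

  structure(list(uniCDS = uniCDS,
                 final_transcripts = fin$final_transcripts,
                 categories = categories,
                 cds = cds,
                 concatenated = concatenated,
                 step5_clusters = step5,
                 step8_clusters = step8,
                 extensions = extensions,
                 stats = stats,
                 params = params,
                 labels = labels),
            class = "consensus_result")
}

designate_reps <- function(members, cds, labels) {
  src <- cds$source[match(members$id, cds$cds_id)]
  lab_rank <- match(src, labels)
  split_idx <- split(seq_len(nrow(members)), as.character(members$cluster))
  vapply(split_idx, function(ix) {
    sub <- members[ix, ]
    best <- ix[order(-sub$length, lab_rank[ix], sub$id)][[1L]]
    members$id[[best]]
  }, character(1L))
}

#' @export
print.consensus_result <- function(x, ...) {
  s <- x$stats
  cat("consensus_result\n")
  cat(sprintf("  assemblies: %s\n", paste(x$labels, collapse = ", ")))
  cat(sprintf("  concatenated transcripts: %d\n",
              s$n_concatenated_transcripts))
  cat(sprintf("  CDSs: %d  uniCDS: %d  (%.1f%% redundant)\n",
              s$n_cds, s$n_uniCDS, s$step8_redundancy_pct))
  cat(sprintf("  final transcripts: %d (multi-CDS: %d, redundant CDSs: %d)\n",
              s$n_final_transcripts, s$n_multi_cds_transcripts,
              s$n_redundant_cds))
  cat("  categories:", paste(sprintf("%s=%d", names(s$category_counts),
                                     as.integer(s$category_counts)),
                             collapse = " "), "\n")
  invisible(x)
}

#' Trace every uniCDS back to its assembler and original transcript name
#'
#' @param result a `consensus_result`.
#' @return data.frame with columns `cds_id`, `transcript_id`, `label`,
#'   `original`.
#' @export
trace_provenance <- function(result) {
  u <- result$uniCDS
  parts <- split_harmonized(u$transcript_id, sep = result$params$sep)
  data.frame(cds_id = u$cds_id, transcript_id = u$transcript_id,
             label = parts$label, original = parts$original,
             stringsAsFactors = FALSE)
}
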