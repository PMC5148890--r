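# Manifest oracle: predicts every downstream count of a synthetic run
# from the generator's manifest by plain string comparison and
# arithmetic.  It never calls the package's alignment kernel, greedy
# clusterer or ORF scanner.  The alignment-free merge rule is exact for
# the generator's constructions: substitutions keep clear of CDS/cut
# ends, so the best local alignment of two same-family CDSs is their
# full coordinate overlap, and a member can only satisfy aS = 1 when its
# CDS nests inside the representative's.

manifest_expected <- function(fx, cds_identity = 0.98, min_cov = 0.5,
                              sep = "|") {
  eps <- 1e-9
  man <- fx$manifest
  labels <- names(fx$assemblies)
  out <- man$outputs
  present <- out[out$kind != "dropped", , drop = FALSE]
  retained <- present[present$kind != "duplicate", , drop = FALSE]

  step5 <- do.call(rbind, lapply(labels, function(lab) {
    n_in <- sum(present$assembler == lab)
    n_keep <- sum(retained$assembler == lab)
    data.frame(label = lab, n_input = n_in, n_retained = n_keep,
               redundancy_pct = 100 * (n_in - n_keep) / n_in,
               stringsAsFactors = FALSE)
  }))

  seq_of <- function(lab, oid) {
    recs <- fx$assemblies[[lab]]
    recs$seq[match(oid, recs$id)]
  }

  # expected CDS table with harmonized ids, numbered like extract_cds
  cds <- man$cds
  keep <- paste(cds$assembler, cds$out_id) %in%
    paste(retained$assembler, retained$out_id)
  cds <- cds[keep, , drop = FALSE]
  parts <- split(cds, paste(cds$assembler, cds$out_id))
  cds <- do.call(rbind, lapply(parts, function(p) {
    p <- p[order(-p$len_nt, p$start_in_out), , drop = FALSE]
    p$k <- seq_len(nrow(p))
    p
  }))
  cds$tid <- paste0(cds$assembler, sep, cds$out_id)
  cds$cds_id <- paste0(cds$tid, sep, "cds", cds$k)
  cds$seq <- vapply(seq_len(nrow(cds)), function(i)
    substr(seq_of(cds$assembler[[i]], cds$out_id[[i]]),
           cds$start_in_out[[i]] + 1L,
           cds$start_in_out[[i]] + cds$len_nt[[i]]), "")
  rownames(cds) <- NULL

  # greedy clustering at (cds_identity, aS = 1, aL = 0.005)
  ord <- order(-cds$len_nt, cds$cds_id, method = "radix")
  cds <- cds[ord, , drop = FALSE]
  cluster <- integer(nrow(cds))
  rep_row <- integer(0)
  matchfrac <- function(a, b) {
    mean(strsplit(a, "")[[1L]] == strsplit(b, "")[[1L]])
  }
  for (i in seq_len(nrow(cds))) {
    hit <- NA_integer_
    for (cl in seq_along(rep_row)) {
      r <- rep_row[[cl]]
      if (cds$family_key[[i]] != cds$family_key[[r]]) next
      if (cds$orf_index[[i]] != cds$orf_index[[r]]) next
      nested <- cds$rel_start[[i]] >= cds$rel_start[[r]] &&
        cds$rel_end[[i]] <= cds$rel_end[[r]]
      if (!nested) next
      if (cds$len_nt[[i]] / cds$len_nt[[r]] + eps < 0.005) next
      off <- cds$rel_start[[i]] - cds$rel_start[[r]]
      idb <- substr(cds$seq[[r]], off + 1L, off + cds$len_nt[[i]])
      if (matchfrac(cds$seq[[i]], idb) + eps >= cds_identity) {
        hit <- cl
        break
      }
    }
    if (is.na(hit)) {
      rep_row <- c(rep_row, i)
      cluster[[i]] <- length(rep_row)
    } else {
      cluster[[i]] <- hit
    }
  }
  cds$cluster <- cluster - 1L
  n_clusters <- length(rep_row)

  # designated representative: longest, ties by label order then id
  desig <- vapply(seq_len(n_clusters) - 1L, function(cl) {
    sub <- cds[cds$cluster == cl, , drop = FALSE]
    sub <- sub[order(-sub$len_nt, match(sub$assembler, labels),
                     sub$cds_id), , drop = FALSE]
    sub$cds_id[[1L]]
  }, "")

  # categories under the default mapping
  cat_of <- function(members) {
    ix <- sort(unique(match(members, labels)))
    key <- paste(ix, collapse = ",")
    if (length(labels) != 3L) stop("oracle assumes three assemblers")
    switch(key, "1,2,3" = 1L, "1,2" = 2L, "1,3" = 3L, "2,3" = 4L,
           "1" = 5L, "3" = 6L, "2" = 7L)
  }
  categories <- vapply(seq_len(n_clusters) - 1L, function(cl)
    cat_of(cds$assembler[cds$cluster == cl]), integer(1L))

  # per-assembler extensions against the designated representative
  rep_len <- cds$len_nt[match(desig, cds$cds_id)]
  extensions <- do.call(rbind, lapply(labels, function(lab) {
    sel <- cds[cds$assembler == lab, , drop = FALSE]
    if (!nrow(sel)) {
      return(data.frame(label = lab, n_clusters_present = 0L,
                        n_extended = 0L, cumulated_extension_bp = 0L))
    }
    longest <- tapply(sel$len_nt, sel$cluster, max)
    rl <- rep_len[as.integer(names(longest)) + 1L]
    ext <- rl - longest
    data.frame(label = lab, n_clusters_present = length(longest),
               n_extended = sum(ext > 0L),
               cumulated_extension_bp = as.integer(sum(ext[ext > 0L])),
               stringsAsFactors = FALSE)
  }))

  final_tids <- unique(cds$tid[match(desig, cds$cds_id)])
  on_final <- cds[cds$tid %in% final_tids, , drop = FALSE]
  per <- table(on_final$tid)

  list(step5 = step5,
       cds = cds,
       n_cds = nrow(cds),
       n_uniCDS = n_clusters,
       rep_cds = desig,
       categories = categories,
       category_counts = table(factor(categories, levels = 1:7)),
       extensions = extensions,
       final_tids = final_tids,
       n_final = length(final_tids),
       n_multi_cds = sum(per > 1L),
       n_total_cds_on_final = nrow(on_final),
       n_redundant_cds = sum(!(on_final$cds_id %in% desig)))
}

# recovery oracle for a set of assembled records drawn from the fixture
# (records identified by (assembler, out_id)); qualification mirrors the
# published rule: identity >= min_id over >= min_cov of the original
oracle_recovery <- function(fx, subset, min_id = 0.98, min_cov = 0.5) {
  eps <- 1e-9
  man <- fx$manifest
  truth <- fx$truth
  glen <- stats::setNames(nchar(truth$seq), truth$id)
  qualifies <- logical(nrow(subset))
  for (i in seq_len(nrow(subset))) {
    g <- subset$gene_id[[i]]
    if (is.na(g)) next
    span <- subset$src_end[[i]] - subset$src_start[[i]]
    if (span + eps < min_cov * glen[[g]]) next
    tseq <- substr(truth$seq[match(g, truth$id)],
                   subset$src_start[[i]] + 1L, subset$src_end[[i]])
    mf <- mean(strsplit(subset$seq[[i]], "")[[1L]] ==
                 strsplit(tseq, "")[[1L]])
    qualifies[[i]] <- mf + eps >= min_id
  }
  recovered <- unique(subset$gene_id[qualifies])
  recovered <- recovered[!is.na(recovered)]
  list(missing = setdiff(truth$id, recovered),
       invented = subset$out_key[!qualifies])
}

# assembled-record table (with sequences) for one assembler, or for a set
# of harmonized transcript ids
fixture_records <- function(fx, label = NULL, tids = NULL, sep = "|") {
  out <- fx$manifest$outputs
  out <- out[out$kind != "dropped", , drop = FALSE]
  out$out_key <- paste0(out$assembler, sep, out$out_id)
  if (!is.null(label)) out <- out[out$assembler == label, , drop = FALSE]
  if (!is.null(tids)) out <- out[out$out_key %in% tids, , drop = FALSE]
  out$seq <- vapply(seq_len(nrow(out)), function(i) {
    recs <- fx$assemblies[[out$assembler[[i]]]]
    recs$seq[match(out$out_id[[i]], recs$id)]
  }, "")
  out
}
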