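# Synthetic fixture factory.
#
# Truth transcripts are built so that the planted ORFs are provably the
# only reportable ones:
#   * a 21-nt block carrying stop codons in all six reading frames caps
#     both transcript ends, so no stretch abutting a sequence end can
#     reach the reporting floor;
#   * outside planted start codons the sequence never contains the
#     substrings ATG or CAT (CAT is ATG on the reverse strand), so no
#     stretch away from the ends can ever be reported;
#   * planted ORF interiors are free of in-frame stops by construction.
# Mock assembler outputs derive from truth by dropout, substitution
# error, end truncation and exact duplication; substitutions avoid the
# terminal two codons of every planted CDS and truncation points keep
# clear of substitutions, so downstream clustering decisions depend on
# identity alone and stay arithmetically predictable from the manifest.

STOP_BLOCK <- "TGATTACTGATTACTGATTAC"
BASES <- c("A", "C", "G", "T")

# next letter that cannot complete ATG or CAT
safe_letter <- function(prev2, exclude = character(0)) {
  cand <- setdiff(BASES, exclude)
  if (endsWith(prev2, "AT")) cand <- setdiff(cand, "G")
  if (endsWith(prev2, "CA")) cand <- setdiff(cand, "T")
  if (!length(cand)) stop("letter alphabet exhausted")   # cannot happen
  cand[[sample.int(length(cand), 1L)]]
}

# n random letters continuing state prev2; final_exclude constrains the
# last letter (junction safety with whatever is appended next)
safe_filler <- function(n, prev2, final_exclude = character(0)) {
  out <- character(n)
  for (i in seq_len(n)) {
    excl <- if (i == n) final_exclude else character(0)
    l <- safe_letter(prev2, excl)
    out[[i]] <- l
    prev2 <- paste0(substr(prev2, 2L, 2L), l)
  }
  list(letters = out, prev2 = prev2)
}

# interior codons of a planted ORF (everything after ATG, before the
# stop): no in-frame stops, automaton-safe, and the final letter pair is
# kept off "CA" so the stop codon TAA can follow
orf_interior <- function(n_codons, prev2) {
  out <- character(3L * n_codons)
  k <- 0L
  for (ci in seq_len(n_codons)) {
    l1 <- safe_letter(prev2)
    prev2 <- paste0(substr(prev2, 2L, 2L), l1)
    l2 <- safe_letter(prev2)
    prev2 <- paste0(substr(prev2, 2L, 2L), l2)
    excl <- character(0)
    if (paste0(l1, l2) == "TA") excl <- c("A", "G")
    if (paste0(l1, l2) == "TG") excl <- "A"
    if (ci == n_codons && l2 == "C") excl <- c(excl, "A")
    l3 <- safe_letter(prev2, excl)
    prev2 <- paste0(substr(prev2, 2L, 2L), l3)
    out[k + 1:3] <- c(l1, l2, l3)
    k <- k + 3L
  }
  list(letters = out, prev2 = prev2)
}

# Build one transcript of (approximately) length L carrying the given
# planted ORF amino-acid lengths.  Returns the sequence and a table of
# 0-based half-open sense-region coordinates (stop codon excluded).
build_transcript <- function(L, aa_lens, interiors = NULL) {
  n_orfs <- length(aa_lens)
  inter <- if (n_orfs > 1L) rep(12L, n_orfs - 1L) else integer(0)
  slack <- L - 42L - sum(3L * aa_lens + 3L) - sum(inter)
  if (slack < 16L) stop("infeasible length constraints")
  f5 <- 8L + sample.int(slack - 15L, 1L) - 1L
  f3 <- slack - f5
  lets <- strsplit(STOP_BLOCK, "")[[1L]]
  prev2 <- "AC"
  ostart <- integer(n_orfs); oend <- integer(n_orfs)
  for (i in seq_len(n_orfs)) {
    fl <- safe_filler(if (i == 1L) f5 else inter[[i - 1L]], prev2,
                      final_exclude = "C")
    lets <- c(lets, fl$letters)
    ostart[[i]] <- length(lets)          # 0-based position of ATG
    lets <- c(lets, "A", "T", "G")
    body <- if (is.null(interiors)) orf_interior(aa_lens[[i]] - 1L, "TG")
            else list(letters = strsplit(interiors[[i]], "")[[1L]],
                      prev2 = substr(interiors[[i]],
                                     nchar(interiors[[i]]) - 1L,
                                     nchar(interiors[[i]])))
    lets <- c(lets, body$letters)
    oend[[i]] <- length(lets)            # sense-region end, stop excluded
    lets <- c(lets, "T", "A", "A")
    prev2 <- "AA"
  }
  fl <- safe_filler(f3, prev2, final_exclude = "A")
  lets <- c(lets, fl$letters, strsplit(STOP_BLOCK, "")[[1L]])
  list(seq = paste(lets, collapse = ""),
       orfs = data.frame(orf_index = seq_len(n_orfs), start = ostart,
                         end = oend, aa_len = as.integer(aa_lens)))
}

#' Generate a truth transcriptome with planted ORFs
#'
#' Each transcript consists of a random 5' UTR, one (or, for bicistronic
#' genes, two) stop-free ORFs starting at ATG and ending before a planted
#' stop, and a random 3' UTR, constructed so that [find_orfs()] reports
#' exactly the planted ORFs.  Paralog pairs share their ORF interior at
#' the stated per-base divergence (substitutions only, away from the
#' terminal two codons).
#'
#' @param n_genes number of genes (paralog partners count extra).
#' @param length_range transcript length range in nt.
#' @param orf_fraction_range fraction of the transcript occupied by each
#'   planted ORF.
#' @param n_paralog_pairs how many genes receive a diverged paralog.
#' @param paralog_divergence per-base substitution rate within the ORF.
#' @param n_bicistronic how many genes carry two planted ORFs.
#' @param min_aa ORF reporting floor the fixture is built for.
#' @param seed RNG seed; the same seed gives byte-identical output.
#' @return list with `records` (truth transcripts, source `"truth"`) and
#'   `manifest` (list: `params`, `genes`, `orfs`, `coverage`).
#' @export
generate_truth <- function(n_genes = 50L, length_range = c(600L, 2000L),
                           orf_fraction_range = c(0.5, 0.8),
                           n_paralog_pairs = 0L, paralog_divergence = 0.08,
                           n_bicistronic = 0L, min_aa = 100L, seed = 1L) {
  stopifnot(n_genes >= 1L, paralog_divergence >= 0, paralog_divergence <= 1,
            n_paralog_pairs <= n_genes, n_bicistronic + n_paralog_pairs <= n_genes)
  if (length_range[[1L]] < 3L * min_aa + 70L) {
    stop("infeasible length constraints: minimum length must allow a ",
         min_aa, "-aa ORF plus caps")
  }
  set.seed(as.integer(seed))
  total <- n_genes + n_paralog_pairs
  ids <- sprintf("g%03d", seq_len(total))
  # the last n_paralog_pairs genes are paralogs of the first ones among
  # the mono-cistronic genes
  parent_pool <- setdiff(seq_len(n_genes), seq_len(n_bicistronic))
  stopifnot(length(parent_pool) >= n_paralog_pairs)
  paralog_parent <- integer(total)
  if (n_paralog_pairs > 0L) {
    paralog_parent[n_genes + seq_len(n_paralog_pairs)] <-
      parent_pool[seq_len(n_paralog_pairs)]
  }
  family <- seq_len(total)
  recs <- vector("list", total)
  orfs <- vector("list", total)
  genes <- vector("list", total)
  orf_body <- vector("list", total)    # interior strings for paralog reuse
  for (i in seq_len(total)) {
    parent <- paralog_parent[[i]]
    if (parent > 0L) family[[i]] <- family[[parent]]
    L <- sample(length_range[[1L]]:length_range[[2L]], 1L)
    n_orf <- if (i <= n_bicistronic) 2L else 1L
    if (parent > 0L) {
      paa <- orfs[[parent]]$aa_len
      body <- mutate_orf_interior(orf_body[[parent]][[1L]],
                                  paralog_divergence)
      aa <- paa
      L <- max(L, 3L * sum(aa) + 3L * n_orf + 70L)
      bt <- build_transcript(L, aa, interiors = list(body))
    } else {
      L <- max(L, 3L * n_orf * min_aa + 73L + 3L * (n_orf - 1L))
      frac <- stats::runif(n_orf, orf_fraction_range[[1L]],
                           orf_fraction_range[[2L]]) / n_orf
      aa <- pmax(min_aa, pmin(floor(frac * L / 3),
                              (L - 73L - 3L * (n_orf - 1L)) %/% (3L * n_orf)))
      bt <- build_transcript(L, aa)
    }
    recs[[i]] <- data.frame(id = ids[[i]], source = "truth", seq = bt$seq,
                            stringsAsFactors = FALSE)
    o <- bt$orfs
    o$gene_id <- ids[[i]]
    o$family_key <- sprintf("fam%d_orf%d", family[[i]], o$orf_index)
    orfs[[i]] <- o
    orf_body[[i]] <- lapply(seq_len(nrow(o)), function(k)
      substr(bt$seq, o$start[[k]] + 4L, o$end[[k]]))
    genes[[i]] <- data.frame(gene_id = ids[[i]], length = nchar(bt$seq),
                             family = family[[i]],
                             n_orfs = n_orf,
                             paralog_of = if (parent > 0L) ids[[parent]]
                                          else NA_character_,
                             stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  coverage <- stats::setNames(round(stats::rlnorm(total, log(20), 1), 1),
                              ids)
  manifest <- list(
    params = list(n_genes = n_genes, length_range = length_range,
                  orf_fraction_range = orf_fraction_range,
                  n_paralog_pairs = n_paralog_pairs,
                  paralog_divergence = paralog_divergence,
                  n_bicistronic = n_bicistronic, min_aa = min_aa,
                  seed = as.integer(seed)),
    genes = do.call(rbind, genes),
    orfs = do.call(rbind, orfs),
    coverage = coverage)
  list(records = records, manifest = manifest)
}

# substitute interior positions of an ORF body (the letters after ATG)
# at the given rate, keeping the constrained-alphabet and no-in-frame-
# stop guarantees and the terminal two codons untouched
mutate_orf_interior <- function(body, rate) {
  if (rate <= 0) return(body)
  lets <- strsplit(body, "")[[1L]]
  n <- length(lets)
  # body codons are frame 0 within the body; CDS codon 1 is the ATG, so
  # skip body codons 1-2 and the last two
  ncod <- n %/% 3L
  eligible <- integer(0)
  if (ncod > 4L) eligible <- (3L * 2L + 1L):(3L * (ncod - 2L))
  hit <- eligible[stats::runif(length(eligible)) < rate]
  for (p in hit) {
    lets <- try_substitute(lets, p, frame_anchor = 1L)
  }
  paste(lets, collapse = "")
}

# substitute position p (1-based) in a letter vector when a safe letter
# exists: no ATG/CAT in any window, no stop codon in the frame anchored
# at frame_anchor (1-based position of a codon start; NA = no frame)
try_substitute <- function(lets, p, frame_anchor = NA_integer_) {
  n <- length(lets)
  for (cand in sample(setdiff(BASES, lets[[p]]))) {
    tmp <- lets
    tmp[[p]] <- cand
    ok <- TRUE
    for (w in (p - 2L):p) {
      if (w < 1L || w + 2L > n) next
      tri <- paste(tmp[w + 0:2], collapse = "")
      if (tri %in% c("ATG", "CAT")) { ok <- FALSE; break }
    }
    if (ok && !is.na(frame_anchor)) {
      cs <- frame_anchor + 3L * ((p - frame_anchor) %/% 3L)
      if (cs >= 1L && cs + 2L <= n) {
        if (paste(tmp[cs + 0:2], collapse = "") %in% STOP_CODONS) ok <- FALSE
      }
    }
    if (ok) return(tmp)
  }
  lets
}

#' Default per-assembler imperfection plan
#'
#' The canonical three-assembler study conditions: 10% gene dropout, 20%
#' end truncation keeping 50-90% of the transcript, 0.5% substitution
#' error, five artifact transcripts per assembler, and 30% exact
#' duplication on the Trinity-like assembler only (the one assembler
#' whose real counterpart shows substantial internal redundancy).
#'
#' @param labels assembler labels.
#' @return named list of plan lists (fields `dropout_rate`, `dup_rate`,
#'   `fragment_rate`, `fragment_keep`, `error_rate`, `n_artifacts`,
#'   `artifact_orf`).
#' @export
default_assembly_plans <- function(labels = c("CLC", "IDBA_tran",
                                              "Trinity")) {
  base <- list(dropout_rate = 0.1, dup_rate = 0, fragment_rate = 0.2,
               fragment_keep = c(0.5, 0.9), error_rate = 0.005,
               n_artifacts = 5L, artifact_orf = TRUE)
  plans <- stats::setNames(rep(list(base), length(labels)), labels)
  if ("Trinity" %in% labels) plans[["Trinity"]]$dup_rate <- 0.3
  plans
}

#' Derive mock assembler outputs from a truth transcriptome
#'
#' Each assembler output is derived gene by gene: a gene is dropped with
#' `dropout_rate`, otherwise copied with substitution errors at
#' `error_rate`, truncated from one end with `fragment_rate` (keeping a
#' `fragment_keep` fraction), and duplicated with `dup_rate` (an exact
#' copy or exact substring, which the intra-assembly deduplication pass
#' must remove).  Artifact transcripts are random sequences unique to one
#' assembler, with or without a planted ORF.  Every realized fate is
#' recorded in the returned manifest, including the arithmetically
#' expected CDS complement of every output record.
#'
#' @param truth result of [generate_truth()].
#' @param plans named list of per-assembler plans
#'   (see [default_assembly_plans()]).
#' @param seed RNG seed.
#' @return list with `assemblies` (named list of record data.frames),
#'   `truth` (the input records), and `manifest` (the truth manifest
#'   extended with `outputs` and `cds` tables and the realized plans).
#' @export
generate_assemblies <- function(truth, plans = default_assembly_plans(),
                                seed = 1L) {
  set.seed(as.integer(seed) + 1L)
  tman <- truth$manifest
  trecs <- truth$records
  min_aa <- tman$params$min_aa
  out_asm <- list(); out_rows <- list(); cds_rows <- list()
  for (lab in names(plans)) {
    plan <- plans[[lab]]
    k <- 0L
    rows <- list(); recs <- list()
    for (gi in seq_len(nrow(trecs))) {
      gene <- trecs$id[[gi]]
      if (stats::runif(1L) < plan$dropout_rate) {
        rows[[length(rows) + 1L]] <- output_row(lab, NA, gene, "dropped",
                                                0L, NA, NA, 0L)
        next
      }
      gorfs <- tman$orfs[tman$orfs$gene_id == gene, , drop = FALSE]
      cp <- make_copy(trecs$seq[[gi]], gorfs, plan, min_aa)
      k <- k + 1L
      oid <- sprintf("ctg%04d", k)
      recs[[length(recs) + 1L]] <-
        data.frame(id = oid, source = lab, seq = cp$seq,
                   stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- output_row(lab, oid, gene, "copy",
                                              nchar(cp$seq), cp$src_start,
                                              cp$src_end, cp$n_mut)
      if (nrow(cp$cds)) {
        cp$cds$assembler <- lab; cp$cds$out_id <- oid
        cds_rows[[length(cds_rows) + 1L]] <- cp$cds
      }
      if (stats::runif(1L) < plan$dup_rate) {
        dup <- make_duplicate(cp$seq, cp$mut_pos)
        k <- k + 1L
        did <- sprintf("ctg%04d", k)
        recs[[length(recs) + 1L]] <-
          data.frame(id = did, source = lab, seq = dup$seq,
                     stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- output_row(
          lab, did, gene, "duplicate", nchar(dup$seq),
          cp$src_start + dup$from - 1L,
          cp$src_start + dup$to, cp$n_mut, dup_parent = oid)
      }
    }
    for (ai in seq_len(plan$n_artifacts)) {
      L <- sample(tman$params$length_range[[1L]]:
                    tman$params$length_range[[2L]], 1L)
      if (isTRUE(plan$artifact_orf)) {
        aa <- max(min_aa, min(floor(0.6 * L / 3), (L - 73L) %/% 3L))
        bt <- build_transcript(L, aa)
        k <- k + 1L
        oid <- sprintf("ctg%04d", k)
        recs[[length(recs) + 1L]] <-
          data.frame(id = oid, source = lab, seq = bt$seq,
                     stringsAsFactors = FALSE)
        cds_rows[[length(cds_rows) + 1L]] <- data.frame(
          assembler = lab, out_id = oid,
          family_key = sprintf("art_%s_%d", lab, ai), orf_index = 1L,
          start_in_out = bt$orfs$start, len_nt = 3L * bt$orfs$aa_len,
          completeness = "complete", rel_start = 0L,
          rel_end = 3L * bt$orfs$aa_len, stringsAsFactors = FALSE)
      } else {
        lets <- c(strsplit(STOP_BLOCK, "")[[1L]],
                  safe_filler(L - 42L, "AC", final_exclude = "A")$letters,
                  strsplit(STOP_BLOCK, "")[[1L]])
        k <- k + 1L
        oid <- sprintf("ctg%04d", k)
        recs[[length(recs) + 1L]] <-
          data.frame(id = oid, source = lab,
                     seq = paste(lets, collapse = ""),
                     stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- output_row(lab, oid, NA, "artifact",
                                              nchar(recs[[length(recs)]]$seq),
                                              NA, NA, 0L)
    }
    out_asm[[lab]] <- do.call(rbind, recs)
    out_rows[[lab]] <- do.call(rbind, rows)
  }
  manifest <- tman
  manifest$plans <- plans
  manifest$seed_assemblies <- as.integer(seed)
  manifest$outputs <- do.call(rbind, out_rows)
  rownames(manifest$outputs) <- NULL
  manifest$cds <- if (length(cds_rows)) {
    x <- do.call(rbind, cds_rows)
    rownames(x) <- NULL
    x[, c("assembler", "out_id", "family_key", "orf_index", "start_in_out",
          "len_nt", "completeness", "rel_start", "rel_end")]
  } else NULL
  list(assemblies = out_asm, truth = trecs, manifest = manifest)
}

output_row <- function(assembler, out_id, gene_id, kind, length,
                       src_start, src_end, n_mut, dup_parent = NA) {
  data.frame(assembler = assembler, out_id = as.character(out_id),
             gene_id = as.character(gene_id), kind = kind,
             length = as.integer(length),
             src_start = as.integer(src_start),
             src_end = as.integer(src_end), n_mut = as.integer(n_mut),
             dup_parent = as.character(dup_parent),
             stringsAsFactors = FALSE)
}

# one assembler's version of a truth transcript: substitution errors
# away from planted-CDS terminal codons and cap blocks, then optionally
# an end truncation at a cut point that is (1) at least 7 nt from every
# substitution and (2) verified not to expose any reportable stretch
# other than the arithmetically expected partial CDS
make_copy <- function(seq, gorfs, plan, min_aa) {
  L <- nchar(seq)
  lets <- strsplit(seq, "")[[1L]]
  protected <- rep(FALSE, L)
  protected[1:21] <- TRUE
  protected[(L - 20L):L] <- TRUE
  for (i in seq_len(nrow(gorfs))) {
    os <- gorfs$start[[i]]; oe <- gorfs$end[[i]]
    protected[(os + 1L):(os + 6L)] <- TRUE          # first two codons
    protected[(oe - 5L):(oe + 3L)] <- TRUE          # last two codons + stop
  }
  eligible <- which(!protected)
  hit <- eligible[stats::runif(length(eligible)) < plan$error_rate]
  mut_pos <- integer(0)
  for (p in hit) {
    anchor <- NA_integer_
    for (i in seq_len(nrow(gorfs))) {
      if (p > gorfs$start[[i]] && p <= gorfs$end[[i]]) {
        anchor <- gorfs$start[[i]] + 1L
      }
    }
    new <- try_substitute(lets, p, frame_anchor = anchor)
    if (!identical(new[[p]], lets[[p]])) {
      mut_pos <- c(mut_pos, p)
      lets <- new
    }
  }
  s <- paste(lets, collapse = "")
  cut5 <- 0L; keep <- L
  if (stats::runif(1L) < plan$fragment_rate) {
    side <- if (stats::runif(1L) < 0.5) "5" else "3"
    f <- stats::runif(1L, plan$fragment_keep[[1L]], plan$fragment_keep[[2L]])
    target <- round((1 - f) * L)
    cut <- pick_safe_cut(s, side, target, gorfs, mut_pos, min_aa)
    if (!is.na(cut)) {
      if (side == "5") { cut5 <- cut; s <- substr(s, cut + 1L, L) }
      else { keep <- L - cut; s <- substr(s, 1L, keep) }
    }
  }
  cds <- expected_cds(gorfs, cut5 = cut5, keep = keep, min_aa = min_aa)
  list(seq = s, src_start = cut5, src_end = cut5 + nchar(s),
       n_mut = length(mut_pos),
       mut_pos = mut_pos - cut5,        # output coordinates
       cds = cds)
}

# search cut offsets around the target (0, +3, -3, +6, ...) for one that
# keeps 7 nt clear of substitutions and passes the frame-exposure scan
pick_safe_cut <- function(s, side, target, gorfs, mut_pos, min_aa) {
  L <- nchar(s)
  for (d in c(0L, as.vector(rbind(seq(3L, 45L, 3L), -seq(3L, 45L, 3L))))) {
    cut <- target + d
    if (cut < 22L || cut > L - 22L) next
    if (length(mut_pos) && any(abs(mut_pos - cut) <= 6L)) next
    if (cut_exposure_safe(s, side, cut, gorfs, min_aa)) return(cut)
  }
  NA_integer_
}

# TRUE when every reading frame abutting the newly cut end either hits a
# stop (or a planted ATG) within min_aa codons or runs out of sequence
cut_exposure_safe <- function(s, side, cut, gorfs, min_aa) {
  L <- nchar(s)
  walk <- function(ss, expected_frame = NA_integer_) {
    n <- nchar(ss)
    for (g in 0:2) {
      ncod <- (n - g) %/% 3L
      limit <- min(ncod, min_aa)
      seen <- FALSE
      if (limit >= min_aa) {
        j <- 0L
        while (j < limit) {
          cod <- substr(ss, g + 3L * j + 1L, g + 3L * j + 3L)
          if (cod %in% STOP_CODONS || cod == "ATG") { seen <- TRUE; break }
          j <- j + 1L
        }
        if (!seen && !identical(g, expected_frame)) return(FALSE)
      }
    }
    TRUE
  }
  if (side == "5") {
    frag <- substr(s, cut + 1L, L)
    exp_frame <- NA_integer_
    for (i in seq_len(nrow(gorfs))) {
      if (cut > gorfs$start[[i]] && cut < gorfs$end[[i]]) {
        exp_frame <- (gorfs$start[[i]] - cut) %% 3L
      }
    }
    walk(frag, exp_frame)
  } else {
    keep <- L - cut
    walk(.revcomp_cpp(substr(s, 1L, keep)))
  }
}

# arithmetically expected CDS complement of a (possibly truncated) copy;
# coordinates are 0-based on the output sequence
expected_cds <- function(gorfs, cut5, keep, min_aa) {
  rows <- list()
  for (i in seq_len(nrow(gorfs))) {
    os <- gorfs$start[[i]]; oe <- gorfs$end[[i]]
    start <- NA_integer_; len <- NA_integer_; comp <- NA_character_
    rel <- 0L
    if (cut5 <= os) {
      start <- os - cut5
      if (keep >= oe + 3L) { len <- oe - os; comp <- "complete" }
      else if (keep > oe) { len <- oe - os; comp <- "3prime_partial" }
      else {
        aa2 <- (keep - os) %/% 3L
        if (aa2 >= min_aa) { len <- 3L * aa2; comp <- "3prime_partial" }
      }
    } else if (cut5 < oe) {
      off <- (os - cut5) %% 3L
      start <- off
      rel <- cut5 + off - os
      if (keep >= oe + 3L) {
        len <- oe - cut5 - off
        comp <- "5prime_partial"
      } else {
        end_sense <- min(keep, oe)
        len <- 3L * ((end_sense - cut5 - off) %/% 3L)
        comp <- if (keep > oe) "5prime_partial" else "internal"
      }
      if (is.na(len) || len < 3L * min_aa) len <- NA_integer_
      if (!is.na(len) && len / 3L < min_aa) len <- NA_integer_
    }
    if (!is.na(len) && len >= 3L * min_aa) {
      rows[[length(rows) + 1L]] <- data.frame(
        family_key = gorfs$family_key[[i]], orf_index = gorfs$orf_index[[i]],
        start_in_out = start, len_nt = len, completeness = comp,
        rel_start = rel, rel_end = rel + len, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(family_key = character(0), orf_index = integer(0),
                      start_in_out = integer(0), len_nt = integer(0),
                      completeness = character(0), rel_start = integer(0),
                      rel_end = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# exact duplicate of a copy: the full sequence or an exact substring with
# endpoints kept 7 nt clear of substitutions
make_duplicate <- function(seq, mut_pos) {
  L <- nchar(seq)
  if (stats::runif(1L) < 0.5) {
    return(list(seq = seq, from = 1L, to = L))
  }
  f <- stats::runif(1L, 0.55, 0.95)
  span <- max(50L, round(f * L))
  from <- sample.int(L - span + 1L, 1L)
  adj <- function(p) {
    for (d in c(0L, 1:10, -(1:10))) {
      q <- p + d
      if (q >= 1L && q <= L &&
          (!length(mut_pos) || all(abs(mut_pos - q) > 6L))) return(q)
    }
    p
  }
  from <- adj(from)
  to <- adj(min(L, from + span - 1L))
  list(seq = substr(seq, from, to), from = from, to = to)
}

#' Write a synthetic fixture to a directory
#'
#' @param fixture result of [generate_assemblies()].
#' @param dir output directory (created when missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(fixture$truth, file.path(dir, "truth.fasta"))
  for (lab in names(fixture$assemblies)) {
    write_fasta(fixture$assemblies[[lab]],
                file.path(dir, paste0(lab, ".fasta")))
  }
  cov <- fixture$manifest$coverage
  utils::write.table(data.frame(id = names(cov), coverage = unname(cov)),
                     file.path(dir, "coverage.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  man <- fixture$manifest
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
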