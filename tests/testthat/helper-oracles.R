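# Independent oracles used across the suite.  None of these call the
# package's alignment kernel, clustering loop, or ORF scanner.

BASES4 <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES4, n, replace = TRUE),
                              collapse = "")

substitute_at <- function(s, pos) {
  for (p in pos) {
    old <- substr(s, p, p)
    substr(s, p, p) <- sample(setdiff(BASES4, old), 1L)
  }
  s
}

rc_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# ---- full Smith-Waterman reference kernel (Biostrings) -----------------

sw_submat <- local({
  m <- matrix(-3, 5, 5, dimnames = list(c(BASES4, "N"), c(BASES4, "N")))
  diag(m) <- 2
  m["N", ] <- -3
  m[, "N"] <- -3
  m
})

# summaries for one member against many representatives, one orientation
bs_align_many <- function(member, rep_seqs) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(rep_seqs), Biostrings::DNAString(member),
    type = "local", substitutionMatrix = sw_submat,
    gapOpening = 5, gapExtension = 2)
  gp <- as.character(Biostrings::pattern(al))   # gapped representative
  gs <- as.character(Biostrings::subject(al))   # gapped member
  n <- length(rep_seqs)
  ident <- numeric(n); cov_m <- numeric(n); cov_r <- numeric(n)
  for (i in seq_len(n)) {
    p <- strsplit(gp[[i]], "")[[1L]]
    s <- strsplit(gs[[i]], "")[[1L]]
    cols <- length(p)
    matches <- sum(p == s & p != "-" & p != "N")
    ident[[i]] <- if (cols > 0) matches / cols else 0
    cov_r[[i]] <- sum(p != "-") / nchar(rep_seqs[[i]])
    cov_m[[i]] <- sum(s != "-") / nchar(member)
  }
  list(score = BiocGenerics::score(al), identity = ident,
       cov_member = cov_m, cov_rep = cov_r)
}

# reference greedy clustering: full SW for every comparison, no
# prescreen; mirrors the documented canonical order and join rule
ref_greedy <- function(records, c = 1.0, aS = 1.0, aL = 0.005,
                       both_strands = TRUE) {
  eps <- 1e-9
  len <- nchar(records$seq)
  ord <- order(-len, records$id, method = "radix")
  ids <- records$id[ord]; seqs <- records$seq[ord]; len <- len[ord]
  rep_seq <- character(0)
  assign <- integer(length(ids))
  for (i in seq_along(ids)) {
    hit <- NA_integer_
    if (length(rep_seq)) {
      fw <- bs_align_many(seqs[[i]], rep_seq)
      best <- fw
      if (both_strands) {
        rv <- bs_align_many(rc_chr(seqs[[i]]), rep_seq)
        take <- rv$score > fw$score
        for (f in c("score", "identity", "cov_member", "cov_rep")) {
          best[[f]][take] <- rv[[f]][take]
        }
      }
      for (cl in seq_along(rep_seq)) {
        shorter_is_member <- len[[i]] <= nchar(rep_seq[[cl]])
        cs <- if (shorter_is_member) best$cov_member[[cl]]
              else best$cov_rep[[cl]]
        cl_ <- if (shorter_is_member) best$cov_rep[[cl]]
               else best$cov_member[[cl]]
        if (best$identity[[cl]] + eps >= c && cs + eps >= aS &&
            cl_ + eps >= aL) { hit <- cl; break }
      }
    }
    if (is.na(hit)) {
      rep_seq <- c(rep_seq, seqs[[i]])
      assign[[i]] <- length(rep_seq)
    } else {
      assign[[i]] <- hit
    }
  }
  data.frame(id = ids, cluster = assign - 1L,
             stringsAsFactors = FALSE)
}

# ---- tiny pure-R affine Smith-Waterman (desk-size inputs only) ---------

r_dp_align <- function(a, b) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1); E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 1:n) for (j in 1:m) {
    E[i + 1, j + 1] <- max(H[i + 1, j] - 7, E[i + 1, j] - 2)
    F[i + 1, j + 1] <- max(H[i, j + 1] - 7, F[i, j + 1] - 2)
    sub <- if (av[[i]] == bv[[j]] && av[[i]] %in% BASES4) 2 else -3
    H[i + 1, j + 1] <- max(0, H[i, j] + sub, E[i + 1, j + 1],
                           F[i + 1, j + 1])
    if (H[i + 1, j + 1] > best) best <- H[i + 1, j + 1]
  }
  best
}

# ---- naive six-frame ORF scan ------------------------------------------

naive_orfs <- function(s, min_aa = 100L) {
  L <- nchar(s)
  out <- list()
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") s else rc_chr(s)
    for (f in 0:2) {
      ncod <- (L - f) %/% 3L
      if (ncod < 1L) next
      cods <- vapply(0:(ncod - 1L), function(j)
        substr(ss, f + 3L * j + 1L, f + 3L * j + 3L), "")
      stops <- cods %in% c("TAA", "TAG", "TGA")
      j <- 1L
      while (j <= ncod) {
        if (stops[[j]]) { j <- j + 1L; next }
        k <- j
        while (k < ncod && !stops[[k + 1L]]) k <- k + 1L
        # stretch is codons j..k
        atg <- which(cods[j:k] == "ATG")
        stop_after <- k < ncod
        o1 <- NA_integer_; comp <- NA_character_
        if (length(atg)) {
          o1 <- j + atg[[1L]] - 1L
          comp <- if (stop_after) "complete" else "3prime_partial"
        } else if (j == 1L) {
          o1 <- j
          comp <- if (stop_after) "5prime_partial" else "internal"
        }
        if (!is.na(o1) && (k - o1 + 1L) >= min_aa) {
          s0 <- f + (o1 - 1L) * 3L
          e0 <- f + k * 3L
          st <- if (strand == "+") s0 else L - e0
          en <- if (strand == "+") e0 else L - s0
          out[[length(out) + 1L]] <- data.frame(
            strand = strand, frame = f, start = st, end = en,
            aa_len = k - o1 + 1L, completeness = comp,
            stringsAsFactors = FALSE)
        }
        j <- k + 1L
      }
    }
  }
  if (!length(out)) {
    return(data.frame(strand = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      aa_len = integer(0), completeness = character(0)))
  }
  df <- do.call(rbind, out)
  df[order(-df$aa_len, df$strand, df$start), , drop = FALSE]
}

# ---- random clustering instances ---------------------------------------

# A planted-family instance whose clustering decisions sit well clear of
# the identity/coverage thresholds: exact copies, interior-substituted
# copies (pass c = 0.98, fail c = 1.0), exact truncations (cov_short = 1),
# reverse-complement copies, chimeric members with a 0.55 or 0.85 matching
# fraction (exercising the aS thresholds), and unrelated singletons.
make_instance <- function(n_seqs, len_range) {
  recs <- list()
  k <- 0L
  add <- function(seq) {
    k <<- k + 1L
    recs[[k]] <<- data.frame(id = sprintf("s%03d", k), source = "x",
                             seq = seq, stringsAsFactors = FALSE)
  }
  while (k < n_seqs) {
    L <- sample(len_range[[1L]]:len_range[[2L]], 1L)
    base <- rand_seq(L)
    add(base)
    n_mem <- sample(0:3, 1L)
    for (j in seq_len(n_mem)) {
      if (k >= n_seqs) break
      kind <- sample(c("exact", "mut", "trunc", "rc", "chimera"), 1L)
      if (kind == "exact") {
        add(base)
      } else if (kind == "mut" && L >= 160L) {
        pos <- sample(10:(L - 10L), sample(1:3, 1L))
        add(substitute_at(base, pos))
      } else if (kind == "trunc") {
        keep <- max(30L, round(stats::runif(1L, 0.3, 0.9) * L))
        if (stats::runif(1L) < 0.5) add(substr(base, 1L, keep))
        else add(substr(base, L - keep + 1L, L))
      } else if (kind == "rc") {
        add(rc_chr(base))
      } else if (kind == "chimera") {
        fr <- sample(c(0.55, 0.85), 1L)
        cut <- round(fr * L)
        add(paste0(substr(base, 1L, cut), rand_seq(L - cut)))
      }
    }
  }
  do.call(rbind, recs)
}

# canonical comparable form of a clustering: sets of member ids
partition_sets <- function(df_id_cluster) {
  sets <- split(df_id_cluster$id, df_id_cluster$cluster)
  sets <- lapply(sets, sort)
  unname(sets[order(vapply(sets, `[[`, "", 1L))])
}

cluster_partition <- function(cs) {
  partition_sets(cs$members[, c("id", "cluster")])
}

# ---- dedup fixtures and the containment oracle -------------------------

make_dup_fixture <- function(n) {
  recs <- list(); k <- 0L
  add <- function(seq) {
    k <<- k + 1L
    recs[[k]] <<- data.frame(id = sprintf("d%03d", k), source = "x",
                             seq = seq, stringsAsFactors = FALSE)
  }
  while (k < n) {
    L <- sample(40:300, 1L)
    base <- rand_seq(L)
    add(base)
    for (j in seq_len(sample(0:2, 1L))) {
      if (k >= n) break
      kind <- sample(c("copy", "sub", "rcsub", "near"), 1L)
      if (kind == "copy") add(base)
      else if (kind == "sub") {
        a <- sample.int(L %/% 2, 1L)
        add(substr(base, a, a + sample.int(L - a, 1L)))
      } else if (kind == "rcsub") {
        a <- sample.int(L %/% 2, 1L)
        add(rc_chr(substr(base, a, a + sample.int(L - a, 1L))))
      } else {
        add(substitute_at(base, sample.int(L, 1L)))
      }
    }
  }
  do.call(rbind, recs)
}

# brute-force both-strand exact-substring removal in canonical order
containment_filter <- function(recs) {
  len <- nchar(recs$seq)
  ord <- order(-len, recs$id, method = "radix")
  kept_id <- character(0); kept_seq <- character(0)
  for (i in ord) {
    s <- recs$seq[[i]]
    contained <- any(vapply(kept_seq, function(k)
      grepl(s, k, fixed = TRUE) || grepl(rc_chr(s), k, fixed = TRUE),
      logical(1L)))
    if (!contained) {
      kept_id <- c(kept_id, recs$id[[i]])
      kept_seq <- c(kept_seq, s)
    }
  }
  kept_id
}

# ---- aS-sweep fixture ---------------------------------------------------

# Five genes; gene B's CDS shares its first 90% (540 of 600 nt) verbatim
# with gene A's CDS and diverges over the last 10%, so the pair merges
# exactly when aS drops to 0.90.  Each CDS carries its own planted
# database subject in the accompanying hit table.
sweep_fixture <- function() {
  btA <- transcat:::build_transcript(1100L, 200L)
  bodyA <- substr(btA$seq, btA$orfs$start + 4L, btA$orfs$end)
  shared <- substr(bodyA, 1L, 537L)
  fresh <- transcat:::orf_interior(20L, substr(shared, 536L, 537L))
  bodyB <- paste0(shared, paste(fresh$letters, collapse = ""))
  btB <- transcat:::build_transcript(1100L, 200L,
                                     interiors = list(bodyB))
  recs <- rbind(
    data.frame(id = "gA", source = "x", seq = btA$seq,
               stringsAsFactors = FALSE),
    data.frame(id = "gB", source = "x", seq = btB$seq,
               stringsAsFactors = FALSE))
  for (g in c("gC", "gD", "gE")) {
    bt <- transcat:::build_transcript(sample(800:1200, 1L),
                                      sample(120:180, 1L))
    recs <- rbind(recs, data.frame(id = g, source = "x", seq = bt$seq,
                                   stringsAsFactors = FALSE))
  }
  cds <- extract_cds(recs)
  stopifnot(nrow(cds) == 5L)
  hits <- do.call(rbind, lapply(seq_len(nrow(cds)), function(i) {
    data.frame(qseqid = cds$cds_id[[i]],
               sseqid = paste0("SUBJ_", cds$transcript_id[[i]]),
               pident = 99, length = 150L, mismatch = 0L, gapopen = 0L,
               qstart = 1L, qend = 150L, sstart = 1L, send = 150L,
               evalue = 1e-6, bitscore = 200,
               stringsAsFactors = FALSE)
  }))
  list(records = recs, cds = cds, hits = hits)
}
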