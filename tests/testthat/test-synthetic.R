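test_that("generation is deterministic under a fixed seed", {
  t1 <- generate_truth(n_genes = 10L, seed = 99L)
  t2 <- generate_truth(n_genes = 10L, seed = 99L)
  expect_identical(t1, t2)
  t3 <- generate_truth(n_genes = 10L, seed = 100L)
  expect_false(identical(t1$records$seq, t3$records$seq))

  f1 <- generate_assemblies(t1, seed = 5L)
  f2 <- generate_assemblies(t2, seed = 5L)
  expect_identical(f1$assemblies, f2$assemblies)
  expect_identical(f1$manifest$outputs, f2$manifest$outputs)
})

test_that("every truth transcript yields exactly its planted ORFs", {
  truth <- generate_truth(n_genes = 12L, n_bicistronic = 3L,
                          n_paralog_pairs = 2L, seed = 4L)
  man <- truth$manifest
  for (i in seq_len(nrow(truth$records))) {
    rec <- truth$records[i, , drop = FALSE]
    orfs <- find_orfs(rec)
    planted <- man$orfs[man$orfs$gene_id == rec$id, , drop = FALSE]
    expect_equal(nrow(orfs), nrow(planted))
    got <- orfs[order(orfs$start), ]
    want <- planted[order(planted$start), ]
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$aa_len, want$aa_len)
    expect_true(all(got$strand == "+"))
    expect_true(all(got$completeness == "complete"))
  }
})

test_that("paralogs share their ORF at the planted divergence", {
  truth <- generate_truth(n_genes = 6L, n_paralog_pairs = 2L,
                          paralog_divergence = 0, seed = 6L)
  man <- truth$manifest
  pairs <- man$genes[!is.na(man$genes$paralog_of), ]
  expect_equal(nrow(pairs), 2L)
  for (i in seq_len(nrow(pairs))) {
    a <- man$orfs[man$orfs$gene_id == pairs$paralog_of[[i]], ]
    b <- man$orfs[man$orfs$gene_id == pairs$gene_id[[i]], ]
    sa <- substr(truth$records$seq[match(a$gene_id, truth$records$id)],
                 a$start + 1L, a$end)
    sb <- substr(truth$records$seq[match(b$gene_id, truth$records$id)],
                 b$start + 1L, b$end)
    expect_identical(sa, sb)     # divergence 0: identical ORFs
  }

  div <- generate_truth(n_genes = 6L, n_paralog_pairs = 2L,
                        paralog_divergence = 0.08, seed = 6L)
  man <- div$manifest
  pairs <- man$genes[!is.na(man$genes$paralog_of), ]
  for (i in seq_len(nrow(pairs))) {
    a <- man$orfs[man$orfs$gene_id == pairs$paralog_of[[i]], ]
    b <- man$orfs[man$orfs$gene_id == pairs$gene_id[[i]], ]
    sa <- strsplit(substr(div$records$seq[match(a$gene_id, div$records$id)],
                          a$start + 1L, a$end), "")[[1L]]
    sb <- strsplit(substr(div$records$seq[match(b$gene_id, div$records$id)],
                          b$start + 1L, b$end), "")[[1L]]
    d <- mean(sa != sb)
    expect_gt(d, 0.03)
    expect_lt(d, 0.13)
  }
})

test_that("an all-rates-zero plan reproduces the truth in every assembly", {
  truth <- generate_truth(n_genes = 8L, seed = 11L)
  plans <- default_assembly_plans()
  for (lab in names(plans)) {
    plans[[lab]][c("dropout_rate", "dup_rate", "fragment_rate",
                   "error_rate")] <- list(0, 0, 0, 0)
    plans[[lab]]$n_artifacts <- 0L
  }
  fx <- generate_assemblies(truth, plans = plans, seed = 11L)
  for (lab in names(fx$assemblies)) {
    expect_equal(fx$assemblies[[lab]]$seq, truth$records$seq)
  }
  res <- run_consensus(fx$assemblies, quiet = TRUE)
  expect_equal(res$stats$n_uniCDS, 8L)
  expect_true(all(res$categories$category == 1L))
  expect_equal(sum(res$extensions$n_extended), 0L)
})

test_that("realized fates are recorded exactly in the manifest", {
  truth <- generate_truth(n_genes = 30L, seed = 21L)
  fx <- generate_assemblies(truth, seed = 21L)
  out <- fx$manifest$outputs
  for (lab in names(fx$assemblies)) {
    sub <- out[out$assembler == lab & out$kind != "dropped", ]
    expect_setequal(sub$out_id, fx$assemblies[[lab]]$id)
    expect_equal(sub$length[match(fx$assemblies[[lab]]$id, sub$out_id)],
                 nchar(fx$assemblies[[lab]]$seq))
    # dropped + emitted copies account for every gene
    gsub <- out[out$assembler == lab & out$kind %in% c("copy", "dropped"), ]
    expect_setequal(gsub$gene_id, truth$records$id)
  }
  # duplicates are exact copies or substrings of their parent
  dups <- out[out$kind == "duplicate", ]
  for (i in seq_len(nrow(dups))) {
    asm <- fx$assemblies[[dups$assembler[[i]]]]
    child <- asm$seq[match(dups$out_id[[i]], asm$id)]
    parent <- asm$seq[match(dups$dup_parent[[i]], asm$id)]
    expect_true(grepl(child, parent, fixed = TRUE))
  }
})

test_that("step-5 deduplication removes exactly the planted duplicates", {
  truth <- generate_truth(n_genes = 25L, seed = 31L)
  fx <- generate_assemblies(truth, seed = 31L)
  out <- fx$manifest$outputs
  for (lab in names(fx$assemblies)) {
    h <- harmonize_names(fx$assemblies[[lab]], lab)$records
    dd <- dedup_exact(h)
    n_dup <- sum(out$assembler == lab & out$kind == "duplicate")
    expect_equal(nrow(h) - nrow(dd$retained), n_dup)
    removed <- setdiff(h$id, dd$retained$id)
    dup_ids <- out$out_id[out$assembler == lab & out$kind == "duplicate"]
    planted <- sprintf("%s|%s", lab, dup_ids)
    expect_setequal(removed, planted)
  }
})

test_that("a lone ORF-bearing artifact creates one single-assembler cluster", {
  truth <- generate_truth(n_genes = 5L, seed = 41L)
  plans <- default_assembly_plans()
  for (lab in names(plans)) {
    plans[[lab]][c("dropout_rate", "dup_rate", "fragment_rate",
                   "error_rate")] <- list(0, 0, 0, 0)
    plans[[lab]]$n_artifacts <- 0L
  }
  plans$Trinity$n_artifacts <- 1L
  fx <- generate_assemblies(truth, plans = plans, seed = 41L)
  res <- run_consensus(fx$assemblies, quiet = TRUE)
  expect_equal(res$stats$n_uniCDS, 6L)
  expect_equal(sum(res$categories$category == 6L), 1L)
  expect_equal(sum(res$categories$category == 1L), 5L)
})

test_that("truncated copies carry exactly the manifest's expected CDSs", {
  truth <- generate_truth(n_genes = 40L, seed = 51L)
  fx <- generate_assemblies(truth, seed = 51L)
  man <- fx$manifest
  checked <- 0L
  for (lab in names(fx$assemblies)) {
    asm <- fx$assemblies[[lab]]
    out <- man$outputs
    copies <- out[out$assembler == lab & out$kind == "copy" &
                    (out$src_start > 0L |
                       out$src_end < nchar(truth$records$seq[
                         match(out$gene_id, truth$records$id)])), ]
    for (i in seq_len(nrow(copies))) {
      oid <- copies$out_id[[i]]
      orfs <- find_orfs(asm[match(oid, asm$id), , drop = FALSE])
      want <- man$cds[man$cds$assembler == lab & man$cds$out_id == oid, ]
      expect_equal(nrow(orfs), nrow(want))
      if (nrow(want)) {
        o <- orfs[order(orfs$start), ]
        w <- want[order(want$start_in_out), ]
        expect_equal(o$start, w$start_in_out)
        expect_equal(3L * o$aa_len, w$len_nt)
        expect_equal(o$completeness, w$completeness)
      }
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 10L)   # the fixture must actually contain truncations
})

test_that("infeasible length constraints are rejected", {
  expect_error(generate_truth(n_genes = 1L, length_range = c(200L, 250L),
                              seed = 1L), "infeasible")
})
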