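CAP2 <- transcat:::STOP_BLOCK

# distinct codon bodies so different test genes never cross-cluster
one_gene <- function(n_codons = 150L, codon = "GCT") {
  paste0(CAP2, "ATG", strrep(codon, n_codons), "TAA", CAP2)
}

test_that("three identical assemblies give one category-1 cluster", {
  s <- one_gene()
  asm <- list(CLC = seq_records("c1", s),
              IDBA_tran = seq_records("i1", s),
              Trinity = seq_records("t1", s))
  res <- run_consensus(asm, quiet = TRUE)
  expect_equal(res$stats$n_uniCDS, 1L)
  expect_equal(res$stats$n_final_transcripts, 1L)
  expect_equal(res$categories$category, 1L)
  expect_equal(sum(res$extensions$n_extended), 0L)
  expect_equal(res$stats$n_redundant_cds, 0L)
})

test_that("a gene seen by one assembler lands in its own category", {
  s <- one_gene()
  other <- one_gene(120L, codon = "GAC")
  for (solo in c("CLC", "Trinity", "IDBA_tran")) {
    asm <- list(CLC = seq_records("c1", other),
                IDBA_tran = seq_records("i1", other),
                Trinity = seq_records("t1", other))
    asm[[solo]] <- rbind(asm[[solo]], seq_records("extra", s,
                                                  source = solo))
    res <- run_consensus(asm, quiet = TRUE)
    expect_equal(res$stats$n_uniCDS, 2L)
    solo_cat <- c(CLC = 5L, Trinity = 6L, IDBA_tran = 7L)[[solo]]
    expect_setequal(res$categories$category, c(1L, solo_cat))
  }
})

test_that("the 7 label subsets map bijectively onto categories 1-7", {
  labs <- c("CLC", "IDBA_tran", "Trinity")
  subsets <- list(labs, c("CLC", "IDBA_tran"), c("CLC", "Trinity"),
                  c("IDBA_tran", "Trinity"), "CLC", "Trinity",
                  "IDBA_tran")
  cats <- assign_categories(subsets, labels = labs)
  expect_equal(cats, c(1L, 2L, 3L, 4L, 5L, 6L, 7L))
  expect_equal(sort(cats), 1:7)   # bijection
  # order inside the set must not matter
  expect_equal(assign_categories(c("Trinity", "CLC"), labels = labs), 3L)
  expect_error(assign_categories("SOAP", labels = labs), "unknown label")
  expect_error(assign_categories(character(0), labels = labs), "empty")
})

test_that("categories generalize to other assembler counts", {
  labs <- c("A", "B")
  expect_equal(assign_categories(list(c("A", "B"), "A", "B"),
                                 labels = labs), c(1L, 2L, 3L))
  # a custom mapping overrides the default
  cm <- stats::setNames(c(9L, 8L, 7L), c("A+B", "A", "B"))
  expect_equal(assign_categories("A", labels = labs, category_map = cm), 8L)
})

test_that("extension statistics follow the length arithmetic", {
  cds <- data.frame(
    cds_id = c("t1", "c1", "i1"),
    transcript_id = c("T|x", "C|y", "I|z"),
    source = c("Trinity", "CLC", "IDBA_tran"),
    nt_seq = c(strrep("A", 900), strrep("A", 600), strrep("A", 900)),
    stringsAsFactors = FALSE)
  members <- data.frame(
    cluster = 0L, id = c("t1", "c1", "i1"),
    length = c(900L, 600L, 900L), is_rep = c(TRUE, FALSE, FALSE),
    identity = c(NA, 1, 1), strand = "+",
    cov_short = c(NA, 1, 1), cov_long = c(NA, 600 / 900, 1),
    stringsAsFactors = FALSE)
  cs <- transcat:::new_cluster_set(members, list())
  ext <- compute_extensions(cs, cds,
                            labels = c("CLC", "IDBA_tran", "Trinity"))
  # CLC's longest member is 300 bp short of the representative
  expect_equal(ext$n_extended[ext$label == "CLC"], 1L)
  expect_equal(ext$cumulated_extension_bp[ext$label == "CLC"], 300L)
  expect_equal(ext$mean_extension_bp[ext$label == "CLC"], 300)
  # a member equal in length to the representative is not extended
  expect_equal(ext$n_extended[ext$label == "IDBA_tran"], 0L)
  # the representative's own assembler is never extended in its cluster
  expect_equal(ext$n_extended[ext$label == "Trinity"], 0L)
})

test_that("finalize_transcripts counts multi-CDS and redundant CDSs", {
  tx <- seq_records(c("T|a", "T|b"), c(strrep("ACG", 200), strrep("ACG", 200)))
  cds1 <- data.frame(cds_id = "T|a|cds1", transcript_id = "T|a",
                     stringsAsFactors = FALSE)
  fin <- finalize_transcripts("T|a|cds1", cds1, tx)
  expect_equal(fin$final_transcripts$id, "T|a")
  expect_equal(fin$n_multi_cds, 0L)
  expect_equal(fin$n_redundant_cds, 0L)

  # one transcript carrying two representative CDSs: n_final < n_uniCDS
  cds2 <- data.frame(cds_id = c("T|a|cds1", "T|a|cds2"),
                     transcript_id = c("T|a", "T|a"),
                     stringsAsFactors = FALSE)
  fin <- finalize_transcripts(c("T|a|cds1", "T|a|cds2"), cds2, tx)
  expect_equal(nrow(fin$final_transcripts), 1L)
  expect_equal(fin$n_multi_cds, 1L)
  expect_equal(fin$n_redundant_cds, 0L)

  # a non-representative CDS riding on a final transcript is redundant
  fin <- finalize_transcripts("T|a|cds1", cds2, tx)
  expect_equal(fin$n_redundant_cds, 1L)
  expect_equal(fin$n_total_cds_on_final, 2L)

  expect_error(finalize_transcripts("nope", cds1, tx),
               "no owning transcript")
})

test_that("bicistronic transcripts make n_final < n_uniCDS", {
  truth <- generate_truth(n_genes = 6L, n_bicistronic = 2L, seed = 3L)
  plans <- default_assembly_plans()
  for (lab in names(plans)) {
    plans[[lab]][c("dropout_rate", "dup_rate", "fragment_rate",
                   "error_rate")] <- list(0, 0, 0, 0)
    plans[[lab]]$n_artifacts <- 0L
  }
  fx <- generate_assemblies(truth, plans = plans, seed = 3L)
  res <- run_consensus(fx$assemblies, quiet = TRUE)
  expect_equal(res$stats$n_uniCDS, 8L)        # 6 genes + 2 extra ORFs
  expect_equal(res$stats$n_final_transcripts, 6L)
  expect_equal(res$stats$n_multi_cds_transcripts, 2L)
  expect_lt(res$stats$n_final_transcripts, res$stats$n_uniCDS)
  s <- res$stats
  expect_lte(s$n_final_transcripts, s$n_uniCDS)
  expect_lte(s$n_uniCDS, s$n_total_cds_on_final_transcripts)
})

test_that("a single-assembly run warns but works", {
  s <- one_gene()
  expect_warning(res <- run_consensus(list(CLC = seq_records("c1", s)),
                                      quiet = TRUE), "degenerate")
  expect_equal(res$stats$n_uniCDS, 1L)
})

test_that("provenance closure holds from uniCDS back to original names", {
  truth <- generate_truth(n_genes = 8L, seed = 13L)
  fx <- generate_assemblies(truth, seed = 13L)
  res <- run_consensus(fx$assemblies, quiet = TRUE)
  tr <- trace_provenance(res)
  expect_equal(nrow(tr), res$stats$n_uniCDS)
  expect_true(all(tr$label %in% res$labels))
  for (i in seq_len(nrow(tr))) {
    expect_true(tr$original[[i]] %in% fx$assemblies[[tr$label[[i]]]]$id)
  }
})
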