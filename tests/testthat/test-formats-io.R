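test_that("diff tables round-trip exactly, including infinite fold changes", {
  rec <- make_diff(c("g1", "g2", "g3"),
                   value_a = c(10, 0, 3.5), value_b = c(20, 8, 0),
                   log2_fc = c(1, Inf, -Inf),
                   p_value = c(0.001, 0.2, 1), q_value = c(0.01, 0.5, 1),
                   status = c("OK", "OK", "NOTEST"))
  path <- withr::local_tempfile(fileext = ".diff")
  write_diff_table(rec, path)
  back <- read_diff_table(path, "S1_vs_W")
  expect_equal(back, rec)
  # zero reference FPKM yields the +infinity sentinel, record retained
  expect_identical(back$log2_fc[2], Inf)
  expect_identical(back$log2_fc[3], -Inf)
})

test_that("diff reader validates dialect and values", {
  path <- withr::local_tempfile(fileext = ".diff")
  writeLines("gene_id\tvalue_1\tvalue_2\tp_value\tq_value\tstatus", path)
  expect_error(read_diff_table(path), "log2\\(fold_change\\)")
  # header-only file is an empty collection
  writeLines(paste("gene_id", "value_1", "value_2", "log2(fold_change)",
                   "p_value", "q_value", "status", sep = "\t"), path)
  expect_equal(nrow(read_diff_table(path)), 0)
  writeLines(c(paste("gene_id", "value_1", "value_2", "log2(fold_change)",
                     "p_value", "q_value", "status", sep = "\t"),
               "g1\t-4\t2\t1\t0.1\t0.2\tOK"), path)
  expect_error(read_diff_table(path), "negative FPKM at data row 1")
  writeLines(c(paste("gene_id", "value_1", "value_2", "log2(fold_change)",
                     "p_value", "q_value", "status", sep = "\t"),
               "g1\t1\t2\t1\t0.1\t0.2\tOK",
               "g1\t1\t2\t1\t0.1\t0.2\tOK"), path)
  expect_error(read_diff_table(path), "duplicated gene_id")
})

test_that("BLAST tabular reader enforces the 12-column dialect", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste("g1", "AT1G01010.1", "88.5", "240", "20", "2", "1",
                   "240", "5", "244", "1e-63", "500", sep = "\t"), path)
  hits <- read_blast_tab(path)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$e_value, 1e-63)
  expect_equal(hits$pid, 88.5)
  expect_equal(hits$aln_length, 240)

  writeLines(character(0), path)
  expect_equal(nrow(read_blast_tab(path)), 0)

  writeLines(paste("g1", "s1", "90", "100", "1", "0", "1", "100", "1",
                   "100", "0.0", "100", sep = "\t"), path)
  expect_equal(read_blast_tab(path)$e_value, 0)

  writeLines("g1\tonly\tthree", path)
  expect_error(read_blast_tab(path), "12 columns.*line 1")
})

test_that("BLAST tables round-trip through write and read", {
  sim <- simulate_blast_hits(sim_config(n_genes = 10, seed = 3,
                                        n_queries = 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_blast_tab(sim$hits, path)
  back <- read_blast_tab(path)
  expect_equal(back$e_value, sim$hits$e_value)
  expect_equal(back$subject_id, sim$hits$subject_id)
  expect_equal(back$pid, sim$hits$pid)
})

test_that("GO reader normalizes domains and collapses duplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tgo_id\tdomain\tterm",
               "g1\tGO:0000001\tmolecular function\tkinase activity",
               "g1\tGO:0000001\tMolecular Function\tkinase activity",
               "g2\tGO:0000002\tBP\tresponse to water"), path)
  expect_warning(go <- read_go_tsv(path), "duplicated")
  expect_equal(nrow(go), 2)
  expect_equal(go$domain, c("molecular_function", "biological_process"))

  writeLines(c("gene_id\tgo_id\tdomain\tterm",
               "g1\tGO:1\tnot_a_domain\tx"), path)
  expect_error(read_go_tsv(path), "unknown GO domain")

  # round trip
  ann <- data.frame(gene_id = c("g1", "g2"), go_id = c("GO:1", "GO:2"),
                    domain = c("cellular_component", "biological_process"),
                    term = c("membrane", "response to water"),
                    stringsAsFactors = FALSE)
  write_go_tsv(ann, path)
  expect_equal(read_go_tsv(path), ann)
})

test_that("FPKM tables round-trip in wide layout and pivot from long", {
  m <- make_fpkm(c(1, 2.5), c(4, 5), c(0, 7))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fpkm_table(m, path)
  expect_equal(read_fpkm_table(path), m)

  long <- data.frame(gene_id = rep(rownames(m), each = ncol(m)),
                     condition = rep(sub("_.*", "", colnames(m)), 2),
                     replicate = rep(sub(".*_", "", colnames(m)), 2),
                     fpkm = as.vector(t(m)))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_fpkm_table(path), m)

  m2 <- m; m2[1, 1] <- -1
  expect_error(validate_fpkm(m2), "negative FPKM")
})
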