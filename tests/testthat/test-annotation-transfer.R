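mk_hits <- function(e, len = 100, pid = 90, subj = NULL) {
  n <- length(e)
  if (is.null(subj)) subj <- sprintf("AT1G%05d.1", seq_len(n))
  data.frame(query_id = rep("q", n), qseqid = rep("q", n),
             subject_id = rep_len(subj, n),
             e_value = e, aln_length = rep_len(len, n),
             pid = rep_len(pid, n), stringsAsFactors = FALSE)
}

test_that("hits sort by e-value, then length, then identity, then subject", {
  h <- mk_hits(c(1e-5, 1e-9))
  expect_equal(sort_hits(h)$e_value, c(1e-9, 1e-5))
  h <- mk_hits(c(1e-9, 1e-9), len = c(240, 300))
  expect_equal(sort_hits(h)$aln_length, c(300, 240))
  h <- mk_hits(c(1e-9, 1e-9), len = 240, pid = c(80, 95))
  expect_equal(sort_hits(h)$pid, c(95, 80))
  h <- mk_hits(c(1e-9, 1e-9), subj = c("AT2G1.1", "AT1G1.1"))
  expect_equal(sort_hits(h)$subject_id, c("AT1G1.1", "AT2G1.1"))
  expect_equal(sort_hits(mk_hits(1e-4)), mk_hits(1e-4))
})

test_that("the e-value window spans ten orders of magnitude, inclusive", {
  w <- evalue_window(sort_hits(mk_hits(c(1e-63, 1e-60, 1e-53, 1e-50))))
  expect_equal(w$hits$e_value, c(1e-63, 1e-60, 1e-53))
  expect_equal(w$e_cutoff, 1e-53)
  # single hit is its own window
  expect_equal(nrow(evalue_window(sort_hits(mk_hits(1e-8)))$hits), 1)
  # empty input gives an empty window
  expect_equal(nrow(evalue_window(mk_hits(numeric(0)))$hits), 0)
  # best e = 0 degenerates to {e = 0} plus the absolute guard
  w0 <- evalue_window(sort_hits(mk_hits(c(0, 1e-200, 1e-100))))
  expect_equal(w0$hits$e_value, c(0, 1e-200))
  # window membership is monotone in the factor
  h4 <- mk_hits(c(1e-63, 1e-60, 1e-53, 1e-50))
  wide <- evalue_window(sort_hits(h4), 1e15)
  expect_true(all(w$hits$subject_id %in% wide$hits$subject_id))
  expect_equal(nrow(wide$hits), 4)
})

test_that("common substrings match the stated examples", {
  expect_equal(common_substrings("protein kinase 1"), "protein kinase 1")
  got <- common_substrings(c("ABC transporter 1", "ABC transporter 2"))
  expect_equal(got[1], "abc transporter")
  expect_equal(common_substrings(c("xyz", "abc")), character(0))
  # case and whitespace variants normalize before matching
  expect_equal(
    common_substrings(c("Heat  Shock Protein", "heat shock protein 70"))[1],
    "heat shock protein")
})

test_that("common substrings agree with the brute-force oracle", {
  set.seed(33)
  for (i in 1:60) {
    strs <- vapply(1:3, function(j) random_string(sample(10:40, 1)), "")
    expect_equal(common_substrings(strs, word_boundary = FALSE),
                 lcs_oracle(strs),
                 info = paste(strs, collapse = " | "))
  }
})

test_that("GO aggregation counts unique subject genes and ranks terms", {
  ann <- data.frame(
    gene_id = c("AT1", "AT1", "AT2", "AT3", "AT4"),
    go_id = sprintf("GO:%07d", 1:5),
    domain = c("biological_process", "biological_process",
               "biological_process", "biological_process",
               "biological_process"),
    term = c("T", "U", "T", "T", "U"), stringsAsFactors = FALSE)
  # window of one subject with two BP terms
  w1 <- evalue_window(sort_hits(mk_hits(1e-10, subj = "AT1.1")))
  got <- aggregate_go(w1, ann)
  expect_equal(got$biological_process$count, c(1, 1))
  # 3 subjects share T, one has U: T outranks U
  w <- evalue_window(sort_hits(mk_hits(rep(1e-10, 4),
                                       subj = c("AT1.1", "AT2.1", "AT3.1",
                                                "AT4.2"))))
  got <- aggregate_go(w, ann)
  expect_equal(got$biological_process$term[1], "T")
  expect_equal(got$biological_process$count, c(3, 2))
  # counts conserve: sum equals unique (gene, term) pairs per domain
  expect_equal(sum(got$biological_process$count), 5)
  # isoforms of the same gene do not double-count
  wiso <- evalue_window(sort_hits(mk_hits(rep(1e-10, 2),
                                          subj = c("AT1.1", "AT1.2"))))
  expect_equal(aggregate_go(wiso, ann)$biological_process$count, c(1, 1))
  # no annotations: empty lists
  wnone <- evalue_window(sort_hits(mk_hits(1e-10, subj = "ATX.1")))
  expect_equal(nrow(aggregate_go(wnone, ann)$biological_process), 0)
})

test_that("inferred annotations keep native descriptions but always infer GO", {
  ann <- data.frame(gene_id = "AT1", go_id = "GO:1",
                    domain = "biological_process", term = "response to water")
  desc <- data.frame(gene_id = "AT1",
                     description = "dehydrin family protein")
  w <- evalue_window(sort_hits(mk_hits(1e-10, subj = "AT1.1")))

  a <- infer_annotation("q", "asparagine synthase", w, ann, desc)
  expect_equal(a$source, "native")
  expect_equal(a$description, "asparagine synthase")
  expect_equal(a$go_terms$biological_process$term, "response to water")

  for (absent in c("hypothetical protein", "Putative protein", "", NA)) {
    a <- infer_annotation("q", absent, w, ann, desc)
    expect_equal(a$source, "inferred")
    expect_equal(a$description, "dehydrin family protein")
  }

  # no hits at all: flagged unannotated
  wempty <- evalue_window(mk_hits(numeric(0)))
  a <- infer_annotation("q", NA, wempty, ann, desc)
  expect_true(a$flagged)
  expect_equal(a$description, "")
})

test_that("annotate_queries drives the full transfer over many queries", {
  sim <- simulate_blast_hits(sim_config(n_genes = 10, seed = 9,
                                        n_queries = 6))
  genes <- unique(strip_isoform(sim$hits$subject_id))
  ann <- data.frame(gene_id = genes, go_id = "GO:0009737",
                    domain = "biological_process",
                    term = "response to abscisic acid")
  desc <- data.frame(gene_id = genes,
                     description = paste("abc transporter family protein",
                                         seq_along(genes)))
  out <- annotate_queries(sim$hits, NULL, desc, ann)
  expect_equal(sort(out$query_id), sort(unique(sim$hits$query_id)))
  expect_true(all(out$source == "inferred"))
  expect_true(all(grepl("abc transporter family protein",
                        out$description[!out$flagged])))
  expect_true(all(grepl("response to abscisic acid (", out$bp_terms,
                        fixed = TRUE)))
})
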