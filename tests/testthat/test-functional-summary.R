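test_that("the percentage rule reproduces printed-parity cells", {
  expect_equal(category_pct(42, 162), 26)
  expect_equal(category_pct(163, 533), 31)
  expect_equal(category_pct(18, 49), 37)
  expect_equal(category_pct(8, 17), 47)
  expect_true(is.na(category_pct(0, 0)))
  # half-away-from-zero rounding
  expect_equal(category_pct(1, 8), 13)    # 12.5 -> 13
})

mk_ann <- function(gene_id, term, domain = "biological_process") {
  data.frame(gene_id = gene_id, go_id = "", domain = domain, term = term,
             stringsAsFactors = FALSE)
}

test_that("build_matrix counts per class with multi-category membership", {
  lab <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    class = c("[+/+]", "[+/+]", "[+/-]", "[-/=]"))
  ann <- rbind(
    mk_ann("g1", "integral component of membrane"),
    mk_ann("g1", "response to jasmonic acid"),   # multi-category gene
    mk_ann("g2", "integral component of membrane"),
    mk_ann("g3", "response to jasmonic acid"))
  m <- build_matrix(lab, ann)
  expect_equal(m$counts["Membrane-associated", "[+/+]"], 2L)
  expect_equal(m$counts["Response to JA", "[+/+]"], 1L)
  expect_equal(m$counts["Response to JA", "[+/-]"], 1L)
  expect_equal(m$pct["Membrane-associated", "[+/+]"], 100)
  # unannotated class: zero counts, class total still registered
  expect_equal(m$counts["Membrane-associated", "[-/=]"], 0L)
  expect_equal(unname(m$class_totals), c(2L, 0L, 1L, 0L, 0L, 1L))
  # empty class: undefined percentage
  expect_true(is.na(m$pct["Membrane-associated", "[-/-]"]))
  # empty category: a row of zeros
  expect_true(all(m$counts["Lea", ] == 0))
})

test_that("TF sub-family percentages use the class TF count as denominator", {
  lab <- data.frame(gene_id = sprintf("g%02d", 1:20),
                    class = rep("[+/+]", 20))
  tf_genes <- sprintf("g%02d", 1:17)
  nac_genes <- sprintf("g%02d", 1:8)
  ann <- rbind(
    mk_ann(tf_genes, "dna-binding transcription factor activity",
           "molecular_function"),
    mk_ann(nac_genes, "nac domain transcription factor",
           "molecular_function"))
  m <- build_matrix(lab, ann)
  expect_equal(m$counts["Transcription factors", "[+/+]"], 17L)
  expect_equal(m$counts["NAC", "[+/+]"], 8L)
  expect_equal(m$pct["NAC", "[+/+]"], 47)    # 8/17, not 8/20
})

test_that("heatmap intensities ramp linearly to the cap and saturate", {
  expect_equal(heatmap_intensities(0), 0)
  expect_equal(heatmap_intensities(60), 1)
  expect_equal(heatmap_intensities(90), 1)
  expect_equal(heatmap_intensities(30), 0.5)
  expect_error(heatmap_intensities(10, cap = 0), "cap")
  # monotone and saturating on a grid
  pct <- seq(0, 100, 5)
  ii <- heatmap_intensities(pct)
  expect_true(all(diff(ii) >= 0))
  expect_true(all(ii[pct >= 60] == 1))
})

test_that("pairwise species matrices interleave columns and share scaling", {
  lab <- data.frame(gene_id = c("g1", "g2"), class = c("[+/+]", "[-/-]"))
  ann <- mk_ann(c("g1", "g2"), "chloroplast", "cellular_component")
  m <- build_matrix(lab, ann)
  both <- pairwise_species_matrix(m, m)
  expect_equal(ncol(both$pct), 12)
  expect_equal(both$pct[, "ZM.[+/+]"], both$pct[, "AT.[+/+]"])
  # worked intensities: 24% -> 0.4 and 6% -> 0.1 under the 60% cap
  pz <- m$pct; pz["Chloroplast", "[-/-]"] <- 6
  pa <- m$pct; pa["Chloroplast", "[-/-]"] <- 24
  both <- pairwise_species_matrix(pz, pa)
  expect_equal(both$intensity["Chloroplast", "ZM.[-/-]"], 0.1)
  expect_equal(both$intensity["Chloroplast", "AT.[-/-]"], 0.4)
  # mismatched category rows are rejected with the offenders named
  expect_error(pairwise_species_matrix(m$pct[-1, , drop = FALSE], m$pct),
               "Membrane-associated")
})

test_that("category matrices render to TSV with totals and dashes", {
  lab <- data.frame(gene_id = c("g1", "g2"), class = c("[+/+]", "[+/+]"))
  ann <- mk_ann("g1", "chloroplast", "cellular_component")
  m <- build_matrix(lab, ann)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_category_matrix(m, path)
  out <- readLines(path)
  expect_match(out[2], "^Class total\t2")
  expect_match(out[grep("^Chloroplast", out)], "1 \\(50%\\)")
})
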