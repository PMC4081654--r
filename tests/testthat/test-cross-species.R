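test_that("homolog partitions count unique reference genes by outcome", {
  map <- data.frame(maize_id = "m1", ref_id = "a1")
  ref <- data.frame(gene_id = "a1", class = "[=/=]")
  part <- partition_homologs("m1", map, ref)
  expect_equal(unname(part["no_S1_response"]), 1L)
  expect_equal(attr(part, "total"), 1L)

  # empty map: all counts zero
  part0 <- partition_homologs("m1", map[0, ], ref)
  expect_true(all(part0 == 0))

  # late-response homologs did not respond in S1
  ref$class <- "[=/+]"
  expect_equal(unname(partition_homologs("m1", map, ref)["no_S1_response"]),
               1L)

  # unlabeled homolog is an error naming the id
  expect_error(partition_homologs("m1", map, ref[0, ]), "a1")
})

test_that("planted outcome fractions are recovered within a binomial envelope", {
  set.seed(17)
  n <- 2000
  outcomes <- sample(c("no", "nonmem", "mem"), n, TRUE,
                     prob = c(0.5, 0.25, 0.25))
  cls <- ifelse(outcomes == "no", "[=/=]",
                ifelse(outcomes == "nonmem", "[+/=]", "[+/+]"))
  map <- data.frame(maize_id = sprintf("m%d", seq_len(n)),
                    ref_id = sprintf("a%d", seq_len(n)))
  ref <- data.frame(gene_id = map$ref_id, class = cls)
  part <- partition_homologs(map$maize_id, map, ref)
  expect_equal(sum(part), n)
  expect_true(part["no_S1_response"] >= qbinom(0.005, n, 0.5) &&
                part["no_S1_response"] <= qbinom(0.995, n, 0.5))
  expect_true(part["responds_memory"] >= qbinom(0.005, n, 0.25) &&
                part["responds_memory"] <= qbinom(0.995, n, 0.25))
})

test_that("conservation verdicts follow the precedence order", {
  mem <- data.frame(gene_id = "m1", class = "[+/+]")
  mk <- function(hcls) {
    map <- data.frame(maize_id = rep("m1", length(hcls)),
                      ref_id = sprintf("a%d", seq_along(hcls)))
    ref <- data.frame(gene_id = map$ref_id, class = hcls)
    as.character(conservation_verdicts(mem, map, ref)$verdict)
  }
  expect_equal(mk(c("[+/+]", "[=/=]")), "memory_same_type")
  expect_equal(mk(c("[-/-]", "[+/=]", "[=/=]")), "memory_different_type")
  expect_equal(mk(c("[+/=]", "[=/=]")), "homolog_non_memory")
  expect_equal(mk("[=/=]"), "homolog_no_response")
  expect_equal(mk(character(0)), "no_homolog")
  # a [+/-] maize gene with only a [-/-] homolog: both memory, types differ
  mem2 <- data.frame(gene_id = "m1", class = "[+/-]")
  map <- data.frame(maize_id = "m1", ref_id = "a1")
  ref <- data.frame(gene_id = "a1", class = "[-/-]")
  expect_equal(as.character(conservation_verdicts(mem2, map, ref)$verdict),
               "memory_different_type")
  # verdicts are invariant to homolog enumeration order
  expect_equal(mk(c("[=/=]", "[+/+]")), "memory_same_type")
})

test_that("conservation tables reconcile gene-level and homolog-level tallies", {
  mem <- data.frame(gene_id = "m1", class = "[+/+]")
  map <- data.frame(maize_id = c("m1", "m1"), ref_id = c("a1", "a2"))
  ref <- data.frame(gene_id = c("a1", "a2"), class = c("[+/+]", "[=/=]"))
  t5 <- conservation_tables(mem, map, ref)
  # one maize-level verdict, two homolog-level tallies
  expect_equal(sum(t5$verdict_counts), 1)
  expect_equal(unname(t5$verdict_counts["memory_same_type"]), 1L)
  expect_equal(sum(t5$pair_outcomes_by_class["[+/+]", ]), 2L)
  expect_equal(sum(t5$homolog_partition), 2L)

  # bijective maps collapse the two conventions
  mem <- data.frame(gene_id = c("m1", "m2"), class = c("[+/+]", "[-/-]"))
  map <- data.frame(maize_id = c("m1", "m2"), ref_id = c("a1", "a2"))
  ref <- data.frame(gene_id = c("a1", "a2"), class = c("[+/=]", "[=/=]"))
  t5 <- conservation_tables(mem, map, ref)
  expect_equal(unname(colSums(t5$pair_outcomes_by_class)),
               unname(as.vector(t5$homolog_partition)))

  # empty inputs give empty tables
  t0 <- conservation_tables(mem[0, ], map[0, ], ref)
  expect_equal(sum(t0$verdict_counts), 0)
  expect_equal(sum(t0$homolog_partition), 0)
})

test_that("planted conservation fractions are estimated from verdicts", {
  cfg <- sim_config(n_genes = 12000, seed = 29, conservation_fraction = 0.3)
  sim <- simulate_expression(cfg)
  hom <- simulate_homology(cfg, sim$truth)
  mem <- sim$truth[class_group(sim$truth$class) == "memory",
                   c("gene_id", "class")]
  rec <- conservation_verdicts(mem, hom$map, hom$ref_classes)
  est <- mean(rec$verdict == "memory_same_type")
  n <- nrow(rec)
  ci <- 2.576 * sqrt(0.3 * 0.7 / n)
  expect_lt(abs(est - 0.3), ci + 1e-12)
  # and the verdicts agree gene-by-gene with the planted truth
  expect_equal(rec$verdict == "memory_same_type",
               hom$truth$conserved[match(rec$gene_id, hom$truth$gene_id)])
})
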