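# Synthetic inputs with planted ground truth for every pipeline stage.
#
# The generator emulates the study design: three conditions (W, S1, S3) with
# two biological replicates, log-normal baseline FPKM, per-class fold-change
# programs across W -> S1 -> S3, multiplicative replicate noise, class-biased
# GO annotation draws, and homolog maps with a planted conservation fraction.

# Table-1-flavoured default class proportions (counts over 39,635 genes:
# response ~5% of the transcriptome, memory ~40% of responders).
.DEFAULT_CLASS_PROPS <- local({
  counts <- c("[+/+]" = 162, "[-/-]" = 72, "[+/-]" = 533, "[-/+]" = 49,
              "[+/=]" = 941, "[-/=]" = 305, "[=/+]" = 1678, "[=/-]" = 1246)
  p <- counts / 39635
  c(p, "[=/=]" = unname(1 - sum(p)))
})

#' Simulation configuration
#'
#' Defaults are the study-like conditions: class proportions echoing the
#' observed partition (dehydration response about 5% of genes, memory about
#' 40% of responders), log-normal baseline FPKM (meanlog 3, sdlog 1.5 —
#' median ~20 FPKM), planted effects of |log2FC| = 2, multiplicative
#' replicate noise at CV 0.2, two replicates per condition. Planted
#' responders have their baseline resampled above the `floor_safe_quantile`
#' of the baseline distribution so their planted labels are recoverable in
#' principle (the expression-floor criterion would otherwise censor lowly
#' expressed responders by design).
#'
#' @param n_genes number of genes.
#' @param class_proportions named probabilities over the nine class symbols
#'   (must sum to 1).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline FPKM
#'   parameters (natural log).
#' @param effect_log2fc planted |log2 fold change| for each responding step.
#' @param replicate_cv coefficient of variation of the multiplicative
#'   replicate noise (0 = noise-free).
#' @param n_replicates replicates per condition (>= 1; >= 2 for the
#'   stand-in DE test).
#' @param floor_safe_quantile baseline quantile above which responder
#'   baselines are placed.
#' @param seed integer seed (mandatory; all generators are bit-reproducible
#'   under it).
#' @param n_queries queries for [simulate_blast_hits()].
#' @param annotation_base_rate base per-category membership probability for
#'   [simulate_annotations()].
#' @param annotation_enrichment named list: category name -> named numeric
#'   multipliers over class symbols.
#' @param homologs_lambda extra homologs per memory gene are
#'   `Poisson(homologs_lambda)` (plus the one guaranteed homolog).
#' @param conservation_fraction fraction of memory genes planted with a
#'   same-class homolog.
#' @param outcome_probs outcome split for non-conserved homologs
#'   (`no_response`, `non_memory`, `memory`).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000,
                       class_proportions = .DEFAULT_CLASS_PROPS,
                       baseline_meanlog = 3, baseline_sdlog = 1.5,
                       effect_log2fc = 2, replicate_cv = 0.2,
                       n_replicates = 2, floor_safe_quantile = 0.3,
                       seed,
                       n_queries = 25,
                       annotation_base_rate = 0.10,
                       annotation_enrichment = list(
                         "Membrane-associated" = c("[+/+]" = 3, "[-/+]" = 3),
                         "Response to JA" = c("[+/-]" = 4),
                         "NAC" = c("[+/+]" = 5)),
                       homologs_lambda = 1.8,
                       conservation_fraction = 0.25,
                       outcome_probs = c(no_response = 0.5,
                                         non_memory = 0.25, memory = 0.25)) {
  if (missing(seed)) stop("sim_config: seed is mandatory", call. = FALSE)
  stopifnot(abs(sum(class_proportions) - 1) < 1e-8,
            all(names(class_proportions) %in% unname(MEMORY_CLASSES)),
            replicate_cv >= 0, n_replicates >= 1,
            conservation_fraction >= 0, conservation_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

.noise_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -s^2 / 2, sdlog = s)   # mean exactly 1
}

#' Simulate a replicate FPKM table with planted classes
#'
#' Condition means follow the planted class program (e.g. `[+/-]`: W = mu,
#' S1 = mu * 2^d, S3 back to mu); replicates are mean times a mean-one
#' log-normal factor with the configured CV.
#'
#' @param cfg a [sim_config()].
#' @return list: `fpkm` (wide matrix), `truth` (data.frame `gene_id`,
#'   `class`, `mu_w`, `mu_s1`, `mu_s3`).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  gene_id <- sprintf("ZmG%06d", seq_len(n))
  cls <- sample(names(cfg$class_proportions), n, replace = TRUE,
                prob = cfg$class_proportions)
  base <- rlnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog)
  if (cfg$floor_safe_quantile > 0 && cfg$baseline_sdlog > 0) {
    # responders must clear the expression floor in every tested contrast
    # even after the deepest planted down-step (a factor 2^effect_log2fc),
    # so the safety margin scales with the planted effect
    floor_q <- 2^cfg$effect_log2fc *
      stats::qlnorm(cfg$floor_safe_quantile, cfg$baseline_meanlog,
                    cfg$baseline_sdlog)
    low <- cls != "[=/=]" & base < floor_q
    while (any(low)) {
      base[low] <- rlnorm(sum(low), cfg$baseline_meanlog, cfg$baseline_sdlog)
      low <- cls != "[=/=]" & base < floor_q
    }
  }
  d <- cfg$effect_log2fc
  s1_sign <- ifelse(cls %in% c("[+/+]", "[+/-]", "[+/=]"), 1,
                    ifelse(cls %in% c("[-/-]", "[-/+]", "[-/=]"), -1, 0))
  s3_sign <- ifelse(cls %in% c("[+/+]", "[-/+]", "[=/+]"), 1,
                    ifelse(cls %in% c("[-/-]", "[+/-]", "[=/-]"), -1, 0))
  mu_w <- base
  mu_s1 <- mu_w * 2^(s1_sign * d)
  mu_s3 <- mu_s1 * 2^(s3_sign * d)
  mus <- list(W = mu_w, S1 = mu_s1, S3 = mu_s3)
  cols <- unlist(lapply(.CONDITIONS, function(cd)
    paste(cd, seq_len(cfg$n_replicates), sep = "_")))
  fpkm <- matrix(0, n, length(cols), dimnames = list(gene_id, cols))
  for (cd in .CONDITIONS)
    for (r in seq_len(cfg$n_replicates))
      fpkm[, paste(cd, r, sep = "_")] <-
        mus[[cd]] * .noise_factor(n, cfg$replicate_cv)
  list(fpkm = fpkm,
       truth = data.frame(gene_id = gene_id, class = cls, mu_w = mu_w,
                          mu_s1 = mu_s1, mu_s3 = mu_s3,
                          stringsAsFactors = FALSE))
}

#' Simulate BLAST tabular hits with known window membership
#'
#' Per query, a best hit and a spread of further hits whose e-values fall
#' inside and outside the 1e10 window; the truth table lists the intended
#' window members. One query with a best e-value of exactly 0 exercises the
#' degenerate-case rule.
#'
#' @param cfg a [sim_config()].
#' @return list: `hits` (outfmt-6 data.frame as from [read_blast_tab()]),
#'   `truth` (data.frame `query_id`, `subject_id`, `e_value`, `in_window`).
#' @export
simulate_blast_hits <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  rows <- list()
  subj_counter <- 0L
  for (qi in seq_len(cfg$n_queries)) {
    q <- sprintf("ZmP%04d", qi)
    zero_best <- qi == cfg$n_queries   # last query: degenerate best e = 0
    best_e <- if (zero_best) 0 else 10^(-runif(1, 20, 80))
    n_extra <- rpois(1, 3)
    extra_e <- if (zero_best)
      10^(-runif(n_extra, 100, 250))
    else pmin(best_e * 10^runif(n_extra, 0, 15), 1e-3)
    e <- c(best_e, extra_e)
    n_hits <- length(e)
    subj <- sprintf("AT%dG%05d.%d", sample(1:5, n_hits, TRUE),
                    subj_counter + seq_len(n_hits), sample(1:2, n_hits, TRUE))
    subj_counter <- subj_counter + n_hits
    len <- sample(80:600, n_hits, TRUE)
    pid <- round(runif(n_hits, 35, 99), 2)
    rows[[qi]] <- data.frame(
      qseqid = q, sseqid = subj, pident = pid, length = len,
      mismatch = pmax(0L, round(len * (1 - pid / 100))), gapopen = 0L,
      qstart = 1L, qend = len, sstart = 1L, send = len,
      evalue = e, bitscore = round(runif(n_hits, 50, 900), 1),
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows)
  # shuffle so consumers must sort
  hits <- hits[sample(nrow(hits)), , drop = FALSE]
  rownames(hits) <- NULL
  hits$query_id <- hits$qseqid; hits$subject_id <- hits$sseqid
  hits$pid <- hits$pident; hits$aln_length <- hits$length
  hits$e_value <- hits$evalue
  truth <- do.call(rbind, lapply(split(hits, hits$query_id), function(h) {
    best <- min(h$e_value)
    inw <- if (best == 0) h$e_value == 0 | h$e_value <= 1e-170
    else h$e_value <= best * 1e10
    data.frame(query_id = h$query_id, subject_id = h$subject_id,
               e_value = h$e_value, in_window = inw,
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  list(hits = hits, truth = truth)
}

# simulated functional categories: name, parent, go_id, domain, term; the
# terms are chosen to satisfy the default_categories() predicates
.SIM_CATEGORIES <- data.frame(
  name = c("Membrane-associated", "Chloroplast", "RESP. Aba/Salt/Cold/Heat",
           "Response to JA", "Transcription factors", "NAC", "AP2/ERF"),
  parent = c(NA, NA, NA, NA, NA, "Transcription factors",
             "Transcription factors"),
  go_id = c("GO:0016020", "GO:0009507", "GO:0009737", "GO:0009753",
            "GO:0003700", "GO:0003700", "GO:0003700"),
  domain = c("cellular_component", "cellular_component",
             "biological_process", "biological_process",
             "molecular_function", "molecular_function",
             "molecular_function"),
  term = c("integral component of membrane", "chloroplast",
           "response to abscisic acid", "response to jasmonic acid",
           "dna-binding transcription factor activity",
           "nac domain transcription factor",
           "ap2 ethylene-responsive element binding factor"),
  stringsAsFactors = FALSE
)

#' Simulate class-biased GO annotations and descriptions
#'
#' Genes draw functional-category memberships with per-class enrichment
#' multipliers so that [build_matrix()] shows the planted contrasts;
#' sub-family membership implies the parent category. Descriptions are built
#' from shared stems plus variable suffixes to exercise the
#' longest-common-substring synthesis.
#'
#' @param cfg a [sim_config()].
#' @param truth truth table from [simulate_expression()].
#' @return list: `go` (data.frame `gene_id`, `go_id`, `domain`, `term`),
#'   `descriptions` (data.frame `gene_id`, `description`), `truth`
#'   (data.frame `gene_id`, `category` memberships).
#' @export
simulate_annotations <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  cats <- .SIM_CATEGORIES
  go <- list(); members <- list()
  for (i in seq_len(nrow(cats))) {
    mult <- rep(1, nrow(truth))
    enr <- cfg$annotation_enrichment[[cats$name[i]]]
    if (!is.null(enr))
      for (cl in names(enr)) mult[truth$class == cl] <- enr[[cl]]
    p <- pmin(cfg$annotation_base_rate * mult, 1)
    hit <- runif(nrow(truth)) < p
    if (!any(hit)) next
    genes <- truth$gene_id[hit]
    rows <- data.frame(gene_id = genes, go_id = cats$go_id[i],
                       domain = cats$domain[i], term = cats$term[i],
                       stringsAsFactors = FALSE)
    if (!is.na(cats$parent[i])) {
      pi <- match(cats$parent[i], cats$name)
      rows <- rbind(rows, data.frame(gene_id = genes, go_id = cats$go_id[pi],
                                     domain = cats$domain[pi],
                                     term = cats$term[pi],
                                     stringsAsFactors = FALSE))
    }
    go[[i]] <- rows
    members[[i]] <- data.frame(gene_id = genes, category = cats$name[i],
                               stringsAsFactors = FALSE)
  }
  go <- do.call(rbind, go)
  go <- go[!duplicated(go[, c("gene_id", "go_id")]), , drop = FALSE]
  go <- go[order(go$gene_id, go$go_id), , drop = FALSE]
  rownames(go) <- NULL
  stems <- c("protein kinase family protein", "abc transporter family",
             "dehydrin family protein", "nac domain transcription factor")
  desc <- data.frame(
    gene_id = truth$gene_id,
    description = paste(sample(stems, nrow(truth), TRUE),
                        sample(99, nrow(truth), TRUE)),
    stringsAsFactors = FALSE)
  list(go = go, descriptions = desc,
       truth = do.call(rbind, members))
}

#' Simulate a homolog map with a planted conservation fraction
#'
#' Every memory gene in `truth` receives one guaranteed homolog plus a
#' Poisson number of extras. With probability `conservation_fraction` the
#' guaranteed homolog carries the identical memory class (the gene is
#' planted conserved); otherwise, and for all extra homologs, the outcome is
#' drawn from `outcome_probs`, with memory outcomes drawn from the *other*
#' three memory classes so that planted conservation is exactly the
#' designated fraction.
#'
#' @param cfg a [sim_config()].
#' @param truth truth table from [simulate_expression()].
#' @return list: `map` (`maize_id`, `ref_id`), `ref_classes` (`gene_id`,
#'   `class`), `truth` (`gene_id`, `class`, `conserved`).
#' @export
simulate_homology <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 3L)
  mem <- truth[class_group(truth$class) == "memory", , drop = FALSE]
  memory_classes <- .CLASS_SETS$memory
  draw_nonconserved <- function(maize_class) {
    outcome <- sample(names(cfg$outcome_probs), 1, prob = cfg$outcome_probs)
    switch(outcome,
           no_response = sample(c("[=/=]", "[=/+]", "[=/-]"), 1,
                                prob = c(0.8, 0.1, 0.1)),
           non_memory = sample(.CLASS_SETS$non_memory, 1),
           memory = sample(setdiff(memory_classes, maize_class), 1))
  }
  map <- list(); ref_cls <- list(); conserved <- logical(nrow(mem))
  counter <- 0L
  for (i in seq_len(nrow(mem))) {
    n_hom <- 1L + rpois(1, cfg$homologs_lambda)
    ids <- sprintf("AT1G%05d", counter + seq_len(n_hom))
    counter <- counter + n_hom
    conserved[i] <- runif(1) < cfg$conservation_fraction
    cls <- vapply(seq_len(n_hom), function(j) {
      if (j == 1 && conserved[i]) mem$class[i]
      else draw_nonconserved(mem$class[i])
    }, "")
    map[[i]] <- data.frame(maize_id = mem$gene_id[i], ref_id = ids,
                           stringsAsFactors = FALSE)
    ref_cls[[i]] <- data.frame(gene_id = ids, class = cls,
                               stringsAsFactors = FALSE)
  }
  list(map = do.call(rbind, map),
       ref_classes = do.call(rbind, ref_cls),
       truth = data.frame(gene_id = mem$gene_id, class = mem$class,
                          conserved = conserved, stringsAsFactors = FALSE))
}
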