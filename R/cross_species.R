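# Cross-species memory conservation: map each maize memory gene to its
# reference-species homologs' response classes and partition the outcomes.

.VERDICTS <- c("memory_same_type", "memory_different_type",
               "homolog_non_memory", "homolog_no_response", "no_homolog")

# homolog outcome of a single reference class label
.homolog_outcome <- function(class) {
  grp <- class_group(class)
  ifelse(grp == "memory", "responds_memory",
         ifelse(grp == "non_memory", "responds_non_memory",
                "no_S1_response"))  # late + nonresponsive: no S1 response
}

.ref_class_lookup <- function(map, ref_classes) {
  lookup <- setNames(ref_classes$class, ref_classes$gene_id)
  missing_ids <- setdiff(unique(map$ref_id), names(lookup))
  if (length(missing_ids) > 0)
    stop("homolog(s) without a reference class label: ",
         paste(head(missing_ids, 10), collapse = ", "), call. = FALSE)
  lookup
}

#' Partition the homologs of a gene set by their reference response
#'
#' Counts, over the *unique* reference genes mapped from `genes`, how many
#' show no S1 response (late-response and non-responsive classes included),
#' how many respond without memory, and how many are memory genes in the
#' reference species. The three counts sum to the number of distinct mapped
#' homologs.
#'
#' @param genes character vector of (maize) gene ids whose homologs to
#'   partition.
#' @param map homolog map data.frame (`maize_id`, `ref_id`).
#' @param ref_classes reference class labels (`gene_id`, `class`).
#' @return named integer vector `no_S1_response`, `responds_non_memory`,
#'   `responds_memory`, plus attribute `total` (distinct homologs).
#' @export
partition_homologs <- function(genes, map, ref_classes) {
  sub <- map[map$maize_id %in% genes, , drop = FALSE]
  homologs <- unique(sub$ref_id)
  lookup <- .ref_class_lookup(sub, ref_classes)
  outcome <- .homolog_outcome(unname(lookup[homologs]))
  out <- c(no_S1_response = sum(outcome == "no_S1_response"),
           responds_non_memory = sum(outcome == "responds_non_memory"),
           responds_memory = sum(outcome == "responds_memory"))
  attr(out, "total") <- length(homologs)
  out
}

#' Conservation verdict per maize memory gene
#'
#' Each maize memory gene is judged by its best homolog outcome, with
#' precedence `memory_same_type` (some homolog has the *identical* class
#' symbol) > `memory_different_type` (some homolog is a memory gene of
#' another type) > `homolog_non_memory` > `homolog_no_response` >
#' `no_homolog`. Any-homolog semantics: gene families commonly contain
#' several members with different behaviour, and conservation is granted if
#' at least one member retains the same memory type.
#'
#' @param memory_labels data.frame (`gene_id`, `class`) of maize memory
#'   genes (classes must be memory classes).
#' @param map homolog map (`maize_id`, `ref_id`).
#' @param ref_classes reference class labels (`gene_id`, `class`).
#' @return data.frame `gene_id`, `class`, `n_homologs`, `verdict` (factor
#'   ordered by precedence).
#' @export
conservation_verdicts <- function(memory_labels, map, ref_classes) {
  if (!all(class_group(memory_labels$class) == "memory"))
    stop("conservation_verdicts expects memory-class genes only",
         call. = FALSE)
  if (nrow(memory_labels) == 0)
    return(data.frame(gene_id = character(0), class = character(0),
                      n_homologs = integer(0),
                      verdict = factor(character(0), levels = .VERDICTS),
                      stringsAsFactors = FALSE))
  lookup <- .ref_class_lookup(map[map$maize_id %in% memory_labels$gene_id, ,
                                  drop = FALSE], ref_classes)
  verdict_one <- function(gene, cls) {
    hom <- unique(map$ref_id[map$maize_id == gene])
    if (length(hom) == 0) return(c(0L, "no_homolog"))
    hcls <- unname(lookup[hom])
    grp <- class_group(hcls)
    v <- if (any(hcls == cls & grp == "memory")) "memory_same_type"
    else if (any(grp == "memory")) "memory_different_type"
    else if (any(grp == "non_memory")) "homolog_non_memory"
    else "homolog_no_response"
    c(length(hom), v)
  }
  res <- mapply(verdict_one, memory_labels$gene_id, memory_labels$class)
  data.frame(gene_id = memory_labels$gene_id, class = memory_labels$class,
             n_homologs = as.integer(res[1, ]),
             verdict = factor(res[2, ], levels = .VERDICTS),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Conservation summary tables
#'
#' Produces the nested count tables describing how maize memory genes map
#' onto reference-species responses: the overall homolog-level partition,
#' maize-gene-level verdict counts (overall and per maize memory class), and
#' the homolog outcome distribution per maize class tallied two ways — over
#' unique homolog genes and over (maize gene, homolog) pairs. The two
#' tallies differ when maps are one-to-many; with a bijective map they
#' coincide.
#'
#' @inheritParams conservation_verdicts
#' @return list: `homolog_partition` (from [partition_homologs()]),
#'   `verdict_counts`, `verdicts_by_class` (class x verdict matrix),
#'   `pair_outcomes_by_class` (class x outcome, multiset of pairs),
#'   `records` (the per-gene verdicts).
#' @export
conservation_tables <- function(memory_labels, map, ref_classes) {
  records <- conservation_verdicts(memory_labels, map, ref_classes)
  part <- partition_homologs(memory_labels$gene_id, map, ref_classes)
  classes <- .CLASS_SETS$memory
  verdicts_by_class <- t(vapply(classes, function(k)
    table(records$verdict[records$class == k]),
    setNames(integer(length(.VERDICTS)), .VERDICTS)))
  pairs <- map[map$maize_id %in% memory_labels$gene_id, , drop = FALSE]
  if (nrow(pairs) > 0) {
    lookup <- .ref_class_lookup(pairs, ref_classes)
    pairs$outcome <- .homolog_outcome(unname(lookup[pairs$ref_id]))
    pairs$class <- memory_labels$class[match(pairs$maize_id,
                                             memory_labels$gene_id)]
  } else {
    pairs$outcome <- character(0)
    pairs$class <- character(0)
  }
  outcomes <- c("no_S1_response", "responds_non_memory", "responds_memory")
  pair_outcomes <- t(vapply(classes, function(k)
    vapply(outcomes, function(o)
      sum(pairs$class == k & pairs$outcome == o), 0L),
    setNames(integer(3), outcomes)))
  list(homolog_partition = part,
       verdict_counts = table(records$verdict),
       verdicts_by_class = verdicts_by_class,
       pair_outcomes_by_class = pair_outcomes,
       records = records)
}
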