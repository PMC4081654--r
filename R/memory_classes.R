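# Nine-way response classification from the (S1 vs W, S3 vs S1) call pair,
# and the memory / non-memory / late-response summary arithmetic.

#' Response class symbols
#'
#' Named character vector of the nine class symbols. The first sign encodes
#' the S1-vs-W call, the second the S3-vs-S1 call: `+` up, `-` down, `=`
#' nochange. Memory classes are `[+/+]`, `[-/-]`, `[+/-]`, `[-/+]`;
#' non-memory `[+/=]`, `[-/=]`; late-response `[=/+]`, `[=/-]`;
#' non-responsive `[=/=]`.
#'
#' @format character vector, names `PP, MM, PM, MP, PE, ME, EP, EM, EE`.
#' @export
MEMORY_CLASSES <- c(PP = "[+/+]", MM = "[-/-]", PM = "[+/-]", MP = "[-/+]",
                    PE = "[+/=]", ME = "[-/=]", EP = "[=/+]", EM = "[=/-]",
                    EE = "[=/=]")

.CLASS_SETS <- list(
  memory = c("[+/+]", "[-/-]", "[+/-]", "[-/+]"),
  non_memory = c("[+/=]", "[-/=]"),
  late = c("[=/+]", "[=/-]"),
  nonresponsive = "[=/=]"
)

#' Memory/non-memory/late grouping of a class symbol
#'
#' @param class character vector of class symbols (e.g. `"[+/+]"`).
#' @return character vector: `memory`, `non_memory`, `late` or
#'   `nonresponsive`.
#' @export
class_group <- function(class) {
  grp <- rep(NA_character_, length(class))
  for (g in names(.CLASS_SETS)) grp[class %in% .CLASS_SETS[[g]]] <- g
  if (anyNA(grp))
    stop("unknown class symbol(s): ",
         paste(unique(class[is.na(grp)]), collapse = ", "), call. = FALSE)
  grp
}

#' Combine two contrast calls into a response class
#'
#' Pure function of the call pair: `(up, up)` is `[+/+]`, `(down, up)` is
#' `[-/+]`, `(nochange, nochange)` is `[=/=]`, etc.
#'
#' @param call_s1 character vector of S1-vs-W calls (`up`/`down`/`nochange`).
#' @param call_s3 matching vector of S3-vs-S1 calls.
#' @return character vector of class symbols.
#' @export
#' @examples
#' classify_gene("up", "down")  # "[+/-]"
classify_gene <- function(call_s1, call_s3) {
  stopifnot(length(call_s1) == length(call_s3))
  sym <- c(up = "+", down = "-", nochange = "=")
  if (!all(call_s1 %in% names(sym)) || !all(call_s3 %in% names(sym)))
    stop("calls must be up/down/nochange", call. = FALSE)
  paste0("[", sym[call_s1], "/", sym[call_s3], "]")
}

#' Classify all genes from the two per-contrast call tables
#'
#' @param calls_s1 data.frame from [call_responses()] for S1_vs_W.
#' @param calls_s3 data.frame from [call_responses()] for S3_vs_S1; must
#'   cover the same gene ids.
#' @return data.frame `gene_id`, `call_s1`, `call_s3`, `class`,
#'   `memory_flag` (the [class_group()] of the class).
#' @export
classify_genes <- function(calls_s1, calls_s3) {
  if (!setequal(calls_s1$gene_id, calls_s3$gene_id))
    stop("gene id mismatch between the two contrast call tables",
         call. = FALSE)
  calls_s3 <- calls_s3[match(calls_s1$gene_id, calls_s3$gene_id), ]
  cls <- classify_gene(calls_s1$call, calls_s3$call)
  data.frame(gene_id = calls_s1$gene_id, call_s1 = calls_s1$call,
             call_s3 = calls_s3$call, class = cls,
             memory_flag = class_group(cls), stringsAsFactors = FALSE)
}

#' Summarize a classification into the partition arithmetic
#'
#' Derived totals follow the partition identities: the dehydration response
#' is everything responding in S1 (`induced = [+/+]+[+/-]+[+/=]`,
#' `repressed = [-/-]+[-/+]+[-/=]`); it splits exactly into memory and
#' non-memory; late-response genes (`[=/+]`, `[=/-]`) respond only in S3 and
#' are reported separately, excluded from memory statistics. The memory
#' fraction uses the dehydration response as denominator and is `NA` (with
#' `undefined_fractions = TRUE`) when nothing responded.
#'
#' @param labels character vector of class symbols, or a data.frame with a
#'   `class` column (one label per gene).
#' @return object of class `class_summary`: list with `counts` (named over
#'   the nine classes), `induced`, `repressed`, `dehydration_response`,
#'   `memory_total`, `non_memory_total`, `late_total`, `nonresponsive`,
#'   `total_genes`, `memory_fraction`, `undefined_fractions`.
#' @export
summarize_classes <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$class
  bad <- setdiff(unique(labels), unname(MEMORY_CLASSES))
  if (length(bad) > 0)
    stop("unknown class symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  counts <- vapply(unname(MEMORY_CLASSES), function(cl) sum(labels == cl), 0L)
  cnt <- function(cls) sum(counts[cls])
  induced <- cnt(c("[+/+]", "[+/-]", "[+/=]"))
  repressed <- cnt(c("[-/-]", "[-/+]", "[-/=]"))
  response <- induced + repressed
  memory <- cnt(.CLASS_SETS$memory)
  non_memory <- cnt(.CLASS_SETS$non_memory)
  late <- cnt(.CLASS_SETS$late)
  structure(list(
    counts = counts, induced = induced, repressed = repressed,
    dehydration_response = response, memory_total = memory,
    non_memory_total = non_memory, late_total = late,
    nonresponsive = cnt("[=/=]"), total_genes = length(labels),
    memory_fraction = if (response > 0) memory / response else NA_real_,
    undefined_fractions = response == 0
  ), class = "class_summary")
}

#' @export
print.class_summary <- function(x, ...) {
  cat("Response classification of", x$total_genes, "genes\n")
  cat(sprintf("  Dehydration response %6d  (induced %d, repressed %d)\n",
              x$dehydration_response, x$induced, x$repressed))
  cat(sprintf("  Memory genes         %6d", x$memory_total))
  if (!x$undefined_fractions)
    cat(sprintf("  (%.0f%% of the response fraction)",
                100 * x$memory_fraction))
  cat("\n")
  for (cl in .CLASS_SETS$memory)
    cat(sprintf("    %s %6d\n", cl, x$counts[[cl]]))
  cat(sprintf("  Non-memory genes     %6d  ([+/=] %d, [-/=] %d)\n",
              x$non_memory_total, x$counts[["[+/=]"]], x$counts[["[-/=]"]]))
  cat(sprintf("  Late-response genes  %6d  ([=/+] %d, [=/-] %d)\n",
              x$late_total, x$counts[["[=/+]"]], x$counts[["[=/-]"]]))
  cat(sprintf("  Non-responsive       %6d\n", x$nonresponsive))
  invisible(x)
}

#' Scatter-plot coordinates of response genes
#'
#' Per gene: x = log2 of the S1 mean level, y1 = log2 of the S1/W ratio,
#' y2 = log2 of the S3/W ratio, with the class symbol as colour key. On the
#' y2 axis, revised-response genes (`[+/-]`, `[-/+]`) cluster near 0 (their
#' S3 levels return toward pre-stressed W levels) while `[+/+]`/`[-/-]`
#' genes separate further.
#'
#' @param fpkm wide FPKM matrix.
#' @param labels classification data.frame from [classify_genes()] (or a
#'   data.frame with `gene_id` and `class`).
#' @param epsilon pseudocount applied to zero FPKM before taking logs.
#' @return data.frame `gene_id`, `class`, `x`, `y1`, `y2`.
#' @export
scatter_coordinates <- function(fpkm, labels, epsilon = 1e-3) {
  means <- condition_means(fpkm)
  idx <- match(labels$gene_id, rownames(fpkm))
  if (anyNA(idx))
    stop("labels contain gene ids absent from the FPKM matrix",
         call. = FALSE)
  w <- means[idx, "W"] + epsilon
  s1 <- means[idx, "S1"] + epsilon
  s3 <- means[idx, "S3"] + epsilon
  data.frame(gene_id = labels$gene_id, class = labels$class,
             x = log2(s1), y1 = log2(s1 / w), y2 = log2(s3 / w),
             stringsAsFactors = FALSE)
}
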