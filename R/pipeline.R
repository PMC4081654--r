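# End-to-end orchestration: DE calling -> classification -> annotation ->
# functional summary -> cross-species comparison, with a run manifest.

.stage_msg <- function(...) message("[stressmem] ", sprintf(...))

#' Run the full classification pipeline
#'
#' Executes every stage for which inputs are available and writes all
#' outputs plus a run manifest under `out_dir`. Either two external
#' differential tables (`diff_s1`, `diff_s3`) or a replicate FPKM matrix
#' (processed by the stand-in DE test, [simple_de_test()]) must be given.
#' Optional stages degrade gracefully: without BLAST/GO inputs annotation
#' and the functional matrix are skipped with a logged notice; without a
#' homolog map the species comparison is skipped. The run is deterministic
#' for fixed inputs: re-running with the same inputs reproduces
#' byte-identical classification tables.
#'
#' @param out_dir output directory (created if needed).
#' @param fpkm wide FPKM matrix (optional if diff tables given).
#' @param diff_s1,diff_s3 differential tables for S1_vs_W / S3_vs_S1
#'   (data.frames as from [read_diff_table()]).
#' @param criteria [significance_criteria()].
#' @param de_method stand-in DE method (see [simple_de_test()]).
#' @param epsilon pseudocount for the stand-in test and scatter plots.
#' @param go_annotations gene-level GO annotations for the query species
#'   (`gene_id`, `go_id`, `domain`, `term`); if absent but BLAST inputs are
#'   given, they are inferred via annotation transfer.
#' @param blast_hits BLAST hit table ([read_blast_tab()]) for annotation
#'   transfer (optional).
#' @param native_descriptions native descriptions (`gene_id`,
#'   `description`) (optional).
#' @param ref_descriptions reference description table for the LCS
#'   synthesis (required with `blast_hits`).
#' @param ref_go reference GO annotations (required with `blast_hits`).
#' @param categories category definitions for [build_matrix()].
#' @param homolog_map homolog map (`maize_id`, `ref_id`) (optional).
#' @param ref_classes reference response classes (`gene_id`, `class`)
#'   (required with `homolog_map`).
#' @param seed recorded in the manifest (the pipeline itself draws no random
#'   numbers; the seed documents upstream simulation).
#' @return list: `labels`, `summary`, `calls_s1`, `calls_s3`, `scatter`,
#'   `annotation`, `matrix`, `conservation`, `manifest` (invisibly returns
#'   the same list).
#' @export
run_all <- function(out_dir, fpkm = NULL, diff_s1 = NULL, diff_s3 = NULL,
                    criteria = significance_criteria(),
                    de_method = "moderated", epsilon = 1e-3,
                    go_annotations = NULL, blast_hits = NULL,
                    native_descriptions = NULL, ref_descriptions = NULL,
                    ref_go = NULL, categories = default_categories(),
                    homolog_map = NULL, ref_classes = NULL, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  outputs <- character(0)
  clock <- function(stage, expr) {
    st <- Sys.time()
    res <- force(expr)
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), st, units = "secs"))
    res
  }
  emit <- function(name) outputs <<- c(outputs, file.path(out_dir, name))

  # stage 1: per-contrast differential statistics
  if (is.null(diff_s1) || is.null(diff_s3)) {
    if (is.null(fpkm))
      stop("run_all: supply either diff tables or an FPKM matrix (stage: de)",
           call. = FALSE)
    .stage_msg("stage de: stand-in %s test on FPKM replicates", de_method)
    diff_s1 <- clock("de_s1", simple_de_test(fpkm, "S1_vs_W",
                                             epsilon = epsilon,
                                             method = de_method))
    diff_s3 <- clock("de_s3", simple_de_test(fpkm, "S3_vs_S1",
                                             epsilon = epsilon,
                                             method = de_method))
    write_diff_table(diff_s1, file.path(out_dir, "diff_S1_vs_W.tsv"))
    write_diff_table(diff_s3, file.path(out_dir, "diff_S3_vs_S1.tsv"))
    emit("diff_S1_vs_W.tsv"); emit("diff_S3_vs_S1.tsv")
  }

  # stage 2-3: calls and classification
  .stage_msg("stage classify: calling responses and classes")
  calls_s1 <- clock("call_s1", call_responses(diff_s1, criteria))
  calls_s3 <- clock("call_s3", call_responses(diff_s3, criteria))
  labels <- clock("classify", classify_genes(calls_s1, calls_s3))
  write.table(labels, file.path(out_dir, "classification.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  emit("classification.tsv")

  # stage 4: summary
  summary <- summarize_classes(labels)
  jsonlite::write_json(
    list(counts = as.list(summary$counts),
         induced = summary$induced, repressed = summary$repressed,
         dehydration_response = summary$dehydration_response,
         memory_total = summary$memory_total,
         non_memory_total = summary$non_memory_total,
         late_total = summary$late_total,
         memory_fraction = summary$memory_fraction),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  emit("summary.json")

  scatter <- NULL
  if (!is.null(fpkm)) {
    scatter <- scatter_coordinates(fpkm, labels, epsilon = epsilon)
    write.table(scatter, file.path(out_dir, "scatter.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
    emit("scatter.tsv")
  }

  # stage 5: annotation transfer
  annotation <- NULL
  if (!is.null(blast_hits)) {
    if (is.null(ref_descriptions) || is.null(ref_go))
      stop("run_all: blast_hits given without ref_descriptions/ref_go ",
           "(stage: annotate)", call. = FALSE)
    .stage_msg("stage annotate: transferring annotation over %d queries",
               length(unique(blast_hits$query_id)))
    annotation <- clock("annotate",
                        annotate_queries(blast_hits, native_descriptions,
                                         ref_descriptions, ref_go))
    write.table(annotation, file.path(out_dir, "annotations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    emit("annotations.tsv")
    if (is.null(go_annotations)) {
      long <- attr(annotation, "go_long")
      if (!is.null(long) && nrow(long) > 0)
        go_annotations <- data.frame(gene_id = long$query_id,
                                     go_id = "", domain = long$domain,
                                     term = long$term,
                                     stringsAsFactors = FALSE)
    }
  }

  # stage 6: functional matrix
  cat_matrix <- NULL
  if (!is.null(go_annotations)) {
    .stage_msg("stage summarize: class x category matrix")
    cat_matrix <- clock("matrix",
                        build_matrix(labels, go_annotations, categories))
    write_category_matrix(cat_matrix,
                          file.path(out_dir, "category_matrix.tsv"))
    emit("category_matrix.tsv")
    intens <- heatmap_intensities(cat_matrix)
    write.table(data.frame(category = rownames(intens), intens,
                           check.names = FALSE),
                file.path(out_dir, "heatmap_intensities.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
    emit("heatmap_intensities.tsv")
  } else {
    .stage_msg("stage summarize: skipped (no GO annotations available)")
  }

  # stage 7: cross-species comparison
  conservation <- NULL
  if (!is.null(homolog_map)) {
    if (is.null(ref_classes))
      stop("run_all: homolog_map given without ref_classes ",
           "(stage: compare-species)", call. = FALSE)
    .stage_msg("stage compare-species: conservation of memory classes")
    mem_labels <- labels[labels$memory_flag == "memory",
                         c("gene_id", "class")]
    conservation <- clock("cross_species",
                          conservation_tables(mem_labels, homolog_map,
                                         ref_classes))
    write.table(conservation$records,
                file.path(out_dir, "conservation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
    emit("conservation.tsv")
    jsonlite::write_json(
      list(homolog_partition = as.list(conservation$homolog_partition),
           verdict_counts = as.list(conservation$verdict_counts)),
      file.path(out_dir, "conservation_summary.json"), auto_unbox = TRUE,
      digits = NA)
    emit("conservation_summary.json")
  } else {
    .stage_msg("stage compare-species: skipped (no homolog map supplied)")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("stressmem")),
    seed = seed,
    criteria = unclass(criteria),
    de_method = de_method,
    epsilon = epsilon,
    n_genes = if (!is.null(fpkm)) nrow(fpkm) else nrow(diff_s1),
    stage_timings_sec = timings,
    outputs = outputs,
    output_digests = as.list(tools::md5sum(outputs)),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  invisible(list(labels = labels, summary = summary, calls_s1 = calls_s1,
                 calls_s3 = calls_s3, scatter = scatter,
                 annotation = annotation, matrix = cat_matrix,
                 conservation = conservation, manifest = manifest))
}
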