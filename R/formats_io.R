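# Readers and writers for every external table the pipeline touches.
# All files are UTF-8, tab-separated, decimal point (no locale commas).

# ---- differential-expression tables (cuffdiff gene_exp.diff dialect) ------

.DIFF_REQUIRED <- c("gene_id", "value_1", "value_2", "log2(fold_change)",
                    "p_value", "q_value", "status")

.parse_signed_numeric <- function(x) {
  # cuffdiff prints "inf"/"-inf" for fold changes with a zero denominator;
  # keep them as signed infinity sentinels, never NaN (sign carries the call).
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  out[tolower(x) %in% c("inf", "+inf")] <- Inf
  out[tolower(x) == "-inf"] <- -Inf
  out
}

#' Read a cuffdiff-style differential-expression table
#'
#' Parses the tab-separated `gene_exp.diff` dialect (header row with at least
#' `gene_id`, `value_1`, `value_2`, `log2(fold_change)`, `p_value`, `q_value`,
#' `status`). `value_1` is the reference condition of the contrast (W for
#' S1_vs_W; S1 for S3_vs_S1) and `value_2` the test condition. Infinite fold
#' changes printed as `inf`/`-inf` become `Inf`/`-Inf`.
#'
#' @param path file path.
#' @param contrast `"S1_vs_W"` or `"S3_vs_S1"`; stamped on every record.
#' @return data.frame with columns `gene_id`, `contrast`, `value_a`,
#'   `value_b`, `log2_fc`, `p_value`, `q_value`, `status`.
#' @export
read_diff_table <- function(path, contrast = c("S1_vs_W", "S3_vs_S1")) {
  contrast <- match.arg(contrast)
  raw <- read.delim(path, check.names = FALSE, colClasses = "character",
                    fileEncoding = "UTF-8")
  missing_cols <- setdiff(.DIFF_REQUIRED, names(raw))
  if (length(missing_cols) > 0)
    .stop_format("diff table %s: missing required column(s): %s",
                 path, paste(missing_cols, collapse = ", "))
  rec <- data.frame(
    gene_id  = raw[["gene_id"]],
    contrast = rep(contrast, nrow(raw)),
    value_a  = .parse_signed_numeric(raw[["value_1"]]),
    value_b  = .parse_signed_numeric(raw[["value_2"]]),
    log2_fc  = .parse_signed_numeric(raw[["log2(fold_change)"]]),
    p_value  = .parse_signed_numeric(raw[["p_value"]]),
    q_value  = .parse_signed_numeric(raw[["q_value"]]),
    status   = toupper(trimws(raw[["status"]])),
    stringsAsFactors = FALSE
  )
  bad <- which(rec$value_a < 0 | rec$value_b < 0)
  if (length(bad) > 0)
    .stop_format("diff table %s: negative FPKM at data row %d", path, bad[1])
  bad <- which(rec$p_value < 0 | rec$p_value > 1 |
                 rec$q_value < 0 | rec$q_value > 1)
  if (length(bad) > 0)
    .stop_format("diff table %s: p/q outside [0,1] at data row %d",
                 path, bad[1])
  if (anyDuplicated(rec$gene_id))
    .stop_format("diff table %s: duplicated gene_id '%s'",
                 path, rec$gene_id[anyDuplicated(rec$gene_id)])
  unknown <- setdiff(unique(rec$status), .CUFFDIFF_STATUS)
  if (length(unknown) > 0)
    .stop_format("diff table %s: unknown status value(s): %s",
                 path, paste(unknown, collapse = ", "))
  rec
}

#' Write a differential-expression table
#'
#' Inverse of [read_diff_table()]; infinite fold changes are serialized as
#' `inf`/`-inf` so the round trip is exact.
#'
#' @param records data.frame as returned by [read_diff_table()] or
#'   [simple_de_test()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diff_table <- function(records, path) {
  fmt_num <- function(x) {
    out <- vapply(x, function(v) format(v, digits = 17, scientific = NA), "")
    out[is.infinite(x) & x > 0] <- "inf"
    out[is.infinite(x) & x < 0] <- "-inf"
    out
  }
  out <- data.frame(
    gene_id = records$gene_id,
    value_1 = fmt_num(records$value_a),
    value_2 = fmt_num(records$value_b),
    `log2(fold_change)` = fmt_num(records$log2_fc),
    p_value = fmt_num(records$p_value),
    q_value = fmt_num(records$q_value),
    status = records$status,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

# ---- FPKM tables ----------------------------------------------------------

#' Read an FPKM table (wide or long layout)
#'
#' Wide layout: `gene_id` then one column per sample named `<condition>_<rep>`
#' (`W_1`, `W_2`, `S1_1`, ...). Long layout (autodetected by header):
#' columns `gene_id`, `condition`, `replicate`, `fpkm`. The internal model is
#' always the wide matrix: genes in rows, samples in columns.
#'
#' @param path file path.
#' @return numeric matrix, rownames = gene ids, colnames = `cond_rep` samples.
#' @export
read_fpkm_table <- function(path) {
  raw <- read.delim(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (all(c("gene_id", "condition", "replicate", "fpkm") %in% names(raw))) {
    raw$sample <- paste(raw$condition, raw$replicate, sep = "_")
    genes <- unique(raw$gene_id)
    samples <- unique(raw$sample)
    mat <- matrix(NA_real_, length(genes), length(samples),
                  dimnames = list(genes, samples))
    mat[cbind(match(raw$gene_id, genes), match(raw$sample, samples))] <-
      as.numeric(raw$fpkm)
    if (anyNA(mat))
      .stop_format("FPKM table %s: long layout is not rectangular", path)
  } else {
    if (names(raw)[1] != "gene_id")
      .stop_format("FPKM table %s: first column must be 'gene_id'", path)
    mat <- as.matrix(raw[, -1, drop = FALSE])
    mode(mat) <- "numeric"
    rownames(mat) <- raw$gene_id
  }
  validate_fpkm(mat, what = path)
  mat
}

#' @rdname read_fpkm_table
#' @param fpkm wide FPKM matrix.
#' @export
write_fpkm_table <- function(fpkm, path) {
  validate_fpkm(fpkm)
  out <- data.frame(gene_id = rownames(fpkm), fpkm,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate an FPKM matrix
#'
#' Checks rectangularity, non-negativity, sample naming (`cond_rep`) and that
#' each of W, S1, S3 present has at least one replicate.
#'
#' @param fpkm matrix to validate.
#' @param what label used in error messages.
#' @return `fpkm`, invisibly.
#' @export
validate_fpkm <- function(fpkm, what = "FPKM matrix") {
  if (!is.matrix(fpkm) || !is.numeric(fpkm))
    .stop_format("%s: expected a numeric matrix", what)
  if (anyNA(fpkm)) .stop_format("%s: missing values not allowed", what)
  if (any(fpkm < 0)) {
    row <- which(rowSums(fpkm < 0) > 0)[1]
    .stop_format("%s: negative FPKM at row %d (%s)", what, row,
                 rownames(fpkm)[row])
  }
  cond <- sample_conditions(colnames(fpkm))
  if (anyNA(cond))
    .stop_format("%s: sample names must look like W_1, S1_2, ... (got %s)",
                 what, paste(colnames(fpkm)[is.na(cond)], collapse = ", "))
  invisible(fpkm)
}

#' Parse condition labels out of sample column names
#'
#' @param sample_names character vector like `c("W_1", "S1_2")`.
#' @return character vector of conditions (`NA` where unparseable).
#' @export
sample_conditions <- function(sample_names) {
  cond <- sub("_[^_]+$", "", sample_names)
  cond[!cond %in% .CONDITIONS] <- NA_character_
  cond
}

#' Per-condition mean FPKM
#'
#' @param fpkm wide FPKM matrix.
#' @return matrix genes x conditions of replicate means.
#' @export
condition_means <- function(fpkm) {
  cond <- sample_conditions(colnames(fpkm))
  present <- intersect(.CONDITIONS, cond)
  out <- vapply(present, function(cd)
    rowMeans(fpkm[, cond == cd, drop = FALSE]), numeric(nrow(fpkm)))
  out
}

# ---- BLAST tabular (outfmt 6) ---------------------------------------------

.BLAST_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read BLAST tabular hits (outfmt 6)
#'
#' 12 tab-separated columns, no header: qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore.
#'
#' @param path file path.
#' @return data.frame with the 12 outfmt-6 columns plus aliases `query_id`,
#'   `subject_id`, `pid`, `aln_length`, `e_value`.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    hits <- as.data.frame(setNames(rep(list(character(0)), 12), .BLAST_COLS),
                          stringsAsFactors = FALSE)
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 12))
      .stop_format("BLAST table %s: expected 12 columns, got %d at line %d",
                   path, nf[which(nf != 12)[1]], which(nf != 12)[1])
    hits <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
    names(hits) <- .BLAST_COLS
  }
  for (col in c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
                "sstart", "send", "evalue", "bitscore"))
    hits[[col]] <- as.numeric(hits[[col]])
  hits$query_id <- hits$qseqid
  hits$subject_id <- hits$sseqid
  hits$pid <- hits$pident
  hits$aln_length <- hits$length
  hits$e_value <- hits$evalue
  if (any(hits$e_value < 0))
    .stop_format("BLAST table %s: negative e-value", path)
  if (any(hits$pid < 0 | hits$pid > 100))
    .stop_format("BLAST table %s: percent identity outside [0,100]", path)
  if (any(hits$aln_length < 1))
    .stop_format("BLAST table %s: alignment length < 1", path)
  hits
}

#' @rdname read_blast_tab
#' @param hits data.frame of hits (at least the 12 outfmt-6 columns).
#' @export
write_blast_tab <- function(hits, path) {
  out <- hits[, .BLAST_COLS, drop = FALSE]
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) format(x, digits = 17,
                                                  trim = TRUE,
                                                  scientific = NA))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# ---- GO annotations -------------------------------------------------------

.GO_DOMAINS <- c("cellular_component", "molecular_function",
                 "biological_process")

.normalize_go_domain <- function(x) {
  key <- gsub("[ -]+", "_", tolower(trimws(x)))
  alias <- c(cc = "cellular_component", c = "cellular_component",
             mf = "molecular_function", f = "molecular_function",
             bp = "biological_process", p = "biological_process")
  hit <- !is.na(match(key, names(alias)))
  key[hit] <- alias[key[hit]]
  key
}

#' Read a GO annotation TSV
#'
#' Four named columns: `gene_id`, `go_id`, `domain`, `term`. Domain strings
#' are normalized (case/space variants and CC/MF/BP abbreviations map onto
#' `cellular_component`, `molecular_function`, `biological_process`).
#' Duplicate `(gene_id, go_id)` rows are collapsed with a warning.
#'
#' @param path file path.
#' @return data.frame with the four columns, domains normalized.
#' @export
read_go_tsv <- function(path) {
  raw <- read.delim(path, check.names = FALSE, colClasses = "character",
                    fileEncoding = "UTF-8")
  need <- c("gene_id", "go_id", "domain", "term")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0)
    .stop_format("GO table %s: missing required column(s): %s",
                 path, paste(missing_cols, collapse = ", "))
  raw <- raw[, need, drop = FALSE]
  raw$domain <- .normalize_go_domain(raw$domain)
  unknown <- setdiff(unique(raw$domain), .GO_DOMAINS)
  if (length(unknown) > 0 && nrow(raw) > 0)
    .stop_format("GO table %s: unknown GO domain(s): %s",
                 path, paste(unknown, collapse = ", "))
  dup <- duplicated(raw[, c("gene_id", "go_id")])
  if (any(dup)) {
    warning(sprintf("GO table %s: collapsed %d duplicated (gene_id, go_id) row(s)",
                    path, sum(dup)), call. = FALSE)
    raw <- raw[!dup, , drop = FALSE]
    rownames(raw) <- NULL
  }
  raw
}

#' @rdname read_go_tsv
#' @param annotations data.frame with `gene_id`, `go_id`, `domain`, `term`.
#' @export
write_go_tsv <- function(annotations, path) {
  write.table(annotations[, c("gene_id", "go_id", "domain", "term")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

# ---- small two-column helper tables ---------------------------------------

#' Read/write two-column helper tables
#'
#' `read_class_tsv` reads reference response-class labels (`gene_id`,
#' `class`); `read_homolog_map` reads a homolog map (`maize_id`, `ref_id`);
#' `read_descriptions` reads functional descriptions (`gene_id`,
#' `description`). Each has a `write_*` counterpart.
#'
#' @param path file path.
#' @return data.frame with the two named columns.
#' @export
read_class_tsv <- function(path) {
  out <- read.delim(path, colClasses = "character", fileEncoding = "UTF-8")
  if (!all(c("gene_id", "class") %in% names(out)))
    .stop_format("class table %s: need columns gene_id, class", path)
  bad <- setdiff(unique(out$class), unname(MEMORY_CLASSES))
  if (length(bad) > 0)
    .stop_format("class table %s: unknown class symbol(s): %s",
                 path, paste(bad, collapse = ", "))
  out[, c("gene_id", "class")]
}

#' @rdname read_class_tsv
#' @param labels data.frame (`gene_id`, `class`).
#' @export
write_class_tsv <- function(labels, path) {
  write.table(labels[, c("gene_id", "class")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_class_tsv
#' @export
read_homolog_map <- function(path) {
  out <- read.delim(path, colClasses = "character", fileEncoding = "UTF-8")
  if (!all(c("maize_id", "ref_id") %in% names(out)))
    .stop_format("homolog map %s: need columns maize_id, ref_id", path)
  out[, c("maize_id", "ref_id")]
}

#' @rdname read_class_tsv
#' @param map data.frame (`maize_id`, `ref_id`).
#' @export
write_homolog_map <- function(map, path) {
  write.table(map[, c("maize_id", "ref_id")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_class_tsv
#' @export
read_descriptions <- function(path) {
  out <- read.delim(path, colClasses = "character", fileEncoding = "UTF-8")
  if (!all(c("gene_id", "description") %in% names(out)))
    .stop_format("description table %s: need columns gene_id, description",
                 path)
  out[, c("gene_id", "description")]
}

#' @rdname read_class_tsv
#' @param descriptions data.frame (`gene_id`, `description`).
#' @export
write_descriptions <- function(descriptions, path) {
  write.table(descriptions[, c("gene_id", "description")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
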