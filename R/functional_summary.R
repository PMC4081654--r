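# Class x functional-category count/percentage matrices and the capped
# heatmap intensity scaling used to display them.

.SIX_CLASSES <- c("[+/+]", "[-/-]", "[+/-]", "[-/+]", "[+/=]", "[-/=]")

#' Percentage rule for category matrices
#'
#' `round_half_up(100 * count / total)`; `NA` when the denominator is 0
#' (rendered `-` on output).
#'
#' @param count gene count in the cell.
#' @param total class (or parent-category) denominator.
#' @return integer percentage, `NA` if `total` is 0.
#' @export
#' @examples
#' category_pct(42, 162)  # 26
category_pct <- function(count, total) {
  ifelse(total > 0, round_half_up(100 * count / total), NA_real_)
}

#' Default functional category definitions
#'
#' An editable table of category predicates: a gene belongs to a category
#' when any of its GO ids is listed in `go_ids` or any of its GO terms
#' contains one of the `term_patterns` substrings (case-insensitive).
#' Multi-pattern predicates are unions. Transcription-factor sub-families
#' carry `parent = "Transcription factors"`: their percentages use the
#' class's TF count as denominator. The shipped set approximates the
#' functional rows commonly summarised for dehydration-response classes;
#' users studying other categories should supply their own table.
#'
#' @return data.frame `name`, `parent`, `go_ids` (`";"`-separated, may be
#'   empty), `term_patterns` (`";"`-separated).
#' @export
default_categories <- function() {
  cat2 <- function(name, patterns, parent = NA_character_, go = "")
    data.frame(name = name, parent = parent, go_ids = go,
               term_patterns = patterns, stringsAsFactors = FALSE)
  tf <- "Transcription factors"
  rbind(
    cat2("Membrane-associated", "membrane"),
    cat2("Chloroplast", "chloroplast"),
    cat2("Thylakoid membrane", "thylakoid"),
    cat2("RESP. Aba/Salt/Cold/Heat",
         "abscisic acid;response to salt;response to cold;response to heat"),
    cat2("Response to light", "response to light"),
    cat2("Response to JA", "jasmonic acid"),
    cat2("Response to SA", "salicylic acid"),
    cat2("Response to Auxin", "auxin"),
    cat2("Response to ethylene", "ethylene"),
    cat2("Response to GA", "gibberellin"),
    cat2("Lea", "late embryogenesis"),
    cat2("Ribosomal and protein synthesis", "ribosom;translation"),
    cat2("Protein degradation", "proteolysis;proteasome;ubiquitin"),
    cat2(tf, "transcription factor;dna-binding transcription"),
    cat2("AP2/ERF", "ap2;ethylene-responsive element", tf),
    cat2("bHLH", "bhlh;basic helix-loop-helix", tf),
    cat2("bZIP", "bzip", tf),
    cat2("HD-like", "homeobox;homeodomain", tf),
    cat2("MYB", "myb", tf),
    cat2("ZF", "zinc finger", tf),
    cat2("NAC", "nac domain", tf),
    cat2("GRAS", "gras", tf),
    cat2("HSF", "heat shock factor;heat stress transcription", tf),
    cat2("CCAAT", "ccaat", tf),
    cat2("WRKY", "wrky", tf)
  )
}

.split_semi <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)[[1]]
  trimws(out[nzchar(trimws(out))])
}

# gene ids matching one category predicate
.category_genes <- function(category_row, annotations) {
  ids <- .split_semi(category_row$go_ids)
  pats <- tolower(.split_semi(category_row$term_patterns))
  hit <- rep(FALSE, nrow(annotations))
  if (length(ids) > 0) hit <- hit | annotations$go_id %in% ids
  if (length(pats) > 0) {
    term <- tolower(annotations$term)
    for (p in pats) hit <- hit | grepl(p, term, fixed = TRUE)
  }
  unique(annotations$gene_id[hit])
}

#' Build the class x category count/percentage matrix
#'
#' Cell (c, k) counts the genes of class k matching category c's predicate;
#' genes matching several categories are counted in each (columns need not
#' sum to the class totals). Percentages follow [category_pct()] with the
#' class total as denominator, except sub-family rows which use their parent
#' category's count within the class.
#'
#' @param labels classification data.frame (`gene_id`, `class`).
#' @param annotations gene-level GO annotations (`gene_id`, `go_id`,
#'   `domain`, `term`).
#' @param categories category definition table (see [default_categories()]).
#' @param classes class columns to report; default the six response classes.
#' @return object of class `category_matrix`: list with `counts`, `pct`
#'   (matrices categories x classes), `class_totals`, `categories`.
#' @export
build_matrix <- function(labels, annotations,
                         categories = default_categories(),
                         classes = .SIX_CLASSES) {
  class_totals <- vapply(classes, function(k) sum(labels$class == k), 0L)
  member <- lapply(seq_len(nrow(categories)), function(i)
    .category_genes(categories[i, ], annotations))
  names(member) <- categories$name
  counts <- vapply(classes, function(k) {
    genes_k <- labels$gene_id[labels$class == k]
    vapply(member, function(g) sum(genes_k %in% g), 0L)
  }, integer(nrow(categories)))
  counts <- matrix(counts, nrow = nrow(categories),
                   dimnames = list(categories$name, classes))
  denom <- matrix(rep(class_totals, each = nrow(categories)),
                  nrow = nrow(categories),
                  dimnames = dimnames(counts))
  sub <- !is.na(categories$parent)
  if (any(sub)) {
    parent_idx <- match(categories$parent[sub], categories$name)
    if (anyNA(parent_idx))
      stop("sub-family with unknown parent category", call. = FALSE)
    denom[sub, ] <- counts[parent_idx, , drop = FALSE]
  }
  pct <- category_pct(counts, denom)
  dimnames(pct) <- dimnames(counts)
  structure(list(counts = counts, pct = pct, class_totals = class_totals,
                 categories = categories),
            class = "category_matrix")
}

#' Heatmap intensities from percentage values
#'
#' Linear ramp from 0 at 0% to 1 at `cap` percent, saturating above the cap
#' (black at 0%, brightest at >= 60% with the default cap).
#'
#' @param pct numeric matrix/vector of percentages (a `category_matrix` is
#'   also accepted; its `pct` slot is used). `NA` cells stay `NA`.
#' @param cap saturation percentage (> 0).
#' @return same shape as `pct`, values in \[0, 1\].
#' @export
heatmap_intensities <- function(pct, cap = 60) {
  if (inherits(pct, "category_matrix")) pct <- pct$pct
  if (cap <= 0) stop("cap must be > 0", call. = FALSE)
  if (any(pct < 0, na.rm = TRUE))
    stop("percentages must be >= 0", call. = FALSE)
  pmin(pct, cap) / cap
}

#' Interleaved two-species comparison matrix
#'
#' Pairs the two species' percentage matrices column-by-column
#' (`ZM.[+/+]`, `AT.[+/+]`, ...) and computes the capped heatmap
#' intensities for both on a common scale.
#'
#' @param matrix_zm,matrix_at `category_matrix` objects (or bare pct
#'   matrices) with identical category rows and class columns.
#' @param cap saturation percentage.
#' @param species labels for the two inputs.
#' @return list with `pct` and `intensity` matrices, columns interleaved.
#' @export
pairwise_species_matrix <- function(matrix_zm, matrix_at, cap = 60,
                                    species = c("ZM", "AT")) {
  pz <- if (inherits(matrix_zm, "category_matrix")) matrix_zm$pct else matrix_zm
  pa <- if (inherits(matrix_at, "category_matrix")) matrix_at$pct else matrix_at
  missing_rows <- c(setdiff(rownames(pz), rownames(pa)),
                    setdiff(rownames(pa), rownames(pz)))
  if (length(missing_rows) > 0 || !identical(colnames(pz), colnames(pa)))
    stop("species matrices differ; missing categories: ",
         paste(unique(missing_rows), collapse = ", "), call. = FALSE)
  pa <- pa[rownames(pz), , drop = FALSE]
  k <- ncol(pz)
  out <- matrix(NA_real_, nrow(pz), 2 * k)
  out[, seq(1, 2 * k, 2)] <- pz
  out[, seq(2, 2 * k, 2)] <- pa
  cn <- character(2 * k)
  cn[seq(1, 2 * k, 2)] <- paste(species[1], colnames(pz), sep = ".")
  cn[seq(2, 2 * k, 2)] <- paste(species[2], colnames(pa), sep = ".")
  dimnames(out) <- list(rownames(pz), cn)
  list(pct = out, intensity = heatmap_intensities(out, cap))
}

#' Write a category matrix as a readable TSV
#'
#' Cells render as `count (pct%)`, with `-` for zero counts in a class and
#' for undefined percentages; the first data row carries the class totals.
#'
#' @param matrix a `category_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_category_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "category_matrix"))
  render <- function(count, pct) {
    ifelse(count == 0, "-",
           ifelse(is.na(pct), sprintf("%d (-)", count),
                  sprintf("%d (%d%%)", count, as.integer(pct))))
  }
  cells <- matrix(render(matrix$counts, matrix$pct),
                  nrow = nrow(matrix$counts), dimnames = dimnames(matrix$counts))
  out <- rbind(`Class total` = as.character(matrix$class_totals), cells)
  df <- data.frame(category = rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
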