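# Homology-based annotation transfer: per query protein, keep the reference
# hits whose e-value is within a 1e10 multiplicative window of the best hit,
# synthesize a functional description from longest common substrings of the
# reference descriptions, and aggregate the top-10 GO terms per domain.

#' Sort homology hits for windowing
#'
#' Stable lexicographic order: ascending e-value, then descending alignment
#' length, then descending percent identity; remaining ties broken by
#' ascending subject id.
#'
#' @param hits data.frame of hits for one query (see [read_blast_tab()]).
#' @return the hits reordered.
#' @export
sort_hits <- function(hits) {
  hits[order(hits$e_value, -hits$aln_length, -hits$pid, hits$subject_id), ,
       drop = FALSE]
}

#' Best-e-value window over sorted hits
#'
#' Retains every hit whose e-value is at most `window_factor` times the best
#' (smallest) e-value, bound inclusive — a best hit at 1e-63 keeps everything
#' up to and including 1e-53. When the best e-value is exactly 0 the
#' multiplicative rule degenerates; the window then keeps hits with e = 0
#' plus any hit at or below `zero_guard` (an absolute cutoff preserving the
#' closest-homology intent without admitting everything).
#'
#' @param sorted_hits hits for one query, ordered by [sort_hits()].
#' @param window_factor multiplicative width of the window.
#' @param zero_guard absolute e-value cutoff used when the best e-value is 0.
#' @return list of class `hit_window`: `query_id`, `hits` (the members,
#'   sorted), `e_cutoff`.
#' @export
evalue_window <- function(sorted_hits, window_factor = 1e10,
                          zero_guard = 1e-170) {
  if (nrow(sorted_hits) == 0)
    return(structure(list(query_id = NA_character_,
                          hits = sorted_hits, e_cutoff = NA_real_),
                     class = "hit_window"))
  best_e <- sorted_hits$e_value[1]
  if (best_e == 0) {
    cutoff <- zero_guard
    keep <- sorted_hits$e_value == 0 | sorted_hits$e_value <= zero_guard
  } else {
    cutoff <- best_e * window_factor
    keep <- sorted_hits$e_value <= cutoff
  }
  structure(list(query_id = sorted_hits$query_id[1],
                 hits = sorted_hits[keep, , drop = FALSE],
                 e_cutoff = cutoff),
            class = "hit_window")
}

# ---- longest common substrings --------------------------------------------

# Longest substring (>= min_len) common to all strings; candidates are
# substrings of the first string, scanned longest-first, ties by first
# occurrence then lexically. Returns NULL when none exists.
.longest_common_substring <- function(strings, min_len) {
  s0 <- strings[1]
  n0 <- nchar(s0)
  if (n0 < min_len) return(NULL)
  others <- strings[-1]
  for (len in seq(n0, min_len)) {
    starts <- seq_len(n0 - len + 1)
    cand <- substring(s0, starts, starts + len - 1)
    keep <- !duplicated(cand)      # first occurrence wins
    cand <- cand[keep]
    ok <- vapply(cand, function(cs)
      all(vapply(others, function(s) grepl(cs, s, fixed = TRUE), TRUE)),
      TRUE, USE.NAMES = FALSE)
    if (any(ok)) {
      hits <- cand[ok]
      # among equally long first-occurrence candidates, the earliest one;
      # substring() preserved position order, so take the first, with a
      # lexical tie-break only among identical positions (impossible here)
      return(hits[1])
    }
  }
  NULL
}

# Trim a substring to word boundaries using its first occurrence in `ref`:
# a leading or trailing token cut mid-word is dropped, then whitespace and
# punctuation at the ends are stripped.
.trim_word_boundary <- function(s, ref) {
  is_word <- function(ch) nzchar(ch) && grepl("[[:alnum:]]", ch)
  m <- regexpr(s, ref, fixed = TRUE)
  if (m[1] > 0) {
    before <- if (m[1] > 1) substr(ref, m[1] - 1, m[1] - 1) else ""
    if (is_word(before) && is_word(substr(s, 1, 1))) {
      sp <- regexpr(" ", s, fixed = TRUE)[1]
      if (sp < 0) return("")
      s <- substr(s, sp + 1, nchar(s))
    }
    end_pos <- m[1] + attr(m, "match.length")
    after <- if (end_pos <= nchar(ref)) substr(ref, end_pos, end_pos) else ""
    if (is_word(after) && is_word(substr(s, nchar(s), nchar(s)))) {
      sps <- gregexpr(" ", s, fixed = TRUE)[[1]]
      if (sps[1] < 0) return("")
      s <- substr(s, 1, max(sps) - 1)
    }
  }
  gsub("^[[:space:][:punct:]]+|[[:space:][:punct:]]+$", "", s)
}

#' Top-k longest common substrings of a set of descriptions
#'
#' Returns up to `k` substrings common to *all* descriptions, extracted
#' greedily longest-first; after each extraction the matched occurrence is
#' masked in every description, so the results are mutually non-overlapping
#' within each description. Strings are case-normalized (lower case) and
#' whitespace-collapsed first; results are trimmed to word boundaries and
#' must remain at least `min_len` characters.
#'
#' @param descriptions character vector (>= 1) of functional descriptions.
#' @param k maximum number of substrings.
#' @param min_len minimum substring length (characters).
#' @param word_boundary trim results to word boundaries (set `FALSE` for raw
#'   substrings).
#' @return character vector of length <= k (possibly empty).
#' @export
#' @examples
#' common_substrings(c("ABC transporter 1", "ABC transporter 2"))
common_substrings <- function(descriptions, k = 3, min_len = 4,
                              word_boundary = TRUE) {
  stopifnot(length(descriptions) >= 1, k >= 1, min_len >= 1)
  norm <- tolower(gsub("\\s+", " ", trimws(descriptions)))
  work <- norm
  out <- character(0)
  for (i in seq_len(k)) {
    hit <- .longest_common_substring(work, min_len)
    if (is.null(hit)) break
    out <- c(out, hit)
    # mask the first occurrence with a per-string sentinel so later rounds
    # cannot bridge across an extracted region or match inside it
    work <- vapply(seq_along(work), function(j)
      sub(hit, sprintf("\u0001%d\u0001", j), work[j], fixed = TRUE), "")
  }
  if (word_boundary && length(out) > 0) {
    out <- vapply(out, .trim_word_boundary, "", ref = norm[1],
                  USE.NAMES = FALSE)
    out <- unique(out[nchar(out) >= min_len])
  }
  out
}

# ---- GO aggregation -------------------------------------------------------

#' Strip protein-isoform suffixes to gene ids
#'
#' `AT1G01010.1` -> `AT1G01010`; reference GO annotation is gene-level.
#'
#' @param ids character vector of protein or gene ids.
#' @return character vector of gene ids.
#' @export
strip_isoform <- function(ids) sub("\\.[0-9]+$", "", ids)

#' Top-10 GO terms per domain for a hit window
#'
#' Window subject proteins are mapped to genes ([strip_isoform()]); term
#' occurrences are counted over unique (subject gene, term) pairs so isoform
#' duplicates do not inflate counts; per domain, the top `top_n` terms by
#' descending count with lexical tie-break are returned.
#'
#' @param window a `hit_window` from [evalue_window()].
#' @param annotations GO annotation data.frame (see [read_go_tsv()]).
#' @param top_n terms retained per domain.
#' @return named list (`cellular_component`, `molecular_function`,
#'   `biological_process`) of data.frames `term`, `count`.
#' @export
aggregate_go <- function(window, annotations, top_n = 10) {
  genes <- unique(strip_isoform(window$hits$subject_id))
  ann <- annotations[annotations$gene_id %in% genes, , drop = FALSE]
  ann <- ann[!duplicated(ann[, c("gene_id", "domain", "term")]), ,
             drop = FALSE]
  out <- lapply(.GO_DOMAINS, function(dom) {
    sub <- ann[ann$domain == dom, , drop = FALSE]
    if (nrow(sub) == 0)
      return(data.frame(term = character(0), count = integer(0),
                        stringsAsFactors = FALSE))
    tab <- table(sub$term)
    df <- data.frame(term = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$count, df$term), , drop = FALSE]
    rownames(df) <- NULL
    head(df, top_n)
  })
  names(out) <- .GO_DOMAINS
  out
}

# native descriptions that count as absent
.is_absent_description <- function(x) {
  x <- tolower(trimws(ifelse(is.na(x), "", x)))
  x == "" | grepl("^(hypothetical|putative)( protein)?$", x) |
    x %in% c("hypothetical protein", "putative protein")
}

#' Infer the annotation of one query protein
#'
#' The native description is kept when informative; when absent (empty,
#' "hypothetical protein" or "putative protein") a description is
#' synthesized as the top-3 longest common substrings of the window
#' subjects' reference descriptions, joined by `"; "`. GO terms are *always*
#' aggregated from the window via [aggregate_go()], regardless of the
#' description source.
#'
#' @param query_id query protein/gene id.
#' @param native_description native description (may be `NA` or empty).
#' @param window `hit_window` for the query.
#' @param annotations reference GO annotations.
#' @param descriptions reference description table (`gene_id`,
#'   `description`), gene-level ids.
#' @return list of class `inferred_annotation`: `query_id`, `source`
#'   (`"native"`/`"inferred"`), `description`, `go_terms` (per-domain lists),
#'   `flagged` (`TRUE` when no description and no GO terms could be found).
#' @export
infer_annotation <- function(query_id, native_description, window,
                             annotations, descriptions) {
  go_terms <- aggregate_go(window, annotations)
  native_ok <- !.is_absent_description(native_description)
  if (native_ok) {
    desc <- native_description
    source <- "native"
  } else {
    source <- "inferred"
    genes <- unique(strip_isoform(window$hits$subject_id))
    refdesc <- descriptions$description[descriptions$gene_id %in% genes]
    refdesc <- refdesc[!.is_absent_description(refdesc)]
    desc <- if (length(refdesc) > 0)
      paste(common_substrings(refdesc, k = 3), collapse = "; ")
    else ""
  }
  flagged <- !nzchar(desc) && all(vapply(go_terms, nrow, 0L) == 0)
  structure(list(query_id = query_id, source = source, description = desc,
                 go_terms = go_terms, flagged = flagged),
            class = "inferred_annotation")
}

#' Annotate a set of query proteins from BLAST hits
#'
#' Driver over [sort_hits()], [evalue_window()] and [infer_annotation()].
#' Queries without hits are returned with empty annotation and flagged.
#'
#' @param hits BLAST hit table ([read_blast_tab()]), possibly many queries.
#' @param native data.frame (`gene_id`, `description`) of native
#'   descriptions for the queries (optional; missing = absent).
#' @param descriptions reference description table (`gene_id`,
#'   `description`).
#' @param annotations reference GO annotations ([read_go_tsv()]).
#' @param queries character vector of query ids to annotate; defaults to the
#'   queries present in `hits`.
#' @return data.frame `query_id`, `source`, `description`, `cc_terms`,
#'   `mf_terms`, `bp_terms` (terms `";"`-joined as `term (count)`), plus a
#'   per-domain long attribute `go_long` (query_id, domain, term, count).
#' @export
annotate_queries <- function(hits, native = NULL, descriptions, annotations,
                             queries = unique(hits$query_id)) {
  native_lookup <- if (is.null(native)) character(0) else
    setNames(native$description, native$gene_id)
  join_terms <- function(df) {
    if (nrow(df) == 0) return("")
    paste(sprintf("%s (%d)", df$term, df$count), collapse = "; ")
  }
  rows <- lapply(queries, function(q) {
    qh <- hits[hits$query_id == q, , drop = FALSE]
    window <- evalue_window(sort_hits(qh))
    ann <- infer_annotation(q, native_lookup[q][[1]] %||% NA_character_,
                            window, annotations, descriptions)
    long <- do.call(rbind, lapply(.GO_DOMAINS, function(dom) {
      df <- ann$go_terms[[dom]]
      if (nrow(df) == 0) return(NULL)
      data.frame(query_id = q, domain = dom, term = df$term,
                 count = df$count, stringsAsFactors = FALSE)
    }))
    list(row = data.frame(
      query_id = q, source = ann$source, description = ann$description,
      cc_terms = join_terms(ann$go_terms$cellular_component),
      mf_terms = join_terms(ann$go_terms$molecular_function),
      bp_terms = join_terms(ann$go_terms$biological_process),
      flagged = ann$flagged, stringsAsFactors = FALSE), long = long)
  })
  out <- do.call(rbind, lapply(rows, `[[`, "row"))
  attr(out, "go_long") <- do.call(rbind, lapply(rows, `[[`, "long"))
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a
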