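# Tri-state response calling from per-contrast differential statistics.
#
# A gene is significantly differentially expressed in a contrast when all
# three criteria hold: q <= q_max; |log2 fold change| >= min_abs_log2fc; and
# the FPKM of at least one of the two contrasted samples is larger (strictly)
# than the floor percentile of that sample's full FPKM distribution.

#' Significance criteria for response calling
#'
#' The defaults are the study thresholds: q <= 0.05, |log2FC| >= 1, and an
#' expression floor at the 25th percentile of each sample's FPKM distribution
#' (at least one of the two contrasted samples must exceed it, strictly).
#' Both q and fold-change bounds are inclusive, so a gene exactly at both
#' boundaries is significant.
#'
#' @param q_max maximum FDR-adjusted p-value (inclusive).
#' @param min_abs_log2fc minimum absolute log2 fold change (inclusive);
#'   infinite fold changes always satisfy it.
#' @param floor_percentile percentile (0-100) of the per-sample FPKM
#'   distribution used as the expression floor.
#' @return object of class `significance_criteria`.
#' @export
significance_criteria <- function(q_max = 0.05, min_abs_log2fc = 1,
                                  floor_percentile = 25) {
  stopifnot(q_max > 0, q_max <= 1, min_abs_log2fc >= 0,
            floor_percentile >= 0, floor_percentile <= 100)
  structure(list(q_max = q_max, min_abs_log2fc = min_abs_log2fc,
                 floor_percentile = floor_percentile),
            class = "significance_criteria")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: q_i = min over p_(j) >= p_(i) of m * p_(j) / j,
#' clipped to 1, returned in input order (delegates to
#' [stats::p.adjust()] with `method = "BH"` after validation).
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order as the input.
#' @export
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03))
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(!is.finite(p_values)) ||
      any(p_values < 0 | p_values > 1))
    stop("p-values must be finite and within [0, 1]", call. = FALSE)
  p.adjust(p_values, method = "BH")
}

#' Expression floor of a per-sample FPKM distribution
#'
#' Percentile with the linear-interpolation definition
#' ([stats::quantile()] type 7), so `expression_floor(0:4, 25)` is 1.
#'
#' @param fpkm_sample non-empty, non-negative numeric vector (one sample's
#'   FPKM over all genes).
#' @param percentile percentile in \[0, 100\].
#' @return the floor threshold (scalar).
#' @export
expression_floor <- function(fpkm_sample, percentile = 25) {
  if (length(fpkm_sample) == 0)
    stop("expression_floor: empty FPKM vector", call. = FALSE)
  stopifnot(percentile >= 0, percentile <= 100, all(fpkm_sample >= 0))
  quantile(fpkm_sample, percentile / 100, type = 7, names = FALSE)
}

#' Tri-state response calls for one contrast
#'
#' Applies the three significance criteria to a differential-expression
#' table. Rows whose cuffdiff status is not `OK` carry no valid test and are
#' `nochange`. The floor criterion is satisfied when the FPKM of at least one
#' of the two contrasted samples is strictly larger than that sample's floor.
#'
#' @param records data.frame from [read_diff_table()] / [simple_de_test()].
#' @param criteria a [significance_criteria()] object.
#' @param floors optional numeric length-2 vector `c(a, b)` of pre-computed
#'   floors for the reference and test samples; by default each is the
#'   criteria percentile of the corresponding column of `records` (the
#'   sample's full per-gene FPKM distribution).
#' @return data.frame `gene_id`, `contrast`, `call` (up/down/nochange) plus
#'   logical columns `passed_q`, `passed_fc`, `passed_floor`, `tested`.
#' @export
call_responses <- function(records, criteria = significance_criteria(),
                           floors = NULL) {
  stopifnot(inherits(criteria, "significance_criteria"))
  if (is.null(floors))
    floors <- c(expression_floor(records$value_a, criteria$floor_percentile),
                expression_floor(records$value_b, criteria$floor_percentile))
  tested <- records$status == "OK"
  passed_q <- tested & records$q_value <= criteria$q_max
  passed_fc <- tested & abs(records$log2_fc) >= criteria$min_abs_log2fc
  passed_floor <- tested & (records$value_a > floors[1] |
                              records$value_b > floors[2])
  sig <- passed_q & passed_fc & passed_floor
  call <- rep("nochange", nrow(records))
  call[sig & records$log2_fc > 0] <- "up"
  call[sig & records$log2_fc < 0] <- "down"
  data.frame(gene_id = records$gene_id, contrast = records$contrast,
             call = call, passed_q = passed_q, passed_fc = passed_fc,
             passed_floor = passed_floor, tested = tested,
             stringsAsFactors = FALSE)
}

#' Stand-in differential-expression test on replicate FPKM
#'
#' Produces a per-gene differential table for one contrast directly from the
#' replicate FPKM matrix, for synthetic or re-analysed data where no external
#' cuffdiff run is available. Fold changes are
#' `log2((mean_b + eps) / (mean_a + eps))` over replicate means. P-values come
#' either from a limma moderated t on `log2(FPKM + eps)` (default; variance
#' shrinkage across genes is essential at two replicates per condition) or
#' from a per-gene Welch t test (`method = "welch"`). Q-values are
#' Benjamini-Hochberg over the whole gene set. The method used is recorded in
#' the `de_method` attribute of the result.
#'
#' @param fpkm wide FPKM matrix (see [read_fpkm_table()]).
#' @param contrast `"S1_vs_W"` or `"S3_vs_S1"`.
#' @param epsilon pseudocount (FPKM) guarding zeros; applies only to this
#'   stand-in test, never to external diff tables.
#' @param method `"moderated"` (limma) or `"welch"`.
#' @return data.frame in the [read_diff_table()] layout.
#' @export
simple_de_test <- function(fpkm, contrast = c("S1_vs_W", "S3_vs_S1"),
                           epsilon = 1e-3, method = c("moderated", "welch")) {
  contrast <- match.arg(contrast)
  method <- match.arg(method)
  validate_fpkm(fpkm)
  cond <- sample_conditions(colnames(fpkm))
  ab <- strsplit(contrast, "_vs_")[[1]]   # c(test, reference)
  cond_a <- ab[2]; cond_b <- ab[1]
  ia <- which(cond == cond_a); ib <- which(cond == cond_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("simple_de_test needs >= 2 replicates per condition; ",
         "supply external diff tables instead", call. = FALSE)
  mean_a <- rowMeans(fpkm[, ia, drop = FALSE])
  mean_b <- rowMeans(fpkm[, ib, drop = FALSE])
  log2_fc <- log2((mean_b + epsilon) / (mean_a + epsilon))
  y <- log2(fpkm[, c(ia, ib), drop = FALSE] + epsilon)
  grp <- rep(c(0, 1), c(length(ia), length(ib)))
  within_ss <- rowSums((y - cbind(
    matrix(rowMeans(y[, grp == 0, drop = FALSE]), nrow(y), sum(grp == 0)),
    matrix(rowMeans(y[, grp == 1, drop = FALSE]), nrow(y), sum(grp == 1))))^2)
  delta <- rowMeans(y[, grp == 1, drop = FALSE]) -
    rowMeans(y[, grp == 0, drop = FALSE])
  if (max(within_ss) < 1e-20) {
    # noise-free data: every replicate equals its condition mean, so the
    # test degenerates to an exact comparison of means
    p <- ifelse(abs(delta) > 1e-12, 0, 1)
  } else if (method == "moderated") {
    design <- cbind(intercept = 1, diff = grp)
    fit <- limma::lmFit(y, design)
    fit <- suppressWarnings(limma::eBayes(fit))
    p <- fit$p.value[, "diff"]
  } else {
    p <- vapply(seq_len(nrow(y)), function(i) {
      a <- y[i, grp == 0]; b <- y[i, grp == 1]
      if (sd(a) == 0 && sd(b) == 0) return(if (mean(a) == mean(b)) 1 else 0)
      tryCatch(t.test(b, a)$p.value, error = function(e) 1)
    }, numeric(1))
  }
  out <- data.frame(gene_id = rownames(fpkm), contrast = contrast,
                    value_a = mean_a, value_b = mean_b, log2_fc = log2_fc,
                    p_value = unname(p),
                    q_value = benjamini_hochberg(unname(p)),
                    status = "OK", stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "de_method") <- paste0("stand-in ", method,
                                   " test on log2(FPKM+eps)")
  out
}
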