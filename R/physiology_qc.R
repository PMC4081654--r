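# Leaf physiology and replicate-quality utilities.

#' Relative water content of a leaf
#'
#' `RWC (%) = ((FW - DW) / (TW - DW)) * 100`, from the fresh weight at
#' harvest, the turgid weight after 24 h submersion and the oven-dry weight.
#' Invariant under a common rescaling of all three weights. A fresh weight
#' below the dry weight is physically implausible and is flagged with a
#' warning (the value is still returned).
#'
#' @param fw fresh weight (g).
#' @param tw turgid weight (g); must exceed `dw`.
#' @param dw dry weight (g).
#' @return RWC percentage.
#' @export
#' @examples
#' compute_rwc(fw = 2.0, tw = 2.5, dw = 0.5)  # 75
compute_rwc <- function(fw, tw, dw) {
  if (any(tw <= dw))
    stop("compute_rwc: turgid weight must exceed dry weight", call. = FALSE)
  if (any(fw < dw))
    warning("fresh weight below dry weight; check the measurements",
            call. = FALSE)
  (fw - dw) / (tw - dw) * 100
}

#' Replicate-quality regression
#'
#' Least-squares simple linear regression of replicate 2 on replicate 1 over
#' all genes; R-squared measures goodness-of-fit and the slope measures
#' agreement of scale. Used as a QC gate on biological replicates (good
#' replicates sit near R-squared >= 0.94 and slope in 0.8-1.0 on this
#' study design). Regression can be run on raw or log2 FPKM.
#'
#' @param rep1,rep2 equal-length numeric vectors (n >= 3) of per-gene FPKM.
#' @param log2_scale regress on `log2(FPKM + epsilon)` instead of raw FPKM.
#' @param epsilon pseudocount for the log scale.
#' @return list `r_squared`, `slope`, `intercept`, `n`.
#' @export
replicate_regression <- function(rep1, rep2, log2_scale = FALSE,
                                 epsilon = 1e-3) {
  stopifnot(length(rep1) == length(rep2), length(rep1) >= 3)
  if (log2_scale) {
    rep1 <- log2(rep1 + epsilon)
    rep2 <- log2(rep2 + epsilon)
  }
  if (sd(rep1) == 0)
    stop("replicate_regression: zero variance in rep1", call. = FALSE)
  fit <- lm(rep2 ~ rep1)
  # R^2 of a simple regression is the squared correlation (avoids the
  # perfect-fit caveat summary.lm() raises on exact replicates)
  list(r_squared = cor(rep1, rep2)^2,
       slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       n = length(rep1))
}

#' Replicate QC over a whole FPKM matrix
#'
#' Runs [replicate_regression()] for each condition's first two replicates.
#'
#' @param fpkm wide FPKM matrix.
#' @inheritParams replicate_regression
#' @return data.frame `condition`, `r_squared`, `slope`.
#' @export
qc_replicates <- function(fpkm, log2_scale = FALSE, epsilon = 1e-3) {
  cond <- sample_conditions(colnames(fpkm))
  present <- intersect(.CONDITIONS, cond)
  rows <- lapply(present, function(cd) {
    idx <- which(cond == cd)
    if (length(idx) < 2) return(NULL)
    fit <- replicate_regression(fpkm[, idx[1]], fpkm[, idx[2]],
                                log2_scale = log2_scale, epsilon = epsilon)
    data.frame(condition = cd, r_squared = fit$r_squared, slope = fit$slope,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
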