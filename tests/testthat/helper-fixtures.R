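# Shared fixtures and independent oracles used across the suite.

# data.frame in the diff-record layout
make_diff <- function(gene_id, value_a, value_b, log2_fc, p_value, q_value,
                      status = "OK", contrast = "S1_vs_W") {
  data.frame(gene_id = gene_id, contrast = contrast, value_a = value_a,
             value_b = value_b, log2_fc = log2_fc, p_value = p_value,
             q_value = q_value, status = status, stringsAsFactors = FALSE)
}

# small wide FPKM matrix from per-condition means, optionally noise-free
make_fpkm <- function(mu_w, mu_s1, mu_s3, n_rep = 2) {
  n <- length(mu_w)
  cols <- unlist(lapply(c("W", "S1", "S3"), function(cd)
    paste(cd, seq_len(n_rep), sep = "_")))
  m <- matrix(0, n, length(cols),
              dimnames = list(sprintf("g%03d", seq_len(n)), cols))
  for (r in seq_len(n_rep)) {
    m[, paste0("W_", r)] <- mu_w
    m[, paste0("S1_", r)] <- mu_s1
    m[, paste0("S3_", r)] <- mu_s3
  }
  m
}

# hand step-up Benjamini-Hochberg: q_i = min over p_(j) >= p_(i) of m p_(j)/j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- rev(cummin(rev(m * ps / seq_len(m))))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# brute-force longest-common-substring extraction: enumerate all substrings,
# intersect, pick longest (ties: earliest in the first string, then lexical),
# mask and repeat
lcs_oracle <- function(strings, k = 3, min_len = 4) {
  work <- tolower(gsub("\\s+", " ", trimws(strings)))
  all_subs <- function(s) {
    n <- nchar(s)
    if (n == 0) return(character(0))
    unlist(lapply(seq_len(n), function(i) substring(s, i, i:n)))
  }
  out <- character(0)
  for (round in seq_len(k)) {
    subs1 <- unique(all_subs(work[1]))
    subs1 <- subs1[nchar(subs1) >= min_len]
    common <- subs1[vapply(subs1, function(cs)
      all(vapply(work, function(s) grepl(cs, s, fixed = TRUE), TRUE)),
      TRUE, USE.NAMES = FALSE)]
    if (length(common) == 0) break
    cand <- common[nchar(common) == max(nchar(common))]
    pos <- vapply(cand, function(cs) regexpr(cs, work[1], fixed = TRUE)[1],
                  0L, USE.NAMES = FALSE)
    cand <- sort(cand[pos == min(pos)])
    pick <- cand[1]
    out <- c(out, pick)
    work <- vapply(seq_along(work), function(j)
      sub(pick, sprintf("\u0001%d\u0001", j), work[j], fixed = TRUE), "")
  }
  out
}

# random description-like string over a small alphabet
random_string <- function(len, alphabet = c(letters[1:5], " ")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
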