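# Independent oracles and fixture builders shared across the suite.

# Textbook OLS from raw (uncentred) sums -- deliberately a different algebra
# from the package's centred-sums implementation.
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x) - sx^2 / n
  sxy <- sum(x * y) - sx * sy / n
  syy <- sum(y * y) - sy^2 / n
  slope <- sxy / sxx
  intercept <- (sy - slope * sx) / n
  sse <- syy - slope * sxy
  r2 <- 1 - sse / syy
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
  se <- sqrt(sse / ((n - 2) * sxx))
  tval <- slope / se
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  list(n = n, slope = slope, intercept = intercept, r2 = r2,
       adj_r2 = adj_r2, p_value = p, x_intercept = -intercept / slope)
}

# Brute-force node-to-tip distance: walk parent pointers tip -> node, summing
# branch lengths edge by edge (independent of the package's depth table).
brute_distances <- function(tree, node_id) {
  phy <- tree$phy
  parent <- integer(max(phy$edge))
  plen <- numeric(max(phy$edge))
  for (i in seq_len(nrow(phy$edge))) {
    parent[phy$edge[i, 2]] <- phy$edge[i, 1]
    plen[phy$edge[i, 2]] <- phy$edge.length[i]
  }
  v <- tree$preorder[node_id]
  tips <- tree$desc[[v]]
  d <- vapply(tips, function(tp) {
    acc <- 0; w <- tp
    while (w != v) {
      acc <- acc + plen[w]
      w <- parent[w]
    }
    acc
  }, numeric(1))
  stats::setNames(d, phy$tip.label[tips])
}

# Brute-force variant-column scan: per-column loop re-deriving the rule
# (>= 2 distinct states among the allowed set), 0-based output.
brute_variant_columns <- function(mat, gap_as_state = FALSE) {
  allowed <- c("A", "C", "G", "T", if (gap_as_state) "-")
  out <- integer(0)
  for (j in seq_len(ncol(mat))) {
    seen <- character(0)
    for (i in seq_len(nrow(mat))) {
      s <- mat[i, j]
      if (s %in% allowed && !(s %in% seen)) seen <- c(seen, s)
    }
    if (length(seen) >= 2) out <- c(out, j - 1L)
  }
  out
}

random_alignment <- function(n_seq, n_col, p_special = 0.1) {
  states <- c("A", "C", "G", "T")
  special <- c("-", "N", "R", "Y", "W")
  mat <- matrix(sample(states, n_seq * n_col, replace = TRUE),
                nrow = n_seq)
  k <- rbinom(1, n_seq * n_col, p_special)
  if (k > 0) {
    idx <- sample(n_seq * n_col, k)
    mat[idx] <- sample(special, k, replace = TRUE)
  }
  rownames(mat) <- paste0("s", seq_len(n_seq))
  mat
}

as_alignment <- function(mat) {
  structure(list(seqs = mat, names = rownames(mat), length = ncol(mat)),
            class = "alignment")
}

tree_from_text <- function(text) {
  tf <- tempfile(fileext = ".nwk")
  writeLines(text, tf)
  read_tree(tf)
}

dated_tree_from_text <- function(text, ...) {
  parse_tip_dates(tree_from_text(text), ...)
}

TOY_NEWICK <- "((A_2000:0.1,B_2001:0.2):0.05,C_2002:0.3);"

# Locate the scan report whose clade is exactly `tips` (order-free).
report_for_tips <- function(scan, tree, tips) {
  for (r in scan$reports) {
    if (setequal(descendant_tips(tree, r$node_id), tips)) return(r)
  }
  NULL
}
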