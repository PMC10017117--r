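#' Simulate a dated tree under a strict molecular clock
#'
#' Generates a rooted binary tree with heterochronously sampled tips and
#' branch lengths proportional to elapsed time, so the true substitution
#' rate and every node's true date are known. This is the validation
#' harness for [scan_tree()]: with `noise = "none"` every node-to-tip
#' distance equals `rate * (tip_date - node_date)` up to floating-point
#' summation, so the per-node regression must recover the rate as its slope
#' and the node date as its x-intercept.
#'
#' The generator works as follows. The topology comes from recursive random
#' splits of the tip set (at each internal node the tip set is split
#' uniformly at random into two non-empty parts). Tip sampling dates are
#' drawn uniformly in the window `[root_date + depth - sampling_window,
#' root_date + depth]`. Internal-node dates are then placed top-down: each
#' internal node's date is uniform between its parent's date and the
#' earliest sampling date among its descendant tips. Each branch length is
#' the governing rate times the elapsed time on the branch, optionally
#' perturbed by noise and clamped at zero.
#'
#' `rate_map` emulates clade-heterogeneous signal (e.g. one measurably
#' evolving clade inside a tree with no whole-tree signal): it gives one
#' rate per child subtree of the root (recycled), overriding `rate` on every
#' branch inside that subtree including the root edge leading to it.
#'
#' Tip labels are `t<i>_<decimal date>` with the date printed in shortest
#' round-trip form, so [parse_tip_dates()] recovers the true dates exactly.
#'
#' @param n_tips number of tips (>= 3).
#' @param rate substitution rate in substitutions/site/year (default 1e-3,
#'   a typical fast-evolving virus).
#' @param root_date decimal year of the root (default 1990).
#' @param depth years from the root to the end of sampling (default 30).
#' @param sampling_window width in years of the tip sampling window, ending
#'   at `root_date + depth` (default 20; must be positive — identical
#'   sampling dates would make every node ineligible — and at most `depth`).
#' @param noise `"none"` (default), `"gaussian"` (additive, clamped at 0) or
#'   `"gamma"` (multiplicative with mean 1, preserving expectations).
#' @param noise_sd absolute s.d. of gaussian branch noise (subst/site).
#' @param noise_sd_frac alternative to `noise_sd`: s.d. as a fraction of the
#'   mean noiseless branch length.
#' @param noise_shape shape of the gamma multiplier (mean fixed at 1).
#' @param rate_map optional numeric vector of per-root-child-subtree rates.
#' @param seed integer seed; the same seed gives a bit-identical tree.
#' @return list with `tree` (a dated [dated_tree]) and `truth`: `rate`,
#'   `root_date`, `node_dates` (true date per preorder node id),
#'   `node_rates` (governing rate per node's subtree; `NA` at the root when
#'   `rate_map` mixes rates), and `clades` (per root-child subtree: tip
#'   labels and rate).
#' @export
simulate_clock_tree <- function(n_tips = 50L, rate = 1e-3, root_date = 1990,
                                depth = 30, sampling_window = 20,
                                noise = c("none", "gaussian", "gamma"),
                                noise_sd = NULL, noise_sd_frac = NULL,
                                noise_shape = NULL, rate_map = NULL,
                                seed = 1L) {
  noise <- match.arg(noise)
  n_tips <- as.integer(n_tips)
  if (n_tips < 3L) stop("n_tips must be >= 3")
  if (depth <= 0) stop("depth must be positive")
  if (sampling_window <= 0) {
    stop("sampling_window must be positive: with a single sampling date ",
         "no node can satisfy the distinct-dates condition")
  }
  if (sampling_window > depth) stop("sampling_window cannot exceed depth")
  if (rate < 0 || (!is.null(rate_map) && any(rate_map < 0))) {
    stop("rates must be non-negative")
  }
  if (noise == "gaussian" && is.null(noise_sd) && is.null(noise_sd_frac)) {
    stop("gaussian noise needs noise_sd or noise_sd_frac")
  }
  if (noise == "gamma" && is.null(noise_shape)) {
    stop("gamma noise needs noise_shape")
  }

  with_seed(seed, {
    ## topology: recursive uniform splits, recorded directly in preorder so
    ## the resulting edge matrix is cladewise-ordered.
    nnode <- n_tips - 1L
    root <- n_tips + 1L
    edge_from <- integer(2L * n_tips); edge_to <- integer(2L * n_tips)
    n_edges <- 0L
    tip_counter <- 0L; int_counter <- n_tips + 1L
    rec <- function(k) {
      # returns the node number for a subtree of k tips, appending edges
      if (k == 1L) {
        tip_counter <<- tip_counter + 1L
        return(tip_counter)
      }
      v <- int_counter
      int_counter <<- int_counter + 1L
      j <- sample.int(k - 1L, 1L)
      for (kk in c(j, k - j)) {
        # reserve edge slot before recursing so edges come out preorder
        n_edges <<- n_edges + 1L
        slot <- n_edges
        edge_from[slot] <<- v
        ch <- rec(kk)
        edge_to[slot] <<- ch
      }
      v
    }
    rec(n_tips)
    edge <- cbind(edge_from[seq_len(n_edges)], edge_to[seq_len(n_edges)])

    ## tip dates in the sampling window
    t_end <- root_date + depth
    tip_time <- t_end - runif(n_tips, 0, sampling_window)

    ## minimum descendant tip time per node (children listed after parents)
    n_all <- n_tips + nnode
    min_tip <- rep(Inf, n_all)
    min_tip[seq_len(n_tips)] <- tip_time
    for (i in rev(seq_len(nrow(edge)))) {
      p <- edge[i, 1L]; ch <- edge[i, 2L]
      min_tip[p] <- min(min_tip[p], min_tip[ch])
    }

    ## node dates top-down
    node_time <- numeric(n_all)
    node_time[seq_len(n_tips)] <- tip_time
    node_time[root] <- root_date
    for (i in seq_len(nrow(edge))) {
      ch <- edge[i, 2L]
      if (ch > n_tips) {
        p <- edge[i, 1L]
        node_time[ch] <- node_time[p] +
          runif(1) * (min_tip[ch] - node_time[p])
      }
    }

    ## per-subtree rates
    edge_rate <- rep(rate, nrow(edge))
    subtree_of <- rep(NA_integer_, n_all)     # which root-child subtree
    root_children <- edge[edge[, 1L] == root, 2L]
    if (!is.null(rate_map)) {
      rates <- rep_len(as.numeric(rate_map), length(root_children))
      for (ci in seq_along(root_children)) {
        subtree_of[root_children[ci]] <- ci
      }
      for (i in seq_len(nrow(edge))) {        # preorder: parents first
        ch <- edge[i, 2L]; p <- edge[i, 1L]
        if (is.na(subtree_of[ch]) && !is.na(subtree_of[p])) {
          subtree_of[ch] <- subtree_of[p]
        }
        edge_rate[i] <- rates[subtree_of[ch]]
      }
    }

    len <- edge_rate * (node_time[edge[, 2L]] - node_time[edge[, 1L]])
    if (noise == "gaussian") {
      sd <- noise_sd %||% (noise_sd_frac * mean(len))
      len <- pmax(len + rnorm(length(len), 0, sd), 0)
    } else if (noise == "gamma") {
      len <- len * rgamma(length(len), shape = noise_shape,
                          rate = noise_shape)
    }

    labels <- paste0("t", seq_len(n_tips), "_", fmt_num(tip_time))
    phy <- structure(
      list(edge = edge, edge.length = len, Nnode = nnode,
           tip.label = labels),
      class = "phylo")
    tree <- dated_tree(phy, stats::setNames(tip_time, labels))

    ## truth keyed by the tree's own preorder node ids
    node_dates <- stats::setNames(node_time[tree$preorder],
                                  seq_along(tree$preorder))
    node_rates <- rep(rate, n_all)
    clades <- NULL
    if (!is.null(rate_map)) {
      node_rates <- ifelse(is.na(subtree_of), NA_real_, rates[subtree_of])
      node_rates[root] <- if (length(unique(rates)) == 1L) rates[1L] else NA_real_
      clades <- lapply(seq_along(root_children), function(ci) {
        v <- root_children[ci]
        tips <- if (v <= n_tips) labels[v] else
          labels[tree$desc[[v]][tree$desc[[v]] <= n_tips]]
        list(tips = tips, rate = rates[ci])
      })
    }
    node_rates <- stats::setNames(node_rates[tree$preorder],
                                  seq_along(tree$preorder))

    list(tree = tree,
         truth = list(rate = rate, root_date = root_date,
                      node_dates = node_dates, node_rates = node_rates,
                      clades = clades, seed = as.integer(seed)))
  })
}

#' Shuffle tip dates to destroy temporal signal
#'
#' Permutes the sampling dates uniformly at random among the tips, leaving
#' topology and branch lengths untouched — the standard null model for
#' asking whether an observed date–distance correlation is stronger than
#' chance.
#'
#' @param tree a dated [dated_tree] with at least 2 distinct dates.
#' @param seed integer seed.
#' @return a [dated_tree] with the same date multiset reassigned to tips.
#' @export
permute_dates <- function(tree, seed) {
  stopifnot(inherits(tree, "dated_tree"))
  if (is.null(tree$dates)) stop("tree has no tip dates")
  if (sum(!duplicated(tree$dates)) < 2L) {
    stop("need at least 2 distinct dates to permute")
  }
  with_seed(seed, {
    perm <- sample.int(length(tree$dates))
    dated_tree(tree$phy,
               stats::setNames(unname(tree$dates)[perm], names(tree$dates)))
  })
}
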