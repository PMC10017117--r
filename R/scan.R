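#' Configuration for a temporal-signal scan
#'
#' @param alpha significance threshold on the regression p-value
#'   (default 0.05).
#' @param min_tips minimum descendant tips for a node to be tested
#'   (default 3).
#' @param min_distinct_combos minimum distinct (date, distance) pairs
#'   (default 3).
#' @param min_distinct_dates minimum distinct sampling dates (default 2).
#' @param correction multiple-testing correction across eligible nodes:
#'   `"none"` (default — the scan is an exploratory tool) or
#'   `"benjamini-hochberg"`.
#' @param combo_tolerance absolute tolerance below which two (date,
#'   distance) pairs count as identical (default 0 = exact equality; raise
#'   for trees written with truncated precision).
#' @param sided sidedness of the slope t-test, `"two"` (default) or `"one"`.
#' @return a `scan_config` list.
#' @export
scan_config <- function(alpha = 0.05, min_tips = 3L, min_distinct_combos = 3L,
                        min_distinct_dates = 2L,
                        correction = c("none", "benjamini-hochberg"),
                        combo_tolerance = 0, sided = c("two", "one")) {
  correction <- match.arg(correction)
  sided <- match.arg(sided)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number in (0, 1)")
  }
  if (min_tips < 3L) stop("min_tips must be >= 3")
  if (combo_tolerance < 0) stop("combo_tolerance must be >= 0")
  structure(
    list(alpha = alpha, min_tips = as.integer(min_tips),
         min_distinct_combos = as.integer(min_distinct_combos),
         min_distinct_dates = as.integer(min_distinct_dates),
         correction = correction, combo_tolerance = combo_tolerance,
         sided = sided),
    class = "scan_config"
  )
}

# Count distinct (date, distance) pairs. tol = 0 uses exact float equality;
# tol > 0 uses a greedy representative scan (pairs within tol of an already
# kept representative, in both coordinates, are merged).
n_distinct_pairs <- function(dates, distances, tol = 0) {
  if (tol == 0) return(sum(!duplicated(cbind(dates, distances))))
  keep_d <- numeric(0); keep_r <- numeric(0)
  for (i in seq_along(dates)) {
    if (!any(abs(keep_d - dates[i]) <= tol & abs(keep_r - distances[i]) <= tol)) {
      keep_d <- c(keep_d, dates[i]); keep_r <- c(keep_r, distances[i])
    }
  }
  length(keep_d)
}

#' Can a node's (dates, distances) support a regression?
#'
#' A node is eligible for the root-to-tip regression only if (i) it is the
#' parent of at least `min_tips` (3) tips, (ii) there are at least
#' `min_distinct_combos` (3) distinct combinations of node-to-tip distance
#' and sampling date, and (iii) there are at least `min_distinct_dates` (2)
#' different sampling dates. Conditions are checked in that order and the
#' first failure is reported.
#'
#' @param dates,distances paired per-tip vectors of equal length.
#' @param config a [scan_config()].
#' @return list with `eligible` (logical) and `reason` (one of
#'   `"too-few-tips"`, `"too-few-distinct-combinations"`,
#'   `"too-few-distinct-dates"`, `"none"`).
#' @export
check_eligibility <- function(dates, distances, config = scan_config()) {
  if (length(dates) != length(distances)) {
    stop("dates and distances differ in length")
  }
  if (length(dates) < config$min_tips) {
    return(list(eligible = FALSE, reason = "too-few-tips"))
  }
  nc <- n_distinct_pairs(dates, distances, config$combo_tolerance)
  if (nc < config$min_distinct_combos) {
    return(list(eligible = FALSE, reason = "too-few-distinct-combinations"))
  }
  if (sum(!duplicated(dates)) < config$min_distinct_dates) {
    return(list(eligible = FALSE, reason = "too-few-distinct-dates"))
  }
  list(eligible = TRUE, reason = "none")
}

#' Scan every internal node of a dated tree for temporal signal
#'
#' Visits each internal node (root included) in preorder. For every node
#' passing [check_eligibility()], fits the root-to-tip regression of
#' node-to-tip distance on sampling date ([fit_rtt_regression()]) and flags
#' the node as significant when the slope is positive and the (optionally
#' corrected) p-value is at most `alpha`.
#'
#' Distances are measured from the focal node itself to its descendant tips
#' (the node is treated as the local root), so the x-intercept estimates the
#' focal node's own date. Measuring from the global root instead would shift
#' every distance by a constant, which changes the intercepts but none of
#' slope, p-value or R-squared — the significance verdict is identical under
#' either convention.
#'
#' @param tree a dated [dated_tree].
#' @param config a [scan_config()].
#' @return an object of class `rtt_scan`: list with `config`, `reports`
#'   (one per internal node, in preorder; each has `node_id`, `anchor` — the
#'   lexicographically smallest descendant tip label — `n_tips`, `eligible`,
#'   `ineligibility_reason`, `fit` (an `rtt_fit`, eligible nodes only),
#'   `p_adj` when a correction is applied, and `significant`) and
#'   `tree_fingerprint`.
#' @export
scan_tree <- function(tree, config = scan_config()) {
  stopifnot(inherits(tree, "dated_tree"))
  if (is.null(tree$dates)) {
    stop("tree has no tip dates; run parse_tip_dates() first")
  }
  if (n_tips(tree) < 3L) stop("tree has fewer than 3 tips")
  ntip <- n_tips(tree)

  reports <- list()
  for (v in tree$preorder) {
    if (v <= ntip) next
    tips <- tree$desc[[v]]
    labels <- tree$phy$tip.label[tips]
    dates <- unname(tree$dates[labels])
    distances <- tree$depths[tips] - tree$depths[v]
    elig <- check_eligibility(dates, distances, config)
    fit <- NULL
    if (elig$eligible) {
      fit <- fit_rtt_regression(dates, stats::setNames(distances, labels),
                                sided = config$sided)
    }
    reports[[length(reports) + 1L]] <- list(
      node_id = tree$node_id[v],
      anchor = min(labels),
      n_tips = length(tips),
      eligible = elig$eligible,
      ineligibility_reason = elig$reason,
      fit = fit,
      p_adj = NA_real_,
      significant = FALSE
    )
  }

  elig_idx <- which(vapply(reports, `[[`, TRUE, "eligible"))
  p_raw <- vapply(reports[elig_idx], function(r) r$fit$p_value, numeric(1))
  p_use <- if (config$correction == "benjamini-hochberg") {
    stats::p.adjust(p_raw, method = "BH")
  } else {
    p_raw
  }
  for (j in seq_along(elig_idx)) {
    i <- elig_idx[j]
    if (config$correction != "none") reports[[i]]$p_adj <- p_use[j]
    reports[[i]]$significant <-
      reports[[i]]$fit$slope > 0 && p_use[j] <= config$alpha
  }

  structure(
    list(config = config, reports = reports,
         tree_fingerprint = tree_fingerprint(tree)),
    class = "rtt_scan"
  )
}

#' @export
print.rtt_scan <- function(x, ...) {
  n <- length(x$reports)
  ne <- sum(vapply(x$reports, `[[`, TRUE, "eligible"))
  ns <- sum(vapply(x$reports, `[[`, TRUE, "significant"))
  cat("Temporal-signal scan: ", n, " internal nodes, ", ne, " eligible, ",
      ns, " with signal (alpha = ", fmt_num(x$config$alpha), ")\n", sep = "")
  invisible(x)
}

#' Per-tip regression data for one node
#'
#' The (tip, date, distance) triples behind a node's regression, for external
#' plotting or outlier inspection.
#'
#' @param tree a dated [dated_tree].
#' @param node_id preorder id of an internal node.
#' @return data.frame with columns `tip`, `date`, `distance`.
#' @export
node_regression_data <- function(tree, node_id) {
  if (is.null(tree$dates)) stop("tree has no tip dates")
  d <- node_to_tip_distances(tree, node_id)
  data.frame(tip = names(d), date = unname(tree$dates[names(d)]),
             distance = unname(d), stringsAsFactors = FALSE)
}
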