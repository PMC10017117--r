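#' Read a rooted phylogenetic tree from Newick or Nexus
#'
#' Reads and validates a rooted tree whose branch lengths are genetic
#' distances (substitutions/site), e.g. a maximum-likelihood tree. Nexus
#' TRANSLATE tables are resolved to full tip labels. The returned tree
#' carries no tip dates yet; follow with [parse_tip_dates()].
#'
#' Validation is strict: every edge must have a non-negative branch length,
#' tip labels must be unique, and the root must have at least two children.
#' A basal polytomy (root degree >= 3) is accepted with a warning, since
#' Newick cannot always distinguish a deliberately rooted tree from an
#' unrooted one.
#'
#' @param path path to the tree file.
#' @param format `"newick"`, `"nexus"`, or `"auto"` (default; sniffs a
#'   leading `#NEXUS` token).
#' @return an undated [dated_tree].
#' @export
read_tree <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tree file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  if (format == "auto") {
    first <- trimws(paste(txt[nzchar(trimws(txt))][1], collapse = ""))
    format <- if (grepl("^#NEXUS", first, ignore.case = TRUE)) "nexus" else "newick"
  }
  phy <- tryCatch(
    if (format == "newick") ape::read.tree(path) else ape::read.nexus(path),
    error = function(e) {
      stop("cannot parse ", format, " file '", path, "': ",
           conditionMessage(e), diagnose_newick(txt), call. = FALSE)
    }
  )
  if (inherits(phy, "multiPhylo")) {
    warning("file contains ", length(phy), " trees; using the first")
    phy <- phy[[1L]]
  }
  if (is.null(phy)) {
    stop("cannot parse ", format, " file '", path, "'", diagnose_newick(txt))
  }
  dated_tree(phy)
}

# Best-effort error location for malformed Newick: report the character
# offset at which parenthesis nesting first breaks.
diagnose_newick <- function(txt) {
  s <- paste(txt, collapse = "")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(paste0(" (unmatched ')' at character ", i, ")"))
    }
  }
  if (depth > 0L) return(paste0(" (", depth, " unclosed '(')"))
  ""
}

#' Parse decimal-year sampling dates out of tip labels
#'
#' Sampling dates must be embedded in the tip labels as decimal years
#' (negative values encode B.C.E. dates, e.g. `-400.5`). By default the date
#' is the last `"_"`-delimited field of the label; both the delimiter and the
#' field index are configurable, and a regular expression with one capture
#' group is available for labels that do not follow a delimited layout.
#'
#' @param tree an undated [dated_tree] from [read_tree()].
#' @param delim field delimiter (default `"_"`). Ignored when `regex` is
#'   given.
#' @param field 1-based field index; negative counts from the end
#'   (default `-1`, the last field).
#' @param regex optional regular expression with exactly one capture group
#'   that extracts the date from the whole label.
#' @param on_missing `"error"` (default) aborts listing every label without a
#'   parsable date; `"prune"` drops those tips (merging their parent edges so
#'   all remaining tip-to-tip path lengths are unchanged) and reports them.
#' @return a dated [dated_tree]; when tips were pruned, their labels are
#'   attached as attribute `"pruned"`.
#' @export
parse_tip_dates <- function(tree, delim = "_", field = -1L, regex = NULL,
                            on_missing = c("error", "prune")) {
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(tree, "dated_tree"))
  labs <- tree$phy$tip.label
  raw <- if (!is.null(regex)) {
    m <- regmatches(labs, regexec(regex, labs))
    vapply(m, function(g) if (length(g) >= 2L) g[2L] else NA_character_,
           character(1))
  } else {
    vapply(strsplit(labs, delim, fixed = TRUE), function(p) {
      i <- if (field < 0L) length(p) + field + 1L else field
      if (i >= 1L && i <= length(p)) p[i] else NA_character_
    }, character(1))
  }
  dates <- suppressWarnings(as.numeric(raw))
  bad <- !is.finite(dates)
  if (any(bad) && on_missing == "error") {
    stop("no parsable sampling date in tip label(s): ",
         paste(labs[bad], collapse = ", "),
         "\n(use on_missing = \"prune\" to drop them)")
  }
  if (sum(!bad) < 3L) {
    stop("fewer than 3 tips with parsable dates (", sum(!bad), " remain)")
  }
  if (any(bad)) {
    phy <- ape::drop.tip(tree$phy, labs[bad])
    message("pruned ", sum(bad), " undated tip(s): ",
            paste(labs[bad], collapse = ", "))
    out <- dated_tree(phy, stats::setNames(dates[!bad], labs[!bad]))
    attr(out, "pruned") <- labs[bad]
    return(out)
  }
  dated_tree(tree$phy, stats::setNames(dates, labs))
}

#' Convert calendar dates to decimal years
#'
#' Maps `YYYY-MM-DD` (or [Date]) to `year + (day_of_year - 0.5) / days_in_year`,
#' placing each day at its midpoint.
#'
#' @param x a [Date] vector or character in ISO `YYYY-MM-DD` format.
#' @return numeric decimal years.
#' @export
#' @examples
#' as_decimal_year("2000-07-02")  # ~2000.5
as_decimal_year <- function(x) {
  d <- as.Date(x)
  year <- as.integer(format(d, "%Y"))
  yday <- as.integer(format(d, "%j"))
  ndays <- ifelse(
    (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0, 366, 365)
  year + (yday - 0.5) / ndays
}

# ---- Newick/Nexus serialisation -------------------------------------------

# Serialise a dated_tree to a Newick string, with optional per-node comment
# strings (indexed by ape node number) inserted FigTree-style after the node
# (before its branch-length colon). Branch lengths and any numbers inside the
# comments use shortest round-trip formatting.
write_newick_string <- function(tree, comments = NULL, labels = NULL) {
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  if (is.null(labels)) labels <- phy$tip.label
  children <- vector("list", ntip + phy$Nnode)
  elen <- numeric(ntip + phy$Nnode)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; ch <- phy$edge[i, 2L]
    children[[p]] <- c(children[[p]], ch)
    elen[ch] <- phy$edge.length[i]
  }
  root <- ntip + 1L
  rec <- function(v) {
    com <- if (!is.null(comments)) comments[v] else ""
    if (is.na(com)) com <- ""
    body <- if (v <= ntip) {
      labels[v]
    } else {
      paste0("(", paste(vapply(children[[v]], rec, character(1)),
                        collapse = ","), ")")
    }
    if (v == root) paste0(body, com)
    else paste0(body, com, ":", fmt_num(elen[v]))
  }
  paste0(rec(root), ";")
}

#' Write a scan-annotated Nexus tree
#'
#' Serialises the tree with FigTree-style bracketed comments on every
#' internal node carrying that node's scan verdict:
#' `[&node_id=..,anchor=..,eligible=..,signal=..,p=..,slope=..,adj_r2=..,x_intercept=..]`.
#' `anchor` is the lexicographically smallest descendant tip label, a stable
#' human-readable handle for the node across tools that renumber nodes.
#' Branch lengths are written in shortest round-trip decimal form, so
#' re-reading the file recovers them exactly.
#'
#' @param tree the [dated_tree] the scan was run on.
#' @param scan the matching [scan_tree()] result.
#' @param path output path (Nexus).
#' @return the path, invisibly.
#' @seealso [read_annotated_tree()]
#' @export
write_annotated_tree <- function(tree, scan, path) {
  stopifnot(inherits(tree, "dated_tree"), inherits(scan, "rtt_scan"))
  if (!identical(scan$tree_fingerprint, tree_fingerprint(tree))) {
    stop("scan result does not match this tree (fingerprint mismatch)")
  }
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  comments <- rep(NA_character_, ntip + phy$Nnode)
  for (r in scan$reports) {
    v <- ape_node(tree, r$node_id)
    fields <- c(
      node_id = as.character(r$node_id),
      anchor = quote_nexus(r$anchor),
      eligible = as.character(as.integer(r$eligible)),
      signal = as.character(as.integer(r$significant))
    )
    if (r$eligible) {
      fields <- c(fields,
                  p = fmt_num(r$fit$p_value),
                  slope = fmt_num(r$fit$slope),
                  adj_r2 = fmt_num(r$fit$adj_r2),
                  x_intercept = fmt_num(r$fit$x_intercept))
    } else {
      fields <- c(fields, reason = r$ineligibility_reason)
    }
    comments[v] <- paste0("[&", paste(names(fields), fields, sep = "=",
                                      collapse = ","), "]")
  }
  translate <- paste0("\t\t", seq_len(ntip), "\t",
                      quote_nexus(phy$tip.label),
                      c(rep(",", ntip - 1L), ""))
  nwk <- write_newick_string(tree, comments = comments,
                             labels = as.character(seq_len(ntip)))
  lines <- c(
    "#NEXUS",
    "BEGIN TAXA;",
    paste0("\tDIMENSIONS NTAX=", ntip, ";"),
    "\tTAXLABELS",
    paste0("\t\t", quote_nexus(phy$tip.label)),
    "\t;",
    "END;",
    "BEGIN TREES;",
    "\tTRANSLATE",
    translate,
    "\t;",
    paste0("\tTREE annotated = [&R] ", nwk),
    "END;"
  )
  write_lines_atomic(lines, path)
}

#' Read back an annotated Nexus tree
#'
#' Counterpart of [write_annotated_tree()]: recovers the tree (topology,
#' labels, branch lengths) and the per-node statistics table from the
#' bracketed node comments.
#'
#' @param path Nexus file written by [write_annotated_tree()].
#' @return list with `tree` (undated [dated_tree]) and `annotations`
#'   (data.frame keyed by `node_id`).
#' @export
read_annotated_tree <- function(path) {
  txt <- readLines(path, warn = FALSE)
  blocks <- unlist(regmatches(txt, gregexpr("\\[&[^]]*\\]", txt)))
  ann <- lapply(blocks, function(b) {
    inner <- sub("^\\[&", "", sub("\\]$", "", b))
    kv <- strsplit(strsplit(inner, ",", fixed = TRUE)[[1L]], "=", fixed = TRUE)
    kv <- kv[vapply(kv, length, 0L) == 2L]
    if (length(kv) == 0L) return(NULL)
    vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
    if (!"node_id" %in% names(vals)) return(NULL)
    vals
  })
  ann <- Filter(Negate(is.null), ann)
  annotations <- NULL
  if (length(ann) > 0L) {
    keys <- unique(unlist(lapply(ann, names)))
    annotations <- as.data.frame(
      lapply(stats::setNames(keys, keys), function(k)
        vapply(ann, function(a) if (k %in% names(a)) a[[k]] else NA_character_,
               character(1))),
      stringsAsFactors = FALSE)
    for (k in intersect(keys, c("node_id", "eligible", "signal", "p",
                                "slope", "adj_r2", "x_intercept"))) {
      annotations[[k]] <- suppressWarnings(as.numeric(annotations[[k]]))
    }
    annotations <- annotations[order(annotations$node_id), , drop = FALSE]
    rownames(annotations) <- NULL
  }
  clean <- gsub("\\[&[^]]*\\]", "", txt)
  tmp <- tempfile(fileext = ".nex")
  on.exit(unlink(tmp))
  writeLines(clean, tmp)
  list(tree = read_tree(tmp, format = "nexus"), annotations = annotations)
}

#' Write a dated tree as plain Newick
#'
#' Tip labels are written as-is (they carry the dates); branch lengths use
#' shortest round-trip decimals, so `read_tree()` on the output reproduces
#' the tree exactly.
#'
#' @param tree a [dated_tree].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  write_lines_atomic(write_newick_string(tree), path)
}
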