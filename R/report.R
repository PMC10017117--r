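#' Tabulate a temporal-signal scan
#'
#' One row per node, in preorder. `"significant-only"` keeps the nodes with
#' temporal signal — the summary a user acts on; `"all-nodes"` keeps every
#' internal node and adds the `ineligibility_reason` diagnostic column.
#'
#' @param scan an [scan_tree()] result.
#' @param mode `"significant-only"` (default) or `"all-nodes"`.
#' @return data.frame with columns `node_id`, `n_tips`, `p_value`, `slope`,
#'   `adj_r2`, `x_intercept`, `significant` (and `ineligibility_reason` in
#'   all-nodes mode).
#' @export
summary_table <- function(scan, mode = c("significant-only", "all-nodes")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scan, "rtt_scan"))
  rows <- lapply(scan$reports, function(r) {
    data.frame(
      node_id = r$node_id,
      n_tips = r$n_tips,
      p_value = if (r$eligible) r$fit$p_value else NA_real_,
      slope = if (r$eligible) r$fit$slope else NA_real_,
      adj_r2 = if (r$eligible) r$fit$adj_r2 else NA_real_,
      x_intercept = if (r$eligible) r$fit$x_intercept else NA_real_,
      significant = r$significant,
      ineligibility_reason = r$ineligibility_reason,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$node_id), , drop = FALSE]
  if (mode == "significant-only") {
    df <- df[df$significant, setdiff(names(df), "ineligibility_reason"),
             drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write the scan summary as TSV plus a JSON twin
#'
#' The TSV has a header row, tab delimiters, LF endings, and every numeric
#' field in shortest round-trip decimal form, so re-running on identical
#' input is byte-identical. A JSON file with exactly the same rows is always
#' written alongside (same path with a `.json` extension).
#'
#' @param scan an [scan_tree()] result.
#' @param path output TSV path.
#' @param mode see [summary_table()].
#' @return invisibly, the paths written (tsv, json).
#' @export
write_summary <- function(scan, path,
                          mode = c("significant-only", "all-nodes")) {
  mode <- match.arg(mode)
  df <- summary_table(scan, mode)
  cols <- names(df)
  fmt_col <- function(v) {
    if (is.numeric(v)) fmt_num(v)
    else if (is.logical(v)) tolower(as.character(v))
    else as.character(v)
  }
  body <- if (nrow(df) == 0L) character(0) else {
    do.call(paste, c(lapply(df, fmt_col), sep = "\t"))
  }
  write_lines_atomic(c(paste(cols, collapse = "\t"), body), path)

  json_path <- paste0(tools::file_path_sans_ext(path), ".json")
  tmp <- tempfile(tmpdir = dirname(json_path))
  jsonlite::write_json(df, tmp, dataframe = "rows", digits = NA,
                       na = "null", auto_unbox = TRUE, pretty = TRUE)
  if (!file.rename(tmp, json_path)) stop("cannot write to ", json_path)
  invisible(c(tsv = path, json = json_path))
}
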