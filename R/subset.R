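#' Read a nucleotide multiple-sequence alignment from FASTA
#'
#' Sequences are case-folded to upper case and `U` is mapped to `T`. All
#' records must have the same length.
#'
#' @param path FASTA file (single- or multi-line records).
#' @return an `alignment` object: list with `seqs` (character matrix, one row
#'   per record, one column per site), `names`, `length` (columns).
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  # read as "AA" so every character (gaps, ambiguity codes, RNA u) survives
  dna <- seqinr::read.fasta(path, seqtype = "AA", set.attributes = FALSE)
  if (length(dna) == 0L) stop("no FASTA records in ", path)
  chars <- dna
  lens <- lengths(chars)
  if (length(unique(lens)) != 1L) {
    stop("sequences are not aligned (lengths ",
         paste(sort(unique(lens)), collapse = ", "), ")")
  }
  nms <- names(dna)
  if (anyDuplicated(nms)) {
    stop("duplicate record names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  mat <- do.call(rbind, chars)
  mat <- toupper(mat)
  mat[mat == "U"] <- "T"
  rownames(mat) <- nms
  structure(list(seqs = mat, names = nms, length = ncol(mat)),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("Alignment: ", length(x$names), " sequences x ", x$length,
      " columns\n", sep = "")
  invisible(x)
}

#' Match alignment records to tree tips
#'
#' Exact string matching between tip labels and record names. Every tree tip
#' must have a record; alignment-only extras are tolerated with a warning.
#'
#' @param aln an [read_alignment()] result.
#' @param tree a [dated_tree].
#' @return list with `matched` (labels present in both), `missing_tips`
#'   (always empty on success) and `extra_records`.
#' @export
match_alignment_to_tree <- function(aln, tree) {
  tips <- tree$phy$tip.label
  missing <- setdiff(tips, aln$names)
  if (length(missing) > 0L) {
    stop("tree tip(s) absent from the alignment: ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(aln$names, tips)
  if (length(extra) > 0L) {
    warning("alignment record(s) not in the tree (ignored): ",
            paste(extra, collapse = ", "))
  }
  list(matched = intersect(tips, aln$names), missing_tips = missing,
       extra_records = extra)
}

# IUPAC codes that never count as an observed state under the default rule.
.ambiguous_states <- c("N", "R", "Y", "S", "W", "K", "M",
                       "B", "D", "H", "V", "?")
.gap_states <- c("-", ".")

#' Variant columns of a sequence set
#'
#' A column is variant when it shows at least two distinct states among the
#' included records. By default only the unambiguous nucleotides A, C, G, T
#' count as states: gaps (`-`, `.`) and IUPAC ambiguity codes are ignored, so
#' missing data never creates spurious variation against a single real
#' state. With `gap_as_state = TRUE` the gap character counts as a fifth
#' state.
#'
#' @param seqs character matrix (records x columns, upper case) or an
#'   `alignment`.
#' @param gap_as_state treat `-` as an additional state (default `FALSE`).
#' @return sorted integer vector of 0-based column indices.
#' @export
variant_columns <- function(seqs, gap_as_state = FALSE) {
  mat <- if (inherits(seqs, "alignment")) seqs$seqs else seqs
  if (!is.matrix(mat)) stop("`seqs` must be a character matrix or alignment")
  if (nrow(mat) < 2L) stop("need at least 2 sequences")
  states <- c("A", "C", "G", "T", if (gap_as_state) "-")
  is_var <- vapply(seq_len(ncol(mat)), function(j) {
    length(unique(mat[mat[, j] %in% states, j])) >= 2L
  }, logical(1))
  which(is_var) - 1L
}

#' Extract a clade's variant-sites-only sub-alignment
#'
#' Implements the post-scan step of building a dataset suitable for
#' tip-dating a clade with temporal signal: takes the descendant tips of the
#' chosen node, restricts the alignment to those records, and keeps only the
#' columns that are variant *within that subset* (a column variant in the
#' full alignment but constant inside the clade is dropped). Writes the
#' FASTA (60-column lines, LF endings, records in the tree's left-to-right
#' tip order) plus a plain-text sidecar `<out-minus-extension>.sites.txt`
#' listing the kept columns as 1-based positions in the original alignment.
#'
#' @param aln an [read_alignment()] result covering all descendant tips.
#' @param tree a [dated_tree].
#' @param node_id preorder id of an internal node.
#' @param out output FASTA path; set `NULL` to skip writing.
#' @param gap_as_state passed to [variant_columns()].
#' @return invisibly, a `sub_alignment`: list with `records` (named character
#'   vector of subset sequences), `kept_columns` (0-based original indices)
#'   and `variant_rule` (human-readable description).
#' @export
make_subset_fasta <- function(aln, tree, node_id, out,
                              gap_as_state = FALSE) {
  stopifnot(inherits(aln, "alignment"), inherits(tree, "dated_tree"))
  if (!is_internal_id(tree, node_id)) {
    stop("node_id ", node_id, " is not an internal node")
  }
  tips <- descendant_tips(tree, node_id)   # tree left-to-right order
  present <- tips[tips %in% aln$names]
  if (length(present) < 2L) {
    stop("node ", node_id, " has ", length(present),
         " descendant tip(s) in the alignment; need at least 2")
  }
  sub <- aln$seqs[present, , drop = FALSE]
  keep <- variant_columns(sub, gap_as_state = gap_as_state)
  if (length(keep) == 0L) {
    warning("no variant sites among the ", length(present),
            " descendant sequences; writing empty-length records")
  }
  records <- stats::setNames(
    apply(sub[, keep + 1L, drop = FALSE], 1L, paste, collapse = ""),
    present)
  rule <- paste0(">=2 distinct states among {A,C,G,T",
                 if (gap_as_state) ",-", "}; gaps",
                 if (!gap_as_state) " and", " ambiguity codes ignored")
  if (!is.null(out)) {
    write_fasta(records, out)
    sidecar <- paste0(tools::file_path_sans_ext(out), ".sites.txt")
    write_lines_atomic(
      c(paste0("# variant rule: ", rule),
        "# kept columns, 1-based positions in the original alignment",
        as.character(keep + 1L)),
      sidecar)
  }
  invisible(structure(
    list(records = records, kept_columns = keep, variant_rule = rule),
    class = "sub_alignment"))
}

# 60-column FASTA writer, LF endings, atomic.
write_fasta <- function(records, path, width = 60L) {
  lines <- unlist(lapply(names(records), function(nm) {
    s <- records[[nm]]
    body <- if (nchar(s) == 0L) character(0)
            else substring(s, seq(1L, nchar(s), width),
                           pmin(seq(1L, nchar(s), width) + width - 1L,
                                nchar(s)))
    c(paste0(">", nm), body)
  }))
  write_lines_atomic(lines, path)
}
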