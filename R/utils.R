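#' @importFrom stats pt runif rnorm rgamma p.adjust setNames
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shortest round-trip decimal formatting
#'
#' Formats doubles with the fewest significant digits that still reproduce the
#' value exactly when re-parsed. Used for every numeric field the package
#' writes (branch lengths, dates, statistics) so that serialised output is
#' byte-stable and round-trips losslessly.
#'
#' @param x numeric vector.
#' @return character vector, `"NA"` for missing values.
#' @keywords internal
fmt_num <- function(x) {
  vapply(as.numeric(x), function(v) {
    if (is.na(v)) return("NA")
    if (!is.finite(v)) return(as.character(v))
    if (v == round(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

# Run code under a fixed RNG seed, restoring the caller's RNG state on exit.
# All stochastic entry points route through this so a single integer seed
# determines the output and no global state leaks.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Write lines to `path` atomically with LF endings: write to a temp file in
# the same directory, then rename. On any error nothing is left at `path`.
write_lines_atomic <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  tmp <- tempfile(pattern = ".tmp-", tmpdir = dir)
  con <- file(tmp, open = "wb")
  ok <- FALSE
  on.exit({
    try(close(con), silent = TRUE)
    if (!ok && file.exists(tmp)) unlink(tmp)
  }, add = TRUE)
  writeLines(lines, con, sep = "\n")
  close(con)
  if (!file.rename(tmp, path)) stop("cannot write to ", path)
  ok <- TRUE
  invisible(path)
}

# Nexus-safe label quoting (single quotes, doubled internal quotes).
quote_nexus <- function(x) {
  needs <- grepl("[^A-Za-z0-9_.|+-]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

# md5 of a canonical string, via a temp file (tools::md5sum is file-based).
md5_string <- function(s) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, open = "wb")
  writeLines(s, con, sep = "\n")
  close(con)
  unname(tools::md5sum(tmp))
}
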