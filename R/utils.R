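## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs \code{expr} with the random number generator seeded to \code{seed},
#' restoring the caller's RNG state afterwards. All stochastic operations in
#' the package go through this helper so that every result is a pure
#' function of its inputs and an explicit integer seed.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a stage-specific seed from a master seed; stays below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

#' Read a tab-separated table
#'
#' TSV dialect used throughout: tab separator, \code{#} comment lines,
#' UTF-8, header row required.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE,
             fileEncoding = "UTF-8")
}

#' Write a tab-separated table
#'
#' @param x data.frame.
#' @param path file path.
#' @return invisibly, \code{path}.
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

## Deterministic JSON sidecar writer (no timestamps; see run manifest docs).
write_json_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

## Quantile convention used for every quartile in the package: linear
## interpolation between order statistics (stats::quantile type 7).
quartiles <- function(x) {
  q <- quantile(x, probs = c(0.25, 0.75), names = FALSE, type = 7)
  list(Q1 = q[[1L]], Q3 = q[[2L]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
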