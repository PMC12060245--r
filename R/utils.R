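#' @keywords internal
"_PACKAGE"

#' @importFrom stats median mad rbinom rpois runif rnorm rnbinom setNames
#'   aov TukeyHSD t.test var ave
#' @importFrom utils write.table read.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code under a fixed RNG state and restore the caller's stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Derive a reproducible child seed; kept below 2^31 - 1.
child_seed <- function(seed, k) {
  (as.double(seed) * 1103L + as.double(k) * 12289L) %% 2147483629
}

## Deterministic TSV writers: fixed column order, no quoting surprises,
## '.' never used for NA so round-trips are exact.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA", fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             na.strings = "NA", check.names = FALSE, quote = "", comment.char = "", ...)
}

## Numeric formatter used in emitted files: enough digits to round-trip,
## locale-independent.
fmt_num <- function(x, digits = 6) {
  out <- formatC(x, format = "f", digits = digits, drop0trailing = TRUE)
  out[!is.finite(x)] <- "NA"
  out
}

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}
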