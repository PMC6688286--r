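#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
.msgf <- function(fmt, ...) message(sprintf(fmt, ...))

## Write a data.frame as TSV without quoting; NA as empty string for
## character columns is avoided on purpose: keep literal "NA" so round
## trips are lossless.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

read_tsv <- function(path, colClasses = NA) {
  utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                    colClasses = colClasses, check.names = FALSE,
                    na.strings = "NA")
}
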