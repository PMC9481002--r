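# internal helpers

abort_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(x, y) if (is.null(x)) y else x

# x * log(x / e) with the x -> 0 limit (contributes 0 for a zero cell)
xlogx_ratio <- function(x, e) {
  out <- numeric(length(x))
  nz <- x > 0
  out[nz] <- x[nz] * log(x[nz] / e[nz])
  out
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

write_tsv_file <- function(x, path, digits = NULL) {
  x <- as.data.frame(x)
  if (!is.null(digits)) {
    num <- vapply(x, is.numeric, logical(1))
    x[num] <- lapply(x[num], round, digits = digits)
  }
  write.table(x, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
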