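# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream. Every stochastic operation in the package funnels through
# this so runs are reproducible from recorded seeds alone.
with_seed <- function(seed, expr) {
  if (is.null(seed) || !is.finite(seed))
    stop("an explicit integer 'seed' is required for stochastic operations",
         call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Delimiter by extension, overridable.
infer_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_delim_table <- function(path, sep = NULL) {
  utils::read.table(path, header = TRUE, sep = infer_sep(path, sep),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "\"", comment.char = "", fileEncoding = "UTF-8")
}

write_delim_table <- function(x, path, sep = NULL) {
  utils::write.table(x, path, sep = infer_sep(path, sep), quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Format numbers for delimited output so that decimal inputs of modest
# precision survive a write/read round trip exactly.
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else format(v, digits = 15, scientific = FALSE)
  }, character(1))
  out
}
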