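# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "simdex_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

assert_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(trimws(x))) {
    stopf("simdex_usage_error", "%s must be a non-empty string", what)
  }
  invisible(x)
}

# case-insensitive, whitespace-normalized folding used for all term matching
fold_term <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

is_flag_true <- function(x) {
  tolower(trimws(as.character(x))) %in% c("true", "t", "yes", "1")
}

# deterministic identifier from content (simple polynomial rolling hash), so
# fixtures and assembly give reproducible ids without supplying them
content_id <- function(..., prefix = "id") {
  txt <- paste(unlist(list(...)), collapse = "\x1f")
  bytes <- utf8ToInt(txt)
  h <- 7
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%s-%08x", prefix, as.integer(h))
}

read_simdex_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character", fileEncoding = "UTF-8")
}
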