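#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Stable 31-polynomial string hash modulo 2^31 - 1. Intermediate values stay
# below 2^53 so the arithmetic is exact in doubles.
str_hash <- function(x) {
  h <- 0
  for (c in utf8ToInt(x)) h <- (h * 31 + c) %% 2147483647
  h
}

#' Derive a reproducible child seed from a master seed and a label
#'
#' Any experiment cell can be re-run in isolation: its seed is a pure
#' function of the master seed and the cell's coordinate string.
#'
#' @param master_seed Integer master seed.
#' @param label Character label identifying the consumer (e.g. an
#'   experiment-cell coordinate string).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, label) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  as.integer((str_hash(label) + (master_seed %% 2147483647) * 7919) %% 2147483647)
}

# Detect comma vs tab delimiter from the header line of a delimited file.
detect_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) abort(paste0("empty file: ", path))
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

read_delim_table <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- delim %||% detect_delim(path)
  readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                    progress = FALSE, show_col_types = FALSE, trim_ws = TRUE)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0("format error in ", path, ": missing column(s) ",
                 paste(missing, collapse = ", ")))
  }
}
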