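# Hierarchical aggregation of mono-hierarchical diagnosis (ICD-10-GM-like)
# and procedure (OPS-like) codes. Category level is the third hierarchy level
# (L40, 5-12) and is purely syntactic; block level is the second level, a
# labeled inclusive range of categories (L40…L45, 5-08…5-16) supplied by a
# block map because ranges are catalogue content, not syntax.

BLOCK_SEP <- "…"  # the ellipsis used to render block range keys

#' Aggregation levels
#' @return Character vector of the three supported aggregation levels.
#' @export
aggregation_levels <- function() c("none", "category", "block")

is_block_key <- function(code) grepl(BLOCK_SEP, code, fixed = TRUE)

#' Reduce a code to its category (third hierarchy level)
#'
#' Diagnosis codes are truncated to their first three characters (letter plus
#' two digits, e.g. `L40.4` to `L40`); procedure codes to their first four
#' (chapter digit, hyphen, two digits, e.g. `5-121.1` to `5-12`). Codes
#' already at category level or above (chapter letters/digits, block range
#' keys) are returned unchanged, making the operation idempotent.
#'
#' @param code Character vector of normalized codes.
#' @param system `"diagnosis"` or `"procedure"` (scalar, recycled).
#' @return Character vector of category-level codes.
#' @export
category_of <- function(code, system) {
  system <- match.arg(system, CODE_SYSTEMS)
  out <- character(length(code))
  for (i in seq_along(code)) {
    x <- code[i]
    if (is_block_key(x)) { out[i] <- x; next }
    if (system == "diagnosis") {
      if (grepl("^[A-Z][0-9]{2}", x)) out[i] <- substr(x, 1, 3)
      else if (grepl("^[A-Z]$", x)) out[i] <- x  # chapter level
      else abort(paste0("cannot map diagnosis code '", x, "' to category level"))
    } else {
      if (grepl("^[0-9]-[0-9]{2}", x)) out[i] <- substr(x, 1, 4)
      else if (grepl("^[0-9]-?$", x)) out[i] <- x  # chapter level
      else abort(paste0("cannot map procedure code '", x, "' to category level"))
    }
  }
  out
}

# Total order on category codes within a system, as an integer key:
# diagnosis L40 -> position('L')*100 + 40; procedure 5-12 -> 5*100 + 12.
# Plain lexicographic comparison would fail for mixed-width numerics.
category_key <- function(category, system) {
  if (system == "diagnosis") {
    ok <- grepl("^[A-Z][0-9]{2}$", category)
    if (any(!ok)) abort(paste0("not a diagnosis category code: ", category[!ok][1]))
    match(substr(category, 1, 1), LETTERS) * 100L +
      as.integer(substr(category, 2, 3))
  } else {
    ok <- grepl("^[0-9]-[0-9]{2}$", category)
    if (any(!ok)) abort(paste0("not a procedure category code: ", category[!ok][1]))
    as.integer(substr(category, 1, 1)) * 100L +
      as.integer(substr(category, 3, 4))
  }
}

#' Construct a block map
#'
#' @param df Data frame with columns `system`, `range_start`, `range_end`,
#'   `label`; `range_start`/`range_end` are category-level codes and ranges
#'   are inclusive. Within a system, ranges must be ordered
#'   (`range_start <= range_end`) and non-overlapping.
#' @return A tibble of class `ctrss_block_map` with an additional `block`
#'   column holding the rendered range key (`"L40…L45"`).
#' @export
block_map <- function(df) {
  df <- as_tibble(df)
  require_columns(df, c("system", "range_start", "range_end", "label"), "block map")
  df <- df |>
    mutate(system = tolower(trimws(.data$system)),
           range_start = normalize_code(.data$range_start),
           range_end = normalize_code(.data$range_end))
  if (any(!df$system %in% CODE_SYSTEMS)) {
    abort("block map: system must be 'diagnosis' or 'procedure'")
  }
  for (sys in unique(df$system)) {
    sub <- df[df$system == sys, ]
    lo <- category_key(sub$range_start, sys)
    hi <- category_key(sub$range_end, sys)
    bad <- which(lo > hi)
    if (length(bad) > 0) {
      abort(paste0("block map: range start after end: ", sub$range_start[bad[1]],
                   BLOCK_SEP, sub$range_end[bad[1]]))
    }
    ord <- order(lo)
    lo <- lo[ord]; hi <- hi[ord]; sub <- sub[ord, ]
    if (nrow(sub) > 1) {
      ov <- which(lo[-1] <= hi[-nrow(sub)])
      if (length(ov) > 0) {
        i <- ov[1]
        abort(paste0("block map: overlapping ranges in system ", sys, ": ",
                     sub$range_start[i], BLOCK_SEP, sub$range_end[i], " and ",
                     sub$range_start[i + 1], BLOCK_SEP, sub$range_end[i + 1]))
      }
    }
  }
  df$block <- paste0(df$range_start, BLOCK_SEP, df$range_end)
  class(df) <- c("ctrss_block_map", class(df))
  df
}

#' Load a block map from a delimited file
#'
#' @param path Delimited text with columns `system`, `range_start`,
#'   `range_end`, `label`.
#' @param delim Optional delimiter.
#' @return A `ctrss_block_map`.
#' @export
load_block_map <- function(path, delim = NULL) {
  block_map(read_delim_table(path, delim))
}

#' Write a block map to a delimited file
#' @param map A `ctrss_block_map`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_block_map <- function(map, path) {
  readr::write_csv(map[, c("system", "range_start", "range_end", "label")], path)
  invisible(path)
}

#' Reduce a code to its block (second hierarchy level)
#'
#' The code is first reduced to category level, then matched against the
#' system's inclusive block ranges. The returned key renders the range as
#' `"start…end"` (e.g. `L40.4` with a map containing (L40, L45) yields
#' `"L40…L45"`). Codes whose category falls in no range fall back to their
#' category code with a warning — the alternative, dropping them, would break
#' the guarantee that aggregation only coarsens the attribute set. With
#' `strict = TRUE` an unmapped code is an error instead.
#'
#' @param code Character vector of normalized codes.
#' @param system `"diagnosis"` or `"procedure"`.
#' @param map A `ctrss_block_map`.
#' @param strict Error on unmapped codes instead of falling back to category.
#' @return Character vector of block keys (or fallback category codes).
#' @export
block_of <- function(code, system, map, strict = FALSE) {
  system <- match.arg(system, CODE_SYSTEMS)
  stopifnot(inherits(map, "ctrss_block_map"))
  cats <- category_of(code, system)
  sub <- map[map$system == system, ]
  out <- character(length(code))
  chapter_like <- !grepl(if (system == "diagnosis") "^[A-Z][0-9]{2}$" else "^[0-9]-[0-9]{2}$",
                         cats)
  mappable <- !chapter_like
  if (any(mappable)) {
    key <- category_key(cats[mappable], system)
    if (nrow(sub) > 0) {
      lo <- category_key(sub$range_start, system)
      hi <- category_key(sub$range_end, system)
      idx <- vapply(key, function(k) {
        j <- which(lo <= k & k <= hi)
        if (length(j) == 0L) NA_integer_ else j[1]
      }, integer(1))
    } else {
      idx <- rep(NA_integer_, length(key))
    }
    hit <- !is.na(idx)
    res <- character(length(key))
    res[hit] <- sub$block[idx[hit]]
    res[!hit] <- cats[mappable][!hit]
    out[mappable] <- res
    if (any(!hit)) {
      unmapped <- unique(cats[mappable][!hit])
      if (strict) {
        abort(paste0("no block range covers ", system, " categor",
                     if (length(unmapped) > 1) "ies: " else "y: ",
                     paste(utils::head(unmapped, 5), collapse = ", ")))
      }
      warn(paste0("unmapped ", system, " categories fall back to category level: ",
                  paste(utils::head(unmapped, 5), collapse = ", ")))
    }
  }
  out[chapter_like] <- cats[chapter_like]  # already above category level
  out
}

#' Aggregate a code to a given hierarchy level
#'
#' Dispatch helper over [category_of()] and [block_of()].
#'
#' @param code Character vector of normalized codes.
#' @param system `"diagnosis"` or `"procedure"`.
#' @param level One of `"none"`, `"category"`, `"block"`.
#' @param map Block map, required for `level = "block"`.
#' @param strict Passed to [block_of()].
#' @return Character vector of aggregated codes.
#' @export
aggregate_code <- function(code, system, level, map = NULL, strict = FALSE) {
  level <- match.arg(level, aggregation_levels())
  switch(level,
         none = code,
         category = category_of(code, system),
         block = {
           if (is.null(map)) abort("block-level aggregation requires a block map")
           block_of(code, system, map, strict = strict)
         })
}
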