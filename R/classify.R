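#' Read completeness classes
#'
#' Single-molecule cDNA reads are classified by which transcript ends they
#' capture. A read carrying the 5' primer, the 3' primer and a polyA tail
#' represents its transcript end to end (`FULL_LENGTH`). A read with exactly
#' one primer anchors one transcript end (`NFL_5ONLY` / `NFL_3ONLY`, the
#' "non-full-length boundary reads"); a read with neither primer carries no
#' boundary information and is treated like a short read (`NFL_INTERNAL`).
#'
#' @format Character vector of the four class labels, in display order.
#' @export
READ_CLASSES <- c("FULL_LENGTH", "NFL_5ONLY", "NFL_3ONLY", "NFL_INTERNAL")

#' Classify reads from primer/polyA detection flags
#'
#' Maps the three per-read detection flags to a completeness class:
#'
#' | has_5p | has_3p | has_polyA | class         |
#' |--------|--------|-----------|---------------|
#' | 1      | 1      | 1         | FULL_LENGTH   |
#' | 1      | 1      | 0         | NFL_5ONLY     |
#' | 1      | 0      | any       | NFL_5ONLY     |
#' | 0      | 1      | any       | NFL_3ONLY     |
#' | 0      | 0      | any       | NFL_INTERNAL  |
#'
#' A read with both primers but no polyA tail is not full length; its 3' end
#' is untrusted without the polyA signal, so only the 5' boundary is kept.
#'
#' @param has_5p,has_3p,has_polyA Logical (or 0/1) vectors, recycled together.
#' @return Character vector of class labels (see [READ_CLASSES]).
#' @export
#' @examples
#' classify_flags(1, 1, 1) # FULL_LENGTH
#' classify_flags(0, 1, 1) # NFL_3ONLY
classify_flags <- function(has_5p, has_3p, has_polyA) {
  has_5p <- as.logical(has_5p)
  has_3p <- as.logical(has_3p)
  has_polyA <- as.logical(has_polyA)
  if (anyNA(has_5p) || anyNA(has_3p) || anyNA(has_polyA)) {
    abort("classification flags must be 0/1 or TRUE/FALSE without NAs")
  }
  case_when(
    has_5p & has_3p & has_polyA ~ "FULL_LENGTH",
    has_5p ~ "NFL_5ONLY",
    has_3p ~ "NFL_3ONLY",
    TRUE ~ "NFL_INTERNAL"
  )
}

#' Parse a read-classification table
#'
#' Reads the TSV produced by a primer/polyA classifier (columns `read_id`,
#' `has_5p`, `has_3p`, `has_polyA`) and assigns each read its completeness
#' class. Consistent duplicate rows are collapsed; duplicates with conflicting
#' flags are an error naming the offending read.
#'
#' @param table_source Path to a TSV file (header required) or a data frame
#'   with the four columns.
#' @return A tibble with columns `read_id`, `read_class`.
#' @export
parse_classification <- function(table_source) {
  if (is.character(table_source) && length(table_source) == 1L) {
    tab <- readr::read_tsv(table_source, show_col_types = FALSE,
                           progress = FALSE)
  } else if (is.data.frame(table_source)) {
    tab <- as_tibble(table_source)
  } else {
    abort("`table_source` must be a file path or a data frame")
  }
  required <- c("read_id", "has_5p", "has_3p", "has_polyA")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    abort(paste0("classification table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tab <- distinct(tab, .data$read_id, .data$has_5p, .data$has_3p,
                  .data$has_polyA)
  dup <- tab$read_id[duplicated(tab$read_id)]
  if (length(dup)) {
    abort(paste0("conflicting classification flags for read(s): ",
                 paste(unique(dup), collapse = ", ")))
  }
  tibble(
    read_id = as.character(tab$read_id),
    read_class = classify_flags(tab$has_5p, tab$has_3p, tab$has_polyA)
  )
}

#' Convert classifier FASTA headers to classification flags
#'
#' Convenience for headers of the form
#' `"<name> fiveseen=1;polyAseen=1;threeseen=1;..."` as emitted by the
#' Iso-Seq-style classification step. The TSV contract of
#' [parse_classification()] remains the supported input; this is a helper
#' for producing it.
#'
#' @param headers Character vector of FASTA header lines (without `>`).
#' @return A tibble with columns `read_id`, `has_5p`, `has_3p`, `has_polyA`.
#' @export
parse_isoseq_headers <- function(headers) {
  grab <- function(key) {
    hit <- stringr::str_match(headers, paste0(key, "=([01])"))[, 2]
    ifelse(is.na(hit), 0L, as.integer(hit))
  }
  tibble(
    read_id = stringr::str_split_fixed(headers, "\\s+", 2)[, 1],
    has_5p = grab("fiveseen"),
    has_3p = grab("threeseen"),
    has_polyA = grab("polyAseen")
  )
}
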