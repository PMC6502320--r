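#' Capture-history contingency table for two sources
#'
#' A two-source capture history reduces to three observed counts: cases seen
#' by both sources (`m`), by source A only (`a_only`), and by source B only
#' (`b_only`). The never-observed cell is what capture-recapture estimates.
#'
#' @param m count captured by both sources.
#' @param a_only count captured by source A only.
#' @param b_only count captured by source B only.
#' @param label stratum identifier, `"overall"` by default.
#' @return an object of class `contingency_table` with derived totals
#'   `n1 = m + a_only` (source A list size), `n2 = m + b_only` (source B
#'   list size) and `union = m + a_only + b_only`.
#' @examples
#' contingency_table(856, 2968, 1738)
#' @export
contingency_table <- function(m, a_only, b_only, label = "overall") {
  counts <- c(m = m, a_only = a_only, b_only = b_only)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("contingency counts must be non-negative integers")
  structure(
    list(m = as.numeric(m), a_only = as.numeric(a_only),
         b_only = as.numeric(b_only),
         n1 = as.numeric(m + a_only), n2 = as.numeric(m + b_only),
         union = as.numeric(m + a_only + b_only),
         label = as.character(label)),
    class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("Capture-history table [%s]\n", x$label))
  cat(sprintf("  both: %d   A only: %d   B only: %d\n",
              as.integer(x$m), as.integer(x$a_only), as.integer(x$b_only)))
  cat(sprintf("  n1 = %d, n2 = %d, union = %d\n",
              as.integer(x$n1), as.integer(x$n2), as.integer(x$union)))
  invisible(x)
}

#' @export
as.data.frame.contingency_table <- function(x, ...) {
  data.frame(label = x$label, m = x$m, a_only = x$a_only, b_only = x$b_only,
             n1 = x$n1, n2 = x$n2, union = x$union,
             stringsAsFactors = FALSE)
}

#' Total number of observed cases
#'
#' @param t a [contingency_table()].
#' @return `m + a_only + b_only`, the number of distinct cases seen by at
#'   least one source.
#' @export
union_count <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  t$union
}

#' Proportion of cases common to both sources
#'
#' @param t a [contingency_table()].
#' @param as_percent if `TRUE`, return a percentage rounded half-up to one
#'   decimal (the conventional reporting form); otherwise the raw fraction.
#' @return overlap `m / union` as fraction or percentage.
#' @export
overlap_proportion <- function(t, as_percent = FALSE) {
  stopifnot(inherits(t, "contingency_table"))
  if (t$union == 0)
    stop("overlap proportion undefined for an empty table")
  frac <- t$m / t$union
  if (as_percent) round_half_up(100 * frac, 1) else frac
}

#' Cell-wise sum of stratum tables
#'
#' @param tables list of [contingency_table()] objects.
#' @param label label for the pooled table.
#' @return a single `contingency_table` with summed cells.
#' @export
pool_tables <- function(tables, label = "overall") {
  stopifnot(length(tables) >= 1,
            all(vapply(tables, inherits, TRUE, "contingency_table")))
  contingency_table(sum(vapply(tables, `[[`, 0, "m")),
                    sum(vapply(tables, `[[`, 0, "a_only")),
                    sum(vapply(tables, `[[`, 0, "b_only")),
                    label = label)
}

#' Write contingency tables to JSON or CSV
#'
#' @param tables a `contingency_table` or list of them.
#' @param path output path; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_tables <- function(tables, path) {
  if (inherits(tables, "contingency_table")) tables <- list(tables)
  df <- do.call(rbind, lapply(tables, as.data.frame))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read contingency tables written by [write_tables()]
#'
#' @param path JSON or CSV file with columns `label,m,a_only,b_only`.
#' @return list of `contingency_table` objects.
#' @export
read_tables <- function(path) {
  df <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i)
    contingency_table(df$m[i], df$a_only[i], df$b_only[i], df$label[i]))
}
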