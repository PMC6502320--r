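#' Build a validated case-record data frame
#'
#' A case record is one surveillance report: an opaque person key, the
#' person's age in completed years at first capture, and gender. Both case
#' lists of a two-source study use the same layout.
#'
#' @param person_id character vector of non-empty person keys.
#' @param age integer ages in years, in \[0, 130\]; `NA` allowed (such
#'   records are dropped, with a warning, at stratification).
#' @param gender `"F"` or `"M"` (or `NA`).
#' @return a `data.frame` with columns `person_id`, `age`, `gender`.
#' @export
case_records <- function(person_id, age, gender) {
  person_id <- as.character(person_id)
  age <- as.integer(age)
  gender <- as.character(gender)
  df <- data.frame(person_id = person_id, age = age, gender = gender,
                   stringsAsFactors = FALSE)
  validate_case_records(df)
}

validate_case_records <- function(df) {
  need <- c("person_id", "age", "gender")
  if (!all(need %in% names(df)))
    stop("case list must have columns person_id, age, gender")
  df$person_id <- as.character(df$person_id)
  df$age <- as.integer(df$age)
  df$gender <- as.character(df$gender)
  if (any(is.na(df$person_id) | !nzchar(df$person_id)))
    stop("person_id must be non-empty")
  bad_age <- !is.na(df$age) & (df$age < 0 | df$age > 130)
  if (any(bad_age))
    stop(sprintf("%d record(s) with age outside [0, 130]", sum(bad_age)))
  bad_g <- !is.na(df$gender) & !df$gender %in% c("F", "M")
  if (any(bad_g))
    stop("gender must be coded F or M")
  df[, need]
}

#' Read one surveillance case list from CSV
#'
#' Expects a UTF-8 CSV with header `person_id,age,gender`, gender coded F/M.
#'
#' @param path CSV file path.
#' @return validated case-record data frame.
#' @export
read_case_list <- function(path) {
  if (!file.exists(path)) stop("case list file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(person_id = "character"))
  if (nrow(df) == 0 && !all(c("person_id", "age", "gender") %in% names(df)))
    stop("empty or malformed case list: ", path)
  validate_case_records(df)
}

#' Collapse repeat reports of the same person within one source
#'
#' Each person counts once per source regardless of how many visits or
#' claims generated records. Demographics are taken from the first
#' occurrence. Repeat records whose age differs by more than one year, or
#' whose gender differs, are flagged: a person's reports should agree.
#'
#' @param records case-record data frame from a single source.
#' @param strict if `TRUE`, conflicting duplicates raise an error instead of
#'   a warning.
#' @return deduplicated data frame, with attribute `n_removed` giving the
#'   number of duplicate records dropped.
#' @export
dedupe_cases <- function(records, strict = FALSE) {
  records <- validate_case_records(records)
  if (nrow(records) == 0) {
    attr(records, "n_removed") <- 0L
    return(records)
  }
  dup <- duplicated(records$person_id)
  if (any(dup)) {
    first <- records[!dup, , drop = FALSE]
    rownames(first) <- NULL
    idx <- match(records$person_id[dup], first$person_id)
    age_conflict <- !is.na(records$age[dup]) & !is.na(first$age[idx]) &
      abs(records$age[dup] - first$age[idx]) > 1
    gender_conflict <- !is.na(records$gender[dup]) &
      !is.na(first$gender[idx]) &
      records$gender[dup] != first$gender[idx]
    n_conflict <- sum(age_conflict | gender_conflict)
    if (n_conflict > 0) {
      msg <- sprintf(
        "%d duplicate record(s) conflict on age (>1 y) or gender", n_conflict)
      if (strict) stop(msg) else warning(msg)
    }
    out <- first
  } else {
    out <- records
    rownames(out) <- NULL
  }
  attr(out, "n_removed") <- sum(dup)
  out
}

#' Link two deduplicated case lists on the person key
#'
#' Exact-key linkage: a person appearing in both lists (same `person_id`)
#' is a recapture. Produces the overall capture-history table.
#'
#' @param a,b deduplicated case-record data frames for sources A and B.
#' @param label label for the resulting table.
#' @return a [contingency_table()].
#' @examples
#' a <- case_records(paste0("p", 1:5), 80, "F")
#' b <- case_records(paste0("p", 4:7), 80, "F")
#' link_sources(a, b) # m = 2, a_only = 3, b_only = 2
#' @export
link_sources <- function(a, b, label = "overall") {
  a <- validate_case_records(a)
  b <- validate_case_records(b)
  if (anyDuplicated(a$person_id) || anyDuplicated(b$person_id))
    stop("lists must be deduplicated before linkage; see dedupe_cases()")
  m <- sum(a$person_id %in% b$person_id)
  contingency_table(m, nrow(a) - m, nrow(b) - m, label = label)
}

#' Stratification scheme: age classes crossed with gender
#'
#' The default mirrors the covariate structure used for inhomogeneous
#' catchability in elderly-disease surveillance: three age classes
#' (at or below 84, 85 to 89, 90 and over) crossed with gender.
#'
#' @param age_breaks upper bounds of all but the last age class (default
#'   `c(84, 89)`, giving classes `<=84`, `85-89`, `>=90`).
#' @param use_gender cross the age classes with gender?
#' @return an object of class `stratum_scheme`.
#' @export
stratum_scheme <- function(age_breaks = c(84, 89), use_gender = TRUE) {
  stopifnot(length(age_breaks) >= 1, !is.unsorted(age_breaks))
  labs <- character(length(age_breaks) + 1)
  labs[1] <- sprintf("<=%d", age_breaks[1])
  if (length(age_breaks) > 1)
    for (i in 2:length(age_breaks))
      labs[i] <- sprintf("%d-%d", age_breaks[i - 1] + 1, age_breaks[i])
  labs[length(labs)] <- sprintf(">=%d", age_breaks[length(age_breaks)] + 1)
  structure(list(age_breaks = age_breaks, age_labels = labs,
                 use_gender = isTRUE(use_gender)),
            class = "stratum_scheme")
}

#' Age class index under a stratification scheme
#'
#' @param age integer ages.
#' @param scheme a [stratum_scheme()].
#' @return integer class index (1-based); `NA` for missing ages.
#' @export
age_class <- function(age, scheme = stratum_scheme()) {
  findInterval(age, scheme$age_breaks + 1L) + 1L
}

stratum_labels <- function(scheme) {
  if (scheme$use_gender)
    as.vector(outer(scheme$age_labels, c("F", "M"),
                    function(a, g) paste(a, g, sep = ".")))
  else scheme$age_labels
}

stratum_of <- function(age, gender, scheme) {
  k <- age_class(age, scheme)
  lab <- scheme$age_labels[k]
  if (scheme$use_gender) ifelse(is.na(lab) | is.na(gender), NA,
                                paste(lab, gender, sep = ".")) else lab
}

#' Stratified capture-history tables
#'
#' Links the two lists, resolves each linked person's demographics, assigns
#' every observed person to a stratum, and counts capture histories per
#' stratum. For persons in both lists whose recorded demographics differ
#' across sources, one source's values win (`prefer`); administrative
#' insurance records usually carry verified civil-status data, so source A
#' is the default.
#'
#' @param a,b deduplicated case-record data frames.
#' @param scheme a [stratum_scheme()].
#' @param prefer which source's demographics win on cross-source conflict.
#' @param strict if `TRUE`, records with missing age or gender raise an
#'   error; by default they are excluded with a warning.
#' @return named list of [contingency_table()] objects, one per stratum
#'   (empty strata included), with attribute `n_excluded`.
#' @export
stratify_sources <- function(a, b, scheme = stratum_scheme(),
                             prefer = c("A", "B"), strict = FALSE) {
  prefer <- match.arg(prefer)
  a <- validate_case_records(a)
  b <- validate_case_records(b)
  if (anyDuplicated(a$person_id) || anyDuplicated(b$person_id))
    stop("lists must be deduplicated before stratification")
  ids <- union(a$person_id, b$person_id)
  ia <- match(ids, a$person_id)
  ib <- match(ids, b$person_id)
  in_a <- !is.na(ia)
  in_b <- !is.na(ib)
  pick <- function(col) {
    va <- rep(NA, length(ids)); vb <- rep(NA, length(ids))
    va[in_a] <- a[[col]][ia[in_a]]
    vb[in_b] <- b[[col]][ib[in_b]]
    if (prefer == "A") ifelse(in_a, va, vb) else ifelse(in_b, vb, va)
  }
  age <- pick("age")
  gender <- pick("gender")
  missing_demo <- is.na(age) | (scheme$use_gender & is.na(gender))
  if (any(missing_demo)) {
    msg <- sprintf("%d record(s) excluded for missing age/gender",
                   sum(missing_demo))
    if (strict) stop(msg) else warning(msg)
  }
  keep <- !missing_demo
  strat <- stratum_of(age[keep], gender[keep], scheme)
  pattern <- ifelse(in_a[keep] & in_b[keep], "m",
                    ifelse(in_a[keep], "a_only", "b_only"))
  labs <- stratum_labels(scheme)
  tables <- lapply(labs, function(s) {
    sel <- strat == s
    contingency_table(sum(sel & pattern == "m"),
                      sum(sel & pattern == "a_only"),
                      sum(sel & pattern == "b_only"),
                      label = s)
  })
  names(tables) <- labs
  attr(tables, "n_excluded") <- sum(missing_demo)
  tables
}
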