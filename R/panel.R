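#' Longitudinal arrest-count panels
#'
#' An `arrest_panel` is a long-format data frame with one row per person and
#' integer age, carrying a nonnegative arrest count and (optionally)
#' per-offense-category counts.  Persons belong to birth cohorts that may be
#' observed over different age windows (an unbalanced, accelerated
#' longitudinal design).  Each person's observation window is the inclusive
#' range `[min observed age, max observed age]`; by default every in-window
#' age must have a row (dense emission), because the mixture likelihood
#' treats every in-window age as observed.
#'
#' Offense-category counts (`n_drugs`, `n_violence`, `n_property`,
#' `n_other`) count an arrest once per charge category it carries, so the
#' categories need not sum to the total count, but each category count is
#' bounded by the total at that age.
#'
#' @param df data frame with columns `person_id`, `cohort`, `age`, `count`
#'   and optionally `n_drugs`, `n_violence`, `n_property`, `n_other`,
#'   `n_drug_only`.
#' @param dense require a row for every in-window age (default `TRUE`).
#' @return validated `arrest_panel` (a data frame).
#' @export
as_panel <- function(df, dense = TRUE) {
  required <- c("person_id", "cohort", "age", "count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop_arg("panel is missing required column(s): ",
             paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$person_id <- as.character(df$person_id)
  df$cohort <- as.character(df$cohort)

  if (nrow(df) > 0L) {
    if (any(!is.finite(df$age)) || any(df$age != as.integer(df$age)))
      stop_arg("ages must be finite integers")
    df$age <- as.integer(df$age)
    bad <- which(!is.finite(df$count) | df$count < 0 |
                   df$count != as.integer(df$count))
    if (length(bad) > 0L)
      stop_arg("invalid count (negative or non-integer) at row(s): ",
               paste(utils::head(bad, 5L), collapse = ", "))
    df$count <- as.integer(df$count)

    key <- paste(df$person_id, df$age, sep = "\r")
    if (anyDuplicated(key))
      stop_arg("duplicate (person_id, age) at row(s): ",
               paste(utils::head(which(duplicated(key)), 5L), collapse = ", "))

    for (cc in intersect(charge_columns(), names(df))) {
      bad <- which(!is.finite(df[[cc]]) | df[[cc]] < 0 |
                     df[[cc]] != as.integer(df[[cc]]) | df[[cc]] > df$count)
      if (length(bad) > 0L)
        stop_arg("invalid ", cc, " (negative, non-integer or exceeding the ",
                 "age's total count) at row(s): ",
                 paste(utils::head(bad, 5L), collapse = ", "))
      df[[cc]] <- as.integer(df[[cc]])
    }

    n_labels <- tapply(df$cohort, df$person_id,
                       function(x) length(unique(x)))
    if (any(n_labels > 1L))
      stop_arg("a person must carry a single cohort label")

    df <- df[order(df$person_id, df$age), , drop = FALSE]
    rownames(df) <- NULL

    if (dense) {
      span <- tapply(df$age, df$person_id, function(a) diff(range(a)) + 1L)
      nobs <- tapply(df$age, df$person_id, length)
      gap <- names(span)[span != nobs]
      if (length(gap) > 0L)
        stop_arg("persons with missing in-window ages (set dense = FALSE to ",
                 "allow gaps): ", paste(utils::head(gap, 5L), collapse = ", "))
    }
  }
  class(df) <- c("arrest_panel", "data.frame")
  df
}

charge_columns <- function() {
  c("n_drugs", "n_violence", "n_property", "n_other", "n_drug_only")
}

#' Read an arrest panel from CSV
#'
#' @param path CSV file path.
#' @param schema optional named character vector mapping canonical column
#'   names (`person_id`, `cohort`, `age`, `count`, ...) to the file's column
#'   names, e.g. `c(person_id = "id", count = "arrests")`.
#' @param dense passed to [as_panel()].
#' @return an `arrest_panel`.
#' @export
read_panel <- function(path, schema = NULL, dense = TRUE) {
  if (!file.exists(path)) stop_arg("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df))
        stop_arg("schema maps '", canon, "' to missing column '", src, "'")
      names(df)[names(df) == src] <- canon
    }
  }
  if (!"cohort" %in% names(df)) df$cohort <- "all"
  as_panel(df, dense = dense)
}

#' Write an arrest panel to CSV
#'
#' Columns are emitted in a stable order (`person_id`, `cohort`, `age`,
#' `count`, then any offense-category columns) with integer counts, so that
#' `read_panel(write_panel(p))` reproduces `p` and a second write is
#' byte-identical.
#'
#' @param panel an `arrest_panel`.
#' @param path output file path.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "arrest_panel"))
  cols <- c("person_id", "cohort", "age", "count",
            intersect(charge_columns(), names(panel)))
  utils::write.csv(as.data.frame(panel)[, cols, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a panel to an age range
#'
#' Drops records outside `[min_age, max_age]`, clipping observation windows;
#' persons left with no records are dropped (their number is reported via a
#' message).  Used e.g. to truncate analysis at a maximum common-support age.
#'
#' @param panel an `arrest_panel`.
#' @param min_age,max_age inclusive bounds.
#' @return the restricted `arrest_panel`.
#' @export
restrict_ages <- function(panel, min_age, max_age) {
  stopifnot(inherits(panel, "arrest_panel"))
  if (min_age > max_age) stop_arg("min_age must be <= max_age")
  keep <- panel$age >= min_age & panel$age <= max_age
  out <- panel[keep, , drop = FALSE]
  dropped <- setdiff(unique(panel$person_id), unique(out$person_id))
  if (length(dropped) > 0L)
    message("restrict_ages: dropped ", length(dropped),
            " person(s) with no records in [", min_age, ", ", max_age, "]")
  rownames(out) <- NULL
  class(out) <- c("arrest_panel", "data.frame")
  out
}

#' Per-person observation windows
#'
#' @param panel an `arrest_panel`.
#' @return data frame with `person_id`, `cohort`, `min_age`, `max_age`.
#' @export
panel_windows <- function(panel) {
  stopifnot(inherits(panel, "arrest_panel"))
  sp <- split(panel$age, panel$person_id)
  ids <- names(sp)
  coh <- panel$cohort[match(ids, panel$person_id)]
  data.frame(person_id = ids, cohort = coh,
             min_age = vapply(sp, min, integer(1L)),
             max_age = vapply(sp, max, integer(1L)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Relabel cohorts
#'
#' Collapses or renames cohort labels, e.g. mapping several birth cohorts
#' into "younger"/"older" analysis cohorts.
#'
#' @param panel an `arrest_panel`.
#' @param mapping named character vector, `old label -> new label`.  Labels
#'   absent from the mapping are kept as-is.
#' @export
map_cohorts <- function(panel, mapping) {
  stopifnot(inherits(panel, "arrest_panel"))
  hit <- panel$cohort %in% names(mapping)
  panel$cohort[hit] <- unname(mapping[panel$cohort[hit]])
  panel
}

#' Drop arrests that carried only drug charges
#'
#' Sensitivity filter: removes from each age's total count the arrests whose
#' only charge category was drugs, prior to refitting.  Requires the
#' `n_drug_only` column (emitted by the synthetic generator; not derivable
#' from the non-exclusive category counts alone).
#'
#' @param panel an `arrest_panel` with an `n_drug_only` column.
#' @export
drop_drug_only <- function(panel) {
  stopifnot(inherits(panel, "arrest_panel"))
  if (!"n_drug_only" %in% names(panel))
    stop_arg("drop_drug_only needs an 'n_drug_only' column")
  panel$count <- panel$count - panel$n_drug_only
  if ("n_drugs" %in% names(panel))
    panel$n_drugs <- pmax(0L, panel$n_drugs - panel$n_drug_only)
  panel$n_drug_only <- 0L
  panel
}

#' @export
print.arrest_panel <- function(x, ...) {
  w <- panel_windows(x)
  cat("<arrest_panel> ", nrow(w), " persons, ", nrow(x), " person-age rows, ",
      sum(x$count), " arrests\n", sep = "")
  tab <- table(w$cohort)
  cat("  cohorts: ",
      paste(names(tab), " (n=", as.integer(tab), ")", sep = "", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
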