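#' Within-group arrest-rate table
#'
#' Mean arrests per person over a fixed age window, by assigned trajectory
#' group and cohort (optionally per offense category).  Only persons whose
#' observation window covers the full requested window enter; others are
#' excluded with a logged count (or an error with `incomplete = "error"`).
#' Empty (group, cohort) cells are simply absent, not reported as zero.
#'
#' @param panel an `arrest_panel`.
#' @param assignments named integer vector mapping `person_id` to group
#'   (e.g. a `traj_fit$assignments`).
#' @param window inclusive `c(min_age, max_age)` analysis ages.
#' @param by_offense add per-category mean counts (requires the offense
#'   columns).
#' @param incomplete `"drop"` (default) or `"error"` for persons without
#'   full window coverage.
#' @return a `rate_table` data frame: `group`, `cohort`, `n_persons`,
#'   `rate`, and with `by_offense` also `rate_drugs`, `rate_violence`,
#'   `rate_property`, `rate_other`.
#' @export
rate_table <- function(panel, assignments, window, by_offense = FALSE,
                       incomplete = c("drop", "error")) {
  stopifnot(inherits(panel, "arrest_panel"), length(window) == 2L)
  incomplete <- match.arg(incomplete)
  w <- panel_windows(panel)
  covered <- w$person_id[w$min_age <= window[1L] & w$max_age >= window[2L]]
  n_out <- sum(!w$person_id %in% covered)
  if (n_out > 0L) {
    if (incomplete == "error")
      stop_arg(n_out, " person(s) lack full coverage of [", window[1L],
               ", ", window[2L], "]")
    message("rate_table: excluded ", n_out,
            " person(s) without full window coverage")
  }
  if (anyNA(match(covered, names(assignments))))
    stop_arg("assignments missing for some persons")
  sub <- panel[panel$person_id %in% covered &
                 panel$age >= window[1L] & panel$age <= window[2L], ,
               drop = FALSE]
  cols <- "count"
  if (by_offense) {
    need <- paste0("n_", charge_categories())
    if (!all(need %in% names(sub)))
      stop_arg("by_offense requires columns: ", paste(need, collapse = ", "))
    cols <- c(cols, need)
  }
  per <- rowsum(as.matrix(sub[, cols, drop = FALSE]), sub$person_id)
  ids <- rownames(per)
  cell <- data.frame(group = unname(assignments[ids]),
                     cohort = panel$cohort[match(ids, panel$person_id)])
  agg <- stats::aggregate(per, by = cell, FUN = mean)
  n_p <- stats::aggregate(list(n_persons = ids), by = cell, FUN = length)
  out <- merge(n_p, agg, by = c("group", "cohort"), sort = TRUE)
  names(out)[names(out) == "count"] <- "rate"
  if (by_offense)
    names(out) <- sub("^n_", "rate_", names(out))
  out <- out[order(out$group, out$cohort), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rate_table", "data.frame")
  out
}

#' Percent excess of one rate over another
#'
#' `100 (rate_a / rate_b - 1)`: how much more often, in percent, population
#' a is arrested than population b.
#'
#' @param rate_a,rate_b nonnegative rates; `rate_b` must be positive.
#' @export
percent_excess <- function(rate_a, rate_b) {
  if (any(rate_b <= 0)) stop_arg("rate_b must be positive")
  100 * (rate_a / rate_b - 1)
}

#' Cohort gap in arrest rates
#'
#' `rate_old - rate_young`.
#'
#' @param rate_young,rate_old per-person arrest rates.
#' @export
cohort_gap <- function(rate_young, rate_old) rate_old - rate_young

#' Counterfactual decomposition of a cohort rate difference
#'
#' Splits the difference in overall arrest rates between two cohorts into a
#' group-composition component and a within-group-rate component by
#' counterfactual swaps.  The actual rate of a cohort is the share-weighted
#' sum of its within-group rates (exact when shares and rates come from the
#' same hard assignment).  Counterfactuals for the younger cohort:
#' `rate_swap` keeps the younger cohort's group shares but applies the older
#' cohort's within-group rates; `composition_swap` applies the older
#' cohort's shares to the younger cohort's rates; `targeted` replaces only
#' the named group's rate with the older cohort's.  Percent differences are
#' against the younger cohort's actual rate.
#'
#' @param shares_young,shares_old per-group membership shares (each summing
#'   to 1 within `tol`), aligned group order.
#' @param rates_young,rates_old per-group mean arrest rates, same order.
#' @param target_group index of the group for the targeted swap (default
#'   the last, highest-rate group).
#' @param tol tolerance for share normalization.
#' @return a `traj_decomposition` list: `actual_young`, `actual_old`,
#'   `gap`, `counterfactuals` (named vector), `pct_vs_actual` (named
#'   vector of percent differences).
#' @export
decompose <- function(shares_young, rates_young, shares_old, rates_old,
                      target_group = length(shares_young), tol = 0.01) {
  k <- length(shares_young)
  if (length(rates_young) != k || length(shares_old) != k ||
      length(rates_old) != k)
    stop_arg("shares and rates must have one entry per group, aligned")
  if (abs(sum(shares_young) - 1) > tol || abs(sum(shares_old) - 1) > tol)
    stop_arg("group shares must sum to 1 (within tol = ", tol, ")")
  actual_young <- sum(shares_young * rates_young)
  actual_old <- sum(shares_old * rates_old)
  rates_target <- rates_young
  rates_target[target_group] <- rates_old[target_group]
  cf <- c(rate_swap = sum(shares_young * rates_old),
          composition_swap = sum(shares_old * rates_young),
          targeted = sum(shares_young * rates_target))
  structure(list(actual_young = actual_young, actual_old = actual_old,
                 gap = cohort_gap(actual_young, actual_old),
                 counterfactuals = cf,
                 pct_vs_actual = percent_excess(cf, actual_young),
                 target_group = target_group),
            class = "traj_decomposition")
}

#' @export
print.traj_decomposition <- function(x, ...) {
  cat("<traj_decomposition>\n")
  cat(sprintf("  actual rates: younger %.3f, older %.3f (gap %.3f)\n",
              x$actual_young, x$actual_old, x$gap))
  for (nm in names(x$counterfactuals))
    cat(sprintf("  %-17s %.3f (%+.1f%% vs younger actual)\n", nm,
                x$counterfactuals[[nm]], x$pct_vs_actual[[nm]]))
  invisible(x)
}

#' Permutation test for a cohort difference in within-group rates
#'
#' Two-sided test of the difference in mean per-person arrest totals (over
#' an age window) between the two cohorts present in one trajectory group,
#' permuting cohort labels across the group's persons.  The p-value is
#' `(1 + #{|perm diff| >= |obs diff|}) / (n_perm + 1)`.
#'
#' @param panel an `arrest_panel` whose cohort labels take exactly two
#'   values among the group's persons (collapse with [map_cohorts()] first
#'   if needed).
#' @param assignments named person-to-group vector.
#' @param group group index to test within.
#' @param window inclusive age window; persons must cover it fully.
#' @param n_perm number of label permutations (>= 1).
#' @param seed RNG seed.
#' @return list with `observed` (mean difference, second cohort level minus
#'   first), `p_value`, `n_perm`, `cohorts`.
#' @export
permutation_test <- function(panel, assignments, group, window,
                             n_perm = 999L, seed = 1L) {
  stopifnot(inherits(panel, "arrest_panel"), n_perm >= 1L)
  w <- panel_windows(panel)
  ids <- w$person_id[w$min_age <= window[1L] & w$max_age >= window[2L] &
                       unname(assignments[w$person_id]) == group]
  ids <- ids[!is.na(ids)]
  coh <- w$cohort[match(ids, w$person_id)]
  levs <- sort(unique(coh))
  if (length(levs) != 2L)
    stop_arg("the group must contain exactly two cohorts (found ",
             length(levs), ")")
  sub <- panel[panel$person_id %in% ids &
                 panel$age >= window[1L] & panel$age <= window[2L], ]
  tot <- rowsum(sub$count, sub$person_id)
  tot <- tot[match(ids, rownames(tot)), 1L]
  is_b <- coh == levs[2L]
  obs <- mean(tot[is_b]) - mean(tot[!is_b])
  set.seed(seed)
  nb <- sum(is_b)
  perm <- replicate(n_perm, {
    lab <- sample(is_b)
    mean(tot[lab]) - mean(tot[!lab])
  })
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  list(observed = obs, p_value = p, n_perm = as.integer(n_perm),
       cohorts = levs)
}
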