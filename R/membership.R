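#' Covariate effects on group membership
#'
#' Membership-logit coefficients against the low (reference) group, with
#' odds ratios (`exp(coefficient)`), observed-information standard errors
#' and Wald z-tests.  Requires a covariate-conditioned fit with standard
#' errors (`fit_trajectories(..., se = TRUE)`).
#'
#' @param fit a `traj_fit`.
#' @return a `membership_effects` data frame: one row per non-reference
#'   group and term (intercept + covariates), with `estimate`, `se`,
#'   `odds_ratio`, `z`, `p_value`.
#' @export
membership_effects <- function(fit) {
  stopifnot(inherits(fit, "traj_fit"))
  model <- fit$model
  if (is.null(model$covariate_names))
    stop_arg("fit does not condition membership on covariates")
  if (is.null(fit$se))
    stop_arg("standard errors unavailable; refit with se = TRUE")
  if (!any(fit$assignments == 1L))
    stop_arg("reference (low) group is empty")
  J <- model$J
  terms <- colnames(model$theta)
  rows <- expand.grid(term = terms, group = 2:J, stringsAsFactors = FALSE)
  est <- model$theta[cbind(rows$group, match(rows$term, terms))]
  se_names <- paste0("group", rows$group, ":theta.", rows$term)
  ses <- fit$se[se_names]
  z <- est / ses
  out <- data.frame(group = rows$group, term = rows$term, estimate = est,
                    se = unname(ses), odds_ratio = exp(est), z = z,
                    p_value = 2 * stats::pnorm(-abs(z)))
  attr(out, "reference") <- "group1"
  class(out) <- c("membership_effects", "data.frame")
  out
}

#' Odds ratio implied by two membership probability pairs
#'
#' `(p_group_a / p_ref_a) / (p_group_b / p_ref_b)`: the focal-vs-reference
#' membership odds in population a relative to population b, e.g. the
#' high-vs-low odds ratio implied by the older and younger cohorts'
#' membership probabilities.
#'
#' @param p_group_a,p_ref_a focal- and reference-group probabilities in
#'   population a.
#' @param p_group_b,p_ref_b the same in population b.
#' @export
odds_ratio <- function(p_group_a, p_ref_a, p_group_b, p_ref_b) {
  if (min(p_group_a, p_ref_a, p_group_b, p_ref_b) <= 0)
    stop_arg("probabilities must be positive")
  (p_group_a / p_ref_a) / (p_group_b / p_ref_b)
}

#' Predicted membership probabilities at covariate profiles
#'
#' For each profile (a named list of covariate values), predicts group
#' membership probabilities from the fitted membership logit.  By default
#' the average-predicted-probability convention is used: the focal
#' covariates are overridden for every person in the sample and the softmax
#' probabilities are averaged over the remaining observed covariates.  With
#' `at_means = TRUE`, prediction is at the sample means of the non-focal
#' covariates instead.
#'
#' @param fit a covariate-conditioned `traj_fit`.
#' @param profiles named list of profiles; each profile is a named list /
#'   vector of covariate values to override (e.g. `list(older = list(older
#'   = 1))`).  An empty profile predicts at the observed sample.
#' @param at_means use the at-means convention.
#' @return a `profile_probabilities` data frame: one row per profile, one
#'   column per group; rows sum to 1.
#' @export
profile_probabilities <- function(fit, profiles, at_means = FALSE) {
  stopifnot(inherits(fit, "traj_fit"))
  model <- fit$model
  if (is.null(model$covariate_names))
    stop_arg("fit does not condition membership on covariates")
  Z <- fit$covariate_data
  if (at_means) Z <- rbind(colMeans(Z))
  if (is.null(names(profiles)))
    names(profiles) <- paste0("profile", seq_along(profiles))
  out <- t(vapply(profiles, function(pr) {
    pr <- unlist(pr)
    bad <- setdiff(names(pr), model$covariate_names)
    if (length(bad) > 0L)
      stop_arg("unknown covariate(s) in profile: ",
               paste(bad, collapse = ", "))
    Zp <- Z
    for (nm in names(pr)) Zp[, nm] <- pr[[nm]]
    colMeans(softmax_rows(cbind(1, Zp) %*% t(model$theta)))
  }, numeric(model$J)))
  out <- as.data.frame(out)
  names(out) <- paste0("group", seq_len(model$J))
  out <- cbind(profile = names(profiles), out)
  rownames(out) <- NULL
  class(out) <- c("profile_probabilities", "data.frame")
  out
}

#' Difference between two profiles' membership probability in one group
#'
#' @param probA,probB single rows of a [profile_probabilities()] result (or
#'   named numeric vectors of per-group probabilities over the same groups).
#' @param group group index or `"groupJ"` column name.
#' @return `probA - probB` for the named group.
#' @export
contrast <- function(probA, probB, group) {
  pick <- function(p) {
    if (is.data.frame(p)) {
      if (nrow(p) != 1L) stop_arg("contrast expects single-profile inputs")
      p <- unlist(p[, grep("^group", names(p)), drop = FALSE])
    }
    p
  }
  a <- pick(probA); b <- pick(probB)
  if (length(a) != length(b) || !identical(names(a), names(b)))
    stop_arg("profiles cover different group sets")
  g <- if (is.character(group)) group else paste0("group", group)
  if (!g %in% names(a)) stop_arg("no such group: ", g)
  unname(a[[g]] - b[[g]])
}

#' Pool estimates across multiple imputations (Rubin's rules)
#'
#' Pooled estimate = mean of the per-imputation estimates; total variance =
#' mean within-imputation variance plus `(1 + 1/m)` times the
#' between-imputation variance; degrees of freedom and two-sided p-values
#' per Rubin.  Vectorized over named parameter vectors.
#'
#' @param estimates m-by-p matrix (or length-p vector when m = 1) of
#'   per-imputation estimates; column names identify parameters and must
#'   agree with `variances`.
#' @param variances matching matrix of squared standard errors.
#' @return data frame with `parameter`, `estimate`, `variance`, `se`, `df`,
#'   `p_value`.
#' @export
pool_imputations <- function(estimates, variances) {
  estimates <- rbind(estimates)
  variances <- rbind(variances)
  if (!identical(dim(estimates), dim(variances)))
    stop_arg("estimates and variances must have matching dimensions")
  if (!identical(colnames(estimates), colnames(variances)))
    stop_arg("estimates and variances must have matching parameter names")
  m <- nrow(estimates)
  qbar <- colMeans(estimates)
  wbar <- colMeans(variances)
  if (m == 1L) {
    total <- wbar
    df <- rep(Inf, length(qbar))
  } else {
    b <- apply(estimates, 2L, stats::var)
    total <- wbar + (1 + 1 / m) * b
    r <- (1 + 1 / m) * b / wbar
    df <- ifelse(b == 0, Inf, (m - 1) * (1 + 1 / r)^2)
  }
  se <- sqrt(total)
  tstat <- qbar / se
  data.frame(parameter = colnames(estimates) %||%
               paste0("par", seq_along(qbar)),
             estimate = unname(qbar), variance = unname(total),
             se = unname(se), df = unname(df),
             p_value = unname(2 * stats::pt(-abs(tstat), df = df)),
             row.names = NULL)
}
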