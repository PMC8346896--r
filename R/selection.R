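#' Bayesian information criterion
#'
#' `-2 loglik + n_params log(n)`; lower is better.  The sample-size
#' convention is a choice: persons are the independent units of the mixture
#' likelihood, so fits report BIC with `n` = persons by default and the
#' person-period convention alongside.
#'
#' @param loglik maximized log-likelihood.
#' @param n_params number of free parameters.
#' @param n sample size (persons or person-periods).
#' @export
bic <- function(loglik, n_params, n) {
  if (n < 1L) stop_arg("n must be >= 1")
  -2 * loglik + n_params * log(n)
}

#' Model selection over numbers of groups and functional forms
#'
#' Fits every candidate `(J, trajectory spec)` with shared settings and
#' picks the converged candidate with the lowest BIC; ties break to the
#' smaller `J`, then to the lower total polynomial order.
#'
#' @param panel an `arrest_panel`.
#' @param covariates optional covariate table passed to every fit.
#' @param J_range integer vector of candidate group counts.
#' @param specs list of candidate [trajectory_spec()]s (default: one cubic).
#' @param bic_n `"persons"` (default) or `"person-periods"`.
#' @param seed shared base seed.
#' @param ... further arguments to [fit_trajectories()] (`n_starts`,
#'   `em_tol`, `polish`, ...).
#' @return a `traj_selection`: `table` (one row per candidate with loglik,
#'   n_params, both BICs, convergence), `fits`, and `chosen` (index into the
#'   candidate list; `NA` if no candidate converged).
#' @export
select_model <- function(panel, covariates = NULL, J_range = 1:4,
                         specs = list(trajectory_spec()),
                         bic_n = c("persons", "person-periods"),
                         seed = 1L, ...) {
  bic_n <- match.arg(bic_n)
  if (length(J_range) == 0L || length(specs) == 0L)
    stop_arg("the candidate grid is empty")
  grid <- expand.grid(spec_i = seq_along(specs), J = J_range)
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fits[[i]] <- withCallingHandlers(
      fit_trajectories(panel, spec = specs[[grid$spec_i[i]]],
                       J = grid$J[i], covariates = covariates,
                       seed = seed, ...),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  tab <- data.frame(
    J = grid$J,
    basis = vapply(specs[grid$spec_i], function(s) s$basis, character(1L)),
    order = vapply(specs[grid$spec_i], basis_order, numeric(1L)),
    loglik = vapply(fits, `[[`, numeric(1L), "loglik"),
    n_params = vapply(fits, `[[`, numeric(1L), "n_params"),
    bic_persons = vapply(fits, `[[`, numeric(1L), "bic"),
    bic_person_periods = vapply(fits, `[[`, numeric(1L), "bic_obs"),
    converged = vapply(fits, `[[`, logical(1L), "converged"))
  crit <- if (bic_n == "persons") tab$bic_persons else tab$bic_person_periods

  conv <- which(tab$converged)
  chosen <- NA_integer_
  if (length(conv) > 0L) {
    o <- conv[order(crit[conv], tab$J[conv], tab$order[conv])]
    chosen <- o[1L]
  }
  structure(list(table = tab, fits = fits, chosen = chosen,
                 bic_n = bic_n),
            class = "traj_selection")
}

#' @export
print.traj_selection <- function(x, ...) {
  cat("<traj_selection> BIC convention: n = ", x$bic_n, "\n", sep = "")
  print(x$table, row.names = FALSE)
  if (!is.na(x$chosen))
    cat("chosen: J = ", x$table$J[x$chosen], " (",
        x$table$basis[x$chosen], ")\n", sep = "")
  else cat("chosen: none (no candidate converged)\n")
  invisible(x)
}

#' Hard group assignment from a posterior matrix
#'
#' Maximum posterior probability per person; ties go to the lowest group
#' index.
#'
#' @param posterior persons-by-J matrix with rows summing to 1.
#' @return integer vector of group indices, named when the posterior has
#'   rownames.
#' @export
assign_groups <- function(posterior) {
  posterior <- rbind(posterior)
  if (any(!is.finite(posterior)))
    stop_arg("posterior contains non-finite values")
  stats::setNames(max.col(posterior, ties.method = "first"),
                  rownames(posterior))
}

#' Classification adequacy diagnostics
#'
#' Per group: the model's estimated membership probability (mean of the
#' membership probabilities over persons), the share of the sample assigned
#' by maximum posterior, the average posterior probability among assigned
#' persons (AvePP), and the odds of correct classification.  AvePP below
#' 0.7 flags inadequate separation.  Groups with no assigned persons get
#' `NA` AvePP with a warning.
#'
#' @param fit a `traj_fit`.
#' @param covariates covariates used in the fit (only needed for a
#'   covariate-conditioned model).
#' @return an `adequacy_report` data frame with one row per group.
#' @export
adequacy <- function(fit, covariates = NULL) {
  stopifnot(inherits(fit, "traj_fit"))
  post <- fit$posterior
  J <- ncol(post)
  assigned <- fit$assignments
  model <- fit$model
  if (is.null(model$covariate_names)) {
    pi_hat <- rep(softmax_rows(t(model$theta[, 1L, drop = FALSE]))[1L, ],
                  length.out = J)
  } else {
    W <- cbind(1, fit$covariate_data)
    pi_hat <- colMeans(softmax_rows(W %*% t(model$theta)))
  }
  share <- tabulate(assigned, nbins = J) / length(assigned)
  avepp <- vapply(seq_len(J), function(j) {
    in_j <- assigned == j
    if (!any(in_j)) return(NA_real_)
    mean(post[in_j, j])
  }, numeric(1L))
  if (anyNA(avepp))
    warning("group(s) with no assigned persons: AvePP undefined",
            call. = FALSE)
  occ <- (avepp / (1 - avepp)) / (pi_hat / (1 - pi_hat))
  out <- data.frame(group = seq_len(J), pi_hat = pi_hat,
                    assigned_share = share, avepp = avepp, occ = occ,
                    adequate = !is.na(avepp) & avepp >= 0.7)
  class(out) <- c("adequacy_report", "data.frame")
  out
}
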