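#' Poisson trajectory mixture model
#'
#' A finite mixture over `J` latent trajectory groups.  Group `j`'s expected
#' arrest count at age `a` is `lambda_j(a) = exp(beta_j . basis(a))`, and a
#' person's membership probabilities follow a multinomial logit
#' `pi_j(x) = softmax_j(theta_j . (1, x))` over an intercept plus optional
#' baseline covariates, with group 1 the reference (`theta_1 = 0`).  Given
#' group membership, counts at distinct ages are conditionally independent
#' Poisson draws, so a person's component likelihood is the product over
#' their observed ages.
#'
#' @param beta numeric matrix, `J x n_basis(spec)`: per-group log-rate
#'   coefficients.
#' @param theta numeric matrix, `J x (1 + n covariates)`: membership-logit
#'   coefficients; the first row must be zero (reference group).
#' @param spec a [trajectory_spec()].
#' @param covariate_names character vector naming the membership covariates
#'   (columns of `theta` after the intercept); `NULL` for an unconditional
#'   model.
#' @return a `mixture_model` object.
#' @export
mixture_model <- function(beta, theta = NULL, spec = trajectory_spec(),
                          covariate_names = NULL) {
  beta <- rbind(beta)
  J <- nrow(beta)
  if (ncol(beta) != n_basis(spec))
    stop_arg("beta must have ", n_basis(spec), " columns for this basis")
  if (is.null(theta)) theta <- matrix(0, J, 1L)
  theta <- rbind(theta)
  if (nrow(theta) != J) stop_arg("theta must have one row per group")
  if (ncol(theta) != 1L + length(covariate_names))
    stop_arg("theta needs 1 + length(covariate_names) columns")
  if (any(theta[1L, ] != 0))
    stop_arg("group 1 is the reference: theta[1, ] must be zero")
  rownames(beta) <- rownames(theta) <- paste0("group", seq_len(J))
  colnames(beta) <- basis_names(spec)
  colnames(theta) <- c("(Intercept)", covariate_names)
  structure(list(J = J, beta = beta, theta = theta, spec = spec,
                 covariate_names = covariate_names),
            class = "mixture_model")
}

#' Expected count on a group's trajectory
#'
#' @param model a `mixture_model`.
#' @param group group index in `1:J`.
#' @param age age(s) in years.
#' @return expected count(s) `exp(beta_group . basis(age))`, strictly
#'   positive.
#' @export
rate <- function(model, group, age) {
  stopifnot(inherits(model, "mixture_model"))
  if (length(group) != 1L || group < 1L || group > model$J)
    stop_arg("group must be a single index in 1:", model$J)
  drop(exp(traj_basis(model$spec, age) %*% model$beta[group, ]))
}

# Aligns covariate rows to the panel's persons and builds the logit design
# matrix W = [1, x].  covariates may carry several imputations; imputation
# selects one (default the first present).
membership_design <- function(model, person_ids, covariates,
                              imputation = NULL) {
  if (is.null(model$covariate_names)) {
    return(matrix(1, length(person_ids), 1L,
                  dimnames = list(NULL, "(Intercept)")))
  }
  if (is.null(covariates))
    stop_arg("model conditions membership on covariates (",
             paste(model$covariate_names, collapse = ", "),
             ") but none were supplied")
  covariates <- as.data.frame(covariates)
  if ("imputation_id" %in% names(covariates)) {
    imputation <- imputation %||% min(covariates$imputation_id)
    covariates <- covariates[covariates$imputation_id == imputation, ,
                             drop = FALSE]
  }
  idx <- match(person_ids, as.character(covariates$person_id))
  if (anyNA(idx))
    stop_arg("covariates missing for person(s): ",
             paste(utils::head(person_ids[is.na(idx)], 5L), collapse = ", "))
  miss <- setdiff(model$covariate_names, names(covariates))
  if (length(miss) > 0L)
    stop_arg("covariate column(s) not found: ", paste(miss, collapse = ", "))
  W <- cbind(1, as.matrix(covariates[idx, model$covariate_names,
                                     drop = FALSE]))
  colnames(W) <- c("(Intercept)", model$covariate_names)
  if (any(!is.finite(W))) stop_arg("covariates contain non-finite values")
  W
}

# Per-person pieces of the mixture likelihood, all in log space:
#   logpi  (n x J)  log membership probabilities
#   logcomp(n x J)  log P(Y_i | group j) = sum_t log Poisson(y_it; lambda_j)
mixture_terms <- function(model, panel, covariates = NULL,
                          imputation = NULL) {
  stopifnot(inherits(model, "mixture_model"))
  if (nrow(panel) == 0L) stop_arg("panel is empty")
  person <- factor(panel$person_id, levels = unique(panel$person_id))
  X <- traj_basis(model$spec, panel$age)
  eta <- X %*% t(model$beta)                       # rows x J log-rates
  lam <- pmax(exp(eta), RATE_FLOOR)
  logpmf <- panel$count * log(lam) - lam - lgamma(panel$count + 1)
  logcomp <- rowsum(logpmf, person, reorder = FALSE)
  ids <- levels(person)
  W <- membership_design(model, ids, covariates, imputation)
  lin <- W %*% t(model$theta)
  logpi <- lin - logsumexp_rows(lin)
  list(person_ids = ids, logpi = logpi, logcomp = logcomp, W = W,
       X = X, person = person)
}

#' Mixture log-likelihood of a panel
#'
#' Sum over persons of `log sum_j pi_j(x_i) prod_t Poisson(y_it;
#' lambda_j(age_it))`, evaluated stably in log space (log-sum-exp).
#'
#' @param model a `mixture_model`.
#' @param panel an `arrest_panel`.
#' @param covariates covariate data frame (`person_id`, optional
#'   `imputation_id`, covariate columns), required when the model conditions
#'   membership on covariates.
#' @param imputation which imputation to use when `covariates` holds several.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(model, panel, covariates = NULL,
                           imputation = NULL) {
  tm <- mixture_terms(model, panel, covariates, imputation)
  sum(logsumexp_rows(tm$logpi + tm$logcomp))
}

#' Posterior group-membership probabilities
#'
#' Bayes' rule per person: `pi_j(x_i) P(Y_i|j) / sum_l pi_l(x_i) P(Y_i|l)`,
#' computed in log space.  Rows sum to one.
#'
#' @inheritParams log_likelihood
#' @return persons-by-J matrix with `person_id` rownames.
#' @export
posterior_probabilities <- function(model, panel, covariates = NULL,
                                    imputation = NULL) {
  tm <- mixture_terms(model, panel, covariates, imputation)
  lp <- tm$logpi + tm$logcomp
  post <- exp(lp - logsumexp_rows(lp))
  rownames(post) <- tm$person_ids
  colnames(post) <- paste0("group", seq_len(model$J))
  post
}

#' @export
print.mixture_model <- function(x, ...) {
  cat("<mixture_model> J = ", x$J, ", ", sep = "")
  print(x$spec)
  if (!is.null(x$covariate_names))
    cat("  membership covariates: ",
        paste(x$covariate_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}
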