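#' Fit a group-based trajectory model
#'
#' Maximum-likelihood estimation of the Poisson trajectory mixture by
#' expectation-maximization with multiple seeded starts, followed by a
#' quasi-Newton (BFGS) polish of the full likelihood using the analytic
#' score.  The E-step computes posterior membership probabilities; the
#' M-step runs a posterior-weighted Poisson regression per group
#' (delegated to [stats::glm.fit()]) and, when membership is conditioned on
#' covariates, a posterior-weighted multinomial-logit update (delegated to
#' [nnet::multinom()]).  Groups are relabeled in ascending order of mean
#' rate over the pooled observed ages, so group 1 is always "low" and the
#' membership logit is reported against the low reference.
#'
#' Starts assign persons to `J` strata by quantiles of their mean observed
#' count, perturbed multiplicatively; the best converged log-likelihood over
#' starts wins (ties break to the lowest start index).
#'
#' @param panel an `arrest_panel`.
#' @param spec a [trajectory_spec()]; the same basis is used for all groups.
#' @param J number of latent groups (>= 1).
#' @param covariates optional covariate data frame (`person_id`, optional
#'   `imputation_id`, numeric covariate columns).
#' @param covariate_names which covariate columns enter the membership
#'   logit; default all columns except identifiers.  Ignored when
#'   `covariates` is `NULL`.
#' @param n_starts number of seeded initializations.
#' @param seed integer seed governing all starts.
#' @param em_tol relative log-likelihood change declaring EM convergence.
#' @param em_maxit maximum EM iterations per start.
#' @param polish run the BFGS polish on the best start (default `TRUE`).
#' @param se compute coefficient standard errors from the observed
#'   information (finite differences of the analytic score, ridge 1e-8).
#' @param imputation which imputation of `covariates` to use.
#' @param verbose print per-start progress.
#' @return a `traj_fit` with elements `model`, `loglik`, `bic`,
#'   `bic_obs` (person-period convention), `n_params`, `posterior`,
#'   `assignments`, `converged`, `n_starts_used`, `start_logliks`,
#'   `em_trace`, `gradient_norm`, and optionally `se`, `vcov`.
#' @export
fit_trajectories <- function(panel, spec = trajectory_spec(), J,
                             covariates = NULL, covariate_names = NULL,
                             n_starts = 20L, seed = 1L,
                             em_tol = 1e-8, em_maxit = 500L,
                             polish = TRUE, se = FALSE,
                             imputation = NULL, verbose = FALSE) {
  stopifnot(inherits(panel, "arrest_panel"))
  if (J < 1L) stop_arg("J must be >= 1")
  person <- factor(panel$person_id, levels = unique(panel$person_id))
  n <- nlevels(person)
  if (n < J) stop_arg("panel must contain at least J persons")

  pattern <- tapply(paste(panel$age, panel$count, sep = ":"), person,
                    paste, collapse = ";")
  if (J > length(unique(pattern)))
    warning("J exceeds the number of distinct response patterns; ",
            "the mixture is degenerate", call. = FALSE)

  if (!is.null(covariates) && is.null(covariate_names)) {
    covariate_names <- setdiff(names(covariates),
                               c("person_id", "imputation_id"))
  }
  proto <- mixture_model(matrix(0, J, n_basis(spec)),
                         matrix(0, J, 1L + length(covariate_names)),
                         spec, covariate_names)

  X <- traj_basis(spec, panel$age)
  y <- panel$count
  pidx <- as.integer(person)
  W <- membership_design(proto, levels(person), covariates, imputation)
  q <- ncol(W)
  p <- ncol(X)

  eval_ll <- function(beta, theta) {
    lam <- pmax(exp(X %*% t(beta)), RATE_FLOOR)
    logpmf <- y * log(lam) - lam - lgamma(y + 1)
    S <- rowsum(logpmf, person, reorder = FALSE)
    lin <- W %*% t(theta)
    logpi <- lin - logsumexp_rows(lin)
    lp <- logpi + S
    den <- logsumexp_rows(lp)
    list(ll = sum(den), post = exp(lp - den), lam = lam,
         pi = exp(logpi))
  }

  m_step <- function(post, beta_prev) {
    beta <- beta_prev
    for (j in seq_len(J)) {
      w <- post[pidx, j]
      if (sum(w) < 1e-8) next  # empty group: keep previous coefficients
      fitj <- tryCatch(
        suppressWarnings(stats::glm.fit(X, y, weights = w,
                                        family = stats::poisson(),
                                        start = beta_prev[j, ])),
        error = function(e)
          suppressWarnings(stats::glm.fit(X, y, weights = w,
                                          family = stats::poisson())))
      beta[j, ] <- fitj$coefficients
    }
    theta <- matrix(0, J, q)
    if (J > 1L) {
      if (q == 1L) {
        pi_hat <- pmax(colMeans(post), 1e-12)
        theta[, 1L] <- log(pi_hat / pi_hat[1L])
      } else {
        dat <- as.data.frame(W[, -1L, drop = FALSE])
        resp <- post
        colnames(resp) <- paste0("g", seq_len(J))
        mfit <- nnet::multinom(resp ~ ., data = dat, trace = FALSE,
                               maxit = 200L)
        cf <- stats::coef(mfit)
        cf <- rbind(cf)  # J=2 returns a vector
        theta[-1L, ] <- cf
      }
    }
    list(beta = beta, theta = theta)
  }

  run_em <- function(start_seed) {
    set.seed(start_seed)
    m <- tapply(y, person, mean)
    z <- m * exp(stats::rnorm(n, 0, 0.3)) + stats::runif(n) * 1e-6
    strata <- ceiling(rank(z, ties.method = "first") * J / n)
    post <- matrix(0.2 / J, n, J)
    post[cbind(seq_len(n), strata)] <- post[cbind(seq_len(n), strata)] + 0.8

    beta <- matrix(0, J, p)
    beta[, 1L] <- log(mean(y) + 1e-3)
    theta <- matrix(0, J, q)
    ll_old <- -Inf
    trace <- numeric(0)
    conv <- FALSE
    for (it in seq_len(em_maxit)) {
      ms <- m_step(post, beta)
      beta <- ms$beta; theta <- ms$theta
      ev <- eval_ll(beta, theta)
      post <- ev$post
      trace <- c(trace, ev$ll)
      if (is.finite(ll_old) &&
          abs(ev$ll - ll_old) / (abs(ev$ll) + 0.1) < em_tol) {
        conv <- TRUE
        break
      }
      ll_old <- ev$ll
    }
    list(ll = ev$ll, beta = beta, theta = theta, converged = conv,
         trace = trace)
  }

  n_starts_used <- if (J == 1L) 1L else as.integer(n_starts)
  runs <- vector("list", n_starts_used)
  for (s in seq_len(n_starts_used)) {
    runs[[s]] <- run_em(seed + s - 1L)
    if (verbose)
      message("start ", s, ": loglik ", format(runs[[s]]$ll),
              if (runs[[s]]$converged) " (converged)" else "")
  }
  lls <- vapply(runs, `[[`, numeric(1L), "ll")
  best_i <- which.max(lls + seq_along(lls) * 0)  # which.max ties -> first
  best <- runs[[best_i]]
  beta <- best$beta; theta <- best$theta

  # free parameters: all beta rows + non-reference theta rows
  pack <- function(beta, theta) c(t(beta), t(theta[-1L, , drop = FALSE]))
  unpack <- function(par) {
    beta <- matrix(par[seq_len(J * p)], J, p, byrow = TRUE)
    theta <- matrix(0, J, q)
    if (J > 1L)
      theta[-1L, ] <- matrix(par[-seq_len(J * p)], J - 1L, q, byrow = TRUE)
    list(beta = beta, theta = theta)
  }
  negll <- function(par) {
    pr <- unpack(par)
    -eval_ll(pr$beta, pr$theta)$ll
  }
  neggrad <- function(par) {
    pr <- unpack(par)
    ev <- eval_ll(pr$beta, pr$theta)
    gb <- matrix(0, J, p)
    for (j in seq_len(J))
      gb[j, ] <- crossprod(X, ev$post[pidx, j] * (y - ev$lam[, j]))
    gt <- crossprod(W, ev$post - ev$pi)  # q x J
    -c(t(gb), t(t(gt)[-1L, , drop = FALSE]))
  }

  polished <- FALSE
  if (polish) {
    par <- pack(beta, theta)
    for (pass in 1:3) {  # restart BFGS until the score is flat
      opt <- tryCatch(
        stats::optim(par, negll, neggrad, method = "BFGS",
                     control = list(maxit = 300L, reltol = 1e-12)),
        error = function(e) NULL)
      if (is.null(opt) || -opt$value < -negll(par) - 1e-10) break
      par <- opt$par
      polished <- TRUE
      if (max(abs(neggrad(par))) < 1e-5) break
    }
    if (polished && -negll(par) >= best$ll - 1e-6) {
      pr <- unpack(par)
      beta <- pr$beta; theta <- pr$theta
    } else polished <- FALSE
  }
  grad_norm <- max(abs(neggrad(pack(beta, theta))))
  final_ll <- eval_ll(beta, theta)$ll

  # canonical label order: ascending mean rate over the pooled age grid
  grid <- sort(unique(panel$age))
  mean_rate <- rowMeans(exp(beta %*% t(traj_basis(spec, grid))))
  ord <- order(mean_rate)
  beta <- beta[ord, , drop = FALSE]
  theta <- theta[ord, , drop = FALSE]
  theta <- sweep(theta, 2L, theta[1L, ])  # re-reference to new group 1

  model <- mixture_model(beta, theta, spec, covariate_names)
  post <- posterior_probabilities(model, panel, covariates, imputation)
  n_params <- J * p + (J - 1L) * q
  n_obs <- nrow(panel)
  res <- structure(list(
    model = model,
    loglik = final_ll,
    bic = -2 * final_ll + n_params * log(n),
    bic_obs = -2 * final_ll + n_params * log(n_obs),
    n_params = n_params,
    n_persons = n,
    n_obs = n_obs,
    posterior = post,
    assignments = assign_groups(post),
    converged = if (polish) grad_norm < 1e-5 else best$converged,
    n_starts_used = n_starts_used,
    start_logliks = lls,
    em_trace = best$trace,
    gradient_norm = grad_norm,
    polished = polished,
    panel_person_ids = levels(person),
    covariate_data = if (q > 1L) W[, -1L, drop = FALSE] else NULL,
    seed = seed
  ), class = "traj_fit")
  if (!res$converged)
    warning("fit did not converge (gradient norm ", format(grad_norm),
            ")", call. = FALSE)

  if (se) {
    H <- tryCatch(
      stats::optimHess(pack(beta, theta), negll, neggrad),
      error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H + diag(1e-8, nrow(H))), error = function(e) NULL)
      if (!is.null(V)) {
        ses <- sqrt(pmax(diag(V), 0))
        pr_names <- c(
          as.vector(t(outer(paste0("group", seq_len(J)),
                            colnames(model$beta), paste, sep = ":beta."))),
          if (J > 1L)
            as.vector(t(outer(paste0("group", 2:J),
                              colnames(model$theta), paste, sep = ":theta."))))
        names(ses) <- pr_names
        dimnames(V) <- list(pr_names, pr_names)
        res$se <- ses
        res$vcov <- V
      }
    }
    if (is.null(res$se))
      warning("observed-information standard errors unavailable",
              call. = FALSE)
  }
  res
}

#' @export
print.traj_fit <- function(x, ...) {
  cat("<traj_fit> J = ", x$model$J, ", loglik = ", format(x$loglik),
      ", BIC(persons) = ", format(x$bic), "\n", sep = "")
  pi_hat <- colMeans(x$posterior)
  cat("  mean posterior shares:",
      paste(sprintf("%.3f", pi_hat), collapse = " / "), "\n")
  cat("  converged: ", x$converged, " (gradient norm ",
      format(x$gradient_norm, digits = 3), ", ", x$n_starts_used,
      " start(s))\n", sep = "")
  invisible(x)
}

#' @export
logLik.traj_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, class = "logLik")
}
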