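# Independent oracles and small fixture builders.  These deliberately avoid
# the package's own computational paths: the IRLS oracle hand-codes the
# Poisson-regression normal equations, and the brute-force likelihood
# multiplies raw Poisson densities person by person.

# hand-coded iteratively reweighted least squares for a Poisson log-linear
# model (no glm(), no package code)
irls_poisson <- function(X, y, tol = 1e-12, maxit = 200L) {
  beta <- c(log(mean(y) + 1e-8), rep(0, ncol(X) - 1L))
  for (it in seq_len(maxit)) {
    mu <- as.vector(exp(X %*% beta))
    z <- X %*% beta + (y - mu) / mu
    WX <- X * mu
    beta_new <- solve(crossprod(X, WX), crossprod(WX, z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  as.vector(beta)
}

# naive mixture log-likelihood: enumerate groups per person, multiply
# Poisson probabilities directly (no log-space tricks)
brute_mixture_loglik <- function(panel_df, pi, rate_fun) {
  J <- length(pi)
  total <- 0
  for (id in unique(panel_df$person_id)) {
    rows <- panel_df[panel_df$person_id == id, ]
    person_lik <- 0
    for (j in seq_len(J)) {
      lam <- rate_fun(j, rows$age)
      person_lik <- person_lik + pi[j] * prod(dpois(rows$count, lam))
    }
    total <- total + log(person_lik)
  }
  total
}

make_panel <- function(person_id, cohort, age, count, ...) {
  as_panel(data.frame(person_id = person_id, cohort = cohort, age = age,
                      count = count, ..., stringsAsFactors = FALSE))
}

# random small dense panel for property tests
random_panel <- function(seed, n_persons = 8L, cohorts = c("a", "b")) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n_persons), function(i) {
    a0 <- sample(10:20, 1L)
    a1 <- a0 + sample(1:8, 1L)
    data.frame(person_id = sprintf("p%02d", i),
               cohort = sample(cohorts, 1L),
               age = a0:a1,
               count = rpois(a1 - a0 + 1L, lambda = runif(1L, 0.1, 3)),
               stringsAsFactors = FALSE)
  }))
  as_panel(rows)
}

# constant-rate single-basis model helper
constant_model <- function(rates, pi = rep(1 / length(rates), length(rates))) {
  J <- length(rates)
  spec <- trajectory_spec(degree = 0L)
  theta <- matrix(0, J, 1L)
  theta[, 1L] <- log(pi / pi[1L])
  mixture_model(matrix(log(rates), J, 1L), theta, spec)
}
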