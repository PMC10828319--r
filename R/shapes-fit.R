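# Per-gene count-family fitting.
#
# All four families share a log-link mean model with replicate as the only
# covariate, i.e. a free mean per replicate group. For P and NB the group
# mean MLE is the group sample mean (the NB score in mu is a weighted sum
# of (y - mu), so mu_hat = ybar for any fixed theta); theta is profiled by
# 1-D optimisation. ZIP and ZINB are fitted by coordinate ascent: an EM
# step for the group means (and theta) given the zero-atom memberships,
# then exact 1-D maximisation of the observed likelihood in pi. Every step
# increases the observed log-likelihood, so the inflated families can never
# fall below their non-inflated submodels (up to optimiser tolerance).
#
# Likelihood evaluations run over tabulated (value, multiplicity) pairs per
# replicate group, which makes the parametric-bootstrap KS screen cheap.

LOG_THETA_RANGE <- c(-7, 12)
THETA_POISSON_LIMIT <- 1e4
PI_COLLAPSE <- 1e-4
EM_TOL <- 1e-6
EM_MAX_ITER <- 200

# Tabulate a count vector per replicate group.
tab_counts <- function(y, groups) {
  lapply(split(y, groups), function(v) {
    tb <- table(v)
    list(v = as.integer(names(tb)), w = as.numeric(tb), n = length(v),
         sum = sum(v))
  })
}

nb_loglik_tab <- function(tabs, mu, theta) {
  s <- 0
  for (r in seq_along(tabs)) {
    s <- s + sum(tabs[[r]]$w * dnbinom(tabs[[r]]$v, size = theta,
                                       mu = mu[r], log = TRUE))
  }
  s
}

pois_loglik_tab <- function(tabs, mu) {
  s <- 0
  for (r in seq_along(tabs)) {
    s <- s + sum(tabs[[r]]$w * dpois(tabs[[r]]$v, mu[r], log = TRUE))
  }
  s
}

# Observed-data log-likelihood of a zero-inflated family.
zi_loglik_tab <- function(tabs, pi, mu, theta = NULL) {
  s <- 0
  for (r in seq_along(tabs)) {
    v <- tabs[[r]]$v
    w <- tabs[[r]]$w
    base <- if (is.null(theta)) dpois(v, mu[r], log = TRUE) else
      dnbinom(v, size = theta, mu = mu[r], log = TRUE)
    ll <- log1p(-pi) + base
    zero <- v == 0L
    if (any(zero)) {
      ll[zero] <- log(pi + exp(log1p(-pi) + base[zero]))
    }
    s <- s + sum(w * ll)
  }
  s
}

# Exact 1-D maximisation of the observed likelihood in pi.
optimize_pi <- function(tabs, mu, theta = NULL, upper = 0.995) {
  opt <- optimize(function(p) zi_loglik_tab(tabs, p, mu, theta),
                  interval = c(0, upper), maximum = TRUE, tol = 1e-7)
  # optimize() never returns the exact boundary; probe it.
  if (zi_loglik_tab(tabs, 0, mu, theta) >= opt$objective) 0 else opt$maximum
}

fit_pois_tab <- function(tabs, n) {
  mu <- vapply(tabs, function(tb) tb$sum / tb$n, numeric(1))
  if (all(mu == 0)) {
    return(list(mu = mu, loglik = 0, converged = FALSE))
  }
  list(mu = mu, loglik = pois_loglik_tab(tabs, mu), converged = TRUE)
}

fit_nb_tab <- function(tabs, n) {
  mu <- vapply(tabs, function(tb) tb$sum / tb$n, numeric(1))
  if (all(mu == 0)) {
    return(list(mu = mu, theta = NA_real_, loglik = 0, converged = FALSE,
                poisson_limit = FALSE))
  }
  opt <- optimize(function(lt) nb_loglik_tab(tabs, mu, exp(lt)),
                  interval = LOG_THETA_RANGE, maximum = TRUE, tol = 1e-7)
  theta <- exp(opt$maximum)
  list(mu = mu, theta = theta, loglik = opt$objective, converged = TRUE,
       poisson_limit = theta > THETA_POISSON_LIMIT)
}

# Shared coordinate-ascent loop for ZIP (theta = NULL) and ZINB.
fit_zi_tab <- function(tabs, n, nb = FALSE, init = NULL) {
  if (all(vapply(tabs, function(tb) tb$sum, numeric(1)) == 0)) {
    return(list(pi = NA_real_, mu = rep(0, length(tabs)),
                theta = if (nb) NA_real_ else NULL, loglik = 0,
                converged = FALSE, collapsed = FALSE, poisson_limit = FALSE))
  }
  if (is.null(init)) {
    mu <- vapply(tabs, function(tb) tb$sum / tb$n, numeric(1))
    theta <- if (nb) fit_nb_tab(tabs, n)$theta else NULL
  } else {
    mu <- init$mu
    theta <- if (nb) init$theta else NULL
  }
  pi <- optimize_pi(tabs, mu, theta)
  ll <- zi_loglik_tab(tabs, pi, mu, theta)
  for (it in seq_len(EM_MAX_ITER)) {
    # E-step: posterior zero-atom membership z for observed zeros, held
    # fixed through the whole M-step (generalised EM, monotone).
    z0 <- numeric(length(tabs))
    wpos_sum <- numeric(length(tabs))
    wy_sum <- numeric(length(tabs))
    for (r in seq_along(tabs)) {
      v <- tabs[[r]]$v
      w <- tabs[[r]]$w
      p0 <- if (is.null(theta)) exp(-mu[r]) else
        dnbinom(0L, size = theta, mu = mu[r])
      z0[r] <- pi / (pi + (1 - pi) * p0)
      z <- ifelse(v == 0L, z0[r], 0)
      wpos_sum[r] <- sum(w * (1 - z))
      wy_sum[r] <- sum(w * v)
    }
    # M-step for the count-component means (weighted group means).
    mu_new <- ifelse(wpos_sum > 0, wy_sum / wpos_sum, 0)
    theta_new <- theta
    if (nb) {
      obj <- function(lt) {
        s <- 0
        for (r in seq_along(tabs)) {
          v <- tabs[[r]]$v
          w <- tabs[[r]]$w
          wz <- ifelse(v == 0L, w * (1 - z0[r]), w)
          s <- s + sum(wz * dnbinom(v, size = exp(lt), mu = mu_new[r],
                                    log = TRUE))
        }
        s
      }
      theta_new <- exp(optimize(obj, interval = LOG_THETA_RANGE,
                                maximum = TRUE, tol = 1e-6)$maximum)
    }
    pi_new <- optimize_pi(tabs, mu_new, theta_new)
    ll_new <- zi_loglik_tab(tabs, pi_new, mu_new, theta_new)
    done <- abs(ll_new - ll) < EM_TOL
    mu <- mu_new
    theta <- theta_new
    pi <- pi_new
    ll <- ll_new
    if (done) break
  }
  collapsed <- pi < PI_COLLAPSE
  if (collapsed) {
    # Zero inflation vanished: the fit is the non-inflated family.
    base <- if (nb) fit_nb_tab(tabs, n) else fit_pois_tab(tabs, n)
    mu <- base$mu
    theta <- if (nb) base$theta else NULL
    pi <- 0
    ll <- base$loglik
  }
  list(pi = pi, mu = mu, theta = theta, loglik = ll, converged = TRUE,
       collapsed = collapsed,
       poisson_limit = nb && !is.na(theta) && theta > THETA_POISSON_LIMIT)
}

#' Fit one count family to a gene's counts with replicate adjustment
#'
#' Maximum-likelihood fit of one of the four families `P`, `ZIP`, `NB`,
#' `ZINB` with a log link on the mean and replicate as a categorical
#' covariate (a free mean per replicate group); the zero inflation `pi`,
#' where present, is constant across replicates. Parameter counts are
#' `k = 1 + (#replicates - 1)` for `P`, plus 1 for `theta` or `pi`, plus 2
#' for `ZINB`; `BIC = k log(n) - 2 logLik`.
#'
#' Genes that are all-zero cannot identify a non-degenerate mean (nor a
#' zero-inflation below 1) and are returned with `converged = FALSE`.
#' Fits where the zero inflation collapses below `1e-4` are refitted as the
#' non-inflated family (with `collapsed = TRUE`); fits where `theta`
#' exceeds `1e4` carry a `poisson_limit` flag.
#'
#' @param y non-negative integer count vector.
#' @param replicate_labels factor (or coercible) of replicate assignments,
#'   same length as `y`.
#' @param family one of `"P"`, `"ZIP"`, `"NB"`, `"ZINB"`.
#' @param init optional warm start: list with `mu` (per-replicate means)
#'   and, as applicable, `theta` and `pi`.
#' @return a `ShapeFit` list: `family`, `coef` (log-scale intercept and
#'   replicate contrasts), `mu` (per-replicate fitted means), `theta`,
#'   `pi`, `loglik`, `k`, `n`, `bic`, `converged`, `collapsed`,
#'   `poisson_limit`, and the replicate design (`groups`).
#' @export
fit_family <- function(y, replicate_labels = NULL, family, init = NULL) {
  family <- match.arg(family, c("P", "ZIP", "NB", "ZINB"))
  if (any(y < 0) || any(y != round(y))) {
    stop("y must be non-negative integers")
  }
  if (is.null(replicate_labels)) replicate_labels <- rep("R1", length(y))
  groups <- factor(replicate_labels)
  if (length(groups) != length(y)) stop("replicate label length mismatch")
  n <- length(y)
  n_rep <- nlevels(groups)
  k <- n_rep + switch(family, P = 0L, ZIP = 1L, NB = 1L, ZINB = 2L)
  if (n < 10 * k) {
    warning("fewer than 10 observations per parameter; fit may be unstable")
  }
  tabs <- tab_counts(as.integer(y), groups)
  res <- switch(family,
    P = fit_pois_tab(tabs, n),
    NB = fit_nb_tab(tabs, n),
    ZIP = fit_zi_tab(tabs, n, nb = FALSE, init = init),
    ZINB = fit_zi_tab(tabs, n, nb = TRUE, init = init))
  mu <- res$mu
  coef <- if (all(mu > 0)) {
    setNames(c(log(mu[[1]]), log(mu[-1] / mu[[1]])),
             c("intercept", if (n_rep > 1)
               paste0("rep_", levels(groups)[-1])))
  } else {
    setNames(rep(NA_real_, n_rep),
             c("intercept", if (n_rep > 1)
               paste0("rep_", levels(groups)[-1])))
  }
  ll <- res$loglik
  converged <- isTRUE(res$converged)
  structure(list(
    family = family,
    coef = coef,
    mu = setNames(mu, levels(groups)),
    theta = if (family %in% c("NB", "ZINB")) res$theta else NA_real_,
    pi = if (family %in% c("ZIP", "ZINB")) res$pi else NA_real_,
    loglik = ll, k = k, n = n,
    bic = if (converged) k * log(n) - 2 * ll else NA_real_,
    converged = converged,
    collapsed = isTRUE(res$collapsed),
    poisson_limit = isTRUE(res$poisson_limit),
    groups = groups), class = "ShapeFit")
}

#' @method print ShapeFit
#' @export
print.ShapeFit <- function(x, ...) {
  cat(sprintf("ShapeFit [%s]: logLik %.4f, k = %d, BIC %.4f%s\n", x$family,
              x$loglik, x$k, x$bic,
              if (!x$converged) " (non-converged)" else ""))
  invisible(x)
}

# Fitted pooled CDF over the observed replicate mix, evaluated at 0..t_max.
fit_cdf <- function(fit, t_max) {
  t <- 0:t_max
  wts <- as.numeric(table(fit$groups)) / fit$n
  cdf <- numeric(t_max + 1)
  for (r in seq_along(wts)) {
    base <- switch(fit$family,
      P = ppois(t, fit$mu[r]),
      ZIP = ppois(t, fit$mu[r]),
      NB = pnbinom(t, size = fit$theta, mu = fit$mu[r]),
      ZINB = pnbinom(t, size = fit$theta, mu = fit$mu[r]))
    if (fit$family %in% c("ZIP", "ZINB") && !is.na(fit$pi)) {
      base <- fit$pi + (1 - fit$pi) * base
    }
    cdf <- cdf + wts[r] * base
  }
  cdf
}

# Sup-distance between the empirical CDF of y and the fitted pooled CDF.
ks_stat <- function(fit, y) {
  t_max <- max(y, 1L)
  emp <- cumsum(tabulate(y + 1L, nbins = t_max + 1L)) / length(y)
  max(abs(emp - fit_cdf(fit, t_max)))
}

# Simulate one dataset from a fitted model over its replicate design.
sim_from_fit <- function(fit) {
  sizes <- as.numeric(table(fit$groups))
  y <- integer(fit$n)
  idx <- split(seq_len(fit$n), fit$groups)
  for (r in seq_along(sizes)) {
    y[idx[[r]]] <- r_family(sizes[r], fit$family, fit$mu[r], fit$theta,
                            fit$pi)
  }
  y
}

#' Parametric-bootstrap Kolmogorov-Smirnov goodness of fit
#'
#' Computes the sup-distance `D` between the empirical CDF of `y` and the
#' fitted CDF (pooled over the observed replicate mix), then simulates
#' `n_boot` datasets from the fitted model over the same replicate design,
#' refits the same family to each, and returns the add-one bootstrap
#' p-value `(1 + #\{D_b >= D\}) / (n_boot + 1)`.
#'
#' @param fit a converged `ShapeFit`.
#' @param y the count vector the fit was computed from.
#' @param n_boot bootstrap replicates (>= 19 so p can resolve 0.05).
#' @param seed integer seed for the bootstrap draws.
#' @return the bootstrap p-value, with attributes `D` (observed statistic)
#'   and `n_boot`.
#' @export
ks_gof <- function(fit, y, n_boot = 100, seed = 1) {
  stopifnot(inherits(fit, "ShapeFit"))
  if (!fit$converged) stop("fit did not converge")
  if (n_boot < 19) stop("n_boot must be >= 19")
  d_obs <- ks_stat(fit, as.integer(y))
  warm <- list(mu = unname(fit$mu), theta = fit$theta, pi = fit$pi)
  d_boot <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    yb <- sim_from_fit(fit)
    fb <- suppressWarnings(
      fit_family(yb, fit$groups, fit$family, init = warm))
    if (!fb$converged) return(1)  # degenerate draw: conservative
    ks_stat(fb, yb)
  }, numeric(1)))
  p <- (1 + sum(d_boot >= d_obs)) / (n_boot + 1)
  attr(p, "D") <- d_obs
  attr(p, "n_boot") <- n_boot
  p
}
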