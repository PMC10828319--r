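test_that("Poisson fit reproduces the closed-form MLE, likelihood and BIC", {
  f <- suppressWarnings(fit_family(c(2, 2, 2, 2), family = "P"))
  expect_equal(unname(f$mu), 2)
  expect_equal(f$loglik, 4 * dpois(2, 2, log = TRUE))
  expect_equal(f$loglik, -5.2274, tolerance = 1e-4)
  expect_equal(f$bic, 1 * log(4) - 2 * f$loglik)
  expect_equal(f$bic, 11.841, tolerance = 1e-3)
  expect_equal(f$k, 1)

  # replicate-adjusted parameter counts
  reps <- rep(c("R1", "R2", "R3"), each = 20)
  y <- rep(1L, 60)
  ks <- vapply(c(P = "P", ZIP = "ZIP", NB = "NB", ZINB = "ZINB"),
               function(fam) fit_family(y, reps, fam)$k, numeric(1))
  expect_equal(unname(ks), c(3, 4, 4, 5))

  expect_error(fit_family(c(1.5, 2), family = "P"), "non-negative integers")
  expect_error(fit_family(c(-1L, 2L), family = "P"), "non-negative integers")
})

test_that("all-zero genes are flagged non-converged in every family", {
  for (fam in c("P", "ZIP", "NB", "ZINB")) {
    f <- suppressWarnings(fit_family(rep(0L, 50), family = fam))
    expect_false(f$converged)
    expect_true(is.na(f$bic))
  }
})

test_that("ZINB fitting recovers planted parameters at n = 5000", {
  sp <- shape_spec("g", "ZINB", mu = 5, theta = 2, pi = 0.3,
                   cells_per_group = 5000)
  sim <- gen_shape_counts(list(sp), seed = 1, timepoints = "T0",
                          replicates = "R1")
  y <- as.integer(sim$matrix$counts[1, ])
  f <- fit_family(y, family = "ZINB")
  expect_lt(abs(f$pi - 0.3), 0.05)
  expect_lt(abs(unname(f$mu) - 5) / 5, 0.05)
})

test_that("replicate effects are recovered as multiplicative shifts on the mean", {
  sp <- shape_spec("g", "NB", mu = 6, theta = 3,
                   rep_effect = c(1, 1.5, 0.5), cells_per_group = 3000)
  sim <- gen_shape_counts(list(sp), seed = 3, timepoints = "T0")
  y <- as.integer(sim$matrix$counts[1, ])
  f <- fit_family(y, sim$matrix$cell_data$replicate, "NB")
  expect_equal(unname(f$mu), c(6, 9, 3), tolerance = 0.05)
  # log-link coefficients: intercept and contrasts
  expect_equal(unname(f$coef["intercept"]), log(f$mu[[1]]))
  expect_equal(unname(exp(f$coef["rep_R2"])), f$mu[[2]] / f$mu[[1]])
})

test_that("inflated families never fall below their non-inflated submodels", {
  set.seed(17)
  for (i in 1:6) {
    fam <- sample(c("P", "NB", "ZIP", "ZINB"), 1)
    sp <- switch(fam,
      P = shape_spec("g", "P", mu = runif(1, 1, 8), cells_per_group = 400),
      NB = shape_spec("g", "NB", mu = runif(1, 1, 8),
                      theta = runif(1, 0.5, 4), cells_per_group = 400),
      ZIP = shape_spec("g", "ZIP", mu = runif(1, 1, 8),
                       pi = runif(1, 0.05, 0.5), cells_per_group = 400),
      ZINB = shape_spec("g", "ZINB", mu = runif(1, 1, 8),
                        theta = runif(1, 0.5, 4), pi = runif(1, 0.05, 0.5),
                        cells_per_group = 400))
    sim <- gen_shape_counts(list(sp), seed = 100 + i, timepoints = "T0",
                            replicates = "R1")
    y <- as.integer(sim$matrix$counts[1, ])
    fits <- lapply(c("P", "ZIP", "NB", "ZINB"), function(fm) {
      fit_family(y, family = fm)
    })
    names(fits) <- c("P", "ZIP", "NB", "ZINB")
    expect_gte(fits$ZIP$loglik, fits$P$loglik - 1e-4)
    expect_gte(fits$ZINB$loglik, fits$NB$loglik - 1e-4)
  }
})

test_that("bootstrap KS p-values are bounded, calibrated and error-checked", {
  sp <- shape_spec("g", "P", mu = 3, cells_per_group = 1000)
  sim <- gen_shape_counts(list(sp), seed = 5, timepoints = "T0",
                          replicates = "R1")
  y <- as.integer(sim$matrix$counts[1, ])
  f <- fit_family(y, family = "P")
  expect_error(ks_gof(f, y, n_boot = 10), "n_boot")

  # add-one formula bounds
  p <- ks_gof(f, y, n_boot = 49, seed = 2)
  expect_gte(as.numeric(p), 1 / 50)
  expect_lte(as.numeric(p), 1)

  # calibration: data drawn from the fitted model passes in >= 90% of seeds
  passes <- vapply(1:20, function(s) {
    sims <- gen_shape_counts(list(sp), seed = 200 + s, timepoints = "T0",
                             replicates = "R1")
    ys <- as.integer(sims$matrix$counts[1, ])
    fs <- fit_family(ys, family = "P")
    as.numeric(ks_gof(fs, ys, n_boot = 99, seed = s)) > 0.05
  }, logical(1))
  expect_gte(mean(passes), 0.9)

  # point-mass data fit by a wide NB: D at least the CDF gap at the atom
  y_atom <- rep(5L, 100)
  fa <- fit_family(y_atom, family = "NB")
  pa <- ks_gof(fa, y_atom, n_boot = 19, seed = 1)
  cdf_fit_at_5 <- pnbinom(5, size = fa$theta, mu = fa$mu[[1]])
  cdf_fit_at_4 <- pnbinom(4, size = fa$theta, mu = fa$mu[[1]])
  expect_gte(attr(pa, "D"), max(abs(1 - cdf_fit_at_5), abs(cdf_fit_at_4)))
})

test_that("family assignment identifies planted P, NB and ZINB genes", {
  cases <- list(
    P = shape_spec("g", "P", mu = 3, cells_per_group = 2000),
    NB = shape_spec("g", "NB", mu = 5, theta = 0.5, cells_per_group = 2000),
    ZINB = shape_spec("g", "ZINB", mu = 8, theta = 2, pi = 0.4,
                      cells_per_group = 2000))
  for (truth in names(cases)) {
    hits <- vapply(1:10, function(i) {
      sim <- gen_shape_counts(list(cases[[truth]]), seed = 300 + i,
                              timepoints = "T0", replicates = "R1")
      a <- assign_shape(as.integer(sim$matrix$counts[1, ]), seed = i)
      a$family == truth
    }, logical(1))
    expect_gte(mean(hits), 0.9)
  }
})

test_that("assignment is invariant to cell order and NONE when nothing passes", {
  sp <- shape_spec("g", "NB", mu = 5, theta = 1, cells_per_group = 500)
  sim <- gen_shape_counts(list(sp), seed = 9, timepoints = "T0",
                          replicates = "R1")
  y <- as.integer(sim$matrix$counts[1, ])
  a1 <- assign_shape(y, seed = 4)
  set.seed(1)
  a2 <- assign_shape(sample(y), seed = 4)
  expect_equal(a1$family, a2$family)
  expect_equal(a1$fit$bic, a2$fit$bic)

  # a bimodal mixture of far-apart positive Poissons fits none of the
  # families (zero inflation cannot absorb a mode at 5)
  set.seed(2)
  y_bad <- c(rpois(200, 5), rpois(200, 60))
  a_bad <- assign_shape(y_bad, seed = 8, n_boot = 49)
  expect_equal(a_bad$family, "NONE")
  expect_null(a_bad$fit)
})

test_that("switch classification partitions all 64 family triples", {
  # paper-anchored examples
  expect_equal(classify_switch("P", "NB", "ZIP"), "distinct_triple")
  expect_equal(classify_switch("P", "NB", "P"), "reverting")
  expect_equal(classify_switch("P", "P", "P"), "stable")
  expect_equal(classify_switch("P", "P", "NB"), "single_transition")
  expect_equal(classify_switch("P", "NONE", "NB"), "unassigned")
  expect_error(classify_switch("P", "QQ", "NB"), "unknown family")

  # brute-force enumeration: counts per category over all 4^3 triples
  fams <- c("P", "ZIP", "NB", "ZINB")
  grid <- expand.grid(a = fams, b = fams, c = fams,
                      stringsAsFactors = FALSE)
  cats <- mapply(classify_switch, grid$a, grid$b, grid$c)
  expect_equal(length(cats), 64)
  tab <- table(cats)
  expect_equal(unname(tab["stable"]), 4, ignore_attr = TRUE)
  expect_equal(unname(tab["reverting"]), 4 * 3, ignore_attr = TRUE)
  expect_equal(unname(tab["single_transition"]), 24, ignore_attr = TRUE)
  expect_equal(unname(tab["distinct_triple"]), 4 * 3 * 2, ignore_attr = TRUE)
  expect_equal(sum(tab), 64)
})

test_that("shape census counts and percentages follow the chosen denominator", {
  one <- data.frame(gene = "g1", timepoint = c("T0", "T1", "T2"),
                    family = "P", stringsAsFactors = FALSE)
  cen <- shape_census(one)
  expect_equal(cen$pct[cen$family == "P"], c(100, 100, 100))

  fix <- data.frame(gene = rep(sprintf("g%02d", 1:10), 2),
                    timepoint = rep(c("T0", "T1"), each = 10),
                    family = c(rep("P", 6), rep("NB", 4),
                               rep("ZIP", 5), rep("NONE", 5)),
                    stringsAsFactors = FALSE)
  cen2 <- shape_census(fix)
  expect_equal(cen2$count[cen2$timepoint == "T0" & cen2$family == "P"], 6)
  expect_equal(cen2$pct[cen2$timepoint == "T0" & cen2$family == "P"], 60)
  # NONE rows drop out of the per-timepoint denominator
  expect_equal(cen2$pct[cen2$timepoint == "T1" & cen2$family == "ZIP"], 100)
  cen3 <- shape_census(fix, denominator = "fixed", total = 20)
  expect_equal(cen3$pct[cen3$timepoint == "T0" & cen3$family == "P"], 30)

  dup <- rbind(one, one[1, ])
  expect_error(shape_census(dup), "duplicate")
})

test_that("switch census totals handle empty, stable and mixed inputs", {
  empty <- switch_census(data.frame(gene = character(), t0 = character(),
                                    t1 = character(), t2 = character()))
  expect_equal(empty$changed_total, 0)

  stable <- data.frame(gene = paste0("g", 1:5), t0 = "P", t1 = "P",
                       t2 = "P", stringsAsFactors = FALSE)
  expect_equal(switch_census(stable)$changed_total, 0)
  expect_equal(unname(switch_census(stable)$category_counts["stable"]), 5)

  expect_error(switch_census(rbind(stable, stable[1, ])), "one record")
})
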