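# CRLBs: closed form, scaling, covariance structure, Monte-Carlo
# consistency, and delta-method derived quantities with gradient caching.

# A fit fixture reused across blocks.
uncertainty_fit <- function(sigma = 0.1, seed = 17, shared_phase = TRUE) {
  meta <- test_meta(n = 512)
  fid <- simulate_fid(two_peak_truth(), meta, sigma = sigma, seed = seed)
  fit_amares(fid, compile_prior(two_peak_prior(shared_phase = shared_phase),
                                120.3))
}

test_that("amplitude-only CRLB of an undamped sinusoid is sigma/sqrt(N)", {
  n <- 400; sigma <- 0.37
  meta <- test_meta(n = n)
  truth <- sinusoids(5, phase = 0.2, damping = 0, frequency = 150)
  fid <- simulate_fid(truth, meta, sigma = 0)
  pk <- peak_prior("S", shift = 150 / 120.3,
                   shift_bounds = 150 / 120.3 * c(1, 1),
                   linewidth = 0, linewidth_bounds = c(0, 0),
                   amplitude = 5,
                   phase = rad_to_deg(0.2),
                   phase_bounds = rad_to_deg(0.2) * c(1, 1))
  cm <- compile_prior(pk, 120.3)
  expect_equal(cm$n_free, 1L)
  fit <- fit_amares(fid, cm, amares_options(compute_uncertainty = FALSE))
  fit <- compute_crlb(fit, sigma = sigma)
  expect_rel_equal(unname(fit$crlbs["S_am"]), sigma / sqrt(n), 1e-10)
})

test_that("doubling sigma doubles every CRLB exactly", {
  fit <- uncertainty_fit()
  c1 <- compute_crlb(fit, sigma = 0.1)$crlbs
  c2 <- compute_crlb(fit, sigma = 0.2)$crlbs
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
})

test_that("covariance is symmetric positive semidefinite", {
  fit <- uncertainty_fit()
  for (C in list(fit$covariance, fit$covariance_full)) {
    expect_equal(C, t(C), tolerance = 1e-12)
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-10 * sum(diag(C))))
  }
})

test_that("CRLBs are invariant to peak order and shared over groups", {
  meta <- test_meta(n = 512)
  fid <- simulate_fid(two_peak_truth(), meta, sigma = 0.1, seed = 23)
  pk <- two_peak_prior(shared_phase = TRUE)
  fit_ab <- fit_amares(fid, compile_prior(pk, 120.3))
  fit_ba <- fit_amares(fid, compile_prior(pk[2:1, ], 120.3))
  expect_equal(fit_ab$crlbs[names(fit_ba$crlbs)], fit_ba$crlbs,
               tolerance = 1e-8)
  # shared phase parameter: identical CRLB on every member row
  expect_equal(unname(fit_ab$crlbs["PCR_ph"]),
               unname(fit_ab$crlbs["ATP_GAMMA_ph"]))
})

test_that("Monte-Carlo estimate scatter matches the CRLB at SNR 50", {
  # two-peak model, per-channel sigma = a_max / 50, 500 seeded realizations
  meta <- test_meta(n = 512)
  truth <- two_peak_truth()
  sigma <- max(truth$amplitude) / 50
  cm <- compile_prior(two_peak_prior(shared_phase = TRUE), 120.3)
  n_mc <- 500
  ests <- matrix(NA_real_, n_mc, cm$n_free)
  crlb_sum <- 0
  for (s in seq_len(n_mc)) {
    fid <- simulate_fid(truth, meta, sigma = sigma, seed = 40000 + s)
    fit <- fit_amares(fid, cm)
    ests[s, ] <- unname(fit$estimates)
    crlb_sum <- crlb_sum + sqrt(diag(fit$covariance))
  }
  mc_sd <- apply(ests, 2, sd)
  crlb <- crlb_sum / n_mc
  expect_lt(max(abs(mc_sd / crlb - 1)), 0.10)
})

test_that("identity and linear derived expressions reproduce covariance algebra", {
  cache <- local_cache_dir()
  fit <- uncertainty_fit()
  # identity: value and crlb equal the parameter's own estimate and CRLB
  d <- derived_param_crlb(fit, "PCR_am", cache_dir = cache)
  expect_equal(d$value, unname(fit$full["PCR_am"]))
  expect_equal(d$crlb, unname(fit$crlbs["PCR_am"]), tolerance = 1e-12)
  # sum: exact linear-combination variance including covariance
  d2 <- derived_param_crlb(fit, "PCR_am + ATP_GAMMA_am", cache_dir = cache)
  Cf <- fit$covariance_full
  expected <- sqrt(Cf["PCR_am", "PCR_am"] + Cf["ATP_GAMMA_am", "ATP_GAMMA_am"] +
                     2 * Cf["PCR_am", "ATP_GAMMA_am"])
  expect_equal(d2$crlb, unname(expected), tolerance = 1e-12)
})

test_that("ratio expression CRLB matches a finite-difference delta method", {
  cache <- local_cache_dir()
  meta <- test_meta(n = 512)
  f0 <- 120.3
  truth <- sinusoids(amplitude = c(10, 4, 4), phase = 0.2,
                     damping = lw_to_damping(c(12, 14, 14)),
                     frequency = c(0, ppm_to_hz(-2.48, f0) - 8.5,
                                   ppm_to_hz(-2.48, f0) + 8.5))
  fid <- simulate_fid(truth, meta, sigma = 0.15, seed = 77)
  pk <- dplyr::bind_rows(
    peak_prior("PCR", shift = 0, amplitude = 8, linewidth = 10),
    peak_prior("ATP_GAMMA", shift = -2.45, multiplet_n = 2, j_coupling = 17,
               amplitude = 3, linewidth = 12))
  fit <- fit_amares(fid, compile_prior(pk, f0))
  constants <- c(PCR_sat = 0.85, ATP_GAMMA_sat = 0.76)
  expr <- "(PCR_am / PCR_sat) / ((ATP_GAMMA1_am + ATP_GAMMA2_am) / ATP_GAMMA_sat)"
  d <- derived_param_crlb(fit, expr, constants = constants, cache_dir = cache)

  # oracle: central finite differences of the expression over free params
  eval_expr <- function(x) {
    full <- full_parameters(fit$cmap, x)
    env <- list2env(c(as.list(full), as.list(constants)))
    eval(str2lang(expr), env)
  }
  x <- unname(fit$estimates)
  g_fd <- vapply(seq_along(x), function(j) {
    h <- 1e-6 * max(abs(x[j]), 1)
    up <- x; up[j] <- up[j] + h
    dn <- x; dn[j] <- dn[j] - h
    (eval_expr(up) - eval_expr(dn)) / (2 * h)
  }, numeric(1))
  crlb_fd <- sqrt(as.numeric(t(g_fd) %*% fit$covariance %*% g_fd))
  expect_rel_equal(d$crlb, crlb_fd, 1e-8)
  expect_rel_equal(d$value, eval_expr(x), 1e-12)
})

test_that("derived expression errors name the offending identifier", {
  fit <- uncertainty_fit()
  cache <- local_cache_dir()
  expect_error(derived_param_crlb(fit, "NOPE_am + PCR_am", cache_dir = cache),
               regexp = "NOPE_am", class = "mrsfit_error_derived")
  expect_error(derived_param_crlb(fit, "PCR_am / (PCR_am - PCR_am)",
                                  cache_dir = cache),
               class = "mrsfit_error_derived")
  expect_error(derived_param_crlb(fit, "PCR_am +* 2", cache_dir = cache),
               class = "mrsfit_error_derived")
})

test_that("gradient cache avoids recompilation within and across sessions", {
  cache <- local_cache_dir()
  fit <- uncertainty_fit()
  labels <- names(fit$full)
  e1 <- "PCR_am / ATP_GAMMA_am"
  # earlier tests may have compiled the same expression in this session
  reset_derived_memory()
  n0 <- derived_compilations()
  derived_param_crlb(fit, e1, cache_dir = cache)
  expect_equal(derived_compilations(), n0 + 1L)
  # identical expression (even reformatted): cache hit
  derived_param_crlb(fit, "PCR_am   /  ATP_GAMMA_am", cache_dir = cache)
  expect_equal(derived_compilations(), n0 + 1L)
  # changed label set: miss, recompilation
  reset_derived_memory()
  warm_cache(e1, labels = c(labels, "EXTRA_am"), cache_dir = cache)
  expect_equal(derived_compilations(), n0 + 2L)
  # simulated restart: only the on-disk cache survives; still no recompile
  reset_derived_memory()
  derived_param_crlb(fit, e1, cache_dir = cache)
  expect_equal(derived_compilations(), n0 + 2L)
})

test_that("warmed cache persists across a real process restart", {
  cache <- local_cache_dir()
  fit <- uncertainty_fit()
  exprs <- sprintf("PCR_am * %d + ATP_GAMMA_am", 1:10)
  warm_cache(exprs, labels = names(fit$full), cache_dir = cache)
  script <- sprintf(
    'library(mrsfit)
     exprs <- sprintf("PCR_am * %%d + ATP_GAMMA_am", 1:10)
     labels <- readRDS("%s")
     warm_cache(exprs, labels = labels, cache_dir = "%s")
     cat(derived_compilations())',
    file.path(cache, "labels.rds"), cache)
  saveRDS(names(fit$full), file.path(cache, "labels.rds"))
  sf <- file.path(cache, "warm.R")
  writeLines(script, sf)
  out <- system2(file.path(R.home("bin"), "Rscript"), sf, stdout = TRUE)
  expect_equal(tail(out, 1), "0")
})

test_that("unwritable cache path degrades to in-memory with a warning", {
  fit <- uncertainty_fit()
  # a path that cannot become a directory: an existing regular file
  blocker <- withr::local_tempfile(lines = "x")
  expect_warning(
    res <- derived_param_crlb(fit, "PCR_am + 2 * ATP_GAMMA_am",
                              cache_dir = blocker),
    class = "mrsfit_warning_cache")
  expect_true(is.finite(res$crlb))
})
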