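# Shared fixture builders: a 31P-like acquisition at 7 T, a two-peak
# ground truth, and the matching prior knowledge. All randomness in tests
# goes through explicit seeds.

test_meta <- function(n = 512, dwell = 2.5e-4, dead = 0, f0 = 120.3,
                      ref = 0) {
  fid_meta(n, dwell_time = dwell, dead_time = dead, transmitter_freq = f0,
           reference_shift = ref)
}

two_peak_truth <- function(f0 = 120.3, phase = 0.3) {
  peaks <- sinusoids(amplitude = c(10, 5), phase = phase,
                     damping = lw_to_damping(c(12, 15)),
                     frequency = ppm_to_hz(c(0, -2.48), f0))
  peaks$component <- c("PCR", "ATP_GAMMA")
  peaks
}

two_peak_prior <- function(shift_perturb = 0, lw_scale = 1, amp_scale = 1,
                           shared_phase = FALSE) {
  gp <- if (shared_phase) "p0" else NA_character_
  dplyr::bind_rows(
    peak_prior("PCR", shift = 0 + shift_perturb, shift_bounds = c(-1, 1),
               linewidth = 12 * lw_scale, linewidth_bounds = c(2, 80),
               amplitude = 10 * amp_scale, phase = 0,
               group_phase = gp),
    peak_prior("ATP_GAMMA", shift = -2.48 + shift_perturb,
               shift_bounds = c(-3.5, -1.5),
               linewidth = 15 * lw_scale, linewidth_bounds = c(2, 80),
               amplitude = 5 * amp_scale, phase = 0,
               group_phase = gp))
}

random_sinusoids <- function(k = 2) {
  sinusoids(amplitude = runif(k, 0.5, 10),
            phase = runif(k, -pi, pi),
            damping = runif(k, 5, 80),
            frequency = runif(k, -1500, 1500),
            lineshape_g = sample(c(0, runif(1), 1), k, replace = TRUE))
}

# Central finite-difference Jacobian of the forward model: the
# independent oracle for the analytic Jacobian.
fd_model_jacobian <- function(peaks, meta, rel_step = 1e-6) {
  cols <- list()
  par_names <- c("amplitude", "phase", "damping", "frequency")
  for (k in seq_len(nrow(peaks))) {
    for (p in par_names) {
      h <- rel_step * max(abs(peaks[[p]][k]), 1)
      up <- peaks; up[[p]][k] <- up[[p]][k] + h
      dn <- peaks; dn[[p]][k] <- dn[[p]][k] - h
      cols[[length(cols) + 1]] <-
        (evaluate_model(up, meta) - evaluate_model(dn, meta)) / (2 * h)
    }
  }
  do.call(cbind, cols)
}

# Largest relative column deviation between two Jacobians.
jac_rel_err <- function(J1, J2) {
  max(vapply(seq_len(ncol(J1)), function(j) {
    denom <- max(Mod(J1[, j]), 1e-12)
    max(Mod(J1[, j] - J2[, j])) / denom
  }, numeric(1)))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}

local_cache_dir <- function(env = parent.frame()) {
  dir <- file.path(tempdir(), paste0("mrsfit-test-cache-",
                                     as.integer(stats::runif(1, 1, 1e8))))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  withr::defer(unlink(dir, recursive = TRUE), envir = env)
  dir
}

# simulate a "fresh process" for the gradient cache: drop the in-memory
# layer and the session counter, keeping only the on-disk cache
reset_derived_memory <- function() {
  state <- get(".mrsfit_state", envir = asNamespace("mrsfit"))
  state$mem_cache <- list()
  invisible(state)
}
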