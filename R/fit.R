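#' Solver and preprocessing options for the AMARES fit
#'
#' @param ftol,ptol Relative function-value and step tolerances of the
#'   bounded Levenberg-Marquardt solver.
#' @param max_iterations Iteration cap; hitting it flags the result as
#'   non-converged.
#' @param truncate_initial Number of initial FID points to drop before
#'   fitting (the dead time is advanced accordingly). Default 0: the first
#'   point receives no special treatment.
#' @param linear_init Run the linear amplitude/phase initialisation before
#'   the nonlinear fit.
#' @param compute_uncertainty Fill covariance and CRLBs after the fit.
#' @return A named list of options.
#' @export
amares_options <- function(ftol = 1e-10, ptol = 1e-10,
                           max_iterations = 1000L,
                           truncate_initial = 0L,
                           linear_init = TRUE,
                           compute_uncertainty = TRUE) {
  list(ftol = ftol, ptol = ptol,
       max_iterations = as.integer(max_iterations),
       truncate_initial = as.integer(truncate_initial),
       linear_init = isTRUE(linear_init),
       compute_uncertainty = isTRUE(compute_uncertainty))
}

# Drop the first m points, advancing the dead time.
truncate_fid <- function(fid, m) {
  if (m <= 0) return(fid)
  stop_unless(m < fid$n_points, "cannot truncate all FID points.")
  fid_series(fid$samples[-seq_len(m)], fid$dwell_time,
             fid$dead_time + m * fid$dwell_time,
             fid$transmitter_freq, fid$reference_shift, fid$nucleus)
}

#' Linear least-squares initialisation of amplitudes and phases
#'
#' First step of the AMARES fit: with frequencies, dampings and lineshapes
#' held at their starting values, the FID is solved as a linear
#' least-squares problem in the complex amplitudes `c_k` of the
#' unit-amplitude, zero-phase component bases. Free amplitude parameters
#' are set to the mean of the member magnitudes `|c_k|` divided by their
#' fixed ratios, clipped into bounds; free phase parameters to the
#' amplitude-weighted circular mean of the member phases `arg(c_k)` minus
#' their fixed offsets, wrapped and clipped into bounds. If the basis is
#' numerically rank-deficient the declared starting values are kept and a
#' warning is logged.
#'
#' @param fid A [fid_series()] with samples.
#' @param cmap A [compile_prior()] result.
#' @param x Free-parameter vector holding the starting frequencies and
#'   dampings (defaults to the declared starts).
#' @return Updated free-parameter vector.
#' @export
initialize_linear <- function(fid, cmap, x = cmap$free_start) {
  stopifnot(inherits(fid, "fid_series"), inherits(cmap, "constraint_map"))
  stop_unless(!is.null(fid$samples), "`fid` must carry samples.")
  peaks <- apply_constraints(cmap, x)
  stop_unless(all(is.finite(peaks$damping)) && all(is.finite(peaks$frequency)),
              "starting frequencies and dampings must be finite.")
  t <- fid_time_axis(fid)
  K <- nrow(peaks)
  B <- vapply(seq_len(K), function(k) {
    d <- peaks$damping[k]; f <- peaks$frequency[k]; g <- peaks$lineshape_g[k]
    exp(-d * (1 - g + g * t) * t) * exp(2i * pi * f * t)
  }, complex(fid$n_points))
  qrB <- qr(B)
  if (qrB$rank < K) {
    warn("linear initialisation basis is rank-deficient; keeping declared starting values.",
         class = "mrsfit_warning_rank_deficient")
    return(x)
  }
  cc <- as.complex(qr.coef(qrB, fid$samples))

  am_rows <- seq(1, cmap$n_full, by = 4)
  ph_rows <- seq(2, cmap$n_full, by = 4)
  out <- x
  for (idx in which(cmap$free_quantity == "amplitude")) {
    coefs <- cmap$scale[am_rows, idx]
    members <- which(coefs != 0)
    if (length(members) == 0) next
    est <- mean(Mod(cc[members]) / coefs[members])
    out[idx] <- min(max(est, cmap$free_lower[idx]), cmap$free_upper[idx])
  }
  for (idx in which(cmap$free_quantity == "phase")) {
    members <- which(cmap$scale[ph_rows, idx] != 0)
    if (length(members) == 0) next
    offs <- deg_to_rad(cmap$offset[ph_rows][members])
    z <- sum(Mod(cc[members]) * exp(1i * (Arg(cc[members]) - offs)))
    est_deg <- rad_to_deg(Arg(z))
    out[idx] <- wrap_phase_deg(est_deg, cmap$free_lower[idx], cmap$free_upper[idx])
  }
  out
}

#' Estimate the per-channel noise standard deviation from a residual
#'
#' Pools the real and imaginary residual channels:
#' `sigma = sqrt(sum(|r|^2) / (2 N - n_free))`, where `n_free` degrees of
#' freedom are removed when the residual came from a fit.
#'
#' @param residual Complex residual vector (length >= 8).
#' @param n_free Number of free parameters consumed by the fit (0 for raw
#'   noise).
#' @return Estimated standard deviation of each noise channel.
#' @export
estimate_noise <- function(residual, n_free = 0) {
  residual <- as.complex(residual)
  stop_unless(length(residual) >= 8, "residual must have at least 8 points.")
  dof <- 2 * length(residual) - n_free
  sqrt(sum(Re(residual)^2 + Im(residual)^2) / dof)
}

#' Fit an FID by prior-knowledge-constrained nonlinear least squares
#'
#' The AMARES two-step fit. Step 1 ([initialize_linear()]) solves the
#' linear least-squares problem for amplitudes and phases at the starting
#' frequencies and dampings. Step 2 minimises the time-domain residual
#' `sum_n |y_n - yhat_n(p(x))|^2` (real and imaginary parts stacked) over
#' the free parameters `x` within their box bounds, using bounded
#' Levenberg-Marquardt ([minpack.lm::nls.lm]) with the analytic model and
#' constraint Jacobians. The result carries per-parameter Cramer-Rao lower
#' bounds computed from the constrained Fisher information (see
#' [compute_crlb()]).
#'
#' @param fid A [fid_series()] with samples.
#' @param cmap A [compile_prior()] result (or a [peak_prior()] tibble,
#'   which is compiled against the FID's transmitter frequency and
#'   reference shift).
#' @param options An [amares_options()] list.
#' @return An object of class `amares_fit`; see [tidy.amares_fit()] and
#'   [glance.amares_fit()].
#' @examples
#' meta <- fid_meta(512, dwell_time = 2.5e-4, transmitter_freq = 120.3)
#' truth <- sinusoids(c(10, 5), damping = lw_to_damping(c(12, 15)),
#'                    frequency = ppm_to_hz(c(0, -2.48), 120.3))
#' fid <- simulate_fid(truth, meta, sigma = 0.05, seed = 42)
#' pk <- dplyr::bind_rows(
#'   peak_prior("PCR", shift = 0, amplitude = 8),
#'   peak_prior("ATP_GAMMA", shift = -2.4, amplitude = 4))
#' fit <- fit_amares(fid, pk)
#' tidy(fit)
#' @export
fit_amares <- function(fid, cmap, options = amares_options()) {
  stopifnot(inherits(fid, "fid_series"))
  if (!inherits(cmap, "constraint_map")) {
    cmap <- compile_prior(cmap, fid$transmitter_freq, fid$reference_shift)
  }
  stop_unless(!is.null(fid$samples), "`fid` must carry samples.")
  if (any(!is.finite(Re(fid$samples))) || any(!is.finite(Im(fid$samples)))) {
    abort("FID samples contain non-finite values.",
          class = "mrsfit_error_validation")
  }
  fid <- truncate_fid(fid, options$truncate_initial)
  stop_unless(fid$n_points > cmap$n_free,
              "need more data points than free parameters.")

  x0 <- cmap$free_start
  if (options$linear_init) {
    x0 <- initialize_linear(fid, cmap, x0)
  }
  y <- fid$samples

  residual_fn <- function(x) {
    r <- y - evaluate_model(apply_constraints(cmap, x), fid)
    c(Re(r), Im(r))
  }
  jacobian_fn <- function(x) {
    peaks <- apply_constraints(cmap, x)
    Jc <- model_jacobian(peaks, fid) %*% constraint_jacobian(cmap, x)
    -rbind(Re(Jc), Im(Jc))
  }

  sol <- minpack.lm::nls.lm(
    par = x0, lower = cmap$free_lower, upper = cmap$free_upper,
    fn = residual_fn, jac = jacobian_fn,
    control = minpack.lm::nls.lm.control(
      ftol = options$ftol, ptol = options$ptol,
      maxiter = options$max_iterations,
      maxfev = 100 * (cmap$n_free + 1)^2))

  x_hat <- pmin(pmax(unname(sol$par), cmap$free_lower), cmap$free_upper)
  peaks_hat <- apply_constraints(cmap, x_hat)
  residual <- y - evaluate_model(peaks_hat, fid)
  sigma <- estimate_noise(residual, n_free = cmap$n_free)
  converged <- sol$info %in% c(1L, 2L, 3L, 4L) &&
    sol$niter < options$max_iterations

  fit <- structure(
    list(estimates = setNames(x_hat, cmap$free_labels),
         full = full_parameters(cmap, x_hat),
         peaks = peaks_hat,
         cmap = cmap,
         fid = fid,
         residual = residual,
         noise_sigma = sigma,
         covariance = NULL,
         covariance_full = NULL,
         crlbs = NULL,
         converged = converged,
         solver_info = sol$info,
         solver_message = sol$message,
         n_iterations = sol$niter,
         rss_trace = sol$rsstrace,
         deviance = sol$deviance,
         at_bound = x_hat <= cmap$free_lower | x_hat >= cmap$free_upper,
         options = options),
    class = "amares_fit")

  if (options$compute_uncertainty && sigma > 0) {
    fit <- compute_crlb(fit)
  }
  fit
}

#' @export
print.amares_fit <- function(x, ...) {
  cat(sprintf("<amares_fit> %d component(s), %d free parameter(s), %s in %d iteration(s)\n",
              x$cmap$n_components, x$cmap$n_free,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  cat(sprintf("residual sum of squares %.6g, noise sigma %.6g\n",
              x$deviance, x$noise_sigma))
  print(peak_estimates(x))
  invisible(x)
}

#' Per-component fit results in user units
#'
#' @param fit An [fit_amares()] result.
#' @return A tibble with one row per sinusoid component: amplitude,
#'   phase (degrees), linewidth (Hz FWHM), chemical shift (ppm), and the
#'   matching CRLBs when available.
#' @export
peak_estimates <- function(fit) {
  stopifnot(inherits(fit, "amares_fit"))
  full <- fit$full
  pick <- function(sfx) unname(full[seq(match(sfx, pk_suffix), length(full), by = 4)])
  out <- tibble(
    component = fit$cmap$components$component,
    peak = fit$cmap$components$parent,
    amplitude = pick("am"),
    phase_deg = pick("ph"),
    linewidth_hz = pick("lw"),
    shift_ppm = pick("cs"))
  if (!is.null(fit$crlbs)) {
    pickc <- function(sfx) unname(fit$crlbs[seq(match(sfx, pk_suffix),
                                                length(fit$crlbs), by = 4)])
    out$amplitude_crlb <- pickc("am")
    out$phase_crlb <- pickc("ph")
    out$linewidth_crlb <- pickc("lw")
    out$shift_crlb <- pickc("cs")
  }
  out
}

#' Tidy an AMARES fit into one row per parameter
#'
#' @param x An [fit_amares()] result.
#' @param ... Unused.
#' @return A tibble with columns `term` (full-parameter label), `component`,
#'   `quantity`, `estimate`, `crlb`.
#' @method tidy amares_fit
#' @export
tidy.amares_fit <- function(x, ...) {
  tibble(
    term = names(x$full),
    component = rep(x$cmap$components$component, each = 4),
    quantity = rep(c("amplitude", "phase_deg", "linewidth_hz", "shift_ppm"),
                   x$cmap$n_components),
    estimate = unname(x$full),
    crlb = if (is.null(x$crlbs)) NA_real_ else unname(x$crlbs))
}

#' One-row summary of an AMARES fit
#'
#' @inheritParams tidy.amares_fit
#' @return A one-row tibble: residual sum of squares, noise sigma, free
#'   parameter count, iterations, convergence flag.
#' @method glance amares_fit
#' @export
glance.amares_fit <- function(x, ...) {
  tibble(rss = x$deviance,
         noise_sigma = x$noise_sigma,
         n_free = x$cmap$n_free,
         n_points = x$fid$n_points,
         n_iterations = x$n_iterations,
         converged = x$converged)
}
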