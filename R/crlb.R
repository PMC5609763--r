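#' Cramer-Rao lower bounds from the constrained Fisher information
#'
#' With `J` the complex model Jacobian at the estimates (columns per
#' sinusoid in internal units) and `D` the constraint Jacobian mapping free
#' parameters to internal parameters, the Fisher information for complex
#' data whose real and imaginary channels carry independent `N(0, sigma^2)`
#' noise is `F = Re(J^H J) / sigma^2`. The free-parameter covariance is
#' `C = (D' F D)^-1`; the full-parameter covariance in user units is
#' `S C S'` with `S` the affine constraint `scale` matrix, and each CRLB is
#' the square root of its diagonal — so grouped parameters share one CRLB
#' and the covariance between parameters is fully retained for derived
#' quantities ([derived_param_crlb()]).
#'
#' Box bounds are ignored in the information matrix (the standard
#' unconstrained-information CRLB); estimates sitting on a bound are
#' flagged via `fit$at_bound`. A singular `D' F D` falls back to the
#' Moore-Penrose pseudo-inverse with a conditioning warning and
#' `fit$ill_conditioned = TRUE`.
#'
#' @param fit An [fit_amares()] result.
#' @param sigma Per-channel noise standard deviation (defaults to the
#'   fit's residual estimate).
#' @return The fit with `covariance` (free parameters, user units),
#'   `covariance_full` (full labels, user units) and `crlbs` filled.
#' @export
compute_crlb <- function(fit, sigma = fit$noise_sigma) {
  stopifnot(inherits(fit, "amares_fit"))
  stop_unless(is.numeric(sigma) && length(sigma) == 1 && sigma > 0,
              "`sigma` must be a single positive number.")
  cmap <- fit$cmap
  J <- model_jacobian(fit$peaks, fit$fid)
  D <- constraint_jacobian(cmap, unname(fit$estimates))
  Fisher <- Re(Conj(t(J)) %*% J) / sigma^2
  Ffree <- t(D) %*% Fisher %*% D
  C <- tryCatch(solve(Ffree), error = function(e) NULL)
  ill <- is.null(C)
  if (ill) {
    warn("Fisher information is singular; using pseudo-inverse — CRLBs are unreliable.",
         class = "mrsfit_warning_conditioning")
    C <- pseudo_inverse(Ffree)
  }
  C <- (C + t(C)) / 2
  dimnames(C) <- list(cmap$free_labels, cmap$free_labels)
  Cfull <- cmap$scale %*% C %*% t(cmap$scale)
  dimnames(Cfull) <- list(cmap$labels, cmap$labels)
  fit$covariance <- C
  fit$covariance_full <- Cfull
  fit$crlbs <- setNames(sqrt(pmax(diag(Cfull), 0)), cmap$labels)
  fit$crlb_sigma <- sigma
  fit$ill_conditioned <- ill
  if (any(fit$at_bound)) {
    fit$crlb_bound_warning <- cmap$free_labels[fit$at_bound]
  }
  fit
}

pseudo_inverse <- function(M, tol = 1e-12) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
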