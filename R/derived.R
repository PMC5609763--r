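# Delta-method CRLBs for derived quantities: arbitrary arithmetic
# expressions over full-parameter labels (e.g. "PCR_am") and named scalar
# constants (e.g. "PCR_sat"). Gradients are obtained by symbolic
# differentiation (stats::D) once per (expression, label set) and cached
# on disk, so later calls — including in later sessions pointing at the
# same cache directory — perform no symbolic work.

derived_cache_version <- 1L

.mrsfit_state <- new.env(parent = emptyenv())
.mrsfit_state$n_symbolic <- 0L
.mrsfit_state$mem_cache <- list()

#' Number of symbolic-differentiation compilations performed
#'
#' Instrumentation counter for the derived-quantity gradient cache: it
#' increments once per expression actually differentiated, and stays flat
#' on cache hits.
#'
#' @return Integer count for this session.
#' @export
derived_compilations <- function() .mrsfit_state$n_symbolic

#' Default on-disk location of the derived-gradient cache
#'
#' @return Directory path (created on demand); override per call via the
#'   `cache_dir` argument or globally via `options(mrsfit.cache_dir = )`.
#' @export
mrsfit_cache_dir <- function() {
  getOption("mrsfit.cache_dir", file.path(tempdir(), "mrsfit-cache"))
}

derived_cache_file <- function(cache_dir) {
  file.path(cache_dir, sprintf("derived-cache-v%d.rds", derived_cache_version))
}

canonical_expression <- function(expression) {
  lang <- tryCatch(str2lang(expression), error = function(e) {
    abort(sprintf("cannot parse expression '%s': %s", expression,
                  conditionMessage(e)),
          class = "mrsfit_error_derived")
  })
  list(lang = lang, canon = paste(deparse(lang), collapse = " "))
}

derived_cache_key <- function(canon, labels) {
  rlang::hash(list(derived_cache_version, canon, sort(labels)))
}

read_derived_cache <- function(cache_dir) {
  f <- derived_cache_file(cache_dir)
  if (!file.exists(f)) return(list())
  entries <- tryCatch(readRDS(f), error = function(e) NULL)
  if (!is.list(entries)) return(list())
  entries
}

write_derived_cache <- function(entries, cache_dir) {
  ok <- dir.exists(cache_dir) || dir.create(cache_dir, recursive = TRUE,
                                            showWarnings = FALSE)
  if (!ok || file.access(cache_dir, mode = 2) != 0) {
    warn(sprintf("cache directory '%s' is not writable; keeping gradients in memory only.",
                 cache_dir),
         class = "mrsfit_warning_cache")
    return(invisible(FALSE))
  }
  saveRDS(entries, derived_cache_file(cache_dir))
  invisible(TRUE)
}

# Compile (or fetch) the gradient of an expression w.r.t. the labels that
# appear in it. Returns list(canon, vars, grad) with grad a named list of
# deparsed derivative expressions.
compile_derived <- function(expression, labels, cache_dir) {
  ce <- canonical_expression(expression)
  key <- derived_cache_key(ce$canon, labels)
  hit <- .mrsfit_state$mem_cache[[key]]
  if (!is.null(hit)) return(hit)
  disk <- read_derived_cache(cache_dir)
  hit <- disk[[key]]
  if (!is.null(hit)) {
    .mrsfit_state$mem_cache[[key]] <- hit
    return(hit)
  }
  vars <- intersect(all.vars(ce$lang), labels)
  grad <- lapply(setNames(vars, vars), function(v) {
    paste(deparse(D(ce$lang, v)), collapse = " ")
  })
  .mrsfit_state$n_symbolic <- .mrsfit_state$n_symbolic + 1L
  entry <- list(canon = ce$canon, vars = vars, grad = grad)
  .mrsfit_state$mem_cache[[key]] <- entry
  disk[[key]] <- entry
  write_derived_cache(disk, cache_dir)
  entry
}

#' Value and CRLB of a derived expression of the fit parameters
#'
#' Evaluates an arithmetic expression over full-parameter labels and named
#' constants at the fitted estimates, and propagates the full parameter
#' covariance through its gradient (delta method):
#' `crlb = sqrt(g' C g)` with `g` the expression gradient mapped onto the
#' free parameters. Because the full covariance — including
#' cross-covariances — enters, sums and ratios of correlated amplitudes
#' (e.g. a saturation-corrected
#' `"(PCR_am / PCR_sat) / ((ATP_GAMMA1_am + ATP_GAMMA2_am) / ATP_GAMMA_sat)"`)
#' get tighter, correct bounds than any independent-error combination.
#'
#' Gradients are compiled symbolically once per (expression, label set)
#' and reused from the on-disk cache afterwards (see [warm_cache()],
#' [derived_compilations()]).
#'
#' @param fit An [fit_amares()] result with covariance filled (see
#'   [compute_crlb()]).
#' @param expression Character scalar; identifiers must be full-parameter
#'   labels of the fit or names in `constants`.
#' @param constants Named numeric vector of scalar constants.
#' @param cache_dir Directory for the persistent gradient cache.
#' @return A one-row tibble: `expression`, `value`, `crlb`, and a
#'   list-column `gradient` (named vector over the free parameters).
#' @export
derived_param_crlb <- function(fit, expression, constants = c(),
                               cache_dir = mrsfit_cache_dir()) {
  stopifnot(inherits(fit, "amares_fit"))
  if (is.null(fit$covariance)) {
    abort("fit has no covariance; run compute_crlb() first.",
          class = "mrsfit_error_derived")
  }
  labels <- names(fit$full)
  ce <- canonical_expression(expression)
  idents <- all.vars(ce$lang)
  unknown <- setdiff(idents, c(labels, names(constants)))
  if (length(unknown) > 0) {
    abort(sprintf("unknown identifier '%s' in expression '%s' (not a parameter label or constant).",
                  unknown[1], expression),
          class = "mrsfit_error_derived")
  }
  entry <- compile_derived(expression, labels, cache_dir)
  env <- list2env(c(as.list(fit$full), as.list(constants)),
                  parent = baseenv())
  value <- eval(ce$lang, env)
  if (!is.finite(value)) {
    abort(sprintf("expression '%s' is not finite at the estimates (division by zero or invalid operand).",
                  expression),
          class = "mrsfit_error_derived")
  }
  g_full <- numeric(length(labels))
  names(g_full) <- labels
  for (v in entry$vars) {
    gv <- eval(str2lang(entry$grad[[v]]), env)
    if (!is.finite(gv)) {
      abort(sprintf("gradient of '%s' with respect to '%s' is not finite at the estimates.",
                    expression, v),
            class = "mrsfit_error_derived")
    }
    g_full[v] <- gv
  }
  g_free <- as.numeric(t(fit$cmap$scale) %*% g_full)
  names(g_free) <- fit$cmap$free_labels
  crlb <- sqrt(max(as.numeric(t(g_free) %*% fit$covariance %*% g_free), 0))
  tibble(expression = expression, value = as.numeric(value), crlb = crlb,
         gradient = list(g_free))
}

#' Pre-compile derived-expression gradients into the cache
#'
#' After warming, [derived_param_crlb()] calls for these expressions — in
#' this session or any later one pointing at the same cache directory —
#' perform no symbolic differentiation.
#'
#' @param expressions Character vector of expressions.
#' @param labels Full-parameter label set they will be evaluated against
#'   (e.g. `names(fit$full)`).
#' @param cache_dir Directory for the persistent gradient cache.
#' @return The cache file path, invisibly.
#' @export
warm_cache <- function(expressions, labels, cache_dir = mrsfit_cache_dir()) {
  for (e in expressions) compile_derived(e, labels, cache_dir)
  invisible(derived_cache_file(cache_dir))
}
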