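pk_file_version <- 1L

# Fields a prior-knowledge record may carry, with the peak_prior() argument
# each maps onto. Used both for validation (unknown/malformed fields are
# reported by name) and for writing.
pk_file_fields <- c(
  "name", "shift", "shift_bounds", "linewidth", "linewidth_bounds",
  "amplitude", "amplitude_bounds", "phase", "phase_bounds", "lineshape_g",
  "multiplet_n", "j_coupling", "amplitude_ratios",
  "group_amplitude", "group_linewidth", "group_phase", "group_shift",
  "amplitude_ratio", "phase_offset", "shift_offset", "base_linewidth")

#' Read or write a prior-knowledge file
#'
#' Prior knowledge lives in a declarative YAML file: a `version` field and
#' a `peaks` list whose records take the same fields as [peak_prior()]
#' arguments (bounds as two-element lists). A schema description ships as
#' `system.file("extdata", "prior_knowledge_schema.yaml", package =
#' "mrsfit")`, alongside an illustrative 7 T cardiac 31P peak set
#' (`pk_7t_cardiac_31p.yaml`: PCr, the gamma/alpha/beta-ATP multiplets,
#' PDE and 2,3-DPG with a shared phase; the numeric bounds are
#' repository fixtures, not literature values).
#'
#' @param path File path.
#' @return `read_prior_knowledge()`: a tibble of [peak_prior()] rows.
#' @export
read_prior_knowledge <- function(path) {
  stop_unless(file.exists(path), sprintf("prior-knowledge file '%s' not found.", path),
              class = "mrsfit_error_io")
  doc <- yaml::read_yaml(path)
  if (is.null(doc$version) || doc$version != pk_file_version) {
    abort(sprintf("prior-knowledge file '%s': field 'version' must be %d.",
                  path, pk_file_version),
          class = "mrsfit_error_schema")
  }
  if (is.null(doc$peaks) || length(doc$peaks) == 0) {
    abort(sprintf("prior-knowledge file '%s': field 'peaks' is missing or empty.", path),
          class = "mrsfit_error_schema")
  }
  peaks <- purrr::map_dfr(seq_along(doc$peaks), function(i) {
    rec <- doc$peaks[[i]]
    unknown <- setdiff(names(rec), pk_file_fields)
    if (length(unknown) > 0) {
      abort(sprintf("prior-knowledge file '%s', peak %d: unknown field '%s'.",
                    path, i, unknown[1]),
            class = "mrsfit_error_schema")
    }
    for (fld in c("name", "shift")) {
      if (is.null(rec[[fld]])) {
        abort(sprintf("prior-knowledge file '%s', peak %d: required field '%s' is missing.",
                      path, i, fld),
              class = "mrsfit_error_schema")
      }
    }
    for (fld in grep("_bounds$", names(rec), value = TRUE)) {
      if (length(rec[[fld]]) != 2) {
        abort(sprintf("prior-knowledge file '%s', peak '%s': field '%s' must have two entries.",
                      path, rec$name, fld),
              class = "mrsfit_error_schema")
      }
      rec[[fld]] <- as.numeric(rec[[fld]])
    }
    do.call(peak_prior, rec)
  })
  validate_priors(peaks)
  peaks
}

#' @rdname read_prior_knowledge
#' @param priors Tibble of [peak_prior()] rows.
#' @return `write_prior_knowledge()`: `path`, invisibly.
#' @export
write_prior_knowledge <- function(priors, path) {
  validate_priors(priors)
  defaults <- peak_prior("x", shift = 0)
  recs <- purrr::map(seq_len(nrow(priors)), function(i) {
    p <- priors[i, ]
    rec <- list(
      name = p$name,
      shift = p$shift_start, shift_bounds = c(p$shift_lower, p$shift_upper),
      linewidth = p$linewidth_start,
      linewidth_bounds = c(p$linewidth_lower, p$linewidth_upper),
      amplitude = p$amplitude_start,
      amplitude_bounds = c(p$amplitude_lower, p$amplitude_upper),
      phase = p$phase_start, phase_bounds = c(p$phase_lower, p$phase_upper),
      lineshape_g = p$lineshape_g,
      multiplet_n = p$multiplet_n, j_coupling = p$j_coupling,
      amplitude_ratios = p$amplitude_ratios[[1]],
      group_amplitude = p$group_amplitude, group_linewidth = p$group_linewidth,
      group_phase = p$group_phase, group_shift = p$group_shift,
      amplitude_ratio = p$amplitude_ratio, phase_offset = p$phase_offset,
      shift_offset = p$shift_offset, base_linewidth = p$base_linewidth)
    rec[!vapply(rec, function(v) all(is.na(v)), logical(1))]
  })
  yaml::write_yaml(list(version = pk_file_version, peaks = recs), path)
  invisible(path)
}

#' Illustrative 7 T cardiac 31P prior knowledge
#'
#' Loads the shipped example peak set (PCr, gamma/alpha/beta-ATP
#' multiplets, PDE, 2,3-DPG) used throughout the documentation and tests.
#' The numeric bounds are illustrative fixtures for synthetic data.
#'
#' @return A tibble of [peak_prior()] rows.
#' @export
pk_cardiac_31p <- function() {
  read_prior_knowledge(system.file("extdata", "pk_7t_cardiac_31p.yaml",
                                   package = "mrsfit", mustWork = TRUE))
}
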