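#' Declare prior knowledge for one spectral peak
#'
#' AMARES-style fitting constrains every peak by prior knowledge: starting
#' values and box bounds for its chemical shift (ppm), linewidth (Hz FWHM),
#' amplitude (signal units) and phase (degrees), a fixed lineshape, and
#' optional relationships to other peaks. Relationships are expressed via
#' group identifiers: all peaks naming the same `group_*` id share a single
#' free parameter for that quantity, with per-peak additive offsets
#' (`shift_offset` ppm, `phase_offset` degrees, `base_linewidth` Hz) and a
#' multiplicative `amplitude_ratio`. A multiplet peak is expanded into
#' `multiplet_n` sinusoid components spaced `j_coupling` Hz apart,
#' symmetric about the peak's chemical shift, with fixed
#' `amplitude_ratios` (binomial by default) tied to one free amplitude.
#'
#' A quantity whose lower and upper bounds coincide is held fixed at that
#' value and contributes no free parameter.
#'
#' @param name Unique peak identifier; full-parameter labels are derived
#'   from it (`<NAME>_am`, `<NAME>_ph`, `<NAME>_lw`, `<NAME>_cs`, with
#'   multiplet components suffixed `1..n`).
#' @param shift,shift_bounds Starting chemical shift (ppm) and bounds
#'   `c(lower, upper)`.
#' @param linewidth,linewidth_bounds Starting linewidth (Hz FWHM) and bounds.
#' @param amplitude,amplitude_bounds Starting amplitude and bounds.
#' @param phase,phase_bounds Starting phase (degrees) and bounds.
#' @param lineshape_g Lineshape in `[0,1]`: 0 Lorentzian, 1 Gaussian. Fixed
#'   during fitting.
#' @param multiplet_n Number of multiplet components (1 = singlet).
#' @param j_coupling J-coupling in Hz between adjacent components.
#' @param amplitude_ratios Relative component amplitudes (length
#'   `multiplet_n`); defaults to binomial coefficients.
#' @param group_amplitude,group_linewidth,group_phase,group_shift Optional
#'   group ids tying this quantity to one shared free parameter.
#' @param amplitude_ratio Multiplier on the shared group amplitude
#'   (requires `group_amplitude`).
#' @param phase_offset Additive offset (degrees) on the shared group phase.
#' @param shift_offset Additive offset (ppm) on the shared group shift.
#' @param base_linewidth Additive offset (Hz) on the (own or group)
#'   linewidth free parameter.
#' @return A one-row tibble; combine peaks with [dplyr::bind_rows()].
#' @seealso [compile_prior()], [read_prior_knowledge()]
#' @export
peak_prior <- function(name,
                       shift, shift_bounds = shift + c(-1, 1),
                       linewidth = 20, linewidth_bounds = c(1, 200),
                       amplitude = 1, amplitude_bounds = c(0, Inf),
                       phase = 0, phase_bounds = c(-180, 180),
                       lineshape_g = 0,
                       multiplet_n = 1L, j_coupling = 0,
                       amplitude_ratios = NULL,
                       group_amplitude = NA_character_,
                       group_linewidth = NA_character_,
                       group_phase = NA_character_,
                       group_shift = NA_character_,
                       amplitude_ratio = 1,
                       phase_offset = 0,
                       shift_offset = 0,
                       base_linewidth = 0) {
  multiplet_n <- as.integer(multiplet_n)
  if (is.null(amplitude_ratios)) {
    amplitude_ratios <- choose(multiplet_n - 1, seq_len(multiplet_n) - 1)
  }
  tibble(
    name = as.character(name),
    shift_start = shift, shift_lower = shift_bounds[1], shift_upper = shift_bounds[2],
    linewidth_start = linewidth, linewidth_lower = linewidth_bounds[1],
    linewidth_upper = linewidth_bounds[2],
    amplitude_start = amplitude, amplitude_lower = amplitude_bounds[1],
    amplitude_upper = amplitude_bounds[2],
    phase_start = phase, phase_lower = phase_bounds[1], phase_upper = phase_bounds[2],
    lineshape_g = lineshape_g,
    multiplet_n = multiplet_n,
    j_coupling = j_coupling,
    amplitude_ratios = list(as.numeric(amplitude_ratios)),
    group_amplitude = group_amplitude,
    group_linewidth = group_linewidth,
    group_phase = group_phase,
    group_shift = group_shift,
    amplitude_ratio = amplitude_ratio,
    phase_offset = phase_offset,
    shift_offset = shift_offset,
    base_linewidth = base_linewidth
  )
}

pk_quantities <- c("amplitude", "phase", "linewidth", "shift")
pk_suffix <- c(amplitude = "am", phase = "ph", linewidth = "lw", shift = "cs")

validate_priors <- function(priors) {
  stop_unless(is.data.frame(priors) && nrow(priors) >= 1,
              "prior knowledge must be a data frame with at least one peak.")
  if (anyDuplicated(priors$name)) {
    abort(paste0("duplicate peak name(s): ",
                 paste(unique(priors$name[duplicated(priors$name)]),
                       collapse = ", ")),
          class = "mrsfit_error_prior")
  }
  for (q in pk_quantities) {
    lo <- priors[[paste0(q, "_lower")]]
    st <- priors[[paste0(q, "_start")]]
    hi <- priors[[paste0(q, "_upper")]]
    bad <- which(!(lo <= st & st <= hi))
    if (length(bad) > 0) {
      abort(sprintf("peak '%s': %s bounds must satisfy lower <= start <= upper.",
                    priors$name[bad[1]], q),
            class = "mrsfit_error_prior")
    }
  }
  bad_ratio <- which(priors$amplitude_ratio != 1 & is.na(priors$group_amplitude))
  if (length(bad_ratio) > 0) {
    abort(sprintf(
      "peak '%s': amplitude_ratio requires group_amplitude to be set.",
      priors$name[bad_ratio[1]]), class = "mrsfit_error_prior")
  }
  bad_po <- which(priors$phase_offset != 0 & is.na(priors$group_phase))
  if (length(bad_po) > 0) {
    abort(sprintf("peak '%s': phase_offset requires group_phase to be set.",
                  priors$name[bad_po[1]]), class = "mrsfit_error_prior")
  }
  bad_so <- which(priors$shift_offset != 0 & is.na(priors$group_shift))
  if (length(bad_so) > 0) {
    abort(sprintf("peak '%s': shift_offset requires group_shift to be set.",
                  priors$name[bad_so[1]]), class = "mrsfit_error_prior")
  }
  for (i in seq_len(nrow(priors))) {
    r <- priors$amplitude_ratios[[i]]
    if (length(r) != priors$multiplet_n[i] || any(!(r > 0))) {
      abort(sprintf(
        "peak '%s': amplitude_ratios must have %d positive entries.",
        priors$name[i], priors$multiplet_n[i]), class = "mrsfit_error_prior")
    }
  }
  invisible(priors)
}

#' Compile prior knowledge into an affine constraint map
#'
#' Turns the declarative per-peak table into (i) a list of sinusoid
#' components (multiplets expanded), (ii) an affine map `p = S x + o` from
#' the free parameter vector `x` to the full per-component parameter vector
#' `p` (user units: signal units, degrees, Hz FWHM, ppm; full labels in the
#' fixed order `am, ph, lw, cs` per component), and (iii) bounds and
#' starting values for `x`. Every row of `S` has at most one nonzero entry,
#' so constraints are separable-affine: grouped quantities share a free
#' parameter, multiplet amplitudes are fixed ratios of one free amplitude,
#' multiplet shifts are fixed offsets of one free shift, `base_linewidth`
#' is an additive constant. Bounds of a shared parameter are the
#' intersection of its members' bounds; its start is the mean of members'
#' starts clipped into those bounds.
#'
#' @param priors Tibble of [peak_prior()] rows.
#' @param transmitter_freq Transmitter frequency in MHz (needed to convert
#'   J-couplings and chemical shifts to model frequencies).
#' @param reference_shift Chemical shift (ppm) mapped to 0 Hz.
#' @return An object of class `constraint_map`.
#' @examples
#' pk <- dplyr::bind_rows(
#'   peak_prior("PCR", shift = 0, amplitude = 10, group_phase = "ph0"),
#'   peak_prior("ATP_GAMMA", shift = -2.48, amplitude = 5, multiplet_n = 2,
#'              j_coupling = 17, group_phase = "ph0"))
#' cm <- compile_prior(pk, transmitter_freq = 120.3)
#' cm$free_labels
#' @export
compile_prior <- function(priors, transmitter_freq, reference_shift = 0) {
  validate_priors(priors)
  stop_unless(is.numeric(transmitter_freq) && transmitter_freq > 0,
              "`transmitter_freq` must be positive (MHz).")

  # --- expand multiplets into components -------------------------------
  comps <- purrr::map_dfr(seq_len(nrow(priors)), function(i) {
    p <- priors[i, ]
    n <- p$multiplet_n
    ratios <- p$amplitude_ratios[[1]]
    # components symmetric about the parent shift, spaced J Hz apart
    centred <- (seq_len(n) - (n + 1) / 2) * p$j_coupling / transmitter_freq
    tibble(
      component = if (n == 1) p$name else paste0(p$name, seq_len(n)),
      parent = p$name,
      parent_row = i,
      ratio = ratios,
      shift_comp_offset = centred,
      lineshape_g = p$lineshape_g
    )
  })

  # --- owners: one free parameter per (quantity, peak-or-group) --------
  owner_key <- function(p, q) {
    gid <- p[[paste0("group_", q)]]
    if (q %in% c("amplitude", "phase", "linewidth", "shift") && !is.na(gid)) {
      paste0("group:", q, ":", gid)
    } else {
      paste0("peak:", q, ":", p$name)
    }
  }
  owner_label <- function(key) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    paste0(parts[3], "_", pk_suffix[[parts[2]]])
  }

  owners <- list()  # key -> list(lower, upper, starts, members)
  for (i in seq_len(nrow(priors))) {
    p <- priors[i, ]
    for (q in pk_quantities) {
      key <- owner_key(p, q)
      lo <- p[[paste0(q, "_lower")]]
      hi <- p[[paste0(q, "_upper")]]
      st <- p[[paste0(q, "_start")]]
      if (is.null(owners[[key]])) {
        owners[[key]] <- list(lower = lo, upper = hi, starts = st,
                              members = p$name, quantity = q)
      } else {
        o <- owners[[key]]
        o$lower <- max(o$lower, lo)
        o$upper <- min(o$upper, hi)
        o$starts <- c(o$starts, st)
        o$members <- c(o$members, p$name)
        owners[[key]] <- o
      }
    }
  }
  for (key in names(owners)) {
    o <- owners[[key]]
    if (o$lower > o$upper) {
      abort(sprintf(
        "incompatible bounds for shared parameter '%s' (intersection empty).",
        owner_label(key)), class = "mrsfit_error_prior")
    }
    owners[[key]]$start <- min(max(mean(o$starts), o$lower), o$upper)
    owners[[key]]$fixed <- o$lower == o$upper
  }

  # assign free indices in peak order, quantity order am, ph, lw, cs
  free_keys <- character(0)
  for (i in seq_len(nrow(priors))) {
    p <- priors[i, ]
    for (q in pk_quantities) {
      key <- owner_key(p, q)
      if (!owners[[key]]$fixed && !(key %in% free_keys)) {
        free_keys <- c(free_keys, key)
      }
    }
  }
  free_index <- setNames(seq_along(free_keys), free_keys)
  n_free <- length(free_keys)

  # --- full rows: 4 per component in order am, ph, lw, cs --------------
  n_comp <- nrow(comps)
  n_full <- 4L * n_comp
  scale <- matrix(0, n_full, n_free)
  offset <- numeric(n_full)
  labels <- character(n_full)
  for (ci in seq_len(n_comp)) {
    cmp <- comps[ci, ]
    p <- priors[cmp$parent_row, ]
    rows <- 4L * (ci - 1L) + 1:4
    labels[rows] <- paste0(cmp$component, "_", pk_suffix[pk_quantities])
    specs <- list(
      amplitude = list(coef = cmp$ratio *
                         (if (!is.na(p$group_amplitude)) p$amplitude_ratio else 1),
                       off = 0),
      phase = list(coef = 1, off = if (!is.na(p$group_phase)) p$phase_offset else 0),
      linewidth = list(coef = 1, off = p$base_linewidth),
      shift = list(coef = 1,
                   off = cmp$shift_comp_offset +
                     (if (!is.na(p$group_shift)) p$shift_offset else 0))
    )
    for (j in seq_along(pk_quantities)) {
      q <- pk_quantities[j]
      key <- owner_key(p, q)
      o <- owners[[key]]
      sp <- specs[[q]]
      row <- rows[j]
      if (o$fixed) {
        offset[row] <- sp$coef * o$lower + sp$off
      } else {
        scale[row, free_index[[key]]] <- sp$coef
        offset[row] <- sp$off
      }
    }
  }

  structure(
    list(
      n_free = n_free,
      n_full = n_full,
      n_components = n_comp,
      scale = scale,
      offset = offset,
      labels = labels,
      free_labels = vapply(free_keys, owner_label, character(1), USE.NAMES = FALSE),
      free_lower = vapply(free_keys, function(k) owners[[k]]$lower, numeric(1), USE.NAMES = FALSE),
      free_upper = vapply(free_keys, function(k) owners[[k]]$upper, numeric(1), USE.NAMES = FALSE),
      free_start = vapply(free_keys, function(k) owners[[k]]$start, numeric(1), USE.NAMES = FALSE),
      free_quantity = vapply(free_keys, function(k) owners[[k]]$quantity, character(1), USE.NAMES = FALSE),
      components = comps,
      priors = priors,
      transmitter_freq = transmitter_freq,
      reference_shift = reference_shift
    ),
    class = "constraint_map"
  )
}

#' @export
print.constraint_map <- function(x, ...) {
  cat(sprintf("<constraint_map> %d peak(s), %d sinusoid component(s), %d free / %d full parameters\n",
              nrow(x$priors), x$n_components, x$n_free, x$n_full))
  cat("free:", paste(x$free_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Full parameter vector (user units) for a free vector
#'
#' Applies only the affine map `p = S x + o`; values stay in user units
#' (signal units, degrees, Hz FWHM, ppm), named by the full labels.
#'
#' @param cmap A [compile_prior()] result.
#' @param x Free parameter vector (defaults to the starting values).
#' @return Named numeric vector of length `cmap$n_full`.
#' @export
full_parameters <- function(cmap, x = cmap$free_start) {
  stopifnot(inherits(cmap, "constraint_map"))
  if (length(x) != cmap$n_free) {
    abort(sprintf("free vector has length %d, expected %d.",
                  length(x), cmap$n_free),
          class = "mrsfit_error_validation")
  }
  setNames(as.numeric(cmap$scale %*% x + cmap$offset), cmap$labels)
}

#' Map free parameters to internal sinusoid parameters
#'
#' Applies the affine constraint map and then the unit conversions
#' (degrees to radians, Hz FWHM to damping via the lineshape, ppm to Hz
#' relative to the reference shift).
#'
#' @inheritParams full_parameters
#' @return A [sinusoids()] tibble with one row per component, plus a
#'   `component` column.
#' @export
apply_constraints <- function(cmap, x = cmap$free_start) {
  p <- full_parameters(cmap, x)
  idx <- function(sfx) p[seq(match(sfx, pk_suffix), length(p), by = 4)]
  g <- cmap$components$lineshape_g
  out <- tibble(
    component = cmap$components$component,
    amplitude = unname(idx("am")),
    phase = deg_to_rad(unname(idx("ph"))),
    damping = lw_to_damping(unname(idx("lw")), g),
    frequency = ppm_to_hz(unname(idx("cs")), cmap$transmitter_freq,
                          cmap$reference_shift),
    lineshape_g = g
  )
  out
}

#' Jacobian of the free-to-internal parameter map
#'
#' Derivative of the internal per-sinusoid parameter vector (amplitude,
#' phase rad, damping, frequency Hz; rows in the same order as
#' [model_jacobian()] columns) with respect to the free parameters, i.e.
#' the affine `scale` matrix composed with the unit-conversion chain rule.
#' The linewidth-to-damping conversion is nonlinear for Gaussian-weighted
#' lineshapes, so the Jacobian depends on the evaluation point `x`.
#'
#' @inheritParams full_parameters
#' @return Numeric matrix `cmap$n_full` x `cmap$n_free`.
#' @export
constraint_jacobian <- function(cmap, x = cmap$free_start) {
  p <- full_parameters(cmap, x)
  g <- cmap$components$lineshape_g
  lw <- p[seq(3, length(p), by = 4)]
  conv <- numeric(cmap$n_full)
  conv[seq(1, cmap$n_full, by = 4)] <- 1                       # amplitude
  conv[seq(2, cmap$n_full, by = 4)] <- pi / 180                # phase
  conv[seq(3, cmap$n_full, by = 4)] <- lw_to_damping_grad(lw, g)
  conv[seq(4, cmap$n_full, by = 4)] <- cmap$transmitter_freq   # shift
  conv * cmap$scale
}
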