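# Prior-knowledge compilation: constraint map structure, affine
# application, unit-conversion Jacobian, and the declarative file format.

test_that("a single unconstrained peak compiles to an identity map", {
  cm <- compile_prior(peak_prior("PCR", shift = 0), 120.3)
  expect_equal(cm$n_free, 4L)
  expect_equal(cm$n_full, 4L)
  expect_equal(cm$scale, diag(4))
  expect_equal(cm$offset, rep(0, 4))
  expect_equal(cm$labels, c("PCR_am", "PCR_ph", "PCR_lw", "PCR_cs"))
})

test_that("a 1:1 doublet shares one free amplitude and splits shifts by J", {
  f0 <- 120.3
  cm <- compile_prior(peak_prior("ATP_GAMMA", shift = -2.48, multiplet_n = 2,
                                 j_coupling = 17), f0)
  expect_equal(cm$n_free, 4L)  # 2 sinusoids, still 4 free parameters
  expect_equal(cm$n_full, 8L)
  expect_equal(cm$components$component, c("ATP_GAMMA1", "ATP_GAMMA2"))
  full <- full_parameters(cm)
  # both components carry the full free amplitude (1:1 ratio)
  expect_equal(unname(full["ATP_GAMMA1_am"]), unname(full["ATP_GAMMA2_am"]))
  # shifts symmetric about the parent at +/- J/2 Hz
  expect_equal(unname(full["ATP_GAMMA1_cs"]), -2.48 - 17 / 2 / f0)
  expect_equal(unname(full["ATP_GAMMA2_cs"]), -2.48 + 17 / 2 / f0)
})

test_that("amplitude ratios scale multiplet components off one free value", {
  cm <- compile_prior(peak_prior("X", shift = 1, multiplet_n = 2,
                                 j_coupling = 10,
                                 amplitude_ratios = c(1, 2)), 100)
  am_idx <- which(cm$free_labels == "X_am")
  x <- cm$free_start
  x[am_idx] <- 5
  full <- full_parameters(cm, x)
  expect_equal(unname(full[c("X1_am", "X2_am")]), c(5, 10))
})

test_that("a shared phase group collapses to one free parameter", {
  pk <- dplyr::bind_rows(lapply(1:5, function(i) {
    peak_prior(paste0("P", i), shift = i, group_phase = "ph0")
  }))
  cm <- compile_prior(pk, 100)
  expect_equal(sum(cm$free_quantity == "phase"), 1L)
  ph_col <- which(cm$free_labels == "ph0_ph")
  ph_rows <- seq(2, cm$n_full, by = 4)
  expect_equal(cm$scale[ph_rows, ph_col], rep(1, 5))
  # applying x sets all five phases
  x <- cm$free_start
  x[ph_col] <- 30
  full <- full_parameters(cm, x)
  expect_equal(unname(full[ph_rows]), rep(30, 5))
})

test_that("base_linewidth adds a constant on the linewidth row", {
  pk <- dplyr::bind_rows(
    peak_prior("A", shift = 0, group_linewidth = "lw0", linewidth = 10),
    peak_prior("B", shift = 1, group_linewidth = "lw0", linewidth = 10,
               base_linewidth = 4))
  cm <- compile_prior(pk, 100)
  expect_equal(sum(cm$free_quantity == "linewidth"), 1L)
  x <- cm$free_start
  x[cm$free_labels == "lw0_lw"] <- 12
  full <- full_parameters(cm, x)
  expect_equal(unname(full["A_lw"]), 12)
  expect_equal(unname(full["B_lw"]), 16)
})

test_that("apply_constraints converts units for the model", {
  f0 <- 120.3; ref <- 0.7
  cm <- compile_prior(peak_prior("PCR", shift = 0.2, linewidth = 10,
                                 amplitude = 3, phase = 90), f0,
                      reference_shift = ref)
  p <- apply_constraints(cm)
  expect_equal(p$amplitude, 3)
  expect_equal(p$phase, pi / 2)
  expect_equal(p$damping, pi * 10)
  expect_equal(p$frequency, (0.2 - ref) * f0)
})

test_that("apply_constraints on a doublet with ratio ties amplitudes", {
  cm <- compile_prior(peak_prior("X", shift = 0, multiplet_n = 2,
                                 j_coupling = 20,
                                 amplitude_ratios = c(1, 2)), 100)
  x <- cm$free_start
  x[cm$free_labels == "X_am"] <- 5
  p <- apply_constraints(cm, x)
  expect_equal(p$amplitude, c(5, 10))
})

test_that("constraint map is exactly affine in the free parameters", {
  pk <- dplyr::bind_rows(
    peak_prior("A", shift = 0, multiplet_n = 3, j_coupling = 16,
               group_phase = "g"),
    peak_prior("B", shift = 2, group_phase = "g", base_linewidth = 3))
  cm <- compile_prior(pk, 120.3)
  set.seed(5)
  x <- cm$free_start
  for (i in 1:10) {
    delta <- rnorm(cm$n_free, sd = 0.1)
    lhs <- full_parameters(cm, x + delta) - full_parameters(cm, x)
    expect_equal(unname(lhs), as.numeric(cm$scale %*% delta), tolerance = 1e-13)
  }
})

test_that("free starting values always lie within their bounds", {
  pk <- dplyr::bind_rows(
    peak_prior("A", shift = 0, shift_bounds = c(-0.2, 0.9),
               group_linewidth = "lw"),
    peak_prior("B", shift = 0.5, linewidth = 30, linewidth_bounds = c(25, 60),
               group_linewidth = "lw"))
  cm <- compile_prior(pk, 100)
  expect_true(all(cm$free_start >= cm$free_lower))
  expect_true(all(cm$free_start <= cm$free_upper))
  # grouped linewidth bounds are the intersection of member bounds
  i <- which(cm$free_labels == "lw_lw")
  expect_equal(cm$free_lower[i], 25)
  expect_equal(cm$free_upper[i], 60)
})

test_that("constraint Jacobian matches finite differences of apply_constraints", {
  pk <- dplyr::bind_rows(
    peak_prior("A", shift = 0, lineshape_g = 0.5, multiplet_n = 2,
               j_coupling = 12),
    peak_prior("B", shift = 3, lineshape_g = 1, group_phase = "g"),
    peak_prior("C", shift = -4, group_phase = "g", base_linewidth = 2))
  cm <- compile_prior(pk, 120.3, reference_shift = 0.3)
  x <- cm$free_start
  D <- constraint_jacobian(cm, x)
  to_vec <- function(x) {
    p <- apply_constraints(cm, x)
    as.numeric(t(as.matrix(p[, c("amplitude", "phase", "damping", "frequency")])))
  }
  fd <- vapply(seq_along(x), function(j) {
    h <- 1e-6 * max(abs(x[j]), 1)
    up <- x; up[j] <- up[j] + h
    dn <- x; dn[j] <- dn[j] - h
    (to_vec(up) - to_vec(dn)) / (2 * h)
  }, numeric(cm$n_full))
  expect_lt(max(abs(D - fd)) / max(abs(D)), 1e-8)
})

test_that("fixed parameters (equal bounds) drop out of the free vector", {
  cm <- compile_prior(
    peak_prior("A", shift = 0, phase = 0, phase_bounds = c(0, 0),
               linewidth = 10, linewidth_bounds = c(10, 10)), 100)
  expect_equal(cm$n_free, 2L)
  expect_setequal(cm$free_labels, c("A_am", "A_cs"))
  full <- full_parameters(cm)
  expect_equal(unname(full["A_ph"]), 0)
  expect_equal(unname(full["A_lw"]), 10)
})

test_that("invalid prior specifications raise typed errors naming the issue", {
  expect_error(compile_prior(dplyr::bind_rows(peak_prior("A", shift = 0),
                                              peak_prior("A", shift = 1)), 100),
               class = "mrsfit_error_prior")
  expect_error(compile_prior(peak_prior("A", shift = 5, shift_bounds = c(0, 1)),
                             100),
               class = "mrsfit_error_prior")
  expect_error(compile_prior(peak_prior("A", shift = 0, amplitude_ratio = 2),
                             100),
               regexp = "requires group_amplitude",
               class = "mrsfit_error_prior")
  # incompatible grouped bounds
  pk <- dplyr::bind_rows(
    peak_prior("A", shift = 0, linewidth = 5, linewidth_bounds = c(1, 9),
               group_linewidth = "g"),
    peak_prior("B", shift = 1, linewidth = 30, linewidth_bounds = c(20, 60),
               group_linewidth = "g"))
  expect_error(compile_prior(pk, 100), class = "mrsfit_error_prior")
})

test_that("prior-knowledge files round-trip and validate field-by-field", {
  pk <- dplyr::bind_rows(
    peak_prior("PCR", shift = 0, amplitude = 10, group_phase = "p"),
    peak_prior("ATP_GAMMA", shift = -2.48, multiplet_n = 2, j_coupling = 17,
               group_phase = "p"))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_prior_knowledge(pk, path)
  back <- read_prior_knowledge(path)
  expect_equal(back$name, pk$name)
  expect_equal(back$shift_start, pk$shift_start)
  expect_equal(back$multiplet_n, pk$multiplet_n)
  expect_equal(back$amplitude_ratios, pk$amplitude_ratios)

  # schema errors name the offending field
  doc <- yaml::read_yaml(path)
  doc$peaks[[1]]$no_such_field <- 1
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(doc, bad)
  expect_error(read_prior_knowledge(bad), regexp = "no_such_field",
               class = "mrsfit_error_schema")

  doc2 <- yaml::read_yaml(path)
  doc2$peaks[[1]]$shift <- NULL
  yaml::write_yaml(doc2, bad)
  expect_error(read_prior_knowledge(bad), regexp = "'shift'",
               class = "mrsfit_error_schema")

  doc3 <- yaml::read_yaml(path)
  doc3$version <- 99
  yaml::write_yaml(doc3, bad)
  expect_error(read_prior_knowledge(bad), class = "mrsfit_error_schema")
})

test_that("the shipped cardiac 31P prior compiles with shared phase", {
  pk <- pk_cardiac_31p()
  cm <- compile_prior(pk, 120.3)
  # PCr + 2x gamma-ATP + 2x alpha-ATP + 3x beta-ATP + PDE + DPG
  expect_equal(cm$n_components, 10L)
  expect_equal(sum(cm$free_quantity == "phase"), 1L)
  expect_true(all(cm$free_start >= cm$free_lower &
                    cm$free_start <= cm$free_upper))
})
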