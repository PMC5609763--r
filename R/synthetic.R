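#' Simulate a free-induction decay with complex white Gaussian noise
#'
#' Evaluates the damped-sinusoid model and adds independent zero-mean
#' Gaussian noise of standard deviation `sigma` to the real and imaginary
#' channels. The ground-truth sinusoid table is attached as attribute
#' `"truth"` so recovery tests need no side channel.
#'
#' @param peaks [sinusoids()] table (internal units) — the ground truth.
#' @param fid [fid_meta()] or [fid_series()] supplying the acquisition
#'   metadata.
#' @param sigma Per-channel noise standard deviation (`>= 0`).
#' @param seed Integer seed; the same seed reproduces the identical FID.
#'   `NULL` leaves the RNG state alone.
#' @return A [fid_series()] with a `"truth"` attribute.
#' @examples
#' meta <- fid_meta(512, dwell_time = 2.5e-4, transmitter_freq = 120.3)
#' fid <- simulate_fid(sinusoids(10, damping = 40, frequency = -100),
#'                     meta, sigma = 0.1, seed = 1)
#' @export
simulate_fid <- function(peaks, fid, sigma = 0, seed = NULL) {
  stop_unless(is.numeric(sigma) && length(sigma) == 1 && sigma >= 0,
              "`sigma` must be a single non-negative number.")
  clean <- evaluate_model(peaks, fid)
  if (sigma > 0) {
    if (!is.null(seed)) {
      old <- get0(".Random.seed", globalenv(), inherits = FALSE)
      on.exit(restore_rng(old), add = TRUE)
      set.seed(as.integer(seed))
    }
    noise <- complex(real = rnorm(length(clean), sd = sigma),
                     imaginary = rnorm(length(clean), sd = sigma))
    clean <- clean + noise
  }
  out <- fid_series(clean, fid$dwell_time, fid$dead_time,
                    fid$transmitter_freq, fid$reference_shift, fid$nucleus)
  attr(out, "truth") <- peaks
  out
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Default smooth amplitude pattern for phantom grids
#'
#' A radial Gaussian bump over the in-plane voxel grid, scaled into
#' `[floor, 1]`; used by [simulate_csi_phantom()] for map-recovery tests.
#'
#' @param nx,ny In-plane voxel counts.
#' @param floor Minimum relative amplitude at the grid corners.
#' @return `nx` x `ny` numeric matrix.
#' @export
phantom_amplitude_map <- function(nx, ny, floor = 0.4) {
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  w2 <- 2 * (max(nx, ny) / 3)^2
  outer(seq_len(nx) - 1, seq_len(ny) - 1, function(i, j) {
    floor + (1 - floor) * exp(-((i - cx)^2 + (j - cy)^2) / w2)
  })
}

#' Simulate a CSI phantom grid
#'
#' Generates one noisy FID per voxel from a template peak set whose
#' amplitudes are scaled by a spatial map (constant along the third axis).
#' A single root seed derives an independent per-voxel substream
#' deterministically from the voxel's linear index, so any voxel subset is
#' reproducible in isolation. Ground truth (template, map, per-voxel
#' sinusoid tables) is attached as attribute `"truth"`.
#'
#' @param dims Voxel counts `(nx, ny, nz)`.
#' @param peaks Template [sinusoids()] table; default a two-peak 31P-like
#'   Lorentzian pair (amplitudes 10 and 5).
#' @param amplitude_map `nx` x `ny` matrix of relative amplitudes; default
#'   [phantom_amplitude_map()].
#' @param fid [fid_meta()] acquisition metadata; default 1024 points at
#'   4 kHz bandwidth, 120.3 MHz (31P at 7 T).
#' @param sigma Per-channel noise standard deviation.
#' @param seed Root integer seed.
#' @param position,voxel_size Grid geometry passed to [csi_grid()].
#' @return A [csi_grid()] with a `"truth"` attribute.
#' @export
simulate_csi_phantom <- function(dims = c(8, 8, 1),
                                 peaks = NULL,
                                 amplitude_map = NULL,
                                 fid = NULL,
                                 sigma = 0,
                                 seed = 1,
                                 position = c(0, 0, 0),
                                 voxel_size = c(10, 10, 10)) {
  dims <- as.integer(dims)
  stop_unless(length(dims) == 3 && all(dims >= 1),
              "`dims` must be three voxel counts >= 1.")
  if (is.null(fid)) {
    fid <- fid_meta(1024, dwell_time = 2.5e-4, transmitter_freq = 120.3,
                    reference_shift = 0, nucleus = "31P")
  }
  if (is.null(peaks)) {
    peaks <- sinusoids(amplitude = c(10, 5),
                       phase = 0,
                       damping = lw_to_damping(c(12, 15)),
                       frequency = ppm_to_hz(c(0, -2.48), fid$transmitter_freq),
                       lineshape_g = 0)
    peaks$component <- c("PCR", "ATP_GAMMA")
  }
  if (is.null(amplitude_map)) {
    amplitude_map <- phantom_amplitude_map(dims[1], dims[2])
  }
  stop_unless(all(dim(amplitude_map) == dims[1:2]),
              "`amplitude_map` must be an nx x ny matrix.")

  n_vox <- prod(dims)
  truth_by_voxel <- vector("list", n_vox)
  fids <- vector("list", n_vox)
  v <- 0L
  for (k in seq_len(dims[3]) - 1L) {
    for (j in seq_len(dims[2]) - 1L) {
      for (i in seq_len(dims[1]) - 1L) {
        v <- v + 1L
        truth <- peaks
        truth$amplitude <- peaks$amplitude * amplitude_map[i + 1, j + 1]
        fids[[v]] <- simulate_fid(truth, fid, sigma = sigma,
                                  seed = voxel_seed(seed, v))
        truth_by_voxel[[v]] <- truth
      }
    }
  }
  grid <- csi_grid(fids, dims, position = position, voxel_size = voxel_size)
  attr(grid, "truth") <- list(peaks = peaks, amplitude_map = amplitude_map,
                              by_voxel = truth_by_voxel, sigma = sigma,
                              seed = seed)
  grid
}

# Independent, reproducible per-voxel substream seed from a root seed.
voxel_seed <- function(seed, v) {
  as.integer((as.numeric(seed) %% 2147483647 * 1000003 + v * 7919) %% 2147483647)
}
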