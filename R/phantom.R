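#' Lesion specification for the synthetic phantom
#'
#' Describes how many elliptical lesions a severity grade carries and how
#' large they are. Lesion count is drawn uniformly from `n_lesions`
#' (inclusive integer range) and each ellipse's two semi-axes are drawn
#' uniformly from `semiaxes` (pixels), with a uniform random orientation.
#' Lesions are placed entirely inside the white-matter region of the
#' phantom, so they always lie inside the brain.
#'
#' @param n_lesions integer length-2 vector, inclusive range for the number
#'   of lesions per slice; minimum must be >= 0.
#' @param semiaxes numeric length-2 vector, range for ellipse semi-axes in
#'   pixels; minimum must be >= 1.
#' @return An object of class `lesion_spec`.
#' @examples
#' lesion_spec(c(1, 3), c(1, 3))
#' @export
lesion_spec <- function(n_lesions = c(1L, 3L), semiaxes = c(1, 3)) {
  n_lesions <- as.integer(round(n_lesions))
  if (length(n_lesions) != 2L || anyNA(n_lesions) || n_lesions[1] < 0L ||
      n_lesions[1] > n_lesions[2]) {
    stop("'n_lesions' must be an ordered integer range with minimum >= 0")
  }
  if (length(semiaxes) != 2L || anyNA(semiaxes) || semiaxes[1] < 1 ||
      semiaxes[1] > semiaxes[2]) {
    stop("'semiaxes' must be an ordered range with minimum >= 1 pixel")
  }
  structure(list(n_lesions = n_lesions, semiaxes = as.numeric(semiaxes)),
            class = "lesion_spec")
}

# Expected total lesion area (pixels) implied by a spec; used to verify that
# severity grades are strictly ordered by lesion load.
expected_lesion_load <- function(spec) {
  mean(spec$n_lesions) * pi * mean(spec$semiaxes)^2
}

#' Default severity grades
#'
#' Mild, moderate and severe lesion loads used by the phantom: separable but
#' overlapping classes in which both lesion count and lesion size increase
#' with severity.
#'
#' @return Named list of [lesion_spec()] objects (`mild`, `moderate`,
#'   `severe`).
#' @export
default_severity_specs <- function() {
  list(
    mild     = lesion_spec(c(1L, 3L),  c(1, 3)),
    moderate = lesion_spec(c(4L, 8L),  c(2, 5)),
    severe   = lesion_spec(c(9L, 15L), c(4, 8))
  )
}

#' Default tissue mean intensities per modality
#'
#' Arbitrary-unit tissue means chosen to reproduce the qualitative contrast
#' of each MRI sequence: MS lesions are hyperintense relative to white
#' matter on T2 and FLAIR and hypointense on T1; FLAIR suppresses CSF below
#' gray matter.
#'
#' @param modality one of `"T1"`, `"T2"`, `"FLAIR"`.
#' @return Named numeric vector with entries `background`, `csf`, `gm`,
#'   `wm`, `lesion`.
#' @export
default_tissue_intensities <- function(modality = c("T2", "T1", "FLAIR")) {
  modality <- match.arg(modality)
  switch(modality,
    T1    = c(background = 0, csf = 50,  gm = 120, wm = 160, lesion = 90),
    T2    = c(background = 0, csf = 200, gm = 120, wm = 90,  lesion = 170),
    FLAIR = c(background = 0, csf = 40,  gm = 120, wm = 100, lesion = 190)
  )
}

#' Phantom configuration
#'
#' Collects every knob of the synthetic MRI generator: geometry, modality,
#' tissue intensities, noise, multiplicative intensity non-uniformity (INU)
#' and the severity grading. Defaults emulate a modest-quality clinical
#' acquisition at desk scale.
#'
#' @param image_size integer length-2, slice size in pixels (rows, cols);
#'   each dimension must be >= 32.
#' @param slices_per_subject number of axial slices generated per subject.
#' @param modality `"T1"`, `"T2"` or `"FLAIR"`.
#' @param tissue_intensities named numeric vector as returned by
#'   [default_tissue_intensities()]; `NULL` selects the modality default.
#' @param noise_sigma additive noise standard deviation (intensity units),
#'   >= 0.
#' @param noise_model `"gaussian"` or `"rician"`. Magnitude MR noise is
#'   Rician; Gaussian is the default simple model.
#' @param inu_amplitude fractional amplitude of the smooth multiplicative
#'   bias field, in `[0, 1)`; the field spans `1 +/- inu_amplitude`.
#' @param severity_specs named list (`mild`, `moderate`, `severe`) of
#'   [lesion_spec()] objects; expected lesion load must increase strictly
#'   with severity.
#' @param seed integer seed used by [generate_dataset()]; `NULL` leaves the
#'   RNG state untouched.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = c(64L, 64L),
                           slices_per_subject = 30L,
                           modality = c("T2", "T1", "FLAIR"),
                           tissue_intensities = NULL,
                           noise_sigma = 3,
                           noise_model = c("gaussian", "rician"),
                           inu_amplitude = 0.1,
                           severity_specs = default_severity_specs(),
                           seed = NULL) {
  modality <- match.arg(modality)
  noise_model <- match.arg(noise_model)
  image_size <- as.integer(round(image_size))
  if (length(image_size) != 2L || any(image_size < 32L)) {
    stop("'image_size' must be at least 32 x 32 pixels")
  }
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0")
  if (inu_amplitude < 0 || inu_amplitude >= 1) {
    stop("'inu_amplitude' must lie in [0, 1)")
  }
  if (is.null(tissue_intensities)) {
    tissue_intensities <- default_tissue_intensities(modality)
  }
  needed <- c("background", "csf", "gm", "wm", "lesion")
  if (!all(needed %in% names(tissue_intensities))) {
    stop("'tissue_intensities' must name: ", paste(needed, collapse = ", "))
  }
  if (!all(c("mild", "moderate", "severe") %in% names(severity_specs))) {
    stop("'severity_specs' must name mild, moderate and severe grades")
  }
  loads <- vapply(severity_specs[c("mild", "moderate", "severe")],
                  expected_lesion_load, numeric(1))
  if (any(diff(loads) <= 0)) {
    stop("expected lesion load must increase strictly mild < moderate < severe")
  }
  structure(list(
    image_size = image_size,
    slices_per_subject = as.integer(slices_per_subject),
    modality = modality,
    tissue_intensities = tissue_intensities,
    noise_sigma = noise_sigma,
    noise_model = noise_model,
    inu_amplitude = inu_amplitude,
    severity_specs = severity_specs,
    seed = seed
  ), class = "phantom_config")
}

#' Generate the brain mask and tissue label map
#'
#' Builds a 2D anatomy proxy: a filled ellipse "brain" containing three
#' concentric tissue regions — an outer CSF ring, a gray-matter band and a
#' white-matter core. The outer semi-axes are jittered a few percent so
#' subjects differ anatomically; the function is deterministic given the RNG
#' state.
#'
#' Tissue codes in the label map: 0 background, 1 CSF, 2 gray matter,
#' 3 white matter. Every in-brain pixel carries exactly one tissue label.
#'
#' @param image_size integer length-2 (rows, cols), each >= 32.
#' @return List with elements `mask` (logical matrix, TRUE inside the brain)
#'   and `tissue` (integer matrix of tissue codes).
#' @export
generate_brain_mask <- function(image_size) {
  image_size <- as.integer(round(image_size))
  if (length(image_size) != 2L || any(image_size < 32L)) {
    stop("image too small to contain all three tissue regions (need >= 32 x 32)")
  }
  nr <- image_size[1]; nc <- image_size[2]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  a <- 0.45 * nc * stats::runif(1, 0.97, 1.03)
  b <- 0.45 * nr * stats::runif(1, 0.97, 1.03)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  r <- sqrt(((cols - cx) / a)^2 + ((rows - cy) / b)^2)
  tissue <- matrix(0L, nr, nc)
  tissue[r <= 1] <- 1L      # CSF ring (outermost)
  tissue[r <= 0.88] <- 2L   # gray-matter band
  tissue[r <= 0.70] <- 3L   # white-matter core
  list(mask = tissue > 0L, tissue = tissue)
}

#' Place elliptical lesions inside white matter
#'
#' Draws `k ~ Uniform(n_lesions)` filled ellipses with uniform semi-axes and
#' orientation, centered on white-matter pixels, and returns their union as
#' a boolean mask. A candidate lesion is accepted only when every one of its
#' pixels lies in white matter (hence inside the brain); rejected candidates
#' are re-drawn up to `max_attempts` times before the function fails.
#'
#' @param tissue_map integer tissue label map from [generate_brain_mask()].
#' @param spec a [lesion_spec()].
#' @param max_attempts rejection-sampling budget per lesion.
#' @return Logical matrix the size of `tissue_map`; lesions may overlap.
#' @export
place_lesions <- function(tissue_map, spec, max_attempts = 100L) {
  stopifnot(inherits(spec, "lesion_spec"))
  wm <- which(tissue_map == 3L, arr.ind = TRUE)
  if (nrow(wm) == 0L) stop("tissue map contains no white-matter region")
  nr <- nrow(tissue_map); nc <- ncol(tissue_map)
  lo <- spec$n_lesions[1]; hi <- spec$n_lesions[2]
  k <- if (lo == hi) lo else sample(seq.int(lo, hi), 1L)
  mask <- matrix(FALSE, nr, nc)
  if (k == 0L) return(mask)
  for (les in seq_len(k)) {
    placed <- FALSE
    for (attempt in seq_len(max_attempts)) {
      ctr <- wm[sample.int(nrow(wm), 1L), ]
      ax <- stats::runif(2, spec$semiaxes[1], spec$semiaxes[2])
      th <- stats::runif(1, 0, pi)
      rad <- ceiling(max(ax))
      r0 <- ctr[1] - rad; r1 <- ctr[1] + rad
      c0 <- ctr[2] - rad; c1 <- ctr[2] + rad
      if (r0 < 1L || c0 < 1L || r1 > nr || c1 > nc) next
      rr <- seq.int(r0, r1); cc <- seq.int(c0, c1)
      dy <- matrix(rr - ctr[1], length(rr), length(cc))
      dx <- matrix(cc - ctr[2], length(rr), length(cc), byrow = TRUE)
      u <-  cos(th) * dx + sin(th) * dy
      v <- -sin(th) * dx + cos(th) * dy
      inside <- (u / ax[1])^2 + (v / ax[2])^2 <= 1
      if (all(tissue_map[rr, cc][inside] == 3L)) {
        sub <- mask[rr, cc]
        sub[inside] <- TRUE
        mask[rr, cc] <- sub
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place a lesion of the requested size inside white ",
           "matter after ", max_attempts, " attempts")
    }
  }
  mask
}

#' Render one modality slice from tissue and lesion maps
#'
#' Assigns each tissue its mean intensity, overwrites lesion pixels with the
#' modality's lesion intensity, multiplies by a smooth second-order
#' polynomial bias field spanning `1 +/- inu_amplitude`, adds Gaussian or
#' Rician noise, and clips negative intensities at zero.
#'
#' @param tissue_map integer tissue label map.
#' @param lesion_mask logical lesion mask (same size); may be `NULL` or
#'   all-FALSE for a lesion-free slice.
#' @param config a [phantom_config()].
#' @return Numeric intensity matrix (one image slice).
#' @export
render_modality <- function(tissue_map, lesion_mask, config) {
  stopifnot(inherits(config, "phantom_config"))
  ints <- config$tissue_intensities
  lut <- c(ints[["background"]], ints[["csf"]], ints[["gm"]], ints[["wm"]])
  img <- matrix(lut[tissue_map + 1L], nrow(tissue_map), ncol(tissue_map))
  if (!is.null(lesion_mask) && any(lesion_mask)) {
    img[lesion_mask] <- ints[["lesion"]]
  }
  if (config$inu_amplitude > 0) {
    img <- img * inu_field(dim(img), config$inu_amplitude)
  }
  s <- config$noise_sigma
  if (s > 0) {
    n <- length(img)
    img <- switch(config$noise_model,
      gaussian = img + stats::rnorm(n, 0, s),
      rician   = sqrt((img + stats::rnorm(n, 0, s))^2 + stats::rnorm(n, 0, s)^2)
    )
  }
  img[img < 0] <- 0
  img
}

# Smooth multiplicative bias field: random second-order polynomial in
# normalized coordinates, rescaled so the field spans exactly [1-a, 1+a].
inu_field <- function(dims, amplitude) {
  nr <- dims[1]; nc <- dims[2]
  ys <- matrix((seq_len(nr) - (nr + 1) / 2) / nr, nr, nc)
  xs <- matrix((seq_len(nc) - (nc + 1) / 2) / nc, nr, nc, byrow = TRUE)
  cf <- stats::runif(5, -1, 1)
  f <- cf[1] * xs + cf[2] * ys + cf[3] * xs^2 + cf[4] * ys^2 + cf[5] * xs * ys
  rg <- range(f)
  if (diff(rg) > 0) f <- 2 * (f - rg[1]) / diff(rg) - 1 else f <- f * 0
  1 + amplitude * f
}

# Generate a full subject: one anatomy, slices_per_subject rendered slices
# with per-slice lesion re-sampling. severity = NULL gives a lesion-free
# (non-MS) subject.
generate_subject <- function(config, subject_id, severity = NULL) {
  anat <- generate_brain_mask(config$image_size)
  nr <- config$image_size[1]; nc <- config$image_size[2]
  ns <- config$slices_per_subject
  vol <- array(0, c(nr, nc, ns))
  les <- array(FALSE, c(nr, nc, ns))
  spec <- if (!is.null(severity)) config$severity_specs[[severity]]
  for (k in seq_len(ns)) {
    lm <- if (is.null(spec)) NULL else place_lesions(anat$tissue, spec)
    vol[, , k] <- render_modality(anat$tissue, lm, config)
    if (!is.null(lm)) les[, , k] <- lm
  }
  has_lesion <- any(les)
  structure(list(
    subject_id = subject_id,
    modality = config$modality,
    label_binary = if (has_lesion) "MS" else "non-MS",
    label_severity = if (has_lesion) severity else NA_character_,
    volume = vol,
    lesion_mask = les
  ), class = "subject_record")
}

#' Generate a synthetic labelled dataset
#'
#' Produces a list of subject records for the binary detection task (non-MS
#' subjects with zero lesions versus MS subjects carrying lesions) or for
#' the three-class severity task (mild / moderate / severe). Lesions are
#' re-sampled independently per slice from the subject's severity grade;
#' the anatomy (brain mask) is fixed per subject.
#'
#' For the binary task, MS subjects carry the `binary_severity` lesion
#' grade — by default the representative `"moderate"` load, which keeps the
#' two classes well separated. `binary_severity = "cycle"` instead rotates
#' MS subjects through mild/moderate/severe; note that mild lesions (1-3
#' ellipses of 1-3 px) displace only a handful of the ~441 block statistics
#' and their histogram footprint falls below the histogram's own sampling
#' noise, so a cycled binary population is deliberately much harder.
#'
#' The binary label is derived from the lesion mask itself: a subject is
#' labelled MS exactly when its mask contains at least one lesion voxel.
#'
#' @param config a [phantom_config()]; `config$seed`, when non-NULL, seeds
#'   the generator so identical configurations yield identical datasets.
#' @param n_subjects_per_class subjects per class, >= 1.
#' @param task `"binary"` or `"severity"`.
#' @param binary_severity lesion grade given to MS subjects in the binary
#'   task: one of `"moderate"` (default), `"mild"`, `"severe"`, `"cycle"`.
#' @return List of `subject_record` objects, each holding `subject_id`,
#'   `modality`, `label_binary`, `label_severity`, a 3D `volume` and a 3D
#'   logical `lesion_mask`.
#' @examples
#' cfg <- phantom_config(slices_per_subject = 4L, seed = 1L)
#' ds <- generate_dataset(cfg, n_subjects_per_class = 2L, task = "binary")
#' length(ds)
#' @export
generate_dataset <- function(config, n_subjects_per_class,
                             task = c("binary", "severity"),
                             binary_severity = c("moderate", "mild",
                                                 "severe", "cycle")) {
  stopifnot(inherits(config, "phantom_config"))
  task <- match.arg(task)
  binary_severity <- match.arg(binary_severity)
  if (n_subjects_per_class < 1L) stop("'n_subjects_per_class' must be >= 1")
  if (!is.null(config$seed)) set.seed(config$seed)
  grades <- c("mild", "moderate", "severe")
  out <- list()
  if (task == "binary") {
    for (i in seq_len(n_subjects_per_class)) {
      out[[length(out) + 1L]] <-
        generate_subject(config, sprintf("ctl%03d", i), severity = NULL)
    }
    for (i in seq_len(n_subjects_per_class)) {
      sev <- if (binary_severity == "cycle") {
        grades[((i - 1L) %% 3L) + 1L]
      } else {
        binary_severity
      }
      out[[length(out) + 1L]] <-
        generate_subject(config, sprintf("ms%03d", i), severity = sev)
    }
  } else {
    for (g in grades) {
      for (i in seq_len(n_subjects_per_class)) {
        out[[length(out) + 1L]] <-
          generate_subject(config, sprintf("%s%03d", g, i), severity = g)
      }
    }
  }
  out
}
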