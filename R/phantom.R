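# Synthetic multi-modal phantom slices with a nested three-compartment
# tumor (edema > enhancing > necrotic core) on a circular "brain" on dark
# background, so every downstream module can be exercised without external
# data. Compartments are concentric ellipses: enough structure to exercise
# overlap and contour metrics, with no claim of anatomical realism.

phantom_tissues <- c("background", "brain", "edema", "enhancing", "necrotic")
phantom_modalities <- c("t1", "t2", "t1ce", "flair")

default_intensity_table <- function() {
  # rows: modality, cols: tissue class; chosen for the clinical contrast
  # pattern (FLAIR-bright edema, T1ce-bright enhancing rim, T1ce-dark
  # necrotic core), values in [0, 1]
  m <- rbind(
    t1    = c(0, 0.45, 0.35, 0.50, 0.20),
    t2    = c(0, 0.40, 0.65, 0.55, 0.70),
    t1ce  = c(0, 0.45, 0.40, 0.90, 0.15),
    flair = c(0, 0.35, 0.85, 0.60, 0.45)
  )
  colnames(m) <- phantom_tissues
  m
}

#' Phantom specification
#'
#' Geometry, contrast and noise of a synthetic multi-modal slice. The tumor
#' is three concentric ellipses — edema (label 2) containing enhancing tumor
#' (label 4) containing necrotic core (label 1) — on a circular brain disc
#' (label 0) whose outside is zero background.
#'
#' @param image_size square image side in pixels.
#' @param compartment_radii strictly decreasing semi-major radii of the
#'   edema, enhancing and necrotic ellipses, as fractions of `image_size`.
#' @param intensity_table 4 x 5 matrix of per-modality (t1, t2, t1ce,
#'   flair), per-tissue (background, brain, edema, enhancing, necrotic)
#'   mean intensities in `[0, 1]`.
#' @param noise_sd additive i.i.d. Gaussian noise standard deviation.
#' @param seed integer RNG seed controlling the noise.
#' @param brain_radius brain disc radius as a fraction of `image_size`.
#' @param axis_ratio minor/major axis ratio of the tumor ellipses.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(image_size = 160L,
                         compartment_radii = c(0.30, 0.18, 0.08),
                         intensity_table = default_intensity_table(),
                         noise_sd = 0.03,
                         seed = 1L,
                         brain_radius = 0.45,
                         axis_ratio = 0.85) {
  stopifnot(length(compartment_radii) == 3)
  if (any(diff(compartment_radii) >= 0)) {
    stop("compartment radii must be strictly decreasing ",
         "(edema > enhancing > necrotic)")
  }
  if (compartment_radii[1] >= brain_radius) {
    stop("edema radius must be smaller than the brain radius")
  }
  if (!all(dim(intensity_table) == c(4, 5))) {
    stop("intensity_table must be 4 modalities x 5 tissue classes")
  }
  structure(list(
    image_size = as.integer(image_size),
    n_modalities = 4L,
    compartment_radii = compartment_radii,
    intensity_table = intensity_table,
    noise_sd = noise_sd,
    seed = as.integer(seed),
    brain_radius = brain_radius,
    axis_ratio = axis_ratio
  ), class = "phantom_spec")
}

in_ellipse <- function(xg, yg, cx, cy, a, b) {
  ((xg - cx) / a)^2 + ((yg - cy) / b)^2 <= 1
}

#' Generate one phantom slice
#'
#' Builds the nested label map and the four noisy intensity channels.
#' Deterministic: the same (spec, offset) always yields bit-identical
#' output.
#'
#' @param spec a [phantom_spec()].
#' @param offset length-2 pixel displacement of the tumor center from the
#'   image center; must keep all compartments inside the brain disc.
#' @param id sample identifier string.
#' @param radius_scale multiplier on all compartment radii (used by
#'   [generate_dataset()] for jitter); a scale of 0 yields a tumor-free
#'   slice.
#' @return a `slice_sample` list with `image` (`H x W x 4`, channel order
#'   t1, t2, t1ce, flair), `label` (`H x W` integer map with values in
#'   0/1/2/4) and `id`.
#' @export
generate_slice <- function(spec, offset = c(0, 0), id = "phantom_001",
                           radius_scale = 1) {
  stopifnot(inherits(spec, "phantom_spec"), length(offset) == 2)
  n <- spec$image_size
  radii <- spec$compartment_radii * n * radius_scale
  if (radius_scale > 0 &&
      sqrt(sum(offset^2)) + radii[1] > spec$brain_radius * n) {
    stop("offset (", offset[1], ", ", offset[2], ") pushes the edema ",
         "compartment (radius ", round(radii[1], 1), " px) outside the ",
         "brain disc (radius ", round(spec$brain_radius * n, 1), " px)")
  }
  ctr <- (n + 1) / 2
  xg <- matrix(seq_len(n), n, n)
  yg <- matrix(seq_len(n), n, n, byrow = TRUE)
  brain <- (xg - ctr)^2 + (yg - ctr)^2 <= (spec$brain_radius * n)^2

  label <- matrix(0L, n, n)
  tissue <- matrix(1L, n, n)          # index into intensity columns
  tissue[brain] <- 2L
  if (radius_scale > 0) {
    cx <- ctr + offset[1]; cy <- ctr + offset[2]
    ar <- spec$axis_ratio
    ed <- in_ellipse(xg, yg, cx, cy, radii[1], radii[1] * ar)
    en <- in_ellipse(xg, yg, cx, cy, radii[2], radii[2] * ar)
    nc <- in_ellipse(xg, yg, cx, cy, radii[3], radii[3] * ar)
    label[ed] <- 2L; label[en] <- 4L; label[nc] <- 1L
    tissue[ed] <- 3L; tissue[en] <- 4L; tissue[nc] <- 5L
  }

  set.seed(spec$seed)
  img <- array(0, c(n, n, 4L))
  for (m in 1:4) {
    base <- matrix(spec$intensity_table[m, tissue], n, n)
    noise <- if (spec$noise_sd > 0) {
      matrix(rnorm(n * n, sd = spec$noise_sd), n, n)
    } else {
      0
    }
    ch <- base + noise
    ch[!brain] <- 0   # keep the zero background exact for support masks
    img[, , m] <- ch
  }
  dimnames(img) <- list(NULL, NULL, phantom_modalities)
  structure(list(image = img, label = label, id = id),
            class = "slice_sample")
}

#' Generate a phantom dataset
#'
#' Draws `n` slices with randomized tumor offsets and radius jitter, each
#' with its own noise stream; fully deterministic under a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @param n number of slices (>= 1).
#' @param seed integer seed for offsets, jitter and per-slice noise seeds.
#' @return list of `slice_sample`s.
#' @export
generate_dataset <- function(spec, n, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  out <- vector("list", n)
  max_off <- (spec$brain_radius - spec$compartment_radii[1] * 1.1) *
    spec$image_size
  for (i in seq_len(n)) {
    ang <- runif(1, 0, 2 * pi)
    rad <- runif(1, 0, max(0, max_off))
    off <- c(cos(ang), sin(ang)) * rad
    jit <- runif(1, 0.9, 1.1)
    si <- sample.int(.Machine$integer.max - 1L, 1)
    sp <- spec
    sp$seed <- si
    out[[i]] <- generate_slice(sp, offset = off,
                               id = sprintf("phantom_%03d", i),
                               radius_scale = jit)
  }
  out
}

#' Normalize a slice's channels over their nonzero support
#'
#' Applies the same z-score normalization as the volume preprocessing,
#' channel by channel: mean 0, sd 1 over nonzero pixels, background kept
#' at 0.
#'
#' @param sample a `slice_sample`.
#' @return the sample with normalized image channels.
#' @export
normalize_slice <- function(sample) {
  for (m in seq_len(dim(sample$image)[3])) {
    sample$image[, , m] <- zscore_normalize(sample$image[, , m])
  }
  sample
}

#' Write a phantom case in the BraTS on-disk layout
#'
#' Builds co-registered 3-D modality volumes plus a label volume by stacking
#' phantom slices whose tumor radii follow an ellipsoidal profile along Z,
#' and writes them as gzipped NIfTI files named
#' `<case_id>_<t1|t2|t1ce|flair|seg>.nii.gz` in `dir/case_id/`, the layout
#' the case reader consumes.
#'
#' @param dir parent directory.
#' @param case_id case name.
#' @param dims volume dimensions (X, Y, Z); the BraTS shape is
#'   `c(240, 240, 155)`.
#' @param spec a [phantom_spec()]; its `image_size` is overridden by
#'   `dims[1]`.
#' @param offset in-plane tumor center displacement.
#' @param seed seed for the per-slice noise.
#' @param compress write gzipped `.nii.gz` (default) or plain `.nii`.
#' @return the case directory path, invisibly.
#' @export
write_phantom_case <- function(dir, case_id = "phantom_case",
                               dims = c(240L, 240L, 155L),
                               spec = phantom_spec(),
                               offset = c(0, 0), seed = 1L,
                               compress = TRUE) {
  if (dims[1] != dims[2]) stop("in-plane dims must be square")
  case_dir <- file.path(dir, case_id)
  dir.create(case_dir, recursive = TRUE, showWarnings = FALSE)
  sp <- spec
  sp$image_size <- as.integer(dims[1])
  zc <- (dims[3] + 1) / 2
  zr <- dims[3] * 0.35
  set.seed(seed)
  slice_seeds <- sample.int(.Machine$integer.max - 1L, dims[3])
  vols <- lapply(1:4, function(m) array(0, dims))
  label <- array(0L, dims)
  for (k in seq_len(dims[3])) {
    prof <- sqrt(max(0, 1 - ((k - zc) / zr)^2))
    sp$seed <- slice_seeds[k]
    sl <- generate_slice(sp, offset = offset, id = sprintf("z%03d", k),
                         radius_scale = if (prof < 0.2) 0 else prof)
    for (m in 1:4) vols[[m]][, , k] <- sl$image[, , m]
    label[, , k] <- sl$label
  }
  mods <- phantom_modalities
  ext <- if (compress) ".nii.gz" else ".nii"
  for (m in 1:4) {
    RNifti::writeNifti(vols[[m]],
                       file.path(case_dir,
                                 paste0(case_id, "_", mods[m], ext)))
  }
  RNifti::writeNifti(label,
                     file.path(case_dir, paste0(case_id, "_seg", ext)))
  invisible(case_dir)
}
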