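# BraTS-layout NIfTI reading and the preprocessing pipeline: z-score
# normalization over the brain support, center crop to 160x160 in-plane,
# axial slicing, modality stacking, and the label -> nested-region mapping.

#' Region label mapping
#'
#' The BraTS convention: whole tumor = labels 1, 2, 4 (necrotic/non-
#' enhancing core + edema + enhancing), core tumor = 1, 4, enhancing
#' tumor = 4. Kept as a function so an alternative mapping is one switch
#' away.
#'
#' @return named list of label vectors for `wt`, `ct`, `et`.
#' @export
brats_region_map <- function() {
  list(wt = c(1, 2, 4), ct = c(1, 4), et = 4)
}

#' Read a BraTS-layout case
#'
#' Expects `<case_id>_<t1|t2|t1ce|flair>.nii(.gz)` (and optionally
#' `<case_id>_seg.nii(.gz)`) inside `case_dir`.
#'
#' @param case_dir case directory.
#' @param case_id case name; defaults to the directory name.
#' @return list with `volumes` (named list of 3-D arrays t1, t2, t1ce,
#'   flair), `label` (3-D integer array or NULL), `case_id`.
#' @export
read_brats_case <- function(case_dir, case_id = basename(case_dir)) {
  find_file <- function(suffix, required = TRUE) {
    for (ext in c(".nii.gz", ".nii")) {
      p <- file.path(case_dir, paste0(case_id, "_", suffix, ext))
      if (file.exists(p)) return(p)
    }
    if (required) {
      stop("missing modality file: ", case_id, "_", suffix, ".nii(.gz) in ",
           case_dir)
    }
    NULL
  }
  vols <- lapply(setNames(phantom_modalities, phantom_modalities),
                 function(m) {
                   v <- RNifti::readNifti(find_file(m))
                   array(as.numeric(v), dim(v))
                 })
  d <- dim(vols[[1]])
  for (m in phantom_modalities) {
    if (!all(dim(vols[[m]]) == d)) {
      stop("modality ", m, " shape ", paste(dim(vols[[m]]), collapse = "x"),
           " differs from t1 shape ", paste(d, collapse = "x"))
    }
  }
  segp <- find_file("seg", required = FALSE)
  label <- if (is.null(segp)) NULL else {
    v <- RNifti::readNifti(segp)
    array(as.integer(round(as.numeric(v))), dim(v))
  }
  list(volumes = vols, label = label, case_id = case_id)
}

#' Z-score normalize a volume over its nonzero support
#'
#' Subtracts the mean and divides by the standard deviation computed over
#' the nonzero (brain) voxels only; zero background voxels remain zero.
#' Idempotent to numerical tolerance.
#'
#' @param vol numeric array (any dimension).
#' @return normalized array, same shape.
#' @export
zscore_normalize <- function(vol) {
  support <- vol != 0
  if (!any(support)) stop("cannot normalize an all-zero volume")
  v <- vol[support]
  s <- stats::sd(v)
  if (s == 0) stop("cannot normalize a constant volume (zero variance)")
  vol[support] <- (v - mean(v)) / s
  vol
}

#' Center-crop a volume in-plane
#'
#' Crops the first two (in-plane) dimensions to `target`, centered on the
#' in-plane center; all axial planes are retained. A 240 x 240 input is
#' cropped with offsets (40, 40).
#'
#' @param vol 3-D array `X x Y x Z` (or 2-D matrix).
#' @param target in-plane output size, default `c(160, 160)`.
#' @return cropped array.
#' @export
center_crop <- function(vol, target = c(160L, 160L)) {
  d <- dim(vol)
  if (d[1] < target[1] || d[2] < target[2]) {
    stop("input in-plane size ", d[1], "x", d[2],
         " is smaller than the crop target ", target[1], "x", target[2])
  }
  off <- c((d[1] - target[1]) %/% 2, (d[2] - target[2]) %/% 2)
  idx1 <- off[1] + seq_len(target[1])
  idx2 <- off[2] + seq_len(target[2])
  out <- if (length(d) == 2) vol[idx1, idx2, drop = FALSE]
         else vol[idx1, idx2, , drop = FALSE]
  attr(out, "crop_offset") <- off
  out
}

#' Slice co-registered volumes into stacked multi-modal samples
#'
#' Slices the four modality volumes (and the label volume) along the Z
#' axis and stacks the four planes of each index into one `H x W x 4`
#' image, channel order t1, t2, t1ce, flair.
#'
#' @param vols named list of the four modality volumes, identical shapes.
#' @param label_vol integer label volume of the same shape, or NULL.
#' @param case_id string used in the sample ids.
#' @return list of `slice_sample`s, one per axial plane.
#' @export
slice_and_stack <- function(vols, label_vol = NULL, case_id = "case") {
  if (!all(phantom_modalities %in% names(vols))) {
    stop("vols must contain t1, t2, t1ce, flair")
  }
  d <- dim(vols$t1)
  for (m in phantom_modalities) {
    if (!all(dim(vols[[m]]) == d)) stop("modality shapes differ")
  }
  if (!is.null(label_vol) && !all(dim(label_vol) == d)) {
    stop("label volume shape differs from the modalities")
  }
  lapply(seq_len(d[3]), function(k) {
    img <- array(0, c(d[1], d[2], 4L))
    for (m in 1:4) img[, , m] <- vols[[phantom_modalities[m]]][, , k]
    dimnames(img) <- list(NULL, NULL, phantom_modalities)
    structure(list(
      image = img,
      label = if (is.null(label_vol)) NULL
              else matrix(as.integer(label_vol[, , k]), d[1], d[2]),
      id = sprintf("%s_%03d", case_id, k)
    ), class = "slice_sample")
  })
}

#' Re-stack per-slice label maps into a volume
#'
#' Inverse of [slice_and_stack()] for predictions.
#'
#' @param labels list of `H x W` integer label maps.
#' @return `H x W x length(labels)` integer array.
#' @export
stack_labels <- function(labels) {
  d <- dim(labels[[1]])
  out <- array(0L, c(d, length(labels)))
  for (k in seq_along(labels)) out[, , k] <- labels[[k]]
  out
}

#' Map a label image to nested region masks
#'
#' Whole tumor (WT) = labels 1, 2, 4; core tumor (CT) = 1, 4; enhancing
#' tumor (ET) = 4. The nesting ET within CT within WT holds by
#' construction.
#'
#' @param label integer map with values in 0, 1, 2, 4.
#' @param map region mapping, see [brats_region_map()].
#' @return a `region_targets` list of logical masks `wt`, `ct`, `et`.
#' @export
labels_to_regions <- function(label, map = brats_region_map()) {
  bad <- setdiff(unique(as.vector(label)), c(0, unlist(map)))
  if (length(bad) > 0) {
    stop("unexpected label value(s): ", paste(sort(bad), collapse = ", "))
  }
  mk <- function(vals) {
    m <- array(label %in% vals, dim(label))
    m
  }
  structure(list(wt = mk(map$wt), ct = mk(map$ct), et = mk(map$et)),
            class = "region_targets")
}

#' Region masks as a target array
#'
#' Stacks the WT, CT, ET masks into the `H x W x 3` numeric array the loss
#' and the network heads use.
#'
#' @param regions a `region_targets` list.
#' @return `H x W x 3` array of 0/1.
#' @export
regions_to_array <- function(regions) {
  d <- dim(regions$wt)
  out <- array(0, c(d, 3L))
  out[, , 1] <- regions$wt
  out[, , 2] <- regions$ct
  out[, , 3] <- regions$et
  dimnames(out) <- list(NULL, NULL, c("wt", "ct", "et"))
  out
}

#' Region masks back to a label image
#'
#' Inverse of [labels_to_regions()]: ET pixels get label 4, the rest of CT
#' label 1, the rest of WT label 2. With `repair = TRUE` the masks are
#' first composed to enforce the nesting by intersection
#' (CT := CT & WT, ET := ET & CT).
#'
#' @param regions a `region_targets` list (masks need not be nested if
#'   `repair` is on).
#' @param repair enforce nesting by intersection before mapping.
#' @return integer label matrix with values in 0, 1, 2, 4.
#' @export
regions_to_label <- function(regions, repair = FALSE) {
  wt <- regions$wt; ct <- regions$ct; et <- regions$et
  if (repair) {
    ct <- ct & wt
    et <- et & ct
  }
  lab <- array(0L, dim(wt))
  lab[wt & !ct] <- 2L
  lab[ct & !et] <- 1L
  lab[et] <- 4L
  lab
}

#' Preprocess a BraTS-layout case
#'
#' Normalizes each modality to mean 0 / sd 1 over its nonzero support,
#' center-crops in-plane to 160 x 160 (keeping all axial planes), slices
#' along Z and stacks modalities, yielding one `H x W x 4` sample per
#' plane. When `out_dir` is given, samples are saved as compressed `.rds`
#' archives with a `manifest.csv` (case_id, slice_index, path).
#'
#' @param case_dir case directory in the BraTS layout.
#' @param out_dir output directory for the sample archives, or NULL to
#'   return the samples in memory only.
#' @param target in-plane crop size.
#' @return list with `samples` (list of `slice_sample`) and `manifest`
#'   (data.frame or NULL).
#' @export
preprocess_case <- function(case_dir, out_dir = NULL,
                            target = c(160L, 160L)) {
  case <- read_brats_case(case_dir)
  vols <- lapply(case$volumes,
                 function(v) center_crop(zscore_normalize(v), target))
  label <- if (is.null(case$label)) NULL else center_crop(case$label, target)
  samples <- slice_and_stack(vols, label, case$case_id)
  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(length(samples))
    for (k in seq_along(samples)) {
      paths[k] <- file.path(out_dir, paste0(samples[[k]]$id, ".rds"))
      saveRDS(samples[[k]], paths[k], compress = "gzip")
    }
    manifest <- data.frame(case_id = case$case_id,
                           slice_index = seq_along(samples),
                           path = paths, stringsAsFactors = FALSE)
    write.csv(manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
  }
  list(samples = samples, manifest = manifest)
}
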