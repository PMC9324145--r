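#' Perfusion series container
#'
#' A 4D DSC-PWI intensity series indexed `(t, slice, row, col)` in arbitrary
#' scanner units, with voxel spacing in mm. During bolus passage of the
#' contrast agent, perfused tissue transiently darkens; lesion tissue shows a
#' smaller, delayed intensity dip than healthy tissue.
#'
#' @param data 4D numeric array `(t, s, r, c)`; all values finite.
#' @param spacing numeric length-3, voxel spacing `(slice, row, col)` in mm.
#' @return object of class `perfusion_series`.
#' @export
perfusion_series <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array (t, slice, row, col)")
  if (!all(is.finite(data))) stop("all intensities must be finite")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive values (mm)")
  structure(
    list(data = data, spacing = as.numeric(spacing),
         n_timepoints = dim(data)[1L]),
    class = "perfusion_series"
  )
}

#' @export
print.perfusion_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<perfusion_series> %d timepoints, volume %d x %d x %d, spacing %s mm\n",
              d[1], d[2], d[3], d[4], paste(signif(x$spacing, 3), collapse = " x ")))
  invisible(x)
}

#' Lesion / mirrored normal-tissue ROI pair
#'
#' The normal-tissue (NT) mask is the lesion (LT) mask reflected across the
#' left-right image midline (the column axis); masks must be disjoint and
#' have equal voxel counts.
#'
#' @param lt_mask 3D 0/1 array, the lesion mask.
#' @param nt_mask 3D 0/1 array, the mirrored normal-tissue mask. If missing
#'   it is computed with [mirror_roi()].
#' @return object of class `roi_pair`.
#' @export
roi_pair <- function(lt_mask, nt_mask = NULL) {
  check_mask(lt_mask)
  if (is.null(nt_mask)) nt_mask <- mirror_roi(lt_mask)
  check_mask(nt_mask)
  if (!identical(dim(lt_mask), dim(nt_mask)))
    stop("LT and NT masks must share a shape")
  if (any(lt_mask == 1 & nt_mask == 1))
    stop("LT and NT masks overlap")
  if (sum(lt_mask) != sum(nt_mask))
    stop("LT and NT masks must have equal voxel counts")
  structure(list(lt_mask = lt_mask, nt_mask = nt_mask, mirror_axis = 3L),
            class = "roi_pair")
}

check_mask <- function(mask) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array")
  if (!all(mask %in% c(0, 1))) stop("mask values must be strictly 0/1")
  invisible(TRUE)
}

#' Mirror a lesion mask across the image midline
#'
#' Voxel `(s, r, c)` maps to `(s, r, W - 1 - c)` (0-based) where `W` is the
#' column count; this defines the contralateral normal-tissue region. A mask
#' whose mirror intersects itself (a midline-crossing lesion) is rejected.
#'
#' @param lt_mask 3D 0/1 array.
#' @param check if `TRUE` (default) error when the mirrored mask overlaps
#'   the input.
#' @return 3D 0/1 array, the mirrored mask.
#' @export
mirror_roi <- function(lt_mask, check = TRUE) {
  check_mask(lt_mask)
  if (sum(lt_mask) == 0) stop("lesion mask is empty")
  W <- dim(lt_mask)[3L]
  nt <- lt_mask[, , W:1, drop = FALSE]
  dim(nt) <- dim(lt_mask)
  if (check && any(nt == 1 & lt_mask == 1))
    stop("mirrored mask overlaps the lesion: lesion crosses the midline")
  nt
}

#' Triple moving-average smoothing of the time dimension
#'
#' Each voxel's time-intensity curve `I(t)` is convolved three successive
#' times with the length-3 uniform kernel `(1, 1, 1) / 3` (equivalently, once
#' with the 7-tap kernel `(1, 3, 6, 7, 6, 3, 1) / 27`), with replicate
#' padding at the ends so the series length is preserved. Spatial dimensions
#' are untouched.
#'
#' @param series a [perfusion_series()].
#' @param passes number of moving-average passes (default 3).
#' @return a smoothed [perfusion_series()].
#' @export
smooth_series <- function(series, passes = 3L) {
  stopifnot(inherits(series, "perfusion_series"))
  if (series$n_timepoints < 3L)
    stop("smoothing needs at least 3 timepoints")
  x <- series$data
  for (i in seq_len(passes)) x <- conv_along_axis(x, rep(1 / 3, 3), axis = 1L)
  perfusion_series(x, series$spacing)
}

#' Read / write perfusion series and masks as NIfTI
#'
#' Round trips preserve data, shape and voxel spacing. NIfTI stores spatial
#' dims first, so a series array `(t, s, r, c)` is written as an
#' `(c, r, s, t)` NIfTI volume and permuted back on read. Masks are read as
#' strict 0/1 and rejected otherwise.
#'
#' @param series a [perfusion_series()].
#' @param path file path (`.nii` / `.nii.gz`).
#' @return `read_series()` returns a [perfusion_series()];
#'   `read_mask()` a 3D 0/1 array; the writers return `path` invisibly.
#' @name perfusion_io
NULL

#' @rdname perfusion_io
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "perfusion_series"))
  vol <- aperm(series$data, c(4L, 3L, 2L, 1L))
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(rev(series$spacing), 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname perfusion_io
#' @export
read_series <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L)
    stop("expected a 4D NIfTI series, got ", length(dim(arr)), "D")
  pd <- RNifti::pixdim(img)
  perfusion_series(aperm(arr, c(4L, 3L, 2L, 1L)), spacing = rev(pd[1:3]))
}

#' @rdname perfusion_io
#' @param mask 3D 0/1 array.
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  vol <- aperm(mask, c(3L, 2L, 1L))
  storage.mode(vol) <- "integer"
  RNifti::writeNifti(RNifti::asNifti(vol), path, datatype = "uint8")
  invisible(path)
}

#' @rdname perfusion_io
#' @export
read_mask <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3L)
    stop("expected a 3D NIfTI mask, got ", length(dim(arr)), "D")
  if (!all(arr %in% c(0, 1))) stop("mask file contains non-binary values")
  out <- aperm(arr, c(3L, 2L, 1L))
  storage.mode(out) <- "double"
  out
}
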