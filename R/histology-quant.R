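#' Fluorescence micrograph container
#'
#' A single-channel 2-D fluorescence image with its physical pixel scale
#' and study metadata, as captured at 20X from stained tissue sections.
#'
#' @param pixels Numeric matrix of nonnegative intensities.
#' @param scale Pixel size in micrometers per pixel. Default 0.65 (typical
#'   20X camera pixel).
#' @param channel Marker label, e.g. `"GFAP"`, `"Iba1"`, `"S100b"`,
#'   `"bAPP"`, `"NFL"`, `"DAPI"`.
#' @param subject_id,group Study labels.
#'
#' @return An object of class `fluor_image`.
#' @export
fluorescence_image <- function(pixels, scale = 0.65, channel = "GFAP",
                               subject_id = "s1", group = "sham") {
  stopifnot(is.matrix(pixels), is.numeric(pixels), scale > 0)
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("`pixels` must be finite and >= 0")
  structure(list(pixels = pixels, scale = scale, channel = channel,
                 subject_id = subject_id, group = group),
            class = "fluor_image")
}

#' @export
print.fluor_image <- function(x, ...) {
  cat(sprintf("<fluor_image> %s %s/%s: %dx%d px @ %.3g um/px, max %.3g\n",
              x$channel, x$group, x$subject_id, nrow(x$pixels),
              ncol(x$pixels), x$scale, max(x$pixels)))
  invisible(x)
}

#' Threshold positive signal
#'
#' Builds the binary mask of marker-positive pixels (intensity at or above
#' the threshold). Otsu's method, computed per image, is the default; a
#' fixed threshold is available for cross-image comparability. The
#' threshold actually used is always recorded (as the `threshold` attribute
#' and in [quantify_image()] output).
#'
#' @param img A [fluorescence_image()].
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_value Threshold intensity when `method = "fixed"`.
#'
#' @return Logical matrix mask with attribute `threshold`.
#' @export
threshold_positive <- function(img, method = c("otsu", "fixed"),
                               fixed_value = NULL) {
  stopifnot(inherits(img, "fluor_image"))
  method <- match.arg(method)
  px <- img$pixels
  if (method == "otsu") {
    rng <- range(px)
    if (diff(rng) == 0)
      stop("constant image: Otsu thresholding is undefined; use method = \"fixed\"")
    thr <- EBImage::otsu(EBImage::Image((px - rng[1L]) / diff(rng)),
                         range = c(0, 1), levels = 256L)
    thr <- rng[1L] + thr * diff(rng)
  } else {
    if (is.null(fixed_value)) stop("`fixed_value` required for method = \"fixed\"")
    thr <- fixed_value
  }
  mask <- px >= thr
  attr(mask, "threshold") <- thr
  mask
}

#' Area fraction of positive signal
#'
#' @param mask Logical mask from [threshold_positive()].
#'
#' @return Fraction of positive pixels, in `[0, 1]`.
#' @export
area_fraction <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(c(mask)))
  mean(mask)
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a small union-find pass
.label8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask * 1))
  m <- max(lab)
  if (m < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(m), find, integer(1))
  lab[lab > 0] <- root[lab[lab > 0]]
  lab
}

#' Count marker-positive cells
#'
#' Counts 8-connected components of the positive mask whose physical area
#' falls within `[min_area, max_area]`. The minimum area excludes
#' single-pixel noise at 20X scale; no watershed splitting of touching
#' cells is applied.
#'
#' @param mask Logical mask from [threshold_positive()].
#' @param scale Micrometers per pixel.
#' @param min_area Minimum component area in um^2 (> 0). Default 20.
#' @param max_area Maximum component area in um^2. Default `Inf`.
#'
#' @return Integer cell count.
#' @export
count_cells <- function(mask, scale, min_area = 20, max_area = Inf) {
  stopifnot(is.matrix(mask), is.logical(c(mask)), scale > 0)
  if (min_area <= 0) stop("`min_area` must be > 0 um^2")
  if (!any(mask)) return(0L)
  lab <- .label8(mask)
  areas_um2 <- tabulate(lab[lab > 0]) * scale^2
  areas_um2 <- areas_um2[areas_um2 > 0]
  sum(areas_um2 >= min_area & areas_um2 <= max_area)
}

#' Integrated density
#'
#' Sum of raw (unthresholded) pixel intensities over a region — the whole
#' image when no mask is given. Satisfies the identity
#' `integrated density = mean intensity x pixel count of the region`.
#'
#' @param img A [fluorescence_image()].
#' @param mask Optional logical mask on the same grid.
#'
#' @return Integrated density in intensity x pixel units. Multiply by
#'   `img$scale^2` for intensity x um^2.
#' @export
integrated_density <- function(img, mask = NULL) {
  stopifnot(inherits(img, "fluor_image"))
  if (is.null(mask)) return(sum(img$pixels))
  stopifnot(is.matrix(mask), all(dim(mask) == dim(img$pixels)))
  sum(img$pixels[mask])
}

#' Positive-signal area per cell
#'
#' Total positive area divided by the cell count; undefined (returned as
#' `NA` with a warning suppressed into the `defined` flag) when no cells
#' were counted — never 0 and never infinite.
#'
#' @param mask Logical mask from [threshold_positive()].
#' @param count Cell count from [count_cells()] on the same mask.
#' @param scale Micrometers per pixel.
#'
#' @return A list with `area_per_cell_um2` (`NA` when undefined) and
#'   `defined` (logical).
#' @export
area_per_cell <- function(mask, count, scale) {
  stopifnot(is.matrix(mask), is.logical(c(mask)), scale > 0,
            is.numeric(count), count >= 0)
  if (count == 0)
    return(list(area_per_cell_um2 = NA_real_, defined = FALSE))
  list(area_per_cell_um2 = sum(mask) * scale^2 / count, defined = TRUE)
}

#' Quantify one micrograph
#'
#' Runs the full per-image quantification: thresholding, area fraction,
#' cell count, integrated density (raw intensities over the whole image)
#' and area of positive signal per cell. Deterministic: the same image and
#' configuration always produce the identical result row.
#'
#' @param img A [fluorescence_image()].
#' @param method,fixed_value Thresholding; see [threshold_positive()].
#' @param min_area,max_area Cell size filter in um^2; see [count_cells()].
#'
#' @return A one-row tibble with study labels, `threshold_used`,
#'   `area_fraction`, `cell_count`, `positive_area_um2`,
#'   `integrated_density` (intensity x pixel), `integrated_density_um2`,
#'   and `area_per_cell_um2` (`NA` when `cell_count` is 0).
#' @export
quantify_image <- function(img, method = c("otsu", "fixed"),
                           fixed_value = NULL, min_area = 20, max_area = Inf) {
  mask <- threshold_positive(img, method, fixed_value)
  count <- count_cells(mask, img$scale, min_area, max_area)
  apc <- area_per_cell(mask, count, img$scale)
  id <- integrated_density(img)
  tibble::tibble(
    subject_id = img$subject_id, group = img$group, channel = img$channel,
    threshold_used = attr(mask, "threshold"),
    area_fraction = area_fraction(mask),
    cell_count = count,
    positive_area_um2 = sum(mask) * img$scale^2,
    integrated_density = id,
    integrated_density_um2 = id * img$scale^2,
    area_per_cell_um2 = apc$area_per_cell_um2)
}

#' Aggregate per-image quantification to subjects
#'
#' Averages the six (or however many) representative images of each subject
#' before group statistics, so the subject — not the image — is the
#' statistical unit.
#'
#' @param quant A tibble of [quantify_image()] rows.
#'
#' @return A tibble with one row per subject x channel, mean of each
#'   numeric measure.
#' @export
aggregate_by_subject <- function(quant) {
  stopifnot(is.data.frame(quant),
            all(c("subject_id", "group", "channel") %in% names(quant)))
  metrics <- setdiff(names(quant)[vapply(quant, is.numeric, logical(1))],
                     "threshold_used")
  agg <- stats::aggregate(
    quant[metrics],
    by = list(subject_id = quant$subject_id, group = quant$group,
              channel = quant$channel),
    FUN = function(v) mean(v, na.rm = TRUE))
  tibble::as_tibble(agg)
}

#' Read a grayscale micrograph with metadata
#'
#' Reads a TIFF or PNG via EBImage, converts to a single-channel intensity
#' matrix (graylevel average when the file has color channels), and wraps
#' it with scale and study labels.
#'
#' @param path Image file path.
#' @param scale Micrometers per pixel.
#' @param channel,subject_id,group Study labels.
#'
#' @return A [fluorescence_image()].
#' @export
read_fluorescence_image <- function(path, scale, channel = "GFAP",
                                    subject_id = "s1", group = "sham") {
  px <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(px)) == 3L) px <- apply(px, c(1L, 2L), mean)
  fluorescence_image(px, scale = scale, channel = channel,
                     subject_id = subject_id, group = group)
}
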