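#' A single fluorescence image field
#'
#' @param pixels Non-negative numeric matrix of intensities.
#' @param pixel_size_um Micrometres per pixel (> 0).
#' @param well_id,field_index Identifiers.
#' @return An object of class `image_field`.
#' @export
image_field <- function(pixels, pixel_size_um = 1, well_id = NA_character_,
                        field_index = 1L) {
  pixels <- as.matrix(pixels)
  assert_scalar_num(pixel_size_um, "pixel_size_um", positive = TRUE)
  if (nrow(pixels) < 64L || ncol(pixels) < 64L)
    stopf("image error: fields must be at least 64x64 pixels")
  if (any(pixels < 0)) stopf("image error: intensities must be >= 0")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 well_id = well_id, field_index = field_index),
            class = "image_field")
}

as_image_field <- function(x, ...) {
  if (inherits(x, "image_field")) x
  else if (is.list(x) && !is.null(x$pixels))
    image_field(x$pixels, ...)
  else image_field(x, ...)
}

#' Configuration of the image-quantification pipeline
#'
#' Parameters of the enhance / segment / quantify stages. The stages use
#' the canonical operators for neurite quantification: opening-based
#' background subtraction, a multiscale Hessian ridge (tubeness) filter,
#' Otsu or fixed thresholding, morphological soma extraction and
#' skeleton-length measurement; every choice is overridable here.
#'
#' @param background_radius Radius (pixels) of the morphological opening
#'   used to estimate background.
#' @param tubeness_scales Gaussian scales (pixels) of the multiscale ridge
#'   filter.
#' @param neurite_threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold Threshold on the ridge response when
#'   `neurite_threshold_method = "fixed"`.
#' @param soma_min_area_um2 Minimum connected-component area kept as a soma.
#' @param min_object_length_um Neurite-mask components whose pixel extent
#'   corresponds to less than this length are discarded as debris.
#' @param prune_spur_um Skeleton spurs shorter than this are pruned (see
#'   [prune_spurs()]).
#' @param soma_opening_radius_um Radius of the opening that isolates soma
#'   bodies from thin processes before area filtering.
#' @param soma_exclusion_um Width of the exclusion ring around detected
#'   somata removed from the neurite mask, so that the blurred halo of a
#'   cell body is not skeletonized as neurite.
#' @return A list of class `quant_config`.
#' @export
quant_config <- function(background_radius = 15,
                         tubeness_scales = c(1, 1.5, 2),
                         neurite_threshold_method = c("otsu", "fixed"),
                         fixed_threshold = NULL,
                         soma_min_area_um2 = 50,
                         min_object_length_um = 10,
                         prune_spur_um = 5,
                         soma_opening_radius_um = 2,
                         soma_exclusion_um = 4) {
  neurite_threshold_method <- match.arg(neurite_threshold_method)
  vals <- c(background_radius, tubeness_scales, soma_min_area_um2,
            min_object_length_um, soma_opening_radius_um)
  if (any(vals <= 0)) stopf("config error: all lengths/areas must be > 0")
  if (prune_spur_um < 0) stopf("config error: prune_spur_um must be >= 0")
  if (soma_exclusion_um < 0)
    stopf("config error: soma_exclusion_um must be >= 0")
  structure(list(
    background_radius = background_radius,
    tubeness_scales = tubeness_scales,
    neurite_threshold_method = neurite_threshold_method,
    fixed_threshold = fixed_threshold,
    soma_min_area_um2 = soma_min_area_um2,
    min_object_length_um = min_object_length_um,
    prune_spur_um = prune_spur_um,
    soma_opening_radius_um = soma_opening_radius_um,
    soma_exclusion_um = soma_exclusion_um
  ), class = "quant_config")
}

# Smaller Hessian eigenvalue at each pixel of a smoothed image.
hessian_min_eigen <- function(sm) {
  hxx <- shift_mat_num(sm, 0, -1) - 2 * sm + shift_mat_num(sm, 0, 1)
  hyy <- shift_mat_num(sm, -1, 0) - 2 * sm + shift_mat_num(sm, 1, 0)
  hxy <- (shift_mat_num(sm, -1, -1) + shift_mat_num(sm, 1, 1) -
            shift_mat_num(sm, -1, 1) - shift_mat_num(sm, 1, -1)) / 4
  0.5 * ((hxx + hyy) - sqrt((hxx - hyy)^2 + 4 * hxy^2))
}

shift_mat_num <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  ri <- max(1, 1 + di):min(nr, nr + di)
  rj <- max(1, 1 + dj):min(nc, nc + dj)
  out[ri, rj] <- m[ri - di, rj - dj]
  out
}

#' Enhance curvilinear structures in a fluorescence field
#'
#' Estimates background by morphological opening at
#' `cfg$background_radius`, subtracts it (clipping at zero), then amplifies
#' curvilinear structures with a multiscale Hessian ridge (tubeness)
#' response: at each scale the image is Gaussian-smoothed and the
#' scale-normalized magnitude of the negative minor Hessian eigenvalue is
#' taken; the response is the maximum over `cfg$tubeness_scales`.
#'
#' @param image An [image_field()] (or plain matrix).
#' @param cfg A [quant_config()].
#' @return An `image_field` whose pixels hold the ridge response.
#' @export
enhance <- function(image, cfg = quant_config()) {
  image <- as_image_field(image)
  if (cfg$background_radius >= min(dim(image$pixels)))
    stopf("config error: background_radius must be smaller than the image")
  brush <- EBImage::makeBrush(2 * floor(cfg$background_radius) + 1, "disc")
  bg <- as.matrix(EBImage::imageData(
    EBImage::opening(EBImage::Image(image$pixels), brush)))
  sub <- pmax(image$pixels - bg, 0)
  resp <- matrix(0, nrow(sub), ncol(sub))
  for (s in cfg$tubeness_scales) {
    sm <- as.matrix(EBImage::imageData(
      EBImage::gblur(EBImage::Image(sub), sigma = s)))
    resp <- pmax(resp, s^2 * pmax(-hessian_min_eigen(sm), 0))
  }
  # the finite-difference stencil is undefined in a band at the image
  # border (and the PSF tail is clipped there); suppress it
  margin <- ceiling(2 * max(cfg$tubeness_scales)) + 1L
  n <- nrow(resp); m <- ncol(resp)
  resp[c(seq_len(margin), (n - margin + 1L):n), ] <- 0
  resp[, c(seq_len(margin), (m - margin + 1L):m)] <- 0
  out <- image
  out$pixels <- resp
  out
}

# Otsu threshold on a [0, max] image; returns threshold on the input scale.
otsu_threshold <- function(pixels) {
  mx <- max(pixels)
  if (mx <= 0) return(Inf)
  EBImage::otsu(EBImage::Image(pixels / mx), range = c(0, 1)) * mx
}

#' Segment neurites and somata
#'
#' The neurite mask is the thresholded ridge response with components whose
#' pixel extent is shorter than `cfg$min_object_length_um` removed. The
#' soma mask is the thresholded raw image, opened with a disc of radius
#' `cfg$soma_opening_radius_um` (which erases thin processes), keeping
#' components of at least `cfg$soma_min_area_um2`. Soma pixels are removed
#' from the neurite mask so that cell bodies never contribute to neurite
#' length.
#'
#' @param image_enhanced Output of [enhance()].
#' @param image_raw The corresponding raw [image_field()].
#' @param cfg A [quant_config()].
#' @return A list of class `segmentation_result` with logical
#'   `neurite_mask` and `soma_mask`, `soma_count`, `pixel_size_um`, and
#'   placeholders for `skeleton` / `total_length_um` filled by
#'   [measure_neurite_length()].
#' @export
segment_field <- function(image_enhanced, image_raw, cfg = quant_config()) {
  image_enhanced <- as_image_field(image_enhanced)
  image_raw <- as_image_field(image_raw)
  if (!all(dim(image_enhanced$pixels) == dim(image_raw$pixels)))
    stopf("enhanced and raw images must have the same shape")
  px <- image_raw$pixel_size_um

  thr <- if (cfg$neurite_threshold_method == "fixed") {
    if (is.null(cfg$fixed_threshold))
      stopf("config error: fixed_threshold required for method 'fixed'")
    cfg$fixed_threshold
  } else otsu_threshold(image_enhanced$pixels)
  neurite <- image_enhanced$pixels > thr

  if (any(neurite)) {
    lab <- EBImage::bwlabel(EBImage::Image(neurite))
    sizes <- tabulate(as.integer(EBImage::imageData(lab)))
    keep <- which(sizes * px >= cfg$min_object_length_um)
    neurite <- matrix(as.integer(EBImage::imageData(lab)) %in% keep,
                      nrow(neurite), ncol(neurite))
  }

  raw_thr <- otsu_threshold(image_raw$pixels)
  soma <- image_raw$pixels > raw_thr
  if (any(soma)) {
    r <- max(1L, round(cfg$soma_opening_radius_um / px))
    brush <- EBImage::makeBrush(2L * r + 1L, "disc")
    soma <- as.matrix(EBImage::imageData(
      EBImage::opening(EBImage::Image(soma), brush))) > 0
  }
  soma_count <- 0L
  if (any(soma)) {
    lab <- EBImage::bwlabel(EBImage::Image(soma))
    areas <- tabulate(as.integer(EBImage::imageData(lab)))
    keep <- which(areas * px^2 >= cfg$soma_min_area_um2)
    soma <- matrix(as.integer(EBImage::imageData(lab)) %in% keep,
                   nrow(soma), ncol(soma))
    soma_count <- length(keep)
  }
  excl <- soma
  if (any(soma) && cfg$soma_exclusion_um > 0) {
    r <- max(1L, round(cfg$soma_exclusion_um / px))
    excl <- as.matrix(EBImage::imageData(EBImage::dilate(
      EBImage::Image(soma), EBImage::makeBrush(2L * r + 1L, "disc")))) > 0
  }
  neurite[excl] <- FALSE

  structure(list(neurite_mask = neurite, soma_mask = soma,
                 skeleton = NULL, total_length_um = NA_real_,
                 soma_count = soma_count, pixel_size_um = px),
            class = "segmentation_result")
}

#' Measure total neurite length from a segmentation
#'
#' Skeletonizes the neurite mask by topology-preserving thinning, prunes
#' spurs shorter than `prune_spur_um`, and sums geometric step lengths
#' (1 per lateral step, sqrt(2) per diagonal step) times the pixel size.
#'
#' @param seg A [segment_field()] result.
#' @param pixel_size_um Micrometres per pixel (defaults to the value stored
#'   in `seg`).
#' @param prune_spur_um Spur-pruning threshold in micrometres.
#' @return The updated `segmentation_result`, with `skeleton` and
#'   `total_length_um` filled in.
#' @export
measure_neurite_length <- function(seg, pixel_size_um = seg$pixel_size_um,
                                   prune_spur_um = 5) {
  stopifnot(inherits(seg, "segmentation_result"))
  skel <- skeletonize(seg$neurite_mask)
  skel <- prune_spurs(skel, prune_um = prune_spur_um,
                      pixel_size_um = pixel_size_um)
  seg$skeleton <- skel
  seg$total_length_um <- skeleton_length_um(skel, pixel_size_um)
  seg
}

#' Count somata in a segmentation
#'
#' Number of 8-connected components of the soma mask.
#'
#' @param seg A [segment_field()] result.
#' @return Integer soma count.
#' @export
count_somata <- function(seg) {
  stopifnot(inherits(seg, "segmentation_result"))
  if (!any(seg$soma_mask)) return(0L)
  max(as.integer(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(seg$soma_mask)))))
}

#' Quantify total neurite length for one well
#'
#' Runs the full enhance / segment / measure pipeline on each image field
#' and averages the per-field total neurite lengths.
#'
#' @param fields List of 1-8 [image_field()] objects (or matrices).
#' @param cfg A [quant_config()].
#' @return A list with `mean_total_length_um`, `per_field_um`,
#'   `soma_counts` and `status` (`"ok"` or `"failed"` when every field is
#'   blank or segmentation fails).
#' @export
quantify_well <- function(fields, cfg = quant_config()) {
  if (length(fields) == 0L) stopf("input error: at least one field required")
  if (length(fields) > 8L) stopf("input error: at most 8 fields per well")
  res <- lapply(fields, function(f) {
    tryCatch({
      f <- as_image_field(f)
      seg <- segment_field(enhance(f, cfg), f, cfg)
      seg <- measure_neurite_length(seg, prune_spur_um = cfg$prune_spur_um)
      list(len = seg$total_length_um, somata = count_somata(seg))
    }, error = function(e) list(len = NA_real_, somata = NA_integer_))
  })
  per <- vapply(res, `[[`, numeric(1), "len")
  somata <- vapply(res, `[[`, integer(1), "somata")
  failed <- all(is.na(per)) || all(per == 0, na.rm = TRUE)
  list(mean_total_length_um = if (failed) NA_real_ else mean(per, na.rm = TRUE),
       per_field_um = per, soma_counts = somata,
       status = if (failed) "failed" else "ok")
}
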