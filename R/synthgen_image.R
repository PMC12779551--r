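#' Ground truth geometry for a synthetic fluorescence image field
#'
#' @param filament_paths List of two-column matrices (x, y pixel
#'   coordinates) of polyline vertices, one per filament.
#' @param soma_centers Two-column matrix of soma centre coordinates
#'   (may have zero rows).
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @param soma_radius_px Soma disc radius in pixels.
#'
#' @return A list of class `image_truth` with the geometry plus
#'   `total_length_um`, the summed polyline arc length times the pixel size.
#' @export
image_truth <- function(filament_paths, soma_centers = NULL,
                        pixel_size_um = 1, soma_radius_px = 6) {
  assert_scalar_num(pixel_size_um, "pixel_size_um", positive = TRUE)
  filament_paths <- lapply(filament_paths, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L) stopf("filament paths must be two-column matrices")
    p
  })
  if (is.null(soma_centers)) soma_centers <- matrix(numeric(0), ncol = 2)
  soma_centers <- as.matrix(soma_centers)
  structure(list(
    filament_paths = filament_paths,
    soma_centers = soma_centers,
    pixel_size_um = pixel_size_um,
    soma_radius_px = soma_radius_px,
    total_length_um = polyline_length_px(filament_paths) * pixel_size_um
  ), class = "image_truth")
}

# Total arc length (pixels) of a list of polylines: point-to-point sum.
polyline_length_px <- function(paths) {
  sum(vapply(paths, function(p) {
    if (nrow(p) < 2L) return(0)
    sum(sqrt(rowSums(diff(p)^2)))
  }, numeric(1)))
}

#' Render a synthetic fluorescence image field from ground-truth geometry
#'
#' Filaments are rasterized at sub-pixel resolution at a fixed intensity,
#' somata as brighter discs; the field is blurred with a Gaussian PSF,
#' offset by a uniform background, and corrupted with Poisson or Gaussian
#' noise. The returned truth is untouched by rendering.
#'
#' @param truth An [image_truth()] object.
#' @param shape Integer vector `c(nrow, ncol)` of the image in pixels.
#' @param psf_sigma Gaussian PSF standard deviation in pixels.
#' @param background Uniform background intensity (arbitrary units).
#' @param noise_model List with elements `model` (`"poisson"`,
#'   `"gaussian"` or `"none"`) and `scale`: for Poisson noise, expected
#'   photon count per unit intensity; for Gaussian, the additive s.d.
#' @param seed Integer seed or `NULL`.
#' @param filament_intensity,soma_intensity Rendered intensities.
#'
#' @return A list with `pixels` (numeric matrix) and `truth`.
#' @examples
#' tr <- image_truth(list(cbind(14:100, 50)), cbind(30, 30))
#' img <- render_image(tr, shape = c(128, 128), seed = 1)
#' @export
render_image <- function(truth, shape = c(256L, 256L), psf_sigma = 1.5,
                         background = 0.05,
                         noise_model = list(model = "poisson", scale = 100),
                         seed = NULL, filament_intensity = 1,
                         soma_intensity = 3) {
  stopifnot(inherits(truth, "image_truth"))
  nr <- shape[1]; nc <- shape[2]
  all_xy <- do.call(rbind, c(truth$filament_paths,
                             list(truth$soma_centers)))
  if (nrow(all_xy) > 0 &&
      (any(all_xy < 1) || any(all_xy[, 1] > nc) || any(all_xy[, 2] > nr)))
    stopf("input error: filament/soma coordinates outside image shape")
  img <- matrix(0, nr, nc)
  for (p in truth$filament_paths) {
    pts <- densify_polyline(p, step = 0.25)
    idx <- unique(cbind(pmin(pmax(round(pts[, 2]), 1), nr),
                        pmin(pmax(round(pts[, 1]), 1), nc)))
    img[idx] <- filament_intensity
  }
  if (nrow(truth$soma_centers) > 0) {
    r <- truth$soma_radius_px
    for (i in seq_len(nrow(truth$soma_centers))) {
      cx <- truth$soma_centers[i, 1]; cy <- truth$soma_centers[i, 2]
      xs <- max(1, floor(cx - r)):min(nc, ceiling(cx + r))
      ys <- max(1, floor(cy - r)):min(nr, ceiling(cy + r))
      dsq <- outer((ys - cy)^2, (xs - cx)^2, `+`)
      img[ys, xs][dsq <= r^2] <- soma_intensity
    }
  }
  if (psf_sigma > 0)
    img <- as.matrix(EBImage::imageData(
      EBImage::gblur(EBImage::Image(img), sigma = psf_sigma)))
  img <- img + background
  img <- with_seed(seed, switch(
    noise_model$model %||% "none",
    poisson = matrix(rpois(length(img), pmax(img, 0) * noise_model$scale) /
                       noise_model$scale, nr, nc),
    gaussian = img + matrix(rnorm(length(img), 0, noise_model$scale), nr, nc),
    none = img,
    stopf("unknown noise model '%s'", noise_model$model)))
  list(pixels = pmax(img, 0), truth = truth)
}

# Resample a polyline at roughly `step`-pixel spacing.
densify_polyline <- function(p, step = 0.25) {
  if (nrow(p) < 2L) return(p)
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  n <- max(2L, ceiling(s[length(s)] / step) + 1L)
  si <- seq(0, s[length(s)], length.out = n)
  cbind(approx(s, p[, 1], xout = si)$y, approx(s, p[, 2], xout = si)$y)
}

#' Simulate a random image field of curved filaments and somata
#'
#' Filaments are cubic-spline polylines through random control points,
#' rasterized at sub-pixel resolution; somata are discs. The returned
#' ground truth records the exact arc length.
#'
#' @param n_filaments,n_somata Object counts.
#' @param shape Image shape in pixels.
#' @param pixel_size_um Micrometres per pixel.
#' @param seed Integer seed or `NULL`.
#' @inheritParams render_image
#' @return As [render_image()], plus the `image_truth` in `$truth`.
#' @export
simulate_image_field <- function(n_filaments = 4, n_somata = 3,
                                 shape = c(256L, 256L), pixel_size_um = 1,
                                 psf_sigma = 1.5, background = 0.05,
                                 noise_model = list(model = "poisson",
                                                    scale = 100),
                                 seed = NULL) {
  nr <- shape[1]; nc <- shape[2]
  margin <- 12
  with_seed(seed, {
    paths <- lapply(seq_len(n_filaments), function(i) {
      n_ctrl <- sample(4:6, 1)
      ctrl <- cbind(runif(n_ctrl, margin, nc - margin),
                    runif(n_ctrl, margin, nr - margin))
      # order control points along their first principal direction for a
      # mostly self-avoiding curve
      d <- ctrl[, which.max(apply(ctrl, 2, stats::var))]
      ctrl <- ctrl[order(d), , drop = FALSE]
      tt <- seq_len(n_ctrl)
      ti <- seq(1, n_ctrl, length.out = 40 * n_ctrl)
      path <- cbind(spline(tt, ctrl[, 1], xout = ti)$y,
                    spline(tt, ctrl[, 2], xout = ti)$y)
      path[, 1] <- pmin(pmax(path[, 1], 2), nc - 1)
      path[, 2] <- pmin(pmax(path[, 2], 2), nr - 1)
      path
    })
    centers <- if (n_somata > 0)
      cbind(runif(n_somata, margin, nc - margin),
            runif(n_somata, margin, nr - margin))
    else NULL
    tr <- image_truth(paths, centers, pixel_size_um = pixel_size_um)
    render_image(tr, shape = shape, psf_sigma = psf_sigma,
                 background = background, noise_model = noise_model,
                 seed = NULL)
  })
}
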