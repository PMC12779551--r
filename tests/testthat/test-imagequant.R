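cfg <- quant_config()

render_line_field <- function(path, shape = c(128L, 128L), seed = 2,
                              pixel_size_um = 1) {
  tr <- image_truth(list(path), NULL, pixel_size_um = pixel_size_um)
  img <- render_image(tr, shape = shape, seed = seed,
                      noise_model = list(model = "poisson", scale = 200))
  image_field(img$pixels, pixel_size_um = pixel_size_um)
}

measure_field <- function(f, qc = cfg) {
  seg <- segment_field(enhance(f, qc), f, qc)
  measure_neurite_length(seg, prune_spur_um = qc$prune_spur_um)
}

test_that("flat fields have no ridge response and ridges outrank background", {
  flat <- image_field(matrix(0.3, 96, 96))
  expect_true(all(enhance(flat, cfg)$pixels == 0))

  px <- matrix(0, 96, 96)
  px[48, ] <- 1  # 1-px line spanning the width: no endpoint effects
  enh <- enhance(image_field(px), cfg)$pixels
  interior <- 10:86
  line_resp <- enh[48, interior]
  bg_resp <- enh[-(46:50), ]
  expect_gt(min(line_resp), max(bg_resp))
})

test_that("enhancement raises the filament/background contrast of rendered fields", {
  sim <- suppressWarnings(simulate_image_field(3, 0, shape = c(192, 192),
                                               seed = 5))
  f <- image_field(sim$pixels)
  enh <- enhance(f, cfg)
  fil <- do.call(rbind, lapply(sim$truth$filament_paths, function(p)
    unique(cbind(pmin(pmax(round(p[, 2]), 1), 192),
                 pmin(pmax(round(p[, 1]), 1), 192)))))
  interior <- fil[fil[, 1] > 8 & fil[, 1] < 184 & fil[, 2] > 8 &
                    fil[, 2] < 184, ]
  on_raw <- mean(f$pixels[interior]); on_enh <- mean(enh$pixels[interior])
  bg_mask <- matrix(TRUE, 192, 192); bg_mask[interior] <- FALSE
  off_raw <- mean(f$pixels[bg_mask][f$pixels[bg_mask] > 0])
  off_enh <- mean(enh$pixels[bg_mask])
  expect_gt(on_enh / max(off_enh, 1e-12), on_raw / off_raw)
})

test_that("segmentation of blank and single-disc fields is exact", {
  blank <- image_field(matrix(0, 96, 96))
  seg <- segment_field(enhance(blank, cfg), blank, cfg)
  expect_false(any(seg$neurite_mask))
  expect_false(any(seg$soma_mask))
  expect_equal(count_somata(seg), 0L)

  # one disc of about 400 um^2 (radius ~11.3 px at 1 um/px)
  tr <- image_truth(list(), cbind(48, 48), soma_radius_px = 11.3)
  img <- render_image(tr, shape = c(96, 96), seed = 1,
                      noise_model = list(model = "poisson", scale = 200))
  f <- image_field(img$pixels)
  seg <- segment_field(enhance(f, cfg), f,
                       quant_config(soma_min_area_um2 = 100))
  expect_equal(count_somata(seg), 1L)
})

test_that("generated fields recover soma count and cover the filaments", {
  sim <- suppressWarnings(simulate_image_field(4, 3, shape = c(256, 256),
                                               seed = 7))
  f <- image_field(sim$pixels)
  seg <- segment_field(enhance(f, cfg), f, cfg)
  expect_equal(count_somata(seg), 3L)

  # coverage of true filament pixels by the neurite mask (or the soma
  # exclusion zone, where filament pixels are deliberately reassigned),
  # checked away from the suppressed border band
  fil <- do.call(rbind, lapply(sim$truth$filament_paths, function(p) {
    dp <- neuritescreen:::densify_polyline(p, 0.25)
    unique(cbind(pmin(pmax(round(dp[, 2]), 1), 256),
                 pmin(pmax(round(dp[, 1]), 1), 256)))
  }))
  fil <- fil[fil[, 1] > 8 & fil[, 1] < 248 & fil[, 2] > 8 & fil[, 2] < 248, ]
  near <- EBImage::dilate(EBImage::Image(seg$neurite_mask | seg$soma_mask),
                          EBImage::makeBrush(9, "disc"))
  covered <- as.matrix(EBImage::imageData(near))[fil] > 0
  expect_gte(mean(covered), 0.9)
})

test_that("skeleton length measures straight and diagonal chains exactly", {
  expect_equal(skeleton_length_um(matrix(FALSE, 64, 64)), 0)

  m <- matrix(FALSE, 128, 128); m[64, 14:114] <- TRUE
  expect_equal(skeleton_length_um(m, 1), 100)

  d <- matrix(FALSE, 128, 128); d[cbind(14:114, 14:114)] <- TRUE
  expect_equal(skeleton_length_um(d, 1), 100 * sqrt(2))

  # half the pixel size, half the metric length
  expect_equal(skeleton_length_um(m, 0.5), 50)
})

test_that("spur pruning removes short side branches but not open curves", {
  m <- matrix(FALSE, 64, 64)
  m[32, 10:50] <- TRUE      # main axis, 41 px
  m[29:31, 30] <- TRUE      # 3-px spur hanging off a junction
  pruned <- prune_spurs(m, prune_um = 5, pixel_size_um = 1)
  # the spur body goes; the junction-adjacent pixel may survive
  expect_false(any(pruned[29:30, 30]))
  expect_true(all(pruned[32, 10:50]))

  open_curve <- matrix(FALSE, 64, 64); open_curve[20, 20:23] <- TRUE
  expect_equal(prune_spurs(open_curve, 5, 1), open_curve)
})

test_that("rendered straight and rotated filaments measure consistently", {
  horiz <- render_line_field(cbind(14:114, 64))
  vert <- render_line_field(cbind(64, 14:114), seed = 3)
  diag <- render_line_field(cbind(14:114, 14:114), seed = 4)
  lh <- measure_field(horiz)$total_length_um
  lv <- measure_field(vert)$total_length_um
  ld <- measure_field(diag)$total_length_um / sqrt(2)
  lens <- c(lh, lv, ld)
  expect_lt((max(lens) - min(lens)) / mean(lens), 0.05)
  expect_lt(abs(lh - 100) / 100, 0.05)
})

test_that("halving the pixel size with a supersampled rendering preserves length", {
  path1 <- cbind(14:114, seq(30, 90, length.out = 101))
  l1 <- measure_field(render_line_field(path1))$total_length_um
  f2 <- render_line_field(path1 * 2, shape = c(256L, 256L),
                          pixel_size_um = 0.5, seed = 6)
  l2 <- measure_field(f2)$total_length_um
  expect_lt(abs(l2 - l1) / l1, 0.05)
})

test_that("adding a disjoint filament never decreases total length", {
  base <- image_truth(list(cbind(14:100, 40)), NULL)
  both <- image_truth(list(cbind(14:100, 40), cbind(14:100, 90)), NULL)
  l1 <- measure_field(image_field(render_image(
    base, c(128, 128), seed = 8,
    noise_model = list(model = "poisson", scale = 200))$pixels))$total_length_um
  l2 <- measure_field(image_field(render_image(
    both, c(128, 128), seed = 8,
    noise_model = list(model = "poisson", scale = 200))$pixels))$total_length_um
  expect_gte(l2, l1)
})

test_that("well quantification averages fields and flags blank wells", {
  f <- render_line_field(cbind(14:114, 64))
  q <- quantify_well(list(f, f, f), cfg)
  expect_equal(q$status, "ok")
  expect_equal(q$mean_total_length_um, q$per_field_um[1])
  expect_equal(q$mean_total_length_um, mean(q$per_field_um))

  blankq <- quantify_well(list(image_field(matrix(0, 96, 96))), cfg)
  expect_equal(blankq$status, "failed")
  expect_error(quantify_well(list()), "at least one")
})

test_that("soma counting is exact for separated discs", {
  tr <- image_truth(list(), rbind(c(30, 30), c(80, 80)), soma_radius_px = 6)
  img <- render_image(tr, shape = c(112, 112), seed = 1,
                      noise_model = list(model = "poisson", scale = 200))
  f <- image_field(img$pixels)
  expect_equal(count_somata(segment_field(enhance(f, cfg), f, cfg)), 2L)
})
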