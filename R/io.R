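# Interchange formats: long/tidy CSV for well series (one row per
# plate-well-field-day), TIFF + JSON sidecar for image fields, JSON for
# ground truth and summaries. UTF-8, comma-separated, '.' decimal.

WELL_SERIES_COLUMNS <- c("plate", "well", "donor", "group", "treatment",
                         "dose_uM", "day", "field", "total_length_um",
                         "status")

#' Read a long-format well-series CSV
#'
#' Expects one row per plate-well-field-day with columns `plate`, `well`,
#' `donor`, `group`, `treatment`, `dose_uM`, `day`, `field`,
#' `total_length_um`, `status` (`ok` or `failed`). Field values of each
#' well-day are averaged into the well series; a day whose fields all
#' failed is marked as failed quantification.
#'
#' @param path CSV file path.
#' @return Named list of [well_series()] objects (one per plate-well).
#' @export
read_well_series <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(WELL_SERIES_COLUMNS, names(df))
  if (length(missing))
    stopf("schema error: missing column(s): %s",
          paste(missing, collapse = ", "))
  len <- suppressWarnings(as.numeric(df$total_length_um))
  bad <- which(is.na(len) & !is.na(df$total_length_um) &
                 df$total_length_um != "" & df$status != "failed")
  if (length(bad))
    stopf("parse error: non-numeric total_length_um at line %d",
          bad[1] + 1L)  # +1 for the header row
  df$total_length_um <- len
  key <- paste(df$plate, df$well, sep = "\r")
  out <- lapply(split(df, key), function(w) {
    per_day <- lapply(split(w, w$day), function(d) {
      ok <- d$status == "ok" & !is.na(d$total_length_um)
      if (!any(ok)) NA_real_ else mean(d$total_length_um[ok])
    })
    days <- as.integer(names(per_day))
    o <- order(days)
    grp <- w$group[1]
    well_series(days[o], unlist(per_day)[o], well_id = w$well[1],
                donor_id = w$donor[1],
                group = if (grp %in% c("control", "SALS", "FALS", "PLS"))
                  grp else "control",
                treatment = if (is.na(w$treatment[1]) ||
                                w$treatment[1] == "") NA_character_
                else w$treatment[1],
                dose_uM = suppressWarnings(as.numeric(w$dose_uM[1])))
  })
  setNames(out, vapply(out, `[[`, character(1), "well_id"))
}

#' Write well series to a long-format CSV
#'
#' Inverse of [read_well_series()]: one row per well-day with `field = 1`
#' (field-level detail is not retained in a `well_series`).
#'
#' @param wells Named list of [well_series()] objects.
#' @param path Output CSV path.
#' @param plate Plate identifier written to every row.
#' @return `path`, invisibly.
#' @export
write_well_series <- function(wells, path, plate = "P1") {
  rows <- do.call(rbind, lapply(wells, function(w) data.frame(
    plate = plate, well = w$well_id, donor = w$donor_id, group = w$group,
    treatment = w$treatment, dose_uM = w$dose_uM, day = w$days,
    field = 1L,
    total_length_um = ifelse(is.na(w$length_um), "", w$length_um),
    status = ifelse(is.na(w$length_um), "failed", "ok"),
    stringsAsFactors = FALSE)))
  write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write an image field as TIFF with a JSON sidecar
#'
#' The image is stored as 16-bit single-plane TIFF scaled to its maximum;
#' the scale factor and the pixel size in micrometres are recorded in a
#' `<path>.json` sidecar so that quantification in physical units can be
#' reproduced from disk.
#'
#' @param field An [image_field()] (or matrix plus `pixel_size_um`).
#' @param path Output TIFF path.
#' @param pixel_size_um Pixel size, if `field` is a plain matrix.
#' @return `path`, invisibly.
#' @export
write_image_field <- function(field, path, pixel_size_um = 1) {
  field <- as_image_field(field, pixel_size_um = pixel_size_um)
  mx <- max(field$pixels)
  scale <- if (mx > 0) mx else 1
  EBImage::writeImage(EBImage::Image(field$pixels / scale), path,
                      type = "tiff", bits.per.sample = 16L)
  jsonlite::write_json(list(pixel_size_um = field$pixel_size_um,
                            intensity_scale = scale,
                            well_id = field$well_id,
                            field_index = field$field_index),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image field written by [write_image_field()]
#'
#' @param path TIFF path (the `<path>.json` sidecar must exist).
#' @return An [image_field()].
#' @export
read_image_field <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stopf("sidecar not found: %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  px <- as.matrix(EBImage::imageData(EBImage::readImage(path)))
  image_field(px * (meta$intensity_scale %||% 1),
              pixel_size_um = meta$pixel_size_um %||% 1,
              well_id = meta$well_id %||% NA_character_,
              field_index = meta$field_index %||% 1L)
}

#' Read ROI fluorescence traces from a wide CSV
#'
#' Expects a `time` column (seconds) plus one column per ROI; the sampling
#' rate is inferred from the time column unless given.
#'
#' @param path CSV path.
#' @param sampling_rate Hz; inferred from the median time step if `NULL`.
#' @return Named list of [fluor_trace()] objects.
#' @export
read_traces <- function(path, sampling_rate = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"time" %in% names(df)) stopf("schema error: missing column(s): time")
  if (is.null(sampling_rate)) {
    dt <- median(diff(df$time))
    if (!is.finite(dt) || dt <= 0)
      stopf("parse error: cannot infer sampling rate from time column")
    sampling_rate <- 1 / dt
  }
  rois <- setdiff(names(df), "time")
  setNames(lapply(rois, function(r)
    fluor_trace(df[[r]], sampling_rate = sampling_rate, roi_id = r)), rois)
}
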