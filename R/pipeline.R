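#' Configuration for an end-to-end pipeline run
#'
#' @param out_dir Output directory; created if absent.
#' @param seed Integer seed recorded in the manifest and used for every
#'   stochastic stage.
#' @param plate A [sim_plate_config()] for the simulate stage.
#' @param qc A [qc_config()].
#' @param quant A [quant_config()] for the quantify stage.
#' @param detect A [detect_config()] for the calcium stage.
#' @param screen_mode `"screen_relative"` or `"vs_dmso"`.
#' @param cap_days Rescue truncation cap (see [truncate_rescues()]).
#' @param responder_threshold Days threshold for [classify_responders()].
#' @param well_series_csv,image_dir,traces_csv Input paths for stages
#'   whose inputs are not produced by an earlier stage in the same run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("nsrun"), seed = 1L,
                       plate = sim_plate_config(seed = seed),
                       qc = qc_config(), quant = quant_config(),
                       detect = detect_config(),
                       screen_mode = c("screen_relative", "vs_dmso"),
                       cap_days = 5, responder_threshold = 10,
                       well_series_csv = NULL, image_dir = NULL,
                       traces_csv = NULL) {
  screen_mode <- match.arg(screen_mode)
  structure(list(out_dir = out_dir, seed = as.integer(seed), plate = plate,
                 qc = qc, quant = quant, detect = detect,
                 screen_mode = screen_mode, cap_days = cap_days,
                 responder_threshold = responder_threshold,
                 well_series_csv = well_series_csv, image_dir = image_dir,
                 traces_csv = traces_csv),
            class = "run_config")
}

#' Run the phenotyping / screening pipeline
#'
#' Executes the requested stages in order, each writing its outputs under
#' `config$out_dir` and recording them in a machine-readable manifest
#' (`manifest.json`: stages run, seed, configuration, files written,
#' package and R versions). A stage failure aborts with an error naming
#' the stage.
#'
#' Stages: `simulate` (plate layout + well-series CSV + ground-truth
#' JSON), `quantify` (directory of TIFF fields to well-series CSV),
#' `phenotype` (well-series CSV to well/donor phenotype CSVs), `screen`
#' (donor phenotypes to rescue CSV + screen summary JSON), `calcium`
#' (traces CSV to per-ROI event CSV), `report` (group statistics JSON).
#'
#' @param config A [run_config()].
#' @param stages Character vector, subset of
#'   `c("simulate", "quantify", "phenotype", "screen", "calcium",
#'   "report")`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "phenotype", "screen")) {
  known <- c("simulate", "quantify", "phenotype", "screen", "calcium",
             "report")
  bad <- setdiff(stages, known)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(f) { files <<- c(files, f); f }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  path <- function(f) file.path(config$out_dir, f)

  for (stage in intersect(known, stages)) {
    switch(stage,
      simulate = run_stage("simulate", {
        plate <- simulate_plate(config$plate)
        write.csv(plate$layout, emit(path("plate_layout.csv")),
                  row.names = FALSE)
        write_well_series(plate$wells, emit(path("well_series.csv")))
        jsonlite::write_json(plate$truth, emit(path("ground_truth.json")),
                             dataframe = "rows", digits = NA)
      }),
      quantify = run_stage("quantify", {
        dir <- config$image_dir
        if (is.null(dir) || !dir.exists(dir))
          stopf("image_dir not set or missing: %s", dir %||% "<unset>")
        tiffs <- list.files(dir, pattern = "\\.tiff?$", full.names = TRUE)
        if (length(tiffs) == 0L) stopf("no TIFF files in %s", dir)
        rows <- do.call(rbind, lapply(tiffs, function(tf) {
          f <- read_image_field(tf)
          seg <- segment_field(enhance(f, config$quant), f, config$quant)
          seg <- measure_neurite_length(seg,
                                        prune_spur_um =
                                          config$quant$prune_spur_um)
          data.frame(file = basename(tf), well = f$well_id,
                     field = f$field_index,
                     total_length_um = seg$total_length_um,
                     soma_count = count_somata(seg))
        }))
        write.csv(rows, emit(path("field_quant.csv")), row.names = FALSE)
      }),
      phenotype = run_stage("phenotype", {
        src <- config$well_series_csv %||% path("well_series.csv")
        wells <- read_well_series(src)
        ph <- phenotype_plate(wells, config$qc)
        write.csv(ph$well_table, emit(path("well_phenotypes.csv")),
                  row.names = FALSE)
        write.csv(ph$donor_table, emit(path("donor_phenotypes.csv")),
                  row.names = FALSE)
      }),
      screen = run_stage("screen", {
        dt <- read.csv(path("donor_phenotypes.csv"),
                       stringsAsFactors = FALSE)
        dt <- dt[dt$status == "ok", ]
        if (all(is.na(dt$treatment)))
          stopf("no treated wells: screen stage needs a treated plate")
        rescue <- do.call(rbind, lapply(split(dt, dt$donor), function(d) {
          if (config$screen_mode == "screen_relative") {
            ld <- setNames(d$mean_ld50, d$treatment)
            r <- screen_relative_rescue(ld)
            data.frame(donor = d$donor[1], drug = names(r),
                       days_of_rescue = unname(r))
          } else {
            dmso <- d$mean_ld50[d$treatment == "DMSO"]
            if (length(dmso) != 1L) stopf("donor %s lacks a DMSO arm",
                                          d$donor[1])
            dd <- d[d$treatment != "DMSO", ]
            data.frame(donor = dd$donor, drug = dd$treatment,
                       days_of_rescue = days_of_rescue(dd$mean_ld50, dmso))
          }
        }))
        rownames(rescue) <- NULL
        write.csv(rescue, emit(path("rescue_table.csv")), row.names = FALSE)
        summ <- summarize_screen(rescue)
        jsonlite::write_json(
          list(per_drug = summ$per_drug,
               omnibus = summ$omnibus[c("H", "df", "p")],
               n_tested = summ$n_tested, n_effective = summ$n_effective,
               percent_failed = summ$percent_failed),
          emit(path("screen_summary.json")),
          dataframe = "rows", auto_unbox = TRUE, digits = NA)
      }),
      calcium = run_stage("calcium", {
        src <- config$traces_csv
        if (is.null(src)) stopf("traces_csv not set")
        traces <- read_traces(src)
        events <- lapply(traces, detect_transients, cfg = config$detect)
        rows <- do.call(rbind, lapply(events, function(e) data.frame(
          roi = e$roi_id, n_events = e$n_events, frequency = e$frequency,
          mean_amplitude = e$mean_amplitude,
          threshold = e$threshold_used)))
        write.csv(rows, emit(path("calcium_events.csv")), row.names = FALSE)
      }),
      report = run_stage("report", {
        dt <- read.csv(path("donor_phenotypes.csv"),
                       stringsAsFactors = FALSE)
        dt <- dt[dt$status == "ok" &
                   (is.na(dt$treatment) | dt$treatment == "DMSO"), ]
        groups <- split(dt$mean_ld50, dt$group)
        rep <- list(n_donors = vapply(groups, length, integer(1)),
                    mean_ld50 = vapply(groups, mean, numeric(1)))
        if (length(groups) == 2L) {
          tt <- t.test(groups[[1]], groups[[2]])
          endpoint <- config$plate$day_range[2]
          lr <- logrank_test(groups[[1]], groups[[1]] < endpoint,
                             groups[[2]], groups[[2]] < endpoint)
          rep$welch_t_p <- tt$p.value
          rep$logrank_chi2 <- lr$chi2
          rep$logrank_p <- lr$p
        }
        jsonlite::write_json(rep, emit(path("stats_report.json")),
                             auto_unbox = TRUE, digits = NA)
      }))
  }

  manifest <- list(stages = intersect(known, stages),
                   seed = config$seed,
                   screen_mode = config$screen_mode,
                   files = basename(files),
                   package_version =
                     as.character(utils::packageVersion("neuritescreen")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
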