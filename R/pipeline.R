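#' Resolve a pipeline configuration
#'
#' Accepts a YAML or JSON config file (or an R list) and merges it over
#' the documented defaults. Unknown keys are rejected so typos fail loudly
#' rather than silently falling back to defaults.
#'
#' @param config path to a YAML/JSON file, a named list, or `NULL` for
#'   pure defaults.
#' @param ... individual overrides applied after the file (name = value).
#' @return a `pipeline_config` list: `out_dir`, `conditions` (data.frame
#'   aTc_ng_ml, k1), `variant`, `n_cells`, `t_sample`, `master_seed`,
#'   `tau1_sd`, `sd_grid`, `phi`, `imaging` (list of segmentation/spot
#'   parameters), `log_level`.
#' @export
pipeline_config <- function(config = NULL, ...) {
  defaults <- list(
    out_dir = ".",
    conditions = tet_conditions(),
    variant = 1,
    n_cells = 1000,
    t_sample = 25000,
    master_seed = 1L,
    tau1_sd = 400,
    sd_grid = c(0, 25, 50, 100, 200, 400, 800, 1600),
    phi = NULL,
    imaging = list(threshold_frac = 0.1, opening_radius = 2,
                   solidity_min = 0.9, ecc_min = 0.7, split_h_frac = 0.1,
                   area_range = c(30, 5000), spot_sigma = 1.5,
                   unit_intensity = NULL, exclude = integer(0),
                   background = NULL),
    log_level = "info")
  user <- list()
  if (is.character(config)) {
    user <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  } else if (is.list(config)) user <- config
  user <- utils::modifyList(user, list(...))
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(user$imaging)) {
    badi <- setdiff(names(user$imaging), names(defaults$imaging))
    if (length(badi))
      stop("unknown imaging config keys: ", paste(badi, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, user)
  if (is.list(cfg$conditions) && !is.data.frame(cfg$conditions))
    cfg$conditions <- as.data.frame(cfg$conditions)
  structure(cfg, class = "pipeline_config")
}

log_msg <- function(cfg, level, ...) {
  levels <- c(debug = 1, info = 2, warning = 3, error = 4)
  if (levels[[level]] >= levels[[cfg$log_level]])
    message(sprintf("[%s] %s", level, paste0(...)))
}

write_manifest <- function(cfg, out_dir, command, outputs, extra = list()) {
  man <- c(list(command = command,
                package = as.character(utils::packageVersion("tetnoise")),
                config = config_to_list(cfg),
                outputs = outputs), extra)
  path <- file.path(out_dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  path
}

config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$conditions <- as.list(cfg$conditions)
  out
}

#' Pipeline command: simulate cell populations
#'
#' Simulates every induction condition of the configured model variant,
#' writes one per-cell CSV per condition plus a summary table with the
#' measurement-report column order (condition, cell count, mean, SD,
#' relative mean, Fano factor of protein counts), and a run manifest.
#'
#' @param config a [pipeline_config()] (or anything it accepts).
#' @return invisibly, a list with the summary data.frame and file paths.
#' @export
cmd_simulate <- function(config = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg(cfg, "info", "simulating variant ", cfg$variant, ", ",
          cfg$n_cells, " cells x ", nrow(cfg$conditions), " conditions")
  pops <- simulate_conditions(cfg$conditions, variant = cfg$variant,
                              n_cells = cfg$n_cells, t_sample = cfg$t_sample,
                              master_seed = cfg$master_seed,
                              tau1_sd = cfg$tau1_sd)
  files <- character(0)
  for (nm in names(pops)) {
    f <- file.path(cfg$out_dir, sprintf("population_aTc_%s.csv", nm))
    write_population_csv(pops[[nm]], f)
    files <- c(files, f)
  }
  summary <- summarize_conditions(lapply(pops, function(p)
    summarize_population(p$protein, condition = p$condition[1])))
  summary <- summary[, c("condition", "n_cells", "mean", "sd",
                         "relative_mean", "fano")]
  sf <- file.path(cfg$out_dir, "population_summary.csv")
  utils::write.csv(summary, sf, row.names = FALSE)
  mf <- write_manifest(cfg, cfg$out_dir, "simulate",
                       c(files, sf))
  invisible(list(summary = summary, files = c(files, sf), manifest = mf))
}

#' Pipeline command: fit the open-complex delay SD
#'
#' Reads a measured per-condition summary CSV (columns `aTc_ng_ml`,
#' `mean`, `sd`), checks that every configured condition is present, runs
#' [scan_open_complex_sd()] over the configured grid and writes the scan
#' CSV, a JSON report and a manifest.
#'
#' @param config a [pipeline_config()] (or anything it accepts).
#' @param measured_csv path to the measured summary CSV; defaults to the
#'   bundled [measured_gfp_summary()].
#' @return invisibly, the `fit_scan`.
#' @export
cmd_fit <- function(config = NULL, measured_csv = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  measured <- if (is.null(measured_csv)) measured_gfp_summary()
              else utils::read.csv(measured_csv)
  need <- c("aTc_ng_ml", "mean", "sd")
  if (!all(need %in% names(measured)))
    stop("measured summary must have columns: ", paste(need, collapse = ", "))
  missing <- setdiff(cfg$conditions$aTc_ng_ml, measured$aTc_ng_ml)
  if (length(missing))
    stop("measured summary is missing conditions (aTc ng/ml): ",
         paste(missing, collapse = ", "))
  measured <- measured[match(cfg$conditions$aTc_ng_ml, measured$aTc_ng_ml), ]
  log_msg(cfg, "info", "scanning ", length(cfg$sd_grid),
          " delay SDs with n = ", cfg$n_cells)
  scan <- scan_open_complex_sd(measured, cfg$conditions,
                               sd_grid = cfg$sd_grid, n_cells = cfg$n_cells,
                               t_sample = cfg$t_sample,
                               seed = cfg$master_seed, phi = cfg$phi)
  csv <- file.path(cfg$out_dir, "fit_scan.csv")
  json <- file.path(cfg$out_dir, "fit_scan.json")
  write_fit_scan(scan, csv, json)
  write_manifest(cfg, cfg$out_dir, "fit", c(csv, json))
  invisible(scan)
}

#' Pipeline command: quantify microscopy images
#'
#' Protein mode: for each z-stack TIFF, runs preprocessing, segmentation,
#' per-cell measurement and outlier flagging; subtracts the configured (or
#' fitted) autofluorescence background and writes a per-cell CSV, a label
#' mask and a per-image population summary. RNA mode additionally counts
#' MS2-GFP spots per cell. Unreadable images are skipped with a warning;
#' if every image fails the command errors.
#'
#' @param config a [pipeline_config()] (or anything it accepts). The
#'   `imaging$background` entry may be `list(slope =, intercept =)` or a
#'   CSV path of control-cell (`area`, `autofluorescence`) pairs.
#' @param inputs character vector of TIFF paths.
#' @param mode `"protein"` or `"rna"`.
#' @return invisibly, a list with the per-cell records (one element per
#'   image) and the combined summary.
#' @export
cmd_quantify <- function(config = NULL, inputs, mode = c("protein", "rna")) {
  mode <- match.arg(mode)
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  imp <- cfg$imaging
  bg <- imp$background
  model <- if (is.null(bg)) structure(list(slope = 0, intercept = 0),
                                      class = "background_model")
           else if (is.character(bg)) fit_background(utils::read.csv(bg))
           else structure(list(slope = bg$slope, intercept = bg$intercept),
                          class = "background_model")
  all_records <- list()
  files <- character(0)
  for (path in inputs) {
    stack <- tryCatch(read_stack_tiff(path), error = function(e) e)
    if (inherits(stack, "error")) {
      warning("skipping unreadable image ", path, ": ",
              conditionMessage(stack))
      next
    }
    pre <- preprocess_stack(stack)
    rna <- NULL
    mask <- if (mode == "rna") {
      # spot images segment inside count_rna (mean-intensity threshold
      # on the despiked raw projection, opening, no cluster splitting)
      rna <- count_rna(rowSums(stack, dims = 2L) / dim(stack)[3],
                       unit_intensity = imp$unit_intensity,
                       spot_sigma = imp$spot_sigma,
                       opening_radius = imp$opening_radius,
                       area_range = imp$area_range, exclude = imp$exclude)
      structure(list(labels = rna$labels, n_cells = max(rna$labels),
                     objects = NULL), class = "cell_mask")
    } else {
      segment_cells(pre$i_sum, threshold_frac = imp$threshold_frac,
                    opening_radius = imp$opening_radius,
                    solidity_min = imp$solidity_min,
                    ecc_min = imp$ecc_min,
                    split_h_frac = imp$split_h_frac,
                    area_range = imp$area_range,
                    exclude = imp$exclude)
    }
    base <- tools::file_path_sans_ext(basename(path))
    if (mask$n_cells == 0L) {
      log_msg(cfg, "warning", "no cells found in ", path)
      records <- measure_cells(pre$filtered, mask)
    } else {
      records <- measure_cells(pre$filtered, mask)
      records <- remove_outliers(records)
      records <- subtract_background(records, model)
    }
    if (mode == "rna" && mask$n_cells > 0L) {
      records$rna_count <- rna$per_cell$rna_count[match(
        records$label, rna$per_cell$label)]
    }
    f <- file.path(cfg$out_dir, paste0(base, "_cells.csv"))
    utils::write.csv(records, f, row.names = FALSE)
    write_mask_image(mask, file.path(cfg$out_dir, paste0(base, "_mask.png")))
    files <- c(files, f)
    all_records[[base]] <- records
  }
  if (!length(all_records)) stop("no readable input images")
  combined <- do.call(rbind, all_records)
  kept <- combined[!combined$flag_discarded_slice &
                     !combined$flag_outlier_intensity &
                     !combined$flag_outlier_area, ]
  summary <- if (nrow(kept) >= 2)
    summarize_conditions(list(summarize_population(kept$corrected_intensity,
                                                   condition = mode)))
  else NULL
  if (!is.null(summary)) {
    sf <- file.path(cfg$out_dir, "quantify_summary.csv")
    utils::write.csv(summary[, c("condition", "n_cells", "mean", "sd",
                                 "relative_mean", "fano")],
                     sf, row.names = FALSE)
    files <- c(files, sf)
  }
  write_manifest(cfg, cfg$out_dir, "quantify", files,
                 extra = list(mode = mode, inputs = inputs))
  invisible(list(records = all_records, summary = summary))
}

#' Pipeline command: emit a deterministic synthetic fixture set
#'
#' Generates a seeded synthetic scene, renders the protein z-stack and
#' the RNA spot image, and writes them as TIFFs alongside ground-truth
#' CSVs — a self-contained test set for the quantification pipeline.
#'
#' @param config a [pipeline_config()] (or anything it accepts);
#'   `master_seed` seeds the scene.
#' @param n_cells cells in the fixture scene.
#' @param cluster_fraction fraction of cells placed in clusters.
#' @return invisibly, the rendered `synthetic_scene`.
#' @export
cmd_synth <- function(config = NULL, n_cells = 30, cluster_fraction = 0.1) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  gcfg <- generator_config(n_cells = n_cells,
                           cluster_fraction = cluster_fraction,
                           seed = cfg$master_seed)
  scene <- synthetic_scene(gcfg)
  scene <- render_stack(scene)
  scene <- render_spot_image(scene)
  paths <- c(stack = file.path(cfg$out_dir, "synthetic_stack.tif"),
             spots = file.path(cfg$out_dir, "synthetic_spots.tif"),
             truth = file.path(cfg$out_dir, "synthetic_truth.csv"),
             spot_truth = file.path(cfg$out_dir, "synthetic_spot_truth.csv"))
  write_stack_tiff(scene$stack, paths[["stack"]])
  write_stack_tiff(scene$spot_image, paths[["spots"]])
  utils::write.csv(scene$truth, paths[["truth"]], row.names = FALSE)
  utils::write.csv(scene$spot_truth, paths[["spot_truth"]], row.names = FALSE)
  write_manifest(cfg, cfg$out_dir, "synth", unname(paths))
  invisible(scene)
}
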