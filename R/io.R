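#' Write / read a template set as CSV + JSON provenance header
#'
#' One CSV row per template: `position_index`, `direction_index`, `az`, `el`,
#' then `v0..v{L-1}` (template values, model units). A JSON sidecar
#' (`<path>.json`) records the grid, sample interval and design so the set
#' round-trips exactly.
#'
#' @param set a `template_set`.
#' @param path CSV path; the sidecar is written next to it.
#' @return `path`, invisibly (writer); a `template_set` (reader).
#' @export
write_template_set <- function(set, path) {
  L <- ncol(set$values)
  df <- cbind(set$meta, as.data.frame(set$values))
  names(df)[seq_len(L) + ncol(set$meta)] <- paste0("v", seq_len(L) - 1)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  side <- list(format = "echoplace-template-set", version = 1L,
               n_templates = nrow(set$values), template_length = L,
               sample_interval = set$sample_interval,
               design_name = set$design_name, spacing = set$spacing,
               grid = list(azimuths = set$grid$azimuths,
                           elevations = set$grid$elevations))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_template_set
#' @export
read_template_set <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(side$format, "echoplace-template-set"))
    stop("not a template-set sidecar: ", paste0(path, ".json"))
  df <- read.table(path, sep = ",", header = TRUE)
  meta_cols <- c("position_index", "direction_index", "az", "el")
  if (!all(meta_cols %in% names(df)))
    stop("template CSV is missing metadata columns")
  values <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  dimnames(values) <- NULL
  if (ncol(values) != side$template_length)
    stop("template length mismatch between CSV and sidecar")
  new_template_set(values, df[, meta_cols],
                   direction_grid(side$grid$azimuths, side$grid$elevations),
                   sample_interval = side$sample_interval,
                   design_name = side$design_name,
                   spacing = if (is.null(side$spacing)) NA_real_
                             else side$spacing)
}

#' Write / read an echo dataset (array container + JSON sidecar)
#'
#' Waveforms are stored as little-endian float64 in `<path>/waves.bin`
#' (column = echo train), the index table as `<path>/meta.csv`, and the
#' device/axis description in `<path>/sidecar.json`. The reader validates
#' the axis lengths against the sidecar and fails naming the offending
#' field.
#'
#' @param dataset an [generate_dataset()] result.
#' @param path directory to create.
#' @return `path`, invisibly (writer); an `echo_dataset` (reader).
#' @export
write_echo_dataset <- function(dataset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(path, "waves.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(dataset$waves), con, size = 8, endian = "little")
  write.table(dataset$meta, file.path(path, "meta.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  spec <- dataset$spec
  side <- list(format = "echoplace-echo-dataset", version = 1L,
               n_samples = nrow(dataset$waves),
               n_trains = ncol(dataset$waves),
               sample_rate = spec$sample_rate,
               record_duration = spec$record_duration,
               call_f0 = spec$call_f0, call_f1 = spec$call_f1,
               call_duration = spec$call_duration,
               n_mics = spec$n_mics, n_repeats = spec$n_repeats,
               n_directions = n_directions(spec$grid),
               grid = list(azimuths = spec$grid$azimuths,
                           elevations = spec$grid$elevations),
               mic_offsets = spec$mic_offsets,
               beam_width_3db = spec$beam_width_3db,
               beam_ref_khz = spec$beam_ref_khz,
               self_noise_level = spec$self_noise_level,
               saturation_gain = spec$saturation_gain,
               c = spec$c)
  jsonlite::write_json(side, file.path(path, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "columnmajor")
  invisible(path)
}

#' @rdname write_echo_dataset
#' @export
read_echo_dataset <- function(path) {
  sfile <- file.path(path, "sidecar.json")
  if (!file.exists(sfile)) stop("missing sidecar: ", sfile)
  side <- jsonlite::read_json(sfile, simplifyVector = TRUE)
  if (!identical(side$format, "echoplace-echo-dataset"))
    stop("not an echo-dataset sidecar: ", sfile)
  meta <- read.table(file.path(path, "meta.csv"), sep = ",", header = TRUE)
  n <- side$n_samples * side$n_trains
  con <- file(file.path(path, "waves.bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "double", n = n + 1, size = 8, endian = "little")
  if (length(raw) != n)
    stop("field n_trains/n_samples: container holds ", length(raw),
         " values, sidecar promises ", n)
  if (nrow(meta) != side$n_trains)
    stop("field n_trains: meta.csv has ", nrow(meta), " rows, sidecar ",
         side$n_trains)
  if (max(meta$direction_index) > side$n_directions)
    stop("field n_directions: meta references direction ",
         max(meta$direction_index), " > ", side$n_directions)
  grid <- direction_grid(side$grid$azimuths, side$grid$elevations)
  if (n_directions(grid) != side$n_directions)
    stop("field n_directions: sidecar grid has ", n_directions(grid),
         " directions, sidecar promises ", side$n_directions)
  spec <- device_spec(sample_rate = side$sample_rate,
                      record_duration = side$record_duration,
                      call_f0 = side$call_f0, call_f1 = side$call_f1,
                      call_duration = side$call_duration,
                      n_mics = side$n_mics,
                      mic_offsets = matrix(side$mic_offsets, nrow = 3),
                      grid = grid, n_repeats = side$n_repeats,
                      beam_width_3db = side$beam_width_3db,
                      beam_ref_khz = side$beam_ref_khz,
                      self_noise_level = side$self_noise_level,
                      saturation_gain = side$saturation_gain, c = side$c)
  structure(list(waves = matrix(raw, nrow = side$n_samples), meta = meta,
                 spec = spec),
            class = "echo_dataset")
}

#' Write an experiment report bundle
#'
#' Emits TSV tables (classification per template, angular/linear catchment
#' where present, trade-off statistics) plus a JSON run manifest with the
#' noise model, counts and seeds, into `dir`.
#'
#' @param results a [run_spots_experiment()] / [run_transect_experiment()] /
#'   [corridor_contrast()] result (lists are inspected for known fields).
#' @param dir output directory.
#' @param rng_seed seed recorded in the manifest.
#' @return invisible character vector of files written.
#' @export
write_report <- function(results, dir, rng_seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    files <<- c(files, p)
  }
  manifest <- list(package = "echoplace",
                   version = as.character(utils::packageVersion("echoplace")),
                   rng_seed = rng_seed, created = format(Sys.time()))
  if (!is.null(results$classification)) {
    wr(results$classification, "classification.tsv")
  } else {
    wr(data.frame(), "classification.tsv")
    manifest$note <- "no classification results"
  }
  if (!is.null(results$angular))
    wr(results$angular$catchment, "angular_catchment.tsv")
  if (!is.null(results$linear)) {
    wr(results$linear$per_direction, "linear_catchment_by_direction.tsv")
    wr(results$linear$per_template, "linear_catchment.tsv")
  } else if (is.null(results$angular)) {
    manifest$no_transect_data <- TRUE
  }
  if (!is.null(results$tradeoff)) {
    tr <- results$tradeoff
    wr(data.frame(rho = tr$correlation$rho, p = tr$correlation$p,
                  note = if (is.null(tr$correlation$note)) ""
                         else tr$correlation$note),
       "tradeoff.tsv")
  }
  if (!is.null(results$noise))
    manifest$noise <- list(n_f = results$noise$n_f,
                           sigma_n2 = results$noise$sigma_n2,
                           jnd_db = results$noise$jnd_db,
                           criterion = results$noise$criterion)
  if (!is.null(results$counts)) manifest$counts <- results$counts
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(files, mp))
}
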