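#' Read a long-format plate table
#'
#' Kinetic plate exports are long CSVs with header `time_min, well, channel,
#' signal` (additional annotation columns such as `receptor`, `ligand`,
#' `conc_M`, `is_vehicle`, `block` are preserved); endpoint tables need only
#' `well, signal`, and concentration-response tables `ligand, conc_M,
#' response`. Lines starting with `#` (provenance headers written by
#' [run_pipeline()]) are ignored. Duplicate (well, time, channel) rows and
#' non-numeric signals are rejected with the offending row number.
#'
#' @param path CSV file path.
#' @return Validated tibble, per-well times strictly increasing.
#' @export
read_plate_table <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  kinetic <- "time_min" %in% names(df)
  req <- if (kinetic) {
    c("time_min", "well", "channel", "signal")
  } else if ("response" %in% names(df)) {
    c("ligand", "conc_M", "response")  # endpoint concentration-response table
  } else {
    c("well", "signal")
  }
  if (!all(req %in% names(df))) {
    abort(paste0("Plate table must have columns: ",
                 paste(req, collapse = ", "), " (", path, ")"))
  }
  value_col <- if ("signal" %in% req) "signal" else "response"
  if (!is.numeric(df[[value_col]])) {
    bad <- which(is.na(suppressWarnings(as.numeric(df[[value_col]]))))
    abort(paste0("Non-numeric ", value_col, " at data row(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  if (kinetic) {
    if (!is.numeric(df$time_min)) abort("`time_min` must be numeric.")
    key <- paste(df$well, df$time_min, df$channel)
    if (anyDuplicated(key)) {
      abort(paste0("Duplicate (well, time, channel) at data row(s): ",
                   paste(head(which(duplicated(key)), 5), collapse = ", ")))
    }
    ord <- df |>
      dplyr::group_by(.data$well, .data$channel) |>
      dplyr::summarise(ok = !is.unsorted(.data$time_min, strictly = TRUE),
                       .groups = "drop")
    if (!all(ord$ok)) {
      df <- dplyr::arrange(df, .data$well, .data$channel, .data$time_min)
    }
    nchan <- df |>
      dplyr::group_by(.data$well) |>
      dplyr::summarise(chans = paste(sort(unique(.data$channel)),
                                     collapse = ","), .groups = "drop")
    if (length(unique(nchan$chans)) > 1) {
      abort("Channel set differs between wells.")
    }
  }
  df
}

#' Read a plate map
#'
#' CSV with header `well, receptor, ligand, conc_M, condition, block`.
#' Concentrations are molar (scientific notation accepted); vehicle rows have
#' `conc_M = 0`. Negative concentrations are rejected.
#'
#' @param path CSV file path.
#' @return Tibble with an added logical `is_vehicle` column.
#' @export
read_plate_map <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  req <- c("well", "receptor", "ligand", "conc_M", "condition", "block")
  if (!all(req %in% names(df))) {
    abort(paste0("Plate map must have columns: ", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(df$well)) abort("Plate map well ids must be unique.")
  if (!is.numeric(df$conc_M)) abort("`conc_M` must be numeric (molar).")
  if (any(df$conc_M < 0)) {
    abort(paste0("Negative concentration at row(s): ",
                 paste(head(which(df$conc_M < 0), 5), collapse = ", ")))
  }
  df$is_vehicle <- df$conc_M == 0 | df$condition == "vehicle"
  df
}

#' Attach plate-map annotations to a plate table
#'
#' Wells present in the plate table but absent from the map are excluded with
#' a warning; the run continues.
#'
#' @param table Tibble from [read_plate_table()].
#' @param map Tibble from [read_plate_map()].
#' @return Annotated tibble.
#' @export
join_plate_map <- function(table, map) {
  unmapped <- setdiff(unique(table$well), map$well)
  if (length(unmapped) > 0) {
    warn(paste0("Excluding unmapped well(s): ",
                paste(unmapped, collapse = ", ")))
  }
  dplyr::inner_join(table, map, by = "well")
}

#' Write a results table with an embedded provenance header
#'
#' Prepends `#` comment lines recording the package version, the seed and
#' the configuration hash, so every emitted file is traceable to the run
#' that produced it; [read_plate_table()] and friends skip these lines.
#'
#' @param x Data frame to write.
#' @param path Output CSV path.
#' @param seed Integer seed recorded in the header.
#' @param config_hash Configuration hash string.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path, seed = NA_integer_,
                             config_hash = "unhashed") {
  header <- sprintf("# incretinbias %s seed=%s config=%s",
                    as.character(utils::packageVersion("incretinbias")),
                    seed, config_hash)
  writeLines(header, path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}
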