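# Delimited-text readers/writers for follicle tracks, hormone series and
# parameter files, plus the run manifest. Plain CSV with documented headers;
# there is no standard ultrasound-tracking exchange format.

#' Build follicle tracks from a long-format data frame
#'
#' @param df Data frame with columns `day`, `follicle_id`, `diameter_mm`.
#' @param thresholds A [class_thresholds()] for the derived annotations.
#' @return List of [follicle_track()] objects, id-sorted.
#' @export
tracks_from_df <- function(df, thresholds = class_thresholds()) {
  need <- c("day", "follicle_id", "diameter_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df[, c("day", "follicle_id")])) {
    stop("duplicate (day, follicle_id) rows", call. = FALSE)
  }
  ids <- sort(unique(as.character(df$follicle_id)))
  lapply(ids, function(id) {
    sub <- df[as.character(df$follicle_id) == id, , drop = FALSE]
    sub <- sub[order(sub$day), , drop = FALSE]
    follicle_track(id, sub$day, sub$diameter_mm, thresholds)
  })
}

#' Read follicle tracks from a CSV file
#'
#' Expects header `day,follicle_id,diameter_mm` (long format, one row per
#' follicle per scan day). Rows are grouped by follicle and day-sorted;
#' atresia onset and dominance are derived on construction.
#'
#' @param path File path.
#' @param thresholds A [class_thresholds()].
#' @return List of [follicle_track()] objects.
#' @export
read_tracks <- function(path, thresholds = class_thresholds()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("day", "follicle_id", "diameter_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("read_tracks: missing columns ", paste(miss, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  if (!is.numeric(df$diameter_mm) || anyNA(df$diameter_mm)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$diameter_mm))))[1]
    stop("read_tracks: non-numeric diameter at data line ", bad,
         call. = FALSE)
  }
  if (any(df$diameter_mm < 0)) {
    stop("read_tracks: negative diameter at data line ",
         which(df$diameter_mm < 0)[1], call. = FALSE)
  }
  tracks_from_df(df, thresholds)
}

#' Write follicle tracks to CSV with derived annotations
#'
#' Emits the long-format columns plus `class` (ReF/SeF/DmF/AtrDmF/excluded),
#' `atretic` and `delay` per row.
#'
#' @param tracks List of [follicle_track()] objects.
#' @param path Output path.
#' @param thresholds A [class_thresholds()].
#' @param t0 Start of the calculations for the delays.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path, thresholds = class_thresholds(),
                         t0 = 0) {
  rows <- lapply(tracks, function(tr) {
    atretic <- !is.na(tr$atresia_onset_day) & tr$days >= tr$atresia_onset_day
    cls <- ifelse(!atretic,
                  ifelse(tr$diameters < thresholds$ref_upper, "ReF",
                         ifelse(tr$diameters <= thresholds$dmf_lower,
                                "SeF", "DmF")),
                  ifelse(tr$ever_dominant, "AtrDmF", "excluded"))
    data.frame(day = tr$days, follicle_id = as.character(tr$follicle_id),
               diameter_mm = tr$diameters, class = cls, atretic = atretic,
               delay = ifelse(atretic, tr$atresia_onset_day - t0, NA),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a hormone time series from CSV
#'
#' Expects header `time_days,value_scaled[,source]`; a missing `source`
#' column defaults to `"measured"`. The series is time-sorted; fractional
#' day stamps (8-hour sampling) are preserved.
#'
#' @param path File path.
#' @return Data frame `time_days`, `value_scaled`, `source`.
#' @export
read_hormone <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("read_hormone: empty file ", path, call. = FALSE)
  need <- c("time_days", "value_scaled")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("read_hormone: missing columns ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$time_days)) {
    stop("read_hormone: duplicate time points", call. = FALSE)
  }
  if (is.null(df$source)) df$source <- "measured"
  df <- df[order(df$time_days), c("time_days", "value_scaled", "source")]
  rownames(df) <- NULL
  df
}

#' Write a hormone time series to CSV
#'
#' @param series Data frame `time_days`, `value_scaled` and optional
#'   `source`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hormone <- function(series, path) {
  if (is.null(series$source)) series$source <- "measured"
  utils::write.csv(series[, c("time_days", "value_scaled", "source")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read model parameters from a YAML or JSON file
#'
#' Named fields follow the model symbols (`e1`..`e4`, `a1`..`a4`, `m`, `m2`,
#' `T`, `n`, `TI`, `nI`, `alpha_E2`, `E2_0`); missing fields keep the
#' identified default values.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return An [e2_params()].
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(update_e2_params, c(list(e2_params()), vals))
}

#' Write model parameters to YAML
#'
#' @param params An [e2_params()].
#' @param path Output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "e2_params"))
  flat <- list(e1 = params$e1, e2 = params$e2, e3 = params$e3,
               e4 = params$e4, a1 = params$a1, a2 = params$a2,
               a3 = params$a3, a4 = params$a4, m = params$m, m2 = params$m2,
               T = params$hill$T, n = params$hill$n, TI = params$hill$TI,
               nI = params$hill$nI, alpha_E2 = params$alpha_E2,
               E2_0 = params$E2_0)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the command, seeds, tolerances, input/output paths, package
#' version and a timestamp as JSON, so that reruns with identical inputs
#' reproduce stochastic outputs.
#'
#' @param path Output `.json` path.
#' @param command Command or stage name.
#' @param seed Seed(s) used.
#' @param inputs,outputs Character vectors of paths.
#' @param extra Named list of additional fields (tolerances etc.).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, seed = NA, inputs = character(),
                           outputs = character(), extra = list()) {
  manifest <- c(list(command = command, seed = seed, inputs = inputs,
                     outputs = outputs,
                     package_version =
                       as.character(utils::packageVersion("follE2")),
                     timestamp = format(Sys.time(), tz = "UTC",
                                        usetz = TRUE)),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
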