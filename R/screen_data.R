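# 384-well geometry: rows A..P, columns 1..24
.WELL_ROWS <- LETTERS[1:16]
.WELL_COLS <- 1:24
.WELL_ROLES <- c("library", "vehicle", "positive_control", "empty")

#' Parse and normalize a 384-well address
#'
#' Accepts both unpadded (`A1`) and zero-padded (`A01`) forms and returns
#' the canonical unpadded form. Row letters must be A-P and columns 1-24.
#'
#' @param well character vector of well labels.
#' @return character vector of canonical labels (e.g. `"A1"`, `"P24"`).
#' @examples
#' parse_well(c("A01", "p24"))
#' @export
parse_well <- function(well) {
  well <- toupper(trimws(as.character(well)))
  m <- regmatches(well, regexec("^([A-Z])0*([0-9]{1,2})$", well))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed well address: ", paste(unique(well[bad]), collapse = ", "))
  }
  row <- vapply(m, `[[`, "", 2L)
  col <- as.integer(vapply(m, `[[`, "", 3L))
  ok <- row %in% .WELL_ROWS & col %in% .WELL_COLS
  if (!all(ok)) {
    stop("well address outside 384-well geometry (rows A-P, columns 1-24): ",
         paste(unique(well[!ok]), collapse = ", "))
  }
  paste0(row, col)
}

#' Split a canonical well address into row letter and column number
#' @param well character vector of well labels.
#' @return data.frame with columns `row` (letter) and `column` (integer).
#' @export
well_coordinates <- function(well) {
  well <- parse_well(well)
  data.frame(row = substr(well, 1L, 1L),
             column = as.integer(substring(well, 2L)),
             stringsAsFactors = FALSE)
}

#' Read a plate-map CSV into well annotations
#'
#' Expected columns: `plate_id`, `well`, `role`, `compound_id`,
#' `concentration_nM`, `cell_line`. Roles are one of `library`, `vehicle`,
#' `positive_control`, `empty`. Library wells must carry a compound id and a
#' positive concentration (nM); vehicle and empty wells must not carry a
#' compound id.
#'
#' @param path CSV file path.
#' @param strict logical; when TRUE (default) any violation is an error.
#' @return data.frame of annotations with canonical well labels.
#' @export
read_plate_map <- function(path, strict = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("plate_id", "well", "role", "compound_id",
                "concentration_nM", "cell_line")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("plate map missing required columns: ",
         paste(missing, collapse = ", "))
  }
  df$well <- parse_well(df$well)
  df$concentration_nM <- suppressWarnings(as.numeric(df$concentration_nM))
  df$compound_id[!nzchar(trimws(df$compound_id))] <- NA_character_
  as_well_annotations(df[required], strict = strict)
}

#' Validate a data.frame of well annotations
#'
#' @param df data.frame with the plate-map columns.
#' @param strict logical; violations are errors when TRUE.
#' @return the validated data.frame, class `well_annotations`.
#' @export
as_well_annotations <- function(df, strict = TRUE) {
  bad_role <- !df$role %in% .WELL_ROLES
  if (any(bad_role)) {
    stop("unknown role token(s): ",
         paste(unique(df$role[bad_role]), collapse = ", "))
  }
  key <- paste(df$plate_id, df$well)
  if (anyDuplicated(key)) {
    stop("duplicate (plate_id, well) in plate map: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  lib <- df$role == "library"
  bad_lib <- lib & (is.na(df$compound_id) | is.na(df$concentration_nM) |
                      df$concentration_nM <= 0)
  novehicle <- df$role %in% c("vehicle", "empty") & !is.na(df$compound_id)
  msgs <- character(0)
  if (any(bad_lib)) {
    msgs <- c(msgs, paste0("library wells need compound_id and positive ",
                           "concentration_nM: ",
                           paste(key[bad_lib], collapse = ", ")))
  }
  if (any(novehicle)) {
    msgs <- c(msgs, paste0("vehicle/empty wells must not carry compound_id: ",
                           paste(key[novehicle], collapse = ", ")))
  }
  if (length(msgs) > 0) {
    if (strict) stop(paste(msgs, collapse = "\n")) else warning(
      paste(msgs, collapse = "\n"))
  }
  rownames(df) <- NULL
  class(df) <- c("well_annotations", "data.frame")
  df
}

#' Read a long-format imaging measurement CSV
#'
#' Expected columns: `plate_id`, `well`, `field`, `timepoint_h`,
#' `tracker_count` (live-stain objects), `draq7_count` (dead-stain objects).
#' Counts must be non-negative integers; duplicate
#' (plate, well, field, timepoint) rows are rejected.
#'
#' @param path CSV file path.
#' @param timepoints allowed imaging schedule in hours.
#' @param strict when TRUE an off-schedule timepoint is an error, otherwise a
#'   warning.
#' @return data.frame of typed measurement records.
#' @export
read_measurements <- function(path, timepoints = c(0, 24, 48, 72),
                              strict = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("plate_id", "well", "field", "timepoint_h",
                "tracker_count", "draq7_count")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("measurement file missing required columns: ",
         paste(missing, collapse = ", "))
  }
  df <- df[required]
  df$well <- parse_well(df$well)
  for (cc in c("field", "tracker_count", "draq7_count")) {
    v <- df[[cc]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != floor(v))) {
      stop("column ", cc, " must be integer-valued")
    }
    df[[cc]] <- as.integer(v)
  }
  if (any(df$tracker_count < 0) || any(df$draq7_count < 0)) {
    stop("negative object counts are not allowed")
  }
  off <- !df$timepoint_h %in% timepoints
  if (any(off)) {
    msg <- paste0("timepoint(s) outside configured schedule: ",
                  paste(unique(df$timepoint_h[off]), collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  key <- paste(df$plate_id, df$well, df$field, df$timepoint_h)
  if (anyDuplicated(key)) {
    stop("duplicate (plate_id, well, field, timepoint) records: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  rownames(df) <- NULL
  df
}

#' Read a luminescence CSV (plate_id, well, rlu)
#' @param path CSV file path.
#' @return data.frame with non-negative `rlu` values.
#' @export
read_luminescence <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("plate_id", "well", "rlu")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("luminescence file missing required columns: ",
         paste(missing, collapse = ", "))
  }
  df <- df[required]
  df$well <- parse_well(df$well)
  if (!is.numeric(df$rlu) || any(is.na(df$rlu)) || any(df$rlu < 0)) {
    stop("rlu must be non-negative numbers")
  }
  rownames(df) <- NULL
  df
}

#' Assemble a screen dataset
#'
#' Joins plate annotations with imaging (and optionally luminescence)
#' measurements. Every measurement must reference an annotated
#' (plate_id, well) and imaging keys must be unique.
#'
#' @param annotations well annotations (see [read_plate_map()]).
#' @param imaging imaging measurements (see [read_measurements()]).
#' @param luminescence optional luminescence readings.
#' @param metadata free-form provenance list (seed, generator parameters,
#'   source files).
#' @return object of class `screen_dataset`.
#' @export
screen_dataset <- function(annotations, imaging, luminescence = NULL,
                           metadata = list()) {
  ann_key <- paste(annotations$plate_id, annotations$well)
  img_key <- paste(imaging$plate_id, imaging$well)
  orphan <- !img_key %in% ann_key
  if (any(orphan)) {
    stop("imaging measurements reference unannotated wells: ",
         paste(unique(img_key[orphan]), collapse = ", "))
  }
  full_key <- paste(img_key, imaging$field, imaging$timepoint_h)
  if (anyDuplicated(full_key)) {
    stop("duplicate imaging records for the same (well, field, timepoint)")
  }
  if (!is.null(luminescence)) {
    lum_key <- paste(luminescence$plate_id, luminescence$well)
    orphan <- !lum_key %in% ann_key
    if (any(orphan)) {
      stop("luminescence measurements reference unannotated wells: ",
           paste(unique(lum_key[orphan]), collapse = ", "))
    }
  }
  structure(list(annotations = annotations, imaging = imaging,
                 luminescence = luminescence, metadata = metadata),
            class = "screen_dataset")
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat("screen_dataset:",
      nrow(x$annotations), "annotated wells on",
      length(unique(x$annotations$plate_id)), "plate(s);",
      nrow(x$imaging), "imaging records",
      if (!is.null(x$luminescence))
        paste0("; ", nrow(x$luminescence), " luminescence records"),
      "\n")
  invisible(x)
}

#' Validate an assembled screen dataset
#'
#' Report-producing QC: never raises on syntactically valid input. Issues
#' found: orphan measurements, wells with incomplete timepoint series, and
#' well/timepoints with zero pooled tracker count (undefined death fraction).
#'
#' @param ds a `screen_dataset`.
#' @param timepoints expected imaging schedule.
#' @return data.frame with columns `issue`, `plate_id`, `well`, `detail`;
#'   zero rows when the dataset is clean.
#' @export
validate_dataset <- function(ds, timepoints = c(0, 24, 48, 72)) {
  issues <- list()
  add <- function(issue, plate_id, well, detail) {
    issues[[length(issues) + 1L]] <<- data.frame(
      issue = issue, plate_id = plate_id, well = well, detail = detail,
      stringsAsFactors = FALSE)
  }
  ann_key <- paste(ds$annotations$plate_id, ds$annotations$well)
  img <- ds$imaging
  img_key <- paste(img$plate_id, img$well)
  orphan <- !img_key %in% ann_key
  for (k in unique(img_key[orphan])) {
    i <- match(k, img_key)
    add("orphan_measurement", img$plate_id[i], img$well[i],
        "imaging record without annotation")
  }
  # pooled per-well/timepoint tracker counts and series completeness
  measured <- ds$annotations$role %in% c("library", "vehicle",
                                         "positive_control")
  mk <- unique(ann_key[measured])
  for (k in mk) {
    rows <- img[img_key == k, , drop = FALSE]
    if (nrow(rows) == 0) next
    tp_present <- sort(unique(rows$timepoint_h))
    miss <- setdiff(timepoints, tp_present)
    if (length(miss) > 0) {
      add("incomplete_series", rows$plate_id[1], rows$well[1],
          paste("missing timepoints:", paste(miss, collapse = ",")))
    }
    pooled <- tapply(rows$tracker_count, rows$timepoint_h, sum)
    zero <- names(pooled)[pooled == 0]
    for (z in zero) {
      add("zero_tracker_count", rows$plate_id[1], rows$well[1],
          paste0("pooled tracker count 0 at ", z, " h"))
    }
  }
  if (length(issues) == 0) {
    return(data.frame(issue = character(0), plate_id = character(0),
                      well = character(0), detail = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

#' Write a screen dataset to a directory of plain-text files
#'
#' Emits `plate_map.csv`, `imaging.csv`, optionally `luminescence.csv`, and
#' a `metadata.json` sidecar. [read_screen_dataset()] round-trips exactly.
#'
#' @param ds a `screen_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
write_screen_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- as.data.frame(ds$annotations)
  utils::write.csv(ann, file.path(dir, "plate_map.csv"), row.names = FALSE,
                   na = "")
  utils::write.csv(ds$imaging, file.path(dir, "imaging.csv"),
                   row.names = FALSE)
  if (!is.null(ds$luminescence)) {
    utils::write.csv(ds$luminescence, file.path(dir, "luminescence.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(ds$metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a screen dataset written by [write_screen_dataset()]
#' @param dir directory containing the dataset files.
#' @param timepoints imaging schedule for validation.
#' @return a `screen_dataset`.
#' @export
read_screen_dataset <- function(dir, timepoints = c(0, 24, 48, 72)) {
  ann <- read_plate_map(file.path(dir, "plate_map.csv"))
  img <- read_measurements(file.path(dir, "imaging.csv"),
                           timepoints = timepoints)
  lum_path <- file.path(dir, "luminescence.csv")
  lum <- if (file.exists(lum_path)) read_luminescence(lum_path) else NULL
  meta_path <- file.path(dir, "metadata.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  screen_dataset(ann, img, lum, metadata = meta)
}
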