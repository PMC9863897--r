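#' Write a cohort to a directory of delimited-text files
#'
#' Persists every trace as a two-column CSV (`time_s`, `value`), pixel
#' patches as long-format CSVs (`frame`, `row`, `col`, `temp_c`), ground
#' truth and planted-feature flags as CSVs, and a JSON manifest tying the
#' files together with their sampling rates and exercise-end markers. The
#' layout is plain text throughout so a run is inspectable with standard
#' tools; the round trip through [read_cohort()] is lossless.
#'
#' @param cohort A `tm_cohort`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "tm_cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  rec <- cohort$recordings
  series <- vector("list", nrow(rec))
  for (k in seq_len(nrow(rec))) {
    sid <- rec$subject_id[k]
    sidx <- rec$series_index[k]
    stem <- sprintf("%s_series%d", sid, sidx)
    emg_file <- paste0(stem, "_emg.csv")
    write_trace(rec$emg[[k]], rec$emg_fs[k], file.path(path, emg_file))
    rois <- rec$thermal_rois[[k]]
    roi_entries <- vector("list", nrow(rois))
    for (j in seq_len(nrow(rois))) {
      trace_file <- sprintf("%s_roi%d_thermal.csv", stem, rois$roi_id[j])
      write_trace(rois$mean_trace[[j]], rec$thermal_fs[k],
                  file.path(path, trace_file))
      patch_file <- NULL
      patches <- rois$patch_frames[[j]]
      if (!is.null(patches)) {
        patch_file <- sprintf("%s_roi%d_patches.csv", stem, rois$roi_id[j])
        write_patches(patches, file.path(path, patch_file))
      }
      roi_entries[[j]] <- list(roi_id = rois$roi_id[j],
                               trace_file = trace_file,
                               patch_file = patch_file)
    }
    series[[k]] <- list(
      subject_id = sid, series_index = sidx,
      duration_s = rec$duration_s[k], emg_file = emg_file,
      exercise_end_index = rec$exercise_end_index[k], rois = roi_entries
    )
  }
  gt <- cohort$ground_truth
  gt$true_arv <- fmt_dbl(gt$true_arv)
  gt$true_mdf <- fmt_dbl(gt$true_mdf)
  readr::write_csv(gt, file.path(path, "ground_truth.csv"), quote = "none")
  readr::write_csv(cohort$planted, file.path(path, "planted_features.csv"))
  manifest <- list(
    format = "thermomyo-cohort/1",
    spec = unclass(cohort$spec),
    emg_fs = rec$emg_fs[1], thermal_fs = rec$thermal_fs[1],
    n_subjects = cohort$spec$n_subjects, n_series = cohort$spec$n_series,
    series = series,
    ground_truth_file = "ground_truth.csv",
    planted_file = "planted_features.csv"
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

# %.17g round-trips IEEE doubles exactly through text
fmt_dbl <- function(x) sprintf("%.17g", x)

write_trace <- function(x, fs, file) {
  readr::write_csv(
    tibble::tibble(time_s = fmt_dbl((seq_along(x) - 1) / fs),
                   value = fmt_dbl(x)),
    file, quote = "none"
  )
}

write_patches <- function(arr, file) {
  dm <- dim(arr)
  grid <- expand.grid(row = seq_len(dm[1]), col = seq_len(dm[2]),
                      frame = seq_len(dm[3]))
  readr::write_csv(
    tibble::tibble(frame = grid$frame, row = grid$row, col = grid$col,
                   temp_c = fmt_dbl(as.vector(arr))),
    file, quote = "none"
  )
}

#' Read a cohort back from disk
#'
#' Inverse of [write_cohort()]. Validates that every series has its EMG file
#' and all three ROI records, failing with an error naming the offending
#' subject/series/ROI.
#'
#' @param path Directory written by [write_cohort()].
#' @return A `tm_cohort`.
#' @export
read_cohort <- function(path) {
  manifest_file <- file.path(path, "manifest.json")
  if (!file.exists(manifest_file)) {
    stop("no cohort at '", path, "': manifest.json not found (empty cohort?)",
         call. = FALSE)
  }
  man <- jsonlite::read_json(manifest_file, simplifyVector = FALSE)
  if (!identical(man$format, "thermomyo-cohort/1")) {
    stop("unrecognized cohort format in ", manifest_file, call. = FALSE)
  }
  spec <- man$spec
  spec$series_duration_s <- as.numeric(unlist(spec$series_duration_s))
  spec <- do.call(cohort_spec, spec[names(spec) %in%
                                      names(formals(cohort_spec))])
  rows <- vector("list", length(man$series))
  for (k in seq_along(man$series)) {
    s <- man$series[[k]]
    ctx <- sprintf("subject %s series %d", s$subject_id, s$series_index)
    emg <- read_trace(path, s$emg_file, ctx)
    rois_raw <- s$rois
    if (length(rois_raw) != 3) {
      stop("cohort validation: ", ctx, " has ", length(rois_raw),
           " ROI records, expected 3", call. = FALSE)
    }
    rois <- vector("list", 3)
    for (j in seq_along(rois_raw)) {
      r <- rois_raw[[j]]
      rctx <- sprintf("%s ROI %d", ctx, r$roi_id)
      trace <- read_trace(path, r$trace_file, rctx)
      patches <- NULL
      if (!is.null(r$patch_file)) {
        patches <- read_patches(path, r$patch_file, rctx)
      }
      rois[[j]] <- tibble::tibble(roi_id = as.integer(r$roi_id),
                                  mean_trace = list(trace),
                                  patch_frames = list(patches))
    }
    rows[[k]] <- tibble::tibble(
      subject_id = s$subject_id,
      series_index = as.integer(s$series_index),
      duration_s = as.numeric(s$duration_s),
      emg = list(emg),
      emg_fs = as.numeric(man$emg_fs),
      thermal_fs = as.numeric(man$thermal_fs),
      exercise_end_index = as.integer(s$exercise_end_index),
      thermal_rois = list(dplyr::bind_rows(rois))
    )
  }
  ground_truth <- readr::read_csv(
    file.path(path, man$ground_truth_file), show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  ground_truth$series_index <- as.integer(ground_truth$series_index)
  ground_truth$true_arv <- as.numeric(ground_truth$true_arv)
  ground_truth$true_mdf <- as.numeric(ground_truth$true_mdf)
  planted <- readr::read_csv(file.path(path, man$planted_file),
                             show_col_types = FALSE)
  structure(
    list(recordings = dplyr::bind_rows(rows),
         ground_truth = tibble::as_tibble(ground_truth),
         planted = tibble::as_tibble(planted), spec = spec),
    class = "tm_cohort"
  )
}

read_trace <- function(path, file, ctx) {
  full <- file.path(path, file)
  if (!file.exists(full)) {
    stop("cohort validation: missing trace file '", file, "' for ", ctx,
         call. = FALSE)
  }
  df <- readr::read_csv(full, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("time_s", "value") %in% names(df))) {
    stop("malformed trace file '", full, "': expected columns time_s,value",
         call. = FALSE)
  }
  as.numeric(df$value)  # strtod is correctly rounded; vroom's fast path is not
}

read_patches <- function(path, file, ctx) {
  full <- file.path(path, file)
  if (!file.exists(full)) {
    stop("cohort validation: missing patch file '", file, "' for ", ctx,
         call. = FALSE)
  }
  df <- readr::read_csv(full, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("frame", "row", "col", "temp_c")
  if (!all(need %in% names(df))) {
    stop("malformed patch file '", full,
         "': expected columns frame,row,col,temp_c", call. = FALSE)
  }
  idx <- cbind(as.integer(df$row), as.integer(df$col), as.integer(df$frame))
  arr <- array(NA_real_, c(max(idx[, 1]), max(idx[, 2]), max(idx[, 3])))
  arr[idx] <- as.numeric(df$temp_c)
  arr
}
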