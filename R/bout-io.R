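#' Read a bout table and its trial sidecar
#'
#' Bout tables are stored as flat CSV with fixed columns
#' `trial_id,fly_id,action,start_frame,end_frame`; trial metadata lives in a
#' JSON (or YAML) sidecar next to the CSV (same path with extension
#' `.json`/`.yaml`). All invariants are enforced on read: unknown actions,
#' `end <= start` rows and overlapping same-fly same-action bouts are
#' rejected with the offending row named; a sidecar without a frame rate is
#' rejected.
#'
#' @param path Path to the bout CSV.
#' @param catalog [action_catalog()] used to validate action labels.
#' @param sidecar Optional explicit path to the metadata sidecar; by default
#'   `<path-sans-ext>.json` then `.yaml`/`.yml` are tried.
#' @return A list with elements `trial` ([trial()] object) and `bouts`
#'   (validated tibble with columns `fly_id`, `action`, `start`, `end`).
#' @seealso [write_bout_table()]
#' @export
read_bout_table <- function(path, catalog = action_catalog(), sidecar = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sidecar)) {
    base <- sub("\\.[^.]+$", "", path)
    cands <- paste0(base, c(".json", ".yaml", ".yml"))
    sidecar <- cands[file.exists(cands)][1]
    if (is.na(sidecar)) stop("no metadata sidecar found next to ", path)
  }
  meta <- if (grepl("\\.json$", sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml package required to read YAML sidecars")
    }
    yaml::read_yaml(sidecar)
  }
  if (is.null(meta$frame_rate)) stop("sidecar missing frame_rate: ", sidecar)
  roster <- tibble::as_tibble(as.data.frame(meta$roster,
                                            stringsAsFactors = FALSE))
  tr <- trial(
    trial_id = meta$trial_id, assay = meta$assay,
    frame_rate = meta$frame_rate, duration = meta$duration,
    roster = roster,
    copulation_onset = if (is.null(meta$copulation_onset)) NA_integer_
                       else as.integer(meta$copulation_onset),
    protocol = if (is.null(meta$protocol)) NULL else
      ps_protocol_from_list(meta$protocol)
  )
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(trial_id = "character",
                                        fly_id = "character",
                                        action = "character",
                                        start_frame = "integer",
                                        end_frame = "integer"))
  need <- c("trial_id", "fly_id", "action", "start_frame", "end_frame")
  if (!all(need %in% names(raw))) {
    stop("bout CSV must have columns ", paste(need, collapse = ","))
  }
  if (nrow(raw) && any(raw$trial_id != tr$trial_id)) {
    stop("bout CSV trial_id does not match sidecar")
  }
  bouts <- tibble::tibble(fly_id = raw$fly_id, action = raw$action,
                          start = raw$start_frame, end = raw$end_frame)
  bouts <- validate_bouts(bouts, tr, catalog)
  list(trial = tr, bouts = bouts)
}

#' Write a bout table and its trial sidecar
#'
#' Serializes a trial + bout table to the flat CSV dialect read by
#' [read_bout_table()], plus a JSON sidecar. Round-trips exactly.
#'
#' @param trial A [trial()] object.
#' @param bouts Bout tibble (`fly_id`, `action`, `start`, `end`).
#' @param path Output CSV path; the sidecar is written at the same path with
#'   a `.json` extension.
#' @return Invisibly, the CSV path.
#' @export
write_bout_table <- function(trial, bouts, path) {
  bouts <- validate_bouts(bouts, trial)
  df <- data.frame(trial_id = rep(trial$trial_id, nrow(bouts)),
                   fly_id = bouts$fly_id, action = bouts$action,
                   start_frame = bouts$start, end_frame = bouts$end)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(
    trial_id = trial$trial_id, assay = trial$assay,
    frame_rate = trial$frame_rate, duration = trial$duration,
    roster = trial$roster)
  if (!is.na(trial$copulation_onset)) {
    meta$copulation_onset <- trial$copulation_onset
  }
  if (!is.null(trial$protocol)) {
    meta$protocol <- ps_protocol_to_list(trial$protocol)
  }
  sidecar <- paste0(sub("\\.[^.]+$", "", path), ".json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Drop short bouts of one action
#'
#' Classifier output for unilateral wing extension is conventionally
#' filtered to retain only bouts lasting at least 0.5 s (15 frames at
#' 30 Hz). The threshold in frames is `round(min_s * frame_rate)` and the
#' comparison is inclusive ("at least"), so a 15-frame bout survives the
#' 0.5 s filter at 30 Hz. Bouts of other actions are untouched.
#'
#' @param bouts Bout tibble.
#' @param action Action label to filter.
#' @param min_s Minimum duration in seconds (>= 0).
#' @param frame_rate Frames per second.
#' @param catalog Optional catalog; if given, `action` must be in it.
#' @return Filtered bout tibble.
#' @export
filter_min_duration <- function(bouts, action, min_s, frame_rate,
                                catalog = NULL) {
  stopifnot(min_s >= 0, frame_rate > 0)
  if (!is.null(catalog) && !action %in% catalog$action) {
    stop("unknown action: ", action)
  }
  thr <- round(min_s * frame_rate)
  keep <- bouts$action != action | (bouts$end - bouts$start) >= thr
  bouts[keep, , drop = FALSE]
}

#' Truncate analysis at copulation
#'
#' For male-female pairings, analysis ends at the point of copulation when
#' it occurred and the latency to copulation replaces the recording length
#' for normalization. Bouts straddling the onset are clipped to end at it;
#' bouts entirely after it are dropped. Without a recorded copulation the
#' input is returned unchanged with `effective_duration` equal to the trial
#' length. Idempotent.
#'
#' @param trial A [trial()] object.
#' @param bouts Bout tibble.
#' @return List with `trial`, `bouts` (clipped) and `effective_duration`
#'   (frames) to be used as the normalization denominator.
#' @export
truncate_at_copulation <- function(trial, bouts) {
  onset <- trial$copulation_onset
  if (is.na(onset)) {
    return(list(trial = trial, bouts = bouts,
                effective_duration = trial$duration))
  }
  keep <- bouts$start < onset
  out <- bouts[keep, , drop = FALSE]
  out$end <- pmin(out$end, onset)
  list(trial = trial, bouts = out, effective_duration = as.integer(onset))
}
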