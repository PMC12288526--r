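#' Write a session to a directory
#'
#' Serializes a full session (trial table, neural activity, tracking streams,
#' surrogate video components, metadata) to a directory of plain-text files:
#' `trials.csv` for the trial table (stimulus event times joined with `;`),
#' one CSV per array, and `meta.json` for scalar metadata (frame rate, seeds,
#' generator parameters, trial-start frames). Numeric arrays are written with
#' 17 significant digits so the round trip through [read_session()] is
#' bit-identical.
#'
#' @param session_data List with elements `table`, `activity`
#'   (neurons x frames), `frame_rate`, `trial_start_frames`, and optionally
#'   `chest_xy`, `head_angles`, `video_svd`, `motion_svd` (frames x k
#'   matrices) and `meta` (named list).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session_data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- session_data$table
  validate_trial_table(tab)
  out <- tab
  if (!is.null(out$stimulus_events)) {
    out$stimulus_events <- vapply(out$stimulus_events, function(ev)
      paste(sprintf("%.17g", ev), collapse = ";"), character(1))
  }
  num <- vapply(out, is.numeric, logical(1)) &
    !vapply(out, is.integer, logical(1))
  for (cn in names(out)[num]) {
    v <- out[[cn]]
    s <- sprintf("%.17g", v)
    s[is.na(v)] <- NA_character_
    out[[cn]] <- s
  }
  data.table::fwrite(out, file.path(dir, "trials.csv"), quote = FALSE, na = "NA")

  write_mat <- function(m, name) {
    if (is.null(m)) return(invisible(NULL))
    ch <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
    data.table::fwrite(data.table::as.data.table(ch),
                       file.path(dir, paste0(name, ".csv")),
                       quote = FALSE, col.names = FALSE)
  }
  write_mat(session_data$activity, "activity")
  write_mat(session_data$chest_xy, "chest_xy")
  write_mat(session_data$head_angles, "head_angles")
  write_mat(session_data$video_svd, "video_svd")
  write_mat(session_data$motion_svd, "motion_svd")

  meta <- session_data$meta
  if (is.null(meta)) meta <- list()
  meta$frame_rate <- session_data$frame_rate
  meta$trial_start_frames <- as.integer(session_data$trial_start_frames)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir Session directory.
#' @return A session list with the same structure as the input to
#'   [write_session()]. A missing `meta.json` sidecar triggers a warning and
#'   a default frame rate of 30; a trial table with missing required columns
#'   is a schema error naming the columns.
#' @export
read_session <- function(dir) {
  tf <- file.path(dir, "trials.csv")
  if (!file.exists(tf)) stop("no trials.csv in ", dir)
  tab <- as.data.frame(data.table::fread(tf, na.strings = "NA"))
  missing <- setdiff(.trial_table_required, names(tab))
  if (length(missing))
    stop("trials.csv schema mismatch, missing column(s): ",
         paste(missing, collapse = ", "))
  if (!is.null(tab$stimulus_events)) {
    tab$stimulus_events <- lapply(as.character(tab$stimulus_events), function(s) {
      if (is.na(s) || !nzchar(s)) numeric(0)
      else as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
    })
  }

  read_mat <- function(name) {
    f <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(f)) return(NULL)
    m <- as.matrix(data.table::fread(f, header = FALSE, colClasses = "numeric"))
    dimnames(m) <- NULL
    m
  }

  mf <- file.path(dir, "meta.json")
  if (file.exists(mf)) {
    meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  } else {
    warning("meta.json sidecar absent in ", dir, "; applying defaults (30 fps)")
    meta <- list(frame_rate = 30, trial_start_frames = integer(0))
  }
  list(
    table = tab,
    activity = read_mat("activity"),
    chest_xy = read_mat("chest_xy"),
    head_angles = read_mat("head_angles"),
    video_svd = read_mat("video_svd"),
    motion_svd = read_mat("motion_svd"),
    frame_rate = meta$frame_rate,
    trial_start_frames = as.integer(meta$trial_start_frames),
    meta = meta
  )
}
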