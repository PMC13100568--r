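# On-disk formats: transparent, diffable tab-separated UTF-8 tables.
#   eeg.tsv    line 1: "sample_rate_hz<TAB><rate>"; line 2: channel labels;
#              then one row per sample (channels as columns).
#   gaze.tsv   '#'-prefixed screen-geometry comment lines, one header line
#              (time_s, x_px, y_px, pupil_mm, lost); missing gaze encoded
#              as empty fields plus lost=1.
#   events.tsv one header line (onset_s, duration_s, type, condition,
#              trial_id).
# Event onsets refer to the same clock as EEG sample 0.

EVENT_TYPES <- c("stimulus_on", "stimulus_off", "saccade",
                 "fixation_control", "blink")

fmt_num <- function(x) {
  out <- formatC(x, format = "g", digits = 9)
  out[is.na(x)] <- ""
  out
}

#' Write a session to disk
#'
#' @param dir output directory (created if needed).
#' @param eeg an `oculo_eeg`.
#' @param gaze an `oculo_gaze`.
#' @param events event data.frame (onset, duration, type, condition,
#'   trial_id).
#' @return Invisibly, the three file paths.
#' @export
write_session <- function(dir, eeg, gaze, events) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_eeg <- file.path(dir, "eeg.tsv")
  p_gaze <- file.path(dir, "gaze.tsv")
  p_ev <- file.path(dir, "events.tsv")

  con <- file(p_eeg, "w", encoding = "UTF-8")
  writeLines(paste0("sample_rate_hz\t", fmt_num(eeg$sample_rate)), con)
  writeLines(paste(eeg$labels, collapse = "\t"), con)
  # apply over rows yields a samples x channels character matrix
  utils::write.table(apply(eeg$data, 1, fmt_num), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  close(con)

  scr <- gaze$screen
  con <- file(p_gaze, "w", encoding = "UTF-8")
  writeLines(sprintf("# screen\twidth_px=%g\theight_px=%g\twidth_cm=%g\tdistance_cm=%g",
                     scr$width_px, scr$height_px, scr$width_cm,
                     scr$distance_cm), con)
  writeLines("time_s\tx_px\ty_px\tpupil_mm\tlost", con)
  gt <- data.frame(fmt_num(gaze$time), fmt_num(gaze$x), fmt_num(gaze$y),
                   fmt_num(gaze$pupil), as.integer(gaze$loss_mask))
  utils::write.table(gt, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)

  bad <- setdiff(unique(events$type), EVENT_TYPES)
  if (length(bad)) stop("unknown event type(s): ", paste(bad, collapse = ", "))
  con <- file(p_ev, "w", encoding = "UTF-8")
  writeLines("onset_s\tduration_s\ttype\tcondition\ttrial_id", con)
  if (nrow(events)) {
    et <- data.frame(fmt_num(events$onset), fmt_num(events$duration),
                     events$type, events$condition,
                     ifelse(is.na(events$trial_id), "",
                            as.character(events$trial_id)))
    utils::write.table(et, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  close(con)
  invisible(c(eeg = p_eeg, gaze = p_gaze, events = p_ev))
}

format_error <- function(path, line, msg) {
  stop(sprintf("format error in %s (line %d): %s", path, line, msg),
       call. = FALSE)
}

#' Read a session from disk
#'
#' Round-trip contract: `read_session(write_session(x))` reproduces `x`
#' to 1e-6 relative tolerance on floats and exactly on labels and types.
#'
#' @param dir directory containing `eeg.tsv`, `gaze.tsv`, `events.tsv`.
#' @return list with `eeg`, `gaze`, `events` (see [generate_session()]).
#' @export
read_session <- function(dir) {
  p_eeg <- file.path(dir, "eeg.tsv")
  p_gaze <- file.path(dir, "gaze.tsv")
  p_ev <- file.path(dir, "events.tsv")

  hdr <- readLines(p_eeg, n = 2L)
  h1 <- strsplit(hdr[1], "\t", fixed = TRUE)[[1]]
  if (length(h1) != 2L || h1[1] != "sample_rate_hz" ||
      is.na(suppressWarnings(as.numeric(h1[2])))) {
    format_error(p_eeg, 1L, "expected 'sample_rate_hz<TAB><rate>'")
  }
  fs <- as.numeric(h1[2])
  labels <- strsplit(hdr[2], "\t", fixed = TRUE)[[1]]
  mat <- utils::read.table(p_eeg, sep = "\t", skip = 2L,
                           colClasses = "numeric")
  if (ncol(mat) != length(labels)) {
    format_error(p_eeg, 3L, "column count does not match channel labels")
  }
  eeg <- eeg_recording(unname(t(as.matrix(mat))), fs, labels)

  glines <- readLines(p_gaze)
  cm <- grepl("^#", glines)
  screen <- default_screen()
  if (any(cm)) {
    kv <- unlist(strsplit(sub("^#\\s*screen\\t?", "", glines[cm][1]), "\t"))
    for (pair in kv) {
      p <- strsplit(pair, "=", fixed = TRUE)[[1]]
      if (length(p) == 2L && p[1] %in% names(screen)) {
        screen[[p[1]]] <- as.numeric(p[2])
      }
    }
  }
  body_start <- which(!cm)[1]
  header <- strsplit(glines[body_start], "\t", fixed = TRUE)[[1]]
  if (!identical(header, c("time_s", "x_px", "y_px", "pupil_mm", "lost"))) {
    format_error(p_gaze, body_start, "unexpected gaze header")
  }
  gt <- utils::read.table(text = glines[-seq_len(body_start)][!cm[-seq_len(body_start)]],
                          sep = "\t", na.strings = "",
                          colClasses = c("numeric", "numeric", "numeric",
                                         "numeric", "integer"))
  dt <- diff(gt[[1]])
  if (length(dt) && any(abs(dt - dt[1]) > 1e-9)) {
    format_error(p_gaze, body_start + which(abs(dt - dt[1]) > 1e-9)[1] + 1L,
                 "non-uniform time base")
  }
  gaze <- gaze_recording(gt[[1]], gt[[2]], gt[[3]], gt[[4]],
                         as.logical(gt[[5]]), screen)

  elines <- readLines(p_ev)
  if (elines[1] != "onset_s\tduration_s\ttype\tcondition\ttrial_id") {
    format_error(p_ev, 1L, "unexpected events header")
  }
  if (length(elines) > 1L) {
    et <- utils::read.table(text = elines[-1], sep = "\t", na.strings = "",
                            colClasses = c("numeric", "numeric",
                                           "character", "character",
                                           "integer"))
    names(et) <- c("onset", "duration", "type", "condition", "trial_id")
    bad <- which(!(et$type %in% EVENT_TYPES))
    if (length(bad)) {
      format_error(p_ev, bad[1] + 1L,
                   paste0("unknown event type '", et$type[bad[1]], "'"))
    }
  } else {
    et <- data.frame(onset = numeric(0), duration = numeric(0),
                     type = character(0), condition = character(0),
                     trial_id = integer(0), stringsAsFactors = FALSE)
  }
  list(eeg = eeg, gaze = gaze, events = et)
}
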