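## Canonical on-disk format: a plain CSV with columns
## t,head_pitch,head_roll,head_yaw,torso_pitch,torso_roll,torso_yaw
## (plus pos_x,pos_y,pos_z for flight trials) and a JSON sidecar
## (same path, .json extension) carrying the trial metadata.

trial_columns <- function(with_position) {
  base <- c("t", "head_pitch", "head_roll", "head_yaw",
            "torso_pitch", "torso_roll", "torso_yaw")
  if (with_position) c(base, "pos_x", "pos_y", "pos_z") else base
}

sidecar_path <- function(path) sub("\\.[^.]*$", ".json", path)

fmt_num <- function(x) sprintf("%.12g", x)

#' Write a trial recording to the canonical CSV + JSON sidecar
#'
#' Numbers are formatted to 12 significant digits, so writing, reading
#' and re-writing a file is byte-stable and field values round-trip
#' within 1e-9.
#'
#' @param trial A [trial_recording()] with at least one sample.
#' @param path Output CSV path; the metadata sidecar is written next to
#'   it with a `.json` extension.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "trial_recording"))
  if (n_samples(trial$head) < 2L)
    stop("refusing to write a degenerate (empty) trial", call. = FALSE)
  with_pos <- !is.null(trial$position)
  cols <- cbind(trial$head$t,
                trial$head$pitch, trial$head$roll, trial$head$yaw,
                trial$torso$pitch, trial$torso$roll, trial$torso$yaw)
  if (with_pos) cols <- cbind(cols, trial$position)
  lines <- c(paste(trial_columns(with_pos), collapse = ","),
             apply(cols, 1, function(r) paste(fmt_num(r), collapse = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  meta <- trial$meta
  meta <- meta[order(names(meta))]
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a trial recording from the canonical CSV format
#'
#' Non-uniform time grids are resampled to the nominal 0.068 s step by
#' linear interpolation and flagged with `meta$resampled = TRUE`.
#'
#' @param path CSV path written by [write_trial()] (or any file with the
#'   canonical columns). Metadata are taken from the `.json` sidecar if
#'   present.
#' @param dialect Format tag; only `"canonical"` is defined.
#' @return A validated [trial_recording()].
#' @export
read_trial <- function(path, dialect = "canonical") {
  dialect <- match.arg(dialect, "canonical")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- trial_columns(FALSE)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  t <- df$t
  if (any(diff(t) <= 0))
    stop("data error: time stamps must be strictly increasing",
         call. = FALSE)
  meta <- list()
  sc <- sidecar_path(path)
  if (file.exists(sc))
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  with_pos <- all(c("pos_x", "pos_y", "pos_z") %in% names(df))
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-9) {
    grid <- seq(t[1], t[length(t)], by = SAMPLE_PERIOD)
    res <- function(y) approx(t, y, xout = grid)$y
    df2 <- data.frame(t = grid)
    for (cn in setdiff(names(df), "t")) df2[[cn]] <- res(df[[cn]])
    df <- df2
    t <- grid
    meta$resampled <- TRUE
  }
  hd <- angle_series(t, df$head_pitch, df$head_roll, df$head_yaw)
  tr <- angle_series(t, df$torso_pitch, df$torso_roll, df$torso_yaw)
  pos <- if (with_pos) cbind(df$pos_x, df$pos_y, df$pos_z) else NULL
  trial_recording(hd, tr, pos, meta)
}
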