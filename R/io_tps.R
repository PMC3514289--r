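#' Read a TPS landmark file
#'
#' Parses the TPS dialect written by landmark digitising tools: blocks
#' starting with `LM=<n>`, followed by `n` whitespace-separated x/y
#' coordinate lines and optional `IMAGE=`, `ID=` and `SCALE=` lines. The
#' scale factor converts pixel coordinates to mm; when absent it defaults
#' to 1 with a warning.
#'
#' @param path Path to a TPS file.
#' @return A list of landmark sets; each element is a list with
#'   `specimen_id` (from `ID=`, else `IMAGE=`, else the block index),
#'   `landmarks` (an n x 2 numeric matrix of x/y coordinates) and
#'   `scale` (mm per pixel).
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  out <- list()
  i <- 1L
  block <- 0L
  any_scale_missing <- FALSE
  while (i <= length(lines)) {
    if (!grepl("^LM\\s*=", lines[i], ignore.case = TRUE))
      stop("TPS parse error: expected 'LM=' at line '", lines[i], "'")
    block <- block + 1L
    n_lm <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", lines[i],
                                            ignore.case = TRUE)))
    if (is.na(n_lm) || n_lm < 1)
      stop("TPS block ", block, ": invalid landmark count")
    i <- i + 1L
    coords <- matrix(NA_real_, n_lm, 2)
    for (k in seq_len(n_lm)) {
      if (i > length(lines) || grepl("^[A-Za-z]+\\s*=", lines[i]))
        stop("TPS block ", block, ": expected ", n_lm,
             " coordinate lines, found ", k - 1L)
      xy <- suppressWarnings(as.numeric(strsplit(lines[i], "\\s+")[[1]]))
      if (length(xy) != 2 || anyNA(xy))
        stop("TPS block ", block, ": malformed coordinate line '",
             lines[i], "'")
      coords[k, ] <- xy
      i <- i + 1L
    }
    id <- NULL; image <- NULL; scale <- NA_real_
    while (i <= length(lines) && grepl("^[A-Za-z]+\\s*=", lines[i]) &&
           !grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      key <- toupper(sub("\\s*=.*$", "", lines[i]))
      val <- sub("^[A-Za-z]+\\s*=\\s*", "", lines[i])
      if (key == "ID") id <- val
      else if (key == "IMAGE") image <- val
      else if (key == "SCALE") scale <- suppressWarnings(as.numeric(val))
      i <- i + 1L
    }
    if (is.na(scale)) {
      any_scale_missing <- TRUE
      scale <- 1
    }
    if (scale <= 0) stop("TPS block ", block, ": SCALE must be > 0")
    out[[block]] <- list(
      specimen_id = if (!is.null(id)) id else if (!is.null(image)) image
                    else as.character(block),
      landmarks = coords,
      scale = scale
    )
  }
  if (any_scale_missing)
    warning("one or more TPS blocks lack a SCALE line; scale set to 1")
  out
}

#' Write landmark sets to a TPS file
#'
#' @param sets List of landmark sets as returned by [read_tps()] or
#'   [gen_landmarks()].
#' @param path Output file path.
#' @param digits Significant digits for coordinates (default keeps full
#'   double precision so read/write round-trips are lossless).
#' @return `path`, invisibly.
#' @export
write_tps <- function(sets, path, digits = 17) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in sets) {
    writeLines(sprintf("LM=%d", nrow(s$landmarks)), con)
    writeLines(paste(format(s$landmarks[, 1], digits = digits, trim = TRUE,
                            scientific = FALSE),
                     format(s$landmarks[, 2], digits = digits, trim = TRUE,
                            scientific = FALSE)), con)
    writeLines(sprintf("ID=%s", s$specimen_id), con)
    writeLines(sprintf("SCALE=%s",
                       format(s$scale, digits = digits, trim = TRUE,
                              scientific = FALSE)), con)
  }
  invisible(path)
}
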