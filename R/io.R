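#' Read an accelerometer recording from a CSV file
#'
#' Two dialects are supported. `"generic_csv"` is the package's canonical
#' format: a header `t,ax,ay,az` with session-relative timestamps in seconds
#' and acceleration in g. `"clemson"` reads the layout of the public
#' wrist-pedometer dataset (15 Hz, acceleration in g); its column mapping is
#' not hard-coded but taken from a small YAML dialect description, so minor
#' layout variants can be accommodated by editing that file.
#'
#' The sampling rate is inferred from the median timestamp spacing unless the
#' dialect fixes it. Spacing must be uniform within 1% relative tolerance.
#'
#' @param path CSV file path.
#' @param dialect `"generic_csv"` (default) or `"clemson"`.
#' @param subject_id,device_id provenance identifiers stored on the result.
#' @param dialect_file optional path to a YAML dialect description; defaults
#'   to the one shipped in `inst/extdata/dialects/<dialect>.yaml`.
#' @return An [accel_recording()].
#' @export
read_recording <- function(path, dialect = c("generic_csv", "clemson"),
                           subject_id = "unknown", device_id = "unknown",
                           dialect_file = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  spec <- read_dialect(dialect, dialect_file)
  df <- tryCatch(
    read.csv(path, header = spec$header, sep = spec$sep,
             strip.white = TRUE),
    error = function(e) stop("malformed CSV in ", path, ": ",
                             conditionMessage(e)))
  need <- max(unlist(spec$columns))
  if (ncol(df) < need)
    stop("expected at least ", need, " columns in ", path)
  cols <- lapply(spec$columns[c("t", "ax", "ay", "az")], function(i) df[[i]])
  bad <- which(!vapply(cols, is.numeric, logical(1)))
  if (length(bad)) {
    # locate the first offending row for a useful message
    col <- cols[[bad[1]]]
    line <- which(is.na(suppressWarnings(as.numeric(as.character(col)))))[1]
    stop("non-numeric value in ", path, " near data row ",
         ifelse(is.na(line), 1L, line))
  }
  t <- cols$t
  if (any(!is.finite(t)) || length(t) < 1L)
    stop("invalid timestamps in ", path)
  samples <- cbind(cols$ax, cols$ay, cols$az) / spec$scale_to_g
  if (!is.null(spec$sampling_rate)) {
    rate <- spec$sampling_rate
  } else {
    if (length(t) < 2L) stop("cannot infer sampling rate from one sample")
    dt <- diff(t)
    rate <- 1 / stats::median(dt)
  }
  if (length(t) >= 2L) {
    dt <- diff(t)
    if (any(abs(dt * rate - 1) > 0.01))
      stop("non-uniform sampling in ", path,
           ": spacing deviates more than 1% from 1/", signif(rate, 6), " s")
  }
  accel_recording(samples, rate, subject_id, device_id, t0 = t[1])
}

read_dialect <- function(dialect, dialect_file = NULL) {
  if (is.null(dialect_file))
    dialect_file <- system.file("extdata", "dialects",
                                paste0(dialect, ".yaml"), package = "steplr")
  if (!nzchar(dialect_file) || !file.exists(dialect_file))
    stop("no dialect description found for '", dialect, "'")
  spec <- yaml::read_yaml(dialect_file)
  spec$header <- isTRUE(spec$header)
  if (is.null(spec$sep)) spec$sep <- ","
  if (is.null(spec$scale_to_g)) spec$scale_to_g <- 1
  spec
}

#' Write an accelerometer recording as canonical generic CSV
#'
#' Columns `t,ax,ay,az`: seconds and g. Values are written with enough
#' digits that a read round-trip reproduces them to better than 1e-9 g.
#'
#' @param rec an [accel_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "accel_recording"))
  df <- data.frame(t = rec_times(rec), rec$samples)
  old <- options(digits = 17, scipen = 100)
  on.exit(options(old))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write step annotations (`t,label` CSV with labels `L`/`R`)
#'
#' @param path CSV file path.
#' @return `read_annotation()`: a [step_annotation()].
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, strip.white = TRUE)
  if (!all(c("t", "label") %in% names(df)))
    stop("annotation CSV must have header 't,label'")
  step_annotation(df$t, df$label)
}

#' @rdname read_annotation
#' @param ann a [step_annotation()].
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "step_annotation"))
  old <- options(digits = 17, scipen = 100)
  on.exit(options(old))
  write.csv(data.frame(t = ann$timestamps, label = ann$labels), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
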