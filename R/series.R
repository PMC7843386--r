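#' Construct a single-case experimental design (SCED) series
#'
#' A two-phase SCED series holds one subject's repeatedly measured outcome
#' together with the design change-point: the time index of the first
#' intervention-phase observation. Time indexing is 1-based, so the baseline
#' phase occupies time points `1 .. design_cp - 1` and the intervention phase
#' `design_cp .. n`. Observations must be equally spaced: the AR(1) error model
#' assumes a constant sampling interval, so gaps are rejected rather than
#' imputed.
#'
#' Both phases must contain at least three observations (`n >= 6` and
#' `4 <= design_cp <= n - 2`), the minimum needed to discern a statistical
#' pattern in either phase and the same rule that bounds the change-point
#' support in [bucp_fit()].
#'
#' @param values numeric vector of outcomes, one per time point.
#' @param design_cp integer, index of the first intervention-phase
#'   observation.
#' @param times integer time indices; defaults to `1:length(values)` and must
#'   be consecutive integers starting at 1.
#' @param label free-text identifier carried into results.
#' @return An object of class `sced_series`: a list with elements `values`,
#'   `times`, `design_cp`, `label`, and `n`.
#' @examples
#' y <- c(rnorm(5, 10), rnorm(7, 20))
#' s <- sced_series(y, design_cp = 6, label = "demo")
#' s
#' @seealso [read_sced_csv()], [simulate_sced()], [bucp_fit()], [sma_test()]
#' @export
sced_series <- function(values, design_cp, times = seq_along(values),
                        label = "series") {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 6L)
    stop("a SCED series needs at least 6 observations (3 per phase), got ",
         n, call. = FALSE)
  if (anyNA(values) || !all(is.finite(values)))
    stop("all outcome values must be finite and non-missing", call. = FALSE)
  times <- as.integer(times)
  if (length(times) != n || anyNA(times) ||
      !identical(times, seq_len(n)))
    stop("'times' must be consecutive integers 1..n with no gaps; ",
         "irregularly spaced series are not supported", call. = FALSE)
  design_cp <- as.integer(design_cp)
  if (length(design_cp) != 1L || is.na(design_cp))
    stop("'design_cp' must be a single integer", call. = FALSE)
  if (design_cp < 4L || design_cp > n - 2L)
    stop("'design_cp' must lie in [4, n-2] so both phases have >= 3 points; ",
         "got ", design_cp, " for n = ", n, call. = FALSE)
  structure(
    list(values = values, times = times, design_cp = design_cp,
         label = as.character(label)[1L], n = n),
    class = "sced_series")
}

#' @export
print.sced_series <- function(x, ...) {
  cat("SCED series '", x$label, "': ", x$n, " time points (",
      x$design_cp - 1L, " baseline + ", x$n - x$design_cp + 1L,
      " intervention)\n", sep = "")
  cat("  design change-point (first intervention index):", x$design_cp, "\n")
  cat("  phase A mean ", format(mean(baseline(x)), digits = 4),
      ", phase B mean ", format(mean(intervention(x)), digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Phase accessors
#'
#' Extract the baseline (phase A) or intervention (phase B) observations of a
#' SCED series, split at the design change-point.
#'
#' @param series an [sced_series()] object.
#' @return numeric vector of outcomes in the phase.
#' @export
baseline <- function(series) {
  stopifnot(inherits(series, "sced_series"))
  series$values[seq_len(series$design_cp - 1L)]
}

#' @rdname baseline
#' @export
intervention <- function(series) {
  stopifnot(inherits(series, "sced_series"))
  series$values[series$design_cp:series$n]
}

#' Read a SCED series from CSV
#'
#' The file must have a header with columns `time` and `value`, and optionally
#' `phase`. The design change-point is taken from the `design_cp` argument,
#' derived from the `phase` column (exactly two distinct labels in contiguous
#' blocks; the change-point is the first index of the second block), or both —
#' in which case they must agree.
#'
#' @param path path to a CSV file (comma separator, dot decimal, UTF-8).
#' @param design_cp integer index of the first intervention observation, or
#'   `NULL` to derive it from a `phase` column.
#' @param label identifier for the series; defaults to the file name.
#' @return An [sced_series()] object.
#' @export
read_sced_csv <- function(path, design_cp = NULL, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  req <- c("time", "value")
  if (!all(req %in% names(df)))
    stop("CSV must have columns 'time' and 'value'; found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  if (!is.numeric(df$value))
    stop("column 'value' contains non-numeric entries", call. = FALSE)
  ord <- order(df$time)
  df <- df[ord, , drop = FALSE]
  cp_from_phase <- NULL
  if ("phase" %in% names(df)) {
    ph <- as.character(df$phase)
    labs <- unique(ph)
    if (length(labs) != 2L)
      stop("'phase' column must contain exactly two distinct labels, found ",
           length(labs), call. = FALSE)
    blocks <- rle(ph)
    if (length(blocks$values) != 2L)
      stop("'phase' labels must form two contiguous blocks ",
           "(baseline then intervention)", call. = FALSE)
    cp_from_phase <- blocks$lengths[1L] + 1L
  }
  if (is.null(design_cp)) {
    if (is.null(cp_from_phase))
      stop("supply 'design_cp' or include a 'phase' column", call. = FALSE)
    design_cp <- cp_from_phase
  } else if (!is.null(cp_from_phase) &&
             as.integer(design_cp) != cp_from_phase) {
    stop("design_cp = ", design_cp, " disagrees with the phase column ",
         "(first intervention index ", cp_from_phase, ")", call. = FALSE)
  }
  if (is.null(label)) label <- sub("\\.[Cc][Ss][Vv]$", "", basename(path))
  sced_series(df$value, design_cp = design_cp, times = df$time, label = label)
}

#' Write a SCED series to CSV
#'
#' Writes columns `time,value,phase` (phase labels `A`/`B` split at the design
#' change-point). Values round-trip exactly through [read_sced_csv()]: they are
#' written with full double precision.
#'
#' @param series an [sced_series()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sced_csv <- function(series, path) {
  stopifnot(inherits(series, "sced_series"))
  ph <- ifelse(series$times < series$design_cp, "A", "B")
  df <- data.frame(time = series$times,
                   value = formatC(series$values, digits = 17, format = "g"),
                   phase = ph)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
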