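#' Assemble a result bundle
#'
#' A result bundle is the flat, machine-readable summary written by the
#' command-line interface and by [write_results()]: one row per reported
#' parameter with a point estimate, interval bounds where defined, and free
#' extra columns, plus provenance (seed and a hash of the settings used).
#'
#' @param series_label identifier of the analyzed series.
#' @param method `"bucp"` or `"sma"`.
#' @param rows a `data.frame` with at least columns `parameter` and
#'   `estimate`; optional `lower`, `upper` and extras.
#' @param seed the random seed used, or `NA`.
#' @param settings list of settings to hash into the provenance record.
#' @return An object of class `sced_results`.
#' @export
result_bundle <- function(series_label, method = c("bucp", "sma"), rows,
                          seed = NA_integer_, settings = list()) {
  method <- match.arg(method)
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    stop("'rows' must be a non-empty data.frame", call. = FALSE)
  if (!all(c("parameter", "estimate") %in% names(rows)))
    stop("'rows' needs columns 'parameter' and 'estimate'", call. = FALSE)
  if (all(c("lower", "upper") %in% names(rows))) {
    ok <- is.na(rows$lower) | is.na(rows$upper) |
      (rows$lower <= rows$upper + 1e-12)
    if (!all(ok))
      stop("interval lower bound exceeds upper bound in rows: ",
           paste(rows$parameter[!ok], collapse = ", "), call. = FALSE)
  }
  structure(
    list(series_label = as.character(series_label)[1L], method = method,
         rows = rows, seed = seed,
         settings_hash = settings_hash(settings)),
    class = "sced_results")
}

# order-independent digest of a settings list; stable across sessions
settings_hash <- function(settings) {
  if (length(settings) == 0L) return("0")
  settings <- settings[order(names(settings))]
  txt <- paste(names(settings),
               vapply(settings, function(v)
                 paste(format(v, digits = 15), collapse = ","),
                 character(1L)),
               sep = "=", collapse = ";")
  # FNV-1a 32-bit over the UTF-8 bytes
  h <- 2166136261
  for (b in as.integer(charToRaw(txt))) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^31 * (h %% 2^32 >= 2^31)),
                 b)
    h <- (h %% 2^32) * 16777619 %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' @export
print.sced_results <- function(x, ...) {
  cat(toupper(x$method), "results for '", x$series_label, "'\n", sep = "")
  print(x$rows, row.names = FALSE)
  cat("seed:", x$seed, " settings hash:", x$settings_hash, "\n")
  invisible(x)
}

#' Write analysis results to CSV and JSON
#'
#' Writes the bundle's summary table as a flat CSV and a JSON mirror
#' (`<path>.csv` and `<path>.json` if `path` has no extension, else the given
#' path plus a `.json` sibling). Numeric columns are formatted to 6
#' significant digits so repeated writes of the same bundle are bit-exact.
#'
#' @param bundle a [result_bundle()].
#' @param path output path; a `.csv` extension is added if absent.
#' @return the CSV path, invisibly.
#' @export
write_results <- function(bundle, path) {
  if (!inherits(bundle, "sced_results"))
    stop("'bundle' must be a result_bundle()", call. = FALSE)
  if (!grepl("\\.csv$", path)) path <- paste0(path, ".csv")
  json_path <- sub("\\.csv$", ".json", path)
  rows <- bundle$rows
  for (j in seq_along(rows))
    if (is.numeric(rows[[j]]))
      rows[[j]] <- ifelse(is.na(rows[[j]]), "",
                          formatC(rows[[j]], digits = 6, format = "g"))
  meta <- data.frame(series = bundle$series_label, method = bundle$method,
                     seed = as.character(bundle$seed),
                     settings_hash = bundle$settings_hash,
                     stringsAsFactors = FALSE)
  out <- cbind(meta[rep(1L, nrow(rows)), , drop = FALSE], rows)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("cannot write results to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  jl <- list(series = bundle$series_label, method = bundle$method,
             seed = bundle$seed, settings_hash = bundle$settings_hash,
             results = bundle$rows)
  jsonlite::write_json(jl, json_path, auto_unbox = TRUE, digits = 6,
                       na = "null", dataframe = "rows")
  invisible(path)
}
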