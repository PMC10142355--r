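#' Write current traces to CSV
#'
#' Writes one or more traces as long-format CSV with header
#' `time_s,phi_mV,current_au`, numbers serialized to 9 significant
#' digits so that write/read round-trips stay within test tolerance.
#'
#' @param traces a `"current_trace"`, a list of them, or a
#'   [current_family()] / [generate_synthetic()] object.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_trace_csv <- function(traces, path) {
  traces <- as_trace_list(traces)
  rows <- do.call(rbind, lapply(traces, function(tr)
    data.frame(time_s = tr$times, phi_mV = tr$phi, current_au = tr$current)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_s,phi_mV,current_au", con)
  if (!is.null(rows) && nrow(rows) > 0L)
    writeLines(sprintf("%.9g,%.9g,%.9g",
                       rows$time_s, rows$phi_mV, rows$current_au), con)
  invisible(path)
}

as_trace_list <- function(traces) {
  if (inherits(traces, "current_trace")) return(list(traces))
  if (inherits(traces, c("current_family", "synthetic_traces")))
    return(traces$traces)
  stopifnot(is.list(traces),
            all(vapply(traces, inherits, logical(1L), "current_trace")))
  traces
}

#' Read current traces from CSV
#'
#' Parses a long-format trace CSV (header `time_s,phi_mV,current_au`),
#' grouping rows by potential in order of first appearance.  Time must
#' be strictly increasing within each group.  Malformed headers,
#' non-numeric cells and non-monotone times raise errors naming the
#' offending line; an empty data section returns an empty list with a
#' warning.  The trace direction is inferred from the sign of the most
#' extreme sample.
#'
#' @param path input file path.
#' @return List of `"current_trace"` objects.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0L || trimws(lines[1L]) != "time_s,phi_mV,current_au")
    stop("malformed header in ", path,
         ": expected 'time_s,phi_mV,current_au'", call. = FALSE)
  body <- lines[-1L]
  body_no <- which(nzchar(trimws(body))) # file line = index + 1
  if (length(body_no) == 0L) {
    warning("no data rows in ", path, call. = FALSE)
    return(list())
  }
  cells <- strsplit(trimws(body[body_no]), ",", fixed = TRUE)
  bad_len <- which(lengths(cells) != 3L)
  if (length(bad_len))
    stop(sprintf("parse error in %s at line %d: expected 3 fields",
                 path, body_no[bad_len[1L]] + 1L), call. = FALSE)
  mat <- suppressWarnings(
    matrix(as.numeric(unlist(cells)), ncol = 3L, byrow = TRUE))
  bad_num <- which(apply(!is.finite(mat), 1L, any))
  if (length(bad_num))
    stop(sprintf("parse error in %s at line %d: non-numeric value",
                 path, body_no[bad_num[1L]] + 1L), call. = FALSE)
  phis <- unique(mat[, 2L])
  lapply(phis, function(phi) {
    sel <- mat[, 2L] == phi
    tms <- mat[sel, 1L]
    if (any(diff(tms) <= 0)) {
      k <- which(diff(tms) <= 0)[1L]
      stop(sprintf(
        "parse error in %s at line %d: time not strictly increasing for phi = %g",
        path, body_no[which(sel)[k + 1L]] + 1L, phi), call. = FALSE)
    }
    cur <- mat[sel, 3L]
    dir <- if (length(cur) && min(cur) < 0 &&
               abs(min(cur)) >= max(cur)) "inward" else "outward"
    new_current_trace(tms, cur, phi, dir, scale = NA_real_, rates = NULL)
  })
}

write_trace_metadata <- function(path, meta) {
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
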