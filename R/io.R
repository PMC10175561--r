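#' @name io
#' @title Tidy-table readers and writers
#' @description All file I/O is concentrated here; analysis functions never
#'   touch the filesystem. Traces travel as tidy CSV
#'   (`trace_id, time_s, temp_C, current_nA`) with capsaicin reference
#'   currents in a sidecar JSON (`{"trace_id": reference_nA, ...}`);
#'   dose-response tables and melt plates as tidy CSV; mutant panels as TSV.
#'   Malformed headers and rows raise errors naming the offending column or
#'   line.
NULL

.check_header <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    .stopf("%s: header is missing column(s): %s", path,
           paste(missing, collapse = ", "))
}

.check_numeric <- function(df, cols, path) {
  for (cc in cols) {
    v <- df[[cc]]
    suppress <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(suppress))
    if (length(bad))
      .stopf("%s: column '%s' has a non-numeric value at data row %d",
             path, cc, bad[1])
    df[[cc]] <- suppress
  }
  df
}

#' Read heat-ramp traces from CSV (+ optional capsaicin sidecar JSON)
#'
#' @param path CSV with columns `trace_id, time_s, temp_C, current_nA`.
#' @param sidecar Path to a JSON object mapping trace_id to capsaicin
#'   reference current (nA). Defaults to `<path>.json` when that file exists.
#' @return A named list of [temperature_trace()] objects.
#' @rdname io
#' @export
read_traces <- function(path, sidecar = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_header(df, c("trace_id", "time_s", "temp_C", "current_nA"), path)
  df <- .check_numeric(df, c("time_s", "temp_C", "current_nA"), path)
  if (is.null(sidecar) && file.exists(paste0(path, ".json")))
    sidecar <- paste0(path, ".json")
  refs <- if (!is.null(sidecar)) {
    if (!file.exists(sidecar)) .stopf("sidecar not found: %s", sidecar)
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else list()
  ids <- unique(df$trace_id)
  traces <- lapply(ids, function(id) {
    d <- df[df$trace_id == id, , drop = FALSE]
    d <- d[order(d$time_s), , drop = FALSE]
    ref <- refs[[id]]
    temperature_trace(id, d$time_s, d$temp_C, d$current_nA,
                      i_capsaicin_nA = if (is.null(ref)) NULL else as.numeric(ref))
  })
  setNames(traces, ids)
}

#' Write traces to CSV (+ sidecar JSON of capsaicin references)
#'
#' @param traces A list of [temperature_trace()] objects.
#' @param path Output CSV path; references go to `<path>.json` when any
#'   trace carries one.
#' @rdname io
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "temperature_trace")) traces <- list(traces)
  tab <- do.call(rbind, lapply(traces, function(tr)
    data.frame(trace_id = tr$trace_id, time_s = tr$time_s,
               temp_C = tr$temp_C, current_nA = tr$current_nA,
               stringsAsFactors = FALSE)))
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  refs <- Filter(Negate(is.null),
                 setNames(lapply(traces, `[[`, "i_capsaicin_nA"),
                          vapply(traces, `[[`, "", "trace_id")))
  if (length(refs))
    jsonlite::write_json(refs, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' Read a dose-response table from CSV
#'
#' @rdname io
#' @export
read_dose <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_header(df, c("construct", "stimulus_kind", "dose", "replicate",
                      "response"), path)
  df <- .check_numeric(df, c("dose", "response"), path)
  bad <- which(!df$stimulus_kind %in% c("capsaicin", "acid"))
  if (length(bad))
    .stopf("%s: column 'stimulus_kind' has invalid value '%s' at data row %d",
           path, df$stimulus_kind[bad[1]], bad[1])
  caps <- df$stimulus_kind == "capsaicin"
  if (any(df$dose[caps] <= 0))
    .stopf("%s: capsaicin doses must be > 0 (data row %d)", path,
           which(caps & df$dose <= 0)[1])
  if (any(df$dose[!caps] <= 0 | df$dose[!caps] >= 14))
    .stopf("%s: pH doses must lie in (0, 14)", path)
  df
}

#' Read a melt-curve plate from CSV
#'
#' @rdname io
#' @export
read_melt <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_header(df, c("sample_id", "temp_C", "fluorescence"), path)
  .check_numeric(df, c("temp_C", "fluorescence"), path)
}

#' Read a mutant stability/threshold panel from TSV
#'
#' @rdname io
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  .check_header(df, c("mutant_id", "position", "ddG_kcal_mol", "threshold_C"),
                path)
  df <- .check_numeric(df, c("ddG_kcal_mol", "threshold_C"), path)
  dup <- duplicated(df$mutant_id)
  if (any(dup))
    .stopf("%s: duplicate mutant_id '%s'", path, df$mutant_id[which(dup)[1]])
  df
}

#' Write a mutant panel to TSV
#'
#' @rdname io
#' @export
write_panel <- function(panel, path) {
  write.table(panel, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a generic tidy table to CSV
#'
#' @rdname io
#' @export
write_tidy_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
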