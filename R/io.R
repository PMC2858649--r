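#' Write an epoched session to a self-describing single-file container
#'
#' Layout: line 1 is a UTF-8 JSON header carrying the array shape
#' (trials, channels, samples), dtype (`float32`, little-endian), `units`
#' (`"V"`), `sfreq_hz`, `onset_sample` (0-based), `channel_names`,
#' `eog_index` (0-based or null) and the `meta` group; the header line is
#' followed by the raw float32 payload in trial-major order (sample index
#' fastest). Round-trips are lossless within float32 precision.
#'
#' @param session an [eeg_session()].
#' @param path output file path (conventional extension `.teps`).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "eeg_session"))
  d <- dim(session$data)
  header <- list(
    format = "tepdi-session", version = 1L,
    shape = list(trials = d[1], channels = d[2], samples = d[3]),
    dtype = "float32", byte_order = "little", units = "V",
    sfreq_hz = session$sfreq_hz,
    onset_sample = session$onset_sample,
    channel_names = session$channel_names,
    eog_index = if (is.na(session$eog_index)) NULL else session$eog_index,
    meta = session$meta)
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  hjson <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA, null = "null")
  writeBin(c(charToRaw(as.character(hjson)), charToRaw("\n")), con)
  # sample-fastest within each (trial, channel) row
  payload <- as.numeric(aperm(session$data, c(3, 2, 1)))
  writeBin(payload, con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an epoched session written by [write_session()]
#'
#' Validates the header strictly: every missing required field and any
#' shape/payload mismatch raises an error naming the offending field.
#'
#' @param path file path.
#' @return an [eeg_session()].
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, open = "rb")
  on.exit(close(con), add = TRUE)
  hline <- raw()
  repeat {
    b <- readBin(con, "raw", 1L)
    if (length(b) == 0L) stop("malformed file: no header line")
    if (b == charToRaw("\n")) break
    hline <- c(hline, b)
    if (length(hline) > 1e6) stop("malformed file: header too long")
  }
  header <- tryCatch(jsonlite::fromJSON(rawToChar(hline), simplifyVector = TRUE),
                     error = function(e) stop("malformed JSON header: ",
                                              conditionMessage(e)))
  if (!identical(header$format, "tepdi-session"))
    stop("not a tepdi session file (missing/ wrong 'format')")
  for (fld in c("shape", "dtype", "sfreq_hz", "onset_sample", "channel_names"))
    if (is.null(header[[fld]])) stop("header missing required field '", fld, "'")
  for (fld in c("trials", "channels", "samples"))
    if (is.null(header$shape[[fld]])) stop("header missing required field 'shape.", fld, "'")
  if (!identical(header$dtype, "float32"))
    stop("unsupported dtype '", header$dtype, "'")
  d <- c(header$shape$trials, header$shape$channels, header$shape$samples)
  if (length(header$channel_names) != d[2])
    stop("channel_names length (", length(header$channel_names),
         ") != channels (", d[2], ")")
  n_val <- prod(d)
  payload <- readBin(con, "numeric", n = n_val + 1L, size = 4L, endian = "little")
  if (length(payload) != n_val)
    stop("payload size mismatch: expected ", n_val, " float32 values, found ",
         length(payload))
  data <- aperm(array(payload, dim = d[c(3, 2, 1)]), c(3, 2, 1))
  meta <- header$meta
  if (is.null(meta)) meta <- list()
  eeg_session(data,
              sfreq_hz = as.numeric(header$sfreq_hz),
              onset_sample = header$onset_sample,
              channel_names = header$channel_names,
              eog_index = if (is.null(header$eog_index)) NA_integer_
                          else header$eog_index,
              meta = as.list(meta),
              require_spans = FALSE)
}

report_columns <- c("comparison_id", "label", "parameter_changed",
                    "DI_total", "DI_0_60", "DI_60_120", "DI_120_250",
                    "alpha", "n_permutations", "seed")

validate_report <- function(records) {
  missing <- setdiff(report_columns, names(records))
  if (length(missing))
    stop("report missing column(s): ", paste(missing, collapse = ", "))
  records <- records[, report_columns]
  if (anyDuplicated(records$comparison_id))
    stop("duplicate comparison ids: ",
         paste(unique(records$comparison_id[duplicated(records$comparison_id)]),
               collapse = ", "))
  di <- as.matrix(records[, c("DI_total", "DI_0_60", "DI_60_120", "DI_120_250")])
  if (any(!is.finite(di)) || any(di < 0) || any(di > 100))
    stop("DI values must be within [0, 100]")
  if (!all(records$label %in% c("C", "NC"))) stop("label must be 'C' or 'NC'")
  chg <- c("site", "intensity", "angle")
  is_c <- records$parameter_changed %in% chg
  if (!all((records$label == "C") == is_c))
    stop("label must be 'C' exactly when parameter_changed is one of ",
         paste(chg, collapse = "/"))
  records
}

#' Write / read a comparison report
#'
#' UTF-8 TSV with one header row and one row per pairwise comparison:
#' comparison id, C/NC label, parameter changed (site / intensity / angle /
#' same-day / one-week), total and per-window Divergence Indices (percent),
#' and provenance (alpha, permutation count, seed).
#'
#' @param records data.frame of comparison records (see [compare_sessions()]).
#' @param path TSV file path.
#' @return `write_report()`: `path`, invisibly. `read_report()`: the
#'   validated data.frame.
#' @export
write_report <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data.frame")
  records <- validate_report(records)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_report(df)
}
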