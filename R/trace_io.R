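#' Read an instrument-exported wide trace table
#'
#' Parses the wide-format CSV produced when exporting a CGE run: the first
#' column is migration time in seconds, every further column is one lane's
#' detector signal, and the header row carries the lane ids. European
#' instrument locales exporting semicolon-separated files with comma decimals
#' are supported via `sep`/`dec`.
#'
#' @param path Path to the CSV file.
#' @param metadata Optional per-lane metadata, either a data.frame with a
#'   `lane_id` column (see [read_lane_metadata]) or a named list of lists.
#'   The `role` entry sets each lane's role (default `"sample"`); all other
#'   entries land in the trace's `meta`.
#' @param sep Field separator, `","` by default.
#' @param dec Decimal mark, `"."` by default.
#' @param run_params Named list of run parameters stored on the batch.
#' @return A [cge_batch] with one trace per signal column.
#' @details Rows containing non-numeric cells abort the read with an error
#'   naming the offending row indices; no rows are silently dropped. The time
#'   column must be strictly increasing and header names unique.
#' @export
read_trace_table <- function(path, metadata = NULL, sep = ",", dec = ".",
                             run_params = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"")
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("format error: table must have a time column, at least one signal ",
         "column and at least one data row", call. = FALSE)
  hdr <- names(raw)
  if (anyDuplicated(hdr))
    stop("validation error: duplicate header names: ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "), call. = FALSE)

  conv <- function(col) {
    col <- trimws(col)
    if (dec != ".") col <- gsub(dec, ".", col, fixed = TRUE)
    suppressWarnings(as.numeric(col))
  }
  num <- vapply(raw, conv, numeric(nrow(raw)))
  num <- matrix(num, nrow = nrow(raw), dimnames = list(NULL, hdr))
  bad_rows <- which(apply(num, 1L, anyNA))
  if (length(bad_rows))
    stop("non-numeric cells in row(s): ",
         paste(bad_rows, collapse = ", "), call. = FALSE)

  time <- num[, 1L]
  if (any(diff(time) <= 0))
    stop("validation error: time column must be strictly increasing",
         call. = FALSE)

  meta_for <- function(id) {
    if (is.null(metadata)) return(list())
    if (is.data.frame(metadata)) {
      row <- metadata[metadata$lane_id == id, , drop = FALSE]
      if (nrow(row) == 0L) return(list())
      m <- as.list(row[1L, setdiff(names(row), "lane_id"), drop = FALSE])
      return(m[!vapply(m, function(v) is.na(v) || identical(v, ""), logical(1))])
    }
    m <- metadata[[id]]
    if (is.null(m)) list() else as.list(m)
  }

  traces <- lapply(hdr[-1L], function(id) {
    m <- meta_for(id)
    role <- if (!is.null(m$role)) as.character(m$role) else "sample"
    m$role <- NULL
    cge_trace(id, time = time, signal = num[, id], role = role, meta = m)
  })
  cge_batch(traces, run_params = run_params)
}

#' Read a sidecar lane-metadata table
#'
#' Tab-separated table keyed by `lane_id` with any of the columns `role`,
#' `capillary_id`, `concentration_ng_per_uL`, `prepared_sc_fraction`,
#' `incubation_time_min`, `run_index`, `replicate_id`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame suitable for the `metadata` argument of
#'   [read_trace_table].
#' @export
read_lane_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"lane_id" %in% names(md))
    stop("metadata table must have a `lane_id` column", call. = FALSE)
  md$lane_id <- as.character(md$lane_id)
  if (anyDuplicated(md$lane_id))
    stop("duplicate lane_id in metadata", call. = FALSE)
  md
}

# Fixed column order of the quantification table on disk.
quant_columns <- function() {
  c("lane_id", "area_lin", "area_sc", "area_oc", "total_area",
    "f_lin", "f_sc", "f_oc", "clipped", "included", "qc_reasons")
}

#' Write a quantification table
#'
#' Writes per-lane quantification records as a TSV with a fixed column order
#' and C-locale numbers. Fractions and areas are printed with 12 significant
#' digits so a write/read round trip preserves them to well below 1e-9.
#'
#' @param results A data.frame of per-lane records as produced by
#'   [quantify_batch] (columns `lane_id`, areas, fractions, and optionally
#'   `clipped`, `included`, `qc_reasons`).
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_quant_table <- function(results, path) {
  stopifnot(is.data.frame(results))
  cols <- quant_columns()
  out <- data.frame(lane_id = character(0))
  if (nrow(results)) {
    miss <- setdiff(c("lane_id", "area_lin", "area_sc", "area_oc",
                      "total_area", "f_lin", "f_sc", "f_oc"), names(results))
    if (length(miss))
      stop("results are missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    out <- results
    if (is.null(out$clipped)) out$clipped <- FALSE
    if (is.null(out$included)) out$included <- TRUE
    if (is.null(out$qc_reasons)) out$qc_reasons <- ""
    out <- out[, cols]
    for (nm in c("area_lin", "area_sc", "area_oc", "total_area",
                 "f_lin", "f_sc", "f_oc"))
      out[[nm]] <- sprintf("%.12g", out[[nm]])
  }
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing", call. = FALSE))
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(out)) {
    lines <- do.call(paste, c(lapply(cols, function(nm) as.character(out[[nm]])),
                              sep = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read back a quantification table
#'
#' @param path Path to a TSV written by [write_quant_table].
#' @return Data.frame with numeric areas/fractions and logical flags.
#' @export
read_quant_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  for (nm in c("area_lin", "area_sc", "area_oc", "total_area",
               "f_lin", "f_sc", "f_oc"))
    df[[nm]] <- as.numeric(df[[nm]])
  for (nm in c("clipped", "included"))
    df[[nm]] <- as.logical(df[[nm]])
  if (is.null(df$qc_reasons)) df$qc_reasons <- character(nrow(df))
  df$qc_reasons[is.na(df$qc_reasons)] <- ""
  df
}

#' Read a ladder specification table
#'
#' @param path TSV with columns `size_bp` and optionally `label`.
#' @return A [ladder_spec].
#' @export
read_ladder_spec <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  ladder_spec(df$size_bp, df$label)
}
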