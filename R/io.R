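# On-disk formats.  Curve files are UTF-8 TSV with "# key: value" header
# lines carrying the metadata, then columns time_s, z_nm, deflection_nm,
# segment.  Event tables are plain TSV.  Numeric formatting is fixed
# (%.10g) so that writing the same object twice yields byte-identical files.

.curve_header_keys <- c(spring_constant_pN_per_nm = "spring_constant_k",
                        velocity_um_per_s         = "velocity_v",
                        max_load_pN               = "max_load",
                        dwell_s                   = "dwell_time",
                        sampling_rate_Hz          = "sampling_rate",
                        temperature_K             = "temperature",
                        condition                 = "condition_label",
                        treatment                 = "treatment_label",
                        curve_id                  = "curve_id")

.fmt_num <- function(x) sprintf("%.10g", x)

#' Write a force curve to a TSV file
#'
#' Writes metadata as `# key: value` header lines followed by the
#' tab-separated columns `time_s`, `z_nm`, `deflection_nm`, `segment`.
#' Output is deterministic: identical curves produce byte-identical files.
#'
#' @param curve a [force_curve()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  m <- curve$metadata
  head_lines <- vapply(names(.curve_header_keys), function(key) {
    val <- m[[.curve_header_keys[[key]]]]
    if (is.numeric(val)) val <- .fmt_num(val)
    sprintf("# %s: %s", key, val)
  }, character(1))
  body <- paste(.fmt_num(curve$time), .fmt_num(curve$z_position),
                .fmt_num(curve$deflection), curve$segment, sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(head_lines, "time_s\tz_nm\tdeflection_nm\tsegment", body),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a force curve from a TSV file
#'
#' Counterpart of [write_force_curve()].  Metadata keys absent from the
#' header fall back to the [curve_metadata()] defaults (60 pN/nm cantilever,
#' 3 um/s, 2 kHz, 310.15 K, ...).  A malformed header line or a non-monotone
#' time column raises an error naming the offending content.
#'
#' @param path input path
#' @return a [force_curve()]
#' @export
read_force_curve <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_head <- startsWith(lines, "#")
  meta_defaults <- curve_metadata()
  meta_vals <- list()
  for (ln in lines[is_head]) {
    mm <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_]+):\\s*(.*)$", ln))[[1]]
    if (length(mm) != 3)
      stop(sprintf("read_force_curve: malformed header line: '%s'", ln))
    key <- mm[2]
    if (!key %in% names(.curve_header_keys))
      stop(sprintf("read_force_curve: unknown header key in line: '%s'", ln))
    field <- .curve_header_keys[[key]]
    val <- mm[3]
    if (is.numeric(meta_defaults[[field]])) {
      val <- suppressWarnings(as.numeric(val))
      if (is.na(val))
        stop(sprintf("read_force_curve: non-numeric value in header line: '%s'", ln))
    }
    meta_vals[[field]] <- val
  }
  meta <- do.call(curve_metadata, meta_vals)

  body <- lines[!is_head]
  if (length(body) < 2 || body[1] != "time_s\tz_nm\tdeflection_nm\tsegment")
    stop("read_force_curve: missing or malformed column header line")
  tab <- utils::read.table(text = body[-1], sep = "\t",
                           col.names = c("time_s", "z_nm", "deflection_nm", "segment"),
                           colClasses = c("numeric", "numeric", "numeric", "character"))
  force_curve(time = tab$time_s, z_position = tab$z_nm,
              deflection = tab$deflection_nm, segment = tab$segment,
              metadata = meta)
}

.event_cols <- c("curve_id", "index", "separation_nm", "step_height_nm",
                 "force_pN", "class", "loading_rate_pN_per_s",
                 "pre_slope_pN_per_nm")

#' Write a rupture-event table to TSV
#'
#' One row per detected event, ordered by (`curve_id`, `index`); an empty
#' event set yields a header-only file.
#'
#' @param events data frame of rupture events (see [process_curve()])
#' @param path output path
#' @return invisibly, `path`
#' @export
write_event_table <- function(events, path) {
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0) {
    events <- as.data.frame(stats::setNames(
      replicate(length(.event_cols), character(0), simplify = FALSE), .event_cols))
  } else {
    stopifnot(all(.event_cols %in% names(events)))
    events <- events[order(events$curve_id, events$index), .event_cols]
  }
  # 17 significant digits: doubles (forces in particular) round-trip exactly
  num <- vapply(events, is.numeric, logical(1))
  events[num] <- lapply(events[num], function(x) sprintf("%.17g", x))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(.event_cols, collapse = "\t"),
               if (nrow(events)) do.call(paste, c(events, sep = "\t"))),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a rupture-event table written by [write_event_table()]
#'
#' @param path input path
#' @return data frame with class `rupture_events`
#' @export
read_event_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "integer", "numeric",
                                          "numeric", "numeric", "character",
                                          "numeric", "numeric"))
  names(tab) <- .event_cols
  class(tab) <- c("rupture_events", "data.frame")
  tab
}
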