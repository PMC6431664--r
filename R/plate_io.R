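# Delimited-table interface for fluorometer exports.
#
# Schema: one row per shot, columns
#   sample_id, temperature_C, channel (em440|em490|VV|VH|HV|HH),
#   intensity, is_blank (0|1), replicate
# Blank rows are matched to sample rows by (sample_id, temperature_C, channel)
# and their mean intensity is subtracted.

PLATE_CHANNELS <- c("em440", "em490", "VV", "VH", "HV", "HH")

#' Read a fluorometer plate table
#'
#' @param path CSV or TSV file (delimiter sniffed from the header line)
#' @return validated data frame in the plate schema
#' @export
read_plate <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  plate <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
  validate_plate(plate)
}

#' Write a plate table as CSV
#' @param plate plate-schema data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_plate <- function(plate, path) {
  utils::write.csv(validate_plate(plate), path, row.names = FALSE)
  invisible(path)
}

validate_plate <- function(plate) {
  need <- c("sample_id", "temperature_C", "channel", "intensity",
            "is_blank", "replicate")
  miss <- setdiff(need, names(plate))
  if (length(miss)) {
    abort_schema(paste("plate table missing columns:", paste(miss, collapse = ", ")))
  }
  bad <- setdiff(unique(plate$channel), PLATE_CHANNELS)
  if (length(bad)) {
    abort_schema(paste("unknown channel(s):", paste(bad, collapse = ", ")))
  }
  if (any(!is.finite(plate$intensity))) abort_schema("non-finite intensities in plate")
  if (!all(plate$is_blank %in% c(0, 1))) abort_schema("is_blank must be 0 or 1")
  plate
}

#' Blank-correct a plate table
#'
#' The mean blank intensity per (sample_id, temperature_C, channel) is
#' subtracted from every matching sample shot. Sample rows with no matching
#' blank are corrected by zero.
#'
#' @param plate plate-schema data frame
#' @return sample rows only, `intensity` replaced by its blank-subtracted value
#' @export
subtract_blanks <- function(plate) {
  plate <- validate_plate(plate)
  key <- interaction(plate$sample_id, plate$temperature_C, plate$channel, drop = TRUE)
  blanks <- tapply(plate$intensity[plate$is_blank == 1], key[plate$is_blank == 1], mean)
  samp <- plate[plate$is_blank == 0, , drop = FALSE]
  b <- blanks[as.character(key[plate$is_blank == 0])]
  b[is.na(b)] <- 0
  samp$intensity <- blank_subtract(samp$intensity, as.numeric(b))
  samp
}

plate_wide <- function(samp, channels) {
  # average shots are NOT taken here; one row per replicate, channels as columns
  f <- samp[samp$channel %in% channels, , drop = FALSE]
  if (nrow(f) == 0) abort_schema("no rows for requested channels")
  out <- stats::reshape(
    f[, c("sample_id", "temperature_C", "replicate", "channel", "intensity")],
    idvar = c("sample_id", "temperature_C", "replicate"),
    timevar = "channel", direction = "wide")
  names(out) <- sub("^intensity\\.", "", names(out))
  miss <- setdiff(channels, names(out))
  if (length(miss)) abort_schema(paste("plate lacks channel(s):", paste(miss, collapse = ", ")))
  if (any(!stats::complete.cases(out[channels]))) {
    abort_schema("incomplete replicate: some channels missing for a (sample, T, replicate)")
  }
  out
}

#' GP table from a raw plate
#'
#' Blank-corrects, averages replicate intensities per temperature, and
#' computes GP per sample. The averaging convention is that of
#' [build_gp_curve()].
#'
#' @inheritParams subtract_blanks
#' @param average see [build_gp_curve()]
#' @return tidy data frame `(sample_id, temperature_C, GP, sd, n)`
#' @export
gp_table <- function(plate, average = c("intensity", "per_shot")) {
  average <- match.arg(average)
  samp <- subtract_blanks(plate)
  wide <- plate_wide(samp, c("em440", "em490"))
  out <- lapply(split(wide, wide$sample_id), function(d) {
    curve <- build_gp_curve(
      data.frame(temperature_C = d$temperature_C, I440 = d$em440, I490 = d$em490),
      composition_label = d$sample_id[1], average = average)
    cbind(sample_id = d$sample_id[1], as.data.frame(curve))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Anisotropy table from a raw plate
#'
#' Blank-corrects, averages the (at least 12) replicate intensities of each
#' polarizer combination per (sample, temperature), then computes `r` and
#' `G` from the averaged quadruplet.
#'
#' @inheritParams subtract_blanks
#' @return tidy data frame `(sample_id, temperature_C, r, G, n)`
#' @export
anisotropy_table <- function(plate) {
  samp <- subtract_blanks(plate)
  wide <- plate_wide(samp, c("VV", "VH", "HV", "HH"))
  grp <- interaction(wide$sample_id, wide$temperature_C, drop = TRUE)
  out <- lapply(split(wide, grp), function(d) {
    res <- anisotropy(mean(d$VV), mean(d$VH), mean(d$HV), mean(d$HH))
    data.frame(sample_id = d$sample_id[1], temperature_C = d$temperature_C[1],
               r = res$r, G = res$G, n = nrow(d))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$sample_id, out$temperature_C), ]
  rownames(out) <- NULL
  out
}

#' Tm report for every sample in a plate
#'
#' @inheritParams gp_table
#' @param ... passed to [estimate_tm()]
#' @return named list of `tm_estimate` objects (JSON-serializable via
#'   [write_tm_report()])
#' @export
tm_report <- function(plate, ...) {
  tab <- gp_table(plate)
  lapply(split(tab, tab$sample_id), function(d) {
    unclass(estimate_tm(d, ...))
  })
}

#' Write a Tm report as JSON
#' @param report result of [tm_report()]
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_tm_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
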