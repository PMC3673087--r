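## Arrangement tables: (alpha, h, d, n) records relating camera pose to the
## pixel resolution of the ground ROI. CSV dialect:
## header `alpha_deg,height_cm,distance_m,n_pixels`.

arrangementCols <- c("alpha_deg", "height_cm", "distance_m", "n_pixels")

validateArrangementTable <- function(table) {
  if (!is.data.frame(table) || !all(arrangementCols %in% names(table)))
    stop("arrangement table must be a data.frame with columns ",
         paste(arrangementCols, collapse = ", "), call. = FALSE)
  if (!nrow(table)) stop("arrangement table is empty", call. = FALSE)
  invisible(table)
}

#' Read / write arrangement tables
#'
#' Arrangement tables are exchanged as CSV with the fixed header
#' `alpha_deg,height_cm,distance_m,n_pixels`, or as an array of JSON records
#' with the same field names.
#'
#' @param path file path; format chosen by extension (`.csv` or `.json`)
#'   unless `format` is given.
#' @param format `"csv"` or `"json"`.
#' @return `readArrangementTable`: a data.frame.
#' @export
readArrangementTable <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  table <- if (format == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path)
  }
  validateArrangementTable(table)
  table
}

#' @param table arrangement data.frame.
#' @rdname readArrangementTable
#' @export
writeArrangementTable <- function(table, path,
                                  format = c("auto", "csv", "json")) {
  validateArrangementTable(table)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    jsonlite::write_json(table[arrangementCols], path, digits = NA)
  } else {
    utils::write.csv(table[c(arrangementCols,
                             intersect(names(table), c("clipped", "projectable")))],
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' The packaged field-measured arrangement table
#'
#' Loads the bundled table of 125 field measurements of ROI pixel counts
#' `n`, one per combination of pitch angle (10..50 deg), camera height
#' (210..230 cm) and ROI distance (3..5 m), obtained by photographing a
#' 1 x 1 m orange cardboard and counting its segmented pixels. Five entries
#' of the d = 4.0 m / h = 225 cm row are printed with decimal points in the
#' source material; they are stored here with those points read as thousands
#' separators.
#'
#' @return data.frame with 125 rows and columns `alpha_deg`, `height_cm`,
#'   `distance_m`, `n_pixels`.
#' @examples
#' t1 <- table1Arrangements()
#' max(t1$n_pixels)  # 129423 at (alpha = 50, h = 230, d = 3)
#' @export
table1Arrangements <- function() {
  path <- system.file("extdata", "table1_arrangements.csv",
                      package = "agrocam", mustWork = TRUE)
  readArrangementTable(path)
}
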