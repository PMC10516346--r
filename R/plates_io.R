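#' Write a plate table to CSV
#'
#' Serializes the long plate table in the dialect [read_plates()] expects.
#'
#' @param plates long plate data.frame as returned by
#'   [simulate_experiment()]`$plates`.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_plates <- function(plates, path) {
  utils::write.csv(plates[plate_columns()], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

plate_columns <- function() {
  c("plate_id", "treatment", "focal", "opponent", "ph", "replicate",
    "plug_index", "day", "area_mm2", "excluded", "exclusion_reason")
}

#' Read a plate table from CSV
#'
#' Validates structure and content: all required columns must be present
#' (format error otherwise); rows with non-positive or missing area, or
#' missing day, are rejected individually and reported with their line
#' numbers, the remaining rows are loaded. Days must be strictly increasing
#' within each plug series; duplicated days are rejected as data errors.
#'
#' @param path CSV file in the dialect written by [write_plates()].
#' @return long plate data.frame; rejected rows (if any) are attached as
#'   attribute `rejected` (data.frame with `line` and `reason`) and reported
#'   via warning.
#' @export
read_plates <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- plate_columns()
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("format error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw$opponent <- as.character(raw$opponent)
  raw$exclusion_reason <- as.character(raw$exclusion_reason)
  raw$opponent[!is.na(raw$opponent) & raw$opponent == ""] <- NA_character_
  raw$exclusion_reason[is.na(raw$exclusion_reason)] <- ""
  # header is line 1, so data row i sits on file line i + 1
  line <- seq_len(nrow(raw)) + 1L
  bad_area <- is.na(raw$area_mm2) | raw$area_mm2 <= 0
  bad_day <- is.na(raw$day) | raw$day < 0
  bad <- bad_area | bad_day
  rejected <- data.frame(
    line = line[bad],
    reason = ifelse(bad_area[bad], "non-positive or missing area",
                    "missing or negative day"),
    stringsAsFactors = FALSE
  )
  plates <- raw[!bad, , drop = FALSE]
  rownames(plates) <- NULL
  # duplicated days within a plug series surface data errors
  key <- paste(plates$plate_id, plates$plug_index)
  dup <- stats::ave(plates$day, key, FUN = function(d) duplicated(d)) > 0
  if (any(dup)) {
    stop("validation error: duplicated day within plug series on plate(s) ",
         paste(unique(plates$plate_id[dup]), collapse = ", "), call. = FALSE)
  }
  if (nrow(rejected)) {
    warning(sprintf("rejected %d malformed row(s) at line(s): %s",
                    nrow(rejected),
                    paste(utils::head(rejected$line, 10), collapse = ", ")),
            call. = FALSE)
  }
  attr(plates, "rejected") <- rejected
  plates
}
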