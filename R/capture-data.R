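# CSV header names (external) -> internal column names
.capture_col_map <- c(
  shark_id           = "shark_id",
  date               = "date",
  wound_area_cm2     = "wound_area",
  wound_perimeter_cm = "wound_perimeter",
  pcl_cm             = "pcl",
  mass_kg            = "mass",
  site               = "site",
  sex                = "sex",
  cord_remnants      = "cord_remnants"
)
.required_cols <- c("shark_id", "date", "wound_area_cm2", "wound_perimeter_cm",
                    "pcl_cm", "mass_kg")

#' Parse capture dates in a fixed dialect
#'
#' Dates are stored internally as `Date` (an absolute proleptic day count),
#' never as day-of-year: the parturition season spans a calendar year
#' boundary, so a January capture back-calculated by 30 days must land in
#' December of the previous year.
#'
#' @param x character vector of dates.
#' @param format `strptime` format; default `dd/mm/yyyy`.
#' @return `Date` vector.
#' @keywords internal
parse_capture_date <- function(x, format = "%d/%m/%Y") {
  d <- as.Date(as.character(x), format = format)
  bad <- which(is.na(d) & !is.na(x) & nzchar(trimws(as.character(x))))
  if (length(bad) > 0) {
    stop("unparseable date(s) at row(s) ", paste(bad, collapse = ", "),
         ": ", paste(utils::head(x[bad], 3), collapse = ", "), call. = FALSE)
  }
  d
}

#' Elapsed whole days between two dates
#'
#' @param d1,d2 `Date` vectors (recycled).
#' @return Integer days, `d2 - d1`; negative when `d2` precedes `d1`.
#' @examples
#' elapsed_days(as.Date("2021-11-30"), as.Date("2021-12-28"))  # 28
#' @export
elapsed_days <- function(d1, d2) {
  as.integer(as.numeric(as.Date(d2)) - as.numeric(as.Date(d1)))
}

#' Validate a capture-event table
#'
#' Checks the invariants a capture record must satisfy: non-negative wound
#' sizes, positive morphometrics, and parseable dates. A fully healed
#' wound is recorded as area and perimeter both exactly zero; a one-sided
#' zero (zero area with a positive perimeter, or vice versa) is accepted —
#' a wound closing to a thin slit has vanishing area while its perimeter
#' is still measurable. A days-old flag on an event with a fully closed
#' wound is contradictory and warns.
#'
#' @param events data.frame of capture events (internal column names).
#' @return the validated data.frame, invisibly.
#' @keywords internal
validate_captures <- function(events) {
  for (col in c("wound_area", "wound_perimeter")) {
    bad <- which(!is.na(events[[col]]) & events[[col]] < 0)
    if (length(bad) > 0) {
      stop("negative ", col, " at row(s) ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  for (col in c("pcl", "mass")) {
    bad <- which(!is.na(events[[col]]) & events[[col]] <= 0)
    if (length(bad) > 0) {
      stop("non-positive ", col, " at row(s) ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  a <- events$wound_area
  p <- events$wound_perimeter
  cr <- events$cord_remnants
  badcord <- which(!is.na(cr) & cr & !is.na(a) & !is.na(p) &
                     a == 0 & p == 0)
  if (length(badcord) > 0) {
    warning(length(badcord), " event(s) flagged days-old but with a closed ",
            "wound", call. = FALSE)
  }
  invisible(events)
}

#' Read capture records from CSV
#'
#' Expects a header with columns `shark_id, date, wound_area_cm2,
#' wound_perimeter_cm, pcl_cm, mass_kg` and optionally `site, sex,
#' cord_remnants`. Empty numeric cells become `NA` (missing), never zero:
#' a missing wound measurement is not a healed wound.
#'
#' @param path CSV file path.
#' @param date_format date dialect, default `dd/mm/yyyy`.
#' @return data.frame with columns `shark_id` (character), `date` (`Date`),
#'   `wound_area` (cm^2), `wound_perimeter` (cm), `pcl` (cm), `mass` (kg),
#'   `site`, `sex` (character or `NA`), `cord_remnants` (logical or `NA`).
#' @seealso [write_captures()], [build_histories()]
#' @export
read_captures <- function(path, date_format = "%d/%m/%Y") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = c("", "NA"))
  missing_cols <- setdiff(.required_cols, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  num <- function(col) {
    if (!col %in% names(raw)) return(rep(NA_real_, nrow(raw)))
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      stop("non-numeric ", col, " at row(s) ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    v
  }
  chr <- function(col) if (col %in% names(raw)) raw[[col]] else NA_character_
  cord <- if ("cord_remnants" %in% names(raw)) {
    tolower(trimws(raw$cord_remnants)) %in% c("true", "t", "1", "yes")
  } else NA
  cord[is.na(chr("cord_remnants"))] <- NA
  events <- data.frame(
    shark_id        = raw$shark_id,
    date            = parse_capture_date(raw$date, date_format),
    wound_area      = num("wound_area_cm2"),
    wound_perimeter = num("wound_perimeter_cm"),
    pcl             = num("pcl_cm"),
    mass            = num("mass_kg"),
    site            = chr("site"),
    sex             = chr("sex"),
    cord_remnants   = cord,
    stringsAsFactors = FALSE
  )
  validate_captures(events)
  events
}

#' Write capture records to CSV
#'
#' Inverse of [read_captures()]: the round trip through a file is the
#' identity on valid event tables.
#'
#' @param events capture-event data.frame (internal column names).
#' @param path output CSV path.
#' @param date_format date dialect used for the `date` column.
#' @return `path`, invisibly.
#' @export
write_captures <- function(events, path, date_format = "%d/%m/%Y") {
  out <- data.frame(
    shark_id           = events$shark_id,
    date               = format(events$date, date_format),
    wound_area_cm2     = events$wound_area,
    wound_perimeter_cm = events$wound_perimeter,
    pcl_cm             = events$pcl,
    mass_kg            = events$mass,
    site               = events$site,
    sex                = events$sex,
    cord_remnants      = events$cord_remnants,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Group capture events into per-shark histories
#'
#' Recaptured sharks are identified by their tag id; each history is the
#' date-ordered sequence of that individual's capture events. Two events
#' for one shark on the same date are ambiguous (a tag collision or data
#' entry error) and raise an error.
#'
#' @param events capture-event data.frame.
#' @return named list of data.frames (one per shark, rows in ascending
#'   date order), class `shark_histories`.
#' @export
build_histories <- function(events) {
  if (nrow(events) == 0) {
    return(structure(list(), class = "shark_histories"))
  }
  dup <- duplicated(events[, c("shark_id", "date")])
  if (any(dup)) {
    ids <- unique(events$shark_id[dup])
    stop("two events on the same date for shark(s): ",
         paste(utils::head(ids, 5), collapse = ", "), call. = FALSE)
  }
  histories <- split(events, events$shark_id)
  histories <- lapply(histories, function(h) {
    h <- h[order(h$date), , drop = FALSE]
    rownames(h) <- NULL
    h
  })
  structure(histories, class = "shark_histories")
}

#' @export
print.shark_histories <- function(x, ...) {
  n_events <- vapply(x, nrow, integer(1))
  cat("<shark_histories> ", length(x), " sharks, ", sum(n_events),
      " capture events (", sum(n_events > 1), " recaptured)\n", sep = "")
  invisible(x)
}
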