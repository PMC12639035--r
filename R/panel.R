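# Panel container, validation, I/O and region geometry.

PANEL_COLUMNS <- c("region", "year", "month", "conflict", "TA", "DL", "PA")

#' Chronological period index
#'
#' Maps a (year, month) pair to the 1-based monthly period index
#' `12 * (year - first_year) + month`, so that January of `first_year` is
#' period 1 and the index increases by one per calendar month.
#'
#' @param year Integer calendar year(s).
#' @param month Integer month(s), 1--12.
#' @param first_year First calendar year of the panel.
#' @return Integer period index, strictly increasing in chronological order.
#' @examples
#' period_index(1997, 1, 1997)  # 1
#' period_index(2009, 12, 1997) # 156
#' @export
period_index <- function(year, month, first_year) {
  if (any(!is_wholenumber(month)) || any(month < 1) || any(month > 12)) {
    stop_validation("month must be an integer in 1..12")
  }
  as.integer(12L * (round(year) - round(first_year)) + round(month))
}

#' Construct a balanced regional panel
#'
#' Validates and orders a data frame of region-by-month observations into a
#' `regional_panel`: one row per (region, period) pair, regions in lexical
#' order, periods in chronological order. Counts must be non-negative
#' integers (values integral to within 1e-9 are cast; anything else is
#' rejected -- silent rounding of event counts would corrupt every model
#' downstream).
#'
#' @param df Data frame with columns `region`, `year`, `month`, `conflict`,
#'   `TA`, `DL`, `PA`.
#' @param first_year First calendar year; defaults to the minimum year present.
#' @param strict If `TRUE` (default) an unbalanced panel is an error; if
#'   `FALSE` the unbalanced data frame is returned untouched with the
#'   validation report attached as attribute `"validation"`.
#' @return A `regional_panel` (a data frame with attributes `regions`,
#'   `periods`, `first_year`, `n_regions`, `n_periods`).
#' @export
regional_panel <- function(df, first_year = NULL, strict = TRUE) {
  rep_ <- validate_panel(df, first_year = first_year)
  if (length(rep_$type_violations)) {
    stop_validation("panel type violations:\n  ",
                    paste(rep_$type_violations, collapse = "\n  "))
  }
  if (!rep_$is_balanced) {
    if (strict) {
      stop_validation(
        "panel is not balanced; missing (region, period) cells: ",
        paste(utils::head(paste0("(", rep_$missing_cells$region, ", ",
                                 rep_$missing_cells$period, ")"), 10),
              collapse = " "))
    }
    attr(df, "validation") <- rep_
    return(df)
  }
  first_year <- first_year %||% min(df$year)
  df$region <- as.character(df$region)
  df$conflict <- as.integer(round(df$conflict))
  df$year <- as.integer(round(df$year))
  df$month <- as.integer(round(df$month))
  df$period <- period_index(df$year, df$month, first_year)
  df <- df[order(df$region, df$period), , drop = FALSE]
  rownames(df) <- NULL
  regions <- sort(unique(df$region))
  periods <- sort(unique(df$period))
  structure(df,
            class = c("regional_panel", "data.frame"),
            regions = regions, periods = periods,
            first_year = first_year,
            n_regions = length(regions), n_periods = length(periods))
}

#' Validate a panel data frame
#'
#' Checks column presence, value types and balance without modifying the
#' input. The report is serializable with [report_to_json()].
#'
#' @inheritParams regional_panel
#' @return A `validation_report` list: `is_balanced`, `missing_cells`
#'   (data frame of region/period), `type_violations` (character vector of
#'   row-level messages).
#' @export
validate_panel <- function(df, first_year = NULL) {
  missing_cols <- setdiff(PANEL_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop_config("panel is missing required columns: ",
                paste(missing_cols, collapse = ", "))
  }
  viol <- character(0)
  bad_month <- which(!is_wholenumber(df$month) | df$month < 1 | df$month > 12)
  for (i in utils::head(bad_month, 20)) {
    viol <- c(viol, sprintf("row %d: month %s outside 1..12", i, df$month[i]))
  }
  bad_count <- which(!is_wholenumber(df$conflict) | df$conflict < 0)
  for (i in utils::head(bad_count, 20)) {
    viol <- c(viol, sprintf(
      "row %d: conflict count %s is not a non-negative integer", i,
      format(df$conflict[i])))
  }
  for (col in c("TA", "PA")) {
    bad <- which(!is.finite(df[[col]]))
    for (i in utils::head(bad, 20)) {
      viol <- c(viol, sprintf("row %d: %s is not finite", i, col))
    }
  }
  missing_cells <- data.frame(region = character(0), period = integer(0))
  is_balanced <- FALSE
  if (!length(bad_month)) {
    first_year <- first_year %||% min(df$year)
    per <- period_index(df$year, df$month, first_year)
    regions <- sort(unique(as.character(df$region)))
    periods <- sort(unique(per))
    key <- paste(df$region, per)
    full <- expand.grid(region = regions, period = periods,
                        stringsAsFactors = FALSE)
    miss <- !(paste(full$region, full$period) %in% key)
    missing_cells <- full[miss, , drop = FALSE]
    rownames(missing_cells) <- NULL
    dup <- any(duplicated(key))
    if (dup) viol <- c(viol, "duplicated (region, period) cells present")
    is_balanced <- !any(miss) && !dup &&
      nrow(df) == length(regions) * length(periods)
  }
  structure(list(is_balanced = is_balanced, missing_cells = missing_cells,
                 type_violations = viol),
            class = "validation_report")
}

#' Serialize a validation report to JSON
#' @param report A `validation_report`.
#' @param path Optional file path; if omitted the JSON string is returned.
#' @return JSON string (invisibly, when writing to a file).
#' @export
report_to_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read a panel from delimited text
#'
#' @param path CSV (or TSV, by extension) file with a header row and one row
#'   per (region, year, month).
#' @param column_map Optional named character vector mapping standard names
#'   (`region`, `year`, ...) to the column names used in the file.
#' @param strict Passed to [regional_panel()].
#' @inheritParams regional_panel
#' @return A `regional_panel`.
#' @export
load_panel <- function(path, column_map = NULL, first_year = NULL,
                       strict = TRUE) {
  if (!file.exists(path)) stop_config("panel file does not exist: ", path)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    absent <- setdiff(unname(column_map), names(df))
    if (length(absent)) {
      stop_config("mapped columns not present in file: ",
                  paste(absent, collapse = ", "))
    }
    for (std in names(column_map)) {
      names(df)[names(df) == column_map[[std]]] <- std
    }
  }
  regional_panel(df, first_year = first_year, strict = strict)
}

#' Write a panel to CSV
#'
#' Real-valued columns are written with 17 significant digits so that a
#' write/load round trip reproduces every double bit-identically.
#'
#' @param panel A `regional_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  df <- as.data.frame(panel)[, c(PANEL_COLUMNS, "period")]
  for (col in names(df)) {
    if (is.double(df[[col]])) df[[col]] <- sprintf("%.17g", df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.regional_panel <- function(x, ...) {
  cat(sprintf("Regional panel: %d regions x %d periods (%d rows)\n",
              attr(x, "n_regions"), attr(x, "n_periods"), nrow(x)))
  cat(sprintf("  first year %d; counts: %.1f%% zeros, max %d\n",
              attr(x, "first_year"), 100 * mean(x$conflict == 0),
              max(x$conflict)))
  invisible(x)
}

#' Region centroid geometry
#'
#' Stores region centroids (decimal degrees) and the derived great-circle
#' distance matrix used by the spatial HAC kernel.
#'
#' @param df Data frame with columns `region`, `lat`, `lon` (one row per
#'   region), or a path to such a CSV file.
#' @return A `region_geometry` list: `centroids` (data frame) and `distances`
#'   (symmetric n x n matrix, km, zero diagonal, dimnames = regions).
#' @export
region_geometry <- function(df) {
  if (is.character(df)) {
    df <- utils::read.csv(df, stringsAsFactors = FALSE)
  }
  need <- c("region", "lat", "lon")
  if (!all(need %in% names(df))) {
    stop_config("geometry needs columns: ", paste(need, collapse = ", "))
  }
  df$region <- as.character(df$region)
  df <- df[order(df$region), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(centroids = df, distances = pairwise_distances(df)),
            class = "region_geometry")
}

#' Great-circle distance matrix between region centroids
#'
#' Haversine distances on a sphere of mean Earth radius 6371.0088 km.
#'
#' @param centroids Data frame with `region`, `lat`, `lon`, or a
#'   `region_geometry`.
#' @return Symmetric matrix of distances in km with zero diagonal.
#' @export
pairwise_distances <- function(centroids) {
  if (inherits(centroids, "region_geometry")) centroids <- centroids$centroids
  if (any(abs(centroids$lat) > 90)) {
    stop_validation("latitude outside [-90, 90]")
  }
  if (any(abs(centroids$lon) > 360)) {
    stop_validation("longitude outside plausible range")
  }
  n <- nrow(centroids)
  lat <- centroids$lat * pi / 180
  lon <- centroids$lon * pi / 180
  d <- matrix(0, n, n, dimnames = list(centroids$region, centroids$region))
  R <- 6371.0088
  for (i in seq_len(n)) {
    dlat <- lat - lat[i]
    dlon <- lon - lon[i]
    a <- sin(dlat / 2)^2 + cos(lat[i]) * cos(lat) * sin(dlon / 2)^2
    d[i, ] <- 2 * R * asin(pmin(1, sqrt(a)))
  }
  diag(d) <- 0
  (d + t(d)) / 2
}
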