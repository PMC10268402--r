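#' Construct a validated region-by-year indicator panel
#'
#' A `region_panel` is the table every analysis stage consumes: one row per
#' (region, year) holding the elderly population ratio (EPR, stored in
#' percentage points) and three per-1000-population medical resource
#' indicators -- health institutions (NHI), beds in health institutions
#' (NBHI) and health technical personnel (NHTP).
#'
#' Invariants enforced here: exactly one record per (region, year); years form
#' a contiguous range; the region set is identical in every year; all four
#' indicator values are strictly positive (downstream models take logs).
#' Rows are sorted by (region_id, year) and region ordering is lexicographic
#' everywhere in the package, so vectors and weight matrices align by
#' construction.
#'
#' @param data data.frame with columns `region_id`, `year`, `epr`, `nhi`,
#'   `nbhi`, `nhtp` and optionally `region_name`.
#' @param epr_unit `"percent"` if `epr` is already in percentage points,
#'   `"fraction"` if it is a proportion in (0, 1] to be multiplied by 100.
#' @return A `region_panel`: a data.frame with the columns above, sorted by
#'   (region_id, year).
#' @examples
#' df <- expand.grid(region_id = c("A", "B"), year = 2011:2013,
#'                   stringsAsFactors = FALSE)
#' df[c("epr", "nhi", "nbhi", "nhtp")] <- abs(rnorm(nrow(df) * 4)) + 1
#' p <- region_panel(df)
#' @export
region_panel <- function(data, epr_unit = c("percent", "fraction")) {
  epr_unit <- match.arg(epr_unit)
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  required <- c("region_id", "year", "epr", "nhi", "nbhi", "nhtp")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"region_name" %in% names(data)) data$region_name <- data$region_id
  data$region_id <- as.character(data$region_id)
  data$region_name <- as.character(data$region_name)
  data$year <- as.integer(data$year)
  for (col in c("epr", "nhi", "nbhi", "nhtp")) {
    data[[col]] <- as.numeric(data[[col]])
  }
  if (epr_unit == "fraction") data$epr <- 100 * data$epr

  key <- paste(data$region_id, data$year, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate (region_id, year) record(s): ",
         paste(unique(gsub("\r", "/", key[dup])), collapse = ", "),
         call. = FALSE)
  }
  for (col in c("epr", "nhi", "nbhi", "nhtp")) {
    bad <- !is.finite(data[[col]]) | data[[col]] <= 0
    if (any(bad)) {
      rows <- paste(data$region_id[bad], data$year[bad], sep = "/")
      stop("indicator '", col, "' must be strictly positive and finite; ",
           "offending rows: ", paste(utils::head(rows, 10L), collapse = ", "),
           call. = FALSE)
    }
  }
  years <- sort(unique(data$year))
  if (!identical(years, seq(min(years), max(years)))) {
    stop("years must form a contiguous range; observed: ",
         paste(years, collapse = ", "), call. = FALSE)
  }
  regions <- sort(unique(data$region_id))
  tab <- table(data$region_id, data$year)
  if (any(tab != 1L)) {
    stop("region set must be identical across years: every (region, year) ",
         "cell must appear exactly once", call. = FALSE)
  }
  data <- data[order(data$region_id, data$year),
               c("region_id", "region_name", "year", "epr", "nhi", "nbhi", "nhtp")]
  rownames(data) <- NULL
  structure(data,
            class = c("region_panel", "data.frame"),
            regions = regions,
            years = years)
}

#' @export
print.region_panel <- function(x, ...) {
  cat(sprintf("region_panel: %d regions x %d years (%d-%d)\n",
              length(attr(x, "regions")), length(attr(x, "years")),
              min(attr(x, "years")), max(attr(x, "years"))))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... ", nrow(x) - 6L, " more rows\n", sep = "")
  invisible(x)
}

#' Regions of a panel, in canonical (lexicographic) order
#' @param panel a `region_panel`
#' @return character vector of region identifiers
#' @export
panel_regions <- function(panel) attr(panel, "regions")

#' Years covered by a panel
#' @param panel a `region_panel`
#' @return integer vector of calendar years (contiguous)
#' @export
panel_years <- function(panel) attr(panel, "years")

#' Extract one indicator as a region x year matrix
#'
#' @param panel a `region_panel`
#' @param indicator one of `"epr"`, `"nhi"`, `"nbhi"`, `"nhtp"`
#' @return numeric matrix, rows = regions in canonical order, columns = years
#' @export
panel_matrix <- function(panel, indicator = c("epr", "nhi", "nbhi", "nhtp")) {
  indicator <- match.arg(indicator)
  regions <- panel_regions(panel)
  years <- panel_years(panel)
  m <- matrix(NA_real_, length(regions), length(years),
              dimnames = list(regions, years))
  m[cbind(match(panel$region_id, regions), match(panel$year, years))] <-
    panel[[indicator]]
  m
}

#' Read a region-by-year panel from CSV
#'
#' Accepts either a wide layout (`region_id, year, epr, nhi, nbhi, nhtp`,
#' optional `region_name`) or a long layout (`region_id, region_name, year,
#' indicator, value`). Column names can be remapped through `schema`.
#'
#' @param path path to a CSV file
#' @param schema optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(region_id = "province", epr = "ageing_ratio")`.
#' @param epr_unit see [region_panel()]
#' @return a validated [region_panel()]
#' @export
read_panel <- function(path, schema = NULL, epr_unit = c("percent", "fraction")) {
  epr_unit <- match.arg(epr_unit)
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      src <- schema[[canonical]]
      if (!src %in% names(df)) {
        stop("schema maps '", canonical, "' to column '", src,
             "' which is absent from ", path, call. = FALSE)
      }
      names(df)[names(df) == src] <- canonical
    }
  }
  long <- all(c("region_id", "year", "indicator", "value") %in% names(df))
  wide <- all(c("region_id", "year", "epr", "nhi", "nbhi", "nhtp") %in% names(df))
  if (!long && !wide) {
    need <- setdiff(c("region_id", "year", "epr", "nhi", "nbhi", "nhtp"),
                    names(df))
    stop("panel file matches neither the wide nor the long layout; ",
         "missing column(s) for wide: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (long && !wide) {
    bad <- setdiff(unique(df$indicator), c("epr", "nhi", "nbhi", "nhtp"))
    if (length(bad) > 0L) {
      stop("unknown indicator name(s) in long panel: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    keep_name <- "region_name" %in% names(df)
    wide_df <- stats::reshape(
      df[c("region_id", if (keep_name) "region_name", "year", "indicator", "value")],
      idvar = c("region_id", if (keep_name) "region_name", "year"),
      timevar = "indicator", direction = "wide")
    names(wide_df) <- sub("^value\\.", "", names(wide_df))
    df <- wide_df
  }
  region_panel(df, epr_unit = epr_unit)
}

#' Write any tabular pipeline result to CSV or JSON
#'
#' Round-trips values at full double precision (CSV uses 17 significant
#' digits). List-like results (e.g. a single Moran test) become one-row
#' tables in CSV and a keyed object in JSON.
#'
#' @param result a data.frame or a named list of scalars/vectors
#' @param path output path
#' @param format `"csv"` or `"json"` (default inferred from the extension)
#' @return `invisible(path)`
#' @export
write_table <- function(result, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (inherits(result, "moran_result")) result <- unclass(result)
  if (format == "json") {
    jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    df <- if (is.data.frame(result)) result else
      as.data.frame(lapply(result, function(v) if (length(v) == 0) NA else v),
                    stringsAsFactors = FALSE)
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}
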