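#' Construct a radar survey dataset
#'
#' Bundles a table of dawn radar surveys into a validated `murre_data` object,
#' the container every downstream step (filtering, model configuration,
#' fitting) consumes. One row is one survey: the number of incoming murrelets
#' counted before dawn at a monitoring station, with the covariates the trend
#' model adjusts for.
#'
#' @param records data.frame with columns `region` (one of HG, NC, WC, CC,
#'   EV, SC), `site`, `year`, `doy` (integer Julian day), `tilt_deg`,
#'   `count_in`, and optionally `complete` and `rain_gt10min`. Missing flag
#'   columns default to `complete = TRUE`, `rain_gt10min = FALSE` (synthetic
#'   data is generated clean; the flags describe the historical record).
#' @return A `murre_data` object: list with `records` (the validated
#'   data.frame), `site_index` (named character vector, site -> region),
#'   `n_sites`, `n_regions`.
#' @export
murre_data <- function(records) {
  required <- c("region", "site", "year", "doy", "tilt_deg", "count_in")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (is.null(records$complete)) records$complete <- TRUE
  if (is.null(records$rain_gt10min)) records$rain_gt10min <- FALSE
  records$region <- as.character(records$region)
  records$site <- as.character(records$site)

  for (col in c("year", "doy", "tilt_deg", "count_in")) {
    v <- records[[col]]
    if (is.character(v) || is.factor(v)) {
      parsed <- suppressWarnings(as.numeric(as.character(v)))
      bad <- which(is.na(parsed) & !is.na(v))
      if (length(bad) > 0) {
        stop(sprintf("parse error: non-numeric '%s' at row %d (value '%s')",
                     col, bad[1], as.character(v)[bad[1]]))
      }
      records[[col]] <- parsed
    }
  }

  bad_region <- which(!records$region %in% REGION_CODES)
  if (length(bad_region) > 0) {
    stop(sprintf("validation error: unknown region code '%s' at row %d",
                 records$region[bad_region[1]], bad_region[1]))
  }
  if (any(records$count_in < 0, na.rm = TRUE)) {
    stop("validation error: negative count_in")
  }
  if (any(records$doy < 1 | records$doy > 366, na.rm = TRUE)) {
    stop("validation error: day of year outside [1, 366]")
  }
  if (any(records$tilt_deg < 0, na.rm = TRUE)) {
    stop("validation error: negative radar tilt")
  }

  # every site must map to exactly one region
  sr <- unique(records[, c("site", "region")])
  dup <- sr$site[duplicated(sr$site)]
  if (length(dup) > 0) {
    stop("validation error: site(s) mapped to more than one region: ",
         paste(unique(dup), collapse = ", "))
  }
  site_index <- setNames(sr$region, sr$site)

  structure(
    list(records = records,
         site_index = site_index,
         n_sites = length(site_index),
         n_regions = length(unique(sr$region))),
    class = "murre_data")
}

#' @export
print.murre_data <- function(x, ...) {
  cat(sprintf("<murre_data> %d surveys, %d sites, %d regions, years %d-%d\n",
              nrow(x$records), x$n_sites, x$n_regions,
              min(x$records$year), max(x$records$year)))
  rep <- attr(x, "filter_report")
  if (!is.null(rep)) {
    cat(sprintf("  filtered: %d incomplete, %d rain-obstructed dropped; %d zero counts set to 1\n",
                rep$dropped_incomplete, rep$dropped_rain, rep$zeros_substituted))
  }
  invisible(x)
}

#' Read a radar survey table from disk
#'
#' Canonical interchange format is CSV with header
#' `region,site,year,doy,tilt_deg,count_in,complete,rain_gt10min` (the two
#' flag columns optional). An XLSX reader is provided to ingest supplementary
#' spreadsheets whose column headers differ; supply `col_map` to rename them.
#'
#' @param path file path.
#' @param format `"csv"` (default, inferred from extension) or `"xlsx"`
#'   (requires the readxl package).
#' @param col_map optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(region = "Conservation Region")`.
#' @param sheet sheet name or index for XLSX input.
#' @return A [murre_data] object, unfiltered, row order preserved.
#' @export
load_surveys <- function(path, format = c("csv", "xlsx"), col_map = NULL,
                         sheet = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(format)) {
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  format <- match.arg(format)
  raw <- if (format == "csv") {
    read.csv(path, stringsAsFactors = FALSE)
  } else {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading xlsx requires the 'readxl' package")
    }
    as.data.frame(readxl::read_excel(path, sheet = sheet))
  }
  if (!is.null(col_map)) {
    for (canonical in names(col_map)) {
      src <- col_map[[canonical]]
      if (!src %in% names(raw)) {
        stop("schema error: mapped column not found in file: ", src)
      }
      names(raw)[names(raw) == src] <- canonical
    }
  }
  murre_data(raw)
}

#' Apply the study's data-selection rules
#'
#' Drops surveys that were incomplete or had continuous rain obstruction of
#' the radar screen for more than 10 minutes before sunrise, then replaces
#' zero counts with 1 so the lognormal observation model applies. The filter
#' report is attached as attribute `"filter_report"`.
#'
#' @param data a [murre_data] object.
#' @return A filtered `murre_data`; attribute `filter_report` is a list with
#'   `dropped_incomplete`, `dropped_rain`, `zeros_substituted`, `n_before`,
#'   `n_after`.
#' @export
filter_surveys <- function(data) {
  stopifnot(inherits(data, "murre_data"))
  rec <- data$records
  n_before <- nrow(rec)
  incomplete <- !rec$complete
  rain <- rec$rain_gt10min & !incomplete  # attribute each drop to one rule
  keep <- !(incomplete | rec$rain_gt10min)
  rec <- rec[keep, , drop = FALSE]
  if (nrow(rec) == 0) stop("no usable surveys after filtering")
  zeros <- rec$count_in == 0
  rec$count_in[zeros] <- 1
  rownames(rec) <- NULL
  out <- murre_data(rec)
  attr(out, "filter_report") <- list(
    n_before = n_before,
    n_after = nrow(rec),
    dropped_incomplete = sum(incomplete),
    dropped_rain = sum(rain),
    zeros_substituted = sum(zeros))
  out
}

#' Summarize the survey design of a dataset
#'
#' Tallies sites per region, years surveyed per site, and observations per
#' region-year cell. Cells with a single observation are flagged: a year
#' effect estimated from one survey would be confounded with residual error,
#' which is why such years are candidates for fixing at zero in the model
#' configuration.
#'
#' @param data a [murre_data] object.
#' @return list with data.frames `sites_per_region`, `years_per_site`,
#'   `region_year` (columns `region`, `year`, `n_obs`, `n_sites`,
#'   `low_count`).
#' @export
summarize_dataset <- function(data) {
  stopifnot(inherits(data, "murre_data"))
  rec <- data$records
  if (nrow(rec) == 0) stop("empty dataset")
  spr <- aggregate(site ~ region, data = unique(rec[, c("region", "site")]),
                   FUN = length)
  names(spr) <- c("region", "n_sites")
  yps <- aggregate(year ~ site, data = unique(rec[, c("site", "year")]),
                   FUN = length)
  names(yps) <- c("site", "n_years")
  ry <- aggregate(cbind(n_obs = count_in) ~ region + year, data = rec,
                  FUN = length)
  ns <- aggregate(site ~ region + year, data = unique(rec[, c("region", "year", "site")]),
                  FUN = length)
  names(ns) <- c("region", "year", "n_sites")
  ry <- merge(ry, ns, by = c("region", "year"))
  ry$low_count <- ry$n_obs == 1
  ry <- ry[order(ry$region, ry$year), ]
  rownames(ry) <- NULL
  list(sites_per_region = spr, years_per_site = yps, region_year = ry)
}
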