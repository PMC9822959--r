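#' Assemble an annual stock-assessment series
#'
#' Builds the package's central data container: a tibble of aligned annual
#' spawning stock biomass (SSB, tonnes), recruitment (thousands of fish at age
#' `recruitment_age`) and fishing mortality (per year), one row per calendar
#' year. Missing observations are carried as explicit `NA`s and excluded
#' pairwise by downstream analyses; they are never imputed.
#'
#' @param years Integer vector of consecutive calendar years (step 1).
#' @param ssb Numeric SSB per year, tonnes; positive where present.
#' @param recruitment Numeric recruitment per year, thousands; positive where
#'   present. Indexed at age `recruitment_age`.
#' @param fmort Numeric fishing mortality per year (per year); non-negative.
#' @param stock_id Label for the stock.
#' @param recruitment_age Integer age (>= 0) at which recruitment is reported.
#' @return A `stock_series` tibble with columns `year`, `ssb`, `recruitment`,
#'   `fmort` and attributes `stock_id` and `recruitment_age`.
#' @seealso [read_stock_csv()], [align_srr()]
#' @export
stock_series <- function(years, ssb, recruitment, fmort,
                         stock_id = "stock", recruitment_age = 0L) {
  out <- tibble(
    year = as.integer(years),
    ssb = as.numeric(ssb),
    recruitment = as.numeric(recruitment),
    fmort = as.numeric(fmort)
  )
  out <- out[order(out$year), ]
  out <- new_tibble(out, class = "stock_series",
                    stock_id = as.character(stock_id)[1],
                    recruitment_age = as.integer(recruitment_age)[1])
  validate_stock_series(out)
  out
}

#' Validate a stock series against its invariants
#'
#' Checks consecutive years, array lengths, strictly positive SSB and
#' recruitment where present, and non-negative fishing mortality. Called by
#' every constructor and reader; exposed so externally assembled tibbles can be
#' checked too.
#'
#' @param x A `stock_series` tibble.
#' @return `x`, invisibly, if valid; otherwise a validation error.
#' @export
validate_stock_series <- function(x) {
  need <- c("year", "ssb", "recruitment", "fmort")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("stock series lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "fishshift_validation_error")
  }
  yrs <- x$year
  if (anyNA(yrs)) {
    abort("stock series has missing years", class = "fishshift_validation_error")
  }
  if (anyDuplicated(yrs) > 0) {
    abort(paste0("duplicate year(s): ",
                 paste(unique(yrs[duplicated(yrs)]), collapse = ", ")),
          class = "fishshift_validation_error")
  }
  if (length(yrs) > 1) {
    d <- diff(sort(yrs))
    if (any(d != 1L)) {
      gaps <- sort(yrs)[which(d != 1L)] + 1L
      abort(paste0("years are not consecutive; gap at: ",
                   paste(gaps, collapse = ", ")),
            class = "fishshift_validation_error")
    }
  }
  if (any(x$ssb[!is.na(x$ssb)] <= 0)) {
    abort("ssb must be > 0 where present", class = "fishshift_validation_error")
  }
  if (any(x$recruitment[!is.na(x$recruitment)] <= 0)) {
    abort("recruitment must be > 0 where present",
          class = "fishshift_validation_error")
  }
  if (any(x$fmort[!is.na(x$fmort)] < 0)) {
    abort("fmort must be >= 0 where present",
          class = "fishshift_validation_error")
  }
  age <- attr(x, "recruitment_age")
  if (is.null(age) || is.na(age) || age < 0) {
    abort("recruitment_age must be an integer >= 0",
          class = "fishshift_validation_error")
  }
  invisible(x)
}

#' Management reference points for annotation
#'
#' Holds the ICES-style fishing-mortality and biomass reference levels
#' (F_MSY, F_pa, F_lim, MSY B_trigger, B_pa, B_lim). These are used only for
#' annotating plots and reports; no inference depends on them.
#'
#' @param f_msy,f_pa,f_lim Fishing mortality levels (per year).
#' @param msy_btrigger,b_pa,b_lim Biomass levels (tonnes).
#' @return A one-row `reference_points` tibble.
#' @export
reference_points <- function(f_msy = NA_real_, f_pa = NA_real_,
                             f_lim = NA_real_, msy_btrigger = NA_real_,
                             b_pa = NA_real_, b_lim = NA_real_) {
  vals <- c(f_msy = f_msy, f_pa = f_pa, f_lim = f_lim,
            msy_btrigger = msy_btrigger, b_pa = b_pa, b_lim = b_lim)
  if (any(vals[!is.na(vals)] < 0)) {
    abort("reference points must be non-negative",
          class = "fishshift_validation_error")
  }
  if (!is.na(b_lim) && !is.na(b_pa) && b_lim > b_pa) {
    abort("b_lim must not exceed b_pa", class = "fishshift_validation_error")
  }
  new_tibble(tibble(f_msy = f_msy, f_pa = f_pa, f_lim = f_lim,
                    msy_btrigger = msy_btrigger, b_pa = b_pa, b_lim = b_lim),
             class = "reference_points")
}

.parse_numeric_col <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  out[trimws(as.character(x)) %in% c("", "NA", "na", "NaN")] <- NA_real_
  out
}

#' Read a stock assessment series from CSV
#'
#' Reads an ICES "standard graphs"-style extract: one header row, one row per
#' assessment year, columns for year, SSB, recruitment and fishing mortality.
#' Column names are configurable through `column_map`; unparseable numeric
#' cells become explicit missing values, while an unparseable or missing year
#' is an error.
#'
#' @param path Path to a CSV file.
#' @param column_map Named character vector mapping the internal names
#'   `year`, `ssb`, `recruitment`, `fmort` to the file's column names.
#' @param recruitment_age Integer age at which recruitment is indexed.
#' @param stock_id Stock label; defaults to the file name.
#' @return A validated [stock_series()] tibble, rows sorted by year.
#' @export
read_stock_csv <- function(path,
                           column_map = c(year = "Year", ssb = "SSB",
                                          recruitment = "R", fmort = "F"),
                           recruitment_age = 0L,
                           stock_id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "fishshift_input_error")
  }
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", strip.white = TRUE)
  need <- c("year", "ssb", "recruitment", "fmort")
  map <- column_map[need]
  absent <- need[is.na(map) | !(map %in% names(raw))]
  if (length(absent) > 0) {
    abort(paste0("mapped column(s) not found in ", path, ": ",
                 paste(column_map[absent], collapse = ", ")),
          class = "fishshift_format_error")
  }
  yr <- suppressWarnings(as.integer(raw[[map[["year"]]]]))
  if (anyNA(yr)) {
    abort(paste0("unparseable year in row(s): ",
                 paste(which(is.na(yr)), collapse = ", ")),
          class = "fishshift_format_error")
  }
  stock_series(
    years = yr,
    ssb = .parse_numeric_col(raw[[map[["ssb"]]]]),
    recruitment = .parse_numeric_col(raw[[map[["recruitment"]]]]),
    fmort = .parse_numeric_col(raw[[map[["fmort"]]]]),
    stock_id = stock_id %||% sub("\\.[Cc][Ss][Vv]$", "", basename(path)),
    recruitment_age = recruitment_age
  )
}

#' Write a stock series to CSV
#'
#' Inverse of [read_stock_csv()]: writes the same dialect (comma separated,
#' header row) with full double precision, so write-then-read round-trips
#' values bit-exactly.
#'
#' @param x A `stock_series` tibble.
#' @param path Output path.
#' @param column_map Named character vector as in [read_stock_csv()].
#' @return `path`, invisibly.
#' @export
write_stock_csv <- function(x, path,
                            column_map = c(year = "Year", ssb = "SSB",
                                           recruitment = "R", fmort = "F")) {
  validate_stock_series(x)
  out <- tibble(year = x$year, ssb = x$ssb,
                recruitment = x$recruitment, fmort = x$fmort)
  names(out) <- column_map[c("year", "ssb", "recruitment", "fmort")]
  readr::write_csv(out, path, na = "NA")
  invisible(path)
}

#' Read an annual sea-surface-temperature series from CSV
#'
#' Expects columns `Year` and `SST` (annual mean, degrees Celsius). Rows are
#' sorted ascending by year; duplicate years and non-numeric SST are errors.
#'
#' @param path Path to a CSV file.
#' @return An `env_series` tibble with columns `year` and `sst`.
#' @export
read_sst_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "fishshift_input_error")
  }
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", strip.white = TRUE)
  if (!all(c("Year", "SST") %in% names(raw))) {
    abort("SST file must have columns Year and SST",
          class = "fishshift_format_error")
  }
  yr <- suppressWarnings(as.integer(raw$Year))
  if (anyNA(yr)) {
    abort(paste0("unparseable year in row(s): ",
                 paste(which(is.na(yr)), collapse = ", ")),
          class = "fishshift_format_error")
  }
  sst <- suppressWarnings(as.numeric(raw$SST))
  if (anyNA(sst)) {
    abort(paste0("non-numeric SST in row(s): ",
                 paste(which(is.na(sst)), collapse = ", ")),
          class = "fishshift_format_error")
  }
  env_series(yr, sst)
}

#' Assemble an annual environmental (SST) series
#'
#' @param years Integer years.
#' @param sst Annual mean sea surface temperature, degrees Celsius.
#' @return An `env_series` tibble sorted by year.
#' @export
env_series <- function(years, sst) {
  out <- tibble(year = as.integer(years), sst = as.numeric(sst))
  out <- out[order(out$year), ]
  if (anyDuplicated(out$year) > 0) {
    abort(paste0("duplicate SST year(s): ",
                 paste(unique(out$year[duplicated(out$year)]), collapse = ", ")),
          class = "fishshift_validation_error")
  }
  if (any(!is.finite(out$sst))) {
    abort("SST values must be finite", class = "fishshift_validation_error")
  }
  new_tibble(out, class = "env_series")
}

#' Write an SST series to CSV
#'
#' @param x An `env_series` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sst_csv <- function(x, path) {
  readr::write_csv(tibble(Year = x$year, SST = x$sst), path, na = "NA")
  invisible(path)
}

#' Align recruitment to its spawn year (stock-recruitment pairs)
#'
#' Recruitment reported at age `a` in assessment year `y` originated from
#' spawning in year `y - a`. This shifts recruitment back to the year of
#' origin and pairs it with the parent SSB of that year: for every year `t`
#' with SSB present and recruitment present at `t + a`, the pair
#' `(s = SSB_t, r = R_{t+a})` is emitted. Incomplete pairs are dropped, never
#' imputed.
#'
#' @param series A [stock_series()] tibble with attribute `recruitment_age`.
#' @return An `srr_data` tibble with columns `year` (spawn year), `s` (tonnes)
#'   and `r` (thousands).
#' @export
align_srr <- function(series) {
  validate_stock_series(series)
  a <- attr(series, "recruitment_age")
  if (nrow(series) <= a) {
    abort("series shorter than the recruitment age; no pairs possible",
          class = "fishshift_input_error")
  }
  idx <- seq_len(nrow(series) - a)
  out <- tibble(
    year = series$year[idx],
    s = series$ssb[idx],
    r = series$recruitment[idx + a]
  )
  out <- out[complete.cases(out), ]
  if (nrow(out) == 0) {
    abort("no complete stock-recruitment pairs after alignment",
          class = "fishshift_input_error")
  }
  new_tibble(out, class = "srr_data",
             stock_id = attr(series, "stock_id"),
             recruitment_age = a)
}

#' Assemble a stock-recruitment dataset directly
#'
#' Convenience constructor for spawn-year-aligned stock-recruitment pairs,
#' mostly used by simulations and examples.
#'
#' @param years Spawn years.
#' @param s Parent SSB per spawn year (tonnes); positive.
#' @param r Resulting recruitment per spawn year (thousands); positive.
#' @return An `srr_data` tibble.
#' @export
srr_data <- function(years, s, r) {
  out <- tibble(year = as.integer(years), s = as.numeric(s), r = as.numeric(r))
  out <- out[complete.cases(out), ]
  if (nrow(out) == 0) {
    abort("no complete stock-recruitment pairs",
          class = "fishshift_input_error")
  }
  if (any(out$s <= 0) || any(out$r <= 0)) {
    abort("stock-recruitment pairs must have s > 0 and r > 0",
          class = "fishshift_validation_error")
  }
  new_tibble(out[order(out$year), ], class = "srr_data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
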