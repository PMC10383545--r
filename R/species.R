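#' Default PM2.5 speciation set
#'
#' The 18 measured species used throughout the package: 2 carbonaceous
#' fractions (OC, EC), 3 water-soluble inorganic ions (NO3, SO4, K) and 13
#' trace elements. `typical_ngm3` is a campaign-mean scale used to seed
#' default detection limits and field-blank magnitudes; it is not a
#' measurement.
#'
#' @return A tibble with columns `species`, `group` (carbon/ion/element),
#'   `default_unit` and `typical_ngm3`.
#' @export
pm25_species <- function() {
  tibble::tribble(
    ~species, ~group,     ~default_unit, ~typical_ngm3,
    "OC",     "carbon",   "ug/m3",       12000,
    "EC",     "carbon",   "ug/m3",        3000,
    "NO3",    "ion",      "ug/m3",       15210,
    "SO4",    "ion",      "ug/m3",        7900,
    "K",      "ion",      "ug/m3",         800,
    "Fe",     "element",  "ng/m3",         700,
    "Si",     "element",  "ng/m3",         500,
    "Ca",     "element",  "ng/m3",         400,
    "Mn",     "element",  "ng/m3",          60,
    "Pb",     "element",  "ng/m3",          50,
    "Ba",     "element",  "ng/m3",          40,
    "Cu",     "element",  "ng/m3",          25,
    "As",     "element",  "ng/m3",           9,
    "Cr",     "element",  "ng/m3",           7,
    "Cd",     "element",  "ng/m3",         3.5,
    "Ni",     "element",  "ng/m3",           2,
    "Hg",     "element",  "ng/m3",           1,
    "V",      "element",  "ng/m3",           4
  )
}

#' Names of the measured (mass) species
#' @return Character vector of the 18 measured species names.
#' @export
mass_species_default <- function() pm25_species()$species

# unit -> factor to ng/m3
.unit_factor <- function(unit) {
  u <- gsub("µ", "u", trimws(unit))
  switch(u,
    "ng/m3" = 1,
    "ug/m3" = 1000,
    "mg/m3" = 1e6,
    NA_real_
  )
}

#' Read a speciation table from CSV
#'
#' Expects a header row with a `timestamp` column followed by one column per
#' species; each species column carries its unit as a bracketed suffix, e.g.
#' `OC [ug/m3]`. All concentrations are converted to the internal unit,
#' ng/m3. Missing cells are permitted (downstream replacement is handled by
#' [apply_missing_policy()]); negative values are rejected with the offending
#' cell named.
#'
#' @param path Path to a CSV file.
#' @return A tibble with a POSIXct `timestamp` column and one numeric column
#'   per species (ng/m3). The units as read are attached as attribute
#'   `units_in`.
#' @export
read_species_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"timestamp" %in% names(raw)[1]) {
    abort("first column must be named 'timestamp'")
  }
  ts <- tryCatch(
    as.POSIXct(raw$timestamp, tz = "UTC",
               tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                              "%Y-%m-%dT%H:%M", "%Y-%m-%d")),
    error = function(e) rep(as.POSIXct(NA), nrow(raw)))
  if (anyNA(ts)) {
    abort(sprintf("unparseable timestamp at row %d", which(is.na(ts))[1]))
  }
  if (is.unsorted(ts, strictly = TRUE)) {
    abort("timestamps must be strictly increasing")
  }

  sp_cols <- names(raw)[-1]
  m <- regmatches(sp_cols, regexec("^(.*?)\\s*\\[(.+)\\]$", sp_cols))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    abort(sprintf("column '%s' has no unit suffix like 'OC [ug/m3]'",
                  sp_cols[bad][1]))
  }
  species <- vapply(m, `[`, "", 2)
  units <- vapply(m, `[`, "", 3)
  fac <- vapply(units, .unit_factor, 0)
  if (anyNA(fac)) {
    abort(sprintf("unknown unit '%s' for species '%s'",
                  units[is.na(fac)][1], species[is.na(fac)][1]))
  }

  vals <- as.matrix(raw[-1])
  storage.mode(vals) <- "double"
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    abort(sprintf("negative concentration at row %d, species '%s'",
                  neg[1, 1], species[neg[1, 2]]))
  }
  vals <- sweep(vals, 2, fac, `*`)
  colnames(vals) <- species

  out <- dplyr::bind_cols(tibble::tibble(timestamp = ts), as_tibble(vals))
  attr(out, "units_in") <- setNames(units, species)
  out
}

#' Write a speciation table to CSV
#'
#' Writes the internal-unit table with `[ng/m3]` suffixes so that a
#' write/read round trip is the identity.
#'
#' @param data A species table as returned by [read_species_table()] or
#'   [simulate_campaign()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_species_table <- function(data, path) {
  stopifnot(names(data)[1] == "timestamp")
  out <- data
  names(out)[-1] <- paste0(names(out)[-1], " [ng/m3]")
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Extract the numeric species matrix from a species table
#'
#' @param data A species table (timestamp + species columns).
#' @param species Optional character vector selecting/ordering columns.
#' @return A numeric matrix (samples x species) with column names.
#' @export
species_matrix <- function(data, species = NULL) {
  cols <- setdiff(names(data), "timestamp")
  if (!is.null(species)) {
    missing <- setdiff(species, cols)
    if (length(missing)) {
      abort(sprintf("species not present in table: %s",
                    paste(missing, collapse = ", ")))
    }
    cols <- species
  }
  m <- as.matrix(data[cols])
  storage.mode(m) <- "double"
  rownames(m) <- NULL
  m
}
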