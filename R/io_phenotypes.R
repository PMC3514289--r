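#' Read a per-individual phenotype table
#'
#' Parses a tab-separated phenotype table with one row per individual
#' (site, habitat, sex, calendar-year age class, centroid size, mass,
#' fecundity, clutch dry mass, lateral plate morph). Column names in the
#' file are mapped to the canonical field names through `dialect`, so
#' tables with arbitrary headers can be declared without code change.
#'
#' Canonical fields: `individual_id`, `site`, `system`, `habitat`, `sex`,
#' `sampling_year`, `age_calendar_year`, `centroid_size`, `mass`,
#' `fecundity`, `clutch_dry_mass`, `plate_morph`. Only `individual_id`,
#' `site` and `habitat` are mandatory. Empty cells and the literal string
#' `"NA"` are read as missing; missing values are never silently coerced
#' to zero.
#'
#' @param path Path to a TSV file with a header row.
#' @param dialect Named list mapping canonical field names to the column
#'   names used in the file (fields not listed are looked up under their
#'   canonical name). The logical entry `coerce_invalid` (default FALSE)
#'   controls whether unparseable numeric cells become missing with a
#'   warning instead of an error.
#' @return A data frame with the canonical columns, one row per
#'   individual. `habitat` is one of `"lake"`, `"stream"`, `"marine"`;
#'   `sex` is `"M"`, `"F"` or `"unknown"`.
#' @export
read_phenotypes <- function(path, dialect = list()) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  coerce <- isTRUE(dialect$coerce_invalid)
  dialect$coerce_invalid <- NULL

  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("", "NA"), colClasses = "character")
  fields <- c("individual_id", "site", "system", "habitat", "sex",
              "sampling_year", "age_calendar_year", "centroid_size", "mass",
              "fecundity", "clutch_dry_mass", "plate_morph")
  colmap <- stats::setNames(fields, fields)
  for (f in names(dialect)) {
    if (!f %in% fields) stop("unknown dialect field: ", f)
    colmap[[f]] <- dialect[[f]]
  }
  mandatory <- c("individual_id", "site", "habitat")
  for (f in mandatory) {
    if (!colmap[[f]] %in% names(raw))
      stop("phenotype table is missing mandatory column '", colmap[[f]],
           "' (field ", f, ")")
  }

  n <- nrow(raw)
  get_chr <- function(f) {
    if (colmap[[f]] %in% names(raw)) as.character(raw[[colmap[[f]]]])
    else rep(NA_character_, n)
  }
  get_num <- function(f, integer = FALSE) {
    x <- get_chr(f)
    out <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(out)
    if (any(bad)) {
      if (!coerce)
        stop("unparseable numeric value(s) in column '", colmap[[f]], "': ",
             paste(unique(x[bad]), collapse = ", "))
      warning("coerced ", sum(bad), " unparseable value(s) in '",
              colmap[[f]], "' to missing")
    }
    if (integer) out <- as.integer(round(out))
    out
  }

  rec <- data.frame(
    individual_id = get_chr("individual_id"),
    site = get_chr("site"),
    system = get_chr("system"),
    habitat = get_chr("habitat"),
    sex = get_chr("sex"),
    sampling_year = get_num("sampling_year", integer = TRUE),
    age_calendar_year = get_num("age_calendar_year", integer = TRUE),
    centroid_size = get_num("centroid_size"),
    mass = get_num("mass"),
    fecundity = get_num("fecundity"),
    clutch_dry_mass = get_num("clutch_dry_mass"),
    plate_morph = get_chr("plate_morph"),
    stringsAsFactors = FALSE
  )
  if (n == 0) return(rec)

  bad_hab <- !is.na(rec$habitat) & !rec$habitat %in% .habitats
  if (any(bad_hab))
    stop("unknown habitat label(s): ",
         paste(unique(rec$habitat[bad_hab]), collapse = ", "))
  if (any(is.na(rec$habitat)))
    stop("missing habitat for individual(s): ",
         paste(utils::head(rec$individual_id[is.na(rec$habitat)], 5),
               collapse = ", "))
  rec$sex[is.na(rec$sex)] <- "unknown"
  bad_sex <- !rec$sex %in% .sexes
  if (any(bad_sex))
    stop("unknown sex label(s): ", paste(unique(rec$sex[bad_sex]), collapse = ", "))
  bad_pm <- !is.na(rec$plate_morph) & !rec$plate_morph %in% .plate_morphs
  if (any(bad_pm))
    stop("unknown plate morph label(s): ",
         paste(unique(rec$plate_morph[bad_pm]), collapse = ", "))
  bad_age <- !is.na(rec$age_calendar_year) & rec$age_calendar_year < 1
  if (any(bad_age)) stop("age_calendar_year must be >= 1 when present")
  for (f in c("centroid_size", "mass")) {
    bad <- !is.na(rec[[f]]) & rec[[f]] <= 0
    if (any(bad)) stop(f, " must be > 0 when present")
  }
  for (f in c("fecundity", "clutch_dry_mass")) {
    bad <- !is.na(rec[[f]]) & rec[[f]] < 0
    if (any(bad)) stop(f, " must be >= 0 when present")
  }
  rec
}

#' Write a phenotype table to TSV
#'
#' Deterministic inverse of [read_phenotypes()] under the default dialect:
#' missing values are written as empty cells.
#'
#' @param records Data frame as returned by [read_phenotypes()] or
#'   [gen_phenotypes()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
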