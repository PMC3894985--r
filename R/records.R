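#' @rdname read_records
#' @section File format:
#' The main table has one row per field-year and columns
#' `field_id`, `year`, `species` (`pima` or `upland`), `yield_kg_ha`,
#' `prior_crop_1` ... `prior_crop_10` (crop grown 1..10 years before the
#' focal season; `prior_crop_1` is the year immediately before), and
#' `adj_<crop>` for each of the 15 crops (number of the 8 adjacent fields
#' planted with that crop). Missing values are empty cells. Sweep-net
#' samples live in a companion long table with columns `field_id`, `year`,
#' `day_of_year`, `density_per_sweep`.
NULL

fields_schema <- function() {
  c("field_id", "year", "species", "yield_kg_ha",
    paste0("prior_crop_", 1:10),
    paste0("adj_", crop_vocabulary()))
}

lygus_schema <- function() {
  c("field_id", "year", "day_of_year", "density_per_sweep")
}

#' Construct a field-year record set
#'
#' Bundles the rectangular field-year table and the long Lygus sweep-sample
#' table into a single object of class `fy_records`. Structural checks
#' (column names and basic types) are enforced here; the scientific
#' invariants are checked by [validate_records()], which reports rather
#' than errors.
#'
#' @param fields Data frame following the main-table schema (see
#'   [read_records()]).
#' @param lygus Data frame of sweep samples (`field_id`, `year`,
#'   `day_of_year`, `density_per_sweep`). May be empty.
#' @return An object of class `fy_records`: a list with elements `fields`
#'   and `lygus`, both tibbles.
#' @export
fy_records <- function(fields, lygus = NULL) {
  fields <- tibble::as_tibble(fields)
  missing_cols <- setdiff(fields_schema(), names(fields))
  if (length(missing_cols) > 0) {
    stop("fields table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  fields <- fields[fields_schema()]
  fields$field_id <- as.character(fields$field_id)
  fields$year <- as.integer(fields$year)
  fields$species <- as.character(fields$species)
  fields$yield_kg_ha <- as.numeric(fields$yield_kg_ha)
  for (cc in paste0("prior_crop_", 1:10)) fields[[cc]] <- as.character(fields[[cc]])
  for (cc in paste0("adj_", crop_vocabulary())) fields[[cc]] <- as.integer(fields[[cc]])

  if (is.null(lygus)) {
    lygus <- tibble::tibble(field_id = character(), year = integer(),
                            day_of_year = integer(), density_per_sweep = numeric())
  }
  lygus <- tibble::as_tibble(lygus)
  missing_cols <- setdiff(lygus_schema(), names(lygus))
  if (length(missing_cols) > 0) {
    stop("lygus table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  lygus <- lygus[lygus_schema()]
  lygus$field_id <- as.character(lygus$field_id)
  lygus$year <- as.integer(lygus$year)
  lygus$day_of_year <- as.integer(lygus$day_of_year)
  lygus$density_per_sweep <- as.numeric(lygus$density_per_sweep)

  structure(list(fields = fields, lygus = lygus), class = "fy_records")
}

#' @export
print.fy_records <- function(x, ...) {
  cat("<fy_records> ", nrow(x$fields), " field-year records, ",
      length(unique(x$fields$field_id)), " fields, ",
      nrow(x$lygus), " sweep samples\n", sep = "")
  invisible(x)
}

#' Read and write field-year record CSV files
#'
#' `read_records()` reads the main field-year table and (optionally) the
#' companion Lygus sample table, validates them against the documented
#' schema, and returns an [fy_records] object. Empty cells become `NA`.
#' A malformed cell is an error naming the row and column; a crop name
#' outside the closed 15-crop vocabulary is an error listing the
#' vocabulary. `write_records()` is its inverse; reading a written file
#' recovers the same logical table.
#'
#' @param path Path of the main field-year CSV.
#' @param lygus_path Path of the Lygus sample CSV, or `NULL` for none.
#' @param records An `fy_records` object.
#' @return `read_records()` returns an `fy_records` object;
#'   `write_records()` returns `invisible(NULL)`.
#' @export
read_records <- function(path, lygus_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  spec <- readr::cols(
    field_id = readr::col_character(),
    year = readr::col_integer(),
    species = readr::col_character(),
    yield_kg_ha = readr::col_double(),
    .default = readr::col_character()
  )
  for (cc in paste0("adj_", crop_vocabulary())) {
    spec$cols[[cc]] <- readr::col_integer()
  }
  fields <- suppressWarnings(
    readr::read_csv(path, col_types = spec, na = "",
                    progress = FALSE, show_col_types = FALSE))
  .stop_on_problems(fields, path)
  missing_cols <- setdiff(fields_schema(), names(fields))
  if (length(missing_cols) > 0) {
    stop("header of ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (cc in paste0("prior_crop_", 1:10)) {
    bad <- which(!is.na(fields[[cc]]) & !(fields[[cc]] %in% crop_vocabulary()))
    if (length(bad) > 0) {
      stop("unknown crop name '", fields[[cc]][bad[1]], "' in column ", cc,
           ", row ", bad[1], "; the crop vocabulary is: ",
           paste(crop_vocabulary(), collapse = ", "))
    }
  }
  bad <- which(!is.na(fields$species) & !(fields$species %in% c("pima", "upland")))
  if (length(bad) > 0) {
    stop("unknown species '", fields$species[bad[1]], "' in row ", bad[1],
         "; must be 'pima' or 'upland'")
  }

  lygus <- NULL
  if (!is.null(lygus_path)) {
    if (!file.exists(lygus_path)) stop("no such file: ", lygus_path)
    lygus <- suppressWarnings(readr::read_csv(
      lygus_path,
      col_types = readr::cols(
        field_id = readr::col_character(),
        year = readr::col_integer(),
        day_of_year = readr::col_integer(),
        density_per_sweep = readr::col_double()
      ),
      na = "", progress = FALSE, show_col_types = FALSE
    ))
    .stop_on_problems(lygus, lygus_path)
    missing_cols <- setdiff(lygus_schema(), names(lygus))
    if (length(missing_cols) > 0) {
      stop("header of ", lygus_path, " is missing column(s): ",
           paste(missing_cols, collapse = ", "))
    }
  }
  fy_records(fields, lygus)
}

.stop_on_problems <- function(tbl, path) {
  pr <- readr::problems(tbl)
  if (nrow(pr) > 0) {
    stop("malformed value in ", path, ": row ", pr$row[1], ", column ",
         pr$col[1], " (expected ", pr$expected[1], ", got '", pr$actual[1], "')")
  }
}

#' @rdname read_records
#' @export
write_records <- function(records, path, lygus_path = NULL) {
  stopifnot(inherits(records, "fy_records"))
  readr::write_csv(records$fields, path, na = "")
  if (!is.null(lygus_path)) {
    readr::write_csv(records$lygus, lygus_path, na = "")
  }
  invisible(NULL)
}

#' Validate a record set against its invariants
#'
#' Checks every field-year record against the data-model invariants and
#' returns a report of violations; it never throws. The checks are:
#' species is `pima` or `upland`; yield, when present, is finite and
#' positive; every rotation-history entry is in the crop vocabulary or
#' missing; surrounding counts, when present, are non-negative and sum to
#' at most 8 (the 8 adjacent fields); sweep-sample days are strictly
#' increasing with finite, non-negative densities; and `(field_id, year)`
#' pairs are unique.
#'
#' @param records An [fy_records] object.
#' @return Tibble with one row per violation (`row`, `field_id`, `year`,
#'   `rule`, `detail`); zero rows if and only if all records are valid.
#' @export
validate_records <- function(records) {
  stopifnot(inherits(records, "fy_records"))
  f <- records$fields
  out <- list()
  add <- function(row, rule, detail) {
    out[[length(out) + 1]] <<- tibble::tibble(
      row = row, field_id = f$field_id[row], year = f$year[row],
      rule = rule, detail = detail)
  }

  dup <- duplicated(f[c("field_id", "year")])
  for (i in which(dup)) add(i, "duplicate_field_year", "field-year appears more than once")

  adj_cols <- paste0("adj_", crop_vocabulary())
  prior_cols <- paste0("prior_crop_", 1:10)
  for (i in seq_len(nrow(f))) {
    if (is.na(f$species[i]) || !(f$species[i] %in% c("pima", "upland"))) {
      add(i, "species", paste0("species is '", f$species[i], "', not pima/upland"))
    }
    y <- f$yield_kg_ha[i]
    if (!is.na(y) && (!is.finite(y) || y <= 0)) {
      add(i, "yield_positive", paste0("yield_kg_ha = ", y, " is not finite and > 0"))
    }
    pc <- unlist(f[i, prior_cols], use.names = FALSE)
    bad <- pc[!is.na(pc) & !(pc %in% crop_vocabulary())]
    if (length(bad) > 0) {
      add(i, "crop_vocabulary", paste0("unknown crop(s): ", paste(bad, collapse = ", ")))
    }
    adj <- unlist(f[i, adj_cols], use.names = FALSE)
    if (any(!is.na(adj))) {
      known <- adj[!is.na(adj)]
      if (any(known < 0)) add(i, "adjacency_nonnegative", "negative surrounding count")
      s <- sum(known)
      if (s > 8) add(i, "adjacency_sum", paste0("surrounding counts sum to ", s, " > 8"))
    }
  }

  lg <- records$lygus
  if (nrow(lg) > 0) {
    key <- paste(lg$field_id, lg$year)
    fkey <- paste(f$field_id, f$year)
    by_key <- split(seq_len(nrow(lg)), key)
    for (k in names(by_key)) {
      idx <- by_key[[k]]
      row <- match(k, fkey)
      d <- lg$day_of_year[idx]
      dens <- lg$density_per_sweep[idx]
      if (is.na(row)) {
        out[[length(out) + 1]] <- tibble::tibble(
          row = NA_integer_, field_id = lg$field_id[idx[1]], year = lg$year[idx[1]],
          rule = "orphan_samples", detail = "samples with no matching field-year record")
        next
      }
      if (any(diff(d) <= 0)) add(row, "sample_days_increasing",
                                 "sample days not strictly increasing")
      if (any(!is.finite(dens) | dens < 0)) add(row, "density_nonnegative",
                                                "density not finite and >= 0")
    }
  }

  if (length(out) == 0) {
    tibble::tibble(row = integer(), field_id = character(), year = integer(),
                   rule = character(), detail = character())
  } else {
    do.call(rbind, out)
  }
}

#' Extract the sweep samples for one field-year
#'
#' @param records An [fy_records] object.
#' @param field_id,year Identify the record.
#' @return Tibble of that record's samples, ordered by day.
#' @keywords internal
lygus_samples_for <- function(records, field_id, year) {
  lg <- records$lygus
  s <- lg[lg$field_id == field_id & lg$year == year, ]
  s[order(s$day_of_year), ]
}
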