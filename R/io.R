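#' Read a long-format diet table
#'
#' Reads a CSV with one row per prey item recovered from a stomach. The
#' canonical columns are `lake_id`, `fish_id`, `prey_order` (taxonomic order),
#' `life_stage` (`juvenile`/`adult`/`unknown`), `habitat`
#' (`aquatic`/`terrestrial`/`unknown`) and `length_mm`. Header matching is
#' case-insensitive, and `col_map` can rename arbitrary file columns onto the
#' canonical schema (names = canonical, values = file column names).
#'
#' Prey too digested to identify or measure carry an empty `length_mm` cell,
#' which becomes `NA`; sentinel numerics are rejected because a silent 0 or -1
#' corrupts every downstream variance.
#'
#' @param path Path to a CSV file (RFC 4180, UTF-8).
#' @param col_map Optional named character vector mapping canonical column
#'   names to the file's column names.
#' @return A tibble with the six canonical columns, one row per prey item,
#'   row order preserved. `life_stage` and `habitat` are lower-case with
#'   missing values coded `"unknown"`.
#' @export
#' @examples
#' path <- system.file("extdata", "example_diet.csv", package = "nichevar")
#' read_diet_csv(path)
read_diet_csv <- function(path, col_map = NULL) {
  raw <- read_mapped_csv(path, col_map,
    required = c("lake_id", "fish_id", "prey_order", "life_stage",
                 "habitat", "length_mm"))
  out <- tibble::tibble(
    lake_id = as.character(raw$lake_id),
    fish_id = as.character(raw$fish_id),
    prey_order = as.character(raw$prey_order),
    life_stage = normalize_level(raw$life_stage, c("juvenile", "adult")),
    habitat = normalize_level(raw$habitat, c("aquatic", "terrestrial")),
    length_mm = parse_length(raw$length_mm)
  )
  bad <- which(!is.na(out$length_mm) & out$length_mm <= 0)
  if (length(bad) > 0) {
    abort_validation(paste0(
      "non-positive prey length_mm at row(s) ",
      paste(utils::head(bad, 5), collapse = ", "),
      " (missing lengths must be empty cells, not sentinels)"))
  }
  out
}

#' Read a per-fish table
#'
#' One row per fish: `fish_id`, `lake_id`, `standard_length_mm`, `wet_mass_g`,
#' `d13C`, `d15N` (per-mil). Isotope values may be jointly absent for a fish
#' but never singly; sizes must be positive.
#'
#' @inheritParams read_diet_csv
#' @return A tibble, one row per fish.
#' @export
read_fish_csv <- function(path, col_map = NULL) {
  raw <- read_mapped_csv(path, col_map,
    required = c("fish_id", "lake_id", "standard_length_mm", "wet_mass_g",
                 "d13C", "d15N"))
  out <- tibble::tibble(
    fish_id = as.character(raw$fish_id),
    lake_id = as.character(raw$lake_id),
    standard_length_mm = as.numeric(raw$standard_length_mm),
    wet_mass_g = as.numeric(raw$wet_mass_g),
    d13C = as.numeric(raw$d13C),
    d15N = as.numeric(raw$d15N)
  )
  if (anyDuplicated(paste(out$lake_id, out$fish_id))) {
    abort_validation("duplicate fish_id within a lake in fish table")
  }
  if (any(out$standard_length_mm <= 0 | out$wet_mass_g <= 0, na.rm = TRUE)) {
    abort_validation("standard_length_mm and wet_mass_g must be positive")
  }
  half <- xor(is.na(out$d13C), is.na(out$d15N))
  if (any(half)) {
    abort_validation(paste0(
      "d13C and d15N must be jointly present or jointly absent; offending fish: ",
      paste(utils::head(out$fish_id[half], 5), collapse = ", ")))
  }
  out
}

#' Read a per-lake table
#'
#' One row per lake: `lake_id`, `elevation_m`, `area_ha` (both positive,
#' finite).
#'
#' @inheritParams read_diet_csv
#' @return A tibble, one row per lake.
#' @export
read_lake_csv <- function(path, col_map = NULL) {
  raw <- read_mapped_csv(path, col_map,
    required = c("lake_id", "elevation_m", "area_ha"))
  out <- tibble::tibble(
    lake_id = as.character(raw$lake_id),
    elevation_m = as.numeric(raw$elevation_m),
    area_ha = as.numeric(raw$area_ha)
  )
  if (anyDuplicated(out$lake_id)) abort_validation("duplicate lake_id")
  ok <- is.finite(out$elevation_m) & is.finite(out$area_ha) & out$area_ha > 0
  if (!all(ok)) abort_validation("elevation_m and area_ha must be finite and area positive")
  out
}

# Shared CSV reader: case-insensitive header match plus optional user mapping.
read_mapped_csv <- function(path, col_map, required) {
  if (!file.exists(path)) abort_schema(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  nm <- names(raw)
  if (!is.null(col_map)) {
    if (is.null(names(col_map)) || any(names(col_map) == "")) {
      abort_config("col_map must be a named character vector (canonical = file column)")
    }
    hit <- match(tolower(col_map), tolower(nm))
    if (anyNA(hit)) {
      abort_schema(paste0("col_map refers to missing column(s): ",
                          paste(col_map[is.na(hit)], collapse = ", ")))
    }
    nm[hit] <- names(col_map)
  }
  idx <- match(tolower(required), tolower(nm))
  if (anyNA(idx)) {
    abort_schema(paste0("missing required column(s): ",
                        paste(required[is.na(idx)], collapse = ", ")))
  }
  out <- raw[, idx]
  names(out) <- required
  out
}

normalize_level <- function(x, levels) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x) | x == ""] <- "unknown"
  bad <- !(x %in% c(levels, "unknown"))
  if (any(bad)) {
    abort_validation(paste0("invalid level(s): ",
                            paste(unique(x[bad]), collapse = ", "),
                            "; expected one of ",
                            paste(c(levels, "unknown"), collapse = "/")))
  }
  x
}

parse_length <- function(x) {
  x <- trimws(as.character(x))
  x[x == "" | toupper(x) == "NA"] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  unparseable <- !is.na(x) & is.na(out)
  # unparseable text means "too digested to measure": record as absent
  out[unparseable] <- NA_real_
  out
}
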