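#' Registered element symbols
#'
#' The default element registry covers the five metals the pipeline was built
#' around: Cu, Pb, Cr, Cd and Ni. Every dataset and reference table row must
#' reference a registered symbol; pass a longer vector to the readers and
#' constructors to extend the registry.
#'
#' @return Character vector of element symbols.
#' @export
default_elements <- function() {
  c("Cu", "Pb", "Cr", "Cd", "Ni")
}

assert_elements <- function(x, elements, context = "dataset") {
  bad <- setdiff(unique(x), elements)
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "Unregistered element symbol(s) in %s: %s (registered: %s)",
      context, paste(bad, collapse = ", "), paste(elements, collapse = ", ")
    ))
  }
  invisible(x)
}

#' Brewing specification
#'
#' Fixed conditions under which made tea is brewed into infusion. The default
#' is the 7 g / 150 mL / 10 min protocol used throughout the package; steep
#' time is carried as metadata only (no leaching kinetics are modelled).
#'
#' @param tea_mass_g Mass of made tea brewed, grams. Must be > 0.
#' @param water_volume_l Volume of water (= infusion volume), litres. Must be > 0.
#' @param steep_time_min Steeping time, minutes (metadata only).
#' @return An object of class `brewing_spec`.
#' @export
#' @examples
#' brewing_spec() # 7 g in 150 mL for 10 min
brewing_spec <- function(tea_mass_g = 7, water_volume_l = 0.150,
                         steep_time_min = 10) {
  if (!is.numeric(tea_mass_g) || length(tea_mass_g) != 1 || tea_mass_g <= 0) {
    abort_validation("`tea_mass_g` must be a single value > 0")
  }
  if (!is.numeric(water_volume_l) || length(water_volume_l) != 1 ||
      water_volume_l <= 0) {
    abort_validation("`water_volume_l` must be a single value > 0")
  }
  structure(
    list(tea_mass_g = tea_mass_g, water_volume_l = water_volume_l,
         steep_time_min = steep_time_min),
    class = "brewing_spec"
  )
}

#' @rdname brewing_spec
#' @export
default_brewing <- function() brewing_spec()

#' @export
print.brewing_spec <- function(x, ...) {
  cat(sprintf("<brewing_spec> %g g tea in %g L water, %g min steep\n",
              x$tea_mass_g, x$water_volume_l, x$steep_time_min))
  invisible(x)
}

valid_matrices <- c("made_tea", "infusion", "blank", "spike")

#' Unit of a measurement matrix
#'
#' Made tea concentrations are per dry mass (mg/kg, numerically equal to
#' microgram/g); infusion, blank and spike concentrations are per volume (ug/L). The
#' matrix tag carries the unit, so mixing the two scales without an explicit
#' conversion is impossible by construction.
#'
#' @param matrix One of `"made_tea"`, `"infusion"`, `"blank"`, `"spike"`.
#' @return Unit string.
#' @export
matrix_unit <- function(matrix) {
  match.arg(matrix, valid_matrices)
  if (matrix == "made_tea") "mg/kg" else "ug/L"
}

#' Construct a concentration dataset
#'
#' Validates and wraps a long-format table of per-sample, per-element
#' measurements. Censored measurements (below detection) carry `NA` in
#' `value` until a substitution policy is applied with
#' [substitute_censored()].
#'
#' @param measurements Data frame with columns `sample_id`, `element`,
#'   `matrix`, `value`, `censored`.
#' @param brewing A [brewing_spec()] describing how infusions were prepared.
#' @param elements Registered element symbols.
#' @return A tibble of class `conc_dataset` with the brewing spec attached as
#'   an attribute.
#' @export
concentration_dataset <- function(measurements, brewing = default_brewing(),
                                  elements = default_elements()) {
  required <- c("sample_id", "element", "matrix", "value", "censored")
  missing_cols <- setdiff(required, names(measurements))
  if (length(missing_cols) > 0) {
    abort_format(sprintf("measurements lack column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  m <- tibble::as_tibble(measurements)[required]
  m$sample_id <- as.character(m$sample_id)
  m$element <- as.character(m$element)
  m$matrix <- as.character(m$matrix)
  m$value <- as.numeric(m$value)
  m$censored <- as.logical(m$censored)

  assert_elements(m$element, elements)
  bad_matrix <- setdiff(unique(m$matrix), valid_matrices)
  if (length(bad_matrix) > 0) {
    abort_validation(sprintf("Unknown matrix tag(s): %s",
                             paste(bad_matrix, collapse = ", ")))
  }
  # censored rows may be NA (pre-substitution) or carry the substituted
  # value (the flag is kept for provenance); uncensored rows must have one
  if (any(!m$censored & is.na(m$value))) {
    abort_validation("Uncensored measurements must carry a value")
  }
  neg <- which(!is.na(m$value) & m$value < 0)
  if (length(neg) > 0) {
    abort_validation(sprintf(
      "Negative concentration in row %d (sample %s, element %s)",
      neg[1], m$sample_id[neg[1]], m$element[neg[1]]))
  }
  key <- paste(m$sample_id, m$element, m$matrix, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort_validation(sprintf(
      "Duplicate (sample_id, element, matrix) measurement: %s",
      gsub("\r", " / ", dup)))
  }

  structure(m, class = c("conc_dataset", class(tibble::tibble())),
            brewing = brewing, elements = elements)
}

#' Read a long-format concentration CSV
#'
#' Expects columns `sample_id`, `element`, `value`; `value` is either a
#' nonnegative number or the censoring token (default `"ND"`) marking a
#' below-detection measurement.
#'
#' @param path CSV file path.
#' @param matrix Matrix tag applied to every row (the file stores one matrix;
#'   its unit follows from [matrix_unit()]).
#' @param nd_token Token marking censored values.
#' @param brewing,elements See [concentration_dataset()].
#' @return A `conc_dataset`.
#' @export
read_concentrations <- function(path, matrix, nd_token = "ND",
                                brewing = default_brewing(),
                                elements = default_elements()) {
  matrix <- match.arg(matrix, valid_matrices)
  if (!file.exists(path)) {
    abort_validation(sprintf("File not found: %s", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("sample_id", "element", "value")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort_format(sprintf("%s lacks column(s): %s", path,
                         paste(missing_cols, collapse = ", ")))
  }
  censored <- !is.na(raw$value) & raw$value == nd_token
  value <- suppressWarnings(as.numeric(raw$value))
  value[censored] <- NA_real_
  unparsed <- which(!censored & is.na(value) & !is.na(raw$value))
  if (length(unparsed) > 0) {
    abort_format(sprintf(
      "Row %d of %s: value '%s' is neither numeric nor the '%s' token",
      unparsed[1], path, raw$value[unparsed[1]], nd_token))
  }
  concentration_dataset(
    tibble::tibble(sample_id = raw$sample_id, element = raw$element,
                   matrix = matrix, value = value, censored = censored),
    brewing = brewing, elements = elements
  )
}

#' Write a concentration dataset to CSV
#'
#' Inverse of [read_concentrations()]: writes `sample_id`, `element`, `value`
#' with censored values rendered as the censoring token. Numeric values use
#' shortest round-trip formatting, so a write/read cycle reproduces them
#' bit-for-bit.
#'
#' @param dataset A `conc_dataset`.
#' @param path Output CSV path.
#' @param nd_token Token written for censored values.
#' @return `path`, invisibly.
#' @export
write_concentrations <- function(dataset, path, nd_token = "ND") {
  out <- tibble::tibble(
    sample_id = dataset$sample_id,
    element = dataset$element,
    value = ifelse(dataset$censored, nd_token,
                   vapply(dataset$value, format_roundtrip, character(1)))
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# shortest decimal representation that round-trips a double
format_roundtrip <- function(x) {
  if (is.na(x)) return(NA_character_)
  for (digits in 1:17) {
    s <- formatC(x, digits = digits, format = "g")
    if (as.numeric(s) == x) return(s)
  }
  formatC(x, digits = 17, format = "g")
}

#' Toxicological reference table for the five default elements
#'
#' Oral reference doses (RfD, microgram per kg body weight per day), oral
#' carcinogenic slope factors (Sf, per mg per kg body weight per day; `NA`
#' for the non-carcinogens Cu and Ni) and oral bioavailability fractions for
#' Cu, Pb, Cr, Cd and Ni, as compiled in the Tieguanyin tea survey whose
#' summary statistics ship as this package's defaults.
#'
#' @return Tibble with columns `element`, `rfd`, `sf`, `bioavailability`.
#' @export
#' @examples
#' default_toxref()
default_toxref <- function() {
  toxref_table(tibble::tibble(
    element = c("Cu", "Pb", "Cr", "Cd", "Ni"),
    rfd = c(40, 3.57, 3, 1, 20),
    sf = c(NA, 0.0085, 0.5, 6.3, NA),
    bioavailability = c(0.40, 0.60, 0.01, 0.50, 0.10)
  ))
}

#' Validate a toxicological reference table
#'
#' @param df Data frame with columns `element`, `rfd` (ug/kg bw/day),
#'   `sf` (per mg/kg bw/day, `NA` = non-carcinogen), `bioavailability`
#'   (fraction in (0, 1]).
#' @param elements Registered element symbols.
#' @return Validated tibble.
#' @export
toxref_table <- function(df, elements = default_elements()) {
  required <- c("element", "rfd", "sf", "bioavailability")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort_format(sprintf("toxref lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::as_tibble(df)[required]
  assert_elements(out$element, elements, "toxref")
  if (anyDuplicated(out$element)) {
    abort_validation("toxref elements must be unique")
  }
  if (any(is.na(out$rfd) | out$rfd <= 0)) {
    abort_validation("toxref rfd must be > 0")
  }
  if (any(!is.na(out$sf) & out$sf < 0)) {
    abort_validation("toxref sf must be >= 0 when present")
  }
  if (any(is.na(out$bioavailability) | out$bioavailability <= 0 |
            out$bioavailability > 1)) {
    abort_validation("toxref bioavailability must lie in (0, 1]")
  }
  out
}

#' Look up one element in a toxicological reference table
#'
#' @param toxref A table from [toxref_table()] or [default_toxref()].
#' @param element Element symbol.
#' @return One-row tibble.
#' @export
toxref_lookup <- function(toxref, element) {
  hit <- toxref[toxref$element == element, ]
  if (nrow(hit) != 1) {
    abort_validation(sprintf("Element %s not found in toxref", element))
  }
  hit
}

#' Read a toxicological reference table from CSV or YAML
#'
#' CSV needs columns `element`, `rfd`, `sf` (empty = non-carcinogen),
#' `bioavailability`; YAML a list of mappings with the same keys.
#'
#' @param path File path (`.csv`, `.yml` or `.yaml`).
#' @inheritParams toxref_table
#' @return Validated tibble.
#' @export
read_toxref <- function(path, elements = default_elements()) {
  if (!file.exists(path)) abort_validation(sprintf("File not found: %s", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    rows <- yaml::read_yaml(path)
    df <- dplyr::bind_rows(lapply(rows, function(r) {
      tibble::tibble(element = r$element, rfd = as.numeric(r$rfd),
                     sf = as.numeric(r$sf %||% NA),
                     bioavailability = as.numeric(r$bioavailability))
    }))
  } else {
    df <- readr::read_csv(path, col_types = readr::cols(
      element = "c", rfd = "d", sf = "d", bioavailability = "d"
    ), progress = FALSE)
  }
  toxref_table(df, elements)
}

#' Validate a table of consumption profiles
#'
#' A profile is a subpopulation's tea consumption habit, reduced internally to
#' the canonical ratio r = D / Bw (grams of made tea per kg body weight per
#' day). Either the ratio itself or the pair (daily tea mass D in g/day, body
#' weight Bw in kg) may be supplied.
#'
#' @param df Data frame with column `name` plus either `ratio_g_per_kg_day`
#'   or both `daily_tea_mass_g` and `body_weight_kg`.
#' @return Tibble with columns `name`, `ratio_g_per_kg_day` (plus the mass
#'   and weight columns when supplied).
#' @export
consumption_profiles <- function(df) {
  df <- tibble::as_tibble(df)
  if (!"name" %in% names(df)) abort_format("profiles need a `name` column")
  if (anyDuplicated(df$name)) abort_validation("profile names must be unique")
  has_ratio <- "ratio_g_per_kg_day" %in% names(df)
  has_pair <- all(c("daily_tea_mass_g", "body_weight_kg") %in% names(df))
  if (!has_ratio && !has_pair) {
    abort_format(
      "profiles need `ratio_g_per_kg_day` or both `daily_tea_mass_g` and `body_weight_kg`")
  }
  if (!has_ratio) {
    df$ratio_g_per_kg_day <- NA_real_
  }
  if (has_pair) {
    if (any(!is.na(df$body_weight_kg) & df$body_weight_kg <= 0)) {
      abort_validation("body_weight_kg must be > 0")
    }
    if (any(!is.na(df$daily_tea_mass_g) & df$daily_tea_mass_g < 0)) {
      abort_validation("daily_tea_mass_g must be >= 0")
    }
    fill <- is.na(df$ratio_g_per_kg_day)
    df$ratio_g_per_kg_day[fill] <-
      df$daily_tea_mass_g[fill] / df$body_weight_kg[fill]
  }
  if (any(is.na(df$ratio_g_per_kg_day) | df$ratio_g_per_kg_day < 0)) {
    abort_validation("every profile needs a nonnegative consumption ratio")
  }
  df
}

#' Read consumption profiles from CSV or YAML
#'
#' @param path File path; YAML holds a list of mappings with keys `name` and
#'   `ratio_g_per_kg_day` (or `daily_tea_mass_g` + `body_weight_kg`), CSV the
#'   same columns.
#' @return Validated profile tibble.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("File not found: %s", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    rows <- yaml::read_yaml(path)
    df <- dplyr::bind_rows(lapply(rows, function(r) {
      tibble::tibble(
        name = r$name,
        daily_tea_mass_g = as.numeric(r$daily_tea_mass_g %||% NA),
        body_weight_kg = as.numeric(r$body_weight_kg %||% NA),
        ratio_g_per_kg_day = as.numeric(r$ratio_g_per_kg_day %||% NA)
      )
    }))
  } else {
    df <- readr::read_csv(path, col_types = readr::cols(.default = "d",
                                                        name = "c"),
                          progress = FALSE)
  }
  consumption_profiles(df)
}
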