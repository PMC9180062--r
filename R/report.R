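#' Format a dimensionless quantity as percent in 2-significant-figure
#' scientific notation
#'
#' The reporting dialect for hazard quotients: the dimensionless HQ is
#' multiplied by 100 and rendered as `m x 10^e` with a 2-significant-figure
#' mantissa, e.g. `1.671e-4 -> "1.7 x 10^-2"` (percent).
#'
#' @param x Dimensionless fraction(s).
#' @param digits Significant figures of the mantissa.
#' @return Character vector.
#' @export
#' @examples
#' format_sci_percent(1.671e-4)
format_sci_percent <- function(x, digits = 2) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    pct <- v * 100
    if (pct == 0) return("0")
    e <- floor(log10(abs(pct)))
    m <- signif(pct / 10^e, digits)
    if (abs(m) >= 10) { m <- m / 10; e <- e + 1 }  # rounding carried a digit
    sprintf("%s × 10^%d", format(m, nsmall = digits - 1), e)
  }, character(1))
}

#' Risk report table (wide layout)
#'
#' One row per element plus an `HI` row; per profile, a column pair of HQ
#' and adjusted HQ rendered on the percent scale at 2 significant figures.
#' The HI row is computed from the full-precision sums, not from the
#' rendered cells.
#'
#' @param assessment A `risk_assessment` from [assess()].
#' @return Wide tibble of formatted strings.
#' @export
risk_report_table <- function(assessment) {
  ex <- assessment$exposure
  if (nrow(ex) == 0) abort_validation("assessment holds no exposure results")
  elements <- attr(assessment, "elements")
  profiles <- unique(ex$profile)
  out <- tibble::tibble(element = c(elements, "HI"))
  for (p in profiles) {
    sub <- ex[ex$profile == p, ]
    hz <- assessment$hazard[assessment$hazard$profile == p, ]
    out[[paste0(p, "_hq_pct")]] <- c(
      format_sci_percent(sub$hq[match(elements, sub$element)]),
      format_sci_percent(hz$hi))
    out[[paste0(p, "_adjusted_hq_pct")]] <- c(
      format_sci_percent(sub$adjusted_hq[match(elements, sub$element)]),
      format_sci_percent(hz$adjusted_hi))
  }
  out
}

#' Write a risk report
#'
#' Writes the wide HQ/HI table from [risk_report_table()] as CSV or a
#' markdown pipe table.
#'
#' @param assessment A `risk_assessment`.
#' @param path Output path.
#' @param format `"csv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_risk_report <- function(assessment, path,
                              format = c("csv", "markdown")) {
  format <- match.arg(format)
  tbl <- risk_report_table(assessment)
  if (format == "csv") {
    readr::write_csv(tbl, path, progress = FALSE)
  } else {
    lines <- c(
      paste0("| ", paste(names(tbl), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(tbl)), collapse = "|"), "|"),
      vapply(seq_len(nrow(tbl)), function(i) {
        paste0("| ", paste(unlist(tbl[i, ]), collapse = " | "), " |")
      }, character(1))
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Write a carcinogenic-risk report
#'
#' Long-format CSV of per-profile, per-element target risks, the
#' bioavailability-scaled variant, contribution fractions and the profile's
#' total.
#'
#' @param assessment A `risk_assessment`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cancer_report <- function(assessment, path) {
  if (nrow(assessment$cancer) == 0) {
    abort_validation("assessment holds no carcinogenic results")
  }
  tbl <- dplyr::left_join(assessment$cancer, assessment$cancer_total,
                          by = "profile")
  readr::write_csv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Write a transfer-rate report
#'
#' Per-element mean/SD/n table from [mean_transfer_rates()], as CSV (the
#' long form behind a transfer-rate bar chart).
#'
#' @param transfer_tbl Tibble from [mean_transfer_rates()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transfer_report <- function(transfer_tbl, path) {
  readr::write_csv(transfer_tbl, path, progress = FALSE)
  invisible(path)
}

#' Write a QC report
#'
#' @param qc_tbl Tibble from [qc_report()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc_tbl, path) {
  readr::write_csv(qc_tbl, path, progress = FALSE)
  invisible(path)
}

#' Machine-readable summary of a risk assessment
#'
#' @param assessment A `risk_assessment`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_risk_json <- function(assessment, path) {
  payload <- list(
    exposure = assessment$exposure,
    hazard = assessment$hazard,
    cancer = assessment$cancer,
    cancer_total = assessment$cancer_total,
    tr_threshold = attr(assessment, "tr_threshold")
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
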