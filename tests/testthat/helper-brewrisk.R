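# Agreement with a published value rounded to 2 significant figures:
# |x - printed| at most half a unit in the printed value's last significant
# digit (plus a float epsilon). Handles decade boundaries (e.g. 9.94e-3
# agrees with a printed 1.0e-2) that naive signif() string comparison fails.
agrees_2sf <- function(x, printed) {
  ulp <- 10^(floor(log10(abs(printed))) - 1)
  abs(x - printed) <= 0.5 * ulp * (1 + 1e-9) + 1e-15
}

expect_2sf <- function(x, printed) {
  expect_true(agrees_2sf(x, printed),
              label = sprintf("%.6g agrees with printed %.3g to 2 sf",
                              x, printed))
}

# parse the report dialect "4.7 × 10^-3" back to a number (percent scale)
parse_sci <- function(s) {
  as.numeric(sub(" × 10\\^", "e", s))
}

# small paired made-tea/infusion dataset built in code
toy_paired_dataset <- function(brewing = default_brewing()) {
  made <- tibble::tibble(
    sample_id = c("a", "b", "a", "b"),
    element = c("Cu", "Cu", "Pb", "Pb"),
    matrix = "made_tea",
    value = c(8, 10, 0.8, 1.0),
    censored = FALSE
  )
  inf <- tibble::tibble(
    sample_id = c("a", "b", "a", "b"),
    element = c("Cu", "Cu", "Pb", "Pb"),
    matrix = "infusion",
    value = infusion_concentration(made$value, c(0.10, 0.12, 0.30, 0.34),
                                  brewing),
    censored = FALSE
  )
  concentration_dataset(rbind(made, inf), brewing = brewing)
}
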