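#' Convert a molar specific flux to carbon-molar units
#'
#' Multiplies a specific rate (mmol/gDW/h) by the number of carbon atoms per
#' molecule, giving Cmmol/gDW/h — the unit used to compare substrates of
#' different carbon content.
#'
#' @param rate Specific flux in mmol/gDW/h, >= 0. Vectorized.
#' @param carbon_count Carbon atoms per molecule, integer >= 1. Vectorized.
#' @return Flux in Cmmol/gDW/h.
#' @examples
#' to_cmmol(5.2, 3) # DHA: 15.6 Cmmol/gDW/h
#' @export
to_cmmol <- function(rate, carbon_count) {
  if (any(!is.finite(rate)) || any(rate < 0)) {
    stop("`rate` must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(carbon_count)) || any(carbon_count < 1) ||
      any(carbon_count != round(carbon_count))) {
    stop("`carbon_count` must be a positive integer", call. = FALSE)
  }
  rate * carbon_count
}

#' Default carbon counts for the DHA co-consumption system
#'
#' @return Named integer vector: DHA 3, formate 1, glycolate 2, acetate 2.
#' @export
carbon_counts <- function() {
  c(DHA = 3, formate = 1, glycolate = 2, acetate = 2)
}

#' Partition total carbon uptake among co-consumed substrates
#'
#' Each substrate's share is its carbon-molar uptake rate divided by the
#' summed carbon-molar uptake over all substrates. Rates follow the
#' uptake-positive reporting convention.
#'
#' @param substrates A data frame with columns `name`, `rate` (mmol/gDW/h,
#'   >= 0) and `carbon_count` (atoms per molecule).
#' @return A tibble with `name`, `rate_mmol`, `rate_cmmol` and `share`
#'   (fractions summing to 1).
#' @examples
#' carbon_shares(tibble::tibble(
#'   name = c("DHA", "formate", "glycolate", "acetate"),
#'   rate = c(5.2, 3.2, 1.0, 0.1),
#'   carbon_count = c(3, 1, 2, 2)
#' ))
#' @export
carbon_shares <- function(substrates) {
  substrates <- tibble::as_tibble(substrates)
  required <- c("name", "rate", "carbon_count")
  missing_cols <- setdiff(required, names(substrates))
  if (length(missing_cols) > 0) {
    stop("`substrates` is missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(substrates) == 0) stop("need at least one substrate", call. = FALSE)
  cmmol <- to_cmmol(substrates$rate, substrates$carbon_count)
  total <- sum(cmmol)
  if (total <= 0) stop("all uptake rates are zero; shares undefined", call. = FALSE)
  tibble::tibble(
    name = substrates$name,
    rate_mmol = substrates$rate,
    rate_cmmol = cmmol,
    share = cmmol / total
  )
}
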