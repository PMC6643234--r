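#' Kinetic parameters for batch growth with abiotic degradation
#'
#' Bundles the parameters of the batch-culture model: initial biomass `x0`
#' (gDW/L), specific growth rate `mu` (1/h), an optional lag `t_lag` (h), and
#' one row per extracellular metabolite with its initial concentration `m0`
#' (mM), specific exchange flux `q` (mmol/gDW/h; positive = net production,
#' negative = net uptake) and first-order abiotic degradation constant `k`
#' (1/h).
#'
#' @param x0 Initial biomass concentration in gDW/L; must be > 0.
#' @param mu Specific growth rate in 1/h; must be >= 0.
#' @param t_lag Lag-phase duration in h; must be >= 0. During the lag the
#'   biomass is constant and biological exchange is inactive, but abiotic
#'   degradation still acts.
#' @param metabolites A data frame with columns `name`, `m0`, `q`, `k`
#'   (one row per metabolite), or `NULL` for a biomass-only model.
#'
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params(
#'   x0 = 0.0185, mu = 0.15,
#'   metabolites = tibble::tibble(name = "DHA", m0 = 15, q = -5.2, k = 0.0086)
#' )
#' @export
kinetic_params <- function(x0, mu, t_lag = 0, metabolites = NULL) {
  stopifnot(is.numeric(x0), length(x0) == 1, is.numeric(mu), length(mu) == 1,
            is.numeric(t_lag), length(t_lag) == 1)
  if (!is.finite(x0) || x0 <= 0) stop("`x0` must be a positive, finite biomass concentration", call. = FALSE)
  if (!is.finite(mu) || mu < 0) stop("`mu` must be a finite, nonnegative growth rate", call. = FALSE)
  if (!is.finite(t_lag) || t_lag < 0) stop("`t_lag` must be finite and nonnegative", call. = FALSE)

  if (is.null(metabolites)) {
    metabolites <- tibble::tibble(name = character(), m0 = numeric(),
                                  q = numeric(), k = numeric())
  }
  metabolites <- tibble::as_tibble(metabolites)
  required <- c("name", "m0", "q", "k")
  missing_cols <- setdiff(required, names(metabolites))
  if (length(missing_cols) > 0) {
    stop("`metabolites` is missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  metabolites <- metabolites[required]
  if (anyDuplicated(metabolites$name)) stop("metabolite names must be unique", call. = FALSE)
  if (any(!is.finite(metabolites$m0)) || any(metabolites$m0 < 0)) {
    stop("all `m0` must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(metabolites$k)) || any(metabolites$k < 0)) {
    stop("all `k` must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(metabolites$q))) stop("all `q` must be finite", call. = FALSE)

  structure(
    list(x0 = as.numeric(x0), mu = as.numeric(mu), t_lag = as.numeric(t_lag),
         metabolites = metabolites),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  cat(sprintf("  x0   : %.4g gDW/L\n", x$x0))
  cat(sprintf("  mu   : %.4g 1/h\n", x$mu))
  cat(sprintf("  t_lag: %.4g h\n", x$t_lag))
  if (nrow(x$metabolites) > 0) {
    cat("  metabolites:\n")
    print(x$metabolites)
  } else {
    cat("  (no metabolites)\n")
  }
  invisible(x)
}

#' @method tidy kinetic_params
#' @export
tidy.kinetic_params <- function(x, ...) {
  base <- tibble::tibble(
    term = c("x0", "mu", "t_lag"),
    estimate = c(x$x0, x$mu, x$t_lag),
    unit = c("gDW/L", "1/h", "h")
  )
  if (nrow(x$metabolites) > 0) {
    met <- tidyr::pivot_longer(x$metabolites, cols = c("m0", "q", "k"),
                               names_to = "what", values_to = "estimate")
    met <- dplyr::mutate(
      met,
      term = paste0(.data$what, "_", .data$name),
      unit = dplyr::case_when(
        .data$what == "m0" ~ "mM",
        .data$what == "q" ~ "mmol/gDW/h",
        TRUE ~ "1/h"
      )
    )
    base <- dplyr::bind_rows(base, met[c("term", "estimate", "unit")])
  }
  base
}

met_row <- function(params, name) {
  i <- match(name, params$metabolites$name)
  if (is.na(i)) {
    stop("unknown metabolite `", name, "`; available: ",
         paste(params$metabolites$name, collapse = ", "), call. = FALSE)
  }
  params$metabolites[i, ]
}

check_times <- function(times) {
  if (!is.numeric(times) || length(times) == 0) {
    stop("`times` must be a nonempty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("`times` must be finite and nonnegative", call. = FALSE)
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  invisible(times)
}
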