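#' Specification for a constraint-based (FBA/FVA) comparison
#'
#' Bundles a genome-scale model file with the mapping from measured
#' substrates to exchange reactions, the measured uptake rates, and the FVA
#' fraction of optimum. Exchange reactions follow the standard
#' uptake-negative convention: a measured uptake rate `u` becomes a lower
#' bound of `-u` on the exchange.
#'
#' @param model_path Path to an SBML (Level 3 + FBC) or BiGG-style JSON
#'   model.
#' @param uptake_rates Named vector of measured uptake rates (mmol/gDW/h,
#'   >= 0), names matching `exchange_map`.
#' @param exchange_map Named character vector mapping substrate names to
#'   exchange reaction identifiers. Defaults cover the DHA co-consumption
#'   system in iJO1366 naming.
#' @param objective Objective reaction id, or `NULL` to keep the model's own
#'   (typically the biomass reaction).
#' @param fraction_of_optimum FVA constraint: objective must stay at or above
#'   this fraction of its optimum. In (0, 1], default 0.95.
#' @param close_uptake Character vector of additional exchange reaction ids
#'   whose uptake should be shut (lower bound 0), e.g. the model's default
#'   carbon source; other exchanges keep the model's baseline bounds.
#' @return A list of class `fba_model_spec`.
#' @export
fba_model_spec <- function(model_path,
                           uptake_rates,
                           exchange_map = c(DHA = "EX_dha_e", formate = "EX_for_e",
                                            glycolate = "EX_glyclt_e", acetate = "EX_ac_e"),
                           objective = NULL,
                           fraction_of_optimum = 0.95,
                           close_uptake = character()) {
  if (!file.exists(model_path)) stop("model file not found: ", model_path, call. = FALSE)
  if (!is.numeric(uptake_rates) || is.null(names(uptake_rates))) {
    stop("`uptake_rates` must be a named numeric vector", call. = FALSE)
  }
  if (any(!is.finite(uptake_rates)) || any(uptake_rates < 0)) {
    stop("uptake rates must be finite and >= 0", call. = FALSE)
  }
  unknown <- setdiff(names(uptake_rates), names(exchange_map))
  if (length(unknown) > 0) {
    stop("no exchange mapping for: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(fraction_of_optimum) || fraction_of_optimum <= 0 ||
      fraction_of_optimum > 1) {
    stop("`fraction_of_optimum` must be in (0, 1]", call. = FALSE)
  }
  structure(list(model_path = model_path, uptake_rates = uptake_rates,
                 exchange_map = exchange_map, objective = objective,
                 fraction_of_optimum = fraction_of_optimum,
                 close_uptake = close_uptake),
            class = "fba_model_spec")
}

fba_worker_path <- function() {
  path <- system.file("python", "fba_worker.py", package = "batchflux")
  if (path == "") stop("bundled FBA worker script not found", call. = FALSE)
  path
}

#' Is the constraint-based analysis backend available?
#'
#' The FBA/FVA operations run on COBRApy through a bundled worker script;
#' this checks that a `python` interpreter with the `cobra` package is on the
#' PATH.
#'
#' @return `TRUE` or `FALSE`.
#' @export
fba_available <- function() {
  python <- Sys.which("python")
  if (python == "") return(FALSE)
  status <- suppressWarnings(system2(python, c("-c", shQuote("import cobra")),
                                     stdout = FALSE, stderr = FALSE))
  identical(status, 0L)
}

run_fba_worker <- function(job) {
  python <- Sys.which("python")
  if (python == "") stop("no `python` interpreter on PATH; FBA backend unavailable", call. = FALSE)
  job_path <- tempfile(fileext = ".json")
  out_path <- tempfile(fileext = ".json")
  on.exit(unlink(c(job_path, out_path)), add = TRUE)
  job$out <- out_path
  jsonlite::write_json(job, job_path, auto_unbox = TRUE, null = "null", digits = NA)
  err <- tempfile(fileext = ".txt")
  on.exit(unlink(err), add = TRUE)
  system2(python, c(fba_worker_path(), job_path), stdout = FALSE, stderr = err)
  if (!file.exists(out_path)) {
    stop("FBA worker produced no output; stderr:\n",
         paste(readLines(err, warn = FALSE), collapse = "\n"), call. = FALSE)
  }
  res <- jsonlite::read_json(out_path, simplifyVector = FALSE)
  if (!isTRUE(res$ok)) {
    stop("constraint-based analysis failed: ", res$error %||% "unknown error", call. = FALSE)
  }
  res
}

#' List the reactions of a metabolic model
#'
#' @param model_path SBML or BiGG JSON model file.
#' @return A tibble with `id`, `lower_bound`, `upper_bound`,
#'   `objective_coefficient`.
#' @export
inspect_fba_model <- function(model_path) {
  res <- run_fba_worker(list(model_path = model_path, mode = "inspect"))
  dplyr::bind_rows(lapply(res$reactions, function(r) {
    tibble::tibble(id = r$id, lower_bound = r$lower_bound,
                   upper_bound = r$upper_bound,
                   objective_coefficient = r$objective_coefficient)
  }))
}

#' Translate measured uptake rates into exchange-bound changes
#'
#' Validates the exchange mapping against the model and returns the bound
#' changes that constrain it: each measured substrate's exchange lower bound
#' is set to minus its uptake rate (upper bound untouched), and each reaction
#' in `close_uptake` gets a lower bound of 0.
#'
#' @param spec An [fba_model_spec()].
#' @return A tibble with `reaction`, `lower`, `upper` (NA = leave unchanged).
#' @export
apply_uptake_constraints <- function(spec) {
  stopifnot(inherits(spec, "fba_model_spec"))
  model <- inspect_fba_model(spec$model_path)
  mapped <- spec$exchange_map[names(spec$uptake_rates)]
  missing_rxn <- c(setdiff(mapped, model$id), setdiff(spec$close_uptake, model$id))
  if (length(missing_rxn) > 0) {
    candidates <- grep("^EX_", model$id, value = TRUE)
    stop("reaction(s) not in model: ", paste(missing_rxn, collapse = ", "),
         "; exchange reactions available include: ",
         paste(utils::head(candidates, 8), collapse = ", "),
         if (length(candidates) > 8) ", ..." else "", call. = FALSE)
  }
  dplyr::bind_rows(
    tibble::tibble(reaction = unname(mapped),
                   lower = -unname(spec$uptake_rates),
                   upper = NA_real_),
    tibble::tibble(reaction = setdiff(spec$close_uptake, mapped),
                   lower = 0, upper = NA_real_)
  )
}

bounds_payload <- function(changes) {
  lapply(seq_len(nrow(changes)), function(i) {
    list(reaction = changes$reaction[i],
         lower = if (is.na(changes$lower[i])) NULL else changes$lower[i],
         upper = if (is.na(changes$upper[i])) NULL else changes$upper[i])
  })
}

#' Flux balance analysis under measured uptake constraints
#'
#' Maximizes the objective (biomass by default) over steady-state
#' stoichiometry and bounds, with the exchange bounds of
#' [apply_uptake_constraints()] applied on top of the model's baseline.
#'
#' @param spec An [fba_model_spec()].
#' @return A list with `objective_value`, `fluxes` (tibble `reaction`,
#'   `flux`) and `status`.
#' @export
run_fba <- function(spec) {
  stopifnot(inherits(spec, "fba_model_spec"))
  changes <- apply_uptake_constraints(spec)
  res <- run_fba_worker(list(
    model_path = spec$model_path, mode = "fba",
    bounds = bounds_payload(changes), objective = spec$objective
  ))
  fluxes <- tibble::tibble(reaction = names(res$fluxes),
                           flux = as.numeric(unlist(res$fluxes)))
  list(objective_value = res$objective_value, fluxes = fluxes,
       status = res$status)
}

#' Flux variability analysis at a fraction of the optimum
#'
#' For each reaction, the minimum and maximum attainable flux while the
#' objective is held at or above `fraction_of_optimum` times its FBA optimum.
#'
#' @param spec An [fba_model_spec()].
#' @param reactions Reaction ids to scan; `NULL` for all.
#' @return A tibble with `reaction`, `minimum`, `maximum`, plus attributes
#'   `objective_value` and `fraction_of_optimum`.
#' @export
run_fva <- function(spec, reactions = NULL) {
  stopifnot(inherits(spec, "fba_model_spec"))
  changes <- apply_uptake_constraints(spec)
  res <- run_fba_worker(list(
    model_path = spec$model_path, mode = "fva",
    bounds = bounds_payload(changes), objective = spec$objective,
    reactions = reactions, fraction_of_optimum = spec$fraction_of_optimum
  ))
  out <- dplyr::bind_rows(lapply(names(res$fva), function(rid) {
    tibble::tibble(reaction = rid,
                   minimum = res$fva[[rid]]$minimum,
                   maximum = res$fva[[rid]]$maximum)
  }))
  attr(out, "objective_value") <- res$objective_value
  attr(out, "fraction_of_optimum") <- spec$fraction_of_optimum
  out
}

#' A minimal toy metabolic network for testing and demonstration
#'
#' One substrate exchange (uptake capacity `uptake`), two parallel internal
#' routes converting the substrate to a product, and a sink ("biomass")
#' consuming the product. The FBA optimum equals the uptake capacity, and at
#' any fraction of optimum below 1 each parallel route can individually span
#' the full range.
#'
#' @param uptake Maximum substrate uptake (mmol/gDW/h).
#' @return A nested list in BiGG JSON shape; write it with
#'   [write_fba_model()].
#' @export
toy_fba_model <- function(uptake = 10) {
  list(
    id = "toy_parallel_routes", version = "1",
    metabolites = list(
      list(id = "A_c", name = "substrate", compartment = "c"),
      list(id = "B_c", name = "product", compartment = "c")
    ),
    reactions = list(
      list(id = "EX_A", name = "substrate exchange",
           metabolites = list(A_c = -1), lower_bound = -uptake,
           upper_bound = 1000, gene_reaction_rule = ""),
      list(id = "R1", name = "route 1", metabolites = list(A_c = -1, B_c = 1),
           lower_bound = 0, upper_bound = 1000, gene_reaction_rule = ""),
      list(id = "R2", name = "route 2", metabolites = list(A_c = -1, B_c = 1),
           lower_bound = 0, upper_bound = 1000, gene_reaction_rule = ""),
      list(id = "BIOMASS", name = "biomass sink", metabolites = list(B_c = -1),
           lower_bound = 0, upper_bound = 1000, gene_reaction_rule = "",
           objective_coefficient = 1)
    ),
    genes = list(), compartments = list(c = "cytosol")
  )
}

#' Write a model list as a BiGG-style JSON file
#'
#' @param model A nested list as produced by [toy_fba_model()].
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_fba_model <- function(model, path) {
  jsonlite::write_json(model, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
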