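.response_column <- function(response) {
  if (response %in% c("jaccard", "aitchison")) paste0("similarity_", response)
  else response
}

.new_model_spec <- function(response, fixed_terms, interaction_terms,
                            member_columns, chains, iterations, warmup, seed) {
  stopifnot(warmup < iterations, chains >= 2)
  structure(
    list(response = response, fixed_terms = fixed_terms,
         interaction_terms = interaction_terms, member_columns = member_columns,
         chains = chains, iterations = iterations, warmup = warmup, seed = seed),
    class = "dyad_model_spec"
  )
}

#' @export
print.dyad_model_spec <- function(x, ...) {
  cat("dyad_model_spec\n  response:", x$response, "\n  fixed:",
      paste(x$fixed_terms, collapse = " + "), "\n")
  if (length(x$interaction_terms)) {
    cat("  interactions:",
        paste(vapply(x$interaction_terms, paste, "", collapse = ":"),
              collapse = ", "), "\n")
  }
  cat("  members:", paste(x$member_columns, collapse = ", "),
      "\n  sampler:", x$chains, "chains x", x$iterations, "iterations (",
      x$warmup, "warmup ), seed", x$seed, "\n")
  invisible(x)
}

#' Model specification for the wild hybrid-zone dataset
#'
#' Similarity response regressed on the five scaled pairwise predictors —
#' spatial distance, subspecies' genetic distance, difference in admixture
#' (hHe-dist), mean admixture (hHe-mean) and temporal distance — plus the
#' genetic-distance x hHe-dist interaction, which lets the admixture effect
#' vary along the gradient of subspecies divergence. Multi-membership random
#' effects over the two mice of each dyad.
#'
#' @param response `"jaccard"`, `"aitchison"`, or a dyad-table column name.
#' @param chains,iterations,warmup,seed Sampler settings (defaults: 4 chains,
#'   3000 iterations, 1000 warmup).
#' @return A `dyad_model_spec`.
#' @export
wild_model_spec <- function(response = "jaccard", chains = 4, iterations = 3000,
                            warmup = 1000, seed = 1) {
  .new_model_spec(
    response = .response_column(response),
    fixed_terms = c("spatial_dist_sc", "gen_dist_sc", "hhe_dist_sc",
                    "hhe_mean_sc", "temporal_dist_sc"),
    interaction_terms = list(c("gen_dist_sc", "hhe_dist_sc")),
    member_columns = c("ind_i", "ind_j"),
    chains = chains, iterations = iterations, warmup = warmup, seed = seed
  )
}

#' Model specification for the laboratory (infection) dataset
#'
#' Controlled-environment variant: no spatial or temporal terms; similarity is
#' regressed on subspecies' genetic distance, difference in admixture and
#' infection-status distance (pairs with equal status — both non-infected or
#' both infected — score 0, mixed pairs score 1). No interaction term.
#'
#' @inheritParams wild_model_spec
#' @return A `dyad_model_spec`.
#' @export
lab_model_spec <- function(response = "jaccard", chains = 4, iterations = 3000,
                           warmup = 1000, seed = 1) {
  .new_model_spec(
    response = .response_column(response),
    fixed_terms = c("gen_dist_sc", "hhe_dist_sc", "infection_dist_sc"),
    interaction_terms = list(),
    member_columns = c("ind_i", "ind_j"),
    chains = chains, iterations = iterations, warmup = warmup, seed = seed
  )
}

#' Model specification for the fungi-to-bacteria association model
#'
#' Tests whether fungal community composition predicts bacterial composition:
#' bacterial similarity is the response and the matched fungal similarity
#' (Jaccard with Jaccard, Aitchison with Aitchison) enters as a dyad-level
#' covariate — it is a property of the pair, not a membership term — while
#' controlling for genetic distance, hHe-dist, hHe-mean, spatial and temporal
#' distance. The dyad table must carry the scaled fungal-similarity column
#' `fungal_sim_sc` (built by [run_pipeline()] or by hand with
#' [scale_minmax()]).
#'
#' @inheritParams wild_model_spec
#' @return A `dyad_model_spec`.
#' @export
fungi_bacteria_model_spec <- function(response = "jaccard", chains = 4,
                                      iterations = 3000, warmup = 1000,
                                      seed = 1) {
  .new_model_spec(
    response = .response_column(response),
    fixed_terms = c("fungal_sim_sc", "gen_dist_sc", "hhe_dist_sc",
                    "hhe_mean_sc", "spatial_dist_sc", "temporal_dist_sc"),
    interaction_terms = list(),
    member_columns = c("ind_i", "ind_j"),
    chains = chains, iterations = iterations, warmup = warmup, seed = seed
  )
}

.spec_formula <- function(spec) {
  rhs <- spec$fixed_terms
  if (length(spec$interaction_terms)) {
    rhs <- c(rhs, vapply(spec$interaction_terms, paste, "", collapse = ":"))
  }
  stats::as.formula(paste(spec$response, "~", paste(rhs, collapse = " + ")),
                    env = baseenv())
}

#' Fit a dyadic model from a model specification
#'
#' Assembles the formula from a `dyad_model_spec` and fits it with
#' [dyad_mm()]. Member columns fall back to `member_i`/`member_j` when the
#' spec's columns are absent from the table.
#'
#' @param dyads A [build_dyads()] table containing the spec's response and
#'   predictor columns; rows must be complete.
#' @param spec A `dyad_model_spec` (from [wild_model_spec()],
#'   [lab_model_spec()] or [fungi_bacteria_model_spec()]).
#' @param ... Passed on to [dyad_mm()] (e.g. `prior`, `member_weight`,
#'   `standardize_response`).
#' @return A [dyad_mm] fit.
#' @export
fit_dyadic_model <- function(dyads, spec, ...) {
  stopifnot(inherits(spec, "dyad_model_spec"))
  need <- c(spec$response, spec$fixed_terms, unlist(spec$interaction_terms))
  miss <- setdiff(unique(need), names(dyads))
  if (length(miss)) {
    stop("dyad table lacks column(s) required by the model spec: ",
         paste(miss, collapse = ", "))
  }
  members <- if (all(spec$member_columns %in% names(dyads))) {
    spec$member_columns
  } else c("member_i", "member_j")
  dyad_mm(.spec_formula(spec), dyads, members = members, chains = spec$chains,
          iter = spec$iterations, warmup = spec$warmup, seed = spec$seed, ...)
}

#' Recapitulate a dyadic model for every community component
#'
#' Fits the specified model per component dyad table and per response type
#' (occurrence-based Jaccard and abundance-based Aitchison by default),
#' yielding the forest-plot set of fits. Components whose dyad table was built
#' from fewer than 3 taxa (recorded in the table's `n_taxa` attribute) are
#' skipped with a warning.
#'
#' @param tables Named list of per-component dyad tables (e.g. `overall`,
#'   `bacteria`, `fungi`, `parasites`, `diet`).
#' @param spec Baseline `dyad_model_spec`; its `response` is overridden per
#'   response type.
#' @param responses Character vector of response types / column names.
#' @param ... Passed to [fit_dyadic_model()].
#' @return Named list of [dyad_mm] fits keyed `"<component>.<response>"`.
#' @export
run_component_models <- function(tables, spec,
                                 responses = c("jaccard", "aitchison"), ...) {
  stopifnot(inherits(spec, "dyad_model_spec"))
  fits <- list()
  for (comp in names(tables)) {
    tab <- tables[[comp]]
    n_taxa <- attr(tab, "n_taxa")
    if (!is.null(n_taxa) && n_taxa < 3L) {
      warning("component `", comp, "` has fewer than 3 taxa; skipped")
      next
    }
    for (resp in responses) {
      s <- spec
      s$response <- .response_column(resp)
      fit <- tryCatch(fit_dyadic_model(tab, s, ...), error = function(e) {
        if (grepl("constant response", conditionMessage(e))) {
          warning("component `", comp, "`, response `", resp,
                  "`: constant similarity; fit skipped")
          NULL
        } else stop(e)
      })
      if (!is.null(fit)) fits[[paste(comp, resp, sep = ".")]] <- fit
    }
  }
  fits
}

#' Coefficient table for a set of component fits
#'
#' Stacks [summary.dyad_mm()] rows over a list of fits, keyed by fit name —
#' the machine-readable companion of the forest plot.
#'
#' @param fits Named list of [dyad_mm] fits (e.g. from
#'   [run_component_models()]).
#' @param path Optional TSV output path.
#' @return Data frame with columns `model`, `parameter`, `estimate`,
#'   `ci_lower`, `ci_upper`, `rhat`, `significant`, `reliable`.
#' @export
coefficient_table <- function(fits, path = NULL) {
  out <- do.call(rbind, lapply(names(fits), function(nm) {
    s <- as.data.frame(summary(fits[[nm]]))
    cbind(model = nm, s)
  }))
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  out
}
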