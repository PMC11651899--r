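#' Default pipeline configuration
#'
#' Full default configuration of [run_pipeline()], as a nested list that can
#' also be written/read as YAML. User configs are merged over these defaults.
#'
#' @param mode `"simulate"` (generate data with the synthetic generator) or
#'   `"ingest"` (read host + per-amplicon count TSVs from disk).
#' @return Nested configuration list.
#' @export
pipeline_config <- function(mode = c("simulate", "ingest")) {
  list(
    seed = 1,
    mode = match.arg(mode),
    simulate = list(preset = "wild", n_mice = 60),
    ingest = list(hosts = NULL, amplicons = list()),
    filter = list(min_prevalence = 0.01, min_rel_abund = 5e-5,
                  min_sample_reads = 100, abundance_rule = "pooled"),
    casv = list(alpha = 0.01),
    dyads = list(pseudocount = 1, rescale = 1e6),
    model = list(variant = NULL, chains = 4, iterations = 3000, warmup = 1000,
                 responses = c("jaccard", "aitchison"),
                 fungi_bacteria = NULL),
    report = list(figure = TRUE)
  )
}

.merge_config <- function(base, user) {
  for (nm in names(user)) {
    ## recurse only into named maps; unnamed lists (e.g. amplicon rosters)
    ## replace the default wholesale
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(user[[nm]])) && length(base[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

.hash_obj <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

.stage_runner <- function(out_dir, prev_manifest, force, log_level) {
  manifest <- list()
  log <- function(level, ...) {
    if (log_level != "quiet") message("[", level, "] ", ...)
  }
  run <- function(name, key_obj, outputs, compute, load = NULL) {
    key <- .hash_obj(list(name, key_obj))
    prev <- prev_manifest$stages[[name]]
    paths <- file.path(out_dir, outputs)
    cached <- !force && !is.null(prev) && identical(prev$key, key) &&
      all(file.exists(paths)) && !is.null(load)
    t0 <- Sys.time()
    value <- if (cached) {
      log("info", "stage ", name, ": cached, loading outputs")
      load()
    } else {
      log("info", "stage ", name, ": running")
      compute()
    }
    manifest$stages[[name]] <<- list(
      key = key, cached = cached, outputs = outputs,
      checksums = as.list(tools::md5sum(paths[file.exists(paths)])),
      timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
    attr(value, "stage_key") <- key
    value
  }
  list(run = run, manifest = function() manifest)
}

.load_community_stage <- function(dir, prefix) {
  rel <- read_community_tsv(file.path(dir, paste0(prefix, ".tsv")),
                            taxonomy = file.path(dir, paste0(prefix, "_taxonomy.tsv")))
  compo <- utils::read.delim(file.path(dir, paste0(prefix, "_components.tsv")),
                             sep = "\t", stringsAsFactors = FALSE)
  ct <- community_table(rel$counts, taxonomy = rel$taxonomy,
                        amplicon = stats::setNames(compo$amplicon, compo$taxon_id)[colnames(rel$counts)],
                        component = stats::setNames(compo$component, compo$taxon_id)[colnames(rel$counts)])
  ct$rel_abund <- ct$counts   # stored matrix holds relative abundances
  ct
}

.write_community_stage <- function(ct, dir, prefix) {
  write_community_tsv(ct, file.path(dir, paste0(prefix, ".tsv")),
                      file.path(dir, paste0(prefix, "_components.tsv")))
  utils::write.table(ct$taxonomy, file.path(dir, paste0(prefix, "_taxonomy.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

#' Run the full dyadic-model pipeline
#'
#' Orchestrates the stages end to end: obtain hosts and per-amplicon count
#' tables (synthetic generation or TSV ingestion), quality-filter and
#' total-sum-scale each amplicon, collate, merge co-abundant ASVs into cASVs,
#' decompose into community components, build per-component dyad tables, fit
#' the dyadic multi-membership models per component and response, and write a
#' coefficient report plus a run manifest. Stage outputs are cached by content
#' hash (config section + upstream stage keys): re-running with an unchanged
#' config reuses cached TSVs and skips recomputation.
#'
#' @param config Configuration list (merged over [pipeline_config()]) or the
#'   path of a YAML file holding one.
#' @param out_dir Artifact directory (created if needed).
#' @param force Recompute everything, ignoring cached stage outputs.
#' @param log_level `"info"` or `"quiet"`.
#' @return Invisibly, a list with `fits`, `coefficients`, `dyads`, `table`
#'   (the merged cASV table), `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir, force = FALSE,
                         log_level = "info") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(pipeline_config(
    mode = if (is.null(config$mode)) "simulate" else config$mode), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prev <- NULL
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path)) {
    prev <- tryCatch(jsonlite::read_json(manifest_path), error = function(e) NULL)
  }
  st <- .stage_runner(out_dir, prev, force, log_level)

  ## -- stage 1: hosts + raw per-amplicon tables ------------------------------
  is_lab <- identical(cfg$simulate$preset, "lab")
  ingest_key <- if (cfg$mode == "ingest") {
    list(cfg$ingest, as.list(tools::md5sum(c(
      cfg$ingest$hosts,
      vapply(cfg$ingest$amplicons, `[[`, "", "counts")))))
  } else list(cfg$simulate, cfg$seed)
  raw <- st$run("input", ingest_key,
                outputs = "hosts.tsv",
                compute = function() {
    if (cfg$mode == "simulate") {
      sc_args <- cfg$simulate[setdiff(names(cfg$simulate), "preset")]
      sc_args$seed <- cfg$seed
      if (is_lab) {
        hosts <- lab_preset()
        sc_args$n_mice <- nrow(hosts)
        sim <- simulate_communities(hosts, do.call(sim_config, sc_args))
      } else {
        config_sim <- do.call(sim_config, sc_args)
        hosts <- simulate_hosts(config_sim)
        sim <- simulate_communities(hosts, config_sim)
      }
      write_simulation(sim, out_dir)
      list(hosts = sim$truth$hosts, tables = sim$tables)
    } else {
      hosts <- read_hosts(cfg$ingest$hosts)
      tables <- lapply(cfg$ingest$amplicons, function(a) {
        read_community_tsv(a$counts, taxonomy = a$taxonomy, amplicon = a$name)
      })
      names(tables) <- vapply(cfg$ingest$amplicons, `[[`, "", "name")
      utils::write.table(hosts, file.path(out_dir, "hosts.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
      list(hosts = hosts, tables = tables)
    }
  }, load = function() {
    hosts <- read_hosts(file.path(out_dir, "hosts.tsv"))
    if (cfg$mode == "ingest") {
      tables <- lapply(cfg$ingest$amplicons, function(a) {
        read_community_tsv(a$counts, taxonomy = a$taxonomy, amplicon = a$name)
      })
      names(tables) <- vapply(cfg$ingest$amplicons, `[[`, "", "name")
    } else {
      cf <- list.files(out_dir, pattern = "^counts_.*\\.tsv$", full.names = TRUE)
      amps <- sub("^counts_(.*)\\.tsv$", "\\1", basename(cf))
      tables <- Map(function(f, a) {
        read_community_tsv(f, taxonomy = file.path(out_dir, paste0("taxonomy_", a, ".tsv")),
                           amplicon = a)
      }, cf, amps)
      names(tables) <- amps
    }
    list(hosts = hosts, tables = tables)
  })

  ## -- stage 2: filter, normalize, collate -----------------------------------
  filt_key <- list(attr(raw, "stage_key"), cfg$filter)
  collated <- st$run("filter_normalize", filt_key,
                     outputs = c("community.tsv", "community_components.tsv",
                                 "community_taxonomy.tsv"),
                     compute = function() {
    per_amp <- lapply(raw$tables, function(ct) {
      total_sum_scale(filter_asvs(
        ct, min_prevalence = cfg$filter$min_prevalence,
        min_rel_abund = cfg$filter$min_rel_abund,
        min_sample_reads = cfg$filter$min_sample_reads,
        abundance_rule = cfg$filter$abundance_rule))
    })
    ct <- merge_amplicons(per_amp)
    .write_community_stage(ct, out_dir, "community")
    ct
  }, load = function() .load_community_stage(out_dir, "community"))

  ## -- stage 3: cASV merge ---------------------------------------------------
  casv_key <- list(attr(collated, "stage_key"), cfg$casv)
  merged <- st$run("casv_merge", casv_key,
                   outputs = c("casv_table.tsv", "casv_table_components.tsv",
                               "casv_table_taxonomy.tsv", "casv_map.tsv",
                               "casv_edges.tsv"),
                   compute = function() {
    m <- merge_casvs(collated, alpha = cfg$casv$alpha)
    .write_community_stage(m$table, out_dir, "casv_table")
    write_casv_map(m, file.path(out_dir, "casv_map.tsv"),
                   file.path(out_dir, "casv_edges.tsv"))
    m$table
  }, load = function() .load_community_stage(out_dir, "casv_table"))

  ## -- stage 4: per-component dyad tables ------------------------------------
  components <- c("overall",
                  intersect(c("bacteria", "fungi", "parasites", "diet"),
                            unique(merged$component)))
  dyad_key <- list(attr(merged, "stage_key"), cfg$dyads, components)
  dyads <- st$run("dyads", dyad_key,
                  outputs = paste0("dyads_", components, ".tsv"),
                  compute = function() {
    out <- lapply(components, function(comp) {
      taxa <- if (comp == "overall") colnames(merged$rel_abund) else
        names(merged$component)[merged$component == comp]
      sub <- merged$rel_abund[, taxa, drop = FALSE]
      sims <- similarity_matrices(sub, pseudocount = cfg$dyads$pseudocount,
                                  rescale = cfg$dyads$rescale)
      sims <- lapply(sims, function(m) {
        if (any(!is.finite(m))) {
          warning("empty-vs-empty sample pair(s) in component `", comp,
                  "`; similarity set to 0")
          m[!is.finite(m)] <- 0
        }
        m
      })
      d <- build_dyads(raw$hosts, sims, component = comp)
      attr(d, "n_taxa") <- length(taxa)
      write_dyads_tsv(d, file.path(out_dir, paste0("dyads_", comp, ".tsv")))
      d
    })
    stats::setNames(out, components)
  }, load = function() {
    out <- lapply(components, function(comp) {
      d <- utils::read.delim(file.path(out_dir, paste0("dyads_", comp, ".tsv")),
                             sep = "\t", stringsAsFactors = FALSE)
      class(d) <- c("dyad_table", "data.frame")
      attr(d, "n_taxa") <- if (comp == "overall") ncol(merged$rel_abund) else
        sum(merged$component == comp)
      d
    })
    stats::setNames(out, components)
  })

  ## -- stage 5: model fits ---------------------------------------------------
  variant <- cfg$model$variant
  if (is.null(variant)) variant <- if (is_lab) "lab" else "wild"
  spec <- switch(variant,
                 wild = wild_model_spec(chains = cfg$model$chains,
                                        iterations = cfg$model$iterations,
                                        warmup = cfg$model$warmup,
                                        seed = cfg$seed),
                 lab = lab_model_spec(chains = cfg$model$chains,
                                      iterations = cfg$model$iterations,
                                      warmup = cfg$model$warmup,
                                      seed = cfg$seed),
                 stop("unknown model variant: ", variant))
  fb <- cfg$model$fungi_bacteria
  if (is.null(fb)) fb <- variant == "wild" &&
      all(c("bacteria", "fungi") %in% components)
  fit_key <- list(attr(dyads, "stage_key"), cfg$model, variant, fb, cfg$seed)
  fits_out <- st$run("fits", fit_key, outputs = "coefficients.tsv",
                     compute = function() {
    fits <- run_component_models(dyads, spec, responses = cfg$model$responses)
    if (fb) {
      for (resp in cfg$model$responses) {
        col <- .response_column(resp)
        fbd <- dyads$bacteria
        fbd$fungal_sim_sc <- tryCatch(scale_minmax(dyads$fungi[[col]]),
                                      error = function(e) NULL)
        if (is.null(fbd$fungal_sim_sc)) {
          warning("fungi-bacteria model (", resp,
                  "): constant fungal similarity; fit skipped")
          next
        }
        s <- fungi_bacteria_model_spec(response = resp,
                                       chains = cfg$model$chains,
                                       iterations = cfg$model$iterations,
                                       warmup = cfg$model$warmup,
                                       seed = cfg$seed)
        fits[[paste0("fungi_bacteria.", resp)]] <- fit_dyadic_model(fbd, s)
      }
    }
    coefs <- coefficient_table(fits, file.path(out_dir, "coefficients.tsv"))
    list(fits = fits, coefficients = coefs)
  }, load = function() {
    list(fits = NULL,
         coefficients = utils::read.delim(file.path(out_dir, "coefficients.tsv"),
                                          sep = "\t", stringsAsFactors = FALSE))
  })

  ## -- stage 6: report -------------------------------------------------------
  if (isTRUE(cfg$report$figure) && !is.null(fits_out$fits)) {
    for (resp in cfg$model$responses) {
      sel <- grep(paste0("\\.", resp, "$"), names(fits_out$fits), value = TRUE)
      if (!length(sel)) next
      grDevices::svg(file.path(out_dir, paste0("forest_", resp, ".svg")),
                     width = 7, height = 2.5 * length(sel))
      old <- graphics::par(mfrow = c(length(sel), 1), mar = c(4, 9, 2, 1))
      for (nm in sel) {
        plot(fits_out$fits[[nm]], type = "forest", main = nm)
      }
      graphics::par(old)
      grDevices::dev.off()
    }
  }

  manifest <- c(
    list(package_version = as.character(utils::packageVersion("dyadmm")),
         r_version = as.character(getRversion()),
         seed = cfg$seed, config_hash = .hash_obj(cfg),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    st$manifest()
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(list(fits = fits_out$fits, coefficients = fits_out$coefficients,
                 dyads = dyads, table = merged, manifest = manifest))
}
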