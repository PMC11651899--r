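#' Configuration for the synthetic hybrid-zone generator
#'
#' Defines the study conditions the generator emulates: a hybrid-index cline
#' over a planar transect, multi-amplicon community tables whose taxon counts
#' echo the wild dataset's shape (383 bacteria, 65 fungi, 11 parasite and 45
#' diet cASVs), multi-amplicon redundancy (one true taxon emitted as several
#' correlated pseudo-ASVs), host-genetic filtering, spatially autocorrelated
#' environmental filtering with exponential distance decay, sampling-year
#' effects, hybridization-dependent extra variance restricted to the fungal
#' component, and an optional infection perturbation sparing fungi.
#'
#' @param n_mice Number of mice.
#' @param n_loci Diagnostic marker loci (diploid; `2 * n_loci` alleles).
#' @param cline_center,cline_width Center and logistic scale (length units) of
#'   the HI-vs-x cline.
#' @param transect Half-width of the x transect; x is uniform on
#'   `[-transect, transect]`, y uniform on `[0, y_extent]`.
#' @param y_extent Transect depth.
#' @param years Sampling years to draw from.
#' @param taxa_per_component Named counts of true taxa.
#' @param amplicon_redundancy Expected extra pseudo-ASVs per true taxon
#'   (each taxon yields `1 + Poisson(amplicon_redundancy)` pseudo-ASVs).
#' @param taxa_per_genus How many true taxa share a genus annotation (the
#'   genus is the merging unit of the cASV step).
#' @param pseudo_asv_noise_sd Log-scale noise separating pseudo-ASVs of one
#'   taxon; small values give strongly co-abundant (Spearman ~1) pseudo-ASVs.
#' @param depth Sequencing depth per amplicon per sample.
#' @param base_sd Log-scale spread of baseline taxon abundances.
#' @param sd_host SD of per-taxon hybrid-index loadings (host filtering).
#' @param env_range Range of the exponential spatial covariance.
#' @param sd_env SD of the per-taxon environmental field.
#' @param sd_year SD of per-taxon year effects.
#' @param sd_noise SD of per-(taxon, sample) idiosyncratic log-scale noise.
#' @param fungal_hybrid_variance_inflation Factor by which fungal idiosyncratic
#'   noise SD grows with admixture: fungal noise SD is
#'   `sd_noise * (1 + inflation * 2 * hHe)`.
#' @param infection_shift SD of per-taxon infection loadings, applied to
#'   bacteria, parasites and diet (not fungi) of infected samples.
#' @param seed Master seed for all randomness.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_mice = 60, n_loci = 14, cline_center = 0,
                       cline_width = 5, transect = 50, y_extent = 30,
                       years = 2015:2018,
                       taxa_per_component = c(bacteria = 383, fungi = 65,
                                              parasites = 11, diet = 45),
                       amplicon_redundancy = 0.5, pseudo_asv_noise_sd = 0.15,
                       taxa_per_genus = 3,
                       depth = 20000, base_sd = 2.5, sd_host = 0.6,
                       env_range = 20, sd_env = 0.6, sd_year = 0.3,
                       sd_noise = 0.3, fungal_hybrid_variance_inflation = 4,
                       infection_shift = 1, seed = 1) {
  taxa_per_component <- unlist(taxa_per_component)   # YAML maps arrive as lists
  if (is.null(names(taxa_per_component))) {
    ## YAML serialization of atomic vectors loses names; repair the canonical
    ## four-component layout, refuse anything else unnamed
    if (length(taxa_per_component) == 4L) {
      names(taxa_per_component) <- c("bacteria", "fungi", "parasites", "diet")
    } else {
      stop("`taxa_per_component` must be a named vector of component sizes")
    }
  }
  years <- as.integer(unlist(years))
  stopifnot(n_mice >= 2, n_loci >= 1, cline_width > 0,
            all(taxa_per_component > 0), amplicon_redundancy >= 0, depth > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate hybrid-zone hosts
#'
#' Places mice uniformly on the planar transect; each mouse's expected HI
#' follows a logistic cline of its x coordinate, and its diagnostic-allele
#' count is drawn binomially (`2 * n_loci` trials) around that expectation, so
#' realized HI values scatter around the cline as genotypes do. Sampling years
#' are uniform over the configured set.
#'
#' @param config A [sim_config()].
#' @return Host data frame (`host_id`, allele counts, `hybrid_index`, `hhe`,
#'   `x`, `y`, `year`).
#' @export
simulate_hosts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_mice
  x <- stats::runif(n, -config$transect, config$transect)
  y <- stats::runif(n, 0, config$y_extent)
  p <- stats::plogis((x - config$cline_center) / config$cline_width)
  n_typed <- rep(2L * config$n_loci, n)
  n_mmm <- stats::rbinom(n, n_typed, p)
  hosts <- data.frame(
    host_id = sprintf("m%04d", seq_len(n)),
    n_mmm_alleles = n_mmm, n_typed_alleles = n_typed,
    hybrid_index = compute_hybrid_index(n_mmm, n_typed),
    x = x, y = y,
    year = sample(config$years, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  hosts$hhe <- expected_hybrid_heterozygosity(hosts$hybrid_index)
  hosts
}

#' Laboratory preset: wild-derived strains before and during infection
#'
#' The controlled-environment roster: four parental inbred strains (two Mmd:
#' SCHUNT, STRA; two Mmm: BUSNA, PWD; 3 mice each), two intra-subspecies F1
#' crosses (PWD x BUSNA n = 3, SCHUNT x STRA n = 2) and two inter-subspecies
#' hybrid crosses (STRA x BUSNA n = 2, SCHUNT x PWD n = 3) — 22 mice. Each
#' mouse is sampled twice: before infection (day 0, `infection_status` 0) and
#' at the peak of infection (day 6, status 1), giving 44 samples. The
#' `individual` column carries the mouse id for the multi-membership terms;
#' there are no spatial or temporal covariates (controlled environment).
#'
#' @return Sample-level host data frame (44 rows).
#' @export
lab_preset <- function() {
  groups <- data.frame(
    strain = c("SCHUNT", "STRA", "BUSNA", "PWD",
               "PWDxBUSNA", "SCHUNTxSTRA", "STRAxBUSNA", "SCHUNTxPWD"),
    n = c(3L, 3L, 3L, 3L, 3L, 2L, 2L, 3L),
    hi = c(0, 0, 1, 1, 1, 0, 0.5, 0.5),
    stringsAsFactors = FALSE
  )
  mice <- data.frame(
    individual = sprintf("%s_%d", rep(groups$strain, groups$n),
                         unlist(lapply(groups$n, seq_len))),
    strain = rep(groups$strain, groups$n),
    hybrid_index = rep(groups$hi, groups$n),
    stringsAsFactors = FALSE
  )
  hosts <- do.call(rbind, lapply(c(0L, 6L), function(day) {
    data.frame(
      host_id = paste0(mice$individual, "_d", day),
      individual = mice$individual,
      strain = mice$strain,
      hybrid_index = mice$hybrid_index,
      day = day,
      infection_status = as.integer(day > 0),
      stringsAsFactors = FALSE
    )
  }))
  hosts$hhe <- expected_hybrid_heterozygosity(hosts$hybrid_index)
  rownames(hosts) <- NULL
  hosts
}

.component_genera <- function(component, k, size = 3L) {
  ## parasites must carry recognized parasitic genera so component labels
  ## round-trip through assign_component()
  if (component == "parasites") {
    gs <- .genera_parasites
    return(gs[((seq_len(k) - 1L) %/% size) %% length(gs) + 1L])
  }
  prefix <- c(bacteria = "Bactgen", fungi = "Fungen", diet = "Plantgen")[component]
  sprintf("%s%03d", prefix, (seq_len(k) - 1L) %/% size + 1L)
}

.component_phyla <- function(component, k, size = 3L) {
  pool <- switch(component,
                 bacteria = c("Firmicutes", "Bacteroidota", "Proteobacteria",
                              "Verrucomicrobiota", "Actinobacteriota"),
                 fungi = c("Ascomycota", "Basidiomycota", "Mucoromycota"),
                 parasites = c("Apicomplexa", "Nematoda", "Platyhelminthes"),
                 diet = c("Anthophyta", "Phragmoplastophyta", "Charophyta"))
  ## keep a taxon's phylum tied to its genus block so genera are coherent
  pool[((seq_len(k) - 1L) %/% size) %% length(pool) + 1L]
}

.component_amplicons <- list(
  bacteria = c("16Sv34", "16Sv67"),
  fungi = c("ITS1", "ITS2", "28S"),
  parasites = c("18Sv4", "28S"),
  diet = c("18Sv9", "trnL")
)

#' Simulate multi-amplicon community tables with known ground truth
#'
#' Builds a latent log-abundance for every (true taxon, sample) pair as the
#' sum of a baseline, a host-genetic term (per-taxon loading times the host's
#' HI), a spatially autocorrelated environmental field (exponential
#' distance-decay covariance over sampling locations), a sampling-year effect,
#' idiosyncratic noise — inflated with admixture for fungal taxa — and, when
#' samples carry an `infection_status`, an infection shift applied to all
#' components except fungi. Each true taxon is then emitted as
#' `1 + Poisson(amplicon_redundancy)` correlated pseudo-ASVs distributed over
#' that component's amplicons, and per-amplicon counts are drawn multinomially
#' at the configured depth.
#'
#' Spatial/temporal terms are skipped for hosts without coordinates or years
#' (the laboratory preset).
#'
#' @param hosts Host table from [simulate_hosts()] or [lab_preset()].
#' @param config A [sim_config()].
#' @return List with `tables` (named list of per-amplicon raw-count
#'   [community_table]s), and `truth` (class `sim_truth`): the generating
#'   config and effect realizations — per-taxon loadings, fields, the latent
#'   matrix `latent`, and the pseudo-ASV-to-taxon map `asv_map`.
#' @export
simulate_communities <- function(hosts, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- nrow(hosts)
  comps <- rep(names(config$taxa_per_component), config$taxa_per_component)
  Tn <- length(comps)
  taxa <- sprintf("%s%03d", c(bacteria = "bact", fungi = "fung",
                              parasites = "para", diet = "diet")[comps],
                  unlist(lapply(config$taxa_per_component, seq_len)))
  genus <- unlist(lapply(names(config$taxa_per_component), function(cc) {
    .component_genera(cc, config$taxa_per_component[[cc]], config$taxa_per_genus)
  }))
  phylum <- unlist(lapply(names(config$taxa_per_component), function(cc) {
    .component_phyla(cc, config$taxa_per_component[[cc]], config$taxa_per_genus)
  }))

  base <- stats::rnorm(Tn, 0, config$base_sd)
  host_load <- stats::rnorm(Tn, 0, config$sd_host)
  hi <- hosts$hybrid_index
  hhe <- hosts$hhe
  latent <- matrix(base, Tn, n) + outer(host_load, hi)

  has_space <- !is.null(hosts$x) && !is.null(hosts$y)
  env_field <- NULL
  if (has_space) {
    D <- as.matrix(stats::dist(cbind(hosts$x, hosts$y)))
    Sigma <- exp(-D / config$env_range)
    L <- t(chol(Sigma + diag(1e-8, n)))
    env_field <- config$sd_env * t(L %*% matrix(stats::rnorm(n * Tn), n, Tn))
    latent <- latent + env_field
  }
  year_eff <- NULL
  if (!is.null(hosts$year)) {
    yrs <- sort(unique(hosts$year))
    year_eff <- matrix(stats::rnorm(Tn * length(yrs), 0, config$sd_year),
                       Tn, length(yrs), dimnames = list(NULL, yrs))
    latent <- latent + year_eff[, as.character(hosts$year), drop = FALSE]
  }
  ## idiosyncratic noise; fungal SD inflates with admixture
  noise_sd <- matrix(config$sd_noise, Tn, n)
  fungal <- comps == "fungi"
  noise_sd[fungal, ] <- config$sd_noise *
    (1 + config$fungal_hybrid_variance_inflation *
       matrix(2 * hhe, sum(fungal), n, byrow = TRUE))
  eps <- matrix(stats::rnorm(Tn * n), Tn, n) * noise_sd
  latent <- latent + eps
  inf_load <- NULL
  if (!is.null(hosts$infection_status) && !all(is.na(hosts$infection_status))) {
    inf_load <- stats::rnorm(Tn, 0, config$infection_shift)
    inf_load[fungal] <- 0
    latent <- latent + outer(inf_load, as.numeric(hosts$infection_status))
  }

  ## pseudo-ASV expansion: 1 + Poisson(redundancy) markers per true taxon
  k_pseudo <- 1L + stats::rpois(Tn, config$amplicon_redundancy)
  asv_taxon <- rep(seq_len(Tn), k_pseudo)
  asv_rank <- unlist(lapply(k_pseudo, seq_len))
  asv_id <- sprintf("%s_a%d", taxa[asv_taxon], asv_rank)
  asv_amp <- vapply(seq_along(asv_taxon), function(i) {
    amps <- .component_amplicons[[comps[asv_taxon[i]]]]
    amps[(asv_rank[i] - 1L) %% length(amps) + 1L]
  }, character(1L))
  split_off <- stats::rnorm(length(asv_id), 0, 0.5)
  asv_latent <- latent[asv_taxon, , drop = FALSE] + split_off +
    matrix(stats::rnorm(length(asv_id) * n, 0, config$pseudo_asv_noise_sd),
           length(asv_id), n)

  taxonomy_all <- data.frame(
    taxon_id = asv_id,
    kingdom = c(bacteria = "Bacteria", fungi = "Fungi",
                parasites = "Eukaryota", diet = "Eukaryota")[comps[asv_taxon]],
    phylum = phylum[asv_taxon],
    class = NA_character_, order = NA_character_, family = NA_character_,
    genus = genus[asv_taxon],
    stringsAsFactors = FALSE
  )

  tables <- lapply(sort(unique(asv_amp)), function(a) {
    sel <- which(asv_amp == a)
    probs <- exp(asv_latent[sel, , drop = FALSE])
    counts <- matrix(vapply(seq_len(n), function(m) {
      stats::rmultinom(1L, config$depth, probs[, m])[, 1L]
    }, integer(length(sel))), nrow = length(sel))
    counts <- t(counts)  # samples x ASVs
    dimnames(counts) <- list(hosts$host_id, asv_id[sel])
    community_table(counts, taxonomy = taxonomy_all[sel, , drop = FALSE],
                    amplicon = a)
  })
  names(tables) <- sort(unique(asv_amp))

  truth <- structure(
    list(config = config, hosts = hosts,
         taxa = data.frame(taxon = taxa, component = comps, genus = genus,
                           base = base, host_load = host_load,
                           inf_load = if (is.null(inf_load)) NA else inf_load,
                           stringsAsFactors = FALSE),
         latent = `dimnames<-`(latent, list(taxa, hosts$host_id)),
         env_field = env_field, year_eff = year_eff, eps = eps,
         asv_map = data.frame(asv_id = asv_id, taxon = taxa[asv_taxon],
                              component = comps[asv_taxon],
                              genus = genus[asv_taxon], amplicon = asv_amp,
                              stringsAsFactors = FALSE)),
    class = "sim_truth")
  list(tables = tables, truth = truth)
}

#' Simulate dyad responses directly from the multi-membership model
#'
#' Operating-characteristic generator for the dyadic regression itself:
#' simulates hosts, builds the scaled pairwise predictors, then draws
#' `y = X beta + u_i + u_j + eps` with known coefficients and variance
#' components. The response column is named `similarity`.
#'
#' @param beta Named coefficient vector; names must be dyad-table columns (use
#'   the `_sc` scaled names) plus optionally `"(Intercept)"`. Unnamed terms
#'   default to 0.
#' @param sigma_u Member random-effect SD.
#' @param sigma Residual SD.
#' @param config [sim_config()] controlling the hosts (its seed also seeds the
#'   response noise).
#' @param hosts Optional precomputed host table (overrides simulation).
#' @return List: `dyads` (dyad table with `similarity` response), `truth`
#'   (class `sim_truth_dyadic`: `beta` on the full design, `sigma_u`, `sigma`,
#'   `u`).
#' @export
simulate_dyad_data <- function(beta = c("(Intercept)" = 0.5),
                               sigma_u = 0.1, sigma = 0.1,
                               config = sim_config(), hosts = NULL) {
  if (is.null(hosts)) hosts <- simulate_hosts(config)
  dyads <- build_dyads(hosts, similarity = list(), scale = TRUE)
  set.seed(config$seed + 2L)
  terms <- setdiff(names(beta), "(Intercept)")
  miss <- setdiff(terms, names(dyads))
  if (length(miss)) stop("unknown predictor(s) in `beta`: ",
                         paste(miss, collapse = ", "))
  lp <- rep(if ("(Intercept)" %in% names(beta)) beta[["(Intercept)"]] else 0,
            nrow(dyads))
  for (tm in terms) lp <- lp + beta[[tm]] * dyads[[tm]]
  ids <- sort(unique(c(dyads$member_i, dyads$member_j)))
  u <- stats::setNames(stats::rnorm(length(ids), 0, sigma_u), ids)
  dyads$similarity <- lp + u[dyads$member_i] + u[dyads$member_j] +
    stats::rnorm(nrow(dyads), 0, sigma)
  truth <- structure(list(beta = beta, sigma_u = sigma_u, sigma = sigma,
                          u = u, linear_predictor = lp),
                     class = "sim_truth_dyadic")
  list(dyads = dyads, truth = truth)
}

#' Score parameter recovery of a fit against simulation truth
#'
#' @param fit A [dyad_mm] fit or its [summary.dyad_mm()].
#' @param truth A `sim_truth_dyadic` (from [simulate_dyad_data()]) or a named
#'   vector of true coefficient values. Every truth name must match a fitted
#'   parameter.
#' @return Data frame per scored parameter: `truth`, `estimate`, `bias`,
#'   `ci_lower`, `ci_upper`, `covered` (CI contains the truth), `sign_correct`
#'   (NA when the truth is 0: sign agreement is then undefined).
#' @export
score_recovery <- function(fit, truth) {
  s <- if (inherits(fit, "dyad_mm")) summary(fit) else fit
  stopifnot(inherits(s, "summary.dyad_mm") || is.data.frame(s))
  tv <- if (inherits(truth, "sim_truth_dyadic")) {
    c(truth$beta, sigma_u = truth$sigma_u, sigma = truth$sigma)
  } else truth
  miss <- setdiff(names(tv), s$parameter)
  if (length(miss)) {
    stop("truth parameter(s) not in the fit: ", paste(miss, collapse = ", "))
  }
  rows <- match(names(tv), s$parameter)
  out <- data.frame(
    parameter = names(tv), truth = unname(tv),
    estimate = s$estimate[rows],
    bias = s$estimate[rows] - unname(tv),
    ci_lower = s$ci_lower[rows], ci_upper = s$ci_upper[rows],
    stringsAsFactors = FALSE
  )
  out$covered <- out$ci_lower <= out$truth & out$truth <= out$ci_upper
  out$sign_correct <- ifelse(out$truth == 0, NA,
                             sign(out$estimate) == sign(out$truth))
  out
}

#' Aggregate a coverage indicator over replicates
#'
#' @param covered Logical vector (one entry per replicate).
#' @param conf Confidence level of the exact binomial interval.
#' @return List: `n`, `covered`, `fraction`, `ci` (exact Clopper-Pearson).
#' @export
coverage_summary <- function(covered, conf = 0.95) {
  n <- length(covered); k <- sum(covered)
  ci <- stats::binom.test(k, n, conf.level = conf)$conf.int
  list(n = n, covered = k, fraction = k / n, ci = as.numeric(ci))
}

#' Write a simulated dataset to disk
#'
#' Emits the hosts TSV, one raw-count TSV + taxonomy TSV per amplicon, and a
#' JSON file with the generating effect sizes (the machine-readable part of
#' the truth; latent matrices stay in R).
#'
#' @param sim Result of [simulate_communities()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hosts <- sim$truth$hosts
  utils::write.table(hosts, file.path(dir, "hosts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  for (a in names(sim$tables)) {
    ct <- sim$tables[[a]]
    df <- data.frame(sample_id = rownames(ct$counts), ct$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, paste0("counts_", a, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    utils::write.table(ct$taxonomy, file.path(dir, paste0("taxonomy_", a, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  cfg <- sim$truth$config
  effect_names <- c("sd_host", "sd_env", "env_range", "sd_year", "sd_noise",
                    "fungal_hybrid_variance_inflation", "infection_shift",
                    "amplicon_redundancy", "seed")
  jsonlite::write_json(cfg[effect_names], file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
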