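# sampler settings kept small here; operating-characteristic suites at the
# full settings live in test-acceptance.R
fast <- list(chains = 2L, iter = 600L, warmup = 200L)

test_that("fits are deterministic given a seed and differ across seeds", {
  sd <- simulate_dyad_data(beta = c("(Intercept)" = 0.4, gen_dist_sc = -0.15),
                          sigma_u = 0.1, sigma = 0.1,
                          config = sim_config(n_mice = 25, seed = 14))
  f1 <- dyad_mm(similarity ~ gen_dist_sc, sd$dyads, chains = fast$chains,
                iter = fast$iter, warmup = fast$warmup, seed = 99)
  f2 <- dyad_mm(similarity ~ gen_dist_sc, sd$dyads, chains = fast$chains,
                iter = fast$iter, warmup = fast$warmup, seed = 99)
  f3 <- dyad_mm(similarity ~ gen_dist_sc, sd$dyads, chains = fast$chains,
                iter = fast$iter, warmup = fast$warmup, seed = 100)
  expect_identical(f1$draws, f2$draws)
  expect_identical(as.data.frame(summary(f1)), as.data.frame(summary(f2)))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("posterior summaries are invariant to dyad row order", {
  sd <- simulate_dyad_data(beta = c("(Intercept)" = 0.4, spatial_dist_sc = -0.2),
                          sigma_u = 0.1, sigma = 0.1,
                          config = sim_config(n_mice = 20, seed = 5))
  set.seed(1)
  perm <- sample(nrow(sd$dyads))
  f1 <- dyad_mm(similarity ~ spatial_dist_sc, sd$dyads, chains = fast$chains,
                iter = fast$iter, warmup = fast$warmup, seed = 7)
  f2 <- dyad_mm(similarity ~ spatial_dist_sc, sd$dyads[perm, ],
                chains = fast$chains, iter = fast$iter, warmup = fast$warmup,
                seed = 7)
  s1 <- summary(f1); s2 <- summary(f2)
  expect_equal(s1$estimate, s2$estimate, tolerance = 1e-6)
  expect_equal(s1$ci_lower, s2$ci_lower, tolerance = 1e-6)
})

test_that("with negligible member variance the fit agrees with OLS", {
  ## independent dyads (sigma_u -> 0): the fixed effects must match ordinary
  ## least squares on the same design within 2 posterior SDs
  sd <- simulate_dyad_data(
    beta = c("(Intercept)" = 0.5, spatial_dist_sc = -0.2, gen_dist_sc = 0.1),
    sigma_u = 0, sigma = 0.15, config = sim_config(n_mice = 40, seed = 21))
  f <- dyad_mm(similarity ~ spatial_dist_sc + gen_dist_sc, sd$dyads,
               chains = fast$chains, iter = fast$iter, warmup = fast$warmup,
               seed = 3)
  ols <- lm(similarity ~ spatial_dist_sc + gen_dist_sc, sd$dyads)
  s <- summary(f)
  for (pn in names(coef(ols))) {
    row <- s[s$parameter == pn, ]
    expect_lt(abs(row$estimate - coef(ols)[[pn]]), 2 * row$sd)
  }
})

test_that("summary exposes CI containment, significance and rhat flags", {
  sd <- simulate_dyad_data(beta = c("(Intercept)" = 0.5, spatial_dist_sc = -0.3),
                          sigma_u = 0.05, sigma = 0.1,
                          config = sim_config(n_mice = 30, seed = 8))
  f <- dyad_mm(similarity ~ spatial_dist_sc, sd$dyads, chains = fast$chains,
               iter = fast$iter, warmup = fast$warmup, seed = 12)
  s <- summary(f)
  expect_true(all(s$ci_lower <= s$estimate & s$estimate <= s$ci_upper))
  co <- !s$parameter %in% c("sigma", "sigma_u")
  expect_identical(s$significant[co],
                   (s$ci_lower > 0 | s$ci_upper < 0)[co])
  expect_true(all(c("sigma_u", "sigma") %in% s$parameter))
  expect_true(all(is.na(s$significant[s$parameter %in% c("sigma", "sigma_u")])))
  expect_true(attr(s, "converged"))
  ## a deliberately broken draws array must be flagged, not suppressed
  fbad <- f
  fbad$draws[, 1, "spatial_dist_sc"] <- fbad$draws[, 1, "spatial_dist_sc"] + 50
  expect_warning(sbad <- summary(fbad), "convergence failure")
  expect_false(attr(sbad, "converged"))
  expect_false(sbad$reliable[sbad$parameter == "spatial_dist_sc"])
})

test_that("model methods behave like a classed regression fit", {
  sd <- simulate_dyad_data(beta = c("(Intercept)" = 0.5, gen_dist_sc = -0.2),
                          sigma_u = 0.1, sigma = 0.1,
                          config = sim_config(n_mice = 25, seed = 30))
  f <- dyad_mm(similarity ~ gen_dist_sc, sd$dyads, chains = fast$chains,
               iter = fast$iter, warmup = fast$warmup, seed = 4)
  expect_named(coef(f), c("(Intercept)", "gen_dist_sc"))
  expect_length(ranef(f), 25)
  expect_equal(unname(fitted(f) + residuals(f)), unname(f$y))
  p0 <- predict(f)
  pm <- predict(f, re_form = "member")
  expect_length(p0, nrow(sd$dyads))
  expect_gt(stats::cor(pm, f$y), stats::cor(p0, f$y) - 1e-9)
  yrep <- simulate(f, nsim = 3, seed = 1)
  expect_identical(dim(yrep), c(nrow(sd$dyads), 3L))
  ## member effects recovered up to shrinkage: correlation with truth
  expect_gt(stats::cor(ranef(f)[names(sd$truth$u)], sd$truth$u), 0.5)
})

test_that("multi-membership random effects restore CI coverage", {
  ## dyads sharing a member are dependent; ignoring that dependence is
  ## anti-conservative. With sigma_u = 0.3 the naive model (sigma_u pinned
  ## near 0 via a point-mass-like prior is not available, so we compare to
  ## OLS intervals) must under-cover while the full model attains >= 90%.
  reps <- 20
  full_cover <- logical(reps)
  ols_cover <- logical(reps)
  b_true <- -0.2
  for (r in seq_len(reps)) {
    sd <- simulate_dyad_data(
      beta = c("(Intercept)" = 0.5, spatial_dist_sc = b_true),
      sigma_u = 0.3, sigma = 0.1, config = sim_config(n_mice = 30, seed = 400 + r))
    f <- dyad_mm(similarity ~ spatial_dist_sc, sd$dyads, chains = 2,
                 iter = 500, warmup = 150, seed = r)
    s <- summary(f)
    row <- s[s$parameter == "spatial_dist_sc", ]
    full_cover[r] <- row$ci_lower <= b_true & b_true <= row$ci_upper
    ci <- confint(lm(similarity ~ spatial_dist_sc, sd$dyads))["spatial_dist_sc", ]
    ols_cover[r] <- ci[1] <= b_true & b_true <= ci[2]
  }
  expect_gte(mean(full_cover), 0.9)
  expect_lt(mean(ols_cover), 0.9)
})

test_that("model specs encode the three study designs", {
  w <- wild_model_spec()
  expect_length(w$fixed_terms, 5)
  expect_identical(w$interaction_terms, list(c("gen_dist_sc", "hhe_dist_sc")))
  expect_identical(w$member_columns, c("ind_i", "ind_j"))
  expect_identical(c(w$chains, w$iterations, w$warmup), c(4, 3000, 1000))
  l <- lab_model_spec(response = "aitchison")
  expect_identical(l$response, "similarity_aitchison")
  expect_length(l$fixed_terms, 3)
  expect_length(l$interaction_terms, 0)
  expect_false(any(grepl("spatial|temporal", l$fixed_terms)))
  fb <- fungi_bacteria_model_spec()
  expect_length(fb$fixed_terms, 6)
  expect_identical(fb$fixed_terms[1], "fungal_sim_sc")
})

test_that("infection-status distance is 1 only for mixed pairs", {
  hosts <- lab_preset()[1:6, ]
  hosts$infection_status <- c(0, 0, 1, 1, 0, 1)
  hosts$individual <- NULL
  sim <- diag(6)
  dimnames(sim) <- list(hosts$host_id, hosts$host_id)
  d <- build_dyads(hosts, list(jaccard = sim), scale = FALSE)
  inf <- setNames(hosts$infection_status, hosts$host_id)
  expect_equal(d$infection_dist,
               abs(inf[d$member_i] - inf[d$member_j]), ignore_attr = TRUE)
  expect_setequal(unique(d$infection_dist), c(0, 1))
})

test_that("fit_dyadic_model wires spec terms into the formula", {
  set.seed(77)
  sd <- simulate_dyad_data(
    beta = c("(Intercept)" = 0.4, spatial_dist_sc = -0.1),
    sigma_u = 0.05, sigma = 0.1, config = sim_config(n_mice = 20, seed = 44))
  d <- sd$dyads
  d$similarity_jaccard <- d$similarity
  spec <- wild_model_spec(chains = 2, iterations = 400, warmup = 100)
  f <- fit_dyadic_model(d, spec)
  expect_s3_class(f, "dyad_mm")
  ## intercept + 5 fixed + 1 interaction
  expect_length(f$fixed_names, 7)
  expect_true("gen_dist_sc:hhe_dist_sc" %in% f$fixed_names)
  bad <- d; bad$hhe_mean_sc <- NULL
  expect_error(fit_dyadic_model(bad, spec), "hhe_mean_sc")
})

test_that("component runner recapitulates fits and skips tiny components", {
  set.seed(55)
  sd <- simulate_dyad_data(beta = c("(Intercept)" = 0.4),
                          sigma_u = 0.05, sigma = 0.1,
                          config = sim_config(n_mice = 15, seed = 66))
  d <- sd$dyads
  d$similarity_jaccard <- d$similarity
  d$similarity_aitchison <- d$similarity + 0.1
  tabs <- list(overall = d, fungi = d)
  attr(tabs$fungi, "n_taxa") <- 2L
  spec <- wild_model_spec(chains = 2, iterations = 300, warmup = 100)
  expect_warning(fits <- run_component_models(tabs, spec), "fungi")
  expect_named(fits, c("overall.jaccard", "overall.aitchison"))
  ct <- coefficient_table(fits)
  expect_true(all(c("model", "parameter", "estimate", "rhat") %in% names(ct)))
})
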