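fixture_mat <- function() {
  df <- read.delim(extdata("coabundance_fixture.tsv"), sep = "\t")
  m <- as.matrix(df[, -1])
  rownames(m) <- df$sample_id
  m
}

test_that("co-abundance edges match the brute-force Spearman+BH oracle", {
  m <- fixture_mat()
  tax <- read.delim(extdata("coabundance_fixture_taxonomy.tsv"), sep = "\t")
  for (g in unique(tax$genus)) {
    cols <- tax$taxon_id[tax$genus == g]
    net <- genus_network(m[, cols, drop = FALSE], genus = g)
    got <- sort(paste(net$edges$asv_a, net$edges$asv_b, sep = "|"))
    expect_identical(got, edges_oracle(m[, cols, drop = FALSE]),
                     label = paste("edge set for", g))
  }
})

test_that("edge rules: perfect co-ranking in, anti-ranking out", {
  m <- fixture_mat()
  ## two ASVs with identical rank order over 8 samples: rho = 1, kept
  netA <- genus_network(m[, c("A1", "A2")], genus = "GenusA")
  expect_identical(nrow(netA$edges), 1L)
  expect_equal(netA$edges$rho, 1)
  expect_lt(netA$edges$p_adj, 0.01)
  ## perfectly anti-ranked pair: rho = -1, excluded by the positivity rule
  netB <- genus_network(m[, c("B1", "B2")], genus = "GenusB")
  expect_identical(nrow(netB$edges), 0L)
})

test_that("degenerate networks: single ASV, constant ASV", {
  m <- fixture_mat()
  one <- genus_network(m[, "A1", drop = FALSE], genus = "solo")
  expect_identical(one$nodes, "A1")
  expect_identical(nrow(one$edges), 0L)
  const <- cbind(m[, c("A1", "A2")], FLAT = 7)
  expect_warning(net <- genus_network(const, genus = "g"), "constant")
  expect_false("FLAT" %in% c(net$edges$asv_a, net$edges$asv_b))
  expect_true("FLAT" %in% net$nodes)  # retained as an isolated node
})

test_that("greedy clustering equals exhaustive modularity on shipped fixtures", {
  edges_df <- read.delim(extdata("network_fixture_edges.tsv"), sep = "\t")
  nodes_df <- read.delim(extdata("network_fixture_nodes.tsv"), sep = "\t")
  for (fix in unique(nodes_df$fixture)) {
    net <- fixture_network(fix, edges_df, nodes_df)
    cl <- greedy_clusters(net)
    memb <- as.integer(factor(cl$casv_id))[match(net$nodes, cl$asv_id)]
    got <- modularity_oracle(net$nodes, net$edges, memb)
    best <- best_modularity_oracle(net$nodes, net$edges)
    expect_equal(got, best, tolerance = 1e-12, label = paste("modularity of", fix))
    if (best > 0) expect_gte(got, 0)
  }
})

test_that("cluster structure of the canonical fixtures is as designed", {
  edges_df <- read.delim(extdata("network_fixture_edges.tsv"), sep = "\t")
  nodes_df <- read.delim(extdata("network_fixture_nodes.tsv"), sep = "\t")
  groups <- function(fix) {
    cl <- greedy_clusters(fixture_network(fix, edges_df, nodes_df))
    unname(lapply(split(cl$asv_id, cl$casv_id), sort))
  }
  expect_setequal(groups("tri_iso"), list(c("n1", "n2", "n3"), "n4"))
  expect_setequal(groups("doubletons"), list(c("n1", "n2"), c("n3", "n4")))
  expect_setequal(groups("edgeless"), list("n1", "n2", "n3"))
})

test_that("merging sums abundances and conserves per-sample totals", {
  rel <- matrix(c(0.1, 0.3, 0.2, 0.0, 0.7, 0.7), 2, 3,
                dimnames = list(c("s1", "s2"), c("x1", "x2", "x3")))
  ct <- community_table(rel * 100)
  ct$rel_abund <- rel
  map <- data.frame(asv_id = c("x1", "x2", "x3"),
                    casv_id = c("cA", "cA", "x3"))
  out <- merge_by_cluster(ct, map)
  expect_equal(out$rel_abund[, "cA"], c(s1 = 0.1 + 0.2, s2 = 0.3 + 0.0))
  expect_equal(rowSums(out$rel_abund), rowSums(rel), tolerance = 1e-9)
  ## all-singleton map is the identity
  idmap <- data.frame(asv_id = colnames(rel), casv_id = colnames(rel))
  expect_equal(merge_by_cluster(ct, idmap)$rel_abund, rel)
  expect_error(merge_by_cluster(ct, data.frame(asv_id = "nope", casv_id = "c")),
               "unknown ASV")
})

test_that("full cASV merge recovers split taxa and never spans genera", {
  m <- fixture_mat()
  tax <- read.delim(extdata("coabundance_fixture_taxonomy.tsv"), sep = "\t")
  ct <- total_sum_scale(community_table(m, taxonomy = tax))
  res <- merge_casvs(ct)
  ## designed structure: A1+A2 merge, C1+C2+C3 merge, everything else singleton
  sizes <- tapply(res$map$asv_id, res$map$casv_id, length)
  expect_equal(sort(as.integer(sizes)), c(1L, 1L, 1L, 1L, 1L, 2L, 3L))
  expect_identical(ncol(res$table$rel_abund), 7L)
  by_casv <- split(res$map$genus, res$map$casv_id)
  expect_true(all(vapply(by_casv, function(g) length(unique(g)) == 1L, TRUE)))
  expect_equal(rowSums(res$table$rel_abund), rowSums(ct$rel_abund),
               tolerance = 1e-9)
  expect_lte(ncol(res$table$rel_abund), ncol(ct$rel_abund))
})

test_that("greedy modularity is optimal across random small networks", {
  ## property check against enumeration on random graphs of up to 6 nodes:
  ## the greedy result must be non-negative whenever a positive-modularity
  ## partition exists
  set.seed(202)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    nodes <- paste0("v", seq_len(n))
    pairs <- combn(nodes, 2)
    keep <- runif(ncol(pairs)) < 0.45
    edges <- data.frame(asv_a = pairs[1, keep], asv_b = pairs[2, keep],
                        rho = round(runif(sum(keep), 0.2, 1), 2),
                        p = rep(0, sum(keep)), p_adj = rep(0, sum(keep)),
                        stringsAsFactors = FALSE)
    net <- structure(list(genus = "rnd", nodes = nodes, edges = edges),
                     class = "coabundance_network")
    cl <- greedy_clusters(net)
    memb <- as.integer(factor(cl$casv_id))[match(nodes, cl$asv_id)]
    got <- modularity_oracle(nodes, edges, memb)
    best <- best_modularity_oracle(nodes, edges)
    if (best > 1e-12) expect_gte(got, -1e-12)
    expect_lte(got, best + 1e-12)
  }
})

test_that("merging recovers the true taxon count from redundant pseudo-ASVs", {
  ## controlled experiment isolating the redundancy mechanism: one taxon per
  ## genus, otherwise-independent taxa (no shared host/environment loadings),
  ## each split into correlated marker copies. Every split taxon whose
  ## realized copy correlation reaches the designed strength (Spearman >= 0.9
  ## across all copy pairs) must come back as exactly one cASV; replicate
  ## success requires that for all such taxa
  hits <- logical(20)
  for (r in seq_len(20)) {
    cfg <- sim_config(n_mice = 30, seed = 7000 + r, amplicon_redundancy = 1.5,
                      taxa_per_genus = 1, sd_host = 0, sd_env = 0,
                      sd_year = 0, sd_noise = 0.8, base_sd = 1,
                      taxa_per_component = c(bacteria = 12, fungi = 6,
                                             parasites = 3, diet = 3))
    sim <- simulate_communities(simulate_hosts(cfg), cfg)
    per_amp <- lapply(sim$tables, function(ct) {
      total_sum_scale(filter_asvs(ct, min_prevalence = 0, min_rel_abund = 0))
    })
    merged <- merge_amplicons(per_amp)
    res <- suppressWarnings(merge_casvs(merged))
    asv2casv <- stats::setNames(res$map$casv_id, res$map$asv_id)
    map <- sim$truth$asv_map
    ok <- vapply(unique(map$taxon), function(tx) {
      ids <- intersect(map$asv_id[map$taxon == tx], colnames(merged$rel_abund))
      if (length(ids) < 2L) return(NA)     # not split: nothing to merge
      prs <- utils::combn(ids, 2L)
      rhos <- apply(prs, 2L, function(ab) {
        suppressWarnings(stats::cor(merged$rel_abund[, ab[1]],
                                    merged$rel_abund[, ab[2]],
                                    method = "spearman"))
      })
      if (any(is.na(rhos)) || min(rhos) < 0.9) return(NA)  # below the
      length(unique(asv2casv[ids])) == 1L                  # designed strength
    }, NA)
    expect_gt(sum(!is.na(ok)), 0)
    hits[r] <- all(ok[!is.na(ok)])
  }
  expect_gte(mean(hits), 0.95)
})
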