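## Spearman correlation test used for co-abundance edges.
## Exact null distribution (via stats::cor.test AS89 machinery) for n <= 9
## without ties; t-distribution approximation otherwise. One-sided tests are
## not used: the positivity rule (rho > 0) is applied separately.
spearman_test <- function(x, y) {
  n <- length(x)
  exact <- n <= 9L && !anyDuplicated(x) && !anyDuplicated(y)
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact, continuity = FALSE)
  )
  c(rho = unname(ht$estimate), p = ht$p.value)
}

#' Within-genus co-abundance network
#'
#' Multi-amplicon data can carry the same taxon as several ASVs from different
#' marker loci. To find them, all pairs of ASVs annotated to one genus are
#' tested for Spearman correlation of their abundances across samples; edges
#' are kept only for positive correlations (rho > 0) that remain significant
#' (adjusted p < 0.01) after Benjamini-Hochberg correction over the genus's
#' set of pairwise tests.
#'
#' Zero-variance ASVs have undefined correlations; they are excluded from
#' testing (with a warning) and remain isolated nodes, ending up as singleton
#' cASVs.
#'
#' @param rel_abund Samples-by-ASV matrix restricted to one genus's ASVs.
#' @param genus Genus name (metadata only).
#' @param alpha Adjusted-p threshold for keeping an edge.
#' @return Object of class `coabundance_network`: list with `genus`, `nodes`,
#'   and an `edges` data frame (`asv_a`, `asv_b`, `rho`, `p`, `p_adj`).
#' @export
genus_network <- function(rel_abund, genus = "genus", alpha = 0.01) {
  rel_abund <- as.matrix(rel_abund)
  nodes <- colnames(rel_abund)
  if (is.null(nodes)) stop("`rel_abund` must have ASV column names")
  edges <- data.frame(asv_a = character(0), asv_b = character(0),
                      rho = numeric(0), p = numeric(0), p_adj = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(nodes) >= 2L) {
    if (nrow(rel_abund) < 4L) {
      stop("at least 4 samples are required for co-abundance testing")
    }
    variable <- apply(rel_abund, 2L, function(v) stats::var(v) > 0)
    if (any(!variable)) {
      warning("constant-abundance ASV(s) excluded from correlation testing: ",
              paste(nodes[!variable], collapse = ", "))
    }
    test_nodes <- nodes[variable]
    if (length(test_nodes) >= 2L) {
      pr <- utils::combn(sort(test_nodes), 2L)
      res <- apply(pr, 2L, function(ab) {
        spearman_test(rel_abund[, ab[1L]], rel_abund[, ab[2L]])
      })
      edges <- data.frame(asv_a = pr[1L, ], asv_b = pr[2L, ],
                          rho = res["rho", ], p = res["p", ],
                          stringsAsFactors = FALSE)
      edges$p_adj <- stats::p.adjust(edges$p, method = "BH")
      edges <- edges[!is.na(edges$rho) & edges$rho > 0 &
                       !is.na(edges$p_adj) & edges$p_adj < alpha, , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  structure(list(genus = genus, nodes = nodes, edges = edges),
            class = "coabundance_network")
}

#' @export
print.coabundance_network <- function(x, ...) {
  cat("coabundance_network for genus", x$genus, "-", length(x$nodes),
      "ASVs,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Cluster a co-abundance network into cASVs
#'
#' Greedy modularity maximization (agglomerative: start from singleton
#' communities and repeatedly perform the merge with the largest modularity
#' increase) on the positive-correlation network, weighting edges by their
#' Spearman rho. Isolated nodes become singleton cASVs. cASV ids are
#' deterministic: clusters are ordered by their lexicographically smallest
#' member.
#'
#' @param net A [genus_network()] result.
#' @param casv_prefix Prefix for cASV ids; defaults to the genus name.
#' @return Data frame mapping `asv_id` to `casv_id`, with `genus` and
#'   `cluster_size`.
#' @export
greedy_clusters <- function(net, casv_prefix = NULL) {
  stopifnot(inherits(net, "coabundance_network"))
  if (is.null(casv_prefix)) casv_prefix <- net$genus
  nodes <- sort(net$nodes)
  if (nrow(net$edges) == 0L) {
    membership <- stats::setNames(seq_along(nodes), nodes)
  } else {
    g <- igraph::graph_from_data_frame(
      net$edges[, c("asv_a", "asv_b")], directed = FALSE,
      vertices = data.frame(name = nodes))
    comm <- igraph::cluster_fast_greedy(g, weights = net$edges$rho)
    ## cut the agglomerative merge path at its modularity maximum ourselves:
    ## igraph's returned membership can stop short of the best cut when the
    ## maximum sits at the final (fully merged) step
    k <- which.max(comm$modularity)
    membership <- stats::setNames(igraph::cut_at(comm, steps = k - 1L),
                                  igraph::V(g)$name)[nodes]
  }
  ## renumber clusters by smallest member id for determinism
  first <- tapply(nodes, membership, min)
  newid <- stats::setNames(rank(first, ties.method = "first"), names(first))
  cl <- newid[as.character(membership)]
  size <- table(cl)
  data.frame(
    asv_id = nodes,
    casv_id = sprintf("%s_cASV%02d", casv_prefix, cl),
    genus = net$genus,
    cluster_size = as.integer(size[as.character(cl)]),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Build co-abundance networks for every genus in a table
#'
#' @param ct Normalized [community_table].
#' @param alpha Adjusted-p threshold passed to [genus_network()].
#' @return Named list of `coabundance_network` objects, one per genus with at
#'   least two ASVs. ASVs without a genus annotation are not networked (they
#'   remain singleton cASVs downstream).
#' @export
casv_networks <- function(ct, alpha = 0.01) {
  stopifnot(inherits(ct, "community_table"))
  if (is.null(ct$rel_abund)) stop("run total_sum_scale() before cASV merging")
  genus <- ct$taxonomy$genus
  if (is.null(genus)) return(list())
  ok <- !is.na(genus) & genus != ""
  gsplit <- split(ct$taxonomy$taxon_id[ok], genus[ok])
  gsplit <- gsplit[vapply(gsplit, length, 1L) >= 2L]
  nets <- lapply(names(gsplit), function(g) {
    genus_network(ct$rel_abund[, gsplit[[g]], drop = FALSE], genus = g,
                  alpha = alpha)
  })
  stats::setNames(nets, names(gsplit))
}

#' Merge ASVs into cASVs by cluster map
#'
#' Sums member ASV abundances (both counts and relative abundances) per
#' sample. The cASV keeps the genus-level lineage shared by its members and
#' inherits their component label and amplicon tags. Per-sample totals are
#' conserved exactly.
#'
#' @param ct A [community_table]; every ASV in `map` must exist in it, and
#'   `map` must cover all of the table's ASVs (unmapped ASVs pass through as
#'   themselves).
#' @param map Data frame with columns `asv_id`, `casv_id` (from
#'   [greedy_clusters()], possibly row-bound over genera).
#' @return A merged `community_table` whose columns are cASVs.
#' @export
merge_by_cluster <- function(ct, map) {
  stopifnot(inherits(ct, "community_table"))
  unknown <- setdiff(map$asv_id, colnames(ct$counts))
  if (length(unknown)) {
    stop("cluster map references unknown ASVs: ", paste(unknown, collapse = ", "))
  }
  taxa <- colnames(ct$counts)
  casv <- stats::setNames(map$casv_id, map$asv_id)[taxa]
  casv[is.na(casv)] <- taxa[is.na(casv)]   # unmapped ASVs stay themselves
  groups <- split(taxa, casv)
  ## deterministic output order: by first member's position in the input table
  ord <- order(vapply(groups, function(m) min(match(m, taxa)), 1L))
  groups <- groups[ord]
  collapse <- function(mat) {
    out <- vapply(groups, function(m) rowSums(mat[, m, drop = FALSE]),
                  numeric(nrow(mat)))
    if (nrow(mat) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(rownames(mat), names(groups)))
    out
  }
  first <- vapply(groups, `[`, character(1L), 1L)
  tx <- ct$taxonomy[match(first, ct$taxonomy$taxon_id), , drop = FALSE]
  tx$taxon_id <- names(groups)
  ## members below genus may disagree; blank sub-genus ranks for true merges
  multi <- vapply(groups, length, 1L) > 1L
  for (col in intersect(c("species"), names(tx))) tx[[col]][multi] <- NA
  rownames(tx) <- NULL
  community_table(
    collapse(ct$counts), taxonomy = tx,
    amplicon = vapply(groups, function(m) paste(sort(unique(ct$amplicon[m])), collapse = "+"),
                      character(1L)),
    rel_abund = if (!is.null(ct$rel_abund)) collapse(ct$rel_abund),
    component = ct$component[first]
  )
}

#' Full cASV merge of a normalized community table
#'
#' Convenience wrapper: builds per-genus co-abundance networks, clusters each
#' by greedy modularity, and merges the table. ASVs lacking genus annotation
#' are retained as singleton cASVs.
#'
#' @param ct Normalized [community_table].
#' @param alpha Adjusted-p threshold for network edges.
#' @return List with the merged `table`, the ASV-to-cASV `map`, and the
#'   per-genus `networks`.
#' @export
merge_casvs <- function(ct, alpha = 0.01) {
  nets <- casv_networks(ct, alpha = alpha)
  map <- if (length(nets)) {
    do.call(rbind, lapply(nets, greedy_clusters))
  } else {
    data.frame(asv_id = character(0), casv_id = character(0),
               genus = character(0), cluster_size = integer(0))
  }
  rownames(map) <- NULL
  list(table = merge_by_cluster(ct, map), map = map, networks = nets)
}

#' Write cASV merge artifacts to TSV
#'
#' @param merged Result of [merge_casvs()].
#' @param map_path TSV path for the ASV-to-cASV map.
#' @param edges_path Optional TSV path for the audit edge list
#'   (`asv_a`, `asv_b`, `rho`, `p_adj`).
#' @return `map_path`, invisibly.
#' @export
write_casv_map <- function(merged, map_path, edges_path = NULL) {
  utils::write.table(merged$map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(edges_path)) {
    edges <- do.call(rbind, lapply(merged$networks, `[[`, "edges"))
    if (is.null(edges)) {
      edges <- data.frame(asv_a = character(0), asv_b = character(0),
                          rho = numeric(0), p = numeric(0), p_adj = numeric(0))
    }
    utils::write.table(edges, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(map_path)
}
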