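# Independent oracles used to cross-check the implementation. These are kept
# deliberately naive (enumeration / direct formulas) and share no code with
# the package internals they verify.

## all permutations of 1..n as a matrix (n! rows)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

## Spearman rho by the rank-Pearson definition
rho_oracle <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}

## exact two-sided permutation p-value for Spearman rho (no ties assumed)
spearman_p_oracle <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- stats::cor(rx, ry)
  perms <- all_perms(n)
  null_rho <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
  eps <- 1e-12
  min(1, 2 * min(mean(null_rho >= obs - eps), mean(null_rho <= obs + eps)))
}

## brute-force edge set: positive rho AND BH-adjusted exact p < alpha,
## correcting over all pairs within the given set of ASVs
edges_oracle <- function(mat, alpha = 0.01) {
  pr <- utils::combn(sort(colnames(mat)), 2L)
  rho <- apply(pr, 2L, function(ab) rho_oracle(mat[, ab[1]], mat[, ab[2]]))
  p <- apply(pr, 2L, function(ab) spearman_p_oracle(mat[, ab[1]], mat[, ab[2]]))
  padj <- stats::p.adjust(p, method = "BH")
  keep <- rho > 0 & padj < alpha
  sort(paste(pr[1, keep], pr[2, keep], sep = "|"))
}

## weighted Newman-Girvan modularity, straight from the definition
modularity_oracle <- function(nodes, edges, membership) {
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      A[edges$asv_a[k], edges$asv_b[k]] <- edges$rho[k]
      A[edges$asv_b[k], edges$asv_a[k]] <- edges$rho[k]
    }
  }
  m2 <- sum(A)
  if (m2 == 0) return(0)
  deg <- rowSums(A)
  same <- outer(membership, membership, "==")
  sum((A - outer(deg, deg) / m2) * same) / m2
}

## every set partition of n elements (Bell(n) partitions; fine for n <= 6)
all_partitions <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1L)) {
    for (b in seq_len(max(p) + 1L)) out <- c(out, list(c(p, b)))
  }
  out
}

## exhaustive modularity maximization
best_modularity_oracle <- function(nodes, edges) {
  max(vapply(all_partitions(length(nodes)), function(p) {
    modularity_oracle(nodes, edges, p)
  }, numeric(1)))
}

## turn a fixture edge list into a coabundance_network object
fixture_network <- function(fix, edges_df, nodes_df) {
  e <- edges_df[edges_df$fixture == fix, c("asv_a", "asv_b", "rho")]
  e$p <- rep(0, nrow(e)); e$p_adj <- rep(0, nrow(e))
  rownames(e) <- NULL
  structure(list(genus = fix, nodes = nodes_df$node[nodes_df$fixture == fix],
                 edges = e),
            class = "coabundance_network")
}

extdata <- function(f) system.file("extdata", f, package = "dyadmm")

## small deterministic community table used by several suites
toy_community <- function(seed = 42, n_samples = 12, n_taxa = 8,
                          amplicon = "16S") {
  set.seed(seed)
  counts <- matrix(rpois(n_samples * n_taxa, lambda = 40),
                   n_samples, n_taxa,
                   dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                                   sprintf("t%02d", seq_len(n_taxa))))
  tax <- data.frame(taxon_id = colnames(counts),
                    kingdom = "Bacteria", phylum = "Firmicutes",
                    genus = rep(c("G1", "G2"), length.out = n_taxa),
                    stringsAsFactors = FALSE)
  community_table(counts, taxonomy = tax, amplicon = amplicon)
}
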