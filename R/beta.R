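#' Jaccard similarity of two abundance vectors
#'
#' Occurrence-based resemblance: presence is abundance > 0, the Jaccard
#' distance is `1 - |shared| / |union|`, and the similarity returned is its
#' complement `|shared| / |union|`. A pair in which both vectors are entirely
#' empty has an undefined 0/0 ratio; it is defined here as similarity 0, with
#' a warning.
#'
#' @param x,y Equal-length non-negative numeric vectors.
#' @return Similarity in `[0, 1]`.
#' @examples
#' jaccard_similarity(c(1, 2, 0), c(0, 5, 3)) # share B of {A,B} vs {B,C}: 1/3
#' @export
jaccard_similarity <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  px <- x > 0; py <- y > 0
  un <- sum(px | py)
  if (un == 0L) {
    warning("both vectors empty; Jaccard similarity undefined, returning 0")
    return(0)
  }
  sum(px & py) / un
}

#' Aitchison similarity of two composition vectors
#'
#' Abundance-based, compositionally coherent resemblance: a pseudocount is
#' added to every entry, each vector is centred-log-ratio (clr) transformed
#' (log of each entry minus the mean log of the vector), and the Aitchison
#' distance is the Euclidean distance between the clr vectors. The similarity
#' returned is `1 - distance`, which is unbounded below (large compositional
#' differences give negative similarities); the Gaussian dyadic model accepts
#' that.
#'
#' When the inputs are relative abundances (values at or below 1), a
#' pseudocount of 1 would swamp the signal; set `rescale` to a large factor
#' (the pipeline default is `1e6`) to put values on a count-like scale before
#' the pseudocount is added. The default here (`rescale = 1`) takes the input
#' as given.
#'
#' @param x,y Equal-length non-negative numeric vectors.
#' @param pseudocount Value added to every entry before the log transform.
#' @param rescale Multiplicative factor applied to `x` and `y` before the
#'   pseudocount.
#' @return Similarity (at most 1; 1 means identical compositions).
#' @export
aitchison_similarity <- function(x, y, pseudocount = 1, rescale = 1) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  lx <- log(x * rescale + pseudocount)
  ly <- log(y * rescale + pseudocount)
  clrx <- lx - mean(lx)
  clry <- ly - mean(ly)
  1 - sqrt(sum((clrx - clry)^2))
}

#' Occurrence and abundance similarity matrices for a community table
#'
#' Computes the two sample-by-sample similarity matrices used as dyadic-model
#' responses: occurrence-based Jaccard (`1 -` binary Jaccard distance, via
#' [vegan::vegdist()]) and abundance-based Aitchison (`1 -` Euclidean distance
#' between clr-transformed compositions, pseudocount added after rescaling).
#' The default `rescale = 1e6` assumes relative-abundance input; pass
#' `rescale = 1` for raw counts.
#'
#' @param mat Samples-by-taxa abundance matrix with sample row names.
#' @param pseudocount Added to every entry before the clr transform.
#' @param rescale Multiplicative factor applied before the pseudocount.
#' @return List with elements `jaccard` and `aitchison`, each a symmetric
#'   sample-by-sample similarity matrix.
#' @export
similarity_matrices <- function(mat, pseudocount = 1, rescale = 1e6) {
  mat <- as.matrix(mat)
  dj <- as.matrix(vegan::vegdist(mat, method = "jaccard", binary = TRUE))
  da <- as.matrix(vegan::vegdist(mat * rescale, method = "aitchison",
                                 pseudocount = pseudocount))
  list(jaccard = 1 - dj, aitchison = 1 - da)
}

#' Smallest sample count reaching a prevalence fraction
#'
#' The number of samples a taxon must occur in to reach a prevalence
#' threshold: the smallest integer at or above `frac * n_samples`.
#'
#' @param n_samples Positive sample count.
#' @param frac Prevalence fraction in (0, 1).
#' @return Integer count.
#' @examples
#' prevalence_cutoff(619, 0.05) # 31 samples
#' @export
prevalence_cutoff <- function(n_samples, frac) {
  stopifnot(n_samples > 0, frac > 0, frac < 1)
  as.integer(ceiling(n_samples * frac))
}

#' Min-max scale a predictor to [0, 1]
#'
#' All dyadic-model predictors are expressed on a common 0-1 scale so their
#' standardized estimates are comparable within a model. Order-preserving and
#' idempotent on already-scaled input.
#'
#' @param x Numeric vector; must not be constant.
#' @return Scaled vector in `[0, 1]`.
#' @export
scale_minmax <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) {
    stop("constant predictor (max == min): drop it from the model instead of scaling")
  }
  (x - r[1]) / (r[2] - r[1])
}

#' Build the dyad table for the dyadic models
#'
#' One row per unordered pair of samples, combining the community-similarity
#' responses with the genetic and environmental predictor distances. All
#' predictors are min-max scaled to `[0, 1]` over this table (columns suffixed
#' `_sc`); raw values are kept alongside. For repeated-measures designs the
#' optional `individual` column of `hosts` populates `ind_i`/`ind_j`, the
#' multi-membership grouping used by [dyad_mm()]; otherwise the sample ids
#' are the members.
#'
#' @param hosts Host/sample metadata data frame (`host_id`, `hybrid_index`,
#'   `x`, `y`, `year`, optional `infection_status`, optional `individual`).
#' @param similarity Named list of sample-by-sample similarity matrices (e.g.
#'   from [similarity_matrices()]: elements `jaccard` and `aitchison`), or a
#'   single matrix which is taken as `jaccard`. Row/column names must cover
#'   the host ids.
#' @param component Label recorded in the table's `component` column.
#' @param scale Logical; add min-max scaled predictor columns (default TRUE).
#'   Constant predictors are an error: drop them from the model instead.
#' @param predictors Which predictor sets to attach; spatial/temporal columns
#'   require coordinates and years, infection requires `infection_status`.
#' @return Data frame of class `dyad_table` with columns `member_i`,
#'   `member_j`, `ind_i`, `ind_j`, `component`, one `similarity_<name>` column
#'   per similarity matrix, and raw + `_sc` predictor columns.
#' @export
build_dyads <- function(hosts, similarity, component = "overall", scale = TRUE,
                        predictors = c("genetic", "environmental", "infection")) {
  hosts <- .validate_hosts(hosts)
  if (is.matrix(similarity)) similarity <- list(jaccard = similarity)
  p <- .pair_indices(hosts$host_id)
  ids <- as.character(hosts$host_id)
  out <- data.frame(member_i = ids[p$i], member_j = ids[p$j],
                    stringsAsFactors = FALSE)
  ind <- if (!is.null(hosts$individual)) as.character(hosts$individual) else ids
  out$ind_i <- ind[p$i]
  out$ind_j <- ind[p$j]
  out$component <- component
  for (nm in names(similarity)) {
    m <- similarity[[nm]]
    missing_ids <- setdiff(ids, rownames(m))
    if (length(missing_ids)) {
      stop("similarity matrix `", nm, "` lacks samples: ",
           paste(missing_ids, collapse = ", "))
    }
    out[[paste0("similarity_", nm)]] <- m[cbind(ids[p$i], ids[p$j])]
  }
  if ("genetic" %in% predictors) {
    gd <- genetic_dyads(hosts)
    out$gen_dist <- gd$gen_dist
    out$hhe_dist <- gd$hhe_dist
    out$hhe_mean <- gd$hhe_mean
  }
  if ("environmental" %in% predictors &&
      !is.null(hosts$year) && (!is.null(hosts$x) || !is.null(hosts$x_coord))) {
    ed <- environmental_dyads(hosts)
    out$spatial_dist <- ed$spatial_dist
    out$temporal_dist <- ed$temporal_dist
  }
  if ("infection" %in% predictors && !is.null(hosts$infection_status)) {
    inf <- hosts$infection_status
    if (any(is.na(inf))) stop("missing infection_status for host(s): ",
                              paste(ids[is.na(inf)], collapse = ", "))
    out$infection_dist <- abs(inf[p$i] - inf[p$j])
  }
  if (scale) {
    for (col in intersect(c("gen_dist", "hhe_dist", "hhe_mean", "spatial_dist",
                            "temporal_dist", "infection_dist"), names(out))) {
      out[[paste0(col, "_sc")]] <- scale_minmax(out[[col]])
    }
  }
  class(out) <- c("dyad_table", "data.frame")
  out
}

#' Write a dyad table to TSV
#'
#' @param dyads A [build_dyads()] table.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_dyads_tsv <- function(dyads, path) {
  utils::write.table(dyads, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
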