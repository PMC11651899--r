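#' Hybrid index from diagnostic allele counts
#'
#' The hybrid index (HI) of a mouse is the proportion of *Mus musculus
#' musculus* (Mmm) alleles among its typed alleles at the subspecies-diagnostic
#' markers (14 loci, hence up to 28 alleles for diploid genotypes). HI = 0 is a
#' pure *M. m. domesticus* (Mmd) genotype, HI = 1 a pure Mmm genotype.
#'
#' The operation is defined on allele totals, so haploid-style encodings (one
#' allele per locus) work identically. Hosts with no typed alleles are rejected
#' rather than defaulted or imputed: imputation of incomplete genotypes is out
#' of scope and must happen upstream.
#'
#' @param n_mmm Non-negative integer vector; number of Mmm alleles observed.
#' @param n_typed Positive integer vector; number of alleles successfully typed.
#' @return Numeric vector of hybrid indices in `[0, 1]`.
#' @examples
#' compute_hybrid_index(14, 28) # balanced hybrid, 0.5
#' @export
compute_hybrid_index <- function(n_mmm, n_typed) {
  if (length(n_mmm) != length(n_typed)) {
    stop("`n_mmm` and `n_typed` must have the same length")
  }
  if (any(is.na(n_mmm)) || any(is.na(n_typed))) {
    stop("allele counts must not be missing")
  }
  if (any(n_typed <= 0)) {
    stop("missing genotype: `n_typed` must be positive for every host ",
         "(imputation of ungenotyped hosts is not performed here)")
  }
  if (any(n_mmm < 0) || any(n_mmm > n_typed)) {
    stop("`n_mmm` must lie in [0, n_typed]")
  }
  n_mmm / n_typed
}

#' Expected hybrid heterozygosity
#'
#' Degree of genomic admixture of a (possibly hybrid) genotype, computed with
#' the expected-heterozygosity function `2 * hi * (1 - hi)`. Both pure parental
#' genotypes (HI = 0 or 1) have an expected hybrid heterozygosity of 0; a
#' balanced hybrid (HI = 0.5) attains the maximum of 0.5.
#'
#' @param hi Numeric vector of hybrid indices in `[0, 1]`.
#' @return Numeric vector in `[0, 0.5]`.
#' @examples
#' expected_hybrid_heterozygosity(c(0, 0.25, 0.5, 1))
#' @export
expected_hybrid_heterozygosity <- function(hi) {
  if (any(is.na(hi))) stop("`hi` must not contain missing values")
  if (any(hi < 0 | hi > 1)) stop("`hi` must lie in [0, 1]")
  2 * hi * (1 - hi)
}

## canonical unordered pairs over sorted ids; shared by all dyad builders
.pair_indices <- function(ids) {
  n <- length(ids)
  if (n < 2L) stop("at least two hosts are required to form dyads")
  if (anyDuplicated(ids)) {
    stop("duplicate host_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  ord <- order(as.character(ids))
  idx <- utils::combn(ord, 2L)
  list(i = idx[1L, ], j = idx[2L, ])
}

.validate_hosts <- function(hosts) {
  if (!is.data.frame(hosts)) stop("`hosts` must be a data frame")
  if (is.null(hosts$host_id)) stop("`hosts` must have a `host_id` column")
  if (is.null(hosts$hybrid_index)) {
    if (!is.null(hosts$n_mmm_alleles) && !is.null(hosts$n_typed_alleles)) {
      hosts$hybrid_index <- compute_hybrid_index(hosts$n_mmm_alleles,
                                                 hosts$n_typed_alleles)
    } else {
      stop("`hosts` must carry `hybrid_index` or allele counts ",
           "(`n_mmm_alleles`, `n_typed_alleles`)")
    }
  }
  bad <- is.na(hosts$hybrid_index)
  if (any(bad)) {
    stop("missing hybrid_index for host(s): ",
         paste(hosts$host_id[bad], collapse = ", "),
         " (impute or drop them before building dyads)")
  }
  if (is.null(hosts$hhe)) {
    hosts$hhe <- expected_hybrid_heterozygosity(hosts$hybrid_index)
  }
  hosts
}

#' Pairwise genetic predictors for all host dyads
#'
#' Builds one record per unordered pair of hosts with the genetic predictors of
#' the dyadic models: the subspecies' genetic distance `gen_dist = |HI_i -
#' HI_j|`, the difference in admixture `hhe_dist = |hHe_i - hHe_j|`, and the
#' mean admixture of the pair `hhe_mean = (hHe_i + hHe_j) / 2`. The mean (not
#' the sum) is used; after the min-max scaling applied downstream the two
#' encodings give identical model inputs.
#'
#' @param hosts Data frame with columns `host_id` and `hybrid_index` (or allele
#'   counts `n_mmm_alleles`/`n_typed_alleles` from which HI is computed).
#' @return Data frame with one row per unordered pair: `host_i`, `host_j`
#'   (sorted so that `host_i < host_j`), `gen_dist`, `hhe_dist`, `hhe_mean`.
#' @examples
#' hosts <- data.frame(host_id = c("a", "b", "c"),
#'                     hybrid_index = c(0, 0.5, 1))
#' genetic_dyads(hosts)
#' @export
genetic_dyads <- function(hosts) {
  hosts <- .validate_hosts(hosts)
  p <- .pair_indices(hosts$host_id)
  hi <- hosts$hybrid_index
  hhe <- hosts$hhe
  data.frame(
    host_i = as.character(hosts$host_id[p$i]),
    host_j = as.character(hosts$host_id[p$j]),
    gen_dist = abs(hi[p$i] - hi[p$j]),
    hhe_dist = abs(hhe[p$i] - hhe[p$j]),
    hhe_mean = (hhe[p$i] + hhe[p$j]) / 2,
    stringsAsFactors = FALSE
  )
}

#' Pairwise spatial and temporal distances for all host dyads
#'
#' Spatial distance is the Euclidean distance between the planar sampling
#' coordinates of the two hosts; temporal distance is the absolute difference
#' of their sampling years. Coordinates are treated as planar (no geodesic
#' projection), matching a transect-scale sampling design.
#'
#' @param hosts Data frame with columns `host_id`, `x`, `y` (or
#'   `x_coord`/`y_coord`) and `year`.
#' @return Data frame with `host_i`, `host_j`, `spatial_dist`, `temporal_dist`.
#' @export
environmental_dyads <- function(hosts) {
  if (!is.data.frame(hosts)) stop("`hosts` must be a data frame")
  if (is.null(hosts$host_id)) stop("`hosts` must have a `host_id` column")
  x <- if (!is.null(hosts$x)) hosts$x else hosts$x_coord
  y <- if (!is.null(hosts$y)) hosts$y else hosts$y_coord
  if (is.null(x) || is.null(y)) stop("`hosts` must have coordinate columns `x`, `y`")
  if (is.null(hosts$year)) stop("`hosts` must have a `year` column")
  for (col in list(c("x", "x"), c("y", "y"), c("year", "year"))) {
    v <- switch(col[1L], x = x, y = y, year = hosts$year)
    if (any(is.na(v))) {
      stop("missing ", col[2L], " for host(s): ",
           paste(hosts$host_id[is.na(v)], collapse = ", "))
    }
  }
  p <- .pair_indices(hosts$host_id)
  data.frame(
    host_i = as.character(hosts$host_id[p$i]),
    host_j = as.character(hosts$host_id[p$j]),
    spatial_dist = sqrt((x[p$i] - x[p$j])^2 + (y[p$i] - y[p$j])^2),
    temporal_dist = abs(hosts$year[p$i] - hosts$year[p$j]),
    stringsAsFactors = FALSE
  )
}

#' Read a host metadata table
#'
#' Reads a tab-delimited, UTF-8, headered host table. Either a `hybrid_index`
#' column or the allele-count pair `n_mmm_alleles`/`n_typed_alleles` must be
#' present; in the latter case HI is computed. An `hhe` column is always
#' (re)computed from HI.
#'
#' @param path Path to a TSV file with columns `host_id`, `hybrid_index` (or
#'   `n_mmm_alleles` and `n_typed_alleles`), `x`, `y`, `year`, and optionally
#'   `infection_status` and `individual` (for repeated-measures designs where
#'   several samples share one individual).
#' @return Data frame of host records.
#' @export
read_hosts <- function(path) {
  if (!file.exists(path)) stop("host table not found: ", path)
  hosts <- utils::read.delim(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (is.null(hosts$host_id)) {
    stop("host table ", path, " lacks required column `host_id`")
  }
  hosts <- .validate_hosts(hosts)
  hosts$hhe <- expected_hybrid_heterozygosity(hosts$hybrid_index)
  hosts
}
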