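#' Construct a community table
#'
#' Container for one (or, after [merge_amplicons()], several) amplicon's ASV
#' abundances: a samples-by-taxa count matrix plus per-taxon taxonomy,
#' community-component labels and the source-amplicon tag. Relative abundances
#' (`rel_abund`) are filled in by [total_sum_scale()].
#'
#' @param counts Numeric matrix, samples in rows, taxa in columns; must have
#'   row and column names. Non-negative.
#' @param taxonomy Data frame with a `taxon_id` column and lineage columns
#'   (any of `kingdom`, `phylum`, `class`, `order`, `family`, `genus`); one row
#'   per taxon in `counts`. May be `NULL` (empty taxonomy).
#' @param amplicon Single string tagging the source marker (e.g. `"16S"`), or a
#'   per-taxon character vector.
#' @param rel_abund Optional samples-by-taxa relative-abundance matrix.
#' @param component Optional per-taxon component labels; computed from
#'   taxonomy via [assign_component()] when missing.
#' @return Object of class `community_table`.
#' @export
community_table <- function(counts, taxonomy = NULL, amplicon = "amplicon1",
                            rel_abund = NULL, component = NULL) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      (ncol(counts) > 0L && is.null(colnames(counts)))) {
    stop("`counts` must have sample (row) and taxon (column) names")
  }
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (any(counts < 0)) stop("`counts` must be non-negative")
  if (anyDuplicated(colnames(counts))) stop("duplicate taxon ids in `counts`")
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids in `counts`")
  if (is.null(taxonomy)) {
    taxonomy <- data.frame(taxon_id = colnames(counts), stringsAsFactors = FALSE)
  }
  if (is.null(taxonomy$taxon_id)) stop("`taxonomy` must have a `taxon_id` column")
  taxonomy <- taxonomy[match(colnames(counts), taxonomy$taxon_id), , drop = FALSE]
  if (any(is.na(taxonomy$taxon_id))) {
    stop("taxonomy missing for taxa: ",
         paste(setdiff(colnames(counts), taxonomy$taxon_id), collapse = ", "))
  }
  rownames(taxonomy) <- NULL
  if (length(amplicon) == 1L) amplicon <- rep(amplicon, ncol(counts))
  if (length(amplicon) != ncol(counts)) {
    stop("`amplicon` must be a single tag or one tag per taxon")
  }
  if (is.null(component)) component <- assign_component(taxonomy)
  structure(
    list(counts = counts, rel_abund = rel_abund, taxonomy = taxonomy,
         component = stats::setNames(as.character(component), colnames(counts)),
         amplicon = stats::setNames(as.character(amplicon), colnames(counts))),
    class = "community_table"
  )
}

#' @export
print.community_table <- function(x, ...) {
  cat("community_table:", nrow(x$counts), "samples x", ncol(x$counts), "taxa\n")
  cat("  amplicons:", paste(unique(x$amplicon), collapse = ", "), "\n")
  if (ncol(x$counts)) {
    tab <- table(factor(x$component,
                        levels = c("bacteria", "fungi", "parasites", "diet", "other")))
    cat("  components:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  cat("  normalized:", !is.null(x$rel_abund), "\n")
  invisible(x)
}

#' @export
dim.community_table <- function(x) dim(x$counts)

## subset a community table by sample / taxon index or name
subset_community <- function(ct, samples = NULL, taxa = NULL) {
  if (is.null(samples)) samples <- rownames(ct$counts)
  if (is.null(taxa)) taxa <- colnames(ct$counts)
  community_table(
    ct$counts[samples, taxa, drop = FALSE],
    taxonomy = ct$taxonomy[match(colnames(ct$counts[, taxa, drop = FALSE]),
                                 ct$taxonomy$taxon_id), , drop = FALSE],
    amplicon = ct$amplicon[taxa],
    rel_abund = if (!is.null(ct$rel_abund)) ct$rel_abund[samples, taxa, drop = FALSE],
    component = ct$component[taxa]
  )
}

.phyla_bacteria <- c("Firmicutes", "Bacteroidota", "Deferribacterota",
                     "Proteobacteria", "Desulfobacterota", "Verrucomicrobiota",
                     "Actinobacteriota", "Campylobacterota", "Cyanobacteria",
                     "Fusobacteriota", "Patescibacteria")
.phyla_fungi <- c("Mucoromycota", "Ascomycota", "Basidiomycota")
.phyla_diet <- c("Anthophyta", "Phragmoplastophyta", "Charophyta", "Ochrophyta")
.genera_parasites <- c("Eimeria", "Cryptosporidium", "Syphacia", "Aspiculuris",
                       "Mastophorus", "Trichuris", "Hymenolepis", "Tritrichomonas")

#' Assign community-component labels from taxonomy
#'
#' Decomposes the collated community into its components: `bacteria` (the
#' common murine gut bacterial phyla, or unclassified bacteria), `fungi`
#' (Mucoromycota, Ascomycota, Basidiomycota), `diet` (plant-derived phyla used
#' as a diet proxy), `parasites` (known intestinal parasitic genera plus the
#' order Ascaridida), and `other` for everything unmatched. Total function:
#' every lineage receives exactly one label. Parasite genera take precedence
#' over phylum rules (e.g. *Tritrichomonas* annotations).
#'
#' @param taxonomy Data frame with any of the lineage columns `kingdom`,
#'   `phylum`, `order`, `genus`.
#' @return Character vector of labels, one per row of `taxonomy`, each one of
#'   `"bacteria"`, `"fungi"`, `"parasites"`, `"diet"`, `"other"`.
#' @export
assign_component <- function(taxonomy) {
  n <- nrow(taxonomy)
  get <- function(col) {
    v <- taxonomy[[col]]
    if (is.null(v)) rep(NA_character_, n) else as.character(v)
  }
  phylum <- get("phylum"); genus <- get("genus")
  ord <- get("order"); kingdom <- get("kingdom")
  lab <- rep("other", n)
  lab[phylum %in% .phyla_bacteria] <- "bacteria"
  unclass_bact <- !is.na(kingdom) & kingdom == "Bacteria" &
    (is.na(phylum) | phylum == "" | grepl("unclassified", phylum, ignore.case = TRUE))
  lab[unclass_bact] <- "bacteria"
  lab[phylum %in% .phyla_fungi] <- "fungi"
  lab[phylum %in% .phyla_diet] <- "diet"
  lab[genus %in% .genera_parasites] <- "parasites"
  lab[!is.na(ord) & ord == "Ascaridida"] <- "parasites"
  lab
}

.empty_table_condition <- function(msg) {
  warning(warningCondition(msg, class = "dyadmm_empty_table"))
}

#' Quality-filter an ASV table
#'
#' Applies the standard amplicon quality filters, per amplicon, in a fixed
#' order: (1) drop samples with fewer than `min_sample_reads` total reads;
#' (2) drop taxa with prevalence (fraction of *retained* samples in which the
#' taxon is observed) below `min_prevalence`; (3) drop taxa whose relative
#' abundance falls below `min_rel_abund`. Prevalence is computed on the
#' post-depth-filter sample set, because retained-sample identity changes
#' prevalence denominators.
#'
#' Defaults are 1% prevalence, 0.005% relative abundance, 100 reads.
#'
#' @param ct A [community_table] of raw counts.
#' @param min_prevalence Minimum fraction of retained samples with count > 0.
#' @param min_rel_abund Minimum relative abundance. With
#'   `abundance_rule = "pooled"` (default) this is the taxon's total count over
#'   the grand total of the retained table; with `"per_sample_mean"` it is the
#'   mean of the taxon's per-sample relative abundances.
#' @param min_sample_reads Minimum library size for a sample to be retained.
#' @param abundance_rule `"pooled"` or `"per_sample_mean"`.
#' @return Filtered `community_table`. If nothing survives, an empty table is
#'   returned with a `dyadmm_empty_table` warning.
#' @export
filter_asvs <- function(ct, min_prevalence = 0.01, min_rel_abund = 5e-5,
                        min_sample_reads = 100,
                        abundance_rule = c("pooled", "per_sample_mean")) {
  stopifnot(inherits(ct, "community_table"))
  abundance_rule <- match.arg(abundance_rule)
  counts <- ct$counts

  keep_s <- rowSums(counts) >= min_sample_reads
  counts <- counts[keep_s, , drop = FALSE]
  if (nrow(counts) == 0L) {
    .empty_table_condition("all samples removed by the read-depth filter")
    return(subset_community(ct, samples = character(0)))
  }

  prev <- colMeans(counts > 0)
  keep_t <- prev >= min_prevalence
  counts <- counts[, keep_t, drop = FALSE]

  if (ncol(counts)) {
    rel <- if (abundance_rule == "pooled") {
      colSums(counts) / sum(counts)
    } else {
      colMeans(counts / pmax(rowSums(counts), 1))
    }
    counts <- counts[, rel >= min_rel_abund, drop = FALSE]
  }
  if (ncol(counts) == 0L) {
    .empty_table_condition("all taxa removed by prevalence/abundance filters")
  }
  subset_community(ct, samples = rownames(counts), taxa = colnames(counts))
}

#' Total sum scaling
#'
#' Converts filtered counts to relative abundances: each sample's row is
#' divided by its library size, so every retained sample's relative abundances
#' sum to one.
#'
#' @param ct A filtered [community_table]; every sample total must be positive.
#' @return The table with its `rel_abund` slot filled.
#' @export
total_sum_scale <- function(ct) {
  stopifnot(inherits(ct, "community_table"))
  tot <- rowSums(ct$counts)
  if (any(tot <= 0)) {
    stop("zero-total sample(s): ",
         paste(rownames(ct$counts)[tot <= 0], collapse = ", "),
         " (run filter_asvs() first)")
  }
  ct$rel_abund <- ct$counts / tot
  ct
}

#' Collate per-amplicon tables into one community table
#'
#' Column-wise concatenation keyed by sample id. Each amplicon is expected to
#' have been filtered and total-sum-scaled on its own; after collation a
#' sample's relative abundances sum to the number of amplicons in which it was
#' observed. Samples absent from an amplicon get zeros for that amplicon's
#' taxa. Taxon ids must be unique across amplicons (tag them with the amplicon
#' name upstream).
#'
#' @param tables List of normalized [community_table] objects.
#' @return A single collated `community_table`.
#' @export
merge_amplicons <- function(tables) {
  stopifnot(length(tables) >= 1L, all(vapply(tables, inherits, TRUE, "community_table")))
  all_taxa <- unlist(lapply(tables, function(t) colnames(t$counts)), use.names = FALSE)
  if (anyDuplicated(all_taxa)) {
    stop("duplicate taxon id across amplicons: ",
         paste(unique(all_taxa[duplicated(all_taxa)]), collapse = ", "))
  }
  samples <- sort(unique(unlist(lapply(tables, function(t) rownames(t$counts)))))
  fill <- function(mat) {
    out <- matrix(0, length(samples), ncol(mat),
                  dimnames = list(samples, colnames(mat)))
    out[rownames(mat), ] <- mat
    out
  }
  counts <- do.call(cbind, lapply(tables, function(t) fill(t$counts)))
  has_rel <- !vapply(tables, function(t) is.null(t$rel_abund), TRUE)
  rel <- if (all(has_rel)) {
    do.call(cbind, lapply(tables, function(t) fill(t$rel_abund)))
  } else NULL
  taxonomy <- do.call(rbind, lapply(tables, function(t) {
    tx <- t$taxonomy
    for (col in c("kingdom", "phylum", "class", "order", "family", "genus")) {
      if (is.null(tx[[col]])) tx[[col]] <- NA_character_
    }
    tx[, c("taxon_id", "kingdom", "phylum", "class", "order", "family", "genus")]
  }))
  community_table(counts, taxonomy = taxonomy,
                  amplicon = unlist(lapply(tables, `[[`, "amplicon"), use.names = FALSE),
                  rel_abund = rel,
                  component = unlist(lapply(tables, `[[`, "component"), use.names = FALSE))
}

#' Read an ASV count table from TSV
#'
#' Accepts tab-delimited tables in either orientation. If the header's first
#' column is named `taxon_id` (or `asv_id`) the file is taken as taxa-by-
#' samples and transposed; if it is `sample_id` (or `host_id`) it is taken as
#' samples-by-taxa. Anything else is an error naming the file and column.
#'
#' @param path TSV path.
#' @param taxonomy Optional taxonomy data frame or TSV path
#'   (see [read_taxonomy_tsv()]).
#' @param amplicon Amplicon tag for all taxa in the file.
#' @return A [community_table] of raw counts.
#' @export
read_community_tsv <- function(path, taxonomy = NULL, amplicon = "amplicon1") {
  if (!file.exists(path)) stop("count table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  key <- names(df)[1L]
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- as.character(df[[1L]])
  if (key %in% c("taxon_id", "asv_id")) {
    mat <- t(mat)
  } else if (!key %in% c("sample_id", "host_id")) {
    stop("cannot ingest ", path, ": first header column is `", key,
         "`; expected `taxon_id`/`asv_id` (taxa x samples) or ",
         "`sample_id`/`host_id` (samples x taxa)")
  }
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("non-numeric or missing counts in ", path)
  if (is.character(taxonomy)) taxonomy <- read_taxonomy_tsv(taxonomy)
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[taxonomy$taxon_id %in% colnames(mat), , drop = FALSE]
  }
  community_table(mat, taxonomy = taxonomy, amplicon = amplicon)
}

#' Read a taxonomy table from TSV
#'
#' @param path TSV with columns `taxon_id` and lineage ranks
#'   (`kingdom` ... `genus`).
#' @return Data frame.
#' @export
read_taxonomy_tsv <- function(path) {
  if (!file.exists(path)) stop("taxonomy table not found: ", path)
  tx <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (is.null(tx$taxon_id)) stop("taxonomy table ", path, " lacks column `taxon_id`")
  tx
}

#' Read a BIOM v1 (JSON) count table
#'
#' Thin wrapper over the `biomformat` package; taxonomy is taken from the
#' BIOM observation metadata when present.
#'
#' @param path BIOM v1 JSON file.
#' @param amplicon Amplicon tag.
#' @return A [community_table] of raw counts.
#' @export
read_community_biom <- function(path, amplicon = "amplicon1") {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("reading BIOM files requires the `biomformat` package")
  }
  b <- biomformat::read_biom(path)
  mat <- t(as.matrix(biomformat::biom_data(b)))   # biom stores taxa x samples
  md <- biomformat::observation_metadata(b)
  taxonomy <- NULL
  if (is.data.frame(md) && ncol(md) >= 1L) {
    taxonomy <- data.frame(taxon_id = rownames(md), md,
                           stringsAsFactors = FALSE, row.names = NULL)
    ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
    names(taxonomy)[-1L] <- ranks[seq_len(ncol(md))]
  }
  community_table(mat, taxonomy = taxonomy, amplicon = amplicon)
}

#' Write a community table (and its component map) to TSV
#'
#' @param ct A [community_table].
#' @param path Output TSV for the abundance matrix (samples x taxa; relative
#'   abundances if normalized, raw counts otherwise).
#' @param component_path Optional TSV path for the per-taxon component map.
#' @return `path`, invisibly.
#' @export
write_community_tsv <- function(ct, path, component_path = NULL) {
  mat <- if (!is.null(ct$rel_abund)) ct$rel_abund else ct$counts
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(component_path)) {
    utils::write.table(
      data.frame(taxon_id = colnames(mat), component = ct$component[colnames(mat)],
                 amplicon = ct$amplicon[colnames(mat)], stringsAsFactors = FALSE),
      component_path, sep = "\t", quote = FALSE, row.names = FALSE,
      fileEncoding = "UTF-8")
  }
  invisible(path)
}
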