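test_that("read-depth filter drops shallow samples first", {
  counts <- rbind(s1 = c(150, 50), s2 = c(100, 50), s3 = c(30, 20))
  colnames(counts) <- c("t1", "t2")
  ct <- community_table(counts)
  out <- filter_asvs(ct, min_prevalence = 0, min_rel_abund = 0)
  expect_setequal(rownames(out$counts), c("s1", "s2"))
})

test_that("prevalence is computed on retained samples", {
  ## t2 occurs only in the to-be-dropped shallow sample: prevalence 0 after
  ## the depth filter, so it must go
  counts <- rbind(s1 = c(200, 0), s2 = c(150, 0), s3 = c(30, 20))
  colnames(counts) <- c("t1", "t2")
  out <- filter_asvs(community_table(counts), min_prevalence = 0.01,
                     min_rel_abund = 0)
  expect_identical(colnames(out$counts), "t1")
})

test_that("pooled relative-abundance rule drops 1-in-a-million taxa", {
  set.seed(5)
  n <- 10
  base <- matrix(100000, n, 1, dimnames = list(sprintf("s%d", 1:n), "big"))
  rare <- matrix(c(1, rep(0, n - 1)), n, 1,
                 dimnames = list(rownames(base), "rare"))
  ct <- community_table(cbind(base, rare))
  out <- filter_asvs(ct)  # grand total 1e6 + 1; 1/total < 5e-5
  expect_false("rare" %in% colnames(out$counts))
  expect_true("big" %in% colnames(out$counts))
})

test_that("filtering is idempotent and order-stable", {
  ct <- toy_community(seed = 2, n_samples = 20, n_taxa = 12)
  ## make it interesting: zero out some cells, shrink one sample
  ct$counts[1, ] <- c(rep(0, 11), 50)
  once <- filter_asvs(ct)
  twice <- filter_asvs(once)
  expect_equal(once$counts, twice$counts)
  perm <- subset_ord <- ct
  set.seed(9)
  perm$counts <- ct$counts[sample(nrow(ct$counts)), sample(ncol(ct$counts))]
  perm <- community_table(perm$counts, taxonomy = ct$taxonomy,
                          amplicon = ct$amplicon[colnames(perm$counts)])
  reord <- filter_asvs(perm)
  expect_setequal(colnames(reord$counts), colnames(once$counts))
  expect_setequal(rownames(reord$counts), rownames(once$counts))
  expect_equal(reord$counts[rownames(once$counts), colnames(once$counts)],
               once$counts)
})

test_that("an emptied table signals an explicit empty-result condition", {
  counts <- matrix(5, 2, 2, dimnames = list(c("s1", "s2"), c("t1", "t2")))
  expect_warning(out <- filter_asvs(community_table(counts)),
                 class = "dyadmm_empty_table")
  expect_identical(nrow(out$counts), 0L)
})

test_that("total sum scaling yields row-stochastic relative abundances", {
  counts <- rbind(s1 = c(2, 2, 0), s2 = c(1, 0, 3))
  colnames(counts) <- c("a", "b", "c")
  ct <- total_sum_scale(community_table(counts))
  expect_equal(ct$rel_abund["s1", ], c(a = 0.5, b = 0.5, c = 0))
  expect_equal(ct$rel_abund["s2", ], c(a = 0.25, b = 0, c = 0.75))
  expect_equal(unname(rowSums(ct$rel_abund)), c(1, 1), tolerance = 1e-9)
  zero <- community_table(matrix(c(1, 0, 1, 0), 2, 2,
                                 dimnames = list(c("s1", "s2"), c("a", "b"))))
  expect_error(total_sum_scale(zero), "zero-total")
})

test_that("component assignment partitions taxa into the five labels", {
  tax <- data.frame(
    taxon_id = sprintf("t%d", 1:8),
    kingdom = c("Bacteria", "Bacteria", "Fungi", "Eukaryota", "Eukaryota",
                "Eukaryota", "Eukaryota", "Bacteria"),
    phylum = c("Firmicutes", "Proteobacteria", "Ascomycota", "Anthophyta",
               "Apicomplexa", "Ciliophora", "Nematoda", NA),
    order = c(NA, NA, NA, NA, NA, NA, "Ascaridida", NA),
    genus = c("Lactobacillus", "Escherichia", "Kazachstania", "Triticum",
              "Eimeria", "Paramecium", NA, NA),
    stringsAsFactors = FALSE
  )
  lab <- assign_component(tax)
  expect_equal(lab, c("bacteria", "bacteria", "fungi", "diet", "parasites",
                      "other", "parasites", "bacteria"))
  expect_true(all(lab %in% c("bacteria", "fungi", "parasites", "diet", "other")))
  ## Tritrichomonas is a parasite even though its phylum is not listed
  expect_equal(assign_component(data.frame(taxon_id = "x",
                                           phylum = "Parabasalia",
                                           genus = "Tritrichomonas")),
               "parasites")
})

test_that("amplicon collation zero-fills missing samples and sums taxa", {
  m1 <- matrix(c(4, 2, 4, 6), 2, 2,
               dimnames = list(c("s1", "s2"), c("16S_t1", "16S_t2")))
  m2 <- matrix(10, 2, 1, dimnames = list(c("s1", "s3"), "ITS_t1"))
  c1 <- community_table(m1, amplicon = "16S")
  c2 <- community_table(m2, amplicon = "ITS")
  merged <- merge_amplicons(list(total_sum_scale(c1), total_sum_scale(c2)))
  expect_setequal(rownames(merged$counts), c("s1", "s2", "s3"))
  expect_identical(ncol(merged$counts), 3L)
  expect_equal(merged$rel_abund["s2", "ITS_t1"], 0)   # s2 absent from ITS
  expect_equal(merged$rel_abund["s1", "16S_t1"], 0.5)
  ## duplicate taxon ids across amplicons are rejected
  dup <- community_table(matrix(1, 1, 1, dimnames = list("s1", "16S_t1")),
                         amplicon = "x")
  expect_error(merge_amplicons(list(c1, dup)), "duplicate taxon id")
})

test_that("TSV ingestion auto-detects orientation and rejects bad headers", {
  ct <- toy_community(seed = 7)
  d <- withr::local_tempdir()
  f1 <- file.path(d, "samples_by_taxa.tsv")
  write.table(data.frame(sample_id = rownames(ct$counts), ct$counts,
                         check.names = FALSE),
              f1, sep = "\t", quote = FALSE, row.names = FALSE)
  f2 <- file.path(d, "taxa_by_samples.tsv")
  write.table(data.frame(taxon_id = colnames(ct$counts), t(ct$counts),
                         check.names = FALSE),
              f2, sep = "\t", quote = FALSE, row.names = FALSE)
  a <- read_community_tsv(f1)
  b <- read_community_tsv(f2)
  expect_equal(a$counts, b$counts)
  f3 <- file.path(d, "bad.tsv")
  write.table(data.frame(wrong = "x", v = 1), f3, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_community_tsv(f3), "bad.tsv.*wrong")
})

test_that("BIOM v1 tables ingest with taxonomy metadata", {
  skip_if_not_installed("biomformat")
  ct <- toy_community(seed = 3, n_samples = 4, n_taxa = 3)
  d <- withr::local_tempdir()
  ## build a minimal BIOM v1 JSON by hand
  biom_json <- list(
    id = "toy", format = "Biological Observation Matrix 1.0.0",
    format_url = "http://biom-format.org",
    type = "OTU table", generated_by = "dyadmm-test",
    date = "2026-01-01T00:00:00",
    matrix_type = "dense", matrix_element_type = "int",
    shape = c(ncol(ct$counts), nrow(ct$counts)),
    rows = lapply(colnames(ct$counts), function(t)
      list(id = t, metadata = list(taxonomy = list("Bacteria", "Firmicutes")))),
    columns = lapply(rownames(ct$counts), function(s)
      list(id = s, metadata = NULL)),
    data = unname(lapply(seq_len(ncol(ct$counts)), function(i)
      as.integer(ct$counts[, i])))
  )
  f <- file.path(d, "toy.biom")
  jsonlite::write_json(biom_json, f, auto_unbox = TRUE, digits = NA)
  b <- read_community_biom(f)
  expect_equal(b$counts[rownames(ct$counts), colnames(ct$counts)],
               ct$counts)
})
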