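test_that("structural report flags codon features", {
  g <- plant_gene("ATGAAATAA")
  r <- structural_report(g$model, g$genome)
  expect_true(r$has_start); expect_true(r$has_stop)
  expect_identical(r$inframe_stop_count, 0L)
  expect_identical(r$cds_length, 9L)
  expect_true(r$is_monoexonic)
  expect_true(is.na(r$min_intron_len))

  planted <- plant_gene("ATGTAAAAATAA")
  r2 <- structural_report(planted$model, planted$genome)
  expect_identical(r2$inframe_stop_count, 1L)

  # lowercase carries no sequence meaning; N fails the codon check
  soft <- plant_gene("atgAAAtaa")
  r3 <- structural_report(soft$model, soft$genome)
  expect_true(r3$has_start); expect_true(r3$has_stop)
  nstart <- plant_gene("ANGAAATAA")
  expect_false(structural_report(nstart$model, nstart$genome)$has_start)

  # non-zero phase on the transcript-first segment marks start-absent
  ph <- plant_gene("ATGAAATAA")
  ph$model$phases[1] <- 1L
  expect_false(structural_report(ph$model, ph$genome)$has_start)
})

test_that("structural report agrees with a codon-walking oracle", {
  set.seed(21)
  genome <- random_genome(2500L, c("c1", "c2"))
  for (i in 1:200) {
    m <- random_model(paste0("g", i), genome)
    got <- structural_report(m, genome)
    exp <- oracle_report(m, genome)
    for (f in names(exp)) expect_equal(got[[f]], exp[[f]], info = f)
  }
})

test_that("structural filters remove each defect class for its own reason", {
  bundle <- generate_fixture(fixture_spec(
    seed = 31, clean_multi = 8, clean_mono = 2, short_cds = 10,
    short_exon = 10, short_intron = 10, no_start = 10, no_stop = 10,
    internal_stop = 10, softmasked = 0, te_domain = 0, mono_no_domain = 0,
    no_function = 0, duplicate_pairs = 0, nested_cluster_sizes = integer(),
    partial_overlap_pairs = 0))
  out <- apply_structural_filters(bundle$primary, bundle$genome)
  expect_identical(length(out), 10L)
  expect_identical(sort(gene_ids(out)),
                   sort(grep("^clean", bundle$truth$gene_id, value = TRUE)))
  counts <- table(out$log$reason)
  for (r in c("min_cds", "min_exon", "min_intron", "no_start", "no_stop",
              "inframe_stop"))
    expect_identical(as.integer(counts[[r]]), 10L, info = r)
})

test_that("filters conserve genes, are idempotent, and min_cds is monotone", {
  bundle <- canonical_bundle(seed = 32)
  set <- bundle$primary
  cfg <- filter_config()
  out <- apply_structural_filters(set, bundle$genome, cfg)
  expect_identical(length(set), length(out) + nrow(out$log))
  twice <- apply_structural_filters(out, bundle$genome, cfg)
  expect_identical(twice$models, out$models)
  survivors <- integer()
  for (mc in c(100L, 300L, 500L, 1000L)) {
    survivors <- c(survivors, length(apply_structural_filters(
      set, bundle$genome, filter_config(min_cds = mc))))
  }
  expect_true(all(diff(survivors) <= 0L))
})

test_that("deduplication keeps one representative per identity or overlap", {
  a <- gene_model("g2", "chr1", "+", c(0L, 50L), c(20L, 80L))
  b <- gene_model("g1", "chr1", "+", c(0L, 50L), c(20L, 80L))
  set <- annotation_set(list(a, b))
  out <- deduplicate_unique(set)
  expect_identical(gene_ids(out), "g1")      # lexicographically smallest id
  expect_identical(out$log$reason, "duplicate")

  disjoint <- annotation_set(list(
    gene_model("a", "chr1", "+", 0L, 10L),
    gene_model("b", "chr1", "+", 20L, 30L),
    gene_model("c", "chr1", "-", 5L, 25L)))   # opposite strand may overlap
  expect_identical(deduplicate_unique(disjoint)$models, disjoint$models)
})

test_that("deduplication matches the exhaustive pairwise oracle", {
  set.seed(22)
  for (rep in 1:10) {
    genome <- random_genome(800L)
    models <- lapply(sprintf("x%02d", 1:30), random_model, genome = genome)
    # plant a few exact copies to exercise the duplicate branch
    models[[31]] <- models[[3]]; models[[31]]$gene_id <- "x99"
    models[[32]] <- models[[7]]; models[[32]]$gene_id <- "x00"
    set <- annotation_set(models)
    out <- deduplicate_unique(set)
    expect_identical(sort(gene_ids(out)), oracle_dedup_survivors(models))
    expect_identical(length(set), length(out) + nrow(out$log))
    expect_identical(deduplicate_unique(out)$models, out$models)
  }
})

test_that("summary statistics match a flat recomputation", {
  one <- annotation_set(list(gene_model("g", "chr1", "+", 0L, 500L)))
  s <- summarize_annotation(one)
  expect_identical(s$total_genes, 1L)
  expect_equal(s$average_gene_length, 500)
  expect_equal(s$median_gene_length, 500L)
  expect_identical(s$longest_intron, 0L)

  two <- annotation_set(list(gene_model("a", "chr1", "+", 0L, 100L),
                             gene_model("b", "chr1", "+", 200L, 500L)))
  expect_equal(summarize_annotation(two)$average_gene_length, 200)
  # lower-middle median for even counts
  expect_identical(summarize_annotation(two)$median_gene_length, 100L)

  empty <- summarize_annotation(annotation_set())
  expect_identical(empty$total_genes, 0L)
  expect_equal(empty$average_gene_length, 0)

  set.seed(23)
  genome <- random_genome(60000L, c("c1", "c2", "c3"))
  models <- lapply(sprintf("s%03d", 1:500), random_model, genome = genome)
  ids <- vapply(models, function(m) m$gene_id, character(1))
  set <- annotation_set(models)
  got <- summarize_annotation(set)
  exp <- oracle_summary(set)
  expect_identical(got$total_genes, exp$total)
  expect_equal(got$average_gene_length, exp$avg)
  expect_identical(as.integer(got$median_gene_length), as.integer(exp$med))
  expect_identical(got$multiexonic_count, exp$multi)
  expect_identical(got$monoexonic_count, exp$mono)
  expect_identical(got$longest_intron, exp$longest_intron)
  expect_equal(got$mean_exons_per_multiexonic, exp$mean_ex_multi)
})

test_that("shared-model counting is by coordinates, not gene ids", {
  set.seed(24)
  genome <- random_genome(20000L)
  models <- lapply(sprintf("a%02d", 1:50), random_model, genome = genome)
  a <- annotation_set(models)
  expect_equal(shared_models(a, a)$fraction, 1.0)
  # rename 37 of them in b and drop the rest: still shared by coordinates
  renamed <- lapply(models[1:37], function(m) { m$gene_id <- paste0("b_", m$gene_id); m })
  b <- annotation_set(renamed)
  sh <- shared_models(a, b)
  expect_identical(sh$count, 37L)
  expect_equal(sh$fraction, 0.74)
  expect_equal(shared_models(a, annotation_set())$fraction, 0)
  expect_equal(shared_models(annotation_set(), a)$fraction, 0)
})
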