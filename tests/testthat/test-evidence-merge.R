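span_model <- function(id, start, end, strand = "+", seq_id = "chr1")
  gene_model(id, seq_id, strand, as.integer(start), as.integer(end))

test_that("overlap classification covers all span relations", {
  expect_identical(classify_overlap(span_model("a", 100, 200),
                                    span_model("b", 150, 400)), "partial")
  expect_identical(classify_overlap(span_model("a", 150, 180),
                                    span_model("b", 100, 400)), "a_in_b")
  expect_identical(classify_overlap(span_model("a", 100, 400),
                                    span_model("b", 150, 180)), "b_in_a")
  expect_identical(classify_overlap(span_model("a", 100, 200),
                                    span_model("b", 100, 200)), "identical")
  expect_identical(classify_overlap(span_model("a", 100, 200),
                                    span_model("b", 200, 300)), "none")
  expect_identical(classify_overlap(span_model("a", 100, 200),
                                    span_model("b", 150, 400, strand = "-")),
                   "none")
  expect_identical(classify_overlap(span_model("a", 100, 200),
                                    span_model("b", 100, 300)), "a_in_b")
})

test_that("overlap classification matches a per-base set oracle", {
  set.seed(61)
  for (i in 1:1000) {
    s1 <- sample.int(200, 1); e1 <- s1 + sample.int(60, 1)
    s2 <- sample.int(200, 1); e2 <- s2 + sample.int(60, 1)
    strands <- sample(c("+", "-"), 2, replace = TRUE)
    a <- span_model("a", s1, e1, strands[1])
    b <- span_model("b", s2, e2, strands[2])
    expect_identical(classify_overlap(a, b), oracle_overlap(a, b))
    # symmetry of the nested pair
    ab <- classify_overlap(a, b); ba <- classify_overlap(b, a)
    if (ab == "a_in_b") expect_identical(ba, "b_in_a")
    if (ab == "partial") expect_identical(ba, "partial")
  }
})

test_that("completeness dominates length, then CDS, span, and id decide", {
  complete <- plant_gene(clean_cds(300), id = "comp")     # 900 bp complete
  incomplete_cds <- paste0("GTG", substr(clean_cds(500), 4, 1500))
  incomplete <- plant_gene(incomplete_cds, id = "inc")
  kc <- completeness_key(complete$model, complete$genome)
  ki <- completeness_key(incomplete$model, incomplete$genome)
  expect_identical(compare_completeness(kc, ki), 1L)

  a <- plant_gene(clean_cds(400), id = "g1")              # 1200 bp
  b <- plant_gene(clean_cds(300), id = "g2")              # 900 bp
  expect_identical(compare_completeness(
    completeness_key(a$model, a$genome),
    completeness_key(b$model, b$genome)), 1L)

  # full tie decided by gene id, smaller id wins
  g <- plant_gene(clean_cds(120), id = "g1")
  m2 <- g$model; m2$gene_id <- "g2"
  expect_identical(compare_completeness(
    completeness_key(g$model, g$genome),
    completeness_key(m2, g$genome)), 1L)
})

test_that("nested primary models are displaced by evidence", {
  g <- plant_gene(clean_cds(300), id = "evid1")           # 900 bp + pads
  evidence <- annotation_set(list(g$model))
  nested <- gene_model("prim1", "chr1", "+",
                       g$model$starts[1] + 30L, g$model$starts[1] + 120L)
  primary <- annotation_set(list(nested))
  res <- merge_annotations(primary, evidence, g$genome)
  expect_identical(gene_ids(res$set), "evid1")
  expect_identical(res$decisions$action, "replaced_nested")
  expect_identical(res$decisions$displaced_ids, "prim1")
  expect_identical(res$set$log$reason, "displaced_by:evid1")

  # empty evidence: identity
  res2 <- merge_annotations(primary, annotation_set(), g$genome)
  expect_identical(res2$set$models, primary$models)
  expect_identical(res2$decisions$action, "kept")
})

test_that("novel evidence loci are excluded unless requested", {
  bundle <- plant_gene(clean_cds(120), id = "p1")
  far <- gene_model("e1", "chr1", "+",
                    nchar(bundle$genome[[1]]) - 12L,
                    nchar(bundle$genome[[1]]) - 3L)
  primary <- annotation_set(list(bundle$model))
  evidence <- annotation_set(list(far))
  res <- merge_annotations(primary, evidence, bundle$genome)
  expect_identical(gene_ids(res$set), "p1")
  res2 <- merge_annotations(primary, evidence, bundle$genome,
                            include_novel_evidence = TRUE)
  expect_identical(sort(gene_ids(res2$set)), c("e1", "p1"))
})

test_that("clusters of primaries under one evidence span collapse to one", {
  bundle <- generate_fixture(fixture_spec(
    seed = 62, clean_multi = 5, clean_mono = 0, short_cds = 0, short_exon = 0,
    short_intron = 0, no_start = 0, no_stop = 0, internal_stop = 0,
    softmasked = 0, te_domain = 0, mono_no_domain = 0, no_function = 0,
    duplicate_pairs = 0, nested_cluster_sizes = c(3L, 7L, 20L),
    partial_overlap_pairs = 4L))
  res <- merge_annotations(bundle$primary, bundle$evidence, bundle$genome)
  dec <- res$decisions
  clusters <- dec[dec$action == "extended_cluster", ]
  expect_identical(nrow(clusters), 3L)
  sizes <- sort(vapply(strsplit(clusters$displaced_ids, ","), length,
                       integer(1)))
  expect_identical(sizes, c(3L, 7L, 20L))
  expect_identical(sum(dec$action == "replaced_partial"), 4L)

  # exhaustive pairwise truth: primaries nested in some evidence are gone
  exp_gone <- character()
  for (p in bundle$primary$models) {
    for (e in bundle$evidence$models) {
      if (classify_overlap(p, e) %in% c("a_in_b", "identical"))
        exp_gone <- c(exp_gone, p$gene_id)
    }
  }
  expect_true(all(!exp_gone %in% gene_ids(res$set)))

  # provenance conservation: each primary id appears exactly once
  displaced <- unlist(strsplit(dec$displaced_ids[dec$displaced_ids != ""], ","))
  kept_primary <- dec$output_gene_id[dec$origin == "abinitio"]
  expect_identical(sort(c(displaced, kept_primary)),
                   sort(gene_ids(bundle$primary)))

  # no same-strand nested pair survives
  out <- res$set$models
  for (i in seq_along(out)) for (j in seq_along(out)) {
    if (i != j)
      expect_false(classify_overlap(out[[i]], out[[j]]) %in%
                     c("a_in_b", "identical"))
  }

  # determinism under permutation of both inputs
  set.seed(63)
  p2 <- annotation_set(sample(unname(bundle$primary$models)))
  e2 <- annotation_set(sample(unname(bundle$evidence$models)))
  res2 <- merge_annotations(p2, e2, bundle$genome)
  expect_identical(res2$set$models, res$set$models)
  expect_identical(res2$decisions, res$decisions)

  # size bound
  expect_true(length(res$set) <=
                length(bundle$primary) + length(bundle$evidence))
})

test_that("partial overlaps resolve toward the more complete, longer model", {
  # evidence wins: longer complete CDS
  bundle <- generate_fixture(fixture_spec(
    seed = 64, clean_multi = 2, clean_mono = 0, short_cds = 0, short_exon = 0,
    short_intron = 0, no_start = 0, no_stop = 0, internal_stop = 0,
    softmasked = 0, te_domain = 0, mono_no_domain = 0, no_function = 0,
    duplicate_pairs = 0, nested_cluster_sizes = integer(),
    partial_overlap_pairs = 3L))
  res <- merge_annotations(bundle$primary, bundle$evidence, bundle$genome)
  dec <- res$decisions
  expect_identical(sum(dec$action == "replaced_partial"), 3L)
  expect_true(all(grepl("^evid_part", dec$output_gene_id[
    dec$action == "replaced_partial"])))

  # primary wins when it is the more complete model
  set.seed(65)
  g <- plant_gene(clean_cds(200), exon_lens = c(300L, 300L),
                  intron_lens = 50L, id = "strong_p")
  sp <- g$model$starts
  weak <- gene_model("weak_e", "chr1", "+", sp[2] + 10L, sp[2] + 400L)
  genome <- g$genome
  # extend the sequence so the weak model fits
  genome[[1]] <- paste0(genome[[1]],
                        paste(rep("A", 500), collapse = ""))
  expect_identical(classify_overlap(g$model, weak), "partial")
  res2 <- merge_annotations(annotation_set(list(g$model)),
                            annotation_set(list(weak)), genome)
  expect_identical(gene_ids(res2$set), "strong_p")
  expect_identical(res2$decisions$action, "kept")
})
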