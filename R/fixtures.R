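#' Specification for a synthetic annotation fixture
#'
#' Describes a deterministic toy genome plus gene-model sets, functional
#' and domain tables, and the truth table of expected per-gene fates.
#' Each defect class plants genes violating exactly one filtering rule;
#' clean genes violate none. Defaults give the canonical mixed fixture:
#' ten genes per defect class, five nested clusters of 3 to 20 ab initio
#' models under single spanning evidence models, and about 200 genes in
#' total.
#'
#' @param seed Integer RNG seed; identical specs generate byte-identical
#'   bundles.
#' @param n_sequences Number of genome sequences genes are distributed
#'   over.
#' @param sequence_length Optional fixed sequence length in bp; the
#'   generator errors if the planted genes do not fit. `NULL` sizes each
#'   sequence to its content.
#' @param clean_multi,clean_mono Counts of defect-free multiexonic and
#'   monoexonic genes (kept by the full pipeline).
#' @param short_cds,short_exon,short_intron,no_start,no_stop,internal_stop
#'   Counts of genes violating the corresponding structural rule.
#' @param softmasked Count of genes whose CDS is softmasked above the
#'   removal threshold.
#' @param te_domain Count of genes carrying a transposable-element
#'   domain annotation.
#' @param mono_no_domain Count of monoexonic genes lacking any protein
#'   domain.
#' @param no_function Count of genes with no (or only sub-threshold)
#'   functional hits.
#' @param duplicate_pairs Count of byte-identical gene-model pairs.
#' @param nested_cluster_sizes Integer vector; each entry plants that
#'   many primary models inside one spanning evidence model.
#' @param partial_overlap_pairs Count of primary/evidence pairs with
#'   partial span overlap resolved toward the (longer, complete)
#'   evidence model.
#' @param mask_cds_fraction CDS softmask fraction for the `softmasked`
#'   class; must exceed the 0.80 removal threshold.
#' @param mask_tract_count,mask_tract_len Background softmask tracts
#'   placed in intergenic sequence (they touch no CDS).
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_sequences = 2L, sequence_length = NULL,
                         clean_multi = 14L, clean_mono = 6L,
                         short_cds = 10L, short_exon = 10L, short_intron = 10L,
                         no_start = 10L, no_stop = 10L, internal_stop = 10L,
                         softmasked = 10L, te_domain = 10L,
                         mono_no_domain = 10L, no_function = 10L,
                         duplicate_pairs = 10L,
                         nested_cluster_sizes = c(3L, 5L, 8L, 12L, 20L),
                         partial_overlap_pairs = 10L,
                         mask_cds_fraction = 0.85,
                         mask_tract_count = 10L, mask_tract_len = 150L) {
  counts <- c(clean_multi = clean_multi, clean_mono = clean_mono,
              short_cds = short_cds, short_exon = short_exon,
              short_intron = short_intron, no_start = no_start,
              no_stop = no_stop, internal_stop = internal_stop,
              softmasked = softmasked, te_domain = te_domain,
              mono_no_domain = mono_no_domain, no_function = no_function,
              duplicate_pairs = duplicate_pairs,
              partial_overlap_pairs = partial_overlap_pairs)
  stopifnot(all(counts >= 0), all(nested_cluster_sizes >= 1),
            n_sequences >= 1, mask_cds_fraction > 0.80,
            mask_cds_fraction <= 1)
  structure(c(list(seed = as.integer(seed),
                   n_sequences = as.integer(n_sequences),
                   sequence_length = sequence_length,
                   nested_cluster_sizes = as.integer(nested_cluster_sizes),
                   mask_cds_fraction = mask_cds_fraction,
                   mask_tract_count = as.integer(mask_tract_count),
                   mask_tract_len = as.integer(mask_tract_len)),
              as.list(counts)),
            class = "fixture_spec")
}

SENSE_CODONS <- {
  all64 <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                 paste0), c("T", "C", "A", "G"), paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

rand_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a valid CDS of n_codons codons: ATG, sense codons, one stop
rand_cds <- function(n_codons) {
  stopifnot(n_codons >= 2L)
  paste0("ATG",
         paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
               collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

# split length L into k parts, each >= the matching entry of mins
partition_lengths <- function(L, k, mins) {
  stopifnot(L >= sum(mins))
  extra <- L - sum(mins)
  add <- if (k == 1L) extra else {
    cuts <- sort(sample.int(extra + k - 1L, k - 1L))
    diff(c(0L, cuts, extra + k)) - 1L
  }
  mins + add
}

#' Generate a synthetic fixture bundle
#'
#' Builds the genome, primary (ab initio) and evidence
#' (transcriptome-alignment) annotation sets, functional-hit and
#' domain-hit tables, and the truth table assigning every planted gene
#' its expected fate under the default [filter_config()]:
#' `kept`, `removed:<reason>`, or `displaced_by:<evidence id>`.
#' Generation is fully seeded: identical specs give byte-identical
#' bundles.
#'
#' @param spec A [fixture_spec()].
#' @return List with elements `genome`, `primary`, `evidence`,
#'   `functional`, `domains`, `truth` and `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(spec$seed)

  st <- new.env(parent = emptyenv())
  st$chunks <- replicate(spec$n_sequences, list(), simplify = FALSE)
  st$cursor <- integer(spec$n_sequences)
  st$next_seq <- 1L
  st$primary <- list(); st$evidence <- list()
  st$functional <- list(); st$domains <- list(); st$truth <- list()

  add_chunk <- function(seqi, s) {
    at <- st$cursor[seqi]
    st$chunks[[seqi]] <- c(st$chunks[[seqi]], s)
    st$cursor[seqi] <- at + nchar(s)
    at
  }
  pick_seq <- function() {
    seqi <- st$next_seq
    st$next_seq <- if (seqi == spec$n_sequences) 1L else seqi + 1L
    seqi
  }
  add_filler <- function(seqi, n = sample(200:400, 1L)) {
    invisible(add_chunk(seqi, rand_dna(n)))
  }
  add_truth <- function(id, class, fate) {
    st$truth[[length(st$truth) + 1L]] <-
      data.frame(gene_id = id, class = class, fate = fate,
                 stringsAsFactors = FALSE)
  }
  add_hit <- function(id, pass = TRUE, strict = NA) {
    if (isTRUE(pass)) {
      lo <- if (isTRUE(strict)) 80 else 55
      hi <- if (identical(strict, FALSE)) 79 else 95
      qc <- round(stats::runif(1, lo, hi), 1)
      tc <- round(stats::runif(1, lo, hi), 1)
    } else {
      qc <- round(stats::runif(1, 20, 45), 1)
      tc <- round(stats::runif(1, 20, 45), 1)
    }
    st$functional[[length(st$functional) + 1L]] <- data.frame(
      gene_id = id,
      target_id = sprintf("sp|Q%05d|TARG_%s", sample.int(99999L, 1L),
                          toupper(substr(id, 1L, 4L))),
      query_coverage = qc, target_coverage = tc,
      evalue = signif(stats::runif(1, 1e-80, 1e-20), 3),
      description = "hypothetical conserved protein",
      stringsAsFactors = FALSE)
  }
  add_domain <- function(id, te = FALSE) {
    st$domains[[length(st$domains) + 1L]] <- if (te) data.frame(
      gene_id = id, accession = "PF03732", name = "Retrotrans_gag",
      description = "Retrotransposon gag protein", stringsAsFactors = FALSE)
    else data.frame(
      gene_id = id, accession = "PF00069", name = "Pkinase",
      description = "Protein kinase domain", stringsAsFactors = FALSE)
  }

  # --- core gene builder -------------------------------------------------
  # builds genomic content for one gene and returns its genic string plus
  # segment coordinates relative to the genic-string start
  build_gene <- function(class, k_exons = NULL, n_codons = NULL,
                         strand = sample(c("+", "-"), 1L)) {
    if (is.null(n_codons))
      n_codons <- if (class == "short_cds") 99L else sample(100:200, 1L)
    if (is.null(k_exons))
      k_exons <- if (class %in% c("clean_mono", "mono_no_domain")) 1L
                 else sample(2:5, 1L)
    cds <- rand_cds(n_codons)
    L <- nchar(cds)
    if (class == "no_start") substr(cds, 1L, 3L) <- "GTG"
    if (class == "no_stop") substr(cds, L - 2L, L) <- sample(SENSE_CODONS, 1L)
    if (class == "internal_stop") {
      mid <- 3L * (n_codons %/% 2L) + 1L
      substr(cds, mid, mid + 2L) <- "TGA"
    }
    mins <- rep(9L, k_exons)
    if (class == "short_exon") mins[ceiling(k_exons / 2)] <- 8L
    ex_len <- partition_lengths(L, k_exons, mins)
    if (class == "short_exon") {
      short_i <- ceiling(k_exons / 2)
      ex_len[short_i] <- 8L                   # pin the defect exactly
      ex_len[k_exons] <- L - sum(ex_len[-k_exons])
      if (short_i == k_exons) stop("short_exon needs >= 2 exons")
    }
    in_len <- if (k_exons > 1L) sample(20:80, k_exons - 1L, replace = TRUE)
              else integer()
    if (class == "short_intron") in_len[sample.int(length(in_len), 1L)] <- 8L
    # transcript-order exon chunks of the CDS
    stops <- cumsum(ex_len)
    chunks <- substring(cds, c(1L, stops[-k_exons] + 1L), stops)
    genomic_ex <- if (strand == "+") chunks
                  else rev(vapply(chunks, reverse_complement, character(1)))
    if (class == "softmasked") {
      need <- ceiling(spec$mask_cds_fraction * L)
      for (i in seq_along(genomic_ex)) {
        if (need <= 0L) break
        take <- min(need, nchar(genomic_ex[i]))
        substr(genomic_ex[i], 1L, take) <- tolower(substr(genomic_ex[i], 1L, take))
        need <- need - take
      }
    }
    parts <- character(); rel_starts <- integer(); rel_ends <- integer()
    pos <- 0L
    for (i in seq_len(k_exons)) {
      parts <- c(parts, genomic_ex[i])
      rel_starts <- c(rel_starts, pos)
      pos <- pos + nchar(genomic_ex[i])
      rel_ends <- c(rel_ends, pos)
      if (i < k_exons) {
        parts <- c(parts, rand_dna(in_len[i]))
        pos <- pos + in_len[i]
      }
    }
    list(genic = paste(parts, collapse = ""), rel_starts = rel_starts,
         rel_ends = rel_ends, strand = strand, cds_len = L)
  }

  place_gene <- function(id, class, set = "primary", seqi = pick_seq(),
                         g = build_gene(class), source = "abinitio") {
    add_filler(seqi)
    at <- add_chunk(seqi, g$genic)
    m <- gene_model(id, paste0("chr", seqi), g$strand,
                    at + g$rel_starts, at + g$rel_ends, source = source)
    if (set == "primary") st$primary[[id]] <- m else st$evidence[[id]] <- m
    m
  }

  # --- simple per-class genes -------------------------------------------
  simple <- c(clean_multi = "kept", clean_mono = "kept",
              short_cds = "removed:min_cds", short_exon = "removed:min_exon",
              short_intron = "removed:min_intron",
              no_start = "removed:no_start", no_stop = "removed:no_stop",
              internal_stop = "removed:inframe_stop",
              softmasked = "removed:softmasked",
              te_domain = "removed:te_keyword",
              mono_no_domain = "removed:mono_no_domain",
              no_function = "removed:no_function_5050")
  for (class in names(simple)) {
    n <- spec[[class]]
    for (i in seq_len(n)) {
      id <- sprintf("%s_%03d", class, i)
      place_gene(id, class)
      add_truth(id, class, simple[[class]])
      if (class == "no_function") {
        if (i %% 2L == 0L) add_hit(id, pass = FALSE)   # odd ones: no hit at all
      } else {
        add_hit(id, pass = TRUE)
      }
      if (class %in% c("clean_mono", "softmasked")) add_domain(id)
      if (class == "clean_multi" && i %% 2L == 0L) add_domain(id)
      if (class == "te_domain") add_domain(id, te = TRUE)
    }
  }

  # --- byte-identical duplicate pairs ------------------------------------
  for (i in seq_len(spec$duplicate_pairs)) {
    seqi <- pick_seq()
    g <- build_gene("clean_multi")
    add_filler(seqi)
    at <- add_chunk(seqi, g$genic)
    ida <- sprintf("dup_%03d_a", i); idb <- sprintf("dup_%03d_b", i)
    for (id in c(ida, idb)) {
      st$primary[[id]] <- gene_model(id, paste0("chr", seqi), g$strand,
                                     at + g$rel_starts, at + g$rel_ends,
                                     source = "abinitio")
      add_hit(id, pass = TRUE)
    }
    add_truth(ida, "duplicate", "kept")
    add_truth(idb, "duplicate", "removed:duplicate")
  }

  # --- nested clusters: k primary models inside one evidence intron ------
  for (ci in seq_along(spec$nested_cluster_sizes)) {
    k <- spec$nested_cluster_sizes[ci]
    seqi <- pick_seq()
    eid <- sprintf("evid_nest_%03d", ci)
    ecds <- rand_cds(150L)                       # 450 bp, split over 2 exons
    exa <- substr(ecds, 1L, 225L); exb <- substr(ecds, 226L, 450L)
    add_filler(seqi)
    e_start <- add_chunk(seqi, exa)
    add_filler(seqi, sample(40:80, 1L))
    members <- character(k)
    for (j in seq_len(k)) {
      mid <- sprintf("nest_%03d_%03d", ci, j)
      members[j] <- mid
      g <- build_gene("clean_multi", strand = "+")
      at <- add_chunk(seqi, g$genic)
      st$primary[[mid]] <- gene_model(mid, paste0("chr", seqi), "+",
                                      at + g$rel_starts, at + g$rel_ends,
                                      source = "abinitio")
      add_hit(mid, pass = TRUE)
      add_truth(mid, "nested_cluster", paste0("displaced_by:", eid))
      add_filler(seqi, sample(40:80, 1L))
    }
    eb_start <- add_chunk(seqi, exb)
    st$evidence[[eid]] <- gene_model(eid, paste0("chr", seqi), "+",
                                     c(e_start, eb_start),
                                     c(e_start + 225L, eb_start + 225L),
                                     source = "alignment")
    add_hit(eid, pass = TRUE); add_domain(eid)
    add_truth(eid, "nested_evidence", "kept")
  }

  # --- partial-overlap pairs: evidence wins on completeness key ----------
  for (i in seq_len(spec$partial_overlap_pairs)) {
    seqi <- pick_seq()
    eid <- sprintf("evid_part_%03d", i)
    pid <- sprintf("part_%03d", i)
    ecds <- rand_cds(200L)                       # 600 bp evidence CDS
    exa <- substr(ecds, 1L, 300L); exb <- substr(ecds, 301L, 600L)
    pcds <- rand_cds(100L)                       # 300 bp primary CDS
    pxa <- substr(pcds, 1L, 150L); pxb <- substr(pcds, 151L, 300L)
    add_filler(seqi)
    e_start <- add_chunk(seqi, exa)              # evidence exon A
    add_filler(seqi, sample(30:60, 1L))
    p_start <- add_chunk(seqi, pxa)              # primary exon 1, in E's intron
    add_filler(seqi, sample(30:60, 1L))
    eb_start <- add_chunk(seqi, exb)             # evidence exon B
    add_filler(seqi, sample(30:60, 1L))
    pb_start <- add_chunk(seqi, pxb)             # primary exon 2, past E's end
    st$evidence[[eid]] <- gene_model(eid, paste0("chr", seqi), "+",
                                     c(e_start, eb_start),
                                     c(e_start + 300L, eb_start + 300L),
                                     source = "alignment")
    st$primary[[pid]] <- gene_model(pid, paste0("chr", seqi), "+",
                                    c(p_start, pb_start),
                                    c(p_start + 150L, pb_start + 150L),
                                    source = "abinitio")
    add_hit(eid, pass = TRUE); add_domain(eid)
    add_hit(pid, pass = TRUE)
    add_truth(pid, "partial_overlap", paste0("displaced_by:", eid))
    add_truth(eid, "partial_evidence", "kept")
  }

  # --- background softmask tracts in fresh intergenic sequence -----------
  for (i in seq_len(spec$mask_tract_count)) {
    seqi <- pick_seq()
    add_filler(seqi)
    add_chunk(seqi, tolower(rand_dna(spec$mask_tract_len)))
  }
  for (seqi in seq_len(spec$n_sequences)) add_filler(seqi)

  genome <- vapply(seq_len(spec$n_sequences), function(seqi)
    paste(unlist(st$chunks[[seqi]]), collapse = ""), character(1))
  names(genome) <- paste0("chr", seq_len(spec$n_sequences))
  if (!is.null(spec$sequence_length)) {
    for (seqi in seq_len(spec$n_sequences)) {
      n <- nchar(genome[[seqi]])
      if (n > spec$sequence_length)
        stop("infeasible packing: chr", seqi, " needs ", n,
             " bp but sequence_length is ", spec$sequence_length, call. = FALSE)
      genome[[seqi]] <- paste0(genome[[seqi]],
                               rand_dna(spec$sequence_length - n))
    }
  }

  bind <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  list(genome = genome,
       primary = annotation_set(unname(st$primary)),
       evidence = annotation_set(unname(st$evidence)),
       functional = bind(st$functional, data.frame(
         gene_id = character(), target_id = character(),
         query_coverage = numeric(), target_coverage = numeric(),
         evalue = numeric(), description = character(),
         stringsAsFactors = FALSE)),
       domains = bind(st$domains, data.frame(
         gene_id = character(), accession = character(), name = character(),
         description = character(), stringsAsFactors = FALSE)),
       truth = bind(st$truth, data.frame(
         gene_id = character(), class = character(), fate = character(),
         stringsAsFactors = FALSE)),
       spec = spec)
}

#' Write a fixture bundle to disk in its native formats
#'
#' Emits `genome.fa`, `primary.gff3`, `evidence.gff3`, `functional.tsv`,
#' `domains.tsv` and `truth.tsv` into `dir`. All writers are
#' deterministic, so two bundles from the same spec produce
#' byte-identical files.
#'
#' @param bundle A bundle from [generate_fixture()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             primary = file.path(dir, "primary.gff3"),
             evidence = file.path(dir, "evidence.gff3"),
             functional = file.path(dir, "functional.tsv"),
             domains = file.path(dir, "domains.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_fasta(bundle$genome, paths[["genome"]])
  write_gff3(bundle$primary, paths[["primary"]])
  write_gff3(bundle$evidence, paths[["evidence"]])
  for (tab in c("functional", "domains", "truth")) {
    utils::write.table(bundle[[tab]], paths[[tab]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
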