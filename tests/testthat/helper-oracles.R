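# Independent brute-force oracles and small builders used across tests.
# The oracles deliberately share no code with the implementation paths
# they check: per-base loops, codon walks, O(n^2) pairwise scans.

BASES <- c("A", "C", "G", "T")

random_genome <- function(n = 600L, ids = "chr1", lower_frac = 0.2) {
  g <- vapply(ids, function(id) {
    ch <- sample(BASES, n, replace = TRUE)
    low <- runif(n) < lower_frac
    ch[low] <- tolower(ch[low])
    paste(ch, collapse = "")
  }, character(1))
  names(g) <- ids
  g
}

# a random (not necessarily biologically clean) model within the genome
random_model <- function(id, genome, seq_id = sample(names(genome), 1L)) {
  n <- nchar(genome[[seq_id]])
  k <- sample(1:4, 1L)
  # pick k disjoint segments with gaps >= 1
  pts <- sort(sample.int(n, 2L * k))
  starts <- pts[seq(1L, 2L * k, 2L)] - 1L
  ends <- pts[seq(2L, 2L * k, 2L)]
  ok <- ends > starts
  starts <- starts[ok]; ends <- ends[ok]
  if (!length(starts)) { starts <- 0L; ends <- min(3L, n) }
  # enforce non-overlap (trim any touching/overlapping neighbours)
  keep <- c(TRUE, ends[-length(ends)] <= starts[-1L])
  gene_model(id, seq_id, sample(c("+", "-"), 1L),
             starts[keep], ends[keep], source = "test")
}

# plant a gene with an exact CDS at a given position; returns genome + model
plant_gene <- function(cds, strand = "+", exon_lens = nchar(cds),
                       intron_lens = integer(), pad = 25L, id = "g1",
                       seq_id = "chr1") {
  stopifnot(sum(exon_lens) == nchar(cds),
            length(intron_lens) == length(exon_lens) - 1L)
  stops <- cumsum(exon_lens)
  chunks <- substring(cds, c(1L, stops[-length(stops)] + 1L), stops)
  if (strand == "-")
    chunks <- rev(vapply(chunks, annorefine::reverse_complement, character(1)))
  parts <- character(); starts <- integer(); ends <- integer()
  pos <- pad
  rand <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")
  parts <- rand(pad)
  for (i in seq_along(chunks)) {
    parts <- c(parts, chunks[i])
    starts <- c(starts, pos); pos <- pos + nchar(chunks[i])
    ends <- c(ends, pos)
    if (i < length(chunks)) {
      parts <- c(parts, rand(intron_lens[i])); pos <- pos + intron_lens[i]
    }
  }
  parts <- c(parts, rand(pad))
  genome <- setNames(paste(parts, collapse = ""), seq_id)
  list(genome = genome,
       model = gene_model(id, seq_id, strand, starts, ends, source = "test"))
}

# a valid CDS of n codons (ATG ... stop) with no internal stops
clean_cds <- function(n_codons, stop = "TAA") {
  sense <- setdiff(as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0)),
                   c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(sense, n_codons - 2L, replace = TRUE),
                      collapse = ""), stop)
}

# ---- oracles ----------------------------------------------------------

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
          a = "t", c = "g", g = "c", t = "a", n = "n")

oracle_spliced <- function(model, genome) {
  s <- strsplit(genome[[model$seq_id]], "")[[1]]
  out <- character()
  for (i in seq_along(model$starts)) {
    out <- c(out, s[(model$starts[i] + 1L):model$ends[i]])
  }
  if (model$strand == "-") out <- rev(unname(COMP[out]))
  paste(out, collapse = "")
}

oracle_report <- function(model, genome) {
  cds <- toupper(oracle_spliced(model, genome))
  ch <- strsplit(cds, "")[[1]]
  codons <- character()
  i <- 1L
  while (i + 2L <= length(ch)) {
    codons <- c(codons, paste(ch[i:(i + 2L)], collapse = ""))
    i <- i + 3L
  }
  ex <- model$ends - model$starts
  ins <- if (length(ex) > 1L)
    model$starts[-1L] - model$ends[-length(ex)] else integer()
  first_phase <- if (model$strand == "+") model$phases[1L]
                 else model$phases[length(model$phases)]
  stops <- c("TAA", "TAG", "TGA")
  list(cds_length = length(ch),
       exon_count = length(ex),
       is_monoexonic = length(ex) == 1L,
       min_exon_len = min(ex),
       min_intron_len = if (length(ins)) min(ins) else NA_integer_,
       has_start = length(ch) >= 3L &&
         paste(ch[1:3], collapse = "") == "ATG" && first_phase == 0L,
       has_stop = length(ch) >= 3L &&
         paste(ch[(length(ch) - 2L):length(ch)], collapse = "") %in% stops,
       inframe_stop_count = if (length(codons) > 1L)
         sum(codons[-length(codons)] %in% stops) else 0L)
}

oracle_overlap <- function(a, b) {
  if (a$seq_id != b$seq_id || a$strand != b$strand) return("none")
  sa <- seq(model_span(a)[1L], model_span(a)[2L] - 1L)
  sb <- seq(model_span(b)[1L], model_span(b)[2L] - 1L)
  if (setequal(sa, sb)) return("identical")
  if (all(sa %in% sb)) return("a_in_b")
  if (all(sb %in% sa)) return("b_in_a")
  if (length(intersect(sa, sb))) return("partial")
  "none"
}

# exhaustive pairwise dedup: which gene ids survive?
oracle_dedup_survivors <- function(models) {
  ids <- vapply(models, function(m) m$gene_id, character(1))
  names(models) <- ids
  sig <- vapply(models, model_signature_oracle, character(1))
  drop <- rep(FALSE, length(models)); names(drop) <- ids
  for (s in unique(sig)) {
    grp <- sort(ids[sig == s])
    drop[grp[-1L]] <- TRUE
  }
  left <- models[!drop]
  # transitive overlap clusters by pairwise scan
  lid <- names(left)
  adj <- matrix(FALSE, length(left), length(left))
  for (i in seq_along(left)) for (j in seq_along(left)) {
    if (i != j && oracle_overlap(left[[i]], left[[j]]) != "none")
      adj[i, j] <- TRUE
  }
  comp <- seq_along(left)
  repeat {
    changed <- FALSE
    for (i in seq_along(left)) for (j in seq_along(left)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[c(i, j)] <- min(comp[i], comp[j]); changed <- TRUE
      }
    }
    if (!changed) break
  }
  survivors <- character()
  for (cl in unique(comp)) {
    grp <- left[comp == cl]
    cdsl <- vapply(grp, function(m) sum(m$ends - m$starts), integer(1))
    spl <- vapply(grp, function(m)
      max(m$ends) - min(m$starts), integer(1))
    survivors <- c(survivors, names(grp)[order(-cdsl, -spl, names(grp))[1L]])
  }
  sort(survivors)
}

model_signature_oracle <- function(m)
  paste(m$seq_id, m$strand, paste(m$starts, m$ends, collapse = ";"))

oracle_summary <- function(set) {
  ms <- set$models
  spans <- vapply(ms, function(m) max(m$ends) - min(m$starts), integer(1))
  nex <- vapply(ms, function(m) length(m$starts), integer(1))
  introns <- integer()
  for (m in ms) {
    if (length(m$starts) > 1L)
      introns <- c(introns, m$starts[-1L] - m$ends[-length(m$ends)])
  }
  sorted <- sort(spans)
  lower_median <- sorted[ceiling(length(sorted) / 2)]
  list(total = length(ms), avg = mean(spans), med = lower_median,
       multi = sum(nex > 1L), mono = sum(nex == 1L),
       longest_intron = if (length(introns)) max(introns) else 0L,
       mean_ex_multi = if (any(nex > 1L)) sum(nex[nex > 1L]) / sum(nex > 1L)
                       else 0)
}

# canonical small fixture reused by several test files
canonical_bundle <- function(seed = 7L) generate_fixture(fixture_spec(seed = seed))
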