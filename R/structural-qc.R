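STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Structural report for a gene model
#'
#' Computes the per-gene structural facts the filtering cascade judges:
#' CDS length, exon/intron geometry, presence of a start codon (spliced
#' CDS begins `ATG` and the transcript-first segment has phase 0),
#' presence of a terminal stop codon, and the number of in-frame stop
#' codons before the terminal codon. Codon checks are case-insensitive
#' (softmask lowercase carries no sequence meaning) but any `N` in a
#' codon fails the check.
#'
#' @param model A [gene_model()].
#' @param genome Named character vector from [read_genome()].
#' @return A list of class `structural_report` with fields `cds_length`,
#'   `exon_count`, `is_monoexonic`, `min_exon_len`, `min_intron_len`
#'   (`NA` for monoexonic models), `has_start`, `has_stop`,
#'   `inframe_stop_count`.
#' @export
structural_report <- function(model, genome) {
  cds <- toupper(spliced_cds(model, genome))
  n <- nchar(cds)
  exl <- exon_lengths(model)
  inl <- intron_lengths(model)
  # transcript-first segment: leftmost on +, rightmost on -
  first_phase <- if (model$strand == "+") model$phases[1L]
                 else model$phases[length(model$phases)]
  n_codon <- n %/% 3L
  codons <- if (n_codon > 0L)
    substring(cds, seq(1L, by = 3L, length.out = n_codon),
              seq(3L, by = 3L, length.out = n_codon))
  else character()
  internal <- if (n_codon > 1L) codons[-n_codon] else character()
  structure(list(
    cds_length = n,
    exon_count = length(exl),
    is_monoexonic = length(exl) == 1L,
    min_exon_len = min(exl),
    min_intron_len = if (length(inl)) min(inl) else NA_integer_,
    has_start = substr(cds, 1L, 3L) == "ATG" && first_phase == 0L,
    has_stop = n >= 3L && substr(cds, n - 2L, n) %in% STOP_CODONS,
    inframe_stop_count = sum(internal %in% STOP_CODONS)
  ), class = "structural_report")
}

#' @export
print.structural_report <- function(x, ...) {
  cat(sprintf(paste0("<structural_report> CDS %d bp, %d exon(s), start %s, ",
                     "stop %s, %d in-frame stop(s)\n"),
              x$cds_length, x$exon_count, x$has_start, x$has_stop,
              x$inframe_stop_count))
  invisible(x)
}

#' Apply structural filters to an annotation set
#'
#' Removes gene models failing any of the structural rules: spliced CDS
#' shorter than `min_cds`, any exon shorter than `min_exon`, any intron
#' shorter than `min_intron`, a missing start or stop codon (when
#' `require_start_stop`), or more in-frame stop codons than
#' `allowed_inframe_stops`. Each removal is logged once, with the first
#' failing reason in the fixed order `min_cds`, `min_exon`, `min_intron`,
#' `no_start`, `no_stop`, `inframe_stop`. Survivors are unmodified.
#'
#' @param set An [annotation_set()].
#' @param genome Named character vector from [read_genome()].
#' @param config A [filter_config()].
#' @param stage Stage tag recorded in the rejection log.
#' @return The filtered [annotation_set()].
#' @export
apply_structural_filters <- function(set, genome, config = filter_config(),
                                     stage = "structural") {
  ids <- character(); reasons <- character()
  for (m in set$models) {
    r <- structural_report(m, genome)
    reason <-
      if (r$cds_length < config$min_cds) "min_cds"
      else if (r$min_exon_len < config$min_exon) "min_exon"
      else if (!r$is_monoexonic && r$min_intron_len < config$min_intron) "min_intron"
      else if (config$require_start_stop && !r$has_start) "no_start"
      else if (config$require_start_stop && !r$has_stop) "no_stop"
      else if (r$inframe_stop_count > config$allowed_inframe_stops) "inframe_stop"
      else NA_character_
    if (!is.na(reason)) {
      ids <- c(ids, m$gene_id); reasons <- c(reasons, reason)
    }
  }
  drop_models(set, ids, stage, reasons)
}

#' Collapse duplicate and redundant overlapping models
#'
#' Two-phase uniqueness pass. First, models with identical
#' (seq_id, strand, segment coordinates) collapse to the one with the
#' lexicographically smallest gene id (reason `duplicate`). Second,
#' among models whose genomic spans overlap on the same strand, one
#' representative is kept per overlap cluster: greatest CDS length, ties
#' broken by greatest span, then smallest gene id; the rest are logged
#' as `redundant_isoform`.
#'
#' @param set An [annotation_set()].
#' @param stage Stage tag recorded in the rejection log.
#' @return The deduplicated [annotation_set()].
#' @export
deduplicate_unique <- function(set, stage = "dedup") {
  models <- set$models
  if (!length(models)) return(set)

  sig <- vapply(models, model_signature, character(1))
  ids <- names(models)
  dup_drop <- character()
  for (s in unique(sig[duplicated(sig)])) {
    grp <- sort(ids[sig == s])
    dup_drop <- c(dup_drop, grp[-1L])
  }
  set <- drop_models(set, dup_drop, stage, "duplicate")
  models <- set$models

  # cluster same-strand span overlaps by sweep line, keep one per cluster
  key <- vapply(models, function(m) paste(m$seq_id, m$strand), character(1))
  iso_drop <- character()
  for (k in unique(key)) {
    grp <- models[key == k]
    sta <- vapply(grp, function(m) model_span(m)[1L], integer(1))
    end <- vapply(grp, function(m) model_span(m)[2L], integer(1))
    ord <- order(sta, end)
    cluster <- integer(length(grp)); cur <- 0L; reach <- -1L
    for (i in ord) {
      if (sta[i] >= reach) { cur <- cur + 1L; reach <- end[i] }
      else reach <- max(reach, end[i])
      cluster[i] <- cur
    }
    for (cl in unique(cluster)) {
      cm <- grp[cluster == cl]
      if (length(cm) < 2L) next
      cdsl <- vapply(cm, cds_length, integer(1))
      spl <- vapply(cm, span_length, integer(1))
      keep <- order(-cdsl, -spl, names(cm))[1L]
      iso_drop <- c(iso_drop, names(cm)[-keep])
    }
  }
  drop_models(set, iso_drop, stage, "redundant_isoform")
}

#' Summary statistics of an annotation set
#'
#' Gene length is the genomic span (introns included). The median uses
#' the lower-middle convention for even counts, so medians of integer
#' lengths stay integers.
#'
#' @param set An [annotation_set()].
#' @return A list of class `annotation_summary` with fields
#'   `total_genes`, `average_gene_length`, `median_gene_length`,
#'   `multiexonic_count`, `monoexonic_count`, `longest_intron`,
#'   `mean_exons_per_multiexonic`. All zero for an empty set.
#' @export
summarize_annotation <- function(set) {
  models <- set$models
  if (!length(models)) {
    return(structure(list(total_genes = 0L, average_gene_length = 0,
                          median_gene_length = 0, multiexonic_count = 0L,
                          monoexonic_count = 0L, longest_intron = 0L,
                          mean_exons_per_multiexonic = 0),
                     class = "annotation_summary"))
  }
  spans <- unname(vapply(models, span_length, integer(1)))
  nex <- unname(vapply(models, function(m) length(m$starts), integer(1)))
  introns <- unlist(lapply(models, intron_lengths), use.names = FALSE)
  multi <- nex > 1L
  sorted <- sort(spans)
  structure(list(
    total_genes = length(models),
    average_gene_length = mean(spans),
    median_gene_length = sorted[ceiling(length(sorted) / 2)],
    multiexonic_count = sum(multi),
    monoexonic_count = sum(!multi),
    longest_intron = if (length(introns)) max(introns) else 0L,
    mean_exons_per_multiexonic = if (any(multi)) sum(nex[multi]) / sum(multi) else 0
  ), class = "annotation_summary")
}

#' @export
print.annotation_summary <- function(x, ...) {
  cat("Annotation summary\n")
  cat(sprintf("  Total genes:                  %d\n", x$total_genes))
  cat(sprintf("  Average gene length (bp):     %.2f\n", x$average_gene_length))
  cat(sprintf("  Median gene length (bp):      %d\n", as.integer(x$median_gene_length)))
  cat(sprintf("  Multiexonics:                 %d\n", x$multiexonic_count))
  cat(sprintf("  Monoexonics:                  %d\n", x$monoexonic_count))
  cat(sprintf("  Longest intron (bp):          %d\n", as.integer(x$longest_intron)))
  cat(sprintf("  Avg exons per multiexonic:    %.2f\n", x$mean_exons_per_multiexonic))
  invisible(x)
}

#' Shared gene models between two annotation sets
#'
#' A gene of `a` is shared when some gene of `b` has an identical
#' (seq_id, strand, segment coordinate list), irrespective of gene ids.
#'
#' @param a,b [annotation_set()] objects.
#' @return List with `count` (shared genes of `a`) and `fraction`
#'   (`count / |a|`, 0 for an empty `a`).
#' @export
shared_models <- function(a, b) {
  if (!length(a$models)) return(list(count = 0L, fraction = 0))
  sa <- vapply(a$models, model_signature, character(1))
  sb <- vapply(b$models, model_signature, character(1))
  n <- sum(sa %in% sb)
  list(count = n, fraction = n / length(sa))
}
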