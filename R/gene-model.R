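#' Construct a gene model
#'
#' A gene model is one gene's chain of CDS segments on a genome sequence.
#' Coordinates are 0-based half-open internally; the GFF3 reader/writer
#' converts to and from the 1-based inclusive surface convention.
#'
#' @param gene_id Unique identifier within an annotation set.
#' @param seq_id Genome sequence identifier all segments lie on.
#' @param strand `"+"` or `"-"`.
#' @param starts,ends Integer vectors of 0-based half-open segment
#'   coordinates. Segments must be non-overlapping; they are sorted by
#'   genomic start.
#' @param phases Integer vector of GFF3 phases (0/1/2), one per segment,
#'   in the same order as `starts`. Stored but not used to shift
#'   translation: translation always begins at CDS position 0, and a
#'   non-zero phase on the transcript-first segment marks the model as
#'   start-absent downstream.
#' @param source Free-text provenance label, e.g. `"abinitio"` or
#'   `"alignment"`.
#' @param attributes Named character vector of GFF3 attributes.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, seq_id, strand, starts, ends,
                       phases = rep(0L, length(starts)),
                       source = "unknown", attributes = character()) {
  stopifnot(length(gene_id) == 1L, nzchar(gene_id),
            length(seq_id) == 1L, length(strand) == 1L)
  if (!strand %in% c("+", "-"))
    stop("gene ", gene_id, ": strand must be '+' or '-'", call. = FALSE)
  n <- length(starts)
  if (n < 1L || length(ends) != n)
    stop("gene ", gene_id, ": needs >=1 segment with matching starts/ends",
         call. = FALSE)
  starts <- as.integer(starts); ends <- as.integer(ends)
  phases <- as.integer(phases)
  if (length(phases) != n) phases <- rep(0L, n)
  ord <- order(starts, ends)
  starts <- starts[ord]; ends <- ends[ord]; phases <- phases[ord]
  if (any(starts < 0L) || any(ends <= starts))
    stop("gene ", gene_id, ": invalid segment coordinates (need 0 <= start < end)",
         call. = FALSE)
  if (n > 1L && any(starts[-1L] < ends[-n]))
    stop("gene ", gene_id, ": overlapping CDS segments", call. = FALSE)
  structure(list(gene_id = gene_id, seq_id = seq_id, strand = strand,
                 starts = starts, ends = ends, phases = phases,
                 source = source, attributes = attributes),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s:%d-%d (%s)  %d segment(s), CDS %d bp, source %s\n",
              x$gene_id, x$seq_id, model_span(x)[1], model_span(x)[2],
              x$strand, length(x$starts), cds_length(x), x$source))
  invisible(x)
}

#' Genomic span of a gene model
#'
#' @param model A `gene_model`.
#' @return Integer vector `c(start, end)`, 0-based half-open: the minimum
#'   segment start and maximum segment end.
#' @export
model_span <- function(model) c(model$starts[1L], model$ends[length(model$ends)])

#' Span length (gene length) of a model in bp, introns included
#' @param model A `gene_model`.
#' @export
span_length <- function(model) diff(model_span(model))

#' Total CDS length of a model in bp (sum of segment lengths)
#' @param model A `gene_model`.
#' @export
cds_length <- function(model) sum(model$ends - model$starts)

#' Exon (CDS segment) lengths in genomic order
#' @param model A `gene_model`.
#' @export
exon_lengths <- function(model) model$ends - model$starts

#' Intron lengths in genomic order (empty for monoexonic models)
#' @param model A `gene_model`.
#' @export
intron_lengths <- function(model) {
  n <- length(model$starts)
  if (n < 2L) return(integer())
  model$starts[-1L] - model$ends[-n]
}

# canonical identity string used for duplicate collapsing and set comparison
model_signature <- function(model) {
  paste(model$seq_id, model$strand,
        paste(model$starts, model$ends, sep = "-", collapse = ","),
        sep = "|")
}

#' Construct an annotation set
#'
#' A keyed collection of gene models plus the per-gene rejection log that
#' filtering stages append to. Every removed gene carries exactly one log
#' record per removing stage, so `|input| = |kept| + |log removals|` holds
#' for each stage.
#'
#' @param models List of `gene_model` objects; names are taken from their
#'   `gene_id`s, which must be unique.
#' @param log Data frame with columns `gene_id`, `stage`, `reason`.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(models = list(), log = empty_log()) {
  ids <- vapply(models, function(m) m$gene_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate gene_id in annotation set: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(models) <- ids
  models <- models[order_models(models)]
  structure(list(models = models, log = log), class = "annotation_set")
}

empty_log <- function() {
  data.frame(gene_id = character(), stage = character(),
             reason = character(), stringsAsFactors = FALSE)
}

# deterministic gene order: (seq_id, span start, gene_id)
order_models <- function(models) {
  if (!length(models)) return(integer())
  seqs <- vapply(models, function(m) m$seq_id, character(1))
  sta <- vapply(models, function(m) model_span(m)[1L], integer(1))
  ids <- vapply(models, function(m) m$gene_id, character(1))
  order(seqs, sta, ids)
}

#' Number of gene models in an annotation set
#' @param x An `annotation_set`.
#' @param ... Unused.
#' @export
length.annotation_set <- function(x) length(x$models)

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d gene model(s), %d logged removal(s)\n",
              length(x$models), nrow(x$log)))
  invisible(x)
}

#' Gene identifiers of an annotation set, in canonical order
#' @param set An `annotation_set`.
#' @export
gene_ids <- function(set) names(set$models)

# remove `ids` from the set and append one log record each
drop_models <- function(set, ids, stage, reasons) {
  if (!length(ids)) return(set)
  stopifnot(all(ids %in% names(set$models)))
  if (length(reasons) == 1L) reasons <- rep(reasons, length(ids))
  set$log <- rbind(set$log,
                   data.frame(gene_id = ids, stage = stage, reason = reasons,
                              stringsAsFactors = FALSE))
  set$models <- set$models[setdiff(names(set$models), ids)]
  set
}
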