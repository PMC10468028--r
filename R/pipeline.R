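#' Run the full annotation refinement cascade
#'
#' Applies the refinement stages in fixed order to an ab initio
#' annotation, optionally merging in a transcriptome-alignment evidence
#' set that is first pushed through the same cascade:
#' structural filters, duplicate/redundancy collapsing, evidence merge,
#' softmask filter, transposable-element keyword filter, monoexonic
#' domain gate, functional 50/50 filter, and summary statistics.
#' Per-stage in/out counts are recorded; every removed gene carries one
#' rejection-log record, and merge displacements carry the displacing
#' evidence id.
#'
#' @param primary An [annotation_set()] of ab initio models, or a path
#'   to their GFF3 file.
#' @param genome Named character vector from [read_genome()], or a path
#'   to the softmasked FASTA.
#' @param evidence Optional [annotation_set()] (or GFF3 path) of
#'   transcriptome-alignment models.
#' @param functional Optional data frame of functional hits (or TSV
#'   path; see [read_functional_hits()]).
#' @param domains Optional data frame of domain hits (or TSV path; see
#'   [read_domain_hits()]).
#' @param config A [filter_config()]; `config$stages` toggles
#'   individual stages (disabling all of them returns the input set
#'   unchanged).
#' @return A list of class `refinement_result`: `annotation` (final
#'   [annotation_set()]), `summary` ([summarize_annotation()] plus
#'   `functional_rate_5050` and `functional_rate_8080` in percent),
#'   `stages` (data frame of per-stage in/out counts), `decisions`
#'   (merge decisions), `evidence_log` (rejections inside the evidence
#'   cascade), and `config`.
#' @export
run_refinement <- function(primary, genome, evidence = NULL,
                           functional = NULL, domains = NULL,
                           config = filter_config()) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_genome(genome)
  if (is.character(primary)) primary <- parse_gff3(primary, source = "abinitio")
  if (is.character(evidence)) evidence <- parse_gff3(evidence, source = "alignment")
  if (is.character(functional)) functional <- read_functional_hits(functional)
  if (is.character(domains)) domains <- read_domain_hits(domains)
  stopifnot(inherits(primary, "annotation_set"))
  on <- config$stages

  stages <- list()
  note <- function(name, n_in, n_out) {
    stages[[length(stages) + 1L]] <<- data.frame(
      stage = name, n_in = n_in, n_out = n_out, stringsAsFactors = FALSE)
  }
  step <- function(set, name, fun) {
    if (!on[[name]]) return(set)
    n_in <- length(set$models)
    set <- fun(set)
    note(name, n_in, length(set$models))
    set
  }

  cascade <- function(set, merge_target = FALSE) {
    set <- step(set, "structural", function(s)
      apply_structural_filters(s, genome, config))
    set <- step(set, "dedup", deduplicate_unique)
    if (merge_target) return(set)
    set <- step(set, "softmask", function(s)
      apply_repeat_filters(s, genome, domains, functional, config,
                           stage = "softmask", which = "softmask"))
    set <- step(set, "te", function(s)
      apply_repeat_filters(s, genome, domains, functional, config,
                           stage = "te", which = "te"))
    set <- step(set, "mono_domain", function(s)
      apply_repeat_filters(s, genome, domains, functional, config,
                           stage = "mono_domain", which = "mono_domain"))
    set <- step(set, "functional", function(s)
      apply_functional_filter(s, functional, config))
    set
  }

  decisions <- NULL; evidence_log <- NULL
  set <- cascade(primary, merge_target = TRUE)
  if (on[["merge"]] && !is.null(evidence)) {
    stages_main <- stages; stages <- list()     # evidence stages kept apart
    ev <- cascade(evidence)
    evidence_stages <- do.call(rbind, stages)
    stages <- stages_main
    evidence_log <- ev$log
    n_in <- length(set$models)
    merged <- merge_annotations(set, ev, genome,
                                include_novel_evidence =
                                  config$include_novel_evidence)
    set <- merged$set
    decisions <- merged$decisions
    note("merge", n_in, length(set$models))
  } else {
    evidence_stages <- NULL
  }
  set <- step(set, "softmask", function(s)
    apply_repeat_filters(s, genome, domains, functional, config,
                         stage = "softmask", which = "softmask"))
  set <- step(set, "te", function(s)
    apply_repeat_filters(s, genome, domains, functional, config,
                         stage = "te", which = "te"))
  set <- step(set, "mono_domain", function(s)
    apply_repeat_filters(s, genome, domains, functional, config,
                         stage = "mono_domain", which = "mono_domain"))
  set <- step(set, "functional", function(s)
    apply_functional_filter(s, functional, config))

  summary <- summarize_annotation(set)
  summary$functional_rate_5050 <- 100 * annotation_rate(
    set, functional, config$coverage_query, config$coverage_target)
  summary$functional_rate_8080 <- 100 * annotation_rate(
    set, functional, config$strict_query, config$strict_target)

  structure(list(annotation = set, summary = summary,
                 stages = do.call(rbind, stages) %||% data.frame(
                   stage = character(), n_in = integer(), n_out = integer(),
                   stringsAsFactors = FALSE),
                 evidence_stages = evidence_stages,
                 decisions = decisions, evidence_log = evidence_log,
                 config = config),
            class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat("Annotation refinement result\n")
  if (nrow(x$stages)) {
    cat("  Stages (in -> out):\n")
    for (i in seq_len(nrow(x$stages)))
      cat(sprintf("    %-12s %6d -> %6d\n", x$stages$stage[i],
                  x$stages$n_in[i], x$stages$n_out[i]))
  }
  cat(sprintf("  Final genes: %d  (functional 50/50: %.1f%%, 80/80: %.1f%%)\n",
              x$summary$total_genes, x$summary$functional_rate_5050,
              x$summary$functional_rate_8080))
  invisible(x)
}

#' Write refinement outputs to a directory
#'
#' Emits `annotation.gff3` (final models), `rejections.tsv` (per-gene
#' rejection log), `decisions.tsv` (merge decisions, when merging ran),
#' and `summary.json`.
#'
#' @param result A `refinement_result` from [run_refinement()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_refinement_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("annotation.gff3", "rejections.tsv",
                            "summary.json"))
  write_gff3(result$annotation, paths[1L])
  utils::write.table(result$annotation$log, paths[2L], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    c(unclass(result$summary),
      list(stages = result$stages)),
    paths[3L], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(result$decisions)) {
    p <- file.path(dir, "decisions.tsv")
    write_decisions(result$decisions, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
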