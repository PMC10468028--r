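#' Classify the overlap between two gene models
#'
#' Computed on genomic spans. Models on different sequences or strands
#' never interact (`none`; antisense nesting is biologically
#' legitimate). Identical spans are `identical`; a span strictly
#' contained in the other is `a_in_b`/`b_in_a`; any other positive
#' overlap is `partial`.
#'
#' @param a,b [gene_model()] objects.
#' @return One of `"none"`, `"identical"`, `"a_in_b"`, `"b_in_a"`,
#'   `"partial"`.
#' @export
classify_overlap <- function(a, b) {
  if (a$seq_id != b$seq_id || a$strand != b$strand) return("none")
  sa <- model_span(a); sb <- model_span(b)
  if (sa[1L] == sb[1L] && sa[2L] == sb[2L]) return("identical")
  if (sa[1L] >= sb[1L] && sa[2L] <= sb[2L]) return("a_in_b")
  if (sb[1L] >= sa[1L] && sb[2L] <= sa[2L]) return("b_in_a")
  if (sa[1L] < sb[2L] && sb[1L] < sa[2L]) return("partial")
  "none"
}

#' Completeness key used to resolve competing gene models
#'
#' Orders models by (completeness tier, CDS length, genomic span,
#' gene id). The tier counts start and stop codons: both present = 2,
#' exactly one = 1, neither = 0 — so a complete model always beats an
#' incomplete one regardless of length ("more complete" dominates "the
#' longer"). The gene id breaks full ties deterministically: the
#' lexicographically smaller id wins.
#'
#' @param model A [gene_model()].
#' @param genome Named character vector from [read_genome()].
#' @return A list key; compare with [compare_completeness()].
#' @export
completeness_key <- function(model, genome) {
  r <- structural_report(model, genome)
  list(tier = as.integer(r$has_start) + as.integer(r$has_stop),
       cds = r$cds_length,
       span = span_length(model),
       gene_id = model$gene_id)
}

#' Compare two completeness keys
#'
#' @param k1,k2 Keys from [completeness_key()].
#' @return 1 when `k1` wins, -1 when `k2` wins, never 0 (the gene id
#'   tie-break is total for distinct ids).
#' @export
compare_completeness <- function(k1, k2) {
  for (f in c("tier", "cds", "span")) {
    if (k1[[f]] > k2[[f]]) return(1L)
    if (k1[[f]] < k2[[f]]) return(-1L)
  }
  if (k1$gene_id < k2$gene_id) 1L else if (k1$gene_id > k2$gene_id) -1L else 0L
}

#' Merge ab initio gene models with transcriptome-alignment evidence
#'
#' Reconciles a primary (ab initio) annotation with trusted
#' transcriptome-alignment models:
#' \enumerate{
#'   \item every primary model whose span is nested in, or identical
#'     to, an evidence model's span (same sequence and strand) is
#'     displaced by that evidence model (`replaced_nested`);
#'   \item when one evidence model's span covers two or more primary
#'     models, all of them are displaced by the single evidence model
#'     (`extended_cluster`) — the mechanism that extends fragmented
#'     predictions into one long transcript-supported gene;
#'   \item partial span overlaps are resolved toward the longer, more
#'     complete model by [completeness_key()] (`replaced_partial` when
#'     the evidence model wins; the primary model is kept and the
#'     evidence model discarded otherwise), greedily in descending key
#'     order and iterated to a fixpoint, each model displacing or being
#'     displaced at most once per pass;
#'   \item non-overlapping models from both sets pass through (`kept`),
#'     except that evidence models displacing nothing and overlapping
#'     nothing are only added with `include_novel_evidence`.
#' }
#' The merge is deterministic: permuting input order leaves the output
#' set and decision list unchanged.
#'
#' @param primary An [annotation_set()] of ab initio models.
#' @param evidence An [annotation_set()] of transcriptome-alignment
#'   models, assumed already filtered to high quality.
#' @param genome Named character vector from [read_genome()]; every
#'   model's sequence must be present.
#' @param include_novel_evidence Add non-overlapping evidence models as
#'   novel loci.
#' @return List with `set` (the merged [annotation_set()]; displaced
#'   primary genes are logged under stage `merge`) and `decisions`
#'   (data frame: `output_gene_id`, `origin`, `action`,
#'   `displaced_ids`).
#' @export
merge_annotations <- function(primary, evidence, genome,
                              include_novel_evidence = FALSE) {
  for (m in c(primary$models, evidence$models)) {
    if (is.null(genome_seq(genome, m$seq_id)))
      stop("gene ", m$gene_id, ": sequence ", m$seq_id,
           " absent from genome", call. = FALSE)
  }
  pmod <- primary$models
  emod <- evidence$models
  pkey <- lapply(pmod, completeness_key, genome = genome)
  ekey <- lapply(emod, completeness_key, genome = genome)
  eord <- order_by_key_desc(ekey)

  active <- rep(TRUE, length(pmod)); names(active) <- names(pmod)
  used <- rep(FALSE, length(emod)); names(used) <- names(emod)
  dead <- rep(FALSE, length(emod)); names(dead) <- names(emod)
  displaced <- stats::setNames(vector("list", length(emod)), names(emod))
  nested_any <- rep(FALSE, length(emod)); names(nested_any) <- names(emod)

  # pass 1: nesting / identity
  for (ei in eord) {
    e <- emod[[ei]]
    hit <- character()
    for (pi in names(pmod)[active]) {
      cls <- classify_overlap(pmod[[pi]], e)
      if (cls %in% c("a_in_b", "identical")) hit <- c(hit, pi)
    }
    if (length(hit)) {
      active[hit] <- FALSE
      used[ei] <- TRUE
      nested_any[ei] <- TRUE
      displaced[[ei]] <- c(displaced[[ei]], hit)
    }
  }

  # pass 2+: partial overlaps, greedy by completeness, to fixpoint
  repeat {
    changed <- FALSE
    for (ei in eord) {
      if (dead[ei]) next
      e <- emod[[ei]]
      partners <- names(pmod)[active]
      partners <- partners[vapply(partners, function(pi)
        classify_overlap(pmod[[pi]], e) == "partial", logical(1))]
      if (!length(partners)) next
      best <- partners[[1L]]
      for (pi in partners[-1L]) {
        if (compare_completeness(pkey[[pi]], pkey[[best]]) > 0L) best <- pi
      }
      if (compare_completeness(ekey[[ei]], pkey[[best]]) > 0L) {
        active[best] <- FALSE
        used[ei] <- TRUE
        displaced[[ei]] <- c(displaced[[ei]], best)
        changed <- TRUE
      } else if (!used[ei]) {
        dead[ei] <- TRUE       # evidence loses the contest and is discarded
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  novel <- rep(FALSE, length(emod)); names(novel) <- names(emod)
  if (include_novel_evidence) {
    for (ei in names(emod)[!used & !dead]) {
      overlaps <- any(vapply(pmod, function(p)
        classify_overlap(p, emod[[ei]]) != "none", logical(1)))
      if (!overlaps) novel[ei] <- TRUE
    }
  }

  out_models <- c(pmod[active], emod[used | novel])
  out_ids <- vapply(out_models, function(m) m$gene_id, character(1))
  if (anyDuplicated(out_ids))
    stop("merged output would duplicate gene id(s): ",
         paste(unique(out_ids[duplicated(out_ids)]), collapse = ", "),
         call. = FALSE)

  decisions <- rbind(
    if (any(active)) data.frame(
      output_gene_id = names(pmod)[active], origin = "abinitio",
      action = "kept", displaced_ids = "", stringsAsFactors = FALSE),
    if (any(used)) data.frame(
      output_gene_id = names(emod)[used], origin = "alignment",
      action = vapply(names(emod)[used], function(ei) {
        if (length(displaced[[ei]]) >= 2L) "extended_cluster"
        else if (nested_any[ei]) "replaced_nested"
        else "replaced_partial"
      }, character(1)),
      displaced_ids = vapply(names(emod)[used], function(ei)
        paste(sort(displaced[[ei]]), collapse = ","), character(1)),
      stringsAsFactors = FALSE),
    if (any(novel)) data.frame(
      output_gene_id = names(emod)[novel], origin = "alignment",
      action = "kept", displaced_ids = "", stringsAsFactors = FALSE))
  if (is.null(decisions)) decisions <- data.frame(
    output_gene_id = character(), origin = character(),
    action = character(), displaced_ids = character(),
    stringsAsFactors = FALSE)
  decisions <- decisions[order(decisions$output_gene_id), , drop = FALSE]
  rownames(decisions) <- NULL

  merged <- annotation_set(out_models, log = primary$log)
  gone <- names(pmod)[!active]
  if (length(gone)) {
    by_evid <- stats::setNames(rep(NA_character_, length(gone)), gone)
    for (ei in names(displaced)) {
      for (pi in displaced[[ei]]) by_evid[pi] <- ei
    }
    merged$log <- rbind(merged$log, data.frame(
      gene_id = gone, stage = "merge",
      reason = paste0("displaced_by:", by_evid[gone]),
      stringsAsFactors = FALSE))
  }
  list(set = merged, decisions = decisions)
}

# deterministic descending order of completeness keys
order_by_key_desc <- function(keys) {
  if (!length(keys)) return(integer())
  tier <- vapply(keys, `[[`, numeric(1), "tier")
  cds <- vapply(keys, `[[`, numeric(1), "cds")
  span <- vapply(keys, `[[`, numeric(1), "span")
  ids <- vapply(keys, `[[`, character(1), "gene_id")
  order(-tier, -cds, -span, ids)
}

#' Write merge decisions as TSV
#'
#' @param decisions Decision data frame from [merge_annotations()].
#' @param file Output path.
#' @export
write_decisions <- function(decisions, file) {
  utils::write.table(decisions, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(decisions)
}
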