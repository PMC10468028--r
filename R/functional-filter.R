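#' Read functional similarity-search hits
#'
#' Either a headered TSV with columns `gene_id`, `target_id`,
#' `query_coverage`, `target_coverage`, `evalue`, `description`, or
#' 12-column tabular alignment output (BLAST outfmt-6 style) augmented
#' with query/target coverage columns; `qcov_col`, `tcov_col` and
#' `desc_col` map the extra columns.
#'
#' @param file Path to the table.
#' @param format `"table"` or `"outfmt6"`.
#' @param qcov_col,tcov_col,desc_col Column indices for the outfmt6
#'   layout (`desc_col = NULL` means no description column).
#' @return Data frame with the canonical six columns.
#' @export
read_functional_hits <- function(file, format = c("table", "outfmt6"),
                                 qcov_col = 13L, tcov_col = 14L,
                                 desc_col = NULL) {
  format <- match.arg(format)
  if (format == "table") {
    d <- utils::read.delim(file, stringsAsFactors = FALSE)
    need <- c("gene_id", "target_id", "query_coverage", "target_coverage",
              "evalue", "description")
    if (!all(need %in% names(d)))
      stop("functional table must have columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    return(d[need])
  }
  d <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE)
  data.frame(gene_id = d[[1L]], target_id = d[[2L]],
             query_coverage = as.numeric(d[[qcov_col]]),
             target_coverage = as.numeric(d[[tcov_col]]),
             evalue = as.numeric(d[[11L]]),
             description = if (!is.null(desc_col)) d[[desc_col]] else "",
             stringsAsFactors = FALSE)
}

#' Reduce hits to the best hit per gene
#'
#' Best is lowest e-value, ties broken by higher query coverage, then
#' lexicographically smallest target id — a fixed total order, so the
#' retained hit is deterministic.
#'
#' @param hits Data frame of functional hits.
#' @return Data frame with at most one row per `gene_id`.
#' @export
best_hits <- function(hits) {
  if (is.null(hits) || !nrow(hits)) return(hits)
  ord <- order(hits$gene_id, hits$evalue, -hits$query_coverage, hits$target_id)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits$gene_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Reciprocal coverage test
#'
#' Inclusive on both sides ("at least"): a hit passes when its query
#' coverage is >= `qmin` and its target coverage is >= `tmin`.
#'
#' @param hit Data frame of hits (one or more rows) with
#'   `query_coverage` and `target_coverage` columns in percent.
#' @param qmin,tmin Thresholds in percent.
#' @return Logical vector, one element per row of `hit`.
#' @export
coverage_pass <- function(hit, qmin, tmin) {
  hit$query_coverage >= qmin & hit$target_coverage >= tmin
}

#' Filter genes by presence of a functional annotation
#'
#' Removes genes with no hit passing the membership thresholds
#' (`coverage_query`/`coverage_target`, default 50/50); reason
#' `no_function_5050`. The stringent thresholds
#' (`strict_query`/`strict_target`, default 80/80) never remove
#' anything: they only set the `strict` flag on each survivor's
#' retained hit, for reporting. Survivors carry their best hit in the
#' returned set's `functional` element.
#'
#' @param set An [annotation_set()].
#' @param hits Data frame of functional hits (deduplicated internally
#'   via [best_hits()]).
#' @param config A [filter_config()].
#' @param stage Stage tag recorded in the rejection log.
#' @return The filtered [annotation_set()], with a `functional` data
#'   frame of surviving genes' best hits and their `strict` flags.
#' @export
apply_functional_filter <- function(set, hits, config = filter_config(),
                                    stage = "functional") {
  best <- best_hits(hits)
  keep_hit <- if (!is.null(best) && nrow(best))
    best[coverage_pass(best, config$coverage_query, config$coverage_target), ,
         drop = FALSE]
  else best
  passing <- if (is.null(keep_hit)) character() else keep_hit$gene_id
  gone <- setdiff(gene_ids(set), passing)
  set <- drop_models(set, gone, stage, "no_function_5050")
  if (!is.null(keep_hit) && nrow(keep_hit)) {
    keep_hit <- keep_hit[keep_hit$gene_id %in% gene_ids(set), , drop = FALSE]
    keep_hit$strict <- coverage_pass(keep_hit, config$strict_query,
                                     config$strict_target)
    rownames(keep_hit) <- NULL
    set$functional <- keep_hit
  } else {
    set$functional <- NULL
  }
  set
}

#' Fraction of genes with a passing functional annotation
#'
#' @param set An [annotation_set()].
#' @param hits Data frame of functional hits.
#' @param qmin,tmin Coverage thresholds in percent (inclusive).
#' @return Fraction in `[0, 1]`; 0 for an empty set.
#' @export
annotation_rate <- function(set, hits, qmin, tmin) {
  n <- length(set$models)
  if (!n) return(0)
  best <- best_hits(hits)
  if (is.null(best) || !nrow(best)) return(0)
  passing <- best$gene_id[coverage_pass(best, qmin, tmin)]
  sum(gene_ids(set) %in% passing) / n
}
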