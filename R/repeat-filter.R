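#' Softmask fraction of a gene model
#'
#' Fraction of lowercase (repeat-softmasked) bases in the model's
#' spliced CDS, or over its whole genomic span with `mode = "span"`.
#' The CDS mode is the default: in conifers introns are repeat-rich by
#' nature, and span-based masking would discard valid long-intron genes.
#'
#' @param model A [gene_model()].
#' @param genome Named character vector from [read_genome()].
#' @param mode `"cds"` or `"span"`.
#' @return Fraction in `[0, 1]`.
#' @export
mask_fraction <- function(model, genome, mode = c("cds", "span")) {
  mode <- match.arg(mode)
  s <- if (mode == "cds") {
    spliced_cds(model, genome)
  } else {
    seq <- genome_seq(genome, model$seq_id)
    if (is.null(seq))
      stop("gene ", model$gene_id, ": sequence ", model$seq_id,
           " absent from genome", call. = FALSE)
    sp <- model_span(model)
    if (sp[2L] > nchar(seq))
      stop("gene ", model$gene_id, ": span out of sequence bounds", call. = FALSE)
    substr(seq, sp[1L] + 1L, sp[2L])
  }
  lowercase_count(s) / nchar(s)
}

lowercase_count <- function(s) nchar(gsub("[^a-z]", "", s))

#' First transposable-element keyword matching any description
#'
#' Case-insensitive fixed-substring search of each keyword in each text;
#' keywords are tried in list order and the first one found anywhere is
#' returned.
#'
#' @param texts Character vector of description strings.
#' @param keywords Character vector of keywords (see [filter_config()]).
#' @return The matched keyword, or `NA_character_` when none matches.
#' @export
te_keyword_hit <- function(texts, keywords = filter_config()$te_keywords) {
  if (!length(texts)) return(NA_character_)
  lowered <- tolower(texts)
  for (kw in keywords) {
    if (any(grepl(tolower(kw), lowered, fixed = TRUE))) return(kw)
  }
  NA_character_
}

#' Read protein-domain hits
#'
#' Either a headered TSV with columns `gene_id`, `accession`, `name`,
#' `description`, or raw InterProScan 5 TSV output (no header; columns
#' 1, 5 and 6 are the protein id, signature accession and signature
#' description).
#'
#' @param file Path to the table.
#' @param format `"table"` or `"interproscan"`.
#' @return Data frame with columns `gene_id`, `accession`, `name`,
#'   `description`.
#' @export
read_domain_hits <- function(file, format = c("table", "interproscan")) {
  format <- match.arg(format)
  if (format == "table") {
    d <- utils::read.delim(file, stringsAsFactors = FALSE)
    need <- c("gene_id", "accession", "name", "description")
    if (!all(need %in% names(d)))
      stop("domain table must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    return(d[need])
  }
  d <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE)
  data.frame(gene_id = d[[1L]], accession = d[[5L]],
             name = d[[6L]], description = d[[6L]],
             stringsAsFactors = FALSE)
}

#' Apply repeat, transposable-element and monoexonic-domain filters
#'
#' Three ordered tests, each logging its own reason code:
#' \enumerate{
#'   \item `softmasked` — softmask fraction strictly greater than
#'     `max_mask_fraction` ("more than" 80% by default);
#'   \item `te_keyword` — any domain name/description or functional-hit
#'     description matches a TE keyword;
#'   \item `mono_no_domain` — monoexonic gene with no remaining
#'     (non-TE-matching) domain hit, when
#'     `monoexonic_requires_domain` is set.
#' }
#' The survivor set is independent of test order (the predicates do not
#' interact); the order only decides which reason a multiply-failing
#' gene is logged under.
#'
#' @param set An [annotation_set()].
#' @param genome Named character vector from [read_genome()].
#' @param domains Data frame from [read_domain_hits()] (or `NULL`).
#' @param functional Data frame of functional hits with `gene_id` and
#'   `description` columns (or `NULL`); used only for TE keyword text.
#' @param config A [filter_config()].
#' @param stage Stage tag recorded in the rejection log.
#' @param which Subset of tests to run, any of
#'   `c("softmask", "te", "mono_domain")`.
#' @return The filtered [annotation_set()].
#' @export
apply_repeat_filters <- function(set, genome, domains = NULL, functional = NULL,
                                 config = filter_config(), stage = "repeat",
                                 which = c("softmask", "te", "mono_domain")) {
  ids <- character(); reasons <- character()
  dom_by_gene <- if (!is.null(domains) && nrow(domains))
    split(domains, domains$gene_id) else list()
  fun_by_gene <- if (!is.null(functional) && nrow(functional) &&
                     "description" %in% names(functional))
    split(functional$description, functional$gene_id) else list()
  for (m in set$models) {
    g <- m$gene_id
    dom <- dom_by_gene[[g]]
    texts <- c(if (!is.null(dom)) c(dom$name, dom$description),
               fun_by_gene[[g]])
    reason <- NA_character_
    if ("softmask" %in% which &&
        mask_fraction(m, genome, config$mask_mode) > config$max_mask_fraction) {
      reason <- "softmasked"
    } else if ("te" %in% which &&
               !is.na(te_keyword_hit(texts, config$te_keywords))) {
      reason <- "te_keyword"
    } else if ("mono_domain" %in% which && config$monoexonic_requires_domain &&
               length(m$starts) == 1L) {
      valid <- if (is.null(dom) || !nrow(dom)) FALSE else {
        dtexts <- paste(dom$name, dom$description)
        any(vapply(dtexts,
                   function(t) is.na(te_keyword_hit(t, config$te_keywords)),
                   logical(1)))
      }
      if (!valid) reason <- "mono_no_domain"
    }
    if (!is.na(reason)) {
      ids <- c(ids, g); reasons <- c(reasons, reason)
    }
  }
  drop_models(set, ids, stage, reasons)
}
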