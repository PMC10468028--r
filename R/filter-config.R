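#' Filter configuration for the refinement cascade
#'
#' Bundles every threshold and keyword list the cascade uses. Defaults
#' are the published operating point for deep refinement of a draft
#' conifer annotation: minimum CDS 300 bp, minimum exon and intron 9 bp,
#' zero tolerated in-frame stops, removal of models lacking start or
#' stop codons, removal of models more than 80% softmasked, the
#' six-term retrotransposon keyword list, a 50/50 reciprocal coverage
#' membership filter and an 80/80 reporting stringency, and a required
#' protein domain for monoexonic genes.
#'
#' @param min_cds Minimum spliced CDS length in bp (inclusive: a CDS of
#'   exactly `min_cds` passes).
#' @param min_exon,min_intron Minimum exon/intron lengths in bp
#'   (inclusive minima).
#' @param allowed_inframe_stops Maximum tolerated in-frame stop codons
#'   before the terminal codon.
#' @param require_start_stop Remove models whose spliced CDS does not
#'   begin with ATG or end with a stop codon.
#' @param max_mask_fraction Softmask fraction above which (strictly) a
#'   model is removed.
#' @param mask_mode `"cds"` (default) computes the softmask fraction
#'   over the spliced CDS; `"span"` over the whole genomic span.
#' @param te_keywords Character vector of case-insensitive substrings
#'   identifying transposable-element annotations.
#' @param coverage_query,coverage_target Membership coverage thresholds
#'   in percent (inclusive, "at least").
#' @param strict_query,strict_target Reporting-only stringent coverage
#'   thresholds in percent.
#' @param monoexonic_requires_domain Remove monoexonic genes with no
#'   non-TE protein-domain hit.
#' @param include_novel_evidence During merging, add evidence models
#'   that displace nothing and overlap nothing.
#' @param stages Named logical vector toggling pipeline stages.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_cds = 300L, min_exon = 9L, min_intron = 9L,
                          allowed_inframe_stops = 0L,
                          require_start_stop = TRUE,
                          max_mask_fraction = 0.80,
                          mask_mode = c("cds", "span"),
                          te_keywords = c("gag-polypeptide", "retrotransposon",
                                          "reverse transcriptase", "retrovirus",
                                          "copia", "gypsy"),
                          coverage_query = 50, coverage_target = 50,
                          strict_query = 80, strict_target = 80,
                          monoexonic_requires_domain = TRUE,
                          include_novel_evidence = FALSE,
                          stages = c(structural = TRUE, dedup = TRUE,
                                     merge = TRUE, softmask = TRUE,
                                     te = TRUE, mono_domain = TRUE,
                                     functional = TRUE)) {
  mask_mode <- match.arg(mask_mode)
  stopifnot(min_cds > 0, min_exon > 0, min_intron > 0,
            allowed_inframe_stops >= 0,
            max_mask_fraction >= 0, max_mask_fraction <= 1,
            coverage_query >= 0, coverage_query <= 100,
            coverage_target >= 0, coverage_target <= 100,
            strict_query >= 0, strict_query <= 100,
            strict_target >= 0, strict_target <= 100,
            length(te_keywords) >= 1)
  full <- c(structural = TRUE, dedup = TRUE, merge = TRUE, softmask = TRUE,
            te = TRUE, mono_domain = TRUE, functional = TRUE)
  full[names(stages)] <- stages
  structure(list(min_cds = as.integer(min_cds),
                 min_exon = as.integer(min_exon),
                 min_intron = as.integer(min_intron),
                 allowed_inframe_stops = as.integer(allowed_inframe_stops),
                 require_start_stop = isTRUE(require_start_stop),
                 max_mask_fraction = max_mask_fraction,
                 mask_mode = mask_mode,
                 te_keywords = te_keywords,
                 coverage_query = coverage_query,
                 coverage_target = coverage_target,
                 strict_query = strict_query,
                 strict_target = strict_target,
                 monoexonic_requires_domain = isTRUE(monoexonic_requires_domain),
                 include_novel_evidence = isTRUE(include_novel_evidence),
                 stages = full),
            class = "filter_config")
}
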