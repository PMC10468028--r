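#' Parse gene models from a GFF3 file
#'
#' Reads the gene/mRNA/CDS feature hierarchy of a GFF3 file into an
#' [annotation_set()]. Each mRNA (or transcript) becomes an independent
#' gene model; when a file carries bare CDS rows with no transcript
#' features, models are grouped by the shared CDS `Parent` attribute.
#' GFF3 1-based inclusive coordinates are converted to the internal
#' 0-based half-open convention and segments are sorted by genomic start,
#' so row order in the file is immaterial. Feature types other than
#' gene/mRNA/transcript/CDS are ignored.
#'
#' @param file Path to a GFF3 file (plain or gzip).
#' @param text Character vector of GFF3 lines, as an alternative to `file`.
#' @param source Optional label overriding column 2 as each model's
#'   `source` (e.g. `"abinitio"`, `"alignment"`).
#' @return An [annotation_set()].
#' @export
parse_gff3 <- function(file = NULL, text = NULL, source = NULL) {
  lines <- if (is.null(text)) read_text_lines(file) else text
  feats <- list(); nfeat <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L)
      stop("GFF3 line ", i, ": expected 9 tab-separated columns", call. = FALSE)
    type <- f[3L]
    if (!type %in% c("gene", "mRNA", "transcript", "CDS")) next
    start <- suppressWarnings(as.integer(f[4L]))
    end <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start) || is.na(end))
      stop("GFF3 line ", i, ": non-numeric coordinate", call. = FALSE)
    if (end < start)
      stop("GFF3 line ", i, ": malformed coordinate (end ", end,
           " < start ", start, ")", call. = FALSE)
    if (type == "CDS" && !f[7L] %in% c("+", "-"))
      stop("GFF3 line ", i, ": CDS with strand '", f[7L],
           "' (must be + or -)", call. = FALSE)
    attrs <- parse_gff3_attributes(if (length(f) >= 9L) f[9L] else "")
    nfeat <- nfeat + 1L
    feats[[nfeat]] <- list(line = i, seq_id = f[1L], src = f[2L], type = type,
                           start = start - 1L, end = end,
                           strand = f[7L],
                           phase = suppressWarnings(as.integer(f[8L])),
                           attrs = attrs)
  }
  types <- vapply(feats, `[[`, character(1), "type")
  tx <- feats[types %in% c("mRNA", "transcript")]
  tx_ids <- vapply(tx, function(f) attr_get(f$attrs, "ID") %||% NA_character_,
                   character(1))
  gene_ids <- vapply(feats[types == "gene"],
                     function(f) attr_get(f$attrs, "ID") %||% NA_character_,
                     character(1))
  known <- c(tx_ids, gene_ids)
  has_hierarchy <- length(known) > 0L

  groups <- list(); meta <- list()
  for (f in feats[types == "CDS"]) {
    parent <- attr_get(f$attrs, "Parent") %||% attr_get(f$attrs, "ID")
    if (is.null(parent) || !nzchar(parent %||% ""))
      stop("GFF3 line ", f$line, ": CDS with no Parent attribute", call. = FALSE)
    parent <- strsplit(parent, ",", fixed = TRUE)[[1]][1L]
    if (has_hierarchy && !parent %in% known)
      stop("GFF3 line ", f$line, ": CDS Parent '", parent,
           "' references no transcript", call. = FALSE)
    groups[[parent]] <- c(groups[[parent]], list(f))
  }
  for (t in tx) {
    id <- attr_get(t$attrs, "ID")
    if (!is.null(id)) meta[[id]] <- t$attrs
  }

  models <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    gid <- names(groups)[k]
    rows <- groups[[k]]
    seqs <- unique(vapply(rows, `[[`, character(1), "seq_id"))
    strands <- unique(vapply(rows, `[[`, character(1), "strand"))
    if (length(seqs) != 1L || length(strands) != 1L)
      stop("gene ", gid, ": CDS rows disagree on seq_id or strand", call. = FALSE)
    phases <- vapply(rows, `[[`, integer(1), "phase")
    phases[is.na(phases)] <- 0L
    attrs <- meta[[gid]] %||% character()
    attrs <- attrs[setdiff(names(attrs), c("ID", "Parent"))]
    if (!length(attrs)) attrs <- character()
    models[[k]] <- gene_model(
      gene_id = gid, seq_id = seqs, strand = strands,
      starts = vapply(rows, `[[`, integer(1), "start"),
      ends = vapply(rows, `[[`, integer(1), "end"),
      phases = phases,
      source = source %||% rows[[1L]]$src,
      attributes = attrs)
  }
  annotation_set(models)
}

#' Write an annotation set as GFF3
#'
#' Output is deterministic: genes are ordered by (seq_id, span start,
#' gene_id), each emitted as one mRNA row followed by its CDS rows with
#' coordinates back-converted to 1-based inclusive.
#' `parse_gff3(write_gff3(S))` reproduces `S`'s models exactly.
#'
#' @param set An [annotation_set()].
#' @param file Optional path; when `NULL` the GFF3 lines are returned.
#' @return Invisibly (or visibly when `file` is `NULL`) the character
#'   vector of GFF3 lines.
#' @export
write_gff3 <- function(set, file = NULL) {
  out <- "##gff-version 3"
  for (m in set$models) {
    sp <- model_span(m)
    extra <- if (length(m$attributes))
      paste0(";", paste0(names(m$attributes), "=", m$attributes, collapse = ";"))
    else ""
    out <- c(out,
      paste(m$seq_id, m$source, "mRNA", sp[1L] + 1L, sp[2L], ".", m$strand, ".",
            paste0("ID=", m$gene_id, extra), sep = "\t"),
      paste(m$seq_id, m$source, "CDS", m$starts + 1L, m$ends, ".", m$strand,
            m$phases, paste0("Parent=", m$gene_id), sep = "\t"))
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Read a (softmasked) genome from FASTA
#'
#' Case is preserved byte-for-byte, so lowercase residues keep carrying
#' the repeat-softmask signal. Sequence ids are the first
#' whitespace-delimited token of each header. Duplicated ids, empty
#' records and residues outside `ACGTNacgtn` are errors.
#'
#' @param file Path to a FASTA file (plain or gzip).
#' @return Named character vector of residue strings, one per sequence.
#' @export
read_genome <- function(file) {
  recs <- seqinr::read.fasta(file, as.string = TRUE, forceDNAtolower = FALSE,
                             seqtype = "DNA")
  ids <- vapply(recs, function(r) attr(r, "name"), character(1))
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- vapply(recs, function(r) as.character(r)[1L], character(1))
  names(seqs) <- ids
  if (any(!nzchar(seqs) | is.na(seqs)))
    stop("empty sequence record: ",
         paste(ids[!nzchar(seqs) | is.na(seqs)], collapse = ", "), call. = FALSE)
  for (id in ids) {
    bad <- regexpr("[^ACGTNacgtn]", seqs[[id]])
    if (bad > 0L)
      stop("sequence ", id, ": invalid character '",
           substr(seqs[[id]], bad, bad), "' at position ", bad, call. = FALSE)
  }
  seqs
}

#' Write a genome as FASTA, preserving case
#'
#' @param genome Named character vector of residue strings.
#' @param file Output path.
#' @param width Line-wrap width in bp.
#' @export
write_fasta <- function(genome, file, width = 60L) {
  out <- character()
  for (id in names(genome)) {
    s <- genome[[id]]
    n <- nchar(s)
    brk <- seq(1L, n, by = width)
    out <- c(out, paste0(">", id), substring(s, brk, pmin(brk + width - 1L, n)))
  }
  writeLines(out, file)
  invisible(out)
}

#' Spliced CDS of a gene model
#'
#' Concatenates the model's CDS segments in genomic order and
#' reverse-complements the result for minus-strand models, yielding the
#' coding sequence in transcript orientation. Case is preserved, so the
#' softmask signal survives into [mask_fraction()].
#'
#' @param model A [gene_model()].
#' @param genome Named character vector from [read_genome()].
#' @return A single nucleotide string of length equal to the summed
#'   segment lengths.
#' @export
spliced_cds <- function(model, genome) {
  s <- genome_seq(genome, model$seq_id)
  if (is.null(s))
    stop("gene ", model$gene_id, ": sequence ", model$seq_id,
         " absent from genome", call. = FALSE)
  if (model$ends[length(model$ends)] > nchar(s))
    stop("gene ", model$gene_id, ": segment out of sequence bounds", call. = FALSE)
  cds <- paste(substring(s, model$starts + 1L, model$ends), collapse = "")
  if (model$strand == "-") reverse_complement(cds) else cds
}

#' Reverse complement preserving case
#' @param x A nucleotide string over `ACGTNacgtn`.
#' @export
reverse_complement <- function(x) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTNacgtn", "TGCANtgcan", x))))
}

# readLines over plain or gzip path (file() auto-detects compression)
read_text_lines <- function(path) {
  con <- file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

parse_gff3_attributes <- function(s) {
  if (!nzchar(s) || s == ".") return(character())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- vapply(kv, function(p) if (length(p) > 1L)
    paste(p[-1L], collapse = "=") else "", character(1))
  names(vals) <- vapply(kv, `[[`, character(1), 1L)
  vals
}

attr_get <- function(a, k) if (k %in% names(a)) a[[k]] else NULL

# safe lookup: NULL rather than an error for an absent sequence id
genome_seq <- function(genome, seq_id)
  if (seq_id %in% names(genome)) genome[[seq_id]] else NULL

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
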