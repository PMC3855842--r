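#' Construct a table of gene calls
#'
#' The common currency of the pipeline: one row per called feature (CDS, rRNA
#' or tRNA) with 1-based inclusive coordinates. All readers normalize to this
#' representation and all writers consume it, so no call site ever handles
#' off-by-one or reversed-coordinate conventions.
#'
#' @param gene_id character, unique within an annotation set.
#' @param contig character contig/chromosome identifier, non-empty.
#' @param start,end integer 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @param feature_type one of `"CDS"`, `"rRNA"`, `"tRNA"`.
#' @param rna_subtype optional, e.g. `"16S"` or `"tRNA-Ala"`.
#' @param source predictor name, `"consensus"`, or reader provenance.
#' @param score optional numeric predictor score.
#' @param product optional product name carried along for writers.
#' @return a `data.frame` with one row per call and the columns above.
#' @export
#' @examples
#' gene_calls("g1", "c1", 100, 400, "+", "CDS")
gene_calls <- function(gene_id, contig, start, end, strand, feature_type,
                       rna_subtype = NA_character_, source = NA_character_,
                       score = NA_real_, product = NA_character_) {
  df <- data.frame(
    gene_id = as.character(gene_id),
    contig = as.character(contig),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    feature_type = as.character(feature_type),
    rna_subtype = as.character(rna_subtype),
    source = as.character(source),
    score = as.numeric(score),
    product = as.character(product),
    stringsAsFactors = FALSE
  )
  validate_gene_calls(df)
  df
}

#' An empty gene-call table with the full column set
#' @return zero-row `data.frame` with gene-call columns.
#' @export
empty_gene_calls <- function() {
  data.frame(
    gene_id = character(), contig = character(),
    start = integer(), end = integer(), strand = character(),
    feature_type = character(), rna_subtype = character(),
    source = character(), score = numeric(), product = character(),
    stringsAsFactors = FALSE
  )
}

#' Validate a gene-call table
#'
#' Checks the structural invariants: coordinates 1-based with `start <= end`,
#' strand in `{+, -}`, feature type in `{CDS, rRNA, tRNA}`, non-empty contig
#' ids.
#'
#' @param calls data.frame as returned by [gene_calls()].
#' @return `calls`, invisibly; errors on violation.
#' @export
validate_gene_calls <- function(calls) {
  stopifnot(is.data.frame(calls))
  need <- c("gene_id", "contig", "start", "end", "strand", "feature_type")
  miss <- setdiff(need, names(calls))
  if (length(miss) > 0) {
    stop("gene-call table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(calls) == 0) return(invisible(calls))
  if (any(is.na(calls$contig) | calls$contig == "")) {
    stop("gene-call table has empty contig ids")
  }
  if (any(calls$start < 1L)) stop("gene-call coordinates must be >= 1")
  if (any(calls$end < calls$start)) stop("gene-call end < start")
  if (!all(calls$strand %in% c("+", "-"))) {
    stop("gene-call strand must be '+' or '-'")
  }
  if (!all(calls$feature_type %in% c("CDS", "rRNA", "tRNA"))) {
    stop("gene-call feature_type must be CDS, rRNA or tRNA")
  }
  invisible(calls)
}

## Length in nucleotides of each call.
call_length <- function(calls) calls$end - calls$start + 1L
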