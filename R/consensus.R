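#' Parameters for consensus gene calling
#'
#' @param min_cds_len minimum consensus CDS length in nt (default 90, i.e.
#'   30 aa — a common prokaryotic small-ORF floor).
#' @param start_vote `"majority"` (vote over predictors, ties toward the
#'   longest ORF, remaining ties by `predictor_priority`) or `"longest"`.
#' @param orphan_policy `"keep"` or `"drop"` for clusters supported by a
#'   single predictor.
#' @param max_rna_overlap maximum tolerated CDS/RNA overlap in nt (default 0;
#'   RNA genes always take precedence).
#' @param predictor_priority ordered predictor names for the final tie-break.
#' @return a list of class `consensus_params`.
#' @export
consensus_params <- function(min_cds_len = 90L, start_vote = c("majority", "longest"),
                             orphan_policy = c("keep", "drop"),
                             max_rna_overlap = 0L, predictor_priority = character()) {
  start_vote <- match.arg(start_vote)
  orphan_policy <- match.arg(orphan_policy)
  stopifnot(min_cds_len >= 3, max_rna_overlap >= 0)
  structure(list(min_cds_len = as.integer(min_cds_len), start_vote = start_vote,
                 orphan_policy = orphan_policy,
                 max_rna_overlap = as.integer(max_rna_overlap),
                 predictor_priority = predictor_priority),
            class = "consensus_params")
}

#' Build an RNA mask from rRNA/tRNA calls
#'
#' Per-contig strandless union of RNA gene intervals; overlapping or abutting
#' intervals are merged, output sorted by start.
#'
#' @param rna_calls gene-call table containing only rRNA/tRNA features.
#' @return `data.frame` with columns `contig`, `start`, `end` (disjoint,
#'   sorted per contig).
#' @export
build_mask <- function(rna_calls) {
  validate_gene_calls(rna_calls)
  if (any(rna_calls$feature_type == "CDS")) {
    stop("build_mask expects RNA calls only; got CDS records")
  }
  if (nrow(rna_calls) == 0) {
    return(data.frame(contig = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(split(rna_calls, rna_calls$contig), function(d) {
    red <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
    data.frame(contig = d$contig[1], start = IRanges::start(red),
               end = IRanges::end(red), stringsAsFactors = FALSE)
  })
  res <- rbind_df(out[order(names(out))])
  rownames(res) <- NULL
  res
}

#' Merge CDS calls from multiple predictors into a consensus gene set
#'
#' Calls are clustered by shared stop coordinate (`end` on `+`, `start` on
#' `-`, with the contig and strand) — the coordinate prokaryotic callers
#' agree on — and one consensus gene is emitted per cluster. The start is
#' chosen by majority vote over predictors; ties go to the longest ORF, and
#' any remaining tie to the first predictor in `predictor_priority`. Clusters
#' supported by a single predictor are kept or dropped per `orphan_policy`.
#' All consensus CDS must reach `min_cds_len`. Output is sorted by
#' (contig, start) and is invariant under permutation of predictors and of
#' calls within a predictor.
#'
#' @param calls_by_predictor named list: predictor name -> gene-call table of
#'   CDS calls.
#' @param params a [consensus_params()] object.
#' @return consensus gene-call table with `source = "consensus"` and extra
#'   columns `n_predictors` and `predictors`.
#' @export
merge_gene_calls <- function(calls_by_predictor, params = consensus_params()) {
  if (!is.list(calls_by_predictor) || length(calls_by_predictor) == 0) {
    stop("calls_by_predictor must be a non-empty named list of gene-call tables")
  }
  if (is.null(names(calls_by_predictor)) || any(names(calls_by_predictor) == "")) {
    stop("calls_by_predictor must be named by predictor")
  }
  all_calls <- rbind_df(lapply(names(calls_by_predictor), function(p) {
    d <- calls_by_predictor[[p]]
    validate_gene_calls(d)
    if (nrow(d) == 0) return(NULL)
    if (any(d$feature_type != "CDS")) stop("merge_gene_calls expects CDS calls only")
    d$predictor <- p
    d
  }))
  if (is.null(all_calls)) return(empty_gene_calls())
  stop_coord <- ifelse(all_calls$strand == "+", all_calls$end, all_calls$start)
  key <- paste(all_calls$contig, all_calls$strand, stop_coord, sep = "\r")
  clusters <- split(seq_len(nrow(all_calls)), key)
  rows <- lapply(clusters, function(idx) {
    d <- all_calls[idx, , drop = FALSE]
    # one candidate per predictor (a predictor cannot vote twice in a cluster)
    d <- d[!duplicated(d$predictor), , drop = FALSE]
    plus <- d$strand[1] == "+"
    cand_start <- if (plus) d$start else d$end   # the 5' (start-codon) coordinate
    chosen <- if (params$start_vote == "longest") {
      if (plus) min(cand_start) else max(cand_start)
    } else {
      tab <- table(cand_start)
      best <- as.integer(names(tab)[tab == max(tab)])
      if (length(best) > 1) best <- if (plus) min(best) else max(best)
      if (length(best) > 1 && length(params$predictor_priority) > 0) {
        for (p in params$predictor_priority) {       # documented final tie-break
          hit <- cand_start[d$predictor == p]
          if (length(hit) > 0 && hit[1] %in% best) { best <- hit[1]; break }
        }
      }
      best[1]
    }
    data.frame(
      contig = d$contig[1],
      start = if (plus) chosen else d$start[1],
      end = if (plus) d$end[1] else chosen,
      strand = d$strand[1],
      n_predictors = nrow(d),
      predictors = paste(sort(d$predictor), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  cons <- rbind_df(rows)
  keep <- (cons$end - cons$start + 1L) >= params$min_cds_len
  if (params$orphan_policy == "drop") keep <- keep & cons$n_predictors > 1L
  cons <- cons[keep, , drop = FALSE]
  cons <- cons[order(cons$contig, cons$start, cons$end), , drop = FALSE]
  n <- nrow(cons)
  out <- empty_gene_calls()
  if (n > 0) {
    out <- data.frame(
      gene_id = sprintf("CDS_%04d", seq_len(n)),
      contig = cons$contig, start = cons$start, end = cons$end,
      strand = cons$strand, feature_type = "CDS",
      rna_subtype = NA_character_, source = "consensus",
      score = NA_real_, product = NA_character_,
      n_predictors = cons$n_predictors, predictors = cons$predictors,
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
  }
  out
}

#' Remove CDS that conflict with RNA genes
#'
#' A CDS is removed iff its overlap with any single mask interval exceeds
#' `max_rna_overlap` nucleotides. RNA genes always survive (they are the
#' mask, not the input). Idempotent. Removals are reported via `message()`
#' with the overlap length and recorded in the `"removed"` attribute.
#'
#' @param cds gene-call table of CDS.
#' @param mask RNA mask from [build_mask()].
#' @param max_rna_overlap tolerated overlap in nt (default 0).
#' @return the retained CDS calls.
#' @export
resolve_rna_overlap <- function(cds, mask, max_rna_overlap = 0L) {
  validate_gene_calls(cds)
  if (nrow(cds) == 0 || nrow(mask) == 0) { attr(cds, "removed") <- empty_gene_calls(); return(cds) }
  max_ov <- integer(nrow(cds))
  for (ct in unique(cds$contig)) {
    mi <- mask[mask$contig == ct, , drop = FALSE]
    ci <- which(cds$contig == ct)
    if (nrow(mi) == 0 || length(ci) == 0) next
    q <- IRanges::IRanges(cds$start[ci], cds$end[ci])
    s <- IRanges::IRanges(mi$start, mi$end)
    hits <- IRanges::findOverlaps(q, s)
    if (length(hits) == 0) next
    ov <- IRanges::width(IRanges::pintersect(q[S4Vectors::queryHits(hits)],
                                             s[S4Vectors::subjectHits(hits)]))
    agg <- tapply(ov, S4Vectors::queryHits(hits), max)
    max_ov[ci[as.integer(names(agg))]] <- as.integer(agg)
  }
  drop <- max_ov > max_rna_overlap
  if (any(drop)) {
    message(sum(drop), " CDS removed for RNA overlap: ",
            paste(sprintf("%s (%d nt)", cds$gene_id[drop], max_ov[drop]), collapse = ", "))
  }
  out <- cds[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- cds[drop, , drop = FALSE]
  out
}
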