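#' Match test gene calls against a reference
#'
#' Implements the identical / similar / not-detected comparison used for
#' gene-call benchmarking. Candidate pairs require the same contig, same
#' strand, same feature type and at least 1 nt of overlap ("same region").
#' A pair is identical when both start and stop coordinates agree exactly;
#' similar when the start *or* the stop is within `offset` bases. Matching is
#' one-to-one: identical pairs are matched first, then remaining reference
#' genes are matched to remaining similar-eligible test genes by
#' maximum-cardinality bipartite matching, preferring (deterministically) the
#' assignment with the smallest total coordinate shift, then the leftmost
#' reference gene. Unmatched reference genes are not detected (false
#' negatives); unmatched test genes are false positives.
#'
#' @param test,ref gene-call tables sharing a contig namespace.
#' @param offset maximum coordinate offset in bases for a similar match
#'   (default 50).
#' @return list of class `gene_matching`: `ref` (per-reference-gene
#'   `data.frame` with `category`, `test_id`, deltas), `false_positive_ids`,
#'   `n_test`, `n_ref`, `test_types`, `offset`.
#' @export
match_gene_calls <- function(test, ref, offset = 50L) {
  if (offset < 0) stop("offset must be >= 0")
  validate_gene_calls(test); validate_gene_calls(ref)
  ref_res <- data.frame(
    ref_id = ref$gene_id, contig = ref$contig, start = ref$start, end = ref$end,
    strand = ref$strand, feature_type = ref$feature_type,
    category = rep("not_detected", nrow(ref)),
    test_id = rep(NA_character_, nrow(ref)),
    delta_start = rep(NA_integer_, nrow(ref)),
    delta_end = rep(NA_integer_, nrow(ref)),
    stringsAsFactors = FALSE
  )
  test_used <- rep(FALSE, nrow(test))
  blocks <- unique(rbind(ref[c("contig", "strand", "feature_type")],
                         test[c("contig", "strand", "feature_type")]))
  for (b in seq_len(nrow(blocks))) {
    ri <- which(ref$contig == blocks$contig[b] & ref$strand == blocks$strand[b] &
                  ref$feature_type == blocks$feature_type[b])
    ti <- which(test$contig == blocks$contig[b] & test$strand == blocks$strand[b] &
                  test$feature_type == blocks$feature_type[b])
    if (length(ri) == 0 || length(ti) == 0) next
    # pairwise deltas and overlap
    ds <- outer(ref$start[ri], test$start[ti], function(a, b) abs(a - b))
    de <- outer(ref$end[ri], test$end[ti], function(a, b) abs(a - b))
    ov <- outer(seq_along(ri), seq_along(ti), function(i, j) {
      pmin(ref$end[ri][i], test$end[ti][j]) - pmax(ref$start[ri][i], test$start[ti][j]) + 1L
    })
    eligible <- ov >= 1L
    ident <- eligible & ds == 0L & de == 0L
    # identical-first, greedy in reference order (exact pairs are unambiguous)
    for (i in seq_along(ri)) {
      js <- which(ident[i, ] & !test_used[ti])
      if (length(js) > 0) {
        j <- js[1]
        ref_res$category[ri[i]] <- "identical"
        ref_res$test_id[ri[i]] <- test$gene_id[ti[j]]
        ref_res$delta_start[ri[i]] <- 0L; ref_res$delta_end[ri[i]] <- 0L
        test_used[ti[j]] <- TRUE
      }
    }
    open_r <- which(ref_res$category[ri] == "not_detected")
    open_t <- which(!test_used[ti])
    if (length(open_r) == 0 || length(open_t) == 0) next
    sim <- eligible & (ds <= offset | de <= offset)
    pairs <- which(sim[open_r, open_t, drop = FALSE], arr.ind = TRUE)
    if (nrow(pairs) == 0) next
    m <- similar_phase_match(
      n_ref = length(open_r), n_test = length(open_t),
      edges = data.frame(
        r = pairs[, 1], t = pairs[, 2],
        delta = ds[cbind(open_r[pairs[, 1]], open_t[pairs[, 2]])] +
          de[cbind(open_r[pairs[, 1]], open_t[pairs[, 2]])]
      ),
      ref_order = rank(ref$start[ri][open_r], ties.method = "first")
    )
    for (e in seq_len(nrow(m))) {
      i <- open_r[m$r[e]]; j <- open_t[m$t[e]]
      ref_res$category[ri[i]] <- "similar"
      ref_res$test_id[ri[i]] <- test$gene_id[ti[j]]
      ref_res$delta_start[ri[i]] <- ds[i, j]
      ref_res$delta_end[ri[i]] <- de[i, j]
      test_used[ti[j]] <- TRUE
    }
  }
  structure(list(
    ref = ref_res,
    false_positive_ids = test$gene_id[!test_used],
    n_test = nrow(test), n_ref = nrow(ref),
    test_types = table(test$feature_type),
    offset = as.integer(offset)
  ), class = "gene_matching")
}

## Maximum-cardinality matching on the similar-eligible bipartite graph,
## breaking ties toward minimum total coordinate shift, then leftmost
## reference. Encoded as maximum-weight matching: with M > sum of deltas,
## weight M - delta makes cardinality dominate, delta second-order, and a
## sub-1 epsilon favouring left references third-order.
similar_phase_match <- function(n_ref, n_test, edges, ref_order) {
  if (nrow(edges) == 0) return(data.frame(r = integer(), t = integer()))
  M <- sum(edges$delta) + 1
  eps <- (n_ref - ref_order[edges$r] + 1) / ((n_ref + 2) * (nrow(edges) + 2))
  w <- M - edges$delta + eps
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, n_ref), rep(TRUE, n_test)),
    edges = as.vector(rbind(edges$r, n_ref + edges$t))
  )
  mm <- igraph::max_bipartite_match(g, weights = w)
  mvec <- mm$matching[seq_len(n_ref)]
  keep <- !is.na(mvec)
  data.frame(r = which(keep), t = as.integer(mvec[keep]) - n_ref)
}

#' Comparison report from a matching (or from raw category counts)
#'
#' Summarises a [match_gene_calls()] result: per-feature-type call counts,
#' the identical/similar/not-detected partition of the reference set,
#' false negatives (= not detected) and false positives (unmatched test
#' genes), and the category percentages of the reference total, rounded to 2
#' decimals half away from zero. Also accepts a bare named vector/list of
#' category counts (`identical`, `similar`, `not_detected`, optionally
#' `false_positives`) for report arithmetic on externally obtained counts.
#'
#' @param matching a `gene_matching`, or named counts as described.
#' @param test_products optional product-assignment table for the test set,
#'   adding functional/orphan tallies.
#' @return object of class `comparison_report` (a list; see fields in
#'   Details), with `print()` and [report_tsv()] renderings.
#' @export
comparison_report <- function(matching, test_products = NULL) {
  if (!inherits(matching, "gene_matching")) {
    cnt <- as.list(matching)
    need <- c("identical", "similar", "not_detected")
    if (!all(need %in% names(cnt))) {
      stop("counts must name identical, similar and not_detected")
    }
    rep_ <- list(
      n_ref = sum(unlist(cnt[need])),
      n_test = NA_integer_,
      identical = as.integer(cnt$identical),
      similar = as.integer(cnt$similar),
      not_detected = as.integer(cnt$not_detected),
      false_positives = as.integer(cnt$false_positives %||% NA_integer_),
      ref_types = NULL, test_types = NULL, by_type = NULL, offset = NA_integer_
    )
  } else {
    cat_by_type <- table(matching$ref$feature_type, matching$ref$category)
    rep_ <- list(
      n_ref = matching$n_ref,
      n_test = matching$n_test,
      identical = sum(matching$ref$category == "identical"),
      similar = sum(matching$ref$category == "similar"),
      not_detected = sum(matching$ref$category == "not_detected"),
      false_positives = length(matching$false_positive_ids),
      ref_types = table(matching$ref$feature_type),
      test_types = matching$test_types,
      by_type = cat_by_type,
      offset = matching$offset
    )
  }
  rep_$false_negatives <- rep_$not_detected
  if (rep_$n_ref > 0) {
    rep_$pct_identical <- round_half_up(100 * rep_$identical / rep_$n_ref, 2)
    rep_$pct_similar <- round_half_up(100 * rep_$similar / rep_$n_ref, 2)
    rep_$pct_not_detected <- round_half_up(100 * rep_$not_detected / rep_$n_ref, 2)
  } else {
    rep_$pct_identical <- rep_$pct_similar <- rep_$pct_not_detected <- NA_real_
  }
  if (!is.null(test_products)) {
    t <- tally_products(test_products)
    rep_$functional_test <- t$functional
    rep_$orphan_test <- t$orphan
  }
  structure(rep_, class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Gene-call comparison (offset ", x$offset, " bp)\n", sep = "")
  cat(sprintf("  reference genes: %d   test genes: %s\n", x$n_ref,
              ifelse(is.na(x$n_test), "-", x$n_test)))
  cat(sprintf("  identical:    %6d  (%s%%)\n", x$identical, fmt_pct(x$pct_identical)))
  cat(sprintf("  similar:      %6d  (%s%%)\n", x$similar, fmt_pct(x$pct_similar)))
  cat(sprintf("  not detected: %6d  (%s%%)\n", x$not_detected, fmt_pct(x$pct_not_detected)))
  cat(sprintf("  false negatives: %d   false positives: %s\n",
              x$false_negatives, ifelse(is.na(x$false_positives), "-", x$false_positives)))
  if (!is.null(x$functional_test)) {
    cat(sprintf("  test products: %d functional, %d orphan\n",
                x$functional_test, x$orphan_test))
  }
  invisible(x)
}

fmt_pct <- function(p) ifelse(is.na(p), "-", sprintf("%.2f", p))

#' Render a comparison report as TSV lines
#'
#' Fixed two-column (`metric`, `value`) layout.
#'
#' @param report a `comparison_report`.
#' @param path optional output file.
#' @return character vector of TSV lines, invisibly when `path` is given.
#' @export
report_tsv <- function(report, path = NULL) {
  rows <- c(
    paste("metric", "value", sep = "\t"),
    paste("reference_genes", report$n_ref, sep = "\t"),
    paste("test_genes", report$n_test, sep = "\t"),
    paste("identical", report$identical, sep = "\t"),
    paste("similar", report$similar, sep = "\t"),
    paste("not_detected", report$not_detected, sep = "\t"),
    paste("false_negatives", report$false_negatives, sep = "\t"),
    paste("false_positives", report$false_positives, sep = "\t"),
    paste("pct_identical", fmt_pct(report$pct_identical), sep = "\t"),
    paste("pct_similar", fmt_pct(report$pct_similar), sep = "\t"),
    paste("pct_not_detected", fmt_pct(report$pct_not_detected), sep = "\t")
  )
  if (!is.null(report$functional_test)) {
    rows <- c(rows,
              paste("functional_test", report$functional_test, sep = "\t"),
              paste("orphan_test", report$orphan_test, sep = "\t"))
  }
  if (!is.null(path)) { writeLines(rows, path); return(invisible(rows)) }
  rows
}
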