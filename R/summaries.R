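#' Build a hierarchical annotation summary tree
#'
#' Aggregates per-gene lineage paths (e.g. COG functional categories, GO
#' slims, taxonomy lineages) into a rooted tree. Node counts are distinct
#' genes in the subtree (set-union semantics): a gene annotated to several
#' paths through one node is counted once at that node, never twice. Children
#' are sorted by name.
#'
#' @param assignments named list: gene id -> list of character vectors, each
#'   a root-first lineage path (the root name itself excluded). A single
#'   character vector is accepted as one path.
#' @param root_name name of the root node.
#' @return nested list node: `name`, `count`, `children`.
#' @export
#' @examples
#' build_hierarchy(list(g1 = list(c("Metabolism", "Energy"))), "COG")
build_hierarchy <- function(assignments, root_name = "root") {
  recs <- list()
  for (g in names(assignments)) {
    paths <- assignments[[g]]
    if (is.character(paths)) paths <- list(paths)
    for (p in paths) {
      if (length(p) == 0) stop("empty lineage path for gene ", g)
      recs[[length(recs) + 1L]] <- list(gene = g, path = as.character(p))
    }
  }
  build_node(root_name, recs)
}

build_node <- function(name, recs) {
  genes <- unique(vapply(recs, `[[`, character(1), "gene"))
  deeper <- recs[vapply(recs, function(r) length(r$path) > 0, logical(1))]
  children <- list()
  if (length(deeper) > 0) {
    heads <- vapply(deeper, function(r) r$path[1], character(1))
    for (h in sort(unique(heads))) {
      sub <- lapply(deeper[heads == h], function(r) {
        r$path <- r$path[-1]; r
      })
      children[[length(children) + 1L]] <- build_node(h, sub)
    }
  }
  list(name = name, count = length(genes), children = children)
}

#' Core-gene completeness report
#'
#' Fraction of a supplied core COG list observed in the genome, the standard
#' quick completeness estimate for archaeal/bacterial assemblies. Meaningful
#' only relative to the supplied core list.
#'
#' @param observed_cogs character vector of COG ids observed in the
#'   annotation.
#' @param core_list character vector of expected core COG ids (non-empty).
#' @param domain_label `"bacteria"` or `"archaea"`.
#' @return `data.frame` row: `domain_label`, `core_total`, `core_observed`,
#'   `completeness_pct` (2 decimals, half away from zero).
#' @export
completeness <- function(observed_cogs, core_list,
                         domain_label = c("bacteria", "archaea")) {
  domain_label <- match.arg(domain_label)
  if (length(core_list) == 0) stop("core COG list is empty")
  if (anyDuplicated(core_list)) {
    warning("duplicate ids in core COG list; deduplicating")
    core_list <- unique(core_list)
  }
  obs <- length(intersect(unique(observed_cogs), core_list))
  data.frame(domain_label = domain_label,
             core_total = length(core_list), core_observed = obs,
             completeness_pct = round_half_up(100 * obs / length(core_list), 2),
             stringsAsFactors = FALSE)
}

#' Per-pathway gene counts from KEGG Orthology assignments
#'
#' Naive membership counting (no parsimony): a gene counts once per pathway
#' reachable through any of its KOs, deduplicated. Ordered by gene count
#' (descending), then pathway name — a "top N" view is just `head()` of the
#' result.
#'
#' @param gene_to_kos named list: gene id -> character vector of KO ids.
#' @param ko_to_pathways `data.frame` with columns `ko`, `pathway_id`,
#'   `pathway_name`.
#' @return `data.frame`: `pathway_id`, `pathway_name`, `n_genes`.
#' @export
pathway_counts <- function(gene_to_kos, ko_to_pathways) {
  stopifnot(all(c("ko", "pathway_id", "pathway_name") %in% names(ko_to_pathways)))
  if (length(gene_to_kos) == 0) {
    return(data.frame(pathway_id = character(), pathway_name = character(),
                      n_genes = integer(), stringsAsFactors = FALSE))
  }
  pairs <- rbind_df(lapply(names(gene_to_kos), function(g) {
    m <- ko_to_pathways[ko_to_pathways$ko %in% gene_to_kos[[g]], c("pathway_id", "pathway_name")]
    if (nrow(m) == 0) return(NULL)
    m$gene <- g
    m
  }))
  if (is.null(pairs)) {
    return(data.frame(pathway_id = character(), pathway_name = character(),
                      n_genes = integer(), stringsAsFactors = FALSE))
  }
  pairs <- pairs[!duplicated(pairs[c("gene", "pathway_id")]), , drop = FALSE]
  agg <- stats::aggregate(gene ~ pathway_id + pathway_name, data = pairs, FUN = length)
  names(agg)[3] <- "n_genes"
  agg <- agg[order(-agg$n_genes, agg$pathway_name), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Canonical KEGG pathway-highlight URL
#'
#' Builds a URL to the public KEGG `show_pathway` endpoint with each KO of a
#' gene set as a highlighted object on the reference diagram. KOs are sorted
#' and deduplicated so the URL is canonical for a set.
#'
#' @param pathway_id `mapNNNNN` or `koNNNNN`.
#' @param kos character vector of KO ids (`KNNNNN`); may be empty.
#' @return URL string.
#' @export
#' @examples
#' kegg_highlight_url("map00362", c("K04100", "K04100", "K00001"))
kegg_highlight_url <- function(pathway_id, kos = character()) {
  if (length(pathway_id) != 1 || !grepl("^(map|ko)[0-9]{5}$", pathway_id)) {
    stop("malformed pathway id: ", paste(pathway_id, collapse = ","))
  }
  kos <- unique(as.character(kos))
  kos <- kos[!is.na(kos) & kos != ""]
  if (length(kos) > 0 && !all(grepl("^K[0-9]{5}$", kos))) {
    stop("malformed KO id(s): ", paste(kos[!grepl("^K[0-9]{5}$", kos)], collapse = ","))
  }
  kos <- sort(kos)
  paste0("https://www.kegg.jp/kegg-bin/show_pathway?", pathway_id,
         if (length(kos) > 0) paste0("+", paste(kos, collapse = "+")) else "")
}

#' Hypergeometric list enrichment
#'
#' For every term present in the gene list, tests over-representation
#' against the background with the upper-tail hypergeometric probability
#' `P[X >= k]` (population `N` = background genes, `K` = background genes
#' carrying the term, `n` = list size, `k` = list genes carrying the term),
#' then adjusts across all tested terms by Bonferroni or Benjamini-Hochberg.
#' Terms absent from the list (`k = 0`) are skipped.
#'
#' @param list_terms named list: gene id -> character vector of terms, for
#'   the gene list of interest.
#' @param background_terms same, for the background (must contain every list
#'   gene).
#' @param method `"bh"` or `"bonferroni"`.
#' @return `data.frame` sorted by p-value: `term`, `k`, `n`, `K`, `N`,
#'   `p_value`, `p_adjusted`, `method`.
#' @export
enrich <- function(list_terms, background_terms, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  missing_genes <- setdiff(names(list_terms), names(background_terms))
  if (length(missing_genes) > 0) {
    stop("list gene(s) absent from background: ",
         paste(utils::head(missing_genes, 5), collapse = ", "))
  }
  N <- length(background_terms)
  n <- length(list_terms)
  if (n < 1) stop("empty gene list")
  list_sets <- lapply(list_terms, unique)
  bg_sets <- lapply(background_terms, unique)
  terms <- sort(unique(unlist(list_sets)))
  if (length(terms) == 0) {
    return(data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      p_adjusted = numeric(), method = character(),
                      stringsAsFactors = FALSE))
  }
  k <- vapply(terms, function(t) sum(vapply(list_sets, function(s) t %in% s, logical(1))), integer(1))
  K <- vapply(terms, function(t) sum(vapply(bg_sets, function(s) t %in% s, logical(1))), integer(1))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  padj <- stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
  out <- data.frame(term = terms, k = k, n = n, K = K, N = N,
                    p_value = p, p_adjusted = padj, method = method,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
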