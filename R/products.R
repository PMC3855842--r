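#' Parameters for product-name assignment
#'
#' @param db_precedence ordered database labels scanned for a functional
#'   name; earlier databases win.
#' @param max_evalue maximum hit e-value (default 1e-5).
#' @param min_identity minimum percent identity (default 30).
#' @param min_query_cov minimum query coverage fraction (default 0.5; hits
#'   with unknown coverage pass this filter).
#' @param hypothetical_patterns case-insensitive substrings marking a name as
#'   conveying no function.
#' @param name_cleanup_rules ordered list of `c(pattern, replacement)` regex
#'   rewrites applied to raw subject descriptions before the hypothetical
#'   test.
#' @return list of class `product_params`.
#' @export
product_params <- function(db_precedence = c("uniprot", "nr", "kegg", "cdd"),
                           max_evalue = 1e-5, min_identity = 30,
                           min_query_cov = 0.5,
                           hypothetical_patterns = default_hypothetical_patterns(),
                           name_cleanup_rules = default_cleanup_rules()) {
  stopifnot(max_evalue >= 0, min_identity >= 0, min_identity <= 100,
            min_query_cov >= 0, min_query_cov <= 1,
            length(hypothetical_patterns) > 0)
  structure(list(db_precedence = db_precedence, max_evalue = max_evalue,
                 min_identity = min_identity, min_query_cov = min_query_cov,
                 hypothetical_patterns = hypothetical_patterns,
                 name_cleanup_rules = name_cleanup_rules),
            class = "product_params")
}

#' @rdname product_params
#' @export
default_hypothetical_patterns <- function() {
  c("hypothetical", "uncharacterized", "uncharacterised", "unknown function",
    "predicted protein", "DUF")
}

#' @rdname product_params
#' @export
default_cleanup_rules <- function() {
  list(
    c("^MULTISPECIES:\\s*", ""),
    c("^RecName:\\s*Full=", ""),
    c("\\s*\\[[^][]*\\]\\s*$", ""),   # trailing organism bracket
    c(";.*$", ""),                     # UniProt qualifier tail
    c("\\s+", " ")
  )
}

#' Is a product name hypothetical?
#'
#' @param name product name (vectorized). `NA` or empty names are
#'   hypothetical.
#' @param patterns case-insensitive substrings; a match to any makes the name
#'   hypothetical.
#' @return logical vector.
#' @export
#' @examples
#' is_hypothetical(c("hypothetical protein", "DNA gyrase subunit A"))
is_hypothetical <- function(name, patterns = default_hypothetical_patterns()) {
  out <- is.na(name) | trimws(name) == ""
  low <- tolower(name)
  for (p in patterns) out <- out | grepl(tolower(p), low, fixed = TRUE)
  out
}

#' Clean a raw subject description into a product name
#'
#' Applies the rewrite rules in order, then trims whitespace. Removes
#' database formatting artifacts (e.g. `MULTISPECIES:` prefixes, trailing
#' organism brackets) that would otherwise leak into product names.
#'
#' @param name character vector of raw names.
#' @param rules list of `c(pattern, replacement)` pairs.
#' @return character vector of cleaned names.
#' @export
clean_product_name <- function(name, rules = default_cleanup_rules()) {
  for (r in rules) name <- gsub(r[1], r[2], name)
  trimws(name)
}

#' Assign a product name to one gene
#'
#' Databases are scanned in precedence order; within each, the best-ranked
#' hit passing the e-value/identity/coverage thresholds whose cleaned name is
#' non-hypothetical supplies the product. Failing that, the best
#' InterPro-integrated domain yields a `"<signature_desc>-family protein"`
#' name; failing that, the best passing hit's name is used even if
#' hypothetical; the floor is `"hypothetical protein"` with source `"none"`.
#'
#' @param gene_id gene identifier.
#' @param hits_by_db named list (db label -> ranked homology table) or a
#'   single homology table with a `db` column.
#' @param domains optional domain table for this gene (or all genes; it is
#'   filtered by `query_id`).
#' @param params a [product_params()] object.
#' @return one-row `data.frame`: `gene_id`, `product`, `source`, `status`.
#' @export
assign_product <- function(gene_id, hits_by_db = list(), domains = NULL,
                           params = product_params()) {
  if (is.data.frame(hits_by_db)) hits_by_db <- split(hits_by_db, hits_by_db$db)
  fallback <- NULL
  for (db in intersect(params$db_precedence, names(hits_by_db))) {
    h <- hits_by_db[[db]]
    h <- h[h$query_id == gene_id, , drop = FALSE]
    if (nrow(h) == 0) next
    h <- rank_homology_hits(h)
    pass <- h$evalue <= params$max_evalue &
      h$pct_identity >= params$min_identity &
      (is.na(h$query_cov) | h$query_cov >= params$min_query_cov)
    h <- h[pass, , drop = FALSE]
    if (nrow(h) == 0) next
    names_clean <- clean_product_name(h$subject_desc, params$name_cleanup_rules)
    ok <- !is_hypothetical(names_clean, params$hypothetical_patterns)
    if (any(ok)) {
      j <- which(ok)[1]
      return(product_row(gene_id, names_clean[j], db, params))
    }
    if (is.null(fallback) && !is.na(names_clean[1]) && names_clean[1] != "") {
      fallback <- list(name = names_clean[1], db = db)
    }
  }
  if (!is.null(domains)) {
    d <- domains[domains$query_id == gene_id & !is.na(domains$ipr_acc) &
                   !is.na(domains$signature_desc), , drop = FALSE]
    if (nrow(d) > 0) {
      d <- d[order(ifelse(is.na(d$evalue), Inf, d$evalue), d$signature_acc), , drop = FALSE]
      cand <- clean_product_name(d$signature_desc, params$name_cleanup_rules)
      ok <- !is_hypothetical(cand, params$hypothetical_patterns)
      if (any(ok)) {
        return(product_row(gene_id, paste0(cand[which(ok)[1]], "-family protein"),
                           "domain", params))
      }
    }
  }
  if (!is.null(fallback)) {
    return(product_row(gene_id, fallback$name, fallback$db, params))
  }
  product_row(gene_id, "hypothetical protein", "none", params)
}

product_row <- function(gene_id, product, source, params) {
  data.frame(gene_id = gene_id, product = product, source = source,
             status = if (is_hypothetical(product, params$hypothetical_patterns))
               "hypothetical" else "functional",
             stringsAsFactors = FALSE)
}

#' Assign products for every CDS in a call set
#'
#' @param calls gene-call table; only CDS rows receive assignments.
#' @param hits homology table covering all databases (with `db` column), or a
#'   named list per database.
#' @param domains optional domain table.
#' @param params a [product_params()] object.
#' @return product-assignment `data.frame`, one row per CDS.
#' @export
assign_products <- function(calls, hits = NULL, domains = NULL,
                            params = product_params()) {
  validate_gene_calls(calls)
  ids <- calls$gene_id[calls$feature_type == "CDS"]
  if (length(ids) == 0) {
    return(data.frame(gene_id = character(), product = character(),
                      source = character(), status = character(),
                      stringsAsFactors = FALSE))
  }
  hits_by_db <- if (is.null(hits)) list() else if (is.data.frame(hits))
    split(hits, hits$db) else hits
  rbind_df(lapply(ids, assign_product, hits_by_db = hits_by_db,
                  domains = domains, params = params))
}

#' Tally functional vs orphan genes
#'
#' Orphan (hypothetical) genes are those whose assigned product conveys no
#' function; functional genes are the complement, so the two always sum to
#' the number of assignments. RNA genes can optionally be folded into the
#' functional count for totals that include all gene calls.
#'
#' @param assignments product-assignment table.
#' @param n_rna number of RNA genes to add (default 0).
#' @param count_rna_functional whether RNA genes count as functional.
#' @return list with integer `functional` and `orphan`.
#' @export
tally_products <- function(assignments, n_rna = 0L, count_rna_functional = FALSE) {
  orphan <- sum(assignments$status == "hypothetical")
  functional <- sum(assignments$status == "functional")
  if (count_rna_functional) functional <- functional + as.integer(n_rna)
  list(functional = as.integer(functional), orphan = as.integer(orphan))
}
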