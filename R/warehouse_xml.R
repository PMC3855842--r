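#' Default warehouse XML model
#'
#' A minimal explicit schema for the annotation warehouse export: entity
#' (element) names mapped to their allowed attribute names. Cross-references
#' to ontologies, domains and pathways are emitted as bare identifier
#' references only — the warehouse side resolves names and descriptions from
#' its own ontology sources.
#'
#' @return named list: entity name -> character vector of allowed attributes.
#' @export
default_warehouse_model <- function() {
  list(
    organism = c("name", "taxon_id"),
    contig = c("id", "length"),
    gene = c("id", "contig", "start", "end", "strand", "feature_type",
             "source", "rna_subtype"),
    protein = c("id", "gene", "product", "status", "evidence_db"),
    go_ref = c("identifier"),
    pathway_ref = c("identifier"),
    domain_ref = c("identifier")
  )
}

#' Write the annotation as model-validated warehouse XML
#'
#' Serializes calls, product assignments and domain evidence into a flat XML
#' document in which every element and attribute must exist in the supplied
#' model; a violation is an error naming the entity and attribute, never a
#' warning. GO terms, InterPro domains and pathways appear as identifier
#' references only.
#'
#' @param calls gene-call table.
#' @param products optional product-assignment table ([assign_products()]).
#' @param domains optional domain table ([read_domains()]).
#' @param pathways optional `data.frame` with columns `gene_id`, `pathway_id`.
#' @param model schema as from [default_warehouse_model()].
#' @param organism organism name attribute.
#' @param path optional output file.
#' @return an `xml2::xml_document`, invisibly when `path` is given.
#' @export
write_warehouse_xml <- function(calls = empty_gene_calls(), products = NULL,
                                domains = NULL, pathways = NULL,
                                model = default_warehouse_model(),
                                organism = "organism", path = NULL) {
  validate_gene_calls(calls)
  doc <- xml2::xml_new_root("organism")
  add_attrs(doc, "organism", list(name = organism), model)
  for (ct in unique(calls$contig)) {
    node <- xml2::xml_add_child(doc, "contig")
    add_attrs(node, "contig", list(id = ct), model)
  }
  prod_idx <- if (!is.null(products)) match(calls$gene_id, products$gene_id) else rep(NA_integer_, nrow(calls))
  for (k in seq_len(nrow(calls))) {
    g <- xml2::xml_add_child(doc, "gene")
    at <- list(id = calls$gene_id[k], contig = calls$contig[k],
               start = calls$start[k], end = calls$end[k],
               strand = calls$strand[k], feature_type = calls$feature_type[k])
    if (!is.na(calls$source[k])) at$source <- calls$source[k]
    if (!is.na(calls$rna_subtype[k])) at$rna_subtype <- calls$rna_subtype[k]
    add_attrs(g, "gene", at, model)
    if (calls$feature_type[k] != "CDS") next
    p <- xml2::xml_add_child(doc, "protein")
    pat <- list(id = paste0(calls$gene_id[k], "_p"), gene = calls$gene_id[k])
    if (!is.na(prod_idx[k])) {
      pat$product <- products$product[prod_idx[k]]
      pat$status <- products$status[prod_idx[k]]
      pat$evidence_db <- products$source[prod_idx[k]]
    }
    add_attrs(p, "protein", pat, model)
    if (!is.null(domains)) {
      dsub <- domains[domains$query_id == calls$gene_id[k], , drop = FALSE]
      for (ipr in unique(stats::na.omit(dsub$ipr_acc))) {
        d <- xml2::xml_add_child(p, "domain_ref")
        add_attrs(d, "domain_ref", list(identifier = ipr), model)
      }
      for (go in unique(unlist(dsub$go_terms))) {
        gref <- xml2::xml_add_child(p, "go_ref")
        add_attrs(gref, "go_ref", list(identifier = go), model)
      }
    }
    if (!is.null(pathways)) {
      for (pw in unique(pathways$pathway_id[pathways$gene_id == calls$gene_id[k]])) {
        pref <- xml2::xml_add_child(p, "pathway_ref")
        add_attrs(pref, "pathway_ref", list(identifier = pw), model)
      }
    }
  }
  validate_warehouse_xml(doc, model)
  if (!is.null(path)) { xml2::write_xml(doc, path); return(invisible(doc)) }
  doc
}

add_attrs <- function(node, entity, attrs, model) {
  allowed <- model[[entity]]
  if (is.null(allowed)) stop("entity '", entity, "' not in warehouse model")
  for (nm in names(attrs)) {
    if (!nm %in% allowed) {
      stop("entity '", entity, "': attribute '", nm, "' not in warehouse model")
    }
    xml2::xml_set_attr(node, nm, as.character(attrs[[nm]]))
  }
  node
}

#' Re-validate a warehouse XML document against a model
#'
#' @param doc `xml2` document or node, or a path to an XML file.
#' @param model schema as from [default_warehouse_model()].
#' @return `TRUE` invisibly; errors naming the first offending entity or
#'   attribute otherwise.
#' @export
validate_warehouse_xml <- function(doc, model = default_warehouse_model()) {
  if (is.character(doc)) doc <- xml2::read_xml(doc)
  nodes <- xml2::xml_find_all(doc, "//*")
  for (nd in nodes) {
    entity <- xml2::xml_name(nd)
    allowed <- model[[entity]]
    if (is.null(allowed)) stop("entity '", entity, "' not in warehouse model")
    bad <- setdiff(names(xml2::xml_attrs(nd)), allowed)
    if (length(bad) > 0) {
      stop("entity '", entity, "': attribute '", bad[1], "' not in warehouse model")
    }
  }
  invisible(TRUE)
}
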