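#' Read a pipeline run configuration
#'
#' YAML with input paths (predictor and RNA GFF3s, homology tables keyed by
#' database label, optional domains TSV) and parameter blocks for the
#' consensus, products, gbt and summaries stages. Referenced paths are
#' checked at validation time; database labels must be unique.
#'
#' @param path YAML file.
#' @return validated config list (class `run_config`).
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path), base = dirname(path))
}

#' @rdname read_run_config
#' @param config a config list built in code.
#' @param base directory against which relative paths resolve.
#' @export
validate_run_config <- function(config, base = ".") {
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(file.exists(p), p, file.path(base, p))
  }
  for (key in c("predictors", "rna", "homology")) {
    config[[key]] <- lapply(config[[key]] %||% list(), resolve)
  }
  config$domains <- resolve(config$domains)
  paths <- c(unlist(config$predictors), unlist(config$rna),
             unlist(config$homology), config$domains)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("config references missing file(s): ", paste(missing, collapse = ", "))
  }
  if (length(config$predictors) == 0) stop("config lists no predictor GFF3s")
  if (anyDuplicated(names(config$homology))) {
    stop("homology database labels must be unique")
  }
  structure(config, class = c("run_config", "list"))
}

#' Run the full annotation-integration pipeline
#'
#' Fixed stage order: RNA mask -> consensus gene merge -> RNA/CDS overlap
#' resolution -> product assignment -> contig taxonomy vote -> summaries ->
#' writers. Every stage logs input/output counts to `run.log` in the output
#' directory, and `run_summary.json` records all counts and parameter values.
#' Without homology tables the pipeline still completes in degraded mode: all
#' products become "hypothetical protein" and the taxonomy stage is skipped
#' with a warning. Any stage error aborts, naming the stage.
#'
#' @param config a `run_config` (or list passed through
#'   [validate_run_config()]).
#' @param outdir output directory (created).
#' @return invisible list with the in-memory stage results and a `files`
#'   vector of written outputs.
#' @export
run_integrate <- function(config, outdir) {
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  log <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  cons_cfg <- config$consensus %||% list()
  params <- consensus_params(
    min_cds_len = cons_cfg$min_cds_len %||% 90L,
    orphan_policy = cons_cfg$orphan_policy %||% "keep",
    max_rna_overlap = cons_cfg$max_rna_overlap %||% 0L,
    predictor_priority = cons_cfg$predictor_priority %||% names(config$predictors)
  )

  rna <- stage("read_rna", {
    r <- rbind_df(lapply(unlist(config$rna), read_features, dialect = "gff3"))
    if (is.null(r)) empty_gene_calls() else r
  })
  log("read_rna: ", nrow(rna), " RNA calls from ", length(config$rna), " file(s)")

  preds <- stage("read_predictors",
                 lapply(config$predictors, read_features, dialect = "gff3"))
  log("read_predictors: ", paste(sprintf("%s=%d", names(preds),
                                         vapply(preds, nrow, integer(1))), collapse = ", "))

  mask <- stage("build_mask", build_mask(rna))
  log("build_mask: ", nrow(mask), " masked interval(s)")

  consensus <- stage("merge_gene_calls", merge_gene_calls(preds, params))
  log("merge_gene_calls: ", nrow(consensus), " consensus CDS")

  consensus <- stage("resolve_rna_overlap",
                     resolve_rna_overlap(consensus, mask, params$max_rna_overlap))
  log("resolve_rna_overlap: ", nrow(consensus), " CDS retained, ",
      nrow(attr(consensus, "removed") %||% empty_gene_calls()), " removed")

  hits <- stage("read_homology", {
    h <- lapply(names(config$homology), function(db)
      read_homology(config$homology[[db]], db = db))
    names(h) <- names(config$homology)
    h
  })
  domains <- stage("read_domains",
                   if (!is.null(config$domains)) read_domains(config$domains) else NULL)
  if (length(hits) == 0) {
    warning("no homology tables supplied: products degrade to hypothetical, taxonomy skipped")
  }
  prod_cfg <- config$products %||% list()
  pparams <- product_params(
    db_precedence = prod_cfg$db_precedence %||% c("uniprot", "nr", "kegg", "cdd"),
    max_evalue = prod_cfg$max_evalue %||% 1e-5,
    min_identity = prod_cfg$min_identity %||% 30,
    min_query_cov = prod_cfg$min_query_cov %||% 0.5,
    hypothetical_patterns = prod_cfg$hypothetical_patterns %||% default_hypothetical_patterns()
  )
  products <- stage("assign_products",
                    assign_products(consensus, hits = hits, domains = domains,
                                    params = pparams))
  tall <- tally_products(products)
  log("assign_products: ", tall$functional, " functional, ", tall$orphan, " orphan")

  gbt_db <- (config$gbt %||% list())$db %||% "nr"
  gbt <- NULL
  if (gbt_db %in% names(hits)) {
    g2c <- stats::setNames(consensus$contig, consensus$gene_id)
    gbt <- stage("assign_gbt", assign_gbt(hits[[gbt_db]], gene_to_contig = g2c,
                                          scope = "per_contig"))
    winners <- gbt_winners(gbt)
    log("assign_gbt: ", nrow(winners), " contig(s) voted, db=", gbt_db)
  } else {
    warning("taxonomy vote skipped: no homology table labelled '", gbt_db, "'")
    log("assign_gbt: skipped (no '", gbt_db, "' table)")
  }

  all_calls <- rbind_df(list(rna, consensus[names(empty_gene_calls())]))
  all_calls <- all_calls[order(all_calls$contig, all_calls$start), , drop = FALSE]
  all_calls$product <- ifelse(
    all_calls$feature_type == "CDS",
    products$product[match(all_calls$gene_id, products$gene_id)],
    all_calls$rna_subtype)

  files <- c(
    consensus_gff3 = file.path(outdir, "consensus.gff3"),
    products_tsv = file.path(outdir, "products.tsv"),
    annotation_tbl = file.path(outdir, "annotation.tbl"),
    warehouse_xml = file.path(outdir, "warehouse.xml"),
    status_krona = file.path(outdir, "krona_products.txt"),
    run_summary = file.path(outdir, "run_summary.json"),
    run_log = file.path(outdir, "run.log")
  )
  stage("writers", {
    write_features(all_calls, files[["consensus_gff3"]])
    utils::write.table(products, files[["products_tsv"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_feature_table(all_calls, products = products, path = files[["annotation_tbl"]])
    write_warehouse_xml(all_calls, products = products, domains = domains,
                        organism = config$organism %||% "organism",
                        path = files[["warehouse_xml"]])
    status_tree <- build_hierarchy(
      stats::setNames(lapply(seq_len(nrow(products)), function(i)
        list(c(products$status[i], products$source[i]))), products$gene_id),
      root_name = "products")
    write_hierarchy_text(status_tree, files[["status_krona"]])
  })
  if (!is.null(gbt)) {
    files[["gbt_tsv"]] <- file.path(outdir, "gbt.tsv")
    files[["gbt_krona"]] <- file.path(outdir, "krona_taxonomy.txt")
    stage("writers_gbt", {
      utils::write.table(gbt_winners(gbt), files[["gbt_tsv"]], sep = "\t",
                         quote = FALSE, row.names = FALSE)
      # counts are vote totals, encoded as one pseudo-gene per vote
      votes <- gbt[rep(seq_len(nrow(gbt)), gbt$votes), , drop = FALSE]
      tax_tree <- build_hierarchy(
        stats::setNames(lapply(seq_len(nrow(votes)), function(i)
          list(c(votes$scope_id[i], votes$species[i]))), paste0("v", seq_len(nrow(votes)))),
        root_name = "taxonomy")
      write_hierarchy_text(tax_tree, files[["gbt_krona"]])
    })
  }
  summary <- list(
    n_rna = nrow(rna), n_consensus_cds = nrow(consensus),
    n_calls_total = nrow(all_calls),
    functional = tall$functional, orphan = tall$orphan,
    gbt_db = gbt_db, gbt_run = !is.null(gbt),
    params = list(consensus = unclass(params),
                  products = unclass(pparams)[c("db_precedence", "max_evalue",
                                                "min_identity", "min_query_cov")])
  )
  jsonlite::write_json(summary, files[["run_summary"]], auto_unbox = TRUE)
  writeLines(log_lines, files[["run_log"]])
  invisible(list(calls = all_calls, consensus = consensus, rna = rna,
                 products = products, gbt = gbt, summary = summary,
                 files = files))
}

#' Benchmark a test annotation against a reference
#'
#' Thin composition of [read_features()], [match_gene_calls()] and
#' [comparison_report()]; writes the TSV rendering when `out` is given.
#'
#' @param test,ref gene-call tables or file paths (dialect guessed from the
#'   extension: `.tbl` is TBL, anything else GFF3).
#' @param offset similar-match offset in bases (default 50).
#' @param test_products optional product table or TSV path.
#' @param out optional report TSV path.
#' @return the `comparison_report`.
#' @export
run_benchmark <- function(test, ref, offset = 50L, test_products = NULL, out = NULL) {
  load_calls <- function(x) {
    if (is.character(x) && length(x) == 1) {
      read_features(x, dialect = if (grepl("\\.tbl$", x)) "tbl" else "gff3")
    } else x
  }
  if (is.character(test_products) && length(test_products) == 1) {
    test_products <- utils::read.delim(test_products, stringsAsFactors = FALSE)
  }
  m <- match_gene_calls(load_calls(test), load_calls(ref), offset = offset)
  rep_ <- comparison_report(m, test_products = test_products)
  if (!is.null(out)) report_tsv(rep_, out)
  rep_
}
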