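#' Read gene calls from GFF3 or NCBI feature-table (TBL) files
#'
#' Both dialects are normalized to the internal 1-based inclusive
#' representation. Minus-strand TBL records, which are written with reversed
#' coordinates on disk, come back with `start <= end` and strand `"-"`.
#' Unknown feature types are skipped with a warning; structurally malformed
#' lines are an error naming the offending line number. Input order is
#' preserved.
#'
#' @param path file to read.
#' @param dialect `"gff3"` or `"tbl"`.
#' @return gene-call `data.frame` (see [gene_calls()]).
#' @export
read_features <- function(path, dialect = c("gff3", "tbl")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "gff3") read_gff3_lines(lines, path) else read_tbl_lines(lines, path)
}

read_gff3_lines <- function(lines, path = "<text>") {
  recs <- list()
  skipped <- character()
  in_fasta <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (in_fasta) next
    if (ln == "" || startsWith(ln, "#")) {
      if (startsWith(ln, "##FASTA")) in_fasta <- TRUE
      next
    }
    if (startsWith(ln, ">")) { in_fasta <- TRUE; next }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8 || length(f) > 9) {
      stop(sprintf("malformed GFF3 line %d in %s: expected 9 tab-separated columns", i, path))
    }
    type <- f[3]
    if (!type %in% c("CDS", "rRNA", "tRNA")) { skipped <- c(skipped, type); next }
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end)) {
      stop(sprintf("malformed GFF3 line %d in %s: non-numeric coordinates", i, path))
    }
    if (end < start) {
      stop(sprintf("malformed GFF3 line %d in %s: end < start", i, path))
    }
    strand <- f[7]
    if (!strand %in% c("+", "-")) { skipped <- c(skipped, paste0(type, " (strand '", strand, "')")); next }
    attrs <- parse_gff3_attributes(if (length(f) == 9) f[9] else "")
    product <- attrs[["product"]] %||% NA_character_
    recs[[length(recs) + 1L]] <- data.frame(
      gene_id = attrs[["ID"]] %||% attrs[["locus_tag"]] %||%
        sprintf("%s_%d_%d_%s", f[1], start, end, strand),
      contig = f[1],
      start = start, end = end, strand = strand, feature_type = type,
      rna_subtype = if (type != "CDS") attrs[["Name"]] %||% product else NA_character_,
      source = if (f[2] == ".") NA_character_ else f[2],
      score = if (f[6] == ".") NA_real_ else suppressWarnings(as.numeric(f[6])),
      product = product,
      stringsAsFactors = FALSE
    )
  }
  if (length(skipped) > 0) {
    warning("skipped ", length(skipped), " record(s) with unsupported type/strand: ",
            paste(unique(skipped), collapse = ", "), call. = FALSE)
  }
  out <- rbind_df(recs)
  if (is.null(out)) return(empty_gene_calls())
  out$gene_id <- make.unique(out$gene_id, sep = "_dup")
  validate_gene_calls(out)
}

parse_gff3_attributes <- function(s) {
  out <- list()
  if (is.na(s) || s == "" || s == ".") return(out)
  for (kv in strsplit(s, ";", fixed = TRUE)[[1]]) {
    kv <- trimws(kv)
    if (kv == "") next
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) next
    out[[substr(kv, 1, eq - 1)]] <- utils::URLdecode(substr(kv, eq + 1, nchar(kv)))
  }
  out
}

## NCBI feature-table reader. A `gene` line opens a record; a following
## CDS/rRNA/tRNA line with the same normalized coordinates types it; a bare
## gene record defaults to CDS. Qualifier lines attach to the open record.
read_tbl_lines <- function(lines, path = "<text>") {
  recs <- list()
  skipped <- character()
  contig <- NA_character_
  cur <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    if (is.na(cur$feature_type)) cur$feature_type <- "CDS"
    recs[[length(recs) + 1L]] <<- as.data.frame(cur, stringsAsFactors = FALSE)
    cur <<- NULL
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "") next
    if (startsWith(ln, ">Feature")) {
      flush()
      contig <- sub("^>Feature\\s+(\\S+).*$", "\\1", ln)
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) >= 4 && f[1] == "" && f[2] == "" && f[3] == "") {
      # qualifier line
      if (is.null(cur)) {
        stop(sprintf("malformed TBL line %d in %s: qualifier before any feature", i, path))
      }
      qual <- f[4]; val <- if (length(f) >= 5) f[5] else ""
      if (qual == "locus_tag") cur$gene_id <- val
      if (qual == "product") {
        cur$product <- val
        if (!is.na(cur$feature_type) && cur$feature_type != "CDS") cur$rna_subtype <- val
      }
      next
    }
    if (length(f) < 3) {
      stop(sprintf("malformed TBL line %d in %s: expected coordinate line with 3 columns", i, path))
    }
    raw1 <- suppressWarnings(as.integer(sub("^[<>]", "", f[1])))
    raw2 <- suppressWarnings(as.integer(sub("^[<>]", "", f[2])))
    if (is.na(raw1) || is.na(raw2)) {
      stop(sprintf("malformed TBL line %d in %s: non-numeric coordinates", i, path))
    }
    key <- f[3]
    start <- min(raw1, raw2); end <- max(raw1, raw2)
    strand <- if (raw1 > raw2) "-" else "+"
    if (is.na(contig)) {
      stop(sprintf("malformed TBL line %d in %s: feature before any '>Feature' header", i, path))
    }
    if (key == "gene") {
      flush()
      cur <- list(gene_id = sprintf("%s_%d_%d_%s", contig, start, end, strand),
                  contig = contig, start = start, end = end, strand = strand,
                  feature_type = NA_character_, rna_subtype = NA_character_,
                  source = NA_character_, score = NA_real_, product = NA_character_)
    } else if (key %in% c("CDS", "rRNA", "tRNA")) {
      if (!is.null(cur) && is.na(cur$feature_type) &&
          cur$start == start && cur$end == end && cur$strand == strand) {
        cur$feature_type <- key
      } else {
        flush()
        cur <- list(gene_id = sprintf("%s_%d_%d_%s", contig, start, end, strand),
                    contig = contig, start = start, end = end, strand = strand,
                    feature_type = key, rna_subtype = NA_character_,
                    source = NA_character_, score = NA_real_, product = NA_character_)
      }
    } else {
      skipped <- c(skipped, key)
      flush()
    }
  }
  flush()
  if (length(skipped) > 0) {
    warning("skipped ", length(skipped), " TBL record(s) of unsupported type: ",
            paste(unique(skipped), collapse = ", "), call. = FALSE)
  }
  out <- rbind_df(recs)
  if (is.null(out)) return(empty_gene_calls())
  out$gene_id <- make.unique(out$gene_id, sep = "_dup")
  validate_gene_calls(out)
}

#' Write gene calls as GFF3
#'
#' Inverse of [read_features()] for the `gff3` dialect on the normalized
#' representation: writing then reading recovers identical coordinates,
#' strands and feature types.
#'
#' @param calls gene-call table.
#' @param path optional output file; when `NULL` the lines are returned only.
#' @return character vector of GFF3 lines, invisibly when `path` is given.
#' @export
write_features <- function(calls, path = NULL) {
  validate_gene_calls(calls)
  lines <- "##gff-version 3"
  if (nrow(calls) > 0) {
    attrs <- paste0("ID=", calls$gene_id)
    prod <- if ("product" %in% names(calls)) calls$product else rep(NA_character_, nrow(calls))
    sub <- if ("rna_subtype" %in% names(calls)) calls$rna_subtype else rep(NA_character_, nrow(calls))
    extra <- ifelse(!is.na(prod), paste0(";product=", prod),
                    ifelse(!is.na(sub), paste0(";product=", sub), ""))
    src <- if ("source" %in% names(calls)) calls$source else rep(NA_character_, nrow(calls))
    sco <- if ("score" %in% names(calls)) calls$score else rep(NA_real_, nrow(calls))
    lines <- c(lines, paste(
      calls$contig,
      ifelse(is.na(src), ".", src),
      calls$feature_type,
      calls$start, calls$end,
      ifelse(is.na(sco), ".", format(sco, trim = TRUE)),
      calls$strand, ".",
      paste0(attrs, extra),
      sep = "\t"
    ))
  }
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

#' Write gene calls as an NCBI feature table (TBL)
#'
#' Emits one `>Feature <contig>` block per contig (in order of first
#' appearance), and per call a `gene` line with a `locus_tag` qualifier
#' followed by the typed feature line with its `product` qualifier.
#' Minus-strand features are written with reversed coordinates, per the TBL
#' convention. Every CDS must have a product (possibly "hypothetical
#' protein"), supplied either in the `product` column or via `products`.
#'
#' @param calls gene-call table.
#' @param products optional product-assignment table (see [assign_products()])
#'   with columns `gene_id` and `product`; overrides the calls' own column.
#' @param path optional output file.
#' @return character vector of TBL lines, invisibly when `path` is given.
#' @export
write_feature_table <- function(calls, products = NULL, path = NULL) {
  validate_gene_calls(calls)
  prod <- if ("product" %in% names(calls)) calls$product else rep(NA_character_, nrow(calls))
  if (!is.null(products)) {
    idx <- match(calls$gene_id, products$gene_id)
    prod <- ifelse(!is.na(idx), products$product[idx], prod)
  }
  sub <- if ("rna_subtype" %in% names(calls)) calls$rna_subtype else rep(NA_character_, nrow(calls))
  prod <- ifelse(is.na(prod) & !is.na(sub), sub, prod)
  bad <- calls$feature_type == "CDS" & (is.na(prod) | prod == "")
  if (any(bad)) {
    stop("CDS without a product name: ", paste(utils::head(calls$gene_id[bad], 5), collapse = ", "))
  }
  lines <- character()
  for (ct in unique(calls$contig)) {
    lines <- c(lines, paste0(">Feature ", ct))
    sub_calls <- which(calls$contig == ct)
    for (k in sub_calls) {
      a <- calls$start[k]; b <- calls$end[k]
      if (calls$strand[k] == "-") { tmp <- a; a <- b; b <- tmp }
      lines <- c(lines,
                 paste(a, b, "gene", sep = "\t"),
                 paste("", "", "", "locus_tag", calls$gene_id[k], sep = "\t"),
                 paste(a, b, calls$feature_type[k], sep = "\t"))
      if (!is.na(prod[k]) && prod[k] != "") {
        lines <- c(lines, paste("", "", "", "product", prod[k], sep = "\t"))
      }
    }
  }
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

#' Read a tabular homology (BLAST outfmt-6 style) table
#'
#' Expects the standard 12 tab-separated columns (query, subject, percent
#' identity, alignment length, mismatches, gap opens, qstart, qend, sstart,
#' send, e-value, bit score), with an optional 13th column holding the subject
#' description and optional 14th the subject species. Hits are ranked per
#' query by bit score (descending), then e-value (ascending), then subject id
#' (ascending) — a total order, so permuting input rows never changes the
#' ranked output.
#'
#' @param path file to read.
#' @param db database label recorded on every hit.
#' @param query_lengths optional named integer vector of query lengths (aa or
#'   nt, matching the alignment-length unit); enables query coverage.
#' @return `data.frame` with one row per hit and a per-query `rank` column.
#' @export
read_homology <- function(path, db, query_lengths = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !(lines == "" | startsWith(lines, "#"))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) return(empty_homology(db))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 12)) {
    stop(sprintf("malformed homology line %d: fewer than 12 tab-separated columns",
                 lineno[which(ncols < 12)[1]]))
  }
  get <- function(j) vapply(parts, function(p) if (length(p) >= j) p[j] else NA_character_, character(1))
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(get(j)))
    if (anyNA(v)) {
      stop(sprintf("malformed homology line %d: non-numeric %s", lineno[which(is.na(v))[1]], what))
    }
    v
  }
  df <- data.frame(
    query_id = get(1), db = db, subject_id = get(2),
    pct_identity = num(3, "percent identity"),
    aln_length = as.integer(num(4, "alignment length")),
    mismatches = as.integer(num(5, "mismatches")),
    gaps = as.integer(num(6, "gap opens")),
    qstart = as.integer(num(7, "qstart")), qend = as.integer(num(8, "qend")),
    sstart = as.integer(num(9, "sstart")), send = as.integer(num(10, "send")),
    evalue = num(11, "evalue"), bitscore = num(12, "bitscore"),
    subject_desc = get(13), species = get(14),
    stringsAsFactors = FALSE
  )
  if (any(df$aln_length < 1L)) {
    stop(sprintf("malformed homology line %d: alignment length < 1",
                 lineno[which(df$aln_length < 1L)[1]]))
  }
  if (any(df$evalue < 0)) {
    stop(sprintf("malformed homology line %d: negative e-value",
                 lineno[which(df$evalue < 0)[1]]))
  }
  df$query_cov <- if (!is.null(query_lengths)) {
    (df$qend - df$qstart + 1L) / as.numeric(query_lengths[df$query_id])
  } else NA_real_
  rank_homology_hits(df)
}

empty_homology <- function(db = character()) {
  data.frame(query_id = character(), db = character(), subject_id = character(),
             pct_identity = numeric(), aln_length = integer(), mismatches = integer(),
             gaps = integer(), qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(), evalue = numeric(),
             bitscore = numeric(), subject_desc = character(), species = character(),
             query_cov = numeric(), rank = integer(), stringsAsFactors = FALSE)
}

#' Rank homology hits per query
#'
#' Applies the total order (bitscore desc, evalue asc, subject_id asc) within
#' each query, keeping queries in order of first appearance, and records the
#' 1-based rank.
#'
#' @param hits homology table (see [read_homology()]).
#' @return the table, sorted, with a `rank` column.
#' @export
rank_homology_hits <- function(hits) {
  if (nrow(hits) == 0) { hits$rank <- integer(0); return(hits) }
  qf <- factor(hits$query_id, levels = unique(hits$query_id))
  o <- order(qf, -hits$bitscore, hits$evalue, hits$subject_id)
  hits <- hits[o, , drop = FALSE]
  hits$rank <- stats::ave(seq_len(nrow(hits)), hits$query_id, FUN = seq_along)
  rownames(hits) <- NULL
  hits
}

#' Read a domain-scan (InterProScan-style) TSV
#'
#' Standard InterProScan tab-separated layout: query in column 1, analysis
#' (signature library) in 4, signature accession/description in 5/6, e-value
#' in 9 (`-` when the library reports none), InterPro accession in 12 and a
#' pipe- or comma-separated GO list in 14. GO terms are split, filtered to the
#' `GO:nnnnnnn` shape and deduplicated per row.
#'
#' @param path file to read.
#' @return `data.frame` with a `go_terms` list-column.
#' @export
read_domains <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !(lines == "" | startsWith(lines, "#"))
  lines <- lines[keep]
  lineno <- which(keep)
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) {
      stop(sprintf("malformed domain line %d: fewer than 9 tab-separated columns", lineno[i]))
    }
    f <- c(f, rep("-", max(0, 14 - length(f))))
    ev <- suppressWarnings(as.numeric(f[9]))
    if (is.na(ev) && !f[9] %in% c("-", "")) {
      stop(sprintf("malformed domain line %d: non-numeric e-value '%s'", lineno[i], f[9]))
    }
    gos <- character()
    if (!f[14] %in% c("-", "")) {
      gos <- unlist(strsplit(f[14], "[|,]"))
      gos <- sub("\\(.*\\)$", "", trimws(gos))  # strip e.g. (InterPro) provenance suffixes
      gos <- unique(gos[grepl("^GO:[0-9]{7}$", gos)])
    }
    out[[i]] <- data.frame(
      query_id = f[1], analysis = f[4], signature_acc = f[5],
      signature_desc = if (f[6] %in% c("-", "")) NA_character_ else f[6],
      evalue = ev,
      ipr_acc = if (f[12] %in% c("-", "")) NA_character_ else f[12],
      ipr_desc = if (f[13] %in% c("-", "")) NA_character_ else f[13],
      stringsAsFactors = FALSE
    )
    out[[i]]$go_terms <- list(gos)
  }
  res <- rbind_df(out)
  if (is.null(res)) {
    res <- data.frame(query_id = character(), analysis = character(),
                      signature_acc = character(), signature_desc = character(),
                      evalue = numeric(), ipr_acc = character(), ipr_desc = character(),
                      stringsAsFactors = FALSE)
    res$go_terms <- list()
  }
  res
}
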