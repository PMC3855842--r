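#' Flatten a hierarchy tree to Krona text-import rows
#'
#' One row per leaf: the leaf's gene count, a tab, then the tab-separated
#' path of node names from the root down to the leaf. Rows are sorted
#' lexicographically by path, so output is canonical. The result imports
#' directly into Krona's text importer.
#'
#' @param root hierarchy node as built by [build_hierarchy()] (a list with
#'   `name`, `count`, `children`).
#' @param path optional output file.
#' @return character vector of rows (empty for a childless root), invisibly
#'   when `path` is given.
#' @export
write_hierarchy_text <- function(root, path = NULL) {
  stopifnot(is.list(root), !is.null(root$name))
  if (!is.null(root$count) && any(unlist(collect_counts(root)) < 0)) {
    stop("hierarchy counts must be non-negative")
  }
  rows <- character()
  walk <- function(node, prefix) {
    full <- c(prefix, node$name)
    if (length(node$children) == 0) {
      if (length(prefix) > 0 && node$count > 0) {
        rows[[length(rows) + 1L]] <<- paste(c(node$count, full), collapse = "\t")
      }
      return()
    }
    for (ch in node$children) walk(ch, full)
  }
  walk(root, character())
  rows <- unlist(rows)
  if (length(rows) == 0) rows <- character()
  rows <- rows[order(vapply(strsplit(rows, "\t", fixed = TRUE),
                            function(p) paste(p[-1], collapse = "\t"), character(1)))]
  if (!is.null(path)) { writeLines(rows, path); return(invisible(rows)) }
  rows
}

collect_counts <- function(node) {
  c(list(node$count), lapply(node$children, collect_counts))
}
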