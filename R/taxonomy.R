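#' Extract a species name from a homology hit
#'
#' An explicit species field wins; otherwise the last bracketed `[...]`
#' substring of the subject description is used (the NCBI nr convention).
#' With `binomial = TRUE` the name is truncated to its first two tokens
#' (three when the first token is `Candidatus`).
#'
#' @param subject_desc character vector of subject descriptions.
#' @param species_field optional character vector of explicit species names.
#' @param binomial truncate to the binomial?
#' @return character vector; `NA` where no species is recoverable.
#' @export
#' @examples
#' extract_species("chaperonin GroEL [Escherichia coli K-12]", binomial = TRUE)
extract_species <- function(subject_desc, species_field = NA_character_,
                            binomial = FALSE) {
  n <- max(length(subject_desc), length(species_field))
  subject_desc <- rep_len(as.character(subject_desc), n)
  species_field <- rep_len(as.character(species_field), n)
  out <- species_field
  need <- is.na(out) | out == "" | out == "-"
  if (any(need)) {
    m <- regmatches(subject_desc[need], gregexpr("\\[[^][]*\\]", subject_desc[need]))
    out[need] <- vapply(m, function(x) {
      if (length(x) == 0) NA_character_ else {
        s <- x[[length(x)]]
        trimws(substr(s, 2, nchar(s) - 1))
      }
    }, character(1))
  }
  out[!is.na(out) & out == ""] <- NA_character_
  if (binomial) {
    out <- vapply(out, function(s) {
      if (is.na(s)) return(NA_character_)
      tok <- strsplit(trimws(s), "\\s+")[[1]]
      k <- if (length(tok) > 0 && tok[1] == "Candidatus") 3L else 2L
      paste(utils::head(tok, k), collapse = " ")
    }, character(1), USE.NAMES = FALSE)
  }
  out
}

#' Vote a best-supported taxonomy per contig or genome-wide
#'
#' Each gene contributes exactly one vote: the species of its top-ranked
#' species-resolvable homology hit. Species are ranked by votes; ties are
#' broken by the total alignment length summed over *all* of that species'
#' hits among the scope's genes (not only top hits), then lexicographically
#' so the order is total. Genes with no hits contribute nothing; hits without
#' a recoverable species are skipped for voting.
#'
#' @param hits homology table (one designated database; see [read_homology()]).
#' @param gene_to_contig named character vector mapping gene ids to contigs
#'   (required for `scope = "per_contig"`).
#' @param scope `"per_contig"` or `"genome"`.
#' @param binomial truncate species names to the binomial?
#' @return `data.frame` of class `gbt_ranking` with one row per
#'   (scope, species): `scope_id`, `species`, `votes`, `total_aln_length`,
#'   `rank`, `n_genes_with_hits`. The rank-1 row per scope is the winner;
#'   see [gbt_winners()].
#' @export
assign_gbt <- function(hits, gene_to_contig = NULL,
                       scope = c("per_contig", "genome"), binomial = FALSE) {
  scope <- match.arg(scope)
  hits <- rank_homology_hits(hits)
  hits$species_name <- extract_species(hits$subject_desc, hits$species, binomial = binomial)
  if (scope == "per_contig") {
    if (is.null(gene_to_contig)) stop("per-contig scope requires gene_to_contig")
    hits$scope_id <- as.character(gene_to_contig[hits$query_id])
    if (anyNA(hits$scope_id) && nrow(hits) > 0) {
      stop("gene(s) missing from gene_to_contig: ",
           paste(utils::head(unique(hits$query_id[is.na(hits$scope_id)]), 5), collapse = ", "))
    }
  } else {
    hits$scope_id <- rep("genome", nrow(hits))
  }
  res <- lapply(split(hits, hits$scope_id), function(h) {
    n_genes <- length(unique(h$query_id))
    resolvable <- h[!is.na(h$species_name), , drop = FALSE]
    if (nrow(resolvable) == 0) {
      return(data.frame(scope_id = h$scope_id[1], species = character(0),
                        votes = integer(0), total_aln_length = integer(0),
                        rank = integer(0), n_genes_with_hits = integer(0),
                        stringsAsFactors = FALSE))
    }
    top <- resolvable[!duplicated(resolvable$query_id), , drop = FALSE]  # ranked: first = top
    votes <- table(top$species_name)
    aln <- tapply(resolvable$aln_length, resolvable$species_name, sum)
    sp <- names(votes)
    d <- data.frame(scope_id = h$scope_id[1], species = sp,
                    votes = as.integer(votes),
                    total_aln_length = as.integer(aln[sp]),
                    stringsAsFactors = FALSE)
    d <- d[order(-d$votes, -d$total_aln_length, d$species), , drop = FALSE]
    d$rank <- seq_len(nrow(d))
    d$n_genes_with_hits <- nrow(top)
    d
  })
  out <- rbind_df(res[order(names(res))])
  if (is.null(out)) {
    out <- data.frame(scope_id = character(), species = character(),
                      votes = integer(), total_aln_length = integer(),
                      rank = integer(), n_genes_with_hits = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("gbt_ranking", "data.frame")
  out
}

#' Winners of the per-scope taxonomy vote
#'
#' @param ranking result of [assign_gbt()].
#' @return `data.frame` with one row per scope: `scope_id`, `winner`,
#'   `votes`, `total_aln_length`, `n_genes_with_hits`.
#' @export
gbt_winners <- function(ranking) {
  w <- ranking[ranking$rank == 1L, , drop = FALSE]
  data.frame(scope_id = w$scope_id, winner = w$species, votes = w$votes,
             total_aln_length = w$total_aln_length,
             n_genes_with_hits = w$n_genes_with_hits,
             stringsAsFactors = FALSE, row.names = NULL)
}
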