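#' Specification for a synthetic annotated genome
#'
#' Defines the conditions under which synthetic test data are generated:
#' genome layout, perturbation applied to manufacture a test annotation with
#' known comparison categories, the species mixture planted in homology hits,
#' and the fraction of genes whose hits carry only hypothetical names. Every
#' generator keyed by a spec is a pure function of it: the same seed gives
#' byte-identical output.
#'
#' @param seed integer RNG seed.
#' @param n_contigs number of contigs.
#' @param n_genes total genes (CDS + RNA).
#' @param gene_len_range CDS length range in nt (lengths are multiples of 3).
#' @param intergenic_range intergenic gap range in nt.
#' @param rna_genes how many of `n_genes` are RNA genes (rRNA subtypes first,
#'   then tRNAs).
#' @param perturbation list with `k_shift` (genes given a frame-preserving
#'   start shift), `max_shift` (maximum shift, multiple-of-3 shifts require
#'   >= 3), `m_drop` (genes deleted) and `j_add` (spurious genes inserted in
#'   intergenic space).
#' @param species_mix `data.frame` with columns `species` and `fraction`
#'   (fractions sum to 1); the mixture from which each gene's top-hit species
#'   is drawn.
#' @param hypothetical_fraction fraction of genes whose hits all carry
#'   hypothetical product names.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_contigs = 2L, n_genes = 50L,
                         gene_len_range = c(300L, 1500L),
                         intergenic_range = c(100L, 300L),
                         rna_genes = 5L,
                         perturbation = list(k_shift = 5L, max_shift = 50L,
                                             m_drop = 3L, j_add = 4L),
                         species_mix = data.frame(
                           species = c("Salinisphaera shabanensis", "Haloplasma contractile"),
                           fraction = c(0.7, 0.3)),
                         hypothetical_fraction = 0.3) {
  stopifnot(n_contigs >= 1, n_genes >= 0, rna_genes >= 0, rna_genes <= n_genes,
            length(gene_len_range) == 2, gene_len_range[1] >= 90,
            gene_len_range[2] >= gene_len_range[1],
            length(intergenic_range) == 2, intergenic_range[1] >= 1,
            intergenic_range[2] >= intergenic_range[1],
            abs(sum(species_mix$fraction) - 1) < 1e-8,
            hypothetical_fraction >= 0, hypothetical_fraction <= 1)
  p <- perturbation
  stopifnot(p$k_shift >= 0, p$m_drop >= 0, p$j_add >= 0,
            p$k_shift + p$m_drop <= n_genes)
  if (p$k_shift > 0 && p$max_shift < 3) {
    stop("frame-preserving shifts require max_shift >= 3")
  }
  structure(list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
                 n_genes = as.integer(n_genes),
                 gene_len_range = as.integer(gene_len_range),
                 intergenic_range = as.integer(intergenic_range),
                 rna_genes = as.integer(rna_genes), perturbation = p,
                 species_mix = species_mix,
                 hypothetical_fraction = hypothetical_fraction),
            class = "fixture_spec")
}

#' Simulate an annotated genome
#'
#' Places `n_genes` non-overlapping genes sequentially along `n_contigs`
#' contigs with intergenic gaps from the spec range. CDS lengths are
#' multiples of 3; plus-strand CDS get an ATG start and TAA stop written into
#' the (otherwise uniform-random) sequence, minus-strand their reverse
#' complement. Deterministic for a given seed.
#'
#' @param spec a [fixture_spec()].
#' @return list: `contigs` (named character vector of sequences) and `truth`
#'   (gene-call table).
#' @export
simulate_annotated_genome <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    n <- spec$n_genes
    per_contig <- diff(floor(seq(0, n, length.out = spec$n_contigs + 1)))
    rna_subtypes <- c("16S", "23S", "5S")
    rna_lens <- c(`16S` = 1492L, `23S` = 2904L, `5S` = 120L)
    rna_left <- spec$rna_genes
    gene_no <- 0L
    contigs <- character(spec$n_contigs)
    names(contigs) <- sprintf("contig%02d", seq_len(spec$n_contigs))
    truth <- list()
    for (ci in seq_len(spec$n_contigs)) {
      pos <- 0L
      seq_chars <- character()
      for (gi in seq_len(per_contig[ci])) {
        gene_no <- gene_no + 1L
        gap <- sample(spec$intergenic_range[1]:spec$intergenic_range[2], 1)
        is_rna <- rna_left > 0L
        if (is_rna) {
          idx <- spec$rna_genes - rna_left + 1L
          if (idx <= 3L) {
            subtype <- rna_subtypes[idx]; len <- rna_lens[[subtype]]; ftype <- "rRNA"
          } else {
            subtype <- paste0("tRNA-", sample(c("Ala", "Gly", "Leu", "Ser", "Val"), 1))
            len <- sample(72:90, 1); ftype <- "tRNA"
          }
          rna_left <- rna_left - 1L
        } else {
          len <- 3L * sample(ceiling(spec$gene_len_range[1] / 3):
                               floor(spec$gene_len_range[2] / 3), 1)
          ftype <- "CDS"; subtype <- NA_character_
        }
        start <- pos + gap + 1L
        end <- start + len - 1L
        strand <- sample(c("+", "-"), 1)
        gap_seq <- sample(c("A", "C", "G", "T"), gap, replace = TRUE)
        body <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
        if (ftype == "CDS") {
          if (strand == "+") {
            body[1:3] <- c("A", "T", "G"); body[(len - 2):len] <- c("T", "A", "A")
          } else {
            body[1:3] <- c("T", "T", "A"); body[(len - 2):len] <- c("C", "A", "T")
          }
        }
        seq_chars <- c(seq_chars, gap_seq, body)
        pos <- end
        truth[[gene_no]] <- data.frame(
          gene_id = sprintf("%s_g%03d", names(contigs)[ci], gi),
          contig = names(contigs)[ci], start = start, end = end,
          strand = strand, feature_type = ftype, rna_subtype = subtype,
          source = "truth", score = NA_real_, product = NA_character_,
          stringsAsFactors = FALSE
        )
      }
      tail_gap <- sample(spec$intergenic_range[1]:spec$intergenic_range[2], 1)
      seq_chars <- c(seq_chars, sample(c("A", "C", "G", "T"), tail_gap, replace = TRUE))
      contigs[ci] <- paste(seq_chars, collapse = "")
    }
    truth_df <- rbind_df(truth)
    if (is.null(truth_df)) truth_df <- empty_gene_calls()
    list(contigs = contigs, truth = truth_df)
  })
}

#' Write contigs as FASTA
#'
#' @param contigs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contigs_fasta <- function(contigs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(contigs), path)
  invisible(path)
}

#' Perturb a truth annotation with known expected comparison counts
#'
#' Applies `k_shift` frame-preserving inward start shifts (1..`max_shift` nt,
#' multiples of 3, so the shifted gene still overlaps the original and stays
#' within it), deletes `m_drop` genes and inserts `j_add` spurious genes into
#' intergenic gaps (overlapping nothing, so they can never match). By
#' construction the comparison against the truth reads `identical = n-k-m`,
#' `similar = k`, `not_detected = m`, `false_positives = j`.
#'
#' @param truth truth gene-call table from [simulate_annotated_genome()].
#' @param spec the same [fixture_spec()].
#' @return list: `test` (perturbed gene-call table) and `expected` (named
#'   list of category counts).
#' @export
perturb_annotation <- function(truth, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  p <- spec$perturbation
  with_seed(spec$seed + 1017L, {
    test <- truth
    n <- nrow(truth)
    cds_big <- which(truth$feature_type == "CDS" & call_length(truth) > p$max_shift + 9L)
    if (length(cds_big) < p$k_shift) stop("not enough long CDS to shift")
    shift_idx <- sort(sample(cds_big, p$k_shift))
    for (i in shift_idx) {
      s <- 3L * sample(seq_len(p$max_shift %/% 3L), 1)
      if (test$strand[i] == "+") test$start[i] <- test$start[i] + s
      else test$end[i] <- test$end[i] - s
    }
    droppable <- setdiff(seq_len(n), shift_idx)
    if (length(droppable) < p$m_drop) stop("not enough genes to drop")
    drop_idx <- sort(sample(droppable, p$m_drop))
    if (p$m_drop > 0) test <- test[-drop_idx, , drop = FALSE]
    added <- list()
    if (p$j_add > 0) {
      gaps <- intergenic_gaps(truth)
      gaps <- gaps[gaps$width >= 95L, , drop = FALSE]
      if (nrow(gaps) < p$j_add) stop("no intergenic room for added genes")
      pick <- sample(seq_len(nrow(gaps)), p$j_add)
      for (a in seq_len(p$j_add)) {
        g <- gaps[pick[a], ]
        len <- min(150L, 3L * ((g$width - 2L) %/% 3L))
        start <- g$start + 1L
        added[[a]] <- data.frame(
          gene_id = sprintf("added_%02d", a), contig = g$contig,
          start = start, end = start + len - 1L,
          strand = sample(c("+", "-"), 1), feature_type = "CDS",
          rna_subtype = NA_character_, source = "spurious", score = NA_real_,
          product = NA_character_, stringsAsFactors = FALSE
        )
      }
      test <- rbind(test, rbind_df(added))
    }
    test <- test[order(test$contig, test$start, test$end), , drop = FALSE]
    rownames(test) <- NULL
    list(test = test,
         expected = list(identical = n - p$k_shift - p$m_drop,
                         similar = p$k_shift, not_detected = p$m_drop,
                         false_positives = p$j_add))
  })
}

## Gaps strictly between consecutive genes on each contig (genes are disjoint
## by construction). start/end delimit the flanking genes; width is the free
## interior.
intergenic_gaps <- function(truth) {
  out <- list()
  for (ct in unique(truth$contig)) {
    d <- truth[truth$contig == ct, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) < 2) next
    w <- d$start[-1] - d$end[-nrow(d)] - 1L
    out[[ct]] <- data.frame(contig = ct, start = d$end[-nrow(d)],
                            width = w, stringsAsFactors = FALSE)
  }
  res <- rbind_df(out)
  if (is.null(res)) data.frame(contig = character(), start = integer(),
                               width = integer(), stringsAsFactors = FALSE) else res
}

#' Simulate a homology table with a planted taxonomy and name structure
#'
#' Every CDS receives 1-5 ranked hits in the standard 12(+2)-column tabular
#' layout. The top hit's species is drawn from the spec's species mixture
#' (so a mixture fraction > 0.5 plants a known majority winner), alignment
#' lengths and bit scores decrease with rank, and a `hypothetical_fraction`
#' of genes carry only hypothetical product names across all their hits.
#'
#' @param truth truth gene-call table.
#' @param spec the [fixture_spec()].
#' @param path optional file to write the table to.
#' @return character vector of table lines, invisibly when `path` is given.
#' @export
simulate_homology_hits <- function(truth, spec, path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  functional_pool <- c(
    "chaperonin GroEL", "DNA gyrase subunit A", "ABC transporter ATP-binding protein",
    "elongation factor Tu", "50S ribosomal protein L2", "citrate synthase",
    "DNA-directed RNA polymerase subunit beta", "phosphoglycerate kinase",
    "two-component sensor histidine kinase", "glyceraldehyde-3-phosphate dehydrogenase")
  hypothetical_pool <- c("hypothetical protein", "uncharacterized protein",
                         "predicted protein")
  with_seed(spec$seed + 2029L, {
    lines <- character()
    subj_no <- 0L
    cds <- truth[truth$feature_type == "CDS", , drop = FALSE]
    for (k in seq_len(nrow(cds))) {
      nh <- sample(1:5, 1)
      gene_hyp <- stats::runif(1) < spec$hypothetical_fraction
      top_aln <- max(30L, as.integer(0.9 * call_length(cds)[k] / 3))
      bit <- round(stats::runif(1, 200, 400), 1)
      for (r in seq_len(nh)) {
        subj_no <- subj_no + 1L
        species <- if (r == 1) {
          sample(spec$species_mix$species, 1, prob = spec$species_mix$fraction)
        } else {
          sample(spec$species_mix$species, 1, prob = spec$species_mix$fraction)
        }
        name <- if (gene_hyp) sample(hypothetical_pool, 1) else sample(functional_pool, 1)
        aln <- max(25L, top_aln - (r - 1L) * sample(5:20, 1))
        ident <- round(stats::runif(1, 35, 95) - (r - 1) * 3, 1)
        ev <- signif(10^(-stats::runif(1, 20, 60) + (r - 1) * 5), 3)
        lines[[length(lines) + 1L]] <- paste(
          cds$gene_id[k], sprintf("SUBJ_%06d", subj_no), ident, aln,
          sample(0:10, 1), sample(0:3, 1), 1L, aln, 1L, aln,
          format(ev, scientific = TRUE), bit,
          sprintf("%s [%s]", name, species), species,
          sep = "\t")
        bit <- bit - stats::runif(1, 5, 30)
      }
    }
    lines <- unlist(lines)
    if (is.null(lines)) lines <- character()
    if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
    lines
  })
}

#' Write a complete fixture directory
#'
#' Materialises one synthetic study: contig FASTA, truth and perturbed-test
#' GFF3, three predictor GFF3 variants of the truth CDS set, RNA GFF3,
#' homology table, and an `expected.json` manifest with the planted
#' comparison counts.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created).
#' @return invisible list of generated objects and paths.
#' @export
write_fixture_dir <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_annotated_genome(spec)
  pert <- perturb_annotation(sim$truth, spec)
  write_contigs_fasta(sim$contigs, file.path(dir, "contigs.fasta"))
  write_features(sim$truth, file.path(dir, "truth.gff3"))
  write_features(pert$test, file.path(dir, "test.gff3"))
  rna <- sim$truth[sim$truth$feature_type != "CDS", , drop = FALSE]
  cds <- sim$truth[sim$truth$feature_type == "CDS", , drop = FALSE]
  write_features(rna, file.path(dir, "rna.gff3"))
  preds <- predictor_variants(cds, spec)
  for (p in names(preds)) {
    write_features(preds[[p]], file.path(dir, paste0(p, ".gff3")))
  }
  # Homology is searched downstream of consensus calling, so the table's
  # query ids follow the consensus id scheme: CDS_%04d over CDS sorted by
  # (contig, start) — the order in which the truth was generated.
  cds_as_consensus <- cds[order(cds$contig, cds$start), , drop = FALSE]
  cds_as_consensus$gene_id <- sprintf("CDS_%04d", seq_len(nrow(cds_as_consensus)))
  simulate_homology_hits(cds_as_consensus, spec, file.path(dir, "hits_nr.tsv"))
  jsonlite::write_json(pert$expected, file.path(dir, "expected.json"),
                       auto_unbox = TRUE)
  invisible(list(spec = spec, truth = sim$truth, test = pert$test,
                 expected = pert$expected, predictors = preds, dir = dir))
}

## Three deterministic predictor views of the truth CDS set: one exact, one
## with alternative (downstream, frame-preserving) starts for a fifth of the
## genes, one missing every seventh gene. Exercises majority voting and
## shared-stop clustering in the consensus stage.
predictor_variants <- function(cds, spec) {
  with_seed(spec$seed + 3041L, {
    a <- cds
    b <- cds
    alt <- which(call_length(cds) > 120L)
    alt <- alt[seq_along(alt) %% 5L == 0L]
    for (i in alt) {
      if (b$strand[i] == "+") b$start[i] <- b$start[i] + 30L else b$end[i] <- b$end[i] - 30L
    }
    c_ <- cds[seq_len(nrow(cds)) %% 7L != 0L, , drop = FALSE]
    lapply(list(predA = a, predB = b, predC = c_), function(d) {
      d$source <- NA_character_; rownames(d) <- NULL; d
    })
  })
}
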