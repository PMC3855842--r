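test_that("RNA mask is the merged per-contig union of intervals", {
  expect_equal(nrow(build_mask(empty_gene_calls())), 0)

  rna <- gc_tab(list("r1", "c1", 10, 20, "+", "rRNA"),
                list("r2", "c1", 15, 30, "-", "tRNA"))
  m <- build_mask(rna)
  expect_equal(m$start, 10L)
  expect_equal(m$end, 30L)

  rna2 <- gc_tab(list("r1", "c1", 20, 25, "+", "rRNA"),
                 list("r2", "c1", 5, 9, "+", "rRNA"))
  m2 <- build_mask(rna2)
  expect_equal(m2$start, c(5L, 20L))  # disjoint, sorted
  expect_equal(m2$end, c(9L, 25L))

  expect_error(build_mask(gc_tab(list("g", "c1", 1, 90, "+", "CDS"))), "CDS")
})

test_that("unanimous predictors yield a single consensus gene", {
  call <- function(id) gc_tab(list(id, "c1", 200, 700, "+", "CDS"))
  cons <- merge_gene_calls(list(a = call("x"), b = call("y"), c = call("z")))
  expect_equal(nrow(cons), 1)
  expect_equal(cons$start, 200L)
  expect_equal(cons$end, 700L)
  expect_equal(cons$n_predictors, 3L)
  expect_equal(cons$source, "consensus")
})

test_that("start is chosen by majority vote over predictors sharing a stop", {
  cons <- merge_gene_calls(list(
    a = gc_tab(list("a1", "c1", 100, 400, "+", "CDS")),
    b = gc_tab(list("b1", "c1", 130, 400, "+", "CDS")),
    c = gc_tab(list("c1", "c1", 100, 400, "+", "CDS"))))
  expect_equal(nrow(cons), 1)
  expect_equal(cons$start, 100L)  # 2-of-3 vote
  # tie resolves toward the longest ORF
  cons2 <- merge_gene_calls(list(
    a = gc_tab(list("a1", "c1", 100, 400, "+", "CDS")),
    b = gc_tab(list("b1", "c1", 130, 400, "+", "CDS"))))
  expect_equal(cons2$start, 100L)
  # minus strand: the 5' coordinate is the end; longest means largest end
  cons3 <- merge_gene_calls(list(
    a = gc_tab(list("a1", "c1", 100, 400, "-", "CDS")),
    b = gc_tab(list("b1", "c1", 100, 370, "-", "CDS"))))
  expect_equal(cons3$end, 400L)
})

test_that("short single-predictor orphans are dropped by the length floor", {
  lone <- gc_tab(list("a1", "c1", 100, 159, "+", "CDS"))  # 60 nt
  expect_equal(nrow(merge_gene_calls(list(a = lone))), 0)
  kept <- gc_tab(list("a1", "c1", 100, 189, "+", "CDS"))  # 90 nt
  expect_equal(nrow(merge_gene_calls(list(a = kept))), 1)
  expect_equal(nrow(merge_gene_calls(
    list(a = kept), consensus_params(orphan_policy = "drop"))), 0)
  expect_error(merge_gene_calls(list()), "non-empty")
})

test_that("consensus is invariant under predictor and call permutations", {
  set.seed(41)
  preds <- lapply(1:3, function(i) {
    calls <- random_calls(10, seed = 100 + i)
    calls[calls$feature_type == "CDS", , drop = FALSE]
  })
  names(preds) <- c("p1", "p2", "p3")
  base <- merge_gene_calls(preds)
  for (perm in list(c(2, 1, 3), c(3, 1, 2))) {
    expect_equal(merge_gene_calls(preds[perm]), base)
  }
  shuffled <- lapply(preds, function(d) d[sample(nrow(d)), , drop = FALSE])
  expect_equal(merge_gene_calls(shuffled), base)
})

test_that("with one predictor, consensus equals its calls filtered by length", {
  calls <- random_calls(15, 7)
  cds <- calls[calls$feature_type == "CDS", , drop = FALSE]
  cons <- merge_gene_calls(list(only = cds))
  keep <- cds[(cds$end - cds$start + 1) >= 90, , drop = FALSE]
  keep <- keep[order(keep$contig, keep$start), , drop = FALSE]
  expect_equal(cons[c("contig", "start", "end", "strand")],
               keep[c("contig", "start", "end", "strand")], ignore_attr = TRUE)
  expect_lte(nrow(cons), nrow(cds))
})

test_that("shared-stop clustering agrees with brute-force grouping", {
  for (seed in 1:15) {
    set.seed(seed)
    n <- sample(5:30, 1)
    calls <- data.frame(
      gene_id = sprintf("g%d", 1:n),
      contig = sample(c("c1", "c2"), n, replace = TRUE),
      start = sample(seq(1, 3000, 3), n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    calls$end <- calls$start + sample(c(300, 600, 900), n, replace = TRUE) - 1L
    calls$feature_type <- "CDS"
    calls$rna_subtype <- NA; calls$source <- NA; calls$score <- NA; calls$product <- NA
    # distribute the calls over three predictors
    pred <- split(calls, sample(c("a", "b", "c"), n, replace = TRUE))
    cons <- merge_gene_calls(pred, consensus_params(min_cds_len = 3))
    expect_equal(nrow(cons), cluster_count_bruteforce(calls))
  }
})

test_that("CDS overlapping RNA beyond the tolerance are removed, RNA never", {
  mask <- build_mask(gc_tab(list("r", "c1", 500, 2000, "+", "rRNA")))
  far <- gc_tab(list("g1", "c1", 100, 400, "+", "CDS"))
  expect_equal(nrow(resolve_rna_overlap(far, mask, 0)), 1)

  across <- gc_tab(list("g2", "c1", 450, 700, "+", "CDS"))
  expect_message(kept <- resolve_rna_overlap(across, mask, 0), "201 nt")
  expect_equal(nrow(kept), 0)

  graze <- gc_tab(list("g3", "c1", 460, 509, "+", "CDS"))  # 10 nt overlap
  expect_equal(nrow(resolve_rna_overlap(graze, mask, 30)), 1)
})

test_that("RNA-overlap resolution is idempotent", {
  mask <- build_mask(gc_tab(list("r", "c1", 500, 2000, "+", "rRNA")))
  cds <- gc_tab(list("g1", "c1", 100, 400, "+", "CDS"),
                list("g2", "c1", 450, 700, "+", "CDS"),
                list("g3", "c1", 2100, 2400, "-", "CDS"))
  once <- suppressMessages(resolve_rna_overlap(cds, mask, 0))
  twice <- suppressMessages(resolve_rna_overlap(once, mask, 0))
  expect_equal(once[names(empty_gene_calls())], twice[names(empty_gene_calls())],
               ignore_attr = TRUE)
})
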