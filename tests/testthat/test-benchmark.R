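test_that("a test set identical to the reference is all identical", {
  ref <- random_calls(10, 31)
  m <- match_gene_calls(ref, ref)
  r <- comparison_report(m)
  expect_equal(r$identical, 10L)
  expect_equal(r$similar, 0L)
  expect_equal(r$not_detected, 0L)
  expect_equal(r$false_positives, 0L)
  expect_equal(r$pct_identical, 100)
})

test_that("the offset boundary is inclusive at 50 and strict beyond", {
  ref <- gc_tab(list("r1", "c1", 100, 400, "+", "CDS"))
  at50 <- gc_tab(list("t1", "c1", 150, 400, "+", "CDS"))
  m <- match_gene_calls(at50, ref, offset = 50)
  expect_equal(m$ref$category, "similar")
  # both deltas 60: not detected despite overlap
  both60 <- gc_tab(list("t1", "c1", 160, 460, "+", "CDS"))
  m2 <- match_gene_calls(both60, ref, offset = 50)
  expect_equal(m2$ref$category, "not_detected")
  expect_equal(length(m2$false_positive_ids), 1L)
  # a shared stop with a start shifted far beyond 50 is still similar (OR rule)
  farstart <- gc_tab(list("t1", "c1", 250, 400, "+", "CDS"))
  expect_equal(match_gene_calls(farstart, ref)$ref$category, "similar")
  expect_error(match_gene_calls(at50, ref, offset = -1), "offset")
})

test_that("matches require same contig, strand, type and overlap", {
  ref <- gc_tab(list("r1", "c1", 100, 400, "+", "CDS"))
  expect_equal(match_gene_calls(gc_tab(list("t", "c2", 100, 400, "+", "CDS")),
                                ref)$ref$category, "not_detected")
  expect_equal(match_gene_calls(gc_tab(list("t", "c1", 100, 400, "-", "CDS")),
                                ref)$ref$category, "not_detected")
  expect_equal(match_gene_calls(gc_tab(list("t", "c1", 100, 400, "+", "rRNA")),
                                ref)$ref$category, "not_detected")
  # equal start offset but 10 kb away: no overlap, no match
  expect_equal(match_gene_calls(gc_tab(list("t", "c1", 10100, 10400, "+", "CDS")),
                                ref)$ref$category, "not_detected")
})

test_that("identical pairs are matched before similar ones", {
  ref <- gc_tab(list("r1", "c1", 100, 400, "+", "CDS"),
                list("r2", "c1", 130, 400, "+", "CDS"))
  test <- gc_tab(list("t1", "c1", 100, 400, "+", "CDS"),
                 list("t2", "c1", 130, 400, "+", "CDS"))
  m <- match_gene_calls(test, ref)
  got <- m$ref[order(m$ref$ref_id), ]
  expect_equal(got$category, c("identical", "identical"))
  expect_equal(got$test_id, c("t1", "t2"))
})

test_that("categories always partition the reference set", {
  for (seed in 1:10) {
    spec <- fixture_spec(seed = seed)
    sim <- simulate_annotated_genome(spec)
    pert <- perturb_annotation(sim$truth, spec)
    r <- comparison_report(match_gene_calls(pert$test, sim$truth))
    expect_equal(r$identical + r$similar + r$not_detected, r$n_ref)
    expect_equal(r$false_negatives, r$not_detected)
    expect_lte(abs(r$pct_identical + r$pct_similar + r$pct_not_detected - 100), 0.02)
  }
})

test_that("similar-phase matching is maximum cardinality (small-instance oracle)", {
  for (seed in 1:60) {
    set.seed(seed)
    nr <- sample(1:8, 1); nt <- sample(1:8, 1)
    ref <- do.call(rbind, lapply(seq_len(nr), function(i)
      gene_calls(paste0("r", i), "c1", i * 25, i * 25 + sample(c(60, 90, 150), 1),
                 "+", "CDS")))
    test <- do.call(rbind, lapply(seq_len(nt), function(j)
      gene_calls(paste0("t", j), "c1", max(1L, j * 25 + sample(-40:40, 1)),
                 j * 25 + sample(c(60, 90, 150), 1), "+", "CDS")))
    m <- match_gene_calls(test, ref, offset = 50)
    matched <- sum(m$ref$category != "not_detected")
    # oracle: maximum injective assignment over all eligible pairs
    elig <- outer(seq_len(nr), seq_len(nt), function(i, j) {
      ov <- pmin(ref$end[i], test$end[j]) - pmax(ref$start[i], test$start[j]) + 1
      ds <- abs(ref$start[i] - test$start[j]); de <- abs(ref$end[i] - test$end[j])
      ov >= 1 & (ds <= 50 | de <= 50)
    })
    expect_equal(matched, max_matching_enum(elig),
                 label = paste("seed", seed))
  }
})

test_that("increasing the offset never decreases identical+similar", {
  for (seed in 1:5) {
    spec <- fixture_spec(seed = seed)
    sim <- simulate_annotated_genome(spec)
    pert <- perturb_annotation(sim$truth, spec)
    detected <- vapply(c(0, 10, 25, 50, 100), function(off) {
      r <- comparison_report(match_gene_calls(pert$test, sim$truth, offset = off))
      r$identical + r$similar
    }, numeric(1))
    expect_true(all(diff(detected) >= 0))
  }
})

test_that("swapping test and reference swaps false negatives and positives", {
  spec <- fixture_spec(seed = 44, perturbation = list(
    k_shift = 0, max_shift = 50, m_drop = 3, j_add = 4))
  sim <- simulate_annotated_genome(spec)
  pert <- perturb_annotation(sim$truth, spec)
  fwd <- comparison_report(match_gene_calls(pert$test, sim$truth))
  rev_ <- comparison_report(match_gene_calls(sim$truth, pert$test))
  expect_equal(fwd$false_negatives, rev_$false_positives)
  expect_equal(fwd$false_positives, rev_$false_negatives)
})

test_that("an empty reference yields a zero report with absent percentages", {
  r <- comparison_report(match_gene_calls(random_calls(3, 1), empty_gene_calls()))
  expect_equal(r$n_ref, 0L)
  expect_equal(r$identical, 0L)
  expect_true(is.na(r$pct_identical))
  expect_equal(r$false_positives, 3L)
})

test_that("reports built from raw counts reproduce percentage arithmetic", {
  r <- comparison_report(c(identical = 3, similar = 1, not_detected = 1))
  expect_equal(r$n_ref, 5L)
  expect_equal(r$pct_identical, 60)
  expect_equal(r$pct_similar, 20)
  lines <- report_tsv(r)
  expect_equal(lines[1], "metric\tvalue")
  expect_true("identical\t3" %in% lines)
})
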