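test_that("GFF3 reading maps fields and normalizes coordinates", {
  f <- withr::local_tempfile(lines = c(
    "##gff-version 3",
    "c1\tprodigal\tCDS\t100\t400\t52.1\t+\t0\tID=g1;product=chaperonin GroEL",
    "c1\trnammer\trRNA\t1000\t2500\t.\t-\t.\tID=r1;Name=16S"
  ))
  calls <- read_features(f, "gff3")
  expect_equal(nrow(calls), 2)
  expect_equal(calls$gene_id, c("g1", "r1"))
  expect_equal(calls$start, c(100L, 1000L))
  expect_equal(calls$end, c(400L, 2500L))
  expect_equal(calls$strand, c("+", "-"))
  expect_equal(calls$feature_type, c("CDS", "rRNA"))
  expect_equal(calls$rna_subtype[2], "16S")
  expect_equal(calls$score, c(52.1, NA))
})

test_that("empty feature files give empty call tables", {
  f <- withr::local_tempfile(lines = "##gff-version 3")
  expect_equal(nrow(read_features(f, "gff3")), 0)
  f2 <- withr::local_tempfile(lines = character())
  expect_equal(nrow(read_features(f2, "tbl")), 0)
})

test_that("unknown GFF3 feature types are skipped with a warning, not an error", {
  f <- withr::local_tempfile(lines = c(
    "c1\t.\tregion\t1\t5000\t.\t+\t.\tID=x",
    "c1\t.\tCDS\t100\t400\t.\t+\t.\tID=g1"
  ))
  expect_warning(calls <- read_features(f, "gff3"), "region")
  expect_equal(calls$gene_id, "g1")
})

test_that("malformed GFF3 lines are an error naming the line number", {
  f <- withr::local_tempfile(lines = c(
    "c1\t.\tCDS\t100\t400\t.\t+\t.\tID=g1",
    "c1\t.\tCDS\tabc\t400\t.\t+\t.\tID=g2"
  ))
  expect_error(read_features(f, "gff3"), "line 2")
  f2 <- withr::local_tempfile(lines = "c1\tCDS\t100")
  expect_error(read_features(f2, "gff3"), "line 1")
})

test_that("TBL minus-strand records come back normalized start <= end", {
  f <- withr::local_tempfile(lines = c(">Feature c1", "400\t100\tgene"))
  calls <- read_features(f, "tbl")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$start, 100L)
  expect_equal(calls$end, 400L)
  expect_equal(calls$strand, "-")
})

test_that("feature-table writer emits the TBL conventions", {
  calls <- gc_tab(list("g1", "c1", 100, 400, "+", "CDS"),
                  list("g2", "c1", 500, 900, "-", "CDS"))
  calls$product <- c("chaperonin GroEL", "citrate synthase")
  txt <- write_feature_table(calls)
  expect_true(">Feature c1" %in% txt)
  expect_true("100\t400\tgene" %in% txt)
  expect_true("\t\t\tproduct\tchaperonin GroEL" %in% txt)
  expect_true("900\t500\tgene" %in% txt)  # minus strand reversed on disk
  expect_error(write_feature_table(gc_tab(list("g3", "c1", 1, 99, "+", "CDS"))),
               "product")
})

test_that("GFF3 and TBL round trips are identity on the normalized form", {
  cols <- c("contig", "start", "end", "strand", "feature_type")
  for (seed in 1:20) {
    calls <- random_calls(12, seed)
    g <- withr::local_tempfile()
    write_features(calls, g)
    back <- read_features(g, "gff3")
    expect_equal(back[cols], calls[cols], ignore_attr = TRUE)
    expect_equal(back$gene_id, calls$gene_id)

    t <- withr::local_tempfile()
    write_feature_table(calls, path = t)
    back2 <- read_features(t, "tbl")
    expect_equal(back2[cols], calls[cols], ignore_attr = TRUE)
    expect_equal(back2$gene_id, calls$gene_id)
  }
})

test_that("GFF3 writer agrees with an independent GFF3 reader", {
  skip_if_not_installed("rtracklayer")
  calls <- random_calls(15, 99)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_features(calls, f)
  gr <- rtracklayer::import(f)
  expect_equal(length(gr), nrow(calls))
  expect_equal(BiocGenerics::start(gr), calls$start)
  expect_equal(BiocGenerics::end(gr), calls$end)
  expect_equal(as.character(BiocGenerics::strand(gr)), calls$strand)
})

test_that("homology hits are ranked by the total order, whatever the input order", {
  lines <- c(
    "g1\ts_low\t90\t100\t1\t0\t1\t100\t1\t100\t1e-40\t200",
    "g1\ts_high\t91\t120\t1\t0\t1\t120\t1\t120\t1e-50\t250",
    "g1\ts_tie\t92\t110\t1\t0\t1\t110\t1\t110\t1e-50\t200"
  )
  f <- withr::local_tempfile(lines = lines)
  h <- read_homology(f, "nr")
  expect_equal(h$subject_id, c("s_high", "s_tie", "s_low"))  # tie: lower evalue wins
  expect_equal(h$rank, 1:3)
  # permutation invariance
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    f2 <- withr::local_tempfile(lines = lines[perm])
    expect_equal(read_homology(f2, "nr")$subject_id, h$subject_id)
  }
})

test_that("homology reader enforces the 12-column numeric contract", {
  f <- withr::local_tempfile(lines = "g1\ts1\t90\t100\t1")
  expect_error(read_homology(f, "nr"), "line 1")
  f2 <- withr::local_tempfile(lines = c(
    "g1\ts1\t90\t100\t1\t0\t1\t100\t1\t100\t1e-40\t200",
    "g1\ts2\t90\tNOPE\t1\t0\t1\t100\t1\t100\t1e-40\t200"))
  expect_error(read_homology(f2, "nr"), "line 2")
  f3 <- withr::local_tempfile(lines = character())
  expect_equal(nrow(read_homology(f3, "nr")), 0)
})

test_that("query coverage is computed only when query lengths are supplied", {
  f <- withr::local_tempfile(
    lines = "g1\ts1\t90\t100\t1\t0\t1\t100\t1\t100\t1e-40\t200")
  expect_true(is.na(read_homology(f, "nr")$query_cov))
  h <- read_homology(f, "nr", query_lengths = c(g1 = 200L))
  expect_equal(h$query_cov, 0.5)
})

test_that("domain reader splits, filters and deduplicates GO terms", {
  mk <- function(go) paste("g1", "md5", "300", "Pfam", "PF00001", "ABC transporter",
                           "1", "100", "1e-10", "T", "01-01-2020", "IPR000001",
                           "desc", go, sep = "\t")
  f <- withr::local_tempfile(lines = c(
    mk("GO:0003677|GO:0005524"), mk("-"), mk("GO:0003677|GO:0003677"),
    mk("GO:0003677|notago")))
  d <- read_domains(f)
  expect_equal(d$go_terms[[1]], c("GO:0003677", "GO:0005524"))
  expect_equal(d$go_terms[[2]], character(0))
  expect_equal(d$go_terms[[3]], "GO:0003677")
  expect_equal(d$go_terms[[4]], "GO:0003677")
  expect_equal(d$ipr_acc[1], "IPR000001")
})

test_that("warehouse XML validates against its model and refuses extras", {
  empty <- write_warehouse_xml(organism = "org")
  expect_equal(xml2::xml_name(empty), "organism")
  expect_equal(length(xml2::xml_children(empty)), 0)

  calls <- gc_tab(list("g1", "c1", 100, 400, "+", "CDS"))
  prods <- data.frame(gene_id = "g1", product = "chaperonin GroEL",
                      source = "nr", status = "functional")
  doms <- data.frame(query_id = "g1", analysis = "Pfam", signature_acc = "PF1",
                     signature_desc = "x", evalue = 1e-10, ipr_acc = "IPR000001",
                     ipr_desc = NA, stringsAsFactors = FALSE)
  doms$go_terms <- list("GO:0003677")
  doc <- write_warehouse_xml(calls, prods, doms)
  txt <- as.character(doc)
  expect_true(grepl("GO:0003677", txt))           # identifier reference present
  expect_false(grepl("DNA binding", txt))          # no GO names, ids only
  expect_true(validate_warehouse_xml(doc))

  model <- default_warehouse_model()
  model$gene <- setdiff(model$gene, "source")
  calls$source <- "consensus"
  expect_error(write_warehouse_xml(calls, prods, model = model),
               "entity 'gene'.*'source'")
})

test_that("hierarchy text is one sorted row per leaf path", {
  leaf <- function(name, count) list(name = name, count = count, children = list())
  root <- list(name = "Bacteria", count = 12,
               children = list(leaf("Proteobacteria", 12)))
  expect_equal(write_hierarchy_text(root), "12\tBacteria\tProteobacteria")
  expect_equal(write_hierarchy_text(leaf("Bacteria", 0)), character(0))
  two <- list(name = "root", count = 5, children = list(
    list(name = "B", count = 3, children = list(leaf("z", 3), leaf("a", 3)))))
  expect_equal(write_hierarchy_text(two), c("3\troot\tB\ta", "3\troot\tB\tz"))
})
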