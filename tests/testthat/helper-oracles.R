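# Independent oracles used to cross-check the implementation. These share no
# code with the package paths they verify.

# Upper-tail hypergeometric probability P[X >= k] by exhaustive enumeration of
# all C(N, n) draws from a population of N with K successes.
hyper_tail_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  succ <- colSums(draws <= K)  # successes are elements 1..K
  mean(succ >= k)
}

# Same tail as an exact combinatorial sum.
hyper_tail_sum <- function(N, K, n, k) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Maximum number of reference genes matchable one-to-one to eligible test
# genes, by exhaustive recursion over injective assignments.
max_matching_enum <- function(eligible) {
  n_ref <- nrow(eligible)
  if (is.null(n_ref) || n_ref == 0) return(0L)
  best <- 0L
  recurse <- function(i, used, size) {
    remaining <- n_ref - i + 1
    if (size + remaining <= best) return()
    if (i > n_ref) { best <<- max(best, size); return() }
    for (j in which(eligible[i, ])) {
      if (!used[j]) { used[j] <- TRUE; recurse(i + 1, used, size + 1L); used[j] <- FALSE }
    }
    recurse(i + 1, used, size)
  }
  recurse(1L, rep(FALSE, ncol(eligible)), 0L)
  best
}

# Brute-force grouping of calls by (contig, strand, stop coordinate): for each
# pair decide same-cluster by direct key comparison, then count components.
cluster_count_bruteforce <- function(calls) {
  n <- nrow(calls)
  if (n == 0) return(0L)
  stopc <- ifelse(calls$strand == "+", calls$end, calls$start)
  same <- outer(seq_len(n), seq_len(n), function(i, j)
    calls$contig[i] == calls$contig[j] & calls$strand[i] == calls$strand[j] &
      stopc[i] == stopc[j])
  comp <- rep(NA_integer_, n); nc <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) { nc <- nc + 1L; comp[same[i, ]] <- nc }
  }
  nc
}

# Recount the taxonomy vote directly from raw homology table lines: per query
# take the row with max bitscore (ties: min evalue, then min subject id), vote
# its bracketed species; sum alignment lengths per species over all rows.
gbt_recount_bruteforce <- function(lines) {
  f <- strsplit(lines, "\t", fixed = TRUE)
  df <- data.frame(
    q = vapply(f, `[`, "", 1), subj = vapply(f, `[`, "", 2),
    aln = as.integer(vapply(f, `[`, "", 4)),
    ev = as.numeric(vapply(f, `[`, "", 11)),
    bit = as.numeric(vapply(f, `[`, "", 12)),
    sp = vapply(f, `[`, "", 14), stringsAsFactors = FALSE)
  votes <- integer(); names(votes) <- character()
  for (q in unique(df$q)) {
    d <- df[df$q == q, ]
    d <- d[order(-d$bit, d$ev, d$subj), ]
    sp <- d$sp[1]
    votes[sp] <- (if (sp %in% names(votes)) votes[[sp]] else 0L) + 1L
  }
  aln <- tapply(df$aln, df$sp, sum)
  ord <- order(-votes, -as.integer(aln[names(votes)]), names(votes))
  list(winner = names(votes)[ord][1], votes = votes)
}

# Small literal gene-call table builder for tests.
gc_tab <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    gene_calls(r[[1]], r[[2]], as.integer(r[[3]]), as.integer(r[[4]]),
               r[[5]], r[[6]])
  }))
}

# Random gene-call table (non-overlapping per contig) for round-trip and
# permutation properties.
random_calls <- function(n, seed, contigs = 2) {
  set.seed(seed)
  out <- list()
  gid <- 0
  for (ct in paste0("c", seq_len(contigs))) {
    pos <- 0
    for (i in seq_len(ceiling(n / contigs))) {
      gid <- gid + 1
      if (gid > n) break
      start <- pos + sample(20:200, 1)
      len <- sample(c(90, 120, 300, 900, 1500), 1)
      type <- sample(c("CDS", "rRNA", "tRNA"), 1, prob = c(0.8, 0.1, 0.1))
      out[[gid]] <- gene_calls(sprintf("g%03d", gid), ct, start, start + len - 1,
                               sample(c("+", "-"), 1), type,
                               rna_subtype = if (type == "tRNA") "tRNA-Ala" else NA,
                               product = if (type == "CDS") "some protein" else NA)
      pos <- start + len - 1
    }
  }
  do.call(rbind, out)
}
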