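# Unit tests for the core data model: registries, FASTA and pair I/O,
# degree bookkeeping, negative sampling and the AUC primitive.

test_that("canonicalize_pairs orders endpoints and preserves columns", {
  p <- tibble::tibble(a = c("Z", "A", "M"), b = c("A", "B", "M"),
                      label = c(1L, 0L, 1L), extra = 1:3)
  out <- canonicalize_pairs(p)
  expect_true(all(out$a <= out$b))
  expect_equal(out$a, c("A", "A", "M"))
  expect_equal(out$b, c("Z", "B", "M"))
  expect_equal(out$extra, 1:3)
  expect_equal(nrow(canonicalize_pairs(p[0, ])), 0)
})

test_that("FASTA round-trip preserves ids and sequences", {
  reg <- toy_proteins(5)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(reg, f)
  back <- read_fasta(f)
  expect_equal(back$id, reg$id)
  expect_equal(back$sequence, reg$sequence)
})

test_that("read_fasta takes first header token, drops or rejects invalid residues", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "MKVLxAG", ">p2", "acdefgh"), f)
  expect_warning(reg <- read_fasta(f), "non-standard")
  expect_equal(reg$id, c("p1", "p2"))
  expect_equal(reg$sequence[1], "MKVLAG")    # X dropped, upper-cased
  expect_equal(reg$sequence[2], "ACDEFGH")
  expect_error(read_fasta(f, invalid = "error"), "non-standard")
  expect_error(read_fasta(file.path(tempdir(), "nope.fasta")), "not found")
})

test_that("read_fasta rejects duplicates and too-short sequences", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MKVL", ">a", "MKVA"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(c(">a", "MK"), f)
  expect_error(read_fasta(f), "shorter")
})

test_that("read_pairs handles label and affinity input with the pKd threshold", {
  reg <- toy_proteins(4)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "a\tb\tlabel",
               paste("T02", "T01", 1, sep = "\t"),
               paste("T03", "T04", 0, sep = "\t")), f)
  pt <- read_pairs(f, reg)
  expect_equal(pt$a, c("T01", "T03"))      # canonicalized
  expect_equal(pt$label, c(1L, 0L))

  writeLines(c("a\tb\taffinity",
               paste("T01", "T02", 6.3, sep = "\t"),
               paste("T03", "T04", 6.29, sep = "\t"),
               paste("T01", "T03", 9.1, sep = "\t")), f)
  pt <- read_pairs(f, reg)
  expect_equal(pt$label, c(1L, 0L, 1L))    # >= 6.3 is positive

  writeLines(c("a\tb\tlabel", paste("T01", "T09", 1, sep = "\t")), f)
  expect_error(read_pairs(f, reg), "unregistered")
  writeLines(c("a\tb", paste("T01", "T02", sep = "\t")), f)
  expect_error(read_pairs(f, reg), "'label' or 'affinity'")
})

test_that("as_pair_table distinguishes conflicting from plain duplicates", {
  conflict <- tibble::tibble(a = c("A", "B"), b = c("B", "A"),
                             label = c(1L, 0L))
  expect_error(as_pair_table(conflict), "conflicting")
  dup <- tibble::tibble(a = c("A", "B"), b = c("B", "A"),
                        label = c(1L, 1L))
  expect_error(as_pair_table(dup), "duplicate")
  expect_error(as_pair_table(tibble::tibble(a = "A", b = "B", label = 2)),
               "0 or 1")
})

test_that("pair table TSV round-trip is lossless", {
  reg <- toy_proteins(6)
  pt <- as_pair_table(toy_pairs(reg), reg)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pairs(pt, f)
  expect_equal(read_pairs(f, reg), pt)
})

test_that("pkd_from_kd maps 500 nM to 6.3 and rejects non-positive input", {
  expect_equal(round(pkd_from_kd(500e-9), 1), 6.3)
  expect_equal(pkd_from_kd(1), 0)
  expect_error(pkd_from_kd(0), "positive")
  expect_error(pkd_from_kd(-1e-9), "positive")
  expect_error(pkd_from_kd(NA_real_), "positive")
})

test_that("degree table counts endpoints, self-pairs contribute two", {
  pairs <- tibble::tibble(
    a = c("A", "A", "B", "C"),
    b = c("B", "C", "C", "C"),   # (C, C) is a self-pair
    label = c(1L, 1L, 0L, 1L)
  )
  d <- compute_degree_table(pairs)
  expect_equal(d$id, c("A", "B", "C"))
  expect_equal(d$d_pos, c(2L, 1L, 3L))   # C: one endpoint + self-pair 2
  expect_equal(d$d_neg, c(0L, 1L, 1L))
  expect_identical(attr(d, "source"), "train")
})

test_that("degree conservation: sum(d_pos) == 2 * n_positives (property)", {
  for (s in 1:5) {
    reg <- toy_proteins(10, seed = s)
    pt <- toy_pairs(reg, n_pos = 8, seed = s)
    d <- compute_degree_table(pt)
    expect_equal(sum(d$d_pos), 2L * sum(pt$label == 1L))
    expect_equal(sum(d$d_neg), 2L * sum(pt$label == 0L))
  }
})

test_that("unlisted proteins get zero degrees when a registry is given", {
  reg <- toy_proteins(5)
  pairs <- tibble::tibble(a = "T01", b = "T02", label = 1L)
  d <- compute_degree_table(pairs, proteins = reg)
  expect_equal(nrow(d), 5)
  expect_equal(d$d_pos[d$id == "T05"], 0L)
})

test_that("random_negative_sampling avoids positives and is seed-deterministic", {
  reg <- toy_proteins(8)
  pos <- toy_pairs(reg, n_pos = 5)[1:5, ]
  neg1 <- random_negative_sampling(reg, pos, 10, seed = 3)
  neg2 <- random_negative_sampling(reg, pos, 10, seed = 3)
  neg3 <- random_negative_sampling(reg, pos, 10, seed = 4)
  expect_identical(neg1, neg2)
  expect_false(identical(neg1, neg3))
  expect_equal(nrow(neg1), 10)
  expect_true(all(neg1$label == 0L))
  expect_true(all(neg1$a < neg1$b))        # canonical, no self-pairs
  key <- function(p) paste(p$a, p$b)
  expect_length(intersect(key(neg1), key(pos)), 0)
  expect_error(random_negative_sampling(reg, pos, 1e6, seed = 1), "only")
})

test_that("group_based_negative_sampling only pairs disjoint tag sets", {
  reg <- toy_proteins(6)
  groups <- tibble::tibble(
    id = c("T01", "T02", "T03", "T04", "T05", "T06"),
    group = c("nuc", "nuc", "mem", "mem", "cyt", "nuc")
  )
  pos <- tibble::tibble(a = "T01", b = "T03", label = 1L)
  neg <- group_based_negative_sampling(reg, groups, pos, 5, seed = 1)
  tags <- split(groups$group, groups$id)
  for (i in seq_len(nrow(neg))) {
    expect_length(intersect(tags[[neg$a[i]]], tags[[neg$b[i]]]), 0)
  }
  expect_error(
    group_based_negative_sampling(reg, groups[-1, ], pos, 2, seed = 1),
    "without group tags"
  )
})

test_that("auc_score handles perfect, reversed, constant and tied scores", {
  expect_equal(auc_score(c(0.9, 0.8), c(0.1, 0.2)), 1)
  expect_equal(auc_score(c(0.1, 0.2), c(0.9, 0.8)), 0)
  expect_equal(auc_score(rep(0.5, 10), rep(0.5, 7)), 0.5)
  expect_equal(auc_score(c(1, 0), c(1, 0)), 0.5)
  expect_error(auc_score(numeric(0), 1), "non-empty")
})

test_that("auc_score agrees with pROC on random scores", {
  withr::with_seed(99, {
    labels <- rep(c(1, 0), c(40, 60))
    scores <- c(rnorm(40, 0.3), rnorm(60))
    expect_equal(
      auc_score(scores[labels == 1], scores[labels == 0]),
      as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                     direction = "<"))),
      tolerance = 1e-12
    )
  })
})
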