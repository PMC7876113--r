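# Unit tests for the synthetic generator: determinism, planted motif
# structure, degree-bias monotonicity and fixture/dataset serialization.

test_that("synthetic_config validates its arguments", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  expect_error(synthetic_config(n_proteins = 2))
  expect_error(synthetic_config(bias_beta = -1))
  expect_error(synthetic_config(noise_eps = 0.6))
  expect_error(synthetic_config(n_keys = 3))
  expect_error(synthetic_config(n_proteins = 10, n_pos = 100), "exceeds")
})

test_that("generation is a pure function of the configuration", {
  cfg <- synthetic_config(n_proteins = 40, n_pos = 60, bias_beta = 1,
                          seed = 5)
  p1 <- generate_proteome(cfg)
  p2 <- generate_proteome(cfg)
  expect_identical(p1, p2)
  expect_identical(generate_interactions(p1, cfg),
                   generate_interactions(p2, cfg))
  cfg2 <- synthetic_config(n_proteins = 40, n_pos = 60, bias_beta = 1,
                           seed = 6)
  expect_false(identical(generate_proteome(cfg2), p1))
})

test_that("the proteome respects the length bounds and alphabet", {
  cfg <- synthetic_config(n_proteins = 50, seq_len = c(30, 60), n_pos = 40)
  reg <- generate_proteome(cfg)
  expect_equal(nrow(reg), 50)
  expect_false(anyDuplicated(reg$id) > 0)
  lens <- nchar(reg$sequence)
  expect_true(all(lens >= 30 & lens <= 60))
  letters_used <- unique(strsplit(paste(reg$sequence, collapse = ""),
                                  "")[[1]])
  expect_true(all(letters_used %in% AAS))
})

test_that("motif mode plants each key's motif and preserves lengths", {
  cfg <- synthetic_config(n_proteins = 40, n_pos = 60, signal = "motif",
                          motif_len = 8, seed = 3)
  reg <- generate_proteome(cfg)
  motifs <- attr(reg, "motifs")
  expect_length(motifs, 4)
  expect_equal(nchar(motifs), rep(8, 4))
  for (i in seq_len(nrow(reg))) {
    expect_true(grepl(motifs[reg$key[i]], reg$sequence[i], fixed = TRUE))
  }
  lens <- nchar(generate_proteome(
    synthetic_config(n_proteins = 40, n_pos = 60, seed = 3))$sequence)
  expect_equal(nchar(reg$sequence), lens)   # insertion overwrites in place
})

test_that("interaction sets are class-balanced, canonical and distinct", {
  for (scheme in c("random", "degree_matched")) {
    cfg <- synthetic_config(n_proteins = 50, n_pos = 80, bias_beta = 1,
                            neg_scheme = scheme, seed = 8)
    reg <- generate_proteome(cfg)
    pairs <- generate_interactions(reg, cfg)
    expect_equal(sum(pairs$label == 1L), 80)
    expect_equal(sum(pairs$label == 0L), 80)
    expect_true(all(pairs$a < pairs$b))          # canonical, no self-pairs
    expect_false(anyDuplicated(paste(pairs$a, pairs$b)) > 0)
  }
})

test_that("motif labels follow key compatibility up to the noise rate", {
  cfg <- synthetic_config(n_proteins = 80, n_pos = 120, signal = "motif",
                          motif_len = 8, noise_eps = 0.05,
                          neg_scheme = "degree_matched", seed = 12)
  reg <- generate_proteome(cfg)
  pairs <- generate_interactions(reg, cfg)
  key_of <- stats::setNames(reg$key, reg$id)
  compat <- pairaudit:::keys_compatible(key_of[pairs$a], key_of[pairs$b])
  agreement <- mean(as.integer(compat) == pairs$label)
  expect_gt(agreement, 0.85)   # ~5% flips, plus class-count truncation
  expect_lt(agreement, 1)      # some noise was injected
})

test_that("key compatibility pairs keys off as documented", {
  kc <- pairaudit:::keys_compatible
  expect_true(kc(1, 2)); expect_true(kc(2, 1))
  expect_true(kc(3, 4)); expect_true(kc(4, 3))
  expect_false(kc(1, 1)); expect_false(kc(2, 2))
  expect_false(kc(1, 3)); expect_false(kc(2, 4)); expect_false(kc(1, 4))
})

test_that("stronger degree bias raises hub concentration and recurrence AUC", {
  aucs <- vapply(c(0, 1.5), function(beta) {
    cfg <- synthetic_config(n_proteins = 80, n_pos = 250, bias_beta = beta,
                            seed = 7)
    reg <- generate_proteome(cfg)
    pairs <- generate_interactions(reg, cfg)
    sp <- split_in_network(pairs, rounds = 2, seed = 1)
    recurrence_audit(sp, reference_auc = 0.5)$mean_auc
  }, numeric(1))
  expect_gt(aucs[2], aucs[1] + 0.05)   # monotone in the planted bias
  expect_lt(abs(aucs[1] - 0.5), 0.1)   # unbiased data sits near chance
})

test_that("fixtures carry their expected verdict chains", {
  expect_error(make_fixture("unknown"))
  fx <- cached_fixture("null")
  expect_equal(sum(fx$pairs$label == 1L), sum(fx$pairs$label == 0L))
  expect_identical(unname(fx$expected["feature_masked"]),
                   "no_bias_indicated")
  pb <- cached_fixture("pure_bias")
  expect_identical(unname(pb$expected["recurrence"]), "bias_indicated")
  expect_identical(unname(pb$expected["debias_masked_balanced"]),
                   "no_bias_indicated")
  ps <- cached_fixture("pure_signal")
  expect_identical(unname(ps$expected["feature_masked"]),
                   "no_bias_indicated")
  expect_equal(ps$config$motif_len, 12L)
})

test_that("write_dataset round-trips through the file readers", {
  ds <- small_dataset(seed = 44)
  d <- withr::local_tempdir()
  write_dataset(ds$proteins, ds$pairs, d,
                manifest = unclass(ds$config))
  reg <- read_fasta(file.path(d, "proteins.fasta"))
  expect_equal(reg$id, ds$proteins$id)
  expect_equal(reg$sequence, ds$proteins$sequence)
  back <- read_pairs(file.path(d, "pairs.tsv"), reg)
  expect_equal(dplyr::arrange(back, a, b),
               dplyr::arrange(ds$pairs, a, b))
  man <- jsonlite::read_json(file.path(d, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$n_proteins, 60)
})
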