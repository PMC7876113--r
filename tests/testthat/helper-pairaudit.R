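# Shared test utilities: a brute-force AUC oracle, tiny deterministic
# registries/pair tables, and lazily cached synthetic fixtures so that the
# acceptance tests do not regenerate the same datasets.

AAS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# O(n_pos * n_neg) pairwise-count AUC: ties count one half.
brute_auc <- function(scores_pos, scores_neg) {
  cmp <- outer(scores_pos, scores_neg,
               function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

rand_seq <- function(len, seed) {
  withr::with_seed(seed, paste(sample(AAS, len, replace = TRUE),
                               collapse = ""))
}

toy_proteins <- function(n = 6, len = 40, seed = 42) {
  tibble::tibble(
    id = sprintf("T%02d", seq_len(n)),
    sequence = vapply(seq_len(n), function(i) rand_seq(len, seed + i),
                      character(1))
  )
}

# Small class-balanced pair table over a toy registry.
toy_pairs <- function(proteins, n_pos = 6, seed = 7) {
  all_p <- t(utils::combn(proteins$id, 2))
  withr::with_seed(seed, {
    take <- sample.int(nrow(all_p), 2 * n_pos)
    tibble::tibble(
      a = all_p[take, 1], b = all_p[take, 2],
      label = rep(c(1L, 0L), each = n_pos)
    )
  })
}

# A small but audit-capable synthetic dataset (conjoint-triad features
# keep unit tests fast), cached per (beta, signal).
small_dataset <- function(bias_beta = 0, signal = "none", seed = 11) {
  cfg <- synthetic_config(
    n_proteins = 60L, n_pos = 150L, bias_beta = bias_beta,
    signal = signal, motif_len = 12L,
    neg_scheme = if (signal == "motif") "degree_matched" else "random",
    seed = seed
  )
  proteins <- generate_proteome(cfg)
  list(proteins = proteins,
       pairs = generate_interactions(proteins, cfg),
       config = cfg)
}

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name) {
  if (is.null(.fixture_cache[[name]])) {
    .fixture_cache[[name]] <- make_fixture(name)
  }
  .fixture_cache[[name]]
}
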