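## Train/validation/test split construction over rounds, with in-network
## (every test protein has other examples in training) or out-of-network
## (no test protein appears in training) test membership — the two regimes
## whose contrast exposes non-generalizing pair classifiers.

downsample_balance <- function(pairs, seed) {
  n_pos <- sum(pairs$label == 1L)
  n_neg <- sum(pairs$label == 0L)
  k <- min(n_pos, n_neg)
  idx_pos <- which(pairs$label == 1L)
  idx_neg <- which(pairs$label == 0L)
  keep <- withr::with_seed(seed, c(
    if (n_pos > k) sample(idx_pos, k) else idx_pos,
    if (n_neg > k) sample(idx_neg, k) else idx_neg
  ))
  pairs[sort(keep), ]
}

pair_proteins <- function(pairs) unique(c(pairs$a, pairs$b))

new_split_rounds <- function(rows, mode, seed, fractions) {
  out <- dplyr::bind_rows(rows)
  attr(out, "mode") <- mode
  attr(out, "seed") <- seed
  attr(out, "fractions") <- fractions
  class(out) <- c("split_rounds", class(out))
  out
}

#' @export
print.split_rounds <- function(x, ...) {
  cat("<split_rounds> mode:", attr(x, "mode"), "| rounds:", nrow(x), "\n")
  NextMethod()
}

split_fractions_check <- function(fractions) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8 ||
      any(fractions <= 0)) {
    abort("fractions must be three positive numbers summing to 1")
  }
}

#' In-network split rounds
#'
#' For each round, pairs are randomly partitioned into train, validation
#' and test by `fractions`; each subset is class-balanced by down-sampling
#' its majority label; then any validation or test pair with an endpoint
#' absent from the (final) training protein set is removed, so every test
#' protein has examples of its other interactions in training. Removal
#' counts per round are recorded in the `removed` column.
#'
#' @param pairs Class-balanced pair table.
#' @param rounds Number of rounds (default 10).
#' @param fractions `c(train, validation, test)` proportions, summing to 1.
#' @param seed Integer seed; splits are a pure function of (inputs, seed).
#' @return A `split_rounds` tibble with one row per round and list-columns
#'   `train`, `validation`, `test`.
#' @export
split_in_network <- function(pairs, rounds = 10L,
                             fractions = c(0.70, 0.10, 0.20), seed = 1L) {
  split_fractions_check(fractions)
  pairs <- canonicalize_pairs(pairs)
  if (sum(pairs$label == 1L) != sum(pairs$label == 0L)) {
    abort("input pairs must be class-balanced")
  }
  round_seeds <- withr::with_seed(seed, sample.int(2^30, rounds * 3))
  rows <- lapply(seq_len(rounds), function(r) {
    s_part <- round_seeds[3 * r - 2]
    s_bal <- round_seeds[3 * r - 1]
    n <- nrow(pairs)
    perm <- withr::with_seed(s_part, sample.int(n))
    n_tr <- floor(fractions[1] * n)
    n_va <- floor(fractions[2] * n)
    train <- downsample_balance(pairs[perm[seq_len(n_tr)], ], s_bal)
    valid <- pairs[perm[n_tr + seq_len(n_va)], ]
    test <- pairs[perm[(n_tr + n_va + 1):n], ]
    train_prot <- pair_proteins(train)
    in_net <- function(p) p[p$a %in% train_prot & p$b %in% train_prot, ]
    removed <- c(validation = nrow(valid), test = nrow(test))
    valid <- downsample_balance(in_net(valid), s_bal + 1L)
    test <- downsample_balance(in_net(test), s_bal + 2L)
    removed <- removed - c(nrow(valid), nrow(test))
    if (nrow(test) == 0 || length(unique(test$label)) < 2) {
      abort(paste0("round ", r, ": test set empty or single-class after ",
                   "in-network filtering; use more data or a larger ",
                   "train fraction"))
    }
    tibble(round = r, mode = "in_network",
           train = list(train), validation = list(valid), test = list(test),
           removed = list(removed))
  })
  new_split_rounds(rows, "in_network", seed, fractions)
}

#' Out-of-network split rounds
#'
#' For each round, proteins (not pairs) are partitioned into a train-side
#' block (train + validation fractions) and a test-side block. Train and
#' validation pairs have both endpoints train-side; test pairs have both
#' endpoints test-side; straddling pairs are discarded and counted. The
#' cold-start regime: no test protein occurs in any training pair.
#'
#' @inheritParams split_in_network
#' @return A `split_rounds` tibble, `mode = "out_of_network"`.
#' @export
split_out_of_network <- function(pairs, rounds = 10L,
                                 fractions = c(0.70, 0.10, 0.20), seed = 1L) {
  split_fractions_check(fractions)
  pairs <- canonicalize_pairs(pairs)
  prot <- sort(unique(c(pairs$a, pairs$b)))
  round_seeds <- withr::with_seed(seed, sample.int(2^30, rounds * 3))
  rows <- lapply(seq_len(rounds), function(r) {
    s_part <- round_seeds[3 * r - 2]
    s_bal <- round_seeds[3 * r - 1]
    s_tv <- round_seeds[3 * r]
    m <- length(prot)
    n_test_side <- max(1L, round(fractions[3] * m))
    test_side <- withr::with_seed(s_part, sample(prot, n_test_side))
    train_side <- setdiff(prot, test_side)
    both_in <- function(p, set) p[p$a %in% set & p$b %in% set, ]
    train_pool <- both_in(pairs, train_side)
    test <- downsample_balance(both_in(pairs, test_side), s_bal + 2L)
    removed <- nrow(pairs) - nrow(train_pool) -
      nrow(both_in(pairs, test_side))
    if (nrow(test) == 0 || length(unique(test$label)) < 2) {
      abort(paste0("round ", r, ": out-of-network test set empty or ",
                   "single-class; use more data or a larger test fraction"))
    }
    # split the train-side pool into train and validation by the relative
    # train/validation fractions
    f_va <- fractions[2] / (fractions[1] + fractions[2])
    n_pool <- nrow(train_pool)
    perm <- withr::with_seed(s_tv, sample.int(n_pool))
    n_va <- floor(f_va * n_pool)
    valid <- downsample_balance(train_pool[perm[seq_len(n_va)], ], s_bal + 1L)
    train <- downsample_balance(train_pool[perm[(n_va + 1):n_pool], ], s_bal)
    tibble(round = r, mode = "out_of_network",
           train = list(train), validation = list(valid), test = list(test),
           removed = list(c(straddling = removed)))
  })
  new_split_rounds(rows, "out_of_network", seed, fractions)
}

#' Serialize split rounds to a directory of pair TSVs
#'
#' Writes `round_<k>/{train,valid,test}.tsv` plus a `manifest.json`
#' recording seed, fractions, mode and removal counts.
#'
#' @param splits A `split_rounds` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_splits <- function(splits, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in seq_len(nrow(splits))) {
    rd <- file.path(dir, sprintf("round_%d", splits$round[r]))
    dir.create(rd, showWarnings = FALSE)
    write_pairs(splits$train[[r]], file.path(rd, "train.tsv"))
    write_pairs(splits$validation[[r]], file.path(rd, "valid.tsv"))
    write_pairs(splits$test[[r]], file.path(rd, "test.tsv"))
  }
  manifest <- list(
    mode = attr(splits, "mode"),
    seed = attr(splits, "seed"),
    fractions = attr(splits, "fractions"),
    rounds = nrow(splits),
    removed = lapply(splits$removed, as.list)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
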