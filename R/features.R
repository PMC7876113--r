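## Sequence-only protein feature extractors: 3-mer composition, seven-group
## conjoint triads, lagged autocovariance of physicochemical scales; plus
## pair-feature assembly and the sequence masking used by the Feature
## Auditor.

new_feature_map <- function(mat, extractor) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (any(!is.finite(mat))) abort("feature map contains non-finite values")
  structure(mat, extractor = extractor, class = c("feature_map", "matrix"))
}

#' @export
print.feature_map <- function(x, ...) {
  cat("<feature_map> extractor:", attr(x, "extractor"),
      "|", nrow(x), "proteins x", ncol(x), "features\n")
  invisible(x)
}

seq_to_int <- function(sequence, alphabet) {
  chars <- strsplit(sequence, "")[[1]]
  ints <- match(chars, alphabet)
  if (anyNA(ints)) {
    abort(paste0("sequence contains letters outside the alphabet: ",
                 paste(unique(chars[is.na(ints)]), collapse = ", ")))
  }
  ints
}

## Overlapping 3-mer frequency vector over an arbitrary alphabet,
## normalized to sum 1 per sequence.
triad_frequencies <- function(sequence, alphabet) {
  a <- length(alphabet)
  ints <- seq_to_int(sequence, alphabet) - 1L
  n <- length(ints)
  if (n < 3) abort("sequence shorter than 3 residues")
  idx <- ints[1:(n - 2)] * a * a + ints[2:(n - 1)] * a + ints[3:n] + 1L
  counts <- tabulate(idx, nbins = a^3)
  counts / sum(counts)
}

triad_names <- function(alphabet) {
  g <- expand.grid(k3 = alphabet, k2 = alphabet, k1 = alphabet,
                   stringsAsFactors = FALSE)
  paste0(g$k1, g$k2, g$k3)
}

#' Amino-acid 3-mer composition features
#'
#' Represents each protein by the frequencies of its overlapping amino-acid
#' 3-mers: a vector over all 20^3 = 8000 cells, normalized to sum 1.
#'
#' @param proteins Protein registry tibble.
#' @return A `feature_map` (proteins x 8000 matrix).
#' @export
kmer3_features <- function(proteins) {
  proteins <- validate_proteins(proteins, min_len = 3L)
  mat <- t(vapply(proteins$sequence, triad_frequencies,
                  numeric(20^3), alphabet = AA_ALPHABET, USE.NAMES = FALSE))
  rownames(mat) <- proteins$id
  colnames(mat) <- triad_names(AA_ALPHABET)
  new_feature_map(mat, "kmer3")
}

#' The classic seven-group partition of the amino acids
#'
#' Groups the 20 amino acids by dipole moment and side-chain volume:
#' \{AGV\}, \{ILFP\}, \{YMTS\}, \{HNQW\}, \{RK\}, \{DE\}, \{C\}.
#'
#' @return Named integer vector mapping each amino-acid letter to its
#'   group index 1..7.
#' @export
conjoint_groups <- function() {
  groups <- list("1" = c("A", "G", "V"), "2" = c("I", "L", "F", "P"),
                 "3" = c("Y", "M", "T", "S"), "4" = c("H", "N", "Q", "W"),
                 "5" = c("R", "K"), "6" = c("D", "E"), "7" = "C")
  out <- integer(0)
  for (g in names(groups)) out[groups[[g]]] <- as.integer(g)
  out[AA_ALPHABET]
}

translate_to_groups <- function(sequence, groups = conjoint_groups()) {
  ints <- seq_to_int(sequence, AA_ALPHABET)
  paste(as.character(groups[ints]), collapse = "")
}

#' Conjoint-triad features
#'
#' Maps each residue to one of seven physicochemical groups and counts
#' overlapping group 3-mers over the 7^3 = 343 cells, normalized to sum 1.
#' Equivalent to [kmer3_features()] computed on the group-translated
#' sequence over a 7-letter alphabet.
#'
#' @param proteins Protein registry tibble.
#' @param groups Named integer vector from letters to group index 1..7;
#'   defaults to [conjoint_groups()].
#' @return A `feature_map` (proteins x 343 matrix).
#' @export
conjoint_triad_features <- function(proteins, groups = conjoint_groups()) {
  proteins <- validate_proteins(proteins, min_len = 3L)
  alpha7 <- as.character(1:7)
  translated <- vapply(proteins$sequence, translate_to_groups,
                       character(1), groups = groups, USE.NAMES = FALSE)
  mat <- t(vapply(translated, triad_frequencies,
                  numeric(343), alphabet = alpha7, USE.NAMES = FALSE))
  rownames(mat) <- proteins$id
  colnames(mat) <- paste0("g", triad_names(alpha7))
  new_feature_map(mat, "conjoint_triad")
}

#' Default physicochemical property table
#'
#' Seven classic per-residue scales — hydrophobicity, hydrophilicity,
#' side-chain volume, polarity, polarizability, solvent-accessible surface
#' area and net charge index — as routinely used by lagged-autocovariance
#' sequence descriptors. Each column is standardized to mean 0 and unit
#' variance over the 20 amino acids.
#'
#' @return A 20 x 7 matrix with amino-acid letters as row names.
#' @export
aa_property_table <- function() {
  raw <- rbind(
    A = c(0.62, -0.5, 27.5, 8.1, 0.046, 1.181, 0.007187),
    C = c(0.29, -1.0, 44.6, 5.5, 0.128, 1.461, -0.036610),
    D = c(-0.90, 3.0, 40.0, 13.0, 0.105, 1.587, -0.023820),
    E = c(-0.74, 3.0, 62.0, 12.3, 0.151, 1.862, 0.006802),
    F = c(1.19, -2.5, 115.5, 5.2, 0.290, 2.228, 0.037552),
    G = c(0.48, 0.0, 0.0, 9.0, 0.000, 0.881, 0.179052),
    H = c(-0.40, -0.5, 79.0, 10.4, 0.230, 2.025, -0.010690),
    I = c(1.38, -1.8, 93.5, 5.2, 0.186, 1.810, 0.021631),
    K = c(-1.50, 3.0, 100.0, 11.3, 0.219, 2.258, 0.017708),
    L = c(1.06, -1.8, 93.5, 4.9, 0.186, 1.931, 0.051672),
    M = c(0.64, -1.3, 94.1, 5.7, 0.221, 2.034, 0.002683),
    N = c(-0.78, 2.0, 58.7, 11.6, 0.134, 1.655, 0.005392),
    P = c(0.12, 0.0, 41.9, 8.0, 0.131, 1.468, 0.239531),
    Q = c(-0.85, 0.2, 80.7, 10.5, 0.180, 1.932, 0.049211),
    R = c(-2.53, 3.0, 105.0, 10.5, 0.291, 2.560, 0.043587),
    S = c(-0.18, 0.3, 29.3, 9.2, 0.062, 1.298, 0.004627),
    T = c(-0.05, -0.4, 51.3, 8.6, 0.108, 1.525, 0.003352),
    V = c(1.08, -1.5, 71.5, 5.9, 0.140, 1.645, 0.057004),
    W = c(0.81, -3.4, 145.5, 5.4, 0.409, 2.663, 0.037977),
    Y = c(0.26, -2.3, 117.3, 6.2, 0.298, 2.368, 0.023599)
  )
  colnames(raw) <- c("hydrophobicity", "hydrophilicity", "volume", "polarity",
                     "polarizability", "sasa", "net_charge")
  scale(raw[AA_ALPHABET, ])[, , drop = FALSE]
}

#' Read a physicochemical property table from TSV
#'
#' Expects a header line, a first column of amino-acid letters and one
#' numeric column per property; columns are z-scored over the 20 rows.
#'
#' @param path Path to a tab-separated file.
#' @return A standardized 20 x k property matrix.
#' @export
read_property_table <- function(path) {
  raw <- utils::read.delim(path, comment.char = "#", row.names = 1)
  if (!setequal(rownames(raw), AA_ALPHABET)) {
    abort("property table must have exactly the 20 standard amino acids")
  }
  scale(as.matrix(raw[AA_ALPHABET, , drop = FALSE]))[, , drop = FALSE]
}

ac_one_sequence <- function(sequence, table, max_lag) {
  ints <- seq_to_int(sequence, AA_ALPHABET)
  n <- length(ints)
  if (n <= max_lag) {
    abort(paste0("sequence of length ", n,
                 " too short for max_lag ", max_lag))
  }
  vals <- table[ints, , drop = FALSE]                 # L x k property traces
  centered <- sweep(vals, 2, colMeans(vals))
  out <- matrix(0, nrow = ncol(table), ncol = max_lag)
  for (g in seq_len(max_lag)) {
    out[, g] <- colSums(centered[1:(n - g), , drop = FALSE] *
                        centered[(1 + g):n, , drop = FALSE]) / (n - g)
  }
  as.vector(t(out))  # property-major: p1 lags 1..G, p2 lags 1..G, ...
}

#' Lagged autocovariance features
#'
#' Captures amino-acid neighborhood context: for property p and lag g,
#' `AC(p, g) = mean over i of (x[p,i] - xbar_p) * (x[p,i+g] - xbar_p)`
#' where `xbar_p` is the sequence mean of the (standardized) property
#' trace. The vector concatenates all properties over lags `1..max_lag`.
#'
#' @param proteins Protein registry tibble; every sequence must be longer
#'   than `max_lag`.
#' @param table Standardized property matrix, see [aa_property_table()].
#' @param max_lag Largest lag (default 30).
#' @return A `feature_map` (proteins x `ncol(table) * max_lag` matrix).
#' @export
autocovariance_features <- function(proteins, table = aa_property_table(),
                                    max_lag = 30L) {
  proteins <- validate_proteins(proteins, min_len = max_lag + 1L)
  dim_out <- ncol(table) * max_lag
  mat <- t(vapply(proteins$sequence, ac_one_sequence, numeric(dim_out),
                  table = table, max_lag = max_lag, USE.NAMES = FALSE))
  rownames(mat) <- proteins$id
  colnames(mat) <- paste0(rep(colnames(table), each = max_lag),
                          "_lag", rep(seq_len(max_lag), ncol(table)))
  new_feature_map(mat, "autocovariance")
}

#' Extract features by extractor name
#'
#' Dispatcher used by the auditors and the command line.
#'
#' @param proteins Protein registry tibble.
#' @param extractor One of `"kmer3"`, `"conjoint_triad"`,
#'   `"autocovariance"`.
#' @param ... Passed to the specific extractor.
#' @return A `feature_map`.
#' @export
extract_features <- function(proteins,
                             extractor = c("kmer3", "conjoint_triad",
                                           "autocovariance"),
                             ...) {
  extractor <- match.arg(extractor)
  switch(extractor,
    kmer3 = kmer3_features(proteins),
    conjoint_triad = conjoint_triad_features(proteins, ...),
    autocovariance = autocovariance_features(proteins, ...)
  )
}

#' Write a feature map as a TSV matrix
#'
#' @param fm A `feature_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_map <- function(fm, path) {
  df <- data.frame(id = rownames(fm), unclass(fm), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble per-pair feature rows from a per-protein feature map
#'
#' Each pair becomes the concatenation `[v_a, v_b]` in canonical order.
#' With `symmetric = TRUE` every non-self pair contributes both
#' orientations `[v_a, v_b]` and `[v_b, v_a]` as separate rows (the
#' augmentation used to teach orientation-sensitive learners that
#' interactions are non-directional); self-pairs contribute one row. The
#' `"pair_index"` attribute maps each row back to its pair.
#'
#' @param fm A `feature_map` covering all pair endpoints.
#' @param pairs Pair table.
#' @param symmetric Emit both orientations per pair?
#' @return Numeric matrix with `2 * ncol(fm)` columns and attribute
#'   `pair_index` (integer row -> pair mapping).
#' @export
pair_features <- function(fm, pairs, symmetric = FALSE) {
  pairs <- canonicalize_pairs(pairs)
  missing <- setdiff(unique(c(pairs$a, pairs$b)), rownames(fm))
  if (length(missing)) {
    abort(paste0("protein(s) missing from feature map: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  va <- unclass(fm)[pairs$a, , drop = FALSE]
  vb <- unclass(fm)[pairs$b, , drop = FALSE]
  x <- cbind(va, vb)
  index <- seq_len(nrow(pairs))
  if (symmetric) {
    keep <- pairs$a != pairs$b
    x <- rbind(x, cbind(vb, va)[keep, , drop = FALSE])
    index <- c(index, which(keep))
  }
  rownames(x) <- NULL
  colnames(x) <- c(paste0("a.", colnames(fm)), paste0("b.", colnames(fm)))
  attr(x, "pair_index") <- index
  x
}

## Deterministic 32-bit hash of a string, mixed with the user seed, so a
## protein's masked sequence depends only on (seed, id).
protein_subseed <- function(seed, id) {
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(id)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

#' Replace every sequence with a random one (feature masking)
#'
#' The Feature Auditor severs any dependence on the real sequences by
#' replacing each protein's sequence with an i.i.d.-uniform sequence over
#' the 20 letters of the same length. The replacement is a deterministic
#' function of `(seed, id)`, so one experiment uses one fixed masked
#' sequence per protein across all rounds and extractors.
#'
#' @param proteins Protein registry tibble.
#' @param seed Integer seed.
#' @return A registry with identical ids and lengths, masked sequences.
#' @export
mask_sequences <- function(proteins, seed) {
  proteins <- validate_proteins(proteins)
  proteins$sequence <- vapply(seq_len(nrow(proteins)), function(i) {
    withr::with_seed(
      protein_subseed(seed, proteins$id[i]),
      paste(sample(AA_ALPHABET, nchar(proteins$sequence[i]), replace = TRUE),
            collapse = "")
    )
  }, character(1))
  proteins
}
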