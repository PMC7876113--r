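## Core data model: protein registries, labeled pair tables, degree
## bookkeeping, negative-example construction and the AUC metric shared by
## every auditor.
##
## A protein registry is a tibble with columns `id` (unique, no whitespace)
## and `sequence` (upper-case, 20-letter amino-acid alphabet). A pair table
## is a tibble with columns `a`, `b`, `label` (integer 0/1) and optionally
## `affinity` (pK_d scale), stored in canonical orientation a <= b
## (interactions are non-directional).

pair_key <- function(a, b) paste(a, b, sep = "\r")

#' Canonicalize a pair table
#'
#' Reorders each pair so that `a <= b` lexicographically. All storage,
#' deduplication and degree counting in the package use this canonical
#' orientation, reflecting the non-directionality of interactions.
#'
#' @param pairs A data frame with columns `a` and `b` (plus any others,
#'   which are preserved).
#' @return A tibble with `a` and `b` swapped where needed.
#' @export
canonicalize_pairs <- function(pairs) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0) return(pairs)
  flip <- pairs$a > pairs$b
  tmp <- pairs$a[flip]
  pairs$a[flip] <- pairs$b[flip]
  pairs$b[flip] <- tmp
  pairs
}

validate_proteins <- function(proteins, min_len = 0L) {
  proteins <- as_tibble(proteins)
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  if (anyDuplicated(proteins$id)) {
    abort(paste0(
      "duplicate protein id(s): ",
      paste(unique(proteins$id[duplicated(proteins$id)]), collapse = ", ")
    ))
  }
  if (any(grepl("\\s", proteins$id)) || any(!nzchar(proteins$id))) {
    abort("protein ids must be non-empty and contain no whitespace")
  }
  if (min_len > 0) {
    short <- nchar(proteins$sequence) < min_len
    if (any(short)) {
      abort(paste0(
        "sequence shorter than ", min_len, " residues for protein(s): ",
        paste(head(proteins$id[short], 5), collapse = ", ")
      ))
    }
  }
  proteins
}

#' Read protein sequences from a FASTA file
#'
#' Record ids are the first whitespace-delimited token of each header;
#' sequences are upper-cased. Residues outside the 20-letter standard
#' alphabet (B, J, O, U, X, Z, gaps, ...) are handled per `invalid`:
#' `"drop"` removes them with a warning, `"error"` aborts.
#'
#' @param path Path to a FASTA file.
#' @param invalid Policy for non-standard residues.
#' @return A protein registry tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path, invalid = c("drop", "error")) {
  invalid <- match.arg(invalid)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) abort(paste0("empty FASTA file: ", path))
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1)
  sequence <- unname(toupper(as.character(seqs)))
  bad <- gsub(paste0("[", paste(AA_ALPHABET, collapse = ""), "]"), "", sequence)
  if (any(nzchar(bad))) {
    letters_found <- unique(strsplit(paste(bad, collapse = ""), "")[[1]])
    if (invalid == "error") {
      abort(paste0(
        "non-standard residue(s) ", paste(letters_found, collapse = ", "),
        " found; rerun with invalid = \"drop\" to remove them"
      ))
    }
    warn(paste0(
      "dropped non-standard residue(s) ",
      paste(letters_found, collapse = ", "), " from ",
      sum(nzchar(bad)), " sequence(s)"
    ))
    sequence <- vapply(
      strsplit(sequence, ""),
      function(s) paste(s[s %in% AA_ALPHABET], collapse = ""),
      character(1)
    )
  }
  validate_proteins(tibble(id = ids, sequence = sequence), min_len = 3L)
}

#' Write a protein registry to FASTA
#'
#' @param proteins A protein registry tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  proteins <- validate_proteins(proteins)
  set <- Biostrings::AAStringSet(setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a labeled pair table from TSV
#'
#' Expects columns `a`, `b` and either `label` (0/1) or `affinity` (pK_d
#' scale, converted to labels via `affinity >= threshold`). Lines starting
#' with `#` are ignored. Pairs are canonicalized; duplicates and pairs
#' naming unregistered proteins are rejected.
#'
#' @param path Path to a tab-separated file with a header line.
#' @param proteins Protein registry the pairs must reference.
#' @param threshold Affinity threshold on the pK_d scale (default 6.3,
#'   corresponding to a 500 nM dissociation constant) used when the file
#'   carries an `affinity` column.
#' @return A canonical pair table tibble with columns `a`, `b`, `label`
#'   and, for affinity input, `affinity`.
#' @export
read_pairs <- function(path, proteins, threshold = 6.3) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = NA)
  raw <- as_tibble(raw)
  if (!all(c("a", "b") %in% names(raw))) {
    abort("pair file must have columns 'a' and 'b'")
  }
  raw$a <- as.character(raw$a)
  raw$b <- as.character(raw$b)
  if ("label" %in% names(raw)) {
    if (!all(raw$label %in% c(0L, 1L))) abort("label column must be 0 or 1")
    raw$label <- as.integer(raw$label)
  } else if ("affinity" %in% names(raw)) {
    if (is.null(threshold)) abort("affinity input requires a threshold")
    raw$label <- as.integer(raw$affinity >= threshold)
  } else {
    abort("pair file must have a 'label' or 'affinity' column")
  }
  as_pair_table(raw, proteins)
}

#' Validate and canonicalize a pair table against a registry
#'
#' @param pairs Data frame with columns `a`, `b`, `label`.
#' @param proteins Protein registry; when supplied every pair endpoint must
#'   be registered.
#' @return A canonical, validated pair table tibble.
#' @export
as_pair_table <- function(pairs, proteins = NULL) {
  pairs <- canonicalize_pairs(pairs)
  if (!"label" %in% names(pairs)) abort("pair table needs a 'label' column")
  pairs$label <- as.integer(pairs$label)
  if (!all(pairs$label %in% c(0L, 1L))) abort("label must be 0 or 1")
  if (!is.null(proteins)) {
    known <- unique(as_tibble(proteins)$id)
    missing <- setdiff(c(pairs$a, pairs$b), known)
    if (length(missing)) {
      abort(paste0("pair(s) reference unregistered protein(s): ",
                   paste(head(missing, 5), collapse = ", ")))
    }
  }
  key <- pair_key(pairs$a, pairs$b)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    n_lab <- tapply(pairs$label, key, function(x) length(unique(x)))
    if (any(n_lab > 1)) {
      abort(paste0("conflicting duplicate labels for pair(s): ",
                   paste(head(gsub("\r", "-", names(n_lab)[n_lab > 1]), 5),
                         collapse = ", ")))
    }
    abort(paste0("duplicate pair(s): ",
                 paste(head(unique(gsub("\r", "-", dup)), 5), collapse = ", ")))
  }
  keep <- intersect(c("a", "b", "label", "affinity"), names(pairs))
  pairs[keep]
}

#' Write a pair table to TSV
#'
#' @param pairs A pair table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  pairs <- canonicalize_pairs(pairs)
  keep <- intersect(c("a", "b", "label", "affinity"), names(pairs))
  utils::write.table(pairs[keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert a dissociation constant to the pK_d scale
#'
#' `pK_d = -log10(K_d)` with `K_d` in molar units, so 500 nM maps to 6.3.
#'
#' @param kd Dissociation constant(s) in molar units; must be positive.
#' @return `-log10(kd)`.
#' @export
pkd_from_kd <- function(kd) {
  if (any(!is.finite(kd)) || any(kd <= 0)) {
    abort("kd must be positive and finite")
  }
  -log10(kd)
}

#' Per-protein node degrees in the positive and negative training pairs
#'
#' Counts, for every registered protein, the number of positive-pair
#' endpoints (`d_pos`) and negative-pair endpoints (`d_neg`) it occupies in
#' the training pairs. A self-pair (P, P) contributes 2 to P's degree, so
#' `sum(d_pos) == 2 * n_positive` always holds. Proteins occurring in no
#' pair get degrees (0, 0). Degrees must only ever be computed from
#' training pairs; the `source` attribute records their provenance.
#'
#' @param pairs Training pair table.
#' @param proteins Protein registry; defaults to the proteins occurring in
#'   `pairs`.
#' @param source Name recorded as the degree table's training source.
#' @return A tibble with columns `id`, `d_pos`, `d_neg` and attribute
#'   `source`.
#' @export
compute_degree_table <- function(pairs, proteins = NULL, source = "train") {
  pairs <- canonicalize_pairs(pairs)
  ids <- if (is.null(proteins)) {
    sort(unique(c(pairs$a, pairs$b)))
  } else {
    as_tibble(proteins)$id
  }
  count_ends <- function(sub) {
    ends <- c(sub$a, sub$b)  # self-pairs appear twice, contributing 2
    tab <- table(factor(ends, levels = ids))
    as.integer(tab)
  }
  out <- tibble(
    id = ids,
    d_pos = count_ends(pairs[pairs$label == 1L, ]),
    d_neg = count_ends(pairs[pairs$label == 0L, ])
  )
  attr(out, "source") <- source
  out
}

#' Write a degree table to TSV
#'
#' @param degrees A degree table from [compute_degree_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_degree_table <- function(degrees, path) {
  utils::write.table(
    degrees[c("id", "d_pos", "d_neg")], path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

all_candidate_pairs <- function(ids, exclude_keys = character(0)) {
  ids <- sort(unique(ids))
  m <- length(ids)
  if (m < 2) return(tibble(a = character(0), b = character(0)))
  idx <- utils::combn(m, 2)
  cand <- tibble(a = ids[idx[1, ]], b = ids[idx[2, ]])
  cand[!pair_key(cand$a, cand$b) %in% exclude_keys, ]
}

#' Random negative sampling
#'
#' Draws `n` distinct canonical protein pairs uniformly at random from all
#' pairs not reported as positive, the most common negative-construction
#' scheme for interaction data. Self-pairs are never generated.
#'
#' @param proteins Protein registry to pair from.
#' @param positives Pair table (or data frame with `a`, `b`) of known
#'   positives to exclude.
#' @param n Number of negatives to draw.
#' @param seed Integer seed; the draw is a pure function of
#'   (inputs, seed).
#' @return A pair table of `n` negatives (`label = 0`).
#' @export
random_negative_sampling <- function(proteins, positives, n, seed) {
  stopifnot(n >= 1)
  ids <- as_tibble(proteins)$id
  pos <- canonicalize_pairs(positives)
  cand <- all_candidate_pairs(ids, pair_key(pos$a, pos$b))
  if (n > nrow(cand)) {
    abort(paste0("requested ", n, " negatives but only ", nrow(cand),
                 " non-positive pairs exist"))
  }
  take <- withr::with_seed(seed, sample.int(nrow(cand), n))
  out <- cand[sort(take), ]
  out$label <- 0L
  out
}

#' Group-label (non-co-localization style) negative sampling
#'
#' Negatives are drawn only from pairs whose group-tag sets are disjoint —
#' e.g. proteins annotated to different subcellular compartments — mirroring
#' the non-co-localization construction of curated negative pools.
#'
#' @param proteins Protein registry.
#' @param groups Long tibble with columns `id` and `group`; every protein
#'   considered must carry at least one tag.
#' @param positives Positive pairs to exclude.
#' @param n Number of negatives to draw.
#' @param seed Integer seed.
#' @return A pair table of `n` negatives (`label = 0`).
#' @export
group_based_negative_sampling <- function(proteins, groups, positives, n, seed) {
  stopifnot(n >= 1)
  ids <- as_tibble(proteins)$id
  groups <- as_tibble(groups)
  stopifnot(all(c("id", "group") %in% names(groups)))
  untagged <- setdiff(ids, groups$id)
  if (length(untagged)) {
    abort(paste0("protein(s) without group tags: ",
                 paste(head(untagged, 5), collapse = ", ")))
  }
  tagsets <- split(groups$group, groups$id)
  pos <- canonicalize_pairs(positives)
  cand <- all_candidate_pairs(ids, pair_key(pos$a, pos$b))
  disjoint <- !mapply(function(x, y) any(tagsets[[x]] %in% tagsets[[y]]),
                      cand$a, cand$b, USE.NAMES = FALSE)
  cand <- cand[disjoint, ]
  if (n > nrow(cand)) {
    abort(paste0("requested ", n, " negatives but only ", nrow(cand),
                 " disjoint-group non-positive pairs exist"))
  }
  take <- withr::with_seed(seed, sample.int(nrow(cand), n))
  out <- cand[sort(take), ]
  out$label <- 0L
  out
}

#' Rank-based AUC (Mann-Whitney with midranks)
#'
#' `P(score_pos > score_neg) + 0.5 * P(tie)`, so a scorer that assigns one
#' constant to everything gets exactly 0.5, matching the random baseline.
#'
#' @param scores_pos Scores of positive examples.
#' @param scores_neg Scores of negative examples.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores_pos, scores_neg) {
  n_pos <- length(scores_pos)
  n_neg <- length(scores_neg)
  if (n_pos == 0 || n_neg == 0) abort("both score lists must be non-empty")
  r <- rank(c(scores_pos, scores_neg), ties.method = "average")
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

## AUC of a scored pair table (label 1 vs 0).
auc_from_scored <- function(scores, labels) {
  auc_score(scores[labels == 1L], scores[labels == 0L])
}
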