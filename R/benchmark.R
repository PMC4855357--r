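# Truth-set benchmarking of the filtering thresholds.
#
# Unique sequences are classified against a reference set by global pairwise
# identity under a semiglobal alignment (free end gaps): identity = matched
# columns / length of the shorter sequence, with match +1, mismatch -1,
# gap -1 (linear). Among equal-score alignments, the one with the most
# matches defines the match count; this is well defined because the DP
# maximises a single combined value, score * SCALE + matches, in which any
# score difference dominates the match term.

ALIGN_SCALE <- 1e6

align_overlap <- function(a, b, match = 1, mismatch = -1, gap = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A)
  n <- length(B)
  if (m == 0 || n == 0) return(list(score = 0, matches = 0))
  stopifnot(max(m, n) < ALIGN_SCALE)
  G <- ALIGN_SCALE * gap
  v_match <- ALIGN_SCALE * match + 1
  v_mis <- ALIGN_SCALE * mismatch
  jj <- 0:n
  prev <- numeric(n + 1) # free leading gaps
  last_col <- numeric(m)
  for (i in seq_len(m)) {
    diag <- prev[1:n] + ifelse(B == A[i], v_match, v_mis)
    up <- prev[2:(n + 1)] - G
    cand <- pmax(diag, up)
    # best over any horizontal run ending at j (linear gap => cummax trick)
    base <- c(0, cand) + G * jj
    cur <- cummax(base) - G * jj
    cur[1] <- 0 # free leading gap in b
    last_col[i] <- cur[n + 1]
    prev <- cur
  }
  best <- max(prev, last_col) # free trailing gaps on either side
  score <- best %/% ALIGN_SCALE
  list(score = as.numeric(score), matches = as.numeric(best - ALIGN_SCALE * score))
}

#' Pairwise sequence identity (semiglobal alignment, free end gaps)
#'
#' Identity is the number of matched columns divided by the length of the
#' shorter sequence, under the alignment that maximises score (match +1,
#' mismatch -1, gap -1, end gaps free) and, among equal-score alignments,
#' the number of matches.
#'
#' @param a Character vector of query sequences.
#' @param b A single subject sequence.
#' @return Numeric vector of identities in `[0, 1]`.
#' @export
seq_identity <- function(a, b) {
  stopifnot(length(b) == 1L)
  vapply(a, function(s) {
    if (identical(s, b)) return(1)
    al <- align_overlap(s, b)
    al$matches / min(nchar(s), nchar(b))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Classify sequences against a truth reference set
#'
#' A sequence belongs to the true-positive class when it matches at least one
#' reference at or above `identity_threshold` (default 0.97); otherwise it is
#' treated as contamination / PCR or sequencing error (true-negative class).
#' References are tried in order of Hamming distance (computed where lengths
#' match) so the common case needs a single alignment.
#'
#' @param sequences Character vector (duplicates allowed).
#' @param refs Named character vector of reference sequences, a
#'   [read_fasta()] tibble, or a FASTA path.
#' @param identity_threshold Minimum identity to count as a reference match.
#' @return A tibble (`sequence`, `is_tp`, `best_identity`) over the unique
#'   input sequences; `best_identity` is the highest identity seen before the
#'   classification was decided.
#' @export
classify_truth <- function(sequences, refs, identity_threshold = 0.97) {
  refs <- as_ref_set(refs)
  if (!length(refs)) abort("empty truth reference set")
  us <- unique(sequences)
  is_tp <- setNames(logical(length(us)), us)
  best_id <- setNames(numeric(length(us)), us)
  exact <- us %in% refs
  is_tp[exact] <- TRUE
  best_id[exact] <- 1
  todo <- us[!exact]
  if (length(todo)) {
    D <- matrix(NA_real_, length(todo), length(refs))
    for (k in seq_along(refs)) {
      L <- nchar(refs[[k]])
      same <- which(nchar(todo) == L)
      if (length(same)) {
        rv <- charToRaw(refs[[k]])
        mat <- matrix(charToRaw(paste(todo[same], collapse = "")), nrow = L)
        D[same, k] <- colSums(mat != rv)
      }
    }
    len_gap <- abs(outer(nchar(todo), nchar(refs), "-"))
    for (i in seq_along(todo)) {
      pri <- ifelse(is.na(D[i, ]), ALIGN_SCALE + len_gap[i, ], D[i, ])
      best <- 0
      hit <- FALSE
      for (k in order(pri)) {
        id <- seq_identity(todo[i], refs[[k]])
        best <- max(best, id)
        if (id >= identity_threshold) {
          hit <- TRUE
          break
        }
      }
      is_tp[todo[i]] <- hit
      best_id[todo[i]] <- best
    }
  }
  tibble(sequence = us, is_tp = unname(is_tp), best_identity = unname(best_id))
}

as_ref_set <- function(refs) {
  if (is.character(refs) && length(refs) == 1 && file.exists(refs) && !is_dna(toupper(refs))) {
    refs <- read_fasta(refs)
  }
  if (is.data.frame(refs)) refs <- setNames(refs$sequence, refs$header)
  if (!is.character(refs)) abort("refs must be sequences, a FASTA tibble, or a FASTA path")
  toupper(refs)
}

#' True/false positive and negative rates of a filtering run
#'
#' Every unfiltered unique (sample, sequence) row is classified against the
#' truth references with [classify_truth()]; the rates then measure which
#' class members survive the filtering, with denominators fixed at the
#' unfiltered class sizes: `tpr = retained TP / all TP`, `fpr = retained TN /
#' all TN`, `fnr = 1 - tpr`, `tnr = 1 - fpr`. An empty class yields `NA`
#' rates, not 0.
#'
#' @param tables_before Unfiltered `sample_tables`.
#' @param tables_after The same tables after [apply_filters()].
#' @param refs Truth references (see [classify_truth()]).
#' @param identity_threshold Identity cutoff, default 0.97.
#' @return A one-row tibble: `tpr`, `fnr`, `fpr`, `tnr`, `n_tp`, `n_fn`,
#'   `n_fp`, `n_tn` (counts of retained/removed members of each class).
#' @export
benchmark_rates <- function(tables_before, tables_after, refs,
                            identity_threshold = 0.97) {
  before <- distinct(as_tibble(tables_before), .data$sample, .data$sequence)
  after <- distinct(as_tibble(tables_after), .data$sample, .data$sequence)
  if (!nrow(before)) abort("no sequences to classify")
  cls <- classify_truth(before$sequence, refs, identity_threshold)
  before <- left_join(before, cls, by = "sequence")
  before$survived <- paste(before$sample, before$sequence, sep = "\r") %in%
    paste(after$sample, after$sequence, sep = "\r")
  n_tp <- sum(before$is_tp & before$survived)
  n_fn <- sum(before$is_tp & !before$survived)
  n_fp <- sum(!before$is_tp & before$survived)
  n_tn <- sum(!before$is_tp & !before$survived)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble(
    tpr = rate(n_tp, n_tp + n_fn),
    fnr = rate(n_fn, n_tp + n_fn),
    fpr = rate(n_fp, n_fp + n_tn),
    tnr = rate(n_tn, n_fp + n_tn),
    n_tp = n_tp, n_fn = n_fn, n_fp = n_fp, n_tn = n_tn
  )
}
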