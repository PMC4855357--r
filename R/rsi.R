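# Renkonen similarity index between PCR replicates of one sample, computed
# on the relative frequencies of the unique sequences in each replicate.
# Reported on a dissimilarity scale: 0 = identical profiles, 1 = no
# sequence shared. Pairs with a mean above the dissimilarity threshold
# (0.6 by default, a published cutoff for highly dissimilar replicates)
# are flagged.

as_freqs <- function(x) {
  if (is.data.frame(x)) {
    cols <- intersect(c("freq", "count"), names(x))
    if (!("sequence" %in% names(x)) || !length(cols)) {
      abort("profile data frames need columns sequence and freq (or count)")
    }
    x <- setNames(as.numeric(x[[cols[1]]]), x$sequence)
  }
  if (!is.numeric(x)) abort("profile must be a named numeric vector or data frame")
  if (length(x) && is.null(names(x))) abort("profile vector must be named by sequence")
  if (any(x < 0)) abort("frequencies must be non-negative")
  x <- x[x > 0]
  if (length(x) > 1 && anyDuplicated(names(x))) {
    x <- tapply(x, names(x), sum)
  }
  x
}

rsi_pair <- function(pa, pb) {
  if (!length(pa) || !length(pb)) return(1)
  pa <- pa / sum(pa)
  pb <- pb / sum(pb)
  u <- union(names(pa), names(pb))
  a <- unname(pa[u]); a[is.na(a)] <- 0
  b <- unname(pb[u]); b[is.na(b)] <- 0
  1 - sum(pmin(a, b))
}

#' Renkonen similarity index between two replicate profiles
#'
#' `1 - sum_s min(p_a(s), p_b(s))` over the union of sequences. Inputs that
#' do not sum to one (e.g. raw copy numbers) are normalised first, so the
#' index is invariant to uniform rescaling. An empty profile on either side
#' yields 1 (nothing shared) with a warning -- the behaviour wanted for
#' negative controls.
#'
#' @param a,b Named numeric vectors (names = sequences, values = frequencies
#'   or counts) or data frames with columns `sequence` and `freq`/`count`.
#' @return A number in `[0, 1]`; 0 for identical profiles, 1 for disjoint.
#' @export
#' @examples
#' rsi(c(S1 = 0.5, S2 = 0.5), c(S1 = 0.25, S3 = 0.75)) # 0.75
rsi <- function(a, b) {
  pa <- as_freqs(a)
  pb <- as_freqs(b)
  if (!length(pa) || !length(pb)) {
    warning("empty replicate profile; RSI set to 1")
    return(1)
  }
  rsi_pair(pa, pb)
}

#' Renkonen similarity across the PCR replicates of every sample
#'
#' Frequencies are computed within each replicate from the unique-sequence
#' copy numbers over that replicate's total (its tag combination's sorted
#' reads when the table is unfiltered, which is how the index is meant to be
#' used: build the tables with `y = 1, t = 1`). Designed replicates with no
#' sequences at all (e.g. negative controls) score 1 against everything and
#' stay visible in the report.
#'
#' @param tables An (unfiltered) `sample_tables` object.
#' @param explicit If `TRUE`, one row per replicate pair; otherwise one row
#'   per sample with the arithmetic mean over all pairs.
#' @param dissimilar_threshold Pairs/means above this are flagged
#'   `"dissimilar"` (default 0.6).
#' @return An `rsi_report` tibble. Default columns: `sample`, `mean_rsi`,
#'   `n_pairs`, `flag`; explicit columns: `sample`, `rep_i`, `rep_j`, `rsi`,
#'   `flag`.
#' @export
sample_rsi <- function(tables, explicit = FALSE, dissimilar_threshold = 0.6) {
  r <- attr(tables, "replicates_per_sample")
  if (is.null(r) || r < 2) {
    abort("at least 2 PCR replicates per sample are required to compute the RSI")
  }
  rep_map <- attr(tables, "rep_map")
  samples <- sort(unique(c(tables$sample, rep_map$sample)))
  prs <- combn(r, 2)
  df <- as_tibble(tables)
  empties <- character(0)
  rows <- lapply(samples, function(sm) {
    sub <- df[df$sample == sm, ]
    profs <- lapply(seq_len(r), function(k) {
      s <- sub[sub$replicate == k, ]
      setNames(as.numeric(s$count), s$sequence)
    })
    for (k in seq_len(r)) {
      if (!length(profs[[k]])) empties <<- c(empties, sprintf("%s/rep%d", sm, k))
    }
    vals <- apply(prs, 2, function(ij) rsi_pair(profs[[ij[1]]], profs[[ij[2]]]))
    tibble(sample = sm, rep_i = prs[1, ], rep_j = prs[2, ], rsi = vals)
  })
  pairwise <- bind_rows(rows)
  if (length(empties)) {
    warning(paste0("empty replicate profile(s), RSI = 1 for their pairs: ",
                   paste(unique(empties), collapse = ", ")))
  }
  out <- if (explicit) {
    mutate(pairwise,
           flag = ifelse(.data$rsi > dissimilar_threshold, "dissimilar", "ok"))
  } else {
    pairwise |>
      group_by(.data$sample) |>
      summarise(mean_rsi = mean(.data$rsi), n_pairs = n(), .groups = "drop") |>
      mutate(flag = ifelse(.data$mean_rsi > dissimilar_threshold, "dissimilar", "ok"))
  }
  structure(out,
            class = c("rsi_report", class(tibble())),
            explicit = explicit,
            dissimilar_threshold = dissimilar_threshold)
}

#' Write an RSI report as TSV
#'
#' @param report A [sample_rsi()] result.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_rsi <- function(report, path) {
  readr::write_tsv(as_tibble(report), path)
  invisible(path)
}
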