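# Per-sample replicate tables and the reproducibility / copy-number / length
# filter. The thresholds are applied in a fixed order: (1) reproducibility
# (a sequence must occur, at any copy number, in at least y of the sample's
# replicates), (2) copy number (it must reach t copies in at least y
# replicates), (3) minimum length. With t = 1 steps (1) and (2) retain
# identical sets.

new_sample_tables <- function(df, replicates_per_sample, rep_map = NULL) {
  df <- as_tibble(df)[, c("sample", "sequence", "replicate", "count")]
  df <- arrange(df, .data$sample, .data$sequence, .data$replicate)
  structure(
    df,
    replicates_per_sample = as.integer(replicates_per_sample),
    rep_map = rep_map,
    class = c("sample_tables", class(tibble()))
  )
}

#' Coerce a long count table into a `sample_tables` object
#'
#' The long layout is one row per (sample, sequence, replicate) with a
#' positive copy number; replicates where a sequence is absent simply have
#' no row (they count as zeros).
#'
#' @param df A data frame with columns `sample`, `sequence`, `replicate`
#'   (integer in `1..replicates_per_sample`) and `count` (positive integer).
#' @param replicates_per_sample Designed number of PCR replicates per sample.
#' @param rep_map Optional tibble mapping (sample, replicate) to (pool,
#'   combo), as produced by [load_design()].
#' @return A `sample_tables` tibble.
#' @export
as_sample_tables <- function(df, replicates_per_sample = max(df$replicate), rep_map = NULL) {
  need <- c("sample", "sequence", "replicate", "count")
  if (!all(need %in% names(df))) {
    abort(paste0("need columns: ", paste(need, collapse = ", ")))
  }
  r <- as.integer(replicates_per_sample)
  if (any(df$count < 1)) abort("counts must be positive (absent = no row)")
  if (any(df$replicate < 1 | df$replicate > r)) {
    abort(sprintf("replicate indices must lie in 1..%d", r))
  }
  if (anyDuplicated(df[, c("sample", "sequence", "replicate")])) {
    abort("duplicated (sample, sequence, replicate) rows")
  }
  new_sample_tables(df, r, rep_map)
}

#' Merge sorted pools into per-sample replicate count tables
#'
#' Joins each pool's used tag combinations to the design's (sample,
#' replicate) assignment, merging replicates across pools. Sequences seen
#' only under unused combinations enter no sample table. Designed
#' combinations missing from the supplied pools contribute zero counts, with
#' a warning.
#'
#' @param sorted_pools A `sorted_pool` or list of them (one per pool).
#' @param design A [load_design()] object.
#' @return A `sample_tables` tibble (long layout, see [as_sample_tables()]).
#' @export
build_sample_tables <- function(sorted_pools, design) {
  if (inherits(sorted_pools, "sorted_pool")) sorted_pools <- list(sorted_pools)
  seqs_all <- bind_rows(lapply(sorted_pools, function(sp) {
    mutate(filter(sp$seqs, .data$used), pool = sp$pool)
  }))
  pcrs <- design$pcrs
  have <- if (nrow(seqs_all)) distinct(seqs_all, .data$pool, .data$combo) else {
    tibble(pool = character(), combo = character())
  }
  pool_seen <- unique(vapply(sorted_pools, function(sp) sp$pool, character(1)))
  missing <- anti_join(pcrs[pcrs$pool %in% pool_seen, ], have, by = c("pool", "combo"))
  absent_pools <- setdiff(pcrs$pool, pool_seen)
  if (nrow(missing) || length(absent_pools)) {
    warning(sprintf(
      "%d designed tag combination(s) have no sorted sequences%s; they contribute zero counts",
      nrow(missing) + sum(pcrs$pool %in% absent_pools),
      if (length(absent_pools)) {
        paste0(" (no sorted pool supplied for: ", paste(absent_pools, collapse = ", "), ")")
      } else ""
    ))
  }
  joined <- inner_join(seqs_all, pcrs, by = c("pool", "combo"),
                       relationship = "many-to-one")
  new_sample_tables(
    joined[, c("sample", "sequence", "replicate", "count")],
    design$replicates_per_sample,
    rep_map = pcrs[, c("sample", "replicate", "pool", "combo")]
  )
}

#' @export
print.sample_tables <- function(x, ...) {
  cat(sprintf(
    "<sample_tables> %d samples x %d replicates; %d (sample, sequence) rows\n",
    length(unique(x$sample)), attr(x, "replicates_per_sample"),
    nrow(distinct(as_tibble(x), .data$sample, .data$sequence))
  ))
  NextMethod()
}

row_stats <- function(tables, t, t_mode) {
  as_tibble(tables) |>
    group_by(.data$sample, .data$sequence) |>
    summarise(
      n_present = n(),
      n_at_t = sum(.data$count >= t),
      total = sum(.data$count),
      .groups = "drop"
    ) |>
    mutate(
      len = nchar(.data$sequence),
      pass_t_rule = if (t_mode == "per_replicate") NA else .data$total >= t
    )
}

#' Filter sample tables by reproducibility, copy number and length
#'
#' A (sample, sequence) row survives iff (1) the sequence occurs (count >= 1)
#' in at least `y` of the sample's replicates, then (2) it reaches `t` copies
#' in at least `y` replicates (default `t_mode = "per_replicate"`; with
#' `t_mode = "total"` the summed copy number across replicates must reach
#' `t`), and (3) the trimmed sequence length is at least `l`. Surviving rows
#' keep their full per-replicate copy numbers. Per-sample survivor counts
#' after each step are attached as the `steps` attribute (also returned by
#' [glance()]).
#'
#' @param tables A `sample_tables` object.
#' @param y Minimum reproducibility (replicates containing the sequence);
#'   must not exceed the design's replicate count.
#' @param t Minimum copies per replicate (or in total, see `t_mode`).
#' @param l Minimum sequence length.
#' @param t_mode `"per_replicate"` (default) or `"total"`.
#' @return A filtered `sample_tables` with attributes `thresholds` and
#'   `steps` (`sample`, `n_input`, `n_after_y`, `n_after_t`, `n_after_l`).
#' @export
apply_filters <- function(tables, y = 1, t = 1, l = 0,
                          t_mode = c("per_replicate", "total")) {
  t_mode <- match.arg(t_mode)
  r <- attr(tables, "replicates_per_sample")
  if (!is.numeric(y) || y < 1) abort("y must be a positive integer")
  if (!is.numeric(t) || t < 1) abort("t must be a positive integer")
  if (!is.numeric(l) || l < 0) abort("l must be a non-negative integer")
  if (y > r) {
    abort(sprintf(
      "reproducibility threshold y=%d exceeds the design's %d PCR replicates per sample",
      as.integer(y), r
    ))
  }
  st <- row_stats(tables, t, t_mode) |>
    mutate(
      pass_y = .data$n_present >= y,
      pass_t = .data$pass_y & (if (t_mode == "per_replicate") .data$n_at_t >= y else .data$pass_t_rule),
      pass_l = .data$pass_t & .data$len >= l
    )
  steps <- st |>
    group_by(.data$sample) |>
    summarise(
      n_input = n(),
      n_after_y = sum(.data$pass_y),
      n_after_t = sum(.data$pass_t),
      n_after_l = sum(.data$pass_l),
      .groups = "drop"
    )
  keep <- st[st$pass_l, c("sample", "sequence")]
  out <- semi_join(as_tibble(tables), keep, by = c("sample", "sequence"))
  out <- new_sample_tables(out, r, attr(tables, "rep_map"))
  attr(out, "thresholds") <- list(y = as.integer(y), t = as.integer(t),
                                  l = as.integer(l), t_mode = t_mode)
  attr(out, "steps") <- steps
  out
}

#' @rdname apply_filters
#' @param x A `sample_tables` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.sample_tables <- function(x, ...) {
  st <- attr(x, "steps")
  if (!is.null(st)) return(st)
  as_tibble(x) |>
    group_by(.data$sample) |>
    summarise(n_rows = n_distinct(.data$sequence), n_reads = sum(.data$count),
              .groups = "drop")
}

#' @rdname apply_filters
#' @exportS3Method generics::tidy
tidy.sample_tables <- function(x, ...) as_tibble(x)

counts_wide <- function(tables) {
  r <- attr(tables, "replicates_per_sample")
  w <- as_tibble(tables) |>
    tidyr::pivot_wider(
      names_from = "replicate", values_from = "count", values_fill = 0L
    )
  for (k in as.character(seq_len(r))) {
    if (!k %in% names(w)) w[[k]] <- 0L
  }
  w <- w[, c("sample", "sequence", as.character(seq_len(r)))]
  w$counts_str <- do.call(paste, c(w[as.character(seq_len(r))], sep = ","))
  w$total <- rowSums(w[as.character(seq_len(r))])
  w
}

#' Write filtered sample tables as a single FASTA
#'
#' Headers encode the sample, the per-replicate copy numbers (zeros
#' included, in replicate order) and the total, e.g.
#' `>sampleA_seq7 counts=5,3 total=8`. Records are ordered by sample, then
#' descending total, then sequence.
#'
#' @param tables A `sample_tables` object (filtered or not).
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_filtered <- function(tables, path) {
  w <- counts_wide(tables) |>
    arrange(.data$sample, desc(.data$total), .data$sequence) |>
    group_by(.data$sample) |>
    mutate(idx = row_number()) |>
    ungroup()
  write_fasta(tibble(
    header = sprintf("%s_seq%d counts=%s total=%d",
                     w$sample, w$idx, w$counts_str, w$total),
    sequence = w$sequence
  ), path)
}

#' Parse a FASTA written by [write_filtered()]
#'
#' @param path FASTA path.
#' @return A `sample_tables` object.
#' @export
parse_filtered <- function(path) {
  fa <- read_fasta(path)
  if (!nrow(fa)) return(new_sample_tables(
    tibble(sample = character(), sequence = character(),
           replicate = integer(), count = integer()), 1L
  ))
  rx <- "^(.*)_seq(\\d+) counts=([0-9,]+) total=(\\d+)$"
  ok <- grepl(rx, fa$header)
  if (any(!ok)) {
    abort(paste0("header not in write_filtered() format: ", fa$header[!ok][1]))
  }
  sample <- sub(rx, "\\1", fa$header)
  counts <- strsplit(sub(rx, "\\3", fa$header), ",")
  total <- as.integer(sub(rx, "\\4", fa$header))
  r <- unique(lengths(counts))
  if (length(r) != 1) abort("inconsistent replicate counts across headers")
  long <- tibble(
    sample = rep(sample, each = r),
    sequence = rep(fa$sequence, each = r),
    replicate = rep(seq_len(r), nrow(fa)),
    count = as.integer(unlist(counts))
  )
  per_rec <- vapply(counts, function(v) sum(as.integer(v)), integer(1))
  if (!all(per_rec == total)) abort("counts= fields do not sum to total=")
  new_sample_tables(long[long$count > 0L, ], r)
}

#' De-collapse a filtered FASTA back to redundant records
#'
#' Each record with `total=n` is expanded into `n` identical records whose
#' ids carry serial suffixes `_1.._n` (downstream taxonomy tools often need
#' the redundancy).
#'
#' @param input FASTA written by [write_filtered()] (or any FASTA whose
#'   headers carry a `total=<n>` field).
#' @param output Output FASTA path.
#' @return The output path, invisibly.
#' @export
decollapse <- function(input, output) {
  fa <- read_fasta(input)
  m <- regmatches(fa$header, regexec(" total=(\\d+)", fa$header))
  bad <- vapply(m, length, integer(1)) != 2L
  if (any(bad)) {
    abort(paste0("header lacks a total= field: ", fa$header[bad][1]))
  }
  totals <- as.integer(vapply(m, `[`, character(1), 2))
  ids <- sub("\\s.*$", "", fa$header)
  idx <- rep(seq_len(nrow(fa)), totals)
  write_fasta(tibble(
    header = paste0(ids[idx], "_", sequence(totals)),
    sequence = fa$sequence[idx]
  ), output)
}
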