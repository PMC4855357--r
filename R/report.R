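# Diagnostic tables: per-combination summaries, the forward x reverse tag
# occurrence matrix, primer mix-up (swapped-tag) diagnosis, and
# reproducibility x frequency tables.

#' Per-combination sequence content summary
#'
#' One row per observed tag combination with its used/unused flag, the number
#' of unique sequences, the total copy number, and min/median/mean/max of the
#' unique-sequence copy numbers.
#'
#' @param sorted A [sort_pool()] result.
#' @return A tibble ordered by combination.
#' @export
combo_summary <- function(sorted) {
  sorted$seqs |>
    group_by(.data$combo, .data$used) |>
    summarise(
      n_unique = n(),
      n_total = sum(.data$count),
      min = min(.data$count),
      median = median(.data$count),
      mean = mean(.data$count),
      max = max(.data$count),
      .groups = "drop"
    ) |>
    arrange(.data$combo)
}

#' Forward x reverse tag occurrence matrix
#'
#' Cell (f, r) holds the total read copies sorted into combination
#' `F<f>-R<r>`; zero where unobserved. Rows are forward tag ids, columns
#' reverse tag ids, covering every tag in the design, so tag-jumping shows
#' up as off-diagonal mass under a matched-tag scheme. Marginal sums equal
#' the per-combination totals.
#'
#' @param sorted A [sort_pool()] result.
#' @param design A [load_design()] object (defines the tag universe).
#' @return A `tag_matrix`: an integer matrix with tag ids as dimnames and the
#'   pool label as attribute.
#' @export
tag_matrix <- function(sorted, design) {
  ids <- design$tags$tag_id
  totals <- sorted$seqs |>
    group_by(.data$fwd_tag, .data$rev_tag) |>
    summarise(total = sum(.data$count), .groups = "drop")
  m <- matrix(0L, length(ids), length(ids), dimnames = list(fwd = ids, rev = ids))
  if (nrow(totals)) {
    m[cbind(match(totals$fwd_tag, ids), match(totals$rev_tag, ids))] <-
      as.integer(totals$total)
  }
  structure(m, pool = sorted$pool, class = c("tag_matrix", class(m)))
}

#' @rdname tag_matrix
#' @param x A `tag_matrix`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.tag_matrix <- function(x, ...) {
  tibble(
    fwd_tag = rep(rownames(x), ncol(x)),
    rev_tag = rep(colnames(x), each = nrow(x)),
    total = as.integer(x)
  )
}

#' Write a tag matrix as TSV (rows = forward tags, columns = reverse tags)
#'
#' @param x A [tag_matrix()] result.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tag_matrix <- function(x, path) {
  df <- as.data.frame(unclass(x))
  df <- cbind(fwd_tag = rownames(x), df)
  readr::write_tsv(as_tibble(df), path)
  invisible(path)
}

#' Diagnose swapped-tag / primer mix-up candidates
#'
#' A designed combination that is silent (total copies at or below
#' `silent_threshold` across all pools) while an unused combination sharing
#' exactly one of its tag ids is loud (at or above `loud_threshold`) is the
#' signature of a primer mix-up: the loud unused combination was likely used
#' in the laboratory in place of the silent designed one.
#'
#' @param sorted_pools A `sorted_pool` or list of them.
#' @param design A [load_design()] object.
#' @param silent_threshold Designed combinations with totals `<=` this are
#'   silent (default 0, i.e. totally absent).
#' @param loud_threshold Unused combinations with totals `>=` this are
#'   candidates (default 100).
#' @return A tibble (`silent_combo`, `candidate_combo`, `shared_tag`,
#'   `candidate_total`), one row per candidate; silent combinations with no
#'   candidate keep a row with `NA` candidate fields. Empty when nothing is
#'   silent.
#' @export
diagnose_swaps <- function(sorted_pools, design, silent_threshold = 0,
                           loud_threshold = 100) {
  if (inherits(sorted_pools, "sorted_pool")) sorted_pools <- list(sorted_pools)
  obs <- bind_rows(lapply(sorted_pools, function(sp) sp$seqs)) |>
    group_by(.data$combo, .data$fwd_tag, .data$rev_tag) |>
    summarise(total = sum(.data$count), .groups = "drop")
  designed <- distinct(design$pcrs, .data$combo, .data$fwd_tag, .data$rev_tag)
  des_tot <- designed |>
    left_join(obs[, c("combo", "total")], by = "combo") |>
    mutate(total = tidyr::replace_na(.data$total, 0))
  silent <- des_tot[des_tot$total <= silent_threshold, ]
  empty <- tibble(silent_combo = character(), candidate_combo = character(),
                  shared_tag = character(), candidate_total = numeric())
  if (!nrow(silent)) return(empty)
  loud <- obs |>
    filter(!(.data$combo %in% designed$combo), .data$total >= loud_threshold)
  out <- lapply(seq_len(nrow(silent)), function(i) {
    sf <- silent$fwd_tag[i]
    sr <- silent$rev_tag[i]
    cand <- loud |>
      filter(xor(.data$fwd_tag == sf, .data$rev_tag == sr)) |>
      arrange(desc(.data$total))
    if (!nrow(cand)) {
      return(tibble(silent_combo = silent$combo[i], candidate_combo = NA_character_,
                    shared_tag = NA_character_, candidate_total = NA_real_))
    }
    tibble(
      silent_combo = silent$combo[i],
      candidate_combo = cand$combo,
      shared_tag = ifelse(cand$fwd_tag == sf, paste0("F", sf), paste0("R", sr)),
      candidate_total = as.numeric(cand$total)
    )
  })
  bind_rows(out)
}

#' Reproducibility x total-frequency table
#'
#' For each sample, counts the unique sequences by their reproducibility
#' (number of replicates where they occur with at least one copy) and their
#' total copy number across replicates -- the table behind the "how often do
#' low-copy sequences recur across replicates" diagnostic that guides the
#' choice of the filtering thresholds.
#'
#' @param tables An unfiltered `sample_tables` object.
#' @return A tibble (`sample`, `reproducibility`, `n_replicates`, `total`,
#'   `n_unique`); the `n_unique` values sum to the number of unique
#'   (sample, sequence) rows.
#' @export
reproducibility_table <- function(tables) {
  r <- attr(tables, "replicates_per_sample")
  as_tibble(tables) |>
    group_by(.data$sample, .data$sequence) |>
    summarise(reproducibility = n(), total = sum(.data$count), .groups = "drop") |>
    count(.data$sample, .data$reproducibility, .data$total, name = "n_unique") |>
    mutate(n_replicates = r) |>
    select("sample", "reproducibility", "n_replicates", "total", "n_unique") |>
    arrange(.data$sample, .data$reproducibility, .data$total)
}
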