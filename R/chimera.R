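# Interchange with external chimera detectors: write per-combination FASTA
# with usearch-style ";size=N" abundance annotations, and ingest the labels
# the external tool flags as chimeric (plain id list or UCHIME tabbed
# output). Chimera detection itself is delegated.

chimera_seq_id <- function(pool, combo, rank) sprintf("%s_%s_r%d", pool, combo, rank)

#' Write de-novo chimera-detector input files
#'
#' One FASTA per observed tag combination; headers are
#' `<pool>_<combo>_r<rank>;size=<count>` so abundance-aware de-novo
#' detectors (UCHIME and kin) can use the copy numbers.
#'
#' @param sorted A [sort_pool()] result.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
chimera_prep <- function(sorted, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  rk <- ranked_seqs(sorted)
  paths <- character()
  for (cb in unique(rk$combo)) {
    sub <- rk[rk$combo == cb, ]
    p <- file.path(outdir, sprintf("%s_%s_chimera_in.fasta", sorted$pool, cb))
    write_fasta(tibble(
      header = paste0(chimera_seq_id(sorted$pool, cb, sub$rank), ";size=", sub$count),
      sequence = sub$sequence
    ), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

parse_chimera_labels <- function(path) {
  if (!file.exists(path)) abort(paste0("label file not found: ", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(character())
  fields <- strsplit(lines, "\t")
  nf <- vapply(fields, length, integer(1))
  last <- vapply(fields, function(f) f[length(f)], character(1))
  if (all(nf >= 3) && all(last %in% c("Y", "N", "?"))) {
    # UCHIME tabbed output: query label in column 2, verdict in the last column
    ids <- vapply(fields[last == "Y"], `[`, character(1), 2)
  } else {
    ids <- vapply(fields, `[`, character(1), 1)
  }
  sub(";size=\\d+;?$", "", ids)
}

#' Remove externally flagged chimeric sequences from a sorted pool
#'
#' @param labels Path to a label file: one sequence id per line (ids as
#'   written by [chimera_prep()], with or without the `;size=` suffix), or
#'   UCHIME tabbed output (rows whose verdict column is `Y` are taken).
#' @param sorted The [sort_pool()] result the labels refer to.
#' @return The sorted pool with the flagged unique sequences removed;
#'   `n_sorted` shrinks by the removed copies and `n_chimera_removed`
#'   accumulates them, so `n_input == n_sorted + n_discarded +
#'   n_chimera_removed` keeps holding. The per-combination removal counts
#'   are attached as attribute `chimera_removed`.
#' @export
ingest_chimera_labels <- function(labels, sorted) {
  ids <- parse_chimera_labels(labels)
  if (!length(ids)) {
    attr(sorted, "chimera_removed") <- tibble(combo = character(), n_removed = integer())
    return(sorted)
  }
  rk <- ranked_seqs(sorted)
  known <- chimera_seq_id(sorted$pool, rk$combo, rk$rank)
  orphan <- setdiff(ids, known)
  if (length(orphan)) {
    abort(paste0("label(s) reference unknown sequence id(s): ",
                 paste(utils::head(orphan, 10), collapse = ", ")))
  }
  drop <- known %in% ids
  removed <- rk[drop, ] |>
    count(.data$combo, name = "n_removed")
  kept <- rk[!drop, setdiff(names(rk), "rank")]
  sorted$seqs <- arrange(kept, .data$combo, desc(.data$count), .data$sequence)
  n_gone <- sum(rk$count[drop])
  sorted$n_chimera_removed <- sorted$n_chimera_removed + n_gone
  sorted$n_sorted <- sorted$n_sorted - n_gone
  attr(sorted, "chimera_removed") <- removed
  sorted
}
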