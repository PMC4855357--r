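# Demultiplexing: assign each read to a (forward tag, reverse tag)
# combination, trim tags and primers, and collapse to unique sequences.
#
# Matching rules: tags are matched exactly and anchored at the two ends of
# the read; primers may carry up to `max_primer_mismatch` substitutions
# (IUPAC codes in the primer match their degeneracy sets; no indels). Both
# the read and its reverse complement are tried -- a read matching in both
# orientations, or under more than one primer set, or under more than one
# tag-combination interpretation, is discarded as ambiguous. Discarded reads
# (no match or ambiguous) are counted as tag/primer errors.

match_reads_vec <- function(sequences, design, max_primer_mismatch = 2) {
  stopifnot(max_primer_mismatch >= 0)
  seqs <- toupper(sequences)
  n <- length(seqs)
  out <- tibble(
    status = rep("no_match", n),
    fwd_tag = rep(NA_character_, n),
    rev_tag = rep(NA_character_, n),
    insert = rep(NA_character_, n)
  )
  if (n == 0L) return(out)

  tags <- design$tags
  lens <- sort(unique(nchar(tags$sequence)))
  fwd_maps <- lapply(lens, function(L) {
    t <- tags[nchar(tags$sequence) == L, ]
    setNames(t$tag_id, t$sequence)
  })
  rev_maps <- lapply(lens, function(L) {
    t <- tags[nchar(tags$sequence) == L, ]
    setNames(t$tag_id, revcomp(t$sequence))
  })

  orientations <- list(seqs, revcomp(seqs))
  omatch <- vector("list", 2L)
  for (o in 1:2) {
    s <- orientations[[o]]
    nc <- nchar(s)
    n_sets <- integer(n)
    amb <- logical(n)
    f_id <- r_id <- ins <- rep(NA_character_, n)
    for (p in seq_len(nrow(design$primers))) {
      pf <- design$primers$forward[p]
      prc <- revcomp(design$primers$reverse[p])
      Pf <- nchar(pf)
      Pr <- nchar(prc)
      hit <- logical(n)
      hamb <- logical(n)
      hf <- hr <- hi <- rep(NA_character_, n)
      for (a in seq_along(lens)) {
        for (b in seq_along(lens)) {
          Lf <- lens[a]
          Lr <- lens[b]
          fid <- unname(fwd_maps[[a]][substr(s, 1L, Lf)])
          rid <- unname(rev_maps[[b]][substring(s, nc - Lr + 1L)])
          cand <- which(!is.na(fid) & !is.na(rid) & nc >= Lf + Pf + Pr + Lr)
          if (!length(cand)) next
          mmf <- primer_mismatches(s[cand], pf, rep(Lf + 1L, length(cand)))
          mmr <- primer_mismatches(s[cand], prc, nc[cand] - Lr - Pr + 1L)
          keep <- mmf <= max_primer_mismatch & mmr <= max_primer_mismatch
          ok <- cand[keep]
          if (!length(ok)) next
          nf <- fid[ok]
          nr <- rid[ok]
          ni <- substr(s[ok], Lf + Pf + 1L, nc[ok] - Lr - Pr)
          prior <- hit[ok]
          clash <- prior & !(hf[ok] == nf & hr[ok] == nr & hi[ok] == ni)
          hamb[ok[clash]] <- TRUE
          fresh <- ok[!prior]
          hf[fresh] <- nf[!prior]
          hr[fresh] <- nr[!prior]
          hi[fresh] <- ni[!prior]
          hit[ok] <- TRUE
        }
      }
      first <- hit & n_sets == 0L
      f_id[first] <- hf[first]
      r_id[first] <- hr[first]
      ins[first] <- hi[first]
      amb <- amb | hamb | (hit & n_sets > 0L)
      n_sets <- n_sets + hit
    }
    omatch[[o]] <- list(
      hit = n_sets == 1L & !amb,
      amb = amb | n_sets > 1L,
      f = f_id, r = r_id, i = ins
    )
  }

  h1 <- omatch[[1]]$hit
  h2 <- omatch[[2]]$hit
  one <- xor(h1, h2)
  out$status[one] <- "matched"
  out$status[!one & ((h1 & h2) | omatch[[1]]$amb | omatch[[2]]$amb)] <- "ambiguous"
  for (o in 1:2) {
    take <- one & (if (o == 1) h1 else h2)
    out$fwd_tag[take] <- omatch[[o]]$f[take]
    out$rev_tag[take] <- omatch[[o]]$r[take]
    out$insert[take] <- omatch[[o]]$i[take]
  }
  out
}

#' Match a single read against a library design
#'
#' Tries both orientations and every primer set; tags must match exactly at
#' the read ends, primers tolerate up to `max_primer_mismatch` substitutions.
#'
#' @param sequence A single read sequence.
#' @param design A [load_design()] object.
#' @param max_primer_mismatch Maximum substitutions allowed in each primer
#'   (default 2; set 0 for strict matching). No indels.
#' @return A list with `fwd_tag`, `rev_tag`, `combo` and `insert` (the tag-
#'   and primer-trimmed sequence in forward orientation), or `NULL` when the
#'   read does not match (including ambiguous matches).
#' @export
match_read <- function(sequence, design, max_primer_mismatch = 2) {
  stopifnot(length(sequence) == 1L)
  m <- match_reads_vec(sequence, design, max_primer_mismatch)
  if (m$status != "matched") return(NULL)
  list(
    fwd_tag = m$fwd_tag, rev_tag = m$rev_tag,
    combo = combo_id(m$fwd_tag, m$rev_tag), insert = m$insert
  )
}

#' Demultiplex one pool and collapse to unique sequences
#'
#' Every matched read is assigned to exactly one tag combination; within a
#' combination, identical trimmed sequences are collapsed into one record
#' with a summed copy number. Combinations observed in the data but absent
#' from the design (tag jumping, contamination, mix-ups) are retained and
#' flagged unused. Read conservation holds on every run:
#' `n_input == n_sorted + n_discarded`.
#'
#' @param fastq Path to the pool's FASTQ file (merged, quality-trimmed reads).
#' @param design A [load_design()] object.
#' @param pool Pool label; must normally appear in the design (a pool with no
#'   designed combination is allowed with a warning).
#' @param max_primer_mismatch See [match_read()].
#' @return A `sorted_pool` object: list with the pool label, a tibble `seqs`
#'   (`fwd_tag`, `rev_tag`, `combo`, `sequence`, `count`, `used`), read
#'   counts (`n_input`, `n_sorted`, `n_discarded`, `n_ambiguous`), the
#'   designed combinations for this pool, and the primer table.
#' @export
sort_pool <- function(fastq, design, pool, max_primer_mismatch = 2) {
  pool <- as.character(pool)
  designed <- design$pcrs[design$pcrs$pool == pool, , drop = FALSE]
  if (!nrow(designed)) {
    warning(sprintf("pool '%s' has no designed tag combination", pool))
  }
  used_combos <- sort(unique(designed$combo))

  reads <- read_fastq(fastq)
  n_input <- nrow(reads)
  uq <- dplyr::count(reads, .data$sequence, name = "count")
  m <- match_reads_vec(uq$sequence, design, max_primer_mismatch)

  ok <- m$status == "matched"
  seqs <- tibble(
    fwd_tag = m$fwd_tag[ok], rev_tag = m$rev_tag[ok],
    sequence = m$insert[ok], count = uq$count[ok]
  ) |>
    group_by(.data$fwd_tag, .data$rev_tag, .data$sequence) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    mutate(
      combo = combo_id(.data$fwd_tag, .data$rev_tag),
      used = .data$combo %in% used_combos
    ) |>
    arrange(.data$combo, desc(.data$count), .data$sequence) |>
    select("fwd_tag", "rev_tag", "combo", "sequence", "count", "used")

  n_sorted <- sum(seqs$count)
  structure(
    list(
      pool = pool,
      seqs = seqs,
      n_input = n_input,
      n_sorted = n_sorted,
      n_discarded = n_input - n_sorted,
      n_ambiguous = sum(uq$count[m$status == "ambiguous"]),
      n_chimera_removed = 0L,
      used_combos = used_combos,
      primers = design$primers
    ),
    class = "sorted_pool"
  )
}

#' @export
print.sorted_pool <- function(x, ...) {
  cat(sprintf(
    "<sorted_pool '%s'> %d reads in; %d sorted (%d unique over %d combos); %d discarded\n",
    x$pool, x$n_input, x$n_sorted, nrow(x$seqs),
    length(unique(x$seqs$combo)), x$n_discarded
  ))
  invisible(x)
}

#' @rdname sort_pool
#' @param x A `sorted_pool` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.sorted_pool <- function(x, ...) x$seqs

#' @rdname sort_pool
#' @exportS3Method generics::glance
glance.sorted_pool <- function(x, ...) {
  tibble(
    pool = x$pool,
    n_input = x$n_input,
    n_sorted = x$n_sorted,
    n_discarded = x$n_discarded,
    n_ambiguous = x$n_ambiguous,
    n_unique = nrow(x$seqs),
    n_combos = length(unique(x$seqs$combo))
  )
}

#' Partition observed tag combinations into used and unused
#'
#' @param sorted A [sort_pool()] result.
#' @param design A [load_design()] object; the designed set for the sorted
#'   pool defines membership.
#' @return A list with tibbles `used` and `unused`, the unique-sequence
#'   records untouched.
#' @export
classify_combos <- function(sorted, design) {
  designed <- design$pcrs$combo[design$pcrs$pool == sorted$pool]
  list(
    used = sorted$seqs[sorted$seqs$combo %in% designed, , drop = FALSE],
    unused = sorted$seqs[!(sorted$seqs$combo %in% designed), , drop = FALSE]
  )
}

ranked_seqs <- function(sorted) {
  sorted$seqs |>
    arrange(.data$combo, desc(.data$count), .data$sequence) |>
    group_by(.data$combo) |>
    mutate(rank = row_number()) |>
    ungroup()
}

#' Write a sorted pool to a directory
#'
#' Creates `pool_<label>/` under `outdir`, with one text file per observed
#' tag combination (comment header naming the pool, combination, used flag
#' and primers; then rank, count, sequence -- ordered by descending count and
#' then sequence) and a `summary.tsv` listing every observed combination
#' with its used flag, unique-sequence count, and total read count. The
#' summary's comment header carries the pool-level read accounting.
#'
#' @param sorted A [sort_pool()] result.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sorted_pool <- function(sorted, outdir) {
  pooldir <- file.path(outdir, paste0("pool_", sorted$pool))
  dir.create(pooldir, recursive = TRUE, showWarnings = FALSE)
  rk <- ranked_seqs(sorted)
  primer_lines <- sprintf(
    "# primer: %s %s %s",
    sorted$primers$barcode, sorted$primers$forward, sorted$primers$reverse
  )
  paths <- character()
  for (cb in unique(rk$combo)) {
    sub <- rk[rk$combo == cb, ]
    p <- file.path(pooldir, paste0(cb, ".txt"))
    writeLines(c(
      sprintf("# pool: %s", sorted$pool),
      sprintf("# combo: %s", cb),
      sprintf("# used: %s", if (sub$used[1]) "yes" else "no"),
      primer_lines,
      "rank\tcount\tsequence",
      sprintf("%d\t%d\t%s", sub$rank, sub$count, sub$sequence)
    ), p)
    paths <- c(paths, p)
  }
  summ <- rk |>
    group_by(.data$combo, .data$used) |>
    summarise(n_unique = n(), n_total = sum(.data$count), .groups = "drop") |>
    arrange(.data$combo)
  sp <- file.path(pooldir, "summary.tsv")
  writeLines(c(
    sprintf("# pool: %s", sorted$pool),
    sprintf("# n_input: %d", sorted$n_input),
    sprintf("# n_sorted: %d", sorted$n_sorted),
    sprintf("# n_discarded: %d", sorted$n_discarded),
    sprintf("# n_ambiguous: %d", sorted$n_ambiguous),
    sprintf("# n_chimera_removed: %d", sorted$n_chimera_removed),
    "combo\tused\tn_unique\tn_total",
    sprintf("%s\t%s\t%d\t%d",
            summ$combo, ifelse(summ$used, "used", "unused"),
            summ$n_unique, summ$n_total)
  ), sp)
  invisible(c(paths, sp))
}

#' Read back a sorted pool written by [write_sorted_pool()]
#'
#' @param pooldir The `pool_<label>` directory.
#' @return A `sorted_pool` object.
#' @export
read_sorted_pool <- function(pooldir) {
  sp <- file.path(pooldir, "summary.tsv")
  if (!file.exists(sp)) abort(paste0("no summary.tsv under ", pooldir))
  lines <- readLines(sp, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  get_stat <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(ln)) abort(paste0("summary.tsv lacks '", key, "'"))
    sub(paste0("^# ", key, ": "), "", ln[1])
  }
  pool <- get_stat("pool")
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)][-1] # drop column header
  combos <- character(0)
  used_flag <- logical(0)
  if (length(body)) {
    f <- strsplit(body, "\t")
    combos <- vapply(f, `[`, character(1), 1)
    used_flag <- vapply(f, `[`, character(1), 2) == "used"
  }
  seqs_list <- list()
  primers <- NULL
  for (i in seq_along(combos)) {
    cl <- readLines(file.path(pooldir, paste0(combos[i], ".txt")), warn = FALSE)
    if (is.null(primers)) {
      pl <- grep("^# primer: ", cl, value = TRUE)
      pf <- strsplit(sub("^# primer: ", "", pl), " ")
      primers <- tibble(
        barcode = vapply(pf, `[`, character(1), 1),
        forward = vapply(pf, `[`, character(1), 2),
        reverse = vapply(pf, `[`, character(1), 3)
      )
    }
    rows <- cl[!startsWith(cl, "#")]
    rows <- rows[nzchar(rows)][-1]
    if (!length(rows)) next
    f <- strsplit(rows, "\t")
    seqs_list[[i]] <- tibble(
      combo = combos[i],
      sequence = vapply(f, `[`, character(1), 3),
      count = as.integer(vapply(f, `[`, character(1), 2)),
      used = used_flag[i]
    )
  }
  seqs <- if (length(seqs_list)) bind_rows(seqs_list) else {
    tibble(combo = character(), sequence = character(),
           count = integer(), used = logical())
  }
  seqs <- bind_cols(split_combo(seqs$combo), seqs) |>
    arrange(.data$combo, desc(.data$count), .data$sequence)
  structure(
    list(
      pool = pool,
      seqs = seqs,
      n_input = as.integer(get_stat("n_input")),
      n_sorted = as.integer(get_stat("n_sorted")),
      n_discarded = as.integer(get_stat("n_discarded")),
      n_ambiguous = as.integer(get_stat("n_ambiguous")),
      n_chimera_removed = as.integer(get_stat("n_chimera_removed")),
      used_combos = sort(combos[used_flag]),
      primers = primers %||% tibble(barcode = character(),
                                    forward = character(), reverse = character())
    ),
    class = "sorted_pool"
  )
}

#' Write the unique sequences of a sorted pool as FASTA
#'
#' Headers are `combo|rank|count` for interoperability with downstream tools.
#'
#' @param sorted A [sort_pool()] result.
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_sorted_fasta <- function(sorted, path) {
  rk <- ranked_seqs(sorted)
  write_fasta(tibble(
    header = sprintf("%s|%d|%d", rk$combo, rk$rank, rk$count),
    sequence = rk$sequence
  ), path)
}
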