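# Seeded generator of double-tagged amplicon libraries with a full per-read
# truth table. Reads are built as
#   tagF + primerF + insert + revcomp(primerR) + revcomp(tagR)
# where the insert is a reference sequence with point errors (substitutions
# only by default), optionally a two-parent chimera; with probability
# tag_jump_rate one of the two tags is swapped for a random other tag used
# in the pool; about half the reads are emitted reverse-complemented.
# Everything is reproducible from the seed.

#' Simulation configuration
#'
#' Defaults emulate a mock-community benchmark experiment: 4 samples, each
#' amplified in 4 PCR replicates carrying matching tags (same tag id at both
#' ends), one sequencing pool, 10 reference mini-barcodes of 157 bp mixed at
#' equal abundance, 1250 reads per replicate (20,000 reads in total), a
#' residual per-base substitution rate of 0.002, a 5% tag-jump rate and a 1%
#' chimera rate.
#'
#' @param n_samples,replicates_per_sample,n_pools Experiment layout.
#' @param tag_scheme `"matched"` (tag ids equal at both ends, the layout that
#'   makes tag jumps visible as unused combinations) or `"combinatorial"`.
#' @param n_refs,ref_length Reference set size and amplicon insert length.
#' @param reads_per_replicate Reads emitted per PCR replicate.
#' @param abundance `"uniform"` (equimolar mock) or `"lognormal"`; sigma of
#'   the lognormal via `lognormal_sigma`.
#' @param point_error_rate Per-base substitution probability in the insert.
#' @param tag_jump_rate Per-read probability that one tag is replaced by a
#'   random other tag id used in the pool.
#' @param chimera_rate Per-read probability that the insert is a two-parent
#'   breakpoint recombinant.
#' @param indel_rate Per-base indel probability in the insert (default 0).
#' @param swap_plant Optional named character vector planting primer mix-ups:
#'   names are designed combos, values the combos actually emitted, e.g.
#'   `c("F2-R2" = "F2-R1")`.
#' @param n_tags Optional cap on available tags; an error is raised when the
#'   layout needs more.
#' @param tag_length Tag length in bp (default 7).
#' @param primer_forward,primer_reverse Primer pair; the defaults are a
#'   degenerate arthropod COI mini-barcode pair.
#' @param seed Mandatory RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 4, replicates_per_sample = 4, n_pools = 1,
                       tag_scheme = c("matched", "combinatorial"),
                       n_refs = 10, ref_length = 157,
                       reads_per_replicate = 1250,
                       abundance = c("uniform", "lognormal"),
                       lognormal_sigma = 1,
                       point_error_rate = 0.002, tag_jump_rate = 0.05,
                       chimera_rate = 0.01, indel_rate = 0,
                       swap_plant = NULL, n_tags = NULL, tag_length = 7,
                       primer_forward = "AGATATTGGAACWTTATATTTTATTTTTGG",
                       primer_reverse = "WACTAATCAATTWCCAAATCCTCC",
                       seed) {
  tag_scheme <- match.arg(tag_scheme)
  abundance <- match.arg(abundance)
  if (missing(seed) || !is.numeric(seed)) abort("a numeric seed is required")
  rates <- c(point_error_rate, tag_jump_rate, chimera_rate, indel_rate)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  if (any(c(n_samples, replicates_per_sample, n_pools, n_refs, ref_length,
            reads_per_replicate, tag_length) < 1)) {
    abort("layout parameters must be positive")
  }
  if (!is_iupac_dna(toupper(primer_forward)) || !is_iupac_dna(toupper(primer_reverse))) {
    abort("primers must be IUPAC DNA")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config> %d samples x %d replicates in %d pool(s), %s tags; ",
           "%d refs x %d bp, %d reads/replicate\n",
           "  error %.4g/base, tag jump %.4g/read, chimera %.4g/read, seed %s\n"),
    x$n_samples, x$replicates_per_sample, x$n_pools, x$tag_scheme,
    x$n_refs, x$ref_length, x$reads_per_replicate,
    x$point_error_rate, x$tag_jump_rate, x$chimera_rate, format(x$seed)
  ))
  invisible(x)
}

#' Generate a mutually divergent reference set
#'
#' Random sequences whose pairwise identities (see [seq_identity()]) all stay
#' at or below `1 - min_pairwise_divergence`, so truth matching at a 0.97
#' identity cutoff is unambiguous.
#'
#' @param n_refs Number of references.
#' @param length Sequence length (bp).
#' @param min_pairwise_divergence Minimum pairwise divergence (default 0.10).
#' @param seed Optional seed (set it when calling directly; [simulate_library()]
#'   manages the RNG itself).
#' @param max_tries Resampling budget before giving up.
#' @return Named character vector `ref01`, `ref02`, ...
#' @export
make_reference_set <- function(n_refs, length = 157, min_pairwise_divergence = 0.10,
                               seed = NULL, max_tries = 100) {
  if (!is.null(seed)) set.seed(seed)
  refs <- random_dna(n_refs, length)
  limit <- 1 - min_pairwise_divergence
  tries <- 0
  repeat {
    worst <- NULL
    if (n_refs > 1) {
      for (i in seq_len(n_refs - 1)) {
        for (j in (i + 1):n_refs) {
          if (seq_identity(refs[i], refs[j]) > limit) {
            worst <- j
            break
          }
        }
        if (!is.null(worst)) break
      }
    }
    if (is.null(worst)) break
    tries <- tries + 1
    if (tries > max_tries) {
      abort("could not satisfy the pairwise divergence constraint; lower it or shorten the set")
    }
    refs[worst] <- random_dna(1, length)
  }
  setNames(refs, sprintf("ref%02d", seq_len(n_refs)))
}

# Assign replicates to pools and tag ids to (sample, replicate) entries.
build_sim_design <- function(cfg) {
  grid <- tidyr::expand_grid(
    sample = sprintf("S%02d", seq_len(cfg$n_samples)),
    replicate = seq_len(cfg$replicates_per_sample)
  ) |>
    mutate(pool = paste0("pool", ((.data$replicate - 1L) %% cfg$n_pools) + 1L)) |>
    arrange(.data$sample, .data$replicate)
  per_pool <- split(seq_len(nrow(grid)), grid$pool)
  max_n <- max(lengths(per_pool))
  if (cfg$tag_scheme == "matched") {
    K <- max_n
    fwd <- rev <- integer(nrow(grid))
    for (rows in per_pool) {
      fwd[rows] <- seq_along(rows)
      rev[rows] <- seq_along(rows)
    }
  } else {
    K <- ceiling(sqrt(max_n))
    pairs <- tidyr::expand_grid(f = seq_len(K), r = seq_len(K))
    fwd <- rev <- integer(nrow(grid))
    for (rows in per_pool) {
      fwd[rows] <- pairs$f[seq_along(rows)]
      rev[rows] <- pairs$r[seq_along(rows)]
    }
  }
  if (!is.null(cfg$n_tags) && K > cfg$n_tags) {
    abort(sprintf("layout needs %d tags but n_tags = %d", K, cfg$n_tags))
  }
  grid$fwd_tag <- as.character(fwd)
  grid$rev_tag <- as.character(rev)
  list(grid = grid, n_tags = K)
}

#' Simulate a double-tagged amplicon experiment
#'
#' Writes, under `dir`: one FASTQ per pool, the three design files (PCR
#' design, tags, primers), the reference FASTA, and a truth table TSV with
#' one row per emitted read (source sample/replicate, reference or
#' chimera parents, point-error count, intended and emitted tag combination,
#' jump/swap/orientation flags). Bit-reproducible for a given config.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return A list with the config, file paths (`fastq` named by pool,
#'   `pcr_file`, `tag_file`, `primer_file`, `ref_file`, `truth_file`), the
#'   references, the truth tibble, and the loaded `design`.
#' @export
simulate_library <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)

  refs <- make_reference_set(cfg$n_refs, cfg$ref_length)
  layout <- build_sim_design(cfg)
  grid <- layout$grid

  # tag sequences: unique random k-mers
  repeat {
    tag_seqs <- random_dna(layout$n_tags, cfg$tag_length)
    if (!anyDuplicated(tag_seqs)) break
  }
  tags <- tibble(tag_id = as.character(seq_len(layout$n_tags)), sequence = tag_seqs)
  tag_lookup <- setNames(tags$sequence, tags$tag_id)

  # planted primer mix-ups
  emit_fwd <- grid$fwd_tag
  emit_rev <- grid$rev_tag
  grid$swapped <- FALSE
  if (!is.null(cfg$swap_plant)) {
    designed <- combo_id(grid$fwd_tag, grid$rev_tag)
    for (k in seq_along(cfg$swap_plant)) {
      from <- names(cfg$swap_plant)[k]
      to <- split_combo(unname(cfg$swap_plant[k]))
      hit <- designed == from
      if (!any(hit)) abort(paste0("swap_plant names unknown designed combo: ", from))
      if (!(to$fwd_tag %in% tags$tag_id) || !(to$rev_tag %in% tags$tag_id)) {
        abort(paste0("swap_plant target uses unknown tag ids: ", cfg$swap_plant[k]))
      }
      emit_fwd[hit] <- to$fwd_tag
      emit_rev[hit] <- to$rev_tag
      grid$swapped[hit] <- TRUE
    }
  }

  # per-sample community profiles
  samples <- unique(grid$sample)
  weights <- lapply(samples, function(s) {
    w <- if (cfg$abundance == "uniform") rep(1, cfg$n_refs) else rlnorm(cfg$n_refs, 0, cfg$lognormal_sigma)
    w / sum(w)
  })
  names(weights) <- samples

  pool_tag_ids <- lapply(split(grid, grid$pool), function(g) {
    list(f = unique(g$fwd_tag), r = unique(g$rev_tag))
  })

  serial <- 0L
  truth_list <- vector("list", nrow(grid))
  reads_list <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    N <- cfg$reads_per_replicate
    w <- weights[[grid$sample[i]]]
    ref_idx <- sample.int(cfg$n_refs, N, replace = TRUE, prob = w)
    insert <- unname(refs[ref_idx])
    ref_id <- names(refs)[ref_idx]

    is_chim <- (runif(N) < cfg$chimera_rate) & cfg$n_refs >= 2 & cfg$ref_length >= 3
    parent2 <- rep(NA_character_, N)
    breakpoint <- rep(NA_integer_, N)
    if (any(is_chim)) {
      ci <- which(is_chim)
      p2 <- vapply(ref_idx[ci], function(x) sample(setdiff(seq_len(cfg$n_refs), x), 1L), integer(1))
      bp <- sample(seq(2L, cfg$ref_length - 1L), length(ci), replace = TRUE)
      insert[ci] <- paste0(
        substr(refs[ref_idx[ci]], 1L, bp),
        substr(refs[p2], bp + 1L, nchar(refs[p2]))
      )
      parent2[ci] <- names(refs)[p2]
      breakpoint[ci] <- bp
    }

    n_err <- rbinom(N, nchar(insert), cfg$point_error_rate)
    for (k in which(n_err > 0)) insert[k] <- mutate_seq(insert[k], n_err[k])
    if (cfg$indel_rate > 0) {
      n_ind <- rbinom(N, nchar(insert), cfg$indel_rate)
      for (k in which(n_ind > 0)) insert[k] <- apply_indels(insert[k], n_ind[k])
    }

    f_id <- rep(emit_fwd[i], N)
    r_id <- rep(emit_rev[i], N)
    jump <- runif(N) < cfg$tag_jump_rate
    if (any(jump)) {
      pool_ids <- pool_tag_ids[[grid$pool[i]]]
      side_f <- jump & (runif(N) < 0.5)
      side_r <- jump & !side_f
      jump_to <- function(current, universe, idx) {
        for (k in idx) {
          others <- setdiff(universe, current[k])
          if (length(others)) current[k] <- sample(others, 1L) # nothing to jump to in a 1-tag pool
        }
        current
      }
      f_id <- jump_to(f_id, pool_ids$f, which(side_f))
      r_id <- jump_to(r_id, pool_ids$r, which(side_r))
      jump <- (f_id != emit_fwd[i]) | (r_id != emit_rev[i])
    }

    pfr <- realize_iupac(toupper(cfg$primer_forward), N)
    prr <- realize_iupac(toupper(cfg$primer_reverse), N)
    read <- paste0(tag_lookup[f_id], pfr, insert, revcomp(prr), revcomp(tag_lookup[r_id]))
    flip <- runif(N) < 0.5
    read[flip] <- revcomp(read[flip])

    read_id <- sprintf("sim_%07d", serial + seq_len(N))
    serial <- serial + N
    reads_list[[i]] <- tibble(
      pool = grid$pool[i], read_id = read_id,
      sequence = read, quality = strrep("I", nchar(read))
    )
    chim_parents <- ifelse(is_chim, paste(ref_id, parent2, breakpoint, sep = ":"),
                           NA_character_)
    truth_list[[i]] <- tibble(
      read_id = read_id,
      pool = grid$pool[i],
      sample = grid$sample[i],
      replicate = grid$replicate[i],
      ref_id = ifelse(is_chim, NA_character_, ref_id),
      n_point_errors = n_err,
      is_chimera = is_chim,
      chimera_parents = chim_parents,
      intended_combo = combo_id(grid$fwd_tag[i], grid$rev_tag[i]),
      emitted_combo = combo_id(f_id, r_id),
      jumped = jump,
      swapped = grid$swapped[i],
      revcomped = flip
    )
  }
  reads <- bind_rows(reads_list)
  truth <- bind_rows(truth_list)

  fastq <- character()
  for (p in unique(grid$pool)) {
    fp <- file.path(dir, paste0(p, ".fastq"))
    write_fastq(reads[reads$pool == p, ], fp)
    fastq[p] <- fp
  }
  pcr_file <- file.path(dir, "pcrs.txt")
  writeLines(c(
    "# sample fwd_tag rev_tag pool",
    sprintf("%s\t%s\t%s\t%s", grid$sample, grid$fwd_tag, grid$rev_tag, grid$pool)
  ), pcr_file)
  tag_file <- file.path(dir, "tags.txt")
  writeLines(sprintf("%s\t%s", tags$tag_id, tags$sequence), tag_file)
  primer_file <- file.path(dir, "primers.txt")
  writeLines(sprintf("COI\t%s\t%s", toupper(cfg$primer_forward), toupper(cfg$primer_reverse)),
             primer_file)
  ref_file <- file.path(dir, "refs.fasta")
  write_fasta(refs, ref_file)
  truth_file <- file.path(dir, "truth.tsv")
  readr::write_tsv(truth, truth_file)

  list(
    config = cfg,
    dir = dir,
    fastq = fastq,
    pcr_file = pcr_file,
    tag_file = tag_file,
    primer_file = primer_file,
    ref_file = ref_file,
    truth_file = truth_file,
    refs = refs,
    truth = truth,
    design = load_design(pcr_file, tag_file, primer_file)
  )
}

apply_indels <- function(s, k) {
  for (j in seq_len(k)) {
    L <- nchar(s)
    p <- sample.int(L, 1)
    if (runif(1) < 0.5 && L > 1) {
      s <- paste0(substr(s, 1, p - 1), substr(s, p + 1, L)) # deletion
    } else {
      s <- paste0(substr(s, 1, p), sample(c("A", "C", "G", "T"), 1), substr(s, p + 1, L))
    }
  }
  s
}
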