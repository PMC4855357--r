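# Builders and brute-force oracles shared across the test files. The oracles
# deliberately use the slowest, most literal formulation of each rule so that
# the vectorised implementations can be checked against them.

# ---- deterministic toy design ----------------------------------------------

TOY_TAGS <- c(`1` = "ACGTAC", `2` = "TGCATG", `3` = "GGATCC", `4` = "TTGACA")
TOY_FWD <- "ACWGGTCA" # one degenerate position (W = A/T)
TOY_REV <- "TGGRATCA" # one degenerate position (R = A/G)

# Write the three design files under `dir` and load them. The default layout
# is 2 samples x 2 replicates with matched tags in one pool.
write_toy_design <- function(dir, pcrs = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tag_file <- file.path(dir, "tags.txt")
  writeLines(sprintf("%s\t%s", names(TOY_TAGS), TOY_TAGS), tag_file)
  primer_file <- file.path(dir, "primers.txt")
  writeLines(sprintf("P\t%s\t%s", TOY_FWD, TOY_REV), primer_file)
  if (is.null(pcrs)) {
    pcrs <- data.frame(
      sample = c("A", "A", "B", "B"),
      fwd = c("1", "2", "3", "4"),
      rev = c("1", "2", "3", "4"),
      pool = "p1",
      stringsAsFactors = FALSE
    )
  }
  pcr_file <- file.path(dir, "pcrs.txt")
  writeLines(sprintf("%s\t%s\t%s\t%s", pcrs$sample, pcrs$fwd, pcrs$rev, pcrs$pool),
             pcr_file)
  list(design = load_design(pcr_file, tag_file, primer_file),
       pcr_file = pcr_file, tag_file = tag_file, primer_file = primer_file)
}

# concrete realisations of the degenerate toy primers
toy_fwd_real <- function() chartr("W", "A", TOY_FWD)
toy_rev_real <- function() chartr("R", "G", TOY_REV)

toy_read <- function(fwd_tag, insert, rev_tag,
                     fwd = toy_fwd_real(), rev = toy_rev_real()) {
  unname(paste0(TOY_TAGS[[fwd_tag]], fwd, insert,
                revcomp(rev), revcomp(TOY_TAGS[[rev_tag]])))
}

write_reads_fastq <- function(seqs, path, ids = sprintf("r%05d", seq_along(seqs))) {
  lines <- as.vector(rbind(paste0("@", ids), seqs, "+", strrep("I", nchar(seqs))))
  writeLines(lines, path)
  path
}

helper_random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE), collapse = "")
  }, character(1))
}

# ---- brute-force per-read classifier (sorter oracle) ------------------------

IUPAC_ORACLE <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

count_mm <- function(segment, primer) {
  s <- strsplit(segment, "")[[1]]
  p <- strsplit(primer, "")[[1]]
  stopifnot(length(s) == length(p))
  bad <- 0L
  for (j in seq_along(p)) {
    allowed <- strsplit(IUPAC_ORACLE[[p[j]]], "")[[1]]
    if (!(s[j] %in% allowed)) bad <- bad + 1L
  }
  bad
}

# Literal restatement of the matching rules for one read: exact anchored tags,
# primers with <= max_mm substitutions, both orientations tried; ambiguous when
# both orientations match, more than one primer set matches, or one set admits
# more than one (fwd tag, rev tag, insert) interpretation.
oracle_match <- function(seq, design, max_mm = 2) {
  seq <- toupper(seq)
  per_orientation <- lapply(list(seq, revcomp(seq)), function(s) {
    nc <- nchar(s)
    set_hits <- 0L
    set_amb <- FALSE
    first <- NULL
    for (p in seq_len(nrow(design$primers))) {
      pf <- design$primers$forward[p]
      prc <- revcomp(design$primers$reverse[p])
      Pf <- nchar(pf)
      Pr <- nchar(prc)
      triples <- list()
      for (fi in seq_len(nrow(design$tags))) {
        for (ri in seq_len(nrow(design$tags))) {
          ft <- design$tags$sequence[fi]
          rt <- revcomp(design$tags$sequence[ri])
          Lf <- nchar(ft)
          Lr <- nchar(rt)
          if (nc < Lf + Pf + Pr + Lr) next
          if (substr(s, 1, Lf) != ft) next
          if (substring(s, nc - Lr + 1) != rt) next
          if (count_mm(substr(s, Lf + 1, Lf + Pf), pf) > max_mm) next
          if (count_mm(substr(s, nc - Lr - Pr + 1, nc - Lr), prc) > max_mm) next
          triples[[length(triples) + 1]] <- list(
            f = design$tags$tag_id[fi], r = design$tags$tag_id[ri],
            insert = substr(s, Lf + Pf + 1, nc - Lr - Pr)
          )
        }
      }
      if (length(triples)) {
        keys <- vapply(triples, function(x) paste(x$f, x$r, x$insert, sep = "\r"),
                       character(1))
        if (length(unique(keys)) > 1) set_amb <- TRUE
        set_hits <- set_hits + 1L
        if (is.null(first)) first <- triples[[1]]
      }
    }
    list(hit = set_hits == 1L && !set_amb,
         amb = set_amb || set_hits > 1L,
         m = first)
  })
  h1 <- per_orientation[[1]]$hit
  h2 <- per_orientation[[2]]$hit
  if (xor(h1, h2)) {
    m <- if (h1) per_orientation[[1]]$m else per_orientation[[2]]$m
    list(status = "matched", fwd_tag = m$f, rev_tag = m$r, insert = m$insert)
  } else if ((h1 && h2) || per_orientation[[1]]$amb || per_orientation[[2]]$amb) {
    list(status = "ambiguous")
  } else {
    list(status = "no_match")
  }
}

# ---- brute-force filter evaluator -------------------------------------------

oracle_filter <- function(df, y, t, l, t_mode = "per_replicate") {
  df <- as.data.frame(df)
  keys <- unique(df[, c("sample", "sequence")])
  keep <- logical(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$sample == keys$sample[i] & df$sequence == keys$sequence[i], ]
    ok <- sum(sub$count >= 1) >= y
    ok <- ok && (if (t_mode == "per_replicate") sum(sub$count >= t) >= y
                 else sum(sub$count) >= t)
    ok <- ok && nchar(keys$sequence[i]) >= l
    keep[i] <- ok
  }
  keys[keep, , drop = FALSE]
}

key_str <- function(df) sort(paste(df$sample, df$sequence, sep = "\r"))

# ---- direct union-summation RSI ----------------------------------------------

oracle_rsi <- function(a, b) {
  a <- a / sum(a)
  b <- b / sum(b)
  shared <- 0
  for (nm in union(names(a), names(b))) {
    pa <- if (nm %in% names(a)) a[[nm]] else 0
    pb <- if (nm %in% names(b)) b[[nm]] else 0
    shared <- shared + min(pa, pb)
  }
  1 - shared
}

# ---- naive scalar overlap-alignment DP ---------------------------------------

# Full O(mn) matrix over (score, matches) with free end gaps; ties in score
# broken towards more matches, exactly the objective the vectorised
# implementation encodes in a single combined value.
oracle_align <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A)
  n <- length(B)
  S <- matrix(0, m + 1, n + 1) # free leading gaps
  M <- matrix(0, m + 1, n + 1)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      hit <- A[i] == B[j]
      cand_s <- c(S[i, j] + (if (hit) match else mismatch),
                  S[i, j + 1] + gap,
                  S[i + 1, j] + gap)
      cand_m <- c(M[i, j] + hit, M[i, j + 1], M[i + 1, j])
      best <- max(cand_s)
      S[i + 1, j + 1] <- best
      M[i + 1, j + 1] <- max(cand_m[cand_s == best])
    }
  }
  cells_s <- c(S[m + 1, ], S[, n + 1]) # free trailing gaps on either side
  cells_m <- c(M[m + 1, ], M[, n + 1])
  best <- max(cells_s)
  list(score = best, matches = max(cells_m[cells_s == best]))
}

# Independent overlap-alignment score from an established aligner (cross-check
# of the score only; the match-count tie-break is ours).
ref_overlap_score <- function(a, b) {
  ns <- if (requireNamespace("pwalign", quietly = TRUE)) "pwalign" else "Biostrings"
  pa <- getExportedValue(ns, "pairwiseAlignment")
  sm <- getExportedValue(ns, "nucleotideSubstitutionMatrix")(
    match = 1, mismatch = -1, baseOnly = TRUE
  )
  aln <- pa(a, b, type = "overlap", substitutionMatrix = sm,
            gapOpening = 0, gapExtension = 1)
  as.numeric(methods::slot(aln, "score"))
}

# ---- shared simulation for the acceptance tests ------------------------------

.acc_env <- new.env(parent = emptyenv())

# One simulation at the generator's default settings (the study conditions),
# reused by several acceptance tests; sorted once.
acceptance_sim <- function() {
  if (is.null(.acc_env$sim)) {
    dir <- file.path(tempdir(), "twintag-acceptance-sim")
    .acc_env$sim <- simulate_library(sim_config(seed = 20240601), dir)
    .acc_env$sorted <- sort_pool(.acc_env$sim$fastq[["pool1"]], .acc_env$sim$design,
                                 "pool1")
    .acc_env$tables <- build_sample_tables(.acc_env$sorted, .acc_env$sim$design)
  }
  .acc_env
}
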