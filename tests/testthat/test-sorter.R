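# Demultiplexer: matching rules, ambiguity handling, conservation, and the
# on-disk pool layout.

test_that("exact reads match in both orientations and trim to the insert", {
  toy <- write_toy_design(withr::local_tempdir())
  r <- toy_read("1", "ACGTTGCA", "1")
  m <- match_read(r, toy$design)
  expect_identical(m$combo, "F1-R1")
  expect_identical(m$insert, "ACGTTGCA")

  m2 <- match_read(revcomp(r), toy$design)
  expect_identical(m2$combo, "F1-R1")
  expect_identical(m2$insert, "ACGTTGCA")
})

test_that("primer degeneracy and the substitution budget are honoured", {
  toy <- write_toy_design(withr::local_tempdir())
  # W realised as T instead of A: still an exact primer match
  r <- toy_read("2", "ACGTTGCA", "2", fwd = chartr("W", "T", TOY_FWD))
  expect_identical(match_read(r, toy$design)$combo, "F2-R2")

  # up to 2 substitutions in a primer pass, 3 fail
  mangle <- function(p, k) {
    for (i in seq_len(k)) {
      cur <- substr(p, i, i)
      substr(p, i, i) <- setdiff(c("A", "C", "G", "T"), cur)[1]
    }
    p
  }
  fwd2 <- mangle(toy_fwd_real(), 2)
  expect_identical(match_read(toy_read("1", "AAAA", "1", fwd = fwd2),
                              toy$design)$combo, "F1-R1")
  fwd3 <- mangle(toy_fwd_real(), 3)
  expect_null(match_read(toy_read("1", "AAAA", "1", fwd = fwd3), toy$design))
  # a stricter budget rejects the 2-substitution read
  expect_null(match_read(toy_read("1", "AAAA", "1", fwd = fwd2), toy$design,
                         max_primer_mismatch = 1))
})

test_that("tags must match exactly and be anchored at the read ends", {
  toy <- write_toy_design(withr::local_tempdir())
  r <- toy_read("1", "ACGTTGCA", "1")
  # one substitution inside the forward tag kills the match
  substr(r, 2, 2) <- setdiff(c("A", "C", "G", "T"), substr(r, 2, 2))[1]
  expect_null(match_read(r, toy$design))
  # an extra leading base breaks anchoring
  expect_null(match_read(paste0("G", toy_read("1", "ACGT", "1")), toy$design))
})

test_that("empty inserts are kept (the length filter owns that decision)", {
  toy <- write_toy_design(withr::local_tempdir())
  m <- match_read(toy_read("3", "", "3"), toy$design)
  expect_identical(m$combo, "F3-R3")
  expect_identical(m$insert, "")
})

test_that("a read matching in both orientations is discarded as ambiguous", {
  # with an identical forward and reverse primer, a read built as
  # tag1 + P + insert + revcomp(P) + revcomp(tag2) also matches as
  # tag2 + P + revcomp(insert) + revcomp(P) + revcomp(tag1) after
  # reverse complementing, so both orientations hit and the read is dropped
  dir <- withr::local_tempdir()
  writeLines(sprintf("%s\t%s", names(TOY_TAGS), TOY_TAGS), file.path(dir, "tags.txt"))
  pf <- toy_fwd_real()
  writeLines(sprintf("P\t%s\t%s", pf, pf), file.path(dir, "primers.txt"))
  writeLines(c("A\t1\t2\tp1", "A\t2\t1\tp1"), file.path(dir, "pcrs.txt"))
  design <- load_design(file.path(dir, "pcrs.txt"), file.path(dir, "tags.txt"),
                        file.path(dir, "primers.txt"))

  r <- paste0(TOY_TAGS[["1"]], pf, "ACGTTT", revcomp(pf), revcomp(TOY_TAGS[["2"]]))
  expect_null(match_read(r, design))
  expect_identical(oracle_match(r, design)$status, "ambiguous")

  fq <- write_reads_fastq(r, withr::local_tempfile(fileext = ".fastq"))
  sp <- sort_pool(fq, design, "p1")
  expect_identical(sp$n_ambiguous, 1L)
  expect_identical(sp$n_sorted, 0L)
  expect_identical(sp$n_discarded, 1L)
})

test_that("a read matching under two primer sets is discarded as ambiguous", {
  dir <- withr::local_tempdir()
  writeLines(sprintf("%s\t%s", names(TOY_TAGS), TOY_TAGS), file.path(dir, "tags.txt"))
  # second primer set within 2 substitutions of the first: every clean read
  # matches both sets
  fwd_b <- sub("^AC", "GT", TOY_FWD)
  writeLines(c(sprintf("P\t%s\t%s", TOY_FWD, TOY_REV),
               sprintf("Q\t%s\t%s", fwd_b, TOY_REV)),
             file.path(dir, "primers.txt"))
  writeLines("A\t1\t1\tp1", file.path(dir, "pcrs.txt"))
  design <- load_design(file.path(dir, "pcrs.txt"), file.path(dir, "tags.txt"),
                        file.path(dir, "primers.txt"))
  expect_null(match_read(toy_read("1", "ACGTACGT", "1"), design))
})

test_that("sort_pool conserves reads, collapses duplicates and flags unused combos", {
  toy <- write_toy_design(withr::local_tempdir())
  reads <- c(
    rep(toy_read("1", "ACGTACGT", "1"), 3),
    rep(revcomp(toy_read("1", "ACGTACGT", "1")), 2),
    toy_read("1", "ACGTACGA", "1"),
    toy_read("2", "ACGTACGT", "3"), # unused combination (tag jump signature)
    "GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG" # no match
  )
  fq <- write_reads_fastq(reads, withr::local_tempfile(fileext = ".fastq"))
  sp <- sort_pool(fq, toy$design, "p1")

  expect_identical(sp$n_input, 8L)
  expect_identical(sp$n_input, sp$n_sorted + sp$n_discarded)
  expect_identical(sp$n_sorted, 8L - 1L)
  top <- sp$seqs[sp$seqs$combo == "F1-R1" & sp$seqs$sequence == "ACGTACGT", ]
  expect_identical(top$count, 5L) # both orientations collapse together
  expect_true(all(sp$seqs$used[sp$seqs$combo == "F1-R1"]))
  expect_false(any(sp$seqs$used[sp$seqs$combo == "F2-R3"]))
  expect_identical(sort(sp$used_combos),
                   c("F1-R1", "F2-R2", "F3-R3", "F4-R4"))
})

test_that("sorter agrees with the per-read oracle on constructed and mutated reads", {
  toy <- write_toy_design(withr::local_tempdir())
  withr::local_seed(31)
  reads <- character(200)
  for (i in seq_len(200)) {
    f <- sample(names(TOY_TAGS), 1)
    r <- sample(names(TOY_TAGS), 1)
    ins <- helper_random_dna(1, sample(0:20, 1))
    x <- toy_read(f, ins, r)
    nmut <- sample(0:3, 1)
    for (k in seq_len(nmut)) {
      p <- sample.int(nchar(x), 1)
      substr(x, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    if (runif(1) < 0.5) x <- revcomp(x)
    reads[i] <- x
  }
  fq <- write_reads_fastq(reads, withr::local_tempfile(fileext = ".fastq"))
  sp <- sort_pool(fq, toy$design, "p1")

  orc <- lapply(reads, oracle_match, design = toy$design)
  status <- vapply(orc, `[[`, character(1), "status")
  expect_identical(sp$n_sorted, sum(status == "matched"))
  expect_identical(sp$n_ambiguous, sum(status == "ambiguous"))
  matched <- orc[status == "matched"]
  exp_keys <- sort(vapply(matched, function(m) {
    paste0("F", m$fwd_tag, "-R", m$rev_tag, ":", m$insert)
  }, character(1)))
  got_keys <- sort(rep(paste0(sp$seqs$combo, ":", sp$seqs$sequence), sp$seqs$count))
  expect_identical(got_keys, exp_keys)
})

test_that("write_sorted_pool / read_sorted_pool round-trips records and accounting", {
  toy <- write_toy_design(withr::local_tempdir())
  reads <- c(rep(toy_read("1", "ACGTACGT", "1"), 3),
             toy_read("2", "TTTTAAAA", "2"),
             toy_read("2", "TTTTAAAC", "3"),
             "GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG")
  fq <- write_reads_fastq(reads, withr::local_tempfile(fileext = ".fastq"))
  sp <- sort_pool(fq, toy$design, "p1")

  out <- withr::local_tempdir()
  write_sorted_pool(sp, out)
  sp2 <- read_sorted_pool(file.path(out, "pool_p1"))
  expect_identical(sp2$pool, sp$pool)
  expect_identical(sp2$seqs[, c("fwd_tag", "rev_tag", "combo", "sequence", "count", "used")],
                   sp$seqs[, c("fwd_tag", "rev_tag", "combo", "sequence", "count", "used")])
  for (fld in c("n_input", "n_sorted", "n_discarded", "n_ambiguous", "n_chimera_removed")) {
    expect_identical(sp2[[fld]], sp[[fld]])
  }
  expect_identical(sp2$primers$forward, sp$primers$forward)

  # tidy()/glance() views
  expect_identical(generics::tidy(sp), sp$seqs)
  g <- generics::glance(sp)
  expect_identical(g$n_input, sp$n_input)
  expect_identical(g$n_unique, nrow(sp$seqs))
})

test_that("classify_combos partitions the sorted records by design membership", {
  toy <- write_toy_design(withr::local_tempdir())
  reads <- c(toy_read("1", "ACGT", "1"), toy_read("1", "ACGT", "2"))
  fq <- write_reads_fastq(reads, withr::local_tempfile(fileext = ".fastq"))
  sp <- sort_pool(fq, toy$design, "p1")
  cc <- classify_combos(sp, toy$design)
  expect_identical(cc$used$combo, "F1-R1")
  expect_identical(cc$unused$combo, "F1-R2")
  expect_identical(nrow(cc$used) + nrow(cc$unused), nrow(sp$seqs))
})
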