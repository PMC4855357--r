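# Synthetic library generator: truth-table bookkeeping, the noise-free limit,
# determinism and configuration validation.

small_cfg <- function(seed, ...) {
  sim_config(n_samples = 2, replicates_per_sample = 2, reads_per_replicate = 50,
             n_refs = 4, ref_length = 60, seed = seed, ...)
}

test_that("sim_config validates its inputs", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, tag_jump_rate = 1.5), "rates")
  expect_error(sim_config(seed = 1, n_samples = 0), "positive")
  expect_error(sim_config(seed = 1, primer_forward = "AC-GT"), "IUPAC")
  cfg <- sim_config(seed = 1)
  expect_s3_class(cfg, "sim_config")
  expect_identical(cfg$reads_per_replicate, 1250)
  expect_identical(cfg$tag_jump_rate, 0.05)
})

test_that("truth rows equal emitted reads and the files agree with the design", {
  dir <- withr::local_tempdir()
  sim <- simulate_library(small_cfg(1), dir)
  expect_identical(nrow(sim$truth), 200L)
  expect_identical(nrow(read_fastq(sim$fastq[["pool1"]])), 200L)
  expect_identical(sim$design$replicates_per_sample, 2L)
  expect_identical(nrow(sim$design$pcrs), 4L)
  expect_length(sim$refs, 4)
  expect_true(all(nchar(sim$refs) == 60))
  # truth (sample, replicate) pairs match the design rows exactly
  tr <- unique(sim$truth[, c("sample", "replicate", "intended_combo")])
  de <- sim$design$pcrs
  expect_identical(
    sort(paste(tr$sample, tr$replicate, tr$intended_combo)),
    sort(paste(de$sample, de$replicate, de$combo))
  )
})

test_that("the noise-free limit reproduces the design exactly (pipeline closure)", {
  dir <- withr::local_tempdir()
  sim <- simulate_library(
    small_cfg(11, point_error_rate = 0, tag_jump_rate = 0, chimera_rate = 0),
    dir
  )
  sp <- sort_pool(sim$fastq[["pool1"]], sim$design, "pool1")
  expect_identical(sp$n_input, 200L)
  expect_identical(sp$n_discarded, 0L)
  expect_true(all(sp$seqs$used))
  # per-combo totals equal the truth table's per-replicate read counts
  per_combo <- tapply(sp$seqs$count, sp$seqs$combo, sum)
  truth_combo <- table(sim$truth$emitted_combo)
  expect_identical(sort(names(per_combo)), sort(names(truth_combo)))
  expect_identical(as.integer(per_combo[names(truth_combo)]),
                   as.integer(truth_combo))
  # every sorted sequence is one of the references
  expect_true(all(sp$seqs$sequence %in% sim$refs))
  expect_identical(sum(sp$seqs$count), 200L)
})

test_that("tag jumps land in unused combinations and are flagged in the truth table", {
  dir <- withr::local_tempdir()
  sim <- simulate_library(
    sim_config(n_samples = 2, replicates_per_sample = 2, reads_per_replicate = 250,
               n_refs = 4, ref_length = 60, point_error_rate = 0,
               chimera_rate = 0, tag_jump_rate = 0.2, seed = 3),
    dir
  )
  expect_gt(sum(sim$truth$jumped), 0)
  expect_true(all(sim$truth$emitted_combo[sim$truth$jumped] !=
                    sim$truth$intended_combo[sim$truth$jumped]))
  sp <- sort_pool(sim$fastq[["pool1"]], sim$design, "pool1")
  unused_reads <- sum(sp$seqs$count[!sp$seqs$used])
  expect_identical(unused_reads, sum(sim$truth$jumped))
})

test_that("chimeras are breakpoint recombinants with recorded parents", {
  dir <- withr::local_tempdir()
  sim <- simulate_library(
    small_cfg(5, chimera_rate = 0.5, point_error_rate = 0, tag_jump_rate = 0),
    dir
  )
  ch <- sim$truth[sim$truth$is_chimera, ]
  expect_gt(nrow(ch), 0)
  expect_true(all(is.na(ch$ref_id)))
  parts <- strsplit(ch$chimera_parents[1], ":")[[1]]
  expect_length(parts, 3)
  p1 <- sim$refs[[parts[1]]]
  p2 <- sim$refs[[parts[2]]]
  bp <- as.integer(parts[3])
  expect_false(parts[1] == parts[2])
  recombinant <- paste0(substr(p1, 1, bp), substr(p2, bp + 1, nchar(p2)))
  # locate that read and verify its insert via the sorter
  rid <- ch$read_id[1]
  reads <- read_fastq(sim$fastq[[ch$pool[1]]])
  m <- match_read(reads$sequence[reads$read_id == rid], sim$design)
  expect_identical(m$insert, recombinant)
  expect_identical(m$combo, ch$emitted_combo[1])
})

test_that("simulation is bit-reproducible and seeds differ meaningfully", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  simulate_library(small_cfg(21), d1)
  simulate_library(small_cfg(21), d2)
  simulate_library(small_cfg(22), d3)
  f <- sort(list.files(d1))
  expect_identical(unname(tools::md5sum(file.path(d1, f))),
                   unname(tools::md5sum(file.path(d2, f))))
  expect_false(identical(unname(tools::md5sum(file.path(d1, "pool1.fastq"))),
                         unname(tools::md5sum(file.path(d3, "pool1.fastq")))))
})

test_that("layouts: multiple pools, combinatorial tags and the tag cap", {
  dir <- withr::local_tempdir()
  sim <- simulate_library(small_cfg(31, n_pools = 2), dir)
  expect_length(sim$fastq, 2)
  expect_identical(sort(unique(sim$design$pcrs$pool)), c("pool1", "pool2"))

  dir2 <- withr::local_tempdir()
  sim2 <- simulate_library(small_cfg(32, tag_scheme = "combinatorial"), dir2)
  # 4 PCRs in one pool need ceiling(sqrt(4)) = 2 tags under a combinatorial scheme
  expect_identical(nrow(sim2$design$tags), 2L)
  sp <- sort_pool(sim2$fastq[["pool1"]], sim2$design, "pool1")
  expect_identical(sp$n_input, sp$n_sorted + sp$n_discarded)

  expect_error(simulate_library(small_cfg(33, n_tags = 3), withr::local_tempdir()),
               "needs 4 tags")
  expect_error(
    simulate_library(small_cfg(34, swap_plant = c("F9-R9" = "F1-R2")),
                     withr::local_tempdir()),
    "unknown designed combo"
  )
})

test_that("abundance models and indels are exercised", {
  dir <- withr::local_tempdir()
  sim <- simulate_library(small_cfg(41, abundance = "lognormal", indel_rate = 0.01),
                          dir)
  sp <- sort_pool(sim$fastq[["pool1"]], sim$design, "pool1")
  expect_identical(sp$n_input, 200L)
  expect_identical(sp$n_input, sp$n_sorted + sp$n_discarded)
  # indels produce inserts whose length differs from the references
  lens <- unique(nchar(sp$seqs$sequence))
  expect_gt(length(lens), 1)
})
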