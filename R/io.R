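# Readers for the three experiment-description text files and the sequence
# formats. The metadata files are whitespace-delimited; lines starting with
# '#' are comments; an optional header row is detected and skipped.

read_design_lines <- function(path, n_cols, what) {
  if (!file.exists(path)) abort(paste0(what, " file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(list())
  fields <- strsplit(lines, "[ \t]+")
  bad <- which(vapply(fields, length, integer(1)) != n_cols)
  if (length(bad)) {
    abort(sprintf(
      "%s file %s: expected %d whitespace-separated columns, got %d on line '%s'",
      what, path, n_cols, length(fields[[bad[1]]]), lines[bad[1]]
    ))
  }
  fields
}

#' Read a tag file
#'
#' Two whitespace-separated columns: tag id and tag sequence (plain A/C/G/T,
#' no degeneracy). An optional header row (non-DNA second column) is skipped.
#'
#' @param path Path to the tag file.
#' @return A tibble with columns `tag_id` and `sequence`.
#' @export
read_tag_file <- function(path) {
  fields <- read_design_lines(path, 2L, "tag")
  if (!length(fields)) abort(paste0("tag file is empty: ", path))
  if (!is_dna(toupper(fields[[1]][2])) && length(fields) > 1) fields <- fields[-1]
  out <- tibble(
    tag_id = vapply(fields, `[`, character(1), 1),
    sequence = toupper(vapply(fields, `[`, character(1), 2))
  )
  if (any(!is_dna(out$sequence))) {
    abort(paste0(
      "tag sequences must be plain A/C/G/T: ",
      paste(out$tag_id[!is_dna(out$sequence)], collapse = ", ")
    ))
  }
  if (anyDuplicated(out$tag_id)) {
    abort(paste0("duplicated tag id(s): ",
                 paste(unique(out$tag_id[duplicated(out$tag_id)]), collapse = ", ")))
  }
  if (anyDuplicated(out$sequence)) {
    abort(paste0("duplicated tag sequence(s): ",
                 paste(unique(out$sequence[duplicated(out$sequence)]), collapse = ", ")))
  }
  out
}

#' Read a primer file
#'
#' Three whitespace-separated columns: barcode name, forward primer, reverse
#' primer. IUPAC degeneracy codes are allowed in the primers. Several rows
#' describe a multiplexed PCR.
#'
#' @param path Path to the primer file.
#' @return A tibble with columns `barcode`, `forward` and `reverse`.
#' @export
read_primer_file <- function(path) {
  fields <- read_design_lines(path, 3L, "primer")
  if (!length(fields)) abort(paste0("primer file is empty: ", path))
  hdr <- !(is_iupac_dna(toupper(fields[[1]][2])) && is_iupac_dna(toupper(fields[[1]][3])))
  if (hdr && length(fields) > 1) fields <- fields[-1]
  out <- tibble(
    barcode = vapply(fields, `[`, character(1), 1),
    forward = toupper(vapply(fields, `[`, character(1), 2)),
    reverse = toupper(vapply(fields, `[`, character(1), 3))
  )
  ok <- is_iupac_dna(out$forward) & is_iupac_dna(out$reverse)
  if (any(!ok)) {
    abort(paste0("primer sequences must be IUPAC DNA: ",
                 paste(out$barcode[!ok], collapse = ", ")))
  }
  out
}

#' Read a PCR design file
#'
#' Four whitespace-separated columns: sample name, forward tag id, reverse
#' tag id, pool id -- one row per PCR replicate. When `tag_ids` is supplied,
#' a first row whose tag columns match no known tag id while all other rows
#' do is treated as a header and skipped.
#'
#' @param path Path to the PCR design file.
#' @param tag_ids Optional character vector of valid tag ids, used for
#'   header detection.
#' @return A tibble with columns `sample`, `fwd_tag`, `rev_tag`, `pool`.
#' @export
read_pcr_file <- function(path, tag_ids = NULL) {
  fields <- read_design_lines(path, 4L, "PCR design")
  if (!length(fields)) abort(paste0("PCR design file is empty: ", path))
  out <- tibble(
    sample = vapply(fields, `[`, character(1), 1),
    fwd_tag = vapply(fields, `[`, character(1), 2),
    rev_tag = vapply(fields, `[`, character(1), 3),
    pool = vapply(fields, `[`, character(1), 4)
  )
  if (!is.null(tag_ids) && nrow(out) > 1) {
    first_bad <- !(out$fwd_tag[1] %in% tag_ids) && !(out$rev_tag[1] %in% tag_ids)
    rest_ok <- all(out$fwd_tag[-1] %in% tag_ids) && all(out$rev_tag[-1] %in% tag_ids)
    if (first_bad && rest_ok) out <- out[-1, ]
  }
  out
}

#' Load and validate a full library design
#'
#' Reads the PCR design, tag and primer files, cross-validates them (every
#' tag id known, unique (forward tag, reverse tag, pool) triples, the same
#' number of PCR replicates for every sample) and infers the replicate count.
#' Validation is insensitive to the row order of the files; the replicate
#' index of each PCR follows the design file's row order within its sample.
#'
#' @param pcr_file,tag_file,primer_file Paths to the three design files.
#' @return A `tag_design` object: a list with tibbles `tags`, `primers`,
#'   `pcrs` (with added `replicate` and `combo` columns), the inferred
#'   `replicates_per_sample`, and the pool labels.
#' @export
load_design <- function(pcr_file, tag_file, primer_file) {
  tags <- read_tag_file(tag_file)
  primers <- read_primer_file(primer_file)
  pcrs <- read_pcr_file(pcr_file, tag_ids = tags$tag_id)

  unknown <- setdiff(unique(c(pcrs$fwd_tag, pcrs$rev_tag)), tags$tag_id)
  if (length(unknown)) {
    abort(paste0("unknown tag id(s) in PCR design file: ", paste(unknown, collapse = ", ")))
  }
  key <- paste(pcrs$fwd_tag, pcrs$rev_tag, pcrs$pool, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    abort(paste0(
      "duplicate (forward tag, reverse tag, pool) assignment(s): ",
      paste(gsub("\r", "/", dup), collapse = ", ")
    ))
  }
  reps <- table(pcrs$sample)
  if (length(unique(as.integer(reps))) > 1) {
    abort(paste0(
      "unequal replicate counts per sample: ",
      paste(sprintf("%s=%d", names(reps), as.integer(reps)), collapse = ", ")
    ))
  }
  pcrs$replicate <- stats::ave(seq_len(nrow(pcrs)), pcrs$sample, FUN = seq_along)
  pcrs$combo <- combo_id(pcrs$fwd_tag, pcrs$rev_tag)

  structure(
    list(
      tags = tags,
      primers = primers,
      pcrs = pcrs,
      replicates_per_sample = as.integer(reps[1]),
      pools = unique(pcrs$pool)
    ),
    class = "tag_design"
  )
}

#' @export
print.tag_design <- function(x, ...) {
  cat(sprintf(
    "<tag_design> %d samples x %d PCR replicates, %d pools, %d tags, %d primer set(s)\n",
    length(unique(x$pcrs$sample)), x$replicates_per_sample,
    length(x$pools), nrow(x$tags), nrow(x$primers)
  ))
  cat(sprintf("  %d designed tag combinations\n", nrow(x$pcrs)))
  invisible(x)
}

#' Read a FASTQ file
#'
#' Standard 4-line records; quality is carried through but not used by any
#' downstream step. Sequences are uppercased on ingest. A malformed record
#' (line-count desynchronisation, missing '@' or '+') raises an error naming
#' the first offending record.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return A tibble with columns `read_id`, `sequence`, `quality`; zero rows
#'   for an empty file.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTQ file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  empty <- tibble(read_id = character(), sequence = character(), quality = character())
  if (!length(lines)) return(empty)
  n4 <- length(lines) %/% 4
  if (n4 > 0) {
    hd <- lines[seq_len(n4) * 4L - 3L]
    pl <- lines[seq_len(n4) * 4L - 1L]
    bad <- which(!(startsWith(hd, "@") & startsWith(pl, "+")))
    if (length(bad)) {
      abort(sprintf("malformed FASTQ record %d in %s", bad[1], path))
    }
  }
  if (length(lines) %% 4L != 0L) {
    abort(sprintf("malformed FASTQ record %d in %s (truncated record)", n4 + 1L, path))
  }
  sq <- toupper(lines[seq_len(n4) * 4L - 2L])
  ql <- lines[seq_len(n4) * 4L]
  short <- which(nchar(sq) != nchar(ql))
  if (length(short)) {
    abort(sprintf("malformed FASTQ record %d in %s (sequence/quality length differ)",
                  short[1], path))
  }
  tibble(read_id = substring(lines[seq_len(n4) * 4L - 3L], 2), sequence = sq, quality = ql)
}

write_fastq <- function(records, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(records)))
  lines <- as.vector(rbind(
    paste0("@", records$read_id), records$sequence, "+", records$quality
  ))
  writeLines(lines, path)
  invisible(path)
}

#' Write a FASTA file
#'
#' One record per row, in input order (bit-stable output). Headers must be
#' unique.
#'
#' @param records A data frame with columns `header` and `sequence`, or a
#'   named character vector (names become headers).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    records <- tibble(header = names(records), sequence = unname(records))
  }
  stopifnot(all(c("header", "sequence") %in% names(records)))
  if (anyDuplicated(records$header)) {
    abort("FASTA headers must be unique")
  }
  if (!nrow(records)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  writeLines(as.vector(rbind(paste0(">", records$header), records$sequence)), path)
  invisible(path)
}

#' Read a FASTA file
#'
#' Multi-line sequences are concatenated; empty sequences are allowed.
#'
#' @param path Path to an uncompressed FASTA file.
#' @return A tibble with columns `header` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(tibble(header = character(), sequence = character()))
  h <- startsWith(lines, ">")
  if (!h[1]) abort(paste0("malformed FASTA (no leading '>'): ", path))
  grp <- cumsum(h)
  headers <- substring(lines[h], 2)
  sq <- rep("", length(headers))
  nh <- which(!h)
  if (length(nh)) {
    pieces <- vapply(split(lines[nh], grp[nh]), paste, character(1), collapse = "")
    sq[as.integer(names(pieces))] <- pieces
  }
  tibble(header = headers, sequence = toupper(sq))
}
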