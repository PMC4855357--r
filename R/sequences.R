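# Low-level sequence utilities shared by all stages.

# IUPAC nucleotide codes -> the set of plain bases each one stands for.
IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)
IUPAC_SETS <- strsplit(IUPAC_CODES, "")

# complement map covering all IUPAC codes
COMP_FROM <- "ACGTRYSWKMBDHVN"
COMP_TO <- "TGCAYRSWMKVHDBN"

#' Reverse-complement DNA sequences
#'
#' Vectorised over its input; handles IUPAC degeneracy codes (e.g. `W` maps
#' to `W`, `R` to `Y`). Input is uppercased first.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAW"))
revcomp <- function(x) {
  stringi::stri_reverse(chartr(COMP_FROM, COMP_TO, toupper(x)))
}

is_dna <- function(x) grepl("^[ACGT]+$", x)
is_iupac_dna <- function(x) grepl("^[ACGTRYSWKMBDHVN]+$", x)

# Count, per read, the mismatches of `primer` (IUPAC allowed) placed at
# 1-based offset `start` (vectorised over reads and starts). A read base
# matches when it is in the primer code's degeneracy set.
primer_mismatches <- function(seqs, primer, start) {
  pc <- strsplit(primer, "")[[1]]
  mm <- integer(length(seqs))
  for (j in seq_along(pc)) {
    allowed <- IUPAC_SETS[[pc[j]]]
    if (is.null(allowed)) abort(paste0("invalid primer character: ", pc[j]))
    base <- substr(seqs, start + j - 1L, start + j - 1L)
    mm <- mm + !(base %in% allowed)
  }
  mm
}

random_dna <- function(n, len) {
  vapply(
    seq_len(n),
    function(i) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1)
  )
}

# Realise a (possibly degenerate) primer into n concrete sequences, sampling
# each degenerate position independently per copy.
realize_iupac <- function(seq, n) {
  ch <- strsplit(seq, "")[[1]]
  deg <- which(!(ch %in% c("A", "C", "G", "T")))
  out <- rep(seq, n)
  for (j in deg) {
    substr(out, j, j) <- sample(IUPAC_SETS[[ch[j]]], n, replace = TRUE)
  }
  out
}

# Apply k distinct substitution errors to a single sequence.
mutate_seq <- function(s, k) {
  L <- nchar(s)
  k <- min(k, L)
  pos <- sample.int(L, k)
  for (p in pos) {
    cur <- substr(s, p, p)
    substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
  }
  s
}

combo_id <- function(fwd_tag, rev_tag) paste0("F", fwd_tag, "-R", rev_tag)

split_combo <- function(combo) {
  m <- regmatches(combo, regexec("^F(.+?)-R(.+)$", combo))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    abort(paste0("malformed tag combination id(s): ", paste(combo[bad], collapse = ", ")))
  }
  tibble(
    fwd_tag = vapply(m, `[`, character(1), 2),
    rev_tag = vapply(m, `[`, character(1), 3)
  )
}
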