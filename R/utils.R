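#' @useDynLib estpipe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance
#' @import dplyr
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage-specific child seed from a global seed
#'
#' One global seed fans out to per-stage seeds by hashing a stable stage
#' tag, so that each pipeline stage is individually reproducible.
#'
#' @param seed Integer global seed.
#' @param tag Character stage label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  p <- 2147483647  # 2^31 - 1
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 131 + k) %% p
  as.integer((abs(seed) %% p * 48271 + h) %% p)
}

#' Reverse complement of nucleotide strings
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Translate DNA (character vector, length divisible by 3 not required:
# trailing partial codon dropped). Ambiguous codons become X.
translate_dna <- function(x) {
  if (length(x) == 0) return(character(0))
  x <- substr(x, 1, nchar(x) - nchar(x) %% 3)
  x[nchar(x) == 0] <- ""
  out <- character(length(x))
  nz <- nchar(x) > 0
  if (any(nz)) {
    out[nz] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(x[nz]),
      if.fuzzy.codon = "X", no.init.codon = TRUE))
  }
  out
}

#' Pooled GC fraction of a set of sequences
#'
#' (G+C)/(A+C+G+T) pooled over all sequences; ambiguity codes are excluded
#' from both numerator and denominator.
#'
#' @param seqs Character vector of nucleotide sequences.
#' @return A single numeric fraction (NaN on an empty pool).
#' @export
gc_fraction <- function(seqs) {
  if (length(seqs) == 0 || sum(nchar(seqs)) == 0) return(NaN)
  f <- Biostrings::letterFrequency(
    Biostrings::DNAStringSet(toupper(seqs)), letters = c("A", "C", "G", "T"))
  tot <- colSums(f)
  unname((tot["C"] + tot["G"]) / sum(tot))
}

# iid random DNA at a GC target (vectorised over lengths)
random_dna <- function(lens, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(lens, function(n) {
    if (n <= 0) return("")
    paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

# encode DNA string(s) to integer vectors 1..5 (A C G T other)
dna_to_int <- function(s) {
  v <- match(strsplit(toupper(s), "")[[1]], BASES)
  v[is.na(v)] <- 5L
  v
}

aa_to_int <- function(s) {
  v <- match(strsplit(toupper(s), "")[[1]], AA_ALPHABET)
  v[is.na(v)] <- 23L  # unknown -> X
  v
}

# nucleotide scoring matrix for overlap alignment (match/mismatch), with a
# 5th row/column for non-ACGT symbols (scored as mismatch)
nt_submat <- function(match = 1, mismatch = -2) {
  m <- matrix(mismatch, 5, 5)
  diag(m)[1:4] <- match
  m[5, 5] <- mismatch
  m
}

# BLOSUM62 extended to the 24-letter alphabet used by aa_to_int
aa_submat <- function(name = "BLOSUM62") {
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(name, envir = e)) {
    stop("unknown substitution matrix: ", name)
  }
  b <- get(name, envir = e)
  m <- matrix(-4, length(AA_ALPHABET), length(AA_ALPHABET),
              dimnames = list(AA_ALPHABET, AA_ALPHABET))
  common <- intersect(rownames(b), AA_ALPHABET)
  m[common, common] <- b[common, common]
  m
}

#' Read a FASTA file into a tibble
#' @param path FASTA file path.
#' @return A tibble with columns `id` (first word of the header) and `seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  tibble(id = sub("\\s.*$", "", names(x)),
         seq = unname(as.character(x)))
}

#' Write sequences to FASTA
#' @param df Data frame with id and sequence columns.
#' @param path Output path.
#' @param id,seq Column names holding identifiers and sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(df, path, id = "id", seq = "seq") {
  x <- Biostrings::BStringSet(df[[seq]])
  names(x) <- df[[id]]
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Sidecar quality file: ">id" header lines followed by whitespace-separated
# phred integers (one record per read, wrapped arbitrarily).
write_qual <- function(df, path, id = "read_id", qual = "qual") {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(df))) {
    q <- df[[qual]][[i]]
    writeLines(paste0(">", df[[id]][i]), con)
    if (length(q)) writeLines(paste(q, collapse = " "), con)
  }
  invisible(path)
}

read_qual <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  grp <- cumsum(hdr)
  ids <- sub("^>", "", lines[hdr])
  vals <- split(lines[!hdr], grp[!hdr])
  qual <- lapply(seq_along(ids), function(i) {
    v <- vals[[as.character(i)]]
    if (is.null(v)) return(integer(0))
    as.integer(strsplit(paste(v, collapse = " "), "\\s+")[[1]])
  })
  tibble(read_id = ids, qual = qual)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
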