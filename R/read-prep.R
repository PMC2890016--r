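# Read cleaning: end-anchored adapter removal, windowed quality trimming,
# DUST-style low-complexity masking and a minimum-length filter.

hamming_le <- function(a, b, maxmm) {
  # both same length
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]) <= maxmm
}

strip_adapter_ends <- function(seq, adapters, maxmm) {
  left <- 0L; right <- 0L
  repeat {
    hit <- FALSE
    for (ad in adapters) {
      la <- nchar(ad)
      if (la == 0 || nchar(seq) < la) next
      if (hamming_le(substr(seq, 1, la), ad, maxmm)) {
        seq <- substr(seq, la + 1, nchar(seq)); left <- left + la
        hit <- TRUE
      }
      if (nchar(seq) >= la &&
          hamming_le(substr(seq, nchar(seq) - la + 1, nchar(seq)), ad,
                     maxmm)) {
        seq <- substr(seq, 1, nchar(seq) - la); right <- right + la
        hit <- TRUE
      }
    }
    if (!hit) break
  }
  list(seq = seq, left = left, right = right)
}

# windowed mean-quality trim: returns kept 1-based [from, to], or NULL
quality_keep_range <- function(q, window, floor) {
  n <- length(q)
  if (n == 0) return(NULL)
  if (n < window) {
    return(if (mean(q) >= floor) c(1L, n) else NULL)
  }
  means <- as.numeric(stats::filter(q, rep(1 / window, window),
                                    sides = 1))[window:n]
  # means[i] = mean of q[i .. i+window-1] for i = 1 .. n-window+1
  ok <- which(means >= floor)
  if (!length(ok)) return(NULL)
  from <- min(ok)
  to <- max(ok) + window - 1L
  c(as.integer(from), as.integer(to))
}

#' Trim and filter reads
#'
#' Removes end-anchored adapter occurrences (Hamming distance up to
#' `max_adapter_mismatch`), trims low-quality ends with a sliding-window
#' mean-phred rule, and discards reads shorter than `min_len` after
#' trimming. The kept sequence is always a contiguous substring of the
#' input, and each verdict depends only on the read itself.
#'
#' @param reads Tibble with `read_id`, `seq` and optionally `qual`
#'   (list column of per-base phred integers; `NULL` entries skip quality
#'   trimming).
#' @param params A [trim_params()] object.
#' @return The input tibble with trimmed `seq`/`qual` plus audit columns
#'   `trim_left`, `trim_right` (bases removed) and `verdict`
#'   (`"pass"`/`"discard"`). Discarded reads are retained as rows so the
#'   audit log is complete; filter on `verdict` to drop them.
#' @export
trim_reads <- function(reads, params) {
  stopifnot(inherits(params, "trim_params"))
  has_qual <- "qual" %in% names(reads)
  n <- nrow(reads)
  out_seq <- character(n); tl <- integer(n); tr <- integer(n)
  verdict <- character(n)
  out_qual <- if (has_qual) vector("list", n) else NULL
  for (i in seq_len(n)) {
    s <- toupper(reads$seq[i])
    q <- if (has_qual) reads$qual[[i]] else NULL
    if (!is.null(q) && length(q) && length(q) != nchar(s)) {
      stop("quality/sequence length mismatch for read ", reads$read_id[i])
    }
    st <- strip_adapter_ends(s, params$adapters,
                             params$max_adapter_mismatch)
    s <- st$seq
    if (!is.null(q) && length(q)) {
      q <- q[seq.int(st$left + 1, length.out = nchar(s))]
      kr <- quality_keep_range(q, params$quality_window,
                               params$quality_floor)
      if (is.null(kr)) {
        s <- ""; q <- integer(0)
        st$left <- st$left  # whole read dropped by quality
      } else {
        st$left <- st$left + kr[1] - 1L
        st$right <- st$right + (nchar(s) - kr[2])
        s <- substr(s, kr[1], kr[2])
        q <- q[kr[1]:kr[2]]
      }
    }
    out_seq[i] <- s
    if (has_qual) out_qual[[i]] <- q
    tl[i] <- st$left; tr[i] <- st$right
    verdict[i] <- if (nchar(s) >= params$min_len) "pass" else "discard"
  }
  reads$seq <- out_seq
  if (has_qual) reads$qual <- out_qual
  reads$trim_left <- tl
  reads$trim_right <- tr
  reads$verdict <- verdict
  reads
}

#' DUST-style low-complexity score of a sequence window
#'
#' Sum over distinct triplets of `c*(c-1)/2`, divided by the number of
#' overlapping triplet positions in the window.
#'
#' @param seq A single sequence (any case).
#' @return Numeric score (0 for windows shorter than 3 nt).
#' @export
dust_score <- function(seq) {
  s <- toupper(seq)
  L <- nchar(s)
  if (L < 3) return(0)
  tri <- substring(s, 1:(L - 2), 3:L)
  cnt <- table(tri)
  sum(cnt * (cnt - 1) / 2) / (L - 2)
}

#' Mask low-complexity regions
#'
#' Slides half-overlapping windows across the sequence; windows whose
#' DUST-style score exceeds the threshold are lowercased. Length is
#' preserved and the operation is idempotent (scores are computed
#' case-insensitively).
#'
#' @param seq A single nucleotide sequence.
#' @param params A [trim_params()] (uses `dust_threshold`, `dust_window`).
#' @return The sequence with masked regions in lowercase.
#' @export
mask_low_complexity <- function(seq, params = trim_params()) {
  s <- toupper(seq)
  L <- nchar(s)
  w <- params$dust_window
  if (L < 3) return(seq)
  starts <- unique(c(seq(1, max(1, L - w + 1), by = max(1, w %/% 2)),
                     max(1, L - w + 1)))
  mask <- rep(FALSE, L)
  for (st in starts) {
    en <- min(L, st + w - 1)
    if (dust_score(substr(s, st, en)) > params$dust_threshold) {
      mask[st:en] <- TRUE
    }
  }
  if (!any(mask)) return(s)
  ch <- strsplit(s, "")[[1]]
  ch[mask] <- tolower(ch[mask])
  paste(ch, collapse = "")
}
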