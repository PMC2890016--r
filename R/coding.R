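# Hexamer log-odds coding model and a frameshift-aware dynamic program
# that locates the best-scoring coding segment in six frames.

ALL_HEXAMERS <- local({
  g <- expand.grid(b6 = BASES, b5 = BASES, b4 = BASES, b3 = BASES,
                   b2 = BASES, b1 = BASES, stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3, g$b4, g$b5, g$b6)  # ACGT lexicographic order
})

hexamer_counts_phased <- function(seqs) {
  x <- Biostrings::DNAStringSet(toupper(seqs))
  out <- matrix(0, 4096, 3, dimnames = list(ALL_HEXAMERS, NULL))
  for (p in 0:2) {
    long <- x[Biostrings::width(x) >= p + 6]
    if (length(long) == 0) next
    sub <- Biostrings::subseq(long, start = p + 1)
    cnt <- Biostrings::oligonucleotideFrequency(sub, width = 6, step = 3)
    out[, p + 1] <- colSums(cnt)
  }
  out
}

hexamer_counts_flat <- function(seqs) {
  x <- Biostrings::DNAStringSet(toupper(seqs))
  x <- x[Biostrings::width(x) >= 6]
  if (length(x) == 0) return(stats::setNames(rep(0, 4096), ALL_HEXAMERS))
  colSums(Biostrings::oligonucleotideFrequency(x, width = 6, step = 1))
}

#' Train a phase-aware hexamer coding model
#'
#' Log-odds of hexamer frequencies in coding sequence (per codon phase)
#' against a phase-free background, with pseudocount smoothing so that
#' hexamers absent from both classes score 0 and none score +/-Inf.
#'
#' @param cds_sequences Character vector of in-frame coding sequences
#'   (each starting at a codon boundary).
#' @param background_sequences Character vector of non-coding/background
#'   sequences.
#' @param pseudocount Added to every hexamer count (default 1).
#' @return A `coding_model`: 4096 x 3 log-odds matrix plus metadata.
#' @export
train_hexamer_model <- function(cds_sequences, background_sequences,
                                pseudocount = 1) {
  if (length(cds_sequences) == 0 || sum(nchar(cds_sequences)) == 0) {
    stop("empty coding training class")
  }
  if (length(background_sequences) == 0 ||
      sum(nchar(background_sequences)) == 0) {
    stop("empty background training class")
  }
  if (sum(nchar(cds_sequences)) < 1e4 ||
      sum(nchar(background_sequences)) < 1e4) {
    warning("fewer than 10 kb of training sequence in a class; ",
            "hexamer estimates will be noisy")
  }
  cc <- hexamer_counts_phased(cds_sequences)
  bc <- hexamer_counts_flat(background_sequences)
  fc <- sweep(cc + pseudocount, 2, colSums(cc) + pseudocount * 4096, "/")
  fb <- (bc + pseudocount) / (sum(bc) + pseudocount * 4096)
  logodds <- log(fc) - log(fb)
  dimnames(logodds) <- list(ALL_HEXAMERS, paste0("phase", 0:2))
  structure(list(logodds = logodds, pseudocount = pseudocount,
                 trained_on = sprintf(
                   "%d coding (%d nt) vs %d background (%d nt) sequences",
                   length(cds_sequences), sum(nchar(cds_sequences)),
                   length(background_sequences),
                   sum(nchar(background_sequences)))),
            class = "coding_model")
}

#' @export
print.coding_model <- function(x, ...) {
  cat("Phase-aware hexamer coding model\n")
  cat("  trained on:", x$trained_on, "\n")
  cat("  log-odds range:",
      sprintf("[%.2f, %.2f]", min(x$logodds), max(x$logodds)), "\n")
  invisible(x)
}

#' @export
tidy.coding_model <- function(x, ...) {
  as_tibble(x$logodds, rownames = "hexamer") |>
    tidyr::pivot_longer(dplyr::starts_with("phase"), names_to = "phase",
                        names_prefix = "phase", values_to = "log_odds") |>
    mutate(phase = as.integer(.data$phase))
}

#' @export
glance.coding_model <- function(x, ...) {
  tibble(n_hexamers = nrow(x$logodds), pseudocount = x$pseudocount,
         min_log_odds = min(x$logodds), max_log_odds = max(x$logodds),
         trained_on = x$trained_on)
}

STOP_CODES <- local({
  # integer codes of TAA, TAG, TGA with A=0..T=3, code = 16*b1+4*b2+b3
  v <- vapply(c("TAA", "TAG", "TGA"), function(cd) {
    b <- match(strsplit(cd, "")[[1]], BASES) - 1L
    16L * b[1] + 4L * b[2] + b[3]
  }, integer(1))
  unname(v)
})

# per-position, per-frame score contributions on one strand:
# rows f0 = 0..2 (frame offset), cols p0 = 0..P-1 (hexamer start).
# contribution = log-odds of the hexamer at phase (p0 - f0) mod 3, minus
# the stop penalty at in-frame stop codons; non-ACGT positions score 0.
coding_contrib <- function(seq, model, stop_penalty = 100) {
  v <- dna_to_int(seq) - 1L  # 0..3, 4 = other
  n <- length(v)
  P <- n - 5L
  if (P < 1) return(NULL)
  idx <- seq_len(P)
  bad <- v >= 4L
  vv <- ifelse(bad, 0L, v)
  hex <- 1024L * vv[idx] + 256L * vv[idx + 1] + 64L * vv[idx + 2] +
    16L * vv[idx + 3] + 4L * vv[idx + 4] + vv[idx + 5]
  anybad <- bad[idx] | bad[idx + 1] | bad[idx + 2] | bad[idx + 3] |
    bad[idx + 4] | bad[idx + 5]
  cod <- 16L * vv[idx] + 4L * vv[idx + 1] + vv[idx + 2]
  codbad <- bad[idx] | bad[idx + 1] | bad[idx + 2]
  is_stop <- !codbad & cod %in% STOP_CODES
  contrib <- matrix(0, 3, P)
  for (f0 in 0:2) {
    ph <- ((idx - 1L) - f0) %% 3L
    sc <- model$logodds[cbind(hex + 1L, ph + 1L)]
    sc[anybad] <- 0
    sc <- sc - ifelse(ph == 0L & is_stop, stop_penalty, 0)
    contrib[f0 + 1, ] <- sc
  }
  contrib
}

# best local frame path on one strand: DP over 3 frame states with a
# penalty on frame switches; returns score, 0-based hexamer interval,
# frame path and frameshift count
coding_dp_strand <- function(contrib, frameshift_penalty) {
  P <- ncol(contrib)
  V <- matrix(-Inf, 3, P)
  FROM <- matrix(0L, 3, P)  # 0 = fresh start, else previous frame state
  V[, 1] <- contrib[, 1]
  for (p in 2:max(2, P)) {
    if (p > P) break
    prev <- V[, p - 1]
    for (f in 1:3) {
      stay <- prev[f]
      sw <- prev[-f] - frameshift_penalty
      best_prev <- max(0, stay, sw)
      V[f, p] <- contrib[f, p] + best_prev
      FROM[f, p] <- if (best_prev == 0) 0L
        else if (best_prev == stay) f
        else (1:3)[-f][which.max(sw)]
    }
  }
  bp <- arrayInd(which.max(V), dim(V))
  bf <- bp[1]; bpos <- bp[2]
  # traceback
  frames <- integer(0)
  f <- bf; p <- bpos
  repeat {
    frames <- c(f, frames)
    pf <- FROM[f, p]
    if (p == 1 || pf == 0L) break
    f <- pf; p <- p - 1L
  }
  start <- p
  list(score = max(V), p_start = start - 1L, p_end = bpos - 1L,
       frames = frames - 1L,
       n_frameshifts = sum(diff(frames) != 0))
}

# translate a frame path into a peptide; frame switches emit 'X'
path_peptide <- function(seq, p_start, frames) {
  runs <- rle(frames)
  pep <- character(0)
  pos <- p_start  # 0-based hexamer position of the run start
  for (r in seq_along(runs$lengths)) {
    f0 <- runs$values[r]
    run_start <- pos
    run_end <- pos + runs$lengths[r] - 1L  # inclusive hexamer positions
    # first in-frame codon start at or after run_start
    c0 <- run_start + ((f0 - run_start) %% 3)
    c_end <- run_end + 5L  # last base covered by the run's hexamers
    if (c0 + 2L <= c_end) {
      nt <- substr(seq, c0 + 1L, c_end + 1L)
      pep <- c(pep, translate_dna(nt))
    }
    pos <- run_end + 1L
  }
  paste(pep, collapse = "X")
}

#' Predict the best coding segment of a sequence
#'
#' Dynamic program over three frame states per strand: within-frame moves
#' accrue phase-aware hexamer log-odds (in-frame stop codons pay a fixed
#' penalty), frame switches pay `frameshift_penalty`. The best local
#' segment per strand is found and the better strand wins; the verdict is
#' `"none"` when the best score falls below `min_score` or the segment is
#' shorter than `min_len` nt.
#'
#' @param seq A nucleotide sequence (length >= 6).
#' @param model A [train_hexamer_model()] fit.
#' @param min_score Minimum reported segment score (default 40).
#' @param min_len Minimum segment length in nt (default 150).
#' @param frameshift_penalty Cost of a frame switch (default 20).
#' @param stop_penalty Cost of an in-frame stop codon (default 100).
#' @return One-row tibble: `verdict` (`"coding"`/`"none"`), `strand`,
#'   `start`, `end` (0-based half-open on the input), `frame` (codon
#'   phase offset on the reported strand), `score`, `n_frameshifts`,
#'   `peptide` (frameshifts emit `X`).
#' @export
predict_coding <- function(seq, model, min_score = 40, min_len = 150,
                           frameshift_penalty = 20, stop_penalty = 100) {
  stopifnot(nchar(seq) >= 6)
  n <- nchar(seq)
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") toupper(seq) else revcomp(toupper(seq))
    contrib <- coding_contrib(s, model, stop_penalty)
    if (is.null(contrib)) next
    dp <- coding_dp_strand(contrib, frameshift_penalty)
    if (is.null(best) || dp$score > best$dp$score) {
      best <- list(strand = strand, dp = dp, oriented = s)
    }
  }
  dp <- best$dp
  seg_start_or <- dp$p_start
  seg_end_or <- dp$p_end + 6L
  if (best$strand == "+") {
    start <- seg_start_or; end <- seg_end_or
  } else {
    start <- n - seg_end_or; end <- n - seg_start_or
  }
  ok <- dp$score >= min_score && (seg_end_or - seg_start_or) >= min_len
  # dominant frame: the frame of most of the path's positions
  frame0 <- as.integer(names(which.max(table(dp$frames))))
  tibble(
    verdict = if (ok) "coding" else "none",
    strand = if (ok) best$strand else NA_character_,
    start = if (ok) start else NA_integer_,
    end = if (ok) end else NA_integer_,
    frame = if (ok) frame0 else NA_integer_,
    score = dp$score,
    n_frameshifts = if (ok) dp$n_frameshifts else NA_integer_,
    peptide = if (ok) path_peptide(best$oriented, dp$p_start, dp$frames)
              else NA_character_)
}

#' Classify a unigene set as coding or "no coding region detected"
#'
#' @param unigenes Tibble with `unigene_id` and `seq`.
#' @param model A [train_hexamer_model()] fit.
#' @inheritParams predict_coding
#' @return Tibble: one prediction row per unigene (see
#'   [predict_coding()]), prefixed by `unigene_id`.
#' @export
classify_unigenes <- function(unigenes, model, min_score = 40,
                              min_len = 150, frameshift_penalty = 20,
                              stop_penalty = 100) {
  if (nrow(unigenes) == 0) {
    return(tibble(unigene_id = character(0), verdict = character(0),
                  strand = character(0), start = integer(0),
                  end = integer(0), frame = integer(0), score = numeric(0),
                  n_frameshifts = integer(0), peptide = character(0)))
  }
  preds <- purrr::map(unigenes$seq, predict_coding, model = model,
                      min_score = min_score, min_len = min_len,
                      frameshift_penalty = frameshift_penalty,
                      stop_penalty = stop_penalty)
  bind_cols(tibble(unigene_id = unigenes$unigene_id), bind_rows(preds))
}

#' Coding-verdict summary counts
#'
#' @param predictions Output of [classify_unigenes()].
#' @return One-row tibble: totals, count and fraction with no coding
#'   region detected.
#' @export
coding_summary <- function(predictions) {
  n <- nrow(predictions)
  none <- sum(predictions$verdict == "none")
  tibble(n_unigenes = n, n_no_coding = none,
         frac_no_coding = if (n > 0) none / n else NaN)
}
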