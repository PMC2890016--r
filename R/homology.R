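# Seeded local protein alignment with Karlin-Altschul E-values, a full
# Smith-Waterman oracle, top-hit extraction and a 12-column tabular
# import/export adapter so external search tools can stand in.

#' Karlin-Altschul statistics for a raw alignment score
#'
#' `E = kappa * m * n * exp(-lambda * S)`;
#' `bit = (lambda * S - ln kappa) / ln 2`.
#'
#' @param score Raw alignment score(s).
#' @param m Query length (residues).
#' @param n Summed subject length (residues).
#' @param params An [aligner_params()] (for lambda and kappa).
#' @return Tibble with `bitscore` and `evalue`.
#' @export
karlin_stats <- function(score, m, n, params = aligner_params()) {
  tibble(bitscore = (params$lambda * score - log(params$kappa)) / log(2),
         evalue = params$kappa * m * n * exp(-params$lambda * score))
}

#' Exact Smith-Waterman local alignment (test oracle)
#'
#' Full affine-gap local alignment by dynamic programming. Quadratic and
#' written for verification, not throughput; sequences over 2,000
#' residues are refused.
#'
#' @param a,b Amino-acid sequences.
#' @param params An [aligner_params()].
#' @return List: `score`, 0-based half-open `a_start`/`a_end`/
#'   `b_start`/`b_end` (all 0/empty when the optimum is 0).
#' @export
smith_waterman <- function(a, b, params = aligner_params()) {
  if (nchar(a) > 2000 || nchar(b) > 2000) {
    stop("smith_waterman is a test oracle; sequences must be <= 2000 residues")
  }
  sm <- aa_submat(params$matrix_name)
  ai <- aa_to_int(a); bi <- aa_to_int(b)
  n <- length(ai); m <- length(bi)
  go <- params$gap_open; ge <- params$gap_extend
  NEG <- -1e30
  # score matrices plus propagated path-origin coordinates per state
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  oMa <- matrix(0L, n + 1, m + 1); oMb <- oMa
  oXa <- oMa; oXb <- oMa; oYa <- oMa; oYb <- oMa
  best <- 0; bi_ <- 0L; bj_ <- 0L
  for (i in seq_len(n)) {
    srow <- sm[ai[i], bi]
    for (j in seq_len(m)) {
      # X: gap in b (consume a)
      vo <- M[i, j + 1] - go - ge; ve <- X[i, j + 1] - ge
      if (vo >= ve) {
        X[i + 1, j + 1] <- vo
        oXa[i + 1, j + 1] <- oMa[i, j + 1]; oXb[i + 1, j + 1] <- oMb[i, j + 1]
      } else {
        X[i + 1, j + 1] <- ve
        oXa[i + 1, j + 1] <- oXa[i, j + 1]; oXb[i + 1, j + 1] <- oXb[i, j + 1]
      }
      # Y: gap in a (consume b)
      vo <- M[i + 1, j] - go - ge; ve <- Y[i + 1, j] - ge
      if (vo >= ve) {
        Y[i + 1, j + 1] <- vo
        oYa[i + 1, j + 1] <- oMa[i + 1, j]; oYb[i + 1, j + 1] <- oMb[i + 1, j]
      } else {
        Y[i + 1, j + 1] <- ve
        oYa[i + 1, j + 1] <- oYa[i + 1, j]; oYb[i + 1, j + 1] <- oYb[i + 1, j]
      }
      # M: aligned pair, possibly a fresh local start
      prior <- 0; oa <- i - 1L; ob <- j - 1L
      if (M[i, j] > prior) { prior <- M[i, j]; oa <- oMa[i, j]; ob <- oMb[i, j] }
      if (X[i, j] > prior) { prior <- X[i, j]; oa <- oXa[i, j]; ob <- oXb[i, j] }
      if (Y[i, j] > prior) { prior <- Y[i, j]; oa <- oYa[i, j]; ob <- oYb[i, j] }
      h <- prior + srow[j]
      M[i + 1, j + 1] <- h
      oMa[i + 1, j + 1] <- oa; oMb[i + 1, j + 1] <- ob
      if (h > best) { best <- h; bi_ <- i; bj_ <- j }
    }
  }
  if (best <= 0) {
    return(list(score = 0, a_start = 0L, a_end = 0L,
                b_start = 0L, b_end = 0L))
  }
  list(score = unname(best),
       a_start = oMa[bi_ + 1, bj_ + 1], a_end = bi_,
       b_start = oMb[bi_ + 1, bj_ + 1], b_end = bj_)
}

# protein k-mer table: tibble(id, pos (0-based), kmer)
aa_kmer_table <- function(df, k) {
  rows <- purrr::map2(df$id, df$seq, function(id, s) {
    L <- nchar(s)
    if (L < k) {
      return(tibble(id = character(0), pos = integer(0),
                    kmer = character(0)))
    }
    tibble(id = id, pos = 0:(L - k),
           kmer = substring(s, 1:(L - k + 1), k:L))
  })
  bind_rows(rows)
}

empty_hits <- function() {
  tibble(query = character(0), subject = character(0),
         identity = numeric(0), length = integer(0),
         mismatches = integer(0), gapopens = integer(0),
         qstart = integer(0), qend = integer(0),
         sstart = integer(0), send = integer(0),
         evalue = numeric(0), bitscore = numeric(0),
         score = numeric(0), frame = integer(0))
}

# six-frame translations of nucleotide queries:
# tibble(id, frame, seq) where frame is +1..+3 / -1..-3
six_frame <- function(df) {
  out <- list()
  for (f in 1:3) {
    fwd <- substr(df$seq, f, nchar(df$seq))
    out[[length(out) + 1]] <- tibble(id = df$id, frame = f,
                                     seq = translate_dna(fwd))
    rev <- substr(revcomp(df$seq), f, nchar(df$seq))
    out[[length(out) + 1]] <- tibble(id = df$id, frame = -f,
                                     seq = translate_dna(rev))
  }
  bind_rows(out) |> filter(nchar(.data$seq) > 0)
}

#' Seeded local homology search
#'
#' Exact k-mer word matches define diagonals; diagonals carrying two
#' seeds within `two_hit_window` of each other are extended by banded
#' affine-gap local alignment. The best local alignment per
#' query-subject pair is reported when its E-value is at most
#' `evalue_cutoff`. In translated mode nucleotide queries are searched in
#' all six frames and the best frame is reported, with query coordinates
#' mapped back to the nucleotide sequence.
#'
#' @param queries,subjects Tibbles with `id` and `seq` columns (amino
#'   acids; nucleotides for queries in translated mode).
#' @param mode `"prot_prot"` or `"transl_prot"`.
#' @param params An [aligner_params()].
#' @return A hit tibble: query, subject, identity fraction, aligned
#'   columns, mismatches, gap opens, 0-based half-open query and subject
#'   coordinates, E-value, bit score, raw score and frame (`NA` in
#'   protein mode).
#' @export
search_homologs <- function(queries, subjects,
                            mode = c("prot_prot", "transl_prot"),
                            params = aligner_params()) {
  mode <- match.arg(mode)
  stopifnot(nrow(queries) > 0, nrow(subjects) > 0)
  sm <- aa_submat(params$matrix_name)
  k <- params$seed_k

  if (mode == "transl_prot") {
    nt_len <- stats::setNames(nchar(queries$seq), queries$id)
    prot_q <- six_frame(queries) |>
      mutate(qkey = paste0(.data$id, "|", .data$frame))
    qtab <- tibble(id = prot_q$qkey, seq = prot_q$seq)
    frame_of <- stats::setNames(prot_q$frame, prot_q$qkey)
    orig_of <- stats::setNames(prot_q$id, prot_q$qkey)
  } else {
    qtab <- queries[, c("id", "seq")]
  }
  qseq <- stats::setNames(qtab$seq, qtab$id)
  sseq <- stats::setNames(subjects$seq, subjects$id)
  n_total <- sum(nchar(subjects$seq))

  qk <- aa_kmer_table(qtab, k)
  sk <- aa_kmer_table(subjects[, c("id", "seq")], k)
  if (nrow(qk) == 0 || nrow(sk) == 0) return(empty_hits())
  shared <- inner_join(rename(qk, query = "id", qpos = "pos"),
                       rename(sk, subject = "id", spos = "pos"),
                       by = "kmer", relationship = "many-to-many")
  if (nrow(shared) == 0) return(empty_hits())

  cand_diags <- shared |>
    mutate(diag = .data$spos - .data$qpos) |>
    group_by(.data$query, .data$subject, .data$diag) |>
    summarise(n_seeds = dplyr::n_distinct(.data$qpos),
              span_ok = {
                qs <- sort(unique(.data$qpos))
                length(qs) >= 2 && min(diff(qs)) <= params$two_hit_window
              }, .groups = "drop") |>
    filter(.data$span_ok)
  if (nrow(cand_diags) == 0) return(empty_hits())

  pair_hits <- cand_diags |>
    group_by(.data$query, .data$subject) |>
    group_map(function(g, key) {
      a_int <- aa_to_int(qseq[[key$query]])
      b_int <- aa_to_int(sseq[[key$subject]])
      diags <- g$diag[order(-g$n_seeds)]
      cand <- integer(0)
      for (d in diags) {
        if (!length(cand) || all(abs(cand - d) > params$band)) {
          cand <- c(cand, d)
        }
        if (length(cand) >= 3) break
      }
      best <- NULL
      for (d in cand) {
        al <- cpp_align(a_int, b_int, sm, params$gap_open,
                        params$gap_extend, mode = 0L,
                        diag_lo = as.integer(d - params$band),
                        diag_hi = as.integer(d + params$band))
        if (!isTRUE(al$found)) next
        if (is.null(best) || al$score > best$score) best <- al
      }
      if (is.null(best)) return(NULL)
      ks <- karlin_stats(best$score, m = length(a_int), n = n_total,
                         params = params)
      tibble(query = key$query, subject = key$subject,
             identity = best$matches / best$cols,
             length = best$cols, mismatches = best$mismatches,
             gapopens = best$gapopens,
             qstart = best$a_start, qend = best$a_end,
             sstart = best$b_start, send = best$b_end,
             evalue = ks$evalue, bitscore = ks$bitscore,
             score = best$score, frame = NA_integer_)
    }) |>
    bind_rows()
  if (nrow(pair_hits) == 0) return(empty_hits())

  if (mode == "transl_prot") {
    pair_hits <- pair_hits |>
      mutate(frame = as.integer(unname(frame_of[.data$query])),
             orig = unname(orig_of[.data$query])) |>
      mutate(nt_len = nt_len[.data$orig],
             off = abs(.data$frame) - 1L,
             qs_nt = ifelse(.data$frame > 0,
                            .data$off + 3L * .data$qstart,
                            .data$nt_len - (.data$off + 3L * .data$qend)),
             qe_nt = ifelse(.data$frame > 0,
                            .data$off + 3L * .data$qend,
                            .data$nt_len - (.data$off + 3L * .data$qstart)),
             query = .data$orig, qstart = as.integer(.data$qs_nt),
             qend = as.integer(.data$qe_nt)) |>
      select(-"orig", -"nt_len", -"off", -"qs_nt", -"qe_nt") |>
      group_by(.data$query, .data$subject) |>
      arrange(desc(.data$score), .by_group = TRUE) |>
      slice(1) |>
      ungroup()
  }
  pair_hits |>
    filter(.data$evalue <= params$evalue_cutoff) |>
    arrange(.data$query, .data$evalue, desc(.data$bitscore), .data$subject)
}

#' Extract the best hit for one query
#'
#' Minimum E-value wins; ties break by maximum bit score, then maximum
#' identity, then lexicographically smallest subject id.
#'
#' @param hits_for_query Hit tibble rows sharing one query id.
#' @return A one-row tibble, or `NULL` for an empty input.
#' @export
top_hit <- function(hits_for_query) {
  if (is.null(hits_for_query) || nrow(hits_for_query) == 0) return(NULL)
  if (dplyr::n_distinct(hits_for_query$query) > 1) {
    stop("top_hit expects hits for a single query id")
  }
  hits_for_query |>
    arrange(.data$evalue, desc(.data$bitscore), desc(.data$identity),
            .data$subject) |>
    slice(1)
}

# vectorised top hit per query over a whole hit table
top_hits_per_query <- function(hits) {
  hits |>
    group_by(.data$query) |>
    arrange(.data$evalue, desc(.data$bitscore), desc(.data$identity),
            .data$subject, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
}

#' Export hits in 12-column tabular format
#'
#' The classic tab-separated dialect: query, subject, percent identity,
#' alignment length, mismatches, gap opens, 1-based inclusive query and
#' subject coordinates, E-value, bit score.
#'
#' @param hits A hit tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_tabular_hits <- function(hits, path) {
  out <- hits |>
    transmute(.data$query, .data$subject,
              pident = 100 * .data$identity, .data$length,
              .data$mismatches, .data$gapopens,
              qstart = .data$qstart + 1L, qend = .data$qend,
              sstart = .data$sstart + 1L, send = .data$send,
              .data$evalue, .data$bitscore)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Import 12-column tabular hits
#'
#' Coordinates are converted from 1-based inclusive to 0-based half-open
#' and percent identity to a fraction. Malformed lines raise an error
#' naming the line number.
#'
#' @param path A tab-separated file in the 12-column dialect.
#' @return A hit tibble (with `score` and `frame` set to `NA`).
#' @export
import_tabular_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12)
  if (length(bad)) {
    stop("malformed tabular hit line(s) (expected 12 columns): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  mat <- do.call(rbind, parts)
  num <- function(j, line_label) {
    v <- suppressWarnings(as.numeric(mat[, j]))
    if (anyNA(v)) {
      stop("non-numeric value in column ", j, " at line(s): ",
           paste(utils::head(which(is.na(v)), 5), collapse = ", "))
    }
    v
  }
  tibble(query = mat[, 1], subject = mat[, 2],
         identity = num(3) / 100, length = as.integer(num(4)),
         mismatches = as.integer(num(5)), gapopens = as.integer(num(6)),
         qstart = as.integer(num(7)) - 1L, qend = as.integer(num(8)),
         sstart = as.integer(num(9)) - 1L, send = as.integer(num(10)),
         evalue = num(11), bitscore = num(12),
         score = NA_real_, frame = NA_integer_)
}
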