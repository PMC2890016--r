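# Greedy overlap clustering of reads into unigenes: k-mer seeded banded
# overlap alignment, longest-first first-accept joins, majority-call
# consensus, and the two-step hybrid design (454 alone, then 454
# contigs/singletons combined with Sanger reads).

# positions (0-based) and strings of clean uppercase k-mers
seed_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(tibble(pos = integer(0), kmer = character(0)))
  km <- substring(seq, 1:(L - k + 1), k:L)
  keep <- grepl(sprintf("^[ACGT]{%d}$", k), km)
  tibble(pos = which(keep) - 1L, kmer = km[keep])
}

#' Find the best overlap between two sequences
#'
#' Shared-k-mer diagonal seeding followed by banded overlap (free
#' end-gap) alignment, in both orientations. Identity is computed over
#' the aligned columns of the overlap region only. Returns `NULL` when no
#' candidate reaches `min_overlap` aligned columns at `min_identity`.
#'
#' @param a,b Nucleotide sequences (lowercase = masked, excluded from
#'   seeding but still aligned).
#' @param params An [overlap_params()].
#' @return A one-row tibble (`length`, `identity`, `score`, `orientation`,
#'   0-based half-open coordinates on `a` and on the original `b`, and the
#'   traceback in attribute `"ops"` with `b` oriented), or `NULL`.
#' @export
find_overlap <- function(a, b, params = overlap_params()) {
  k <- params$seed_k
  if (nchar(a) < k || nchar(b) < k) return(NULL)
  ka <- seed_kmers(a, k)
  if (nrow(ka) == 0) return(NULL)
  best <- NULL
  submat <- nt_submat()
  a_int <- dna_to_int(a)
  nb <- nchar(b)
  for (orient in c("+", "-")) {
    bseq <- if (orient == "+") b else revcomp(b)
    kb <- seed_kmers(bseq, k)
    if (nrow(kb) == 0) next
    sh <- inner_join(ka, kb, by = "kmer", suffix = c("_a", "_b"),
                     relationship = "many-to-many")
    if (nrow(sh) == 0) next
    diag_counts <- sh |>
      mutate(diag = .data$pos_b - .data$pos_a) |>
      count(.data$diag, sort = TRUE)
    # collapse candidate diagonals that fall inside the same band
    cand <- integer(0)
    for (d in diag_counts$diag) {
      if (!length(cand) || all(abs(cand - d) > params$band)) {
        cand <- c(cand, d)
      }
      if (length(cand) >= 3) break
    }
    b_int <- dna_to_int(bseq)
    for (d in cand) {
      al <- cpp_align(a_int, b_int, submat, gap_open = 3, gap_ext = 1,
                      mode = 1L, diag_lo = as.integer(d - params$band),
                      diag_hi = as.integer(d + params$band))
      if (!isTRUE(al$found)) next
      if (al$cols < params$min_overlap) next
      identity <- al$matches / al$cols
      if (identity < params$min_identity) next
      if (is.null(best) || al$score > best$score) {
        rec <- tibble(
          length = al$cols, identity = identity, score = al$score,
          orientation = orient,
          a_start = al$a_start, a_end = al$a_end,
          b_start = if (orient == "+") al$b_start else nb - al$b_end,
          b_end = if (orient == "+") al$b_end else nb - al$b_start,
          b_start_oriented = al$b_start, b_end_oriented = al$b_end)
        attr(rec, "ops") <- al$ops
        best <- rec
      }
    }
  }
  best
}

# merge an oriented read into a cluster's count profile via the alignment
# traceback; interior read insertions are dropped, end overhangs extend
# the profile
merge_into_profile <- function(counts, bseq_or, ov) {
  ops <- attr(ov, "ops")
  b_int <- dna_to_int(bseq_or)
  L <- ncol(counts)
  nb <- length(b_int)
  left_ext <- NULL
  if (ov$a_start == 0 && ov$b_start_oriented > 0) {
    pre <- b_int[seq_len(ov$b_start_oriented)]
    left_ext <- matrix(0L, 5, length(pre))
    left_ext[cbind(pre, seq_along(pre))] <- 1L
  }
  right_ext <- NULL
  if (ov$a_end == L && ov$b_end_oriented < nb) {
    post <- b_int[(ov$b_end_oriented + 1):nb]
    right_ext <- matrix(0L, 5, length(post))
    right_ext[cbind(post, seq_along(post))] <- 1L
  }
  ai <- ov$a_start; bi <- ov$b_start_oriented
  for (op in ops) {
    if (op == 0L) {
      ai <- ai + 1L; bi <- bi + 1L
      counts[b_int[bi], ai] <- counts[b_int[bi], ai] + 1L
    } else if (op == 1L) {
      ai <- ai + 1L  # read deletion: no evidence for this column
    } else {
      bi <- bi + 1L  # read insertion relative to consensus: dropped
    }
  }
  cbind(left_ext, counts, right_ext)
}

profile_consensus <- function(counts, incumbent) {
  # majority base per column; ties keep the incumbent consensus base
  inc_int <- dna_to_int(incumbent)
  stopifnot(length(inc_int) == ncol(counts))
  out <- inc_int
  for (j in seq_len(ncol(counts))) {
    cj <- counts[1:4, j]
    mx <- max(cj)
    if (mx > 0 && (inc_int[j] > 4 || cj[inc_int[j]] < mx)) {
      out[j] <- which.max(cj)
    }
  }
  paste(c(BASES, "N")[out], collapse = "")
}

#' Greedy incremental clustering of sequences into unigenes
#'
#' Items are processed longest-first (ties by id) and joined to the first
#' existing cluster whose consensus yields an accepted overlap, else they
#' open a new cluster. The consensus is a per-column majority call over
#' the aligned members, ties keeping the incumbent base; reads extending
#' past the consensus extend it. Deterministic for a fixed input set.
#'
#' @param items Tibble with `id` and `seq` columns.
#' @param params An [overlap_params()].
#' @return Tibble of clusters: `cluster_id`, `consensus`, `n_members`,
#'   and a `members` list column of tibbles (`id`, `orientation`,
#'   `overlap_length`, `overlap_identity`).
#' @export
cluster_reads <- function(items, params = overlap_params()) {
  if (nrow(items) == 0) {
    return(tibble(cluster_id = integer(0), consensus = character(0),
                  n_members = integer(0), members = list()))
  }
  ord <- order(-nchar(items$seq), items$id)
  items <- items[ord, ]
  k <- params$seed_k
  kindex <- new.env(parent = emptyenv())  # kmer -> integer cluster ids
  clusters <- list()

  index_add <- function(seq, cid) {
    km <- unique(seed_kmers(seq, k)$kmer)
    for (x in km) {
      cur <- kindex[[x]]
      if (is.null(cur)) assign(x, cid, envir = kindex)
      else if (!cid %in% cur) assign(x, c(cur, cid), envir = kindex)
    }
  }
  candidates_for <- function(seq) {
    km <- unique(c(seed_kmers(seq, k)$kmer,
                   seed_kmers(revcomp(seq), k)$kmer))
    hits <- unlist(lapply(km, function(x) kindex[[x]]), use.names = FALSE)
    sort(unique(hits))
  }

  for (i in seq_len(nrow(items))) {
    id <- items$id[i]; s <- items$seq[i]
    joined <- FALSE
    for (cid in candidates_for(s)) {
      cl <- clusters[[cid]]
      ov <- find_overlap(cl$consensus, s, params)
      if (is.null(ov)) next
      bseq_or <- if (ov$orientation == "+") toupper(s)
                 else revcomp(toupper(s))
      counts <- merge_into_profile(cl$counts, bseq_or, ov)
      # incumbent consensus padded with the read's own extensions
      left_n <- if (ov$a_start == 0 && ov$b_start_oriented > 0)
        ov$b_start_oriented else 0L
      right_n <- ncol(counts) - ncol(cl$counts) - left_n
      incumbent <- paste0(
        if (left_n > 0) substr(bseq_or, 1, left_n) else "",
        toupper(cl$consensus),
        if (right_n > 0)
          substr(bseq_or, nchar(bseq_or) - right_n + 1, nchar(bseq_or))
        else "")
      cl$counts <- counts
      cl$consensus <- profile_consensus(counts, incumbent)
      cl$members <- append(cl$members, list(tibble(
        id = id, orientation = ov$orientation,
        overlap_length = ov$length, overlap_identity = ov$identity)))
      clusters[[cid]] <- cl
      index_add(cl$consensus, cid)
      joined <- TRUE
      break
    }
    if (!joined) {
      su <- toupper(s)
      v <- dna_to_int(su)
      counts <- matrix(0L, 5, length(v))
      counts[cbind(v, seq_along(v))] <- 1L
      cid <- length(clusters) + 1L
      clusters[[cid]] <- list(
        consensus = su, counts = counts,
        members = list(tibble(id = id, orientation = "+",
                              overlap_length = NA_integer_,
                              overlap_identity = NA_real_)))
      index_add(su, cid)
    }
  }
  tibble(
    cluster_id = seq_along(clusters),
    consensus = vapply(clusters, function(cl) cl$consensus, character(1)),
    n_members = vapply(clusters, function(cl) length(cl$members),
                       integer(1)),
    members = lapply(clusters, function(cl) bind_rows(cl$members)))
}

#' Two-step hybrid assembly with provenance classes
#'
#' Step 1 clusters the 454 reads alone; step 2 clusters the step-1 contigs
#' and singletons together with the raw Sanger reads. Final clusters with
#' at least two step-2 members are contigs; final singletons are labelled
#' by what the lone item was: a step-1 contig (`454-only-contig`), a
#' single 454 read (`454-single-read`) or a Sanger read (`sanger-only`).
#'
#' @param reads_454,reads_sanger Read tibbles (`read_id`, `seq`); either
#'   may be empty (zero rows).
#' @param params An [overlap_params()].
#' @return Tibble of unigenes: `unigene_id`, `seq`, `kind`
#'   (contig/singleton), `provenance`, `n_members` (step-2 items),
#'   `n_reads` (underlying raw reads) and a `members` list column of raw
#'   read ids with technology labels.
#' @export
two_step_assemble <- function(reads_454, reads_sanger,
                              params = overlap_params()) {
  empty_reads <- tibble(read_id = character(0), seq = character(0))
  if (is.null(reads_454)) reads_454 <- empty_reads
  if (is.null(reads_sanger)) reads_sanger <- empty_reads

  step1 <- cluster_reads(
    tibble(id = reads_454$read_id, seq = reads_454$seq), params)

  items <- list()
  base_reads <- list()
  if (nrow(step1) > 0) {
    for (i in seq_len(nrow(step1))) {
      mem <- step1$members[[i]]
      if (step1$n_members[i] >= 2) {
        iid <- sprintf("c454_%05d", i)
        items[[iid]] <- tibble(id = iid, seq = step1$consensus[i],
                               item_type = "contig454")
      } else {
        iid <- mem$id[1]
        items[[iid]] <- tibble(id = iid, seq = step1$consensus[i],
                               item_type = "read454")
      }
      base_reads[[iid]] <- tibble(read_id = mem$id, technology = "flx454")
    }
  }
  if (nrow(reads_sanger) > 0) {
    for (i in seq_len(nrow(reads_sanger))) {
      iid <- reads_sanger$read_id[i]
      items[[iid]] <- tibble(id = iid, seq = reads_sanger$seq[i],
                             item_type = "sanger")
      base_reads[[iid]] <- tibble(read_id = iid, technology = "sanger")
    }
  }
  item_tbl <- bind_rows(items)
  if (nrow(item_tbl) == 0) {
    return(tibble(unigene_id = character(0), seq = character(0),
                  kind = character(0), provenance = character(0),
                  n_members = integer(0), n_reads = integer(0),
                  members = list()))
  }
  step2 <- cluster_reads(select(item_tbl, "id", "seq"), params)
  type_of <- stats::setNames(item_tbl$item_type, item_tbl$id)

  out <- vector("list", nrow(step2))
  for (i in seq_len(nrow(step2))) {
    mem_ids <- step2$members[[i]]$id
    nm <- length(mem_ids)
    reads <- bind_rows(base_reads[mem_ids])
    if (nm >= 2) {
      kind <- "contig"; prov <- "contig"
    } else {
      kind <- "singleton"
      prov <- switch(type_of[[mem_ids[1]]],
                     contig454 = "454-only-contig",
                     read454 = "454-single-read",
                     sanger = "sanger-only")
    }
    out[[i]] <- tibble(
      unigene_id = sprintf("uni_%05d", i), seq = step2$consensus[i],
      kind = kind, provenance = prov, n_members = nm,
      n_reads = nrow(reads), members = list(reads))
  }
  bind_rows(out)
}

#' Summary statistics per sequence class
#'
#' Count, arithmetic mean length and pooled GC fraction (ambiguity codes
#' excluded) per group.
#'
#' @param df Tibble with a `seq` column.
#' @param group Optional grouping column name; `NULL` summarises the whole
#'   set as one class.
#' @return A tibble with `class`, `n`, `mean_length`, `gc`; zero rows for
#'   an empty input.
#' @export
assembly_stats <- function(df, group = NULL) {
  if (nrow(df) == 0) {
    return(tibble(class = character(0), n = integer(0),
                  mean_length = numeric(0), gc = numeric(0)))
  }
  cls <- if (is.null(group)) rep("all", nrow(df)) else df[[group]]
  tibble(class = cls, seq = df$seq) |>
    group_by(.data$class) |>
    summarise(n = dplyr::n(),
              mean_length = mean(nchar(.data$seq)),
              gc = gc_fraction(.data$seq), .groups = "drop")
}
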