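test_that("Karlin-Altschul statistics match the closed form", {
  p <- aligner_params(lambda = 0.267, kappa = 0.041)
  ks <- karlin_stats(40, m = 100, n = 100, params = p)
  expect_equal(ks$evalue, 0.041 * 1e4 * exp(-10.68), tolerance = 1e-12)
  expect_equal(ks$evalue, 9.4e-3, tolerance = 0.01)
  expect_equal(ks$bitscore, (0.267 * 40 - log(0.041)) / log(2))
})

test_that("E-values are monotone in score and search-space size", {
  p <- aligner_params()
  scores <- seq(20, 200, by = 10)
  es <- karlin_stats(scores, 200, 1e5, p)$evalue
  expect_true(all(diff(es) < 0))
  ns <- 10^(3:8)
  en <- karlin_stats(50, 200, ns, p)$evalue
  expect_true(all(diff(en) > 0))
})

test_that("smith_waterman scores itself as the diagonal sum and refuses
           oversize input", {
  a <- "MKWVTFISLLLLFSSAYS"
  sw <- smith_waterman(a, a)
  sm <- estpipe:::aa_submat()
  ai <- estpipe:::aa_to_int(a)
  expect_equal(sw$score, sum(sm[cbind(ai, ai)]))
  expect_equal(c(sw$a_start, sw$a_end), c(0, nchar(a)))
  expect_error(smith_waterman(strrep("A", 2001), "MK"), "2000")
})

test_that("disjoint sequences with no positive scores align to nothing", {
  # polyG vs polyL under BLOSUM62: every pairing scores negative
  sw <- smith_waterman(strrep("G", 30), strrep("L", 30))
  expect_equal(sw$score, 0)
})

test_that("smith_waterman agrees with an independent affine-gap DP", {
  set.seed(11)
  for (rep in 1:10) {
    a <- rnd_prot(sample(20:60, 1))
    b <- mutate_prot(a, sub_rate = 0.3, n_indel = sample(0:2, 1))
    mine <- smith_waterman(a, b)$score
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1)
    expect_equal(mine, Biostrings::score(ref))
  }
})

test_that("an identical protein pair yields a full-length self hit", {
  set.seed(12)
  p <- rnd_prot(100)
  hits <- search_homologs(tibble::tibble(id = "q", seq = p),
                          tibble::tibble(id = "s", seq = p),
                          params = aligner_params(evalue_cutoff = 1e9))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$identity, 1)
  expect_equal(c(hits$qstart, hits$qend), c(0, 100))
  expect_equal(hits$score, smith_waterman(p, p)$score)
})

test_that("seeded banded extension equals Smith-Waterman on seeded pairs", {
  set.seed(13)
  p <- aligner_params(evalue_cutoff = 1e9)
  n_checked <- 0
  while (n_checked < 30) {
    a <- rnd_prot(sample(60:120, 1))
    b <- mutate_prot(a, sub_rate = 0.2, n_indel = sample(0:1, 1))
    hits <- search_homologs(tibble::tibble(id = "q", seq = a),
                            tibble::tibble(id = "s", seq = b), params = p)
    if (nrow(hits) == 0) next  # no two-hit seed for this pair
    expect_equal(hits$score, smith_waterman(a, b, p)$score)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 30)
})

test_that("seeded search never exceeds the Smith-Waterman optimum", {
  set.seed(14)
  for (rep in 1:10) {
    a <- rnd_prot(80)
    b <- mutate_prot(a, sub_rate = 0.5, n_indel = 2)
    hits <- search_homologs(tibble::tibble(id = "q", seq = a),
                            tibble::tibble(id = "s", seq = b),
                            params = aligner_params(evalue_cutoff = 1e9))
    if (nrow(hits) == 1) {
      expect_lte(hits$score, smith_waterman(a, b)$score)
    }
  }
})

test_that("translated mode reports the frame that contains the peptide", {
  ts <- shared_truth()
  tr <- ts$transcripts[ts$transcripts$coding, ][1:6, ]
  prot <- ts$proteins[match(tr$transcript_id, ts$proteins$gene_id), ]
  subjects <- tibble::tibble(id = prot$gene_id,
                             seq = sub("\\*$", "", prot$seq))
  queries <- tibble::tibble(id = tr$transcript_id, seq = tr$seq)
  # also push one query onto the minus strand
  queries$seq[2] <- revcomp(queries$seq[2])
  hits <- search_homologs(queries, subjects, mode = "transl_prot")
  self <- hits[hits$query == hits$subject, ]
  expect_equal(nrow(self), 6)
  for (i in seq_len(nrow(self))) {
    q <- queries$seq[queries$id == self$query[i]]
    f <- self$frame[i]
    expect_true(f %in% c(1:3, -1:-3))
    # the aligned query interval, read in the reported frame, translates
    # into the subject protein
    nt <- substr(q, self$qstart[i] + 1, self$qend[i])
    if (f < 0) nt <- revcomp(nt)
    pep <- estpipe:::translate_dna(nt)
    sub_pep <- subjects$seq[subjects$id == self$subject[i]]
    expect_true(grepl(substr(pep, 2, 25), sub_pep, fixed = TRUE))
  }
  expect_true(hits$frame[hits$query == queries$id[2] &
                           hits$subject == queries$id[2]] < 0)
})

test_that("top_hit applies the tie-break cascade", {
  h <- tibble::tibble(
    query = "q", subject = c("s1", "s2", "s3"),
    evalue = c(1e-10, 1e-10, 1e-5),
    bitscore = c(50, 55, 80), identity = c(0.9, 0.8, 1))
  expect_equal(top_hit(h)$subject, "s2")       # min E, then max bits
  h2 <- dplyr::mutate(h, evalue = 1e-10, bitscore = 50, identity = 0.9,
                      subject = c("b", "a", "c"))
  expect_equal(top_hit(h2)$subject, "a")       # full tie -> smallest id
  expect_null(top_hit(h[0, ]))
  expect_equal(top_hit(h[1, ])$subject, "s1")  # single hit
  expect_error(top_hit(dplyr::mutate(h, query = c("q", "q", "r"))),
               "single query")
})

test_that("the 12-column tabular dialect round-trips", {
  set.seed(15)
  a <- rnd_prot(90)
  hits <- search_homologs(
    tibble::tibble(id = "q", seq = a),
    tibble::tibble(id = c("s1", "s2"),
                   seq = c(mutate_prot(a, 0.1), mutate_prot(a, 0.15))),
    params = aligner_params(evalue_cutoff = 1e9))
  path <- tempfile(fileext = ".tsv")
  export_tabular_hits(hits, path)
  back <- import_tabular_hits(path)
  for (col in c("query", "subject", "identity", "length", "mismatches",
                "gapopens", "qstart", "qend", "sstart", "send",
                "evalue", "bitscore")) {
    expect_equal(back[[col]], hits[[col]], tolerance = 1e-12)
  }
  # convention conversion on a hand-written row
  row <- "q\ts\t95.0\t100\t5\t0\t1\t100\t11\t110\t1e-30\t180"
  p2 <- tempfile(); writeLines(row, p2)
  one <- import_tabular_hits(p2)
  expect_equal(c(one$qstart, one$qend), c(0, 100))
  expect_equal(c(one$sstart, one$send), c(10, 110))
  expect_equal(one$identity, 0.95)
  # malformed input names the line
  p3 <- tempfile(); writeLines(c(row, "short\trow"), p3)
  expect_error(import_tabular_hits(p3), "12 columns")
})

test_that("unknown substitution matrices are a configuration error", {
  expect_error(
    search_homologs(tibble::tibble(id = "q", seq = "MKWVTFISLL"),
                    tibble::tibble(id = "s", seq = "MKWVTFISLL"),
                    params = aligner_params(matrix_name = "NOSUCH62")),
    "unknown substitution matrix")
})
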