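test_that("generation is deterministic and respects the zero-rate limit", {
  p0 <- generator_params(
    n_families = 6, seed = 11, paralog_rate = 0, noncoding_fraction = 0,
    divergence = c(streptophyte = 0, ref_plant = 0, charophyte = 0,
                   charoA = 0, charoB = 0, ref_chlorophyte = 0),
    presence_profile = tibble::tibble(
      subset = "ref_plant+charoA+charoB+ref_chlorophyte", prob = 1))
  a <- generate_families(p0)
  b <- generate_families(p0)
  expect_identical(a, b)
  # zero divergence: all four copies of every family share one CDS
  cds <- substr(a$transcripts$seq, a$transcripts$cds_start + 1,
                a$transcripts$cds_end)
  per_fam <- split(cds, a$transcripts$family)
  expect_true(all(vapply(per_fam, function(x)
    length(unique(x)) == 1 && length(x) == 4, logical(1))))
})

test_that("coding intervals are in-bounds, divisible by 3, and truthful", {
  ts <- shared_truth()
  cod <- ts$transcripts[ts$transcripts$coding, ]
  expect_true(all(cod$cds_start >= 0))
  expect_true(all(cod$cds_end <= nchar(cod$seq)))
  expect_true(all((cod$cds_end - cod$cds_start) %% 3 == 0))
  # translated CDS matches the stored protein (bar the stop)
  cds <- substr(cod$seq, cod$cds_start + 1, cod$cds_end)
  pep <- sub("\\*$", "", estpipe:::translate_dna(cds))
  stored <- ts$proteins$seq[match(cod$transcript_id, ts$proteins$gene_id)]
  expect_identical(pep, unname(stored))
})

test_that("realized GC tracks the target within 0.02 on >= 1 Mb", {
  p <- generator_params(n_families = 360, seed = 21, cds_len = 260,
                        gc_target = c(ref_plant = 0.49, charoA = 0.49,
                                      charoB = 0.49, ref_chlorophyte = 0.49))
  ts <- generate_families(p)
  total <- sum(nchar(ts$transcripts$seq))
  expect_gte(total, 1e6)
  expect_lt(abs(gc_fraction(ts$transcripts$seq) - 0.49), 0.02)
})

test_that("per-taxon GC targets separate the focal taxa", {
  ts <- shared_truth()
  gcs <- vapply(split(ts$transcripts$seq, ts$transcripts$species),
                gc_fraction, numeric(1))
  expect_gt(gcs[["charoA"]], gcs[["charoB"]])  # 0.49 vs 0.41 targets
})

test_that("zero-noise reads are exact substrings at truthful coordinates", {
  ts <- shared_truth()
  tr <- ts$transcripts[ts$transcripts$species == "charoA", ][1:20, ]
  m <- read_model("flx454", substitution_rate = 0,
                  homopolymer_indel_rate = 0, adapter_seq = "")
  reads <- simulate_reads(tr, m, depth = 3, seed = 9)
  expect_gt(nrow(reads), 0)
  origin <- tr$seq[match(reads$transcript_id, tr$transcript_id)]
  frag <- substr(origin, reads$origin_start + 1, reads$origin_end)
  frag[reads$orientation == "-"] <-
    revcomp(frag[reads$orientation == "-"])
  expect_identical(reads$seq, frag)
  # qualities cover every base
  expect_identical(lengths(reads$qual), nchar(reads$seq))
})

test_that("sanger model anchors every read at the transcript 5' end", {
  ts <- shared_truth()
  tr <- ts$transcripts[ts$transcripts$species == "charoB", ][1:15, ]
  reads <- simulate_reads(tr, read_model("sanger"), depth = 2, seed = 4)
  expect_true(all(reads$origin_start == 0))
  expect_true(all(reads$orientation == "+"))
})

test_that("substitution errors appear at the configured rate", {
  ts <- shared_truth()
  tr <- ts$transcripts[ts$transcripts$species == "charoA", ]
  m <- read_model("sanger", substitution_rate = 0.01, len_sd = 0)
  reads <- simulate_reads(tr, m, depth = 6, seed = 13)
  origin <- tr$seq[match(reads$transcript_id, tr$transcript_id)]
  frag <- substr(origin, reads$origin_start + 1, reads$origin_end)
  mm <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, reads$seq, frag)
  tot <- sum(nchar(frag))
  expect_gte(tot, 1e5)
  rate <- sum(mm) / tot
  expect_gte(rate, 0.008)
  expect_lte(rate, 0.012)
})

test_that("454 adapter is prepended and homopolymer runs gain/lose a base", {
  tr <- tibble::tibble(transcript_id = "t1",
                       seq = paste0(strrep("AGTC", 100), strrep("G", 8),
                                    strrep("TCCA", 100)))
  m <- read_model("flx454", substitution_rate = 0,
                  homopolymer_indel_rate = 1, len_sd = 0, mean_len = 2000,
                  five_prime_anchored = TRUE)
  reads <- simulate_reads(tr, m, depth = 0, n_reads = 5, seed = 2)
  expect_true(all(startsWith(reads$seq, m$adapter_seq)))
  core <- substring(reads$seq, nchar(m$adapter_seq) + 1)
  runs <- vapply(core, function(s) {
    r <- rle(strsplit(s, "")[[1]])
    max(r$lengths[r$values == "G"])
  }, numeric(1))
  expect_true(all(runs %in% c(7, 9)))  # the G8 run shifted by exactly 1
})

test_that("contaminant injection hits the configured fraction with truth", {
  ts <- shared_truth()
  tr <- ts$transcripts[ts$transcripts$species == "charoA", ]
  base <- simulate_reads(tr, read_model("flx454"), depth = 10000 / nrow(tr),
                         seed = 31)
  base <- base[seq_len(min(10000, nrow(base))), ]
  pool <- make_contaminant_pool(seed = 5)
  p <- generator_params(n_families = 5, contam_fraction = 0.10)
  aug <- inject_contaminants(base, p, pool, seed = 8)
  n_cont <- sum(aug$is_contaminant)
  expect_gte(n_cont, 900)
  expect_lte(n_cont, 1100)
  expect_equal(nrow(aug), nrow(base) + n_cont)  # conservation
  expect_true(all(aug$lineage_category[aug$is_contaminant] %in%
                    c("Bacteria", "Fungi", "Viruses", "Archaea",
                      "OtherEukaryotes")))
  # zero fraction is the identity
  p0 <- generator_params(n_families = 5, contam_fraction = 0)
  same <- inject_contaminants(base, p0, pool, seed = 8)
  expect_identical(same$read_id, base$read_id)
  expect_identical(same$seq, base$seq)
  # empty pool with positive fraction is a configuration error
  expect_error(inject_contaminants(base, p, pool[0, ], seed = 8),
               "empty")
})

test_that("the synthetic bundle round-trips through plain files", {
  ts <- shared_truth()
  tr <- ts$transcripts[1:10, ]
  reads <- simulate_reads(tr, read_model("sanger"), depth = 1, seed = 2)
  dir <- tempfile("bundle_")
  write_synthetic_bundle(ts, reads, dir)
  fa <- read_fasta(file.path(dir, "reads.fasta"))
  expect_identical(fa$id, reads$read_id)
  expect_identical(fa$seq, reads$seq)
  q <- estpipe:::read_qual(file.path(dir, "reads.qual"))
  expect_identical(q$qual, unname(reads$qual))
  cfg <- yaml::read_yaml(file.path(dir, "generator_config.yaml"))
  expect_equal(cfg$seed, ts$params$seed)
})

test_that("parameter validation rejects out-of-range requests", {
  expect_error(generator_params(cds_len = 0), "zero-length CDS")
  expect_error(generator_params(n_families = 0), "n_families")
  expect_error(generator_params(contam_fraction = 1.5), "probabilities")
})
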