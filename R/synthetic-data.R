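# Four-taxon synthetic transcriptome generator with planted ground truth.
#
# Gene families evolve down the fixed topology
# ((ref_plant,(charoA,charoB)),ref_chlorophyte) under a codon-level
# substitution model with a 3:1 synonymous:nonsynonymous weight, so the
# hexamer coding signal survives divergence and "closer to the plant than
# to the chlorophyte" is a planted, checkable property.

GENETIC_CODE_VEC <- Biostrings::GENETIC_CODE
CODONS <- names(GENETIC_CODE_VEC)
SENSE_CODONS <- CODONS[GENETIC_CODE_VEC != "*"]
STOP_CODONS <- setdiff(CODONS, SENSE_CODONS)

# preferred codon per amino acid: deterministic (alphabetically first);
# the strong usage bias is what gives coding sequence its hexamer signal
PREF_CODON <- local({
  aa <- GENETIC_CODE_VEC[SENSE_CODONS]
  ord <- order(aa, SENSE_CODONS)
  pref <- SENSE_CODONS[ord][!duplicated(aa[ord])]
  stats::setNames(ifelse(CODONS %in% pref, 8, 1), CODONS)
})

codon_gc_count <- function(codons) {
  vapply(strsplit(codons, ""), function(b) sum(b %in% c("G", "C")),
         numeric(1))
}
CODON_GC <- stats::setNames(codon_gc_count(CODONS), CODONS)

# single-nucleotide neighbours of every codon, with synonymy flags
NEIGHBOURS <- local({
  aa_of <- GENETIC_CODE_VEC
  lapply(stats::setNames(CODONS, CODONS), function(cd) {
    ch <- strsplit(cd, "")[[1]]
    out <- list()
    for (pos in 1:3) for (b in BASES) {
      if (b == ch[pos]) next
      nb <- ch; nb[pos] <- b
      nbc <- paste(nb, collapse = "")
      if (aa_of[nbc] == "*") next  # never mutate into a stop
      out[[length(out) + 1]] <- c(codon = nbc,
                                  syn = as.numeric(aa_of[nbc] == aa_of[cd]))
    }
    if (!length(out)) return(NULL)
    data.frame(codon = vapply(out, `[[`, "", "codon"),
               syn = as.numeric(vapply(out, `[[`, "", "syn")))
  })
})

# codon sampling weights tilted so the expected GC equals the target
codon_weights <- function(gc) {
  theta <- gc_tilt(gc)
  w <- PREF_CODON[SENSE_CODONS] * exp(theta * CODON_GC[SENSE_CODONS])
  w / sum(w)
}

gc_tilt <- function(gc) {
  f <- function(theta) {
    w <- PREF_CODON[SENSE_CODONS] * exp(theta * CODON_GC[SENSE_CODONS])
    sum(w * CODON_GC[SENSE_CODONS]) / (3 * sum(w)) - gc
  }
  stats::uniroot(f, c(-12, 12), tol = 1e-9)$root
}

# evolve a codon vector along one branch: Poisson(3 * rate) substitution
# events per codon; candidate single-nucleotide changes weighted 3:1
# synonymous:nonsynonymous and GC-tilted toward the branch target
evolve_codons <- function(codons, rate, gc) {
  if (rate <= 0) return(codons)
  theta <- gc_tilt(gc)
  nev <- stats::rpois(length(codons), 3 * rate)
  hit <- which(nev > 0 & !(codons %in% STOP_CODONS))
  for (i in hit) {
    for (k in seq_len(nev[i])) {
      nb <- NEIGHBOURS[[codons[i]]]
      if (is.null(nb)) break
      # 3:1 synonymous:nonsynonymous, tilted toward the taxon GC target;
      # among synonymous alternatives the preferred codon is favoured so
      # the usage bias (the hexamer signal) is stationary under divergence
      w <- (1 + 2 * nb$syn) *
        exp(theta * (CODON_GC[nb$codon] - CODON_GC[codons[i]])) *
        ifelse(nb$syn > 0, PREF_CODON[nb$codon], 1)
      codons[i] <- nb$codon[sample.int(nrow(nb), 1, prob = w)]
    }
  }
  codons
}

#' Generate gene families, per-species sequences and ground truth
#'
#' Draws ancestral coding sequences, evolves them independently down each
#' branch of the fixed four-taxon topology, adds paralogs and UTRs, and
#' appends non-coding transcripts, recording planted truth for every
#' record. Deterministic given `params$seed`.
#'
#' @param params A [generator_params()] object.
#' @return A list of class `est_truth_set` with tibbles `transcripts`
#'   (id, species, family, copy, seq, coding flag, 0-based half-open CDS
#'   interval, strand), `proteins` (translated CDS per coding gene) and
#'   `families` (family id, planted species subset), plus the params.
#' @export
generate_families <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  sp <- params$species_list
  with_seed(child_seed(params$seed, "families"), {
    nf <- params$n_families
    fam_ids <- sprintf("fam%04d", seq_len(nf))
    subsets <- sample(params$presence_profile$subset, nf, replace = TRUE,
                      prob = params$presence_profile$prob)
    n_codons <- pmax(60L, as.integer(round(
      stats::rnorm(nf, params$cds_len, 0.2 * params$cds_len))))
    gc_mean <- mean(params$gc_target)
    w_anc <- codon_weights(gc_mean)
    div <- params$divergence

    rows <- vector("list", nf)
    for (i in seq_len(nf)) {
      present <- strsplit(subsets[i], "+", fixed = TRUE)[[1]]
      anc <- sample(SENSE_CODONS, n_codons[i], replace = TRUE, prob = w_anc)
      # internal nodes
      node_strep <- evolve_codons(anc, div[["streptophyte"]], gc_mean)
      node_charo <- evolve_codons(node_strep, div[["charophyte"]], gc_mean)
      leaf <- list()
      if (sp[1] %in% present) {
        leaf[[sp[1]]] <- evolve_codons(node_strep, div[["ref_plant"]],
                                       params$gc_target[[sp[1]]])
      }
      if (sp[2] %in% present) {
        leaf[[sp[2]]] <- evolve_codons(node_charo, div[["charoA"]],
                                       params$gc_target[[sp[2]]])
      }
      if (sp[3] %in% present) {
        leaf[[sp[3]]] <- evolve_codons(node_charo, div[["charoB"]],
                                       params$gc_target[[sp[3]]])
      }
      if (sp[4] %in% present) {
        leaf[[sp[4]]] <- evolve_codons(anc, div[["ref_chlorophyte"]],
                                       params$gc_target[[sp[4]]])
      }
      fam_rows <- list()
      for (s in names(leaf)) {
        copies <- list(leaf[[s]])
        if (stats::runif(1) < params$paralog_rate) {
          copies[[2]] <- evolve_codons(leaf[[s]], 0.05,
                                       params$gc_target[[s]])
        }
        for (ci in seq_along(copies)) {
          fam_rows[[length(fam_rows) + 1]] <- list(
            species = s, family = fam_ids[i], copy = ci,
            cds = paste(copies[[ci]], collapse = ""))
        }
      }
      rows[[i]] <- fam_rows
    }
    genes <- bind_rows(lapply(unlist(rows, recursive = FALSE), as_tibble))

    # transcripts: 5' UTR + CDS + stop codon + 3' UTR, all on the + strand;
    # the stop codon is a family property (conserved across species)
    fam_stop <- stats::setNames(
      sample(STOP_CODONS, nf, replace = TRUE), fam_ids)
    stops <- unname(fam_stop[genes$family])
    gc_of <- params$gc_target[genes$species]
    u5 <- stats::rpois(nrow(genes), params$utr_len[["utr5"]])
    u3 <- stats::rpois(nrow(genes), params$utr_len[["utr3"]])
    utr5 <- mapply(function(n, g) random_dna(n, g), u5, gc_of)
    utr3 <- mapply(function(n, g) random_dna(n, g), u3, gc_of)
    coding <- genes |>
      mutate(
        transcript_id = paste0(.data$species, "_", .data$family,
                               ifelse(.data$copy > 1,
                                      paste0("p", .data$copy), "")),
        seq = paste0(utr5, .data$cds, stops, utr3),
        coding = TRUE,
        cds_start = nchar(utr5),
        cds_end = nchar(utr5) + nchar(.data$cds) + 3L,
        strand = "+") |>
      select("transcript_id", "species", "family", "copy", "seq",
             "coding", "cds_start", "cds_end", "strand", "cds")

    # non-coding transcripts: iid bases at the taxon GC target, so they
    # carry no hexamer signal relative to the background model
    nc <- params$noncoding_fraction
    nc_rows <- list()
    if (nc > 0) {
      for (s in sp[2:3]) {  # focal (sequenced) taxa only
        ncod <- sum(coding$species == s)
        n_nc <- round(nc / (1 - nc) * ncod)
        if (n_nc < 1) next
        lens <- pmax(150L, as.integer(round(stats::rnorm(
          n_nc, 3 * params$cds_len * 0.8, 0.25 * 3 * params$cds_len))))
        nc_rows[[s]] <- tibble(
          transcript_id = sprintf("%s_nc%04d", s, seq_len(n_nc)),
          species = s, family = NA_character_, copy = 1L,
          seq = random_dna(lens, params$gc_target[[s]]),
          coding = FALSE, cds_start = NA_integer_, cds_end = NA_integer_,
          strand = NA_character_, cds = NA_character_)
      }
    }
    transcripts <- bind_rows(coding, bind_rows(nc_rows))

    proteins <- coding |>
      mutate(gene_id = .data$transcript_id,
             seq = translate_dna(.data$cds)) |>
      select("gene_id", "species", "family", "copy", "seq")

    structure(list(
      transcripts = select(transcripts, -"cds"),
      proteins = proteins,
      families = tibble(family = fam_ids, subset = subsets,
                        n_codons = n_codons),
      params = params), class = "est_truth_set")
  })
}

# mutate one read: substitutions then homopolymer +/-1 indels
corrupt_read <- function(seq, sub_rate, hp_rate) {
  if (sub_rate > 0) {
    n <- nchar(seq)
    k <- stats::rbinom(1, n, sub_rate)
    if (k > 0) {
      pos <- sample.int(n, k)
      ch <- strsplit(seq, "")[[1]]
      for (p in pos) {
        ch[p] <- sample(setdiff(BASES, ch[p]), 1)
      }
      seq <- paste(ch, collapse = "")
    }
  }
  if (hp_rate > 0) {
    r <- rle(strsplit(seq, "")[[1]])
    runs <- which(r$lengths >= 3)
    if (length(runs)) {
      flip <- runs[stats::runif(length(runs)) < hp_rate]
      if (length(flip)) {
        r$lengths[flip] <- pmax(1L, r$lengths[flip] +
                                  sample(c(-1L, 1L), length(flip),
                                         replace = TRUE))
        seq <- paste(inverse.rle(r), collapse = "")
      }
    }
  }
  seq
}

#' Simulate reads from transcripts under a technology error model
#'
#' Sanger reads are 5'-anchored (start at transcript position 0, sense
#' strand); 454 reads start uniformly and come off either strand.
#' Homopolymer runs of length >= 3 receive +/-1 length errors at the model
#' rate; the adapter, when configured, is prepended to the raw read.
#' A read length request past the transcript end truncates to the end.
#'
#' @param transcripts Tibble with `transcript_id` and `seq` columns.
#' @param model A [read_model()].
#' @param depth Mean reads per transcript; per-transcript lognormal
#'   expression weights modulate it.
#' @param seed Integer seed.
#' @param prefix Read-id prefix (keeps ids unique across calls).
#' @param n_reads Optional exact total read count; when given, origins are
#'   sampled with expression weights instead of per-transcript Poisson
#'   draws.
#' @return Tibble of reads: id, technology, sequence, per-base phred
#'   qualities (list column), and origin truth (transcript, 0-based
#'   half-open interval, orientation).
#' @export
simulate_reads <- function(transcripts, model, depth, seed = 1L,
                           prefix = model$technology, n_reads = NULL) {
  stopifnot(nrow(transcripts) > 0, depth >= 0,
            inherits(model, "read_model"))
  with_seed(child_seed(seed, paste0("reads-", prefix)), {
    n_t <- nrow(transcripts)
    w <- stats::rlnorm(n_t, 0, 0.5)
    if (is.null(n_reads)) {
      lam <- depth * w / mean(w)
      idx <- rep(seq_len(n_t), stats::rpois(n_t, lam))
    } else {
      idx <- sample.int(n_t, n_reads, replace = TRUE, prob = w)
    }
    total <- length(idx)
    if (total == 0) {
      return(tibble(read_id = character(), technology = character(),
                    seq = character(), qual = list(),
                    transcript_id = character(), origin_start = integer(),
                    origin_end = integer(), orientation = character()))
    }
    tseq <- transcripts$seq[idx]
    tlen <- nchar(tseq)
    want <- pmax(30L, as.integer(round(
      stats::rnorm(total, model$mean_len, model$len_sd))))
    if (model$five_prime_anchored) {
      start <- rep(0L, total)
      orient <- rep("+", total)
    } else {
      start <- as.integer(floor(stats::runif(total) * pmax(1L, tlen - 30L)))
      orient <- sample(c("+", "-"), total, replace = TRUE)
    }
    end <- pmin(tlen, start + want)
    raw <- substr(tseq, start + 1L, end)
    flip <- orient == "-"
    raw[flip] <- revcomp(raw[flip])
    seqs <- vapply(raw, corrupt_read, character(1),
                   sub_rate = model$substitution_rate,
                   hp_rate = model$homopolymer_indel_rate,
                   USE.NAMES = FALSE)
    if (nzchar(model$adapter_seq)) {
      seqs <- paste0(model$adapter_seq, seqs)
    }
    qual <- lapply(nchar(seqs), function(n) {
      pmin(40L, pmax(2L, as.integer(round(40 - stats::rexp(n, 0.5)))))
    })
    tibble(
      read_id = sprintf("%s_%06d", prefix, seq_len(total)),
      technology = model$technology,
      seq = seqs, qual = qual,
      transcript_id = transcripts$transcript_id[idx],
      origin_start = start, origin_end = end, orientation = orient)
  })
}

#' Build a labelled contaminant source pool
#'
#' Synthetic coding-like source genes for the five contaminant lineage
#' categories, each with a full lineage path string so that taxonomy
#' binning can recover the planted category.
#'
#' @param n_per_category Source genes per category.
#' @param cds_len Mean length in codons.
#' @param gc GC target of the pool.
#' @param seed Integer seed.
#' @return Tibble: `contig_id`, `lineage_category`, `lineage`, `seq` (nt),
#'   `protein`.
#' @export
make_contaminant_pool <- function(n_per_category = 8, cds_len = 250,
                                  gc = 0.50, seed = 1L) {
  cats <- c(Bacteria = "cellular organisms; Bacteria; Synthetibacter",
            Fungi = "cellular organisms; Eukaryota; Opisthokonta; Fungi; Synthetomyces",
            Viruses = "Viruses; Synthetivirus",
            Archaea = "cellular organisms; Archaea; Synthetarchaeum",
            OtherEukaryotes = "cellular organisms; Eukaryota; Opisthokonta; Metazoa; Synthetozoon")
  with_seed(child_seed(seed, "contaminant-pool"), {
    w <- codon_weights(gc)
    rows <- list()
    for (cat in names(cats)) {
      for (i in seq_len(n_per_category)) {
        nc <- max(60L, as.integer(round(stats::rnorm(1, cds_len,
                                                     0.2 * cds_len))))
        cds <- paste(sample(SENSE_CODONS, nc, replace = TRUE, prob = w),
                     collapse = "")
        rows[[length(rows) + 1]] <- tibble(
          contig_id = sprintf("%s_src%03d", tolower(cat), i),
          lineage_category = cat, lineage = unname(cats[cat]),
          seq = cds, protein = translate_dna(cds))
      }
    }
    bind_rows(rows)
  })
}

#' Inject contaminant reads into a read set
#'
#' Adds `Binomial(n_reads, contam_fraction)` contaminant reads drawn from
#' the labelled pool, using the same technology mix and error models as
#' the input reads, and records the source category per read.
#'
#' @param reads Read tibble from [simulate_reads()].
#' @param params A [generator_params()] (for `contam_fraction`).
#' @param contaminant_pool Pool from [make_contaminant_pool()].
#' @param seed Integer seed.
#' @param models Named list of [read_model()]s by technology.
#' @param prefix Read-id prefix for the injected reads.
#' @return The augmented read tibble with a `lineage_category` column
#'   (`NA` for genuine reads) and an `is_contaminant` flag.
#' @export
inject_contaminants <- function(reads, params, contaminant_pool, seed = 1L,
                                models = list(sanger = read_model("sanger"),
                                              flx454 = read_model("flx454")),
                                prefix = "contam") {
  f <- params$contam_fraction
  reads$lineage_category <- NA_character_
  reads$is_contaminant <- FALSE
  if (f == 0) return(reads)
  if (nrow(contaminant_pool) == 0) {
    stop("contam_fraction > 0 but the contaminant pool is empty")
  }
  with_seed(child_seed(seed, "contaminants"), {
    m <- stats::rbinom(1, nrow(reads), f)
    if (m == 0) return(reads)
    techs <- sample(reads$technology, m, replace = TRUE)
    out <- list()
    for (tech in unique(techs)) {
      k <- sum(techs == tech)
      pool_t <- contaminant_pool |>
        rename(transcript_id = "contig_id")
      out[[tech]] <- simulate_reads(
        pool_t, models[[tech]], depth = 0, n_reads = k,
        seed = child_seed(seed, paste0("contam-", tech)),
        prefix = paste0(prefix, "_", tech))
    }
    contam <- bind_rows(out)
    contam <- contam |>
      left_join(select(contaminant_pool, "contig_id", "lineage_category"),
                by = c(transcript_id = "contig_id")) |>
      mutate(is_contaminant = TRUE)
    bind_rows(reads, contam)
  })
}

#' Write generator outputs to plain-text files
#'
#' Reads go to FASTA plus a sidecar phred quality file; truth tables to
#' TSV; the generator configuration is echoed as a YAML file.
#'
#' @param truth An `est_truth_set` from [generate_families()].
#' @param reads Read tibble.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_bundle <- function(truth, reads, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(reads, file.path(dir, "reads.fasta"),
              id = "read_id", seq = "seq")
  write_qual(reads, file.path(dir, "reads.qual"))
  readr::write_tsv(select(reads, -"seq", -"qual"),
                   file.path(dir, "read_truth.tsv"))
  readr::write_tsv(truth$transcripts, file.path(dir, "transcript_truth.tsv"))
  readr::write_tsv(truth$families, file.path(dir, "family_truth.tsv"))
  write_fasta(truth$proteins, file.path(dir, "reference_proteins.fasta"),
              id = "gene_id", seq = "seq")
  p <- truth$params
  cfg <- list(n_families = p$n_families, species = p$species_list,
              divergence = as.list(p$divergence),
              paralog_rate = p$paralog_rate,
              gc_target = as.list(p$gc_target),
              contam_fraction = p$contam_fraction,
              noncoding_fraction = p$noncoding_fraction, seed = p$seed)
  yaml::write_yaml(cfg, file.path(dir, "generator_config.yaml"))
  invisible(dir)
}
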