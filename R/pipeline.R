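# End-to-end orchestration: generate -> prep -> cluster -> code ->
# search -> orthologs -> annotate -> enrich, with per-stage manifests
# and a report bundle mirroring the classic EST-survey tables.

#' Assemble a pipeline configuration
#'
#' @param outdir Output directory.
#' @param seed Global seed; every stochastic stage derives a child seed.
#' @param generator A [generator_params()] for the synthetic run.
#' @param read_depth Named mean reads per transcript by technology.
#' @param trim,overlap,aligner Stage parameter objects.
#' @param coding Named list: `min_score`, `min_len`, `frameshift_penalty`,
#'   `stop_penalty`.
#' @param cutoffs Named list of E-value cutoffs: `taxonomy` (1e-4),
#'   `ortholog` (1e-6), `go` (1e-6), `panel` (1e-20).
#' @param panel Optional panel tibble (`id`, `seq` amino acids, metadata).
#' @param n_per_contaminant_category Pool size per contaminant category.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir = tempfile("estpipe_run_"),
                            seed = 1L,
                            generator = generator_params(seed = seed),
                            read_depth = c(sanger = 2, flx454 = 5),
                            trim = trim_params(
                              adapters = read_model("flx454")$adapter_seq),
                            overlap = overlap_params(),
                            aligner = aligner_params(),
                            coding = list(min_score = 40, min_len = 150,
                                          frameshift_penalty = 20,
                                          stop_penalty = 100),
                            cutoffs = list(taxonomy = 1e-4,
                                           ortholog = 1e-6,
                                           go = 1e-6, panel = 1e-20),
                            panel = NULL,
                            n_per_contaminant_category = 8) {
  structure(list(outdir = outdir, seed = as.integer(seed),
                 generator = generator, read_depth = read_depth,
                 trim = trim, overlap = overlap, aligner = aligner,
                 coding = coding, cutoffs = cutoffs, panel = panel,
                 n_per_contaminant_category = n_per_contaminant_category),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Report-only: returns a tibble of problems (zero rows when valid).
#'
#' @param config A [pipeline_config()].
#' @return Tibble with columns `field` and `issue`.
#' @export
validate_config <- function(config) {
  issues <- list()
  note <- function(field, msg) {
    issues[[length(issues) + 1]] <<- tibble(field = field, issue = msg)
  }
  ok_params <- tryCatch({
    stopifnot(inherits(config$generator, "generator_params"))
    TRUE
  }, error = function(e) FALSE)
  if (!ok_params) note("generator", "not a generator_params object")
  ov <- config$overlap
  if (!inherits(ov, "overlap_params")) {
    note("overlap", "not an overlap_params object")
  } else {
    if (ov$min_identity > 1 || ov$min_identity <= 0) {
      note("overlap$min_identity", "must lie in (0, 1]")
    }
    if (ov$min_overlap < ov$seed_k) {
      note("overlap$min_overlap", "smaller than seed_k")
    }
  }
  for (nm in c("taxonomy", "ortholog", "go", "panel")) {
    v <- config$cutoffs[[nm]]
    if (is.null(v) || v <= 0) note(paste0("cutoffs$", nm),
                                   "missing or non-positive")
  }
  for (nm in intersect(c("panel_path", "obo_path", "reads_fasta"),
                       names(config))) {
    if (!is.null(config[[nm]]) && !file.exists(config[[nm]])) {
      note(nm, paste0("file does not exist: ", config[[nm]]))
    }
  }
  if (length(issues)) bind_rows(issues) else
    tibble(field = character(0), issue = character(0))
}

write_stage <- function(outdir, stage, tables) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(tables)) {
    path <- file.path(outdir, paste0(stage, "_", nm, ".tsv"))
    tab <- tables[[nm]]
    tab <- tab[, !vapply(tab, is.list, logical(1)), drop = FALSE]
    readr::write_tsv(tab, path)
    files <- c(files, path)
  }
  tibble(stage = stage, file = basename(files),
         md5 = unname(tools::md5sum(files)),
         n_records = vapply(tables, nrow, integer(1)))
}

#' Run the full comparative EST analysis on synthetic data
#'
#' Executes every stage in order, writes plain-file outputs plus a
#' per-stage manifest with content digests, and returns the report
#' tables: read/assembly statistics, contig/singleton provenance,
#' reads-per-unigene histogram data, lineage proportions, Venn counts,
#' panel screens and the GO enrichment table. Re-running with an
#' identical configuration reproduces identical digests.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `est_report`; see Details.
#' @export
run_pipeline <- function(config) {
  v <- validate_config(config)
  if (nrow(v) > 0) {
    stop("invalid configuration:\n",
         paste(v$field, v$issue, sep = ": ", collapse = "\n"))
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  gp <- config$generator
  sp <- gp$species_list
  focal <- sp[2:3]
  refs <- sp[c(1, 4)]
  manifests <- list()
  t0 <- Sys.time()
  stage_log <- function(stage, n) {
    message(sprintf("[%s] %s: %d records (%.1fs elapsed)",
                    format(Sys.time(), "%H:%M:%S"), stage, n,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  # ---- generate ----
  truth <- generate_families(gp)
  pool <- make_contaminant_pool(config$n_per_contaminant_category,
                                cds_len = gp$cds_len,
                                seed = child_seed(seed, "pool"))
  reads_by_sp <- list()
  for (s in focal) {
    tr <- filter(truth$transcripts, .data$species == s)
    sang <- simulate_reads(tr, read_model("sanger"),
                           depth = config$read_depth[["sanger"]],
                           seed = child_seed(seed, paste0("sanger-", s)),
                           prefix = paste0(s, "_sanger"))
    flx <- simulate_reads(tr, read_model("flx454"),
                          depth = config$read_depth[["flx454"]],
                          seed = child_seed(seed, paste0("flx454-", s)),
                          prefix = paste0(s, "_454"))
    reads <- inject_contaminants(bind_rows(sang, flx), gp, pool,
                                 seed = child_seed(seed,
                                                   paste0("contam-", s)),
                                 prefix = paste0(s, "_contam"))
    reads_by_sp[[s]] <- reads
  }
  stage_log("generate", sum(vapply(reads_by_sp, nrow, integer(1))))

  # ---- prep + cluster + code per focal species ----
  model_cds <- filter(truth$transcripts, .data$species == refs[1],
                      .data$coding)
  train_cds <- substr(model_cds$seq, model_cds$cds_start + 1,
                      model_cds$cds_end)
  bg <- with_seed(child_seed(seed, "coding-background"), {
    random_dna(rep(2000, 60), mean(gp$gc_target))
  })
  cmodel <- train_hexamer_model(train_cds, bg)

  unigenes_by_sp <- list()
  coding_by_sp <- list()
  read_stats <- list()
  for (s in focal) {
    reads <- trim_reads(reads_by_sp[[s]], config$trim)
    kept <- filter(reads, .data$verdict == "pass")
    uni <- two_step_assemble(
      filter(kept, .data$technology == "flx454"),
      filter(kept, .data$technology == "sanger"),
      config$overlap)
    uni$unigene_id <- paste0(s, "_", uni$unigene_id)
    uni$species <- s
    preds <- classify_unigenes(
      uni, cmodel,
      min_score = config$coding$min_score,
      min_len = config$coding$min_len,
      frameshift_penalty = config$coding$frameshift_penalty,
      stop_penalty = config$coding$stop_penalty)
    unigenes_by_sp[[s]] <- uni
    coding_by_sp[[s]] <- preds
    read_stats[[s]] <- bind_rows(
      mutate(assembly_stats(kept, "technology"), species = s,
             set = "reads"),
      mutate(assembly_stats(uni, "provenance"), species = s,
             set = "unigenes"))
    stage_log(paste0("cluster+code ", s), nrow(uni))
  }

  # ---- taxonomy screen: translated unigenes vs labelled protein db ----
  ref_proteins <- filter(truth$proteins, .data$species %in% refs)
  db <- bind_rows(
    tibble(id = ref_proteins$gene_id, seq = ref_proteins$seq),
    tibble(id = pool$contig_id, seq = pool$protein))
  lineages <- c(
    stats::setNames(
      "cellular organisms; Eukaryota; Viridiplantae; Streptophyta; Embryophyta_synthetic",
      refs[1]),
    stats::setNames(
      "cellular organisms; Eukaryota; Viridiplantae; Chlorophyta; Chlorophyceae_synthetic",
      refs[2]))
  lmap <- build_lineage_map(ref_proteins, lineages, pool)

  lineage_by_sp <- list()
  novelty_by_sp <- list()
  for (s in focal) {
    uni <- unigenes_by_sp[[s]]
    hits <- search_homologs(
      tibble(id = uni$unigene_id, seq = uni$seq), db,
      mode = "transl_prot", params = config$aligner)
    la <- assign_lineage(uni, hits, lmap,
                         evalue_cutoff = config$cutoffs$taxonomy)
    lineage_by_sp[[s]] <- mutate(la, species = s)
    novelty_by_sp[[s]] <-
      mutate(classify_novel(coding_by_sp[[s]], la), species = s)
    stage_log(paste0("taxonomy ", s), nrow(la))
  }

  # ---- orthology on peptides + reference proteomes ----
  pep <- list()
  for (s in focal) {
    cp <- filter(coding_by_sp[[s]], .data$verdict == "coding")
    pep[[s]] <- tibble(species = s, id = cp$unigene_id,
                       seq = gsub("[X*]", "", cp$peptide))
  }
  for (s in refs) {
    pr <- filter(truth$proteins, .data$species == s)
    pep[[s]] <- tibble(species = s, id = pr$gene_id,
                       seq = gsub("\\*", "", pr$seq))
  }
  proteins <- bind_rows(pep) |> filter(nchar(.data$seq) >= 20)
  edges <- all_pairwise_rbh(proteins, config$aligner,
                            config$cutoffs$ortholog)
  os <- ortholog_sets(edges, tibble(species = proteins$species,
                                    gene = proteins$id))
  totals <- table(proteins$species)
  venn <- venn_partition(os$assignments,
                         stats::setNames(as.integer(totals),
                                         names(totals)))
  stage_log("orthology", nrow(edges))

  # ---- novel-gene cross-library comparison ----
  novel_sets <- list()
  for (s in focal) {
    nv <- filter(novelty_by_sp[[s]], .data$novelty == "novel")
    novel_sets[[s]] <- filter(pep[[s]], .data$id %in% nv$unigene_id)[,
                                                                     c("id", "seq")]
  }
  cross_novel <- cross_library_novel_overlap(
    novel_sets[[focal[1]]], novel_sets[[focal[2]]],
    params = config$aligner, evalue_cutoff = config$cutoffs$taxonomy)

  # ---- gene panel screen ----
  panel <- config$panel
  if (is.null(panel)) {
    # default synthetic panel: a few reference-plant proteins plus one
    # absent decoy
    rp <- filter(truth$proteins, .data$species == refs[1])
    pick <- utils::head(rp, 5)
    decoy <- with_seed(child_seed(seed, "panel-decoy"), {
      translate_dna(paste(sample(SENSE_CODONS, 300, replace = TRUE),
                          collapse = ""))
    })
    panel <- bind_rows(
      tibble(id = pick$gene_id, seq = gsub("\\*", "", pick$seq),
             role = "reference gene"),
      tibble(id = "decoy_absent", seq = decoy, role = "absent decoy"))
  }
  panel_by_sp <- list()
  for (s in focal) {
    uni <- unigenes_by_sp[[s]]
    panel_by_sp[[s]] <- screen_gene_panel(
      panel, tibble(unigene_id = uni$unigene_id, seq = uni$seq),
      params = config$aligner,
      evalue_cutoff = config$cutoffs$panel) |>
      mutate(species = s)
  }
  stage_log("panel", nrow(panel))

  # ---- GO enrichment vs the reference proteome ----
  dag <- synthetic_ontology()
  ref_go <- assign_family_go(truth, dag,
                             seed = child_seed(seed, "go")) |>
    select("gene", "term")
  ref_plant_go <- ref_go |>
    filter(.data$gene %in%
             truth$proteins$gene_id[truth$proteins$species == refs[1]])
  ref_counts <- rollup_level3(rename(ref_plant_go, unigene_id = "gene"),
                              dag)
  enrich_by_sp <- list()
  for (s in focal) {
    refdb <- filter(truth$proteins, .data$species == refs[1])
    hits <- search_homologs(
      pep[[s]][, c("id", "seq")],
      tibble(id = refdb$gene_id, seq = gsub("\\*", "", refdb$seq)),
      mode = "prot_prot", params = config$aligner)
    ann <- transfer_annotations(hits, ref_plant_go,
                                evalue_cutoff = config$cutoffs$go)
    sp_counts <- rollup_level3(ann, dag)
    n1 <- dplyr::n_distinct(ann$unigene_id)
    n2 <- dplyr::n_distinct(ref_plant_go$gene)
    enrich_by_sp[[s]] <- compare_proportions(sp_counts, ref_counts,
                                             n1 = max(n1, 1),
                                             n2 = max(n2, 1)) |>
      mutate(species = s)
    stage_log(paste0("enrich ", s), nrow(enrich_by_sp[[s]]))
  }

  report <- list(
    read_stats = bind_rows(read_stats),
    unigenes = bind_rows(unigenes_by_sp),
    coding = bind_rows(coding_by_sp, .id = "species"),
    coding_summary = bind_rows(
      lapply(coding_by_sp, coding_summary), .id = "species"),
    reads_per_unigene = bind_rows(unigenes_by_sp) |>
      count(.data$species, .data$n_reads, name = "n_unigenes"),
    lineage = bind_rows(lapply(lineage_by_sp, summarize_lineages),
                        .id = "species"),
    lineage_assignments = bind_rows(lineage_by_sp),
    novelty = bind_rows(novelty_by_sp),
    cross_novel = cross_novel,
    edges = edges,
    venn = venn,
    ortholog_sets = os$sets,
    assignments = os$assignments,
    panel = bind_rows(panel_by_sp),
    enrichment = bind_rows(enrich_by_sp),
    truth = truth,
    config = config)
  class(report) <- "est_report"

  # ---- write plain-file outputs + manifest ----
  manifests[["report"]] <- write_stage(outdir, "report", list(
    read_stats = report$read_stats,
    unigenes = select(report$unigenes, -"members"),
    coding_summary = report$coding_summary,
    lineage = report$lineage,
    venn = report$venn,
    panel = report$panel,
    enrichment = report$enrichment))
  write_fasta(report$unigenes, file.path(outdir, "unigenes.fasta"),
              id = "unigene_id", seq = "seq")
  report$manifest <- bind_rows(manifests)
  readr::write_tsv(report$manifest, file.path(outdir, "manifest.tsv"))
  report
}

#' @export
print.est_report <- function(x, ...) {
  cat("Comparative EST analysis report\n")
  cat("  unigenes:", nrow(x$unigenes), "\n")
  cat("  RBH edges:", nrow(x$edges), "\n")
  cat("  Venn regions:", dplyr::n_distinct(x$venn$region), "\n")
  cat("  enrichment rows:", nrow(x$enrichment), "\n")
  invisible(x)
}

#' @export
glance.est_report <- function(x, ...) {
  tibble(n_unigenes = nrow(x$unigenes),
         n_contigs = sum(x$unigenes$kind == "contig"),
         n_singletons = sum(x$unigenes$kind == "singleton"),
         n_rbh_edges = nrow(x$edges),
         n_ortholog_sets = nrow(x$ortholog_sets),
         frac_no_coding = mean(x$coding$verdict == "none"))
}
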