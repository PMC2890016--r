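# Taxonomic lineage binning of unigenes from their top translated hit,
# novel-gene classification, cross-library novel-gene comparison and
# gene-panel screening.

LINEAGE_CATEGORIES <- c("Archaea", "Viruses", "Bacteria", "Fungi",
                        "Chlorophyta", "Streptophyta", "OtherEukaryotes",
                        "NoHit")

# most-specific-first precedence: lineage strings can contain several
# category tokens (Fungi lineages also contain Eukaryota)
LINEAGE_PRECEDENCE <- c("Viruses", "Archaea", "Bacteria", "Fungi",
                        "Chlorophyta", "Streptophyta")

categorise_lineage <- function(lineage) {
  for (cat in LINEAGE_PRECEDENCE) {
    if (grepl(cat, lineage, ignore.case = TRUE)) return(cat)
  }
  "OtherEukaryotes"
}

#' Assign a taxonomic lineage category to each unigene
#'
#' The top hit below the E-value cutoff decides the category via its
#' lineage path, matched against category tokens in precedence order
#' Viruses, Archaea, Bacteria, Fungi, Chlorophyta, Streptophyta, with
#' OtherEukaryotes as the fallback; unigenes with no passing hit are
#' NoHit. Subjects missing from the lineage map classify as
#' OtherEukaryotes with a warning.
#'
#' @param unigenes Tibble with `unigene_id` (every unigene receives a
#'   category).
#' @param hits Hit tibble with `query` matching unigene ids.
#' @param lineage_map Tibble: `subject`, `lineage` (semicolon-delimited
#'   path).
#' @param evalue_cutoff Significance cutoff (default 1e-4; hits must have
#'   `evalue < cutoff`).
#' @return Tibble: `unigene_id`, `category`, `top_subject`, `top_evalue`.
#' @export
assign_lineage <- function(unigenes, hits, lineage_map,
                           evalue_cutoff = 1e-4) {
  passing <- filter(hits, .data$evalue < evalue_cutoff)
  tops <- if (nrow(passing) > 0) top_hits_per_query(passing) else passing
  lmap <- stats::setNames(lineage_map$lineage, lineage_map$subject)
  out <- tibble(unigene_id = unigenes$unigene_id) |>
    left_join(transmute(tops, unigene_id = .data$query,
                        top_subject = .data$subject,
                        top_evalue = .data$evalue),
              by = "unigene_id")
  cats <- character(nrow(out))
  missing_subjects <- character(0)
  for (i in seq_len(nrow(out))) {
    if (is.na(out$top_subject[i])) {
      cats[i] <- "NoHit"
    } else if (is.na(lmap[out$top_subject[i]])) {
      missing_subjects <- c(missing_subjects, out$top_subject[i])
      cats[i] <- "OtherEukaryotes"
    } else {
      cats[i] <- categorise_lineage(lmap[[out$top_subject[i]]])
    }
  }
  if (length(missing_subjects)) {
    warning("subjects missing from the lineage map (classified ",
            "OtherEukaryotes): ",
            paste(utils::head(unique(missing_subjects), 5), collapse = ", "))
  }
  out$category <- factor(cats, levels = LINEAGE_CATEGORIES)
  select(out, "unigene_id", "category", "top_subject", "top_evalue")
}

#' Lineage category counts and proportions
#'
#' @param assignments Output of [assign_lineage()].
#' @return Tibble: `category`, `n`, `proportion` (summing to 1).
#' @export
summarize_lineages <- function(assignments) {
  assignments |>
    count(.data$category, name = "n", .drop = FALSE) |>
    mutate(proportion = .data$n / sum(.data$n))
}

#' Classify unigenes as novel, known, or non-coding/contaminant
#'
#' A unigene is novel iff it has a predicted coding region and no
#' significant hit in the reference protein screen; a NoHit unigene
#' without a coding region is most likely genomic or non-coding RNA
#' contamination; everything with a hit is known.
#'
#' @param coding_verdicts Tibble with `unigene_id` and `verdict`
#'   (from [classify_unigenes()]).
#' @param lineage_assignments Tibble with `unigene_id` and `category`
#'   (from [assign_lineage()]).
#' @return Tibble: `unigene_id`, `novelty` in
#'   `{novel, known, noncoding-or-contaminant}`.
#' @export
classify_novel <- function(coding_verdicts, lineage_assignments) {
  inner_join(select(coding_verdicts, "unigene_id", "verdict"),
             select(lineage_assignments, "unigene_id", "category"),
             by = "unigene_id") |>
    mutate(novelty = case_when(
      .data$verdict == "coding" & .data$category == "NoHit" ~ "novel",
      .data$verdict != "coding" & .data$category == "NoHit" ~
        "noncoding-or-contaminant",
      TRUE ~ "known")) |>
    select("unigene_id", "novelty")
}

#' Cross-library comparison of two novel-gene sets
#'
#' Searches the two peptide sets against each other in both directions
#' and reports how many queries of each set have any passing hit, plus
#' the number of reciprocal best hit pairs.
#'
#' @param novel_a,novel_b Tibbles with `id` and `seq` (peptides), disjoint
#'   ids.
#' @param params An [aligner_params()].
#' @param evalue_cutoff Hit significance cutoff (default 1e-4).
#' @return One-row tibble: `n_a`, `n_b`, `a_with_hit`, `b_with_hit`,
#'   `n_rbh`.
#' @export
cross_library_novel_overlap <- function(novel_a, novel_b,
                                        params = aligner_params(),
                                        evalue_cutoff = 1e-4) {
  if (nrow(novel_a) == 0 || nrow(novel_b) == 0) {
    return(tibble(n_a = nrow(novel_a), n_b = nrow(novel_b),
                  a_with_hit = 0L, b_with_hit = 0L, n_rbh = 0L))
  }
  hab <- search_homologs(novel_a, novel_b, mode = "prot_prot",
                         params = params) |>
    filter(.data$evalue < evalue_cutoff)
  hba <- search_homologs(novel_b, novel_a, mode = "prot_prot",
                         params = params) |>
    filter(.data$evalue < evalue_cutoff)
  rbh <- rbh_pairs(hab, hba, evalue_cutoff)
  tibble(n_a = nrow(novel_a), n_b = nrow(novel_b),
         a_with_hit = dplyr::n_distinct(hab$query),
         b_with_hit = dplyr::n_distinct(hba$query),
         n_rbh = nrow(rbh))
}

#' Screen a panel of protein-coding genes against a unigene library
#'
#' Translated search of the nucleotide unigenes against the panel
#' proteins at a stringent cutoff; for each panel gene, reports how many
#' unigenes have a passing hit and the E-value range among them.
#'
#' @param panel_proteins Tibble: `id`, `seq` (amino acids), optional
#'   metadata columns carried through.
#' @param unigenes_nt Tibble: `unigene_id`, `seq` (nucleotides).
#' @param params An [aligner_params()].
#' @param evalue_cutoff Passing-hit threshold (default 1e-20; hits must
#'   have `evalue < cutoff`).
#' @return Tibble: one row per panel gene with `n_hits`, `best_evalue`,
#'   `worst_evalue` (NA when no hits).
#' @export
screen_gene_panel <- function(panel_proteins, unigenes_nt,
                              params = aligner_params(),
                              evalue_cutoff = 1e-20) {
  queries <- tibble(id = unigenes_nt$unigene_id, seq = unigenes_nt$seq)
  hits <- search_homologs(queries, panel_proteins[, c("id", "seq")],
                          mode = "transl_prot", params = params) |>
    filter(.data$evalue < evalue_cutoff)
  per_gene <- hits |>
    group_by(subject = .data$subject) |>
    summarise(n_hits = dplyr::n_distinct(.data$query),
              best_evalue = min(.data$evalue),
              worst_evalue = max(.data$evalue), .groups = "drop")
  panel_proteins |>
    select(-"seq") |>
    left_join(per_gene, by = c(id = "subject")) |>
    mutate(n_hits = dplyr::coalesce(.data$n_hits, 0L))
}

#' Build a lineage map for a synthetic reference database
#'
#' Labels reference proteome subjects with plant-like and
#' chlorophyte-like lineage paths and contaminant-pool subjects with
#' their planted lineages.
#'
#' @param proteins Reference proteins tibble with `gene_id` and `species`.
#' @param species_lineages Named character vector: species -> lineage
#'   path.
#' @param contaminant_pool Optional pool from [make_contaminant_pool()].
#' @return Tibble: `subject`, `lineage`.
#' @export
build_lineage_map <- function(proteins, species_lineages,
                              contaminant_pool = NULL) {
  out <- tibble(subject = proteins$gene_id,
                lineage = unname(species_lineages[proteins$species]))
  if (!is.null(contaminant_pool)) {
    out <- bind_rows(out, tibble(subject = contaminant_pool$contig_id,
                                 lineage = contaminant_pool$lineage))
  }
  out
}
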