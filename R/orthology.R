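# Reciprocal-best-hit orthology: RBH edge extraction per species pair,
# multi-species ortholog sets as pairwise-RBH-complete cliques, and the
# per-species Venn-region partition.

#' Reciprocal best hit pairs between two species
#'
#' An edge (x, y) exists iff y is x's best hit among the other species'
#' genes and x is y's best hit in return (top-hit tie rules of
#' [top_hit()]), both directions passing the E-value cutoff. Self-hits
#' (query equal to subject) are excluded.
#'
#' @param hits_a_to_b,hits_b_to_a Hit tibbles for the two directed
#'   searches.
#' @param evalue_cutoff Hits with `evalue < evalue_cutoff` are considered
#'   (default 1e-6).
#' @return Tibble of edges: `gene_a`, `gene_b`, `bits_ab`, `bits_ba`,
#'   `sum_bits`.
#' @export
rbh_pairs <- function(hits_a_to_b, hits_b_to_a, evalue_cutoff = 1e-6) {
  clean <- function(h) {
    h |>
      filter(.data$evalue < evalue_cutoff, .data$query != .data$subject)
  }
  ab <- top_hits_per_query(clean(hits_a_to_b))
  ba <- top_hits_per_query(clean(hits_b_to_a))
  if (nrow(ab) == 0 || nrow(ba) == 0) {
    return(tibble(gene_a = character(0), gene_b = character(0),
                  bits_ab = numeric(0), bits_ba = numeric(0),
                  sum_bits = numeric(0)))
  }
  inner_join(
    transmute(ab, gene_a = .data$query, gene_b = .data$subject,
              bits_ab = .data$bitscore),
    transmute(ba, gene_b = .data$query, gene_a = .data$subject,
              bits_ba = .data$bitscore),
    by = c("gene_a", "gene_b")) |>
    mutate(sum_bits = .data$bits_ab + .data$bits_ba) |>
    arrange(.data$gene_a)
}

#' Multi-species ortholog sets as pairwise-RBH-complete cliques
#'
#' Every gene has at most one RBH partner per other species; for each
#' gene the candidate ortholog sets are the subsets of the gene plus its
#' partners in which every pair is itself an RBH edge. Each gene is
#' assigned its maximum-size valid set, ties broken by largest summed bit
#' score and then by lexicographic species-subset order. Genes without
#' any edge fall to their own-species singleton set.
#'
#' @param edges Tibble of RBH edges with columns `species_a`, `gene_a`,
#'   `species_b`, `gene_b`, `sum_bits` (see [rbh_pairs()]; species
#'   columns added by the caller).
#' @param genes Tibble of the full gene universe: `species`, `gene`.
#' @return List with `assignments` (one row per gene: `species`, `gene`,
#'   `region` as a `+`-joined sorted species subset, `set_key`) and
#'   `sets` (deduplicated ortholog sets: `set_key`, `size`, `sum_bits`,
#'   and a `members` list column of species/gene tibbles).
#' @export
ortholog_sets <- function(edges, genes) {
  stopifnot(all(c("species", "gene") %in% names(genes)))
  genes <- distinct(genes, .data$species, .data$gene)
  sp_of <- stats::setNames(genes$species, genes$gene)

  # partner map: gene -> (species -> partner gene), plus edge lookup
  partner <- new.env(parent = emptyenv())
  ekey <- function(x, y) paste(sort(c(x, y)), collapse = "\r")
  edge_set <- new.env(parent = emptyenv())
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      ga <- edges$gene_a[r]; gb <- edges$gene_b[r]
      sa <- edges$species_a[r]; sb <- edges$species_b[r]
      pa <- partner[[ga]] %||% list()
      if (!is.null(pa[[sb]]) && pa[[sb]] != gb) {
        stop("RBH uniqueness violated for gene ", ga,
             " toward species ", sb)
      }
      pa[[sb]] <- gb; assign(ga, pa, envir = partner)
      pb <- partner[[gb]] %||% list()
      if (!is.null(pb[[sa]]) && pb[[sa]] != ga) {
        stop("RBH uniqueness violated for gene ", gb,
             " toward species ", sa)
      }
      pb[[sa]] <- ga; assign(gb, pb, envir = partner)
      assign(ekey(ga, gb), edges$sum_bits[r], envir = edge_set)
    }
  }

  assign_rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene[i]; s <- genes$species[i]
    pa <- partner[[g]]
    if (is.null(pa) || length(pa) == 0) {
      assign_rows[[i]] <- tibble(species = s, gene = g, region = s,
                                 set_key = paste0(s, ":", g))
      next
    }
    others <- names(pa)
    best <- NULL
    nsub <- length(others)
    for (mask in 0:(2^nsub - 1)) {
      pick <- others[bitwAnd(mask, 2^(seq_len(nsub) - 1)) > 0]
      memb_genes <- c(g, unlist(pa[pick], use.names = FALSE))
      memb_sp <- c(s, pick)
      # validity: every pair of members must be an RBH edge
      ok <- TRUE; bits <- 0
      if (length(memb_genes) > 1) {
        for (x in seq_len(length(memb_genes) - 1)) {
          for (y in (x + 1):length(memb_genes)) {
            w <- edge_set[[ekey(memb_genes[x], memb_genes[y])]]
            if (is.null(w)) { ok <- FALSE; break }
            bits <- bits + w
          }
          if (!ok) break
        }
      }
      if (!ok) next
      subset_str <- paste(sort(memb_sp), collapse = "+")
      cand <- list(size = length(memb_genes), bits = bits,
                   subset = subset_str, species = memb_sp,
                   genes = memb_genes)
      if (is.null(best) || cand$size > best$size ||
          (cand$size == best$size && cand$bits > best$bits) ||
          (cand$size == best$size && cand$bits == best$bits &&
           cand$subset < best$subset)) {
        best <- cand
      }
    }
    ord <- order(best$species)
    set_key <- paste(paste0(best$species[ord], ":", best$genes[ord]),
                     collapse = ",")
    assign_rows[[i]] <- tibble(species = s, gene = g,
                               region = best$subset, set_key = set_key)
  }
  assignments <- bind_rows(assign_rows)

  sets <- assignments |>
    distinct(.data$set_key) |>
    mutate(members = purrr::map(.data$set_key, function(k) {
      parts <- strsplit(strsplit(k, ",", fixed = TRUE)[[1]], ":",
                        fixed = TRUE)
      tibble(species = vapply(parts, `[[`, "", 1),
             gene = vapply(parts, function(p)
               paste(p[-1], collapse = ":"), ""))
    }),
    size = vapply(.data$members, nrow, integer(1)),
    sum_bits = vapply(.data$members, function(m) {
      if (nrow(m) < 2) return(0)
      tot <- 0
      for (x in seq_len(nrow(m) - 1)) for (y in (x + 1):nrow(m)) {
        w <- edge_set[[ekey(m$gene[x], m$gene[y])]]
        tot <- tot + (w %||% 0)
      }
      tot
    }, numeric(1))) |>
    select("set_key", "size", "sum_bits", "members")
  list(assignments = assignments, sets = sets)
}

#' Venn-region partition of gene assignments
#'
#' Tabulates, for every species, how many of its genes fall in each
#' species-subset region, and enforces the additivity invariant: region
#' counts for a species must sum to that species' gene total.
#'
#' @param assignments Assignment tibble from [ortholog_sets()] covering
#'   every gene exactly once.
#' @param species_totals Optional named totals per species; defaults to
#'   the assignment counts.
#' @return Tibble: `region`, `species`, `n_genes`, sorted by region size
#'   then name.
#' @export
venn_partition <- function(assignments, species_totals = NULL) {
  if (anyDuplicated(assignments[, c("species", "gene")])) {
    stop("double assignment: a gene appears in more than one region")
  }
  counts <- assignments |>
    count(.data$region, .data$species, name = "n_genes")
  tot <- counts |>
    group_by(.data$species) |>
    summarise(n = sum(.data$n_genes), .groups = "drop")
  if (!is.null(species_totals)) {
    for (s in tot$species) {
      if (!is.na(species_totals[s]) &&
          species_totals[[s]] != tot$n[tot$species == s]) {
        stop("Venn additivity violated for species ", s, ": regions sum to ",
             tot$n[tot$species == s], " but total is ", species_totals[[s]])
      }
    }
  }
  counts |>
    mutate(region_size = lengths(strsplit(.data$region, "+",
                                          fixed = TRUE))) |>
    arrange(desc(.data$region_size), .data$region, .data$species) |>
    select("region", "species", "n_genes")
}

#' All-pairwise RBH edges across a set of species proteomes
#'
#' Runs the directed seeded search for every ordered species pair and
#' extracts RBH edges per unordered pair.
#'
#' @param proteins Tibble: `species`, `id`, `seq` (amino acids).
#' @param params An [aligner_params()].
#' @param evalue_cutoff RBH E-value cutoff (default 1e-6).
#' @return Edge tibble with `species_a`, `gene_a`, `species_b`, `gene_b`,
#'   `bits_ab`, `bits_ba`, `sum_bits`.
#' @export
all_pairwise_rbh <- function(proteins, params = aligner_params(),
                             evalue_cutoff = 1e-6) {
  sp <- sort(unique(proteins$species))
  out <- list()
  for (i in seq_along(sp)) {
    for (j in seq_along(sp)) {
      if (j <= i) next
      pa <- filter(proteins, .data$species == sp[i])[, c("id", "seq")]
      pb <- filter(proteins, .data$species == sp[j])[, c("id", "seq")]
      if (nrow(pa) == 0 || nrow(pb) == 0) next
      hab <- search_homologs(pa, pb, mode = "prot_prot", params = params)
      hba <- search_homologs(pb, pa, mode = "prot_prot", params = params)
      e <- rbh_pairs(hab, hba, evalue_cutoff)
      if (nrow(e) > 0) {
        e$species_a <- sp[i]
        e$species_b <- sp[j]
        out[[length(out) + 1]] <- e
      }
    }
  }
  if (!length(out)) {
    return(tibble(gene_a = character(0), gene_b = character(0),
                  bits_ab = numeric(0), bits_ba = numeric(0),
                  sum_bits = numeric(0), species_a = character(0),
                  species_b = character(0)))
  }
  bind_rows(out)
}
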