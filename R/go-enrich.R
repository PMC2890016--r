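# GO annotation transfer, level-3 rollup, and Fisher's exact
# over/underrepresentation testing against a reference proteome.

GO_NAMESPACES <- c(BP = "biological_process", MF = "molecular_function",
                   CC = "cellular_component")

#' Load a GO ontology from an OBO 1.2 file
#'
#' Parses `[Term]` stanzas keeping `is_a` edges only; obsolete terms are
#' dropped and `alt_id`s map to their primary term. Term level is 1 plus
#' the minimum `is_a` distance to the namespace root (the root is level
#' 1). Cycles are a hard failure.
#'
#' @param obo_path Path to an OBO file.
#' @return A list of class `go_dag`: `terms` tibble (`id`, `name`,
#'   `namespace`, `level`), `parents` tibble (`id`, `parent`), `alt`
#'   tibble (`alt`, `id`), `roots` named by namespace.
#' @export
load_ontology <- function(obo_path) {
  lines <- readLines(obo_path, warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  terms <- list(); parents <- list(); alts <- list()
  flush <- function() {
    if (is.null(cur) || isTRUE(cur$obsolete)) return()
    terms[[length(terms) + 1]] <<- tibble(
      id = cur$id, name = cur$name %||% cur$id,
      namespace = cur$namespace %||% NA_character_)
    for (p in cur$is_a) {
      parents[[length(parents) + 1]] <<- tibble(id = cur$id, parent = p)
    }
    for (a in cur$alt_id) {
      alts[[length(alts) + 1]] <<- tibble(alt = a, id = cur$id)
    }
  }
  for (ln in lines) {
    ln <- sub("\\s*!.*$", "", trimws(ln))
    if (ln == "[Term]") {
      flush(); in_term <- TRUE
      cur <- list(is_a = character(0), alt_id = character(0))
      next
    }
    if (grepl("^\\[", ln)) { flush(); in_term <- FALSE; cur <- NULL; next }
    if (!in_term || !nzchar(ln)) next
    kv <- stringr::str_match(ln, "^([a-zA-Z_]+):\\s*(.*)$")
    if (is.na(kv[1, 1])) next
    key <- kv[1, 2]; val <- kv[1, 3]
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_a") cur$is_a <- c(cur$is_a, sub("\\s.*$", "", val))
    else if (key == "alt_id") cur$alt_id <- c(cur$alt_id, val)
    else if (key == "is_obsolete" && val == "true") cur$obsolete <- TRUE
  }
  flush()
  terms <- bind_rows(terms)
  parents <- if (length(parents)) bind_rows(parents) else
    tibble(id = character(0), parent = character(0))
  alts <- if (length(alts)) bind_rows(alts) else
    tibble(alt = character(0), id = character(0))
  parents <- filter(parents, .data$parent %in% terms$id,
                    .data$id %in% terms$id)

  # levels by BFS down from the roots; cycle check via expansion bound
  roots <- setdiff(terms$id, parents$id)
  level <- stats::setNames(rep(NA_integer_, nrow(terms)), terms$id)
  level[roots] <- 1L
  frontier <- roots
  children_of <- split(parents$id, parents$parent)
  depth <- 1L
  while (length(frontier)) {
    depth <- depth + 1L
    if (depth > nrow(terms) + 1L) {
      stop("cycle detected in the ontology near: ",
           paste(utils::head(frontier, 3), collapse = ", "))
    }
    nxt <- unique(unlist(children_of[frontier], use.names = FALSE))
    nxt <- nxt[!is.na(nxt)]
    newly <- nxt[is.na(level[nxt])]
    level[newly] <- depth
    frontier <- newly
  }
  if (anyNA(level)) {
    # unreachable terms under is_a-only graphs: keep but flag level NA
    unreachable <- names(level)[is.na(level)]
    if (length(unreachable)) {
      # reachable-from-nothing with incoming edges means a cycle
      cyc <- intersect(unreachable, parents$id)
      if (length(cyc)) {
        stop("cycle detected in the ontology near: ",
             paste(utils::head(cyc, 3), collapse = ", "))
      }
    }
  }
  terms$level <- unname(level[terms$id])
  root_ns <- terms$namespace[match(roots, terms$id)]
  structure(list(terms = terms, parents = parents, alt = alts,
                 roots = stats::setNames(roots, root_ns)),
            class = "go_dag")
}

# resolve alt ids to primary ids; unknown terms pass through unchanged
resolve_alt <- function(ids, dag) {
  hit <- match(ids, dag$alt$alt)
  ifelse(is.na(hit), ids, dag$alt$id[hit])
}

# all ancestors (inclusive) of a term via is_a edges
go_ancestors <- function(id, dag) {
  parent_of <- split(dag$parents$parent, dag$parents$id)
  seen <- character(0)
  frontier <- id
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(parent_of[frontier],
                                      use.names = FALSE)), seen)
  }
  seen
}

# level-3 ancestor set of a term (itself if exactly level 3)
level3_ancestors <- function(id, dag) {
  anc <- go_ancestors(id, dag)
  lv <- dag$terms$level[match(anc, dag$terms$id)]
  anc[!is.na(lv) & lv == 3L]
}

#' Transfer GO annotations from a reference proteome via top hits
#'
#' Each unigene inherits the complete GO term set of its single top hit
#' against the reference (top-hit tie rules), provided the hit passes the
#' E-value cutoff; unigenes without a passing hit receive no terms.
#'
#' @param unigene_hits Hit tibble of unigene peptides vs the reference.
#' @param reference_go Tibble: `gene`, `term`.
#' @param evalue_cutoff Transfer cutoff (default 1e-6, strict `<`).
#' @return Tibble: `unigene_id`, `term` (zero rows for unannotated
#'   unigenes).
#' @export
transfer_annotations <- function(unigene_hits, reference_go,
                                 evalue_cutoff = 1e-6) {
  passing <- filter(unigene_hits, .data$evalue < evalue_cutoff)
  if (nrow(passing) == 0) {
    return(tibble(unigene_id = character(0), term = character(0)))
  }
  top_hits_per_query(passing) |>
    transmute(unigene_id = .data$query, gene = .data$subject) |>
    inner_join(reference_go, by = "gene",
               relationship = "many-to-many") |>
    distinct(.data$unigene_id, .data$term)
}

#' Roll annotations up to ontology level 3
#'
#' Terms at level >= 3 contribute to each of their level-3 ancestors;
#' terms above level 3 contribute nothing; each gene counts at most once
#' per level-3 bin. Annotation terms absent from the DAG are skipped with
#' a message.
#'
#' @param annotations Tibble: `unigene_id` (or `gene`), `term`.
#' @param dag A [load_ontology()] result.
#' @return Tibble: `namespace`, `term`, `name`, `n` (distinct annotated
#'   genes per level-3 bin).
#' @export
rollup_level3 <- function(annotations, dag) {
  idcol <- if ("unigene_id" %in% names(annotations)) "unigene_id" else "gene"
  ann <- tibble(gene = annotations[[idcol]],
                term = resolve_alt(annotations$term, dag))
  known <- ann$term %in% dag$terms$id
  if (any(!known)) {
    message(sum(!known), " annotation term(s) absent from the ontology; ",
            "skipped")
    ann <- ann[known, ]
  }
  if (nrow(ann) == 0) {
    return(tibble(namespace = character(0), term = character(0),
                  name = character(0), n = integer(0)))
  }
  l3map <- lapply(stats::setNames(unique(ann$term), unique(ann$term)),
                  level3_ancestors, dag = dag)
  expanded <- ann |>
    mutate(l3 = l3map[.data$term]) |>
    select("gene", "l3") |>
    tidyr::unnest_longer("l3", values_to = "term") |>
    filter(!is.na(.data$term)) |>
    distinct(.data$gene, .data$term)
  expanded |>
    count(.data$term, name = "n") |>
    left_join(dag$terms, by = c(term = "id")) |>
    select("namespace", "term", "name", "n") |>
    arrange(.data$namespace, .data$name)
}

#' Two-sided Fisher's exact test for a 2x2 proportion comparison
#'
#' Exact p for observing `a` of `n1` vs `b` of `n2`, computed from the
#' hypergeometric distribution with fixed margins: all tables with
#' probability not exceeding the observed table's contribute (the
#' standard two-sided rule). Vectorised over rows.
#'
#' @param a,n1 Successes and total in group 1.
#' @param b,n2 Successes and total in group 2.
#' @return Numeric p-value(s) in (0, 1]; degenerate all-zero margins give
#'   1.
#' @export
fisher_two_sided <- function(a, n1, b, n2) {
  stopifnot(all(a >= 0), all(b >= 0), all(a <= n1), all(b <= n2))
  mapply(function(a, n1, b, n2) {
    k <- a + b
    if (k == 0 || n1 + n2 == 0) return(1)
    xs <- max(0, k - n2):min(k, n1)
    pr <- stats::dhyper(xs, n1, n2, k)
    p0 <- stats::dhyper(a, n1, n2, k)
    keep <- pr <= p0 * (1 + 1e-7)
    p <- min(1, sum(pr[keep]))
    if (all(keep) || 1 - p < 1e-12) p <- 1  # whole support included
    p
  }, a, n1, b, n2)
}

#' Compare level-3 GO proportions between a species and a reference
#'
#' Per level-3 term: species proportion vs reference proportion,
#' direction of the deviation, two-sided Fisher's exact p, and
#' significance stars (`*` p < 0.01, `**` p < 0.001). A Bonferroni
#' column is included alongside the raw p but stars use raw p.
#'
#' @param species_counts Tibble from [rollup_level3()] for the species.
#' @param reference_counts Same for the reference proteome.
#' @param n1,n2 Annotated-gene totals for species and reference
#'   (defaults: max bin count per table; pass explicit totals when known).
#' @return A tibble of class `go_enrichment`, sorted by namespace then
#'   term name: counts, proportions, `direction` (+1 over, -1 under, 0
#'   equal), `p`, `p_bonferroni`, `stars`.
#' @export
compare_proportions <- function(species_counts, reference_counts,
                                n1 = NULL, n2 = NULL) {
  n1 <- n1 %||% max(species_counts$n, 1)
  n2 <- n2 %||% max(reference_counts$n, 1)
  vocab <- full_join(
    select(species_counts, "namespace", "term", "name", a = "n"),
    select(reference_counts, "term", b = "n"), by = "term") |>
    mutate(a = dplyr::coalesce(.data$a, 0L),
           b = dplyr::coalesce(.data$b, 0L))
  res <- vocab |>
    mutate(n1 = n1, n2 = n2,
           prop_species = .data$a / n1,
           prop_reference = .data$b / n2,
           direction = sign(.data$prop_species - .data$prop_reference),
           p = fisher_two_sided(.data$a, n1, .data$b, n2)) |>
    mutate(p_bonferroni = pmin(1, .data$p * dplyr::n()),
           stars = dplyr::case_when(.data$p < 0.001 ~ "**",
                                    .data$p < 0.01 ~ "*",
                                    TRUE ~ "")) |>
    arrange(.data$namespace, .data$name)
  class(res) <- c("go_enrichment", class(res))
  res
}

#' Generate a small synthetic GO ontology
#'
#' A fixed-shape DAG per namespace: one root (level 1), `n2` children,
#' each with `n3` level-3 children, each with `n4` leaves, plus a few
#' cross-links and alt ids. Deterministic; useful for tests and
#' synthetic pipelines. Written to OBO 1.2 when `path` is given.
#'
#' @param n2,n3,n4 Branching factors per level.
#' @param path Optional OBO output path.
#' @return A `go_dag` (invisibly also writes `path`).
#' @export
synthetic_ontology <- function(n2 = 4, n3 = 3, n4 = 2, path = NULL) {
  stanzas <- character(0)
  term_counter <- 0
  new_id <- function() {
    term_counter <<- term_counter + 1
    sprintf("GO:%07d", term_counter)
  }
  lines <- c("format-version: 1.2", "")
  for (ns_key in names(GO_NAMESPACES)) {
    ns <- GO_NAMESPACES[[ns_key]]
    root <- new_id()
    lines <- c(lines, "[Term]", paste0("id: ", root),
               paste0("name: ", ns), paste0("namespace: ", ns), "")
    for (i in seq_len(n2)) {
      l2 <- new_id()
      lines <- c(lines, "[Term]", paste0("id: ", l2),
                 sprintf("name: %s branch %d", ns_key, i),
                 paste0("namespace: ", ns),
                 paste0("is_a: ", root), "")
      for (j in seq_len(n3)) {
        l3 <- new_id()
        lines <- c(lines, "[Term]", paste0("id: ", l3),
                   sprintf("name: %s category %d.%d", ns_key, i, j),
                   paste0("namespace: ", ns),
                   paste0("is_a: ", l2), "")
        for (kk in seq_len(n4)) {
          l4 <- new_id()
          lines <- c(lines, "[Term]", paste0("id: ", l4),
                     sprintf("name: %s leaf %d.%d.%d", ns_key, i, j, kk),
                     paste0("namespace: ", ns),
                     paste0("is_a: ", l3), "")
        }
      }
    }
  }
  tmp <- path %||% tempfile(fileext = ".obo")
  writeLines(lines, tmp)
  dag <- load_ontology(tmp)
  if (is.null(path)) unlink(tmp)
  dag
}

#' Assign planted GO terms to gene families
#'
#' Each family draws 1-3 terms at level >= 3, uniformly across
#' namespaces; the truth table maps every reference gene of the family to
#' those terms.
#'
#' @param truth An `est_truth_set` from [generate_families()].
#' @param dag A `go_dag`.
#' @param seed Integer seed.
#' @return Tibble: `gene`, `family`, `term`.
#' @export
assign_family_go <- function(truth, dag, seed = 1L) {
  deep <- dag$terms$id[!is.na(dag$terms$level) & dag$terms$level >= 3]
  with_seed(child_seed(seed, "family-go"), {
    fam_terms <- lapply(stats::setNames(truth$families$family,
                                        truth$families$family),
                        function(f) sample(deep, sample(1:3, 1)))
    truth$proteins |>
      filter(!is.na(.data$family)) |>
      transmute(gene = .data$gene_id, family = .data$family) |>
      mutate(term = fam_terms[.data$family]) |>
      tidyr::unnest_longer("term")
  })
}
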