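mk_hits <- function(...) {
  # rows: query, subject, evalue, bitscore
  rows <- list(...)
  tibble::tibble(
    query = vapply(rows, `[[`, "", 1),
    subject = vapply(rows, `[[`, "", 2),
    evalue = as.numeric(vapply(rows, `[[`, "", 3)),
    bitscore = as.numeric(vapply(rows, `[[`, "", 4)),
    identity = 0.9)
}

test_that("mutual best hits form an edge; one-sided bests do not", {
  ab <- mk_hits(c("x", "y", "1e-50", "200"), c("x", "y2", "1e-10", "80"))
  ba <- mk_hits(c("y", "x", "1e-50", "200"))
  e <- rbh_pairs(ab, ba)
  expect_equal(nrow(e), 1)
  expect_equal(e$gene_a, "x")
  expect_equal(e$gene_b, "y")
  # y's best is x2, not x: no edge
  ba2 <- mk_hits(c("y", "x2", "1e-60", "220"), c("y", "x", "1e-50", "200"))
  expect_equal(nrow(rbh_pairs(ab, ba2)), 0)
  # hits above the cutoff never support an edge
  weak <- mk_hits(c("x", "y", "1e-3", "30"))
  weak_b <- mk_hits(c("y", "x", "1e-3", "30"))
  expect_equal(nrow(rbh_pairs(weak, weak_b)), 0)
})

test_that("rbh edges match brute-force recomputation on random tables", {
  set.seed(21)
  for (rep in 1:25) {
    genes_a <- paste0("a", 1:sample(3:20, 1))
    genes_b <- paste0("b", 1:sample(3:20, 1))
    rand_hits <- function(qs, ss) {
      n <- sample(5:40, 1)
      tibble::tibble(query = sample(qs, n, TRUE),
                     subject = sample(ss, n, TRUE),
                     evalue = 10^-sample(3:30, n, TRUE),
                     bitscore = round(runif(n, 30, 300)),
                     identity = runif(n, 0.3, 1)) |>
        dplyr::distinct(query, subject, .keep_all = TRUE)
    }
    ab <- rand_hits(genes_a, genes_b)
    ba <- rand_hits(genes_b, genes_a)
    mine <- rbh_pairs(ab, ba, evalue_cutoff = 1e-6)
    ref <- oracle_rbh(ab, ba, cutoff = 1e-6)
    expect_setequal(paste(mine$gene_a, mine$gene_b),
                    paste(ref$gene_a, ref$gene_b))
  }
})

test_that("a full pairwise triangle collapses to one 3-species clique", {
  edges <- tibble::tibble(
    species_a = c("a", "a", "b"), gene_a = c("a1", "a1", "b1"),
    species_b = c("b", "c", "c"), gene_b = c("b1", "c1", "c1"),
    sum_bits = c(100, 90, 80))
  genes <- tibble::tibble(species = c("a", "b", "c"),
                          gene = c("a1", "b1", "c1"))
  os <- ortholog_sets(edges, genes)
  expect_equal(nrow(os$sets), 1)
  expect_equal(os$sets$size, 3L)
  expect_true(all(os$assignments$region == "a+b+c"))
})

test_that("partner pairs without a closing edge fall back to 2-sets", {
  edges <- tibble::tibble(
    species_a = c("a", "a"), gene_a = c("a3", "a3"),
    species_b = c("b", "d"), gene_b = c("b3", "d3"),
    sum_bits = c(120, 100))
  genes <- tibble::tibble(species = c("a", "b", "d", "c"),
                          gene = c("a3", "b3", "d3", "c9"))
  os <- ortholog_sets(edges, genes)
  a3 <- os$assignments[os$assignments$gene == "a3", ]
  expect_equal(a3$region, "a+b")  # larger sum_bits wins the tie-break
  expect_equal(os$assignments$region[os$assignments$gene == "c9"], "c")
  # deterministic across runs
  os2 <- ortholog_sets(edges, genes)
  expect_identical(os$assignments, os2$assignments)
})

test_that("assignments match exhaustive search on random small instances", {
  set.seed(22)
  for (rep in 1:30) {
    inst <- random_edge_instance(n_genes = sample(2:5, 1), k = 4)
    os <- ortholog_sets(inst$edges, inst$genes)
    ref <- oracle_assignments(inst$edges, inst$genes)
    got <- os$assignments[order(os$assignments$gene), ]
    ref <- ref[order(ref$gene), ]
    expect_equal(got$region, ref$region)
  }
})

test_that("every emitted set is a clique and regions partition the genes", {
  set.seed(23)
  inst <- random_edge_instance(n_genes = 5, k = 4, p_edge = 0.7)
  os <- ortholog_sets(inst$edges, inst$genes)
  # independent all-pairs edge check on each set
  has_edge <- function(x, y) {
    any((inst$edges$gene_a == x & inst$edges$gene_b == y) |
          (inst$edges$gene_a == y & inst$edges$gene_b == x))
  }
  for (i in seq_len(nrow(os$sets))) {
    m <- os$sets$members[[i]]
    expect_false(anyDuplicated(m$species) > 0)
    if (nrow(m) > 1) {
      for (x in seq_len(nrow(m) - 1)) for (y in (x + 1):nrow(m)) {
        expect_true(has_edge(m$gene[x], m$gene[y]))
      }
    }
  }
  expect_setequal(os$assignments$gene, inst$genes$gene)
  expect_false(anyDuplicated(os$assignments$gene) > 0)
})

test_that("venn additivity holds and double assignment is a hard failure", {
  set.seed(24)
  inst <- random_edge_instance(n_genes = 4, k = 4)
  os <- ortholog_sets(inst$edges, inst$genes)
  totals <- table(inst$genes$species)
  venn <- venn_partition(os$assignments,
                         stats::setNames(as.integer(totals),
                                         names(totals)))
  sums <- tapply(venn$n_genes, venn$species, sum)
  expect_equal(as.integer(sums[names(totals)]),
               as.integer(totals))
  dup <- rbind(os$assignments, os$assignments[1, ])
  expect_error(venn_partition(dup), "double assignment")
  # wrong totals are rejected
  bad <- stats::setNames(as.integer(totals) + 1L, names(totals))
  expect_error(venn_partition(os$assignments, bad), "additivity")
})

test_that("a single species with no edges lands in one species-only region", {
  genes <- tibble::tibble(species = "solo", gene = paste0("g", 1:7))
  os <- ortholog_sets(tibble::tibble(species_a = character(0),
                                     gene_a = character(0),
                                     species_b = character(0),
                                     gene_b = character(0),
                                     sum_bits = numeric(0)), genes)
  venn <- venn_partition(os$assignments)
  expect_equal(nrow(venn), 1)
  expect_equal(venn$region, "solo")
  expect_equal(venn$n_genes, 7L)
})

test_that("planted topology yields more charo-plant than charo-chloro
           orthologs", {
  ts <- shared_truth()
  prot <- tibble::tibble(species = ts$proteins$species,
                         id = ts$proteins$gene_id,
                         seq = sub("\\*$", "", ts$proteins$seq))
  edges <- all_pairwise_rbh(prot)
  os <- ortholog_sets(edges, tibble::tibble(species = prot$species,
                                            gene = prot$id))
  reg <- os$assignments$region
  both <- function(x, y) sum(grepl(x, reg, fixed = TRUE) &
                               grepl(y, reg, fixed = TRUE))
  with_plant <- both("charoA", "ref_plant") + both("charoB", "ref_plant")
  with_chloro <- both("charoA", "ref_chlorophyte") +
    both("charoB", "ref_chlorophyte")
  expect_gt(with_plant, with_chloro)
  # planted 4-way families are mostly recovered as 4-species regions
  all4 <- ts$families$family[ts$families$subset ==
                               paste(ts$params$species_list, collapse = "+")]
  four_genes <- ts$proteins$gene_id[ts$proteins$family %in% all4 &
                                      ts$proteins$copy == 1]
  got4 <- os$assignments$region[os$assignments$gene %in% four_genes]
  expect_gte(mean(lengths(strsplit(got4, "+", fixed = TRUE)) == 4), 0.9)
})
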