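test_that("a 3-term chain parses with depths 1,2,3 and alt ids resolve", {
  path <- mini_obo(tempfile(fileext = ".obo"))
  dag <- load_ontology(path)
  lv <- stats::setNames(dag$terms$level, dag$terms$id)
  expect_equal(unname(lv[c("GO:0000001", "GO:0000002", "GO:0000003",
                           "GO:0000004")]), c(1L, 2L, 3L, 4L))
  # obsolete terms are dropped; stanza count matches a direct scan
  expect_false("GO:0000009" %in% dag$terms$id)
  n_live <- length(grep("^\\[Term\\]", readLines(path))) - 1
  expect_equal(nrow(dag$terms), n_live)
  expect_equal(estpipe:::resolve_alt("GO:0000033", dag), "GO:0000003")
})

test_that("cycles are a hard failure", {
  p <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:1", "name: a",
               "namespace: biological_process", "is_a: GO:2", "",
               "[Term]", "id: GO:2", "name: b",
               "namespace: biological_process", "is_a: GO:1", ""), p)
  expect_error(load_ontology(p), "cycle")
})

test_that("level-3 rollup maps terms per the level rules", {
  path <- mini_obo(tempfile(fileext = ".obo"))
  dag <- load_ontology(path)
  ann <- tibble::tibble(
    unigene_id = c("u1", "u2", "u3", "u3"),
    term = c("GO:0000003",   # exactly level 3 -> itself
             "GO:0000002",   # level 2 -> nothing
             "GO:0000004",   # level 4 -> its level-3 ancestor
             "GO:0000003"))  # dedupe with the line above
  roll <- rollup_level3(ann, dag)
  expect_equal(nrow(roll), 1)
  expect_equal(roll$term, "GO:0000003")
  expect_equal(roll$n, 2L)  # u1 and u3 once each
})

test_that("deep terms map to the same level-3 ancestors as a BFS oracle", {
  dag <- synthetic_ontology(n2 = 3, n3 = 3, n4 = 2)
  # independent BFS up the is_a edges
  bfs_l3 <- function(id) {
    lev <- stats::setNames(dag$terms$level, dag$terms$id)
    seen <- character(0); frontier <- id
    while (length(frontier)) {
      seen <- union(seen, frontier)
      frontier <- setdiff(
        dag$parents$parent[dag$parents$id %in% frontier], seen)
    }
    sort(seen[lev[seen] == 3])
  }
  deep <- dag$terms$id[dag$terms$level == 4]
  for (t in sample(deep, 5)) {
    expect_equal(sort(estpipe:::level3_ancestors(t, dag)), bfs_l3(t))
  }
})

test_that("annotation transfer inherits the full top-hit term set", {
  hits <- tibble::tibble(
    query = c("u1", "u1", "u2"),
    subject = c("gA", "gB", "gA"),
    evalue = c(1e-30, 1e-10, 1e-3),
    bitscore = c(200, 100, 40), identity = 0.9)
  ref_go <- tibble::tibble(gene = c("gA", "gA", "gB"),
                           term = c("t1", "t2", "t3"))
  ann <- transfer_annotations(hits, ref_go, evalue_cutoff = 1e-6)
  expect_setequal(ann$term[ann$unigene_id == "u1"], c("t1", "t2"))
  expect_false("u2" %in% ann$unigene_id)  # no passing hit -> no terms
})

test_that("fisher_two_sided matches brute-force enumeration and symmetry", {
  expect_equal(fisher_two_sided(10, 100, 10, 100), 1)
  expect_equal(fisher_two_sided(5, 100, 50, 900),
               oracle_fisher(5, 100, 50, 900))
  # closed-form extreme table
  expect_equal(fisher_two_sided(0, 10, 10, 10),
               min(1, 2 * choose(10, 0) * choose(10, 10) / choose(20, 10)))
  set.seed(41)
  for (rep in 1:50) {
    n1 <- sample(1:30, 1); n2 <- sample(1:30, 1)
    a <- sample(0:n1, 1); b <- sample(0:n2, 1)
    expect_equal(fisher_two_sided(a, n1, b, n2),
                 oracle_fisher(a, n1, b, n2))
    expect_equal(fisher_two_sided(a, n1, b, n2),
                 fisher_two_sided(b, n2, a, n1))  # group-swap symmetry
  }
  expect_equal(fisher_two_sided(0, 5, 0, 9), 1)  # all-zero margin
})

test_that("fisher_two_sided agrees with stats::fisher.test", {
  set.seed(42)
  for (rep in 1:25) {
    n1 <- sample(2:40, 1); n2 <- sample(2:40, 1)
    a <- sample(0:n1, 1); b <- sample(0:n2, 1)
    ft <- stats::fisher.test(matrix(c(a, n1 - a, b, n2 - b), 2))$p.value
    expect_equal(fisher_two_sided(a, n1, b, n2), ft, tolerance = 1e-9)
  }
})

test_that("proportion comparison flags planted effects and stars correctly", {
  counts <- function(n) tibble::tibble(
    namespace = "biological_process",
    term = paste0("T", seq_along(n)),
    name = paste0("term ", seq_along(n)), n = n)
  same <- compare_proportions(counts(c(30, 50, 20)), counts(c(30, 50, 20)),
                              n1 = 200, n2 = 200)
  expect_true(all(same$p == 1))
  expect_true(all(same$stars == ""))
  # star thresholds are exclusive bounds
  expect_equal(dplyr::case_when(0.009 < 0.001 ~ "**", 0.009 < 0.01 ~ "*",
                                TRUE ~ ""), "*")
  sp <- counts(c(400, 300, 300))
  rf <- counts(c(200, 400, 400))
  cmp <- compare_proportions(sp, rf, n1 = 2000, n2 = 2000)
  t1 <- cmp[cmp$term == "T1", ]
  expect_lt(t1$p, 0.01)
  expect_equal(t1$direction, 1)
  expect_true(t1$stars %in% c("*", "**"))
  # vocabulary mismatch: union with zero fill
  extra <- counts(c(10, 10, 10, 10))
  cmp2 <- compare_proportions(counts(c(5, 5, 5)), extra, n1 = 50, n2 = 100)
  expect_equal(nrow(cmp2), 4)
  expect_equal(cmp2$a[cmp2$term == "T4"], 0L)
})

test_that("planted 2x overrepresentation is detected at n ~ 2000", {
  dag <- synthetic_ontology()
  set.seed(43)
  l3 <- dag$terms$id[dag$terms$level == 3 &
                       dag$terms$namespace == "biological_process"]
  n1 <- 2000; n2 <- 2000
  base_p <- rep(0.06, length(l3))
  sp_p <- base_p; sp_p[1] <- 0.12  # the planted 2x term
  sp_counts <- tibble::tibble(namespace = "BP", term = l3,
                              name = l3, n = rbinom(length(l3), n1, sp_p))
  rf_counts <- tibble::tibble(namespace = "BP", term = l3,
                              name = l3, n = rbinom(length(l3), n2, base_p))
  cmp <- compare_proportions(sp_counts, rf_counts, n1 = n1, n2 = n2)
  hit <- cmp[cmp$term == l3[1], ]
  expect_lt(hit$p, 0.01)
  expect_equal(hit$direction, 1)
})

test_that("planted GO terms transfer back through the search at low
           divergence", {
  ts <- shared_truth()
  dag <- synthetic_ontology()
  truth_go <- assign_family_go(ts, dag, seed = 9)
  ref_go <- truth_go[grepl("^ref_plant", truth_go$gene), c("gene", "term")]
  # charoA peptides vs the reference proteome
  pa <- ts$proteins[ts$proteins$species == "charoA" & ts$proteins$copy == 1, ]
  shared_fams <- ts$families$family[grepl("ref_plant", ts$families$subset) &
                                      grepl("charoA", ts$families$subset)]
  pa <- pa[pa$family %in% shared_fams, ]
  rp <- ts$proteins[ts$proteins$species == "ref_plant", ]
  hits <- search_homologs(
    tibble::tibble(id = pa$gene_id, seq = sub("\\*$", "", pa$seq)),
    tibble::tibble(id = rp$gene_id, seq = sub("\\*$", "", rp$seq)))
  ann <- transfer_annotations(hits, ref_go)
  planted <- truth_go[match(pa$gene_id, truth_go$gene), ]
  ok <- vapply(pa$gene_id, function(g) {
    fam <- pa$family[pa$gene_id == g]
    got <- sort(ann$term[ann$unigene_id == g])
    want <- sort(unique(truth_go$term[truth_go$family == fam &
                                        grepl("^ref_plant", truth_go$gene)]))
    length(got) > 0 && identical(got, want)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
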