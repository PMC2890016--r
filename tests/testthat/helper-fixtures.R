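# Shared fixtures and independent oracles used across the suite.

rnd_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

rnd_prot <- function(n) {
  paste(sample(setdiff(estpipe:::AA_ALPHABET, c("B", "Z", "X", "*")), n,
               replace = TRUE), collapse = "")
}

# memoised medium synthetic truth set + hexamer model shared by tests
.fixture_cache <- new.env(parent = emptyenv())

shared_truth <- function() {
  if (is.null(.fixture_cache$truth)) {
    .fixture_cache$truth <- generate_families(
      generator_params(n_families = 60, seed = 3))
  }
  .fixture_cache$truth
}

shared_model <- function() {
  if (is.null(.fixture_cache$model)) {
    ts <- shared_truth()
    cod <- ts$transcripts[ts$transcripts$coding &
                            ts$transcripts$species == "ref_plant", ]
    cds <- substr(cod$seq, cod$cds_start + 1, cod$cds_end)
    set.seed(42)
    bg <- replicate(40, rnd_dna(2000))
    .fixture_cache$model <- train_hexamer_model(cds, bg)
  }
  .fixture_cache$model
}

# ---- independent oracles ----

# DUST score recomputed from the definition with a plain loop
oracle_dust <- function(seq) {
  s <- toupper(seq)
  L <- nchar(s)
  if (L < 3) return(0)
  counts <- list()
  for (i in 1:(L - 2)) {
    t <- substr(s, i, i + 2)
    counts[[t]] <- (counts[[t]] %||% 0) + 1
  }
  tot <- 0
  for (c in counts) tot <- tot + c * (c - 1) / 2
  tot / (L - 2)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive best frame-path score with at most `max_shifts` frame
# switches, over all intervals, from the per-position contribution
# matrix (3 x P) -- enumeration via precomputed interval sums
oracle_coding_paths <- function(contrib, penalty, max_shifts = 2) {
  P <- ncol(contrib)
  IS <- lapply(1:3, function(f) {
    cs <- c(0, cumsum(contrib[f, ]))
    outer(seq_len(P), seq_len(P),
          function(a, b) ifelse(a <= b, cs[b + 1] - cs[a], -Inf))
  })
  best <- max(vapply(IS, max, numeric(1)))                 # 0 shifts
  if (max_shifts >= 1 && P >= 2) {
    # colmax[f, c] = best interval ending exactly at c in frame f
    colmax <- vapply(IS, function(m) apply(m, 2, max), numeric(P))
    # rowmax[f, c] = best interval starting exactly at c in frame f
    rowmax <- vapply(IS, function(m) apply(m, 1, max), numeric(P))
    for (c in 1:(P - 1)) {
      for (f1 in 1:3) for (f2 in 1:3) {
        if (f1 == f2) next
        best <- max(best, colmax[c, f1] + rowmax[c + 1, f2] - penalty)
      }
    }
    if (max_shifts >= 2 && P >= 3) {
      for (c1 in 1:(P - 2)) for (c2 in (c1 + 1):(P - 1)) {
        mid <- vapply(1:3, function(f) IS[[f]][c1 + 1, c2], numeric(1))
        for (f1 in 1:3) for (f2 in 1:3) for (f3 in 1:3) {
          if (f1 == f2 || f2 == f3) next
          best <- max(best, colmax[c1, f1] + mid[f2] +
                        rowmax[c2 + 1, f3] - 2 * penalty)
        }
      }
    }
  }
  best
}

# literal all-paths enumeration (tiny inputs only): every interval and
# every frame assignment per position
oracle_coding_all_paths <- function(contrib, penalty) {
  P <- ncol(contrib)
  stopifnot(P <= 12)
  best <- -Inf
  for (a in 1:P) for (b in a:P) {
    len <- b - a + 1
    grid <- as.matrix(expand.grid(rep(list(1:3), len)))
    for (r in seq_len(nrow(grid))) {
      f <- grid[r, ]
      sc <- sum(contrib[cbind(f, a:b)]) -
        penalty * sum(diff(f) != 0)
      if (sc > best) best <- sc
    }
  }
  best
}

# brute-force RBH edges from raw hit tables (independent of top_hit)
oracle_rbh <- function(hits_ab, hits_ba, cutoff) {
  bestof <- function(h, q) {
    hh <- h[h$query == q & h$evalue < cutoff & h$query != h$subject, ]
    if (nrow(hh) == 0) return(NA_character_)
    hh <- hh[order(hh$evalue, -hh$bitscore, -hh$identity, hh$subject), ]
    hh$subject[1]
  }
  out <- list()
  for (q in unique(hits_ab$query)) {
    s <- bestof(hits_ab, q)
    if (is.na(s)) next
    if (identical(bestof(hits_ba, s), q)) {
      out[[length(out) + 1]] <- c(gene_a = q, gene_b = s)
    }
  }
  if (!length(out)) {
    return(data.frame(gene_a = character(0), gene_b = character(0)))
  }
  as.data.frame(do.call(rbind, out))
}

# exhaustive per-gene maximal valid clique assignment over the full gene
# universe (independent of ortholog_sets' candidate generation)
oracle_assignments <- function(edges, genes) {
  ek <- new.env(parent = emptyenv())
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      key <- paste(sort(c(edges$gene_a[r], edges$gene_b[r])),
                   collapse = "|")
      assign(key, edges$sum_bits[r], envir = ek)
    }
  }
  has_edge <- function(x, y) {
    !is.null(ek[[paste(sort(c(x, y)), collapse = "|")]])
  }
  edge_bits <- function(x, y) {
    ek[[paste(sort(c(x, y)), collapse = "|")]] %||% 0
  }
  species <- unique(genes$species)
  res <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes$gene[gi]; gs <- genes$species[gi]
    # choices per other species: any of its genes, or none
    others <- setdiff(species, gs)
    choice_sets <- lapply(others, function(s)
      c(NA_character_, genes$gene[genes$species == s]))
    grid <- expand.grid(choice_sets, stringsAsFactors = FALSE)
    best <- NULL
    for (r in seq_len(max(1, nrow(grid)))) {
      memb <- g
      msp <- gs
      if (nrow(grid) > 0) {
        sel <- unlist(grid[r, ], use.names = FALSE)
        memb <- c(g, sel[!is.na(sel)])
        msp <- c(gs, others[!is.na(sel)])
      }
      ok <- TRUE; bits <- 0
      if (length(memb) > 1) {
        for (x in seq_len(length(memb) - 1)) for (y in (x + 1):length(memb)) {
          if (!has_edge(memb[x], memb[y])) { ok <- FALSE; break }
          bits <- bits + edge_bits(memb[x], memb[y])
        }
      }
      if (!ok) next
      subset_str <- paste(sort(msp), collapse = "+")
      cand <- list(size = length(memb), bits = bits, subset = subset_str)
      if (is.null(best) || cand$size > best$size ||
          (cand$size == best$size && cand$bits > best$bits) ||
          (cand$size == best$size && cand$bits == best$bits &&
           cand$subset < best$subset)) best <- cand
    }
    res[[gi]] <- data.frame(species = gs, gene = g, region = best$subset)
  }
  do.call(rbind, res)
}

# random RBH-consistent edge instance over k species
random_edge_instance <- function(n_genes = 5, k = 4, p_edge = 0.6) {
  species <- paste0("sp", seq_len(k))
  genes <- do.call(rbind, lapply(species, function(s)
    data.frame(species = s, gene = paste0(s, "_g", seq_len(n_genes)))))
  edges <- list()
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    ga <- sample(genes$gene[genes$species == species[i]])
    gb <- sample(genes$gene[genes$species == species[j]])
    nmatch <- rbinom(1, n_genes, p_edge)
    if (nmatch > 0) {
      for (t in seq_len(nmatch)) {
        edges[[length(edges) + 1]] <- data.frame(
          species_a = species[i], gene_a = ga[t],
          species_b = species[j], gene_b = gb[t],
          sum_bits = round(runif(1, 50, 500), 1))
      }
    }
  }
  list(genes = tibble::as_tibble(genes),
       edges = if (length(edges)) tibble::as_tibble(do.call(rbind, edges))
               else tibble::tibble(species_a = character(0),
                                   gene_a = character(0),
                                   species_b = character(0),
                                   gene_b = character(0),
                                   sum_bits = numeric(0)))
}

# two-sided Fisher p by literal table enumeration with binomial
# coefficients (independent of dhyper)
oracle_fisher <- function(a, n1, b, n2) {
  k <- a + b
  if (k == 0) return(1)
  xs <- max(0, k - n2):min(k, n1)
  pr <- choose(n1, xs) * choose(n2, k - xs) / choose(n1 + n2, k)
  p0 <- choose(n1, a) * choose(n2, b) / choose(n1 + n2, k)
  min(1, sum(pr[pr <= p0 * (1 + 1e-7)]))
}

# mutate a protein: substitutions plus optional small indels
mutate_prot <- function(seq, sub_rate = 0.15, n_indel = 0) {
  aa <- strsplit(seq, "")[[1]]
  alph <- setdiff(estpipe:::AA_ALPHABET, c("B", "Z", "X", "*"))
  hit <- runif(length(aa)) < sub_rate
  aa[hit] <- sample(alph, sum(hit), replace = TRUE)
  if (n_indel > 0) {
    for (t in seq_len(n_indel)) {
      pos <- sample(seq_along(aa), 1)
      if (runif(1) < 0.5 && length(aa) > 10) {
        aa <- aa[-pos]
      } else {
        aa <- append(aa, sample(alph, 1), after = pos)
      }
    }
  }
  paste(aa, collapse = "")
}

# small OBO text for parser tests
mini_obo <- function(path) {
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root", "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: middle", "namespace: biological_process",
    "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: leaf", "namespace: biological_process",
    "alt_id: GO:0000033", "is_a: GO:0000002", "",
    "[Term]", "id: GO:0000004", "name: deep leaf",
    "namespace: biological_process", "is_a: GO:0000003", "",
    "[Term]", "id: GO:0000009", "name: gone",
    "namespace: biological_process", "is_obsolete: true", ""), path)
  path
}
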