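# Tiny annotation world: g genes on chr1, `per` sites each, all intragenic.
block_world <- function(n_genes, per) {
  genes <- tibble::tibble(gene_id = sprintf("g%02d", seq_len(n_genes)),
                          chrom = "chr1",
                          start = seq_len(n_genes) * 100000L,
                          strand = "+")
  genes$end <- genes$start + 50000L
  sites <- tibble::tibble(
    chrom = "chr1",
    pos = as.integer(rep(genes$start, each = per) +
                       seq_len(per) * 10L),
    gene_id = rep(genes$gene_id, each = per),
    zone = "intragenic")
  sites$site_id <- paste0("chr1:", sites$pos)
  list(genes = genes,
       annotated = sites[c("site_id", "chrom", "pos", "gene_id", "zone")])
}

test_that("hypergeometric upper tails match closed-form hand cases", {
  expect_equal(hypergeom_enrichment(10, 4, 5, 4), 6 / 252)
  expect_equal(hypergeom_enrichment(50, 10, 20, 0), 1.0)
  expect_equal(hypergeom_enrichment(30, 7, 30, 7), 1.0)   # n = N forces k = K
  expect_error(hypergeom_enrichment(10, 4, 5, 6), "inconsistent")
  expect_error(hypergeom_enrichment(10, 12, 5, 2), "inconsistent")
})

test_that("hypergeometric tails equal exhaustive subset enumeration", {
  # enumerate all n-subsets of 1..N with K marked elements
  for (N in c(6, 9)) {
    for (K in c(2, 4)) {
      for (n in c(3, 5)) {
        subsets <- utils::combn(N, n)
        overlap <- colSums(subsets <= K)   # elements 1..K are the hits
        for (k in 0:min(K, n)) {
          expect_equal(hypergeom_enrichment(N, K, n, k),
                       mean(overlap >= k), tolerance = 1e-12)
        }
        # pmf sums to one over the support
        pmf <- vapply(0:min(K, n), function(k) mean(overlap == k), numeric(1))
        expect_equal(sum(pmf), 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("enrichment is monotone in the observed overlap", {
  p <- vapply(3:8, function(k) hypergeom_enrichment(40, 10, 12, k), numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("permutation p has the add-one floor and trivial endpoints", {
  w <- block_world(10, 4)
  set.seed(31)
  records <- tibble::tibble(site_id = w$annotated$site_id,
                            p.value = runif(nrow(w$annotated)))
  # GWAS set = entire universe: the null statistic always ties the observed
  expect_equal(permutation_enrichment(records, w$annotated, w$genes$gene_id,
                                      n_perm = 200, seed = 1), 1)
  # no nominal hits at all
  rec0 <- dplyr::mutate(records, p.value = 0.5)
  expect_equal(permutation_enrichment(rec0, w$annotated, w$genes$gene_id[1:3],
                                      n_perm = 200, seed = 1), 1)
  # all hits concentrated in the GWAS genes: the null can only tie by
  # redrawing exactly those genes, so p stays near the add-one floor
  rec1 <- dplyr::mutate(records,
                        p.value = ifelse(w$annotated$gene_id %in%
                                           c("g01", "g02"), 0.001, 0.9))
  p <- permutation_enrichment(rec1, w$annotated, c("g01", "g02"),
                              n_perm = 500, seed = 2)
  expect_gte(p, 1 / 501)
  expect_lt(p, 0.05)
  # same seed is bit-reproducible; the site-level null unit also works
  p2 <- permutation_enrichment(rec1, w$annotated, c("g01", "g02"),
                               n_perm = 500, seed = 2)
  expect_identical(p, p2)
  ps <- permutation_enrichment(rec1, w$annotated, c("g01", "g02"),
                               n_perm = 500, seed = 2, null_unit = "site")
  expect_gte(ps, 1 / 501)
  expect_error(permutation_enrichment(records, w$annotated, "nope",
                                      n_perm = 10, seed = 1), "no GWAS")
})

test_that("multi-gene sites are counted once in the permutation statistic", {
  # two overlapping genes sharing every site, plus two disjoint genes
  ann <- tibble::tibble(
    site_id = c("s1", "s1", "s2", "s2", "s3", "s4"),
    chrom = "chr1", pos = c(1, 1, 2, 2, 3, 4),
    gene_id = c("a", "b", "a", "b", "c", "d"),
    zone = "intragenic")
  records <- tibble::tibble(site_id = paste0("s", 1:4),
                            p.value = c(0.01, 0.01, 0.9, 0.9))
  # gwas = {a, b}: observed statistic must be 2 distinct sites, not 4
  p_ab <- permutation_enrichment(records, ann, c("a", "b"),
                                 n_perm = 400, seed = 5)
  p_cd <- permutation_enrichment(records, ann, c("c", "d"),
                                 n_perm = 400, seed = 5)
  expect_lt(p_ab, p_cd)
})

test_that("the per-measure enrichment report carries consistent counts", {
  w <- block_world(12, 5)
  set.seed(77)
  records <- dplyr::bind_rows(lapply(c("sol_sr", "sol_act"), function(m)
    tibble::tibble(site_id = w$annotated$site_id, measure = m,
                   p.value = runif(nrow(w$annotated)))))
  rep <- enrichment_report(records, w$annotated, w$genes$gene_id[1:4],
                           n_perm = 300, seed = 9)
  expect_equal(nrow(rep), 2L)
  expect_true(all(rep$N == 60 & rep$n == 20))
  expect_true(all(rep$k <= pmin(rep$K, rep$n)))
  expect_true(all(rep$p_hypergeometric > 0 & rep$p_hypergeometric <= 1))
  expect_true(all(rep$p_permutation >= 1 / 301 & rep$p_permutation <= 1))
})

test_that("GO over-representation matches enumeration and handles edge cases", {
  universe <- sprintf("u%02d", 1:10)
  tm <- tibble::tibble(
    gene_id = c(universe[1:3], universe[4:5], universe[1:10]),
    term_id = c(rep("T1", 3), rep("T2", 2), rep("T3", 10)),
    term_name = c(rep("all three", 3), rep("none", 2), rep("everything", 10)),
    ontology = "BP")
  sig <- universe[1:3]
  res <- go_enrichment(sig, universe, tm)
  # P(all 3 significant genes in a 3-gene term) = 1/C(10,3)
  expect_equal(res$p.value[res$term_id == "T1"], 1 / 120)
  expect_equal(res$p.value[res$term_id == "T2"], 1.0)  # disjoint term
  expect_true(all(res$mapped <= res$n_term))
  expect_equal(res$q.value, bh_fdr(res$p.value), tolerance = 1e-12)
  # empty significant set: empty result, not an error
  empty <- go_enrichment(character(), universe, tm)
  expect_equal(nrow(empty), 0L)
  expect_error(go_enrichment(c("zzz"), universe, tm), "subset")
  expect_error(go_enrichment(sig, universe, tm[0, ]), "covers no")
})

test_that("gene overlaps enumerate pairs and triples correctly", {
  sets <- list(sol_sr = c("A", "B", "C"), sol_act = c("B", "C", "D"),
               sol_psg = c("C"))
  ov <- gene_overlap(sets)
  expect_equal(nrow(ov), 3L + 1L)    # three pairs, one triple
  get <- function(m) ov$n_overlap[ov$measures == m]
  expect_equal(get("sol_sr & sol_act"), 2L)
  expect_equal(get("sol_sr & sol_psg"), 1L)
  expect_equal(get("sol_sr & sol_act & sol_psg"), 1L)
  expect_identical(ov$genes[[which(ov$measures == "sol_sr & sol_act")]],
                   c("B", "C"))
  # identical and disjoint sets
  ov2 <- gene_overlap(list(a = c("X", "Y"), b = c("X", "Y"), c = "Q"))
  expect_equal(ov2$n_overlap[ov2$measures == "a & b"], 2L)
  expect_equal(ov2$n_overlap[ov2$measures == "a & c"], 0L)
  expect_error(gene_overlap(list(a = "X")), "at least two")
})
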