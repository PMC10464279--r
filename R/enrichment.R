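#' Upper-tail hypergeometric enrichment p-value
#'
#' For a universe of `N` analyzable sites of which `K` are nominal hits
#' (association p below threshold) and a group of `n` sites (e.g. the
#' GWAS-informed group), the observed overlap `k` is tested against
#' `X ~ Hypergeometric(N, K, n)` with `p = P(X >= k)`.
#'
#' @param N Universe size.
#' @param K Total hits in the universe.
#' @param n Group size.
#' @param k Observed hits inside the group.
#' @return Upper-tail p-value.
#' @export
#' @examples
#' hypergeom_enrichment(N = 10, K = 4, n = 5, k = 4)  # 6/252
hypergeom_enrichment <- function(N, K, n, k) {
  if (anyNA(c(N, K, n, k)) || k < 0 || K < 0 || n < 0 ||
      K > N || n > N || k > min(K, n)) {
    abort_user("inconsistent hypergeometric counts: need 0 <= k <= min(K, n) <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# Shared bookkeeping for the enrichment tests: nominal-hit site sets per
# gene, restricted to the analyzable non-intergenic universe.
enrichment_counts <- function(records, annotated, gwas_genes,
                              p_threshold = 0.05) {
  ann <- annotated[!is.na(annotated$gene_id), c("site_id", "gene_id")]
  ann <- ann[ann$site_id %in% records$site_id, ]
  universe_sites <- unique(ann$site_id)
  hit_sites <- records$site_id[records$p.value < p_threshold]
  hit_sites <- intersect(universe_sites, hit_sites)
  genes <- unique(ann$gene_id)
  gwas <- intersect(gwas_genes, genes)
  gwas_sites <- unique(ann$site_id[ann$gene_id %in% gwas])
  list(ann = ann, genes = genes, gwas = gwas,
       N = length(universe_sites), K = length(hit_sites),
       n = length(gwas_sites),
       k = length(intersect(gwas_sites, hit_sites)),
       hit_sites = hit_sites)
}

#' Permutation test for gene-set enrichment of nominal hits
#'
#' The observed statistic is the number of distinct sites associated at
#' `p < p_threshold` that map to the GWAS-informed genes. The null is
#' resampled by drawing random gene sets of the same gene count from the
#' annotated gene universe (`null_unit = "gene"`, the default, which
#' preserves intra-gene site correlation) or random site sets of the same
#' site count (`null_unit = "site"`), recomputing the statistic each time.
#' The p-value uses the add-one correction
#' `(1 + #\{null >= observed\}) / (n_perm + 1)` and is therefore never
#' below `1/(n_perm + 1)`; it is bit-reproducible for a given seed.
#'
#' @param records Association records for one measure (tibble with
#'   `site_id` and `p.value`).
#' @param annotated Output of [annotate_sites()].
#' @param gwas_genes GWAS-informed gene ids.
#' @param p_threshold Nominal association threshold defining a hit.
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutation draws.
#' @param null_unit Resampling unit, `"gene"` or `"site"`.
#' @return Permutation p-value.
#' @export
permutation_enrichment <- function(records, annotated, gwas_genes,
                                   p_threshold = 0.05, n_perm = 1000,
                                   seed = 1L, null_unit = c("gene", "site")) {
  null_unit <- match.arg(null_unit)
  cnt <- enrichment_counts(records, annotated, gwas_genes, p_threshold)
  if (!length(cnt$gwas)) {
    abort_user("no GWAS-informed gene in the annotated universe")
  }
  if (length(cnt$gwas) > length(cnt$genes)) {
    abort_user("gene universe smaller than the GWAS-informed set")
  }
  observed <- cnt$k
  with_seed(seed, {
    if (null_unit == "gene") {
      hit_ann <- cnt$ann[cnt$ann$site_id %in% cnt$hit_sites, ]
      G <- length(cnt$genes); g <- length(cnt$gwas)
      gene_idx <- match(hit_ann$gene_id, cnt$genes)
      if (!anyDuplicated(hit_ann$site_id)) {
        # every hit site maps to one gene: the statistic is additive
        hit_count <- tabulate(gene_idx, nbins = G)
        null_stat <- vapply(seq_len(n_perm), function(i) {
          sum(hit_count[sample.int(G, g)])
        }, numeric(1))
      } else {
        hits_by_gene <- split(hit_ann$site_id, gene_idx)
        null_stat <- vapply(seq_len(n_perm), function(i) {
          idx <- as.character(sample.int(G, g))
          length(unique(unlist(
            hits_by_gene[intersect(idx, names(hits_by_gene))],
            use.names = FALSE)))
        }, numeric(1))
      }
    } else {
      universe_sites <- unique(cnt$ann$site_id)
      is_hit <- universe_sites %in% cnt$hit_sites
      null_stat <- vapply(seq_len(n_perm), function(i) {
        sum(is_hit[sample.int(length(universe_sites), cnt$n)])
      }, numeric(1))
    }
    (1 + sum(null_stat >= observed)) / (n_perm + 1)
  })
}

#' Hypergeometric + permutation enrichment report for each measure
#'
#' Runs the site-level hypergeometric test and the resampling permutation
#' test of nominal-hit over-representation in the GWAS-informed group, for
#' every measure present in the association records.
#'
#' @param ewas An `ewas_result` or its records tibble (all measures).
#' @param annotated Output of [annotate_sites()].
#' @param gwas_genes GWAS-informed gene ids.
#' @param p_threshold Nominal association threshold defining a hit.
#' @param n_perm,seed,null_unit Passed to [permutation_enrichment()]; the
#'   seed is offset per measure so draws are independent.
#' @return Tibble with one row per measure: universe size `N`, nominal
#'   hits `K`, group size `n`, overlap `k`, `p_hypergeometric`,
#'   `p_permutation`, `n_perm`, `seed`.
#' @export
enrichment_report <- function(ewas, annotated, gwas_genes,
                              p_threshold = 0.05, n_perm = 1000, seed = 1L,
                              null_unit = "gene") {
  records <- if (inherits(ewas, "ewas_result")) ewas$records else ewas
  measures <- unique(records$measure)
  purrr::map_dfr(seq_along(measures), function(i) {
    m <- measures[i]
    rec <- records[records$measure == m, ]
    cnt <- enrichment_counts(rec, annotated, gwas_genes, p_threshold)
    tibble::tibble(
      measure = m, N = cnt$N, K = cnt$K, n = cnt$n, k = cnt$k,
      p_hypergeometric = hypergeom_enrichment(cnt$N, cnt$K, cnt$n, cnt$k),
      p_permutation = permutation_enrichment(
        rec, annotated, gwas_genes, p_threshold, n_perm,
        seed = seed + i - 1L, null_unit = null_unit),
      n_perm = n_perm, seed = seed + i - 1L)
  })
}

#' Read a gene-to-GO-term mapping table
#'
#' @param path TSV with columns `gene_id`, `term_id`, `term_name`,
#'   `ontology` (header required). The mapping is taken as given; no graph
#'   propagation is applied.
#' @return Tibble of the mapping.
#' @export
read_term_map <- function(path) {
  tab <- readr::read_tsv(path, col_types = "cccc", progress = FALSE)
  need <- c("gene_id", "term_id", "term_name", "ontology")
  if (!all(need %in% names(tab))) {
    abort_user(paste0("term map needs columns: ", paste(need, collapse = ", ")))
  }
  tab
}

#' Gene ontology over-representation of significant genes
#'
#' One-sided hypergeometric test per GO term, at the gene level: the
#' universe is every annotated gene with at least one analyzable site, and
#' the significant set is the genes containing at least one site with
#' `q < q_threshold`. q-values are Benjamini-Hochberg within each
#' ontology, mirroring per-ontology reporting.
#'
#' @param significant_genes Character vector of significant gene ids
#'   (subset of `universe`).
#' @param universe Character vector: the annotated gene universe.
#' @param term_map Tibble from [read_term_map()].
#' @return Tibble: `term_id`, `term_name`, `ontology`, `n_term` (universe
#'   genes mapped to the term), `mapped` (significant genes mapped),
#'   `p.value`, `q.value`, sorted by q then p. Empty significant set gives
#'   an empty tibble.
#' @export
go_enrichment <- function(significant_genes, universe, term_map) {
  universe <- unique(universe)
  tm <- term_map[term_map$gene_id %in% universe, ]
  if (nrow(tm) == 0L) abort_user("term map covers no universe gene")
  extra <- setdiff(significant_genes, universe)
  if (length(extra)) {
    abort_user("significant genes must be a subset of the universe")
  }
  sig <- unique(significant_genes)
  if (!length(sig)) {
    return(tibble::tibble(term_id = character(), term_name = character(),
                          ontology = character(), n_term = integer(),
                          mapped = integer(), p.value = numeric(),
                          q.value = numeric()))
  }
  terms <- dplyr::summarise(
    dplyr::group_by(tm, .data$term_id, .data$term_name, .data$ontology),
    n_term = dplyr::n_distinct(.data$gene_id),
    mapped = dplyr::n_distinct(intersect(.data$gene_id, sig)),
    .groups = "drop")
  terms$p.value <- mapply(hypergeom_enrichment,
                          N = length(universe), K = length(sig),
                          n = terms$n_term, k = terms$mapped)
  terms <- dplyr::mutate(dplyr::group_by(terms, .data$ontology),
                         q.value = bh_fdr(.data$p.value))
  dplyr::arrange(dplyr::ungroup(terms), .data$q.value, .data$p.value,
                 .data$term_id)
}

#' Cross-measure overlap of significant gene sets
#'
#' Intersection cardinalities and member lists for every pair of measures
#' and, when at least three sets are supplied, every triple (e.g. the SOL
#' triple across self-report, actigraphy and polysomnography).
#'
#' @param gene_sets Named list of character vectors: significant genes per
#'   measure.
#' @return Tibble: `measures` (ampersand-joined names), `k` (2 or 3),
#'   `n_overlap`, `genes` (list column of the intersection members).
#' @export
#' @examples
#' gene_overlap(list(sol_sr = c("A", "B"), sol_act = c("B", "C"),
#'                   sol_psg = c("B")))
gene_overlap <- function(gene_sets) {
  if (length(gene_sets) < 2L) abort_user("need at least two gene sets")
  if (is.null(names(gene_sets)) || any(!nzchar(names(gene_sets)))) {
    abort_user("gene_sets must be named")
  }
  combos <- function(k) {
    cc <- utils::combn(names(gene_sets), k, simplify = FALSE)
    purrr::map_dfr(cc, function(nms) {
      inter <- Reduce(intersect, gene_sets[nms])
      tibble::tibble(measures = paste(nms, collapse = " & "),
                     k = k, n_overlap = length(inter),
                     genes = list(sort(inter)))
    })
  }
  out <- combos(2L)
  if (length(gene_sets) >= 3L) out <- dplyr::bind_rows(out, combos(3L))
  out
}
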