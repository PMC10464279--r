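# Shared in-code fixtures for the test suite. Everything is generated at
# test time; no binary data ships with the package.

# A small call set with hand-controllable counts.
toy_calls <- function(meth, unmeth, chrom = NULL, pos = NULL) {
  S <- nrow(meth)
  chrom <- chrom %||% rep("chr1", S)
  pos <- pos %||% seq(100, by = 100, length.out = S)
  sites <- tibble::tibble(site_id = paste0(chrom, ":", pos),
                          chrom = chrom, pos = as.integer(pos))
  methyl_calls(sites, sprintf("s%d", seq_len(ncol(meth))), meth, unmeth)
}

# Random gene models on a couple of chromosomes, both strands.
random_genes <- function(n, seed, chrom_len = 1e6,
                         chroms = c("chr1", "chr2")) {
  set.seed(seed)
  tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    start = sample.int(chrom_len - 20000, n),
    strand = sample(c("+", "-"), n, replace = TRUE)
  ) |>
    dplyr::mutate(end = start + sample(500:15000, n, replace = TRUE))
}

random_sites <- function(n, seed, chrom_len = 1e6,
                         chroms = c("chr1", "chr2")) {
  set.seed(seed)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    pos = sample.int(chrom_len, n)
  ) |>
    dplyr::distinct() |>
    dplyr::mutate(site_id = paste0(chrom, ":", pos),
                  .before = 1)
}

# Independent O(S*G) brute-force annotation oracle: strand-aware extended
# borders, zone from the original body.
brute_force_annotate <- function(sites, genes, upstream = 1500,
                                 downstream = 500) {
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    hit <- FALSE
    for (j in seq_len(nrow(genes))) {
      if (sites$chrom[i] != genes$chrom[j]) next
      if (genes$strand[j] == "+") {
        lo <- max(1, genes$start[j] - upstream)
        hi <- genes$end[j] + downstream
      } else {
        lo <- max(1, genes$start[j] - downstream)
        hi <- genes$end[j] + upstream
      }
      p <- sites$pos[i]
      if (p < lo || p > hi) next
      hit <- TRUE
      zone <- if (p >= genes$start[j] && p <= genes$end[j]) {
        "intragenic"
      } else if ((genes$strand[j] == "+") == (p < genes$start[j])) {
        "upstream"
      } else "downstream"
      rows[[length(rows) + 1L]] <- tibble::tibble(
        site_id = sites$site_id[i], gene_id = genes$gene_id[j], zone = zone)
    }
    if (!hit) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        site_id = sites$site_id[i], gene_id = NA_character_,
        zone = "intergenic")
    }
  }
  dplyr::arrange(dplyr::bind_rows(rows), site_id, gene_id)
}

# Hand-written Benjamini-Hochberg step-up, independent of p.adjust.
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, p[o] * m / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

`%||%` <- function(a, b) if (is.null(a)) b else a
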