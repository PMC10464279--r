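#' Read gene models from a BED6 file
#'
#' BED is 0-based half-open on disk; coordinates are converted to the
#' package's 1-based inclusive convention at this boundary (`start = V2 + 1`,
#' `end = V3`).
#'
#' @param path Path to a six-column BED file (chrom, start, end, name,
#'   score, strand).
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_bed6 <- function(path) {
  tab <- readr::read_tsv(
    path, col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicnc", progress = FALSE)
  if (nrow(tab) == 0L) abort_user("empty gene-model file")
  if (any(!tab$strand %in% c("+", "-"))) {
    abort_user("BED6 strand must be '+' or '-'")
  }
  out <- tibble::tibble(gene_id = tab$name, chrom = tab$chrom,
                        start = tab$start + 1L, end = tab$end,
                        strand = tab$strand)
  if (any(out$start > out$end)) abort_user("gene start > end")
  if (anyDuplicated(out$gene_id)) abort_user("duplicate gene ids")
  out
}

#' Write gene models to BED6 (inverse of [read_bed6()])
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`, `strand`,
#'   1-based inclusive).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed6 <- function(genes, path) {
  readr::write_tsv(
    tibble::tibble(chrom = genes$chrom, start = genes$start - 1L,
                   end = genes$end, name = genes$gene_id, score = 0L,
                   strand = genes$strand),
    path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a plain-text gene set (one gene id per line)
#' @param path Path to the gene-list file; blank lines and `#` comments are
#'   skipped.
#' @return Character vector of unique gene ids.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readr::read_lines(path, progress = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (!length(x)) abort_user("empty gene set")
  unique(x)
}

#' Extend gene borders upstream and downstream
#'
#' Extends each gene body by `upstream` bp on its 5' side and `downstream`
#' bp on its 3' side (defaults -1500/+500). With `stranded = TRUE` the
#' extension follows the annotated strand (a minus-strand gene extends
#' upstream to the right); with `stranded = FALSE` every gene is treated as
#' plus-strand. Extended starts are clipped at 1.
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @param upstream,downstream Non-negative extensions in bp.
#' @param stranded Interpret extensions relative to strand?
#' @return The input tibble with `ext_start` and `ext_end` columns added.
#' @export
#' @examples
#' g <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 10000,
#'                     end = 12000, strand = "+")
#' extend_genes(g)[, c("ext_start", "ext_end")]
extend_genes <- function(genes, upstream = 1500, downstream = 500,
                         stranded = TRUE) {
  if (upstream < 0 || downstream < 0) abort_user("extensions must be >= 0")
  plus <- if (stranded) genes$strand == "+" else rep(TRUE, nrow(genes))
  genes$ext_start <- as.integer(pmax(
    1, genes$start - ifelse(plus, upstream, downstream)))
  genes$ext_end <- as.integer(genes$end + ifelse(plus, downstream, upstream))
  genes
}

#' Annotate CpG sites onto genes with extended borders
#'
#' Maps every site against every gene's extended interval (overlap search
#' via `GenomicRanges::findOverlaps`). A site overlapping no extended
#' interval is intergenic; a site may map to multiple genes and all
#' mappings are kept. The zone is `intragenic` when the site lies within
#' the original gene body, otherwise `upstream` or `downstream` according
#' to which extension contains it (strand-aware when `stranded = TRUE`).
#' Chromosomes present among the sites but absent from the gene models
#' yield intergenic sites with a warning, not an error.
#'
#' @param sites Tibble with `site_id`, `chrom`, `pos` (e.g.
#'   `calls$sites`).
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @param upstream,downstream,stranded Passed to [extend_genes()].
#' @return Tibble with one row per (site, gene) mapping plus one row per
#'   intergenic site: `site_id`, `chrom`, `pos`, `gene_id` (NA when
#'   intergenic), `zone` in {intragenic, upstream, downstream, intergenic},
#'   sorted by chromosome, position, gene.
#' @export
annotate_sites <- function(sites, genes, upstream = 1500, downstream = 500,
                           stranded = TRUE) {
  sites <- tibble::as_tibble(sites)
  stopifnot(all(c("site_id", "chrom", "pos") %in% names(sites)))
  if (nrow(genes) > 0) {
    orphan <- setdiff(unique(sites$chrom), unique(genes$chrom))
    if (length(orphan)) {
      rlang::warn(paste0("no gene models on: ",
                         paste(orphan, collapse = ", "),
                         "; their sites are intergenic"))
    }
    ext <- extend_genes(genes, upstream, downstream, stranded)
    lev <- union(unique(genes$chrom), unique(sites$chrom))
    gr_genes <- GenomicRanges::GRanges(
      factor(ext$chrom, lev), IRanges::IRanges(ext$ext_start, ext$ext_end))
    gr_sites <- GenomicRanges::GRanges(
      factor(sites$chrom, lev), IRanges::IRanges(sites$pos, width = 1))
    hits <- GenomicRanges::findOverlaps(gr_sites, gr_genes,
                                        ignore.strand = TRUE)
    si <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
  } else {
    si <- integer(); gi <- integer()
  }
  mapped <- NULL
  if (length(si)) {
    g <- genes[gi, ]
    pos <- sites$pos[si]
    plus <- if (stranded) g$strand == "+" else rep(TRUE, length(gi))
    zone <- dplyr::case_when(
      pos >= g$start & pos <= g$end ~ "intragenic",
      plus == (pos < g$start) ~ "upstream",
      TRUE ~ "downstream"
    )
    mapped <- tibble::tibble(site_id = sites$site_id[si],
                             chrom = sites$chrom[si], pos = pos,
                             gene_id = g$gene_id, zone = zone)
  }
  inter_idx <- setdiff(seq_len(nrow(sites)), unique(si))
  intergenic <- tibble::tibble(site_id = sites$site_id[inter_idx],
                               chrom = sites$chrom[inter_idx],
                               pos = sites$pos[inter_idx],
                               gene_id = NA_character_, zone = "intergenic")
  dplyr::arrange(dplyr::bind_rows(mapped, intergenic),
                 .data$chrom, .data$pos, .data$gene_id)
}

#' Split annotated sites into gene-wide and GWAS-informed groups
#'
#' The gene-wide group is every non-intergenic site; the GWAS-informed
#' group is the subset mapping to at least one gene of a prespecified
#' GWAS-derived list. Sites are counted once per group regardless of how
#' many genes they map to, so the groups form valid enrichment universes.
#' GWAS genes absent from the annotated gene universe are dropped with a
#' warning.
#'
#' @param annotated Output of [annotate_sites()].
#' @param gwas_genes Character vector of GWAS-informed gene ids.
#' @return List with `gene_wide` and `gwas_informed` site-id vectors
#'   (`gwas_informed` is always a subset of `gene_wide`) and the validated
#'   `gwas_genes`.
#' @export
site_groups <- function(annotated, gwas_genes) {
  if (!length(gwas_genes)) abort_user("empty GWAS-informed gene set")
  universe <- unique(annotated$gene_id[!is.na(annotated$gene_id)])
  missing <- setdiff(gwas_genes, universe)
  if (length(missing)) {
    rlang::warn(paste0(length(missing),
                       " GWAS-informed gene(s) absent from the annotated ",
                       "gene universe were dropped"))
    gwas_genes <- intersect(gwas_genes, universe)
  }
  if (!length(gwas_genes)) {
    abort_user("no GWAS-informed gene overlaps the annotated gene universe")
  }
  gene_wide <- unique(annotated$site_id[!is.na(annotated$gene_id)])
  gwas_informed <- unique(
    annotated$site_id[!is.na(annotated$gene_id) &
                        annotated$gene_id %in% gwas_genes])
  list(gene_wide = gene_wide, gwas_informed = gwas_informed,
       gwas_genes = gwas_genes)
}
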