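#' Methylation call-set container
#'
#' Holds per-CpG methylated/unmethylated read counts for a set of samples:
#' a site table, a sample-id vector and two sites-by-samples count
#' matrices. Methylation level is always recomputed as
#' `meth / (meth + unmeth)` and is defined only where a cell is available
#' (coverage at or above the set's minimum, zero-coverage cells never).
#' [filter_sites()] applies the analyzability filter and records the
#' availability mask; masked cells are excluded from all downstream
#' statistics, never imputed.
#'
#' @param sites Tibble with `site_id`, `chrom`, `pos` (1-based).
#' @param samples Character vector of sample/subject ids.
#' @param meth,unmeth Numeric matrices, sites x samples, of methylated and
#'   unmethylated read counts.
#' @param min_coverage Minimum per-cell coverage for a cell to count as
#'   available (default 1: any covered cell).
#' @return An object of class `methyl_calls`.
#' @export
methyl_calls <- function(sites, samples, meth, unmeth, min_coverage = 1) {
  sites <- tibble::as_tibble(sites)
  stopifnot(all(c("site_id", "chrom", "pos") %in% names(sites)))
  meth <- as.matrix(meth); unmeth <- as.matrix(unmeth)
  if (!all(dim(meth) == c(nrow(sites), length(samples))) ||
      !all(dim(unmeth) == dim(meth))) {
    abort_user("count matrices must be sites x samples")
  }
  if (any(meth < 0) || any(unmeth < 0)) abort_user("negative read counts")
  if (any(sites$pos < 1)) abort_user("positions must be >= 1")
  if (anyDuplicated(sites$site_id)) abort_user("duplicate (chrom, pos) sites")
  dimnames(meth) <- dimnames(unmeth) <- list(sites$site_id, samples)
  structure(list(sites = sites, samples = as.character(samples),
                 meth = meth, unmeth = unmeth,
                 min_coverage = min_coverage),
            class = "methyl_calls")
}

#' @export
print.methyl_calls <- function(x, ...) {
  cov <- methyl_coverage(x)
  cat("Methylation call set:", nrow(x$sites), "sites x",
      length(x$samples), "samples\n")
  cat(sprintf("  available cells (coverage >= %s): %.1f%%\n",
              format(x$min_coverage), 100 * mean(cov >= x$min_coverage & cov > 0)))
  invisible(x)
}

#' @rdname methyl_calls
#' @param x A `methyl_calls` object.
#' @export
methyl_coverage <- function(x) x$meth + x$unmeth

#' @rdname methyl_calls
#' @export
methyl_levels <- function(x) {
  cov <- methyl_coverage(x)
  lev <- x$meth / cov
  lev[cov < max(x$min_coverage, 1)] <- NA_real_
  lev
}

#' @rdname methyl_calls
#' @export
methyl_mask <- function(x) {
  cov <- methyl_coverage(x)
  cov >= max(x$min_coverage, 1)
}

#' Tidy a methylation call set into a long tibble
#'
#' @param x A [methyl_calls] object.
#' @param ... Unused.
#' @return One row per site-by-sample cell: `site_id`, `chrom`, `pos`,
#'   `sample`, `meth`, `unmeth`, `coverage`, `level` (NA when the cell is
#'   unavailable).
#' @export
tidy.methyl_calls <- function(x, ...) {
  lev <- methyl_levels(x)
  tibble::tibble(
    site_id = rep(x$sites$site_id, times = length(x$samples)),
    chrom = rep(x$sites$chrom, times = length(x$samples)),
    pos = rep(x$sites$pos, times = length(x$samples)),
    sample = rep(x$samples, each = nrow(x$sites)),
    meth = as.vector(x$meth),
    unmeth = as.vector(x$unmeth),
    coverage = as.vector(x$meth + x$unmeth),
    level = as.vector(lev)
  )
}

#' Read Bismark-coverage-style methylation call files
#'
#' Reads one six-column TSV per sample (chrom, start, end, methylation
#' percent, methylated count, unmethylated count; 1-based inclusive
#' positions with start = end for a CpG) and assembles the union of sites
#' across samples into a [methyl_calls] object. Cells absent from a
#' sample's file get zero coverage. The percentage column is ignored:
#' levels are always recomputed from the counts, and a file whose
#' percentages disagree with its counts by more than half a percentage
#' point triggers a warning.
#'
#' @param paths Character vector of file paths, one per sample.
#' @param sample_ids Sample ids in the same order; defaults to `names(paths)`
#'   or the file base names.
#' @return A [methyl_calls] object with sites sorted by chromosome and
#'   position.
#' @export
read_coverage_files <- function(paths, sample_ids = NULL) {
  if (is.null(sample_ids)) {
    sample_ids <- if (!is.null(names(paths))) names(paths) else
      sub("\\.(cov|txt|tsv)(\\.gz)?$", "", basename(paths))
  }
  if (length(sample_ids) != length(paths)) {
    abort_user("one sample id per file required")
  }
  if (anyDuplicated(sample_ids)) abort_user("duplicate sample ids")
  tabs <- purrr::map2(paths, sample_ids, function(p, id) {
    tab <- readr::read_tsv(
      p, col_names = c("chrom", "start", "end", "pct", "meth", "unmeth"),
      col_types = "ciinnn", progress = FALSE)
    if (nrow(tab) == 0L) return(tibble::tibble(
      chrom = character(), pos = integer(), meth = numeric(),
      unmeth = numeric(), sample = character()))
    if (any(is.na(tab$start)) || any(is.na(tab$meth)) ||
        any(is.na(tab$unmeth)) || any(tab$meth < 0) || any(tab$unmeth < 0)) {
      abort_user(paste0("malformed lines in ", p))
    }
    if (any(tab$start != tab$end)) {
      abort_user(paste0("expected single-base CpG records (start == end) in ", p))
    }
    if (anyDuplicated(paste(tab$chrom, tab$start))) {
      abort_user(paste0("duplicate (chrom, pos) records in ", p))
    }
    tot <- tab$meth + tab$unmeth
    recomputed <- ifelse(tot > 0, 100 * tab$meth / tot, 0)
    if (any(abs(recomputed - tab$pct) > 0.5, na.rm = TRUE)) {
      rlang::warn(paste0("percentage column inconsistent with counts in ", p,
                         "; counts win"))
    }
    tibble::tibble(chrom = tab$chrom, pos = as.integer(tab$start),
                   meth = tab$meth, unmeth = tab$unmeth, sample = id)
  })
  long <- dplyr::bind_rows(tabs)
  if (nrow(long) == 0L) abort_user("no methylation calls in input files")
  sites <- dplyr::arrange(
    dplyr::distinct(long[c("chrom", "pos")]), .data$chrom, .data$pos)
  sites$site_id <- paste0(sites$chrom, ":", sites$pos)
  si <- match(paste0(long$chrom, ":", long$pos), sites$site_id)
  sj <- match(long$sample, sample_ids)
  meth <- matrix(0, nrow(sites), length(sample_ids))
  unmeth <- matrix(0, nrow(sites), length(sample_ids))
  meth[cbind(si, sj)] <- long$meth
  unmeth[cbind(si, sj)] <- long$unmeth
  methyl_calls(sites[c("site_id", "chrom", "pos")], sample_ids, meth, unmeth)
}

#' Write one Bismark-coverage-style TSV per sample
#'
#' @param calls A [methyl_calls] object.
#' @param dir Output directory (created if needed); files are named
#'   `<sample>.cov`. Zero-coverage cells are omitted, matching the
#'   read-side convention that absent records mean zero coverage.
#' @return Invisibly, the written paths named by sample.
#' @export
write_coverage_files <- function(calls, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cov <- methyl_coverage(calls)
  paths <- stats::setNames(
    file.path(dir, paste0(calls$samples, ".cov")), calls$samples)
  for (j in seq_along(calls$samples)) {
    keep <- cov[, j] > 0
    tab <- tibble::tibble(
      chrom = calls$sites$chrom[keep], start = calls$sites$pos[keep],
      end = calls$sites$pos[keep],
      pct = round(100 * calls$meth[keep, j] / cov[keep, j], 6),
      meth = calls$meth[keep, j], unmeth = calls$unmeth[keep, j])
    readr::write_tsv(tab, paths[j], col_names = FALSE, progress = FALSE)
  }
  invisible(paths)
}

#' Filter CpG sites on coverage and sample availability
#'
#' Implements the two-stage analyzability rule for RRBS call sets: a
#' site-by-sample cell is available iff its coverage is at least
#' `min_coverage` (default 10x); a site is retained iff it is available in
#' at least `min_sample_fraction` of all samples (default 50%, with
#' exactly-at-threshold retained). At retained sites, unavailable cells are
#' masked — excluded from every downstream statistic — not imputed. The
#' filter is idempotent and monotone in both thresholds.
#'
#' @param calls A [methyl_calls] object.
#' @param min_coverage Minimum reads for a cell to be available.
#' @param min_sample_fraction Minimum fraction of all samples (not just
#'   covered ones) in which a site must be available.
#' @return A [methyl_calls] object restricted to retained sites, with
#'   `min_coverage` recorded so [methyl_levels()] and [methyl_mask()]
#'   reflect the availability rule.
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_subjects = 20, n_genes = 5,
#'                                    n_intergenic_sites = 10, seed = 2))
#' filter_sites(study$calls)
filter_sites <- function(calls, min_coverage = 10, min_sample_fraction = 0.5) {
  if (!inherits(calls, "methyl_calls")) abort_user("`calls` must be methyl_calls")
  if (nrow(calls$sites) == 0L) abort_user("empty call set")
  if (min_coverage < 0 || min_sample_fraction < 0 || min_sample_fraction > 1) {
    abort_user("thresholds out of range")
  }
  cov <- methyl_coverage(calls)
  available <- cov >= max(min_coverage, 1)  # zero-coverage cells never count
  if (min_coverage <= 0 && min_sample_fraction <= 0) {
    keep <- rep(TRUE, nrow(calls$sites))
  } else {
    keep <- rowMeans(available) >= min_sample_fraction
  }
  methyl_calls(calls$sites[keep, , drop = FALSE], calls$samples,
               calls$meth[keep, , drop = FALSE],
               calls$unmeth[keep, , drop = FALSE],
               min_coverage = max(min_coverage, calls$min_coverage))
}
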