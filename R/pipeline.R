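#' Pipeline run configuration
#'
#' Collects everything one end-to-end run needs: either a simulation
#' config (synthetic study) or input paths (coverage files, BED6 gene
#' models, phenotype CSV, GWAS gene list, optional GO term map), the
#' filter and significance thresholds, enrichment settings and the root
#' seed. All randomness in a run flows from `seed` (stage-specific offsets
#' keep draws independent), so a rerun with the same configuration is
#' byte-identical.
#'
#' @param simulate A [sim_config()] for a synthetic run, or `NULL` to read
#'   `inputs`.
#' @param inputs Named list of paths for a file-based run:
#'   `coverage_dir` (or `coverage`, explicit files), `genes` (BED6),
#'   `phenotypes` (CSV), `gwas_genes` (gene list), optional `term_map`
#'   (TSV).
#' @param gwas_genes For synthetic runs: explicit GWAS-informed gene ids,
#'   or `NULL` to draw `gwas_fraction` of simulated genes (always
#'   including planted genes) deterministically from the seed.
#' @param gwas_fraction Fraction of simulated genes labelled
#'   GWAS-informed when `gwas_genes` is `NULL`.
#' @param term_map Optional gene-to-GO mapping tibble (or path) enabling
#'   the GO stage.
#' @param min_coverage,min_sample_fraction Site filters
#'   (see [filter_sites()]).
#' @param p_threshold Nominal association threshold feeding enrichment.
#' @param q_threshold FDR significance threshold.
#' @param n_perm,null_unit Permutation-test settings.
#' @param upstream,downstream,stranded Gene-border extension settings.
#' @param top_n Rows per measure in the top-site tables.
#' @param measures Measures to scan.
#' @param out_dir Output directory, or `NULL` to keep results in memory.
#' @param seed Root seed for the run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, inputs = NULL,
                            gwas_genes = NULL, gwas_fraction = 0.2,
                            term_map = NULL,
                            min_coverage = 10, min_sample_fraction = 0.5,
                            p_threshold = 0.05, q_threshold = 0.05,
                            n_perm = 1000, null_unit = "gene",
                            upstream = 1500, downstream = 500,
                            stranded = TRUE, top_n = 10,
                            measures = sleep_measures(),
                            out_dir = NULL, seed = 1L) {
  if (is.null(simulate) && is.null(inputs)) {
    abort_user("provide either a simulation config or input paths")
  }
  for (th in c(p_threshold, q_threshold, min_sample_fraction)) {
    if (th < 0 || th > 1) abort_user("thresholds must be in [0, 1]")
  }
  structure(list(simulate = simulate, inputs = inputs,
                 gwas_genes = gwas_genes, gwas_fraction = gwas_fraction,
                 term_map = term_map,
                 min_coverage = min_coverage,
                 min_sample_fraction = min_sample_fraction,
                 p_threshold = p_threshold, q_threshold = q_threshold,
                 n_perm = n_perm, null_unit = null_unit,
                 upstream = upstream, downstream = downstream,
                 stranded = stranded, top_n = top_n, measures = measures,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `simulate:` block is passed to [sim_config()] (its `planted_effects:`
#' list of `{gene_id, measure, effect}` records becomes a data frame).
#'
#' @param path YAML file path.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    sim <- y$simulate
    if (!is.null(sim$planted_effects)) {
      sim$planted_effects <- dplyr::bind_rows(
        lapply(sim$planted_effects, tibble::as_tibble))
    }
    y$simulate <- do.call(sim_config, sim)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    abort_user(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, y)
}

#' Top significant methylation sites per measure
#'
#' One row per CpG site, sorted ascending by q-value with deterministic
#' ties broken by chromosome then position, truncated to `top_n` rows per
#' measure. Sites mapping to several genes list all gene ids
#' comma-joined; by default intergenic sites are excluded, matching
#' gene-site reporting.
#'
#' @param ewas An `ewas_result` or its records tibble.
#' @param annotated Output of [annotate_sites()].
#' @param top_n Maximum rows per measure.
#' @param annotated_only Drop intergenic sites?
#' @return Tibble: `measure`, `chrom`, `pos`, `gene`, `estimate`,
#'   `std.error`, `q.value`, `zone`.
#' @export
make_top_table <- function(ewas, annotated, top_n = 10,
                           annotated_only = TRUE) {
  records <- if (inherits(ewas, "ewas_result")) ewas$records else ewas
  ann <- dplyr::summarise(
    dplyr::group_by(annotated, .data$site_id),
    gene = paste(sort(unique(stats::na.omit(.data$gene_id))), collapse = ","),
    zone = paste(sort(unique(.data$zone)), collapse = ","),
    .groups = "drop")
  out <- dplyr::left_join(records, ann, by = "site_id")
  if (annotated_only) out <- out[!is.na(out$gene) & nzchar(out$gene), ]
  out <- dplyr::arrange(out, .data$measure, .data$q.value, .data$chrom,
                        .data$pos)
  out <- dplyr::slice_head(dplyr::group_by(out, .data$measure), n = top_n)
  dplyr::select(dplyr::ungroup(out), "measure", "chrom", "pos", "gene",
                "estimate", "std.error", "q.value", "zone")
}

# Wide export of a filtered call set: per-sample level and coverage
# columns, plus a parallel availability mask table.
write_filtered_tsv <- function(calls, path, mask_path = NULL) {
  lev <- methyl_levels(calls); cov <- methyl_coverage(calls)
  wide <- calls$sites
  for (j in seq_along(calls$samples)) {
    wide[[paste0(calls$samples[j], ".level")]] <- round(lev[, j], 6)
    wide[[paste0(calls$samples[j], ".coverage")]] <- cov[, j]
  }
  readr::write_tsv(wide, path, progress = FALSE)
  if (!is.null(mask_path)) {
    mask <- calls$sites
    m <- methyl_mask(calls)
    for (j in seq_along(calls$samples)) mask[[calls$samples[j]]] <- m[, j]
    readr::write_tsv(mask, mask_path, progress = FALSE)
  }
  invisible(path)
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    study <- simulate_study(config$simulate)
    genes <- study$genome$genes
    gwas <- config$gwas_genes
    if (is.null(gwas)) {
      if (nrow(genes) == 0L) abort_user("cannot derive a GWAS set: no genes")
      n_gwas <- max(1L, ceiling(config$gwas_fraction * nrow(genes)))
      gwas <- with_seed(config$seed + 3L, {
        pool <- setdiff(genes$gene_id, study$truth$gene_id)
        extra <- max(0L, n_gwas - length(unique(study$truth$gene_id)))
        sort(unique(c(study$truth$gene_id, sample(pool, min(extra, length(pool))))))
      })
    }
    list(calls = study$calls, phenotypes = study$cohort, genes = genes,
         gwas_genes = gwas, truth = study$truth)
  } else {
    inp <- config$inputs
    paths <- if (!is.null(inp$coverage_dir)) {
      sort(list.files(inp$coverage_dir, pattern = "\\.cov$",
                      full.names = TRUE))
    } else inp$coverage
    if (!length(paths)) abort_user("no coverage files found")
    gwas <- inp$gwas_genes
    if (is.character(gwas) && length(gwas) == 1L && file.exists(gwas)) {
      gwas <- read_gene_set(gwas)
    }
    list(calls = read_coverage_files(paths),
         phenotypes = load_phenotypes(inp$phenotypes),
         genes = read_bed6(inp$genes), gwas_genes = gwas, truth = NULL)
  }
}

#' Run the full EWAS pipeline
#'
#' Executes every stage in order — load or simulate inputs, filter sites,
#' per-site association for each measure with per-measure FDR, gene
#' annotation with extended borders, significance summary, hypergeometric
#' and permutation enrichment, optional GO over-representation, top-site
#' tables, cross-measure gene overlaps — and assembles a machine-readable
#' manifest of seeds, thresholds and per-stage row counts. When
#' `config$out_dir` is set (or `out_dir` given), every table is written as
#' TSV/JSON as the stage completes, so a failed run retains the stages
#' that finished; the failing stage is named in the error.
#'
#' @param config A `pipeline_config` (or path to a YAML accepted by
#'   [read_pipeline_config()]).
#' @param out_dir Optional override of `config$out_dir`.
#' @return A list of class `sleep_pipeline`: `calls` (filtered),
#'   `phenotypes`, `annotated`, `ewas`, `summary`, `enrichment`, `go`,
#'   `top_tables`, `overlap`, `truth` (synthetic runs), `manifest`.
#' @export
#' @examples
#' cfg <- pipeline_config(
#'   simulate = sim_config(n_subjects = 30, n_genes = 8,
#'                         n_intergenic_sites = 20, seed = 5),
#'   n_perm = 100, seed = 5)
#' run <- run_pipeline(cfg)
#' run$summary
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    abort_user("`config` must be a pipeline_config or YAML path")
  }
  out_dir <- out_dir %||% config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  emit <- function(tab, name) {
    if (!is.null(out_dir) && is.data.frame(tab)) {
      readr::write_tsv(tab, file.path(out_dir, paste0(name, ".tsv")),
                       progress = FALSE)
    }
    tab
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_user(paste0("pipeline stage '", name, "' failed: ",
                        conditionMessage(e)))
    })
  }

  inp <- stage("load", load_pipeline_inputs(config))
  filtered <- stage("filter", filter_sites(inp$calls, config$min_coverage,
                                           config$min_sample_fraction))
  if (!is.null(out_dir)) {
    write_filtered_tsv(filtered, file.path(out_dir, "filtered_levels.tsv"),
                       file.path(out_dir, "filtered_mask.tsv"))
  }
  ewas <- stage("associate", run_ewas(filtered, inp$phenotypes,
                                      measures = config$measures))
  emit(ewas$records, "association_records")
  emit(ewas$skipped, "association_skipped")
  manhattan <- dplyr::transmute(
    ewas$records, .data$measure, .data$chrom, .data$pos,
    neglog10_p = -log10(pmax(.data$p.value, .Machine$double.xmin)))
  emit(manhattan, "manhattan")

  annotated <- stage("annotate", annotate_sites(
    filtered$sites, inp$genes, upstream = config$upstream,
    downstream = config$downstream, stranded = config$stranded))
  emit(annotated, "annotation")

  summary_tab <- stage("summarize", significant_summary(
    ewas, annotated, inp$gwas_genes, config$q_threshold))
  emit(summary_tab, "significant_summary")

  enr <- stage("enrich", enrichment_report(
    ewas, annotated, inp$gwas_genes, p_threshold = config$p_threshold,
    n_perm = config$n_perm, seed = config$seed + 100L,
    null_unit = config$null_unit))
  emit(enr, "enrichment")

  go <- NULL
  if (!is.null(config$term_map)) {
    tm <- config$term_map
    if (is.character(tm)) tm <- read_term_map(tm)
    go <- stage("go", {
      universe <- unique(annotated$gene_id[!is.na(annotated$gene_id)])
      ann <- annotated[!is.na(annotated$gene_id), c("site_id", "gene_id")]
      purrr::map_dfr(config$measures, function(m) {
        rec <- ewas$records[ewas$records$measure == m &
                              ewas$records$q.value < config$q_threshold, ]
        sig <- unique(ann$gene_id[ann$site_id %in% rec$site_id])
        res <- go_enrichment(sig, universe, tm)
        if (nrow(res)) res$measure <- m
        res
      })
    })
    emit(go, "go_enrichment")
  }

  top <- stage("report", make_top_table(ewas, annotated, config$top_n))
  emit(top, "top_tables")

  ann_sig <- dplyr::inner_join(
    ewas$records[ewas$records$q.value < config$q_threshold,
                 c("site_id", "measure")],
    annotated[!is.na(annotated$gene_id), c("site_id", "gene_id")],
    by = "site_id", relationship = "many-to-many")
  gene_sets <- lapply(split(ann_sig$gene_id, factor(ann_sig$measure,
                                                    config$measures)),
                      unique)
  overlap <- NULL
  if (length(gene_sets) >= 2L) {
    overlap <- stage("overlap", gene_overlap(gene_sets))
    emit(dplyr::mutate(overlap,
                       genes = vapply(.data$genes, paste, character(1),
                                      collapse = ",")),
         "gene_overlap")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("sleepewas")),
    seed = config$seed,
    thresholds = list(min_coverage = config$min_coverage,
                      min_sample_fraction = config$min_sample_fraction,
                      p_threshold = config$p_threshold,
                      q_threshold = config$q_threshold),
    enrichment = list(n_perm = config$n_perm, null_unit = config$null_unit),
    extension = list(upstream = config$upstream,
                     downstream = config$downstream,
                     stranded = config$stranded),
    counts = list(
      n_subjects = ewas$n_samples,
      sites_in = nrow(inp$calls$sites),
      sites_retained = nrow(filtered$sites),
      sites_dropped = nrow(inp$calls$sites) - nrow(filtered$sites),
      association_records = nrow(ewas$records),
      association_skipped = nrow(ewas$skipped),
      sites_annotated = length(unique(
        annotated$site_id[!is.na(annotated$gene_id)])),
      genes_annotated = length(unique(stats::na.omit(annotated$gene_id))),
      significant_records = sum(ewas$records$q.value < config$q_threshold)))
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(config = config, calls = filtered,
                 phenotypes = inp$phenotypes, genes = inp$genes,
                 gwas_genes = inp$gwas_genes, truth = inp$truth,
                 annotated = annotated, ewas = ewas, summary = summary_tab,
                 enrichment = enr, go = go, top_tables = top,
                 overlap = overlap, manifest = manifest),
            class = "sleep_pipeline")
}

#' @export
print.sleep_pipeline <- function(x, ...) {
  cat("sleep-EWAS pipeline run (seed", x$manifest$seed, ")\n")
  cnt <- x$manifest$counts
  cat(sprintf("  sites: %d in -> %d retained; %d association records, %d significant (q < %g)\n",
              cnt$sites_in, cnt$sites_retained, cnt$association_records,
              cnt$significant_records, x$config$q_threshold))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
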