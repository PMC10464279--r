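#' Configuration for the synthetic study generator
#'
#' Builds the single configuration object consumed by [simulate_genome()],
#' [simulate_cohort()], [simulate_methylation()] and [simulate_study()].
#' The defaults emulate the study conditions the pipeline targets: a cohort
#' of 263 adolescents with nine sleep-initiation measures calibrated to the
#' published sample means and SDs (e.g. polysomnography SOL 25.7 min, SD
#' 21.45), RRBS-style over-dispersed read coverage, and beta-binomial
#' methylation counts, at a desk-scale genome (a few hundred CpG sites)
#' rather than the genome-wide site count of a real RRBS run.
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param n_genes Number of simulated genes (0 gives an all-intergenic
#'   genome).
#' @param sites_per_gene_mean Mean CpG sites per gene; each gene gets
#'   `1 + Poisson(mean - 1)` sites placed uniformly within its extended
#'   borders.
#' @param n_intergenic_sites CpG sites placed outside every extended gene
#'   interval.
#' @param n_chrom Number of simulated chromosomes.
#' @param gene_length_range,gap_range Base-pair ranges (min, max) for gene
#'   body lengths and inter-gene gaps. The minimum gap must exceed
#'   `upstream + downstream` so extended intervals stay disjoint.
#' @param upstream,downstream Gene-border extensions in bp (strand-aware):
#'   defaults -1500 upstream, +500 downstream.
#' @param coverage_mean,coverage_dispersion Negative-binomial mean and size
#'   for per-cell read coverage; over-dispersion puts a realistic fraction
#'   of cells below the 10x filter.
#' @param missing_fraction Fraction of site-by-sample cells forced to zero
#'   coverage (dropout), exercising the sample-availability filter.
#' @param meth_site_shape Length-2 beta shape parameters for per-site mean
#'   methylation; the default `(0.8, 0.8)` gives the bimodal
#'   mostly-methylated / mostly-unmethylated profile typical of CpGs.
#' @param meth_precision Beta precision for subject-level methylation
#'   around the site mean; subject proportions are
#'   `Beta(mu * phi, (1 - mu) * phi)`.
#' @param planted_effects `NULL` for a null study, or a data frame with
#'   columns `gene_id`, `measure`, `effect`: one CpG in each named gene
#'   gets a planted linear effect on the named measure, in phenotype units
#'   (minutes for SOL, hours for bedtime/SOT) per unit methylation
#'   proportion.
#' @param phenotype_params Data frame with columns `measure`, `mean`, `sd`,
#'   `min`, `max` for the six primitive measures (bedtimes normal, SOLs
#'   log-normal, both truncated); SOT is always `bedtime + sol/60`.
#' @param covariate_params List of cohort covariate settings (age mean/SD
#'   and range, male and racial/ethnic-minority fractions, BMI-percentile
#'   mean/SD/range, number of assay batches).
#' @param within_method_cor Gaussian-copula correlation among the three
#'   measurement methods within each construct (bedtime, SOL).
#' @param seed Integer seed; fully determines every generator output.
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 40, n_genes = 10, seed = 7)
#' study <- simulate_study(cfg)
#' study$calls
sim_config <- function(n_subjects = 263,
                       n_genes = 60,
                       sites_per_gene_mean = 6,
                       n_intergenic_sites = 120,
                       n_chrom = 2,
                       gene_length_range = c(2000, 20000),
                       gap_range = c(5000, 12000),
                       upstream = 1500,
                       downstream = 500,
                       coverage_mean = 30,
                       coverage_dispersion = 5,
                       missing_fraction = 0.08,
                       meth_site_shape = c(0.8, 0.8),
                       meth_precision = 10,
                       planted_effects = NULL,
                       phenotype_params = default_phenotype_params(),
                       covariate_params = default_covariate_params(),
                       within_method_cor = 0.4,
                       seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_genes = as.integer(n_genes),
    sites_per_gene_mean = sites_per_gene_mean,
    n_intergenic_sites = as.integer(n_intergenic_sites),
    n_chrom = as.integer(n_chrom),
    gene_length_range = as.numeric(gene_length_range),
    gap_range = as.numeric(gap_range),
    upstream = upstream, downstream = downstream,
    coverage_mean = coverage_mean, coverage_dispersion = coverage_dispersion,
    missing_fraction = missing_fraction,
    meth_site_shape = as.numeric(meth_site_shape),
    meth_precision = meth_precision,
    planted_effects = if (!is.null(planted_effects))
      tibble::as_tibble(planted_effects),
    phenotype_params = tibble::as_tibble(phenotype_params),
    covariate_params = covariate_params,
    within_method_cor = within_method_cor,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_subjects < 1) abort_user("n_subjects must be > 0")
  if (cfg$n_genes < 0) abort_user("n_genes must be >= 0")
  if (cfg$n_intergenic_sites < 0) abort_user("n_intergenic_sites must be >= 0")
  if (cfg$n_genes == 0 && cfg$n_intergenic_sites == 0) {
    abort_user("the genome must contain at least one CpG site")
  }
  if (cfg$n_genes > 0 && cfg$sites_per_gene_mean < 1) {
    abort_user("sites_per_gene_mean must be >= 1")
  }
  if (cfg$coverage_mean < 1) abort_user("coverage_mean must be >= 1")
  if (cfg$coverage_dispersion <= 0) abort_user("coverage_dispersion must be > 0")
  if (cfg$missing_fraction < 0 || cfg$missing_fraction >= 1) {
    abort_user("missing_fraction must be in [0, 1)")
  }
  if (any(cfg$meth_site_shape <= 0) || cfg$meth_precision <= 0) {
    abort_user("beta shape parameters must be > 0")
  }
  if (cfg$gap_range[1] <= cfg$upstream + cfg$downstream) {
    abort_user("minimum gene gap must exceed upstream + downstream extension")
  }
  if (any(cfg$phenotype_params$sd < 0)) abort_user("phenotype SDs must be >= 0")
  if (abs(cfg$within_method_cor) >= 1) {
    abort_user("within_method_cor must be in (-1, 1)")
  }
  need <- c("measure", "mean", "sd", "min", "max")
  if (!all(need %in% names(cfg$phenotype_params))) {
    abort_user("phenotype_params needs columns measure, mean, sd, min, max")
  }
  if (!is.null(cfg$planted_effects)) {
    pe <- cfg$planted_effects
    if (!all(c("gene_id", "measure", "effect") %in% names(pe))) {
      abort_user("planted_effects needs columns gene_id, measure, effect")
    }
    if (!all(pe$measure %in% sleep_measures())) {
      abort_user("planted_effects$measure must be one of sleep_measures()")
    }
  }
  cfg
}

#' @rdname sim_config
#' @export
default_phenotype_params <- function() {
  tibble::tibble(
    measure = c("bedtime_sr", "bedtime_act", "bedtime_psg",
                "sol_sr", "sol_act", "sol_psg"),
    mean = c(23 + 40 / 60, 23 + 59 / 60, 22.0, 24.1, 7.5, 25.7),
    sd   = c(1.5, 4 / 3, 0.2, 19.6, 8.5, 21.45),
    min  = c(20, 20, 21, 0.5, 0.5, 0.5),
    max  = c(30, 30, 23.1, 600, 600, 600)
  )
}

#' @rdname sim_config
#' @export
default_covariate_params <- function() {
  list(age_mean = 17.3, age_sd = 2.1, age_range = c(13, 23),
       male_fraction = 0.559, minority_fraction = 0.232,
       bmi_mean = 64.5, bmi_sd = 29, bmi_range = c(0.7, 99.8),
       n_batches = 4L)
}

# Inverse-CDF truncated normal / log-normal draws from uniform quantiles,
# so correlated measures can share a Gaussian copula.
q_trunc_norm <- function(u, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, length(u)))
  pa <- pnorm(lo, mean, sd); pb <- pnorm(hi, mean, sd)
  qnorm(pa + u * (pb - pa), mean, sd)
}

q_trunc_lnorm <- function(u, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, length(u)))
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  pa <- plnorm(lo, meanlog, sdlog); pb <- plnorm(hi, meanlog, sdlog)
  qlnorm(pa + u * (pb - pa), meanlog, sdlog)
}

#' Simulate gene models and CpG site coordinates
#'
#' Lays out non-overlapping genes along `n_chrom` chromosomes with random
#' strands and gaps wide enough that extended gene borders
#' (`-upstream`/`+downstream`, strand-aware) never overlap, then scatters
#' CpG sites both within extended gene intervals and in the intergenic
#' space between them. The generator keeps its own bookkeeping of each
#' site's true gene and zone (intragenic / upstream / downstream /
#' intergenic), which downstream annotation must recover exactly.
#'
#' @param config A [sim_config()] object.
#' @return A list with `genes` (tibble: `gene_id`, `chrom`, `start`, `end`,
#'   `strand`; 1-based inclusive) and `sites` (tibble: `site_id`, `chrom`,
#'   `pos`, `true_gene_id`, `true_zone`), both sorted by coordinate.
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    up <- config$upstream; down <- config$downstream
    genes <- tibble::tibble(gene_id = character(), chrom = character(),
                            start = integer(), end = integer(),
                            strand = character())
    gene_sites <- NULL
    chrom_names <- paste0("chr", seq_len(config$n_chrom))
    chrom_len <- stats::setNames(rep(0, config$n_chrom), chrom_names)

    if (config$n_genes > 0) {
      lens <- floor(runif(config$n_genes, config$gene_length_range[1],
                          config$gene_length_range[2] + 1))
      gaps <- floor(runif(config$n_genes, config$gap_range[1],
                          config$gap_range[2] + 1))
      strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
      chrom <- chrom_names[rep_len(seq_len(config$n_chrom), config$n_genes)]
      start <- integer(config$n_genes); end <- integer(config$n_genes)
      cursor <- stats::setNames(rep(1, config$n_chrom), chrom_names)
      for (i in seq_len(config$n_genes)) {
        start[i] <- cursor[chrom[i]] + gaps[i]
        end[i] <- start[i] + lens[i] - 1
        cursor[chrom[i]] <- end[i]
      }
      genes <- tibble::tibble(
        gene_id = sprintf("G%04d", seq_len(config$n_genes)),
        chrom = chrom, start = as.integer(start), end = as.integer(end),
        strand = strand
      )
      ext <- extend_genes(genes, upstream = up, downstream = down)
      n_sites <- 1L + rpois(config$n_genes,
                            max(config$sites_per_gene_mean - 1, 0))
      pos_list <- lapply(seq_len(config$n_genes), function(i) {
        sort(sample.int(ext$ext_end[i] - ext$ext_start[i] + 1L,
                        min(n_sites[i], ext$ext_end[i] - ext$ext_start[i] + 1L)) +
               ext$ext_start[i] - 1L)
      })
      gene_sites <- tibble::tibble(
        chrom = rep(genes$chrom, lengths(pos_list)),
        pos = unlist(pos_list),
        true_gene_id = rep(genes$gene_id, lengths(pos_list))
      )
      g <- genes[match(gene_sites$true_gene_id, genes$gene_id), ]
      gene_sites$true_zone <- dplyr::case_when(
        gene_sites$pos >= g$start & gene_sites$pos <= g$end ~ "intragenic",
        (g$strand == "+") == (gene_sites$pos < g$start) ~ "upstream",
        TRUE ~ "downstream"
      )
      chrom_len[chrom_names] <- vapply(
        chrom_names,
        function(cn) if (any(genes$chrom == cn))
          max(ext$ext_end[genes$chrom == cn]) + config$gap_range[1] else 0,
        numeric(1))
    }
    # intergenic sites live in the complement of all extended intervals
    default_len <- max(10 * config$n_intergenic_sites, 1e5)
    chrom_len[chrom_len == 0] <- default_len
    free <- lapply(chrom_names, function(cn) {
      if (config$n_genes > 0 && any(genes$chrom == cn)) {
        ext <- extend_genes(genes[genes$chrom == cn, ],
                            upstream = up, downstream = down)
        occ <- IRanges::reduce(IRanges::IRanges(ext$ext_start, ext$ext_end))
        IRanges::setdiff(IRanges::IRanges(1, chrom_len[cn]), occ)
      } else {
        IRanges::IRanges(1, chrom_len[cn])
      }
    })
    widths <- vapply(free, function(r) sum(IRanges::width(r)), numeric(1))
    if (config$n_intergenic_sites > sum(widths)) {
      abort_user("requested intergenic sites cannot fit the simulated chromosomes")
    }
    inter_sites <- NULL
    if (config$n_intergenic_sites > 0) {
      offs <- sort(sample.int(sum(widths), config$n_intergenic_sites))
      cum <- cumsum(widths)
      ci <- findInterval(offs - 1L, c(0, cum), rightmost.closed = TRUE)
      inter_sites <- purrr::map_dfr(seq_along(free), function(j) {
        o <- offs[ci == j] - c(0, cum)[j]   # 1-based offset within chrom j
        if (!length(o)) return(NULL)
        st <- IRanges::start(free[[j]]); w <- IRanges::width(free[[j]])
        cw <- cumsum(w)
        k <- findInterval(o - 1L, c(0, cw), rightmost.closed = TRUE)
        tibble::tibble(chrom = chrom_names[j],
                       pos = as.integer(st[k] + (o - c(0, cw)[k] - 1L)),
                       true_gene_id = NA_character_,
                       true_zone = "intergenic")
      })
    }
    sites <- dplyr::bind_rows(gene_sites, inter_sites)
    sites <- dplyr::arrange(sites, .data$chrom, .data$pos)
    sites <- dplyr::mutate(sites,
                           site_id = paste0(.data$chrom, ":", .data$pos),
                           .before = 1)
    if (anyDuplicated(sites$site_id)) {
      sites <- dplyr::distinct(sites, .data$site_id, .keep_all = TRUE)
    }
    list(genes = genes, sites = sites)
  })
}

#' Simulate a phenotyped cohort
#'
#' Draws per-subject covariates (age, sex, race, BMI percentile, batch) and
#' the nine sleep measures. Bedtimes are truncated normals on the
#' continuous clock scale and SOLs truncated log-normals, calibrated by
#' `config$phenotype_params`; the three measurement methods within each
#' construct share a Gaussian copula with correlation
#' `config$within_method_cor`. SOT is `bedtime + sol/60` exactly, by
#' construction. No methylation effects are present; [simulate_methylation()]
#' plants those.
#'
#' @param config A [sim_config()] object.
#' @return A phenotype tibble with `subject_id`, the nine measures, and the
#'   covariates (`sex` 1 = male, `race` 1 = non-minority).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed + 1L, {
    n <- config$n_subjects
    cp <- config$covariate_params
    age_u <- runif(n)
    cov <- tibble::tibble(
      subject_id = sprintf("S%04d", seq_len(n)),
      age = q_trunc_norm(age_u, cp$age_mean, cp$age_sd,
                         cp$age_range[1], cp$age_range[2]),
      sex = rbinom(n, 1, cp$male_fraction),
      race = rbinom(n, 1, 1 - cp$minority_fraction),
      bmi_percentile = q_trunc_norm(runif(n), cp$bmi_mean, cp$bmi_sd,
                                    cp$bmi_range[1], cp$bmi_range[2]),
      batch = sample(paste0("batch", seq_len(cp$n_batches)), n, replace = TRUE)
    )
    rho <- config$within_method_cor
    R <- matrix(rho, 3, 3); diag(R) <- 1
    L <- chol(R)
    draw_construct <- function(prefix, qfun) {
      z <- matrix(stats::rnorm(n * 3), n, 3) %*% L
      u <- pnorm(z)
      out <- list()
      for (j in seq_along(c("sr", "act", "psg"))) {
        m <- paste0(prefix, "_", c("sr", "act", "psg")[j])
        pp <- config$phenotype_params[config$phenotype_params$measure == m, ]
        out[[m]] <- qfun(u[, j], pp$mean, pp$sd, pp$min, pp$max)
      }
      out
    }
    bt <- draw_construct("bedtime", q_trunc_norm)
    sl <- draw_construct("sol", q_trunc_lnorm)
    for (m in names(bt)) cov[[m]] <- bt[[m]]
    for (m in names(sl)) cov[[m]] <- sl[[m]]
    for (meth in c("sr", "act", "psg")) {
      cov[[paste0("sot_", meth)]] <-
        cov[[paste0("bedtime_", meth)]] + cov[[paste0("sol_", meth)]] / 60
    }
    dplyr::select(cov, "subject_id", dplyr::all_of(sleep_measures()),
                  dplyr::everything())
  })
}

#' Simulate methylation call sets with planted effects
#'
#' Per site-by-sample cell, coverage is negative-binomial (with a
#' configurable fraction of cells dropped to zero coverage) and the
#' methylated count is binomial with a beta-distributed subject-level
#' methylation proportion around a beta-distributed site mean. For each
#' planted effect, one CpG in the designated gene is selected and the
#' designated sleep measure is re-generated as a linear function of that
#' site's observed methylation level plus covariate terms and noise, so the
#' covariate-adjusted regression's estimand at that site is exactly the
#' planted effect. Planting on a bedtime or SOL measure propagates to the
#' corresponding SOT (`sot = bedtime + sol/60` is preserved); planting
#' directly on an SOT measure holds SOL fixed and backs bedtime out of the
#' identity.
#'
#' @param config A [sim_config()] object.
#' @param genome Output of [simulate_genome()] under the same config.
#' @param cohort Output of [simulate_cohort()] under the same config.
#' @return A list with `calls` (a [methyl_calls] object), `truth` (tibble
#'   of planted `site_id`, `gene_id`, `measure`, `effect`, plus attribute-free
#'   bookkeeping usable as ground truth) and `cohort` (the phenotype tibble
#'   with planted measures re-generated).
#' @export
simulate_methylation <- function(config, genome, cohort) {
  validate_sim_config(config)
  with_seed(config$seed + 2L, {
    S <- nrow(genome$sites); n <- nrow(cohort)
    mu <- rbeta(S, config$meth_site_shape[1], config$meth_site_shape[2])
    mu <- pmin(pmax(mu, 0.02), 0.98)
    phi <- config$meth_precision
    pi_true <- matrix(
      rbeta(S * n, rep(mu * phi, n), rep((1 - mu) * phi, n)), S, n)
    coverage <- matrix(
      rnbinom(S * n, mu = config$coverage_mean,
              size = config$coverage_dispersion), S, n)
    coverage[matrix(runif(S * n) < config$missing_fraction, S, n)] <- 0L
    meth <- matrix(rbinom(S * n, coverage, pi_true), S, n)
    calls <- methyl_calls(genome$sites[c("site_id", "chrom", "pos")],
                          cohort$subject_id, meth, coverage - meth)

    truth <- tibble::tibble(site_id = character(), gene_id = character(),
                            measure = character(), effect = numeric())
    pe <- config$planted_effects
    if (!is.null(pe) && nrow(pe)) {
      missing_genes <- setdiff(pe$gene_id, genome$genes$gene_id)
      if (length(missing_genes)) {
        abort_user(paste0("planted gene id absent from genome: ",
                          paste(missing_genes, collapse = ", ")))
      }
      planted_site <- vapply(pe$gene_id, function(g) {
        s <- genome$sites$site_id[!is.na(genome$sites$true_gene_id) &
                                    genome$sites$true_gene_id == g]
        if (!length(s)) abort_user(paste0("gene ", g, " has no CpG sites"))
        s[1]
      }, character(1))
      truth <- tibble::tibble(site_id = unname(planted_site),
                              gene_id = pe$gene_id,
                              measure = pe$measure, effect = pe$effect)
      # observed level drives the phenotype; true proportion fills
      # zero-coverage cells, which per-site complete-case fits drop anyway
      x_of <- function(sid) {
        s <- match(sid, calls$sites$site_id)
        x <- meth[s, ] / coverage[s, ]
        x[coverage[s, ] == 0] <- pi_true[s, coverage[s, ] == 0]
        x
      }
      zage <- as.numeric(scale(cohort$age))
      zbmi <- as.numeric(scale(cohort$bmi_percentile))
      cp <- config$covariate_params
      for (m in unique(truth$measure)) {
        rows <- truth[truth$measure == m, ]
        cons <- measure_construct(m)
        base_m <- if (cons == "sot") sub("^sot", "sol", m) else m
        pp <- config$phenotype_params[
          config$phenotype_params$measure ==
            (if (cons == "sot") sub("^sot", "bedtime", m) else m), ]
        target_mean <- if (cons == "sot") {
          mean(cohort[[m]])
        } else pp$mean
        target_sd <- if (cons == "sot") max(sd(cohort[[m]]), pp$sd) else pp$sd
        xs <- vapply(rows$site_id, x_of, numeric(n))
        signal <- as.numeric(xs %*% rows$effect)
        batch_eff <- stats::rnorm(cp$n_batches, 0, 0.15 * target_sd)
        covterm <- target_sd * (0.2 * zage + 0.2 * (cohort$sex - 0.5) +
                                  0.1 * (cohort$race - 0.5) + 0.1 * zbmi) +
          batch_eff[as.integer(factor(cohort$batch))]
        noise_sd <- target_sd * sqrt(max(1 - 0.2^2 - 0.2^2 - 0.1^2 - 0.1^2 -
                                           0.15^2, 0.2))
        y <- (target_mean - mean(signal)) + signal + covterm +
          stats::rnorm(n, 0, noise_sd)
        cohort[[m]] <- y
        meth3 <- sub("^.*_", "", m)
        if (cons == "bedtime") {
          cohort[[paste0("sot_", meth3)]] <- y + cohort[[paste0("sol_", meth3)]] / 60
        } else if (cons == "sol") {
          cohort[[paste0("sot_", meth3)]] <- cohort[[paste0("bedtime_", meth3)]] + y / 60
        } else {
          cohort[[paste0("bedtime_", meth3)]] <- y - cohort[[paste0("sol_", meth3)]] / 60
        }
      }
    }
    list(calls = calls, truth = truth, cohort = cohort)
  })
}

#' Simulate a complete synthetic study
#'
#' Runs [simulate_genome()], [simulate_cohort()] and
#' [simulate_methylation()] under one configuration and returns all pieces,
#' including ground truth for planted effects. Identical configurations
#' (including the seed) give byte-identical results.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sleep_sim` with elements `config`, `genome`
#'   (genes + sites), `cohort` (phenotype tibble, planted measures
#'   re-generated), `calls` ([methyl_calls]) and `truth`.
#' @export
simulate_study <- function(config) {
  genome <- simulate_genome(config)
  cohort <- simulate_cohort(config)
  m <- simulate_methylation(config, genome, cohort)
  structure(list(config = config, genome = genome, cohort = m$cohort,
                 calls = m$calls, truth = m$truth),
            class = "sleep_sim")
}

#' @export
print.sleep_sim <- function(x, ...) {
  cat("Synthetic sleep-EWAS study\n")
  cat("  subjects:", nrow(x$cohort), "  genes:", nrow(x$genome$genes),
      "  CpG sites:", nrow(x$genome$sites), "\n")
  cat("  planted effects:", nrow(x$truth), "\n")
  invisible(x)
}

#' Serialize a synthetic study to standard file formats
#'
#' Writes one Bismark-coverage-style TSV per sample (chrom, start, end,
#' methylation percent, methylated count, unmethylated count; 1-based
#' inclusive, start = end, zero-coverage cells omitted), a BED6 gene-model
#' file, a CSV phenotype table (clock times in decimal hours) and a JSON
#' ground-truth file.
#'
#' @param study A `sleep_sim` object from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of written paths (`coverage` is a named
#'   vector, one per sample).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cov_dir <- file.path(dir, "coverage")
  cov_paths <- write_coverage_files(study$calls, cov_dir)
  bed <- file.path(dir, "genes.bed")
  write_bed6(study$genome$genes, bed)
  phen <- file.path(dir, "phenotypes.csv")
  readr::write_csv(study$cohort, phen, progress = FALSE)
  truth <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(planted = study$truth,
         genes_by_measure = lapply(split(study$truth$gene_id,
                                         study$truth$measure), unique),
         seed = study$config$seed),
    truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(coverage = cov_paths, genes = bed, phenotypes = phen,
                 ground_truth = truth))
}
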