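small_cfg <- function(...) {
  sim_config(n_subjects = 30, n_genes = 8, sites_per_gene_mean = 4,
             n_intergenic_sites = 15, seed = 101, ...)
}

test_that("identical configs give byte-identical studies, including files", {
  cfg <- small_cfg()
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$calls, s2$calls)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(s1, d1); write_study(s2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("a zero-gene genome is all intergenic and a full one partitions", {
  g0 <- simulate_genome(sim_config(n_genes = 0, n_intergenic_sites = 50,
                                   seed = 7))
  expect_equal(nrow(g0$genes), 0L)
  expect_true(all(g0$sites$true_zone == "intergenic"))
  expect_equal(nrow(g0$sites), 50L)

  # annotation recovers the generator's own intragenic/intergenic bookkeeping
  g <- simulate_genome(sim_config(n_genes = 20, sites_per_gene_mean = 10,
                                  n_intergenic_sites = 100, seed = 8))
  ann <- annotate_sites(g$sites, g$genes)
  merged <- dplyr::inner_join(g$sites, ann, by = c("site_id", "chrom", "pos"))
  expect_equal(nrow(merged), nrow(g$sites))  # disjoint genes: single mapping
  expect_identical(merged$gene_id, merged$true_gene_id)
  expect_identical(merged$zone, merged$true_zone)
})

test_that("genome generation rejects impossible intergenic requests", {
  expect_error(simulate_genome(sim_config(n_genes = 2, sites_per_gene_mean = 2,
                                          n_intergenic_sites = 10^7, seed = 1)),
               "cannot fit")
})

test_that("cohort phenotypes are calibrated and satisfy the SOT identity", {
  cfg <- sim_config(n_subjects = 10000, seed = 33)
  co <- simulate_cohort(cfg)
  # configured PSG SOL mean 25.7, SD 21.45: sample mean within 3 SE
  expect_lt(abs(mean(co$sol_psg) - 25.7), 3 * 21.45 / sqrt(10000))
  for (m in c("sr", "act", "psg")) {
    expect_equal(co[[paste0("sot_", m)]],
                 co[[paste0("bedtime_", m)]] + co[[paste0("sol_", m)]] / 60)
  }
  expect_true(all(co$bmi_percentile >= 0 & co$bmi_percentile <= 100))
  expect_true(all(co$age >= 13 & co$age <= 23))
})

test_that("a zero-SD measure is degenerate at its mean", {
  pp <- default_phenotype_params()
  pp$sd[pp$measure == "bedtime_psg"] <- 0
  co <- simulate_cohort(sim_config(n_subjects = 50, phenotype_params = pp,
                                   seed = 5))
  expect_true(all(co$bedtime_psg == 22))
})

test_that("methylation counts conserve coverage and are seed-stable", {
  cfg <- small_cfg()
  g <- simulate_genome(cfg); co <- simulate_cohort(cfg)
  m <- simulate_methylation(cfg, g, co)
  cov <- methyl_coverage(m$calls)
  expect_true(all(m$calls$meth + m$calls$unmeth == cov))
  expect_true(all(m$calls$meth >= 0 & m$calls$unmeth >= 0))
  lev <- methyl_levels(m$calls)
  expect_true(all(lev >= 0 & lev <= 1, na.rm = TRUE))
  expect_true(anyNA(lev))   # dropout cells exist and are masked
})

test_that("symmetric site-level beta shapes centre methylation at one half", {
  cfg <- sim_config(n_subjects = 400, n_genes = 30, sites_per_gene_mean = 8,
                    n_intergenic_sites = 100, meth_site_shape = c(2, 2),
                    missing_fraction = 0, seed = 21)
  g <- simulate_genome(cfg); co <- simulate_cohort(cfg)
  m <- simulate_methylation(cfg, g, co)
  lev <- methyl_levels(m$calls)
  expect_lt(abs(mean(lev, na.rm = TRUE) - 0.5), 0.05)
})

test_that("planted effects land inside their gene and drive the phenotype", {
  pe <- tibble::tibble(gene_id = c("G0001", "G0002"),
                       measure = c("sol_psg", "bedtime_psg"),
                       effect = c(60, 2))
  cfg <- sim_config(n_subjects = 200, n_genes = 10, sites_per_gene_mean = 5,
                    n_intergenic_sites = 10, planted_effects = pe, seed = 13)
  st <- simulate_study(cfg)
  expect_equal(nrow(st$truth), 2L)
  expect_identical(st$truth$gene_id, pe$gene_id)
  # planted sites lie within the planted genes' extended borders
  merged <- dplyr::inner_join(st$truth, st$genome$sites, by = "site_id")
  expect_identical(merged$true_gene_id, merged$gene_id)
  # the SOT identity survives planting on SOL and bedtime
  for (m in c("sr", "act", "psg")) {
    expect_equal(st$cohort[[paste0("sot_", m)]],
                 st$cohort[[paste0("bedtime_", m)]] +
                   st$cohort[[paste0("sol_", m)]] / 60)
  }
  # absent gene id is an error
  bad <- sim_config(n_subjects = 30, n_genes = 2, seed = 13,
                    planted_effects = tibble::tibble(
                      gene_id = "G9999", measure = "sol_sr", effect = 60))
  expect_error(simulate_study(bad), "absent from genome")
})

test_that("invalid configurations are rejected up front", {
  expect_error(sim_config(n_subjects = 0), "n_subjects")
  expect_error(sim_config(coverage_mean = 0.5), "coverage_mean")
  expect_error(sim_config(missing_fraction = 1), "missing_fraction")
  expect_error(sim_config(n_genes = 0, n_intergenic_sites = 0), "at least one")
  expect_error(sim_config(planted_effects = tibble::tibble(
    gene_id = "G0001", measure = "nap_time", effect = 1)), "sleep_measures")
})
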