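sim_covariates <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(age = rnorm(n, 17, 2), sex = rbinom(n, 1, 0.5),
             race = rbinom(n, 1, 0.75), bmi_percentile = runif(n, 1, 99),
             batch = sample(paste0("b", 1:3), n, replace = TRUE))
}

test_that("a noiseless linear site is fit exactly", {
  meth <- seq(0, 0.9, length.out = 10)
  fit <- fit_site(2 + 60 * meth, meth)
  expect_equal(fit$estimate, 60, tolerance = 1e-10)
  expect_lt(fit$p.value, 1e-12)
  expect_equal(glance(fit)$nobs, 10L)
  expect_named(tidy(fit), c("term", "estimate", "std.error", "statistic",
                            "p.value"))
})

test_that("orthogonal covariates leave the methylation coefficient unchanged", {
  n <- 40
  meth <- rep(c(0.2, 0.8), each = n / 2)
  covar <- rep(c(-1, 1), times = n / 2)   # orthogonal to meth by construction
  expect_equal(sum(scale(meth, scale = FALSE) * covar), 0)
  set.seed(9)
  y <- 3 + 10 * meth + rnorm(n)
  f0 <- fit_site(y, meth)
  f1 <- fit_site(y, meth, data.frame(covar = covar))
  expect_equal(f1$estimate, f0$estimate)
})

test_that("beta scales with the phenotype and resists covariate recoding", {
  n <- 80
  set.seed(11)
  meth <- runif(n)
  covs <- sim_covariates(n, 2)
  y <- 5 + 30 * meth + 0.5 * covs$age + rnorm(n, 0, 3)
  f <- fit_site(y, meth, covs)
  # rescaling the phenotype by c scales beta and se, leaves p unchanged
  f2 <- fit_site(y * 2.5, meth, covs)
  expect_equal(f2$estimate, f$estimate * 2.5)
  expect_equal(f2$std.error, f$std.error * 2.5)
  expect_equal(f2$p.value, f$p.value)
  # centering and scaling covariates leaves the methylation beta unchanged
  covs_cs <- covs
  covs_cs$age <- scale(covs$age)[, 1]
  covs_cs$bmi_percentile <- scale(covs$bmi_percentile)[, 1]
  f3 <- fit_site(y, meth, covs_cs)
  expect_equal(f3$estimate, f$estimate)
  expect_equal(f3$p.value, f$p.value)
})

test_that("degenerate fits are rejected with typed errors", {
  expect_error(fit_site(rnorm(10), rep(0.5, 10)), "zero variance",
               class = "sleepewas_fit_error")
  expect_error(fit_site(rnorm(3), runif(3),
                        data.frame(a = rnorm(3), b = rnorm(3))),
               "complete observations", class = "sleepewas_fit_error")
  # an aliased covariate is dropped with a warning, fit still returned
  n <- 30; set.seed(4)
  meth <- runif(n); covs <- data.frame(a = rnorm(n))
  covs$b <- covs$a
  expect_warning(f <- fit_site(rnorm(n), meth, covs), "aliased")
  expect_true(is.finite(f$estimate))
})

test_that("bh_fdr matches hand examples and an independent step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(c(0.001, 1.0)), c(0.002, 1.0))
  expect_error(bh_fdr(c(0.1, NA)), "NA")
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(123)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, brute_force_bh(p))
    expect_true(all(q >= p & q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # q monotone in p
  }
})

test_that("run_ewas aligns by subject id and accounts for every site", {
  st <- simulate_study(sim_config(n_subjects = 40, n_genes = 10,
                                  n_intergenic_sites = 20, seed = 55))
  f <- filter_sites(st$calls)
  ew <- run_ewas(f, st$cohort)
  S <- nrow(f$sites)
  expect_lte(nrow(ew$records), 9 * S)
  # every (site, measure) pair is either a record or a skip
  expect_equal(nrow(ew$records) + nrow(ew$skipped), 9 * S)
  expect_true(all(ew$records$q.value >= ew$records$p.value))
  expect_true(all(ew$records$q.value <= 1))
  # shuffling phenotype rows changes nothing: alignment is by id
  ew2 <- run_ewas(f, st$cohort[sample(nrow(st$cohort)), ])
  expect_equal(ew$records, ew2$records)
  expect_error(run_ewas(f, dplyr::mutate(st$cohort,
                                         subject_id = paste0("x", subject_id))),
               "no overlapping subjects")
})

test_that("a strongly planted site attains the minimum p for its measure", {
  hits <- 0L
  for (r in 1:20) {
    pe <- tibble::tibble(gene_id = "G0001", measure = "sol_sr", effect = 120)
    st <- simulate_study(sim_config(n_subjects = 120, n_genes = 8,
                                    sites_per_gene_mean = 4,
                                    n_intergenic_sites = 15,
                                    planted_effects = pe, seed = 700 + r))
    ew <- run_ewas(filter_sites(st$calls), st$cohort, measures = "sol_sr")
    best <- ew$records$site_id[which.min(ew$records$p.value)]
    if (identical(best, st$truth$site_id)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("significant_summary tallies sites and genes like a hand count", {
  genes <- tibble::tibble(gene_id = c("a", "b"), chrom = "chr1",
                          start = c(1000, 30000), end = c(2000, 31000),
                          strand = "+")
  sites <- tibble::tibble(site_id = paste0("s", 1:4), chrom = "chr1",
                          pos = c(1500, 1600, 30500, 90000))
  ann <- annotate_sites(sites, genes)
  records <- tibble::tibble(
    site_id = c(paste0("s", 1:4), paste0("s", 1:4)),
    measure = rep(c("sol_sr", "sol_act"), each = 4),
    q.value = c(0.01, 0.02, 0.03, 0.001,   # 3 significant gene sites + 1 intergenic
                0.9, 0.9, 0.9, 0.9))
  tab <- significant_summary(records, ann, gwas_genes = "a")
  gw <- tab[tab$measure == "sol_sr" & tab$group == "gene_wide", ]
  gi <- tab[tab$measure == "sol_sr" & tab$group == "gwas_informed", ]
  expect_equal(c(gw$n_genes, gw$n_sites), c(2L, 3L))
  expect_equal(c(gi$n_genes, gi$n_sites), c(1L, 2L))
  null_rows <- tab[tab$measure == "sol_act", ]
  expect_true(all(null_rows$n_genes == 0 & null_rows$n_sites == 0))
  # the GWAS-informed count never exceeds the gene-wide count
  expect_true(all(gi$n_sites <= gw$n_sites & gi$n_genes <= gw$n_genes))
})
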