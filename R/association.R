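# Core OLS helper: coefficient 2 of y ~ [1, x, C], standard error from the
# normal equations via Cholesky (exact, and fast enough for genome-scale
# loops), falling back to pivoted QR when the design is rank-deficient.
# Returns NULL when the methylation column is aliased or there are no
# residual df.
ols_meth_coef <- function(y, x, C = NULL) {
  X <- cbind(`(Intercept)` = 1, meth = x, C)
  dfres <- length(y) - ncol(X)
  if (dfres >= 1) {
    XtX <- crossprod(X)
    R <- tryCatch(chol(XtX), error = function(e) NULL)
    if (!is.null(R) && min(diag(R)) <= sqrt(max(diag(R))) * 1e-7) {
      R <- NULL   # numerically rank-deficient: use the pivoted QR path
    }
    if (!is.null(R)) {
      beta <- backsolve(R, backsolve(R, crossprod(X, y), transpose = TRUE))
      sigma2 <- sum((y - X %*% beta)^2) / dfres
      se <- sqrt(chol2inv(R)[2L, 2L] * sigma2)
      tstat <- beta[2L] / se
      return(list(estimate = beta[2L], std.error = se, statistic = tstat,
                  p.value = 2 * stats::pt(-abs(tstat), dfres),
                  n = length(y), df = dfres, aliased_covariates = FALSE))
    }
  }
  f <- stats::lm.fit(X, y)
  dfres <- f$df.residual
  if (is.na(f$coefficients[2L]) || dfres < 1) return(NULL)
  rk <- f$rank
  piv <- f$qr$pivot[seq_len(rk)]
  XtXi <- chol2inv(qr.R(f$qr)[seq_len(rk), seq_len(rk), drop = FALSE])
  sigma2 <- sum(f$residuals^2) / dfres
  vars <- rep(NA_real_, ncol(X))
  vars[piv] <- diag(XtXi) * sigma2
  se <- sqrt(vars[2L])
  beta <- unname(f$coefficients[2L])
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), dfres)
  aliased <- anyNA(f$coefficients[-2L])
  list(estimate = beta, std.error = se, statistic = tstat, p.value = p,
       n = length(y), df = dfres, aliased_covariates = aliased)
}

covariate_matrix <- function(covariates) {
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0)) {
    return(NULL)
  }
  covariates <- as.data.frame(covariates)
  chr <- vapply(covariates, function(v) is.character(v) || is.factor(v),
                logical(1))
  for (nm in names(covariates)[chr]) covariates[[nm]] <- factor(covariates[[nm]])
  mm <- stats::model.matrix(~ ., data = covariates)
  mm[, -1, drop = FALSE]  # intercept is supplied by the fit itself
}

#' Fit the per-site multivariable linear model
#'
#' Ordinary least squares of a sleep measure on `[1, methylation level,
#' covariates]`. The reported coefficient is the methylation term: the
#' change in the phenotype per unit methylation proportion (equivalently
#' per 100% methylation change), with its standard error and two-sided
#' t-test p-value on residual degrees of freedom. Observations with
#' missing values in any variable are dropped (complete-case per site).
#' An aliased covariate column is dropped with a warning; constant
#' methylation is an error, since the coefficient is then undefined.
#'
#' @param y Numeric phenotype vector (decimal hours for bedtime/SOT,
#'   minutes for SOL).
#' @param meth Methylation proportions in `[0, 1]`, same length.
#' @param covariates Optional data frame of adjustment covariates
#'   (numeric, or character/factor columns that are one-hot coded with the
#'   first level as reference).
#' @return An object of class `site_fit`; use [tidy()] or [glance()] for a
#'   tibble.
#' @export
#' @examples
#' meth <- seq(0, 1, length.out = 10)
#' tidy(fit_site(2 + 60 * meth, meth))
fit_site <- function(y, meth, covariates = NULL) {
  C <- covariate_matrix(covariates)
  df <- cbind(y = y, meth = meth, C)
  ok <- stats::complete.cases(df)
  y <- y[ok]; meth <- meth[ok]
  if (!is.null(C)) C <- C[ok, , drop = FALSE]
  p <- 2L + if (is.null(C)) 0L else ncol(C)
  if (length(y) < p + 1L) {
    abort_user(sprintf("need at least %d complete observations, got %d",
                       p + 1L, length(y)), class = "sleepewas_fit_error")
  }
  if (stats::var(meth) == 0) {
    abort_user("methylation level has zero variance",
               class = "sleepewas_fit_error")
  }
  fit <- ols_meth_coef(y, meth, C)
  if (is.null(fit)) {
    abort_user("methylation column aliased with covariates",
               class = "sleepewas_fit_error")
  }
  if (fit$aliased_covariates) {
    rlang::warn("rank-deficient design: aliased covariate column dropped")
  }
  structure(fit, class = "site_fit")
}

#' @export
print.site_fit <- function(x, ...) {
  cat(sprintf("site fit: beta = %.4g (se %.4g), p = %.3g, n = %d\n",
              x$estimate, x$std.error, x$p.value, x$n))
  invisible(x)
}

#' @rdname fit_site
#' @param x A `site_fit` object.
#' @param ... Unused.
#' @export
tidy.site_fit <- function(x, ...) {
  tibble::tibble(term = "meth", estimate = x$estimate,
                 std.error = x$std.error, statistic = x$statistic,
                 p.value = x$p.value)
}

#' @rdname fit_site
#' @export
glance.site_fit <- function(x, ...) {
  tibble::tibble(nobs = x$n, df.residual = x$df)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Validating wrapper around `stats::p.adjust(method = "BH")`: the step-up
#' q-value `q_(i) = min_{j >= i} min(1, p_(j) * m / j)`, mapped back to
#' input order. Missing or out-of-range p-values are rejected.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05))
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p)) abort_user("NA/NaN p-values are not allowed")
  if (any(p < 0 | p > 1)) abort_user("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Run the epigenome-wide association scan
#'
#' For every retained CpG site and every requested sleep measure, fits the
#' covariate-adjusted linear model of [fit_site()] on the site's available
#' (unmasked) samples, then applies Benjamini-Hochberg FDR within each
#' measure across its estimable sites. Subjects are aligned between the
#' call set and the phenotype table by id, so row order never matters.
#' Sites that cannot be fit for a measure (too few complete observations,
#' constant methylation, aliasing) are skipped and accounted for in the
#' `skipped` table.
#'
#' @param calls A filtered [methyl_calls] object (see [filter_sites()]).
#' @param phenotypes Phenotype tibble (see [load_phenotypes()] or
#'   [simulate_cohort()]) with `subject_id`, measure and covariate columns.
#' @param measures Character vector of measures to scan (default all nine).
#' @param covariates Covariate column names (default age, sex, race, BMI
#'   percentile and batch; batch and other non-numeric columns are one-hot
#'   coded).
#' @return An `ewas_result` object: `records` tibble (`site_id`, `chrom`,
#'   `pos`, `measure`, `estimate`, `std.error`, `statistic`, `p.value`,
#'   `q.value`, `n`), `skipped` tibble (`site_id`, `measure`, `reason`),
#'   and metadata. [tidy()] returns the records, [glance()] per-measure
#'   summaries, [autoplot()] a Manhattan panel.
#' @export
run_ewas <- function(calls, phenotypes,
                     measures = sleep_measures(),
                     covariates = c("age", "sex", "race", "bmi_percentile",
                                    "batch")) {
  if (!inherits(calls, "methyl_calls")) abort_user("`calls` must be methyl_calls")
  phenotypes <- tibble::as_tibble(phenotypes)
  missing_m <- setdiff(c(measures, covariates), names(phenotypes))
  if (length(missing_m)) {
    abort_user(paste0("phenotype table lacks columns: ",
                      paste(missing_m, collapse = ", ")))
  }
  idx <- match(calls$samples, phenotypes$subject_id)
  if (!any(!is.na(idx))) abort_user("no overlapping subjects between call set and phenotypes")
  keep_samp <- !is.na(idx)
  ph <- phenotypes[idx[keep_samp], ]
  lev <- methyl_levels(calls)[, keep_samp, drop = FALSE]

  C_full <- covariate_matrix(ph[covariates])
  cov_ok <- if (is.null(C_full)) rep(TRUE, nrow(ph)) else
    stats::complete.cases(C_full)
  S <- nrow(calls$sites)
  n_par <- 2L + if (is.null(C_full)) 0L else ncol(C_full)

  res <- vector("list", length(measures))
  skp <- vector("list", length(measures))
  for (mi in seq_along(measures)) {
    m <- measures[mi]
    y_full <- ph[[m]]
    base_ok <- cov_ok & !is.na(y_full)
    est <- matrix(NA_real_, S, 5)
    reason <- rep(NA_character_, S)
    for (s in seq_len(S)) {
      ok <- base_ok & !is.na(lev[s, ])
      nn <- sum(ok)
      if (nn < n_par + 1L) { reason[s] <- "too_few_observations"; next }
      x <- lev[s, ok]
      if (stats::var(x) == 0) { reason[s] <- "constant_methylation"; next }
      fit <- ols_meth_coef(y_full[ok], x,
                           if (is.null(C_full)) NULL else
                             C_full[ok, , drop = FALSE])
      if (is.null(fit)) { reason[s] <- "aliased_methylation"; next }
      est[s, ] <- c(fit$estimate, fit$std.error, fit$statistic, fit$p.value, nn)
    }
    done <- is.na(reason)
    rec <- tibble::tibble(
      site_id = calls$sites$site_id[done], chrom = calls$sites$chrom[done],
      pos = calls$sites$pos[done], measure = m,
      estimate = est[done, 1], std.error = est[done, 2],
      statistic = est[done, 3], p.value = est[done, 4],
      n = as.integer(est[done, 5]))
    rec$q.value <- bh_fdr(rec$p.value)
    res[[mi]] <- rec
    skp[[mi]] <- tibble::tibble(site_id = calls$sites$site_id[!done],
                                measure = m, reason = reason[!done])
  }
  structure(list(records = dplyr::bind_rows(res),
                 skipped = dplyr::bind_rows(skp),
                 measures = measures, covariates = covariates,
                 n_samples = sum(keep_samp)),
            class = "ewas_result")
}

#' @export
print.ewas_result <- function(x, ...) {
  cat("EWAS scan:", length(unique(x$records$site_id)), "sites x",
      length(x$measures), "measures,", x$n_samples, "subjects\n")
  cat("  records:", nrow(x$records), "  skipped:", nrow(x$skipped), "\n")
  print(glance(x))
  invisible(x)
}

#' @rdname run_ewas
#' @param x An `ewas_result` object.
#' @param ... Unused.
#' @export
tidy.ewas_result <- function(x, ...) x$records

#' @rdname run_ewas
#' @export
glance.ewas_result <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$records, .data$measure),
    n_sites = dplyr::n(),
    n_nominal = sum(.data$p.value < 0.05),
    n_significant = sum(.data$q.value < 0.05),
    .groups = "drop")
}

#' Summarize significant sites and genes per measure
#'
#' Counts, for each sleep measure, the CpG sites significant at
#' `q < q_threshold` that annotate to at least one gene, and the unique
#' genes they hit — separately for the gene-wide universe (all annotated
#' genes) and the GWAS-informed subset. Intergenic significant sites are
#' not counted, matching the rule that only intragenic and surrounding
#' sites enter gene-level reporting.
#'
#' @param ewas An `ewas_result` or its `records` tibble.
#' @param annotated Output of [annotate_sites()].
#' @param gwas_genes Character vector of GWAS-informed gene ids.
#' @param q_threshold Significance threshold on the q-value.
#' @return Tibble: `measure`, `group` (gene_wide / gwas_informed),
#'   `n_genes`, `n_sites`, complete for every measure with zero rows
#'   filled in.
#' @export
significant_summary <- function(ewas, annotated, gwas_genes,
                                q_threshold = 0.05) {
  records <- if (inherits(ewas, "ewas_result")) ewas$records else ewas
  measures <- unique(records$measure)
  grp <- site_groups(annotated, gwas_genes)
  ann <- annotated[!is.na(annotated$gene_id), c("site_id", "gene_id")]
  sig <- records[records$q.value < q_threshold, c("site_id", "measure")]
  tally <- function(gene_subset, label) {
    ann_g <- if (is.null(gene_subset)) ann else
      ann[ann$gene_id %in% gene_subset, ]
    hit <- dplyr::inner_join(sig, ann_g, by = "site_id",
                             relationship = "many-to-many")
    out <- dplyr::summarise(
      dplyr::group_by(hit, .data$measure),
      n_genes = dplyr::n_distinct(.data$gene_id),
      n_sites = dplyr::n_distinct(.data$site_id), .groups = "drop")
    out$group <- label
    out
  }
  res <- dplyr::bind_rows(tally(NULL, "gene_wide"),
                          tally(grp$gwas_genes, "gwas_informed"))
  full <- tidyr::expand_grid(measure = measures,
                             group = c("gene_wide", "gwas_informed"))
  out <- dplyr::left_join(full, res, by = c("measure", "group"))
  out$n_genes[is.na(out$n_genes)] <- 0L
  out$n_sites[is.na(out$n_sites)] <- 0L
  out
}
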