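# Downstream regressions on the cohort table: cluster-mean thinning and
# delayed recall; race/ethnicity-by-WMH interaction on cluster-mean
# thinning; stratified fits; and covariate-adjusted group comparisons.
# All fits are ordinary least squares with classical t confidence
# intervals. Standardized coefficients follow the
# beta = b * SD(x) / SD(y) convention, applied to every non-intercept
# term (binary indicators included).

.covariate_sets <- list(
  "primary" = c("age", "female", "apoe4", "entorhinal"),
  "primary-minus-entorhinal" = c("age", "female", "apoe4"),
  "primary-plus-education" = c("age", "female", "apoe4", "entorhinal",
                               "education"))

#' Covariate sets for the association models
#'
#' The three covariate specifications selectable by tag: `"primary"`
#' (age, sex/gender, APOE e4, baseline entorhinal thickness),
#' `"primary-minus-entorhinal"`, and `"primary-plus-education"`.
#' Memory models additionally always include the test-to-scan gap.
#'
#' @param tag One of the three tags.
#' @return Character vector of covariate column names.
#' @export
covariate_set <- function(tag = "primary") {
  if (!tag %in% names(.covariate_sets))
    stop("unknown covariate set tag: ", tag, " (expected ",
         paste(names(.covariate_sets), collapse = ", "), ")")
  .covariate_sets[[tag]]
}

# OLS fit summary with standardized/unstandardized coefficients and
# classical 95% t-intervals, from an explicit design matrix.
.fit_summary <- function(X, y, level = 0.95) {
  n <- nrow(X); k <- ncol(X)
  if (n <= k) stop("fewer subjects than model parameters (n = ", n,
                   ", k = ", k, ")")
  .check_full_rank(X)
  qx <- qr(X)
  b <- qr.coef(qx, y)
  res <- y - X %*% b
  df <- n - k
  rss <- sum(res^2)
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(diag(xtx_inv) * rss / df)
  tcrit <- stats::qt(1 - (1 - level) / 2, df)
  tval <- ifelse(se > 0, b / se, ifelse(b == 0, 0, Inf * sign(b)))
  p <- 2 * stats::pt(-abs(tval), df)
  sdy <- stats::sd(y)
  sdx <- apply(X, 2, stats::sd)
  std <- ifelse(colnames(X) == "intercept", NA_real_,
                b * sdx / ifelse(sdy > 0, sdy, NA_real_))
  out <- data.frame(term = colnames(X), b = unname(b), std_beta = unname(std),
                    se = unname(se),
                    ci_lower = unname(b - tcrit * se),
                    ci_upper = unname(b + tcrit * se),
                    t = unname(tval), p = unname(p),
                    stringsAsFactors = FALSE)
  structure(list(coefficients = out, n = n, df = df,
                 sigma = sqrt(rss / df), rss = rss),
            class = "fit_summary")
}

#' @export
print.fit_summary <- function(x, ...) {
  cat(sprintf("fit_summary: n = %d, residual df = %d, sigma = %.4g\n",
              x$n, x$df, x$sigma))
  co <- x$coefficients
  co$b <- signif(co$b, 4); co$std_beta <- signif(co$std_beta, 3)
  co$ci_lower <- signif(co$ci_lower, 4); co$ci_upper <- signif(co$ci_upper, 4)
  co$t <- signif(co$t, 4); co$p <- signif(co$p, 3); co$se <- signif(co$se, 4)
  print(co, row.names = FALSE)
  invisible(x)
}

.model_matrix <- function(table, columns) {
  miss <- setdiff(columns, names(table))
  if (length(miss)) stop("cohort table is missing columns: ",
                         paste(miss, collapse = ", "))
  cbind(intercept = 1, as.matrix(table[, columns, drop = FALSE]))
}

#' Memory outcome model
#'
#' Regresses the delayed recall score on the cluster-mean SPC of one named
#' cluster, adjusted for the chosen covariate set plus the time between
#' memory testing and the second scan.
#'
#' @param table Cohort data.frame containing `memory`, `test_gap`, the
#'   cluster column, and the covariates.
#' @param cluster_col Name of the cluster-mean SPC column.
#' @param covariates Covariate set tag (see [covariate_set()]) or an
#'   explicit character vector of column names.
#' @return A `fit_summary`.
#' @export
fit_memory_model <- function(table, cluster_col, covariates = "primary") {
  covs <- if (length(covariates) == 1 && covariates %in% names(.covariate_sets))
    covariate_set(covariates) else covariates
  X <- .model_matrix(table, c(cluster_col, covs, "test_gap"))
  .fit_summary(X, table$memory)
}

#' Race/ethnicity-by-WMH interaction model
#'
#' Regresses cluster-mean SPC on the WMH predictor, group indicators
#' (White reference), group-by-WMH products, and the covariate set. The
#' `Black:wmh` and `Hispanic:wmh` rows of the summary are the interaction
#' contrasts of interest.
#'
#' @param table Cohort data.frame.
#' @param cluster_col Name of the cluster-mean SPC outcome column.
#' @param wmh_col Name of the WMH predictor column.
#' @param covariates Covariate set tag or explicit column names.
#' @return A `fit_summary`.
#' @export
fit_interaction_model <- function(table, cluster_col, wmh_col,
                                  covariates = "primary") {
  covs <- if (length(covariates) == 1 && covariates %in% names(.covariate_sets))
    covariate_set(covariates) else covariates
  for (g in c("White", "Black", "Hispanic")) {
    w <- table[[wmh_col]][table$group == g]
    if (length(unique(w)) < 2)
      stop("stratum ", g, " has fewer than 2 distinct WMH values")
  }
  X <- .model_matrix(table, c(wmh_col, covs))
  gb <- as.numeric(table$group == "Black")
  gh <- as.numeric(table$group == "Hispanic")
  X <- cbind(X, Black = gb, Hispanic = gh,
             `Black:wmh` = gb * table[[wmh_col]],
             `Hispanic:wmh` = gh * table[[wmh_col]])
  .fit_summary(X, table[[cluster_col]])
}

#' Stratified WMH-thinning model
#'
#' Regresses cluster-mean SPC on the WMH predictor plus covariates within
#' one racial/ethnic group.
#'
#' @inheritParams fit_interaction_model
#' @param stratum Group level: `"White"`, `"Black"` or `"Hispanic"`.
#' @return A `fit_summary`.
#' @export
fit_stratified <- function(table, cluster_col, wmh_col, stratum,
                           covariates = "primary") {
  if (!stratum %in% c("White", "Black", "Hispanic"))
    stop("unknown stratum: ", stratum)
  sub <- table[table$group == stratum, , drop = FALSE]
  if (nrow(sub) < 2) stop("stratum ", stratum, " has fewer than 2 subjects")
  covs <- if (length(covariates) == 1 && covariates %in% names(.covariate_sets))
    covariate_set(covariates) else covariates
  X <- .model_matrix(sub, c(wmh_col, covs))
  .fit_summary(X, sub[[cluster_col]])
}

#' Stratified association table
#'
#' Convenience wrapper producing one row per (measure, group) with the WMH
#' slope, its 95% CI and p value — the layout of a stratified results
#' table.
#'
#' @param table Cohort data.frame.
#' @param cluster_cols Named character vector of cluster-mean SPC columns.
#' @param wmh_col WMH predictor column.
#' @param covariates Covariate set tag or explicit column names.
#' @return data.frame with columns `measure`, `group`, `n`, `b`,
#'   `ci_lower`, `ci_upper`, `p`.
#' @export
stratified_table <- function(table, cluster_cols, wmh_col,
                             covariates = "primary") {
  rows <- list()
  for (m in seq_along(cluster_cols)) {
    for (g in c("Black", "Hispanic", "White")) {
      fs <- fit_stratified(table, cluster_cols[m], wmh_col, g, covariates)
      co <- fs$coefficients[fs$coefficients$term == wmh_col, ]
      rows[[length(rows) + 1]] <- data.frame(
        measure = names(cluster_cols)[m] %||% cluster_cols[m], group = g,
        n = fs$n, b = co$b, ci_lower = co$ci_lower, ci_upper = co$ci_upper,
        p = co$p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Covariate-adjusted group difference tests
#'
#' One-way analysis of covariance per measure: the F test compares the
#' model with group indicators against the covariates-only model
#' (covariates default to age, sex/gender and APOE e4). Per-group raw
#' means and SDs are reported alongside.
#'
#' @param table Cohort data.frame.
#' @param measures Character vector of outcome column names.
#' @param covariates Covariate column names (default
#'   `c("age", "female", "apoe4")`).
#' @return data.frame with one row per measure: per-group mean and SD,
#'   `F`, `df1`, `df2`, `p`.
#' @export
group_difference_tests <- function(table, measures,
                                   covariates = c("age", "female", "apoe4")) {
  groups <- c("White", "Hispanic", "Black")
  cnt <- table(factor(table$group, levels = groups))
  if (any(cnt < 2)) stop("every group needs >= 2 subjects; counts: ",
                         paste(cnt, collapse = "/"))
  out <- lapply(measures, function(m) {
    y <- table[[m]]
    if (is.null(y)) stop("no such measure column: ", m)
    X0 <- .model_matrix(table, covariates)
    X1 <- cbind(X0, Black = as.numeric(table$group == "Black"),
                Hispanic = as.numeric(table$group == "Hispanic"))
    f0 <- .fit_summary(X0, y); f1 <- .fit_summary(X1, y)
    df1 <- ncol(X1) - ncol(X0); df2 <- f1$df
    Fstat <- ((f0$rss - f1$rss) / df1) / (f1$rss / df2)
    stats <- unlist(lapply(groups, function(g) {
      v <- y[table$group == g]
      c(mean(v), stats::sd(v))
    }))
    names(stats) <- as.vector(outer(c("mean", "sd"), groups,
                                    function(a, b) paste(b, a, sep = "_")))
    data.frame(measure = m, t(stats), F = Fstat, df1 = df1, df2 = df2,
               p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
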