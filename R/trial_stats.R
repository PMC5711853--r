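# Trial-level statistics: treatment ANOVA, grouped Pearson correlation
# tables, forward stepwise regression with per-term variance portions, and
# isotope delta notation.
#
# Conventions: two-sided p-values throughout, no multiple-testing
# correction; missing values are dropped pairwise for correlations and
# listwise for regressions; the pooled ("Combined") group is both
# treatments together without adjustment.

#' Significance stars at the 0.05 / 0.01 / 0.001 levels
#' @param p Numeric p-value(s).
#' @return Character vector: `***`, `**`, `*` or empty.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' One-way treatment ANOVA for a trait
#'
#' Tests the treatment effect on one trait with a one-way analysis of
#' variance and reports per-level means with their standard errors
#' (mean +/- se layout).
#'
#' @param records Data.frame of plot records.
#' @param trait Name of the numeric trait column.
#' @param group Name of the factor column (default `"treatment"`).
#' @return A list with `F`, `p`, `df`, and `means` (data.frame: level, n,
#'   mean, se).
#' @export
treatment_anova <- function(records, trait, group = "treatment") {
  stopifnot(is.data.frame(records), trait %in% names(records),
            group %in% names(records))
  dat <- records[!is.na(records[[trait]]) & !is.na(records[[group]]),
                 c(trait, group)]
  names(dat) <- c("y", "g")
  dat$g <- factor(dat$g)
  counts <- table(dat$g)
  if (length(counts) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(counts < 2L)) {
    stop(sprintf("group(s) with fewer than 2 records: %s",
                 paste(names(counts)[counts < 2L], collapse = ", ")),
         call. = FALSE)
  }
  fit <- stats::aov(y ~ g, data = dat)
  an <- summary(fit)[[1L]]
  means <- do.call(rbind, lapply(split(dat$y, dat$g), function(v) {
    data.frame(n = length(v), mean = mean(v), se = stats::sd(v) / sqrt(length(v)))
  }))
  means <- cbind(level = rownames(means), means, row.names = NULL)
  Fv <- an[["F value"]][1L]
  pv <- an[["Pr(>F)"]][1L]
  # two identical groups give 0/0; report F = 0, p = 1
  if (is.nan(Fv) || an[["Mean Sq"]][2L] == 0 && an[["Mean Sq"]][1L] == 0) {
    Fv <- 0; pv <- 1
  }
  list(F = Fv, p = pv, df = an[["Df"]], means = means)
}

#' Grouped Pearson correlation table
#'
#' Pearson correlation of each index column against a target column,
#' within each treatment group and in the pooled sample ("Combined").
#' Pairs with a missing value are dropped pairwise; a cell with fewer than
#' 3 complete pairs is reported as NA rather than fabricated.
#'
#' @param records Data.frame of plot records.
#' @param index_columns Character vector of index column names.
#' @param target_column Name of the target column (e.g. grain yield).
#' @param group_column Grouping factor column (default `"treatment"`).
#' @param groups Group labels to report; the label `"Combined"` denotes the
#'   pooled sample.
#' @return A data.frame with columns `index`, `group`, `r`, `p`, `n`,
#'   `stars`.
#' @export
pearson_table <- function(records, index_columns, target_column,
                          group_column = "treatment",
                          groups = c("NPF", "OP", "Combined")) {
  stopifnot(is.data.frame(records), target_column %in% names(records))
  missing_idx <- setdiff(index_columns, names(records))
  if (length(missing_idx)) {
    stop(sprintf("missing index column(s): %s", paste(missing_idx, collapse = ", ")),
         call. = FALSE)
  }
  out <- expand.grid(index = index_columns, group = groups,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$r <- NA_real_; out$p <- NA_real_; out$n <- NA_integer_
  for (i in seq_len(nrow(out))) {
    sel <- if (out$group[i] == "Combined") rep(TRUE, nrow(records))
           else records[[group_column]] == out$group[i]
    x <- records[[out$index[i]]][sel]
    y <- records[[target_column]][sel]
    ok <- !is.na(x) & !is.na(y)
    out$n[i] <- sum(ok)
    if (sum(ok) >= 3L && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      out$r[i] <- unname(ct$estimate)
      out$p[i] <- ct$p.value
    }
  }
  out$stars <- significance_stars(out$p)
  out
}

# R^2 of response ~ terms on complete cases (terms may be empty).
.fit_r2 <- function(data, response, terms) {
  f <- if (length(terms) == 0L) stats::as.formula(sprintf("%s ~ 1", response))
       else stats::as.formula(sprintf("%s ~ %s", response,
                                      paste(sprintf("`%s`", terms), collapse = " + ")))
  summary(stats::lm(f, data = data))$r.squared
}

#' Per-term variance portions of a fitted multiple regression
#'
#' Decomposes a model's R-squared over its terms and normalises the shares
#' to sum to 1. The default `"lmg"` method averages each term's incremental
#' R-squared over all orderings of entry (exact enumeration), which is
#' well-defined for correlated predictors and reduces to incremental
#' R-squared shares under orthogonality. `"beta_sq"` uses normalised
#' squared standardised coefficients instead.
#'
#' @param records Data.frame with the response and term columns (complete
#'   cases are used).
#' @param response Response column name.
#' @param terms Character vector of selected term names (>= 1).
#' @param method `"lmg"` (default) or `"beta_sq"`.
#' @return Named numeric vector of nonnegative fractions summing to 1.
#' @export
variance_portions <- function(records, response, terms, method = c("lmg", "beta_sq")) {
  method <- match.arg(method)
  if (length(terms) < 1L) stop("need at least one selected term", call. = FALSE)
  dat <- records[stats::complete.cases(records[, c(response, terms)]),
                 c(response, terms), drop = FALSE]
  X <- as.matrix(dat[, terms, drop = FALSE])
  if (length(terms) > 1L && qr(scale(X, scale = FALSE))$rank < length(terms)) {
    stop(sprintf("degenerate (collinear) design among terms: %s",
                 paste(terms, collapse = ", ")), call. = FALSE)
  }
  if (method == "beta_sq") {
    sdat <- dat
    for (v in c(response, terms)) sdat[[v]] <- as.numeric(scale(sdat[[v]]))
    f <- stats::as.formula(sprintf("%s ~ %s", response,
                                   paste(sprintf("`%s`", terms), collapse = " + ")))
    beta <- stats::coef(stats::lm(f, data = sdat))[-1L]
    share <- beta^2
  } else {
    k <- length(terms)
    if (k > 8L) stop("lmg enumeration limited to 8 terms", call. = FALSE)
    perms <- function(v) {
      if (length(v) <= 1L) return(list(v))
      out <- list()
      for (i in seq_along(v)) {
        for (tail in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], tail)
      }
      out
    }
    share <- stats::setNames(numeric(k), terms)
    all_orders <- perms(terms)
    for (ord in all_orders) {
      prev <- 0
      for (j in seq_along(ord)) {
        r2 <- .fit_r2(dat, response, ord[seq_len(j)])
        share[ord[j]] <- share[ord[j]] + (r2 - prev)
        prev <- r2
      }
    }
    share <- share / length(all_orders)
    share <- pmax(share, 0)
  }
  tot <- sum(share)
  if (tot <= 0) stop("terms explain no variance", call. = FALSE)
  stats::setNames(as.numeric(share / tot), terms)
}

#' Forward stepwise multiple regression
#'
#' Pure forward selection: at each step the candidate with the smallest
#' partial-F p-value enters if that p-value is below `alpha_enter`; the
#' model is refit after each entry and there is no removal step. Returns
#' the final coefficients, R-squared, residual standard error, overall
#' model p-value, and per-term variance portions (see
#' [variance_portions()]).
#'
#' @param records Data.frame of plot records (complete cases over response
#'   and candidates are used).
#' @param response Response column name.
#' @param candidates Character vector of candidate predictor columns.
#' @param alpha_enter Entry threshold on the partial-F p-value (default
#'   0.05).
#' @param portion_method Passed to [variance_portions()].
#' @return A list with `terms`, `coefficients` (including `(Intercept)`),
#'   `r_squared`, `rse`, `model_p`, `portions`, `n`, `intercept_only`
#'   (logical flag), and the fitted `model`.
#' @export
forward_stepwise <- function(records, response, candidates, alpha_enter = 0.05,
                             portion_method = "lmg") {
  stopifnot(is.data.frame(records), response %in% names(records),
            all(candidates %in% names(records)))
  dat <- records[stats::complete.cases(records[, c(response, candidates)]),
                 c(response, candidates), drop = FALSE]
  if (nrow(dat) < 3L) stop("too few complete records", call. = FALSE)
  selected <- character(0)
  remaining <- candidates
  fit <- stats::lm(stats::as.formula(sprintf("%s ~ 1", response)), data = dat)
  while (length(remaining) > 0L && nrow(dat) >= length(selected) + 3L) {
    # add1 needs the full upper scope: current terms plus candidates
    scope <- stats::as.formula(
      sprintf("~ %s", paste(sprintf("`%s`", c(selected, remaining)),
                            collapse = " + ")))
    tab <- stats::add1(fit, scope = scope, test = "F")
    pvals <- tab[["Pr(>F)"]][-1L]
    names(pvals) <- rownames(tab)[-1L]
    pvals <- pvals[!is.na(pvals)]
    if (length(pvals) == 0L) break
    best <- names(pvals)[which.min(pvals)]
    if (min(pvals) >= alpha_enter) break
    best_col <- gsub("`", "", best)
    selected <- c(selected, best_col)
    remaining <- setdiff(remaining, best_col)
    fit <- stats::lm(stats::as.formula(
      sprintf("%s ~ %s", response,
              paste(sprintf("`%s`", selected), collapse = " + "))), data = dat)
  }
  sm <- summary(fit)
  if (length(selected) == 0L) {
    return(list(terms = character(0),
                coefficients = stats::coef(fit),
                r_squared = 0, rse = sm$sigma, model_p = NA_real_,
                portions = numeric(0), n = nrow(dat),
                intercept_only = TRUE, model = fit))
  }
  fstat <- sm$fstatistic
  model_p <- stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  list(terms = selected,
       coefficients = stats::coef(fit),
       r_squared = sm$r.squared,
       rse = sm$sigma,
       model_p = unname(model_p),
       portions = variance_portions(dat, response, selected,
                                    method = portion_method),
       n = nrow(dat),
       intercept_only = FALSE,
       model = fit)
}

#' Isotope delta notation
#'
#' Per-mil deviation of a sample isotope ratio from a standard:
#' `delta = (R_sample / R_standard - 1) * 1000`.
#'
#' @param R_sample Sample isotope ratio(s).
#' @param R_standard Standard (reference) isotope ratio, > 0.
#' @return Delta value(s) in per mil.
#' @examples
#' delta_notation(1.001, 1) # 1 per mil
#' @export
delta_notation <- function(R_sample, R_standard) {
  if (any(R_standard <= 0)) stop("standard ratio must be positive", call. = FALSE)
  (R_sample / R_standard - 1) * 1000
}
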