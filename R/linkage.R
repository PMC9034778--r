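# Neural-behavioral linkage: join per-(subject, zone) LBA estimates
# with pause-locked dF/F, per-subject and overall correlations, and
# the standardized multiple regression of dF/F on the two drift rates.

#' Build the linkage table
#'
#' Inner join of LBA estimates and pause dF/F aggregates on
#' (subject, zone). Rows missing either side are dropped (and counted);
#' nothing is imputed.
#'
#' @param lba_estimates data.frame with columns `subject`, `zone`,
#'   `v_approach`, `v_avoid`, `caution` (e.g. `fit_per_zone()$estimates`).
#' @param dff_aggregates data.frame with columns `subject`, `zone`,
#'   `mean_dff` (e.g. `pause_dff()$per_zone`).
#' @return data.frame of class `linkage_table` with one row per
#'   (subject, zone) covered on both sides; attribute `n_dropped`.
#' @export
build_linkage_table <- function(lba_estimates, dff_aggregates) {
  stopifnot(all(c("subject", "zone", "v_approach", "v_avoid",
                  "caution") %in% names(lba_estimates)),
            all(c("subject", "zone", "mean_dff") %in%
                  names(dff_aggregates)))
  tab <- merge(lba_estimates[, c("subject", "zone", "v_approach",
                                 "v_avoid", "caution")],
               dff_aggregates[, c("subject", "zone", "mean_dff")],
               by = c("subject", "zone"))
  if (nrow(tab) == 0) stop("empty join: no (subject, zone) overlap")
  tab <- tab[order(tab$subject, tab$zone), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "n_dropped") <-
    nrow(lba_estimates) + nrow(dff_aggregates) - 2 * nrow(tab)
  class(tab) <- c("linkage_table", "data.frame")
  tab
}

#' Correlate one LBA parameter with pause dF/F
#'
#' Overall Pearson correlation (and simple-regression R^2, F and p)
#' of mean pause dF/F against one parameter across all rows, plus
#' per-subject coefficients over that subject's zone triples
#' (descriptive only; 3 points cannot support inference).
#'
#' @param table a `linkage_table`.
#' @param parameter one of "v_approach", "v_avoid", "caution".
#' @return list with `r`, `r2`, `F`, `df`, `p`, `n`, and `per_subject`
#'   (data.frame subject, r, slope).
#' @export
correlate_params <- function(table, parameter = c("v_approach",
                                                  "v_avoid",
                                                  "caution")) {
  parameter <- match.arg(parameter)
  x <- table[[parameter]]; y <- table$mean_dff
  if (length(x) < 3) stop("need at least 3 rows")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, r2 = NA_real_, F = NA_real_,
                df = c(NA, NA), p = NA_real_, n = length(x),
                per_subject = NULL, flag = "zero variance"))
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  per <- do.call(rbind, lapply(split(seq_len(nrow(table)),
                                     table$subject), function(ii) {
    if (length(ii) < 3) return(NULL)
    xs <- x[ii]; ys <- y[ii]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NULL)
    data.frame(subject = table$subject[ii[1]],
               r = stats::cor(xs, ys),
               slope = unname(stats::coef(stats::lm(ys ~ xs))[2]))
  }))
  list(r = stats::cor(x, y), r2 = sm$r.squared,
       F = unname(fstat[1]), df = unname(fstat[2:3]),
       p = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
       n = length(x), per_subject = per)
}

#' Regress pause dF/F on LBA drift rates
#'
#' Least-squares fit of mean pause dF/F on z-scored predictors
#' (approach and avoid drift by default; add `"caution"` for the
#' caution-inclusive model). The response is also z-scored, so the
#' coefficients are standardized betas.
#'
#' @param table a `linkage_table`.
#' @param predictors character vector of predictor columns.
#' @return list of class `regression_result`: `beta` (named,
#'   standardized), `r2`, `adj_r2`, `F`, `df`, `p`, `n`.
#' @export
regress_dff <- function(table,
                        predictors = c("v_approach", "v_avoid")) {
  stopifnot(all(predictors %in% names(table)),
            nrow(table) >= length(predictors) + 2)
  X <- scale(as.matrix(table[, predictors, drop = FALSE]))
  y <- as.numeric(scale(table$mean_dff))
  if (length(predictors) > 1) {
    kap <- kappa(crossprod(X), exact = TRUE)
    if (!is.finite(kap) || kap > 1e6) {
      warning("collinear predictors (condition number ",
              signif(kap, 3), ")")
    }
  }
  df_fit <- data.frame(y = y, X)
  fit <- stats::lm(y ~ . - 1, data = df_fit)
  sm <- summary(fit)
  # recompute F against the intercept-only null on the centered data
  n <- length(y); p <- length(predictors)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum(y^2)
  r2 <- 1 - rss / tss
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  Fv <- (r2 / p) / ((1 - r2) / (n - p - 1))
  structure(list(beta = stats::setNames(stats::coef(fit), predictors),
                 r2 = r2, adj_r2 = adj, F = Fv, df = c(p, n - p - 1),
                 p = stats::pf(Fv, p, n - p - 1, lower.tail = FALSE),
                 n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat("Standardized regression of pause dF/F, n =", x$n, "\n")
  for (nm in names(x$beta)) {
    cat(sprintf("  beta %-10s = %6.3f\n", nm, x$beta[[nm]]))
  }
  cat(sprintf("  R2 = %.3f  adj R2 = %.3f  F(%d,%d) = %.2f  p = %.4g\n",
              x$r2, x$adj_r2, x$df[1], x$df[2], x$F, x$p))
  invisible(x)
}
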