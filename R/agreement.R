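## Method-agreement statistics computed from definition: Bland-Altman
## bias / precision / limits of agreement, and the repeated-measures
## correlation (common within-subject correlation from the shared-slope,
## per-subject-intercept analysis of covariance).

#' Bland-Altman agreement analysis
#'
#' Bias is the mean of `estimates - references`, precision the sample SD of
#' the differences (n-1 denominator), and the limits of agreement
#' `bias +/- loa_mult * precision`. With `strata` given, a row is produced
#' per stratum in addition to the overall row; strata with fewer than two
#' pairs are omitted with a warning. Pairs with a missing value are dropped
#' pairwise.
#'
#' @param estimates,references paired numeric vectors.
#' @param strata optional stratum label per pair.
#' @param loa_mult limits-of-agreement multiplier (1.96 by convention).
#' @return a [tibble::tibble()] with columns `stratum`, `n`, `bias`,
#'   `precision`, `loa_low`, `loa_high`.
#' @export
#' @examples
#' bland_altman(c(3, 5, 7), c(2, 5, 8))
bland_altman <- function(estimates, references, strata = NULL,
                         loa_mult = 1.96) {
  if (length(estimates) != length(references)) {
    stop("`estimates` and `references` must have the same length",
         call. = FALSE)
  }
  keep <- is.finite(estimates) & is.finite(references)
  est <- estimates[keep]
  ref <- references[keep]
  strata <- if (is.null(strata)) NULL else as.character(strata)[keep]
  one <- function(d, label) {
    tibble::tibble(
      stratum = label, n = length(d), bias = mean(d), precision = sd(d),
      loa_low = mean(d) - loa_mult * sd(d),
      loa_high = mean(d) + loa_mult * sd(d)
    )
  }
  d <- est - ref
  if (length(d) < 2) stop("need at least 2 complete pairs", call. = FALSE)
  out <- one(d, "overall")
  if (!is.null(strata)) {
    for (s in unique(strata)) {
      ds <- d[strata == s]
      if (length(ds) < 2) {
        warning("stratum `", s, "` has fewer than 2 pairs; omitted",
                call. = FALSE)
        next
      }
      out <- dplyr::bind_rows(out, one(ds, s))
    }
  }
  out
}

#' Repeated-measures correlation
#'
#' The common within-subject correlation, computed from the
#' analysis-of-covariance definition: both variables are centered within
#' subject and `r` is the correlation of the centered values, carrying the
#' sign of the common slope. Degrees of freedom are `N - k - 1` for `N`
#' complete pairs over `k` subjects, and the p-value comes from the t
#' transform `t = r * sqrt(df / (1 - r^2))`. Subjects contributing fewer
#' than two complete pairs are dropped with a warning; with a single
#' subject the statistic reduces to that subject's ordinary correlation.
#'
#' @param subjects subject identifier per pair.
#' @param x,y paired numeric vectors.
#' @return an object of class `rmcorr_result`: `r`, `df`, `p`, `n`,
#'   `n_subjects`.
#' @export
#' @examples
#' rmcorr(rep(1:2, each = 3), c(1, 2, 3, 11, 12, 13), c(2, 4, 6, 1, 3, 5))
rmcorr <- function(subjects, x, y) {
  if (length(x) != length(y) || length(x) != length(subjects)) {
    stop("`subjects`, `x` and `y` must have the same length", call. = FALSE)
  }
  keep <- is.finite(x) & is.finite(y)
  subjects <- as.character(subjects)[keep]
  x <- x[keep]
  y <- y[keep]
  counts <- table(subjects)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning(length(small), " subject(s) with fewer than 2 complete pairs ",
            "dropped", call. = FALSE)
    keep <- !(subjects %in% small)
    subjects <- subjects[keep]
    x <- x[keep]
    y <- y[keep]
  }
  k <- length(unique(subjects))
  n <- length(x)
  if (k < 1 || n < 3) {
    stop("not enough data for a repeated-measures correlation", call. = FALSE)
  }
  xc <- x - ave(x, subjects)
  yc <- y - ave(y, subjects)
  ssx <- sum(xc^2)
  ssy <- sum(yc^2)
  if (ssx <= 0) {
    stop("zero within-subject variance in `x`; correlation undefined",
         call. = FALSE)
  }
  r <- if (ssy <= 0) 0 else sum(xc * yc) / sqrt(ssx * ssy)
  df <- n - k - 1
  if (df < 1) {
    stop("non-positive degrees of freedom (need more pairs per subject)",
         call. = FALSE)
  }
  p <- if (abs(r) >= 1) 0 else {
    2 * pt(-abs(r * sqrt(df / (1 - r^2))), df)
  }
  structure(list(r = r, df = df, p = p, n = n, n_subjects = k),
            class = "rmcorr_result")
}

#' @export
print.rmcorr_result <- function(x, ...) {
  cat(sprintf(
    "<rmcorr> r = %.4f (df = %d, p = %.3g; %d pairs, %d subjects)\n",
    x$r, x$df, x$p, x$n, x$n_subjects))
  invisible(x)
}

#' Condition-level summary table
#'
#' Mean, SD and n of the measured quantities per (volume status x chest
#' wall) cell and overall, in the layout of the experiment's results table:
#' compliances (Crs, Ccw, CL), the occlusion-test ratios (dPes/dPaw,
#' kappa), and the three tidal pleural-swing estimates. Each variable uses
#' its own inclusion set from the exclusion cascade: the directly measured
#' swing and the compliances require a valid pleural measurement, the
#' esophageal swing additionally a valid balloon ratio, the CVP-derived
#' swing a successful occlusion test.
#'
#' @param conditions processed-condition tibble (see [process_record()]).
#' @return a long [tibble::tibble()] with columns `variable`, `cell`,
#'   `mean`, `sd`, `n`. Empty cells carry `NA` means.
#' @export
summarize_study <- function(conditions) {
  excl <- apply_exclusions(conditions)
  valid_d <- conditions[conditions$valid_dppl %in% TRUE, , drop = FALSE]
  ot_ok <- conditions[!(conditions$ot_failed %in% TRUE) &
                        !(conditions$cvp_failed %in% TRUE), , drop = FALSE]
  specs <- list(
    crs = list(data = valid_d, var = "crs"),
    ccw = list(data = valid_d, var = "ccw"),
    cl = list(data = valid_d, var = "cl"),
    ratio_pes_ot = list(data = ot_ok, var = "ratio_pes"),
    kappa = list(data = ot_ok, var = "kappa"),
    d_dppl = list(data = valid_d, var = "d_dppl"),
    d_pes = list(data = excl$sets$pes_vs_dppl, var = "d_pes"),
    est_dppl = list(data = excl$sets$cdcvp_vs_dppl, var = "est_dppl")
  )
  cells <- rbind(CONDITION_GRID,
                 data.frame(volume_status = "all", ccw_level = "all"))
  rows <- list()
  for (v in names(specs)) {
    dat <- specs[[v]]$data
    vals_all <- dat[[specs[[v]]$var]]
    for (g in seq_len(nrow(cells))) {
      vs <- cells$volume_status[g]
      cw <- cells$ccw_level[g]
      vals <- if (vs == "all") vals_all else {
        vals_all[dat$volume_status == vs & dat$ccw_level == cw]
      }
      vals <- vals[is.finite(vals)]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variable = v,
        cell = if (vs == "all") "all" else paste(vs, cw, sep = "."),
        mean = if (length(vals)) mean(vals) else NA_real_,
        sd = if (length(vals) > 1) sd(vals) else NA_real_,
        n = length(vals)
      )
    }
  }
  dplyr::bind_rows(rows)
}
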