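#' Load the bundled 30-case clinical comparison table
#'
#' One row per patient: clinician-judged NPUAP stage, the nurse's
#' ruler-based length-by-width area, and the machine's LW and
#' morphology-based areas (cm^2). Seven cases whose wound location was
#' determined inconsistently between nurse and machine are flagged as
#' outliers.
#'
#' @param path CSV path; defaults to the bundled fixture.
#' @return `data.frame` with columns `case_id`, `stage` (one of `"1"`,
#'   `"2"`, `"3"`, `"4"`, `"unstageable"`), `nurse_lw_cm2`,
#'   `machine_lw_cm2`, `machine_morph_cm2`, `outlier` (logical).
#' @export
pi_case_table <- function(path = system.file("extdata", "pi_cases.csv",
                                             package = "hsiwound")) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "stage", "nurse_lw_cm2", "machine_lw_cm2",
            "machine_morph_cm2", "outlier")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop("case table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d$stage <- as.character(d$stage)
  bad <- setdiff(unique(d$stage), c("1", "2", "3", "4", "unstageable"))
  if (length(bad)) {
    stop("data error: unknown stage label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  d$outlier <- as.logical(d$outlier)
  if (any(d[need[3:5]] < 0)) stop("areas must be >= 0", call. = FALSE)
  d
}

#' Summarize NPUAP stage counts
#'
#' @param records a case table as from [pi_case_table()].
#' @return `data.frame` with `stage`, `n`, `percent` over the five NPUAP
#'   categories (zero rows kept).
#' @export
summarize_stages <- function(records) {
  levels <- c("1", "2", "3", "4", "unstageable")
  st <- as.character(records$stage)
  bad <- setdiff(unique(st), levels)
  if (length(bad)) {
    stop("data error: unknown stage label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- vapply(levels, function(l) sum(st == l), integer(1))
  data.frame(stage = levels, n = n,
             percent = if (sum(n) > 0) round(100 * n / sum(n), 2) else 0,
             row.names = NULL)
}

#' Pearson product-moment correlation
#'
#' Thin, precondition-checked wrapper over [stats::cor()].
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  .check_pair(x, y)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("undefined statistic: zero variance input", call. = FALSE)
  }
  stats::cor(x, y, method = "pearson")
}

#' Spearman rank correlation (midranks for ties)
#'
#' @inheritParams pearson_r
#' @return Correlation coefficient.
#' @export
spearman_rho <- function(x, y) {
  .check_pair(x, y)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("undefined statistic: constant input", call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

.check_pair <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("NA in input", call. = FALSE)
  invisible(NULL)
}

#' Single-measure intraclass correlation for two raters
#'
#' Computed from ANOVA mean squares. `"oneway"` is ICC(1,1) from the
#' one-way random-effects model: (MSB - MSW) / (MSB + (k-1) MSW).
#' `"twoway_agreement"` is the absolute-agreement single-measure form
#' ICC(A,1): (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n). The
#' agreement form penalizes systematic offsets between the raters that
#' plain correlation ignores.
#'
#' @param x,y paired measurements by the two raters.
#' @param form `"oneway"` or `"twoway_agreement"`.
#' @return Coefficient with the form recorded as attribute `"form"`.
#' @export
icc_single <- function(x, y, form = c("oneway", "twoway_agreement")) {
  form <- match.arg(form)
  .check_pair(x, y)
  n <- length(x)
  k <- 2L
  dat <- rbind(x, y)                   # raters in rows, subjects in columns
  grand <- mean(dat)
  subj_means <- colMeans(dat)
  rater_means <- rowMeans(dat)
  if (stats::var(subj_means) == 0) {
    stop("undefined statistic: no between-subject variance", call. = FALSE)
  }
  ssb <- k * sum((subj_means - grand)^2)
  msb <- ssb / (n - 1)
  ssw <- sum((t(dat) - subj_means)^2)
  msw <- ssw / (n * (k - 1))
  val <- if (form == "oneway") {
    (msb - msw) / (msb + (k - 1) * msw)
  } else {
    ssc <- n * sum((rater_means - grand)^2)
    msc <- ssc / (k - 1)
    sse <- sum(dat^2) - k * sum(subj_means^2) - n * sum(rater_means^2) +
      n * k * grand^2
    mse <- sse / ((n - 1) * (k - 1))
    (msb - mse) / (msb + (k - 1) * mse + k * (msc - mse) / n)
  }
  structure(val, form = form)
}

#' Variance-components ICC from replicated measurements
#'
#' One-way random-effects model for repeated measurements of the same
#' subjects: ICC = sigma^2_subject / (sigma^2_subject + sigma^2_residual),
#' estimated by the ANOVA method of moments. Handles unbalanced designs;
#' a negative between-subject component estimate is truncated at 0.
#'
#' @param replicates `data.frame` with columns `subject` and `value`
#'   (a `replicate` column may be present but is not required); >= 2
#'   subjects with >= 2 replicates each.
#' @return ICC estimate in \[0, 1\], with the variance components attached
#'   as attribute `"components"`.
#' @export
icc_mixed <- function(replicates) {
  if (!all(c("subject", "value") %in% names(replicates))) {
    stop("replicates needs columns 'subject' and 'value'", call. = FALSE)
  }
  s <- factor(replicates$subject)
  v <- as.numeric(replicates$value)
  ni <- tabulate(s)
  if (nlevels(s) < 2L || all(ni < 2L)) {
    stop("estimation error: need >= 2 subjects and replicated measurements",
         call. = FALSE)
  }
  N <- length(v)
  n <- nlevels(s)
  means <- tapply(v, s, mean)
  grand <- mean(v)
  ssb <- sum(ni * (means - grand)^2)
  ssw <- sum((v - means[s])^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (N - n)
  k0 <- (N - sum(ni^2) / N) / (n - 1)   # effective replicates per subject
  sigma2_s <- max((msb - msw) / k0, 0)
  sigma2_e <- msw
  icc <- sigma2_s / (sigma2_s + sigma2_e)
  structure(icc, components = c(subject = sigma2_s, residual = sigma2_e))
}

#' Bin continuous areas into ordered categories
#'
#' Kappa statistics need categories; areas are continuous, so a binning
#' scheme must be chosen and recorded. `"quintile"` uses five bins cut at
#' the pooled 20/40/60/80% quantiles of a reference sample (pass the union
#' of both methods' values as `pool` so both raters share one scale);
#' `"fixed_edges"` uses user-supplied cut points. Intervals are
#' right-open: a value equal to an edge falls in the higher bin.
#'
#' @param values numeric vector to categorize (cm^2).
#' @param scheme `"quintile"` or `"fixed_edges"`.
#' @param edges cut points for `"fixed_edges"`, strictly increasing.
#' @param pool reference sample defining the quintile edges; defaults to
#'   `values` itself.
#' @return Integer vector of 1-based ordered categories.
#' @export
bin_areas <- function(values, scheme = c("quintile", "fixed_edges"),
                      edges = NULL, pool = values) {
  scheme <- match.arg(scheme)
  if (scheme == "quintile") {
    if (length(unique(pool)) < 5L) {
      stop("quintile binning needs >= 5 distinct values", call. = FALSE)
    }
    edges <- unname(stats::quantile(pool, probs = c(0.2, 0.4, 0.6, 0.8)))
    edges <- unique(edges)
  } else {
    if (is.null(edges)) stop("fixed_edges needs 'edges'", call. = FALSE)
    if (is.unsorted(edges, strictly = TRUE)) {
      stop("parameter error: edges must be strictly increasing",
           call. = FALSE)
    }
  }
  findInterval(values, edges, left.open = FALSE) + 1L
}

#' Cohen's kappa with optional disagreement weights and 95% CI
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e) with
#' agreement weights w_ij: identity (`"none"`), `1 - |i-j|/(R-1)`
#' (`"linear"`), or `1 - ((i-j)/(R-1))^2` (`"quadratic"`). The confidence
#' interval uses the large-sample variance of the weighted kappa
#' (Fleiss-Cohen-Everitt), of which the unweighted case is the identity
#' special case.
#'
#' @param a,b category vectors of equal length over a shared alphabet
#'   (coerced to factors with the union of levels).
#' @param weights `"none"`, `"linear"` or `"quadratic"`.
#' @param conf_level confidence level for the interval.
#' @return List: `kappa`, `se`, `ci` (length-2), `weights`, `n`.
#' @export
cohen_kappa <- function(a, b, weights = c("none", "linear", "quadratic"),
                        conf_level = 0.95) {
  weights <- match.arg(weights)
  if (length(a) != length(b)) stop("a and b lengths differ", call. = FALSE)
  lev <- sort(union(unique(a), unique(b)))
  R <- length(lev)
  if (R < 2L) {
    stop("undefined statistic: a single category in both raters (p_e = 1)",
         call. = FALSE)
  }
  fa <- factor(a, levels = lev)
  fb <- factor(b, levels = lev)
  n <- length(a)
  p <- table(fa, fb) / n
  pa <- rowSums(p)
  pb <- colSums(p)
  i <- matrix(seq_len(R), R, R)
  j <- t(i)
  w <- switch(weights,
    none = (i == j) * 1,
    linear = 1 - abs(i - j) / (R - 1),
    quadratic = 1 - ((i - j) / (R - 1))^2)
  po <- sum(w * p)
  pe <- sum(w * outer(pa, pb))
  if (pe >= 1) {
    stop("undefined statistic: expected agreement p_e = 1", call. = FALSE)
  }
  kap <- (po - pe) / (1 - pe)
  wbar_i <- as.vector(w %*% pb)     # row-conditional expected weights
  wbar_j <- as.vector(pa %*% w)
  penal <- outer(wbar_i, wbar_j, "+")
  varhat <- (sum(p * (w - penal * (1 - kap))^2) -
               (kap - pe * (1 - kap))^2) / (n * (1 - pe)^2)
  se <- sqrt(max(varhat, 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(kap + c(-1, 1) * z * se, -1), 1)
  list(kappa = kap, se = se, ci = ci, weights = weights, n = n)
}

#' Drop flagged cases from a case table
#'
#' @param records case table with a `case_id` column.
#' @param ids case ids to remove; every id must be present.
#' @return The filtered table, order preserved; removed ids attached as
#'   attribute `"excluded"`.
#' @export
exclude_outliers <- function(records, ids = records$case_id[records$outlier]) {
  unknown <- setdiff(ids, records$case_id)
  if (length(unknown)) {
    stop("lookup error: unknown case id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- records[!records$case_id %in% ids, , drop = FALSE]
  structure(out, excluded = ids)
}

#' Agreement statistics for one method pairing
#'
#' @param x,y the two methods' areas (cm^2) on the same cases.
#' @param binning kappa binning scheme, see [bin_areas()].
#' @param edges cut points when `binning = "fixed_edges"`.
#' @return One-row `data.frame`: n, Pearson r, Spearman rho, ICC(1,1),
#'   ICC(A,1), unweighted and weighted (quadratic) kappa with CI bounds,
#'   and the binning scheme used.
#' @export
agreement_report <- function(x, y, binning = "quintile", edges = NULL) {
  pool <- c(x, y)
  bx <- bin_areas(x, scheme = binning, edges = edges, pool = pool)
  by <- bin_areas(y, scheme = binning, edges = edges, pool = pool)
  ku <- cohen_kappa(bx, by, weights = "none")
  kw <- cohen_kappa(bx, by, weights = "quadratic")
  data.frame(
    n = length(x),
    pearson_r = pearson_r(x, y),
    spearman_rho = spearman_rho(x, y),
    icc_oneway = as.numeric(icc_single(x, y, "oneway")),
    icc_agreement = as.numeric(icc_single(x, y, "twoway_agreement")),
    kappa_unweighted = ku$kappa,
    kappa_unweighted_lo = ku$ci[1], kappa_unweighted_hi = ku$ci[2],
    kappa_weighted = kw$kappa,
    kappa_weighted_lo = kw$ci[1], kappa_weighted_hi = kw$ci[2],
    binning = binning)
}

#' Full method-agreement comparison on a case table
#'
#' Recomputes the clinical comparison: for each of the three method
#' pairings (nurse LW vs machine LW, nurse LW vs machine morphology,
#' machine LW vs machine morphology), the agreement statistics with all
#' cases and again with the flagged outlier cases removed.
#'
#' @param records case table as from [pi_case_table()].
#' @param binning,edges kappa binning, see [bin_areas()].
#' @return Long `data.frame`: one row per pairing x subset with the
#'   columns of [agreement_report()] plus `pairing` and `subset`.
#' @export
reproduce_table4 <- function(records, binning = "quintile", edges = NULL) {
  pairings <- list(
    nurse_vs_machine_lw = c("nurse_lw_cm2", "machine_lw_cm2"),
    nurse_vs_machine_morph = c("nurse_lw_cm2", "machine_morph_cm2"),
    machine_lw_vs_machine_morph = c("machine_lw_cm2", "machine_morph_cm2"))
  subsets <- list(with_outliers = records,
                  without_outliers = exclude_outliers(records))
  out <- list()
  for (sn in names(subsets)) {
    d <- subsets[[sn]]
    for (pn in names(pairings)) {
      cols <- pairings[[pn]]
      rep1 <- agreement_report(d[[cols[1]]], d[[cols[2]]],
                               binning = binning, edges = edges)
      rep1$pairing <- pn
      rep1$subset <- sn
      out[[length(out) + 1L]] <- rep1
    }
  }
  res <- do.call(rbind, out)
  res[, c("pairing", "subset",
          setdiff(names(res), c("pairing", "subset")))]
}
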