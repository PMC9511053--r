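# Paired before/after treatment statistics: classical two-tailed Student
# t-tests (paired within the same nephron/glomerulus, unpaired between
# groups), one-way ANOVA with Sidak-adjusted pairwise comparisons, and
# percent-change summaries.

#' Paired two-tailed Student t-test
#'
#' Equivalent to a one-sample t-test on the paired differences,
#' `t = mean(d) / (sd(d) / sqrt(n))` with `df = n - 1`. When the differences
#' have zero variance: identical pairs give `t = 0, p = 1` (documented
#' convention); a nonzero constant difference is reported as
#' `p < .Machine$double.xmin` with a `zero_variance` flag, since the
#' statistic is unbounded.
#'
#' @param before,after numeric vectors of equal length `n >= 2`.
#' @return list `t`, `df`, `p`, `mean_difference`, `flags`.
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after))
    stop("'before' and 'after' must have equal length")
  n <- length(before)
  if (n < 2) stop("paired t-test needs at least 2 pairs")
  if (any(!is.finite(before)) || any(!is.finite(after)))
    stop("values must be finite")
  d <- after - before
  md <- mean(d)
  sdd <- sd(d)
  flags <- character(0)
  if (sdd == 0) {
    if (md == 0) {
      return(list(t = 0, df = n - 1, p = 1, mean_difference = 0,
                  flags = "identical_pairs"))
    }
    return(list(t = sign(md) * Inf, df = n - 1,
                p = .Machine$double.xmin, mean_difference = md,
                flags = "zero_variance"))
  }
  t <- md / (sdd / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1),
       mean_difference = md, flags = flags)
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m`, capped at 1.
#'
#' @param p raw p-values.
#' @param m number of comparisons in the family (default `length(p)`).
#' @return adjusted p-values.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (m < 1) stop("'m' must be >= 1")
  if (m == 1) return(p)
  # -expm1(m log1p(-p)) is 1 - (1 - p)^m without cancellation for small p;
  # the clamp keeps adjusted >= raw under floating-point rounding
  adj <- -expm1(m * log1p(-p))
  pmin(1, pmax(adj, p))
}

#' One-way ANOVA with Sidak-adjusted pairwise comparisons
#'
#' Classical one-way ANOVA (between/within sums of squares) followed by
#' pairwise t comparisons using the pooled ANOVA mean square error with
#' `N - k` degrees of freedom, Sidak-adjusted over the requested family.
#'
#' @param groups named list of numeric vectors, each of length >= 2.
#' @param comparisons list of length-2 character vectors naming group pairs;
#'   default all pairs.
#' @return list with `anova` (data frame: F, df1, df2, p) and `comparisons`
#'   (data frame: group1, group2, mean_diff, t, p, p_adj).
#' @export
anova_sidak <- function(groups, comparisons = NULL) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) == 0)) stop("empty group supplied")
  if (any(lengths(groups) < 2)) stop("each group needs n >= 2")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  k <- length(groups)
  ns <- lengths(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  df1 <- k - 1; df2 <- N - k
  mse <- ss_within / df2
  f <- (ss_between / df1) / mse
  p_f <- pf(f, df1, df2, lower.tail = FALSE)

  if (is.null(comparisons))
    comparisons <- utils::combn(names(groups), 2, simplify = FALSE)
  m <- length(comparisons)
  rows <- lapply(comparisons, function(pair) {
    if (!all(pair %in% names(groups)))
      stop(sprintf("unknown group in comparison: %s",
                   paste(pair, collapse = " vs ")))
    a <- groups[[pair[1]]]; b <- groups[[pair[2]]]
    se <- sqrt(mse * (1 / length(a) + 1 / length(b)))
    t <- (mean(a) - mean(b)) / se
    p <- 2 * pt(-abs(t), df2)
    data.frame(group1 = pair[1], group2 = pair[2],
               mean_diff = mean(a) - mean(b), t = t, p = p)
  })
  cmp <- do.call(rbind, rows)
  cmp$p_adj <- sidak_adjust(cmp$p, m)
  list(anova = data.frame(F = f, df1 = df1, df2 = df2, p = p_f),
       comparisons = cmp)
}

#' Percent change between group means
#'
#' `100 * (1 - mean_after / mean_before)`; positive values are reductions.
#' The "tilde-integer" reporting mode truncates toward zero, the rounding
#' rule consistent with reporting reductions as approximate integers.
#'
#' @param mean_before,mean_after group means; `mean_before` must be > 0.
#' @return list `percent`, `tilde_integer`.
#' @export
percent_change <- function(mean_before, mean_after) {
  if (!is.finite(mean_before) || mean_before <= 0)
    stop("'mean_before' must be positive")
  pc <- 100 * (1 - mean_after / mean_before)
  list(percent = pc, tilde_integer = trunc(pc))
}

VALID_GROUPS <- c("placebo", "enalapril", "empagliflozin",
                  "enalapril_empagliflozin")
VALID_MEASURES <- c("sngfr_nl_min", "aff_diam_um", "eff_diam_um",
                    "glom_vol_um3")

#' Validate a table of paired nephron records
#'
#' @param records data frame with columns `animal_id`, `unit_id`, `group`,
#'   `measure`, `value_before`, `value_after`.
#' @return the validated data frame, invisibly.
#' @export
validate_records <- function(records) {
  need <- c("animal_id", "unit_id", "group", "measure",
            "value_before", "value_after")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop(sprintf("records missing columns: %s", paste(miss, collapse = ", ")))
  bad <- setdiff(unique(records$group), VALID_GROUPS)
  if (length(bad))
    stop(sprintf("invalid group label(s): %s", paste(bad, collapse = ", ")))
  bad_m <- setdiff(unique(records$measure), VALID_MEASURES)
  if (length(bad_m))
    stop(sprintf("invalid measure(s): %s", paste(bad_m, collapse = ", ")))
  invisible(records)
}

#' Summarize paired records per group and measure
#'
#' For each group x measure: number of animals and measurements, mean and SD
#' before and after, the paired t-test across units (the nephron, not the
#' animal, is the paired unit, matching per-nephron before/after designs),
#' and the percent change of means. An animal-level sensitivity analysis
#' (units averaged within animal first) is included because nephron-level
#' pairing pseudo-replicates animals. A caveat flag is set when animal
#' counts differ between groups (not every structure is measurable at every
#' time point).
#'
#' @param records validated records (see [validate_records()]).
#' @return data frame of class `group_stats`.
#' @export
summarize_groups <- function(records) {
  validate_records(records)
  key <- interaction(records$group, records$measure, drop = TRUE)
  rows <- lapply(split(records, key), function(rec) {
    n_unit <- nrow(rec)
    out <- data.frame(
      group = rec$group[1], measure = rec$measure[1],
      n_animals = length(unique(rec$animal_id)),
      n_measurements = n_unit,
      mean_before = mean(rec$value_before),
      sd_before = if (n_unit > 1) sd(rec$value_before) else NA_real_,
      mean_after = mean(rec$value_after),
      sd_after = if (n_unit > 1) sd(rec$value_after) else NA_real_)
    out$sd_undefined <- n_unit < 2
    if (n_unit >= 2) {
      tt <- paired_t(rec$value_before, rec$value_after)
      out$t <- tt$t; out$df <- tt$df; out$p <- tt$p
      # animal-level sensitivity: average units within animal first
      ab <- tapply(rec$value_before, rec$animal_id, mean)
      aa <- tapply(rec$value_after, rec$animal_id, mean)
      if (length(ab) >= 2) {
        ta <- paired_t(as.numeric(ab), as.numeric(aa))
        out$p_animal_level <- ta$p
      } else out$p_animal_level <- NA_real_
    } else {
      out$t <- NA_real_; out$df <- NA_real_; out$p <- NA_real_
      out$p_animal_level <- NA_real_
    }
    pc <- percent_change(out$mean_before, out$mean_after)
    out$percent_change <- pc$percent
    out$percent_change_tilde <- pc$tilde_integer
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "unbalanced_n") <- length(unique(
    tapply(records$animal_id, records$group,
           function(a) length(unique(a))))) > 1
  class(res) <- c("group_stats", "data.frame")
  res
}

#' @export
print.group_stats <- function(x, ...) {
  cat("<group_stats>\n")
  print.data.frame(x, digits = 4)
  if (isTRUE(attr(x, "unbalanced_n")))
    cat("note: animal counts differ between groups",
        "(not all units measurable at every time point)\n")
  invisible(x)
}
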