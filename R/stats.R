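#' Per-animal incidence and duration metrics
#'
#' For each vigilance state: event count, total event duration, count per
#' hour of that state, duration (s) per hour of that state, and percentage
#' of state time occupied by events. All normalisations are exact
#' arithmetic on counts and durations.
#'
#' @param events event tibble with `state` assigned.
#' @param state_metrics a `state_metrics` object from [summarize_states()].
#' @param kinds event kinds counted (default the epileptic kinds).
#' @return tibble, one row per state.
#' @export
incidence_metrics <- function(events, state_metrics,
                              kinds = c("SWD", "SSWD")) {
  ev <- events[events$kind %in% kinds, , drop = FALSE]
  durs <- state_metrics$durations
  rows <- lapply(durs$state, function(st) {
    sec <- durs$seconds[durs$state == st]
    in_st <- ev[ev$state == st, , drop = FALSE]
    cnt <- nrow(in_st)
    tot <- sum(in_st$duration_s)
    if (sec == 0 && cnt > 0)
      abort(sprintf("events assigned to state '%s' with zero duration", st),
            class = "swd_consistency_error")
    h <- sec / 3600
    tibble(state = st, duration_h = h, event_count = cnt,
           event_total_dur_s = tot,
           events_per_hr = if (h > 0) cnt / h else 0,
           event_dur_s_per_hr = if (h > 0) tot / h else 0,
           event_pct_of_state = if (sec > 0) tot / sec * 100 else 0)
  })
  bind_rows(rows)
}

#' Sleep-spindle density
#'
#' Spindle count divided by seconds of NREM sleep, in Hz.
#'
#' @param events event tibble (kind `"spindle"` counted).
#' @param state_metrics a `state_metrics` object.
#' @return density in Hz.
#' @export
spindle_density <- function(events, state_metrics) {
  nrem_s <- state_metrics$durations$seconds[
    state_metrics$durations$state == "NREM"]
  if (length(nrem_s) == 0 || nrem_s == 0)
    abort("no NREM present; spindle density undefined",
          class = "swd_input_error")
  sum(events$kind == "spindle") / nrem_s
}

new_group_comparison <- function(test, groups, statistic, df, p_value,
                                 degenerate = FALSE, pairwise = NULL) {
  structure(list(test = test, groups = groups, statistic = statistic,
                 df = df, p_value = p_value, degenerate = degenerate,
                 pairwise = pairwise), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.4g, p = %.4g%s\n",
              x$test, x$statistic, x$p_value,
              if (x$degenerate) " (degenerate: zero variance)" else ""))
  print(x$groups)
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}

group_summary <- function(values, labels) {
  tibble(label = labels,
         n = vapply(values, length, integer(1)),
         mean = vapply(values, mean, numeric(1)),
         sem = vapply(values, function(v) sd(v) / sqrt(length(v)), numeric(1)))
}

#' Two-group t-test with mean +/- SEM reporting
#'
#' Classical Student t (pooled variance) by default, matching standard
#' paired/unpaired t usage; Welch available by flag. A paired comparison of
#' identical vectors (zero-variance differences) is reported as t = 0,
#' p = 1 with a `degenerate` flag rather than an error.
#'
#' @param a,b numeric vectors (n >= 2 each; equal length when paired).
#' @param paired paired or independent samples.
#' @param labels group labels for reporting.
#' @param welch use Welch's unequal-variance t instead of pooled.
#' @return a `group_comparison`.
#' @export
compare_groups <- function(a, b, paired = FALSE,
                           labels = c("group_a", "group_b"), welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    abort("need at least 2 observations per group", class = "swd_input_error")
  if (paired && length(a) != length(b))
    abort("paired comparison requires equal lengths", class = "swd_input_error")
  groups <- group_summary(list(a, b), labels)
  test <- if (paired) "paired_t" else "unpaired_t"
  if (paired && sd(a - b) == 0) {
    # identical vectors: t = 0, p = 1; a constant nonzero shift has zero
    # variance but a definite sign, reported as signed infinite t, p = 0
    d <- mean(a - b)
    return(new_group_comparison(test, groups,
                                statistic = if (d == 0) 0 else sign(d) * Inf,
                                df = length(a) - 1,
                                p_value = if (d == 0) 1 else 0,
                                degenerate = TRUE))
  }
  if (!paired && sd(c(a - mean(a), b - mean(b))) == 0 && mean(a) == mean(b)) {
    return(new_group_comparison(test, groups, statistic = 0,
                                df = length(a) + length(b) - 2, p_value = 1,
                                degenerate = TRUE))
  }
  ht <- t.test(a, b, paired = paired, var.equal = !welch)
  new_group_comparison(test, groups, statistic = unname(ht$statistic),
                       df = unname(ht$parameter), p_value = ht$p.value)
}

#' Holm-Sidak step-down adjustment
#'
#' Adjusted p-values `1 - (1 - p_(i))^(m - i + 1)` over the ordered raw
#' p-values, made monotone by a running maximum.
#'
#' @param p raw p-values.
#' @return adjusted p-values in the original order.
#' @export
holm_sidak_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(1, cummax(adj))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' One-way ANOVA with Holm-Sidak pairwise follow-up
#'
#' Classical fixed-effects one-way ANOVA (F and p). Pairwise unpaired
#' t-tests between all group pairs are adjusted by the Holm-Sidak
#' step-down procedure.
#'
#' @param groups named list of numeric vectors (>= 2 groups, n >= 2 each).
#' @param pairwise run the Holm-Sidak follow-up.
#' @return a `group_comparison` with test `"anova_oneway"`; `$pairwise`
#'   holds the adjusted pairwise table.
#' @export
anova_oneway <- function(groups, pairwise = TRUE) {
  if (length(groups) < 2 || any(vapply(groups, length, integer(1)) < 2))
    abort("need >= 2 groups with n >= 2 each", class = "swd_input_error")
  if (is.null(names(groups)))
    names(groups) <- paste0("group_", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), times = vapply(groups, length, integer(1))),
                   levels = names(groups))
  gs <- group_summary(groups, names(groups))
  if (sd(values) == 0) {
    return(new_group_comparison("anova_oneway", gs, statistic = 0,
                                df = c(length(groups) - 1,
                                       length(values) - length(groups)),
                                p_value = 1, degenerate = TRUE))
  }
  fit <- stats::oneway.test(values ~ labels, var.equal = TRUE)
  pw <- NULL
  if (pairwise) {
    pairs <- utils::combn(names(groups), 2, simplify = FALSE)
    raw <- vapply(pairs, function(pr) {
      x <- groups[[pr[1]]]; y <- groups[[pr[2]]]
      if (sd(c(x - mean(x), y - mean(y))) == 0 && mean(x) == mean(y))
        return(1)
      t.test(x, y, var.equal = TRUE)$p.value
    }, numeric(1))
    pw <- tibble(group1 = vapply(pairs, `[`, character(1), 1),
                 group2 = vapply(pairs, `[`, character(1), 2),
                 p_raw = raw, p_adj = holm_sidak_adjust(raw))
  }
  f <- unname(fit$statistic)
  if (!is.finite(f)) f <- 0
  new_group_comparison("anova_oneway", gs, statistic = f,
                       df = unname(fit$parameter),
                       p_value = if (is.finite(fit$p.value)) fit$p.value else 1,
                       pairwise = pw)
}

#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(test = x$test,
         statistic = x$statistic,
         p_value = x$p_value,
         degenerate = x$degenerate,
         df1 = x$df[1],
         df2 = if (length(x$df) > 1) x$df[2] else NA_real_)
}

#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  out <- tidy(x)
  out$n_total <- sum(x$groups$n)
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Group summaries and tests across a cohort
#'
#' Takes a tidy per-animal metric table (one row per animal x phase, one
#' column per metric) and a comparison design, and returns the mean +/- SEM
#' table with the chosen test per comparison: wt vs het and M vs F unpaired
#' t, pre vs post paired t (matched by `animal_id`), state triples one-way
#' ANOVA with Holm-Sidak follow-up.
#'
#' @param animals tibble with columns `animal_id`, grouping columns, and
#'   metric columns.
#' @param comparisons tibble with columns `metric` (column of `animals`),
#'   `by` (grouping column with two levels, or more for ANOVA), `test`
#'   (`"unpaired_t"`, `"paired_t"`, `"anova_oneway"`); paired designs are
#'   matched by `animal_id` within the two levels of `by`.
#' @param alpha significance threshold (default 0.05).
#' @return object of class `cohort_result`: a tibble of comparisons with
#'   group ns, means, SEMs, statistic, p, adjusted p and significance flag.
#' @export
cohort_report <- function(animals, comparisons, alpha = 0.05) {
  rows <- list()
  for (i in seq_len(nrow(comparisons))) {
    cmp <- comparisons[i, ]
    metric <- cmp$metric
    if (!metric %in% names(animals))
      abort(sprintf("metric '%s' not in animal table", metric),
            class = "swd_config_error")
    by <- cmp$by
    if (!by %in% names(animals))
      abort(sprintf("grouping column '%s' not in animal table", by),
            class = "swd_config_error")
    grp <- split(animals[[metric]], animals[[by]])
    if (cmp$test == "anova_oneway") {
      gc <- anova_oneway(grp)
      pmin_adj <- if (!is.null(gc$pairwise)) min(gc$pairwise$p_adj) else NA_real_
      rows[[length(rows) + 1L]] <- tibble(
        metric = metric, comparison = by, test = gc$test,
        groups = paste(gc$groups$label, collapse = "/"),
        n = paste(gc$groups$n, collapse = "/"),
        means = paste(sprintf("%.4g", gc$groups$mean), collapse = "/"),
        sems = paste(sprintf("%.4g", gc$groups$sem), collapse = "/"),
        statistic = gc$statistic, p_value = gc$p_value,
        p_adj_min = pmin_adj,
        significant = gc$p_value < alpha)
    } else {
      if (length(grp) != 2)
        abort(sprintf("comparison '%s' needs exactly 2 groups, found %d",
                      by, length(grp)), class = "swd_config_error")
      paired <- cmp$test == "paired_t"
      if (paired) {
        lv <- names(grp)
        wide <- animals[order(animals$animal_id), ]
        a <- wide[[metric]][wide[[by]] == lv[1]]
        b <- wide[[metric]][wide[[by]] == lv[2]]
        gc <- compare_groups(a, b, paired = TRUE, labels = lv)
      } else {
        gc <- compare_groups(grp[[1]], grp[[2]], paired = FALSE,
                             labels = names(grp))
      }
      rows[[length(rows) + 1L]] <- tibble(
        metric = metric, comparison = by, test = gc$test,
        groups = paste(gc$groups$label, collapse = "/"),
        n = paste(gc$groups$n, collapse = "/"),
        means = paste(sprintf("%.4g", gc$groups$mean), collapse = "/"),
        sems = paste(sprintf("%.4g", gc$groups$sem), collapse = "/"),
        statistic = gc$statistic, p_value = gc$p_value,
        p_adj_min = NA_real_,
        significant = !gc$degenerate && gc$p_value < alpha)
    }
  }
  structure(bind_rows(rows), class = c("cohort_result", "tbl_df", "tbl",
                                       "data.frame"))
}

#' Write a cohort result table
#' @param result a `cohort_result`.
#' @param path output path (CSV).
#' @return `path`, invisibly.
#' @export
write_cohort_result <- function(result, path) {
  readr::write_csv(as.data.frame(result), path, progress = FALSE)
  invisible(path)
}
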