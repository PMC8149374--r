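# Group statistics on per-unit summaries (one value per animal, patient or
# map): Shapiro-Wilk normality gate, then Student t / one-way ANOVA with
# all-pairs Bonferroni on the parametric branch or Mann-Whitney /
# Kruskal-Wallis with Bonferroni-adjusted pairwise Mann-Whitney otherwise.

#' Shapiro-Wilk normality test
#'
#' Royston's algorithm (AS R94), as implemented in base R.
#'
#' @param values Numeric sample, 3 <= n <= 5000, not constant.
#' @return List with `statistic` (W) and `p_value`.
#' @export
shapiro_wilk <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3 || length(values) > 5000) {
    rm_abort("Shapiro-Wilk needs 3 <= n <= 5000", "bad_sample_size")
  }
  if (diff(range(values)) == 0) {
    rm_abort("Shapiro-Wilk is undefined for constant input", "constant_input")
  }
  ts <- stats::shapiro.test(values)
  list(statistic = unname(ts$statistic), p_value = ts$p.value)
}

#' Build a per-unit group table
#'
#' @param unit_id Unit identifiers (animal, patient or map).
#' @param group Group labels.
#' @param value One summary value per unit (mean score or mean abundance).
#' @return data.frame of class `group_table`.
#' @export
group_table <- function(unit_id, group, value) {
  df <- data.frame(unit_id = as.character(unit_id),
                   group = as.character(group),
                   value = as.numeric(value), stringsAsFactors = FALSE)
  check_finite(df$value, "group table values")
  if (length(unique(df$group)) < 2) {
    rm_abort("a group table needs at least 2 groups", "too_few_groups")
  }
  class(df) <- c("group_table", "data.frame")
  df
}

as_group_table <- function(table) {
  if (inherits(table, "group_table")) return(table)
  group_table(table$unit_id %||% seq_len(nrow(table)), table$group,
              table$value)
}

# normality gate: TRUE if every group passes Shapiro-Wilk at alpha.
# Groups too small to test (n < 3) are treated as passing (the test has no
# power there and the field's default at such n is parametric); constant
# groups, where W is undefined, fail the gate and route to the
# nonparametric branch.
normality_gate <- function(values, groups, alpha = 0.05) {
  per_group <- lapply(split(values, groups), function(v) {
    if (length(v) < 3) return(list(p_value = NA_real_, pass = TRUE))
    if (diff(range(v)) == 0) return(list(p_value = NA_real_, pass = FALSE))
    sw <- shapiro_wilk(v)
    list(p_value = sw$p_value, pass = sw$p_value > alpha)
  })
  list(pass = all(vapply(per_group, `[[`, logical(1), "pass")),
       table = data.frame(group = names(per_group),
                          shapiro_p = vapply(per_group, `[[`, numeric(1),
                                             "p_value"),
                          row.names = NULL, stringsAsFactors = FALSE))
}

mann_whitney <- function(x, y) {
  exact <- length(x) <= 8 && length(y) <= 8 &&
    !anyDuplicated(c(x, y))
  suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
}

#' Compare two groups with a normality-gated test
#'
#' If both groups pass Shapiro-Wilk at `alpha`, an unpaired two-sided
#' Student t test (equal variances; set `welch = TRUE` for Welch); otherwise
#' a two-sided Mann-Whitney test, exact for n <= 8 per group without ties,
#' normal approximation with tie correction otherwise.
#'
#' @param table A `group_table` (or data.frame with `unit_id`, `group`,
#'   `value`) holding exactly 2 groups, each with >= 2 units.
#' @param alpha Significance level for the report (and the normality gate).
#' @param welch Use the Welch (unequal variances) t test.
#' @param force `"auto"` (gated), `"parametric"` or `"nonparametric"`.
#' @return List of class `test_report`: `test_name`, `statistic`, `p_value`,
#'   `comparisons` (single row here), `alpha`, `normality` (per-group
#'   Shapiro-Wilk p).
#' @export
compare_two_groups <- function(table, alpha = 0.05, welch = FALSE,
                               force = c("auto", "parametric",
                                         "nonparametric")) {
  force <- match.arg(force)
  table <- as_group_table(table)
  gs <- split(table$value, table$group)
  if (length(gs) != 2) rm_abort("need exactly 2 groups", "too_few_groups")
  if (any(lengths(gs) < 2)) rm_abort("every group needs n >= 2",
                                     "too_few_units")
  gate <- normality_gate(table$value, table$group, alpha)
  parametric <- switch(force, auto = gate$pass, parametric = TRUE,
                       nonparametric = FALSE)
  if (parametric) {
    ht <- stats::t.test(gs[[1]], gs[[2]], var.equal = !welch)
    test_name <- if (welch) "welch_t" else "student_t"
  } else {
    ht <- mann_whitney(gs[[1]], gs[[2]])
    test_name <- "mann_whitney"
  }
  pair <- paste(names(gs), collapse = " vs ")
  structure(list(test_name = test_name,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 comparisons = data.frame(pair = pair, raw_p = ht$p.value,
                                          adjusted_p = ht$p.value,
                                          stringsAsFactors = FALSE),
                 alpha = alpha, normality = gate$table),
            class = "test_report")
}

#' Compare three or more groups with a normality-gated test
#'
#' If all groups pass Shapiro-Wilk at `alpha`: one-way ANOVA, followed by
#' all-pairs Student t comparisons with Bonferroni adjustment
#' (`adjusted = min(1, raw * n_comparisons)`). Otherwise: Kruskal-Wallis,
#' followed by Bonferroni-adjusted pairwise Mann-Whitney. The Bonferroni
#' family is the set of all pairwise comparisons within this call.
#'
#' @inheritParams compare_two_groups
#' @return A `test_report`; `statistic`/`p_value` are the omnibus test,
#'   `comparisons` has one row per group pair with raw and adjusted p.
#' @export
compare_multi_groups <- function(table, alpha = 0.05, welch = FALSE,
                                 force = c("auto", "parametric",
                                           "nonparametric")) {
  force <- match.arg(force)
  table <- as_group_table(table)
  gs <- split(table$value, table$group)
  if (length(gs) < 3) rm_abort("need at least 3 groups (use the two-group
 comparison otherwise)", "too_few_groups")
  if (any(lengths(gs) < 2)) rm_abort("every group needs n >= 2",
                                     "too_few_units")
  gate <- normality_gate(table$value, table$group, alpha)
  parametric <- switch(force, auto = gate$pass, parametric = TRUE,
                       nonparametric = FALSE)
  pairs <- utils::combn(names(gs), 2)
  n_comp <- ncol(pairs)
  if (parametric) {
    ow <- stats::oneway.test(value ~ group, data = table,
                             var.equal = !welch)
    omnibus <- list(name = if (welch) "welch_anova" else "oneway_anova",
                    statistic = unname(ow$statistic), p = ow$p.value)
    raw <- vapply(seq_len(n_comp), function(i) {
      stats::t.test(gs[[pairs[1, i]]], gs[[pairs[2, i]]],
                    var.equal = !welch)$p.value
    }, numeric(1))
  } else {
    kw <- stats::kruskal.test(table$value, factor(table$group))
    omnibus <- list(name = "kruskal_wallis",
                    statistic = unname(kw$statistic), p = kw$p.value)
    raw <- vapply(seq_len(n_comp), function(i) {
      mann_whitney(gs[[pairs[1, i]]], gs[[pairs[2, i]]])$p.value
    }, numeric(1))
  }
  structure(list(test_name = omnibus$name,
                 statistic = omnibus$statistic,
                 p_value = omnibus$p,
                 comparisons = data.frame(
                   pair = paste(pairs[1, ], pairs[2, ], sep = " vs "),
                   raw_p = raw,
                   adjusted_p = pmin(1, raw * n_comp),
                   stringsAsFactors = FALSE),
                 alpha = alpha, normality = gate$table),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("<test_report> %s: statistic = %.4g, p = %.4g (alpha = %g)\n",
              x$test_name, x$statistic, x$p_value, x$alpha))
  if (nrow(x$comparisons) > 1) {
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}
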