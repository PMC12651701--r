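# Pre/post paired comparisons, significance star coding, optional
# multiple-testing adjustment, and the cohort-level improvement summary.

#' Paired-samples t-test for a pre/post metric
#'
#' Two-sided paired t-test on `post - pre` across subjects.  Degenerate
#' all-equal differences (zero variance) are reported with `t = 0`,
#' `p = 1` and `degenerate = TRUE` rather than an error, so screening
#' loops over many metrics never silently drop a comparison.
#'
#' @param pre,post Numeric vectors of per-subject values, aligned by
#'   subject, length >= 2.
#' @return A one-row data frame: `n`, `mean_pre`, `mean_post`, `t`, `df`,
#'   `p`, `stars`, `direction` (sign of the mean difference),
#'   `degenerate`.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post))
    stop("pre and post must be aligned (equal length)", call. = FALSE)
  n <- length(pre)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  d <- post - pre
  if (stats::sd(d) == 0) {
    t_stat <- 0; p <- 1; degenerate <- TRUE
  } else {
    ht <- stats::t.test(post, pre, paired = TRUE)
    t_stat <- unname(ht$statistic); p <- ht$p.value; degenerate <- FALSE
  }
  data.frame(n = n, mean_pre = mean(pre), mean_post = mean(post),
             t = t_stat, df = n - 1L, p = p,
             stars = significance_stars(p),
             direction = sign(mean(d)), degenerate = degenerate)
}

#' Significance star coding
#'
#' `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05
#' (strict inequalities), otherwise `""`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of star strings.
#' @export
significance_stars <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Proportion of subjects improved on a score
#'
#' Counts subjects whose post score rose, stayed equal, or fell relative
#' to pre (e.g. MoCA), with the improved percentage rounded to one
#' decimal.
#'
#' @param pre_scores,post_scores Aligned numeric score vectors.
#' @return List: `improved`, `stable`, `declined` (counts),
#'   `pct_improved`.
#' @export
improvement_proportion <- function(pre_scores, post_scores) {
  if (length(pre_scores) != length(post_scores))
    stop("score lists must be aligned (equal length)", call. = FALSE)
  d <- post_scores - pre_scores
  list(improved = sum(d > 0), stable = sum(d == 0), declined = sum(d < 0),
       pct_improved = round(100 * mean(d > 0), 1))
}

#' Multiple-testing adjustment
#'
#' `"none"` (identity, the default reporting convention here) or `"bh"`
#' (Benjamini-Hochberg step-up FDR).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param method `"none"` or `"bh"`.
#' @return Adjusted p-values.
#' @export
multiple_testing_adjust <- function(p_values, method = c("none", "bh")) {
  method <- match.arg(method)
  if (any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (method == "none") p_values
  else stats::p.adjust(p_values, method = "BH")
}

#' Compare pre vs post across every metric in a tidy table
#'
#' Takes a long metric table with one row per subject-condition-metric and
#' runs a paired t-test per metric id.
#'
#' @param df Data frame with columns `subject`, `condition`, `value`, plus
#'   any id columns (e.g. `band`, `order`, `metric`, `scope`).
#' @param conditions Length-2 character vector naming the pre and post
#'   condition (default `c("pre", "post")`).
#' @param adjust Multiple-testing method, see [multiple_testing_adjust()].
#' @return Data frame: id columns, then the [paired_t()] fields and
#'   `p_adj`, `adjust_method`.
#' @export
compare_conditions <- function(df, conditions = c("pre", "post"),
                               adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  needed <- c("subject", "condition", "value")
  if (!all(needed %in% names(df)))
    stop("'df' must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  id_cols <- setdiff(names(df), needed)
  key <- interaction(df[id_cols], drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(df, key), function(g) {
    pre <- g[g$condition == conditions[1], ]
    post <- g[g$condition == conditions[2], ]
    pre <- pre[order(pre$subject), ]
    post <- post[order(post$subject), ]
    if (!identical(pre$subject, post$subject))
      stop("subjects not aligned across conditions for metric ",
           paste(unlist(g[1, id_cols]), collapse = "/"), call. = FALSE)
    cbind(g[1, id_cols, drop = FALSE], paired_t(pre$value, post$value))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- multiple_testing_adjust(out$p, adjust)
  out$adjust_method <- adjust
  out
}
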