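#' One-way fixed-effects ANOVA across groups
#'
#' Classical one-way ANOVA: `F = MS_between / MS_within` on
#' `(k - 1, N - k)` degrees of freedom, upper-tail p-value
#' (equal-variance form, equivalent to the textbook sum-of-squares
#' computation). Input groups are, e.g., per-slide accuracies by
#' quality grade.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each with
#'   >= 2 observations), or a data frame with columns `group`, `value`.
#' @return Tibble: `F`, `p`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(groups) {
  g <- as_group_list(groups)
  vals <- unlist(g, use.names = FALSE)
  fac <- factor(rep(names(g), lengths(g)))
  if (all(vapply(g, stats::var, numeric(1)) == 0)) {
    if (length(unique(vapply(g, mean, numeric(1)))) == 1) {
      abort_bad("degenerate ANOVA: zero variance within and between groups")
    }
  }
  ht <- stats::oneway.test(vals ~ fac, var.equal = TRUE)
  if (!is.finite(ht$statistic)) abort_bad("degenerate ANOVA")
  tibble::tibble(F = unname(ht$statistic), p = unname(ht$p.value),
                 df_between = unname(ht$parameter[1]),
                 df_within = unname(ht$parameter[2]))
}

as_group_list <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  if (length(groups) < 2) abort_bad("need at least 2 groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  small <- names(groups)[lengths(groups) < 2]
  if (length(small)) {
    abort_bad("group ", small[1], " has fewer than 2 observations")
  }
  groups
}

#' Holm step-down adjustment
#'
#' Sort the raw p-values ascending, multiply the i-th by `m - i + 1`,
#' take the running maximum, clip at 1; values are returned in the
#' input order. Identical to `stats::p.adjust(method = "holm")`, kept
#' explicit here because downstream significance calls depend on it.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in input order.
#' @export
holm_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Pairwise post-hoc t-tests with Holm correction
#'
#' All unordered group pairs are compared with two-sided two-sample
#' t-tests (pooled variance by default, Welch via `welch = TRUE`), and
#' the raw p-values are Holm-adjusted. A pair is significant when its
#' adjusted p-value is below `alpha`. Typically run after
#' [one_way_anova()] flags any group difference.
#'
#' @inheritParams one_way_anova
#' @param alpha Family-wise significance level (default 0.05).
#' @param welch Use Welch (unequal-variance) t-tests?
#' @return A `posthoc_result`: list with `anova` (tibble) and `pairs`
#'   (tibble: `group_i`, `group_j`, `t`, `raw_p`, `adjusted_p`,
#'   `significant`).
#' @export
pairwise_t_holm <- function(groups, alpha = 0.05, welch = FALSE) {
  g <- as_group_list(groups)
  an <- one_way_anova(g)
  nm <- names(g)
  pairs <- utils::combn(seq_along(g), 2)
  rows <- apply(pairs, 2, function(ij) {
    ht <- stats::t.test(g[[ij[1]]], g[[ij[2]]], var.equal = !welch)
    tibble::tibble(group_i = nm[ij[1]], group_j = nm[ij[2]],
                   t = unname(ht$statistic), raw_p = ht$p.value)
  })
  tab <- dplyr::bind_rows(rows)
  tab$adjusted_p <- holm_adjust(tab$raw_p)
  tab$significant <- tab$adjusted_p < alpha
  structure(list(anova = an, pairs = tab, alpha = alpha, welch = welch,
                 groups = g),
            class = "posthoc_result")
}

#' @export
print.posthoc_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%g, %g) = %.4g, p = %.4g\n",
              x$anova$df_between, x$anova$df_within, x$anova$F, x$anova$p))
  cat(sprintf("Pairwise t-tests (%s), Holm-adjusted, alpha = %g:\n",
              if (x$welch) "Welch" else "pooled variance", x$alpha))
  tab <- x$pairs
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %s vs %s: p = %.4g (adj. %.4g)%s\n",
                tab$group_i[i], tab$group_j[i], tab$raw_p[i],
                tab$adjusted_p[i], if (tab$significant[i]) " *" else ""))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname pairwise_t_holm
#' @param x A `posthoc_result`.
#' @param ... Unused.
#' @export
tidy.posthoc_result <- function(x, ...) x$pairs

#' @rdname pairwise_t_holm
#' @export
glance.posthoc_result <- function(x, ...) {
  dplyr::mutate(x$anova,
                n_pairs = nrow(x$pairs),
                n_significant = sum(x$pairs$significant),
                alpha = x$alpha)
}
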