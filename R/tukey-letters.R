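#' One-way ANOVA with Tukey HSD and compact-letter display
#'
#' Compares named groups by one-way ANOVA, runs all pairwise Tukey HSD
#' comparisons using the studentized-range distribution (Tukey-Kramer for
#' unequal group sizes), and summarizes them as a compact-letter display:
#' two groups share a letter iff their HSD comparison is non-significant at
#' `alpha`. Letters are built by the insert-and-absorb algorithm and
#' assigned in order of descending group mean for stable output.
#'
#' Degenerate input is defined rather than fatal: zero within-group variance
#' everywhere with equal means gives `F = 0`, `p = 1` and one shared letter;
#' zero within-group variance with unequal means gives `F = Inf`, `p = 0`.
#'
#' @param groups named list of numeric vectors, at least 2 groups with at
#'   least 2 values each.
#' @param alpha familywise significance level for the HSD comparisons.
#' @return object of class `tukey_letters`: `F`, `p`, `df_between`,
#'   `df_within`, `summary` (per-group `species`, `n`, `mean`, `min`, `max`,
#'   `q3`, `letters`), and `pairwise` (per-pair `q`, `p`, `significant`).
#' @export
anova_tukey_letters <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be named")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least 2 non-missing values")
  k <- length(groups)
  ni <- vapply(groups, length, integer(1))
  mi <- vapply(groups, mean, numeric(1))
  vi <- vapply(groups, stats::var, numeric(1))
  N <- sum(ni)
  grand <- sum(ni * mi) / N
  df_b <- k - 1
  df_w <- N - k
  ssb <- sum(ni * (mi - grand)^2)
  ssw <- sum((ni - 1) * vi)
  msw <- ssw / df_w
  msb <- ssb / df_b
  if (msw > 0) {
    Fstat <- msb / msw
    p <- stats::pf(Fstat, df_b, df_w, lower.tail = FALSE)
  } else if (msb == 0) {
    Fstat <- 0; p <- 1
  } else {
    Fstat <- Inf; p <- 0
  }

  pairs <- utils::combn(k, 2)
  pw <- data.frame(group1 = names(groups)[pairs[1, ]],
                   group2 = names(groups)[pairs[2, ]])
  diff <- abs(mi[pairs[1, ]] - mi[pairs[2, ]])
  if (msw > 0) {
    q <- diff / sqrt((msw / 2) * (1 / ni[pairs[1, ]] + 1 / ni[pairs[2, ]]))
    pw$q <- unname(q)
    pw$p <- stats::ptukey(pw$q, k, df_w, lower.tail = FALSE)
  } else {
    pw$q <- ifelse(diff == 0, 0, Inf)
    pw$p <- ifelse(diff == 0, 1, 0)
  }
  pw$significant <- pw$p < alpha

  letters_by_group <- compact_letters(names(groups), pw, order(-mi))
  summ <- data.frame(species = names(groups), n = ni, mean = mi,
                     min = vapply(groups, min, numeric(1)),
                     max = vapply(groups, max, numeric(1)),
                     q3 = vapply(groups, function(g)
                       unname(stats::quantile(g, 0.75)), numeric(1)),
                     letters = letters_by_group[names(groups)],
                     row.names = NULL)
  structure(list(F = Fstat, p = p, df_between = df_b, df_within = df_w,
                 summary = summ, pairwise = pw, alpha = alpha),
            class = "tukey_letters")
}

# Insert-and-absorb compact letter display. `order_idx` orders groups by
# descending mean so letter 'a' goes to the highest-mean column.
compact_letters <- function(group_names, pairwise, order_idx) {
  k <- length(group_names)
  sig <- matrix(FALSE, k, k, dimnames = list(group_names, group_names))
  for (r in seq_len(nrow(pairwise))) {
    if (pairwise$significant[r]) {
      sig[pairwise$group1[r], pairwise$group2[r]] <- TRUE
      sig[pairwise$group2[r], pairwise$group1[r]] <- TRUE
    }
  }
  cols <- list(group_names)  # start: one column holding every group
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    g1 <- group_names[a]; g2 <- group_names[b]
    if (!sig[g1, g2]) next
    new_cols <- list()
    for (col in cols) {
      if (g1 %in% col && g2 %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, g1)), list(setdiff(col, g2)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb: drop any column contained in another
    keep <- rep(TRUE, length(new_cols))
    for (i in seq_along(new_cols)) for (j in seq_along(new_cols)) {
      if (i != j && keep[i] && keep[j] &&
          all(new_cols[[i]] %in% new_cols[[j]]) &&
          !(length(new_cols[[i]]) == length(new_cols[[j]]) && i < j))
        keep[i] <- FALSE
    }
    cols <- new_cols[keep]
  }
  # order columns by the best (descending-mean) rank of their members
  ranked <- group_names[order_idx]
  col_rank <- vapply(cols, function(col) min(match(col, ranked)), numeric(1))
  cols <- cols[order(col_rank)]
  out <- setNames(rep("", k), group_names)
  for (i in seq_along(cols)) {
    for (g in cols[[i]]) out[g] <- paste0(out[g], letters[i])
  }
  out
}

#' @export
print.tukey_letters <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g; Tukey HSD at alpha = %g\n",
              x$df_between, x$df_within, x$F, x$p, x$alpha))
  print(x$summary, digits = 4)
  invisible(x)
}
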