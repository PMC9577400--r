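# Statistical companions: univariate metadata-vs-label association tests
# and fold-paired method comparison (Friedman omnibus followed by Wilcoxon
# signed-rank tests against a reference method).

#' Univariate association tests between metadata attributes and the label
#'
#' Continuous attributes are first checked for normality with a
#' Shapiro-Wilk test at the 0.05 level; normal attributes are compared
#' across label groups with Student's t test (two groups) or one-way ANOVA
#' (more), non-normal ones with the Mann-Whitney U test (two groups) or
#' its k-group generalization, the Kruskal-Wallis test. Categorical and
#' boolean attributes use a chi-square test on the contingency table.
#' Missing values are excluded per attribute; degenerate tables (an empty
#' row or column, or a constant attribute) are skipped with a warning.
#'
#' @param records List of raw metadata records.
#' @param labels Class labels (any number of groups >= 2).
#' @param schema A [meta_schema()].
#' @param binary_group Optional logical vector replacing the multiclass
#'   grouping with a two-group comparison (e.g. one class versus the
#'   rest), under which the classical two-group tests apply directly.
#' @return Data frame with one row per attribute: `attribute`, `test`
#'   (shapiro-routed choice), `p_value`, `n_used`.
#' @export
univariate_tests <- function(records, labels, schema = build_default_schema(),
                             binary_group = NULL) {
  groups <- if (is.null(binary_group)) factor(labels) else factor(binary_group)
  if (nlevels(droplevels(groups)) < 2L) stop("need >= 2 label groups")
  rows <- lapply(schema$attributes, function(a) {
    v <- lapply(records, function(r) r[[a$name]])
    miss <- vapply(v, function(x) is.null(x) || (length(x) == 1L && is.na(x)),
                   logical(1))
    g <- droplevels(groups[!miss])
    out <- data.frame(attribute = a$name, test = NA_character_,
                      p_value = NA_real_, n_used = sum(!miss))
    if (sum(!miss) < 3L || nlevels(g) < 2L) {
      warning("attribute '", a$name, "' skipped (insufficient data)")
      return(out)
    }
    if (a$kind == "numeric") {
      x <- vapply(v[!miss], as.numeric, numeric(1))
      if (length(unique(x)) < 2L) {
        warning("attribute '", a$name, "' skipped (constant)")
        return(out)
      }
      xs <- if (length(x) > 5000) sample(x, 5000) else x
      normal <- tryCatch(stats::shapiro.test(xs)$p.value > 0.05,
                         error = function(e) FALSE)
      if (normal) {
        if (nlevels(g) == 2L) {
          out$test <- "t"
          out$p_value <- stats::t.test(x ~ g)$p.value
        } else {
          out$test <- "anova"
          out$p_value <- stats::anova(stats::aov(x ~ g))[["Pr(>F)"]][1]
        }
      } else {
        if (nlevels(g) == 2L) {
          out$test <- "mann_whitney"
          out$p_value <- stats::wilcox.test(x ~ g, exact = FALSE)$p.value
        } else {
          out$test <- "kruskal_wallis"
          out$p_value <- stats::kruskal.test(x, g)$p.value
        }
      }
    } else {
      x <- vapply(v[!miss], function(z) as.character(as.vector(z)), character(1))
      tab <- table(x, g)
      tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      if (nrow(tab) < 2L || ncol(tab) < 2L) {
        warning("attribute '", a$name, "' skipped (degenerate table)")
        return(out)
      }
      out$test <- "chi_square"
      out$p_value <- suppressWarnings(stats::chisq.test(tab)$p.value)
    }
    out
  })
  do.call(rbind, rows)
}

#' Wilcoxon signed-rank test with Pratt zero handling
#'
#' Paired two-sided signed-rank test. Zero differences are ranked together
#' with the non-zero ones (Pratt's method) but excluded from the
#' statistic. The null distribution is exact (generating-function
#' convolution over the realized non-zero ranks) for up to 25 non-zero
#' differences, with a tie-corrected normal approximation beyond. All
#' differences zero yields p = 1.
#'
#' @param x,y Paired numeric vectors.
#' @return List with `statistic` (W+, the positive-rank sum), `p_value`
#'   and `n_nonzero`.
#' @export
wilcoxon_pratt <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  r <- rank(abs(d)) # zeros included in the ranking (Pratt)
  nz <- d != 0
  if (!any(nz)) {
    return(list(statistic = 0, p_value = 1, n_nonzero = 0L))
  }
  ranks <- r[nz]
  w <- sum(ranks[d[nz] > 0])
  n <- sum(nz)
  if (n <= 25L) {
    # exact null over sign assignments of the realized ranks; work in
    # doubled units so midranks (x.5) become integers
    r2 <- round(2 * ranks)
    total <- sum(r2)
    dist <- 1 # polynomial coefficients over achievable doubled sums
    offset <- 0L
    for (rk in r2) {
      new <- numeric(length(dist) + rk)
      new[seq_along(dist)] <- dist
      new[seq_along(dist) + rk] <- new[seq_along(dist) + rk] + dist
      dist <- new
    }
    dist <- dist / sum(dist)
    w2 <- round(2 * w)
    p_le <- sum(dist[seq_len(w2 + 1L)])
    p_ge <- sum(dist[(w2 + 1L):length(dist)])
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- sum(ranks) / 2
    sigma2 <- sum(ranks^2) / 4
    z <- (w - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = w, p_value = p, n_nonzero = as.integer(n))
}

#' Fold-paired comparison of methods
#'
#' Friedman omnibus test across all methods on the fold-paired metric
#' vectors, followed by two-sided Wilcoxon signed-rank tests (Pratt zero
#' handling, exact small-n distribution) of every method against a
#' designated reference method. P-values below 0.05 are flagged
#' significant.
#'
#' @param fold_metrics Named list of equal-length numeric vectors, one
#'   per method, paired by fold (e.g. from [cv_fold_metrics()]).
#' @param reference Name of the reference method (default: last entry,
#'   conventionally the full model).
#' @return Object of class `method_comparison`: `friedman_p`, and a data
#'   frame `pairs` with one row per non-reference method.
#' @export
compare_methods <- function(fold_metrics, reference = NULL) {
  stopifnot(is.list(fold_metrics), length(fold_metrics) >= 2L)
  lens <- lengths(fold_metrics)
  if (length(unique(lens)) != 1L) stop("methods must have equal fold counts")
  if (is.null(names(fold_metrics)) || any(!nzchar(names(fold_metrics)))) {
    stop("fold_metrics must be a named list")
  }
  reference <- reference %||% names(fold_metrics)[length(fold_metrics)]
  if (!reference %in% names(fold_metrics)) {
    stop("unknown reference method: ", reference)
  }
  m <- do.call(cbind, fold_metrics)
  friedman_p <- stats::friedman.test(m)$p.value
  # methods identical on every fold carry no ranking information: p = 1
  if (is.nan(friedman_p)) friedman_p <- 1
  others <- setdiff(names(fold_metrics), reference)
  pairs <- do.call(rbind, lapply(others, function(meth) {
    wt <- wilcoxon_pratt(fold_metrics[[meth]], fold_metrics[[reference]])
    data.frame(method = meth, reference = reference,
               wilcoxon_p = wt$p_value,
               significant = wt$p_value < 0.05)
  }))
  structure(list(friedman_p = friedman_p, pairs = pairs,
                 n_folds = lens[[1]]), class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("Friedman omnibus over %d methods, %d folds: p = %.4g\n",
              nrow(x$pairs) + 1L, x$n_folds, x$friedman_p))
  cat("Pairwise Wilcoxon signed-rank vs", x$pairs$reference[1], "\n")
  for (i in seq_len(nrow(x$pairs))) {
    cat(sprintf("  %-12s p = %.4g%s\n", x$pairs$method[i], x$pairs$wilcoxon_p[i],
                if (x$pairs$significant[i]) " *" else ""))
  }
  invisible(x)
}
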