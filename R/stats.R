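#' Summarize angiographic scores per acquisition group
#'
#' @param groups Named list mapping group labels (e.g. `CT1`..`CT4`) to
#'   numeric score vectors; order is preserved.
#' @param expect Optional character vector of group labels that must all be
#'   present.
#' @return Data frame with columns `group`, `mean`, `sd`, `n`.
#' @examples
#' summarize_scores(list(CT1 = c(0.24, 0.27, 0.30)))
#' @export
summarize_scores <- function(groups, expect = NULL) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  if (!is.null(expect)) {
    missing <- setdiff(expect, names(groups))
    if (length(missing))
      stop("missing group(s): ", paste(missing, collapse = ", "))
  }
  bad <- names(groups)[vapply(groups, length, integer(1)) < 2L]
  if (length(bad))
    stop("need at least 2 scores per group; offending: ",
         paste(bad, collapse = ", "))
  data.frame(group = names(groups),
             mean = vapply(groups, mean, numeric(1)),
             sd = vapply(groups, stats::sd, numeric(1)),
             n = vapply(groups, length, integer(1)),
             row.names = NULL)
}

#' Pairwise between-group comparison of angiographic scores
#'
#' All pairwise two-sample tests between the groups, assembled into a
#' symmetric p-value matrix with a unit diagonal and star annotations at
#' the 0.05 (*) and 0.01 (**) levels. Welch's t-test is the default;
#' Mann-Whitney (Wilcoxon rank-sum) is available. No multiple-testing
#' correction is applied by default; Bonferroni (or any
#' [stats::p.adjust()] method) can be requested.
#'
#' @param groups Named list of score vectors, each of length >= 2.
#' @param test `"welch_t"` (default) or `"mann_whitney"`.
#' @param p_adjust Method for [stats::p.adjust()] (default `"none"`).
#' @param alpha Significance levels for the star annotation (default
#'   `c(0.05, 0.01)`).
#' @return A `group_comparison`: list with `p_values` (symmetric matrix,
#'   diagonal 1), `stars` (character matrix), `test_name` and a `log` of
#'   degenerate pairs.
#' @export
compare_pairwise <- function(groups, test = c("welch_t", "mann_whitney"),
                             p_adjust = "none", alpha = c(0.05, 0.01)) {
  test <- match.arg(test)
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(vapply(groups, length, integer(1)) >= 2L))
  labs <- names(groups)
  k <- length(groups)
  p <- matrix(1, k, k, dimnames = list(labs, labs))
  log <- character()
  pairs <- utils::combn(k, 2)
  pvals <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- groups[[pairs[1, j]]]; b <- groups[[pairs[2, j]]]
    pvals[j] <- if (stats::sd(a) == 0 && stats::sd(b) == 0 && test == "welch_t") {
      log <- c(log, sprintf("%s vs %s: constant groups, p set to 1",
                            labs[pairs[1, j]], labs[pairs[2, j]]))
      1
    } else if (test == "welch_t") {
      stats::t.test(a, b)$p.value
    } else {
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))$p.value
    }
  }
  pvals <- stats::p.adjust(pvals, method = p_adjust)
  for (j in seq_len(ncol(pairs)))
    p[pairs[1, j], pairs[2, j]] <- p[pairs[2, j], pairs[1, j]] <- pvals[j]
  stars <- matrix("", k, k, dimnames = list(labs, labs))
  stars[p < max(alpha)] <- "*"
  stars[p < min(alpha)] <- "**"
  diag(stars) <- ""
  structure(list(p_values = p, stars = stars,
                 test_name = test, log = log),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, digits = 2, ...) {
  cat("pairwise", x$test_name, "p-values:\n")
  m <- matrix(paste0(format(round(x$p_values, digits), nsmall = digits),
                     x$stars),
              nrow(x$p_values), dimnames = dimnames(x$p_values))
  print(m, quote = FALSE)
  invisible(x)
}

#' Draw synthetic per-group score samples
#'
#' Generates angiographic-score samples for each group from a normal
#' distribution truncated to `[0, 1]` (scores are pixel fractions). The
#' default means and SDs are the density gradient the package's synthetic
#' eye emulates: highest in the fundus group, lowest anterior to the
#' equator, with the widest spread in the iris group.
#'
#' @param means,sds Per-group parameters (named or unnamed, equal length).
#' @param n Samples per group (default 27, the 3 angles x 3 films x 3
#'   areas scheme).
#' @param seed RNG seed.
#' @return Named list of score vectors.
#' @export
simulate_group_scores <- function(means = c(CT1 = 0.27, CT2 = 0.22,
                                            CT3 = 0.16, CT4 = 0.25),
                                  sds = c(0.029, 0.026, 0.032, 0.083),
                                  n = 27L, seed = NULL) {
  stopifnot(length(means) == length(sds), n >= 2L)
  labs <- names(means) %||% paste0("CT", seq_along(means))
  with_seed(seed, {
    out <- lapply(seq_along(means), function(i) {
      pmin(pmax(stats::rnorm(n, means[i], sds[i]), 0), 1)
    })
    names(out) <- labs
    out
  })
}
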