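check_panel <- function(panel) {
  need <- c("population", "Hd", "Pi", "K")
  if (!all(need %in% names(panel))) {
    stop("panel must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(panel) < 3L) {
    stop("composite scoring needs at least 3 populations", call. = FALSE)
  }
  x <- as.matrix(panel[, c("Hd", "Pi", "K")])
  if (anyNA(x)) stop("panel contains missing values", call. = FALSE)
  storage.mode(x) <- "double"
  rownames(x) <- panel$population
  x
}

#' Pearson correlation screen of the diversity indices
#'
#' Correlations among Hd, Pi and K across populations, with two-sided
#' t-tests (n - 2 df) and significance flags at the 0.01 level. A strong
#' mutual positive correlation justifies compressing the three indices
#' into a single composite axis.
#'
#' @param panel Data frame with columns `population`, `Hd`, `Pi`, `K`.
#' @param alpha Significance level for the flags (default 0.01).
#' @return List with `r` (3x3 correlation matrix), `p` (p-values) and
#'   `significant` (logical matrix at `alpha`).
#' @export
correlation_screen <- function(panel, alpha = 0.01) {
  x <- check_panel(panel)
  if (any(apply(x, 2L, stats::sd) == 0)) {
    stop("correlation undefined: constant column in panel", call. = FALSE)
  }
  r <- stats::cor(x)
  n <- nrow(x)
  p <- matrix(0, 3L, 3L, dimnames = dimnames(r))
  for (i in 1:2) for (j in (i + 1L):3L) {
    pv <- stats::cor.test(x[, i], x[, j])$p.value
    p[i, j] <- p[j, i] <- pv
  }
  list(r = r, p = p, significant = p < alpha & row(p) != col(p))
}

#' Standardize a diversity panel
#'
#' Centers each of Hd, Pi, K by its mean and scales by its sample standard
#' deviation (n - 1 denominator), so each column has mean 0 and sample
#' variance 1.
#'
#' @inheritParams correlation_screen
#' @return Numeric matrix of z-scores (populations x indices).
#' @export
standardize_panel <- function(panel) {
  x <- check_panel(panel)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("cannot standardize a constant column", call. = FALSE)
  }
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Composite genetic-diversity score
#'
#' Compresses the three diversity indices into one axis: eigendecompose
#' the 3x3 Pearson correlation matrix of (Hd, Pi, K), take the unit-norm
#' eigenvector of the leading eigenvalue, oriented so its loadings sum to
#' a positive value (higher diversity then maps to a higher score), and
#' score each population as the dot product of its standardized index row
#' with that eigenvector:
#' \deqn{Fz(F1)_p = \sum_j v_j z_{pj}.}
#' Populations with a positive score are above-average in combined
#' diversity and form the priority set.
#'
#' @inheritParams correlation_screen
#' @return An object of class `hap_composite`: list with
#'   `correlation_matrix`, `eigenvalues` (decreasing; they sum to 3),
#'   `variance_explained_pc1` (percent, `100 * lambda1 / 3`), `loadings`,
#'   `scores` (named per-population Fz values), `ranking` (populations by
#'   decreasing score) and `priority_set` (populations with `Fz > 0`).
#' @examples
#' pan <- data.frame(population = c("a", "b", "c", "d"),
#'                   Hd = c(.2, .4, .6, .8),
#'                   Pi = c(.001, .004, .002, .008),
#'                   K = c(.6, 2.5, 1.3, 5.1))
#' composite_score(pan)$scores
#' @export
composite_score <- function(panel) {
  z <- standardize_panel(panel)
  r <- stats::cor(check_panel(panel))
  e <- eigen(r, symmetric = TRUE)
  lam <- e$values
  if ((lam[1] - lam[2]) <= 1e-10 * max(lam[1], 1)) {
    stop("leading eigenvalue is (numerically) degenerate; ",
         "the first principal axis is not identified", call. = FALSE)
  }
  v <- e$vectors[, 1L]
  s <- sum(v)
  if (s < 0 || (s == 0 && v[which(v != 0)[1L]] < 0)) v <- -v
  names(v) <- colnames(r)
  scores <- drop(z %*% v)
  ranking <- names(scores)[order(-scores)]  # ties keep panel order
  structure(
    list(correlation_matrix = r,
         eigenvalues = lam,
         variance_explained_pc1 = 100 * lam[1L] / 3,
         loadings = v,
         scores = scores,
         ranking = ranking,
         priority_set = names(scores)[scores > 0]),
    class = "hap_composite"
  )
}

#' @export
print.hap_composite <- function(x, ...) {
  cat("<hap_composite> PC1 explains ",
      sprintf("%.3f", x$variance_explained_pc1), "% of variance\n",
      sep = "")
  cat("scores (Fz):\n")
  print(round(x$scores, 3))
  invisible(x)
}

#' Rank populations by composite score
#'
#' @param score A [composite_score()] result.
#' @return Data frame with columns `population`, `Fz`, `rank`, `priority`
#'   (Fz > 0), sorted by decreasing score, plus attribute
#'   `positive_fraction` (share of populations with positive score).
#' @export
rank_by_score <- function(score) {
  stopifnot(inherits(score, "hap_composite"))
  ord <- order(-score$scores)
  out <- data.frame(
    population = names(score$scores)[ord],
    Fz = unname(score$scores[ord]),
    rank = seq_along(ord),
    priority = unname(score$scores[ord] > 0),
    stringsAsFactors = FALSE
  )
  attr(out, "positive_fraction") <- mean(score$scores > 0)
  out
}
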