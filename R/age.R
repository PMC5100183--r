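#' Pairwise identities within a cluster
#'
#' For every unordered pair of reads with an accepted overlap (same criteria
#' as the clustering stage, both orientations considered), returns the
#' identity of the best-scoring overlap alignment. Self-pairs are excluded
#' and pairs with no acceptable overlap are omitted.
#'
#' @inheritParams overlap_hits
#' @return Numeric vector of identity fractions.
#' @export
pairwise_identities <- function(reads, min_overlap_frac = 0.55,
                                min_identity = 0.90, kmer_prefilter = TRUE) {
  if (length(reads) < 2) stop("insufficient pairs: need at least 2 reads")
  overlap_hits(reads, min_overlap_frac, min_identity, kmer_prefilter)$identity
}

#' Histogram of pairwise identities within a window
#'
#' Bins are left-closed, right-open, with the last bin closed; identities
#' outside `[lo, hi]` are excluded. Relative frequencies `y` are normalised
#' to sum to one over the retained pairs.
#'
#' @param identities Numeric vector of identity fractions.
#' @param lo,hi Window bounds (defaults 0.90 and 1.00).
#' @param bin_width Bin width on the identity scale (default 0.001, i.e.
#'   0.1 % identity).
#' @param cluster_id Optional label carried through to reports.
#' @return Object of class `identity_histogram` with `breaks`, `mids`,
#'   `counts`, `y` and `n_pairs`.
#' @export
build_identity_histogram <- function(identities, lo = 0.90, hi = 1.00,
                                     bin_width = 0.001, cluster_id = NA) {
  if (length(identities) == 0) stop("no identities supplied")
  stopifnot(hi > lo, bin_width > 0)
  nb <- round((hi - lo) / bin_width)
  breaks <- lo + bin_width * (0:nb)
  ids <- identities[identities >= lo & identities <= hi]
  # small epsilon keeps boundary values (e.g. 0.95) in their left-closed
  # bin despite floating-point representation of (ids - lo) / bin_width
  idx <- pmin(nb, floor((ids - lo) / bin_width + 1e-9) + 1L)  # last bin closed
  counts <- tabulate(idx, nbins = nb)
  n <- length(ids)
  structure(list(cluster_id = cluster_id, breaks = breaks,
                 mids = (breaks[-1] + breaks[-(nb + 1)]) / 2,
                 counts = counts,
                 y = if (n > 0) counts / n else rep(0, nb),
                 n_pairs = n),
            class = "identity_histogram")
}

#' @export
print.identity_histogram <- function(x, ...) {
  cat("Identity histogram", if (!is.na(x$cluster_id)) paste0("(", x$cluster_id, ")"),
      ":", x$n_pairs, "pairs in [", min(x$breaks), ",", max(x$breaks), "],",
      length(x$counts), "bins\n")
  invisible(x)
}

#' @export
plot.identity_histogram <- function(x, ...) {
  graphics::barplot(x$y, names.arg = NULL, space = 0, border = NA,
                    xlab = "pairwise identity", ylab = "relative frequency",
                    ...)
  invisible(x)
}

#' @keywords internal
ols_fit <- function(x, y, degree) {
  n <- length(y)
  fml <- if (degree == 1) y ~ x else y ~ x + I(x^2)
  fit <- stats::lm(fml)
  cf <- stats::coef(fit)
  rss <- sum(stats::resid(fit)^2)
  k <- degree + 1
  bic <- n * log(max(rss, 1e-12) / n) + k * log(n)
  list(model = if (degree == 1) "linear" else "quadratic",
       a = unname(cf[1]), b = unname(cf[2]),
       c = if (degree == 2) unname(cf[3]) else 0,
       rss = rss, n = n, k = k, bic = bic)
}

#' Fit linear and quadratic models to an identity histogram
#'
#' Ordinary least squares of the relative frequencies `y` on the bin
#' midpoints `X` (identity as a fraction) and on `X^2`. Model comparison
#' uses the Gaussian-residual BIC `n * ln(rss / n) + k * ln(n)` with
#' `k = 2` (linear) or `3` (quadratic); an `rss` of zero is floored at
#' 1e-12.
#'
#' @param h An `identity_histogram`.
#' @return List with elements `linear` and `quadratic`, each containing
#'   coefficients `a`, `b`, `c`, `rss`, `n`, `k` and `bic`.
#' @export
fit_identity_models <- function(h) {
  stopifnot(inherits(h, "identity_histogram"))
  if (length(h$mids) < 4) stop("insufficient bins: need at least 4")
  list(linear = ols_fit(h$mids, h$y, 1L),
       quadratic = ols_fit(h$mids, h$y, 2L))
}

#' Classify a cluster's age category from its two fits
#'
#' The six categories, with `X` the identity fraction and the winning model
#' chosen by lowest BIC (ties go to the linear model):
#' 1. linear wins, `b > b_tol` (rising towards 100 % identity);
#' 2. linear wins, `|b| <= b_tol` (flat);
#' 3. linear wins, `b < -b_tol` (falling);
#' 4. quadratic wins, curve opens upward (`c > 0`);
#' 5. quadratic wins, opens downward, optimum `-b/(2c)` at or below
#'    `optimum_cut`;
#' 6. quadratic wins, opens downward, optimum above `optimum_cut`.
#' Categories 1, 4 and 6 are interpreted as young, dynamic families;
#' 2, 3 and 5 as older, quiescent ones. A selected quadratic with `c = 0`
#' degenerates to a line and falls back to the linear rules.
#'
#' @param linear,quadratic Fits from [fit_identity_models()].
#' @param b_tol Slope tolerance around zero, on the fraction-identity /
#'   relative-frequency scale (default 0.001).
#' @param optimum_cut Identity above which a downward-parabola optimum
#'   counts as young (default 0.99).
#' @return List with `category` (integer 1-6) and `is_young`.
#' @export
classify_age <- function(linear, quadratic, b_tol = 0.001,
                         optimum_cut = 0.99) {
  linear_rules <- function(b) {
    if (b > b_tol) 1L else if (b >= -b_tol) 2L else 3L
  }
  if (linear$bic <= quadratic$bic + 1e-12) {
    category <- linear_rules(linear$b)
  } else if (quadratic$c > 0) {
    category <- 4L
  } else if (quadratic$c < 0) {
    optimum <- -quadratic$b / (2 * quadratic$c)
    category <- if (optimum > optimum_cut) 6L else 5L
  } else {
    category <- linear_rules(quadratic$b)
  }
  list(category = category, is_young = category %in% c(1L, 4L, 6L))
}

#' Fit and classify the age of one repeat cluster
#'
#' Convenience wrapper producing a classed model object from either a read
#' set or a prebuilt identity histogram: computes pairwise identities,
#' builds the histogram, fits both regression models and applies the
#' six-category classification. Clusters with fewer than `min_pairs`
#' accepted pair identities are reported as unclassified (`category` NA).
#'
#' @param x Named character vector of cluster reads, or an
#'   `identity_histogram`.
#' @param min_overlap_frac,min_identity Overlap acceptance criteria.
#' @param lo,hi,bin_width Histogram window and resolution.
#' @param b_tol,optimum_cut Classification tuning; see [classify_age()].
#' @param min_pairs Minimum pair identities required to classify
#'   (default 20).
#' @return Object of class `te_age_fit` with the histogram, both fits, the
#'   selected model, `category` and `is_young`; supports `print()`,
#'   `coef()`, `summary()`, `predict()` and `plot()`.
#' @export
fit_cluster_age <- function(x, min_overlap_frac = 0.55, min_identity = 0.90,
                            lo = 0.90, hi = 1.00, bin_width = 0.001,
                            b_tol = 0.001, optimum_cut = 0.99,
                            min_pairs = 20) {
  h <- if (inherits(x, "identity_histogram")) x else {
    ids <- pairwise_identities(x, min_overlap_frac, min_identity)
    if (length(ids) == 0) {
      build_identity_histogram(-1, lo, hi, bin_width)  # empty window
    } else build_identity_histogram(ids, lo, hi, bin_width)
  }
  out <- list(histogram = h, n_pairs = h$n_pairs, b_tol = b_tol,
              optimum_cut = optimum_cut, min_pairs = min_pairs)
  if (h$n_pairs < min_pairs) {
    out <- c(out, list(fits = NULL, model = "unclassified-age",
                       category = NA_integer_, is_young = NA))
    return(structure(out, class = "te_age_fit"))
  }
  fits <- fit_identity_models(h)
  cl <- classify_age(fits$linear, fits$quadratic, b_tol, optimum_cut)
  sel <- if (fits$linear$bic <= fits$quadratic$bic + 1e-12) "linear" else
    "quadratic"
  structure(c(out, list(fits = fits, model = sel, category = cl$category,
                        is_young = cl$is_young)),
            class = "te_age_fit")
}

#' @export
print.te_age_fit <- function(x, ...) {
  cat("Cluster age fit (", x$n_pairs, " pair identities)\n", sep = "")
  if (is.na(x$category)) {
    cat("  unclassified-age: fewer than", x$min_pairs, "pairs\n")
    return(invisible(x))
  }
  cat("  selected model:", x$model,
      sprintf("(BIC %.2f vs %.2f)", x$fits$linear$bic, x$fits$quadratic$bic),
      "\n")
  cat("  category:", x$category,
      if (x$is_young) "(young/dynamic)" else "(old/quiescent)", "\n")
  invisible(x)
}

#' @export
coef.te_age_fit <- function(object, ...) {
  if (is.na(object$category)) return(NULL)
  f <- object$fits[[object$model]]
  c(a = f$a, b = f$b, c = f$c)
}

#' @export
summary.te_age_fit <- function(object, ...) {
  print(object)
  if (!is.na(object$category)) {
    f <- object$fits
    cat(sprintf("  linear:    a=%.4g b=%.4g rss=%.3g BIC=%.2f\n",
                f$linear$a, f$linear$b, f$linear$rss, f$linear$bic))
    cat(sprintf("  quadratic: a=%.4g b=%.4g c=%.4g rss=%.3g BIC=%.2f\n",
                f$quadratic$a, f$quadratic$b, f$quadratic$c, f$quadratic$rss,
                f$quadratic$bic))
    if (f$quadratic$c < 0) {
      cat(sprintf("  quadratic optimum at identity %.4f\n",
                  -f$quadratic$b / (2 * f$quadratic$c)))
    }
  }
  invisible(object)
}

#' @export
predict.te_age_fit <- function(object, newdata = NULL, ...) {
  if (is.na(object$category)) stop("unclassified fit: nothing to predict")
  x <- if (is.null(newdata)) object$histogram$mids else newdata
  f <- object$fits[[object$model]]
  f$a + f$b * x + f$c * x^2
}

#' @export
plot.te_age_fit <- function(x, ...) {
  h <- x$histogram
  graphics::plot(h$mids, h$y, type = "h", col = "grey60",
                 xlab = "pairwise identity", ylab = "relative frequency",
                 ...)
  if (!is.na(x$category)) {
    f <- x$fits
    graphics::lines(h$mids, f$linear$a + f$linear$b * h$mids, col = 2)
    graphics::lines(h$mids, f$quadratic$a + f$quadratic$b * h$mids +
                      f$quadratic$c * h$mids^2, col = 4)
    graphics::legend("topleft", bty = "n",
                     legend = c(sprintf("linear (BIC %.1f)", f$linear$bic),
                                sprintf("quadratic (BIC %.1f)", f$quadratic$bic),
                                sprintf("category %d", x$category)),
                     col = c(2, 4, NA), lty = c(1, 1, NA))
  }
  invisible(x)
}

#' Classify all clusters of a clustering result
#'
#' @param reads Named character vector of all reads.
#' @param membership data.frame `read_id`, `cluster_id` (e.g. from
#'   [build_clusters()]).
#' @inheritParams fit_cluster_age
#' @return data.frame `cluster_id`, `n_pairs`, `model`, `a`, `b`, `c`,
#'   `bic_lin`, `bic_quad`, `category`, `is_young`.
#' @export
classify_clusters <- function(reads, membership, min_overlap_frac = 0.55,
                              min_identity = 0.90, lo = 0.90, hi = 1.00,
                              bin_width = 0.001, b_tol = 0.001,
                              optimum_cut = 0.99, min_pairs = 20) {
  sp <- split(membership$read_id, membership$cluster_id)
  out <- do.call(rbind, Map(function(cid, rid) {
    fit <- fit_cluster_age(reads[rid], min_overlap_frac, min_identity,
                           lo, hi, bin_width, b_tol, optimum_cut, min_pairs)
    cf <- coef(fit)
    data.frame(cluster_id = cid,
               n_pairs = fit$n_pairs,
               model = fit$model,
               a = if (is.null(cf)) NA_real_ else cf[["a"]],
               b = if (is.null(cf)) NA_real_ else cf[["b"]],
               c = if (is.null(cf)) NA_real_ else cf[["c"]],
               bic_lin = if (is.null(fit$fits)) NA_real_ else fit$fits$linear$bic,
               bic_quad = if (is.null(fit$fits)) NA_real_ else fit$fits$quadratic$bic,
               category = fit$category,
               is_young = fit$is_young,
               stringsAsFactors = FALSE)
  }, names(sp), sp))
  rownames(out) <- NULL
  out
}

#' Percentage of clusters in the young categories
#'
#' @param categories Integer vector of categories 1-6 (NA =
#'   unclassified-age, excluded from the denominator).
#' @return Percent of classified clusters in categories 1, 4 or 6.
#' @examples
#' young_fraction(c(rep(1, 59), rep(5, 54))) # 52.2 %
#' @export
young_fraction <- function(categories) {
  categories <- categories[!is.na(categories)]
  if (length(categories) == 0) return(NA_real_)
  100 * sum(categories %in% c(1, 4, 6)) / length(categories)
}
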