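#' Normalise per-cluster DNA and RNA read counts
#'
#' Adds reads-per-million (RPM) and fragments-per-kilobase-per-million
#' (FPKM, using the cluster representative length) for both assays, plus the
#' log2 FPKM expression ratio with a pseudocount so clusters with zero reads
#' in one assay stay finite. Library totals are computed per accession and
#' assay.
#'
#' @param counts data.frame with `cluster_id`, `accession`, `dna_count`,
#'   `rna_count`, `rep_length` (bp of the cluster representative, i.e. its
#'   longest read).
#' @param pseudocount Added to both FPKM values in the log ratio
#'   (default 0.1).
#' @return The input with `dna_rpm`, `rna_rpm`, `dna_fpkm`, `rna_fpkm` and
#'   `log_ratio` columns appended.
#' @export
normalize_expression <- function(counts, pseudocount = 0.1) {
  need <- c("cluster_id", "accession", "dna_count", "rna_count", "rep_length")
  stopifnot(all(need %in% names(counts)))
  if (any(counts$rep_length <= 0)) stop("rep_length must be positive")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  dna_tot <- tapply(counts$dna_count, counts$accession, sum)
  rna_tot <- tapply(counts$rna_count, counts$accession, sum)
  if (any(dna_tot == 0) || any(rna_tot == 0)) {
    bad <- unique(c(names(dna_tot)[dna_tot == 0], names(rna_tot)[rna_tot == 0]))
    stop("zero library total for accession(s): ", paste(bad, collapse = ", "))
  }
  counts$dna_rpm <- as.numeric(counts$dna_count /
                                 dna_tot[counts$accession] * 1e6)
  counts$rna_rpm <- as.numeric(counts$rna_count /
                                 rna_tot[counts$accession] * 1e6)
  kb <- counts$rep_length / 1000
  counts$dna_fpkm <- counts$dna_rpm / kb
  counts$rna_fpkm <- counts$rna_rpm / kb
  counts$log_ratio <- log2((counts$rna_fpkm + pseudocount) /
                             (counts$dna_fpkm + pseudocount))
  counts
}

#' Regress RNA abundance on DNA abundance across clusters
#'
#' Simple linear regression, per accession, of per-cluster RNA content on
#' DNA content (RPM by default, matching how such scatters are usually
#' drawn; FPKM via `axis`), with a two-sided t-test on the slope.
#'
#' @param tab Normalised table from [normalize_expression()].
#' @param accession Accession to analyse; `NULL` uses all rows.
#' @param axis `"rpm"` or `"fpkm"`.
#' @return Object of class `te_expression_fit` with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n_clusters`.
#' @export
dna_rna_regression <- function(tab, accession = NULL,
                               axis = c("rpm", "fpkm")) {
  axis <- match.arg(axis)
  if (!is.null(accession)) tab <- tab[tab$accession == accession, , drop = FALSE]
  if (nrow(tab) < 3) stop("need at least 3 clusters for regression")
  x <- tab[[paste0("dna_", axis)]]
  y <- tab[[paste0("rna_", axis)]]
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(accession = if (is.null(accession)) "all" else accession,
                 axis = axis,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n_clusters = nrow(tab),
                 lm = fit, x = x, y = y),
            class = "te_expression_fit")
}

#' @export
print.te_expression_fit <- function(x, ...) {
  cat(sprintf(
    "RNA ~ DNA (%s, %s): slope %.4g, R^2 %.3f, p %.3g (n = %d clusters)\n",
    x$accession, toupper(x$axis), x$slope, x$r_squared, x$p_value,
    x$n_clusters))
  invisible(x)
}

#' @export
plot.te_expression_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = paste("DNA", toupper(x$axis)),
                 ylab = paste("RNA", toupper(x$axis)), ...)
  graphics::abline(x$intercept, x$slope, col = 2)
  invisible(x)
}

#' Flag low-abundance/high-expression outlier clusters
#'
#' Flags clusters whose log expression ratio exceeds the per-accession
#' median by more than `k` (scaled) median absolute deviations.
#'
#' @param tab Normalised table from [normalize_expression()].
#' @param k MAD multiplier (default 3).
#' @return data.frame `accession`, `cluster_id`, `log_ratio`, `threshold`
#'   of flagged clusters (zero rows when none).
#' @export
flag_expression_outliers <- function(tab, k = 3) {
  stopifnot("log_ratio" %in% names(tab))
  out <- do.call(rbind, lapply(split(tab, tab$accession), function(d) {
    thr <- stats::median(d$log_ratio) + k * stats::mad(d$log_ratio)
    hit <- d$log_ratio > thr & stats::mad(d$log_ratio) > 0
    data.frame(accession = d$accession[hit], cluster_id = d$cluster_id[hit],
               log_ratio = d$log_ratio[hit], threshold = rep(thr, sum(hit)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
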