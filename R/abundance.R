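#' Genome occupancy of a repeat fraction, in Mb
#'
#' Converts the fraction of sampled read bases belonging to a repeat into Mb
#' of the monoploid genome: `cluster_read_bases / total_read_bases *
#' g_monoploid`. Occupancy is computed from read-base fractions scaled by the
#' monoploid genome size, never from raw read-base sums — low-coverage
#' sampling reads only a fraction of the genome, so absolute base counts mean
#' nothing by themselves.
#'
#' @param cluster_read_bases Total read bases in the cluster(s) (bp).
#' @param total_read_bases Total read bases sampled (bp); must be > 0.
#' @param g_monoploid Monoploid genome size in Mb (default 865).
#' @return Mb of monoploid genome occupied.
#' @examples
#' genome_size_mb(27.35, 100) # a 27.35 % fraction of an 865 Mb genome
#' @export
genome_size_mb <- function(cluster_read_bases, total_read_bases,
                           g_monoploid = 865) {
  if (any(total_read_bases <= 0)) stop("total_read_bases must be > 0")
  cluster_read_bases / total_read_bases * g_monoploid
}

#' Percent of the monoploid genome
#'
#' @param size_mb Occupancy in Mb.
#' @param g_monoploid Monoploid genome size in Mb (default 865).
#' @return Percentage of the monoploid genome.
#' @examples
#' percent_of_genome(236.60) # about 27.35
#' @export
percent_of_genome <- function(size_mb, g_monoploid = 865) {
  size_mb / g_monoploid * 100
}

#' Fraction of the (polyploid) genome covered by sampled reads
#'
#' @param n_reads Number of reads sampled.
#' @param read_length_bp Read length in bp.
#' @param ploidy Ploidy level (3 for a triploid).
#' @param g_monoploid Monoploid genome size in Mb.
#' @return Percent of the polyploid genome covered.
#' @examples
#' sampled_genome_fraction(5e6, 125, 3, 865) # about 24
#' @export
sampled_genome_fraction <- function(n_reads, read_length_bp, ploidy,
                                    g_monoploid = 865) {
  n_reads * read_length_bp / (ploidy * g_monoploid * 1e6) * 100
}

#' Aggregate abundance records at an annotation level
#'
#' Sums `size_mb`, `n_clusters` and `n_clusters_young` within each
#' annotation group at the requested level, per accession, recomputes
#' `percent_genome`, and appends a TOTAL row per accession.
#'
#' @param records data.frame with `accession`, lineage columns (`te_class`,
#'   `order`, `superfamily`, `family`), `size_mb`, `n_clusters`,
#'   `n_clusters_young`.
#' @param level One of `"class"`, `"order"`, `"superfamily"`, `"family"`.
#' @param g_monoploid Monoploid genome size in Mb.
#' @return Aggregated data.frame.
#' @export
aggregate_abundance <- function(records,
                                level = c("class", "order", "superfamily",
                                          "family"),
                                g_monoploid = 865) {
  level <- match.arg(level)
  need <- c("accession", lineage_cols, "size_mb", "n_clusters",
            "n_clusters_young")
  stopifnot(all(need %in% names(records)))
  if (nrow(records) == 0) return(records[, need][0, , drop = FALSE])
  keep <- lineage_cols[seq_len(match(level, c("class", "order", "superfamily",
                                              "family")))]
  grp <- records[, c("accession", keep), drop = FALSE]
  agg <- stats::aggregate(
    records[, c("size_mb", "n_clusters", "n_clusters_young")],
    by = grp, FUN = sum)
  tot <- stats::aggregate(
    records[, c("size_mb", "n_clusters", "n_clusters_young")],
    by = records[, "accession", drop = FALSE], FUN = sum)
  for (cl in keep) tot[[cl]] <- "TOTAL"
  out <- rbind(agg, tot[, names(agg)])
  for (cl in setdiff(lineage_cols, keep)) out[[cl]] <- ""
  out$percent_genome <- percent_of_genome(out$size_mb, g_monoploid)
  out <- out[order(out$accession, out[[keep[1]]] == "TOTAL",
                   -out$size_mb), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("accession", lineage_cols, "size_mb", "percent_genome",
          "n_clusters", "n_clusters_young")]
}

#' Likelihood-ratio (G) test of abundance differences
#'
#' Tests independence of read counts in an accession-by-annotation
#' contingency table with the likelihood-ratio chi-square statistic
#' `G = 2 * sum(O * ln(O / E))`, expected counts from the row/column
#' marginals, `df = (rows - 1) * (cols - 1)`. No continuity or Williams
#' correction is applied.
#'
#' @param counts Numeric matrix or table of read counts
#'   (accessions x annotations).
#' @return An object of class `htest` with the G statistic, degrees of
#'   freedom and p-value.
#' @examples
#' abundance_g_test(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
#' @export
abundance_g_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  rs <- rowSums(counts)
  cs <- colSums(counts)
  if (any(rs == 0)) {
    bad <- if (is.null(rownames(counts))) which(rs == 0) else
      rownames(counts)[rs == 0]
    stop("zero marginal for row(s): ", paste(bad, collapse = ", "))
  }
  if (any(cs == 0)) {
    bad <- if (is.null(colnames(counts))) which(cs == 0) else
      colnames(counts)[cs == 0]
    stop("zero marginal for column(s): ", paste(bad, collapse = ", "))
  }
  expected <- outer(rs, cs) / sum(counts)
  terms <- counts * log(counts / expected)
  terms[counts == 0] <- 0
  g <- 2 * sum(terms)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  p <- stats::pchisq(g, df, lower.tail = FALSE)
  structure(list(statistic = c(G = g), parameter = c(df = df), p.value = p,
                 method = "Likelihood-ratio chi-square (G) test of independence",
                 data.name = deparse(substitute(counts)),
                 expected = expected),
            class = "htest")
}
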