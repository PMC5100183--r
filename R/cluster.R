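#' Best overlap alignment between two reads
#'
#' Computes the optimal free end-gap (overlap) alignment of two reads in both
#' orientations by exact dynamic programming (match +1, mismatch -1, gap -2;
#' leading/trailing gaps free; `N` never matches). Identity is counted over
#' the aligned overlap as matches / alignment columns, gap columns counting
#' as mismatches. A hit is returned only if, in at least one orientation, the
#' overlap spans at least `min_overlap_frac` of the shorter read and its
#' identity reaches `min_identity`.
#'
#' @param read_a,read_b DNA sequences (character strings over A/C/G/T/N).
#' @param min_overlap_frac Minimum overlap, as a fraction of the shorter
#'   read's length (default 0.55).
#' @param min_identity Minimum identity over the overlapping region
#'   (default 0.90).
#' @return `NULL` if the pair does not qualify, otherwise a list with
#'   `overlap_length` (alignment columns), `identity`, `matches` and
#'   `orientation` (`"same"` or `"reverse"`).
#' @examples
#' r <- paste(rep("ACGT", 31), collapse = "")
#' pairwise_overlap(r, r)$identity
#' @export
pairwise_overlap <- function(read_a, read_b, min_overlap_frac = 0.55,
                             min_identity = 0.90) {
  if (!is.character(read_a) || !is.character(read_b) ||
      !nzchar(read_a) || !nzchar(read_b)) {
    stop("reads must be non-empty character strings")
  }
  h <- .overlap_hits_cpp(c(read_a, read_b), min_overlap_frac, min_identity,
                         kmer = 0L)
  if (nrow(h) == 0) return(NULL)
  list(overlap_length = h$overlap_length[1],
       identity = h$identity[1],
       matches = h$matches[1],
       orientation = c("same", "reverse")[h$orientation[1] + 1L])
}

#' Lossless k-mer length for the overlap prefilter
#'
#' For an accepted pair there must exist an alignment with at least
#' `ceil(min_identity * C)` match columns among `C >= min_overlap_frac * L`
#' columns. By pigeonhole the longest run of consecutive match columns —
#' an exact shared k-mer on the aligned strands — has length at least
#' `ceil(M / (C - M + 1))`, minimised over admissible `C`. Any k at or below
#' that bound can therefore never discard a qualifying pair.
#'
#' @param min_read_length Length of the shortest read.
#' @param min_overlap_frac,min_identity Thresholds in use.
#' @return Guaranteed k (0 when no useful k >= 5 exists, meaning the
#'   prefilter should be disabled).
#' @keywords internal
lossless_kmer <- function(min_read_length, min_overlap_frac, min_identity) {
  cmin <- max(1L, ceiling(min_overlap_frac * min_read_length))
  cmax <- 2L * min_read_length  # columns cannot exceed both lengths summed
  cc <- cmin:cmax
  m <- ceiling(min_identity * cc)
  feasible <- m <= min_read_length  # matches are bounded by the shorter read
  if (!any(feasible)) return(0L)
  k <- min(ceiling(m[feasible] / (cc[feasible] - m[feasible] + 1)))
  if (k < 5 || k > 16) 0L else as.integer(k)
}

#' All accepted pairwise overlap hits among a set of reads
#'
#' @param reads Named character vector of reads.
#' @inheritParams pairwise_overlap
#' @param kmer_prefilter Skip pairs sharing no exact k-mer, with k computed
#'   by [lossless_kmer()] so that no qualifying pair can be lost; set to
#'   `FALSE` to force full all-versus-all dynamic programming.
#' @return data.frame with `read_a`, `read_b`, `identity`, `overlap_length`,
#'   `matches`, `orientation`.
#' @export
overlap_hits <- function(reads, min_overlap_frac = 0.55, min_identity = 0.90,
                         kmer_prefilter = TRUE) {
  stopifnot(is.character(reads))
  if (length(reads) < 2) {
    return(data.frame(read_a = character(0), read_b = character(0),
                      identity = numeric(0), overlap_length = integer(0),
                      matches = integer(0), orientation = character(0),
                      stringsAsFactors = FALSE))
  }
  if (is.null(names(reads))) names(reads) <- sprintf("read%06d", seq_along(reads))
  k <- if (isTRUE(kmer_prefilter)) {
    lossless_kmer(min(nchar(reads)), min_overlap_frac, min_identity)
  } else 0L
  h <- .overlap_hits_cpp(unname(reads), min_overlap_frac, min_identity,
                         kmer = k)
  data.frame(read_a = names(reads)[h$i], read_b = names(reads)[h$j],
             identity = h$identity, overlap_length = h$overlap_length,
             matches = h$matches,
             orientation = c("same", "reverse")[h$orientation + 1L],
             stringsAsFactors = FALSE)
}

#' Cluster reads on the similarity graph
#'
#' Builds the read similarity graph whose edges are accepted overlap hits
#' (see [pairwise_overlap()]) and reports its connected components with at
#' least two reads as repeat clusters; singletons are reported as
#' unclustered. Cluster IDs are assigned by descending read count, ties
#' broken by the lexicographically smallest member read ID.
#'
#' @inheritParams overlap_hits
#' @return Object of class `read_clusters`: list with `clusters`
#'   (`cluster_id`, `n_reads`, `total_read_bases`, `read_fraction`),
#'   `membership` (`read_id`, `cluster_id`), `unclustered` (read IDs),
#'   `n_input_reads` and the thresholds used.
#' @export
build_clusters <- function(reads, min_overlap_frac = 0.55,
                           min_identity = 0.90, kmer_prefilter = TRUE) {
  stopifnot(is.character(reads))
  if (is.null(names(reads))) names(reads) <- sprintf("read%06d", seq_along(reads))
  if (anyDuplicated(names(reads))) stop("duplicated read IDs")
  empty <- data.frame(cluster_id = character(0), n_reads = integer(0),
                      total_read_bases = integer(0), read_fraction = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(reads) == 0) {
    return(structure(list(clusters = empty,
                          membership = data.frame(read_id = character(0),
                                                  cluster_id = character(0),
                                                  stringsAsFactors = FALSE),
                          unclustered = character(0), n_input_reads = 0L,
                          min_overlap_frac = min_overlap_frac,
                          min_identity = min_identity),
                     class = "read_clusters"))
  }
  hits <- overlap_hits(reads, min_overlap_frac, min_identity, kmer_prefilter)
  g <- igraph::graph_from_data_frame(
    hits[, c("read_a", "read_b")], directed = FALSE,
    vertices = data.frame(name = names(reads)))
  comp <- igraph::components(g)
  member_of <- comp$membership[names(reads)]
  sizes <- table(member_of)
  keep <- as.integer(names(sizes)[sizes >= 2])

  clusters <- empty
  membership <- data.frame(read_id = character(0), cluster_id = character(0),
                           stringsAsFactors = FALSE)
  if (length(keep)) {
    info <- lapply(keep, function(k) {
      rid <- sort(names(reads)[member_of == k])
      list(read_ids = rid, n = length(rid),
           bases = sum(nchar(reads[rid])), first = rid[1])
    })
    ord <- order(-vapply(info, `[[`, numeric(1), "n"),
                 vapply(info, `[[`, character(1), "first"))
    info <- info[ord]
    cid <- sprintf("CL%04d", seq_along(info))
    clusters <- data.frame(
      cluster_id = cid,
      n_reads = vapply(info, `[[`, numeric(1), "n"),
      total_read_bases = vapply(info, `[[`, numeric(1), "bases"),
      stringsAsFactors = FALSE)
    clusters$read_fraction <- clusters$n_reads / length(reads)
    membership <- data.frame(
      read_id = unlist(lapply(info, `[[`, "read_ids")),
      cluster_id = rep(cid, clusters$n_reads),
      stringsAsFactors = FALSE)
  }
  structure(list(clusters = clusters, membership = membership,
                 unclustered = setdiff(names(reads), membership$read_id),
                 n_input_reads = length(reads),
                 min_overlap_frac = min_overlap_frac,
                 min_identity = min_identity),
            class = "read_clusters")
}

#' @export
print.read_clusters <- function(x, ...) {
  cat("Read clustering:", x$n_input_reads, "reads ->",
      nrow(x$clusters), "clusters (>= 2 reads),",
      length(x$unclustered), "unclustered\n")
  cat("Criteria: overlap >=", x$min_overlap_frac, "of shorter read,",
      "identity >=", x$min_identity, "\n")
  if (nrow(x$clusters)) print(utils::head(x$clusters, 10))
  invisible(x)
}

#' Attach annotation lineages to clusters
#'
#' @param clusters `data.frame` of clusters (from [build_clusters()]'s
#'   `clusters` element) or a `read_clusters` object.
#' @param annotation data.frame with `cluster_id` and the lineage columns
#'   `te_class`, `order`, `superfamily`, `family` (e.g. read from a TSV of
#'   homology-search results). Clusters without a row stay
#'   `"unclassified"`.
#' @return The cluster table with lineage columns attached.
#' @export
annotate_clusters <- function(clusters, annotation) {
  if (inherits(clusters, "read_clusters")) clusters <- clusters$clusters
  stopifnot(all(c("cluster_id", lineage_cols) %in% names(annotation)))
  out <- merge(clusters, annotation[, c("cluster_id", lineage_cols)],
               by = "cluster_id", all.x = TRUE, sort = FALSE)
  out$te_class[is.na(out$te_class)] <- "unclassified"
  for (cl in c("order", "superfamily", "family")) {
    out[[cl]][is.na(out[[cl]])] <- ""
  }
  out[order(out$cluster_id), , drop = FALSE]
}

#' Majority-truth annotation for simulated clusters
#'
#' In simulations the homology search is replaced by labelling each cluster
#' with the annotation of the family contributing the majority of its reads.
#'
#' @param x A `read_clusters` object.
#' @param read_truth,family_truth Truth tables from [simulate_genome()].
#' @return Annotation data.frame suitable for [annotate_clusters()], plus a
#'   `majority_family` and `purity` column.
#' @export
truth_annotation <- function(x, read_truth, family_truth) {
  stopifnot(inherits(x, "read_clusters"))
  mb <- merge(x$membership, read_truth[, c("read_id", "family_id")],
              by = "read_id")
  out <- do.call(rbind, lapply(split(mb, mb$cluster_id), function(d) {
    tt <- sort(table(d$family_id), decreasing = TRUE)
    data.frame(cluster_id = d$cluster_id[1], majority_family = names(tt)[1],
               purity = as.numeric(tt[1]) / nrow(d), stringsAsFactors = FALSE)
  }))
  ann <- merge(out, family_truth[, c("family_id", lineage_cols)],
               by.x = "majority_family", by.y = "family_id", all.x = TRUE)
  ann$te_class[is.na(ann$te_class)] <- "unclassified"
  for (cl in c("order", "superfamily", "family")) {
    ann[[cl]][is.na(ann[[cl]])] <- ""
  }
  rownames(ann) <- NULL
  ann[order(ann$cluster_id), c("cluster_id", lineage_cols,
                               "majority_family", "purity")]
}

#' Keep high-abundance, non-organellar clusters
#'
#' Chloroplast-annotated clusters are removed first; the read-fraction
#' threshold is then applied relative to the remaining (nuclear) input
#' reads, and the returned `read_fraction` column is rescaled accordingly.
#' The threshold boundary is inclusive.
#'
#' @param clusters Annotated cluster data.frame (see [annotate_clusters()]).
#' @param min_fraction Minimum fraction of input nuclear reads
#'   (default 0.002, i.e. 0.2 %).
#' @param n_input_reads Total input reads used for the original
#'   `read_fraction`; defaults to reconstructing it from the table.
#' @return Filtered cluster data.frame with nuclear `read_fraction`.
#' @export
filter_clusters <- function(clusters, min_fraction = 0.002,
                            n_input_reads = NULL) {
  stopifnot("te_class" %in% names(clusters))
  if (is.null(n_input_reads)) {
    if (nrow(clusters) == 0) return(clusters)
    n_input_reads <- round(clusters$n_reads[1] / clusters$read_fraction[1])
  }
  chl <- clusters$te_class == "chloroplast"
  nuclear_total <- n_input_reads - sum(clusters$n_reads[chl])
  out <- clusters[!chl, , drop = FALSE]
  if (nuclear_total <= 0) return(out[0, , drop = FALSE])
  out$read_fraction <- out$n_reads / nuclear_total
  out[out$read_fraction >= min_fraction, , drop = FALSE]
}

#' Merge clusters sharing a full annotation lineage
#'
#' Clusters with identical (class, order, superfamily, family) lineages are
#' merged; read counts, bases and fractions are summed. The result is
#' independent of input order: groups are sorted by lineage key and merged
#' cluster IDs are reassigned by descending read count (ties by lineage key).
#'
#' @param clusters Annotated cluster data.frame.
#' @return Merged cluster data.frame with an `n_merged` column.
#' @export
merge_by_annotation <- function(clusters) {
  stopifnot(all(lineage_cols %in% names(clusters)))
  if (nrow(clusters) == 0) return(clusters)
  key <- lineage_key(clusters)
  agg <- lapply(split(seq_len(nrow(clusters)), key), function(idx) {
    d <- clusters[idx, , drop = FALSE]
    data.frame(te_class = d$te_class[1], order = d$order[1],
               superfamily = d$superfamily[1], family = d$family[1],
               n_reads = sum(d$n_reads),
               total_read_bases = sum(d$total_read_bases),
               read_fraction = sum(d$read_fraction),
               n_merged = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg[sort(names(agg))])
  out <- out[order(-out$n_reads, lineage_key(out)), , drop = FALSE]
  out <- cbind(cluster_id = sprintf("MCL%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
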