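#' Accession names of a methylation count table
#'
#' The wide table format carries, per accession, a `<acc>_total` and a
#' `<acc>_methylated` column next to `locus_id`, `position`, `context`.
#'
#' @param tab Methylation count table.
#' @return Character vector of accession labels.
#' @export
methylation_accessions <- function(tab) {
  tot <- grep("_total$", names(tab), value = TRUE)
  acc <- sub("_total$", "", tot)
  missing <- setdiff(paste0(acc, "_methylated"), names(tab))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  acc
}

#' Filter bisulfite positions by context and coverage
#'
#' Keeps positions whose context is in `contexts` and whose coverage reaches
#' `min_coverage` (inclusive) in every required accession — the
#' "highly confident positions called in all accessions" subset.
#'
#' @param tab Wide methylation count table.
#' @param min_coverage Minimum reads per accession (default 50).
#' @param contexts Cytosine contexts retained (default `"CG"`).
#' @param required_accessions Accessions that must all reach the coverage;
#'   defaults to every accession in the table.
#' @return Filtered table, with attributes `n_positions` and `n_loci`.
#' @export
filter_positions <- function(tab, min_coverage = 50, contexts = "CG",
                             required_accessions = NULL) {
  acc <- methylation_accessions(tab)
  if (is.null(required_accessions)) required_accessions <- acc
  stopifnot(all(required_accessions %in% acc))
  keep <- tab$context %in% contexts
  for (a in required_accessions) {
    keep <- keep & tab[[paste0(a, "_total")]] >= min_coverage
  }
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_positions") <- nrow(out)
  attr(out, "n_loci") <- length(unique(out$locus_id))
  out
}

#' Qualitative methylation level of a proportion
#'
#' Collapses quantitative CG methylation proportions into three levels:
#' low (< 0.25), intermediate (0.25-0.75 inclusive at both bounds), high
#' (> 0.75). CG methylation is typically strongly bimodal, which is what
#' makes this collapse informative.
#'
#' @param proportion Numeric vector in \[0, 1\].
#' @return Character vector of `"low"`, `"intermediate"`, `"high"`.
#' @examples
#' call_levels(c(0.05, 0.25, 0.75, 0.76))
#' @export
call_levels <- function(proportion) {
  if (any(proportion < 0 | proportion > 1, na.rm = TRUE)) {
    stop("proportions must lie in [0, 1]")
  }
  ifelse(proportion < 0.25, "low",
         ifelse(proportion > 0.75, "high", "intermediate"))
}

#' Differential-methylation call from per-accession levels
#'
#' `"true"` when both low and high occur among accessions (the full range),
#' `"partial"` when exactly two adjacent levels occur (low+intermediate or
#' intermediate+high), `"invariant"` when a single level is shared.
#'
#' @param levels Character vector of per-accession levels.
#' @return One of `"invariant"`, `"partial"`, `"true"`.
#' @examples
#' call_dmp(c("low", "low", "high", "low", "low"))
#' @export
call_dmp <- function(levels) {
  u <- unique(levels)
  if (all(c("low", "high") %in% u)) return("true")
  if (length(u) == 2) return("partial")
  "invariant"
}

#' Per-position methylation proportions, levels and DMP calls
#'
#' @param tab Filtered methylation table (see [filter_positions()]).
#' @return data.frame with per-accession proportion and level columns plus a
#'   `call` column.
#' @export
dmp_table <- function(tab) {
  acc <- methylation_accessions(tab)
  out <- tab[, c("locus_id", "position", "context"), drop = FALSE]
  lv <- matrix("", nrow(tab), length(acc))
  for (k in seq_along(acc)) {
    p <- tab[[paste0(acc[k], "_methylated")]] / tab[[paste0(acc[k], "_total")]]
    out[[paste0(acc[k], "_prop")]] <- p
    lv[, k] <- call_levels(p)
    out[[paste0(acc[k], "_level")]] <- lv[, k]
  }
  out$call <- apply(lv, 1, call_dmp)
  rownames(out) <- NULL
  out
}

#' Per-locus methylation averages, levels and DMR calls
#'
#' Per accession, positions of a locus are averaged (unweighted by default,
#' coverage-weighted with `weighted = TRUE`) and the same qualitative
#' thresholds as for positions are applied to the locus mean.
#'
#' @param tab Filtered methylation table.
#' @param weighted Use coverage-weighted means (default `FALSE`).
#' @return data.frame with one row per locus: `n_positions`, per-accession
#'   mean proportion and level, and `call`.
#' @export
dmr_table <- function(tab, weighted = FALSE) {
  acc <- methylation_accessions(tab)
  if (nrow(tab) == 0) stop("no positions: locus needs >= 1 filtered position")
  sp <- split(seq_len(nrow(tab)), tab$locus_id)
  out <- do.call(rbind, Map(function(locus, idx) {
    row <- data.frame(locus_id = locus, n_positions = length(idx),
                      stringsAsFactors = FALSE)
    lv <- character(length(acc))
    for (k in seq_along(acc)) {
      m <- tab[[paste0(acc[k], "_methylated")]][idx]
      n <- tab[[paste0(acc[k], "_total")]][idx]
      mp <- if (weighted) sum(m) / sum(n) else mean(m / n)
      row[[paste0(acc[k], "_prop")]] <- mp
      lv[k] <- call_levels(mp)
      row[[paste0(acc[k], "_level")]] <- lv[k]
    }
    row$call <- call_dmp(lv)
    row
  }, names(sp), sp))
  rownames(out) <- NULL
  out
}

#' Summarise DMR calls and their annotation
#'
#' @param dmr data.frame from [dmr_table()].
#' @param annotations data.frame `locus_id`, `kind` (TE / transcript /
#'   unknown), `detail`.
#' @return Object of class `dm_summary`: counts of invariant/partial/true
#'   loci, the variable fraction (partial + true over filtered loci, in %),
#'   and the annotation breakdown of variable loci with percentages.
#' @export
summarize_methylation <- function(dmr, annotations = NULL) {
  n <- nrow(dmr)
  n_true <- sum(dmr$call == "true")
  n_partial <- sum(dmr$call == "partial")
  n_var <- n_true + n_partial
  breakdown <- NULL
  if (!is.null(annotations) && n_var > 0) {
    v <- merge(dmr[dmr$call != "invariant", "locus_id", drop = FALSE],
               annotations, by = "locus_id", all.x = TRUE)
    v$kind[is.na(v$kind)] <- "unknown"
    cnt <- table(factor(v$kind, levels = c("TE", "transcript", "unknown")))
    breakdown <- data.frame(kind = names(cnt), n = as.integer(cnt),
                            percent = as.numeric(cnt) / n_var * 100,
                            stringsAsFactors = FALSE)
  }
  structure(list(n_filtered_loci = n, n_invariant = n - n_var,
                 n_partial = n_partial, n_true = n_true,
                 n_variable = n_var,
                 variable_fraction_pct = if (n > 0) n_var / n * 100 else 0,
                 breakdown = breakdown),
            class = "dm_summary")
}

#' @export
print.dm_summary <- function(x, ...) {
  cat("Methylation divergence over", x$n_filtered_loci, "filtered loci:\n")
  cat(sprintf("  invariant %d | partial %d | true %d  (variable: %.1f %%)\n",
              x$n_invariant, x$n_partial, x$n_true,
              x$variable_fraction_pct))
  if (!is.null(x$breakdown)) {
    for (i in seq_len(nrow(x$breakdown))) {
      cat(sprintf("  variable loci annotated %s: %d (%.1f %%)\n",
                  x$breakdown$kind[i], x$breakdown$n[i],
                  x$breakdown$percent[i]))
    }
  }
  invisible(x)
}

#' Join differentially methylated TE loci with expression and abundance
#'
#' For every variable (partial or true) DMR annotated as a TE, attaches the
#' per-accession mean CG methylation proportion and, where available, the
#' DNA and RNA content of the matching cluster from the expression table.
#' Missing joins are kept as NA and written out as `#N/A`.
#'
#' @param dmr data.frame from [dmr_table()].
#' @param annotations Locus annotation map (`locus_id`, `kind`, `detail`;
#'   `detail` holds the TE family matching `cluster_id` in `expression`).
#' @param expression Normalised expression table ([normalize_expression()]),
#'   or a raw count table with `cluster_id`, `accession`, `dna_count`,
#'   `rna_count`.
#' @return data.frame, one row per variable TE locus, with
#'   `<acc>_cgm`, `<acc>_dna`, `<acc>_rna` columns per accession.
#' @export
join_te_expression <- function(dmr, annotations, expression) {
  acc <- sub("_prop$", "", grep("_prop$", names(dmr), value = TRUE))
  v <- dmr[dmr$call != "invariant", , drop = FALSE]
  v <- merge(v, annotations, by = "locus_id")
  v <- v[v$kind == "TE", , drop = FALSE]
  dna_col <- if ("dna_rpm" %in% names(expression)) "dna_rpm" else "dna_count"
  rna_col <- if ("rna_rpm" %in% names(expression)) "rna_rpm" else "rna_count"
  out <- data.frame(locus_id = v$locus_id, te_family = v$detail,
                    call = v$call, stringsAsFactors = FALSE)
  if (nrow(out) == 0) {
    for (a in acc) {
      out[[paste0(a, "_cgm")]] <- numeric(0)
      out[[paste0(a, "_dna")]] <- numeric(0)
      out[[paste0(a, "_rna")]] <- numeric(0)
    }
    return(out)
  }
  for (a in acc) {
    out[[paste0(a, "_cgm")]] <- round(v[[paste0(a, "_prop")]], 2)
    idx <- match(paste(v$detail, a), paste(expression$cluster_id,
                                           expression$accession))
    out[[paste0(a, "_dna")]] <- expression[[dna_col]][idx]
    out[[paste0(a, "_rna")]] <- expression[[rna_col]][idx]
  }
  rownames(out) <- NULL
  out
}
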