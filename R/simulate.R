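#' Specify a synthetic repeat family
#'
#' A family is defined by a consensus sequence length, a per-accession copy
#' number, a per-site substitution divergence of its copies from the family
#' consensus (the proxy for family age), and an expression rate relating RNA
#' to DNA read counts. With `age_mixture = TRUE` the family's copies span a
#' range of ages: per-copy divergence is drawn uniformly between
#' `min(0.01, divergence/3)` and `divergence`, emulating a proliferation
#' history that continued at a low level after an old main burst. With
#' `age_mixture = FALSE` every copy diverges at the same rate.
#'
#' @param family_id Unique family label.
#' @param copies_per_accession Named non-negative integer vector, one entry
#'   per accession. Abundant repeat families in a multi-hundred-Mb genome
#'   have hundreds to thousands of copies.
#' @param consensus_length Consensus length in bp; must be at least the read
#'   length used downstream.
#' @param divergence Per-site substitution probability in \[0, 0.25\] applied
#'   independently to each copy (the maximum age under `age_mixture`).
#' @param expression_rate Expected RNA reads per DNA read (non-negative).
#' @param annotation Lineage from [annotation_lineage()].
#' @param age_mixture Logical; see Details above.
#' @return Object of class `family_spec`.
#' @export
family_spec <- function(family_id, copies_per_accession,
                        consensus_length = 1000, divergence = 0.01,
                        expression_rate = 1,
                        annotation = annotation_lineage(),
                        age_mixture = FALSE) {
  stopifnot(is.character(family_id), length(family_id) == 1L)
  if (is.null(names(copies_per_accession)) ||
      any(!nzchar(names(copies_per_accession)))) {
    stop("copies_per_accession must be a named vector (accession -> copies)")
  }
  if (any(copies_per_accession < 0) ||
      any(copies_per_accession != round(copies_per_accession))) {
    stop("copy numbers must be non-negative integers")
  }
  if (divergence < 0 || divergence > 0.25) {
    stop("divergence must lie in [0, 0.25]")
  }
  if (expression_rate < 0) stop("expression_rate must be non-negative")
  if (consensus_length < 1) stop("consensus_length must be positive")
  structure(list(family_id = family_id,
                 copies_per_accession = copies_per_accession,
                 consensus_length = as.integer(consensus_length),
                 divergence = divergence,
                 expression_rate = expression_rate,
                 annotation = annotation,
                 age_mixture = isTRUE(age_mixture)),
            class = "family_spec")
}

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a scaled-down version of a five-accession,
#' 125-bp-read, low-coverage genome sampling design, plus a
#' reduced-representation bisulfite layout with strongly bimodal CG
#' methylation.
#'
#' @param accessions Accession labels.
#' @param read_length Read length in bp.
#' @param reads_per_accession Genomic reads sampled per accession
#'   (scaled-down stand-in for millions of reads in a real design).
#' @param background_genome_length bp of unique, non-repetitive genome per
#'   accession; it acts as the sampling weight of the non-repetitive
#'   fraction, whose reads are unique and stay unclustered.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param n_loci Number of bisulfite (RRBS-style) loci.
#' @param positions_per_locus CG positions simulated per locus.
#' @param coverage_mean Mean per-position read coverage (per-locus depth
#'   varies around it; zero coverages are truncated to 1 so proportions stay
#'   defined).
#' @param prop_true_dmr Fraction of loci planted with a low-to-high
#'   methylation shift between accessions.
#' @param prop_partial_dmr Fraction of loci planted with a shift involving
#'   the intermediate level.
#' @param methylation_profile Optional per-family named list of per-accession
#'   mean CG methylation proportions; when `NULL` locus levels are drawn from
#'   a bimodal law (near 0 or near 1).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(accessions = paste0("acc", 1:5),
                       read_length = 125,
                       reads_per_accession = 1000,
                       background_genome_length = 200000,
                       seed = 1,
                       n_loci = 300,
                       positions_per_locus = 8,
                       coverage_mean = 100,
                       prop_true_dmr = 0.05,
                       prop_partial_dmr = 0.10,
                       methylation_profile = NULL) {
  stopifnot(length(accessions) >= 1, !anyDuplicated(accessions))
  if (reads_per_accession <= 0) stop("reads_per_accession must be > 0")
  if (read_length < 20) stop("read_length unreasonably short")
  props <- c(prop_true_dmr, prop_partial_dmr)
  if (any(props < 0) || sum(props) > 1) {
    stop("DMR proportions must be non-negative and sum to at most 1")
  }
  structure(list(accessions = as.character(accessions),
                 read_length = as.integer(read_length),
                 reads_per_accession = as.integer(reads_per_accession),
                 background_genome_length = as.integer(background_genome_length),
                 seed = as.integer(seed),
                 n_loci = as.integer(n_loci),
                 positions_per_locus = as.integer(positions_per_locus),
                 coverage_mean = coverage_mean,
                 prop_true_dmr = prop_true_dmr,
                 prop_partial_dmr = prop_partial_dmr,
                 methylation_profile = methylation_profile),
            class = "sim_config")
}

#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' @keywords internal
revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                     collapse = ""), character(1),
                USE.NAMES = FALSE))
}

#' Mutate copies of a consensus sequence
#'
#' Each copy receives i.i.d. substitutions at its divergence rate; the
#' substituted base is drawn uniformly among the three alternatives.
#'
#' @param consensus Consensus DNA string.
#' @param divergences Per-copy substitution rates.
#' @return Character vector of copy sequences, one per element of
#'   `divergences`.
#' @export
mutate_copies <- function(consensus, divergences) {
  base <- strsplit(consensus, "", fixed = TRUE)[[1]]
  alphabet <- c("A", "C", "G", "T")
  vapply(divergences, function(d) {
    s <- base
    hit <- which(runif(length(s)) < d)
    if (length(hit)) {
      cur <- match(s[hit], alphabet)
      shift <- sample.int(3, length(hit), replace = TRUE)
      s[hit] <- alphabet[((cur - 1 + shift) %% 4) + 1]
    }
    paste(s, collapse = "")
  }, character(1))
}

#' @keywords internal
copy_divergences <- function(spec, n) {
  d <- spec$divergence
  if (!spec$age_mixture || d == 0) return(rep(d, n))
  runif(n, min(0.01, d / 3), d)
}

#' Simulate genomic reads for a set of repeat families
#'
#' Builds one random consensus per family, derives copies by substitution-only
#' mutation (see [mutate_copies()]), and samples reads of `read_length` bp at
#' uniform positions and strands from the copies. Reads are allocated to
#' families (and to the unique, non-repetitive background fraction)
#' proportionally to total sequence length, so family read fractions reflect
#' genome occupancy. Copy sequences are materialised only
#' for copies that reads actually sample (copy identity is still drawn
#' uniformly over the full copy number, so identical-copy read pairs occur at
#' their realistic rate of about 1/copy-number).
#'
#' @param spec_list List of [family_spec()] objects.
#' @param config A [sim_config()].
#' @return List with elements `reads` (named character vector),
#'   `read_truth` (`read_id`, `accession`, `family_id`, `copy`, `start`,
#'   `strand`), `family_truth` (per-family divergence, age class and
#'   annotation; the age class is `"young"` for divergence <= 0.02, else
#'   `"old"`), `copies` (sequences of the sampled copies) and `consensus`.
#' @export
simulate_genome <- function(spec_list, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(spec_list, "family_spec")) spec_list <- list(spec_list)
  ids <- vapply(spec_list, `[[`, character(1), "family_id")
  if (anyDuplicated(ids)) stop("duplicated family_id")
  for (sp in spec_list) {
    if (sp$consensus_length < config$read_length) {
      stop("family '", sp$family_id, "': consensus_length (",
           sp$consensus_length, ") shorter than read_length (",
           config$read_length, ")")
    }
    if (!setequal(names(sp$copies_per_accession), config$accessions)) {
      stop("family '", sp$family_id,
           "': copies_per_accession keys must equal configured accessions")
    }
  }
  set.seed(config$seed)
  consensus <- stats::setNames(
    vapply(spec_list, function(sp) random_dna(sp$consensus_length),
           character(1)), ids)

  rl <- config$read_length
  reads <- character(0)
  truth <- vector("list", length(config$accessions))
  copies_out <- list()

  for (acc in config$accessions) {
    ncop <- vapply(spec_list, function(sp) sp$copies_per_accession[[acc]],
                   numeric(1))
    w <- ncop * vapply(spec_list, `[[`, numeric(1), "consensus_length")
    w <- c(w, config$background_genome_length)
    n_f <- as.vector(stats::rmultinom(1, config$reads_per_accession,
                                      w / sum(w)))
    acc_reads <- character(0)
    acc_truth <- list()
    serial <- 0L
    for (f in seq_along(spec_list)) {
      if (n_f[f] == 0 || ncop[f] == 0) next
      sp <- spec_list[[f]]
      cp <- sample.int(ncop[f], n_f[f], replace = TRUE)
      ucp <- sort(unique(cp))
      dv <- copy_divergences(sp, ncop[f])
      seqs <- mutate_copies(consensus[[sp$family_id]], dv[ucp])
      names(seqs) <- as.character(ucp)
      copies_out[[length(copies_out) + 1L]] <- data.frame(
        family_id = sp$family_id, accession = acc, copy = ucp,
        divergence = dv[ucp], seq = unname(seqs), stringsAsFactors = FALSE)
      start <- sample.int(sp$consensus_length - rl + 1L, n_f[f],
                          replace = TRUE)
      strand <- ifelse(runif(n_f[f]) < 0.5, "+", "-")
      frag <- substring(seqs[as.character(cp)], start, start + rl - 1L)
      frag[strand == "-"] <- revcomp_chr(frag[strand == "-"])
      rid <- sprintf("%s_r%06d", acc, serial + seq_len(n_f[f]))
      serial <- serial + n_f[f]
      acc_reads <- c(acc_reads, stats::setNames(frag, rid))
      acc_truth[[length(acc_truth) + 1L]] <- data.frame(
        read_id = rid, accession = acc, family_id = sp$family_id,
        copy = cp, start = start, strand = strand, stringsAsFactors = FALSE)
    }
    nb <- n_f[length(n_f)]
    if (nb > 0) {
      # unique non-repetitive fraction: at the (well below 1x) coverages
      # this design emulates, background reads never overlap each other,
      # so they are drawn as independent random sequences
      frag <- vapply(seq_len(nb), function(k) random_dna(rl), character(1))
      rid <- sprintf("%s_r%06d", acc, serial + seq_len(nb))
      acc_reads <- c(acc_reads, stats::setNames(frag, rid))
      acc_truth[[length(acc_truth) + 1L]] <- data.frame(
        read_id = rid, accession = acc, family_id = "background",
        copy = NA_integer_, start = NA_integer_, strand = "+",
        stringsAsFactors = FALSE)
    }
    reads <- c(reads, acc_reads)
    truth[[match(acc, config$accessions)]] <- do.call(rbind, acc_truth)
  }

  family_truth <- data.frame(
    family_id = ids,
    divergence = vapply(spec_list, `[[`, numeric(1), "divergence"),
    age_mixture = vapply(spec_list, `[[`, logical(1), "age_mixture"),
    expression_rate = vapply(spec_list, `[[`, numeric(1), "expression_rate"),
    stringsAsFactors = FALSE)
  family_truth$age_class <- ifelse(family_truth$divergence <= 0.02,
                                   "young", "old")
  ann <- do.call(rbind, lapply(spec_list, `[[`, "annotation"))
  family_truth <- cbind(family_truth, ann)

  list(reads = reads,
       read_truth = do.call(rbind, truth),
       family_truth = family_truth,
       copies = if (length(copies_out)) do.call(rbind, copies_out) else NULL,
       consensus = consensus,
       config = config)
}

#' Simulate per-cluster DNA and RNA read counts
#'
#' DNA counts are the per-family genomic read counts of a simulated genome
#' (clusters are taken as the true families); RNA counts are Poisson with
#' mean `expression_rate * dna_count`. Families given a high expression rate
#' at a low copy number act as low-abundance/high-expression outliers.
#'
#' @param spec_list List of [family_spec()] objects.
#' @param genome Result of [simulate_genome()] for the same specs; its read
#'   truth supplies the DNA counts.
#' @param config A [sim_config()].
#' @return data.frame with `cluster_id`, `accession`, `dna_count`,
#'   `rna_count`, `rep_length`.
#' @export
simulate_expression <- function(spec_list, genome, config = genome$config) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(spec_list, "family_spec")) spec_list <- list(spec_list)
  set.seed(config$seed + 1L)
  rt <- genome$read_truth
  rt <- rt[rt$family_id != "background", , drop = FALSE]
  rate <- stats::setNames(
    vapply(spec_list, `[[`, numeric(1), "expression_rate"),
    vapply(spec_list, `[[`, character(1), "family_id"))
  out <- expand.grid(cluster_id = names(rate), accession = config$accessions,
                     stringsAsFactors = FALSE)
  cnt <- table(factor(rt$family_id, levels = names(rate)),
               factor(rt$accession, levels = config$accessions))
  out$dna_count <- as.integer(cnt[cbind(out$cluster_id, out$accession)])
  out$rna_count <- stats::rpois(nrow(out), rate[out$cluster_id] * out$dna_count)
  out$rep_length <- config$read_length
  out
}

#' Simulate a per-position bisulfite count table
#'
#' Generates RRBS-style loci with strongly bimodal CG methylation: each locus
#' has, per accession, a methylation level near 0 or near 1 (or near 0.5 for
#' planted intermediate shifts). A configurable fraction of loci carries
#' among-accession level shifts: `prop_true_dmr` loci switch between low and
#' high, `prop_partial_dmr` loci between an extreme and the intermediate
#' level. Per position, coverage is Poisson around a per-locus depth
#' (zero truncated to 1) and the methylated count is Binomial(coverage, p).
#'
#' @param config A [sim_config()].
#' @param spec_list Optional list of [family_spec()] objects used to label
#'   TE loci with family names.
#' @return List with `table` (wide per-position counts:
#'   `locus_id position context <acc>_total <acc>_methylated ...`),
#'   `annotations` (`locus_id`, `kind`, `detail`) and `truth`
#'   (`locus_id`, `class` in invariant/partial/true).
#' @export
simulate_methylation <- function(config = sim_config(), spec_list = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  acc <- config$accessions
  nl <- config$n_loci
  npos <- config$positions_per_locus

  kind <- sample(c("TE", "transcript", "unknown"), nl, replace = TRUE,
                 prob = c(0.26, 0.41, 0.33))
  fams <- if (!is.null(spec_list)) {
    vapply(spec_list, `[[`, character(1), "family_id")
  } else paste0("TEfam", 1:6)
  detail <- ifelse(kind == "TE",
                   sample(fams, nl, replace = TRUE),
                   ifelse(kind == "transcript",
                          sprintf("tr%05d", sample.int(99999, nl)), ""))
  locus_id <- sprintf("locus%05d", seq_len(nl))

  draw_low <- function(n) runif(n, 0.01, 0.08)
  draw_high <- function(n) runif(n, 0.90, 0.99)
  draw_mid <- function(n) runif(n, 0.38, 0.62)

  # base level per locus: bimodal, TEs lean methylated
  p_high <- ifelse(kind == "TE", 0.75, ifelse(kind == "transcript", 0.35, 0.5))
  base_high <- runif(nl) < p_high
  p <- matrix(0, nl, length(acc), dimnames = list(locus_id, acc))
  p[base_high, ] <- draw_high(sum(base_high) * length(acc))
  p[!base_high, ] <- draw_low(sum(!base_high) * length(acc))

  n_true <- round(config$prop_true_dmr * nl)
  n_part <- round(config$prop_partial_dmr * nl)
  shifted <- sample.int(nl, n_true + n_part)
  true_loci <- shifted[seq_len(n_true)]
  part_loci <- setdiff(shifted, true_loci)
  n_shift <- function() min(length(acc), sample(1:2, 1))
  for (l in true_loci) {
    k <- sample(seq_along(acc), n_shift())
    p[l, k] <- if (base_high[l]) draw_low(length(k)) else draw_high(length(k))
  }
  for (l in part_loci) {
    k <- sample(seq_along(acc), n_shift())
    p[l, k] <- draw_mid(length(k))
  }
  cls <- rep("invariant", nl)
  cls[true_loci] <- "true"
  cls[part_loci] <- "partial"

  if (!is.null(config$methylation_profile)) {
    prof <- config$methylation_profile
    te_rows <- which(kind == "TE" & detail %in% names(prof))
    for (l in te_rows) {
      pr <- prof[[detail[l]]]
      p[l, names(pr)] <- unlist(pr)
      cls[l] <- "profile"
    }
  }

  # per-locus depth heterogeneity so the coverage filter has work to do
  depth <- config$coverage_mean * stats::rgamma(nl, shape = 4, rate = 4)

  rows <- nl * npos
  li <- rep(seq_len(nl), each = npos)
  tab <- data.frame(locus_id = locus_id[li],
                    position = rep(seq_len(npos), nl) * 5L,
                    context = sample(c("CG", "CHG", "CHH"), rows,
                                     replace = TRUE, prob = c(0.8, 0.1, 0.1)),
                    stringsAsFactors = FALSE)
  for (a in acc) {
    cov <- pmax(1L, stats::rpois(rows, depth[li]))
    pp <- pmin(1, pmax(0, p[cbind(li, match(a, acc))] + rnorm(rows, 0, 0.01)))
    met <- stats::rbinom(rows, cov, pp)
    tab[[paste0(a, "_total")]] <- cov
    tab[[paste0(a, "_methylated")]] <- met
  }
  list(table = tab,
       annotations = data.frame(locus_id = locus_id, kind = kind,
                                detail = detail, stringsAsFactors = FALSE),
       truth = data.frame(locus_id = locus_id, class = cls,
                          stringsAsFactors = FALSE))
}
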