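#' Pipeline configuration
#'
#' Collects every tunable of the analysis in one validated object. Unknown
#' keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param seed Integer seed driving all simulation randomness.
#' @param accessions Accession labels.
#' @param read_length,reads_per_accession,background_genome_length,n_loci,positions_per_locus,coverage_mean,prop_true_dmr,prop_partial_dmr
#'   Passed to [sim_config()].
#' @param min_overlap,min_identity Read-overlap acceptance criteria.
#' @param min_fraction Cluster abundance threshold (fraction of nuclear
#'   reads).
#' @param bin_width,b_tol,optimum_cut,min_pairs Age-classifier tuning.
#' @param min_coverage,contexts Methylation position filter.
#' @param g_monoploid Monoploid genome size in Mb.
#' @param ploidy Ploidy of the sequenced genome.
#' @param pseudocount,outlier_k,axis Expression module tuning.
#' @return Object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(seed = 1,
                            accessions = paste0("acc", 1:5),
                            read_length = 125,
                            reads_per_accession = 1200,
                            background_genome_length = 11e6,
                            n_loci = 300,
                            positions_per_locus = 8,
                            coverage_mean = 100,
                            prop_true_dmr = 0.05,
                            prop_partial_dmr = 0.10,
                            min_overlap = 0.55,
                            min_identity = 0.90,
                            min_fraction = 0.002,
                            bin_width = 0.001,
                            b_tol = 0.001,
                            optimum_cut = 0.99,
                            min_pairs = 20,
                            min_coverage = 50,
                            contexts = "CG",
                            g_monoploid = 865,
                            ploidy = 3,
                            pseudocount = 0.1,
                            outlier_k = 3,
                            axis = "rpm") {
  cfg <- as.list(environment())
  chk <- function(ok, what) if (!ok) stop("invalid config: ", what)
  chk(cfg$min_overlap > 0 && cfg$min_overlap <= 1, "min_overlap in (0, 1]")
  chk(cfg$min_identity > 0 && cfg$min_identity <= 1, "min_identity in (0, 1]")
  chk(cfg$min_fraction >= 0 && cfg$min_fraction < 1, "min_fraction in [0, 1)")
  chk(cfg$bin_width > 0 && cfg$bin_width <= 0.1, "bin_width in (0, 0.1]")
  chk(cfg$optimum_cut > 0.9 && cfg$optimum_cut < 1, "optimum_cut in (0.9, 1)")
  chk(cfg$min_coverage >= 1, "min_coverage >= 1")
  chk(cfg$g_monoploid > 0, "g_monoploid > 0")
  chk(cfg$ploidy >= 1, "ploidy >= 1")
  chk(cfg$axis %in% c("rpm", "fpkm"), "axis is 'rpm' or 'fpkm'")
  chk(cfg$min_pairs >= 2, "min_pairs >= 2")
  structure(cfg, class = "pipeline_config")
}

#' Demonstration family set
#'
#' A small community of repeat families with the structural features the
#' analysis expects: young and old LTR retrotransposon families (Copia and
#' Gypsy superfamilies), a DNA transposon, tandem repeats, rDNA, an
#' unclassified repeat, chloroplast contamination, and copy-number contrasts
#' splitting the accessions into two clades. Two families are low-abundance
#' but highly transcribed (expression outliers).
#'
#' @param accessions Accession labels (at least 4 for the clade contrast).
#' @return List of [family_spec()] objects.
#' @export
demo_family_specs <- function(accessions = paste0("acc", 1:5)) {
  n <- length(accessions)
  cp <- function(base, boost = rep(1, n)) {
    stats::setNames(as.integer(round(base * boost)), accessions)
  }
  clade2 <- as.integer(seq_len(n) > ceiling(n / 2))  # later accessions
  list(
    family_spec("copia_young", cp(800), consensus_length = 1200,
                divergence = 0.006, expression_rate = 0.6,
                annotation = annotation_lineage("I", "LTR", "Copia", "AleII")),
    family_spec("copia_old", cp(900), consensus_length = 1200,
                divergence = 0.08, expression_rate = 0.2, age_mixture = TRUE,
                annotation = annotation_lineage("I", "LTR", "Copia",
                                                "Maximus-SIRE")),
    family_spec("gypsy_young", cp(700, 1 + 1.2 * clade2),
                consensus_length = 1500, divergence = 0.01,
                expression_rate = 0.4,
                annotation = annotation_lineage("I", "LTR", "Gypsy",
                                                "Chromovirus")),
    family_spec("gypsy_old", cp(800), consensus_length = 1500,
                divergence = 0.07, expression_rate = 0.1, age_mixture = TRUE,
                annotation = annotation_lineage("I", "LTR", "Gypsy",
                                                "Ogre-Tat")),
    family_spec("hat_transposon", cp(250, 1 + clade2),
                consensus_length = 900, divergence = 0.012,
                expression_rate = 0.5,
                annotation = annotation_lineage("II", "TIR", "hAT",
                                                "hAT-Tip100")),
    family_spec("pif_harbinger", cp(60), consensus_length = 800,
                divergence = 0.008, expression_rate = 25,
                annotation = annotation_lineage("II", "TIR", "PIF-Harbinger")),
    family_spec("mutator_like", cp(50), consensus_length = 800,
                divergence = 0.01, expression_rate = 30,
                annotation = annotation_lineage("II", "TIR", "Mutator")),
    family_spec("tandem_sat", cp(300), consensus_length = 400,
                divergence = 0.02, expression_rate = 0,
                annotation = annotation_lineage("tandem")),
    family_spec("rdna", cp(200, 1 + 0.8 * clade2), consensus_length = 1000,
                divergence = 0.004, expression_rate = 2,
                annotation = annotation_lineage("rDNA")),
    family_spec("unclassified_rep", cp(300), consensus_length = 700,
                divergence = 0.03, expression_rate = 0.3,
                annotation = annotation_lineage("unclassified")),
    family_spec("chloroplast_frag", cp(400), consensus_length = 1000,
                divergence = 0.001, expression_rate = 0,
                annotation = annotation_lineage("chloroplast"))
  )
}

#' Run the full analysis pipeline on simulated data
#'
#' Simulate -> cluster (per accession) -> annotate -> filter -> merge ->
#' abundance -> age classification -> expression -> methylation -> joined
#' reports. All randomness derives from `config$seed`; rerunning with the
#' same configuration reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param spec_list Family specs; defaults to [demo_family_specs()].
#' @param outdir Optional directory; when given, TSV/JSON reports are
#'   written there.
#' @param verbose Log stage progress to stderr.
#' @return Report bundle (list) with per-stage results, invisibly when
#'   `outdir` is given.
#' @export
run_pipeline <- function(config = pipeline_config(), spec_list = NULL,
                         outdir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[repeatdiv] ", ...)
  scfg <- sim_config(accessions = config$accessions,
                     read_length = config$read_length,
                     reads_per_accession = config$reads_per_accession,
                     background_genome_length = config$background_genome_length,
                     seed = config$seed,
                     n_loci = config$n_loci,
                     positions_per_locus = config$positions_per_locus,
                     coverage_mean = config$coverage_mean,
                     prop_true_dmr = config$prop_true_dmr,
                     prop_partial_dmr = config$prop_partial_dmr)
  if (is.null(spec_list)) spec_list <- demo_family_specs(config$accessions)

  say("simulating genome reads")
  genome <- simulate_genome(spec_list, scfg)

  say("clustering per accession")
  acc_results <- lapply(config$accessions, function(acc) {
    rt <- genome$read_truth[genome$read_truth$accession == acc, ]
    reads <- genome$reads[rt$read_id]
    cl <- build_clusters(reads, config$min_overlap, config$min_identity)
    ann <- truth_annotation(cl, rt, genome$family_truth)
    annotated <- annotate_clusters(cl, ann)
    kept <- filter_clusters(annotated, config$min_fraction,
                            n_input_reads = cl$n_input_reads)
    merged <- merge_by_annotation(kept)
    say(acc, ": ", nrow(cl$clusters), " clusters, ", nrow(kept),
        " kept, ", nrow(merged), " after merging")
    age <- classify_clusters(reads,
                             cl$membership[cl$membership$cluster_id %in%
                                             kept$cluster_id, , drop = FALSE],
                             config$min_overlap, config$min_identity,
                             bin_width = config$bin_width,
                             b_tol = config$b_tol,
                             optimum_cut = config$optimum_cut,
                             min_pairs = config$min_pairs)
    kept_age <- merge(kept, age, by = "cluster_id")
    list(accession = acc, clustering = cl, annotated = annotated,
         kept = kept_age, merged = merged)
  })
  names(acc_results) <- config$accessions

  say("abundance accounting")
  records <- do.call(rbind, lapply(acc_results, function(r) {
    d <- r$kept
    rid <- genome$read_truth$read_id[
      genome$read_truth$accession == r$accession]
    # occupancy fractions are taken over nuclear read bases: organellar
    # (chloroplast-annotated) cluster bases leave the denominator
    chl_bases <- sum(r$annotated$total_read_bases[
      r$annotated$te_class == "chloroplast"])
    total_bases <- sum(nchar(genome$reads[rid])) - chl_bases
    data.frame(accession = r$accession,
               te_class = d$te_class, order = d$order,
               superfamily = d$superfamily, family = d$family,
               size_mb = genome_size_mb(d$total_read_bases, total_bases,
                                        config$g_monoploid),
               n_clusters = 1L,
               n_clusters_young = as.integer(d$is_young %in% TRUE),
               stringsAsFactors = FALSE)
  }))
  abundance <- aggregate_abundance(records, "superfamily", config$g_monoploid)

  say("expression")
  expr_counts <- simulate_expression(spec_list, genome, scfg)
  expr <- normalize_expression(expr_counts, config$pseudocount)
  regressions <- lapply(config$accessions, function(a)
    dna_rna_regression(expr, a, config$axis))
  names(regressions) <- config$accessions
  outliers <- flag_expression_outliers(expr, config$outlier_k)

  say("methylation")
  meth <- simulate_methylation(scfg, spec_list)
  filtered <- filter_positions(meth$table, config$min_coverage,
                               config$contexts)
  dmp <- dmp_table(filtered)
  dmr <- dmr_table(filtered)
  msum <- summarize_methylation(dmr, meth$annotations)
  te_join <- join_te_expression(dmr, meth$annotations, expr)

  bundle <- list(config = config, genome = genome,
                 per_accession = acc_results,
                 abundance_records = records, abundance = abundance,
                 expression = expr, regressions = regressions,
                 expression_outliers = outliers,
                 methylation = meth, methylation_filtered = filtered,
                 dmp = dmp, dmr = dmr, methylation_summary = msum,
                 te_methylation_expression = te_join)
  if (!is.null(outdir)) {
    write_report_bundle(bundle, outdir)
    return(invisible(bundle))
  }
  bundle
}

#' @keywords internal
write_report_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  for (acc in names(bundle$per_accession)) {
    r <- bundle$per_accession[[acc]]
    write_tsv(r$clustering$membership, p(paste0("membership_", acc, ".tsv")))
    write_tsv(r$kept, p(paste0("clusters_", acc, ".tsv")))
  }
  write_tsv(bundle$abundance, p("abundance.tsv"))
  write_tsv(bundle$expression, p("expression.tsv"))
  write_tsv(bundle$dmp, p("dmp.tsv"))
  write_tsv(bundle$dmr, p("dmr.tsv"))
  write_tsv(make_table1(bundle), p("table1.tsv"))
  write_tsv(make_table2(bundle), p("table2.tsv"), na = "#N/A")
  reg <- lapply(bundle$regressions, function(r)
    r[c("accession", "slope", "intercept", "r_squared", "p_value",
        "n_clusters")])
  cfg <- unclass(bundle$config)
  msum <- unclass(bundle$methylation_summary)
  jsonlite::write_json(
    list(config = cfg, regressions = reg, methylation = msum),
    p("report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Abundance summary table (per accession and superfamily)
#'
#' Columns per accession: number of clusters, number in the young categories
#' (1, 4, 6), occupancy in Mb and percent of the monoploid genome; one row
#' per annotation group plus a TOTAL row. Mb and percentages are rounded to
#' 2 decimals.
#'
#' @param bundle Result of [run_pipeline()].
#' @return data.frame in report shape.
#' @export
make_table1 <- function(bundle) {
  ab <- aggregate_abundance(bundle$abundance_records, "superfamily",
                            bundle$config$g_monoploid)
  ab$size_mb <- round(ab$size_mb, 2)
  ab$percent_genome <- round(ab$percent_genome, 2)
  names(ab)[names(ab) == "n_clusters_young"] <- "n_clusters_model_146"
  ab
}

#' Differentially methylated TE loci with their expression
#'
#' @param bundle Result of [run_pipeline()].
#' @return data.frame, one row per variable TE locus, `NA` cells where the
#'   cluster is absent from an accession's expression table (written as
#'   `#N/A`).
#' @export
make_table2 <- function(bundle) {
  bundle$te_methylation_expression
}
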