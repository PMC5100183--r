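meth_table <- function(rows) {
  # rows: list of list(locus, pos, context, cov (named), met (named))
  acc <- names(rows[[1]]$cov)
  out <- data.frame(locus_id = vapply(rows, `[[`, character(1), "locus"),
                    position = vapply(rows, `[[`, numeric(1), "pos"),
                    context = vapply(rows, `[[`, character(1), "context"),
                    stringsAsFactors = FALSE)
  for (a in acc) {
    out[[paste0(a, "_total")]] <- vapply(rows, function(r) r$cov[[a]],
                                         numeric(1))
    out[[paste0(a, "_methylated")]] <- vapply(rows, function(r) r$met[[a]],
                                              numeric(1))
  }
  out
}

row5 <- function(locus, pos, context, cov, met) {
  acc <- paste0("a", 1:5)
  list(locus = locus, pos = pos, context = context,
       cov = stats::setNames(cov, acc), met = stats::setNames(met, acc))
}

test_that("position filtering enforces context and inclusive coverage", {
  tab <- meth_table(list(
    row5("L1", 5, "CG", rep(50, 5), rep(45, 5)),        # exactly 50x: kept
    row5("L1", 10, "CG", c(49, 100, 100, 100, 100), rep(10, 5)),  # dropped
    row5("L2", 5, "CHH", rep(1000, 5), rep(10, 5)),     # wrong context
    row5("L3", 5, "CG", rep(80, 5), rep(70, 5))))
  f <- filter_positions(tab, 50, "CG")
  expect_equal(attr(f, "n_positions"), 2)
  expect_equal(attr(f, "n_loci"), 2)
  expect_setequal(unique(f$locus_id), c("L1", "L3"))
  # CHH retained when asked for
  f2 <- filter_positions(tab, 50, c("CG", "CHH"))
  expect_equal(attr(f2, "n_positions"), 3)
})

test_that("level thresholds match the verbal definition exactly", {
  expect_equal(call_levels(5 / 100), "low")
  expect_equal(call_levels(25 / 100), "intermediate")  # inclusive boundary
  expect_equal(call_levels(75 / 100), "intermediate")  # inclusive boundary
  expect_equal(call_levels(76 / 100), "high")
  expect_error(call_levels(1.2), "0, 1")
  # oracle agreement on 10 000 random proportions
  set.seed(71)
  p <- runif(10000)
  expect_identical(call_levels(p), vapply(p, oracle_level, character(1)))
})

test_that("DMP calls distinguish invariant, partial and true", {
  expect_equal(call_dmp(c("low", "low", "low", "high", "low")), "true")
  expect_equal(call_dmp(c("low", "intermediate", "low", "low", "low")),
               "partial")
  expect_equal(call_dmp(c("intermediate", "high", "high", "high", "high")),
               "partial")
  expect_equal(call_dmp(rep("high", 5)), "invariant")
  # all three levels present still spans low..high
  expect_equal(call_dmp(c("low", "intermediate", "high", "low", "low")),
               "true")
})

test_that("DMR calls average positions per accession", {
  tab <- meth_table(list(
    row5("L1", 5, "CG", rep(100, 5), c(10, 10, 10, 95, 10)),
    row5("L2", 5, "CG", rep(100, 5), c(10, 30, 10, 10, 10)),
    row5("L2", 10, "CG", rep(100, 5), c(30, 30, 30, 30, 30))))
  d <- dmr_table(tab)
  # single-position locus: DMR call equals the DMP call
  p <- dmp_table(tab[tab$locus_id == "L1", ])
  expect_equal(d$call[d$locus_id == "L1"], p$call)
  # proportions 0.1 and 0.3 average to 0.2 -> low
  expect_equal(d$a1_prop[d$locus_id == "L2"], 0.2)
  expect_equal(d$a1_level[d$locus_id == "L2"], "low")
  # coverage-weighted variant changes the mean under unequal coverage
  tab2 <- meth_table(list(
    row5("L3", 5, "CG", rep(100, 5), rep(10, 5)),
    row5("L3", 10, "CG", rep(900, 5), rep(810, 5))))
  dm_u <- dmr_table(tab2)           # (0.1 + 0.9) / 2 = 0.5
  dm_w <- dmr_table(tab2, weighted = TRUE)  # 820 / 1000 = 0.82
  expect_equal(dm_u$a1_prop, 0.5)
  expect_equal(dm_w$a1_prop, 0.82)
})

test_that("raising the coverage floor never adds positions or calls", {
  cfg <- sim_config(n_loci = 200, coverage_mean = 60, seed = 72)
  m <- simulate_methylation(cfg)
  prev_pos <- Inf; prev_dmr <- Inf; prev_true <- Inf
  for (mc in c(10, 30, 50, 70, 90)) {
    f <- filter_positions(m$table, mc, "CG")
    npos <- attr(f, "n_positions")
    expect_lte(npos, prev_pos)
    if (npos > 0) {
      d <- dmr_table(f)
      expect_lte(sum(d$call != "invariant"), prev_dmr)
      expect_lte(sum(d$call == "true"), prev_true)
      prev_dmr <- sum(d$call != "invariant")
      prev_true <- sum(d$call == "true")
    }
    prev_pos <- npos
  }
})

test_that("summary reproduces published proportions from printed counts", {
  # 623 filtered loci, 111 partial, 7 true
  dmr <- data.frame(
    locus_id = sprintf("L%03d", 1:623),
    call = c(rep("partial", 111), rep("true", 7), rep("invariant", 505)),
    stringsAsFactors = FALSE)
  ann <- data.frame(
    locus_id = dmr$locus_id[1:118],
    kind = c(rep("TE", 30), rep("transcript", 48), rep("unknown", 40)),
    detail = "", stringsAsFactors = FALSE)
  s <- summarize_methylation(dmr, ann)
  expect_equal(s$n_variable, 118)
  expect_equal(round(s$variable_fraction_pct, 1), 18.9)
  expect_equal(round(s$breakdown$percent[s$breakdown$kind == "TE"], 1), 25.4)
  expect_equal(round(s$breakdown$percent[s$breakdown$kind == "transcript"],
                     1), 40.7)
  # no variable loci: percentages zero, no division error
  s0 <- summarize_methylation(dmr[dmr$call == "invariant", ], ann)
  expect_equal(s0$variable_fraction_pct, 0)
  expect_equal(s0$n_variable, 0)
})

test_that("containment: true DMRs within variable within filtered", {
  cfg <- sim_config(n_loci = 300, coverage_mean = 100, seed = 73)
  m <- simulate_methylation(cfg)
  f <- filter_positions(m$table, 50, "CG")
  d <- dmr_table(f)
  expect_true(all(d$locus_id[d$call == "true"] %in%
                    d$locus_id[d$call != "invariant"]))
  expect_true(all(d$locus_id %in% unique(f$locus_id)))
})

test_that("TE joins carry expression and mark missing cells", {
  dmr <- data.frame(locus_id = c("L1", "L2", "L3"),
                    call = c("true", "partial", "invariant"),
                    a1_prop = c(0.1, 0.5, 0.9), a2_prop = c(0.9, 0.6, 0.9),
                    a1_level = c("low", "intermediate", "high"),
                    a2_level = c("high", "intermediate", "high"),
                    stringsAsFactors = FALSE)
  ann <- data.frame(locus_id = c("L1", "L2", "L3"),
                    kind = c("TE", "TE", "TE"),
                    detail = c("famX", "famY", "famZ"),
                    stringsAsFactors = FALSE)
  expr <- data.frame(cluster_id = c("famX", "famX", "famY"),
                     accession = c("a1", "a2", "a1"),
                     dna_count = c(100, 120, 50),
                     rna_count = c(10, 5, 200), stringsAsFactors = FALSE)
  j <- join_te_expression(dmr, ann, expr)
  expect_equal(nrow(j), 2)  # invariant L3 excluded
  expect_equal(j$a1_dna[j$locus_id == "L1"], 100)
  # famY has no a2 rows: explicit missing cell
  expect_true(is.na(j$a2_dna[j$locus_id == "L2"]))
  # empty DMR set -> empty report
  expect_equal(nrow(join_te_expression(dmr[0, ], ann, expr)), 0)
})
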