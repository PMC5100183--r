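test_that("overlap acceptance follows the stated criteria", {
  set.seed(21)
  r <- random_dna_str(125)
  hit <- pairwise_overlap(r, r)
  expect_equal(hit$overlap_length, 125)
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$orientation, "same")

  hit_rc <- pairwise_overlap(r, revcomp_str(r))
  expect_equal(hit_rc$identity, 1.0)
  expect_equal(hit_rc$orientation, "reverse")

  # 60 bp exact overlap of 125 bp reads: 60/125 = 0.48 < 0.55 -> no hit
  a <- random_dna_str(125)
  b <- paste0(substr(a, 66, 125), random_dna_str(65))
  expect_null(pairwise_overlap(a, b))
  # but a 70 bp shared prefix/suffix (0.56) qualifies
  b2 <- paste0(substr(a, 56, 125), random_dna_str(55))
  expect_false(is.null(pairwise_overlap(a, b2)))

  # N never matches: a read of Ns has identity 0 against anything
  expect_null(pairwise_overlap(strrep("N", 125), a))
  expect_error(pairwise_overlap("", a), "non-empty")
})

test_that("overlap acceptance and identity are symmetric in read order", {
  set.seed(22)
  for (k in 1:30) {
    a <- random_dna_str(sample(80:125, 1))
    sh <- sample(10:80, 1)
    b <- paste0(substr(a, sh, nchar(a)), random_dna_str(sh + 20))
    if (runif(1) < 0.5) b <- revcomp_str(b)
    h1 <- pairwise_overlap(a, b)
    h2 <- pairwise_overlap(b, a)
    expect_equal(is.null(h1), is.null(h2))
    if (!is.null(h1)) {
      expect_equal(h1$identity, h2$identity)
      expect_equal(h1$overlap_length, h2$overlap_length)
    }
  }
})

test_that("aligner agrees with an independent overlap aligner", {
  # Biostrings pairwiseAlignment with identical scoring is the cross-check
  set.seed(23)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  for (k in 1:25) {
    a <- random_dna_str(100)
    b <- paste0(substr(a, sample(5:60, 1), 100), random_dna_str(40))
    # plant a few substitutions
    bb <- strsplit(b, "")[[1]]
    pos <- sample(seq_along(bb), 3)
    bb[pos] <- sample(c("A", "C", "G", "T"), 3, replace = TRUE)
    b <- paste(bb, collapse = "")
    ours <- .overlap_align_cpp(a, b)$fwd[["score"]]
    theirs <- Biostrings::pairwiseAlignment(
      a, b, type = "overlap", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2, scoreOnly = TRUE)
    expect_equal(ours, theirs)
  }
})

test_that("build_clusters matches the brute-force union-find oracle", {
  # 100 zero-divergence reads tiling a 1000 bp consensus at small steps
  # (every neighbouring pair overlaps well above 55 %) -> one cluster
  set.seed(24)
  cons <- random_dna_str(1000)
  starts <- round(seq(1, 1000 - 125 + 1, length.out = 100))
  tiling <- substring(cons, starts, starts + 124)
  flip <- seq_along(tiling) %% 3 == 0
  tiling[flip] <- vapply(tiling[flip], revcomp_str, character(1))
  names(tiling) <- sprintf("t%03d", seq_along(tiling))
  cl <- build_clusters(tiling)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$n_reads[1], 100)
  expect_identical(membership_sets(cl$membership),
                   sort_sets(oracle_clusters(tiling)))

  # mixed families plus unrelated singleton reads, prefilter on and off
  set.seed(25)
  f1 <- sim_family_reads(80, divergence = 0.01, n_copies = 50,
                         consensus_length = 600, prefix = "x")
  f2 <- sim_family_reads(80, divergence = 0.02, n_copies = 50,
                         consensus_length = 600, prefix = "y")
  singles <- stats::setNames(replicate(40, random_dna_str(125)),
                             sprintf("s%03d", 1:40))
  reads <- c(f1$reads, f2$reads, singles)
  names(reads) <- sprintf("r%04d", seq_along(reads))  # avoid name clashes
  oracle <- sort_sets(oracle_clusters(reads))
  for (pf in c(TRUE, FALSE)) {
    cl2 <- build_clusters(reads, kmer_prefilter = pf)
    expect_identical(membership_sets(cl2$membership), oracle)
    # partition property
    expect_equal(nrow(cl2$membership) + length(cl2$unclustered),
                 length(reads))
    expect_false(anyDuplicated(cl2$membership$read_id) > 0)
  }

  expect_equal(nrow(build_clusters(character(0))$clusters), 0)
})

test_that("clusters recover true families on well-separated simulations", {
  specs <- list(
    family_spec("famA", c(a1 = 300), 800, divergence = 0.005,
                annotation = annotation_lineage("I", "LTR", "Copia")),
    family_spec("famB", c(a1 = 300), 800, divergence = 0.01,
                annotation = annotation_lineage("I", "LTR", "Gypsy")),
    family_spec("famC", c(a1 = 200), 700, divergence = 0.02,
                annotation = annotation_lineage("II", "TIR", "hAT")))
  cfg <- sim_config(accessions = "a1", reads_per_accession = 500,
                    background_genome_length = 20000, seed = 31)
  g <- simulate_genome(specs, cfg)
  cl <- build_clusters(g$reads)
  ann <- truth_annotation(cl, g$read_truth, g$family_truth)
  # majority-family purity of clustered reads
  mb <- merge(cl$membership, g$read_truth[, c("read_id", "family_id")])
  mb <- merge(mb, ann[, c("cluster_id", "majority_family")])
  expect_gte(mean(mb$family_id == mb$majority_family), 0.95)
  # no two clusters share a majority family only if families separated;
  # at least: every family is majority of at most a few clusters
  expect_lte(nrow(ann), 6)
})

test_that("filtering keeps the inclusive boundary and drops chloroplast", {
  clusters <- data.frame(
    cluster_id = c("CL1", "CL2", "CL3"),
    n_reads = c(10, 9, 250),
    total_read_bases = c(1250, 1125, 31250),
    read_fraction = c(10, 9, 250) / 5000,
    te_class = c("I", "I", "chloroplast"),
    order = "", superfamily = "", family = "",
    stringsAsFactors = FALSE)
  kept <- filter_clusters(clusters, 0.002, n_input_reads = 5000)
  # chloroplast removed despite 5 % abundance; boundary 10/4750 > 0.002 kept
  expect_identical(kept$cluster_id, "CL1")
  # without the chloroplast cluster, 9/5000 stays below the threshold
  kept2 <- filter_clusters(clusters[1:2, ], 0.002, n_input_reads = 5000)
  expect_identical(kept2$cluster_id, "CL1")
  # exactly 0.2 % is kept (inclusive)
  cl3 <- clusters[1, ]
  cl3$read_fraction <- 0.002
  expect_equal(nrow(filter_clusters(cl3, 0.002, n_input_reads = 5000)), 1)
})

test_that("same-annotation merging sums and is order-independent", {
  mk <- function(id, n, sf, fam = "Chromovirus") {
    data.frame(cluster_id = id, n_reads = n, total_read_bases = n * 125,
               read_fraction = n / 1000, te_class = "I", order = "LTR",
               superfamily = sf, family = fam, stringsAsFactors = FALSE)
  }
  cl <- rbind(mk("CL1", 100, "Gypsy"), mk("CL2", 50, "Gypsy"),
              mk("CL3", 80, "Gypsy", "Ogre-Tat"), mk("CL4", 70, "Copia", ""))
  m <- merge_by_annotation(cl)
  expect_equal(nrow(m), 3)
  g <- m[m$family == "Chromovirus", ]
  expect_equal(g$n_reads, 150)
  expect_equal(g$total_read_bases, 150 * 125)
  expect_equal(g$n_merged, 2)
  # Chromovirus and Ogre-Tat are distinct lineages: not merged
  expect_equal(m$n_reads[m$family == "Ogre-Tat"], 80)
  # permutation invariance
  m2 <- merge_by_annotation(cl[c(3, 1, 4, 2), ])
  rownames(m2) <- NULL
  expect_identical(m, m2)
})

test_that("annotation lineages reject gaps", {
  expect_error(annotation_lineage("I", "", "Gypsy"), "gaps")
  expect_error(annotation_lineage("retro"), "te_class")
  ok <- annotation_lineage("I", "LTR", "Copia", "AleII")
  expect_identical(ok$family, "AleII")
})

test_that("FASTA round-trip preserves reads", {
  set.seed(26)
  reads <- stats::setNames(replicate(5, random_dna_str(80)), paste0("q", 1:5))
  tmp <- tempfile(fileext = ".fa")
  write_reads_fasta(reads, tmp)
  back <- read_reads_fasta(tmp)
  expect_identical(back, reads)
  unlink(tmp)
})
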