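# Independent oracles and small generators used across the suite.

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_str <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# Brute-force clustering oracle: all pairs through the single-pair aligner
# (no prefilter), union-find over accepted edges, components of size >= 2.
oracle_clusters <- function(reads, min_overlap_frac = 0.55,
                            min_identity = 0.90) {
  n <- length(reads)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        hit <- pairwise_overlap(reads[[i]], reads[[j]],
                                min_overlap_frac, min_identity)
        if (!is.null(hit)) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  comps <- split(names(reads), root)
  comps <- comps[vapply(comps, length, integer(1)) >= 2]
  unname(lapply(comps, sort))
}

sort_sets <- function(sets) {
  sets[order(vapply(sets, `[`, character(1), 1))]
}

# Cluster membership as a canonical set-of-sets for comparison.
membership_sets <- function(membership) {
  sort_sets(unname(lapply(split(membership$read_id, membership$cluster_id),
                          sort)))
}

# Closed-form normal-equations least squares.
oracle_ols <- function(x, y, degree) {
  x <- as.numeric(x); y <- as.numeric(y)
  X <- if (degree == 1) cbind(1, x) else cbind(1, x, x^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  rss <- sum((y - X %*% beta)^2)
  list(beta = as.numeric(beta), rss = rss)
}

# Hand computation of the likelihood-ratio chi-square statistic.
oracle_g <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  t <- m * log(m / e)
  t[m == 0] <- 0
  2 * sum(t)
}

oracle_level <- function(p) {
  if (p < 0.25) "low" else if (p > 0.75) "high" else "intermediate"
}

# Reads tiling one haplotype set: n copies of a consensus at divergence d,
# reads at uniform starts (both strands).
sim_family_reads <- function(n_reads, divergence = 0, n_copies = 10,
                             consensus_length = 1000, read_length = 125,
                             age_mixture = FALSE, prefix = "r",
                             accession = "a1") {
  spec <- family_spec(paste0(prefix, "_fam"),
                      stats::setNames(n_copies, accession),
                      consensus_length = consensus_length,
                      divergence = divergence, age_mixture = age_mixture)
  cfg <- sim_config(accessions = accession, read_length = read_length,
                    reads_per_accession = n_reads,
                    background_genome_length = read_length,
                    seed = sample.int(1e6, 1))
  g <- simulate_genome(list(spec), cfg)
  rt <- g$read_truth[g$read_truth$family_id != "background", ]
  list(reads = g$reads[rt$read_id], genome = g)
}

# One simulated genome per age condition; returns per-family categories.
age_condition_categories <- function(dgrid, age_mixture, seed,
                                     reads_per_cluster = 120,
                                     copies = 1000, consensus = 800) {
  n <- length(dgrid)
  acc <- "a1"
  specs <- lapply(seq_len(n), function(i)
    family_spec(sprintf("fam%03d", i), stats::setNames(copies, acc),
                consensus_length = consensus, divergence = dgrid[i],
                age_mixture = age_mixture))
  cfg <- sim_config(accessions = acc,
                    reads_per_accession = n * reads_per_cluster,
                    background_genome_length = 1000, seed = seed)
  g <- simulate_genome(specs, cfg)
  sp <- split(g$read_truth$read_id, g$read_truth$family_id)
  sp <- sp[grep("^fam", names(sp))]
  vapply(sp, function(rid) fit_cluster_age(g$reads[rid])$category, integer(1))
}

# Two-accession expression tables with or without planted
# low-abundance/high-expression outlier families.
expression_sim_table <- function(with_outliers, seed, n_families = 40) {
  acc <- c("x1", "x2")
  set.seed(seed)
  rate <- runif(n_families, 0.3, 0.9)
  specs <- lapply(seq_len(n_families), function(i)
    family_spec(sprintf("f%02d", i),
                stats::setNames(rep(200 + 40 * i, 2), acc),
                divergence = 0.01, expression_rate = rate[i]))
  if (with_outliers) {
    for (i in 1:3) {
      specs[[i]] <- family_spec(sprintf("f%02d", i),
                                stats::setNames(rep(30, 2), acc),
                                divergence = 0.01, expression_rate = 40)
    }
  }
  cfg <- sim_config(accessions = acc, reads_per_accession = 4000,
                    background_genome_length = 1000, seed = seed)
  g <- simulate_genome(specs, cfg)
  normalize_expression(simulate_expression(specs, g, cfg))
}

table1_records <- function() {
  read.delim(system.file("extdata", "table1_abundance.tsv",
                         package = "repeatdiv"),
             colClasses = c(rep("character", 5), "integer", "integer",
                            "numeric"))
}
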