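test_that("pairwise identities behave on degenerate clusters", {
  set.seed(51)
  r <- random_dna_str(125)
  expect_equal(pairwise_identities(c(a = r, b = r)), 1.0)
  expect_length(pairwise_identities(c(a = r, b = r, c = r)), 3)  # 3 choose 2
  expect_error(pairwise_identities(c(a = r)), "insufficient pairs")
})

test_that("cluster pair identities track the copy divergence", {
  set.seed(52)
  fam <- sim_family_reads(50, divergence = 0.01, n_copies = 200,
                          consensus_length = 500)
  ids <- pairwise_identities(fam$reads)
  # per-site identity of two rate-0.01 copies: (1-d)^2 + d^2/3 = 0.9802;
  # the aligner's optimal-score alignment can trim mismatch-rich ends,
  # so allow a small upward bias
  expect_gt(length(ids), 20)
  expect_equal(mean(ids), 0.9802, tolerance = 0.008)
})

test_that("histogram bins are left-closed with a closed last bin", {
  h <- build_identity_histogram(rep(0.95, 7))
  expect_equal(sum(h$y), 1)
  expect_equal(h$n_pairs, 7)
  expect_equal(which(h$y > 0), 51)  # [0.950, 0.951)
  expect_equal(h$y[51], 1)
  # exact upper bound falls in the last (closed) bin
  h2 <- build_identity_histogram(c(1.0, 0.90, 0.8999))
  expect_equal(h2$n_pairs, 2)  # 0.8999 excluded
  expect_equal(h2$counts[1], 1)
  expect_equal(h2$counts[100], 1)
  expect_error(build_identity_histogram(numeric(0)), "no identities")
})

test_that("uniform identities give a flat histogram", {
  set.seed(53)
  h <- build_identity_histogram(runif(50000, 0.90, 1.00))
  expect_lt(max(abs(h$y - 0.01)), 0.005)
})

test_that("model fits recover planted coefficients and match the oracle", {
  x <- build_identity_histogram(0.95)$mids  # canonical 100 bin midpoints

  # exact linear signal: b recovered to 1e-9, linear preferred by BIC
  y_lin <- (1 - 5 * sum(x)) / 100 + 5 * x
  h <- build_identity_histogram(0.95); h$y <- y_lin; h$n_pairs <- 1000
  f <- fit_identity_models(h)
  expect_equal(f$linear$b, 5, tolerance = 1e-9)
  expect_lt(f$linear$bic, f$quadratic$bic)

  # exact downward parabola with vertex at 0.95 recovered to 1e-6
  y_q <- -(x - 0.95)^2
  y_q <- y_q - mean(y_q) + 0.01
  h$y <- y_q
  f2 <- fit_identity_models(h)
  expect_equal(-f2$quadratic$b / (2 * f2$quadratic$c), 0.95,
               tolerance = 1e-6)
  expect_lt(f2$quadratic$bic, f2$linear$bic)

  # random response: coefficients equal closed-form normal equations
  set.seed(54)
  for (k in 1:20) {
    h$y <- runif(100)
    ff <- fit_identity_models(h)
    o1 <- oracle_ols(x, h$y, 1)
    o2 <- oracle_ols(x, h$y, 2)
    expect_equal(c(ff$linear$a, ff$linear$b), o1$beta, tolerance = 1e-8)
    expect_equal(c(ff$quadratic$a, ff$quadratic$b, ff$quadratic$c),
                 o2$beta, tolerance = 1e-8)
    expect_equal(ff$linear$rss, o1$rss, tolerance = 1e-8)
    expect_equal(ff$quadratic$rss, o2$rss, tolerance = 1e-8)
  }

  short <- build_identity_histogram(0.95, bin_width = 0.05)
  expect_error(fit_identity_models(short), "insufficient bins")
})

test_that("the six classification rules fire on constructed shapes", {
  x <- build_identity_histogram(0.95)$mids
  h <- build_identity_histogram(0.95); h$n_pairs <- 1000
  cat_of <- function(y) {
    h$y <- y
    f <- fit_identity_models(h)
    classify_age(f$linear, f$quadratic)$category
  }
  expect_equal(cat_of(rep(0.01, 100)), 2)                  # flat
  expect_equal(cat_of(0.01 + 0.5 * (x - 0.95)), 1)         # rising line
  expect_equal(cat_of(0.01 - 0.5 * (x - 0.95)), 3)         # falling line
  expect_equal(cat_of((x - 0.95)^2), 4)                    # upward parabola
  expect_equal(cat_of(-(x - 0.95)^2 + 0.01), 5)            # optimum 0.95
  expect_equal(cat_of(-(x - 0.995)^2 + 0.01), 6)           # optimum 0.995
  expect_true(classify_age(list(b = 2, bic = -10),
                           list(c = 1, bic = 0))$category == 1)
  # degenerate quadratic (c = 0) falls back to linear rules
  expect_equal(classify_age(list(b = 2, bic = 0),
                            list(b = -5, c = 0, bic = -10))$category, 3)
})

test_that("category is invariant to rescaling raw pair counts", {
  set.seed(55)
  fam <- sim_family_reads(60, divergence = 0.008, n_copies = 300,
                          consensus_length = 600)
  ids <- pairwise_identities(fam$reads)
  h1 <- build_identity_histogram(ids)
  h2 <- build_identity_histogram(rep(ids, 3))  # tripled counts
  f1 <- fit_identity_models(h1); f2 <- fit_identity_models(h2)
  expect_equal(classify_age(f1$linear, f1$quadratic)$category,
               classify_age(f2$linear, f2$quadratic)$category)
  expect_equal(h1$y, h2$y, tolerance = 1e-12)
})

test_that("small clusters are reported unclassified-age", {
  set.seed(56)
  fam <- sim_family_reads(6, divergence = 0.005, n_copies = 5,
                          consensus_length = 300)
  f <- fit_cluster_age(fam$reads, min_pairs = 20)
  expect_true(is.na(f$category))
  expect_identical(f$model, "unclassified-age")
  expect_null(coef(f))
})

test_that("quadratic is rarely selected when the truth is linear", {
  # BIC consistency: linear signal + noise, n = 100 bins
  set.seed(57)
  x <- build_identity_histogram(0.95)$mids
  h <- build_identity_histogram(0.95); h$n_pairs <- 1000
  picks <- replicate(100, {
    y <- 0.01 + 0.3 * (x - 0.95)
    y <- y + rnorm(100, 0, 0.1 * mean(y))
    h$y <- y
    f <- fit_identity_models(h)
    f$quadratic$bic < f$linear$bic
  })
  expect_lte(mean(picks), 0.10)
})

test_that("young fraction arithmetic matches published ratios", {
  expect_equal(young_fraction(c(rep(1, 59), rep(5, 113 - 59))), 52.2,
               tolerance = 1e-2)
  expect_equal(young_fraction(rep(3, 10)), 0)
  expect_equal(young_fraction(c(1, 4, 6)), 100)
  expect_equal(young_fraction(c(1, 5, NA)), 50)  # NA excluded
})

test_that("te_age_fit methods work end to end", {
  set.seed(58)
  fam <- sim_family_reads(80, divergence = 0.005, n_copies = 400,
                          consensus_length = 600)
  f <- fit_cluster_age(fam$reads)
  expect_s3_class(f, "te_age_fit")
  expect_true(f$is_young)
  expect_length(coef(f), 3)
  expect_length(predict(f, c(0.95, 0.99)), 2)
  expect_output(print(f), "category")
  tab <- classify_clusters(
    fam$reads,
    data.frame(read_id = names(fam$reads), cluster_id = "CL1"))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$category, f$category)
  expect_true(all(c("bic_lin", "bic_quad", "n_pairs") %in% names(tab)))
})
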