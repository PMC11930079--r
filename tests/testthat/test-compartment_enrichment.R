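make_track <- function(chrom, start, end, value, name = "toy") {
  tr <- tibble::tibble(chrom = chrom, start = start, end = end, value = value)
  class(tr) <- c("signal_track", class(tr))
  attr(tr, "track_name") <- name
  tr
}

make_domains <- function(start, end, ids = sprintf("d%02d", seq_along(start))) {
  d <- tibble::tibble(chrom = "chrS", start = start, end = end,
                      domain_id = ids, class_label = NA_character_)
  class(d) <- c("genomic_domains", class(d))
  d
}

test_that("BED and bedGraph files read back as validated tibbles", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrS\t0\t1000\tA", "chrS\t2000\t5000\tB", "chrS\t6000\t9000\tC"),
             bed)
  d <- read_bed(bed)
  expect_equal(nrow(d), 3)
  expect_equal(d$domain_id, c("A", "B", "C"))
  expect_equal(d$start, c(0, 2000, 6000))

  bg <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("track type=bedGraph", "chrS\t0\t100\t2.5", "chrS\t100\t300\t1.0"),
             bg)
  tr <- read_bedgraph(bg)
  expect_equal(tr$value, c(2.5, 1.0))

  overlap <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chrS\t0\t100\t1", "chrS\t50\t150\t2"), overlap)
  expect_error(read_bedgraph(overlap), "overlap")

  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  expect_warning(d0 <- read_bed(empty), "empty")
  expect_equal(nrow(d0), 0)
})

test_that("domain means follow the per-bp definition with zero fill", {
  dom <- make_domains(0, 1000)
  full <- make_track("chrS", 0, 1000, 2.0)
  expect_equal(domain_mean_signal(full, dom), 2.0)
  half <- make_track("chrS", 0, 500, 2.0)
  expect_equal(domain_mean_signal(half, dom), 1.0)
  expect_equal(domain_mean_signal(half, dom, missing_as_zero = FALSE), 2.0)
})

test_that("fragmented coverage matches a per-bp expansion oracle", {
  set.seed(61)
  # fragmented track over a 10 kb toy domain
  starts <- sort(sample(seq(0, 9900, by = 100), 30))
  widths <- sample(c(50, 100), 30, replace = TRUE)
  vals <- round(runif(30, 0, 5), 2)
  tr <- make_track("chrS", starts, starts + widths, vals)
  dom <- make_domains(250, 8750)
  perbp <- numeric(10000)
  for (i in seq_along(starts))
    perbp[(starts[i] + 1):(starts[i] + widths[i])] <- vals[i]
  expect_equal(domain_mean_signal(tr, dom), mean(perbp[251:8750]),
               tolerance = 1e-12)
  # linear in track values; invariant under interval splitting
  tr2 <- tr; tr2$value <- tr2$value * 3
  expect_equal(domain_mean_signal(tr2, dom), 3 * domain_mean_signal(tr, dom))
  split_tr <- make_track("chrS",
                         c(starts, starts + 25),
                         c(starts + 25, starts + widths),
                         rep(vals, 2))
  split_tr <- dplyr::arrange(split_tr, start)
  class(split_tr) <- c("signal_track", class(split_tr))
  expect_equal(domain_mean_signal(split_tr, dom), domain_mean_signal(tr, dom),
               tolerance = 1e-12)
})

test_that("scale-regions bins are exact for constant and aligned tracks", {
  dom <- make_domains(c(10000, 40000), c(20000, 60000))
  const <- make_track("chrS", 0, 100000, 3.25)
  m <- scale_regions_matrix(const, dom, flank_bp = 5000,
                            body_bp_scaled = 10000, bin_size = 1000)
  expect_equal(dim(m$values), c(2, 20))
  expect_true(all(abs(m$values - 3.25) < 1e-12))
})

test_that("body rescaling preserves the domain mean for aligned input", {
  set.seed(62)
  vals <- round(runif(20, 0, 4), 3)
  tr <- make_track("chrS", seq(10000, 29000, by = 1000),
                   seq(11000, 30000, by = 1000), vals)
  dom <- make_domains(10000, 30000)
  m <- scale_regions_matrix(tr, dom, flank_bp = 5000,
                            body_bp_scaled = 10000, bin_size = 1000)
  body <- m$values[1, 6:15]
  expect_equal(mean(body), domain_mean_signal(tr, dom), tolerance = 1e-9)
})

test_that("rescaled bodies are identical for shape-identical domains", {
  # same two-level signal shape on domains of different lengths
  dom <- make_domains(c(10000, 50000), c(20000, 70000))
  tr <- make_track("chrS",
                   c(10000, 15000, 50000, 60000),
                   c(15000, 20000, 60000, 70000),
                   c(1, 4, 1, 4))
  m <- scale_regions_matrix(tr, dom, flank_bp = 2000,
                            body_bp_scaled = 10000, bin_size = 1000)
  n_flank <- 2
  body1 <- m$values[1, (n_flank + 1):(n_flank + 10)]
  body2 <- m$values[2, (n_flank + 1):(n_flank + 10)]
  expect_equal(body1, body2, tolerance = 1e-9)
})

test_that("edge domains get truncated flanks and a flag", {
  dom <- make_domains(1000, 5000)
  tr <- make_track("chrS", 0, 10000, 1)
  expect_warning(
    m <- scale_regions_matrix(tr, dom, flank_bp = 2000,
                              body_bp_scaled = 4000, bin_size = 1000),
    "truncated")
  expect_true(m$truncated[1])
})

test_that("k-means classification recovers planted domain classes", {
  set.seed(63)
  n <- 60
  truth <- rep(c("ACTIVE", "INACTIVE"), each = n / 2)
  mk <- function(mu_hi, mu_lo, sd = 0.5) {
    structure(list(
      values = matrix(rnorm(n * 20, mean = ifelse(truth == "ACTIVE",
                                                  mu_hi, mu_lo), sd = sd),
                      nrow = n),
      domain_id = sprintf("d%02d", 1:n), truncated = rep(FALSE, n),
      bin_scheme = c(flank_bp = 0, body_bp_scaled = 20, bin_size = 1),
      track_name = "sim"), class = "scale_regions_matrix")
  }
  act <- mk(5, 1)
  cl <- kmeans_classify(act, seed = 10)
  expect_equal(cl$class_label, truth)
  # stacking a second (inverted) track keeps perfect recovery
  cl2 <- kmeans_classify(list(act, mk(1, 4)), seed = 10)
  expect_equal(cl2$class_label, truth)
  # partition is stable across seeds on well-separated data
  cl3 <- kmeans_classify(act, seed = 999)
  expect_equal(cl3$class_label, cl$class_label)
})

test_that("k-means refuses degenerate inputs", {
  flat <- structure(list(values = matrix(1, 10, 5),
                         domain_id = sprintf("d%d", 1:10),
                         truncated = rep(FALSE, 10),
                         bin_scheme = c(flank_bp = 0, body_bp_scaled = 5,
                                        bin_size = 1),
                         track_name = "flat"), class = "scale_regions_matrix")
  expect_error(kmeans_classify(flat), "fewer distinct rows")
})

test_that("enrichment test equals a hand-computed Welch oracle", {
  hi <- c(1, 2, 3); lo <- c(4, 5, 6)
  out <- enrichment_test(hi, lo)
  # Welch formulas written out directly
  se2 <- var(hi) / 3 + var(lo) / 3
  t_hand <- (mean(hi) - mean(lo)) / sqrt(se2)
  df_hand <- se2^2 / ((var(hi) / 3)^2 / 2 + (var(lo) / 3)^2 / 2)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(out$t_stat, t_hand, tolerance = 1e-10)
  expect_equal(out$df, df_hand, tolerance = 1e-10)
  expect_equal(out$p_value, p_hand, tolerance = 1e-10)
  expect_equal(out$fold_change, mean(hi) / mean(lo))
})

test_that("enrichment test is scale invariant and handles ties", {
  hi <- c(2, 4, 9, 3); lo <- c(1, 2, 2.5)
  a <- enrichment_test(hi, lo)
  b <- enrichment_test(hi * 10, lo * 10)
  expect_equal(a$t_stat, b$t_stat)
  expect_equal(a$fold_change, b$fold_change)
  same <- enrichment_test(c(1, 1), c(1, 1))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)
  expect_error(enrichment_test(1, c(1, 2)), "at least 2")
})

test_that("regulatory correlations hit the trivial and oracle cases", {
  set.seed(64)
  dom <- make_domains(0, 100000)
  starts <- seq(1000, 96000, by = 5000)
  tr_a <- make_track("chrS", starts, starts + 1000, round(runif(20, 1, 5), 2),
                     name = "a")
  features <- tibble::tibble(chrom = "chrS", start = starts, end = starts + 1000,
                             class = rep(c("promoter", "enhancer"), 10))
  self <- regulatory_correlation(tr_a, tr_a, features, dom)
  expect_true(all(abs(self$spearman_rho - 1) < 1e-12))
  neg <- tr_a; neg$value <- -neg$value
  class(neg) <- class(tr_a)
  anti <- regulatory_correlation(tr_a, neg, features, dom)
  expect_true(all(abs(anti$spearman_rho + 1) < 1e-12))
})

test_that("spearman at features matches a rank-based oracle with ties", {
  set.seed(65)
  dom <- make_domains(0, 100000)
  starts <- seq(1000, 96000, by = 5000)
  va <- sample(c(1, 2, 2, 3, 4), 20, replace = TRUE)
  vb <- va + rnorm(20, sd = 0.8)
  tr_a <- make_track("chrS", starts, starts + 1000, va, name = "a")
  tr_b <- make_track("chrS", starts, starts + 1000, vb, name = "b")
  features <- tibble::tibble(chrom = "chrS", start = starts,
                             end = starts + 1000, class = "promoter")
  out <- regulatory_correlation(tr_a, tr_b, features, dom)
  oracle <- cor(rank(va), rank(vb))  # average ranks for ties
  expect_equal(out$spearman_rho, oracle, tolerance = 1e-10)
  expect_equal(out$n_features, 20L)
})

test_that("feature classes below the reporting minimum are omitted", {
  dom <- make_domains(0, 100000)
  starts <- c(1000, 11000, 21000, 31000)
  tr <- make_track("chrS", starts, starts + 1000, c(1, 2, 3, 4))
  features <- tibble::tibble(chrom = "chrS", start = starts, end = starts + 1000,
                             class = c("promoter", "promoter", "promoter",
                                       "enhancer"))
  expect_warning(out <- regulatory_correlation(tr, tr, features, dom),
                 "omitting")
  expect_equal(out$class, "promoter")
  # midpoint rule: features outside all domains never count
  outside <- tibble::tibble(chrom = "chrS", start = 200000, end = 201000,
                            class = "promoter")
  expect_warning(res <- regulatory_correlation(tr, tr, outside, dom), "no features")
  expect_equal(nrow(res), 0)
})
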