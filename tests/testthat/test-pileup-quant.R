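# Per-site quantification: base counting with phred/strand handling,
# coverage filtering, CEI, expression dominance, and oracle equivalence.

toy_genome_len <- c(chrA = 2000L)

# build a SAM with n_a A-reads and n_g G-reads over position 100 (plus
# strand), with per-read phred at the site position
site_sam <- function(n_a, n_g, phreds = NULL, path = tempfile()) {
  n <- n_a + n_g
  phreds <- phreds %||% rep(35L, n)
  reads <- lapply(seq_len(n), function(i) {
    base <- if (i <= n_a) "A" else "G"
    seq <- paste0(strrep("C", 10), base, strrep("C", 10))
    list(chrom = "chrA", pos = 90L, seq = seq,
         phred = c(rep(35L, 10), phreds[i], rep(35L, 10)))
  })
  write_toy_sam(reads, toy_genome_len, path)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("base counts honour phred filter and strand complement", {
  cat1 <- data.frame(site_id = "s1", chrom = "chrA", pos = 100L,
                     strand = "+", gene = "g", conserved = 1L)
  sam <- site_sam(7, 3)
  counts <- count_site_bases(sam, cat1, quant_config(), "t")
  expect_equal(counts[, c("n_A", "n_G", "n_total")],
               data.frame(n_A = 7L, n_G = 3L, n_total = 10L))
  # one G at phred 20: removed from numerator and denominator
  sam2 <- site_sam(7, 3, phreds = c(rep(35L, 7), 35L, 35L, 20L))
  c2 <- count_site_bases(sam2, cat1, quant_config(), "t")
  expect_equal(c(c2$n_A, c2$n_G, c2$n_total), c(7L, 2L, 9L))
  # phred 26 passes, 25 fails (strict inequality)
  sam3 <- site_sam(0, 2, phreds = c(26L, 25L))
  c3 <- count_site_bases(sam3, cat1, quant_config(), "t")
  expect_equal(c3$n_total, 1L)
  # minus-strand site: T pileup counts as A, C as G
  catm <- cat1; catm$strand <- "-"
  readsm <- lapply(c("T", "T", "C"), function(b) list(
    chrom = "chrA", pos = 95L, seq = paste0(strrep("G", 5), b, strrep("G", 5)),
    phred = rep(35L, 11)))
  samm <- write_toy_sam(readsm, toy_genome_len, tempfile())
  cm <- count_site_bases(samm, catm, quant_config(), "t")
  expect_equal(c(cm$n_A, cm$n_G), c(2L, 1L))
})

test_that("multimapped reads are dropped unless the filter is off", {
  cat1 <- data.frame(site_id = "s1", chrom = "chrA", pos = 100L,
                     strand = "+", gene = "g", conserved = 1L)
  reads <- lapply(1:4, function(i) list(
    chrom = "chrA", pos = 90L, seq = paste0(strrep("C", 10), "G", strrep("C", 10)),
    phred = rep(35L, 21)))
  sam <- write_toy_sam(reads, toy_genome_len, tempfile(),
                       nh = c(1L, 1L, 2L, 3L))
  c_on <- count_site_bases(sam, cat1, quant_config(), "t")
  expect_equal(c_on$n_total, 2L)
  c_off <- count_site_bases(sam, cat1, quant_config(unique_only = FALSE), "t")
  expect_equal(c_off$n_total, 4L)
})

test_that("missing catalog chromosome raises a coordinate error", {
  cat_bad <- data.frame(site_id = "s1", chrom = "chrZ", pos = 100L,
                        strand = "+", gene = "g", conserved = 1L)
  expect_error(count_site_bases(site_sam(1, 1), cat_bad, quant_config()),
               "absent from alignment header")
})

test_that("editing levels apply coverage and group filters", {
  mk <- function(site, sample, group, n_a, n_g) data.frame(
    site_id = site, chrom = "chrA", pos = 1L, strand = "+", gene = site,
    conserved = 1L, sample = sample, n_A = n_a, n_G = n_g, n_other = 0L,
    n_total = n_a + n_g)
  # 3 sites x 4 samples in 2 groups; siteC covered >= 15 in one group only
  counts <- rbind(
    mk("siteA", "s1", "g1", 10, 10), mk("siteA", "s2", "g1", 12, 8),
    mk("siteA", "s3", "g2", 20, 0), mk("siteA", "s4", "g2", 15, 5),
    mk("siteB", "s1", "g1", 5, 5),  mk("siteB", "s2", "g1", 30, 0),
    mk("siteB", "s3", "g2", 8, 8),  mk("siteB", "s4", "g2", 40, 10),
    mk("siteC", "s1", "g1", 30, 10), mk("siteC", "s2", "g1", 25, 5),
    mk("siteC", "s3", "g2", 4, 1),  mk("siteC", "s4", "g2", 3, 2))
  groups <- c(s1 = "g1", s2 = "g1", s3 = "g2", s4 = "g2")
  lv <- editing_levels(counts, quant_config(), groups = groups)
  expect_setequal(unique(lv$site_id), c("siteA", "siteB"))
  expect_equal(attr(lv, "dropped_sites"), "siteC")
  expect_equal(lv$level[lv$site_id == "siteA" & lv$sample == "s1"], 0.5)
  # coverage 14 < 15: missing with reason
  low <- editing_levels(rbind(mk("siteA", "s1", "g1", 7, 7),
                              mk("siteA", "s2", "g2", 20, 0)),
                        quant_config(min_groups = 1), groups = groups)
  expect_true(is.na(low$level[low$sample == "s1"]))
  expect_equal(low$missing_reason[low$sample == "s1"], "low coverage")
})

test_that("CEI is the coverage-weighted aggregate over conserved sites", {
  df <- data.frame(site_id = c("a", "b"), conserved = 1L, sample = "s",
                   n_G = c(5L, 0L), n_total = c(10L, 10L))
  expect_equal(compute_cei(df)$cei, 0.25)
  one <- compute_cei(df[1, ])
  expect_equal(one$cei, 0.5)
  # additivity: splitting one site's reads into two rows leaves CEI fixed
  split_df <- data.frame(site_id = c("a1", "a2", "b"), conserved = 1L,
                         sample = "s", n_G = c(3L, 2L, 0L),
                         n_total = c(6L, 4L, 10L))
  expect_equal(compute_cei(split_df)$cei, 0.25)
  expect_error(compute_cei(data.frame(site_id = "a", conserved = 1L,
                                      sample = "s", n_G = 0L, n_total = 0L)),
               "zero total coverage")
})

test_that("expression dominance flags samples above the threshold share", {
  r1 <- expression_dominance_check(c(g1 = 71, g2 = 20, g3 = 9))
  expect_true(r1$flagged); expect_equal(r1$dominant, "g1")
  expect_false(expression_dominance_check(c(g1 = 70, g2 = 30))$flagged)
  expect_false(expression_dominance_check(setNames(rep(3, 10),
                                                   paste0("g", 1:10)))$flagged)
  expect_error(expression_dominance_check(c(a = 0, b = 0)), "all-zero")
})

test_that("raising min_phred never increases filtered totals", {
  fx <- fix_cohort()
  des <- sample_design("mono", c(neuron = 1), depth = 30L,
                       low_qual_fraction = 0.3, seed = 51L)
  sim <- simulate_sample(fx$gen, fx$catalog, fx$editomes, des, tempfile())
  prev <- NULL
  for (mp in c(10L, 19L, 25L, 34L)) {
    tot <- count_site_bases(sim$sam, fx$catalog,
                            quant_config(min_phred = mp), "m")$n_total
    if (!is.null(prev)) expect_true(all(tot <= prev))
    prev <- tot
  }
})

test_that("counts match the brute-force per-read oracle on toy files", {
  fx <- fix_cohort()
  catalog <- fx$catalog
  des <- sample_design("oracle", c(neuron = 0.6, astrocyte = 0.4),
                       depth = 2L, error_rate = 0.01,
                       low_qual_fraction = 0.2, seed = 52L)
  sim <- simulate_sample(fx$gen, catalog, fx$editomes, des, tempfile())
  counts <- count_site_bases(sim$sam, catalog, quant_config(), "oracle")
  for (i in seq_len(nrow(catalog))) {
    o <- oracle_site_counts(sim$sam, catalog$chrom[i], catalog$pos[i],
                            catalog$strand[i])
    expect_equal(unname(c(counts$n_A[i], counts$n_G[i], counts$n_other[i])),
                 unname(o), info = catalog$site_id[i])
  }
})

test_that("estimated levels regress on truth with unit slope", {
  fx <- fix_cohort()
  catalog <- fx$catalog[1:10, ]
  ed <- make_cell_editomes(catalog, "paperlike", seed = 61L)
  est <- c(); tru <- c()
  for (k in 1:20) {
    f <- k / 21
    mix <- c(neuron = f, astrocyte = 1 - f)
    des <- sample_design(paste0("p", k), mix, depth = 150L, error_rate = 0,
                         seed = 600L + k)
    sim <- simulate_sample(fx$gen, catalog, ed, des, tempfile())
    counts <- count_site_bases(sim$sam, catalog, quant_config(), "p")
    est <- c(est, counts$n_G / (counts$n_A + counts$n_G))
    tru <- c(tru, f * ed$levels[, "neuron"] + (1 - f) * ed$levels[, "astrocyte"])
  }
  slope <- coef(lm(est ~ tru))[2]
  expect_lt(abs(slope - 1), 0.02)
})
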