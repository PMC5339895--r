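# Composition analysis: forward mixing, density change, differential
# statistics, correlation, clustering, and the inverse estimator.

test_that("mixture validation enforces names, sign and unit sum", {
  m <- mixture_spec(neuron = 0.6, astrocyte = 0.4)
  expect_equal(sum(m), 1)
  expect_equal(mixture_spec(c(a = 0.25, b = 0.75))[["b"]], 0.75)
  expect_error(mixture_spec(neuron = 0.6, astrocyte = 0.3), "sum to 1")
  expect_error(mixture_spec(neuron = 1.2, astrocyte = -0.2), "negative")
  expect_error(validate_mixture(c(0.5, 0.5)), "named")
})

test_that("mixing is the expression-weighted convex combination", {
  lev <- matrix(c(0.7, 0.4, 0.03, 0.0), 2, 2,
                dimnames = list(c("s1", "s2"), c("neuron", "astrocyte")))
  mx <- mix_editomes(lev, c(neuron = 0.5, astrocyte = 0.5))
  expect_equal(unname(mx$levels["s1"]), 0.365)
  expect_equal(unname(mx$levels["s2"]), 0.2)
  # pure mixtures return the columns
  expect_equal(unname(mix_editomes(lev, c(neuron = 1, astrocyte = 0))$levels),
               unname(lev[, "neuron"]))
  # expression weights tilt the average toward the dominant expresser
  w <- matrix(c(3, 3, 1, 1), 2, 2,
              dimnames = list(c("s1", "s2"), c("neuron", "astrocyte")))
  mw <- mix_editomes(lev, c(neuron = 0.5, astrocyte = 0.5), weights = w)
  expect_equal(unname(mw$levels["s2"]), 0.5 * 3 * 0.4 / (0.5 * 3 + 0.5 * 1))
  # repeat index mixes linearly
  mp <- mix_editomes(lev, c(neuron = 0.25, astrocyte = 0.75),
                     p_repeat = c(neuron = 0.02, astrocyte = 0.008))
  expect_equal(mp$repeat_index, 0.25 * 0.02 + 0.75 * 0.008)
  expect_error(mix_editomes(lev, c(neuron = 0.5, microglia = 0.5)),
               "no editome for cell type")
})

test_that("mixed levels stay inside the convex hull of the cell levels", {
  set.seed(14)
  lev <- matrix(runif(40), 10, 4,
                dimnames = list(paste0("s", 1:10), paste0("t", 1:4)))
  for (k in 1:5) {
    f <- runif(4); f <- setNames(f / sum(f), colnames(lev))
    mx <- mix_editomes(lev, f)$levels
    expect_true(all(mx >= apply(lev, 1, min) - 1e-12))
    expect_true(all(mx <= apply(lev, 1, max) + 1e-12))
  }
})

test_that("density change rescales neurons and redistributes the rest", {
  base <- c(neuron = 0.5, astrocyte = 0.3, opc = 0.2)
  out <- simulate_density_change(base, -0.2)
  expect_equal(unname(out), c(0.4, 0.36, 0.24))
  expect_equal(sum(out), 1)
  # other types keep their relative proportions
  expect_equal(out[["astrocyte"]] / out[["opc"]],
               base[["astrocyte"]] / base[["opc"]])
  expect_equal(simulate_density_change(base, 0), base)
  expect_error(simulate_density_change(base, 1.5), "outside")
  expect_error(simulate_density_change(base, -0.2, neuron_type = "purkinje"),
               "no 'purkinje' component")
})

test_that("Mann-Whitney p matches full enumeration for small groups", {
  set.seed(31)
  sizes <- list(c(3, 3), c(4, 5), c(2, 6), c(5, 5))
  for (sz in sizes) {
    a <- round(rnorm(sz[1]), 3); b <- round(rnorm(sz[2], 0.5), 3)
    expect_equal(editomix:::mann_whitney_p(a, b), oracle_mw_exact(a, b),
                 tolerance = 1e-12, info = paste(sz, collapse = "x"))
  }
  expect_equal(editomix:::mann_whitney_p(c(2, 2, 2), c(2, 2)), 1)
})

test_that("differential editing reports deltas, q-values and skips", {
  a <- rbind(shift  = c(0.10, 0.12, 0.11, 0.13),
             flat   = c(0.30, 0.31, 0.29, 0.30),
             const  = c(0.2, 0.2, 0.2, 0.2),
             sparse = c(0.5, NA, NA, NA))
  b <- rbind(shift  = c(0.30, 0.32, 0.33, 0.31),
             flat   = c(0.31, 0.29, 0.30, 0.32),
             const  = c(0.2, 0.2, 0.2, 0.2),
             sparse = c(0.5, 0.6, 0.4, 0.5))
  # smallest attainable 4v4 exact p is 2/70; over 3 tested sites the BH
  # floor is 3 * 2/70 = 0.086, so flag at alpha = 0.1
  de <- differential_editing(a, b, alpha = 0.1)
  expect_setequal(de$site_id, c("shift", "flat", "const"))
  sh <- de[de$site_id == "shift", ]
  expect_equal(sh$delta, (mean(b["shift", ]) - mean(a["shift", ])) * 100)
  expect_equal(sh$direction, "up")
  expect_true(sh$significant)
  expect_equal(de$p[de$site_id == "const"], 1)
  expect_false(de$significant[de$site_id == "flat"])
  expect_named(attr(de, "skipped"), "sparse")
  # BH never lowers a p-value and respects the alpha flag
  expect_true(all(de$q >= de$p - 1e-12))
  bon <- differential_editing(a, b, adjust = "bonferroni")
  expect_equal(bon$q, pmin(1, de$p * nrow(de)))
})

test_that("editome correlation recovers exact and null relations", {
  cell_b <- c(s1 = 0.1, s2 = 0.2, s3 = 0.3, s4 = 0.4)
  d_cell <- c(s1 = 0.4, s2 = -0.2, s3 = 0.1, s4 = -0.3)
  cell_a <- cell_b + d_cell
  cond_1 <- c(s1 = 0.5, s2 = 0.5, s3 = 0.5, s4 = 0.5)
  # condition delta proportional to the cell delta: r = 1 exactly
  r1 <- editome_correlation(cell_a, cell_b, cond_1, cond_1 + 0.5 * d_cell)
  expect_equal(r1$r, 1)
  expect_equal(r1$r_squared, 1)
  # orthogonal condition delta: r = 0 by construction
  set.seed(3)
  d0 <- d_cell - mean(d_cell)
  o0 <- residuals(lm(rnorm(4) ~ d0))  # orthogonal to centred d_cell
  r0 <- editome_correlation(cell_a, cell_b, cond_1, cond_1 + o0)
  expect_lt(abs(r0$r), 1e-8)
  # the repeat-index point is appended as one extra pair
  rr <- editome_correlation(cell_a, cell_b, cond_1, cond_1 + 0.5 * d_cell,
                            repeat_deltas = c(0.01, 0.005))
  expect_equal(rr$n, 5)
  expect_true("repeat_index" %in% rr$points$site_id)
  expect_error(editome_correlation(cell_a[1:2], cell_b, cond_1, cond_1 + d_cell),
               "at least 3 shared sites")
  expect_error(editome_correlation(cell_a, cell_b, cond_1, cond_1),
               "zero variance")
})

test_that("correlation clustering separates the two editome families", {
  set.seed(41)
  prof1 <- runif(30); prof2 <- runif(30)
  mat <- cbind(a1 = prof1 + rnorm(30, 0, 0.01),
               a2 = prof1 + rnorm(30, 0, 0.01),
               a3 = prof1 + rnorm(30, 0, 0.01),
               b1 = prof2 + rnorm(30, 0, 0.01),
               b2 = prof2 + rnorm(30, 0, 0.01),
               b3 = prof2 + rnorm(30, 0, 0.01))
  cl <- cluster_editomes(mat)
  g <- cl$groups
  expect_equal(length(unique(g[c("a1", "a2", "a3")])), 1L)
  expect_equal(length(unique(g[c("b1", "b2", "b3")])), 1L)
  expect_false(g[["a1"]] == g[["b1"]])
  expect_equal(unname(diag(cl$correlation)), rep(1, 6))
  # a duplicated sample sits at correlation distance zero
  expect_equal(cl$correlation["a1", "a1"], 1)
  # samples without enough shared sites are dropped with a message
  mat2 <- mat; mat2[3:30, "b3"] <- NA
  expect_message(cl2 <- cluster_editomes(mat2), "dropped sample")
  expect_equal(cl2$dropped, "b3")
  # Newick export round-trips through ape
  nwk <- tempfile(fileext = ".nwk")
  write_tree_newick(cl, nwk)
  tr <- ape::read.tree(nwk)
  expect_setequal(tr$tip.label, colnames(mat))
})

test_that("neuronal samples cluster apart from glial samples", {
  fx <- fix_cohort()
  lv <- fx$editomes$levels
  set.seed(47)
  jitter_col <- function(ct) pmin(pmax(lv[, ct] + rnorm(nrow(lv), 0, 0.01),
                                       0), 1)
  mat <- cbind(neuron_1 = jitter_col("neuron"),
               neuron_2 = jitter_col("neuron"),
               astro = jitter_col("astrocyte"),
               opc = jitter_col("opc"),
               oligo = jitter_col("myel_oligo"),
               micro = jitter_col("microglia"))
  g <- cluster_editomes(mat)$groups
  expect_equal(g[["neuron_1"]], g[["neuron_2"]])
  expect_true(all(g[c("astro", "opc", "oligo", "micro")] != g[["neuron_1"]]))
})

test_that("the inverse estimator recovers fractions exactly without noise", {
  set.seed(52)
  lev <- matrix(runif(30), 10, 3,
                dimnames = list(paste0("s", 1:10),
                                c("neuron", "astrocyte", "microglia")))
  f_pre <- c(neuron = 0.5, astrocyte = 0.3, microglia = 0.2)
  f_post <- simulate_density_change(f_pre, -0.25)
  y_pre <- mix_editomes(lev, f_pre)$levels
  y_post <- mix_editomes(lev, f_post)$levels
  est <- estimate_fraction_change(y_pre, y_post, lev)
  expect_false(est$ill_conditioned)
  expect_equal(est$f_pre, f_pre, tolerance = 1e-9)
  expect_equal(est$f_post, f_post, tolerance = 1e-9)
  expect_equal(est$neuron_delta, -0.25, tolerance = 1e-9)
  expect_lt(est$residual_pre, 1e-10)
})

test_that("degenerate editomes are flagged as ill-conditioned", {
  lev <- matrix(runif(10), 10, 1)[, c(1, 1)]
  dimnames(lev) <- list(paste0("s", 1:10), c("neuron", "astrocyte"))
  y <- mix_editomes(lev, c(neuron = 0.5, astrocyte = 0.5))$levels
  est <- estimate_fraction_change(y, y, lev)
  expect_true(est$ill_conditioned)
  expect_true(is.na(est$neuron_delta))
  expect_true(all(is.na(est$f_pre)))
})
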