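# Hyper-editing rescue: three-letter transform, transformed alignment,
# back-transform calling, cluster filters, signature, and rates.

# deterministic toy genome for hand-built calls
toy_index <- function() {
  gen <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 30)))
  build_transformed_index(gen, seed_length = 16L)
}

test_that("three-letter transform collapses exactly one base pair", {
  expect_identical(three_letter_transform("AAGCTA"), "GGGCTG")
  expect_identical(three_letter_transform("AAGCTA", "T", "C"), "AAGCCA")
  s <- with_seed(7L, random_dna(500))
  t1 <- three_letter_transform(s)
  # no A survives; G count absorbs the A count; C and T untouched
  cnt <- function(x, b) lengths(regmatches(x, gregexpr(b, x)))
  expect_equal(cnt(t1, "A"), 0L)
  expect_equal(cnt(t1, "G"), cnt(s, "A") + cnt(s, "G"))
  expect_equal(cnt(t1, "C"), cnt(s, "C"))
  expect_equal(cnt(t1, "T"), cnt(s, "T"))
  # idempotence
  expect_identical(three_letter_transform(t1), t1)
})

test_that("alignment recovers the planted locus and sense", {
  fx <- fix_cohort()
  idx <- build_transformed_index(fx$gen$genome, 16L)
  chr <- as.character(fx$gen$genome[["chr1"]])
  rd <- substr(chr, 1001, 1075)
  b <- strsplit(rd, "")[[1]]
  # sense read: A -> G at six adenosines
  bp <- b; bp[head(which(b == "A"), 6)] <- "G"
  hp <- align_transformed(paste(bp, collapse = ""), idx)
  expect_equal(hp[c("chrom", "start", "sense")],
               list(chrom = "chr1", start = 1001L, sense = "+"))
  expect_equal(hp$mismatches, 0)
  # antisense read: T -> C at six thymines
  bm <- b; bm[head(which(b == "T"), 6)] <- "C"
  hm <- align_transformed(paste(bm, collapse = ""), idx)
  expect_equal(hm[c("chrom", "start", "sense")],
               list(chrom = "chr1", start = 1001L, sense = "-"))
  # a perfect-match read ties both transformed genomes: ambiguous
  expect_null(align_transformed(rd, idx))
  # a read foreign to the genome does not align
  expect_null(align_transformed(with_seed(99L, random_dna(75)), idx))
})

test_that("cluster calls apply the acceptance rules in order", {
  idx <- toy_index()
  hit <- list(chrom = "chr1", start = 1L, sense = "+")
  base <- strsplit(strrep("ACGT", 10), "")[[1]]  # A at 1,5,...,37
  ph <- rep(35L, 40)
  call1 <- function(b, phred = ph, h = hit)
    back_transform_call(paste(b, collapse = ""), phred, idx, h,
                        hyper_config(), "r")
  b5 <- base; b5[c(5, 9, 13, 17, 21)] <- "G"
  cl <- call1(b5)
  expect_equal(cl$verdict, "accepted")
  expect_equal(cl$n_ag, 5)
  expect_equal(cl$edits$pos, c(5L, 9L, 13L, 17L, 21L))
  expect_true(all(cl$edits$ref == "A" & cl$edits$alt == "G"))
  # four edits: too few
  b4 <- base; b4[c(5, 9, 13, 17)] <- "G"
  expect_equal(call1(b4)$reason, "too few edits")
  # a low-quality edit does not count as an edit
  phl <- ph; phl[5] <- 25L
  cl_lq <- call1(b5, phred = phl)
  expect_equal(cl_lq$n_ag, 4)
  expect_equal(cl_lq$reason, "too few edits")
  # five edits + four other mismatches: fraction 5/9 < 0.6
  b9 <- b5; b9[c(2, 6, 10, 14)] <- "T"
  expect_equal(call1(b9)$reason, "low A-to-G fraction")
  # five edits + two other mismatches: fraction ok, count exceeded
  b7 <- b5; b7[c(2, 6)] <- "T"
  cl7 <- call1(b7)
  expect_equal(cl7$n_other, 2)
  expect_equal(cl7$reason, "other mismatches")
  # antisense hit: T -> C called as the editing type
  hitm <- list(chrom = "chr1", start = 1L, sense = "-")
  bm <- base; bm[c(4, 8, 12, 16, 20)] <- "C"
  clm <- call1(bm, h = hitm)
  expect_equal(clm$verdict, "accepted")
  expect_true(all(clm$edits$ref == "T" & clm$edits$alt == "C"))
})

test_that("rescue recovers every planted hyper read", {
  fx <- fix_cohort()
  des <- sample_design("hyp", c(neuron = 1), depth = 40L,
                       hyper_fraction = 0.05, error_rate = 0, seed = 91L)
  sim <- simulate_sample(fx$gen, fx$catalog, fx$editomes, des, tempfile())
  rs <- rescue_hyper_edited(sim$fastq, fx$gen$genome)
  truth <- sim$truth$hyper
  expect_gt(nrow(truth), 3)
  expect_equal(rs$n_accepted, nrow(truth))
  m <- merge(rs$clusters, truth, by = "read_id")
  expect_equal(nrow(m), nrow(truth))
  expect_true(all(m$verdict == "accepted"))
  expect_equal(m$chrom.x, m$chrom.y)
  expect_equal(m$sense.x, m$sense.y)
  expect_equal(m$start.x, m$start.y)
  # recovered edit positions equal the planted ones, read by read
  for (i in seq_len(nrow(truth))) {
    planted <- as.integer(strsplit(truth$positions[i], ",")[[1]])
    got <- sort(rs$edits$pos[rs$edits$read_id == truth$read_id[i]])
    expect_equal(got, planted, info = truth$read_id[i])
  }
  # the pooled spectrum is pure A>G here
  expect_equal(names(rs$mismatch_spectrum), "A>G")
})

test_that("ordinary reads are not rescued", {
  fx <- fix_cohort()
  des <- sample_design("ord", c(neuron = 0.6, astrocyte = 0.4),
                       depth = 25L, error_rate = 0.005, seed = 92L)
  sim <- simulate_sample(fx$gen, fx$catalog, fx$editomes, des, tempfile())
  lines <- grep("^[^@]", readLines(sim$sam), value = TRUE)
  f <- strsplit(lines, "\t")
  fq <- tempfile(fileext = ".fastq")
  writeLines(unlist(lapply(f, function(x)
    c(paste0("@", x[1]), x[10], "+", x[11]))), fq)
  rs <- rescue_hyper_edited(fq, fx$gen$genome)
  expect_equal(rs$n_accepted, 0)
})

test_that("raising the edit threshold never rescues more reads", {
  fx <- fix_cohort()
  des <- sample_design("mono", c(neuron = 1), depth = 40L,
                       hyper_fraction = 0.04, hyper_edit_range = c(5L, 9L),
                       error_rate = 0.002, seed = 93L)
  sim <- simulate_sample(fx$gen, fx$catalog, fx$editomes, des, tempfile())
  idx <- build_transformed_index(fx$gen$genome)
  acc <- vapply(c(3L, 5L, 7L, 10L), function(k)
    rescue_hyper_edited(sim$fastq, idx,
                        hyper_config(min_edits_per_read = k))$n_accepted,
    numeric(1))
  expect_true(all(diff(acc) <= 0))
})

test_that("signature profile reads sense-space neighbors correctly", {
  gen <- Biostrings::DNAStringSet(c(chr1 = "TTACGAGTAC"))
  # plus site at pos 3 (A): upstream T, downstream C
  pro <- signature_profile(data.frame(chrom = "chr1", pos = 3L,
                                      sense = "+"), gen)
  expect_equal(unname(pro$site_up["T"]), 1)
  expect_equal(unname(pro$site_down["C"]), 1)
  # minus site at pos 8 (T): sense-space upstream = comp(pos 9) = T,
  # downstream = comp(pos 7) = C
  prom <- signature_profile(data.frame(chrom = "chr1", pos = 8L,
                                       sense = "-"), gen)
  expect_equal(unname(prom$site_up["T"]), 1)
  expect_equal(unname(prom$site_down["C"]), 1)
  expect_error(signature_profile(data.frame(chrom = character(0),
                                            pos = integer(0),
                                            sense = character(0)), gen),
               "no accepted edit sites")
})

test_that("sites drawn as background adenosines give unit ratios", {
  gen <- Biostrings::DNAStringSet(c(chr1 = with_seed(17L, random_dna(2000))))
  b <- strsplit(as.character(gen[[1]]), "")[[1]]
  ed <- rbind(
    data.frame(chrom = "chr1", pos = which(b == "A"), sense = "+"),
    data.frame(chrom = "chr1", pos = which(b == "T"), sense = "-"))
  pro <- signature_profile(ed, gen)
  expect_equal(unname(pro$depletion_ratio_upstream_G), 1, tolerance = 1e-9)
  expect_equal(unname(pro$enrichment_ratio_downstream_G), 1, tolerance = 1e-9)
})

test_that("hyper-editing rate is reads per million mapped", {
  expect_equal(hyper_rate(5, 1e6)$rate, 5)
  expect_equal(hyper_rate(3, 2e5)$rate, 15)
  expect_error(hyper_rate(1, 0), "must be positive")
})
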