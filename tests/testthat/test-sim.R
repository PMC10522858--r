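small_cfg <- function(...) {
  sim_config(n_clones = 30L, pool_size = 5e3L, read_depth = 500L,
             error_rate = 0, seed = 17L, ...)
}

test_that("identical config and seed give byte-identical outputs", {
  cfg <- small_cfg()
  c1 <- simulate_campaign(cfg, "phage")
  c2 <- simulate_campaign(cfg, "phage")
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$clones, c2$clones)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_campaign(c1, d1)
  write_campaign(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("degenerate library: one clone takes the whole pool", {
  cfg <- sim_config(n_clones = 1L, pool_size = 1000L, read_depth = 50L,
                    seed = 2L)
  lib <- generate_library(cfg)
  expect_equal(lib$counts0, 1000L)
  expect_equal(nrow(lib$clones), 1L)
})

test_that("library CDR3s respect the length mixture and anchor exclusion", {
  cfg <- sim_config(n_clones = 10000L, pool_size = 1e4L, seed = 29L)
  lib <- generate_library(cfg)
  lens <- nchar(lib$clones$cdr3_aa)
  expect_true(all(lens >= 8L & lens <= 31L))
  # empirical per-length counts within 3 multinomial SDs of expectation
  mix <- default_length_mixture()
  obs <- table(factor(lens, levels = mix$length))
  expected <- 10000 * mix$weight
  sd3 <- 3 * sqrt(10000 * mix$weight * (1 - mix$weight))
  expect_true(all(abs(as.integer(obs) - expected) <= pmax(sd3, 3)))
  # no anchor motifs inside ground-truth CDR3s
  expect_false(any(grepl("[YF][YF]C", lib$clones$cdr3_aa, perl = TRUE)))
  expect_false(any(grepl("[DN]G[AG]GT", lib$clones$cdr3_aa, perl = TRUE)))
  # coding sequences translate back to the amino-acid truth
  idx <- sample(nrow(lib$clones), 50)
  expect_equal(vapply(lib$clones$cdr3_nt[idx], translate_frame,
                      character(1), USE.NAMES = FALSE),
               lib$clones$cdr3_aa[idx])
})

test_that("capture_probability worked values and monotonicity", {
  expect_equal(capture_probability(1e-8, 0), 0)           # no antigen
  # valence 1, no penalty: q reduces to the bound fraction b
  kd <- 10^seq(-9, -4, length.out = 12)
  b <- 1e-7 / (1e-7 + kd)
  expect_equal(capture_probability(kd, 1e-7), b)
  # b = 0.5, d = 1, valence 5: q = 1 - 0.5^5
  expect_equal(capture_probability(1e-7, 1e-7, 0, 0, 5), 0.96875)
  # decreasing in kd and r; increasing in antigen and valence
  expect_true(all(diff(capture_probability(kd, 1e-7)) < 0))
  r <- seq(0, 100, 10)
  expect_true(all(diff(capture_probability(1e-8, 1e-7, r, 0.03, 5)) < 0))
  ag <- 10^seq(-9, -5, length.out = 8)
  expect_true(all(diff(capture_probability(1e-7, ag)) > 0))
  expect_lt(capture_probability(1e-6, 1e-7, 0, 0, 1),
            capture_probability(1e-6, 1e-7, 0, 0, 5))
  expect_true(all(capture_probability(kd, 1e-7, 50, 0.05, 5) >= 0 &
                  capture_probability(kd, 1e-7, 50, 0.05, 5) <= 1))
})

test_that("simulate_round conserves the pool and keeps extinct clones at 0", {
  set.seed(61)
  counts <- c(0L, 100L, 900L)
  q <- c(0.9, 0.5, 0.5)
  for (k in 1:20) {
    out <- simulate_round(counts, q, 2000L)
    expect_equal(sum(out), 2000L)
    expect_equal(out[1], 0L)     # extinction is absorbing
  }
})

test_that("a clone with twice the capture probability doubles its ratio", {
  set.seed(67)
  ratios <- replicate(300, {
    out <- simulate_round(c(5e4L, 5e4L), c(0.02, 0.01), 1e5L)
    out[1] / out[2]
  })
  # expected post-round ratio = 2x the input ratio (1), Monte-Carlo mean
  expect_equal(mean(ratios), 2, tolerance = 0.05)
})

test_that("neutral limit: saturating antigen and no penalty give flat slopes", {
  cfg <- sim_config(n_clones = 100L, pool_size = 1e5L, read_depth = 2e4L,
                    antigen_conc = 1, lambda_phage = 0, error_rate = 0,
                    seed = 71L)
  cam <- simulate_campaign(cfg, "phage")
  expect_true(all(cam$clones$q > 0.999))
  tabs <- lapply(0:4, campaign_round_table, campaign = cam)
  top <- top_n(tabs[[1]], 50)$cdr3
  slopes <- vapply(top, function(s) {
    tryCatch(estimate_enrichment(tabs, s)$slope, error = function(e) NA)
  }, numeric(1))
  expect_lt(mean(abs(slopes), na.rm = TRUE), 0.1)  # drift-only bound
})

test_that("selection limit: a dominant binder sweeps within 4 rounds", {
  cfg <- sim_config(n_clones = 50L, pool_size = 1e5L, read_depth = 1e4L,
                    kd_range = c(1e-4, 1e-4), lambda_phage = 0,
                    error_rate = 0, seed = 73L)
  lib <- generate_library(cfg)
  lib$clones$kd[1] <- 1e-12          # one clone far tighter than the rest
  cam <- simulate_campaign(cfg, "phage", library = lib)
  final <- cam$counts[, "R4"]
  expect_gt(final[1] / sum(final), 0.99)
})

test_that("campaign counts always sum to the pool; reads to the depth", {
  cfg <- small_cfg()
  cam <- simulate_campaign(cfg, "yeast")
  expect_true(all(colSums(cam$counts) == cfg$pool_size))
  for (rd in 0:2) {
    expect_equal(nrow(sample_round_reads(cam, rd)), cfg$read_depth)
  }
  tab <- campaign_round_table(cam, 0)
  expect_equal(tab$total, cfg$read_depth)
})

test_that("paired campaigns share the library and naive counts", {
  cfg <- small_cfg()
  pr <- simulate_paired(cfg)
  expect_identical(pr$phage$clones$cdr3_aa, pr$yeast$clones$cdr3_aa)
  expect_identical(pr$phage$counts[, "R0"], pr$yeast$counts[, "R0"])
  # codon penalty differs: phage q depends on rare content, yeast not
  expect_false(identical(pr$phage$clones$q, pr$yeast$clones$q))
  # rare-codon ground truth scored in the mode's own host
  bact <- load_codon_usage("bacteria")
  expect_equal(pr$phage$clones$r[1],
               rare_codon_fraction(pr$phage$clones$cdr3_nt[1], bact))
})

test_that("written ground truth matches the campaign object", {
  cfg <- small_cfg()
  cam <- simulate_campaign(cfg, "phage")
  d <- withr::local_tempdir()
  paths <- write_campaign(cam, d)
  gt <- utils::read.table(paths$ground_truth, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  expect_equal(gt$cdr3_aa, cam$clones$cdr3_aa)
  expect_equal(gt$count_r4, unname(cam$counts[, "R4"]))
  expect_equal(gt$q, cam$clones$q)
  # FASTQ per round exists and has read_depth records
  reads <- read_sequences(paths$R0)
  expect_equal(nrow(reads), cfg$read_depth)
})
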