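bact <- load_codon_usage("bacteria")
yst <- load_codon_usage("yeast")

# custom table with a controlled Phe family (TTT 30, TTC 10 per thousand)
make_custom_usage <- function() {
  src <- system.file("extdata", "codon_usage_bacteria.tsv",
                     package = "vnarpan")
  df <- utils::read.table(src, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  df$freq_per_thousand[df$codon == "TTT"] <- 30
  df$freq_per_thousand[df$codon == "TTC"] <- 10
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

test_that("relative adaptiveness: majority codon and degenerate families", {
  for (t in list(bact, yst)) {
    # the most frequent codon of every family has w = 1
    fam <- split(names(t$freq), t$aa)
    for (codons in fam) {
      top <- codons[which.max(t$freq[codons])]
      expect_equal(relative_adaptiveness(t, top), 1)
    }
    expect_equal(relative_adaptiveness(t, "ATG"), 1)  # Met
    expect_equal(relative_adaptiveness(t, "TGG"), 1)  # Trp
  }
  expect_error(relative_adaptiveness(bact, "TAA"), "sense")
  expect_error(relative_adaptiveness(bact, "AXT"), "sense")
})

test_that("a 30/10 family gives w = 1/3, exactly at the rare boundary", {
  cu <- load_codon_usage(make_custom_usage())
  expect_equal(relative_adaptiveness(cu, "TTC"), 1 / 3)
  # w exactly at rare_max_w is intermediate (strict lower bound)
  expect_equal(classify_codon(cu, "TTC"), "intermediate")
  expect_equal(classify_codon(cu, "TTT"), "common")
})

test_that("classification covers every sense codon exactly once", {
  for (t in list(bact, yst)) {
    cls <- classify_codon(t, names(t$freq))
    expect_length(cls, 61L)
    expect_true(all(cls %in% c("rare", "intermediate", "common")))
    expect_equal(cls, unname(ifelse(t$w < 1 / 3, "rare",
                                    ifelse(t$w >= 2 / 3, "common",
                                           "intermediate"))))
    # each class non-empty for a real usage table
    expect_true(all(c("rare", "intermediate", "common") %in% cls))
  }
  # a codon with low w under defaults is rare: AGG in E. coli
  expect_lt(relative_adaptiveness(bact, "AGG"), 1 / 3)
  expect_equal(classify_codon(bact, "AGG"), "rare")
})

test_that("rare_codon_fraction arithmetic and preconditions", {
  # all most-frequent codons -> 0 percent rare
  common_nt <- local({
    fam <- split(names(bact$freq), bact$aa)
    paste0(vapply(fam, function(cs) cs[which.max(bact$freq[cs])],
                  character(1))[c("A", "G", "L", "K")], collapse = "")
  })
  expect_equal(rare_codon_fraction(common_nt, bact), 0)

  # exactly 1 rare codon among 10
  rare_codon <- names(bact$w)[bact$w < 1 / 3][1]
  nt10 <- paste0(paste(rep(CU <- "GCG", 9), collapse = ""), rare_codon)
  expect_equal(rare_codon_fraction(nt10, bact), 10)

  expect_error(rare_codon_fraction(strrep("A", 20), bact), "multiple of 3")
  expect_error(rare_codon_fraction("GCGTAA", bact), "sense")
})

test_that("synonymous recoding to all-common codons zeroes the fraction", {
  set.seed(53)
  fam <- split(names(bact$freq), bact$aa)
  for (k in 1:10) {
    aa <- random_aa(12)
    nt <- paste0(vapply(strsplit(aa, "")[[1]], function(a) {
      sample(fam[[a]], 1)
    }, character(1)), collapse = "")
    recoded <- paste0(vapply(strsplit(aa, "")[[1]], function(a) {
      cs <- fam[[a]]
      cs[which.max(bact$freq[cs])]
    }, character(1)), collapse = "")
    expect_equal(rare_codon_fraction(recoded, bact), 0)
    # recoding any codon to a rare synonym never decreases the fraction
    expect_gte(rare_codon_fraction(nt, bact),
               rare_codon_fraction(recoded, bact))
  }
})

test_that("cohort statistics: degenerate n and the two-sequence case", {
  fam <- split(names(bact$freq), bact$aa)
  common_of <- function(a) fam[[a]][which.max(bact$freq[fam[[a]]])]
  rare_of <- function(a) fam[[a]][which.min(bact$w[fam[[a]]])]
  # 10 codons, exactly 1 rare -> 10%
  nt_10pct <- paste0(c(rare_of("R"), rep(common_of("A"), 9)),
                     collapse = "")
  aa1 <- translate_frame(nt_10pct, 0)
  t1 <- round_table(stats::setNames(5L, aa1),
                    stats::setNames(nt_10pct, aa1))
  st <- cohort_rare_codon_stats(t1, bact, top = 10)
  expect_equal(st$mean, 10)
  expect_equal(st$sd, 0)
  expect_equal(st$n, 1L)

  # two clonotypes at 10% and 30% -> mean 20, sd sqrt(200) ~ 14.14
  nt_30pct <- paste0(c(rep(rare_of("R"), 3), rep(common_of("A"), 7)),
                     collapse = "")
  aa2 <- translate_frame(nt_30pct, 0)
  t2 <- round_table(stats::setNames(c(5L, 3L), c(aa1, aa2)),
                    stats::setNames(c(nt_10pct, nt_30pct), c(aa1, aa2)))
  st <- cohort_rare_codon_stats(t2, bact, top = 10)
  expect_equal(st$mean, 20)
  expect_equal(st$sd, sqrt(200))
  expect_equal(st$n, 2L)
  expect_equal(st$per_clonotype$rare_pct, c(10, 30))
})

test_that("cohort equals the brute-force per-sequence recomputation", {
  set.seed(59)
  t <- random_round_table(40L)
  st <- cohort_rare_codon_stats(t, yst, top = 10)
  manual <- vapply(top_n(t, 10)$cdr3, function(s) {
    rare_codon_fraction(t$rep_nt[[s]], yst)
  }, numeric(1))
  expect_equal(st$per_clonotype$rare_pct, unname(manual))
  expect_equal(st$mean, mean(manual))
  expect_equal(st$sd, stats::sd(manual))
})

test_that("usage tables validate coverage and positivity", {
  src <- system.file("extdata", "codon_usage_yeast.tsv",
                     package = "vnarpan")
  df <- utils::read.table(src, sep = "\t", header = TRUE,
                          comment.char = "#")
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df[-1, ], f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(load_codon_usage(f), "61 sense codons")
})
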