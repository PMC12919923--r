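test_that("well-formed files read completely and malformed rows are counted", {
  df <- makeSumstatsData(beta = c(0.1, -0.2, 0.05), se = c(0.02, 0.03, 0.01))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- readSumstats(path, trait = "bmi")
  expect_equal(nrow(ss@data), 3L)
  expect_equal(ss@trait, "bmi")

  bad <- df
  bad$standard_error[2] <- 0
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(ss2 <- readSumstats(path), "malformed")
  expect_equal(nrow(ss2@data), 2L)
  expect_equal(unname(attr(ss2, "rejected")["se_not_positive"]), 1L)
})

test_that("a missing required column is an error", {
  df <- makeSumstatsData(beta = 0.1, se = 0.02)
  df$beta <- NULL
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSumstats(path), "beta")
})

test_that("lower-case alleles normalize and the writer round-trips", {
  df <- makeSumstatsData(beta = c(0.1, 0.2), se = c(0.02, 0.02),
                         ea = c("a", "t"), oa = c("g", "c"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- readSumstats(path)
  expect_identical(ss@data$effect_allele, c("A", "T"))
  # write-read identity
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeSumstats(ss, path2)
  ss2 <- readSumstats(path2)
  expect_equal(ss2@data, ss@data)
})

test_that("column maps rename on the way in", {
  df <- makeSumstatsData(beta = 0.1, se = 0.02)
  names(df)[names(df) == "beta"] <- "b"
  names(df)[names(df) == "standard_error"] <- "se"
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- readSumstats(path, columnMap = c(beta = "b", standard_error = "se"))
  expect_equal(ss@data$beta, 0.1)
})

test_that("the significance threshold excludes boundary violations", {
  ss <- makeSumstats(beta = c(0.1, 0.1), se = c(0.01, 0.01),
                     p = c(6e-8, 4e-8))
  instr <- selectInstruments(ss, pThreshold = 5e-8)
  expect_equal(instr@data$variant_id, "rs0002")
})

test_that("correlated near neighbours are pruned, keeping the smaller p", {
  ss <- makeSumstats(beta = c(0.1, 0.1), se = c(0.01, 0.01),
                     pos = c(1e6, 1.005e6), p = c(1e-10, 1e-9))
  ld <- data.frame(id_a = "rs0001", id_b = "rs0002", r2 = 0.5)
  instr <- selectInstruments(ss, 5e-8, ld)
  expect_equal(instr@data$variant_id, "rs0001")
  # below the r2 threshold both survive
  ld$r2 <- 0.005
  instr2 <- selectInstruments(ss, 5e-8, ld)
  expect_equal(nrow(instr2@data), 2L)
})

test_that("unknown LD within the window is treated as linked", {
  ss <- makeSumstats(beta = c(0.1, 0.1), se = c(0.01, 0.01),
                     pos = c(1e6, 2e6), p = c(1e-10, 1e-9))
  instr <- selectInstruments(ss, 5e-8, ld = NULL)
  expect_equal(instr@data$variant_id, "rs0001")
  # beyond the window the pair is always retained
  ss2 <- makeSumstats(beta = c(0.1, 0.1), se = c(0.01, 0.01),
                      pos = c(1e6, 2e6 + 1e7), p = c(1e-10, 1e-9))
  instr2 <- selectInstruments(ss2, 5e-8, ld = NULL)
  expect_equal(nrow(instr2@data), 2L)
})

test_that("clumping matches a brute-force greedy oracle and ignores row order", {
  for (seed in 1:5) {
    set.seed(seed)
    J <- 50
    df <- makeSumstatsData(
      beta = rnorm(J, 0, 0.05), se = rep(0.01, J),
      chrom = as.character(sample(1:3, J, replace = TRUE)),
      pos = sample(1:20, J, replace = TRUE) * 1e6,
      p = runif(J, 1e-12, 1e-8))
    pairs <- t(combn(J, 2))
    ld <- data.frame(id_a = df$variant_id[pairs[, 1]],
                     id_b = df$variant_id[pairs[, 2]],
                     r2 = runif(nrow(pairs))^2)
    ss <- new("GwasSumstats", data = df, trait = "x")
    got <- selectInstruments(ss, 1e-7, ld)@data$variant_id
    expect_identical(sort(got), bruteForceClump(df, ld))
    # order independence
    shuffled <- new("GwasSumstats", data = df[sample(J), ], trait = "x")
    got2 <- selectInstruments(shuffled, 1e-7, ld)@data$variant_id
    expect_identical(sort(got2), sort(got))
  }
})

test_that("an empty instrument result is a distinct warning, not an error", {
  ss <- makeSumstats(beta = 0.01, se = 0.01, p = 0.5)
  expect_warning(instr <- selectInstruments(ss, 5e-8),
                 class = "trimediate_empty_instruments")
  expect_equal(nVariants(instr), 0L)
})

test_that("swapped outcome alleles flip the outcome beta and complement eaf", {
  exp <- makeSumstats(beta = 0.1, se = 0.01, ea = "A", oa = "G",
                      trait = "bmi")
  out <- makeSumstats(beta = 0.05, se = 0.02, ea = "G", oa = "A",
                      eaf = 0.7, trait = "rcc")
  h <- harmonize(exp, out)
  expect_equal(h@betaOutcome, -0.05)
  expect_equal(h@variants$eaf_outcome, 0.3)
  expect_equal(nrow(h@dropped), 0L)
})

test_that("palindromic variants near eaf 0.5 are dropped as ambiguous", {
  exp <- makeSumstats(beta = 0.1, se = 0.01, ea = "A", oa = "T",
                      eaf = 0.5)
  out <- makeSumstats(beta = 0.05, se = 0.02, ea = "A", oa = "T",
                      eaf = 0.5)
  h <- harmonize(exp, out)
  expect_equal(nVariants(h), 0L)
  expect_equal(h@dropped$reason, "palindromic_ambiguous")
  # clearly one-sided frequencies on both sides are retained
  exp2 <- makeSumstats(beta = 0.1, se = 0.01, ea = "A", oa = "T",
                       eaf = 0.2)
  out2 <- makeSumstats(beta = 0.05, se = 0.02, ea = "A", oa = "T",
                       eaf = 0.25)
  expect_equal(nVariants(harmonize(exp2, out2)), 1L)
  # frequencies on opposite sides signal a strand problem
  out3 <- makeSumstats(beta = 0.05, se = 0.02, ea = "A", oa = "T",
                       eaf = 0.75)
  h3 <- harmonize(exp2, out3)
  expect_equal(h3@dropped$reason, "palindromic_ambiguous")
})

test_that("variants missing in the outcome and allele mismatches get reasons", {
  exp <- makeSumstats(beta = c(0.1, 0.1, 0.1), se = rep(0.01, 3),
                      ea = c("A", "A", "A"), oa = c("G", "G", "G"))
  out <- makeSumstats(beta = c(0.05, 0.05), se = rep(0.02, 2),
                      id = c("rs0001", "rs0002"),
                      ea = c("A", "C"), oa = c("G", "T"))
  h <- harmonize(exp, out)
  expect_equal(nVariants(h), 1L)
  expect_setequal(h@dropped$reason,
                  c("allele_mismatch", "missing_in_outcome"))
})

test_that("harmonization is idempotent", {
  set.seed(8)
  J <- 12
  exp <- makeSumstats(beta = rnorm(J, 0.1, 0.02), se = rep(0.01, J),
                      ea = rep(c("A", "C"), 6), oa = rep(c("G", "T"), 6),
                      eaf = runif(J, 0.1, 0.45), trait = "bmi")
  out <- makeSumstats(beta = rnorm(J, 0, 0.05), se = rep(0.02, J),
                      ea = rep(c("G", "T"), 6), oa = rep(c("A", "C"), 6),
                      eaf = runif(J, 0.1, 0.45), trait = "rcc")
  h1 <- harmonize(exp, out)
  # feed the harmonized outcome back through the harmonizer
  out2 <- new("GwasSumstats", data = within(h1@variants, {
    beta <- h1@betaOutcome
    standard_error <- h1@seOutcome
    p_value <- 2 * pnorm(-abs(beta / standard_error))
    n <- h1@nOutcome
    effect_allele_frequency <- eaf_outcome
  })[, c("variant_id", "chromosome", "base_pair_location",
         "effect_allele", "other_allele", "effect_allele_frequency",
         "beta", "standard_error", "p_value", "n")], trait = "rcc")
  expIn <- new("GwasSumstats",
               data = exp@data[exp@data$variant_id %in%
                                 h1@variants$variant_id, ],
               trait = "bmi")
  h2 <- harmonize(expIn, out2)
  expect_equal(h2@betaOutcome, h1@betaOutcome)
  expect_equal(h2@variants$eaf_outcome, h1@variants$eaf_outcome)
  expect_equal(nrow(h2@dropped), 0L)
})

test_that("duplicate identifiers are an error", {
  exp <- makeSumstats(beta = c(0.1, 0.1), se = c(0.01, 0.01),
                      id = c("rs1", "rs1"))
  out <- makeSumstats(beta = 0.05, se = 0.02, id = "rs1")
  expect_error(harmonize(exp, out), "duplicate")
})

test_that("instrument strength follows the F arithmetic and its closed form", {
  h <- makeHarmonized(bx = 0.1, sx = 0.02, by = 0, sy = 1)
  expect_equal(unname(instrumentStrength(h)$perVariant), 25)
  # at the genome-wide boundary p = 5e-8, F is the squared normal quantile
  z <- qnorm(5e-8 / 2, lower.tail = FALSE)
  hb <- makeHarmonized(bx = rep(z * 0.01, 4), sx = rep(0.01, 4),
                       by = rep(0, 4), sy = rep(1, 4))
  expect_equal(unname(instrumentStrength(hb)$perVariant),
               rep(z^2, 4), tolerance = 1e-10)
  expect_equal(instrumentStrength(hb)$meanF, z^2, tolerance = 1e-10)
  # F is invariant under an allele flip (both beta and coding change sign)
  hf <- makeHarmonized(bx = -0.1, sx = 0.02, by = 0, sy = 1)
  expect_equal(instrumentStrength(hf)$meanF, 25)
})
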