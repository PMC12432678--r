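test_that("positivity scoring is strict at the cutoff and propagates NA", {
  df <- data.frame(serum_id = "S", allele = c("A*01:01", "A*02:01", "A*03:01"),
                   mfi = c(1000, 1001, NA))
  p <- serum_panel(df)
  sc <- score_positivity(p, "S")
  expect_equal(sc$score, c("NEG", "POS", "MISSING"))
  expect_error(score_positivity(p, "nope"), "not present")
})

test_that("the published A1-eluate panel scores reproduce the Score column", {
  fx <- load_fixture("ae1_sab")
  p <- serum_panel(data.frame(serum_id = "AE1", allele = fx$allele,
                              mfi = fx$ae1))
  sc <- score_positivity(p, "AE1")
  printed <- fx$score[match(sc$allele, allele_key(fx$allele))]
  scored <- !is.na(printed)
  expect_equal(sum(scored), 18L)
  expect_equal(sc$score[scored], printed[scored])
  expect_equal(sc$score[!scored], "MISSING")
  expect_equal(sum(sc$score == "POS"), 11L)
  expect_equal(sum(sc$score == "NEG"), 7L)
})

test_that("panel construction validates duplicates, sign and cutoff", {
  df <- data.frame(serum_id = c("S", "S"), allele = c("A*01:01", "A*01:01"),
                   mfi = c(1, 2))
  expect_error(serum_panel(df), "duplicate")
  expect_error(serum_panel(data.frame(serum_id = "S", allele = "A*01:01",
                                      mfi = -5)), "negative")
  expect_error(serum_panel(data.frame(serum_id = "S", allele = "A*01:01",
                                      mfi = 5), cutoff = 0), "positive")
})

test_that("wide panel input converts to the canonical long format", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("serum_id,A*01:01,A*02:01", "S1,5000,10", "S2,20,7000"), path)
  p <- read_panel(path, wide = TRUE)
  expect_equal(nrow(p$data), 4L)
  expect_equal(p$data$mfi[p$data$serum_id == "S1" &
                            p$data$allele == "A*01:01"], 5000)
})

test_that("an exact linear relation regresses to slope 1, R^2 1", {
  sera <- sprintf("S%02d", 1:10)
  mfi <- seq(1500, 15000, length.out = 10)
  df <- rbind(data.frame(serum_id = sera, allele = "B*51:02", mfi = mfi),
              data.frame(serum_id = sera, allele = "B*53:01", mfi = mfi))
  fit <- pairwise_regression(serum_panel(df), "B*51:02", "B*53:01")
  expect_false(fit$degenerate)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$n_sera, 10L)
})

test_that("OLS fit matches the normal-equations oracle to 1e-9", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 40
    x <- round(stats::rlnorm(n, log(4000), 1))
    y <- round(0.9 * x + stats::rnorm(n, 0, 800))
    y <- pmax(y, 0)
    sera <- sprintf("S%03d", seq_len(n))
    panel <- serum_panel(rbind(
      data.frame(serum_id = sera, allele = "B*35:01", mfi = x),
      data.frame(serum_id = sera, allele = "B*35:12", mfi = y)))
    fit <- pairwise_regression(panel, "B*35:01", "B*35:12")
    inc <- x > 1000 | y > 1000
    oracle <- ols_oracle(x[inc], y[inc])
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-9)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-9)
    expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-9)
    # r^2 equals the squared Pearson correlation of included points
    expect_equal(fit$r_squared, stats::cor(x[inc], y[inc])^2,
                 tolerance = 1e-9)
  }
})

test_that("regression degenerates cleanly below two included sera", {
  df <- rbind(data.frame(serum_id = c("S1", "S2"), allele = "A*01:01",
                         mfi = c(500, 600)),
              data.frame(serum_id = c("S1", "S2"), allele = "A*02:01",
                         mfi = c(400, 700)))
  fit <- pairwise_regression(serum_panel(df), "A*01:01", "A*02:01")
  expect_true(fit$degenerate)
  expect_true(is.na(fit$slope))
  expect_equal(fit$n_sera, 0L)
})

test_that("discordant-serum screen applies strict thresholds symmetrically", {
  sera <- sprintf("S%02d", 1:8)
  x <- c(9000, 12000, 6000, 900, 9000, 200, 15000, 1000)
  y <- c(500, 999, 100, 9500, 1000, 14000, 15000, 200)
  panel <- serum_panel(rbind(
    data.frame(serum_id = sera, allele = "B*51:02", mfi = x),
    data.frame(serum_id = sera, allele = "B*53:01", mfi = y)))
  d <- find_discordant_sera(panel, "B*51:02", "B*53:01",
                            high_cutoff = 5000)
  # S05 (y exactly 1000) excluded: negativity is strict < 1000
  expect_equal(d$xy, c("S01", "S02", "S03"))
  expect_equal(d$yx, c("S04", "S06"))
  expect_length(intersect(d$xy, d$yx), 0L)
  # invariant to row order
  perm <- sample(nrow(panel$data))
  d2 <- find_discordant_sera(serum_panel(panel$data[perm, ]),
                             "B*51:02", "B*53:01", high_cutoff = 5000)
  expect_equal(d, d2)
  # nothing above an 8000 gate on a sub-8000 panel
  sub <- serum_panel(panel$data[panel$data$serum_id %in% c("S03", "S08"), ])
  expect_equal(find_discordant_sera(sub, "B*51:02", "B*53:01", 8000),
               list(xy = character(0), yx = character(0)))
  expect_error(find_discordant_sera(panel, "B*51:02", "B*53:01",
                                    high_cutoff = 500), "exceed")
})

test_that("flow crossmatch scoring uses inclusive MCS cutoffs per lineage", {
  expect_equal(score_fxm("T", 104), "POS")
  expect_equal(score_fxm("T", 45), "NEG")
  expect_equal(score_fxm("T", 92), "POS")   # inclusive boundary
  expect_equal(score_fxm("B", 116), "POS")  # inclusive boundary
  expect_equal(score_fxm("B", 115), "NEG")
  fx <- load_fixture("fxm_167")
  expect_equal(score_fxm(fx$compartment, fx$mcs), fx$printed)
  fx2 <- load_fixture("fxm_103")
  expect_equal(score_fxm(fx2$compartment, fx2$mcs), fx2$printed)
  expect_error(score_fxm("X", 100), "compartment")
})
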