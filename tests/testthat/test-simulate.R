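test_that("degenerate generator settings give a flat single-class library", {
  sim <- simulate_library(n = 300, weight_sd = 0, noise_sd = 0, seed = 1)
  expect_equal(length(unique(sim$truth$E)), 1L)
  expect_equal(unique(sim$truth$label), "low")   # E > median(E) never strict
  expect_equal(length(unique(sim$truth$variant)), 300L)
})

test_that("planted positional weights drive expression in the right direction", {
  tpl <- elm_template("utr_strong")
  w <- matrix(0, 4, 25, dimnames = list(c("A", "C", "G", "T"), NULL))
  w[c("A", "G"), 1] <- 1          # purine bonus at the first randomized base
  w[c("C", "T"), 1] <- -1
  sim <- simulate_library(n = 2000, template = tpl, weights = w,
                          noise_sd = 0.1, seed = 2)
  first <- substr(sim$truth$variant, 1, 1)
  expect_gt(mean(sim$truth$E[first %in% c("A", "G")]),
            mean(sim$truth$E[first %in% c("C", "T")]))
})

test_that("seeds give reproducible yet distributionally matched libraries", {
  sim1 <- simulate_library(n = 800, seed = 10)
  sim1b <- simulate_library(n = 800, seed = 10)
  expect_identical(sim1$truth, sim1b$truth)
  sim2 <- simulate_library(n = 800, seed = 11)
  expect_false(any(sim1$truth$variant == sim2$truth$variant))
  ks <- suppressWarnings(ks.test(sim1$truth$logE, sim2$truth$logE))
  expect_gt(ks$p.value, 0.01)
})

test_that("digestion survival follows the four-site independence model", {
  # fix m per variant and check pool frequencies against m^4 / (1-m)^4
  sim <- simulate_library(n = 4, weight_sd = 0, noise_sd = 0, seed = 3)
  sim$truth$m <- c(0.2, 0.4, 0.6, 0.8)
  counts <- simulate_digestion_reads(sim, depth = 1e5, seed = 4)
  ord <- match(sim$truth$variant, counts$variant)
  for (pool in c("dpn", "mbo")) {
    m <- sim$truth$m
    p <- if (pool == "mbo") m^4 else (1 - m)^4
    p <- p / sum(p)
    obs <- counts[[pool]][ord]
    expected <- 1e5 * p
    sds <- sqrt(1e5 * p * (1 - p))
    expect_true(all(abs(obs - expected) <= 3 * sds + 1))
  }
  # uncut samples abundance directly (equimolar here)
  expect_lt(max(abs(counts$uncut - 2.5e4)) / 2.5e4, 0.05)
})

test_that("limits: full methylation empties the DpnI pool; m = 1/2 balances", {
  sim <- simulate_library(n = 50, weight_sd = 0, noise_sd = 0, seed = 5)
  sim$truth$m <- rep(1, 50)
  counts <- simulate_digestion_reads(sim, depth = 1e4, seed = 6)
  expect_equal(sum(counts$dpn), 0L)
  expect_equal(sum(counts$mbo), 1e4L)
  sim$truth$m <- rep(0.5, 50)
  counts2 <- simulate_digestion_reads(sim, depth = 1e5, seed = 7)
  dt <- dam_table(counts2, min_reads = 0)
  expect_lt(abs(median(dt$damratio) - 1), 0.2)
})

test_that("hemimethylation damps ratios toward 1 but preserves ranking", {
  sim <- simulate_library(n = 400, seed = 8)
  c0 <- simulate_digestion_reads(sim, depth = 4e5, h = 0, seed = 9)
  c2 <- simulate_digestion_reads(sim, depth = 4e5, h = 0.2, seed = 9)
  d0 <- dam_table(c0, min_reads = 0); d2 <- dam_table(c2, min_reads = 0)
  stopifnot(identical(d0$variant, d2$variant))
  expect_gte(cor(d0$log10_damratio, d2$log10_damratio,
                 method = "spearman"), 0.98)
  expect_lt(sd(d2$log10_damratio), sd(d0$log10_damratio))
})

test_that("read pools and count tables are two views of one draw", {
  sim <- simulate_library(n = 60, seed = 12)
  pools <- simulate_digestion_reads(sim, depth = 2000, seed = 13,
                                    as_reads = TRUE)
  expect_equal(lengths(pools)[["dpn"]], 2000L)
  counts <- simulate_digestion_reads(sim, depth = 2000, seed = 13)
  got <- extract_variant(pools$mbo, sim$template)
  expect_true(all(is.na(got$reason)))
  tab <- table(got$variant)
  expect_equal(as.integer(tab),
               counts$mbo[match(names(tab), counts$variant)])
})

test_that("sequencing errors break exact anchors at the expected rate", {
  sim <- simulate_library(n = 30, seed = 14)
  pools <- simulate_digestion_reads(sim, depth = 300, seed = 15,
                                    as_reads = TRUE, error_rate = 0.01)
  got <- extract_variant(pools$uncut, sim$template)
  frac_rejected <- mean(!is.na(got$reason))
  # read length 119: P(>=1 error) = 1 - 0.99^119 ~ 0.70, minus errors
  # falling in the 32 variant positions that still pass the anchors
  expect_gt(frac_rejected, 0.4)
  expect_lt(frac_rejected, 0.85)
})

test_that("simulated RNA-seq reads carry planted lengths and barcodes", {
  tpl <- elm_template("utr_strong")
  sim <- simulate_library(n = 40, template = tpl, seed = 16)
  reads <- simulate_rnaseq(sim, depth = 2000, seed = 17)
  expect_true(all(substr(reads, 1, 6) == "ACGTGT"))
  expect_true(all(grepl("ATGAAGAAAAATCG", reads, fixed = TRUE)))
  expect_error(simulate_rnaseq(simulate_library(n = 40, seed = 1), 100),
               "UTR-screen")
})
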