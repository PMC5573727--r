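test_that("position_base_odds matches the direct arithmetic oracle", {
  # 600/1000 A in high vs 300/1000 A in low at position 1
  set.seed(1)
  high <- c(rep("AC", 600), rep("CC", 400))
  low <- c(rep("AC", 300), rep("CC", 700))
  tab <- position_base_odds(high, low)
  cell <- tab[tab$position == 1 & tab$base == "A", ]
  oracle <- log2((600.5 / 400.5) / (300.5 / 700.5))
  expect_equal(cell$log2_odds, oracle, tolerance = 1e-12)
  expect_equal(oracle, 1.80, tolerance = 0.01)
  expect_equal(cell$count_high, 600L)
  expect_lt(cell$p_bonf, 0.05)
})

test_that("odds table is zero for identical sets and negates under class swap", {
  set.seed(2)
  s <- random_seqs(300, 6)
  same <- position_base_odds(s, s)
  expect_true(all(same$log2_odds == 0))
  high <- random_seqs(200, 6); low <- random_seqs(200, 6)
  ab <- position_base_odds(high, low)
  ba <- position_base_odds(low, high)
  expect_equal(ab$log2_odds, -ba$log2_odds)
  expect_equal(ab$p, ba$p)
  # Bonferroni bounds
  expect_true(all(ab$p_bonf >= ab$p - 1e-15))
  expect_true(all(ab$p_bonf <= 1))
  expect_error(position_base_odds(high, random_seqs(10, 7)), "length")
})

test_that("odds vanish for two samples from one generator at large n", {
  set.seed(3)
  probs <- c(0.4, 0.1, 0.2, 0.3)
  a <- random_seqs(1e5, 8, probs)
  b <- random_seqs(1e5, 8, probs)
  tab <- position_base_odds(a, b)
  expect_lt(max(abs(tab$log2_odds)), 0.1)
})

test_that("a planted base enrichment is the table's top cell", {
  set.seed(4)
  L <- 10
  low <- random_seqs(2000, L)
  high <- random_seqs(2000, L)
  # enrich A at position 4 in the high class
  swap <- runif(2000) < 0.5
  substr(high[swap], 4, 4) <- "A"
  tab <- position_base_odds(high, low)
  top <- tab[which.max(tab$log2_odds), ]
  expect_equal(top$position, 4)
  expect_equal(top$base, "A")
})

test_that("motif groups with different ratio distributions separate by t-test", {
  set.seed(5)
  seqs <- c(paste0("TGA", random_seqs(200, 7)),
            paste0("TGC", random_seqs(200, 7)))
  ratios <- c(rnorm(200, 0, 1), rnorm(200, 1, 1))
  res <- motif_group_compare(seqs, ratios, list(TGA = "TGA", TGC = "TGC"),
                             anchor = 1)
  expect_lt(res$p, 1e-10)
  expect_equal(res$mean2 - res$mean1, 1, tolerance = 0.25)
  groups <- attr(res, "groups")
  expect_equal(groups$n, c(200L, 200L))
  # identical groups: no signal
  res0 <- motif_group_compare(rep(c("TGAAA", "TGCAA"), each = 100),
                              rep(rnorm(100), 2),
                              list(TGA = "TGA", TGC = "TGC"))
  expect_lt(abs(res0$t), 1e-10)
  expect_gt(res0$p, 0.999)
})

test_that("alternative Pribnow scanning finds planted and no spurious boxes", {
  tpl <- elm_template("promoter")
  # TATAAT at N25 zero-based offset 3 -> screen coordinate -34
  v <- paste0("CCC", "TATAAT", strrep("C", 16), strrep("C", 7))
  hits <- scan_alternative_pribnow(v, tpl)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$motif, "TATAAT")
  expect_equal(hits$position, -34)
  # motif-free sequence
  expect_equal(nrow(scan_alternative_pribnow(strrep("C", 32), tpl)), 0L)
})

test_that("Pribnow scan counts equal an overlap-aware regex oracle", {
  set.seed(6)
  tpl <- elm_template("promoter")
  motifs <- c("TATAAT", "TAAAAT", "TACAAT", "TAGAAT")
  vs <- random_seqs(400, 32, probs = c(0.45, 0.05, 0.05, 0.45))
  hits <- scan_alternative_pribnow(vs, tpl)
  spans <- paste0(substr(vs, 1, 25), "TATAAT", substr(vs, 26, 32))
  oracle <- sum(sapply(spans, function(s) {
    found <- unlist(lapply(motifs, function(m) {
      starts <- gregexpr(paste0("(?=", m, ")"), s, perl = TRUE)[[1]]
      starts[starts > 0]
    }))
    sum(found != 26)  # exclude the fixed box slot
  }))
  expect_equal(nrow(hits), oracle)
})

test_that("alternative start codons are reported with frame and distance", {
  # ATG starting at -12 within a 25-nt UTR
  utr <- paste0(strrep("C", 13), "ATG", strrep("C", 9))
  hits <- detect_alt_start_codons(utr)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$position, -12)
  expect_equal(hits$distance, 12)
  expect_true(hits$in_frame)
  expect_equal(nrow(detect_alt_start_codons(strrep("C", 25))), 0L)
  # extended codon set
  utr2 <- paste0(strrep("C", 5), "GTG", strrep("C", 17))
  expect_equal(nrow(detect_alt_start_codons(utr2)), 0L)
  ext <- detect_alt_start_codons(utr2, codon_set = c("ATG", "GTG", "TTG"))
  expect_equal(ext$codon, "GTG")
  expect_false(ext$in_frame)  # distance 20
})

test_that("start-codon scan equals a substring-search oracle", {
  set.seed(7)
  for (u in random_seqs(300, 25)) {
    hits <- detect_alt_start_codons(u)
    starts <- gregexpr("(?=ATG)", u, perl = TRUE)[[1]]
    expect_equal(nrow(hits), sum(starts > 0))
  }
})

test_that("SD-like elements are scored by complementarity run length", {
  utr <- paste0(strrep("C", 10), "AGGAGG", strrep("C", 9))
  sc <- sd_score(utr)
  expect_true(sc$has_sd)
  expect_equal(sc$run, 6L)
  polyc <- sd_score(strrep("C", 25))
  expect_false(polyc$has_sd)
  expect_equal(polyc$run, 0L)
  # partial run below the default threshold
  utr3 <- paste0(strrep("C", 12), "AGG", strrep("C", 10))
  sc3 <- sd_score(utr3)
  expect_false(sc3$has_sd)
  expect_equal(sc3$run, 3L)
})
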