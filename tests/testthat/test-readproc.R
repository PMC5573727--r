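tpl_prom <- elm_template("promoter")
tpl_utr <- elm_template("utr_strong")

test_that("demultiplex assigns reads by inline index and rejects unknowns", {
  map <- c(AAC = "uncut", GGT = "dpn", TTA = "mbo")
  reads <- paste0(c("AAC", "GGT", "TTA"), "ACGTACGT")
  out <- demultiplex(reads, map)
  expect_equal(out$uncut, "ACGTACGT")
  expect_equal(out$dpn, "ACGTACGT")
  expect_equal(out$mbo, "ACGTACGT")
  expect_equal(out$n_rejected, 0L)

  out2 <- demultiplex(c(reads, "CCCACGTACGT"), map)
  expect_equal(out2$n_rejected, 1L)
  expect_equal(out2$rejected, "CCCACGTACGT")

  expect_error(demultiplex(reads, c(AAC = "uncut", AAC = "dpn")),
               "distinct")
})

test_that("extract_variant recovers the planted variant from a perfect read", {
  set.seed(7)
  v <- random_seqs(5, 32)
  reads <- template_read(v, tpl_prom)
  got <- extract_variant(reads, tpl_prom)
  expect_equal(got$variant, v)
  expect_true(all(is.na(got$reason)))
  # identity case: all-A randomized region
  vA <- strrep("A", 32)
  expect_equal(extract_variant(template_read(vA, tpl_prom), tpl_prom)$variant,
               vA)
})

test_that("anchor mismatches, N bases and short reads are rejected by reason", {
  v <- strrep("A", 32)
  read <- template_read(v, tpl_prom)
  bad_dam <- paste0("C", substr(read, 2, nchar(read)))
  expect_equal(extract_variant(bad_dam, tpl_prom)$reason, "anchor_dam")
  # one mismatch inside the upstream anchor
  n <- nchar(read)
  bad_up <- paste0(substr(read, 1, n - 1), "A")
  expect_equal(extract_variant(bad_up, tpl_prom)$reason, "anchor_upstream")
  # break the fixed Pribnow box inside the span
  bad_prib <- read
  substr(bad_prib, 34 + 8, 34 + 8) <- "G"
  expect_equal(extract_variant(bad_prib, tpl_prom)$reason, "anchor_pribnow")
  # N inside the variant region
  nread <- read
  substr(nread, 35, 35) <- "N"
  expect_equal(extract_variant(nread, tpl_prom)$reason, "ambiguous_base")
  expect_equal(extract_variant("ACGT", tpl_prom)$reason, "too_short")
})

test_that("extraction is orientation-idempotent", {
  set.seed(11)
  v <- random_seqs(20, 25)
  reads <- template_read(v, tpl_utr)
  a <- extract_variant(reads, tpl_utr, orientation = "reverse")
  b <- extract_variant(revcomp(reads), tpl_utr, orientation = "sense")
  expect_identical(a$variant, b$variant)
})

test_that("floating anchor search tolerates offsets and flags bad spacing", {
  v <- random_seqs(3, 25)
  reads <- paste0("GGGG", template_read(v, tpl_utr), "TT")
  fixed <- extract_variant(reads, tpl_utr)
  expect_true(all(fixed$reason == "anchor_dam"))
  float <- extract_variant(reads, tpl_utr, floating = TRUE)
  expect_equal(float$variant, v)
  # an extra base between anchor and variant breaks the spacing
  bad <- paste0(tpl_utr$anchor_dam, "A", revcomp(v[1]), tpl_utr$anchor_upstream)
  expect_equal(extract_variant(bad, tpl_utr, floating = TRUE)$reason,
               "length_mismatch")
})

test_that("tabulate_variants counts exact multisets per condition", {
  tab <- tabulate_variants(mbo = c("AAA", "AAA", "CCC"))
  expect_equal(tab$mbo[tab$variant == "AAA"], 2L)
  expect_equal(tab$mbo[tab$variant == "CCC"], 1L)
  expect_equal(attr(tab, "totals")[["mbo"]], 3L)
  expect_equal(attr(tab, "totals")[["dpn"]], 0L)

  empty <- tabulate_variants()
  expect_equal(nrow(empty), 0L)
  expect_equal(unname(attr(empty, "totals")), c(0L, 0L, 0L))
})

test_that("tabulation matches an independent recount on multinomial draws", {
  set.seed(3)
  pool <- random_seqs(50, 25)
  draws <- sample(pool, 1e4, replace = TRUE,
                  prob = runif(50))
  tab <- tabulate_variants(dpn = draws)
  oracle <- table(draws)
  expect_equal(tab$dpn[match(names(oracle), tab$variant)],
               as.integer(oracle))
  # order invariance
  tab2 <- tabulate_variants(dpn = rev(draws))
  expect_identical(tab, tab2)
})

test_that("zero-error simulated FASTQ round trip recovers counts exactly", {
  sim <- simulate_library(n = 150, template = tpl_prom, seed = 42)
  pools <- simulate_digestion_reads(sim, depth = 6000, seed = 5,
                                    as_reads = TRUE)
  paths <- file.path(tempdir(), paste0(names(pools), ".fq"))
  names(paths) <- names(pools)
  for (p in names(pools)) write_fastq(pools[[p]], paths[[p]])
  counts <- count_reads(tpl_prom, paths[["uncut"]], paths[["dpn"]],
                        paths[["mbo"]])
  # 100% acceptance
  expect_equal(sum(vapply(attr(counts, "rejected"), sum, numeric(1))), 0)
  expect_equal(unname(attr(counts, "totals")), rep(6000L, 3))
  # exact multiset recovery against the directly simulated count table
  direct <- simulate_digestion_reads(sim, depth = 6000, seed = 5)
  direct <- direct[direct$uncut + direct$dpn + direct$mbo > 0, ]
  expect_equal(counts$variant, direct$variant)
  expect_equal(counts$uncut, direct$uncut)
  expect_equal(counts$dpn, direct$dpn)
  expect_equal(counts$mbo, direct$mbo)
})
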