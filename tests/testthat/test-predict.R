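test_that("one-hot encoding follows the A/C/G/T orthonormal convention", {
  expect_equal(unname(one_hot("A")[1, ]), c(1L, 0L, 0L, 0L))
  expect_equal(unname(one_hot("ACGT")[1, ]),
               c(1L, 0L, 0L, 0L, 0L, 1L, 0L, 0L,
                 0L, 0L, 1L, 0L, 0L, 0L, 0L, 1L))
  set.seed(1)
  s <- random_seqs(25, 12)
  x <- one_hot(s)
  expect_equal(one_hot_decode(x), s)
  expect_true(all(rowSums(x) == 12))
  expect_error(one_hot("ACGN"), "non-ACGT")
})

test_that("naive Bayes separates a deterministic feature and is calibrated on noise", {
  set.seed(2)
  n <- 600
  lab <- rep(c("high", "low"), each = n / 2)
  seqs <- ifelse(lab == "high", paste0("A", random_seqs(n, 5)),
                 paste0("C", random_seqs(n, 5)))
  x <- one_hot(seqs)
  m <- train_nb(x, lab)
  expect_equal(auc(lab, predict_nb(m, x)), 1)
  # label-independent features -> chance AUC on held-out data
  set.seed(3)
  xn <- one_hot(random_seqs(3000, 10))
  labn <- rep(c("high", "low"), 1500)
  mn <- train_nb(xn[1:2000, ], labn[1:2000])
  expect_lt(abs(auc(labn[2001:3000], predict_nb(mn, xn[2001:3000, ])) - 0.5),
            0.05)
  expect_error(train_nb(xn, rep("high", 3000)), "both classes")
})

test_that("naive Bayes posteriors are invariant under training-set duplication", {
  set.seed(4)
  x <- one_hot(random_seqs(200, 8))
  lab <- rep(c("high", "low"), 100)
  m1 <- train_nb(x, lab)
  m2 <- train_nb(rbind(x, x), c(lab, lab))
  p1 <- predict_nb(m1, x); p2 <- predict_nb(m2, x)
  # only the Laplace smoothing shrinks with n: posteriors barely move
  expect_equal(p1, p2, tolerance = 0.02)
  expect_gt(cor(p1, p2, method = "spearman"), 0.999)
})

test_that("naive Bayes agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(5)
  sim <- simulate_library(1500, template = elm_template("utr_strong"),
                          seed = 6)
  x <- one_hot(sim$truth$variant)
  lab <- sim$truth$label
  tr <- 1:1000; te <- 1001:1500
  ours <- predict_nb(train_nb(x[tr, ], lab[tr]), x[te, ])
  df <- as.data.frame(seq_matrix(sim$truth$variant))
  ref <- e1071::naiveBayes(df[tr, ], factor(lab[tr]), laplace = 1)
  theirs <- predict(ref, df[te, ], type = "raw")[, "high"]
  expect_gt(cor(ours, theirs, method = "spearman"), 0.98)
  expect_lt(abs(auc(lab[te], ours) - auc(lab[te], theirs)), 0.02)
})

test_that("SVR recovers a smooth function within the epsilon tube", {
  set.seed(7)
  x <- matrix(runif(120), ncol = 1)
  y <- 2 * x[, 1]
  m <- train_svr(x, y, epsilon = 0.01, C = 100, gamma = 1)
  xt <- matrix(seq(0.05, 0.95, length.out = 50), ncol = 1)
  expect_lt(max(abs(predict_svr(m, xt) - 2 * xt[, 1])), 0.011 + 0.02)
  expect_gt(m$train_r, 0.999)
  expect_error(train_svr(x, rep(1, 120)), "constant")
  expect_error(train_svr(x[1:10, , drop = FALSE], y[1:10]), "at least 50")
})

test_that("permuted responses yield no out-of-sample correlation", {
  set.seed(8)
  v <- random_seqs(1000, 15)
  x <- one_hot(v)
  y <- rnorm(1000)
  m <- train_svr(x[1:500, ], sample(y[1:500]))
  r <- cor(predict_svr(m, x[501:1000, ]), y[501:1000])
  expect_lt(abs(r), 0.1)
})

test_that("feature building appends positive-correlation folding windows only", {
  set.seed(9)
  tpl <- elm_template("utr_strong")
  v <- random_seqs(60, 25)
  mrna <- utr_mrna(v, tpl)
  dg <- fold_energy(substr(mrna, pos_to_index(-20), pos_to_index(8)))
  ratios <- dg + rnorm(60, 0, 0.1)   # positive dG correlation at the window
  scan <- window_scan(v, ratios, tpl, start_range = c(-22, -18),
                      end_range = c(6, 10))
  feats <- build_features(v, scan, tpl)
  wins <- attr(feats, "windows")
  expect_gt(nrow(wins), 0)
  expect_true(any(wins$start == -20 & wins$end == 8))
  expect_equal(ncol(feats), 4 * 25 + nrow(wins))
  # no positive window -> plain one-hot with a warning
  scan_neg <- scan
  scan_neg$r <- -abs(scan_neg$r)
  expect_warning(f0 <- build_features(v, scan_neg, tpl), "sequence features")
  expect_equal(ncol(f0), 100)
})

test_that("AUC follows the rank definition with half-credit ties", {
  expect_equal(auc(c("high", "high", "low", "low"), c(4, 3, 2, 1)), 1)
  expect_equal(auc(c("high", "low", "high", "low"), rep(1, 4)), 0.5)
  set.seed(10)
  lab <- sample(c("high", "low"), 200, replace = TRUE)
  sc <- sample(1:30, 200, replace = TRUE)   # many ties
  expect_equal(auc(lab, sc), oracle_auc(lab == "high", sc), tolerance = 1e-12)
  expect_equal(auc(lab, sc) + auc(lab, -sc), 1)
  expect_error(auc(rep("high", 5), 1:5), "both classes")
})

test_that("AUC matches pROC on a tied instance", {
  skip_if_not_installed("pROC")
  set.seed(11)
  lab <- sample(c("high", "low"), 150, replace = TRUE)
  sc <- rnorm(150)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = factor(lab, levels = c("low", "high")), predictor = sc,
    quiet = TRUE, direction = "<")))
  expect_equal(auc(lab, sc), ref, tolerance = 1e-12)
})
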