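test_that("single-descriptor PLS equals simple least squares", {
  set.seed(21)
  x <- matrix(rnorm(12), 12, 1)
  y <- 2.5 * x[, 1] + rnorm(12, 0, 0.2)
  fit <- pls_train(x, y, 1)
  ref <- lm(y ~ x)
  expect_equal(unname(fit$b), unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(unname(fit$b0), unname(coef(ref)[1]), tolerance = 1e-10)
})

test_that("PLS agrees with an independent implementation on random problems", {
  set.seed(31)
  for (rep in 1:3) {
    X <- matrix(rnorm(160), 8, 20)
    colnames(X) <- paste0("v", seq_len(ncol(X)))
    y <- rnorm(8)
    for (cc in c(1, 3, 5)) {
      mine <- predict(pls_train(X, y, cc), X)
      ref <- mixOmics::pls(X, y, ncomp = cc, mode = "regression",
                           scale = FALSE)
      expect_equal(unname(mine),
                   unname(predict(ref, X)$predict[, 1, cc]),
                   tolerance = 1e-6)
    }
  }
})

test_that("a full-rank linear response is interpolated at full capacity", {
  set.seed(41)
  X <- matrix(rnorm(60), 10, 6)
  beta <- rnorm(6)
  y <- drop(X %*% beta) + 1
  fit <- pls_train(X, y, 6)
  expect_lt(max(abs(y - predict(fit, X))), 1e-8)
  st <- fit_statistics(fit, X, y)
  expect_equal(st$r2, 1, tolerance = 1e-10)
  expect_equal(st$see, 0, tolerance = 1e-6)
})

test_that("training validates its inputs", {
  X <- matrix(rnorm(20), 5, 4)
  expect_error(pls_train(X, rep(1, 5), 2), "zero variance")
  expect_error(pls_train(X, rnorm(5), 0), "ncomp")
  expect_error(pls_train(X, rnorm(5), 5), "ncomp")
  expect_error(pls_train(X[1:2, ], rnorm(2), 1), "at least 3")
})

test_that("LOO cross-validation equals an explicit per-fold refit loop", {
  set.seed(51)
  X <- matrix(rnorm(9 * 30), 9, 30)
  y <- drop(X[, 1:3] %*% c(1, -1, 0.5)) + rnorm(9, 0, 0.3)
  cmax <- 4
  cv <- loo_cv(X, y, cmax)
  for (cc in seq_len(cmax)) {
    sqerr <- numeric(nrow(X))
    for (i in seq_len(nrow(X))) {
      fold <- pls_train(X[-i, , drop = FALSE], y[-i], cc)
      sqerr[i] <- (y[i] - predict(fold, X[i, , drop = FALSE]))^2
    }
    expect_identical(cv$table$press[cc], sum(sqerr))
    expect_equal(cv$table$q2[cc], 1 - sum(sqerr) / sum((y - mean(y))^2))
    expect_equal(cv$table$sep[cc], sqrt(sum(sqerr) / (length(y) - cc - 1)))
  }
  expect_error(loo_cv(X, rep(2, 9), 3), "zero total sum of squares")
  expect_error(loo_cv(X, y, 50), "c_max")
})

test_that("component selection maximizes q2 with smallest-c tie-breaking", {
  set.seed(61)
  X <- matrix(rnorm(10 * 8), 10, 8)
  y <- drop(X[, 1] * 2) + rnorm(10, 0, 0.1)
  cv <- loo_cv(X, y, 5)
  expect_equal(cv$optimal, which.max(cv$table$q2))
  cv_sep <- loo_cv(X, y, 5, selector = "sep")
  expect_equal(cv_sep$optimal, which.min(cv_sep$table$sep))
})

test_that("synthetic field models validate and recover the coefficient signs", {
  for (s in c(20220309, 20220310, 20220311)) {
    ds <- generate_qsar_dataset(synthetic_qsar_spec(seed = s))
    cv <- loo_cv(ds$block$X, ds$y, c_max = 6)
    expect_gt(max(cv$table$q2), 0.5)
    # capacity must cover the true dimensionality for sign recovery
    fit <- pls_train(ds$block$X, ds$y, ds$spec$support_size)
    v <- apply(ds$block$X, 2, sd) * fit$b
    expect_equal(unname(sign(v[ds$support])), sign(ds$beta[ds$support]))
    # cross-validated q2 never beats the training r2
    full <- pls_train(ds$block$X, ds$y, cv$optimal)
    expect_lte(max(cv$table$q2),
               fit_statistics(full, ds$block$X, ds$y)$r2)
  }
})

test_that("r-squared equals the squared correlation of fit and response", {
  set.seed(71)
  X <- matrix(rnorm(80), 10, 8)
  y <- drop(X[, 1:2] %*% c(1, 2)) + rnorm(10, 0.5)
  fit <- pls_train(X, y, 3)
  st <- fit_statistics(fit, X, y)
  expect_equal(st$r2, cor(y, predict(fit, X))^2, tolerance = 1e-10)
  # SEE/F need N > ncomp + 1
  Xs <- matrix(rnorm(50), 5, 10)
  ys <- rnorm(5)
  expect_error(fit_statistics(pls_train(Xs, ys, 4), Xs, ys), "exceed")
})

test_that("field contributions accumulate |coef| x sd per block", {
  blk <- pae_block()
  t2 <- load_fixture("table2")
  y <- t2$I[match(rownames(blk$X), t2$compound)]
  fit <- pls_train(blk$X, y, 4)
  contrib <- field_contributions(fit, blk)
  expect_equal(sum(contrib), 100, tolerance = 1e-9)
  expect_true(all(contrib >= 0))
  # brute-force re-accumulation
  sds <- apply(blk$X, 2, sd)
  for (k in blk$kinds) {
    manual <- sum(abs(fit$b[blk$col_kind == k]) * sds[blk$col_kind == k])
    total <- sum(abs(fit$b) * sds)
    expect_equal(unname(contrib[k]), 100 * manual / total, tolerance = 1e-9)
  }
  # coefficients alive in exactly one block put 100% there
  fake <- fit
  fake$b[blk$col_kind != "H"] <- 0
  ch <- field_contributions(fake, blk)
  expect_equal(unname(ch["H"]), 100)
  expect_equal(unname(ch["S"]), 0)
})

test_that("two identical blocks with identical coefficients split 50/50", {
  m <- point_molecule(rbind(c(0, 0, 0), c(1, 1, 1)), radius = 1.7,
                      logp = 1.7^3)  # H weights equal S weights
  ms <- lapply(1:5, function(i) {
    mm <- m
    mm$atoms$x <- mm$atoms$x + i / 10
    mm$name <- paste0("m", i)
    mm
  })
  g <- build_grid(ms, margin = 2, spacing = 2)
  blk <- assemble_descriptors(ms, g, kinds = c("S", "H"))
  y <- rnorm(5)
  set.seed(81)
  fit <- pls_train(blk$X, y, 2)
  contrib <- field_contributions(fit, blk)
  expect_equal(unname(contrib["S"]), unname(contrib["H"]), tolerance = 1e-6)
})

test_that("contour maps threshold stdev*coeff at the stated percentiles", {
  ds <- generate_qsar_dataset(synthetic_qsar_spec(seed = 20220309))
  fit <- pls_train(ds$block$X, ds$y, 4)
  cm <- contour_map(fit, ds$block, favored_pct = 80, disfavored_pct = 20)
  sds <- apply(ds$block$X, 2, sd)
  v <- sds * fit$b
  for (k in ds$block$kinds) {
    vk <- v[ds$block$col_kind == k]
    qf <- quantile(vk, 0.8, names = FALSE)
    qd <- quantile(vk, 0.2, names = FALSE)
    expect_equal(cm$kinds[[k]]$favored, unname(which(vk > qf & vk > 0)))
    expect_equal(cm$kinds[[k]]$disfavored, unname(which(vk < qd & vk < 0)))
  }
  # all-zero coefficients mark nothing
  z <- fit; z$b[] <- 0
  cz <- contour_map(z, ds$block)
  expect_true(all(sapply(cz$kinds, function(k) length(k$favored) == 0)))
  # extreme percentiles: 100 selects nothing, near-0 selects every
  # correctly-signed point
  cx <- contour_map(fit, ds$block, favored_pct = 100, disfavored_pct = 0)
  for (k in ds$block$kinds) {
    vk <- v[ds$block$col_kind == k]
    expect_length(cx$kinds[[k]]$favored, 0)
    expect_length(cx$kinds[[k]]$disfavored, 0)
  }
  clo <- contour_map(fit, ds$block, favored_pct = 1e-9, disfavored_pct = 0)
  k1 <- ds$block$kinds[1]
  vk1 <- v[ds$block$col_kind == k1]
  expect_equal(clo$kinds[[k1]]$favored,
               unname(which(vk1 > 0 & vk1 > min(vk1))))
  expect_error(contour_map(fit, ds$block, 20, 80), "exceed")
})

test_that("external validation runs on the published train/test split", {
  blk <- pae_block()
  t2 <- load_fixture("table2")
  split <- t2$set[match(rownames(blk$X), t2$compound)]
  train <- grepl("a", split)   # template molecule sits in both sets
  test <- grepl("b", split)
  expect_equal(sum(train), 10L)
  expect_equal(sum(test), 4L)
  y <- t2$I[match(rownames(blk$X), t2$compound)]
  fit <- pls_train(blk$X[train, ], y[train], 4)
  r2p <- r2_pred(y[test], predict(fit, blk$X[test, ]), y[train])
  expect_lte(r2p, 1)
  # brute-force the definition
  expect_equal(r2p, 1 - sum((y[test] - predict(fit, blk$X[test, ]))^2) /
                 sum((y[test] - mean(y[train]))^2))
  # a perfect predictor scores exactly 1
  expect_equal(r2_pred(y[test], y[test], y[train]), 1)
  expect_error(r2_pred(rep(mean(y[train]), 2), 1:2, y[train]), "undefined")
})

test_that("report writers round-trip statistics and index tables", {
  blk <- pae_block()
  t2 <- load_fixture("table2")
  y <- t2$I[match(rownames(blk$X), t2$compound)]
  cv <- loo_cv(blk$X, y, 4)
  fit <- pls_train(blk$X, y, cv$optimal)
  st <- fit_statistics(fit, blk$X, y)
  contrib <- field_contributions(fit, blk)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_statistics_table(cv, st, contrib, tmp)
  back <- read.csv(tmp)
  expect_equal(back$n, cv$optimal)
  expect_equal(back$q2, cv$table$q2[cv$optimal])
  expect_equal(back$r2, st$r2)
  expect_equal(back$S + back$E + back$H + back$D + back$A, 100,
               tolerance = 1e-6)

  cfg <- pae_index_config()
  res <- index_pipeline(load_fixture("table1"), cfg$directions, cfg$weights)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_index_report(res, csv = csv, json = js)
  expect_equal(read.csv(csv)$I, res$report$I)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(meta$provenance$lc50$max, max(load_fixture("table1")$lc50))
  expect_equal(meta$full$I, res$full$I, tolerance = 1e-12)
})

test_that("a pure-noise column barely moves fixed-capacity predictions", {
  set.seed(91)
  ds <- generate_qsar_dataset(synthetic_qsar_spec(seed = 20220310))
  fit <- pls_train(ds$block$X, ds$y, 3)
  Xplus <- cbind(ds$block$X, noise = rnorm(nrow(ds$block$X), 0, 1e-6))
  fit2 <- pls_train(Xplus, ds$y, 3)
  expect_equal(predict(fit, ds$block$X), predict(fit2, Xplus),
               tolerance = 1e-4)
})
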