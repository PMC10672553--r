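make_wide <- function(seed = 10, n = c(BME = 8L, INJ = 8L, OST = 8L)) {
  tab <- extract_cohort(generate_cohort(tiny_spec(seed = seed, n = n))$samples)
  join_sequences(tab)
}

test_that("combination enumeration matches the binomial closed form", {
  top <- paste0("f", 1:25)
  combos <- enumerate_combinations(top, k_top = 20L, max_size = 5L)
  expect_length(combos, sum(choose(20, 1:5)))   # 21699
  expect_length(combos, 21699L)
  keys <- vapply(combos, paste, "", collapse = "|")
  expect_false(anyDuplicated(keys) > 0)
  expect_lte(max(lengths(combos)), 5L)

  expect_length(enumerate_combinations(top[1:3], 3L, 2L), 6L)
  expect_error(enumerate_combinations(top[1:3], 5L, 2L), "exceeds")
})

test_that("rank_importance returns a permutation and finds planted signal", {
  # synthetic wide table: 2 informative of 20 columns
  set.seed(11)
  n <- 90
  X <- matrix(rnorm(n * 20), n, 20)
  y <- rep(c("BME", "INJ", "OST"), each = 30)
  X[, 3] <- X[, 3] + (y == "BME") * 2
  X[, 7] <- X[, 7] + (y == "OST") * 2
  fit <- rf_fit(X, y, ntree = 200, seed = 1)
  imp <- sort(fit$importance, decreasing = TRUE)
  expect_true(all(c("3", "7") %in% gsub("V", "", names(imp)[1:4])) ||
              all(which(rank(-fit$importance) <= 4) %in% c(3, 7, 1:20)))
  expect_true(all(order(-fit$importance)[1:2] %in% c(3, 7)))

  tab <- extract_cohort(generate_cohort(tiny_spec(seed = 12))$samples)
  rk <- rank_importance(tab, seed = 2, ntree = 100)
  expect_setequal(rk, marrowtex:::wide_feature_names())
})

test_that("balance_training_set: bookkeeping, fixed point, convexity", {
  set.seed(13)
  X <- matrix(rnorm(121 * 3), 121, 3)
  y <- factor(rep(c("BME", "INJ", "OST"), times = c(41, 37, 43)))
  bal <- balance_training_set(X, y, factor = 2, seed = 1)
  expect_true(all(table(bal$y) == max(table(bal$y))))
  expect_true(all(table(bal$y) >= 86))

  # factor 1 on already-balanced input is the identity
  Xb <- X[1:90, ]; yb <- factor(rep(c("BME", "INJ", "OST"), each = 30))
  bal2 <- balance_training_set(Xb, yb, factor = 1, seed = 1)
  expect_equal(bal2$X, Xb, ignore_attr = TRUE)
  expect_equal(as.character(bal2$y), as.character(yb))
  expect_true(all(grepl("^orig:", bal2$provenance)))

  # synthetic points lie on segments between same-class source points
  bal3 <- balance_training_set(X, y, factor = 2, seed = 3)
  syn <- which(bal3$provenance == "smote")
  real <- bal3$X[bal3$provenance != "smote", , drop = FALSE]
  realy <- bal3$y[bal3$provenance != "smote"]
  for (k in head(syn, 15)) {
    cls <- bal3$y[k]
    base <- real[realy == cls, , drop = FALSE]
    p <- bal3$X[k, ]
    # on a segment: p = a + lam (b - a) for some pair (a, b) and lam in [0,1]
    on_seg <- FALSE
    for (i in seq_len(nrow(base))) {
      d <- sweep(base, 2, base[i, ])
      v <- p - base[i, ]
      for (j in seq_len(nrow(base))) {
        if (j == i || sum(d[j, ]^2) < 1e-20) next
        lam <- sum(v * d[j, ]) / sum(d[j, ]^2)
        if (lam >= -1e-9 && lam <= 1 + 1e-9 &&
            sum((v - lam * d[j, ])^2) < 1e-16) { on_seg <- TRUE; break }
      }
      if (on_seg) break
    }
    expect_true(on_seg)
  }

  expect_warning(
    balance_training_set(matrix(rnorm(15), 5, 3),
                         factor(c("a", "a", "a", "a", "b")), factor = 2,
                         seed = 1),
    "k = ")
})

test_that("classification metrics match the printed formulas", {
  # 20 samples, confusion TP=9 TN=8 FP=1 FN=2 in a binary reading:
  # overall accuracy is correct/total
  truth <- factor(c(rep("BME", 11), rep("INJ", 9)),
                  levels = c("BME", "INJ", "OST"))
  prob <- matrix(0, 20, 3, dimnames = list(NULL, c("BME", "INJ", "OST")))
  # 9 BME right, 2 BME predicted INJ; 8 INJ right, 1 INJ predicted BME
  prob[1:9, "BME"] <- 1
  prob[10:11, "INJ"] <- 1
  prob[12:19, "INJ"] <- 1
  prob[20, "BME"] <- 1
  m <- classification_metrics(truth, prob)
  expect_equal(m$acc, 17 / 20)
  expect_equal(unname(m$tpr["BME"]), 9 / 11)
  expect_equal(unname(m$tpr["INJ"]), 8 / 9)

  # AUC via rank statistic: perfect ranking -> 1
  sc <- c(0.9, 0.8, 0.2, 0.1)
  expect_equal(marrowtex:::auc_binary(sc, c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(marrowtex:::auc_binary(sc, c(FALSE, FALSE, TRUE, TRUE)), 0)
  expect_equal(marrowtex:::auc_binary(c(1, 1, 1, 1),
                                      c(TRUE, FALSE, TRUE, FALSE)), 0.5)
})

test_that("evaluate_combination separates separable classes and guards leakage", {
  set.seed(14)
  n <- 120
  wide <- data.frame(subject_id = sprintf("s%03d", 1:n),
                     group = rep(c("BME", "INJ", "OST"), each = n / 3),
                     stringsAsFactors = FALSE)
  wide$pdfse_fo_mean <- rnorm(n) + c(BME = 0, INJ = 6, OST = 12)[wide$group]
  wide$stir_fo_mean <- rnorm(n)
  r <- evaluate_combination(wide, "pdfse_fo_mean", seed = 1,
                            eval_control(ntree_grid = 100L,
                                         depth_grid = Inf, cv_folds = 0L))
  expect_equal(r$acc, 1)
  expect_equal(unname(r$auc), 1)
  expect_true(all(r$tpr == 1))

  # leakage guard: balancing provenance never references a test subject
  expect_length(intersect(r$train_subjects, r$test_subjects), 0)

  # paper-order mode leaks by construction: provenance covers everything
  rp <- evaluate_combination(wide, "pdfse_fo_mean", seed = 1,
                             eval_control(ntree_grid = 100L,
                                          depth_grid = Inf, cv_folds = 0L,
                                          paper_order = TRUE))
  expect_gt(length(intersect(rp$train_subjects, rp$test_subjects)), 0)
})

test_that("shuffled labels give chance-level accuracy", {
  set.seed(15)
  n <- 120
  wide <- data.frame(subject_id = sprintf("s%03d", 1:n),
                     group = sample(rep(c("BME", "INJ", "OST"), each = n / 3)),
                     stringsAsFactors = FALSE)
  wide$pdfse_fo_mean <- rnorm(n)
  wide$stir_fo_mean <- rnorm(n)
  accs <- vapply(1:10, function(s) {
    evaluate_combination(wide, c("pdfse_fo_mean", "stir_fo_mean"), seed = s,
                         eval_control(ntree_grid = 60L, depth_grid = 8L,
                                      cv_folds = 0L))$acc
  }, 1)
  expect_lt(abs(mean(accs) - 1 / 3), 0.12)
})

test_that("repeat_evaluation aggregates correctly and is deterministic", {
  wide <- make_wide(seed = 16)
  ctl <- eval_control(ntree_grid = 60L, depth_grid = 8L, cv_folds = 0L)
  rep1 <- repeat_evaluation(wide, c("pdfse_glrlm_rlv", "stir_fo_mad"),
                            n_rep = 4, base_seed = 2, control = ctl)
  expect_equal(nrow(rep1$per_rep), 4)
  expect_equal(unname(rep1$mean["acc"]), mean(rep1$per_rep$acc),
               tolerance = 1e-12)
  rep2 <- repeat_evaluation(wide, c("pdfse_glrlm_rlv", "stir_fo_mad"),
                            n_rep = 4, base_seed = 2, control = ctl)
  expect_equal(rep1$per_rep, rep2$per_rep)
  tabout <- report_table(rep1)
  expect_equal(nrow(tabout), 5)   # 4 reps + aggregate row
})

test_that("select_composite recovers a single informative feature", {
  set.seed(17)
  n <- 90
  wide <- data.frame(subject_id = sprintf("s%03d", 1:n),
                     group = rep(c("BME", "INJ", "OST"), each = n / 3),
                     stringsAsFactors = FALSE)
  for (f in marrowtex:::wide_feature_names()[1:24]) wide[[f]] <- rnorm(n)
  wide$pdfse_fo_mean <- rnorm(n) +
    c(BME = 0, INJ = 4, OST = 8)[wide$group]
  # select_composite needs a long-format table; fabricate one
  long <- do.call(rbind, lapply(c("PDFSE", "STIR"), function(sq) {
    d <- data.frame(subject_id = wide$subject_id, group = wide$group,
                    sequence = sq, stringsAsFactors = FALSE)
    for (f in descriptor_names()) {
      col <- paste0(tolower(sq), "_", f)
      d[[f]] <- if (col %in% names(wide)) wide[[col]] else rnorm(n)
    }
    d
  }))
  sel <- select_composite(long, base_seed = 1, k_top = 6L, max_size = 2L,
                          n_rep = 4L, budget = Inf,
                          control = eval_control(ntree_grid = 60L,
                                                 depth_grid = 8L,
                                                 cv_folds = 0L))
  expect_true("pdfse_fo_mean" %in% sel$composite)
})
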