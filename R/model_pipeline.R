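# Discriminant protocol: random-forest importance ranking, exhaustive small
# feature combinations, bootstrap + SMOTE class balancing (training
# partitions only, unless the paper-order fidelity flag is set), repeated
# stratified 70/30 splits with stratified k-fold CV hyperparameter
# selection, and composite-descriptor selection by per-repetition best
# combinations.

# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Fit the package's random-forest classifier
#'
#' A compact classification random forest (bootstrap + mtry Gini CART,
#' grown in C++): the default model of the evaluation protocol, standing
#' in for an ensemble random forest. Deterministic given `seed`.
#'
#' @param X numeric matrix (rows = samples).
#' @param y factor of class labels.
#' @param ntree number of trees (default 300).
#' @param mtry features tried per split (default `floor(sqrt(ncol(X)))`).
#' @param max_depth maximum tree depth (`Inf` for unlimited).
#' @param min_split minimum node size eligible for splitting.
#' @param seed RNG seed.
#' @return Object of class `mtx_forest` with elements `forest`, `levels`,
#'   `importance` (named, mean impurity decrease).
#' @export
rf_fit <- function(X, y, ntree = 300L, mtry = NULL, max_depth = Inf,
                   min_split = 2L, seed = 1L) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  stopifnot(nrow(X) == length(y))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  depth <- if (is.finite(max_depth)) as.integer(max_depth) else 64L
  f <- cpp_grow_forest(X, as.integer(y) - 1L, nlevels(y), as.integer(ntree),
                       as.integer(mtry), depth, as.integer(min_split),
                       as.integer(seed) %% .Machine$integer.max)
  imp <- as.numeric(f$importance)
  names(imp) <- colnames(X)
  structure(list(forest = f, levels = levels(y), importance = imp,
                 ntree = ntree, mtry = mtry, max_depth = max_depth),
            class = "mtx_forest")
}

#' Predict class probabilities from a fitted forest
#' @param object an `mtx_forest`.
#' @param newdata numeric matrix with the training columns.
#' @param type `"prob"` for the class-probability matrix, `"class"` for
#'   hard labels.
#' @param ... unused.
#' @return Probability matrix (columns = classes) or factor of labels.
#' @export
predict.mtx_forest <- function(object, newdata, type = c("prob", "class"),
                               ...) {
  type <- match.arg(type)
  pr <- cpp_predict_forest(object$forest, as.matrix(newdata))
  colnames(pr) <- object$levels
  if (type == "prob") return(pr)
  factor(object$levels[max.col(pr, ties.method = "first")],
         levels = object$levels)
}

# ---- metrics ---------------------------------------------------------------

# binary AUC by the rank (Mann-Whitney) statistic, ties averaged
auc_binary <- function(scores, positive) {
  npos <- sum(positive); nneg <- sum(!positive)
  if (npos == 0L || nneg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Classification metrics of one evaluated test set
#'
#' Overall accuracy (correct / total, the printed TP+TN over all-cells
#' identity), per-class true positive rate from each class's row of the
#' confusion matrix, and macro one-vs-rest AUC from the probability
#' scores.
#'
#' @param truth factor of true labels.
#' @param prob probability matrix with one column per class.
#' @return List with `acc`, `tpr` (named vector), `auc`, `confusion`.
#' @export
classification_metrics <- function(truth, prob) {
  classes <- colnames(prob)
  truth <- factor(truth, levels = classes)
  pred <- factor(classes[max.col(prob, ties.method = "first")],
                 levels = classes)
  cm <- table(truth = truth, pred = pred)
  tpr <- vapply(classes, function(cl) {
    n <- sum(cm[cl, ])
    if (n == 0) NA_real_ else cm[cl, cl] / n
  }, 1)
  aucs <- vapply(classes, function(cl) {
    auc_binary(prob[, cl], truth == cl)
  }, 1)
  list(acc = sum(diag(cm)) / sum(cm), tpr = tpr,
       auc = mean(aucs, na.rm = TRUE), confusion = cm)
}

# ---- data plumbing ---------------------------------------------------------

#' Join the two sequence channels into one row per subject
#'
#' Produces the 162-column wide design: per subject, the 81 descriptors of
#' each sequence prefixed `pdfse_` / `stir_`.
#'
#' @param table cohort feature table.
#' @return Data frame: `subject_id`, `group`, then 162 feature columns.
#' @export
join_sequences <- function(table) {
  table <- validate_feature_table(table)
  parts <- lapply(SEQUENCE_LEVELS, function(sq) {
    sub <- table[table$sequence == sq, c("subject_id", "group",
                                         descriptor_names())]
    names(sub)[-(1:2)] <- paste0(tolower(sq), "_", descriptor_names())
    sub
  })
  bad <- setdiff(union(parts[[1]]$subject_id, parts[[2]]$subject_id),
                 intersect(parts[[1]]$subject_id, parts[[2]]$subject_id))
  if (length(bad)) {
    stop("subjects missing one sequence: ", paste(head(bad, 5),
                                                  collapse = ", "),
         call. = FALSE)
  }
  wide <- merge(parts[[1]], parts[[2]], by = c("subject_id", "group"),
                sort = TRUE)
  wide[order(wide$subject_id), , drop = FALSE]
}

wide_feature_names <- function() {
  as.vector(vapply(tolower(SEQUENCE_LEVELS),
                   function(s) paste0(s, "_", descriptor_names()),
                   character(81)))
}

stratified_split <- function(y, frac = 0.7, seed = 1L) {
  idx <- with_seed(seed, {
    unlist(lapply(split(seq_along(y), y), function(ii) {
      sample(ii, max(1L, round(frac * length(ii))))
    }), use.names = FALSE)
  })
  train <- sort(idx)
  test <- setdiff(seq_along(y), train)
  if (!all(levels(droplevels(as.factor(y))) %in% unique(y[test]))) {
    stop("stratification error: a class is absent from the test partition",
         call. = FALSE)
  }
  list(train = train, test = test)
}

stratified_folds <- function(y, k = 10L, seed = 1L) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (ii in split(seq_along(y), y)) {
      fold[sample(ii)] <- rep_len(seq_len(k), length(ii))
    }
  })
  fold
}

# ---- protocol operations ---------------------------------------------------

#' Rank features by random-forest importance
#'
#' Fits the forest on the full 162-column two-sequence design against the
#' group label and returns the feature names sorted by mean
#' impurity-decrease importance, descending (ties broken by name).
#'
#' @param table cohort feature table (both sequences complete).
#' @param seed RNG seed.
#' @param ntree trees for the ranking forest (default 500).
#' @return Character vector: permutation of the 162 wide feature names.
#' @export
rank_importance <- function(table, seed = 1L, ntree = 500L) {
  wide <- join_sequences(table)
  feats <- wide_feature_names()
  fit <- rf_fit(as.matrix(wide[, feats]), wide$group, ntree = ntree,
                seed = seed)
  imp <- fit$importance
  feats[order(-imp, feats)]
}

#' Enumerate feature combinations
#'
#' All subsets of the first `k_top` features of sizes 1..`max_size`, in
#' deterministic order (by size, then lexicographically by position in
#' `top`).
#'
#' @param top ordered feature list (importance-ranked).
#' @param k_top how many leading features to combine (default 20).
#' @param max_size largest subset size (default 5).
#' @return List of character vectors.
#' @export
enumerate_combinations <- function(top, k_top = 20L, max_size = 5L) {
  if (k_top > length(top)) {
    stop(sprintf("k_top = %d exceeds the %d available features", k_top,
                 length(top)), call. = FALSE)
  }
  head_feats <- top[seq_len(k_top)]
  out <- list()
  for (sz in seq_len(min(max_size, k_top))) {
    sets <- combn(k_top, sz)
    out <- c(out, lapply(seq_len(ncol(sets)),
                         function(j) head_feats[sets[, j]]))
  }
  out
}

#' Balance a training set by bootstrap augmentation and SMOTE
#'
#' Each class is first bootstrap-resampled to `factor` times its size
#' (`factor = 1` is the identity), then minority classes are grown to the
#' majority size by SMOTE: a synthetic sample is a uniform point on the
#' segment between a class sample and one of its `k = 5` nearest
#' same-class neighbors (Euclidean); a class with fewer than 6 samples
#' falls back to `k = n - 1` with a warning.
#'
#' @param X numeric matrix of training features.
#' @param y factor of training labels.
#' @param factor augmentation factor (default 2).
#' @param seed RNG seed.
#' @return List with `X`, `y`, and `provenance`: `"orig:<row>"` /
#'   `"boot:<row>"` tags pointing at source rows of the input, or
#'   `"smote"` for synthetic points.
#' @export
balance_training_set <- function(X, y, factor = 2, seed = 1L) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  with_seed(seed, {
    parts <- lapply(levels(y), function(cl) {
      rows <- which(y == cl)
      if (factor == 1) {
        list(idx = rows, prov = paste0("orig:", rows))
      } else {
        b <- sample(rows, round(factor * length(rows)), replace = TRUE)
        list(idx = b, prov = paste0("boot:", b))
      }
    })
    sizes <- vapply(parts, function(p) length(p$idx), 1L)
    target <- max(sizes)
    Xs <- list(); ys <- list(); prov <- list()
    for (k in seq_along(parts)) {
      cl <- levels(y)[k]
      base <- X[parts[[k]]$idx, , drop = FALSE]
      Xs[[length(Xs) + 1L]] <- base
      ys[[length(ys) + 1L]] <- rep(cl, nrow(base))
      prov[[length(prov) + 1L]] <- parts[[k]]$prov
      need <- target - nrow(base)
      if (need > 0L) {
        Xs[[length(Xs) + 1L]] <- smote_points(base, need)
        ys[[length(ys) + 1L]] <- rep(cl, need)
        prov[[length(prov) + 1L]] <- rep("smote", need)
      }
    }
    list(X = do.call(rbind, Xs), y = factor(unlist(ys), levels = levels(y)),
         provenance = unlist(prov))
  })
}

# n synthetic points by nearest-neighbor interpolation within one class
smote_points <- function(base, n, k = 5L) {
  m <- nrow(base)
  if (m < 2L) stop("SMOTE needs at least 2 samples in a class", call. = FALSE)
  if (m < 6L) {
    warning(sprintf("SMOTE: class has %d samples, using k = %d", m, m - 1L),
            call. = FALSE)
  }
  k <- min(k, m - 1L)
  d <- as.matrix(dist(base))
  diag(d) <- Inf
  nn <- matrix(0L, m, k)
  for (r in seq_len(m)) nn[r, ] <- order(d[r, ])[seq_len(k)]
  i <- sample(m, n, replace = TRUE)
  j <- nn[cbind(i, sample(k, n, replace = TRUE))]
  lam <- runif(n)
  base[i, , drop = FALSE] +
    lam * (base[j, , drop = FALSE] - base[i, , drop = FALSE])
}

#' Evaluation control parameters
#'
#' @param ntree_grid,depth_grid hyperparameter grid searched by stratified
#'   CV on the balanced training partition; a 1x1 grid skips the CV
#'   search.
#' @param cv_folds folds of the inner CV (default 10).
#' @param balance_factor bootstrap augmentation factor (default 2).
#' @param paper_order if `TRUE`, balance the full data before the 70/30
#'   split, reproducing the source protocol's order (leaks synthetic
#'   copies of test subjects into training; off by default).
#' @param train_frac training fraction (default 0.7).
#' @return List of class `eval_control`.
#' @export
eval_control <- function(ntree_grid = c(100L, 300L, 500L),
                         depth_grid = c(Inf, 5L, 10L), cv_folds = 10L,
                         balance_factor = 2, paper_order = FALSE,
                         train_frac = 0.7) {
  structure(list(ntree_grid = ntree_grid, depth_grid = depth_grid,
                 cv_folds = cv_folds, balance_factor = balance_factor,
                 paper_order = paper_order, train_frac = train_frac),
            class = "eval_control")
}

# cheap control used when scanning thousands of combinations
light_control <- function(paper_order = FALSE) {
  eval_control(ntree_grid = 60L, depth_grid = 10L, cv_folds = 0L,
               paper_order = paper_order)
}

#' Evaluate one feature combination
#'
#' Stratified 70/30 subject split; bootstrap + SMOTE balancing of the
#' training partition only (see `paper_order` in [eval_control()]);
#' stratified k-fold CV over the hyperparameter grid on the balanced
#' training data; final refit on the full balanced training data; metrics
#' on the untouched test partition.
#'
#' @param wide joined two-sequence table from [join_sequences()] (a
#'   cohort feature table is accepted and joined automatically).
#' @param features character vector of wide feature names.
#' @param seed RNG seed driving split, balancing, CV and forest.
#' @param control an [eval_control()].
#' @return List: `acc`, `tpr`, `auc`, `confusion`, `best_params`,
#'   `test_subjects`, `train_subjects`, `balance_provenance`.
#' @export
evaluate_combination <- function(wide, features, seed = 1L,
                                 control = eval_control()) {
  if ("sequence" %in% names(wide)) wide <- join_sequences(wide)
  missing <- setdiff(features, names(wide))
  if (length(missing)) {
    stop("unknown feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  y <- factor(wide$group, levels = GROUP_LEVELS)
  X <- as.matrix(wide[, features, drop = FALSE])

  if (isTRUE(control$paper_order)) {
    bal_all <- balance_training_set(X, y, control$balance_factor, seed)
    tag_subject <- function(tag) {
      if (tag == "smote") return("smote")
      wide$subject_id[as.integer(sub("^[a-z]+:", "", tag))]
    }
    subj_all <- vapply(bal_all$provenance, tag_subject, "",
                       USE.NAMES = FALSE)
    sp <- stratified_split(bal_all$y, control$train_frac, seed + 1L)
    Xtr <- bal_all$X[sp$train, , drop = FALSE]
    ytr <- bal_all$y[sp$train]
    prov <- subj_all[sp$train]
    Xte <- bal_all$X[sp$test, , drop = FALSE]
    yte <- bal_all$y[sp$test]
    test_subjects <- unique(setdiff(subj_all[sp$test], "smote"))
  } else {
    sp <- stratified_split(y, control$train_frac, seed)
    bal <- balance_training_set(X[sp$train, , drop = FALSE], y[sp$train],
                                control$balance_factor, seed + 1L)
    Xtr <- bal$X; ytr <- bal$y
    # provenance indices refer to rows of the training partition; remap to
    # subject ids so leakage can be audited
    prov <- vapply(bal$provenance, function(tag) {
      if (tag == "smote") return("smote")
      i <- as.integer(sub("^[a-z]+:", "", tag))
      wide$subject_id[sp$train[i]]
    }, "", USE.NAMES = FALSE)
    Xte <- X[sp$test, , drop = FALSE]
    yte <- y[sp$test]
    test_subjects <- wide$subject_id[sp$test]
  }

  grid <- expand.grid(ntree = control$ntree_grid, depth = control$depth_grid)
  best <- grid[1, ]
  if (nrow(grid) > 1L && control$cv_folds >= 2L) {
    fold <- stratified_folds(ytr, control$cv_folds, seed + 2L)
    cv_acc <- vapply(seq_len(nrow(grid)), function(g) {
      accs <- vapply(seq_len(control$cv_folds), function(f) {
        tr <- fold != f
        if (!any(!tr) || length(unique(ytr[tr])) < nlevels(ytr)) {
          return(NA_real_)
        }
        fit <- rf_fit(Xtr[tr, , drop = FALSE], ytr[tr],
                      ntree = grid$ntree[g], max_depth = grid$depth[g],
                      seed = seed + 100L + f)
        mean(predict(fit, Xtr[!tr, , drop = FALSE], type = "class") ==
               ytr[!tr])
      }, 1)
      mean(accs, na.rm = TRUE)
    }, 1)
    best <- grid[which.max(cv_acc), ]
  }
  fit <- rf_fit(Xtr, ytr, ntree = best$ntree, max_depth = best$depth,
                seed = seed + 3L)
  prob <- predict(fit, Xte, type = "prob")
  met <- classification_metrics(yte, prob)
  c(met, list(best_params = as.list(best), features = features,
              test_subjects = test_subjects,
              train_subjects = unique(setdiff(prov, "smote")),
              balance_provenance = prov))
}

#' Repeat the split-and-evaluate protocol
#'
#' Runs [evaluate_combination()] on `n_rep` independent stratified splits
#' (seeds `base_seed .. base_seed + n_rep - 1`) and aggregates the test
#' metrics as mean and sd.
#'
#' @inheritParams evaluate_combination
#' @param n_rep number of repetitions (default 10).
#' @param base_seed seed of the first repetition.
#' @return Object of class `model_eval_report`: list with `per_rep` (data
#'   frame: rep, acc, tpr_bme, tpr_inj, tpr_ost, auc), `mean`, `sd`,
#'   `features`, `reps` (raw per-repetition results).
#' @export
repeat_evaluation <- function(wide, features, n_rep = 10L, base_seed = 1L,
                              control = eval_control()) {
  if ("sequence" %in% names(wide)) wide <- join_sequences(wide)
  reps <- lapply(seq_len(n_rep) - 1L, function(r) {
    evaluate_combination(wide, features, seed = base_seed + r, control)
  })
  per_rep <- data.frame(
    rep = seq_len(n_rep),
    acc = vapply(reps, `[[`, 1, "acc"),
    tpr_bme = vapply(reps, function(x) x$tpr[["BME"]], 1),
    tpr_inj = vapply(reps, function(x) x$tpr[["INJ"]], 1),
    tpr_ost = vapply(reps, function(x) x$tpr[["OST"]], 1),
    auc = vapply(reps, `[[`, 1, "auc")
  )
  metr <- per_rep[, -1]
  structure(list(per_rep = per_rep, mean = colMeans(metr),
                 sd = vapply(metr, sd, 1), features = features,
                 n_rep = n_rep, base_seed = base_seed, reps = reps),
            class = "model_eval_report")
}

#' @export
print.model_eval_report <- function(x, ...) {
  cat("<model_eval_report>", x$n_rep, "repetitions of",
      paste(x$features, collapse = " + "), "\n")
  print(round(x$per_rep, 3), row.names = FALSE)
  cat(sprintf("mean (sd): Acc %.2f (%.2f)  TPR %s  AUC %.2f (%.2f)\n",
              x$mean["acc"], x$sd["acc"],
              paste(sprintf("%.2f", x$mean[c("tpr_bme", "tpr_inj",
                                             "tpr_ost")]), collapse = "/"),
              x$mean["auc"], x$sd["auc"]))
  invisible(x)
}

#' Export a model evaluation report as a metrics table
#'
#' One row per repetition plus an aggregate row, mirroring the
#' k-fold / Acc / per-class TPR / AUC report layout.
#'
#' @param report a `model_eval_report`.
#' @param path optional CSV path; when given the table is also written.
#' @return The table, invisibly when `path` is given.
#' @export
report_table <- function(report, path = NULL) {
  tab <- report$per_rep
  tab$rep <- as.character(tab$rep)
  agg <- data.frame(rep = "mean (sd)", t(vapply(names(report$mean),
    function(m) sprintf("%.2f (%.2f)", report$mean[[m]], report$sd[[m]]),
    "")), stringsAsFactors = FALSE)
  names(agg) <- names(tab)
  for (cl in names(tab)[-1]) tab[[cl]] <- sprintf("%.4f", tab[[cl]])
  out <- rbind(tab, agg)
  if (!is.null(path)) {
    write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Select the composite descriptor
#'
#' Ranks features by forest importance, enumerates all combinations of
#' the top `k_top` features up to `max_size`, evaluates each combination
#' per repetition with a cheap single-configuration forest (subsampling
#' `budget` combinations per repetition when the enumeration is larger),
#' records the best combination of each repetition (highest test AUC,
#' ties to the smaller then lexicographically first set), and returns the
#' features present in the majority of the per-repetition winners,
#' together with a full [repeat_evaluation()] report of that composite.
#'
#' @param table cohort feature table.
#' @param base_seed seed of the whole procedure.
#' @param k_top,max_size combination space (defaults 20 and 5).
#' @param n_rep repetitions (default 10).
#' @param budget maximum combinations evaluated per repetition
#'   (default `Inf` = all 21699).
#' @param control control for the final report evaluation.
#' @return List: `composite` (character), `report`
#'   (`model_eval_report`), `best_per_rep` (list of winning combinations),
#'   `ranking` (the importance-ordered feature list).
#' @export
select_composite <- function(table, base_seed = 1L, k_top = 20L,
                             max_size = 5L, n_rep = 10L, budget = Inf,
                             control = eval_control()) {
  wide <- join_sequences(table)
  ranking <- rank_importance(table, seed = base_seed)
  combos <- enumerate_combinations(ranking, k_top, max_size)
  lc <- light_control(paper_order = isTRUE(control$paper_order))
  # one candidate pool for the whole run: per-repetition winners are then
  # comparable and the majority vote is over a shared candidate set
  if (is.finite(budget) && budget < length(combos)) {
    keep <- with_seed(base_seed + 1000L, sample(length(combos), budget))
    combos <- combos[sort(keep)]
  }
  best_per_rep <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    cand <- combos
    aucs <- vapply(cand, function(fs) {
      evaluate_combination(wide, fs, seed = base_seed + r - 1L, lc)$auc
    }, 1)
    sizes <- lengths(cand)
    keys <- vapply(cand, paste, "", collapse = "|")
    ord <- order(-aucs, sizes, keys)
    best_per_rep[[r]] <- cand[[ord[1]]]
  }
  freq <- table(unlist(best_per_rep))
  composite <- sort(names(freq)[freq > n_rep / 2])
  if (length(composite) < 2L) {
    # degenerate majority: fall back to the modal winning combination
    keys <- vapply(best_per_rep, function(fs) paste(sort(fs), collapse = "|"),
                   "")
    modal <- names(sort(table(keys), decreasing = TRUE))[1]
    composite <- sort(strsplit(modal, "|", fixed = TRUE)[[1]])
  }
  report <- repeat_evaluation(wide, composite, n_rep, base_seed, control)
  list(composite = composite, report = report, best_per_rep = best_per_rep,
       ranking = ranking)
}
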