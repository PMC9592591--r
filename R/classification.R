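#' Stratified one-replicate-per-class holdout split
#'
#' For each class, one replicate is chosen uniformly at random as test
#' data; the remaining replicates train. The test set therefore contains
#' exactly one sample per class and train/test partition the samples.
#' The draw is made on a private RNG stream so global RNG state is
#' untouched.
#'
#' @param samples data frame with `sample_id` and `class_label`.
#' @param seed integer seed making the split reproducible.
#' @return List with `test` and `train` (character sample_id vectors).
#' @export
stratified_split <- function(samples, seed) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "class_label") %in% names(samples)))
  by_class <- split(samples$sample_id, samples$class_label)
  sizes <- lengths(by_class)
  if (any(sizes < 2)) {
    stop("every class needs >= 2 replicates to hold one out; offending: ",
         paste(names(by_class)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  test <- with_private_seed(seed, {
    vapply(by_class, function(ids) ids[sample.int(length(ids), 1L)], character(1))
  })
  list(test = unname(test), train = setdiff(samples$sample_id, test))
}

# Evaluate expr under a seeded private RNG stream, restoring global state.
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Per-class F1 from predicted labels
#'
#' For each class c over the label universe (union of truth and
#' prediction): precision TP/(TP+FP), recall TP/(TP+FN),
#' F1 = 2PR/(P+R), with the convention F1 = 0 when P + R = 0 (class
#' absent from both correct predictions and truth hits).
#'
#' @param truth,pred character vectors of equal length.
#' @return Named numeric vector of per-class F1 in [0, 1].
#' @export
#' @examples
#' f1_per_class(c("A", "B", "C"), c("A", "A", "C"))
f1_per_class <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  truth <- as.character(truth); pred <- as.character(pred)
  classes <- sort(union(truth, pred))
  vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (p + r > 0) 2 * p * r / (p + r) else 0
  }, numeric(1))
}

#' Default hyper-parameter grids for the four classifier families
#'
#' Small fixed grids searched by inner cross-validation; the grid
#' actually searched and the chosen values are recorded in the
#' evaluation report.
#'
#' @return Named list of per-algorithm grids.
#' @export
default_grids <- function() {
  list(
    decision_tree = list(cp = c(0.001, 0.01, 0.1)),
    neural_network = list(size = c(3L, 5L, 8L), decay = c(0.01, 0.1, 1)),
    random_forest = list(mtry_frac = c(0.05, 0.1, 0.33)),
    svm = list(C = c(0.25, 1, 4))
  )
}

ALGORITHMS <- c("decision_tree", "neural_network", "random_forest", "svm")

fit_predict <- function(algorithm, x_train, y_train, x_test, pars) {
  y_train <- factor(y_train)
  switch(algorithm,
    decision_tree = {
      d <- data.frame(.y = y_train, x_train, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = d, method = "class",
                          control = rpart::rpart.control(
                            minsplit = 2, minbucket = 1, cp = pars$cp,
                            xval = 0))
      as.character(predict(fit, data.frame(x_test, check.names = FALSE),
                           type = "class"))
    },
    neural_network = {
      mu <- colMeans(x_train)
      sd <- apply(x_train, 2, stats::sd)
      sd[sd == 0] <- 1
      xs <- sweep(sweep(x_train, 2, mu), 2, sd, "/")
      xt <- sweep(sweep(x_test, 2, mu), 2, sd, "/")
      fit <- nnet::nnet(xs, nnet::class.ind(y_train), size = pars$size,
                        decay = pars$decay, maxit = 200, softmax = TRUE,
                        MaxNWts = 20000, trace = FALSE)
      pr <- predict(fit, xt)
      colnames(pr)[max.col(pr, ties.method = "first")]
    },
    random_forest = {
      mtry <- max(1L, floor(pars$mtry_frac * ncol(x_train)))
      fit <- randomForest::randomForest(x_train, y_train, ntree = 500,
                                        mtry = mtry)
      as.character(predict(fit, x_test))
    },
    svm = {
      # standardize here (zero-variance-safe) instead of ksvm's scaled=TRUE,
      # which warns on the all-zero glycoform columns of sparse profiles
      mu <- colMeans(x_train)
      sd <- apply(x_train, 2, stats::sd)
      sd[sd == 0] <- 1
      xs <- sweep(sweep(x_train, 2, mu), 2, sd, "/")
      xt <- sweep(sweep(x_test, 2, mu), 2, sd, "/")
      fit <- kernlab::ksvm(xs, y_train, kernel = "rbfdot",
                           kpar = "automatic", C = pars$C, scaled = FALSE)
      as.character(kernlab::predict(fit, xt))
    },
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  )
}

expand_grid_list <- function(grid) {
  df <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

# Inner CV grid search: stratified folds over the training replicates,
# selecting the grid point with the highest mean accuracy (ties to the
# first grid point, so selection is deterministic given the folds).
tune_algorithm <- function(algorithm, x, y, grid, n_folds = 4L, seed = 1L) {
  points <- expand_grid_list(grid)
  if (length(points) == 1) return(points[[1]])
  folds <- with_private_seed(seed, {
    f <- integer(length(y))
    for (cl in unique(y)) {
      i <- which(y == cl)
      f[i] <- sample(rep_len(seq_len(min(n_folds, length(i))), length(i)))
    }
    f
  })
  acc <- vapply(points, function(pars) {
    hits <- 0L; tot <- 0L
    for (k in sort(unique(folds))) {
      tr <- folds != k; te <- folds == k
      if (length(unique(y[tr])) < 2) next
      pred <- fit_predict(algorithm, x[tr, , drop = FALSE], y[tr],
                          x[te, , drop = FALSE], pars)
      hits <- hits + sum(pred == y[te]); tot <- tot + sum(te)
    }
    if (tot > 0) hits / tot else 0
  }, numeric(1))
  points[[which.max(acc)]]
}

#' Repeated stratified-holdout evaluation of classifier families
#'
#' The atlas discrimination protocol: on each repetition, hold out one
#' replicate per class ([stratified_split()]), fit each algorithm on the
#' remaining replicates, predict the held-out samples, and score
#' per-class F1 from that repetition's one-sample-per-class confusion.
#' Per-class F1 is then aggregated over repetitions as mean and standard
#' error (SD / sqrt(reps)); the across-class average is the unweighted
#' mean of per-class means.
#'
#' Hyper-parameters come from an inner cross-validated grid search on
#' training data. By default (`tune = "once"`) the search runs on the
#' first repetition's training set and the chosen values are reused —
#' with a handful of replicates per class the inner-CV surface is
#' essentially identical across repetitions. `tune = "per_rep"` re-tunes
#' every repetition; `tune = "none"` takes the first grid point.
#'
#' @param profile a `glyco_profile` with class labels.
#' @param algorithms subset of
#'   `c("decision_tree", "neural_network", "random_forest", "svm")`.
#' @param n_reps number of repetitions (default 1000).
#' @param seed integer seed; repetition r uses the derived seed
#'   `seed + r`, so reports are reproducible.
#' @param tune `"once"`, `"per_rep"`, or `"none"`.
#' @param grids hyper-parameter grids, see [default_grids()].
#' @param feature_set optional character vector of composition strings to
#'   restrict features to (e.g. the reference strain's glycoform
#'   library) before evaluation.
#' @return Object of class `evaluation_report`: list with `per_class`
#'   (algorithm, class, mean_f1, se_f1), `overall` (algorithm, mean_f1,
#'   se_f1 of the across-class average), `n_reps`, `tuning` (chosen
#'   parameters and grids), `seed`.
#' @export
evaluate_classifiers <- function(profile,
                                 algorithms = ALGORITHMS,
                                 n_reps = 1000L, seed = 1L,
                                 tune = c("once", "per_rep", "none"),
                                 grids = default_grids(),
                                 feature_set = NULL) {
  tune <- match.arg(tune)
  stopifnot(inherits(profile, "glyco_profile"))
  algorithms <- match.arg(algorithms, ALGORITHMS, several.ok = TRUE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)

  x <- profile$abundance
  if (!is.null(feature_set)) {
    feature_set <- intersect(colnames(x), feature_set)
    if (length(feature_set) == 0) stop("feature_set shares no glycoforms with the profile",
                                       call. = FALSE)
    x <- x[, feature_set, drop = FALSE]
  }
  colnames(x) <- make.names(colnames(x))
  y <- profile$samples$class_label[match(rownames(x), profile$samples$sample_id)]
  classes <- sort(unique(y))

  degenerate <- vapply(classes, function(cl) {
    all(x[y == cl, , drop = FALSE] == 0)
  }, logical(1))
  if (any(degenerate)) {
    warning("classes with all-zero features: ",
            paste(classes[degenerate], collapse = ", "))
  }

  chosen <- vector("list", length(algorithms))
  names(chosen) <- algorithms
  if (tune != "per_rep") {
    split0 <- stratified_split(profile$samples, seed)
    tr0 <- rownames(x) %in% split0$train
    for (alg in algorithms) {
      chosen[[alg]] <- if (tune == "none") expand_grid_list(grids[[alg]])[[1]]
        else tune_algorithm(alg, x[tr0, , drop = FALSE], y[tr0], grids[[alg]],
                            seed = seed)
    }
  }

  f1 <- array(NA_real_, dim = c(n_reps, length(classes), length(algorithms)),
              dimnames = list(NULL, classes, algorithms))
  for (r in seq_len(n_reps)) {
    rep_seed <- as.integer(seed) + r
    sp <- stratified_split(profile$samples, rep_seed)
    tr <- rownames(x) %in% sp$train
    te <- !tr
    for (alg in algorithms) {
      pars <- if (tune == "per_rep") {
        tune_algorithm(alg, x[tr, , drop = FALSE], y[tr], grids[[alg]],
                       seed = rep_seed)
      } else chosen[[alg]]
      if (tune == "per_rep") chosen[[alg]] <- pars
      pred <- with_private_seed(rep_seed, {
        fit_predict(alg, x[tr, , drop = FALSE], y[tr], x[te, , drop = FALSE],
                    pars)
      })
      scores <- f1_per_class(y[te], pred)
      f1[r, , alg] <- scores[classes]
    }
  }
  f1[is.na(f1)] <- 0  # classes absent from a repetition's label universe

  se <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  alg_slice <- function(alg) {
    m <- f1[, , alg, drop = FALSE]
    dim(m) <- dim(f1)[1:2]
    colnames(m) <- classes
    m
  }
  per_class <- do.call(rbind, lapply(algorithms, function(alg) {
    m <- alg_slice(alg)
    data.frame(
      algorithm = alg, class = classes,
      mean_f1 = colMeans(m),
      se_f1 = apply(m, 2, se),
      stringsAsFactors = FALSE
    )
  }))
  rownames(per_class) <- NULL
  overall <- do.call(rbind, lapply(algorithms, function(alg) {
    rep_avg <- rowMeans(alg_slice(alg))
    data.frame(algorithm = alg, mean_f1 = mean(rep_avg), se_f1 = se(rep_avg),
               stringsAsFactors = FALSE)
  }))
  rownames(overall) <- NULL

  structure(
    list(per_class = per_class, overall = overall,
         n_reps = as.integer(n_reps), seed = as.integer(seed),
         tuning = list(mode = tune, grids = grids[algorithms],
                       chosen = chosen)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Holdout evaluation: %d repetitions, seed %d, tuning '%s'\n",
              x$n_reps, x$seed, x$tuning$mode))
  for (i in seq_len(nrow(x$overall))) {
    cat(sprintf("  %-15s mean F1 %5.1f%%  (SE %s)\n",
                x$overall$algorithm[i], 100 * x$overall$mean_f1[i],
                if (is.na(x$overall$se_f1[i])) "n/a"
                else sprintf("%.1f%%", 100 * x$overall$se_f1[i])))
  }
  invisible(x)
}
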