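#' Random class blocks for decoding
#'
#' Per class, randomly partitions the trials into `n_folds` equal-size
#' blocks (remainder trials are dropped at random; the count is recorded)
#' and averages each block trial-wise, yielding one channel vector per time
#' point per block.  Block averaging raises the signal-to-noise ratio of
#' the patterns fed to the classifier.
#'
#' @param x `n_trials x n_channels x n_samples` array (already restricted
#'   to the decoding channels).
#' @param labels Class label per trial (2 levels).
#' @param n_folds Number of blocks per class (default 3).
#' @param seed Integer seed.
#' @return List with `blocks` (array `[class, fold, channel, sample]`),
#'   `classes`, `n_dropped`.
#' @export
make_class_blocks <- function(x, labels, n_folds = 3, seed = NULL) {
  stopifnot(length(dim(x)) == 3L, dim(x)[1] == length(labels))
  classes <- sort(unique(as.character(labels)))
  if (length(classes) != 2L) stop("decoding requires exactly 2 classes")
  per_class <- table(factor(labels, classes))
  if (any(per_class < n_folds)) {
    stop("every class needs at least n_folds = ", n_folds, " trials")
  }
  with_seed(seed, {
    blocks <- array(NA_real_, dim = c(2L, n_folds, dim(x)[2], dim(x)[3]))
    n_dropped <- 0L
    for (ci in 1:2) {
      idx <- which(labels == classes[ci])
      k <- length(idx) %/% n_folds
      use <- sample(idx, k * n_folds)
      n_dropped <- n_dropped + length(idx) - k * n_folds
      fold_of <- rep(seq_len(n_folds), each = k)
      for (f in seq_len(n_folds)) {
        sel <- use[fold_of == f]
        blocks[ci, f, , ] <- apply(x[sel, , , drop = FALSE], c(2, 3), mean)
      }
    }
    list(blocks = blocks, classes = classes, n_dropped = n_dropped)
  })
}

decoding_array <- function(x) {
  if (inherits(x, "eeg_epochs")) {
    # exclude the EOG and reference channels from the features
    keep <- !x$channels %in% c("HEOG", "VEOG", "A1", "A2")
    list(data = x$data[, keep, , drop = FALSE], time = x$time)
  } else {
    stopifnot(length(dim(x)) == 3L)
    list(data = x, time = NULL)
  }
}

svm_fold_predict <- function(train_x, train_y, test_x) {
  # linear-kernel maximum-margin classifier, unit cost; features are
  # standardized with training statistics only (no test leakage)
  mu <- colMeans(train_x)
  sdv <- apply(train_x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  tr <- scale(train_x, mu, sdv)
  te <- scale(test_x, mu, sdv)
  fit <- tryCatch(
    e1071::svm(tr, factor(train_y), kernel = "linear", cost = 1,
               scale = FALSE),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # degenerate training set (e.g. all-identical rows): fall back to the
    # first class, a majority vote under balanced training labels
    warning("degenerate features at a time point; defaulting prediction")
    return(rep(train_y[1], nrow(te)))
  }
  as.character(stats::predict(fit, te))
}

#' Time-resolved decoding of item location
#'
#' Trains a linear support vector machine at each time point to distinguish
#' the scalp voltage topographies of the two classes (patterned vs random
#' item location), using block-averaged trials and an iterated 3-fold
#' cross-validation: per iteration the trials are freshly partitioned into
#' three blocks per class, and every block serves as the test set once
#' while the other two train the classifier.  With the defaults this gives
#' 2 classes x 3 folds x 10 iterations = 60 decoding attempts per time
#' point; accuracy is their correct proportion.  Class sizes are equated by
#' random subsampling before blocking.
#'
#' @param x An `eeg_epochs` (EOG/reference channels are excluded
#'   automatically) or a `trials x channels x samples` array.
#' @param labels Class label per trial (exactly 2 levels).
#' @param n_folds Cross-validation folds / blocks per class (default 3).
#' @param n_iterations Block-assignment iterations (default 10).
#' @param window_ms Optional time window to decode (default: all samples).
#' @param time Time axis, required when `x` is a bare array.
#' @param seed Integer seed.
#' @return Object of class `decoding_timecourse`: `accuracy` per time
#'   point, `time`, `n_attempts_per_point`, `n_dropped`, `config`.
#' @export
decode_timecourse <- function(x, labels, n_folds = 3, n_iterations = 10,
                              window_ms = NULL, time = NULL, seed = NULL) {
  da <- decoding_array(x)
  time <- da$time %||% time
  if (is.null(time)) stop("a bare array needs an explicit time axis")
  dat <- da$data
  stopifnot(dim(dat)[1] == length(labels), dim(dat)[3] == length(time))
  classes <- sort(unique(as.character(labels)))
  if (length(classes) != 2L) stop("decoding requires exactly 2 classes")
  if (!is.null(window_ms)) {
    idx <- window_index(time, window_ms)
    dat <- dat[, , idx, drop = FALSE]
    time <- time[idx]
  }
  n_time <- length(time)
  with_seed(seed, {
    # equate class sizes by random subsampling to the smaller class
    n_min <- min(table(factor(labels, classes)))
    keep <- unlist(lapply(classes, function(cl) {
      idx <- which(labels == cl)
      if (length(idx) > n_min) sample(idx, n_min) else idx
    }))
    dat <- dat[keep, , , drop = FALSE]
    labels <- as.character(labels)[keep]

    correct <- numeric(n_time)
    attempts <- 0L
    n_dropped <- 0L
    for (it in seq_len(n_iterations)) {
      cb <- make_class_blocks(dat, labels, n_folds)
      n_dropped <- cb$n_dropped
      for (f in seq_len(n_folds)) {
        train_folds <- setdiff(seq_len(n_folds), f)
        for (tp in seq_len(n_time)) {
          # blocks[class, folds, , tp] drops to a folds x channels matrix
          train_x <- rbind(cb$blocks[1, train_folds, , tp],
                           cb$blocks[2, train_folds, , tp])
          train_y <- rep(cb$classes, each = n_folds - 1L)
          test_x <- rbind(cb$blocks[1, f, , tp], cb$blocks[2, f, , tp])
          pred <- svm_fold_predict(train_x, train_y, test_x)
          correct[tp] <- correct[tp] + sum(pred == cb$classes)
        }
        attempts <- attempts + 2L
      }
    }
    structure(
      list(accuracy = correct / attempts, time = time,
           n_attempts_per_point = attempts, n_dropped = n_dropped,
           config = list(n_folds = n_folds, n_iterations = n_iterations,
                         classifier = "linear svm", classes = classes),
           seed = seed),
      class = "decoding_timecourse"
    )
  })
}

# internal: call decode_timecourse from a named argument list
decode_timecourse_args <- function(args) {
  do.call(decode_timecourse, args)
}

#' @export
print.decoding_timecourse <- function(x, ...) {
  cat("<decoding_timecourse> ", length(x$time), " time points, ",
      x$n_attempts_per_point, " attempts/point (",
      x$config$n_folds, " folds x ", x$config$n_iterations,
      " iterations x 2 classes)\n", sep = "")
  cat("  mean accuracy: ", signif(mean(x$accuracy), 4), "\n", sep = "")
  invisible(x)
}

#' Window-mean decoding accuracy and group test against chance
#'
#' Averages each participant's decoding accuracy over a time window and
#' tests the group means against chance (0.5) with a one-sample t test and
#' Cohen's d.  With zero between-participant variance the t statistic is
#' reported as a flagged zero-variance case rather than infinity.
#'
#' @param timecourses List of `decoding_timecourse` objects (>= 3 for the
#'   test), one per participant, on a common time axis.
#' @param window_ms Averaging window (default 150-300 ms).
#' @param chance Chance level (default 0.5).
#' @return List with `per_participant`, `mean`, `t`, `df`, `p_value`, `d`,
#'   `zero_variance`.
#' @export
window_mean_accuracy <- function(timecourses, window_ms = c(150, 300),
                                 chance = 0.5) {
  stopifnot(length(timecourses) >= 1L)
  per <- vapply(timecourses, function(tc) {
    idx <- window_index(tc$time, window_ms)
    mean(tc$accuracy[idx])
  }, numeric(1))
  out <- list(per_participant = per, mean = mean(per), window_ms = window_ms,
              chance = chance, t = NA_real_, df = length(per) - 1L,
              p_value = NA_real_, d = NA_real_, zero_variance = FALSE)
  if (length(per) >= 3L) {
    sdv <- stats::sd(per)
    if (sdv == 0) {
      if (mean(per) == chance) {       # all exactly at chance: t is 0
        out$t <- 0
        out$p_value <- 1
        out$d <- 0
      } else {                         # infinite t: flagged, not fabricated
        out$zero_variance <- TRUE
      }
    } else {
      out$t <- (mean(per) - chance) / (sdv / sqrt(length(per)))
      out$p_value <- 2 * stats::pt(-abs(out$t), df = out$df)
      out$d <- (mean(per) - chance) / sdv
    }
  }
  out
}
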