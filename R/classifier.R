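.feature_cols <- c("turbulence_0.01", "turbulence_0.03", "turbulence_0.06",
  "transfer_0.01", "transfer_0.03", "transfer_0.06", "information_cascade")

#' Assemble the 7-feature classification table
#'
#' Builds the fixed feature set used for treatment-response classification:
#' turbulence at lambda = 0.01, 0.03, 0.06; information transfer at the
#' same three scales; and the information cascade. Rows are patients,
#' sorted by id; column order is fixed.
#'
#' @param profiles named list mapping patient id to
#'   [TurbulenceProfile-class]; every profile must contain the three named
#'   scales.
#' @param labels named character/factor vector (same names) with values
#'   "responder" / "non_responder".
#' @return data.frame with the 7 numeric feature columns plus a
#'   \code{label} factor column; patient ids as row names.
#' @export
assembleFeatures <- function(profiles, labels) {
  ids <- sort(names(profiles))
  if (is.null(ids) || any(!nzchar(ids)))
    stop("assembleFeatures: profiles must be a named list")
  if (!all(ids %in% names(labels)))
    stop("assembleFeatures: labels missing for some patients")
  need <- c("0.01", "0.03", "0.06")
  rows <- lapply(ids, function(id) {
    pr <- profiles[[id]]
    tv <- turbulence(pr); iv <- informationTransfer(pr)
    for (s in need) {
      if (!s %in% names(tv))
        stop("assembleFeatures: patient ", id, " lacks turbulence at scale ", s)
      if (!s %in% names(iv))
        stop("assembleFeatures: patient ", id, " lacks transfer at scale ", s)
    }
    c(tv[need], iv[need], informationCascade(pr))
  })
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- .feature_cols
  rownames(tab) <- ids
  if (any(!is.finite(as.matrix(tab))))
    stop("assembleFeatures: non-finite feature values")
  tab$label <- factor(as.character(labels[ids]),
    levels = c("non_responder", "responder"))
  if (anyNA(tab$label))
    stop("assembleFeatures: labels must be responder/non_responder")
  tab
}

# Train a radial SVM on standardized training features, evaluate accuracy
# and ROC-AUC on the validation fold. Standardization statistics and the
# median-distance kernel width come from the training fold only.
.svm_eval <- function(xtr, ytr, xte, yte) {
  mu <- colMeans(xtr)
  sdev <- apply(xtr, 2L, stats::sd)
  sdev[sdev == 0] <- 1
  xtr <- sweep(sweep(xtr, 2L, mu), 2L, sdev, "/")
  xte <- sweep(sweep(xte, 2L, mu), 2L, sdev, "/")
  med <- stats::median(stats::dist(xtr))
  gamma <- if (med > 0) 1 / (2 * med^2) else 1 / ncol(xtr)
  fit <- e1071::svm(xtr, ytr, kernel = "radial", gamma = gamma, cost = 1,
    scale = FALSE)
  pred <- stats::predict(fit, xte, decision.values = TRUE)
  dec <- drop(attr(pred, "decision.values"))
  # e1071 names the decision column "A/B": positive values favor class A
  pos <- strsplit(colnames(attr(pred, "decision.values")), "/")[[1L]][1L]
  neg <- setdiff(levels(ytr), pos)
  auc <- as.numeric(pROC::auc(pROC::roc(response = yte, predictor = dec,
    levels = c(neg, pos), direction = "<", quiet = TRUE)))
  c(acc = mean(pred == yte), auc = auc)
}

.stratified_idx <- function(y, frac_val) {
  val <- integer(0)
  for (lv in levels(y)) {
    idx <- which(y == lv)
    nv <- max(1L, round(length(idx) * frac_val))
    val <- c(val, sample(idx, nv))
  }
  val
}

#' Repeated balanced split evaluation of the response classifier
#'
#' Per repetition: the larger class is randomly subsampled to
#' \code{balanceTo} patients, the balanced set is split stratified into
#' training and validation (default 90/10), features are standardized with
#' training-fold statistics, and a Gaussian-radial-kernel SVM (cost 1,
#' kernel width from the median pairwise training distance) is trained and
#' evaluated on the validation fold. Reports means and SDs of validation
#' ROC-AUC and accuracy over repetitions. \code{mode = "cv"} instead runs
#' a stratified k-fold cross-validation of the balanced subsample within
#' each repetition and averages the folds.
#'
#' @param table feature table from [assembleFeatures()].
#' @param nReps repetitions (default 100).
#' @param trainFrac training fraction per split (default 0.9).
#' @param balanceTo per-class size of the balanced subsample (default 32);
#'   clipped with a warning when a class is smaller.
#' @param seed integer seed.
#' @param mode "split" (default, repeated 90/10) or "cv" (stratified
#'   k-fold per repetition).
#' @param nFolds folds for \code{mode = "cv"} (default 10).
#' @return a [ClassifierReport-class].
#' @export
repeatedSplitEval <- function(table, nReps = 100L, trainFrac = 0.9,
    balanceTo = 32L, seed = 1L, mode = c("split", "cv"), nFolds = 10L) {
  mode <- match.arg(mode)
  stopifnot(nReps >= 1L, trainFrac > 0, trainFrac < 1)
  y <- table$label
  x <- as.matrix(table[, .feature_cols])
  tab_n <- table(y)
  if (min(tab_n) < balanceTo) {
    warning("repeatedSplitEval: smallest class has ", min(tab_n),
      " patients; balanceTo clipped")
    balanceTo <- min(tab_n)
  }
  res <- matrix(NA_real_, nReps, 2L, dimnames = list(NULL, c("acc", "auc")))
  for (r in seq_len(nReps)) {
    res[r, ] <- .with_seed(.derive_seed(seed, r), {
      keep <- unlist(lapply(levels(y), function(lv) {
        idx <- which(y == lv)
        if (length(idx) > balanceTo) sample(idx, balanceTo) else idx
      }))
      xb <- x[keep, , drop = FALSE]
      yb <- droplevels(y[keep])
      if (mode == "split") {
        for (try in 1:20) {
          val <- .stratified_idx(yb, 1 - trainFrac)
          if (length(unique(yb[val])) == 2L && length(val) < length(yb)) break
        }
        .svm_eval(xb[-val, , drop = FALSE], yb[-val],
                  xb[val, , drop = FALSE], yb[val])
      } else {
        folds <- unlist(lapply(levels(yb), function(lv)
          sample(rep_len(seq_len(nFolds), sum(yb == lv)))))
        folds <- folds[order(unlist(lapply(levels(yb),
          function(lv) which(yb == lv))))]
        fold_res <- vapply(seq_len(nFolds), function(f) {
          te <- which(folds == f)
          if (length(unique(yb[te])) < 2L) return(c(acc = NA, auc = NA))
          .svm_eval(xb[-te, , drop = FALSE], yb[-te],
                    xb[te, , drop = FALSE], yb[te])
        }, c(acc = 0, auc = 0))
        rowMeans(fold_res, na.rm = TRUE)
      }
    })
  }
  new("ClassifierReport",
    aucMean = mean(res[, "auc"]), aucSd = stats::sd(res[, "auc"]),
    accMean = mean(res[, "acc"]), accSd = stats::sd(res[, "acc"]),
    pAuc = NA_real_, pAcc = NA_real_, nRepetitions = as.integer(nReps))
}

#' Label-permutation significance of the classifier
#'
#' Re-runs the repeated-split evaluation \code{nNull} times with randomly
#' shuffled class labels and compares the observed mean AUC and accuracy
#' against the null distributions. Default p-values use the add-one
#' convention \eqn{(1 + \#\{null \ge obs\})/(1 + nNull)}; \code{strict =
#' TRUE} counts strictly greater null values over \code{nNull}.
#'
#' @param table feature table from [assembleFeatures()].
#' @param observed the [ClassifierReport-class] under the true labels.
#' @param nNull number of label shuffles (default 1000, >= 100 advised).
#' @param seed integer seed.
#' @param nRepsNull repetitions per null evaluation; defaults to the
#'   observed report's repetition count so null and observed metrics are
#'   exchangeable.
#' @param strict use the strictly-greater counting convention.
#' @param ... passed through to [repeatedSplitEval()] (trainFrac,
#'   balanceTo, mode, nFolds).
#' @return list with \code{pAuc}, \code{pAcc}, the null vectors
#'   \code{nullAuc}, \code{nullAcc}, and \code{report}, the observed
#'   report with its p slots filled in.
#' @export
permutationSignificance <- function(table, observed, nNull = 1000L,
    seed = 1L, nRepsNull = NULL, strict = FALSE, ...) {
  stopifnot(is(observed, "ClassifierReport"), nNull >= 1L)
  if (is.null(nRepsNull)) nRepsNull <- observed@nRepetitions
  null_auc <- null_acc <- numeric(nNull)
  for (k in seq_len(nNull)) {
    tabk <- table
    tabk$label <- .with_seed(.derive_seed(seed, 500000L + k),
      sample(table$label))
    rep_k <- suppressWarnings(repeatedSplitEval(tabk, nReps = nRepsNull,
      seed = .derive_seed(seed, k), ...))
    null_auc[k] <- rep_k@aucMean
    null_acc[k] <- rep_k@accMean
  }
  count_p <- function(null, obs) {
    if (strict) sum(null > obs) / nNull
    else (1 + sum(null >= obs)) / (1 + nNull)
  }
  p_auc <- count_p(null_auc, observed@aucMean)
  p_acc <- count_p(null_acc, observed@accMean)
  observed@pAuc <- p_auc
  observed@pAcc <- p_acc
  list(pAuc = p_auc, pAcc = p_acc, nullAuc = null_auc, nullAcc = null_acc,
    report = observed)
}
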