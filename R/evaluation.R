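#' Evaluation protocols and metrics
#'
#' Session-wise subject-dependent and leave-one-subject-out split protocols,
#' plus accuracy, Cohen's kappa and confusion matrices. Kappa is computed
#' from the pooled confusion matrix with the standard Cohen definition
#' `(p_o - p_e) / (1 - p_e)`, `p_e` from the marginals.
#'
#' @name evaluation
NULL

#' Score predictions against labels
#'
#' @param predictions,labels Equal-length vectors of 0-based class indices.
#' @param n_classes Number of classes C.
#' @return An `eval_report`: `accuracy`, `kappa`, `confusion` (C x C counts,
#'   rows = true, cols = predicted), `n`, and `degenerate_kappa` flag (set
#'   when chance agreement p_e = 1, in which case kappa is 1 if accuracy is
#'   1 and 0 otherwise).
#' @export
#' @examples
#' score(c(0, 1, 1, 0), c(0, 1, 0, 0), n_classes = 2)
score <- function(predictions, labels, n_classes) {
  if (length(predictions) != length(labels)) stop("length mismatch")
  n <- length(labels)
  if (n == 0L) stop("no samples to score")
  predictions <- as.integer(predictions); labels <- as.integer(labels)
  if (any(predictions < 0L | predictions >= n_classes) ||
      any(labels < 0L | labels >= n_classes))
    stop("class index outside 0..C-1")
  conf <- matrix(0L, n_classes, n_classes,
                 dimnames = list(true = 0:(n_classes - 1L),
                                 pred = 0:(n_classes - 1L)))
  for (i in seq_len(n))
    conf[labels[i] + 1L, predictions[i] + 1L] <-
      conf[labels[i] + 1L, predictions[i] + 1L] + 1L
  po <- sum(diag(conf)) / n
  pe <- sum(rowSums(conf) * colSums(conf)) / n^2
  degenerate <- abs(1 - pe) < 1e-12
  kappa <- if (degenerate) {
    if (abs(po - 1) < 1e-12) 1 else 0
  } else (po - pe) / (1 - pe)
  structure(list(accuracy = po, kappa = kappa, confusion = conf, n = n,
                 degenerate_kappa = degenerate),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, accuracy = %.4f, kappa = %.4f\n",
              x$n, x$accuracy, x$kappa))
  print(x$confusion)
  invisible(x)
}

#' Serialize an evaluation report to JSON (+ CSV confusion matrix)
#'
#' @param report An `eval_report`.
#' @param json_path Output JSON path.
#' @param csv_path Optional CSV path for the confusion matrix.
#' @return `json_path`, invisibly.
#' @export
write_eval_report <- function(report, json_path, csv_path = NULL) {
  obj <- list(accuracy = report$accuracy, kappa = report$kappa, n = report$n,
              degenerate_kappa = report$degenerate_kappa,
              confusion = unname(apply(report$confusion, 1L, as.integer,
                                       simplify = FALSE)))
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(report$confusion), csv_path)
  invisible(json_path)
}

#' Subject-dependent (session-wise) split
#'
#' For every subject, session 1 forms the training set and session 2 the
#' test set, matching the competition protocol of training on one recording
#' day and evaluating on the other.
#'
#' @param dataset List of [signal_epoch()] objects with >= 2 sessions per
#'   subject.
#' @return Named list (one entry per subject) of lists with `train` and
#'   `test` index vectors into `dataset`.
#' @export
subject_dependent_split <- function(dataset) {
  man <- epoch_manifest(dataset)
  subjects <- sort(unique(man$subject))
  out <- lapply(subjects, function(s) {
    sess <- sort(unique(man$session[man$subject == s]))
    if (length(sess) < 2L)
      stop(sprintf("subject %d has fewer than 2 sessions", s))
    list(train = which(man$subject == s & man$session == sess[1L]),
         test = which(man$subject == s & man$session == sess[2L]))
  })
  names(out) <- paste0("subject_", subjects)
  out
}

#' Leave-one-subject-out split
#'
#' One fold per subject: that subject's epochs form the test set, all other
#' subjects' epochs the training set.
#'
#' @param dataset List of [signal_epoch()] objects from >= 2 subjects.
#' @return Named list of folds, each with `train`, `test` index vectors and
#'   `test_subject`.
#' @export
loso_split <- function(dataset) {
  man <- epoch_manifest(dataset)
  subjects <- sort(unique(man$subject))
  if (length(subjects) < 2L) stop("leave-one-subject-out needs >= 2 subjects")
  out <- lapply(subjects, function(s)
    list(train = which(man$subject != s), test = which(man$subject == s),
         test_subject = s))
  names(out) <- paste0("subject_", subjects)
  out
}
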