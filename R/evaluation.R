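#' ROC curve and AUC of an SOZ index against clinician labels
#'
#' Sweeps a threshold over the distinct score values to trace the ROC, and
#' computes the AUC as the probability that a randomly chosen positive
#' channel outranks a randomly chosen negative one, ties counting one half
#' (the rank-based concordance form, equivalent to trapezoidal integration
#' of the tie-collapsed ROC). This definition is stated explicitly so
#' results are comparable across implementations.
#'
#' @param scores Per-channel index values (e.g. EI or HI).
#' @param labels Per-channel truth: logical, or 0/1, `TRUE`/1 = SOZ. Must
#'   contain both classes.
#' @return A `seeg_roc` list: `thresholds`, `fpr`, `tpr` (non-decreasing
#'   from (0,0) to (1,1)), `auc`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))$auc  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
    stop_seeg("bad_labels", "scores and labels must match and contain no NA")
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L)
    stop_seeg("single_class", "labels must contain both classes")
  r <- rank(scores)                     # midranks handle ties as 1/2
  auc <- (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  structure(list(thresholds = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr),
                 auc = auc),
            class = "seeg_roc")
}

#' @export
print.seeg_roc <- function(x, ...) {
  cat("<seeg_roc> AUC = ", signif(x$auc, 4), " (",
      length(x$thresholds), " thresholds)\n", sep = "")
  invisible(x)
}

#' Match recovered contacts to ground truth
#'
#' Greedy nearest-neighbor one-to-one matching: repeatedly pair the globally
#' closest (found, truth) contacts while their distance is at most `tol_mm`.
#' The default tolerance of half the 3.5 mm contact pitch prevents a found
#' contact from matching an adjacent truth contact.
#'
#' @param found List of `seeg_contact_set` (or a single one, or an N x 3
#'   matrix of mm coordinates).
#' @param truth A `seeg_truth` from [synth_volume] (or an N x 3 matrix).
#' @param tol_mm Maximum matching distance (mm).
#' @return A `seeg_recovery` list: `n_true`, `n_found`, `n_matched`,
#'   `errors_mm` (per matched pair), `unmatched_truth` and
#'   `unmatched_found` (row indices into the stacked coordinate tables).
#' @export
match_contacts <- function(found, truth, tol_mm = 1.75) {
  as_mat <- function(x) {
    if (is.matrix(x)) return(x)
    if (inherits(x, "seeg_contact_set")) return(x$contacts)
    if (inherits(x, "seeg_truth")) return(do.call(rbind, x$contacts))
    if (is.list(x)) return(do.call(rbind, lapply(x, as_mat)))
    stop_seeg("bad_contacts", "cannot interpret contacts input")
  }
  fm <- as_mat(found); tm <- as_mat(truth)
  nf <- nrow(fm); nt <- nrow(tm)
  if (nf == 0L || nt == 0L)
    return(structure(list(n_true = nt, n_found = nf, n_matched = 0L,
                          errors_mm = numeric(),
                          unmatched_truth = seq_len(nt),
                          unmatched_found = seq_len(nf)),
                     class = "seeg_recovery"))
  d <- sqrt(pmax(outer(rowSums(fm^2), rowSums(tm^2), "+") - 2 * fm %*% t(tm),
                 0))
  err <- numeric(0)
  pairs <- matrix(integer(), 0, 2)
  repeat {
    m <- which.min(d)
    if (!length(m) || d[m] > tol_mm || !is.finite(d[m])) break
    i <- (m - 1) %% nf + 1; j <- (m - 1) %/% nf + 1
    err <- c(err, d[m])
    pairs <- rbind(pairs, c(i, j))
    d[i, ] <- Inf; d[, j] <- Inf
  }
  structure(list(n_true = nt, n_found = nf, n_matched = nrow(pairs),
                 errors_mm = err,
                 unmatched_truth = setdiff(seq_len(nt), pairs[, 2]),
                 unmatched_found = setdiff(seq_len(nf), pairs[, 1])),
            class = "seeg_recovery")
}

#' @export
print.seeg_recovery <- function(x, ...) {
  cat("<seeg_recovery> matched ", x$n_matched, "/", x$n_true,
      " truth contacts (", x$n_found, " found)", sep = "")
  if (x$n_matched)
    cat("; error mean ", signif(mean(x$errors_mm), 3), " mm, max ",
        signif(max(x$errors_mm), 3), " mm", sep = "")
  cat("\n")
  invisible(x)
}
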