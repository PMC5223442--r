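#' Screening confusion counts
#'
#' Builds the count block used by all screening-quality metrics: `D` total
#' library molecules, `A` known actives, `Ht` total hits, `Ha` active hits,
#' and the derived confusion-matrix cells `TP = Ha`, `FN = A - Ha`,
#' `FP = Ht - Ha`, `TN = D - A - FP`.
#'
#' @param D,A,Ht,Ha the four primary counts.
#' @return object of class `screen_counts`.
#' @export
screen_counts <- function(D, A, Ht, Ha) {
  D <- as.numeric(D); A <- as.numeric(A)
  Ht <- as.numeric(Ht); Ha <- as.numeric(Ha)
  if (A > D || Ht > D) stop("A and Ht must not exceed D")
  if (Ha > min(A, Ht) || Ha < 0) stop("Ha must satisfy 0 <= Ha <= min(A, Ht)")
  out <- list(D = D, A = A, Ht = Ht, Ha = Ha,
              TP = Ha, FN = A - Ha, FP = Ht - Ha, TN = D - A - (Ht - Ha))
  if (out$TN < 0) stop("inconsistent counts: derived TN < 0")
  structure(out, class = "screen_counts")
}

#' Confusion counts from identifier sets
#'
#' @param hit_ids character vector of retrieved molecule ids.
#' @param active_ids character vector of known-active ids.
#' @param library_ids character vector of all library ids.
#' @return `screen_counts`.
#' @export
confusion_counts <- function(hit_ids, active_ids, library_ids) {
  library_ids <- unique(as.character(library_ids))
  hit_ids <- unique(as.character(hit_ids))
  active_ids <- unique(as.character(active_ids))
  if (!all(hit_ids %in% library_ids))
    stop("hit ids must be a subset of library ids")
  if (!all(active_ids %in% library_ids))
    stop("active ids must be a subset of library ids")
  screen_counts(D = length(library_ids), A = length(active_ids),
                Ht = length(hit_ids), Ha = length(intersect(hit_ids, active_ids)))
}

#' @export
print.screen_counts <- function(x, ...) {
  cat("Screening counts: D =", x$D, " A =", x$A, " Ht =", x$Ht, " Ha =", x$Ha, "\n")
  cat(sprintf("  TP %d  FN %d  FP %d  TN %d\n", x$TP, x$FN, x$FP, x$TN))
  cat(sprintf("  %% yield of actives (Ha/Ht): %.2f   %% ratio of actives (Ha/A): %.2f\n",
              100 * x$Ha / x$Ht, 100 * x$Ha / x$A))
  invisible(x)
}

#' Sensitivity (true positive rate)
#' @param TP,FN true-positive and false-negative counts.
#' @export
sensitivity <- function(TP, FN) {
  if (TP + FN <= 0) stop("sensitivity undefined: TP + FN = 0")
  TP / (TP + FN)
}

#' Specificity (true negative rate)
#' @param TN,FP true-negative and false-positive counts.
#' @export
specificity <- function(TN, FP) {
  if (TN + FP <= 0) stop("specificity undefined: TN + FP = 0")
  TN / (TN + FP)
}

#' Enrichment factor
#'
#' EF = (Ha * D) / (Ht * A): the active rate among hits relative to the
#' active rate in the whole library. EF = 1 corresponds to random selection;
#' perfect retrieval gives D/A.
#'
#' @param counts a `screen_counts`.
#' @return numeric EF.
#' @export
enrichment_factor <- function(counts) {
  stopifnot(inherits(counts, "screen_counts"))
  if (counts$Ht <= 0 || counts$A <= 0) stop("EF undefined for Ht = 0 or A = 0")
  (counts$Ha * counts$D) / (counts$Ht * counts$A)
}

#' Goodness-of-hit score
#'
#' GH = (Ha (3A + Ht)) / (4 Ht A) * (1 - (Ht - Ha) / (D - A)): a composite of
#' yield and active recovery penalised by false positives. GH > 0.7 is the
#' conventional bar for a good screening model.
#'
#' @param counts a `screen_counts`.
#' @return numeric GH.
#' @export
gh_score <- function(counts) {
  stopifnot(inherits(counts, "screen_counts"))
  if (counts$Ht <= 0 || counts$A <= 0) stop("GH undefined for Ht = 0 or A = 0")
  if (counts$D <= counts$A) stop("GH undefined for D <= A")
  with(counts, (Ha * (3 * A + Ht)) / (4 * Ht * A) * (1 - (Ht - Ha) / (D - A)))
}

#' ROC curve and AUC for active/decoy score lists
#'
#' Thresholds are swept over distinct scores descending; at each threshold a
#' molecule counts as a hit when its score is greater than or equal to the
#' threshold, so tied scores enter as a block (trapezoid over the block is
#' the Mann-Whitney tie convention). `thresholds = "active"` restricts the
#' sweep to observed active scores, mirroring the manual construction used in
#' screening write-ups; `"all"` (default) uses every distinct score.
#'
#' @param active_scores,decoy_scores numeric score vectors (higher = more
#'   active-like).
#' @param thresholds "all" or "active".
#' @return object of class `roc_curve`: data.frame of (threshold, Se,
#'   one_minus_Sp) with attribute `auc`.
#' @export
roc_curve <- function(active_scores, decoy_scores, thresholds = c("all", "active")) {
  thresholds <- match.arg(thresholds)
  stopifnot(length(active_scores) > 0L, length(decoy_scores) > 0L)
  thr <- switch(thresholds,
                all = sort(unique(c(active_scores, decoy_scores)), decreasing = TRUE),
                active = sort(unique(active_scores), decreasing = TRUE))
  nA <- length(active_scores); nD <- length(decoy_scores)
  se <- vapply(thr, function(t) sum(active_scores >= t) / nA, numeric(1))
  fp <- vapply(thr, function(t) sum(decoy_scores >= t) / nD, numeric(1))
  pts <- data.frame(threshold = c(Inf, thr, -Inf),
                    Se = c(0, se, 1),
                    one_minus_Sp = c(0, fp, 1))
  auc <- sum(diff(pts$one_minus_Sp) * (utils::head(pts$Se, -1) + utils::tail(pts$Se, -1)) / 2)
  structure(pts, class = c("roc_curve", "data.frame"), auc = auc)
}

#' Area under a ROC curve
#' @param roc a `roc_curve`.
#' @export
roc_auc <- function(roc) attr(roc, "auc")

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC curve with", nrow(x) - 2L, "thresholds, AUC =",
      format(attr(x, "auc"), digits = 4), "\n")
  invisible(x)
}

#' @method plot roc_curve
#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$one_minus_Sp, x$Se, type = "l", xlab = "1 - Sp", ylab = "Se",
                 main = sprintf("ROC (AUC = %.3f)", attr(x, "auc")), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}
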