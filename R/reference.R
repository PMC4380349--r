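# Published summary figures of the reference cohort: a 299-patient HCC
# hepatectomy series whose printed per-state priors, short-survival
# posteriors, importance values and confusion matrix serve as the package's
# reference inputs. Kept as code (not a data file) so the values are
# greppable next to the functions that consume them.

.hcc_prior_short <- 0.5017

.hcc_reference_rows <- function() {
  # variable, state code, printed prior p(V=j), printed posterior p(S=0|V=j),
  # printed FV, printed MFV, printed importance rank, printed Pearson r,
  # printed Pearson rank
  rows <- list(
    list("sex", c(0.194, 0.806), c(0.5172, 0.4979),
         c(-0.0309, 0.0076), 0.0385, 14L, 0.0153, 14L),
    list("age", c(0.3311, 0.408, 0.2609), c(0.5051, 0.5, 0.5),
         c(-0.0068, 0.0034, 0.0034), 0.0068, 15L, 0.0041, 15L),
    list("hbv", c(0.2341, 0.7659), c(0.5429, 0.4891),
         c(-0.0821, 0.0251), 0.1072, 13L, 0.0455, 12L),
    list("hcv", c(0.9465, 0.0535), c(0.5159, 0.25),
         c(-0.0283, 0.5017), 0.53, 6L, 0.1197, 9L),
    list("afp", c(0.184, 0.4147, 0.4013), c(0.4, 0.5323, 0.5167),
         c(0.2027, -0.061, -0.0299), 0.1468, 12L, -0.0251, 13L),
    list("liver_function", c(0.8194, 0.1806), c(0.4816, 0.5926),
         c(0.0401, -0.1812), 0.2212, 11L, -0.0854, 10L),
    list("tumor_size", c(0.0201, 0.4849, 0.301, 0.194),
         c(0.1667, 0.4, 0.5444, 0.7241),
         c(0.6677, 0.2027, -0.0851, -0.4433), 0.4663, 7L, -0.2044, 5L),
    list("tumor_number", c(0.8328, 0.1672), c(0.4498, 0.76),
         c(0.1034, -0.5148), 0.6183, 4L, -0.2315, 3L),
    list("pvtt", c(0.9164, 0.0836), c(0.4708, 0.84),
         c(0.0616, -0.6743), 0.7359, 1L, -0.2628, 1L),
    list("operative_method", c(0.1304, 0.8696), c(0.8205, 0.4538),
         c(-0.6354, 0.0955), 0.7309, 2L, 0.247, 2L),
    list("metastasis", c(0.8462, 0.1538), c(0.4585, 0.7391),
         c(0.0861, -0.4732), 0.5593, 5L, -0.2025, 6L),
    list("tcph", c(0.4749, 0.5251), c(0.3803, 0.6115),
         c(0.242, -0.2189), 0.4608, 3L, -0.2309, 4L),
    list("blood_loss", c(0.4783, 0.5217), c(0.4196, 0.5769),
         c(0.1636, -0.1499), 0.3135, 9L, -0.1572, 8L),
    list("complication", c(0.5385, 0.4615), c(0.4658, 0.5435),
         c(0.0716, -0.0833), 0.1549, 10L, -0.0774, 11L),
    list("tace", c(0.5351, 0.4649), c(0.5937, 0.3957),
         c(-0.1834, 0.2113), 0.3947, 8L, 0.1976, 7L)
  )
  do.call(rbind, lapply(rows, function(r)
    data.frame(variable = r[[1]], code = seq_along(r[[2]]) - 1L,
               prior = r[[2]], posterior = r[[3]], fv = r[[4]],
               mfv = r[[5]], rank_mfv = r[[6]], pcc = r[[7]],
               rank_pcc = r[[8]], stringsAsFactors = FALSE)))
}

#' Printed importance summary of the reference HCC cohort
#'
#' The per-state priors, posterior short-survival probabilities,
#' Fussell-Vesely values, composite importances (MFV) and ranks published
#' for the 299-patient reference cohort, as a data frame. The printed class
#' prior is attached as attribute `prior_short` (0.5017). These printed
#' values are inputs: [fv_importance()] and [composite_importance()]
#' recompute the FV/MFV columns from the prior/posterior columns, and
#' [replica_counts_cohort()] integer-matches a cohort to them.
#'
#' Note: the published importance-rank column is not everywhere the
#' descending order of the published MFV values; [importance_table()] ranks
#' strictly by descending MFV.
#'
#' @return Data frame with columns `variable`, `code`, `prior`, `posterior`,
#'   `fv`, `mfv`, `rank_mfv`, `pcc`, `rank_pcc`.
#' @export
hcc_importance_reference <- function() {
  out <- .hcc_reference_rows()
  attr(out, "prior_short") <- .hcc_prior_short
  out
}

#' Printed confusion matrix of the reference HCC cohort model
#'
#' The published in-sample confusion matrix of the reference prognostic
#' model at its accuracy-maximizing threshold (0.6127), with the
#' long-survival state as the positive class: TP = 124, FP = 73, FN = 25,
#' TN = 77. Feeding it to [accuracy()] and [rates()] reproduces the
#' published 67.2% accuracy, 83.22% TPR, 48.67% FPR, and 62.94%
#' predicted-positive reliability.
#'
#' @return A `confusion_matrix` object.
#' @export
hcc_confusion_reference <- function() {
  structure(list(tp = 124L, fp = 73L, fn = 25L, tn = 77L,
                 positive = ">10m"),
            class = "confusion_matrix")
}
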