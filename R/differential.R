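#' Per-cell fold changes between two matched tables
#'
#' FOLD[i,k] = treatment[i,k] / reference[i,k]. Any cell where either table
#' is zero is treated as missing and encoded 0, so it can never count as
#' differential.
#'
#' @param treatment,reference `abundance_table`s with identical taxa and days.
#' @return A list of class `"fold_change_matrix"` with `taxa`, `days` and the
#'   `folds` matrix.
#' @export
fold_change <- function(treatment, reference) {
  if (!identical(taxa_names(treatment), taxa_names(reference)))
    stop("treatment and reference tables must share the same taxa, in order")
  if (!identical(treatment$days, reference$days))
    stop("treatment and reference tables must share the same day labels")
  tr <- treatment$values
  rf <- reference$values
  folds <- matrix(0, nrow(tr), ncol(tr), dimnames = dimnames(tr))
  ok <- tr > 0 & rf > 0
  folds[ok] <- tr[ok] / rf[ok]
  structure(list(taxa = taxa_names(treatment), days = treatment$days,
                 folds = folds),
            class = "fold_change_matrix")
}

#' Differential status of each fold change
#'
#' INDEX[i,k] = 1 iff FOLD[i,k] >= fold_threshold (boundary inclusive);
#' ignored cells (fold 0) are never differential.
#'
#' @param folds a `fold_change_matrix`.
#' @param thresholds an [and_thresholds()] object.
#' @return Integer 0/1 matrix of the same shape.
#' @export
differential_status <- function(folds, thresholds = and_thresholds()) {
  status <- (folds$folds >= thresholds$fold_threshold) * 1L
  dimnames(status) <- dimnames(folds$folds)
  status
}

#' Call differentially abundant taxa from an index matrix
#'
#' Splits the `t` time points into an early stage (k <= t_cut) and a late
#' stage (k > t_cut) and calls a taxon differential when it accumulates at
#' least `early_min` differential statuses early AND `late_min` late. The
#' late-stage requirement exists so that taxa differential only during
#' start-up are not called.
#'
#' @param index_matrix 0/1 matrix, rows = taxa, columns = the `t` time points.
#' @param thresholds an [and_thresholds()] object; needs `t_cut < t`.
#' @return data.frame with `taxon`, `early_sum`, `late_sum`, `is_differential`.
#' @export
call_differential <- function(index_matrix, thresholds = and_thresholds()) {
  t_all <- ncol(index_matrix)
  if (thresholds$t_cut >= t_all)
    stop("t_cut (", thresholds$t_cut, ") must be smaller than the number of ",
         "time points (", t_all, ")")
  early <- rowSums(index_matrix[, seq_len(thresholds$t_cut), drop = FALSE])
  late <- rowSums(index_matrix[, (thresholds$t_cut + 1L):t_all, drop = FALSE])
  data.frame(taxon = rownames(index_matrix),
             early_sum = as.integer(early),
             late_sum = as.integer(late),
             is_differential = early >= thresholds$early_min &
               late >= thresholds$late_min,
             row.names = NULL)
}

#' Two-direction differential-abundance table
#'
#' Runs the fold-change caller in both reference directions. With the
#' mesophilic table as reference, a call means the taxon is differentially
#' abundant under thermophilic conditions (direction `UP`); with the
#' thermophilic table as reference, under mesophilic conditions (`DN`).
#' A taxon called in both directions (possible only on pathological input)
#' is flagged `CONFLICT` rather than dropped.
#'
#' @param meso mesophilic `abundance_table`.
#' @param thermo thermophilic `abundance_table` (same taxa and days).
#' @param thresholds an [and_thresholds()] object.
#' @return data.frame with per-taxon early/late sums in each direction and a
#'   `direction` column over `{"UP","DN","CONFLICT","NONE"}`.
#' @export
differential_table <- function(meso, thermo, thresholds = and_thresholds()) {
  up <- call_differential(
    differential_status(fold_change(thermo, meso), thresholds), thresholds)
  dn <- call_differential(
    differential_status(fold_change(meso, thermo), thresholds), thresholds)
  direction <- rep("NONE", nrow(up))
  direction[up$is_differential & !dn$is_differential] <- "UP"
  direction[dn$is_differential & !up$is_differential] <- "DN"
  direction[up$is_differential & dn$is_differential] <- "CONFLICT"
  data.frame(taxon = up$taxon,
             early_up = up$early_sum, late_up = up$late_sum,
             early_dn = dn$early_sum, late_dn = dn$late_sum,
             direction = direction,
             row.names = NULL)
}
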