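#' Construct a trophic (metabolic) index table
#'
#' Ordered taxon pairs with two metabolic indices derived from genome-scale
#' metabolic models: the complementarity index (fraction of one organism's
#' nutritional profile that the other can synthesize; trophic dependence)
#' and the competition index (fraction of the nutritional profile shared;
#' trophic overlap). Both lie in \[0,1\] and are asymmetric in general.
#'
#' @param taxon_a,taxon_b character vectors; the pair is ordered (a, b).
#' @param complementarity,competition numeric vectors in \[0,1\].
#' @param level `"species"` or `"family"`.
#' @return data.frame of class `"trophic_index_table"`.
#' @export
trophic_index_table <- function(taxon_a, taxon_b, complementarity,
                                competition, level = "species") {
  if (any(complementarity < 0 | complementarity > 1) ||
      any(competition < 0 | competition > 1))
    stop("indices must lie in [0, 1]")
  key <- paste(taxon_a, taxon_b, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate ordered pair in index table")
  df <- data.frame(taxon_a = as.character(taxon_a),
                   taxon_b = as.character(taxon_b),
                   complementarity = complementarity,
                   competition = competition, row.names = NULL)
  attr(df, "level") <- match.arg(level, c("species", "family"))
  class(df) <- c("trophic_index_table", "data.frame")
  df
}

#' Read a trophic index table from TSV
#' @param path TSV with columns taxon_a, taxon_b, complementarity, competition.
#' @param level index level of the file.
#' @return A `trophic_index_table`.
#' @export
read_trophic_indices <- function(path, level = "species") {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("taxon_a", "taxon_b", "complementarity", "competition")
  if (!all(need %in% colnames(df)))
    stop("index TSV needs columns ", paste(need, collapse = ", "))
  trophic_index_table(df$taxon_a, df$taxon_b, df$complementarity,
                      df$competition, level)
}

#' Average species-pair indices up to family pairs
#'
#' Every species is mapped to its family and, for each ordered family pair,
#' the member species-pair indices are arithmetically averaged. Applying the
#' operation to a family-level table with the identity mapping is a no-op.
#'
#' @param species_table a species-level `trophic_index_table`.
#' @param species_to_family named character vector, species -> family.
#' @return A family-level `trophic_index_table`.
#' @export
aggregate_to_family <- function(species_table, species_to_family) {
  sp <- unique(c(species_table$taxon_a, species_table$taxon_b))
  unmapped <- setdiff(sp, names(species_to_family))
  if (length(unmapped))
    stop("species without family mapping: ",
         paste(utils::head(unmapped, 5), collapse = ", "))
  fa <- unname(species_to_family[species_table$taxon_a])
  fb <- unname(species_to_family[species_table$taxon_b])
  agg <- stats::aggregate(
    cbind(complementarity, competition) ~ fam_a + fam_b,
    data = data.frame(fam_a = fa, fam_b = fb,
                      complementarity = species_table$complementarity,
                      competition = species_table$competition),
    FUN = mean)
  agg <- agg[order(agg$fam_a, agg$fam_b), , drop = FALSE]
  trophic_index_table(agg$fam_a, agg$fam_b, agg$complementarity,
                      agg$competition, level = "family")
}

#' Join network edges with trophic indices
#'
#' Inner join of the network's directed edges (source -> target) on the
#' ordered index pairs (taxon_a = source, taxon_b = target). Edges without
#' trophic information are dropped; their count is reported via a message
#' and the `"n_unmatched"` attribute.
#'
#' @param network a `confident_network`.
#' @param indices a `trophic_index_table` (family level).
#' @param symmetrize if `TRUE`, use the mean of the (a,b) and (b,a) index
#'   values instead of the directed value (sensitivity mode).
#' @return data.frame with `source`, `target`, `strength`, `sign`,
#'   `complementarity`, `competition`.
#' @export
match_edges <- function(network, indices, symmetrize = FALSE) {
  idx <- as.data.frame(indices)
  if (symmetrize) {
    rev <- idx[, c("taxon_b", "taxon_a", "complementarity", "competition")]
    names(rev) <- names(idx)[1:4]
    both <- rbind(idx, rev)
    idx <- stats::aggregate(cbind(complementarity, competition) ~
                              taxon_a + taxon_b, data = both, FUN = mean)
  }
  m <- merge(network$edges, idx,
             by.x = c("source", "target"), by.y = c("taxon_a", "taxon_b"))
  m <- m[order(m$source, m$target), , drop = FALSE]
  rownames(m) <- NULL
  n_unmatched <- nrow(network$edges) - nrow(m)
  if (n_unmatched > 0)
    message(n_unmatched, " of ", nrow(network$edges),
            " edges had no trophic index and were dropped")
  attr(m, "n_unmatched") <- n_unmatched
  m
}

#' Regress interaction strengths on a metabolic index
#'
#' Positive interactions (strength > 0) are regressed on the
#' complementarity index, negative interactions on the competition index,
#' by ordinary least squares. R-squared is 1 - SSE/SST; the p-value comes
#' from the F statistic on (1, n-2) degrees of freedom (equivalently the
#' two-sided t-test on the slope).
#'
#' @param records output of [match_edges()].
#' @param subset `"positive"` or `"negative"`.
#' @return list with `n`, `slope`, `intercept`, `r_squared`, `p_value`.
#' @export
strength_index_regression <- function(records,
                                      subset = c("positive", "negative")) {
  subset <- match.arg(subset)
  if (subset == "positive") {
    d <- records[records$strength > 0, , drop = FALSE]
    x <- d$complementarity
  } else {
    d <- records[records$strength < 0, , drop = FALSE]
    x <- d$competition
  }
  n <- nrow(d)
  if (n < 3) stop("need at least 3 ", subset, " records, got ", n)
  if (stats::var(x) < .Machine$double.eps)
    stop("index values are constant; regression undefined")
  fit <- stats::lm(d$strength ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(n = n,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                  lower.tail = FALSE)))
}
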