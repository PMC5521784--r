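#' Construct a family-level relative-abundance time series
#'
#' The central data container: a taxa x time-points matrix of relative
#' abundances with integer day labels and a condition tag (e.g. "mesophilic"
#' for a 37 degree C digester). Values are stored as fractions; percentages
#' appear only at I/O.
#'
#' @param values numeric matrix, rows = taxa (rownames required, unique),
#'   columns = time points; all entries finite and >= 0.
#' @param days integer vector of day labels, strictly increasing, one per column.
#' @param condition free-text condition label.
#' @return An object of class `"abundance_table"` with elements `values`,
#'   `days` and `condition`.
#' @examples
#' m <- matrix(c(0.6, 0.4, 0.4, 0.6), 2,
#'             dimnames = list(c("FamA", "FamB"), NULL))
#' abundance_table(m, days = c(18, 24), condition = "mesophilic")
#' @export
abundance_table <- function(values, days, condition = "unspecified") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    stop("abundance values must have taxon rownames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate taxon label: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (any(!is.finite(values)))
    stop("abundance values must be finite and numeric")
  if (any(values < 0))
    stop("abundance values must be non-negative")
  days <- as.integer(days)
  if (length(days) != ncol(values))
    stop("length(days) must equal the number of columns")
  if (length(days) > 1 && any(diff(days) <= 0))
    stop("day labels must be strictly increasing")
  colnames(values) <- paste0("T_", days)
  structure(list(values = values, days = days,
                 condition = as.character(condition)[1]),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d taxa x %d time points (%s), days %s-%s\n",
              nrow(x$values), ncol(x$values), x$condition,
              min(x$days), max(x$days)))
  invisible(x)
}

#' @rdname abundance_table
#' @param x an `abundance_table`.
#' @export
taxa_names <- function(x) rownames(x$values)

#' Subset an abundance table to a set of taxa
#'
#' @param x an `abundance_table`.
#' @param taxa taxon labels to keep; original row order is preserved.
#' @return An `abundance_table` restricted to `taxa`.
#' @export
subset_taxa <- function(x, taxa) {
  missing <- setdiff(taxa, taxa_names(x))
  if (length(missing))
    stop("unknown taxa: ", paste(missing, collapse = ", "))
  keep <- taxa_names(x)[taxa_names(x) %in% taxa]
  abundance_table(x$values[keep, , drop = FALSE], x$days, x$condition)
}

#' Read an abundance table from TSV
#'
#' Expects a UTF-8 tab-separated file whose first column holds taxon labels
#' and whose remaining column headers are day labels, either bare integers or
#' `T_<int>` (the study's `T_18 ... T_60` convention).
#'
#' @param path path to the TSV file.
#' @param condition condition label attached to the table.
#' @param percent if `TRUE`, cell values are percentages and are divided by 100.
#' @return An `abundance_table`.
#' @export
read_abundance_table <- function(path, condition = "unspecified",
                                 percent = FALSE) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("abundance TSV needs a taxon column plus at least one day column")
  taxa <- as.character(df[[1]])
  labels <- colnames(df)[-1]
  days <- suppressWarnings(as.integer(sub("^T_?", "", labels)))
  if (any(is.na(days)))
    stop("day labels must be integers or 'T_<int>': ",
         paste(labels[is.na(days)], collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals))
    stop("non-numeric abundance cell in ", path)
  rownames(vals) <- taxa
  if (percent) vals <- vals / 100
  abundance_table(vals, days, condition)
}

#' Write an abundance table to TSV
#'
#' @param x an `abundance_table`.
#' @param path output path.
#' @export
write_abundance_table <- function(x, path) {
  df <- data.frame(taxon = taxa_names(x), x$values,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Renormalize each time point to relative abundances
#'
#' Divides every column by its sum so columns sum to one (compositional
#' closure). A column with no positive value is an error.
#'
#' @param x an `abundance_table`.
#' @return An `abundance_table` whose columns each sum to 1.
#' @export
to_relative <- function(x) {
  cs <- colSums(x$values)
  if (any(cs <= 0))
    stop("cannot normalize: column(s) ",
         paste(which(cs <= 0), collapse = ", "), " sum to zero")
  abundance_table(sweep(x$values, 2, cs, "/"), x$days, x$condition)
}

#' Mean abundance over the samples where a taxon is present
#'
#' The per-taxon mean statistic: the sum of a taxon's relative abundances
#' divided by the number of time points where it is non-zero. A taxon absent
#' everywhere has mean 0 (rather than 0/0).
#'
#' @param x an `abundance_table`.
#' @param taxon taxon label.
#' @return A single fraction.
#' @examples
#' m <- matrix(c(0.2, 0, 0.4), 1, dimnames = list("FamA", NULL))
#' tab <- abundance_table(m, c(18, 24, 30))
#' mean_nonzero(tab, "FamA")  # 0.6 / 2 = 0.3
#' @export
mean_nonzero <- function(x, taxon) {
  if (!taxon %in% taxa_names(x))
    stop("unknown taxon: ", taxon)
  row <- x$values[taxon, ]
  nz <- sum(row > 0)
  if (nz == 0) return(0)
  sum(row) / nz
}

#' Abundance class of a mean percentage
#'
#' HIGH when a taxon holds strictly more than 1% of total sequences, LOW in
#' the inclusive 0.1%-1% band, RARE below 0.1%.
#'
#' @param mean_percent mean abundance as a percentage (vectorized).
#' @param thresholds an [and_thresholds()] object (cuts stored as fractions).
#' @return Character vector over `{"HIGH","LOW","RARE"}`.
#' @examples
#' classify_abundance(c(13.51, 0.68, 0.06))
#' @export
classify_abundance <- function(mean_percent, thresholds = and_thresholds()) {
  if (any(mean_percent < 0)) stop("mean abundance cannot be negative")
  frac <- mean_percent / 100
  cls <- ifelse(frac > thresholds$high_cut, "HIGH",
                ifelse(frac >= thresholds$low_cut, "LOW", "RARE"))
  as.character(cls)
}

#' Per-taxon mean abundance and class annotation
#'
#' @param x an `abundance_table` (fractions).
#' @param thresholds an [and_thresholds()] object.
#' @return data.frame with columns `taxon`, `mean_abundance` (fraction),
#'   `class`.
#' @export
annotate_abundance <- function(x, thresholds = and_thresholds()) {
  means <- vapply(taxa_names(x), function(tx) mean_nonzero(x, tx), numeric(1))
  data.frame(taxon = taxa_names(x),
             mean_abundance = unname(means),
             class = classify_abundance(means * 100, thresholds),
             row.names = NULL)
}

#' Shannon diversity of one abundance vector
#'
#' H = -sum p_i log p_i in nats, over the positive entries of the normalized
#' vector.
#'
#' @param x non-negative numeric vector with positive sum.
#' @return Shannon index in nats.
#' @examples
#' shannon_index(rep(1, 4))  # log(4)
#' @export
shannon_index <- function(x) {
  if (any(x < 0)) stop("abundances must be non-negative")
  s <- sum(x)
  if (s <= 0) stop("cannot compute Shannon index of an all-zero vector")
  p <- x[x > 0] / s
  -sum(p * log(p))
}

#' Analytic rarefaction curve
#'
#' Expected number of taxa observed in a uniform subsample of `d` reads drawn
#' without replacement from `counts` (hypergeometric expectation):
#' E[S(d)] = sum_i (1 - choose(T - c_i, d) / choose(T, d)), T = sum(counts).
#' Deterministic, no resampling.
#'
#' @param counts non-negative integer read counts per taxon.
#' @param depths integer subsample sizes, each <= sum(counts).
#' @return Numeric vector of expected richness, one per depth.
#' @export
rarefaction_curve <- function(counts, depths) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  total <- sum(counts)
  depths <- as.numeric(depths)
  if (any(depths < 0) || any(depths != floor(depths)))
    stop("depths must be non-negative integers")
  if (any(depths > total))
    stop("depth exceeds the total count (", total, ")")
  vapply(depths, function(d) {
    if (d == 0) return(0)
    # log-scale binomial ratios keep large counts stable
    sum(1 - exp(lchoose(total - counts, d) - lchoose(total, d)))
  }, numeric(1))
}
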