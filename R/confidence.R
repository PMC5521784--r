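#' Build a BRP/NBRP annotation
#'
#' Taxa are exhaustively split into biogas-related-pathway (BRP) families —
#' hydrolysis (p1), acidogenesis (p2), acetogenesis (p3), methanogenesis
#' (p4) or desulfurization (deS) — and all other (NBRP) families.
#'
#' @param taxon character vector of taxon labels.
#' @param group character vector over `{"BRP","NBRP"}`.
#' @param pathway optional pathway tag for BRP taxa (`NA` for NBRP).
#' @return data.frame of class `"brp_annotation"`.
#' @export
brp_annotation <- function(taxon, group, pathway = NA_character_) {
  group <- as.character(group)
  if (!all(group %in% c("BRP", "NBRP")))
    stop("group must be 'BRP' or 'NBRP'")
  if (anyDuplicated(taxon)) stop("duplicate taxon in annotation")
  df <- data.frame(taxon = as.character(taxon), group = group,
                   pathway = as.character(pathway), row.names = NULL)
  class(df) <- c("brp_annotation", "data.frame")
  df
}

#' Read a BRP annotation from TSV (columns taxon, group\[, pathway\])
#' @param path TSV path.
#' @return A `brp_annotation`.
#' @export
read_brp_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("taxon", "group") %in% colnames(df)))
    stop("annotation TSV needs 'taxon' and 'group' columns: ", path)
  brp_annotation(df$taxon, df$group,
                 if ("pathway" %in% colnames(df)) df$pathway else NA)
}

#' Split a table into its BRP sub-table and the NBRP taxon list
#'
#' @param table an `abundance_table`; every taxon must be annotated.
#' @param annotation a `brp_annotation`.
#' @return list with `brp_table` (row-subset, order preserved) and
#'   `nbrp_taxa` (character vector).
#' @export
partition_taxa <- function(table, annotation) {
  tx <- taxa_names(table)
  missing <- setdiff(tx, annotation$taxon)
  if (length(missing))
    stop("unannotated taxa: ", paste(utils::head(missing, 5), collapse = ", "))
  grp <- annotation$group[match(tx, annotation$taxon)]
  list(brp_table = subset_taxa(table, tx[grp == "BRP"]),
       nbrp_taxa = tx[grp == "NBRP"])
}

#' Raw BRP interaction network
#'
#' Interaction inference restricted to the BRP families alone; an N-family
#' group yields N(N-1) raw interactions.
#'
#' @param brp_table BRP-only `abundance_table`.
#' @param ... passed to [infer_interactions()].
#' @return An `interaction_matrix`.
#' @export
raw_brp_network <- function(brp_table, ...) {
  if (nrow(brp_table$values) < 1) stop("BRP table is empty")
  infer_interactions(brp_table, ...)
}

#' Consensus sign profile over resampled mixed networks
#'
#' Repeats interaction inference `n_sim` times on the BRP families plus a
#' random subset of `n_nbrp_sample` NBRP families (uniform, without
#' replacement, fresh each run) and records, for every ordered BRP pair, the
#' fraction P of runs in which the inferred effect is positive. P near 1
#' (or 0) means the sign is coherent across community contexts.
#'
#' @param table full `abundance_table` (BRP + NBRP taxa).
#' @param annotation a `brp_annotation` covering all taxa.
#' @param thresholds an [and_thresholds()] (uses `n_sim`, `n_nbrp_sample`).
#' @param seed integer RNG seed; identical seeds give identical profiles.
#' @param n_components fixed PLS component count used inside each run
#'   (default 3; per-run cross-validated selection would dominate runtime).
#' @return list of class `"consensus_profile"` with a `pairs` data.frame
#'   (`target`, `source`, `positive_count`, `P`), plus `n_sim`, `seed`,
#'   `n_components`.
#' @export
simulate_mixed_networks <- function(table, annotation,
                                    thresholds = and_thresholds(),
                                    seed, n_components = 3) {
  if (missing(seed)) stop("a seed is required for reproducible resampling")
  part <- partition_taxa(table, annotation)
  brp <- taxa_names(part$brp_table)
  nbrp <- part$nbrp_taxa
  if (thresholds$n_nbrp_sample > length(nbrp))
    stop("n_nbrp_sample (", thresholds$n_nbrp_sample,
         ") exceeds available NBRP taxa (", length(nbrp), ")")
  nb <- length(brp)
  pos <- matrix(0L, nb, nb, dimnames = list(brp, brp))
  set.seed(as.integer(seed))
  for (s in seq_len(thresholds$n_sim)) {
    chosen <- sample(nbrp, thresholds$n_nbrp_sample)
    mixed <- subset_taxa(table, c(brp, chosen))
    im <- infer_interactions(mixed, n_components = n_components)
    pos <- pos + (im$effects[brp, brp, drop = FALSE] > 0)
  }
  off <- which(row(pos) != col(pos))
  pairs <- data.frame(
    target = brp[row(pos)[off]],
    source = brp[col(pos)[off]],
    positive_count = as.integer(pos[off]),
    P = pos[off] / thresholds$n_sim,
    row.names = NULL)
  pairs <- pairs[order(pairs$target, pairs$source), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, n_sim = thresholds$n_sim,
                 seed = as.integer(seed), n_components = n_components),
            class = "consensus_profile")
}

#' Classify one interaction from its raw strength and consensus probability
#'
#' The four-condition rule: an interaction is a confident activation when
#' P >= p_threshold and the raw strength is positive, a confident repression
#' when P <= 1 - p_threshold and the raw strength is negative; every other
#' combination — including a zero strength and any intermediate P — is
#' non-confident.
#'
#' @param strength raw BRP effect (vectorized).
#' @param P consensus positive fraction in \[0,1\] (vectorized).
#' @param p_threshold coherence threshold (default 0.95).
#' @return Character vector over `{"CONFIDENT_ACTIVATION",
#'   "CONFIDENT_REPRESSION", "NON_CONFIDENT"}`.
#' @export
classify_interaction <- function(strength, P, p_threshold = 0.95) {
  if (any(P < 0 | P > 1)) stop("P must lie in [0, 1]")
  cls <- rep("NON_CONFIDENT", length(strength))
  cls[P >= p_threshold & strength > 0] <- "CONFIDENT_ACTIVATION"
  cls[P <= 1 - p_threshold & strength < 0] <- "CONFIDENT_REPRESSION"
  cls
}

#' High-confidence BRP interaction network
#'
#' Keeps the ordered BRP pairs whose raw sign agrees with the consensus
#' profile under the four-condition rule. Strengths and signs come from the
#' raw network; P from the profile.
#'
#' @param raw `interaction_matrix` of the BRP families.
#' @param consensus matching `consensus_profile`.
#' @param thresholds an [and_thresholds()] (uses `p_threshold`).
#' @return Object of class `"confident_network"`: a list with `edges`
#'   (data.frame `source`, `target`, `strength`, `sign`, `P`), `taxa`,
#'   `condition`, `p_threshold`.
#' @export
build_confident_network <- function(raw, consensus,
                                    thresholds = and_thresholds()) {
  pr <- consensus$pairs
  if (!setequal(raw$taxa, unique(c(pr$target, pr$source))) ||
      nrow(pr) != length(raw$taxa) * (length(raw$taxa) - 1L))
    stop("raw network and consensus profile cover different taxon pairs")
  strength <- raw$effects[cbind(match(pr$target, raw$taxa),
                                match(pr$source, raw$taxa))]
  cls <- classify_interaction(strength, pr$P, thresholds$p_threshold)
  keep <- cls != "NON_CONFIDENT"
  edges <- data.frame(
    source = pr$source[keep], target = pr$target[keep],
    strength = strength[keep],
    sign = ifelse(strength[keep] > 0, "activation", "repression"),
    P = pr$P[keep], row.names = NULL)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, taxa = raw$taxa,
                 condition = raw$condition,
                 p_threshold = thresholds$p_threshold),
            class = "confident_network")
}

#' @export
print.confident_network <- function(x, ...) {
  cat(sprintf(
    "confident_network (%s): %d edges (%d activation, %d repression) over %d taxa, P threshold %.2f\n",
    x$condition, nrow(x$edges), sum(x$edges$sign == "activation"),
    sum(x$edges$sign == "repression"), length(x$taxa), x$p_threshold))
  invisible(x)
}

#' Write a confident network's edge list to TSV
#' @param x a `confident_network`.
#' @param path output path.
#' @export
write_network_edges <- function(x, path) {
  utils::write.table(x$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
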