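# Independent oracles used across test files. Each is deliberately written
# with a different algorithm than the implementation it checks.

# OLS via normal equations (with intercept), for checking full-rank PLS.
ols_oracle <- function(X, y) {
  Xa <- cbind(1, X)
  beta <- solve(crossprod(Xa), crossprod(Xa, y))
  list(intercept = beta[1], coefficients = beta[-1])
}

# Differential call by direct evaluation of the early/late counting rule,
# including the redundant total >= early_min + late_min clause.
diff_call_oracle <- function(index, t_cut = 7, early_min = 4, late_min = 2) {
  early <- sum(index[seq_len(t_cut)])
  late <- sum(index[(t_cut + 1):length(index)])
  (early + late >= early_min + late_min) &&
    early >= early_min && late >= late_min
}

# Six-cell truth table for interaction classification, written out cell by
# cell rather than via threshold comparisons on vectors.
classify_oracle <- function(strength, P, thr = 0.95) {
  high <- P >= thr
  low <- P <= 1 - thr
  if (high && strength > 0) return("CONFIDENT_ACTIVATION")
  if (high && strength <= 0) return("NON_CONFIDENT")
  if (low && strength >= 0) return("NON_CONFIDENT")
  if (low && strength < 0) return("CONFIDENT_REPRESSION")
  "NON_CONFIDENT"
}

# Betweenness by exhaustive enumeration of all simple paths, keeping the
# shortest ones per ordered pair and splitting credit among ties.
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  bc <- stats::setNames(numeric(n), rownames(adj))
  all_paths <- function(s, t) {
    res <- list()
    recurse <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        res[[length(res) + 1]] <<- path
        return(invisible())
      }
      for (w in which(adj[v, ] > 0)) if (!(w %in% path)) recurse(c(path, w))
    }
    recurse(s)
    res
  }
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    ps <- all_paths(s, t)
    if (!length(ps)) next
    lens <- vapply(ps, length, integer(1))
    sp <- ps[lens == min(lens)]
    for (p in sp) {
      for (v in setdiff(p, c(s, t))) bc[v] <- bc[v] + 1 / length(sp)
    }
  }
  bc
}

# Dominant eigenvector of the symmetrized adjacency from a dense solver.
eigen_oracle <- function(adj) {
  S <- pmax(adj, t(adj))
  ev <- eigen(S, symmetric = TRUE)
  v <- abs(ev$vectors[, which.max(ev$values)])
  v / max(v)
}

# Build a confident_network object directly for topology tests.
mock_network <- function(edges, taxa = NULL) {
  if (is.null(taxa)) taxa <- sort(unique(c(edges$source, edges$target)))
  if (is.null(edges$sign)) edges$sign <- ifelse(edges$strength > 0,
                                                "activation", "repression")
  if (is.null(edges$P)) edges$P <- ifelse(edges$strength > 0, 1, 0)
  structure(list(edges = edges, taxa = taxa, condition = "test",
                 p_threshold = 0.95),
            class = "confident_network")
}

# Small abundance table with given dimensions and positive random entries.
random_table <- function(n_taxa, days, seed, condition = "test") {
  set.seed(seed)
  m <- matrix(stats::runif(n_taxa * length(days), 0.01, 1), n_taxa,
              dimnames = list(sprintf("Fam%02d", seq_len(n_taxa)), NULL))
  to_relative(abundance_table(m, days, condition))
}
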