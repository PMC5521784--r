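#' @keywords internal
#' Replace zeros by half the smallest positive value of the whole table.
replace_zeros <- function(values) {
  pos <- values[values > 0]
  if (!length(pos))
    stop("table contains no positive abundance; cannot take logs")
  values[values == 0] <- min(pos) / 2
  values
}

#' Log-ratio growth gradients of a time series
#'
#' Discretizes the generalized Lotka-Volterra system by exponential-Euler
#' gradient matching: for each transition k the response is
#' g_i(k) = (ln x_i(t_{k+1}) - ln x_i(t_k)) / (t_{k+1} - t_k)
#' and the predictors are the abundances of all taxa at the transition's left
#' endpoint. Zeros are replaced by half the table's smallest positive value
#' before taking logs.
#'
#' @param table an `abundance_table` with at least 3 time points.
#' @return A list of class `"gradient_set"` with `gradients` (transitions x
#'   taxa matrix of per-day log growth rates), `predictors` (transitions x
#'   taxa left-endpoint abundances) and `dt` (day spacings).
#' @export
log_gradients <- function(table) {
  t_all <- ncol(table$values)
  if (t_all < 3)
    stop("need at least 3 time points to form gradients")
  x <- replace_zeros(table$values)
  lx <- log(x)
  dt <- diff(table$days)
  grads <- t((lx[, -1, drop = FALSE] - lx[, -t_all, drop = FALSE])) / dt
  preds <- t(x[, -t_all, drop = FALSE])
  rownames(grads) <- rownames(preds) <- paste0("k", seq_len(t_all - 1))
  structure(list(gradients = grads, predictors = preds, dt = dt,
                 taxa = taxa_names(table)),
            class = "gradient_set")
}

#' Univariate partial least squares regression (NIPALS)
#'
#' Deterministic PLS1: predictors are centered and autoscaled to unit
#' variance (constant columns left unscaled), the response is centered but
#' not scaled, latent components are extracted by NIPALS with deflation, and
#' coefficients are back-transformed to the original predictor scale.
#' Extraction stops early if the residual response is numerically exhausted,
#' so a constant response yields all-zero coefficients with the mean as
#' intercept.
#'
#' @param X predictor matrix, one row per observation.
#' @param y numeric response, length `nrow(X)`.
#' @param n_components number of latent components,
#'   `1 <= n_components <= min(nrow(X) - 1, ncol(X))`.
#' @return list with `coefficients` (original scale), `intercept` and
#'   `n_components` actually extracted.
#' @export
pls_regress <- function(X, y, n_components) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("need at least 2 observations")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  n_components <- as.integer(n_components)
  if (n_components < 1 || n_components > min(n - 1, p))
    stop("n_components must lie in [1, min(nrow - 1, ncol)] = [1, ",
         min(n - 1, p), "]")
  xm <- colMeans(X)
  xs <- apply(X, 2, stats::sd)
  xs[!is.finite(xs) | xs < .Machine$double.eps] <- 1
  Xc <- sweep(sweep(X, 2, xm), 2, xs, "/")
  ym <- mean(y)
  yc <- y - ym

  W <- P <- matrix(0, p, n_components)
  Q <- numeric(n_components)
  used <- 0L
  for (a in seq_len(n_components)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    tt <- drop(Xc %*% w)
    tt2 <- sum(tt^2)
    if (tt2 < 1e-12) break
    pp <- drop(crossprod(Xc, tt)) / tt2
    qq <- sum(yc * tt) / tt2
    Xc <- Xc - tcrossprod(tt, pp)
    yc <- yc - tt * qq
    W[, a] <- w; P[, a] <- pp; Q[a] <- qq
    used <- a
  }
  if (used == 0L) {
    coefs <- numeric(p)
  } else {
    Wa <- W[, seq_len(used), drop = FALSE]
    Pa <- P[, seq_len(used), drop = FALSE]
    b_scaled <- drop(Wa %*% solve(crossprod(Pa, Wa), Q[seq_len(used)]))
    coefs <- b_scaled / xs
  }
  names(coefs) <- colnames(X)
  list(coefficients = coefs,
       intercept = ym - sum(coefs * xm),
       n_components = used)
}

#' Choose a PLS component count by leave-one-out cross-validation
#'
#' Scans 1..max_components, computing the PRESS statistic under leave-one-out
#' refits, and returns the count with the smallest PRESS (ties go to the
#' smallest count). With fewer than 3 observations LOO is impossible and 1
#' component is returned. The procedure is deterministic and invariant to
#' the order of observations.
#'
#' @param X predictor matrix.
#' @param y numeric response.
#' @param max_components upper bound on the component count scanned.
#' @return An integer component count.
#' @export
select_components <- function(X, y, max_components) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) return(1L)
  maxc <- min(as.integer(max_components), n - 2L, ncol(X))
  if (maxc < 1) return(1L)
  press <- numeric(maxc)
  for (a in seq_len(maxc)) {
    sse <- 0
    for (i in seq_len(n)) {
      fit <- pls_regress(X[-i, , drop = FALSE], y[-i], a)
      pred <- sum(fit$coefficients * X[i, ]) + fit$intercept
      sse <- sse + (y[i] - pred)^2
    }
    press[a] <- sse
  }
  # tolerance absorbs float jitter between numerically identical counts
  best <- min(press)
  which(press <= best + 1e-12 * (1 + best))[1]
}

#' Infer a signed gLV interaction matrix from one condition's time series
#'
#' For each target taxon i, regresses its log-ratio growth gradients on the
#' abundances of all taxa at the left transition endpoints using NIPALS PLS.
#' The intercept is the intrinsic growth rate r_i (per day); the coefficient
#' on taxon j is M\[i,j\], the signed effect of j on i (per day per unit
#' abundance). Self-effects sit on the diagonal and are excluded from
#' interaction counts, so an N-taxon table yields N(N-1) interactions.
#'
#' @param table an `abundance_table`.
#' @param n_components fixed component count for every target, or `NULL`
#'   (default) to select per target by leave-one-out PRESS.
#' @param max_components cap on the component scan when selecting; defaults
#'   to `min(t - 2, N)`.
#' @return A list of class `"interaction_matrix"` with `taxa`,
#'   `growth_rates`, `effects` (N x N, rows = targets), `n_components_used`
#'   and `condition`.
#' @export
infer_interactions <- function(table, n_components = NULL,
                               max_components = NULL) {
  gs <- log_gradients(table)
  X <- gs$predictors
  n_obs <- nrow(X)
  n_tax <- ncol(X)
  cap <- min(n_obs - 1L, n_tax)
  if (!is.null(n_components))
    n_components <- min(as.integer(n_components), cap)
  if (is.null(max_components)) max_components <- cap

  r <- numeric(n_tax)
  M <- matrix(0, n_tax, n_tax, dimnames = list(gs$taxa, gs$taxa))
  used <- integer(n_tax)
  for (i in seq_len(n_tax)) {
    y <- gs$gradients[, i]
    a <- if (is.null(n_components)) {
      select_components(X, y, max_components)
    } else n_components
    fit <- pls_regress(X, y, a)
    r[i] <- fit$intercept
    M[i, ] <- fit$coefficients
    used[i] <- fit$n_components
  }
  names(r) <- gs$taxa
  structure(list(taxa = gs$taxa, growth_rates = r, effects = M,
                 n_components_used = used, condition = table$condition),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  n <- length(x$taxa)
  cat(sprintf("interaction_matrix: %d taxa, %d off-diagonal interactions (%s)\n",
              n, n * (n - 1L), x$condition))
  invisible(x)
}

#' Long-format edge list of an interaction matrix
#'
#' @param x an `interaction_matrix`.
#' @param drop_self drop diagonal self-effects (default TRUE).
#' @return data.frame with `source`, `target`, `strength` (effect of source
#'   on target).
#' @export
interaction_edges <- function(x, drop_self = TRUE) {
  n <- length(x$taxa)
  df <- data.frame(
    source = rep(x$taxa, each = n),   # column j of effects
    target = rep(x$taxa, times = n),  # row i
    strength = as.vector(x$effects),  # column-major: target varies fastest
    row.names = NULL)
  if (drop_self) df <- df[df$source != df$target, , drop = FALSE]
  rownames(df) <- NULL
  df
}
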