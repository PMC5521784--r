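#' Simulation configuration for the synthetic gLV community
#'
#' Defaults emulate the anaerobic-digester study design: 173 family-level
#' taxa observed at ten days (18, 24, 30, 34, 38, 42, 46, 50, 58, 60) per
#' condition, compositional tables (closure on), a sparse interaction matrix
#' with strictly self-limiting diagonals, and mild multiplicative lognormal
#' noise.
#'
#' @param n_taxa number of taxa (default 173).
#' @param days sampling days, strictly increasing (default the study grid).
#' @param interaction_density fraction of off-diagonal effects that are
#'   non-zero (default 0.05).
#' @param interaction_scale standard deviation of non-zero off-diagonal
#'   effects, per day per unit abundance (default 1).
#' @param self_limitation magnitude of the negative diagonal, per day per
#'   unit abundance (default 10) — keeps trajectories bounded.
#' @param growth_rate_range range of intrinsic growth rates, per day
#'   (default c(0.05, 0.15)).
#' @param noise_sigma lognormal sigma of multiplicative observation noise
#'   (default 0.05).
#' @param closure renormalize every time point to sum to 1 (default TRUE).
#' @param seed integer RNG seed.
#' @return list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_taxa = 173L,
                              days = c(18L, 24L, 30L, 34L, 38L, 42L, 46L,
                                       50L, 58L, 60L),
                              interaction_density = 0.05,
                              interaction_scale = 1,
                              self_limitation = 10,
                              growth_rate_range = c(0.05, 0.15),
                              noise_sigma = 0.05,
                              closure = TRUE,
                              seed = 1L) {
  days <- as.integer(days)
  if (length(days) > 1 && any(diff(days) <= 0))
    stop("days must be strictly increasing")
  if (interaction_density < 0 || interaction_density > 1)
    stop("interaction_density must lie in [0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  stopifnot(n_taxa >= 1, self_limitation > 0,
            length(growth_rate_range) == 2)
  structure(list(n_taxa = as.integer(n_taxa), days = days,
                 interaction_density = interaction_density,
                 interaction_scale = interaction_scale,
                 self_limitation = self_limitation,
                 growth_rate_range = growth_rate_range,
                 noise_sigma = noise_sigma, closure = isTRUE(closure),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Draw a random sparse gLV system
#'
#' Off-diagonal effects are non-zero with probability
#' `interaction_density`, drawn N(0, interaction_scale^2); every diagonal
#' is `-self_limitation` (strict self-limitation, required for bounded
#' trajectories). Growth rates are uniform on `growth_rate_range` and the
#' initial state is positive, summing to 1.
#'
#' @param config a [simulation_config()]; seeds the RNG.
#' @return list with `r` (growth rates), `M` (effects, rows = targets),
#'   `x0` (initial state), `taxa` (labels).
#' @export
random_glv_system <- function(config) {
  set.seed(config$seed)
  n <- config$n_taxa
  taxa <- sprintf("Family_%03d", seq_len(n))
  r <- stats::runif(n, config$growth_rate_range[1],
                    config$growth_rate_range[2])
  M <- matrix(0, n, n, dimnames = list(taxa, taxa))
  off <- which(row(M) != col(M))
  nz <- off[stats::runif(length(off)) < config$interaction_density]
  M[nz] <- stats::rnorm(length(nz), 0, config$interaction_scale)
  diag(M) <- -config$self_limitation
  x0 <- stats::runif(n, 0.5, 1.5)
  x0 <- x0 / sum(x0)
  names(r) <- names(x0) <- taxa
  list(r = r, M = M, x0 = x0, taxa = taxa)
}

# Deterministic exponential-Euler trajectory, no noise, no closure.
glv_trajectory <- function(r, M, x0, days) {
  n <- length(x0)
  t_all <- length(days)
  X <- matrix(0, n, t_all)
  X[, 1] <- x0
  dt <- diff(days)
  for (k in seq_len(t_all - 1)) {
    x <- X[, k]
    X[, k + 1] <- x * exp((r + drop(M %*% x)) * dt[k])
    if (any(!is.finite(X[, k + 1])))
      stop("trajectory blew up at day ", days[k + 1],
           "; increase self_limitation or shrink interaction_scale")
  }
  rownames(X) <- names(x0)
  X
}

#' Simulate a gLV abundance time series
#'
#' Exponential-Euler update
#' x_i(t_{k+1}) = x_i(t_k) exp\[(r_i + sum_j M_ij x_j(t_k)) dt_k\] * eps_ik,
#' with eps lognormal(0, noise_sigma^2). The update matches the inference
#' discretization exactly, so with noise and closure off the round trip
#' through [infer_interactions()] recovers (r, M) to numerical precision.
#' With closure on, each time point is renormalized to sum to one.
#' Trajectories are clipped below at 1e-12 (with a warning). Noise draws are
#' seeded from `config$seed + 1` (the system itself uses `config$seed`).
#'
#' @param r growth-rate vector.
#' @param M effect matrix (rows = targets).
#' @param x0 positive initial state.
#' @param config a [simulation_config()].
#' @return An `abundance_table` (condition `"synthetic"`).
#' @export
simulate_glv <- function(r, M, x0, config) {
  if (any(x0 <= 0)) stop("x0 must be strictly positive")
  X <- glv_trajectory(r, M, x0, config$days)
  if (config$noise_sigma > 0) {
    set.seed(config$seed + 1L)
    X <- X * matrix(stats::rlnorm(length(X), 0, config$noise_sigma),
                    nrow(X), ncol(X))
  }
  if (any(X < 1e-12)) {
    warning("trajectory clipped below at 1e-12 for ",
            sum(X < 1e-12), " cell(s)")
    X[X < 1e-12] <- 1e-12
  }
  if (config$closure) X <- sweep(X, 2, colSums(X), "/")
  abundance_table(X, config$days, "synthetic")
}

#' Two-condition study with planted differential taxa
#'
#' Emulates the mesophilic/thermophilic design: one deterministic gLV
#' trajectory provides the shared community backbone; each condition then
#' receives independent multiplicative lognormal noise, and the treatment
#' (thermophilic) condition has `n_planted_up` randomly chosen taxa scaled
#' up by `effect_fold` and `n_planted_down` scaled down by `1/effect_fold`
#' across all time points, before compositional closure. The true labels
#' are returned for recovery tests. `UP` means more abundant under the
#' thermophilic condition.
#'
#' @param config a [simulation_config()].
#' @param n_planted_up,n_planted_down number of planted taxa per direction.
#' @param effect_fold planted fold change (> the differential threshold).
#' @return list with `meso`, `thermo` (`abundance_table`s) and `truth`
#'   (data.frame `taxon`, `direction`).
#' @export
make_two_condition_study <- function(config, n_planted_up = 5L,
                                     n_planted_down = 5L, effect_fold = 3) {
  n <- config$n_taxa
  if (n_planted_up + n_planted_down > n)
    stop("more planted taxa than taxa")
  sys <- random_glv_system(config)        # seeds the RNG stream
  raw <- glv_trajectory(sys$r, sys$M, sys$x0, config$days)
  planted <- sample(n, n_planted_up + n_planted_down)
  up <- planted[seq_len(n_planted_up)]
  down <- setdiff(planted, up)
  noisy <- function(m) {
    if (config$noise_sigma > 0)
      m * matrix(stats::rlnorm(length(m), 0, config$noise_sigma),
                 nrow(m), ncol(m))
    else m
  }
  meso_raw <- noisy(raw)
  thermo_raw <- noisy(raw)
  thermo_raw[up, ] <- thermo_raw[up, ] * effect_fold
  thermo_raw[down, ] <- thermo_raw[down, ] / effect_fold
  close_if <- function(m) {
    if (config$closure) m <- sweep(m, 2, colSums(m), "/")
    m
  }
  direction <- rep("NONE", n)
  direction[up] <- "UP"
  direction[down] <- "DN"
  list(meso = abundance_table(close_if(meso_raw), config$days, "mesophilic"),
       thermo = abundance_table(close_if(thermo_raw), config$days,
                                "thermophilic"),
       truth = data.frame(taxon = sys$taxa, direction = direction,
                          row.names = NULL))
}

#' Synthetic BRP annotation and trophic index table
#'
#' Labels the first `n_brp` taxa as BRP with cyclic pathway tags
#' (p1 hydrolysis, p2 acidogenesis, p3 acetogenesis, p4 methanogenesis,
#' deS desulfurization), the rest as NBRP, and draws uniform \[0,1\]
#' complementarity/competition indices for every ordered BRP pair. With the
#' study-sized inputs (173 taxa, 36 BRP) this reproduces the 36/137 split.
#'
#' @param taxa character vector of taxon labels.
#' @param n_brp number of BRP taxa (taken from the front of `taxa`).
#' @param seed integer RNG seed.
#' @return list with `annotation` (a `brp_annotation`) and `indices`
#'   (a family-level `trophic_index_table`).
#' @export
make_annotation_and_indices <- function(taxa, n_brp, seed = 1L) {
  n <- length(taxa)
  if (n_brp > n) stop("n_brp exceeds the number of taxa")
  set.seed(as.integer(seed))
  group <- rep("NBRP", n)
  group[seq_len(n_brp)] <- "BRP"
  pathways <- rep(NA_character_, n)
  pathways[seq_len(n_brp)] <-
    rep_len(c("p1", "p2", "p3", "p4", "deS"), n_brp)
  ann <- brp_annotation(taxa, group, pathways)
  brp <- taxa[seq_len(n_brp)]
  pairs <- expand.grid(taxon_b = brp, taxon_a = brp,
                       stringsAsFactors = FALSE)[, c("taxon_a", "taxon_b")]
  pairs <- pairs[pairs$taxon_a != pairs$taxon_b, , drop = FALSE]
  idx <- trophic_index_table(pairs$taxon_a, pairs$taxon_b,
                             stats::runif(nrow(pairs)),
                             stats::runif(nrow(pairs)),
                             level = "family")
  list(annotation = ann, indices = idx)
}
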