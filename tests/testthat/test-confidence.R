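# Bounded 20-taxon community, 6 BRP families, optionally with 12 strong
# effects (|M| = 3) planted among the BRP pairs.
small_study <- function(seed = 31, sigma = 0.02, plant_strength = NULL) {
  cfg <- simulation_config(n_taxa = 20, days = seq(0, 38, 2),
                           interaction_density = 0.15,
                           interaction_scale = 0.5, self_limitation = 5,
                           growth_rate_range = c(0.5, 0.7),
                           noise_sigma = sigma, seed = seed)
  sys <- random_glv_system(cfg)
  if (!is.null(plant_strength)) {
    set.seed(seed + 1000)
    off <- which(row(matrix(0, 6, 6)) != col(matrix(0, 6, 6)))
    chosen <- sample(off, 12)
    sys$M[1:6, 1:6][chosen] <-
      sample(c(-plant_strength, plant_strength), 12, replace = TRUE)
  }
  tab <- simulate_glv(sys$r, sys$M, sys$x0, cfg)
  ann <- make_annotation_and_indices(sys$taxa, 6, seed = seed)$annotation
  list(cfg = cfg, sys = sys, tab = tab, ann = ann)
}

test_that("annotation partitions taxa exactly and errors on gaps", {
  tab <- random_table(173, 1:10, seed = 1)
  ann <- make_annotation_and_indices(taxa_names(tab), 36)$annotation
  part <- partition_taxa(tab, ann)
  expect_identical(nrow(part$brp_table$values), 36L)
  expect_identical(length(part$nbrp_taxa), 137L)

  all_brp <- brp_annotation(taxa_names(tab), rep("BRP", 173))
  expect_identical(partition_taxa(tab, all_brp)$nbrp_taxa, character(0))

  expect_error(partition_taxa(tab, ann[-1, ]), "unannotated")
  expect_error(brp_annotation("A", "OTHER"), "BRP")
})

test_that("raw BRP networks have N(N-1) interactions", {
  tab <- random_table(2, 1:10, seed = 2)
  expect_identical(nrow(interaction_edges(raw_brp_network(tab))), 2L)
  tab1 <- random_table(1, 1:10, seed = 2)
  expect_identical(nrow(interaction_edges(raw_brp_network(tab1))), 0L)
})

test_that("interaction classification matches the truth-table oracle", {
  strengths <- c(-0.5, 0, 0.5)
  ps <- c(0, 0.03, 0.05, 0.5, 0.95, 0.97, 1)
  for (s in strengths) for (p in ps) {
    expect_identical(classify_interaction(s, p, 0.95),
                     classify_oracle(s, p, 0.95),
                     info = sprintf("strength=%g P=%g", s, p))
  }
  # the printed examples
  expect_identical(classify_interaction(0.5, 0.97), "CONFIDENT_ACTIVATION")
  expect_identical(classify_interaction(-0.5, 0.97), "NON_CONFIDENT")
  expect_identical(classify_interaction(-0.5, 0.03), "CONFIDENT_REPRESSION")
  expect_identical(classify_interaction(0.5, 0.03), "NON_CONFIDENT")
  expect_identical(classify_interaction(0.5, 0.5), "NON_CONFIDENT")
  expect_error(classify_interaction(1, 1.2), "\\[0, 1\\]")
})

test_that("consensus resampling is seed-deterministic with valid P", {
  st <- small_study()
  th <- and_thresholds(n_sim = 12, n_nbrp_sample = 8)
  cp1 <- simulate_mixed_networks(st$tab, st$ann, th, seed = 99)
  cp2 <- simulate_mixed_networks(st$tab, st$ann, th, seed = 99)
  expect_identical(cp1, cp2)
  expect_true(all(cp1$pairs$P >= 0 & cp1$pairs$P <= 1))
  expect_equal(cp1$pairs$P, cp1$pairs$positive_count / th$n_sim)
  expect_identical(nrow(cp1$pairs), 6L * 5L)

  cp3 <- simulate_mixed_networks(st$tab, st$ann, th, seed = 100)
  expect_false(identical(cp1$pairs$positive_count, cp3$pairs$positive_count))

  big <- and_thresholds(n_sim = 2, n_nbrp_sample = 1000)
  expect_error(simulate_mixed_networks(st$tab, st$ann, big, seed = 1),
               "exceeds")
  expect_error(simulate_mixed_networks(st$tab, st$ann, th), "seed")
})

test_that("confidence filtering obeys the conditions and is monotone", {
  st <- small_study()
  th <- and_thresholds(n_sim = 12, n_nbrp_sample = 8, p_threshold = 0.8)
  part <- partition_taxa(st$tab, st$ann)
  raw <- raw_brp_network(part$brp_table, n_components = 3)
  cp <- simulate_mixed_networks(st$tab, st$ann, th, seed = 7)

  net <- build_confident_network(raw, cp, th)
  expect_true(all(net$edges$source != net$edges$target))
  expect_lte(nrow(net$edges), 6 * 5)
  expect_true(all((net$edges$strength > 0 & net$edges$P >= th$p_threshold) |
                  (net$edges$strength < 0 &
                     net$edges$P <= 1 - th$p_threshold)))

  # raising the coherence threshold can only remove edges
  stricter <- and_thresholds(n_sim = 12, n_nbrp_sample = 8,
                             p_threshold = 0.95)
  net2 <- build_confident_network(raw, cp, stricter)
  key <- function(n) paste(n$edges$source, n$edges$target)
  expect_true(all(key(net2) %in% key(net)))

  # all-coherent and all-incoherent corner cases
  cp_one <- cp
  cp_one$pairs$P <- 1
  forced <- build_confident_network(raw, cp_one, stricter)
  expect_identical(nrow(forced$edges), sum(raw$effects > 0 &
                                             row(raw$effects) != col(raw$effects)))
  cp_half <- cp
  cp_half$pairs$P <- 0.5
  expect_identical(nrow(build_confident_network(raw, cp_half,
                                                stricter)$edges), 0L)

  mismatch <- cp
  mismatch$pairs <- mismatch$pairs[-1, ]
  expect_error(build_confident_network(raw, mismatch, th), "different")
})

test_that("planted strong interactions keep their sign among confident edges", {
  st <- small_study(seed = 31, sigma = 0.02, plant_strength = 3)
  th <- and_thresholds(n_sim = 50, n_nbrp_sample = 8, p_threshold = 0.9)
  part <- partition_taxa(st$tab, st$ann)
  raw <- raw_brp_network(part$brp_table, n_components = 6)
  cp <- simulate_mixed_networks(st$tab, st$ann, th, seed = 17,
                                n_components = 6)
  net <- build_confident_network(raw, cp, th)
  expect_gt(nrow(net$edges), 0)

  truth <- st$sys$M[taxa_names(part$brp_table), taxa_names(part$brp_table)]
  idx <- cbind(match(net$edges$target, rownames(truth)),
               match(net$edges$source, colnames(truth)))
  true_vals <- truth[idx]
  planted <- abs(true_vals) >= 3
  expect_gte(sum(planted), 5)
  expect_gt(mean(sign(net$edges$strength[planted]) ==
                   sign(true_vals[planted])), 0.8)
})
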