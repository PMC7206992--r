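# KDE smoothing and Gaussian multi-peak decomposition.

test_that("density argmax sits at the sample concentration point", {
  x <- rep(0.5, 1000)
  cv <- kde_density(x)
  expect_equal(cv$grid[which.max(cv$density)], 0.5, tolerance = 0.005)
})

test_that("curve integral matches the in-window mass fraction", {
  set.seed(21)
  x <- c(rnorm(800, 0.8, 0.1), rnorm(200, 3.6, 0.1))  # 20% outside [0, 3]
  cv <- kde_density(x)
  integral <- sum(cv$density) * diff(cv$grid[1:2])
  expect_equal(integral, mean(x >= 0 & x <= 3), tolerance = 1e-3)
})

test_that("too-small samples give an insufficient-data error naming the count", {
  err <- tryCatch(kde_density(rep(0.5, 10)), error = identity)
  expect_s3_class(err, "wgdscan_insufficient_data")
  expect_match(conditionMessage(err), "10")
})

test_that("kde is translation-equivariant within grid resolution", {
  set.seed(4)
  x <- rnorm(2000, 0.8, 0.1)
  c1 <- kde_density(x); c2 <- kde_density(x + 0.5)
  m1 <- c1$grid[which.max(c1$density)]; m2 <- c2$grid[which.max(c2$density)]
  expect_equal(m2 - m1, 0.5, tolerance = 0.006)
})

test_that("an exact single Gaussian is recovered with one component", {
  grid <- seq(0, 3, length.out = 601)
  curve <- structure(list(grid = grid, density = dnorm(grid, 0.8, 0.1),
                          bandwidth = 0.05, n = 1000, mass_fraction = 1),
                     class = "density_curve")
  fit <- fit_mixture(curve)
  expect_equal(fit$n_components, 1)
  expect_equal(fit$components$mean, 0.8, tolerance = 0.01)
  expect_gte(fit$r2, 0.999)
})

test_that("an exact k-Gaussian curve returns exactly k components (k <= 3)", {
  grid <- seq(0, 3, length.out = 601)
  specs <- list(list(m = 0.9, s = 0.12, w = 1),
                list(m = c(0.5, 1.5), s = c(0.1, 0.1), w = c(0.5, 0.5)),
                list(m = c(0.4, 1.0, 1.8), s = c(0.08, 0.1, 0.12), w = c(0.3, 0.4, 0.3)))
  for (sp in specs) {
    dens <- rowSums(vapply(seq_along(sp$m), function(i)
      sp$w[i] * dnorm(grid, sp$m[i], sp$s[i]), grid))
    curve <- structure(list(grid = grid, density = dens, bandwidth = 0.05,
                            n = 1000, mass_fraction = 1), class = "density_curve")
    fit <- fit_mixture(curve)
    expect_equal(fit$n_components, length(sp$m))
    expect_equal(sort(fit$components$mean), sp$m, tolerance = 0.03)
    ## minimality: one fewer component stays under the threshold
    if (length(sp$m) > 1) {
      fewer <- fit_mixture(curve, n_components = length(sp$m) - 1)
      expect_lt(fewer$r2, 0.95)
    }
  }
})

test_that("two sampled Gaussians at 0.5 and 1.5 are recovered within 0.03", {
  set.seed(33)
  x <- c(rnorm(1500, 0.5, 0.1), rnorm(1500, 1.5, 0.1))
  fit <- fit_mixture(kde_density(x))
  expect_equal(fit$n_components, 2)
  expect_equal(sort(fit$components$mean), c(0.5, 1.5), tolerance = 0.03)
})

test_that("a flat noise curve fails to fit under a strict threshold", {
  set.seed(5)
  grid <- seq(0, 3, length.out = 601)
  curve <- structure(list(grid = grid, density = 1 / 3 + runif(601, -0.02, 0.02),
                          bandwidth = 0.05, n = 1000, mass_fraction = 1),
                     class = "density_curve")
  err <- tryCatch(fit_mixture(curve, r2_threshold = 0.95, max_components = 1),
                  error = identity)
  expect_s3_class(err, "wgdscan_fit_failure")
  expect_s3_class(err$best, "mixture_fit")
})

test_that("components map to events by ascending mean; mismatches error", {
  fit <- structure(list(components = data.frame(weight = c(0.3, 0.5, 0.2),
                                                mean = c(1.6, 0.45, 0.6),
                                                sd = c(0.2, 0.05, 0.06)),
                        n_components = 3, r2 = 0.99, principal = 2,
                        bandwidth = 0.05, window = c(0, 3)),
                   class = "mixture_fit")
  asg <- assign_events(fit, c("A-alpha", "A-beta", "ECH"))
  expect_equal(asg$event, c("A-alpha", "A-beta", "ECH"))
  expect_equal(asg$mean, c(0.45, 0.6, 1.6))
  expect_error(assign_events(fit, c("A-alpha", "ECH")), class = "wgdscan_ambiguity")
})

test_that("block-structured peak fitting recovers separated event peaks end to end", {
  tree <- list(age = 85, rate = 1, children = list(
    list(tip = "V", rate = 1), list(tip = "X", rate = 1)))
  events <- list(
    list(name = "older", age = 58, multiplicity = 2, tag = "b",
         lineages = "X", retain = 0.75, p_loss = 0.3),
    list(name = "younger", age = 25, multiplicity = 2, tag = "a",
         lineages = "X", retain = 0.7, p_loss = 0.3))
  cfg <- history_config(ancestor = list(n_chromosomes = 2, genes_per_chromosome = 350),
                        root_age = 90, tree = tree, events = events,
                        sigma_event = 0.03, seed = 12)
  ds <- simulate_gene_orders(cfg)
  ds <- realize_sequences(ds)
  hom <- filter_families(ds$homology)
  bs <- chain_blocks(hom, ds$annotations$X, ds$annotations$X, strict = FALSE)
  anc <- unique(bs$anchors[, c("gene_a", "gene_b")])
  est <- ks_for_pairs(anc, ds$cds$X)
  bs <- block_ks_median(bs, est)
  tk <- ds$truth$true_ks
  fit <- fit_event_peaks(bs, 2, oldest_ref = tk$ks[tk$event == "older"])
  truth <- sort(tk$ks[tk$type == "within" & tk$genome_a == "X"])
  expect_equal(fit$components$mean, truth, tolerance = 0.05)
})
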