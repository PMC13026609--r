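# Reference models and the five kinship classifiers.

# A reference model with exactly known MS values: one pair per relationship,
# each with a single segment of the desired total length.
model_from_totals <- function(totals, degrees, genome_mbp = 2875) {
  man <- toy_manifest(2)
  segs <- lapply(totals, function(t) {
    s <- kinsnp:::make_segments(1L, 1L, 2L, man)
    s$length_mbp <- t
    s
  })
  build_reference_model(segs, names(totals), degrees, genome_mbp = genome_mbp)
}

test_that("total shared length sums segment lengths", {
  man <- toy_manifest(5)
  s <- kinsnp:::make_segments(c(1L, 1L), c(1L, 3L), c(2L, 5L), man)
  s$length_mbp <- c(30, 20)
  expect_equal(total_shared_length(s), 50)
  expect_equal(total_shared_length(kinsnp:::empty_segments()), 0)
  expect_equal(total_shared_length(NULL), 0)
})

test_that("reference model averages totals and fills the conditional table", {
  man <- toy_manifest(4)
  seg_of <- function(len) {
    s <- kinsnp:::make_segments(1L, 1L, 2L, man)
    s$length_mbp <- len
    s
  }
  model <- build_reference_model(
    list(seg_of(100), seg_of(200), seg_of(120), seg_of(110), seg_of(140), seg_of(160)),
    relationships = c("R1", "R1", "R1", "R1", "R2", "R2"),
    degrees = c(3L, 3L, 3L, 3L, 4L, 4L), genome_mbp = 2875)
  expect_equal(unname(model$ms[["R1"]]), mean(c(100, 200, 120, 110)))
  # bin [100,150): 3 R1 pairs (100,120,110) and 1 R2 pair (140)
  bin <- kinsnp:::cond_bin_of(125)
  expect_equal(unname(model$cond_probs[bin, "R1"]), 0.75)
  expect_equal(unname(model$cond_probs[bin, "R2"]), 0.25)
  pop <- rowSums(model$cond_counts) > 0
  expect_true(all(abs(rowSums(model$cond_probs[pop, , drop = FALSE]) - 1) < 1e-12))
  expect_true(all(model$cond_probs >= 0 & model$cond_probs <= 1))
})

test_that("mean-length classification takes the nearest MS, ties to higher degree", {
  model <- model_from_totals(c(deg3 = 170, deg4 = 90, deg5 = 45),
                             degrees = c(3L, 4L, 5L))
  expect_equal(classify_mean_length(100, model)$inferred_class, "deg4")
  expect_equal(classify_mean_length(100, model)$degree, 4L)
  # 130 is exactly midway between 170 and 90: higher degree wins
  expect_equal(classify_mean_length(130, model)$degree, 4L)
  model_u <- model_from_totals(c(deg1 = 2800, unrelated = 0),
                               degrees = c(1L, 10L))
  expect_equal(classify_mean_length(0, model_u)$inferred_class, "unrelated")
})

test_that("conditional classification clamps into the table and backs off to populated bins", {
  man <- toy_manifest(2)
  seg_of <- function(len) {
    s <- kinsnp:::make_segments(1L, 1L, 2L, man)
    s$length_mbp <- len
    s
  }
  model <- build_reference_model(
    list(seg_of(125), seg_of(125), seg_of(125), seg_of(130), seg_of(2990), seg_of(2995)),
    relationships = c("R1", "R1", "R1", "R2", "PC", "PC"),
    degrees = c(4L, 4L, 4L, 5L, 1L, 1L), genome_mbp = 3000)
  r <- classify_conditional(125, model)
  expect_equal(r$inferred_class, "R1")
  expect_equal(r$score, 0.75)
  # beyond the table: clamps into the last bin, where PC rules
  expect_equal(classify_conditional(3100, model)$inferred_class, "PC")
  # empty bin between populated neighbours consults the nearest populated one
  expect_equal(classify_conditional(180, model)$inferred_class, "R1")
})

test_that("gamma profiles match closed forms and the distance is a mean abs diff", {
  p1 <- gamma_profile(structure(list(shape = 1, scale = 20), class = "gamma_params"))
  expect_equal(p1[20], exp(-1) / 20, tolerance = 1e-12)
  p2 <- gamma_profile(structure(list(shape = 2, scale = 10), class = "gamma_params"))
  expect_equal(p2[10], 10 * exp(-1) / 100, tolerance = 1e-12)
  expect_true(all(p1 >= 0) && all(p2 >= 0))
  expect_equal(gamma_distance(p1, p1), 0)
  expect_equal(gamma_distance(p1, p2), gamma_distance(p2, p1))
  a <- numeric(150); b <- numeric(150)
  b[c(10, 20)] <- 0.1
  expect_equal(gamma_distance(a, b), 0.2 / 150)
  expect_error(gamma_distance(a, b[-1]), "different lengths")
  # profile of a concentrated gamma integrates to ~1 over the grid
  pk <- gamma_profile(structure(list(shape = 2, scale = 15), class = "gamma_params"))
  expect_equal(sum(pk), 1, tolerance = 0.02)
})

test_that("gamma MLE recovers simulated parameters and abstains when it must", {
  set.seed(1234)
  x <- rgamma(5000, shape = 2, scale = 15)
  fit <- fit_gamma(x)
  expect_equal(fit$shape, 2, tolerance = 0.05)
  expect_equal(fit$shape * fit$scale, mean(x), tolerance = 1e-8)
  y <- rgamma(5000, shape = 1, scale = 20)
  expect_equal(fit_gamma(y)$shape, 1, tolerance = 0.05)
  expect_null(fit_gamma(42))            # a single segment
  expect_null(fit_gamma(c(10, 10, 10))) # no spread
})

test_that("gamma classification matches profiles and abstains below two segments", {
  man <- toy_manifest(2)
  seg_of <- function(lens) {
    s <- do.call(rbind, lapply(lens, function(l) kinsnp:::make_segments(1L, 1L, 2L, man)))
    s$length_mbp <- lens
    s
  }
  set.seed(9)
  ref <- list(seg_of(rgamma(40, 2, scale = 30)), seg_of(rgamma(40, 1.2, scale = 10)))
  model <- build_reference_model(ref, c("close", "far"), c(2L, 5L), genome_mbp = 2875)
  pair_close <- seg_of(rgamma(30, 2, scale = 30))
  expect_equal(classify_gamma(pair_close, model)$inferred_class, "close")
  one_seg <- seg_of(25)
  r <- classify_gamma(one_seg, model)
  expect_true(r$abstained)
  expect_true(is.na(r$degree))
})

test_that("IBD0 table matches the published expectations and tiles (0,1]", {
  rng <- ibd0_ranges()
  sib <- rng[rng$class == "siblings", ]
  expect_equal(sib$expected, 0.25)
  expect_equal(sib$lower, 0.1)
  expect_equal(sib$upper, 0.365)
  expect_equal(rng$expected[rng$degree == 4][1], 0.875)
  expect_equal(rng$expected[rng$degree == 5][1], 0.9375)
  expect_equal(ibd0_expected(4), 0.875)
  expect_equal(ibd0_expected(5), 0.9375)
  # intervals tile: each upper bound is the next lower bound
  expect_equal(rng$lower[-(1:2)], rng$upper[-c(1, nrow(rng))])
  # every expected value classifies into its own class
  for (i in seq_len(nrow(rng))) {
    r <- ibd0_classify((1 - rng$expected[i]) * 2875, genome_mbp = 2875)
    expect_equal(r$inferred_class, rng$class[i])
  }
})

test_that("IBD0 classification maps proportions to the published classes", {
  G <- 1000
  expect_equal(ibd0_classify(0.95 * G, G)$inferred_class, "parent-child")
  r3 <- ibd0_classify(0.20 * G, G)   # proportion 0.80
  expect_equal(r3$degree, 3L)
  expect_equal(ibd0_classify(0.001 * G, G)$inferred_class, "unrelated")
  # upper bounds are inclusive
  prop <- 1 - 2^(-5 / 2)
  expect_equal(ibd0_classify((1 - prop) * G, G)$degree, 3L)
  expect_error(ibd0_classify(1100, G), "exceeds genome length")
})

test_that("king_phi matches hand counts and is exactly 0.5 for self pairs", {
  # counts: both-het 30, opposite-hom 5, het(i) 40, het(j) 30
  a <- c(rep(1L, 40), rep(0L, 25), rep(2L, 10))
  b <- c(rep(1L, 30), rep(0L, 10), rep(2L, 5), rep(0L, 20), rep(2L, 10))
  k <- king_phi(a, b)
  expect_equal(k$n_both_het, 30)
  expect_equal(k$n_opp_hom, 5)
  expect_equal(k$n_het_i, 40)
  expect_equal(k$n_het_j, 30)
  expect_equal(k$phi, 0.3125)
  g <- c(0L, 1L, 2L, 1L, 1L, 0L, 2L)
  expect_identical(king_phi(g, g)$phi, 0.5)
  # no heterozygous loci: abstain
  expect_true(is.na(king_phi(c(0L, 2L), c(0L, 2L))$phi))
  expect_error(king_phi(1L, c(1L, 1L)), "differ in length")
})

test_that("king_phi is near zero for HWE-unrelated pairs", {
  man <- toy_manifest(10000, spacing_mbp = 0.01)
  f <- simulate_founders(man, 2, seed = 404)
  phi <- king_phi(f[1, ], f[2, ])$phi
  expect_lt(abs(phi), 0.02)
})

test_that("king ranges tile, contain their expectations and classify boundaries", {
  rng <- king_ranges()
  expect_true(all(rng$expected > rng$lower & rng$expected <= rng$upper))
  expect_equal(rng$lower[1:9], rng$upper[2:10])
  expect_equal(king_classify(0.25)$degree, 1L)
  expect_equal(king_classify(2^(-11 / 2))$degree, 5L)  # upper-inclusive
  expect_equal(king_classify(1e-4)$inferred_class, "unrelated")
  expect_equal(king_classify(0.45)$degree, 1L)  # clamped above the table
  expect_true(king_classify(NA_real_)$abstained)
  for (d in 1:9) expect_equal(king_classify(expected_kinship(d))$degree, d)
})

test_that("pair sharing matrices encode sharing and missingness per policy", {
  g <- c(0L, 1L, 2L, NA)
  pairs <- list(same = list(a = g, b = g),
                opp = list(a = c(0L, 2L, 0L, 2L), b = c(2L, 0L, 2L, 0L)))
  m <- pair_sharing_matrix(pairs, missing_code = "neg1")
  expect_equal(unname(m["same", ]), c(2, 2, 2, -1))
  expect_equal(unname(m["opp", ]), c(0, 0, 0, 0))
  m_na <- pair_sharing_matrix(pairs, missing_code = "na")
  expect_true(is.na(m_na["same", 4]))
})

test_that("embeddings give identical coordinates to duplicated pairings", {
  set.seed(5)
  base <- matrix(sample(0:2, 5 * 60, replace = TRUE), nrow = 5)
  m <- rbind(base, base[1, , drop = FALSE])
  for (method in c("pca", "pcoa")) {
    co <- embed_pairs(m, method = method, n_components = 2)
    expect_equal(unname(co[1, ]), unname(co[6, ]), tolerance = 1e-8)
    expect_lte(ncol(co), 2)
  }
  expect_warning(embed_pairs(base[1:2, ], method = "pca", n_components = 5),
                 "rank")
  expect_error(embed_pairs(base[1, , drop = FALSE]), "at least two")
})

test_that("first-degree pairings separate from unrelated along PC1", {
  man <- cached("embed_man", generate_panel_fixture(2000, 22, seed = 3))
  map <- cached("embed_map", uniform_genetic_map(man))
  cat_ <- relationship_catalogue()
  pairs <- list()
  for (i in 1:12) {
    f <- simulate_founders(man, 2, seed = 600 + i)
    d <- gene_drop_pair(cat_[["parent-child"]], f, map, man, seed = 700 + i)
    pairs[[sprintf("pc_%02d", i)]] <- list(a = d$genotypes[1, ], b = d$genotypes[2, ])
    f2 <- simulate_founders(man, 2, seed = 800 + i)
    pairs[[sprintf("un_%02d", i)]] <- list(a = f2[1, ], b = f2[2, ])
  }
  m <- pair_sharing_matrix(pairs, missing_code = "neg1")
  co <- embed_pairs(m, method = "pca", n_components = 2)
  grp <- substr(rownames(co), 1, 2)
  mu <- tapply(co[, 1], grp, mean)
  sd_pooled <- sqrt(mean(tapply(co[, 1], grp, stats::var)))
  expect_gt(abs(mu[["pc"]] - mu[["un"]]) / sd_pooled, 4)
})
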