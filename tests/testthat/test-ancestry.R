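test_that("PCA separates simulated subpopulations and is permutation stable", {
  cfg <- sim_config(n_cases = 100, n_controls = 100, n_populations = 2,
                    fst = 0.1, n_background_snps = 2000,
                    pop_weights_cases = c(1, 0),
                    pop_weights_controls = c(0, 1), seed = 3)
  co <- simulate_cohort(cfg)
  pca <- compute_pca(co$background)
  sc <- dplyr::left_join(pca$scores, co$samples, by = "sample_id")
  r1 <- range(sc$PC1[sc$population == 1])
  r2 <- range(sc$PC1[sc$population == 2])
  expect_true(r1[2] < r2[1] || r2[2] < r1[1])  # zero overlap on PC1
  # orthogonality of score vectors
  S <- as.matrix(pca$scores[, -1])
  Sn <- sweep(S, 2, sqrt(colSums(S^2)), "/")
  off <- crossprod(Sn) - diag(ncol(Sn))
  expect_lt(max(abs(off)), 1e-8)
  # permutation invariance up to sign
  perm <- sample(nrow(co$background))
  pca_p <- compute_pca(co$background[perm, ])
  m <- match(pca$scores$sample_id, pca_p$scores$sample_id)
  for (k in 1:3) {
    a <- pca$scores[[paste0("PC", k)]]
    b <- pca_p$scores[[paste0("PC", k)]][m]
    expect_equal(min(max(abs(a - b)), max(abs(a + b))), 0, tolerance = 1e-6)
  }
})

test_that("degenerate genotype matrices are rejected", {
  G <- matrix(1L, nrow = 6, ncol = 50)  # identical samples, no variance
  expect_error(compute_pca(G), "degenerate")
})

test_that("KING kinship is exact on duplicates and symmetric by construction", {
  set.seed(4)
  g <- simulate_relative_pair(runif(1500, 0.05, 0.5), "duplicate")
  k <- king_kinship(g)
  expect_equal(k$phi, 0.5, tolerance = 1e-12)
  expect_equal(k$degree, "duplicate_MZ")
  # no heterozygotes in either sample: unevaluable
  g0 <- rbind(rep(0L, 10), rep(2L, 10))
  rownames(g0) <- c("a", "b")
  k0 <- king_kinship(g0)
  expect_true(is.na(k0$phi))
  expect_equal(k0$degree, "unevaluable")
})

test_that("kinship degrees classify simulated relationships accurately", {
  set.seed(5)
  n_rep <- 40
  acc <- function(rel, expected) {
    mean(vapply(seq_len(n_rep), function(i) {
      g <- simulate_relative_pair(runif(4000, 0.05, 0.5), rel)
      king_kinship(g)$degree == expected
    }, logical(1)))
  }
  expect_gte(acc("duplicate", "duplicate_MZ"), 0.95)
  expect_gte(acc("parent_offspring", "first"), 0.95)
  expect_gte(acc("half_sibling", "second"), 0.95)
  expect_gte(acc("unrelated", "unrelated"), 0.95)
  # mean parent-offspring estimate near 0.25
  phis <- vapply(seq_len(n_rep), function(i) {
    king_kinship(simulate_relative_pair(runif(4000, 0.05, 0.5),
                                        "parent_offspring"))$phi
  }, numeric(1))
  expect_equal(mean(phis), 0.25, tolerance = 0.02)
})

test_that("cross-population pairs are never called related (KING robustness)", {
  # the between-family estimator goes negative for unrelated pairs drawn
  # from diverged subpopulations -- the operative robustness guarantee is
  # that such pairs never cross the relatedness threshold
  set.seed(6)
  fst <- 0.1
  res <- vapply(1:100, function(i) {
    p <- runif(3000, 0.05, 0.5)
    p1 <- pmin(pmax(rbeta(3000, p * (1 - fst) / fst,
                          (1 - p) * (1 - fst) / fst), 1e-6), 1 - 1e-6)
    p2 <- pmin(pmax(rbeta(3000, p * (1 - fst) / fst,
                          (1 - p) * (1 - fst) / fst), 1e-6), 1 - 1e-6)
    g <- rbind(rbinom(3000, 2, p1), rbinom(3000, 2, p2))
    rownames(g) <- c("a", "b")
    k <- king_kinship(g)
    c(k$phi, k$degree == "unrelated")
  }, numeric(2))
  expect_gte(mean(res[2, ] == 1), 0.99)
  expect_true(all(res[1, ] < 0.0442))
  expect_lt(mean(res[1, ]), 0)  # the documented cross-population signature
})

test_that("unrelated subset removal follows the greedy deterministic rule", {
  samples <- toy_samples(c("a", "b", "c", "d"))
  # chain a-b, b-c: b has degree 2 and is removed; d untouched
  kin <- tibble::tibble(sample_i = c("a", "b"), sample_j = c("b", "c"),
                        phi = 0.3, degree = "first")
  expect_setequal(unrelated_subset(samples, kin), c("a", "c", "d"))
  # no related pairs: identity
  expect_setequal(unrelated_subset(samples, kin[0, ]), samples$sample_id)
  # tie: keep carriers over non-carriers
  samples2 <- dplyr::mutate(toy_samples(c("a", "b")),
                            carrier = c(TRUE, FALSE))
  kin2 <- tibble::tibble(sample_i = "a", sample_j = "b", phi = 0.3,
                         degree = "first")
  expect_equal(unrelated_subset(samples2, kin2), "a")
  # tie among equals: lexicographically larger id removed
  expect_equal(unrelated_subset(toy_samples(c("a", "b")), kin2), "a")
})

test_that("a planted 30-Mb autozygous block yields the expected ROH rate", {
  # map: 22 chromosomes, ~131 Mb each (2,881 Mb total), 1 SNP / 65 kb;
  # block spans 30 Mb on chromosome 1 -> rate 30/2881 = 1.04% > 1%
  set.seed(7)
  n_chr <- 22
  per_chr <- 2000
  chrom <- rep(as.character(1:n_chr), each = per_chr)
  pos <- rep(seq(65000, by = 65000, length.out = per_chr), n_chr)
  map <- tibble::tibble(chromosome = chrom, position = as.integer(pos))
  p <- runif(nrow(map), 0.2, 0.5)
  g <- rbinom(nrow(map), 2, p)
  in_block <- map$chromosome == "1" & map$position >= 50e6 &
    map$position < 80e6
  g[in_block] <- 2L * rbinom(sum(in_block), 1, p[in_block])
  G <- matrix(g, nrow = 1, dimnames = list("s1", NULL))
  # window: 50 SNPs span 3.2 Mb here, so relax the window-kb cap in
  # proportion to this sparser map while keeping all other defaults
  cfg <- filter_config(roh_window_kb = 4000, roh_min_segment_kb = 4000)
  res <- homozygosity_rate(G, map, cfg)
  expect_equal(res$rates$homozygosity_rate, 30 / 2881, tolerance = 0.1)
  expect_true(res$rates$is_consanguineous)
  # detected segment overlaps the planted interval
  seg <- res$segments[which.max(res$segments$length_bp), ]
  expect_equal(seg$chromosome, "1")
  expect_lt(abs(seg$start - 50e6), 3e6)
  expect_lt(abs(seg$end - 80e6), 3e6)
  # an all-heterozygous sample has no runs and is not flagged
  H <- matrix(1L, nrow = 1, ncol = nrow(map), dimnames = list("h", NULL))
  res_h <- homozygosity_rate(H, map, cfg)
  expect_equal(nrow(res_h$segments), 0)
  expect_equal(res_h$rates$homozygosity_rate, 0)
  expect_false(res_h$rates$is_consanguineous)
  # fewer mapped SNVs than one window: unevaluable
  tiny <- homozygosity_rate(G[, 1:20, drop = FALSE], map[1:20, ],
                            filter_config())
  expect_true(is.na(tiny$rates$homozygosity_rate))
})

test_that("homozygosity rate rises monotonically with the inbreeding level", {
  set.seed(8)
  cfg <- sim_config(n_cases = 4, n_controls = 4, n_background_snps = 4000,
                    n_autosomes = 6, chrom_length = 12e6, seed = 8)
  bg <- recburden:::sim_background_map(cfg)
  p <- bg$pop_freq[1, ]
  grid <- c(0, 1 / 16, 1 / 8, 1 / 4)
  means <- vapply(grid, function(f) {
    rates <- vapply(1:8, function(i) {
      g <- rbinom(length(p), 2, p)
      g2 <- simulate_autozygosity(g, bg$map, p, f, block_kb = 2000)$dosages
      G <- matrix(g2, nrow = 1, dimnames = list("s", NULL))
      homozygosity_rate(G, bg$map, filter_config())$rates$homozygosity_rate
    }, numeric(1))
    mean(rates)
  }, numeric(1))
  expect_equal(cor(means, grid, method = "spearman"), 1)
  # F = 1/16 offspring are flagged; F = 0 samples are not
  expect_gt(means[2], 0.01)
  expect_lt(means[1], 0.01)
})
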