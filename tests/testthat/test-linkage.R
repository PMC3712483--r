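test_that("the Kosambi map function matches its closed form and round-trips", {
  expect_equal(round(kosambi_cm(1 / 102), 2), 0.98)
  expect_equal(round(kosambi_cm(1 / 168), 1), 0.6)
  expect_equal(kosambi_cm(0), 0)
  expect_equal(kosambi_cm(0.25), 25 * log(1.5 / 0.5))
  rs <- seq(0, 0.49, by = 0.01)
  expect_equal(kosambi_r(kosambi_cm(rs)), rs, tolerance = 1e-10)
  # map expansion: d >= 100 r, equality only at zero
  expect_true(all(kosambi_cm(rs[-1]) > 100 * rs[-1]))
  expect_error(kosambi_cm(0.5), "unlinked")
  expect_error(kosambi_r(-1), "non-negative")
})

test_that("two-point statistics follow the backcross LOD formula", {
  # 1 recombinant in 102: lod from the formula evaluated independently
  a <- c(rep(1, 51), rep(0, 51))
  b <- a; b[1] <- 0
  tp <- twopoint(a, b)
  expect_equal(tp$R, 1L); expect_equal(tp$N, 102L)
  expect_equal(round(tp$r_hat, 4), 0.0098)
  lod_direct <- log10(1 / 102) + 101 * log10(101 / 102) + 102 * log10(2)
  expect_equal(tp$lod, lod_direct)
  expect_equal(round(tp$lod, 2), 28.26)

  # identical vectors: N log10(2)
  v <- rep(c(1, 0), 50)
  expect_equal(twopoint(v, v)$lod, 100 * log10(2))
  expect_equal(round(twopoint(v, v)$lod, 2), 30.1)

  # independent vectors: r near 0.5, lod near 0
  set.seed(21)
  x <- rbinom(5000, 1, 0.5); y <- rbinom(5000, 1, 0.5)
  tp2 <- twopoint(x, y)
  expect_lt(abs(tp2$r_hat - 0.5), 3 * sqrt(0.25 / 5000))
  expect_lt(tp2$lod, 2)
})

test_that("two-point statistics are symmetric and phase-flip invariant", {
  set.seed(4)
  a <- rbinom(80, 1, 0.5)
  b <- a; b[sample(80, 8)] <- 1 - b[sample(80, 8)]
  ab <- twopoint(a, b); ba <- twopoint(b, a)
  expect_equal(ab, ba)
  flip <- twopoint(1 - a, b)
  expect_equal(flip$R, ab$N - ab$R)
  expect_equal(flip$lod, ab$lod)
  expect_error(twopoint(c(NA, 1), c(1, NA)), "informative")
})

test_that("missing genotypes reduce to pairwise-complete offspring", {
  a <- c(1, 1, 0, 0, NA, 1)
  b <- c(1, NA, 0, 1, 1, 1)
  tp <- twopoint(a, b)
  expect_equal(tp$N, 4L)
  expect_equal(tp$R, 1L)
})

test_that("linkage groups form by single linkage at the LOD threshold", {
  set.seed(8)
  cfg <- sim_config(seed = 8, n_offspring = 102)
  sg <- simulate_genotypes(cfg)
  g1 <- orient_genotypes(sg$geno, sg$anchor)
  expect_equal(length(form_groups(g1, 3.0)), 1L)

  # a second, independent chromosome splits off
  g2 <- matrix(rbinom(5 * 102, 1, 0.5), 5,
               dimnames = list(paste0("U", 1:5), colnames(g1)))
  cfg2 <- sim_config(seed = 80, n_offspring = 102,
                     markers = data.frame(
                       marker = paste0("V", 1:3),
                       position_cM = c(0, 4, 9), phase = "banding"))
  sgv <- simulate_genotypes(cfg2)
  gv <- orient_genotypes(sgv$geno, sgv$anchor)
  both <- rbind(g1, gv)
  grps <- form_groups(both, 3.0)
  expect_equal(length(grps), 2L)
  expect_setequal(grps[[1]], rownames(g1))
  expect_setequal(grps[[2]], rownames(gv))

  # an isolated marker is its own group
  single <- matrix(rbinom(102, 1, 0.5), 1, dimnames = list("solo", NULL))
  expect_equal(length(form_groups(rbind(g1, single))), 2L)
})

test_that("exhaustive ordering recovers the order implied by pairwise recombinants", {
  # A-B: 1/100, A-C: 5/100, B-C: 6/100  ->  C A B (or reverse)
  geno <- geno_from_flips(100, list(A = integer(0), B = 1, C = 2:6))
  om <- order_markers(geno)
  expect_true(identical(om$order, c("B", "A", "C")) ||
                identical(om$order, c("C", "A", "B")))
  expect_true(om$resolved)

  two <- order_markers(geno[1:2, ])
  expect_setequal(two$order, c("A", "B"))
})

test_that("identical markers are flagged as unresolved", {
  v <- rep(c(1, 0), 20)
  g <- rbind(M1 = v, M2 = v, M3 = v)
  om <- order_markers(g)
  expect_false(om$resolved)
})

test_that("the map builds with Kosambi distances and reversal-invariant length", {
  geno <- geno_from_flips(102, list(A = integer(0), B = 1, C = 2:6))
  mp <- build_map(geno, c("C", "A", "B"))
  adj <- attr(mp, "adjacent")
  expect_equal(round(adj$cM[adj$from == "A" & adj$to == "B"], 2), 0.98)
  expect_equal(attr(mp, "total_length_cM"),
               attr(build_map(geno, c("B", "A", "C")), "total_length_cM"))
  # cosegregating markers sit at distance zero
  g0 <- rbind(geno, D = geno["A", ])
  mp0 <- build_map(g0, c("C", "A", "D", "B"))
  expect_equal(attr(mp0, "adjacent")$cM[2], 0)
  # inconsistent grouping is an error
  set.seed(31)
  bad <- rbind(geno, E = rbinom(102, 1, 0.5))
  r_ae <- twopoint(bad["A", ], bad["E", ])$r_hat
  if (r_ae >= 0.5) expect_error(build_map(bad, c("C", "A", "E", "B")),
                                "inconsistent")
})

test_that("estimated map length is consistent with the simulated 35.8 cM truth", {
  truth <- default_marker_map()$marker
  tot <- vapply(1:30, function(s) {
    cfg <- sim_config(seed = 5000 + s, n_offspring = 102)
    sg <- simulate_genotypes(cfg)
    g <- orient_genotypes(sg$geno, sg$anchor)
    attr(build_map(g, truth), "total_length_cM")
  }, 0)
  se <- sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - 35.8), 3 * se)
})

test_that("pooled recombination estimates combine counts before the map transform", {
  p <- pool_recombination(c(1, 0), c(102, 66))
  expect_equal(p$r_hat, 1 / 168)
  expect_equal(round(p$cM, 1), 0.6)
  p0 <- pool_recombination(c(0, 0), c(10, 10))
  expect_equal(p0$R, 0); expect_equal(p0$N, 20)
  # equal-N pooling equals the average of the component fractions
  p2 <- pool_recombination(c(2, 4), c(50, 50))
  expect_equal(p2$r_hat, mean(c(2 / 50, 4 / 50)))
})

test_that("exhaustive and heuristic ordering agree on small panels", {
  for (seed in 1:12) {
    set.seed(300 + seed)
    n_mk <- sample(4:6, 1)
    pos <- sort(c(0, cumsum(runif(n_mk - 1, 2, 12))))
    cfg <- sim_config(seed = 300 + seed, n_offspring = 100,
                      markers = data.frame(
                        marker = sprintf("M%d", seq_len(n_mk)),
                        position_cM = pos, phase = "banding"))
    sg <- simulate_genotypes(cfg)
    g <- orient_genotypes(sg$geno, sg$anchor)
    ex <- order_markers(g, max_exhaustive = 8)
    he <- order_markers(g, max_exhaustive = 2)
    expect_equal(ex$loglik, he$loglik, tolerance = 1e-9)
    expect_true(identical(ex$order, he$order) ||
                  identical(ex$order, rev(he$order)))
  }
})
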