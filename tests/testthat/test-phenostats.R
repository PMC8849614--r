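# Replicate averaging, correlations, heritability, morphospace.

test_that("average_replicates: means, missing handling, dropped cells", {
  t <- data.frame(line = c("a", "a", "a", "b", "b", "b"),
                  replicate = c(1, 2, 3, 1, 2, 3), das = 35,
                  PRA = c(1, 2, 3, 4, NA, 6),
                  PL = c(2, 2, 2, NA, NA, NA))
  avg <- suppressWarnings(average_replicates(t))
  a <- avg[avg$line == "a", ]; b <- avg[avg$line == "b", ]
  expect_equal(a$PRA, 2)
  expect_equal(b$PRA, 5)
  expect_equal(b$n_replicates, 2)
  expect_true(is.na(b$PL))
  # single replicate -> itself
  t1 <- data.frame(line = "c", replicate = 1, das = 40, PRA = 7)
  expect_equal(average_replicates(t1)$PRA, 7)
  # all-missing cell dropped with warning
  t2 <- rbind(t, data.frame(line = "z", replicate = 1:2, das = 35,
                            PRA = NA, PL = NA))
  expect_warning(avg2 <- average_replicates(t2), "dropped")
  expect_false("z" %in% avg2$line)
})

test_that("correlations_by_das: exact cases and PSD", {
  set.seed(2)
  n <- 30
  x <- rnorm(n)
  t <- data.frame(line = sprintf("l%02d", 1:n), das = 35,
                  PRA = x, PL = -x, Compactness = rnorm(n))
  cm <- correlations_by_das(t, 35)
  expect_equal(diag(cm), c(PRA = 1, PL = 1, Compactness = 1))
  expect_equal(cm["PRA", "PL"], -1)
  expect_equal(cm, t(cm))
  expect_gte(min(eigen(cm, symmetric = TRUE)$values), -1e-10)
  # zero-variance descriptor -> NA off-diagonals, diagonal kept at 1
  t$RMS <- 5
  cm2 <- correlations_by_das(t, 35)
  expect_true(is.na(cm2["RMS", "PRA"]))
  expect_equal(cm2["RMS", "RMS"], 1)
  expect_error(correlations_by_das(t[1:2, ], 35), "at least 3")
})

test_that("heritability: exact limits and affine invariance", {
  # identical replicates within lines, different means -> H2 = 1
  t <- data.frame(line = rep(c("a", "b", "c"), each = 3),
                  replicate = rep(1:3, 3), das = 35,
                  PRA = rep(c(1, 5, 9), each = 3))
  h <- heritability(t, "PRA", 35)
  expect_equal(h$H2, 1, tolerance = 1e-6)
  # all observations equal -> H2 = 0
  t0 <- transform(t, PRA = 3)
  expect_equal(heritability(t0, "PRA", 35)$H2, 0)
  # no line effect -> Vg ~ 0
  set.seed(3)
  tn <- data.frame(line = rep(sprintf("l%02d", 1:40), each = 3),
                   replicate = rep(1:3, 40), das = 35,
                   PRA = rnorm(120))
  expect_lt(heritability(tn, "PRA", 35)$H2, 0.2)
  # affine rescaling leaves H2 unchanged
  set.seed(4)
  tg <- data.frame(line = rep(sprintf("l%02d", 1:40), each = 3),
                   replicate = rep(1:3, 40), das = 35,
                   PRA = rep(rnorm(40, 0, 2), each = 3) + rnorm(120))
  h1 <- heritability(tg, "PRA", 35)
  tg$PRA <- 100 + 7 * tg$PRA
  h2 <- heritability(tg, "PRA", 35)
  expect_equal(h1$H2, h2$H2, tolerance = 1e-6)
  expect_true(h1$H2 >= 0 && h1$H2 <= 1)
  expect_error(heritability(tg[1:3, ], "PRA", 35), ">= 2 lines")
})

test_that("REML heritability agrees with balanced method of moments", {
  set.seed(5)
  n <- 100; J <- 3
  y <- rep(rnorm(n, 0, 1), each = J) + rnorm(n * J, 0, 1.5)
  t <- data.frame(line = rep(sprintf("l%03d", 1:n), each = J),
                  replicate = rep(1:J, n), das = 35, PRA = y)
  h <- heritability(t, "PRA", 35)
  # balanced one-way MoM: Vg = (MSB - MSW) / J
  means <- tapply(y, t$line, mean)
  msb <- J * var(as.numeric(means))
  msw <- sum((y - rep(means[unique(t$line)], each = J))^2) / (n * (J - 1))
  vg_mom <- max(0, (msb - msw) / J)
  h2_mom <- vg_mom / (vg_mom + msw)
  expect_equal(h$H2, h2_mom, tolerance = 0.02)
})

test_that("morphospace: eigenstructure, signs, projection, errors", {
  t <- fx_descriptor_table(60, 3, 35:38, seed = 6)
  avg <- average_replicates(t)
  m <- build_morphospace(avg)
  expect_equal(sum(m$eigenvalues), 9, tolerance = 1e-8)
  expect_equal(sum(m$variance_fractions), 1, tolerance = 1e-12)
  # loadings orthonormal
  expect_equal(crossprod(m$loadings), diag(9), tolerance = 1e-8,
               ignore_attr = TRUE)
  # sign convention: largest |loading| positive per component
  for (k in 1:9)
    expect_gt(m$loadings[which.max(abs(m$loadings[, k])), k], 0)
  # score variances equal eigenvalues, zero means
  sc <- as.matrix(m$scores[, -(1:2)])
  expect_equal(colMeans(sc), rep(0, 9), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(apply(sc, 2, var), m$eigenvalues, tolerance = 1e-8,
               ignore_attr = TRUE)
  # idempotent projection and distance preservation
  pr <- project_morphospace(m, avg)
  expect_equal(max(abs(pr - sc)), 0, tolerance = 1e-8)
  d_orig <- dist(scale(avg[, m$descriptors]))
  expect_equal(as.numeric(dist(pr)), as.numeric(d_orig), tolerance = 1e-8)
  # projecting the pooled mean row -> all-zero scores
  mu <- as.data.frame(as.list(m$center))
  expect_equal(as.numeric(project_morphospace(m, mu)), rep(0, 9),
               tolerance = 1e-10)
  # zero-variance descriptor errors by name
  bad <- avg; bad$RMS <- 1
  expect_error(build_morphospace(bad), "RMS")
  expect_error(project_morphospace(m, avg[, 1:4]), "missing descriptor")
})

test_that("two perfectly correlated descriptors give eigenvalues ~2 and ~0", {
  set.seed(7)
  n <- 200
  base <- matrix(rnorm(n * 8), n)
  x <- cbind(base[, 1], base[, 1], base[, 2:8])
  colnames(x) <- descriptor_names()
  t <- data.frame(line = sprintf("l%03d", 1:n), das = 35, x)
  m <- build_morphospace(t)
  expect_equal(max(m$eigenvalues), 2, tolerance = 0.25)
  expect_lt(min(m$eigenvalues), 1e-8)
})

test_that("summarize_descriptor_table returns the criterion-8 quantities", {
  t <- fx_descriptor_table(50, 3, 35:40, seed = 8)
  avg <- average_replicates(t)
  s <- summarize_descriptor_table(avg, reference_das = 35)
  expect_true(all(c("pc1_fraction", "pc2_fraction", "pc12_fraction",
                    "cor_pra_pl", "mean_compactness", "iso_loading_pc4")
                  %in% names(s)))
  expect_equal(s$pc12_fraction, s$pc1_fraction + s$pc2_fraction)
  expect_true(abs(s$cor_pra_pl) <= 1)
  expect_equal(s$mean_compactness,
               mean(avg$Compactness[avg$das == 35]))
})
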