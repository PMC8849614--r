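# Founder HMM, per-marker scan, permutation thresholds and effects.

test_that("founder posteriors are proper distributions with right shape", {
  fx <- fx_pop()
  p <- fx$probs
  expect_equal(dim(p$prob), c(60, 120, 19))
  expect_equal(dimnames(p$prob)[[2]], fx$panel$map$marker)
  rs <- apply(p$prob, c(1, 2), sum)
  expect_equal(max(abs(rs - 1)), 0, tolerance = 1e-10)
  expect_gte(min(p$prob), 0)
  expect_lte(max(p$prob), 1)
})

test_that("posterior argmax recovers the true founder mosaic", {
  fx <- fx_pop()
  hard <- apply(fx$probs$prob, c(1, 2), which.max)
  acc <- mean(hard == fx$pop$true_founder)
  expect_gte(acc, 0.9)
})

test_that("forward-backward equals brute-force path enumeration", {
  panel <- simulate_founders(4, 1, 6, 100, seed = 301)
  pop <- simulate_magic_population(panel, 5, 1, 0.05, seed = 302)
  pop$calls[1, 3] <- NA                     # include a missing call
  probs <- infer_founder_probabilities(pop, error_rate = 0.05,
                                       mosaic_density = 1)
  for (l in 1:5) {
    brute <- fx_brute_posterior(pop$calls[l, ], panel$alleles,
                                panel$map$pos_cM, 100, 0.05, 1)
    expect_equal(max(abs(probs$prob[l, , ] - brute)), 0, tolerance = 1e-8)
  }
})

test_that("all-missing lines get the uniform posterior; heavy missing drops", {
  panel <- simulate_founders(4, 1, 6, 100, seed = 303)
  pop <- simulate_magic_population(panel, 4, 1, 0, seed = 304)
  pop$calls[2, ] <- NA
  probs <- infer_founder_probabilities(pop, 0.01, 1, max_missing = 1)
  expect_equal(as.vector(probs$prob[2, , ]), rep(0.25, 24),
               tolerance = 1e-12)
  expect_warning(pd <- infer_founder_probabilities(pop, 0.01, 1),
                 "dropping 1 line")
  expect_equal(length(pd$lines), 3)
  expect_false(rownames(pop$calls)[2] %in% pd$lines)
})

test_that("scan finds a strong planted QTL at the causal marker", {
  fx <- fx_scan_pop()
  set.seed(401)
  causal <- 25
  eff <- rnorm(19, 0, 1)
  y <- eff[fx$pop$true_founder[, causal]] + rnorm(200, 0, 0.7)
  names(y) <- rownames(fx$pop$calls)
  s <- scan_trait(fx$probs, y, trait = "PRA", das = 35)
  expect_equal(nrow(s$table), 100)
  peak <- which.max(s$table$logP)
  expect_lte(abs(peak - causal), 2)
  expect_gt(max(s$table$logP), 6)
  expect_true(all(s$table$var_explained >= 0 & s$table$var_explained <= 1))
  expect_true(all(s$table$df2 == 200 - 1 - s$table$df1))
  # variance explained at the peak is in the right ballpark
  vq <- var(eff[fx$pop$true_founder[, causal]])
  expect_equal(s$table$var_explained[causal], vq / (vq + 0.49),
               tolerance = 0.15)
})

test_that("logP is invariant under affine phenotype rescaling", {
  fx <- fx_scan_pop()
  set.seed(402)
  y <- rnorm(200); names(y) <- rownames(fx$pop$calls)
  s1 <- scan_trait(fx$probs, y)
  s2 <- scan_trait(fx$probs, 3 + 2 * y)
  expect_equal(s2$table$logP, s1$table$logP, tolerance = 1e-8)
  expect_equal(s2$raw_effects, 3 + 2 * s1$raw_effects, tolerance = 1e-8)
  expect_equal(s2$effects, 3 + 2 * s1$effects, tolerance = 1e-6)
})

test_that("shrinkage never increases effect deviations; post_sd <= se", {
  fx <- fx_scan_pop()
  set.seed(403)
  causal <- 60
  y <- rnorm(19, 0, 0.8)[fx$pop$true_founder[, causal]] + rnorm(200)
  names(y) <- rownames(fx$pop$calls)
  s <- scan_trait(fx$probs, y)
  dev_raw <- abs(s$raw_effects - s$mean_y)
  dev_shr <- abs(s$effects - s$mean_y)
  expect_true(all(dev_shr <= dev_raw + 1e-12))
  expect_true(all(s$post_sd <= s$se + 1e-12))
})

test_that("scan_trait input validation and constant phenotypes", {
  fx <- fx_pop()
  y <- rnorm(60); names(y) <- fx$probs$lines
  expect_error(scan_trait(fx$probs, y[-1]), "missing for line")
  expect_error(scan_trait(fx$probs, unname(y[-1])), "align")
  y0 <- rep(1, 60); names(y0) <- fx$probs$lines
  expect_warning(s0 <- scan_trait(fx$probs, y0), "constant")
  expect_true(all(s0$table$logP == 0))
  few <- rnorm(10)
  small <- fx$probs
  small$prob <- small$prob[1:10, , , drop = FALSE]
  small$lines <- small$lines[1:10]
  expect_error(scan_trait(small, few), "more than 25")
})

test_that("permutation threshold: reproducible, monotone in alpha, checked", {
  fx <- fx_scan_pop()
  set.seed(404)
  y <- rnorm(200); names(y) <- rownames(fx$pop$calls)
  th1 <- permutation_threshold(fx$probs, y, 0.05, 100, seed = 9)
  th2 <- permutation_threshold(fx$probs, y, 0.05, 100, seed = 9)
  expect_identical(th1$threshold, th2$threshold)
  expect_equal(length(th1$max_logP), 100)
  expect_equal(th1$threshold,
               as.numeric(quantile(th1$max_logP, 0.95, type = 7)))
  th_strict <- permutation_threshold(fx$probs, y, 0.01, 100, seed = 9)
  th_loose <- permutation_threshold(fx$probs, y, 0.20, 100, seed = 9)
  expect_gte(th_strict$threshold, th1$threshold)
  expect_gte(th1$threshold, th_loose$threshold)
  expect_error(permutation_threshold(fx$probs, y, 0), "alpha")
  expect_error(permutation_threshold(fx$probs, y, 0.05, 50), "n_perm")
})

test_that("permutation max logP matches a direct re-scan of one permutation", {
  fx <- fx_scan_pop()
  set.seed(405)
  y <- rnorm(200); names(y) <- rownames(fx$pop$calls)
  th <- permutation_threshold(fx$probs, y, 0.05, 100, seed = 11)
  # regenerate the first permutation exactly as the implementation draws it
  set.seed(11)
  yp <- (y - mean(y))[sample.int(200)]
  names(yp) <- fx$probs$lines
  sp <- suppressWarnings(scan_trait(fx$probs, yp))
  expect_equal(max(sp$table$logP), th$max_logP[1], tolerance = 1e-8)
})

test_that("founder_effect_summary wraps one marker with intervals", {
  fx <- fx_scan_pop()
  set.seed(406)
  y <- rnorm(200); names(y) <- rownames(fx$pop$calls)
  s <- scan_trait(fx$probs, y)
  mk <- s$table$marker[5]
  fes <- founder_effect_summary(s, mk)
  expect_equal(nrow(fes), 19)
  expect_true(all(fes$lower <= fes$effect & fes$effect <= fes$upper))
  expect_equal(fes$effect, unname(s$effects[mk, ]))
  expect_error(founder_effect_summary(s, "nope"), "unknown marker")
})
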