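# Synthetic rosettes (with analytic oracle) and the MAGIC simulator.

test_that("n_leaves = 0 gives a disk with exact analytic values", {
  d <- fx_disk()
  r0 <- d$spec$center_radius_mm
  expect_equal(d$shape$area, pi * r0^2, tolerance = 1e-6)
  # raster area within 2% of vector area (spec fidelity bound; much closer)
  px_area <- sum(d$mask$data) * d$mask$mm_per_px^2
  expect_equal(px_area, pi * r0^2, tolerance = 0.02)
  # single connected component
  expect_equal(max(EBImage::bwlabel(d$mask$data)), 1)
})

test_that("8-leaf rosette renders distinct lobes and a connected mask", {
  r <- fx_rosette()
  expect_equal(max(EBImage::bwlabel(r$mask$data)), 1)
  # 8 leaves -> 8 skeleton tips (checked in detail in test-skeleton.R)
  expect_equal(r$spec$n_leaves, 8)
  expect_gt(r$shape$area, pi * r$spec$center_radius_mm^2)
})

test_that("identical spec + seed give bitwise-identical masks", {
  sp <- rosette_spec(n_leaves = 5, image_size_px = 256, mm_per_px = 0.2,
                     jitter = 0.05, seed = 99)
  g1 <- generate_rosette_mask(sp)
  g2 <- generate_rosette_mask(sp)
  expect_identical(g1$mask$data, g2$mask$data)
})

test_that("invalid geometry errors name the offending leaf", {
  expect_error(generate_rosette_mask(
    rosette_spec(blade_length_mm = 60, petiole_length_mm = 40)),
    "leaf 1 exceeds the image frame")
  expect_error(generate_rosette_mask(
    rosette_spec(petiole_width_mm = 8, center_radius_mm = 3.5)),
    "petiole width")
  expect_error(generate_rosette_mask(rosette_spec(n_leaves = 11)),
    "overlap at the central disk")
})

test_that("analytic descriptors: disk anchors and closed-form ellipse ECC", {
  d <- analytic_descriptors(fx_disk()$shape)
  expect_equal(d[["Compactness"]], 1, tolerance = 1e-9)
  expect_equal(d[["ECC"]], 0, tolerance = 1e-6)
  expect_equal(d[["RND"]], 1, tolerance = 1e-5)
  expect_equal(d[["RMS"]], 0, tolerance = 1e-5)
  # ellipse axes 4 and 2 -> ECC = sqrt(1 - (2/4)^2); via moment axes
  th <- 2 * pi * (0:3999) / 4000
  ell <- cbind(x = 2 * cos(th), y = sin(th))
  ax <- moment_axes(polygon_moments(ell)$cov)
  expect_equal(ax$eccentricity, sqrt(1 - 0.25), tolerance = 1e-4)
})

test_that("simulate_founders: shape, determinism, maf control, errors", {
  p <- simulate_founders(19, 5, 100, 100, seed = 3)
  expect_equal(nrow(p$map), 500)
  expect_equal(dim(p$alleles), c(19, 500))
  expect_false(is.unsorted(order(p$map$chrom, p$map$pos_bp)))
  for (ch in unique(p$map$chrom))
    expect_false(is.unsorted(p$map$pos_bp[p$map$chrom == ch], strictly = TRUE))
  expect_identical(p, simulate_founders(19, 5, 100, 100, seed = 3))
  # fixed maf 0.5: mean allele count per marker ~ 19/2
  q <- simulate_founders(19, 2, 200, 100, maf_range = c(0.5, 0.5), seed = 4)
  expect_equal(mean(colSums(q$alleles)), 9.5,
               tolerance = 3 * sqrt(19 * 0.25 / 400) / 9.5)
  expect_error(simulate_founders(1), "n_founders")
  expect_error(simulate_founders(19, maf_range = c(0, 0.5)), "maf_range")
})

test_that("simulate_magic_population: tiling, zero-rate, no-error cases", {
  fx <- fx_pop()
  pop <- fx$pop
  # segments tile each chromosome exactly
  for (ch in unique(fx$panel$map$chrom)) {
    L <- fx$panel$chrom_length_cM[[ch]]
    for (ln in rownames(pop$calls)[1:5]) {
      seg <- pop$truth[pop$truth$line == ln & pop$truth$chrom == ch, ]
      seg <- seg[order(seg$start_cM), ]
      expect_equal(seg$start_cM[1], 0)
      expect_equal(seg$end_cM[nrow(seg)], L)
      if (nrow(seg) > 1)
        expect_equal(seg$start_cM[-1], seg$end_cM[-nrow(seg)])
    }
  }
  # zero breakpoint rate -> single-founder chromosomes
  p0 <- simulate_magic_population(fx$panel, 10, 0, 0, seed = 5)
  expect_true(all(p0$n_breakpoints == 0))
  for (ch in unique(fx$panel$map$chrom)) {
    cols <- fx$panel$map$chrom == ch
    expect_true(all(apply(p0$true_founder[, cols], 1,
                          function(z) length(unique(z)) == 1)))
  }
  # epsilon = 0 -> calls equal the true founder's alleles everywhere
  idx <- cbind(as.vector(p0$true_founder),
               rep(seq_len(ncol(p0$calls)), each = nrow(p0$calls)))
  expect_identical(as.vector(p0$calls), as.integer(fx$panel$alleles[idx]))
})

test_that("planted breakpoint counts follow the Poisson law", {
  panel <- simulate_founders(4, 1, 10, 100, seed = 6)
  pop <- simulate_magic_population(panel, 1000, 2, 0, seed = 7)
  m <- mean(pop$n_breakpoints)
  se <- sd(pop$n_breakpoints) / sqrt(length(pop$n_breakpoints))
  expect_lt(abs(m - 2), 3 * se)
})

test_that("simulate_phenotypes: noise-free and pure-noise laws", {
  fx <- fx_pop()
  eff <- seq(-9, 9) / 3
  # no noise at all: phenotype exactly determined by the causal founder
  plan <- qtl_plan(fx$panel$map$marker[10], eff, v_line = 0, v_e = 0,
                   n_replicates = 2)
  ph <- simulate_phenotypes(fx$pop, list(PRA = plan), das = 35, seed = 8)
  fo <- fx$pop$true_founder[ph$line[1:60], 10]
  expect_equal(ph$PRA[1:60], eff[fo])
  # pure noise: between-line variance of replicate means ~ V_e / n_reps
  plan0 <- qtl_plan(fx$panel$map$marker[10], rep(0, 19), v_line = 0,
                    v_e = 2, n_replicates = 4)
  ph0 <- simulate_phenotypes(fx$pop, list(PRA = plan0), das = 35, seed = 9)
  means <- tapply(ph0$PRA, ph0$line, mean)
  expect_equal(var(as.numeric(means)), 2 / 4, tolerance = 0.5)
  expect_error(qtl_plan("m", rep(0, 19), v_line = -1), "variance")
})

test_that("targeted QTL variance fraction is realized", {
  panel <- simulate_founders(19, 1, 20, 100, seed = 10)
  pop <- simulate_magic_population(panel, 400, 1, 0, seed = 11)
  fr <- replicate(20, {
    plan <- qtl_plan(panel$map$marker[10], rnorm(19), v_line = 1, v_e = 1,
                     target_variance_fraction = 0.2)
    ph <- simulate_phenotypes(pop, list(PRA = plan), das = 35,
                              seed = sample.int(1e6, 1))
    attr(ph, "realized")$frac_qtl
  })
  expect_lt(abs(mean(fr) - 0.2), 0.05)
})
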