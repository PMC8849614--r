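# Shared, lazily built fixtures. Heavy objects are generated once per test
# run and cached in this environment. The package is attached here so the
# suite runs identically under R CMD check and a bare testthat::test_dir().

library(rosetteqtl)

.fx <- new.env(parent = emptyenv())

# Default 8-leaf rosette (mask + analytic shape) at 1024 px.
fx_rosette <- function() {
  if (is.null(.fx$rosette)) {
    sp <- rosette_spec()
    g <- generate_rosette_mask(sp)
    .fx$rosette <- list(spec = sp, mask = g$mask, shape = g$shape)
  }
  .fx$rosette
}

# Ideal disk (no leaves) at 1024 px.
fx_disk <- function() {
  if (is.null(.fx$disk)) {
    sp <- rosette_spec(n_leaves = 0, center_radius_mm = 10)
    g <- generate_rosette_mask(sp)
    .fx$disk <- list(spec = sp, mask = g$mask, shape = g$shape)
  }
  .fx$disk
}

# Small MAGIC population for HMM and genotype tests.
fx_pop <- function() {
  if (is.null(.fx$pop)) {
    panel <- simulate_founders(19, 3, 40, 100, seed = 101)
    pop <- simulate_magic_population(panel, 60, 1, 0.01, seed = 102)
    probs <- infer_founder_probabilities(pop, 0.01, 1)
    .fx$pop <- list(panel = panel, pop = pop, probs = probs)
  }
  .fx$pop
}

# Larger population for scan calibration/power (100 markers x 200 lines).
fx_scan_pop <- function() {
  if (is.null(.fx$scan_pop)) {
    panel <- simulate_founders(19, 2, 50, 100, seed = 201)
    pop <- simulate_magic_population(panel, 200, 1, 0.01, seed = 202)
    probs <- infer_founder_probabilities(pop, 0.01, 1)
    .fx$scan_pop <- list(panel = panel, pop = pop, probs = probs)
  }
  .fx$scan_pop
}

# Random but well-formed long descriptor table.
fx_descriptor_table <- function(n_lines = 40, n_reps = 3, das = 35:38,
                                seed = 1) {
  set.seed(seed)
  descs <- descriptor_names()
  out <- expand.grid(line = sprintf("l%03d", seq_len(n_lines)),
                     replicate = seq_len(n_reps), das = das,
                     stringsAsFactors = FALSE)
  base <- matrix(rnorm(n_lines * length(descs)), n_lines)
  for (k in seq_along(descs))
    out[[descs[k]]] <- base[match(out$line, sprintf("l%03d", seq_len(n_lines))), k] +
      0.1 * out$das + rnorm(nrow(out), 0, 0.5)
  out
}

# Tiny GFF3 gene annotation fixture.
fx_gff3 <- function(path = tempfile(fileext = ".gff3")) {
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t100\t200\t.\t+\t.\tID=AT1G0001;Note=alpha gene",
    "chr1\ttest\tgene\t400\t500\t.\t-\t.\tID=AT1G0002;Note=beta gene",
    "chr1\ttest\texon\t120\t180\t.\t+\t.\tID=AT1G0001.e1",
    "chr2\ttest\tgene\t1000\t2000\t.\t+\t.\tID=AT2G0001;Note=gamma gene"),
    path)
  path
}

# Brute-force founder-path posterior for small HMM instances: enumerates
# every founder path with the same uniform-reset transition and emission
# model as infer_founder_probabilities.
fx_brute_posterior <- function(calls_line, alleles, pos_cM, L,
                               error_rate, mosaic_density) {
  K <- nrow(alleles); M <- ncol(alleles)
  emis <- matrix(NA_real_, K, M)
  for (m in seq_len(M)) {
    if (is.na(calls_line[m])) emis[, m] <- 1
    else emis[, m] <- ifelse(alleles[, m] == calls_line[m],
                             1 - error_rate, error_rate)
  }
  d <- diff(pos_cM)
  a <- exp(-mosaic_density * d / L)
  trans <- function(m, from, to) {
    p_same <- a[m] + (1 - a[m]) / K
    p_other <- (1 - a[m]) / K
    if (from == to) p_same else p_other
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), M)))
  w <- apply(paths, 1, function(pt) {
    p <- emis[pt[1], 1] / K
    for (m in seq_len(M - 1))
      p <- p * trans(m, pt[m], pt[m + 1]) * emis[pt[m + 1], m + 1]
    p
  })
  post <- matrix(0, M, K)
  for (m in seq_len(M))
    for (k in seq_len(K))
      post[m, k] <- sum(w[paths[, m] == k])
  post / rowSums(post)
}
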