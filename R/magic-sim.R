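# Simulation of a MAGIC-like multiparent population: founder SNP panel,
# founder-mosaic line genomes, SNP calls with genotyping error, and
# replicated phenotypes with planted founder-effect QTLs.

#' Simulate a founder SNP panel
#'
#' Draws a biallelic SNP panel for `n_founders` inbred founders over
#' `n_chromosomes` chromosomes. Each marker's reference-allele frequency is
#' drawn uniformly from `maf_range` and founder alleles are independent
#' Bernoulli draws at that frequency. Map positions are equally spaced in cM
#' along each chromosome; physical positions are a fixed 250 kb/cM scaling.
#'
#' @param n_founders number of founder lines (>= 2), default 19.
#' @param n_chromosomes number of chromosomes.
#' @param n_markers_per_chrom markers per chromosome (scalar or one value per
#'   chromosome).
#' @param chrom_length_cM genetic length of each chromosome (scalar or
#'   per-chromosome).
#' @param maf_range length-2 interval in (0, 1) for the per-marker allele
#'   frequency.
#' @param seed integer seed; identical inputs + seed give an identical panel.
#' @return A `founder_panel`: list with `map` (data.frame `marker`, `chrom`,
#'   `pos_bp`, `pos_cM`, sorted by (chrom, position)), `alleles`
#'   (`n_founders` x n_markers 0/1 matrix, columns named by marker), and
#'   `n_founders`.
#' @export
simulate_founders <- function(n_founders = 19, n_chromosomes = 5,
                              n_markers_per_chrom = 100,
                              chrom_length_cM = 100,
                              maf_range = c(0.2, 0.5), seed = 1) {
  if (n_founders < 2) stop("n_founders must be >= 2")
  if (length(maf_range) != 2 || any(!is.finite(maf_range)) ||
      maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] >= 1)
    stop("maf_range must be an interval inside (0, 1)")
  n_mk <- rep_len(as.integer(n_markers_per_chrom), n_chromosomes)
  len <- rep_len(as.numeric(chrom_length_cM), n_chromosomes)
  if (any(n_mk < 2)) stop("each chromosome needs at least 2 markers")
  if (any(len <= 0)) stop("chromosome lengths must be positive")
  set.seed(seed)
  maps <- vector("list", n_chromosomes)
  for (ch in seq_len(n_chromosomes)) {
    pos_cM <- seq(0, len[ch], length.out = n_mk[ch])
    maps[[ch]] <- data.frame(
      marker = sprintf("chr%d_m%03d", ch, seq_len(n_mk[ch])),
      chrom = sprintf("chr%d", ch),
      pos_bp = as.integer(round(pos_cM * 250000)) + 1L,
      pos_cM = pos_cM,
      stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, maps)
  n_markers <- nrow(map)
  freq <- stats::runif(n_markers, maf_range[1], maf_range[2])
  alleles <- matrix(stats::rbinom(n_founders * n_markers, 1,
                                  rep(freq, each = n_founders)),
                    nrow = n_founders)
  colnames(alleles) <- map$marker
  rownames(alleles) <- sprintf("founder%02d", seq_len(n_founders))
  structure(list(map = map, alleles = alleles, n_founders = n_founders,
                 chrom_length_cM = stats::setNames(len, unique(map$chrom)),
                 seed = seed),
            class = "founder_panel")
}

#' Simulate a MAGIC population as founder-label mosaics
#'
#' Each line's chromosome is tiled by a founder-label mosaic: the number of
#' breakpoints is Poisson with mean `expected_breakpoints_per_chrom`,
#' breakpoint positions are uniform in cM, and each segment's founder is
#' drawn uniformly (adjacent segments may repeat a founder; planted
#' breakpoint counts are returned for calibration checks). SNP calls are the
#' true founder's alleles flipped independently with probability
#' `error_rate`, and set to missing (`NA`) with probability `missing_rate`.
#'
#' @param panel a `founder_panel` from [simulate_founders()].
#' @param n_lines number of lines (>= 1).
#' @param expected_breakpoints_per_chrom Poisson mean of breakpoints per
#'   chromosome per line (0 gives single-founder chromosomes).
#' @param error_rate symmetric allele-flip genotyping error probability.
#' @param missing_rate probability a call is set to missing.
#' @param seed integer seed.
#' @return A `magic_genotypes`: list with `panel`, `calls` (lines x markers,
#'   0/1/NA), `true_founder` (lines x markers founder index, the simulator
#'   truth), `truth` (data.frame `line`, `chrom`, `start_cM`, `end_cM`,
#'   `founder` tiling every chromosome), `n_breakpoints` (lines x
#'   chromosomes), `error_rate`, `seed`.
#' @export
simulate_magic_population <- function(panel, n_lines,
                                      expected_breakpoints_per_chrom = 1,
                                      error_rate = 0.01, missing_rate = 0,
                                      seed = 1) {
  stopifnot(inherits(panel, "founder_panel"))
  if (nrow(panel$map) == 0) stop("empty panel")
  if (n_lines < 1) stop("n_lines must be >= 1")
  if (expected_breakpoints_per_chrom < 0) stop("breakpoint rate must be >= 0")
  set.seed(seed)
  map <- panel$map
  chroms <- unique(map$chrom)
  n_markers <- nrow(map)
  true_founder <- matrix(NA_integer_, n_lines, n_markers,
                         dimnames = list(sprintf("line%04d", seq_len(n_lines)),
                                         map$marker))
  nbp <- matrix(0L, n_lines, length(chroms),
                dimnames = list(rownames(true_founder), chroms))
  segs <- list()
  for (ch in chroms) {
    cm <- map$pos_cM[map$chrom == ch]
    L <- panel$chrom_length_cM[[ch]]
    cols <- which(map$chrom == ch)
    for (i in seq_len(n_lines)) {
      k <- stats::rpois(1, expected_breakpoints_per_chrom)
      bp <- sort(stats::runif(k, 0, L))
      founders <- sample.int(panel$n_founders, k + 1, replace = TRUE)
      nbp[i, ch] <- k
      starts <- c(0, bp); ends <- c(bp, L)
      segs[[length(segs) + 1]] <- data.frame(
        line = rownames(true_founder)[i], chrom = ch,
        start_cM = starts, end_cM = ends, founder = founders,
        stringsAsFactors = FALSE)
      # founder at each marker: index of the segment containing its position
      true_founder[i, cols] <- founders[findInterval(cm, starts)]
    }
  }
  truth <- do.call(rbind, segs)
  rownames(truth) <- NULL
  # SNP calls from founder alleles with symmetric flip errors
  calls <- matrix(panel$alleles[cbind(as.vector(true_founder),
                                      rep(seq_len(n_markers), each = n_lines))],
                  n_lines, n_markers, dimnames = dimnames(true_founder))
  if (error_rate > 0) {
    flip <- matrix(stats::runif(n_lines * n_markers) < error_rate,
                   n_lines, n_markers)
    calls[flip] <- 1L - calls[flip]
  }
  if (missing_rate > 0) {
    miss <- matrix(stats::runif(n_lines * n_markers) < missing_rate,
                   n_lines, n_markers)
    calls[miss] <- NA_integer_
  }
  structure(list(panel = panel, calls = calls, true_founder = true_founder,
                 truth = truth, n_breakpoints = nbp,
                 error_rate = error_rate, seed = seed),
            class = "magic_genotypes")
}

#' Plan a planted QTL for phenotype simulation
#'
#' @param causal_marker marker id at which the QTL acts.
#' @param founder_effects numeric effects, one per founder (trait units).
#' @param v_line variance of the per-line random effect (non-negative).
#' @param v_e variance of the per-replicate residual (non-negative).
#' @param n_replicates replicates per line.
#' @param mu grand mean.
#' @param target_variance_fraction optional: rescale `founder_effects` about
#'   their mean so the QTL variance (under a uniform founder distribution) is
#'   this fraction of the total phenotypic variance.
#' @return A `qtl_plan` list.
#' @export
qtl_plan <- function(causal_marker, founder_effects, v_line = 1, v_e = 1,
                     n_replicates = 3, mu = 0,
                     target_variance_fraction = NULL) {
  if (v_line < 0 || v_e < 0) stop("variance components must be >= 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  founder_effects <- as.numeric(founder_effects)
  if (!is.null(target_variance_fraction)) {
    f <- target_variance_fraction
    if (f <= 0 || f >= 1) stop("target_variance_fraction must be in (0, 1)")
    v_pop <- mean((founder_effects - mean(founder_effects))^2)
    if (v_pop <= 0) stop("cannot rescale all-equal founder effects")
    v_needed <- f / (1 - f) * (v_line + v_e)
    founder_effects <- mean(founder_effects) +
      sqrt(v_needed / v_pop) * (founder_effects - mean(founder_effects))
  }
  structure(list(causal_marker = causal_marker,
                 founder_effects = founder_effects,
                 v_line = v_line, v_e = v_e,
                 n_replicates = n_replicates, mu = mu),
            class = "qtl_plan")
}

#' Simulate replicated phenotypes with planted QTLs
#'
#' Phenotype of replicate `j` of line `i` is `mu + effect[founder of line i
#' at the causal marker] + line_i + eps_ij` with `line_i ~ N(0, v_line)` and
#' `eps_ij ~ N(0, v_e)`, i.e. the one-way random-effects model plus a
#' founder-indexed QTL term. Each (descriptor, day) combination is an
#' independent realisation of its plan's noise terms; the genetic term is
#' fixed by the line's mosaic.
#'
#' @param pop a `magic_genotypes` from [simulate_magic_population()].
#' @param plans a single `qtl_plan` or a named list of plans, one per
#'   descriptor column to simulate (a plan of `NULL` effects simulates pure
#'   noise). A single unnamed plan produces a column named `PRA`.
#' @param das vector of days after sowing to emit (one block per day).
#' @param seed integer seed.
#' @return Long-format data.frame with columns `line`, `replicate`, `das`,
#'   then one column per descriptor. Attribute `realized` holds the realised
#'   variance decomposition (per descriptor and day): `var_qtl`, `var_line`,
#'   `var_e`, `frac_qtl`.
#' @export
simulate_phenotypes <- function(pop, plans, das = 35, seed = 1) {
  stopifnot(inherits(pop, "magic_genotypes"))
  if (inherits(plans, "qtl_plan")) plans <- list(PRA = plans)
  if (is.null(names(plans)) || any(names(plans) == ""))
    stop("plans must be a named list (descriptor names)")
  if (length(unique(vapply(plans, function(p) p$n_replicates, 0))) != 1)
    stop("all plans must share the same n_replicates")
  markers <- colnames(pop$true_founder)
  n_lines <- nrow(pop$true_founder)
  lines <- rownames(pop$true_founder)
  set.seed(seed)
  out <- NULL
  realized <- NULL
  for (d in das) {
    base <- NULL
    for (nm in names(plans)) {
      plan <- plans[[nm]]
      if (length(plan$founder_effects) != pop$panel$n_founders)
        stop("founder_effects length must equal the number of founders")
      if (!plan$causal_marker %in% markers)
        stop(sprintf("causal marker '%s' not in panel", plan$causal_marker))
      founder_at <- pop$true_founder[, plan$causal_marker]
      gen <- plan$founder_effects[founder_at]
      line_eff <- stats::rnorm(n_lines, 0, sqrt(plan$v_line))
      J <- plan$n_replicates
      eps <- matrix(stats::rnorm(n_lines * J, 0, sqrt(plan$v_e)), n_lines, J)
      y <- plan$mu + gen + line_eff + eps          # n_lines x J
      if (is.null(base))
        base <- data.frame(line = rep(lines, J),
                           replicate = rep(seq_len(J), each = n_lines),
                           das = d, stringsAsFactors = FALSE)
      base[[nm]] <- as.vector(y)
      vq <- stats::var(gen); vl <- stats::var(line_eff); ve <- stats::var(as.vector(eps))
      realized <- rbind(realized, data.frame(
        descriptor = nm, das = d, var_qtl = vq, var_line = vl, var_e = ve,
        frac_qtl = vq / (vq + vl + ve), stringsAsFactors = FALSE))
    }
    out <- rbind(out, base)
  }
  attr(out, "realized") <- realized
  out
}
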