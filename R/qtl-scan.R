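# Founder-of-origin HMM (forward-backward posteriors), per-marker F-test
# scan on founder probabilities, permutation genome-wide thresholds and
# shrinkage founder-effect estimates.

#' Infer founder-of-origin probabilities by forward-backward HMM
#'
#' Hidden state = founder of origin at each marker; per chromosome the chain
#' is a uniform-reset jump process: between adjacent markers separated by
#' `d` cM on a chromosome of length `L` cM, a jump event occurs with
#' probability `1 - exp(-mu)`, `mu = mosaic_density * d / L`, after which
#' the founder is redrawn uniformly. This matches the simulator's Poisson/
#' uniform mosaic process; the probability of switching to each specific
#' other founder is `(1 - exp(-mu)) / K`. Emission: `1 - error_rate` when
#' the line's call matches the founder allele, `error_rate` on mismatch,
#' uniform (1) on missing. Lines with more than `max_missing` missing calls
#' are dropped with a warning.
#'
#' @param g a `magic_genotypes`.
#' @param error_rate emission error probability.
#' @param mosaic_density expected breakpoints per chromosome per line.
#' @param max_missing drop lines whose fraction of missing calls exceeds
#'   this (default 0.2).
#' @return A `founder_probabilities`: list with `prob` (lines x markers x
#'   founders array, each row-slice summing to 1), `map`, `lines`,
#'   `n_founders`.
#' @export
infer_founder_probabilities <- function(g, error_rate = 0.01,
                                        mosaic_density = 1,
                                        max_missing = 0.2) {
  stopifnot(inherits(g, "magic_genotypes"))
  map <- g$panel$map
  for (ch in unique(map$chrom)) {
    pc <- map$pos_cM[map$chrom == ch]
    if (is.unsorted(pc, strictly = TRUE)) stop("markers not sorted within chromosome")
  }
  calls <- g$calls
  frac_na <- rowMeans(is.na(calls))
  if (any(frac_na > max_missing)) {
    warning(sprintf("dropping %d line(s) with > %d%% missing calls",
                    sum(frac_na > max_missing), round(100 * max_missing)))
    calls <- calls[frac_na <= max_missing, , drop = FALSE]
  }
  K <- g$panel$n_founders
  N <- nrow(calls)
  M <- nrow(map)
  prob <- array(NA_real_, c(N, M, K),
                dimnames = list(rownames(calls), map$marker, NULL))
  emission <- function(col) {
    # N x K: likelihood of each founder given the line's call at one marker
    al <- g$panel$alleles[, col]          # K alleles
    cl <- calls[, col]                    # N calls
    match <- outer(cl, al, "==")          # NA rows where call missing
    e <- ifelse(match, 1 - error_rate, error_rate)
    e[is.na(e)] <- 1
    e
  }
  for (ch in unique(map$chrom)) {
    cols <- which(map$chrom == ch)
    L <- g$panel$chrom_length_cM[[ch]]
    d <- diff(map$pos_cM[cols])
    a <- exp(-mosaic_density * d / L)     # no-jump probability per interval
    nm <- length(cols)
    fwd <- vector("list", nm)
    f <- emission(cols[1]) / K
    f <- f / rowSums(f)
    fwd[[1]] <- f
    for (m in seq_len(nm - 1)) {
      # T = a I + (1-a)/K J applied to the forward vector, then emission
      f <- (a[m] * f + (1 - a[m]) / K * rowSums(f)) * emission(cols[m + 1])
      f <- f / rowSums(f)
      fwd[[m + 1]] <- f
    }
    b <- matrix(1, N, K)
    post <- fwd[[nm]] * b
    prob[, cols[nm], ] <- post / rowSums(post)
    for (m in rev(seq_len(nm - 1))) {
      be <- b * emission(cols[m + 1])
      b <- a[m] * be + (1 - a[m]) / K * rowSums(be)
      b <- b / rowSums(b)
      post <- fwd[[m]] * b
      prob[, cols[m], ] <- post / rowSums(post)
    }
  }
  structure(list(prob = prob, map = map, lines = rownames(calls),
                 n_founders = K),
            class = "founder_probabilities")
}

# Centered founder-probability design at one marker with its thin QR.
.marker_design <- function(p, m) {
  X <- p$prob[, m, ]
  Xc <- sweep(X, 2, colMeans(X))
  qr <- qr(Xc)
  r <- qr$rank
  list(Q = qr.Q(qr)[, seq_len(r), drop = FALSE], rank = r, Xc = Xc)
}

#' Per-marker founder-probability association scan
#'
#' At each marker the phenotype is regressed on the founder-probability
#' columns (intercept absorbed by centering; rank deficiency handled by the
#' pseudo-inverse). The founder term is tested by an F-test with numerator
#' df equal to the rank of the centered design; `logP = -log10(p)`.
#' Founder effects are reported as empirical-Bayes shrinkage estimates:
#' raw least-squares deviations are shrunk toward zero with weight
#' `tau2 / (tau2 + se_j^2)`, `tau2` estimated by method of moments, so
#' founders carrying little probability mass (large `se_j`) are shrunk
#' hardest and get the widest intervals.
#'
#' @param p a `founder_probabilities`.
#' @param phenotype numeric vector named by line (or aligned with
#'   `p$lines`).
#' @param trait,das labels stored with the result.
#' @return A `scan_result`: list with `table` (data.frame `marker`, `chrom`,
#'   `pos_bp`, `pos_cM`, `logP`, `var_explained`, `df1`, `df2`), `effects`,
#'   `raw_effects`, `se`, `post_sd` (markers x founders matrices), `trait`,
#'   `das`, `n`, `mean_y`.
#' @export
scan_trait <- function(p, phenotype, trait = "trait", das = NA) {
  stopifnot(inherits(p, "founder_probabilities"))
  if (!is.null(names(phenotype))) {
    miss <- setdiff(p$lines, names(phenotype))
    if (length(miss) > 0)
      stop(sprintf("phenotype missing for line(s): %s",
                   paste(utils::head(miss, 3), collapse = ", ")))
    y <- phenotype[p$lines]
  } else {
    if (length(phenotype) != length(p$lines))
      stop("unnamed phenotype must align with genotype lines")
    y <- phenotype
  }
  n <- length(y)
  if (n <= 25) stop("need more than 25 lines")
  M <- nrow(p$map); K <- p$n_founders
  constant <- stats::var(y) == 0
  if (constant) warning("constant phenotype: logP = 0 at all markers")
  yc <- y - mean(y)
  rss0 <- sum(yc^2)
  logP <- varex <- df1 <- df2 <- numeric(M)
  eff <- raw <- se <- psd <- matrix(NA_real_, M, K)
  for (m in seq_len(M)) {
    d <- .marker_design(p, m)
    if (constant || d$rank == 0) { logP[m] <- 0; varex[m] <- 0; df1[m] <- d$rank; df2[m] <- n - 1 - d$rank; next }
    qty <- crossprod(d$Q, yc)
    rss1 <- rss0 - sum(qty^2)
    df1[m] <- d$rank
    df2[m] <- n - 1 - d$rank
    fstat <- ((rss0 - rss1) / df1[m]) / (rss1 / df2[m])
    pv <- stats::pf(fstat, df1[m], df2[m], lower.tail = FALSE)
    logP[m] <- -log10(max(pv, .Machine$double.xmin))
    varex[m] <- 1 - rss1 / rss0
    # pseudo-inverse least squares on the centered design
    sv <- svd(d$Xc)
    pos <- sv$d > max(sv$d) * 1e-8
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], yc)) / sv$d[pos])
    sigma2 <- rss1 / df2[m]
    covb <- sv$v[, pos, drop = FALSE] %*%
      diag(1 / sv$d[pos]^2, sum(pos)) %*% t(sv$v[, pos, drop = FALSE]) * sigma2
    sej <- sqrt(pmax(diag(covb), .Machine$double.eps))
    tau2 <- max(0, mean(beta^2) - mean(sej^2))
    w <- tau2 / (tau2 + sej^2)
    raw[m, ] <- mean(y) + beta
    eff[m, ] <- mean(y) + w * beta
    se[m, ] <- sej
    psd[m, ] <- sqrt(w) * sej
  }
  tab <- data.frame(marker = p$map$marker, chrom = p$map$chrom,
                    pos_bp = p$map$pos_bp, pos_cM = p$map$pos_cM,
                    logP = logP, var_explained = varex,
                    df1 = df1, df2 = df2, stringsAsFactors = FALSE)
  rownames(eff) <- rownames(raw) <- rownames(se) <- rownames(psd) <- p$map$marker
  structure(list(table = tab, effects = eff, raw_effects = raw, se = se,
                 post_sd = psd, trait = trait, das = das, n = n,
                 mean_y = mean(y)),
            class = "scan_result")
}

#' Permutation genome-wide significance threshold
#'
#' Permutes the phenotype across lines `n_perm` times, records each
#' permutation's maximum `logP` over all markers, and returns the
#' `(1 - alpha)` type-7 quantile. All permutations are scanned in a single
#' cross-product against the stacked per-marker orthonormal bases.
#'
#' @param p a `founder_probabilities`.
#' @param phenotype numeric vector named by line (or aligned).
#' @param alpha genome-wide error level in (0, 1).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed; thresholds are reproducible given the seed.
#' @return A `qtl_threshold`: list with `alpha`, `n_perm`, `threshold`,
#'   `seed`, `max_logP` (the permutation null sample).
#' @export
permutation_threshold <- function(p, phenotype, alpha = 0.05, n_perm = 500,
                                  seed = 1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (!is.null(names(phenotype))) phenotype <- phenotype[p$lines]
  y <- as.numeric(phenotype)
  n <- length(y)
  yc <- y - mean(y)
  M <- nrow(p$map)
  designs <- lapply(seq_len(M), function(m) .marker_design(p, m))
  ranks <- vapply(designs, function(d) d$rank, 0L)
  Qbig <- do.call(cbind, lapply(designs, function(d) d$Q))
  idx <- rep.int(seq_len(M), ranks)
  set.seed(seed)
  Yperm <- vapply(seq_len(n_perm), function(i) yc[sample.int(n)],
                  numeric(n))
  rss0 <- sum(yc^2)
  expl <- rowsum((crossprod(Qbig, Yperm))^2, idx)   # M x n_perm explained SS
  maxlp <- numeric(n_perm)
  df2 <- n - 1 - ranks
  for (m in seq_len(M)) {
    if (ranks[m] == 0) next
    rss1 <- rss0 - expl[m, ]
    fstat <- (expl[m, ] / ranks[m]) / (rss1 / df2[m])
    lp <- -log10(pmax(stats::pf(fstat, ranks[m], df2[m], lower.tail = FALSE),
                      .Machine$double.xmin))
    maxlp <- pmax(maxlp, lp)
  }
  structure(list(alpha = alpha, n_perm = n_perm,
                 threshold = as.numeric(stats::quantile(maxlp, 1 - alpha,
                                                        type = 7)),
                 seed = seed, max_logP = maxlp),
            class = "qtl_threshold")
}

#' Founder effects at one marker with intervals
#'
#' @param s a `scan_result`.
#' @param marker marker id present in the scan.
#' @param level interval coverage (default 0.95).
#' @return Data.frame `founder`, `effect` (shrinkage estimate), `raw`
#'   (least-squares estimate), `se`, `lower`, `upper`.
#' @export
founder_effect_summary <- function(s, marker, level = 0.95) {
  stopifnot(inherits(s, "scan_result"))
  if (!marker %in% rownames(s$effects)) stop(sprintf("unknown marker '%s'", marker))
  z <- stats::qnorm(1 - (1 - level) / 2)
  eff <- s$effects[marker, ]
  se <- s$se[marker, ]
  data.frame(founder = seq_along(eff), effect = eff,
             raw = s$raw_effects[marker, ], se = se,
             lower = eff - z * se, upper = eff + z * se)
}
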