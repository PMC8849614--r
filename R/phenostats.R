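# Replicate averaging, per-day correlations, broad-sense heritability and
# the correlation-matrix PCA morphospace.

#' The nine descriptor names in canonical (Table) order
#' @export
descriptor_names <- function() {
  c("PRA", "PL", "Compactness", "RMS", "SOL", "RND", "RCH", "ISO", "ECC")
}

.descriptor_cols <- function(t) {
  setdiff(colnames(t), c("line", "replicate", "das"))
}

#' Average replicates per (line, day)
#'
#' Arithmetic mean over non-missing replicate values for every descriptor
#' column; `(line, das)` cells whose values are all missing are dropped with
#' a warning.
#'
#' @param t long descriptor table with columns `line`, `replicate`, `das`
#'   and one column per descriptor.
#' @return Data.frame with one row per (line, das): `line`, `das`,
#'   `n_replicates` (replicates contributing at least one value), descriptor
#'   means.
#' @export
average_replicates <- function(t) {
  stopifnot(all(c("line", "replicate", "das") %in% colnames(t)))
  descs <- .descriptor_cols(t)
  if (length(descs) == 0) stop("no descriptor columns")
  key <- interaction(t$line, t$das, drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(t)), key)
  rows <- lapply(idx, function(ii) {
    sub <- t[ii, , drop = FALSE]
    vals <- vapply(descs, function(d) mean(sub[[d]], na.rm = TRUE), 0)
    vals[is.nan(vals)] <- NA_real_
    any_val <- rowSums(!is.na(sub[, descs, drop = FALSE])) > 0
    c(list(line = sub$line[1], das = sub$das[1],
           n_replicates = sum(any_val)), as.list(vals))
  })
  out <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  empty <- out$n_replicates == 0
  if (any(empty)) {
    warning(sprintf("%d (line, das) cells had no replicate values; dropped",
                    sum(empty)))
    out <- out[!empty, , drop = FALSE]
  }
  out[order(out$das, out$line), , drop = FALSE]
}

#' Pairwise Pearson correlations of descriptor averages at one day
#'
#' @param t averaged table from [average_replicates()].
#' @param das the day to subset.
#' @return Symmetric correlation matrix over the descriptor columns; entries
#'   for zero-variance descriptors are `NA` (diagonal stays 1).
#' @export
correlations_by_das <- function(t, das) {
  sub <- t[t$das == das, , drop = FALSE]
  if (nrow(sub) < 3) stop("need at least 3 lines at the requested das")
  descs <- setdiff(.descriptor_cols(sub), "n_replicates")
  x <- as.matrix(sub[, descs, drop = FALSE])
  suppressWarnings(cm <- stats::cor(x, use = "pairwise.complete.obs"))
  diag(cm) <- 1
  cm
}

#' Broad-sense heritability at one day
#'
#' Fits the one-way random-effects model `P_ij = mu + R_i + eps_ij` (line as
#' random intercept) by REML and returns `H2 = Vg / (Vg + Ve)` with the
#' among-line variance truncated at zero. Degenerate data (all observations
#' equal) give `Vg = 0`, `H2 = 0`.
#'
#' @param t long descriptor table (with replicates).
#' @param descriptor descriptor column name.
#' @param das day to subset.
#' @return A `heritability_estimate`: list with `descriptor`, `das`, `Vg`,
#'   `Ve`, `H2`.
#' @export
heritability <- function(t, descriptor, das) {
  stopifnot(descriptor %in% colnames(t))
  sub <- t[t$das == das & !is.na(t[[descriptor]]), , drop = FALSE]
  reps_per_line <- table(sub$line)
  if (sum(reps_per_line >= 2) < 2 || length(reps_per_line) < 2)
    stop("need >= 2 lines with >= 2 replicates")
  y <- sub[[descriptor]]
  if (stats::var(y) == 0) {
    est <- list(descriptor = descriptor, das = das, Vg = 0, Ve = 0, H2 = 0)
    return(structure(est, class = "heritability_estimate"))
  }
  dat <- data.frame(y = y, line = factor(sub$line))
  fit <- suppressMessages(lme4::lmer(y ~ 1 + (1 | line), data = dat, REML = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vg <- max(0, vc$vcov[vc$grp == "line"])
  ve <- vc$vcov[vc$grp == "Residual"]
  h2 <- if (vg + ve <= 0) 0 else vg / (vg + ve)
  structure(list(descriptor = descriptor, das = das,
                 Vg = vg, Ve = ve, H2 = h2),
            class = "heritability_estimate")
}

#' Heritability for every descriptor x day combination
#' @param t long descriptor table.
#' @return Data.frame `descriptor`, `das`, `Vg`, `Ve`, `H2`.
#' @export
heritability_all <- function(t) {
  descs <- .descriptor_cols(t)
  days <- sort(unique(t$das))
  out <- NULL
  for (d in days) for (ds in descs) {
    h <- heritability(t, ds, d)
    out <- rbind(out, data.frame(descriptor = ds, das = d,
                                 Vg = h$Vg, Ve = h$Ve, H2 = h$H2,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Build the 9-PC correlation-matrix morphospace
#'
#' Standardizes each descriptor by its pooled mean and SD over all rows,
#' eigendecomposes the correlation matrix and keeps all components. Sign
#' convention: the largest-magnitude loading of each component is positive.
#'
#' @param t averaged table from [average_replicates()] (pooled over days).
#' @return A `morphospace_model`: list with `center`, `scale`, `loadings`
#'   (descriptors x PCs), `eigenvalues`, `variance_fractions`, `scores`
#'   (data.frame `line`, `das`, `PC1`..), `descriptors`.
#' @export
build_morphospace <- function(t) {
  descs <- setdiff(.descriptor_cols(t), "n_replicates")
  if (nrow(t) < 10) stop("need at least 10 rows")
  x <- as.matrix(t[, descs, drop = FALSE])
  if (any(!is.finite(x))) stop("non-finite descriptor values")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop(sprintf("zero-variance descriptor: %s",
                 paste(descs[sds == 0], collapse = ", ")))
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  load <- pc$rotation
  scores <- pc$x
  for (k in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, k])), k] < 0) {
      load[, k] <- -load[, k]
      scores[, k] <- -scores[, k]
    }
  }
  ev <- pc$sdev^2
  structure(list(center = pc$center, scale = pc$scale,
                 loadings = load, eigenvalues = ev,
                 variance_fractions = ev / sum(ev),
                 scores = data.frame(line = t$line, das = t$das, scores,
                                     stringsAsFactors = FALSE),
                 descriptors = descs),
            class = "morphospace_model")
}

#' Project rows into a fitted morphospace
#'
#' Uses the model's stored center/scale; the full 9-component projection is
#' orthogonal, so Euclidean distances between rows are preserved.
#'
#' @param model a `morphospace_model` from [build_morphospace()].
#' @param rows table with the model's descriptor columns.
#' @return Matrix of component scores (rows x PCs).
#' @export
project_morphospace <- function(model, rows) {
  miss <- setdiff(model$descriptors, colnames(rows))
  if (length(miss) > 0)
    stop(sprintf("missing descriptor: %s", paste(miss, collapse = ", ")))
  x <- as.matrix(rows[, model$descriptors, drop = FALSE])
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  xs %*% model$loadings
}

#' Summary statistics of a descriptor table
#'
#' Recomputes, from any averaged descriptor table, the quantities the study
#' reports from its deposited per-day averages: the pooled-PCA variance
#' fractions (PC1, PC2, PC1+PC2), the PRA-PL Pearson correlation and the
#' mean Compactness at a reference day, and the ISO loading on PC4.
#'
#' @param t averaged table (line, das, descriptor columns).
#' @param reference_das day for the correlation/mean summaries (default 35).
#' @return List with `pc1_fraction`, `pc2_fraction`, `pc12_fraction`,
#'   `cor_pra_pl`, `mean_compactness`, `iso_loading_pc4`, `model`.
#' @export
summarize_descriptor_table <- function(t, reference_das = 35) {
  model <- build_morphospace(t)
  cm <- correlations_by_das(t, reference_das)
  sub <- t[t$das == reference_das, , drop = FALSE]
  list(pc1_fraction = model$variance_fractions[1],
       pc2_fraction = model$variance_fractions[2],
       pc12_fraction = sum(model$variance_fractions[1:2]),
       cor_pra_pl = cm["PRA", "PL"],
       mean_compactness = mean(sub$Compactness, na.rm = TRUE),
       iso_loading_pc4 = model$loadings["ISO", 4],
       model = model)
}
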