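# QTL post-processing: peak/interval calling, the day-then-descriptor
# redundancy filter, count tabulations and nearest-gene annotation.

#' Call QTL peaks from a scan
#'
#' Maximal runs of contiguous markers (within a chromosome) with
#' `logP >= threshold` form intervals; each run yields one record whose peak
#' is the run's argmax `logP` (ties broken by lowest position).
#'
#' @param s a `scan_result`.
#' @param threshold numeric genome-wide logP threshold, or a
#'   `qtl_threshold`.
#' @return Data.frame of `qtl_record` rows: `trait`, `das`, `chrom`,
#'   `start_bp`, `end_bp`, `peak_marker`, `peak_logP`, `var_explained`,
#'   `threshold`; zero rows when nothing passes.
#' @export
call_qtl_peaks <- function(s, threshold) {
  stopifnot(inherits(s, "scan_result"))
  if (inherits(threshold, "qtl_threshold")) threshold <- threshold$threshold
  tab <- s$table
  out <- NULL
  for (ch in unique(tab$chrom)) {
    sub <- tab[tab$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$pos_bp), , drop = FALSE]
    pass <- sub$logP >= threshold
    if (!any(pass)) next
    runs <- rle(pass)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (k in which(runs$values)) {
      ii <- starts[k]:ends[k]
      peak <- ii[which.max(sub$logP[ii])]   # first max = lowest position
      out <- rbind(out, data.frame(
        trait = s$trait, das = s$das, chrom = ch,
        start_bp = sub$pos_bp[ii[1]], end_bp = sub$pos_bp[ii[length(ii)]],
        peak_marker = sub$marker[peak], peak_logP = sub$logP[peak],
        var_explained = sub$var_explained[peak], threshold = threshold,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(trait = character(), das = numeric(),
                      chrom = character(), start_bp = integer(),
                      end_bp = integer(), peak_marker = character(),
                      peak_logP = numeric(), var_explained = numeric(),
                      threshold = numeric(), stringsAsFactors = FALSE)
  out
}

# Canonical trait ordering for the redundancy filter: the nine descriptors
# in Table order, then PC1..PC9.
.trait_order <- function() c(descriptor_names(), paste0("PC", 1:9))

#' Remove redundant QTLs, day-then-descriptor order
#'
#' Iterates days ascending and, within a day, traits in canonical order
#' (PRA, PL, Compactness, RMS, SOL, RND, RCH, ISO, ECC, then PC1..PC9); a
#' record is kept iff its peak marker (optionally widened by `window_bp`)
#' has not been kept before. The filter is idempotent and every kept
#' record's peak marker is unique.
#'
#' @param records data.frame from [call_qtl_peaks()] (rows may mix traits
#'   and days).
#' @param window_bp two peaks closer than this on the same chromosome count
#'   as the same locus (default 0 = exact marker identity).
#' @return Filtered records sorted by day then trait order.
#' @export
filter_redundant_qtls <- function(records, window_bp = 0) {
  if (nrow(records) == 0) return(records)
  ord <- .trait_order()
  unknown <- setdiff(unique(records$trait), ord)
  if (length(unknown) > 0)
    stop(sprintf("unknown trait label: %s", paste(unknown, collapse = ", ")))
  o <- order(records$das, match(records$trait, ord), records$chrom,
             records$start_bp)
  records <- records[o, , drop = FALSE]
  keep <- logical(nrow(records))
  seen_marker <- character(0)
  seen_chrom <- character(0)
  seen_pos <- numeric(0)
  for (i in seq_len(nrow(records))) {
    if (window_bp <= 0) {
      dup <- records$peak_marker[i] %in% seen_marker
    } else {
      pos <- .peak_pos(records, i)
      dup <- any(seen_chrom == records$chrom[i] &
                 abs(seen_pos - pos) <= window_bp)
    }
    if (!dup) {
      keep[i] <- TRUE
      seen_marker <- c(seen_marker, records$peak_marker[i])
      seen_chrom <- c(seen_chrom, records$chrom[i])
      seen_pos <- c(seen_pos, .peak_pos(records, i))
    }
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.peak_pos <- function(records, i) {
  if ("peak_bp" %in% colnames(records)) return(records$peak_bp[i])
  # without an explicit peak position, use the interval midpoint
  (records$start_bp[i] + records$end_bp[i]) / 2
}

#' Tabulate QTL counts per day, trait and chromosome
#'
#' @param records filtered records.
#' @return List of three data.frames `by_day`, `by_trait`, `by_chrom`, each
#'   with `n` and cumulative `cum`; their totals all equal `nrow(records)`.
#' @export
tabulate_qtls <- function(records) {
  count_by <- function(keys, levels) {
    n <- as.integer(table(factor(keys, levels = levels)))
    data.frame(level = levels, n = n, cum = cumsum(n),
               stringsAsFactors = FALSE)
  }
  days <- sort(unique(records$das))
  traits <- intersect(.trait_order(), unique(records$trait))
  chroms <- sort(unique(records$chrom))
  list(by_day = count_by(records$das, days),
       by_trait = count_by(records$trait, traits),
       by_chrom = count_by(records$chrom, chroms))
}

#' Read gene records from a GFF3 file
#'
#' Imports features of type `gene` (1-based inclusive coordinates).
#'
#' @param path GFF3 file path.
#' @return Data.frame `gene_id`, `chrom`, `start_bp`, `end_bp`,
#'   `annotation`.
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ann <- if ("Note" %in% colnames(S4Vectors::mcols(gr))) {
    vapply(gr$Note, function(x) paste(x, collapse = "; "), "")
  } else rep("", length(gr))
  ids <- if ("ID" %in% colnames(S4Vectors::mcols(gr))) gr$ID
         else sprintf("gene%04d", seq_along(gr))
  data.frame(gene_id = as.character(ids),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start_bp = GenomicRanges::start(gr),
             end_bp = GenomicRanges::end(gr),
             annotation = ann, stringsAsFactors = FALSE)
}

#' Nearest gene to a marker position
#'
#' Distance is 0 when the position falls within `[start, end]`, otherwise
#' the distance to the nearer gene edge; ties go to the lower start
#' coordinate.
#'
#' @param chrom,pos_bp marker location (1-based bp).
#' @param genes data.frame as from [read_genes_gff3()].
#' @return One-row data.frame `gene_id`, `chrom`, `start_bp`, `end_bp`,
#'   `annotation`, `distance_bp`; a "no annotation" row (NA gene, Inf
#'   distance) when the chromosome has no genes.
#' @export
nearest_gene <- function(chrom, pos_bp, genes) {
  sub <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(sub) == 0)
    return(data.frame(gene_id = NA_character_, chrom = chrom,
                      start_bp = NA_integer_, end_bp = NA_integer_,
                      annotation = "no annotation", distance_bp = Inf,
                      stringsAsFactors = FALSE))
  inside <- pos_bp >= sub$start_bp & pos_bp <= sub$end_bp
  dist <- ifelse(inside, 0, pmin(abs(pos_bp - sub$start_bp),
                                 abs(pos_bp - sub$end_bp)))
  o <- order(dist, sub$start_bp)
  best <- sub[o[1], , drop = FALSE]
  best$distance_bp <- dist[o[1]]
  rownames(best) <- NULL
  best
}

#' Annotate QTL records with their nearest gene
#'
#' Looks up each record's peak-marker position in the map and attaches the
#' nearest gene's id, coordinates and distance.
#'
#' @param records filtered records.
#' @param map marker map (`marker`, `chrom`, `pos_bp`).
#' @param genes gene table from [read_genes_gff3()].
#' @return Records with `peak_bp`, `gene_id`, `gene_start_bp`,
#'   `gene_end_bp`, `gene_annotation`, `gene_distance_bp` columns appended.
#' @export
annotate_qtls <- function(records, map, genes) {
  if (nrow(records) == 0) {
    for (cn in c("peak_bp", "gene_id", "gene_start_bp", "gene_end_bp",
                 "gene_annotation", "gene_distance_bp"))
      records[[cn]] <- vector(mode = if (grepl("bp", cn)) "numeric" else "character", 0)
    return(records)
  }
  pos <- map$pos_bp[match(records$peak_marker, map$marker)]
  if (any(is.na(pos))) stop("peak marker missing from map")
  records$peak_bp <- pos
  ng <- lapply(seq_len(nrow(records)),
               function(i) nearest_gene(records$chrom[i], pos[i], genes))
  records$gene_id <- vapply(ng, function(g) g$gene_id, "")
  records$gene_start_bp <- vapply(ng, function(g) as.numeric(g$start_bp), 0)
  records$gene_end_bp <- vapply(ng, function(g) as.numeric(g$end_bp), 0)
  records$gene_annotation <- vapply(ng, function(g) g$annotation, "")
  records$gene_distance_bp <- vapply(ng, function(g) g$distance_bp, 0)
  records
}
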