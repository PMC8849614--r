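# Peak calling, redundancy filtering, tabulation and gene annotation.

# Minimal scan_result wrapper around a hand-built logP profile.
fake_scan <- function(logP, chrom = rep("chr1", length(logP)),
                      trait = "PRA", das = 35) {
  m <- length(logP)
  tab <- data.frame(marker = sprintf("m%02d", seq_len(m)), chrom = chrom,
                    pos_bp = seq_len(m) * 1000L, pos_cM = seq_len(m),
                    logP = logP, var_explained = logP / 100,
                    df1 = 18, df2 = 180, stringsAsFactors = FALSE)
  structure(list(table = tab, trait = trait, das = das),
            class = "scan_result")
}

test_that("peak calling on the canonical toy profile", {
  s <- fake_scan(c(1, 4, 6, 4, 1))
  r <- call_qtl_peaks(s, 3.5)
  expect_equal(nrow(r), 1)
  expect_equal(r$start_bp, 2000)
  expect_equal(r$end_bp, 4000)
  expect_equal(r$peak_marker, "m03")
  expect_equal(r$peak_logP, 6)
  expect_equal(r$threshold, 3.5)
  expect_equal(r$trait, "PRA")
  expect_equal(r$das, 35)
})

test_that("separate runs give separate records; ties pick lowest position", {
  s <- fake_scan(c(5, 1, 5, 5, 1, 4))
  r <- call_qtl_peaks(s, 3.5)
  expect_equal(nrow(r), 3)
  expect_equal(r$peak_marker, c("m01", "m03", "m06"))
  expect_equal(r$start_bp, c(1000, 3000, 6000))
  expect_equal(r$end_bp, c(1000, 4000, 6000))
})

test_that("runs never span a chromosome boundary", {
  s <- fake_scan(c(4, 4, 4, 4), chrom = c("chr1", "chr1", "chr2", "chr2"))
  r <- call_qtl_peaks(s, 3)
  expect_equal(nrow(r), 2)
  expect_equal(r$chrom, c("chr1", "chr2"))
})

test_that("no significant markers yields a typed zero-row frame", {
  r <- call_qtl_peaks(fake_scan(c(1, 2, 1)), 5)
  expect_equal(nrow(r), 0)
  expect_true(all(c("trait", "das", "peak_marker", "peak_logP")
                  %in% colnames(r)))
  # a qtl_threshold object is accepted in place of a number
  th <- structure(list(threshold = 3.5), class = "qtl_threshold")
  expect_equal(call_qtl_peaks(fake_scan(c(1, 4, 6, 4, 1)), th)$peak_marker,
               "m03")
})

test_that("redundancy filter keeps first hit in day-then-trait order", {
  mk <- function(trait, das, marker, pos) {
    data.frame(trait = trait, das = das, chrom = "chr1",
               start_bp = pos - 1000, end_bp = pos + 1000,
               peak_marker = marker, peak_logP = 5, var_explained = 0.1,
               threshold = 3, stringsAsFactors = FALSE)
  }
  rec <- rbind(mk("ECC", 35, "mA", 5000),   # same day, later trait order
               mk("PRA", 35, "mA", 5000),   # earliest day + trait -> kept
               mk("PRA", 36, "mA", 5000),   # later day, same locus
               mk("PL", 35, "mB", 9000),    # distinct locus -> kept
               mk("PC1", 36, "mC", 20000))  # distinct locus -> kept
  f <- filter_redundant_qtls(rec)
  expect_equal(nrow(f), 3)
  expect_equal(f$trait, c("PRA", "PL", "PC1"))
  expect_equal(f$peak_marker, c("mA", "mB", "mC"))
  # earliest day wins for the shared locus
  expect_equal(f$das[f$peak_marker == "mA"], 35)
  # idempotent, unique peak markers
  expect_identical(filter_redundant_qtls(f), f)
  expect_equal(anyDuplicated(f$peak_marker), 0)
  # window-based de-duplication merges nearby peaks on the same chromosome
  f2 <- filter_redundant_qtls(rbind(mk("PRA", 35, "mA", 5000),
                                    mk("PL", 35, "mB", 5500)),
                              window_bp = 1000)
  expect_equal(nrow(f2), 1)
  expect_equal(f2$trait, "PRA")
  bad <- mk("NotATrait", 35, "mZ", 100)
  expect_error(filter_redundant_qtls(bad), "unknown trait label")
  # zero-row input passes through
  expect_equal(nrow(filter_redundant_qtls(rec[0, ])), 0)
})

test_that("tabulations partition the records and cumulate correctly", {
  rec <- data.frame(trait = c("PRA", "PRA", "PL", "PC2"),
                    das = c(35, 36, 36, 37),
                    chrom = c("chr1", "chr2", "chr2", "chr1"),
                    start_bp = 1, end_bp = 2,
                    peak_marker = sprintf("m%d", 1:4), peak_logP = 5,
                    var_explained = 0.1, threshold = 3,
                    stringsAsFactors = FALSE)
  tb <- tabulate_qtls(rec)
  for (t in tb) {
    expect_equal(sum(t$n), nrow(rec))
    expect_equal(t$cum[nrow(t)], nrow(rec))
    expect_equal(t$cum, cumsum(t$n))
  }
  expect_equal(tb$by_day$n, c(1, 2, 1))
  expect_equal(tb$by_trait$level, c("PRA", "PL", "PC2"))  # canonical order
  expect_equal(tb$by_chrom$n, c(2, 2))
})

test_that("GFF3 import keeps only gene features with ids and notes", {
  g <- read_genes_gff3(fx_gff3())
  expect_equal(nrow(g), 3)
  expect_equal(g$gene_id, c("AT1G0001", "AT1G0002", "AT2G0001"))
  expect_equal(g$start_bp, c(100, 400, 1000))
  expect_equal(g$end_bp, c(200, 500, 2000))
  expect_equal(g$annotation[1], "alpha gene")
})

test_that("nearest_gene distances, ties and empty chromosomes", {
  g <- read_genes_gff3(fx_gff3())
  expect_equal(nearest_gene("chr1", 150, g)$distance_bp, 0)
  expect_equal(nearest_gene("chr1", 150, g)$gene_id, "AT1G0001")
  expect_equal(nearest_gene("chr1", 250, g)$gene_id, "AT1G0001")
  expect_equal(nearest_gene("chr1", 250, g)$distance_bp, 50)
  # exact tie at 300 (50 from each edge): lower start wins
  tie <- nearest_gene("chr1", 300, g)
  expect_equal(tie$gene_id, "AT1G0001")
  expect_equal(tie$distance_bp, 100)
  miss <- nearest_gene("chr9", 42, g)
  expect_true(is.na(miss$gene_id))
  expect_equal(miss$distance_bp, Inf)
  # brute force over a grid of positions
  for (pos in seq(1, 2500, by = 83)) {
    got <- nearest_gene("chr1", pos, g)
    sub <- g[g$chrom == "chr1", ]
    d <- ifelse(pos >= sub$start_bp & pos <= sub$end_bp, 0,
                pmin(abs(pos - sub$start_bp), abs(pos - sub$end_bp)))
    expect_equal(got$distance_bp, min(d))
  }
})

test_that("annotate_qtls attaches peak positions and nearest genes", {
  g <- read_genes_gff3(fx_gff3())
  map <- data.frame(marker = c("m1", "m2"), chrom = c("chr1", "chr2"),
                    pos_bp = c(450, 5000), stringsAsFactors = FALSE)
  rec <- data.frame(trait = "PRA", das = 35, chrom = c("chr1", "chr2"),
                    start_bp = 1, end_bp = 2, peak_marker = c("m1", "m2"),
                    peak_logP = 5, var_explained = 0.1, threshold = 3,
                    stringsAsFactors = FALSE)
  ann <- annotate_qtls(rec, map, g)
  expect_equal(ann$peak_bp, c(450, 5000))
  expect_equal(ann$gene_id, c("AT1G0002", "AT2G0001"))
  expect_equal(ann$gene_distance_bp, c(0, 3000))
  expect_error(annotate_qtls(transform(rec, peak_marker = "mX"), map, g),
               "missing from map")
  empty <- annotate_qtls(rec[0, ], map, g)
  expect_equal(nrow(empty), 0)
  expect_true("gene_id" %in% colnames(empty))
})
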