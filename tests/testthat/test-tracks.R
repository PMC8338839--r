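test_that("bedGraph reading scales, sorts and round-trips", {
  path <- withr::local_tempfile()
  writeLines("1 0 100 800", path)
  tr <- read_bedgraph(path, "B", b_scale = 1000)
  expect_equal(tr[["1"]]$value, 0.8)
  # auto-detected integer scale
  tr2 <- read_bedgraph(path, "B")
  expect_equal(tr2[["1"]]$value, 0.8)

  # unsorted input gives the same track as sorted input
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  writeLines(c("1 100 200 0.5", "1 0 100 0.2"), p1)
  writeLines(c("1 0 100 0.2", "1 100 200 0.5"), p2)
  expect_equal(read_bedgraph(p1, "B"), read_bedgraph(p2, "B"))

  # overlap and bad values are format errors with line numbers
  p3 <- withr::local_tempfile()
  writeLines(c("1 0 100 0.2", "1 50 200 0.5"), p3)
  expect_error(read_bedgraph(p3, "B"), class = "pleioselect_format_error")
  expect_error(read_bedgraph(p3, "B"), "line 2")
  p4 <- withr::local_tempfile()
  writeLines(c("1 0 100 0.2", "1 100 x 0.5"), p4)
  expect_error(read_bedgraph(p4, "B"), "line 2")
})

test_that("generator-written B track reads back identical to truth", {
  dir <- withr::local_tempdir()
  b <- generate_bundle(tiny_config(seed = 4, n_genes = 40L,
                                   min_genes_per_trait = 2L), dir = dir)
  tr <- read_bedgraph(b$files[["b_track"]], "B")
  expect_equal(names(tr), names(b$b_track))
  for (ch in names(tr)) expect_equal(tr[[ch]], b$b_track[[ch]])
})

test_that("genetic map rates apply up to the next position", {
  path <- withr::local_tempfile()
  writeLines(c("chrom\tpos\trate_cM_Mb\tmap_cM",
               "1\t0\t1.5\t0", "1\t1000\t0\t0.0015"), path)
  tr <- read_genetic_map(path)
  expect_equal(tr[["1"]], data.frame(start = 0, end = 1000, value = 1.5))

  single <- withr::local_tempfile()
  writeLines(c("chrom\tpos\trate_cM_Mb\tmap_cM", "1\t0\t1.5\t0"), single)
  expect_warning(tr1 <- read_genetic_map(single), "single row")
  expect_equal(length(tr1), 0L)

  desc <- withr::local_tempfile()
  writeLines(c("chrom\tpos\trate_cM_Mb\tmap_cM",
               "1\t1000\t1\t0", "1\t0\t2\t1"), desc)
  expect_error(read_genetic_map(desc), class = "pleioselect_format_error")
})

test_that("cumulative map distance is reconstructed from segments", {
  set.seed(13)
  pos <- sort(sample.int(1e6, 50))
  rate <- c(round(stats::runif(49, 0, 5), 4), 0)
  cum <- c(0, cumsum(rate[-50] * diff(pos) / 1e6))
  path <- withr::local_tempfile()
  writeLines(c("chrom\tpos\trate_cM_Mb\tmap_cM",
               sprintf("7\t%d\t%.17g\t%.17g", pos, rate, cum)), path)
  tr <- read_genetic_map(path)
  seg <- tr[["7"]]
  rebuilt <- c(0, cumsum(seg$value * (seg$end - seg$start) / 1e6))
  expect_equal(rebuilt, cum, tolerance = 1e-6)
})

test_that("point queries honour segment boundaries and match linear scan", {
  tr <- stepped_track(data.frame(chrom = "1", start = 0, end = 100,
                                 value = 0.8), "B")
  expect_equal(point_value(tr, "1", 100), 0.8)  # last covered base
  expect_true(is.na(point_value(tr, "1", 101)))
  expect_true(is.na(point_value(tr, "2", 5)))

  set.seed(17)
  rtr <- random_track(n_seg = 12)
  pos <- sample.int(520, 1000, replace = TRUE)
  got <- point_value(rtr, "1", pos)
  want <- vapply(pos, function(p) linear_scan_value(rtr, "1", p), numeric(1))
  expect_identical(got, want)
})

test_that("interval means are length-weighted over covered bases", {
  tr <- stepped_track(data.frame(chrom = "1", start = c(0, 100),
                                 end = c(100, 200), value = c(0.8, 0.8)), "B")
  expect_equal(interval_mean(tr, "1", 20, 180)$mean, 0.8)
  tr2 <- stepped_track(data.frame(chrom = "1", start = c(0, 100),
                                  end = c(100, 200), value = c(0.2, 0.4)))
  out <- interval_mean(tr2, "1", 0, 200)
  expect_equal(out$mean, 0.3)
  expect_equal(out$coverage, 1)
  expect_true(is.na(interval_mean(tr2, "1", 300, 400)$mean))
  expect_error(interval_mean(tr2, "1", 10, 10),
               class = "pleioselect_config_error")
})

test_that("interval means equal per-base brute force on random tracks", {
  set.seed(23)
  for (i in 1:100) {
    tr <- random_track(n_seg = sample(3:12, 1))
    qs <- sample.int(480, 1); qe <- qs + sample.int(60, 1)
    want <- per_base_mean(tr, "1", qs, qe)
    got <- interval_mean(tr, "1", qs, qe)
    expect_equal(got$mean, want$mean)
    expect_equal(got$coverage, want$coverage)
    # bounded by min and max segment value when covered
    if (!is.na(got$mean)) {
      vals <- tr[["1"]]$value
      expect_gte(got$mean, min(vals) - 1e-12)
      expect_lte(got$mean, max(vals) + 1e-12)
    }
  }
})

test_that("splitting an interval and length-reweighting reproduces the mean", {
  set.seed(29)
  for (i in 1:20) {
    tr <- random_track(n_seg = 8)
    qs <- 10; qe <- 460
    whole <- interval_mean(tr, "1", qs, qe)
    if (is.na(whole$mean)) next
    cut <- sample(seq.int(qs + 1, qe - 1), 1)
    left <- interval_mean(tr, "1", qs, cut)
    right <- interval_mean(tr, "1", cut, qe)
    wl <- left$coverage * (cut - qs); wr <- right$coverage * (qe - cut)
    parts <- c(left$mean * wl, right$mean * wr)
    recombined <- sum(parts, na.rm = TRUE) / (wl + wr)
    expect_equal(recombined, whole$mean, tolerance = 1e-12)
  }
})

test_that("MHC masking removes contained points and overlapping intervals", {
  snps <- data.frame(chrom = c("6", "6", "6", "2"),
                     pos = c(26e6, 24999999, 25e6, 26e6))
  out <- mhc_mask(snps)
  expect_equal(out$pos, c(24999999, 26e6))
  expect_equal(attr(out, "n_removed"), 2L)
  # idempotent
  again <- mhc_mask(out)
  expect_equal(again$pos, out$pos)
  expect_equal(attr(again, "n_removed"), 0L)

  iv <- data.frame(chrom = "6",
                   start = c(20e6, 24e6, 33.5e6, 34e6),
                   end = c(21e6, 26e6, 35e6, 35e6),
                   label = c("clear", "left_overlap", "right_overlap",
                             "after"))
  out_iv <- mhc_mask(iv)
  expect_setequal(out_iv$label, c("clear", "after"))
})

test_that("MHC masking matches a brute-force overlap test", {
  set.seed(31)
  iv <- data.frame(chrom = sample(c("5", "6"), 200, TRUE),
                   start = sample.int(40e6, 200),
                   stringsAsFactors = FALSE)
  iv$end <- iv$start + sample.int(3e6, 200)
  out <- mhc_mask(iv)
  brute <- logical(200)
  for (i in 1:200) {
    # 1-based positions covered: start+1 .. end
    brute[i] <- iv$chrom[i] == "6" &&
      (iv$start[i] + 1) <= 34e6 && iv$end[i] >= 25e6
  }
  expect_equal(nrow(out), sum(!brute))
  expect_equal(attr(out, "n_removed"), sum(brute))
})

test_that("gene intervals normalize BED and GFF3 to the same span", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("1\t999\t2000\tG1", bed)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "1\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=G1;Name=G1"), gff)
  gb <- read_gene_intervals(bed)
  gg <- read_gene_intervals(gff)
  expect_equal(gb$start, 999); expect_equal(gb$end, 2000)
  expect_equal(gg$start, 999); expect_equal(gg$end, 2000)
  expect_equal(gb$label, "G1"); expect_equal(gg$label, "G1")
})

test_that("generator-written GFF3 genes read back equal to truth", {
  dir <- withr::local_tempdir()
  b <- generate_bundle(tiny_config(seed = 6, n_genes = 50L,
                                   min_genes_per_trait = 2L), dir = dir)
  got <- read_gene_intervals(b$files[["genes_gff3"]])
  want <- b$genes[order(b$genes$label), ]
  got <- got[order(got$label), ]
  expect_equal(got$chrom, want$chrom)
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  bed <- read_gene_intervals(b$files[["genes_bed"]])
  bed <- bed[order(bed$label), ]
  expect_equal(bed$start, got$start)
})

test_that("annotation resolves point and interval values with log10 RR", {
  b_tr <- stepped_track(data.frame(chrom = "1", start = 0, end = 1e6,
                                   value = 0.7), "B")
  rr_tr <- stepped_track(data.frame(chrom = "1", start = 0, end = 1e6,
                                    value = 1.0), "RR")
  snps <- data.frame(locus_id = "L1", chrom = "1", pos = 500L, degree = 2L)
  out <- annotate_items(snps, b_tr, rr_tr, level = "snp")
  expect_equal(out$B, 0.7)
  expect_equal(out$RR, 1.0)
  expect_equal(out$log10RR, 0)

  genes <- data.frame(chrom = "1", start = 100, end = 200, label = "L1")
  out_g <- annotate_items(snps, b_tr, rr_tr, level = "gene", genes = genes)
  expect_equal(out_g$B, 0.7)
  expect_error(annotate_items(snps, b_tr, rr_tr, level = "gene"),
               class = "pleioselect_config_error")
})

test_that("gene annotation on a synthetic genome equals planted truth", {
  b <- tiny_bundle(seed = 12)
  tr <- b$truth[b$truth$expected_kept, ]
  items <- tr[!duplicated(tr$locus), c("locus", "chrom", "pos", "degree")]
  names(items)[1] <- "locus_id"
  ann <- annotate_items(items, b$b_track, b$rr_track, level = "gene",
                        genes = b$genes)
  truth_b <- tr$b_gene[match(ann$id, tr$locus)]
  truth_rr <- tr$rr_gene[match(ann$id, tr$locus)]
  expect_equal(ann$B, truth_b, tolerance = 1e-12)
  expect_equal(ann$RR, truth_rr, tolerance = 1e-12)
  # SNP level: point values equal the same gene-segment truth
  ann_s <- annotate_items(items, b$b_track, b$rr_track, level = "snp")
  expect_equal(ann_s$B, truth_b, tolerance = 1e-12)
})

test_that("synthetic genome-wide B stays in the quoted band", {
  # genome-wide average B is targeted at 0.77; with many segments the
  # length-weighted mean must stay within the 0.74-0.81 range
  b <- generate_bundle(generator_config(seed = 99, n_traits = 15,
                                        n_genes = 400,
                                        baseline_seg_len = 5e4))
  seg <- do.call(rbind, lapply(unclass(b$b_track), identity))
  n_seg <- nrow(seg)
  expect_gt(n_seg, 10000)
  mean_b <- sum(seg$value * (seg$end - seg$start)) / sum(seg$end - seg$start)
  expect_gt(mean_b, 0.74)
  expect_lt(mean_b, 0.81)
  expect_true(all(seg$value >= 0 & seg$value <= 1))
})
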