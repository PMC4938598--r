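test_that("probe maps are sorted per chromosome and restricted to autosomes", {
  df <- tibble::tibble(probe_id = c("a", "b", "c"),
                       chrom = "1", pos = c(100, 50, 200))
  pm <- as_probe_map(df)
  expect_equal(pm$pos, c(50, 100, 200))
  expect_equal(pm$probe_id, c("b", "a", "c"))

  df_x <- tibble::tibble(probe_id = c("a", "x1"), chrom = c("1", "X"),
                         pos = c(100, 100))
  expect_message(pm2 <- as_probe_map(df_x), "dropped 1 non-autosomal")
  expect_equal(nrow(pm2), 1)

  expect_message(as_probe_map(tibble::tibble(
    probe_id = "a", chrom = "chr3", pos = 5)), NA)
  expect_equal(as_probe_map(tibble::tibble(
    probe_id = "a", chrom = "chr3", pos = 5))$chrom, "3")
})

test_that("duplicate coordinates and non-numeric positions are hard errors", {
  dup <- tibble::tibble(probe_id = c("a", "b"), chrom = "2", pos = c(500, 500))
  expect_error(as_probe_map(dup), "duplicate probe coordinate chr2:500")
  bad <- tibble::tibble(probe_id = "a", chrom = "1", pos = "NAN?")
  expect_error(as_probe_map(bad), "non-numeric position")
})

test_that("signal matrices sum allele pairs and reorder to map order", {
  pm <- as_probe_map(tibble::tibble(probe_id = c("p1", "p2", "p3"),
                                    chrom = "1", pos = c(10, 20, 30)))
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    probe_id = c("p2", "p3", "p1"),
    s1.A = c(3, 1, 2), s1.B = c(5, 1, 2),
    s2.A = c(1, 1, 1), s2.B = c(0, 0, 0)), f)
  sm <- read_signal_matrix(f, pm, allele_suffixes = c(".A", ".B"))
  expect_equal(rownames(sm$values), c("p1", "p2", "p3"))  # map order
  expect_equal(unname(sm$values[, "s1"]), c(4, 8, 2))     # A + B
  expect_equal(unname(sm$values[, "s2"]), c(1, 1, 1))

  # single-column intensities pass through unchanged
  f2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(probe_id = c("p1", "p2", "p3"),
                                  s1 = c(1.5, 2.5, 3.5)), f2)
  sm2 <- read_signal_matrix(f2, pm)
  expect_equal(unname(sm2$values[, 1]), c(1.5, 2.5, 3.5))
})

test_that("unknown probes and negative intensities are rejected", {
  pm <- as_probe_map(tibble::tibble(probe_id = c("p1", "p2"),
                                    chrom = "1", pos = c(10, 20)))
  m <- matrix(1, 3, 1, dimnames = list(c("p1", "p2", "zz"), "s1"))
  expect_error(signal_matrix(m, pm), "absent from probe map.*zz")
  m2 <- matrix(c(1, -2), 2, 1, dimnames = list(c("p1", "p2"), "s1"))
  expect_error(signal_matrix(m2, pm), "negative intensities")
  expect_silent(signal_matrix(abs(m2), pm))
})

test_that("gene annotation honors BED and GFF3 coordinate conventions", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr8\t100\t200\tg1", "chr8\t300\t400\tg2",
               "chrX\t10\t20\tgx"), bed)
  expect_message(genes <- read_gene_annotation(bed), "dropped 1 non-autosomal")
  expect_equal(genes$start[genes$gene_id == "g1"], 101)  # 0-based half-open in
  expect_equal(genes$end[genes$gene_id == "g1"], 200)

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "1\tsrc\tgene\t5\t9\t.\t+\t.\tID=gA;Name=geneA",
               "1\tsrc\texon\t5\t7\t.\t+\t.\tID=eA;Parent=gA"), gff)
  g2 <- read_gene_annotation(gff)
  expect_equal(nrow(g2), 1)  # exon feature ignored
  expect_equal(c(g2$start, g2$end), c(5, 9))

  lst <- withr::local_tempfile()
  writeLines("g1", lst)
  g3 <- read_gene_annotation(bed, tumor_gene_list = lst)
  expect_equal(g3$tumor_associated[order(g3$gene_id)], c(TRUE, FALSE))
})

test_that("1-based inclusive and BED half-open conversions are inverse", {
  for (i in 1:20) {
    s <- sample.int(1e6, 1); e <- s + sample.int(1e4, 1)
    bed <- to_bed_coords(s, e)
    back <- from_bed_coords(bed$start, bed$end)
    expect_identical(c(back$start, back$end), c(s, e))
  }
})

test_that("result tables round-trip through TSV and convert to BED", {
  seg <- tibble::tibble(sample = "s1", chrom = "1", start_idx = 1L,
                        end_idx = 5L, start_pos = 101, end_pos = 200,
                        n_markers = 5L, seg_mean = 0.42)
  cat_df <- tibble::tibble(chrom = "2", start_pos = 1000, end_pos = 2000,
                           count_A = 3L, count_normal = 0L, cancer_total = 3L,
                           freq_A = 15, freq_normal = 0, class = 1L, nof = TRUE)
  dir <- withr::local_tempdir()
  write_result_tables(list(segments = seg, bpr_catalog = cat_df), dir)

  bed <- readr::read_tsv(file.path(dir, "segments.bed"), col_names = FALSE,
                         show_col_types = FALSE)
  expect_equal(bed$X2, 100)  # 0-based start
  expect_equal(bed$X3, 200)

  back <- readr::read_tsv(file.path(dir, "bpr_catalog.tsv"),
                          col_types = readr::cols(chrom = "c"))
  expect_equal(as.data.frame(back), as.data.frame(cat_df))

  # empty catalog gives a header-only file
  write_result_tables(list(bpr_catalog = cat_df[0, ]), dir)
  lines <- readLines(file.path(dir, "bpr_catalog.tsv"))
  expect_length(lines, 1)
})
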