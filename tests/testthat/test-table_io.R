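test_that("feature tables round-trip through TSV unchanged", {
  ft <- toy_table()
  tp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft, tp, mp)
  back <- read_feature_table(tp, mp)
  expect_identical(back$counts, ft$counts)
  expect_identical(back$metadata, ft$metadata)
  expect_match(readLines(tp, n = 1), "^#OTU ID\t")
})

test_that("malformed input is rejected with an informative error", {
  ft <- toy_table()
  tp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft, tp, mp)
  # metadata missing one sample
  md <- ft$metadata[1, , drop = FALSE]
  mp2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(md, mp2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_feature_table(tp, mp2), "s2",
               class = "menet_format_error")
  # non-integer counts
  lines <- readLines(tp)
  lines[2] <- sub("5", "1.5", lines[2])
  tp2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, tp2)
  expect_error(read_feature_table(tp2, mp), "asv1",
               class = "menet_format_error")
  # duplicate ids
  writeLines(c(lines[1], lines[2], lines[2], lines[3:4]), tp2)
  expect_error(read_feature_table(tp2, mp), "duplicate",
               class = "menet_format_error")
})

test_that("low-abundance filter applies the total and prevalence rules", {
  mk <- function(rowvals) {
    counts <- do.call(rbind, rowvals)
    rownames(counts) <- paste0("asv", seq_along(rowvals))
    colnames(counts) <- paste0("s", 1:6)
    md <- data.frame(sample_id = colnames(counts), group = "A", month = 1L,
                     subject = colnames(counts))
    feature_table(counts, md)
  }
  ft <- mk(list(c(9, 0, 0, 0, 0, 0),    # total 9 -> removed
                c(4, 3, 3, 0, 0, 0),    # total 10, 3 samples -> kept
                c(5, 5, 0, 0, 0, 0),    # 2 samples -> removed
                c(4, 3, 2, 1, 0, 0)))   # total 10, 4 samples -> kept
  out <- filter_low_abundance(ft)
  expect_setequal(rownames(out$counts), c("asv2", "asv4"))
  # boundary: exactly 3 samples kept, exactly total 10 kept
  expect_true("asv2" %in% rownames(out$counts))
  # all-zero table: warning + empty
  zero <- mk(list(rep(0, 6), rep(0, 6)))
  expect_warning(out0 <- filter_low_abundance(zero), "empty")
  expect_equal(nrow(out0$counts), 0)
})

test_that("low-abundance filter is stratified by month and idempotent", {
  set.seed(11)
  counts <- matrix(rpois(40 * 12, 2), 40, 12,
                   dimnames = list(paste0("asv", 1:40), paste0("s", 1:12)))
  md <- data.frame(sample_id = paste0("s", 1:12), group = "A",
                   month = rep(1:2, each = 6), subject = paste0("s", 1:12))
  ft <- feature_table(counts, md)
  once <- filter_low_abundance(ft)
  twice <- filter_low_abundance(once)
  expect_identical(once$counts, twice$counts)
  # an ASV abundant in month 2 only must survive the month-1 failure
  counts2 <- counts
  counts2["asv1", ] <- c(rep(0, 6), rep(5, 6))
  ft2 <- feature_table(counts2, md)
  expect_true("asv1" %in% rownames(filter_low_abundance(ft2)$counts))
})

test_that("rarefaction subsamples to exact depth, reproducibly", {
  set.seed(2)
  counts <- matrix(rpois(20 * 5, 40), 20, 5,
                   dimnames = list(paste0("a", 1:20), paste0("s", 1:5)))
  counts[, 5] <- 0; counts[1, 5] <- 99   # sample below depth
  md <- data.frame(sample_id = paste0("s", 1:5), group = "A", month = 1L,
                   subject = paste0("s", 1:5))
  ft <- feature_table(counts, md)
  expect_message(r1 <- rarefy(ft, depth = 100, seed = 7), "dropped")
  expect_true(all(colSums(r1$counts) == 100))
  expect_false("s5" %in% colnames(r1$counts))
  r2 <- suppressMessages(rarefy(ft, depth = 100, seed = 7))
  expect_identical(r1$counts, r2$counts)
  r3 <- suppressMessages(rarefy(ft, depth = 100, seed = 8))
  expect_false(identical(r1$counts, r3$counts))
  expect_error(rarefy(ft, depth = 1e6), class = "menet_config_error")
})

test_that("rarefaction is unbiased for relative abundances", {
  counts <- matrix(c(600, 300, 100), ncol = 1,
                   dimnames = list(paste0("a", 1:3), "s1"))
  md <- data.frame(sample_id = "s1", group = "A", month = 1L,
                   subject = "s1")
  ft <- feature_table(counts, md)
  sums <- menet:::with_seed(5, {
    rowSums(vapply(1:1000, function(i)
      rarefy(ft, depth = 100)$counts[, 1], numeric(3)))
  })
  props <- sums / sum(sums)
  # Monte-Carlo error on 1e5 draws ~ 0.002; allow 4 sigma
  expect_true(all(abs(props - c(0.6, 0.3, 0.1)) < 0.01))
})

test_that("prevalence filter keeps ASVs in at least half the samples", {
  counts <- rbind(asv1 = c(1, 1, 1, 1, 0, 0, 0, 0),   # 4 of 8 -> kept
                  asv2 = c(1, 1, 1, 0, 0, 0, 0, 0),   # 3 of 8 -> removed
                  asv3 = rep(1, 8))
  colnames(counts) <- paste0("s", 1:8)
  md <- data.frame(sample_id = paste0("s", 1:8), group = "A", month = 1L,
                   subject = paste0("s", 1:8))
  ft <- feature_table(counts, md)
  expect_setequal(rownames(prevalence_filter(ft)$counts),
                  c("asv1", "asv3"))
  # min_fraction = 1: one absence is fatal
  expect_setequal(rownames(prevalence_filter(ft, 1)$counts), "asv3")
  # tiny fraction: identity
  expect_identical(prevalence_filter(ft, 1e-9)$counts, ft$counts)
  expect_error(prevalence_filter(ft, 0), class = "menet_config_error")
  # idempotent
  expect_identical(prevalence_filter(prevalence_filter(ft))$counts,
                   prevalence_filter(ft)$counts)
})

test_that("log transform follows log10(x + 1) and is monotone", {
  ft <- toy_table()
  la <- log_transform(ft)
  expect_equal(la["asv1", "s2"], 0)            # count 0
  expect_equal(log_transform(matrix(99, dimnames = list("a", "s")))[1, 1], 2)
  x <- sort(sample(0:1000, 50))
  expect_true(all(diff(log_transform(matrix(x, nrow = 1,
    dimnames = list("a", paste0("s", 1:50))))[1, ]) >= 0))
  expect_error(log_transform(ft, pseudocount = 0),
               class = "menet_config_error")
})
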