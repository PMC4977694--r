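adapter <- "TGGAATTCTCGGGTGCCAAGG"

test_that("adapter trimming removes the longest adapter-prefix suffix", {
  opts <- trim_options(adapter = adapter)
  insert <- "TACCACAGGGTAGAACCACGG"

  full <- trim_adapter(paste0(insert, adapter), opts)
  expect_equal(full$sequence, insert)
  expect_true(full$trimmed)
  expect_equal(full$status, "ok")

  partial <- trim_adapter(paste0(insert, substr(adapter, 1, 8)), opts)
  expect_equal(partial$sequence, insert)

  none <- trim_adapter("ACGTACGTACGTACGTACGTAC", opts)
  expect_equal(none$sequence, "ACGTACGTACGTACGTACGTAC")
  expect_false(none$trimmed)
  expect_equal(none$status, "ok")

  short <- trim_adapter(paste0(substr(insert, 1, 14), adapter), opts)
  expect_equal(short$status, "too_short")
  expect_equal(nchar(short$sequence), 14L)

  below_overlap <- trim_adapter(paste0(insert, substr(adapter, 1, 5)), opts)
  expect_false(below_overlap$trimmed)   # 5 < min_overlap 6
})

test_that("exact mapping equals the naive sliding-window oracle", {
  cfg <- sim_config(seed = 21, n_mirnas = 50)
  ref <- simulate_reference(cfg)
  set.seed(99)
  reads <- character(200)
  for (i in seq_along(reads)) {
    if (i %% 2 == 0) {
      # planted: a window cut from a random precursor
      p <- ref$precursors$sequence[sample.int(50, 1)]
      len <- sample(18:24, 1)
      s <- sample.int(nchar(p) - len + 1L, 1)
      reads[i] <- substr(p, s, s + len - 1L)
    } else {
      reads[i] <- random_dna(sample(18:24, 1))
    }
  }
  for (rd in reads) {
    got <- map_read(rd, ref$precursors)
    want <- naive_map(rd, ref$precursors)
    got <- got[order(got$precursor_id, got$start), ]
    want <- want[order(want$precursor_id, want$start), ]
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("offset assignment reproduces the miR-140-3p worked examples", {
  ref <- mir140_reference()
  mature <- "TACCACAGGGTAGAACCACGG"

  hit <- map_read(mature, ref$precursors)
  a <- assign_offsets(hit$precursor_id, hit$start, nchar(mature),
                      ref$annotations)
  expect_equal(c(a$offset5, a$offset3), c(0L, 0L))
  expect_equal(a$notation, "0|0")

  iso <- "ACCACAGGGTAGAACCACGGAC"   # 5' shifted by one, 3' extended by two
  hit <- map_read(iso, ref$precursors)
  a <- assign_offsets(hit$precursor_id, hit$start, nchar(iso),
                      ref$annotations)
  expect_equal(c(a$offset5, a$offset3), c(1L, 2L))
  expect_equal(a$notation, "+1|+2")

  trimmed3 <- substr(mature, 1, nchar(mature) - 3)
  hit <- map_read(trimmed3, ref$precursors)
  a <- assign_offsets(hit$precursor_id, hit$start, nchar(trimmed3),
                      ref$annotations)
  expect_equal(a$notation, "0|-3")

  # beyond the offset bound: no assignment
  far <- substr(ref$precursors$sequence, 1, 20)
  hit <- map_read(far, ref$precursors)
  expect_null(assign_offsets(hit$precursor_id, hit$start, 20L,
                             ref$annotations))
})

test_that("assignment prefers the annotation with the closest 5' end", {
  prec <- data.frame(id = "p", sequence = random_dna(100))
  ann <- data.frame(
    mirna_name = c("syn-miR-9-5p", "syn-miR-9-3p"),
    precursor_id = "p", start = c(10L, 60L), end = c(31L, 81L),
    sequence = NA_character_)
  a <- assign_offsets("p", 61L, 21L, ann)
  expect_equal(a$mirna_name, "syn-miR-9-3p")
  expect_equal(a$offset5, 1L)
})

test_that("collapsing keys by 5' end respects the 18-24 nt window", {
  expect_equal(collapse_to_isoform("m", 0L, 24L)$offset5, 0L)
  expect_equal(collapse_to_isoform("m", 1L, 18L)$mirna_name, "m")
  expect_null(collapse_to_isoform("m", 0L, 17L))
  expect_null(collapse_to_isoform("m", 0L, 25L))
})

test_that("offset notation carries explicit signs", {
  expect_equal(offset_notation(c(0L, 1L, -2L, 0L), c(0L, -2L, 3L, 3L)),
               c("0|0", "+1|-2", "-2|+3", "0|+3"))
})

test_that("rpm normalization: single-key library gets 1e6 rpm", {
  ref <- mir140_reference()
  mature <- "TACCACAGGGTAGAACCACGG"
  reads <- data.frame(id = sprintf("r%d", 1:1000),
                      sequence = rep(mature, 1000))
  mx <- quantify(list(S1 = reads), ref$precursors, ref$annotations)
  expect_equal(unname(mx$rpm[1, "S1"]), 1e6)
  expect_equal(unname(mx$library_sizes["S1"]), 1000)
})

test_that("ambiguous reads get fractional weight and totals are conserved", {
  mat1 <- "TACCACAGGGTAGAACCACGG"
  # same mature embedded in two precursors annotated under different names
  p1 <- paste0("GTGTCTCTCTGTGTCC", mat1, "ACGGGTTATATGGGTTCTCTT")
  p2 <- paste0("ATTGCCATTGAC", mat1, "TTGATATTCCGGATTATCCAA")
  precursors <- data.frame(id = c("prec-a", "prec-b"),
                           sequence = c(p1, p2))
  ann <- data.frame(
    mirna_name = c("syn-miR-a-3p", "syn-miR-b-3p"),
    precursor_id = c("prec-a", "prec-b"), start = c(16L, 12L),
    end = c(16L + 21L, 12L + 21L), sequence = mat1)
  reads <- data.frame(id = sprintf("r%d", 1:10), sequence = rep(mat1, 10))
  mx <- quantify(list(S1 = reads), precursors, ann)
  expect_equal(sort(unname(mx$counts[, "S1"])), c(5, 5))
  expect_equal(unname(mx$library_sizes["S1"]), 10)
  expect_equal(sum(mx$rpm[, "S1"]), 1e6)

  # same miRNA name on duplicate precursors counts once, full weight
  ann2 <- ann
  ann2$mirna_name <- c("syn-miR-a-3p", "syn-miR-a-3p")
  mx2 <- quantify(list(S1 = reads), precursors, ann2)
  expect_equal(nrow(mx2$keys), 1L)
  expect_equal(unname(mx2$counts[1, "S1"]), 10)
})

test_that("an empty library is an error naming the sample", {
  ref <- mir140_reference()
  reads <- data.frame(id = "r1", sequence = "ACGTACGTACGTACGTACGT")
  expect_error(
    quantify(list(badSample = reads), ref$precursors, ref$annotations),
    "badSample")
})

test_that("rpm sums to exactly 1e6 per sample on a mixed synthetic run", {
  cfg <- sim_config(seed = 5, n_mirnas = 4, samples = c("A", "B"),
                    depth_per_sample = 4000)
  ref <- simulate_reference(cfg)
  rds <- simulate_reads(cfg, ref)
  mx <- quantify(rds$samples, ref$precursors, ref$annotations,
                 trim = trim_options(adapter = cfg$adapter))
  for (s in c("A", "B")) {
    expect_equal(sum(mx$rpm[, s]), 1e6, tolerance = 1e-6)
  }
})

test_that("reads built with known offsets are assigned exactly those offsets", {
  cfg <- sim_config(seed = 13, n_mirnas = 1, precursor_length = 100)
  ref <- simulate_reference(cfg)
  ann <- ref$annotations
  prec <- ref$precursors
  plen <- nchar(prec$sequence)
  mlen <- ann$end - ann$start
  for (d5 in -5:5) {
    for (d3 in -6:6) {
      len <- mlen - d5 + d3
      s0 <- ann$start + d5
      if (len < 15 || len > 30 || s0 < 0 || ann$end + d3 > plen) next
      read <- substr(prec$sequence, s0 + 1, ann$end + d3)
      hits <- map_read(read, prec)
      hit <- hits[hits$start == s0, ]
      a <- assign_offsets(hit$precursor_id[1], hit$start[1], nchar(read), ann)
      expect_equal(c(a$offset5, a$offset3), c(d5, d3),
                   label = sprintf("offsets %d|%d", d5, d3))
    }
  }
})

test_that("quantification recovers a planted 70/30 isoform split", {
  cfg <- sim_config(seed = 31, n_mirnas = 1, samples = "S1",
                    depth_per_sample = 10000,
                    spectrum = offset_spectrum("0|0" = 0.7, "+1|+2" = 0.3))
  ref <- simulate_reference(cfg)
  rds <- simulate_reads(cfg, ref)
  mx <- quantify(rds$samples, ref$precursors, ref$annotations,
                 trim = trim_options(adapter = cfg$adapter))
  tab <- as_rpm_table(mx)
  # exact agreement with the generator's truth table
  truth <- rds$truth
  for (k in seq_len(nrow(truth))) {
    got <- tab$S1[tab$offset5 == truth$offset5[k]]
    expect_equal(got, truth$count_in_window[k] / sum(truth$count_in_window) *
                   1e6)
  }
  # and statistical agreement with the planted fractions
  f_iso <- tab$S1[tab$offset5 == 1] / 1e6
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(f_iso - 0.3), 3 * se)
})
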