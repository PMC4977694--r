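test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(8)
  for (n in c(10, 100, 1000)) {
    p <- stats::runif(n)
    expect_equal(bh_adjust(p), naive_bh(p))
  }
  # adjusted values never fall below raw values and never exceed 1
  p <- stats::runif(200)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p) && all(adj <= 1))
})

test_that("the downregulation filter applies strict thresholds per line", {
  de <- expand.grid(gene_id = c("g1", "g2", "g3"),
                    cell_line = c("L1", "L2"),
                    condition = c("A", "B"), stringsAsFactors = FALSE)
  de$ratio <- 1
  de$p <- 1
  # g1: clearly down under A in both lines
  de$ratio[de$gene_id == "g1" & de$condition == "A"] <- 0.64
  de$p[de$gene_id == "g1" & de$condition == "A"] <- 1e-6
  # g2: ratio 0.66 in one line (strictly above threshold): excluded
  de$ratio[de$gene_id == "g2" & de$condition == "A"] <- c(0.5, 0.66)
  de$p[de$gene_id == "g2" & de$condition == "A"] <- 1e-6
  res <- downregulated_genes(de)
  expect_equal(res$sets$A, "g1")
  expect_equal(res$sets$B, character(0))
  expect_equal(unname(res$venn$counts), c(1L, 0L, 0L))

  # a gene missing from one line is an error naming both
  de_miss <- de[!(de$gene_id == "g3" & de$cell_line == "L2"), ]
  expect_error(downregulated_genes(de_miss), "g3.*L2")
})

test_that("the filter recovers planted Venn counts exactly", {
  sim <- simulate_de_table(seed = 4, n_genes = 500,
                           planted = c(a_only = 30, b_only = 10, shared = 4))
  res <- downregulated_genes(sim$de)
  expect_equal(unname(res$venn$counts), c(30L, 10L, 4L))
  expect_equal(res$venn$a_only, sim$truth$a_only)
  expect_equal(res$venn$b_only, sim$truth$b_only)
  expect_equal(res$venn$shared, sim$truth$shared)
})

test_that("with thresholds released, the filter returns all ratio<1 genes", {
  sim <- simulate_de_table(seed = 9, n_genes = 100,
                           planted = c(5, 5, 2))
  res <- downregulated_genes(sim$de, fold_threshold = 1, alpha = 1.0000001)
  de <- sim$de
  for (cond in res$conditions) {
    manual <- Reduce(intersect, lapply(unique(de$cell_line), function(cl) {
      d <- de[de$condition == cond & de$cell_line == cl, ]
      d$gene_id[d$ratio < 1]
    }))
    expect_setequal(res$sets[[cond]], manual)
  }
})

test_that("per-gene DE statistics from replicates use Student's t", {
  de <- data.frame(gene_id = "g1", cell_line = "L1", condition = "A",
                   replicate = 1:3,
                   treated = c(5, 6, 7), control = c(10, 11, 12))
  res <- compute_de_stats(de)
  expect_equal(res$ratio, 6 / 11)
  tt <- t.test(c(5, 6, 7), c(10, 11, 12), var.equal = TRUE)
  expect_equal(res$p, tt$p.value)
})

test_that("isoform correlation handles edge cases and recovers the target", {
  ident <- data.frame(mir_rpm = c(1, 5, 9, 2), isomir_rpm = c(1, 5, 9, 2))
  expect_equal(correlate_isoforms(ident)$r, 1)
  expect_error(
    correlate_isoforms(data.frame(mir_rpm = rep(3, 5),
                                  isomir_rpm = 1:5)), "constant")
  expect_error(
    correlate_isoforms(data.frame(mir_rpm = 1:2, isomir_rpm = 2:1)),
    "at least 3")

  # coverage of the Fisher-z interval around the target correlation
  cc <- cohort_config(er_effect_size = 0, metastasis_effect_size = 0)
  inside <- 0
  for (s in 1:25) {
    coh <- simulate_cohort(cc, seed = 1000 + s)
    r <- correlate_isoforms(coh$patients)$r
    z <- atanh(r); z0 <- atanh(0.85)
    half <- 1.96 / sqrt(616 - 3)
    if (abs(z - z0) <= half) inside <- inside + 1
  }
  expect_gte(inside, 22)   # ~95% coverage, small-sample slack
})

test_that("group comparison is a two-sided unpaired Student's t test", {
  same <- data.frame(er_status = rep(c("negative", "positive"), each = 4),
                     mir_rpm = rep(c(2, 4, 6, 8), 2))
  res <- compare_groups(same, "er_status", "mir_rpm")
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  # closed-form check on a hand-sized example, n = 3 vs 3
  x <- c(1, 2, 3); y <- c(4, 6, 8)
  hand <- data.frame(er_status = rep(c("negative", "positive"), each = 3),
                     mir_rpm = c(x, y))
  res2 <- compare_groups(hand, "er_status", "mir_rpm")
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_manual <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res2$t, t_manual)
  expect_equal(res2$direction, "positive")

  # unknowns dropped; degenerate group sizes are an error
  unk <- rbind(hand, data.frame(er_status = "unknown", mir_rpm = 100))
  expect_equal(sum(compare_groups(unk, "er_status", "mir_rpm")$group_ns), 6)
  tiny <- data.frame(er_status = c("negative", "positive", "positive"),
                     mir_rpm = 1:3)
  expect_error(compare_groups(tiny, "er_status", "mir_rpm"), "at least 2")
})

test_that("a planted group shift is detected with high power", {
  # mean shift 1.0 at sd 1.0, n = 50 per group: analytic power ~0.999
  reject <- 0
  for (s in 1:100) {
    set.seed(3000 + s)
    d <- data.frame(
      er_status = rep(c("negative", "positive"), each = 50),
      mir_rpm = c(rnorm(50, 1, 1), rnorm(50, 0, 1)))
    if (compare_groups(d, "er_status", "mir_rpm")$p < 0.05) {
      reject <- reject + 1
    }
  }
  expect_gte(reject, 99)
})

test_that("quartile grouping uses Q1/Q3 cuts with ties to the lower group", {
  x <- c(1:8)
  g <- quartile_groups(x, sprintf("p%d", 1:8))
  expect_true(all(g$high %in% c("p7", "p8")))
  expect_true(all(c("p1", "p2") %in% g$low))
  expect_equal(length(intersect(g$high, g$low)), 0L)
  # a value tied exactly at Q3 goes to the excluded middle, not to high
  xt <- c(1, 2, 3, 4, 5, 6, 6, 6)
  gt <- quartile_groups(xt, sprintf("q%d", 1:8))
  q3 <- stats::quantile(xt, 0.75, type = 8, names = FALSE)
  expect_true(all(xt[match(gt$high, sprintf("q%d", 1:8))] > q3))
  expect_error(quartile_groups(rep(1, 8), letters[1:8]), "degenerate")
})

test_that("Kaplan-Meier without censoring equals the empirical survivor", {
  set.seed(77)
  cc <- cohort_config(n_patients = 60, censoring_rate = 0)
  coh <- simulate_cohort(cc, seed = 42)
  sv <- quartile_survival(coh$patients, "isomir_rpm")
  km <- summary(sv$km)
  # for each group curve, S(t) = fraction of that group surviving past t
  grp_of <- function(ids) coh$patients$survival_time[
    coh$patients$patient_id %in% ids]
  for (gname in c("low", "high")) {
    times_g <- grp_of(sv$groups[[gname]])
    sel <- grepl(gname, as.character(km$strata))
    for (k in which(sel)) {
      expect_equal(km$surv[k], mean(times_g > km$time[k]),
                   tolerance = 1e-12)
    }
  }
})

test_that("the log-rank statistic matches a hand risk-table computation", {
  cc <- cohort_config(n_patients = 200, hazard_ratio_high_vs_low = 0.5,
                      censoring_rate = 0.3)
  coh <- simulate_cohort(cc, seed = 11)
  sv <- quartile_survival(coh$patients, "isomir_rpm")
  d <- coh$patients[coh$patients$patient_id %in%
                      c(sv$groups$high, sv$groups$low), ]
  manual <- naive_logrank(d$survival_time,
                          as.integer(d$event == "death"),
                          d$patient_id %in% sv$groups$high)
  expect_equal(sv$logrank_statistic, manual, tolerance = 1e-8)

  # invariance under relabeling the two groups
  manual_flip <- naive_logrank(d$survival_time,
                               as.integer(d$event == "death"),
                               d$patient_id %in% sv$groups$low)
  expect_equal(manual, manual_flip, tolerance = 1e-10)
})

test_that("identical survival in both groups gives statistic 0", {
  d <- data.frame(patient_id = sprintf("p%d", 1:8),
                  isomir_rpm = c(1, 2, 3, 4, 101, 102, 103, 104),
                  # low group {p1,p2} and high group {p7,p8} share the same
                  # event times; middle patients are excluded anyway
                  survival_time = c(5, 10, 1, 2, 3, 4, 5, 10),
                  event = rep("death", 8))
  sv <- quartile_survival(d, "isomir_rpm")
  # both selected groups carry the same survival pattern
  expect_lt(sv$logrank_statistic, 1e-10)
  expect_equal(sv$p, 1, tolerance = 1e-8)

  cens <- d
  cens$event <- "censored"
  expect_warning(sv0 <- quartile_survival(cens, "isomir_rpm"),
                 "censored")
  expect_equal(sv0$logrank_statistic, 0)
})

test_that("a planted hazard ratio of 2 is rejected with high power", {
  # n = 200 patients in the two compared quartile groups (cohort of 400);
  # ~160 events at 20% censoring puts the Schoenfeld power near 0.99
  reject <- 0
  cc <- cohort_config(n_patients = 400, hazard_ratio_high_vs_low = 2,
                      censoring_rate = 0.2)
  for (s in 1:100) {
    coh <- simulate_cohort(cc, seed = 5000 + s)
    if (quartile_survival(coh$patients, "isomir_rpm")$p < 0.05) {
      reject <- reject + 1
    }
  }
  expect_gte(reject, 90)
})

test_that("patient tables load with a column mapping", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\treads_mir\treads_isomir\ter",
               "P1\t10\t20\tpositive",
               "P2\t30\t40\tnegative"), f)
  d <- read_patient_table(f, column_map = c(
    patient_id = "id", mir_rpm = "reads_mir", isomir_rpm = "reads_isomir",
    er_status = "er"))
  expect_equal(d$mir_rpm, c(10, 30))
  expect_error(read_patient_table(f, column_map = c(mir_rpm = "nope")),
               "not in file")
  expect_error(read_patient_table("/nonexistent/cohort.tsv"),
               "not bundled")
})
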