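# Synthetic inputs with recorded ground truth for every stage of the
# pipeline: references, reads with planted isomiR offset spectra, DE tables
# with planted downregulated genes, and patient cohorts with planted
# correlation, group-effect and survival structure.
#
# All randomness is driven by the single integer seed in the config; each
# generator derives its own sub-seed so outputs are reproducible
# independently of call order.

#' Default per-miRNA offset spectrum
#'
#' Probability table over (d5, d3) offset pairs, d5 in [-2, +2] and d3 in
#' [-3, +3], as the product of concentrated marginals: most reads are
#' canonical at the 5' end with modest 3' raggedness, a minority shifted by
#' +1 at the 5' end, mirroring deep small-RNA profiles.
#'
#' @return data.frame with columns \code{d5}, \code{d3}, \code{prob}
#'   summing to 1.
#' @export
default_offset_spectrum <- function() {
  p5 <- c("-2" = 0.025, "-1" = 0.05, "0" = 0.75, "1" = 0.15, "2" = 0.025)
  p3 <- c("-3" = 0.05, "-2" = 0.1, "-1" = 0.15, "0" = 0.4,
          "1" = 0.15, "2" = 0.1, "3" = 0.05)
  g <- expand.grid(d5 = as.integer(names(p5)), d3 = as.integer(names(p3)))
  g$prob <- p5[as.character(g$d5)] * p3[as.character(g$d3)]
  rownames(g) <- NULL
  g
}

#' Build an offset spectrum from explicit (d5, d3) probabilities
#' @param ... named probabilities with names "d5|d3", e.g.
#'   \code{offset_spectrum("0|0" = 0.7, "+1|+2" = 0.3)}.
#' @return spectrum data.frame (\code{d5}, \code{d3}, \code{prob}).
#' @export
offset_spectrum <- function(...) {
  p <- c(...)
  parts <- strsplit(names(p), "|", fixed = TRUE)
  data.frame(d5 = as.integer(vapply(parts, `[`, character(1), 1L)),
             d3 = as.integer(vapply(parts, `[`, character(1), 2L)),
             prob = as.numeric(p))
}

.validate_spectrum <- function(sp) {
  stopifnot(is.data.frame(sp), all(c("d5", "d3", "prob") %in% names(sp)))
  if (abs(sum(sp$prob) - 1) > 1e-8) stop("spectrum probabilities must sum to 1")
  if (any(sp$d5 < -2L | sp$d5 > 2L)) stop("spectrum d5 must lie in [-2, +2]")
  if (any(sp$d3 < -3L | sp$d3 > 3L)) stop("spectrum d3 must lie in [-3, +3]")
  invisible(sp)
}

#' Cohort generation parameters
#'
#' @param n_patients cohort size (default 616).
#' @param target_correlation Pearson correlation of the two isoform
#'   expressions on the output (rpm) scale, achieved analytically through
#'   the log-normal moment relation (default 0.85).
#' @param er_fraction fraction of ER-negative patients (default 0.25).
#' @param metastasis_fraction fraction with distant metastasis (default 0.15).
#' @param er_effect_size additive log-scale shift of both isoform
#'   expressions in ER-negative patients (default 0.1, about two thirds of
#'   the log-scale spread).
#' @param metastasis_effect_size log-scale shift in metastatic patients
#'   (default -0.08: lower expression with metastasis).
#' @param hazard_ratio_high_vs_low death hazard of the upper expression
#'   quartile relative to the lower (default 0.5: high expression survives
#'   better).
#' @param censoring_rate expected fraction of censored observations
#'   (default 0.6).
#' @param meanlog,sdlog log-scale location/scale of the canonical and
#'   isomiR expression marginals.  The default scale (0.15) is deliberately
#'   mild so that normal-theory (Fisher-z) inference on the output-scale
#'   Pearson correlation stays calibrated; real rpm data are far more
#'   dispersed (see the methods vignette).
#' @param base_median_days median survival of the low-expression group
#'   (default 2000 days).
#' @return list of cohort parameters.
#' @export
cohort_config <- function(n_patients = 616L, target_correlation = 0.85,
                          er_fraction = 0.25, metastasis_fraction = 0.15,
                          er_effect_size = 0.1,
                          metastasis_effect_size = -0.08,
                          hazard_ratio_high_vs_low = 0.5,
                          censoring_rate = 0.6,
                          meanlog = c(mir = log(150), isomir = log(250)),
                          sdlog = c(mir = 0.15, isomir = 0.15),
                          base_median_days = 2000) {
  if (target_correlation <= -1 || target_correlation >= 1) {
    stop("target_correlation must lie in (-1, 1)")
  }
  rates <- c(er_fraction, metastasis_fraction, censoring_rate)
  if (any(rates < 0 | rates > 1)) stop("fractions/rates must lie in [0, 1]")
  list(n_patients = as.integer(n_patients),
       target_correlation = target_correlation,
       er_fraction = er_fraction,
       metastasis_fraction = metastasis_fraction,
       er_effect_size = er_effect_size,
       metastasis_effect_size = metastasis_effect_size,
       hazard_ratio_high_vs_low = hazard_ratio_high_vs_low,
       censoring_rate = censoring_rate,
       meanlog = meanlog, sdlog = sdlog,
       base_median_days = base_median_days)
}

#' Simulation configuration
#'
#' @param seed integer seed driving all generators.
#' @param n_mirnas number of synthetic miRNAs (default 5).
#' @param precursor_length precursor length in nt (default 80).
#' @param samples sample names (default S1, S2).
#' @param depth_per_sample reads per sample (default 20000).
#' @param expression log-normal expression model across miRNAs:
#'   list(meanlog, sdlog).
#' @param spectrum offset spectrum data.frame applied to every miRNA, or a
#'   named list of per-miRNA spectra (default
#'   \code{\link{default_offset_spectrum}}).
#' @param adapter 3' adapter appended to every read (default the standard
#'   Illumina small-RNA 3' adapter), or NULL for adapter-free reads.
#' @param error_rate per-base substitution rate in [0, 0.05] applied to the
#'   finished record (default 0; corrupted reads become unmappable under
#'   the exact-match policy).
#' @param cohort a \code{\link{cohort_config}} list.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_mirnas = 5L, precursor_length = 80L,
                       samples = c("S1", "S2"), depth_per_sample = 20000L,
                       expression = list(meanlog = log(100), sdlog = 1),
                       spectrum = default_offset_spectrum(),
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       error_rate = 0,
                       cohort = cohort_config()) {
  stopifnot(n_mirnas >= 1L, precursor_length >= 60L,
            length(samples) >= 1L, depth_per_sample >= 0L)
  if (error_rate < 0 || error_rate > 0.05) {
    stop("error_rate must lie in [0, 0.05]")
  }
  if (is.data.frame(spectrum)) {
    .validate_spectrum(spectrum)
  } else {
    lapply(spectrum, .validate_spectrum)
  }
  if (!is.null(adapter)) adapter <- normalize_dna(adapter)
  structure(list(seed = as.integer(seed), n_mirnas = as.integer(n_mirnas),
                 precursor_length = as.integer(precursor_length),
                 samples = samples,
                 depth_per_sample = as.integer(depth_per_sample),
                 expression = expression, spectrum = spectrum,
                 adapter = adapter, error_rate = error_rate,
                 cohort = cohort),
            class = "sim_config")
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a precursor reference with embedded mature annotations
#'
#' Each synthetic precursor embeds one mature sequence (20-23 nt) at a
#' recorded position with at least 5 nt of flank on both sides, leaving
#' room for the offset spectrum.  Mature sequences are pairwise
#' non-substring of one another and occur exactly once in the whole
#' precursor set.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{precursors}, \code{annotations} (internal
#'   layout) and \code{truth} (the annotation table; ground truth for all
#'   coordinates).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$precursor_length
  prec <- character(config$n_mirnas)
  ann <- vector("list", config$n_mirnas)
  for (i in seq_len(config$n_mirnas)) {
    for (try in 1:200) {
      p <- .rand_dna(L)
      mlen <- sample(20:23, 1)
      start0 <- sample(5:(L - mlen - 5), 1)
      mat <- substring(p, start0 + 1L, start0 + mlen)
      prev_mat <- vapply(ann[seq_len(i - 1L)],
                         function(a) a$sequence, character(1))
      ok <- length(gregexpr(mat, p, fixed = TRUE)[[1]]) == 1L &&
        gregexpr(mat, p, fixed = TRUE)[[1]][1] == start0 + 1L &&
        !any(vapply(prev_mat, function(m) grepl(m, p, fixed = TRUE),
                    logical(1))) &&
        !any(vapply(prec[seq_len(i - 1L)],
                    function(q) grepl(mat, q, fixed = TRUE), logical(1)))
      if (ok) break
      if (try == 200) stop("failed to place a unique mature sequence")
    }
    prec[i] <- p
    arm <- if (start0 + mlen / 2 < L / 2) "5p" else "3p"
    ann[[i]] <- data.frame(
      mirna_name = sprintf("syn-miR-%d-%s", i, arm),
      precursor_id = sprintf("syn-mir-%d", i),
      start = start0, end = start0 + mlen, sequence = mat,
      stringsAsFactors = FALSE)
  }
  precursors <- data.frame(id = sprintf("syn-mir-%d",
                                        seq_len(config$n_mirnas)),
                           sequence = prec, stringsAsFactors = FALSE)
  annotations <- do.call(rbind, ann)
  list(precursors = precursors, annotations = annotations,
       truth = annotations)
}

.mutate_bases <- function(seq, n_err) {
  pos <- sample.int(nchar(seq), n_err)
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Simulate small-RNA reads with a planted isomiR spectrum
#'
#' Per sample, per-miRNA abundances are drawn from the log-normal
#' expression model and reads allocated multinomially; each read's (d5, d3)
#' offsets are drawn from the miRNA's spectrum and the read is cut directly
#' from the precursor (every read is exactly templated).  The adapter is
#' then appended and, at \code{error_rate > 0}, bases of the finished
#' record are substituted uniformly, making affected reads unmappable
#' under the exact-match policy.
#'
#' The truth table records, per sample and (miRNA, d5) group, the intended
#' read count, both in total and restricted to reads whose insert length
#' lies in the 18-24 nt collapse window (\code{count_in_window}); recovery
#' checks compare against the latter.
#'
#' @param config a \code{\link{sim_config}}.
#' @param reference output of \code{\link{simulate_reference}}.
#' @return list with \code{samples} (named list of read data.frames with
#'   \code{id}, \code{sequence}, \code{quality}) and \code{truth}.
#' @export
simulate_reads <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  ann <- reference$annotations
  prec_seq <- stats::setNames(reference$precursors$sequence,
                              reference$precursors$id)
  get_spectrum <- function(mirna) {
    if (is.data.frame(config$spectrum)) config$spectrum
    else config$spectrum[[mirna]]
  }
  # configuration error if any spectrum offset leaves the precursor
  for (i in seq_len(nrow(ann))) {
    sp <- get_spectrum(ann$mirna_name[i])
    plen <- nchar(prec_seq[[ann$precursor_id[i]]])
    if (ann$start[i] + min(sp$d5) < 0L || ann$end[i] + max(sp$d3) > plen) {
      stop("offset spectrum falls outside precursor for ", ann$mirna_name[i])
    }
  }
  samples <- list()
  truth <- list()
  for (s in config$samples) {
    w <- stats::rlnorm(nrow(ann), config$expression$meanlog,
                       config$expression$sdlog)
    counts <- if (config$depth_per_sample > 0L) {
      as.vector(stats::rmultinom(1, config$depth_per_sample, w))
    } else rep(0L, nrow(ann))
    seqs <- character(0); mir_of <- character(0)
    d5_of <- integer(0); inlen <- integer(0)
    for (i in seq_len(nrow(ann))) {
      n <- counts[i]
      if (n == 0L) next
      sp <- get_spectrum(ann$mirna_name[i])
      pick <- sample.int(nrow(sp), n, replace = TRUE, prob = sp$prob)
      from <- ann$start[i] + sp$d5[pick] + 1L
      to <- ann$end[i] + sp$d3[pick]
      rd <- substring(prec_seq[[ann$precursor_id[i]]], from, to)
      seqs <- c(seqs, rd)
      mir_of <- c(mir_of, rep(ann$mirna_name[i], n))
      d5_of <- c(d5_of, sp$d5[pick])
      inlen <- c(inlen, nchar(rd))
    }
    if (length(seqs)) {
      perm <- sample.int(length(seqs))
      seqs <- seqs[perm]; mir_of <- mir_of[perm]
      d5_of <- d5_of[perm]; inlen <- inlen[perm]
    }
    out_seq <- if (is.null(config$adapter)) seqs else
      paste0(seqs, config$adapter)
    if (config$error_rate > 0 && length(out_seq)) {
      n_err <- stats::rbinom(length(out_seq), nchar(out_seq),
                             config$error_rate)
      for (j in which(n_err > 0L)) {
        out_seq[j] <- .mutate_bases(out_seq[j], n_err[j])
      }
    }
    samples[[s]] <- data.frame(
      id = sprintf("%s_read%06d", s, seq_along(out_seq)),
      sequence = out_seq,
      quality = vapply(nchar(out_seq), function(n) strrep("I", n),
                       character(1)),
      stringsAsFactors = FALSE)
    if (length(seqs)) {
      in_win <- inlen >= 18L & inlen <= 24L
      agg <- stats::aggregate(
        cbind(count = rep(1L, length(seqs)), count_in_window = in_win),
        by = list(mirna_name = mir_of, offset5 = d5_of), FUN = sum)
      agg$sample <- s
      truth[[s]] <- agg[, c("sample", "mirna_name", "offset5",
                            "count", "count_in_window")]
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sample = character(), mirna_name = character(),
               offset5 = integer(), count = integer(),
               count_in_window = integer())
  rownames(truth) <- NULL
  list(samples = samples, truth = truth)
}

#' Simulate a differential-expression table with planted downregulated genes
#'
#' Every gene appears in every cell line under both conditions.  Planted
#' hits receive expression ratios strictly below the 0.65 threshold and raw
#' p-values small enough that BH correction across the table keeps them
#' strictly below 0.05 in every cell line; null genes receive ratios near 1
#' and large p-values, so recovery at the default thresholds is exact.
#'
#' @param seed integer seed.
#' @param n_genes number of genes (default 500).
#' @param planted integer vector \code{c(a_only, b_only, shared)} of hit
#'   counts (default 30, 10, 4).
#' @param conditions two condition labels; the first maps to
#'   \code{a_only} (default \code{c("isomir", "canonical")}).
#' @param cell_lines cell-line labels (default MCF10A, MDA-MB-231).
#' @return list with \code{de} (gene_id, cell_line, condition, ratio, p)
#'   and \code{truth} (planted id sets).
#' @export
simulate_de_table <- function(seed = 1L, n_genes = 500L,
                              planted = c(a_only = 30L, b_only = 10L,
                                          shared = 4L),
                              conditions = c("isomir", "canonical"),
                              cell_lines = c("MCF10A", "MDA-MB-231")) {
  stopifnot(length(conditions) == 2L, sum(planted) <= n_genes)
  set.seed(seed + 2L)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  hit_ids <- sample(genes, sum(planted))
  a_only <- hit_ids[seq_len(planted[1])]
  b_only <- hit_ids[planted[1] + seq_len(planted[2])]
  shared <- hit_ids[planted[1] + planted[2] + seq_len(planted[3])]
  grid <- expand.grid(gene_id = genes, cell_line = cell_lines,
                      condition = conditions, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  grid$ratio <- stats::runif(n, 0.8, 1.2)
  grid$p <- stats::runif(n, 0.2, 1)
  is_hit <- (grid$condition == conditions[1] &
               grid$gene_id %in% c(a_only, shared)) |
    (grid$condition == conditions[2] & grid$gene_id %in% c(b_only, shared))
  grid$ratio[is_hit] <- stats::runif(sum(is_hit), 0.35, 0.62)
  grid$p[is_hit] <- stats::runif(sum(is_hit), 1e-6, 5e-5)
  truth <- list(a_only = sort(a_only), b_only = sort(b_only),
                shared = sort(shared), conditions = conditions)
  list(de = grid, truth = truth)
}

# Underlying-normal correlation that yields a given Pearson correlation on
# the log-normal scale (moment relation, solved in closed form).
.lognormal_rho <- function(target_r, s1, s2) {
  arg <- 1 + target_r * sqrt(expm1(s1^2) * expm1(s2^2))
  if (arg <= 0) stop("target correlation not attainable for these sdlogs")
  rho <- log(arg) / (s1 * s2)
  if (abs(rho) > 1) stop("target correlation not attainable for these sdlogs")
  rho
}

#' Simulate a patient cohort with planted correlation and survival structure
#'
#' The two isoform expressions are bivariate log-normal; the
#' underlying-normal correlation is solved analytically so the Pearson
#' correlation on the output scale equals the target (exact when the group
#' effect sizes are 0; nonzero shared group shifts add covariance on top).
#' ER and metastasis labels shift both expressions on the log scale by the
#' configured effect sizes.  Survival is exponential with the hazard scaled
#' across the expression quartile groups of the isomiR
#' (low / middle / high get hazard 1, sqrt(HR), HR relative to baseline);
#' censoring times are exponential with rate chosen so the expected
#' censored fraction equals \code{censoring_rate}.
#'
#' @param config a \code{\link{sim_config}} (uses \code{config$cohort} and
#'   the seed) or a \code{\link{cohort_config}} list plus \code{seed}.
#' @param seed used when \code{config} is a bare cohort config.
#' @return list with \code{patients} (patient_id, mir_rpm, isomir_rpm,
#'   er_status, metastasis, survival_time, event) and \code{truth}
#'   (generating parameters, including the solved underlying correlation).
#' @export
simulate_cohort <- function(config, seed = NULL) {
  if (inherits(config, "sim_config")) {
    cc <- config$cohort
    seed <- config$seed
  } else {
    cc <- config
    if (is.null(seed)) stop("seed required with a bare cohort config")
  }
  set.seed(seed + 3L)
  n <- cc$n_patients
  s1 <- cc$sdlog[["mir"]]; s2 <- cc$sdlog[["isomir"]]
  rho <- .lognormal_rho(cc$target_correlation, s1, s2)
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  lmir <- cc$meanlog[["mir"]] + s1 * z1
  liso <- cc$meanlog[["isomir"]] + s2 * z2
  er <- ifelse(stats::runif(n) < cc$er_fraction, "negative", "positive")
  met <- ifelse(stats::runif(n) < cc$metastasis_fraction, "yes", "no")
  shift <- cc$er_effect_size * (er == "negative") +
    cc$metastasis_effect_size * (met == "yes")
  mir_rpm <- exp(lmir + shift)
  isomir_rpm <- exp(liso + shift)
  q <- stats::quantile(isomir_rpm, c(0.25, 0.75), type = 8, names = FALSE)
  g <- ifelse(isomir_rpm <= q[1], 0L, ifelse(isomir_rpm > q[2], 2L, 1L))
  lambda0 <- log(2) / cc$base_median_days
  rate <- lambda0 * cc$hazard_ratio_high_vs_low^(g / 2)
  t_event <- stats::rexp(n, rate)
  crate <- cc$censoring_rate
  time <- t_event
  event <- rep("death", n)
  if (crate > 0) {
    t_cens <- stats::rexp(n, rate * crate / (1 - crate))
    event <- ifelse(t_event <= t_cens, "death", "censored")
    time <- pmin(t_event, t_cens)
  }
  patients <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    mir_rpm = mir_rpm, isomir_rpm = isomir_rpm,
    er_status = er, metastasis = met,
    survival_time = time, event = event, stringsAsFactors = FALSE)
  list(patients = patients,
       truth = c(cc, list(underlying_rho = rho, quartile_cuts = q)))
}

#' Write all simulated inputs for a config into a directory
#'
#' Emits precursors.fa, matures.gff3, one FASTQ per sample, de_table.tsv,
#' cohort.tsv and the corresponding *_truth.tsv tables.
#'
#' @param config a \code{\link{sim_config}}.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the list of written paths.
#' @export
simulate_all <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference(config)
  rds <- simulate_reads(config, ref)
  de <- simulate_de_table(seed = config$seed)
  coh <- simulate_cohort(config)
  paths <- c(
    precursors = file.path(out_dir, "precursors.fa"),
    matures = file.path(out_dir, "matures.gff3"),
    reference_truth = file.path(out_dir, "reference_truth.tsv"),
    reads_truth = file.path(out_dir, "reads_truth.tsv"),
    de_table = file.path(out_dir, "de_table.tsv"),
    de_truth = file.path(out_dir, "de_truth.tsv"),
    cohort = file.path(out_dir, "cohort.tsv"))
  write_precursor_fasta(ref$precursors, paths["precursors"])
  write_mature_gff3(ref$annotations, paths["matures"])
  write_mature_tsv(ref$truth, paths["reference_truth"])
  utils::write.table(rds$truth, paths["reads_truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(de$de, paths["de_table"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  de_truth <- data.frame(
    gene_id = c(de$truth$a_only, de$truth$b_only, de$truth$shared),
    planted = rep(c("a_only", "b_only", "shared"),
                  c(length(de$truth$a_only), length(de$truth$b_only),
                    length(de$truth$shared))))
  utils::write.table(de_truth, paths["de_truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(coh$patients, paths["cohort"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (s in names(rds$samples)) {
    p <- file.path(out_dir, paste0(s, ".fastq"))
    write_fastq(rds$samples[[s]], p)
    paths[paste0("reads_", s)] <- p
  }
  invisible(paths)
}
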