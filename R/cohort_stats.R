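# Downstream statistics: the microarray downregulation filter with Venn
# intersection, isoform-isoform correlation, ER/metastasis group
# comparisons (Student's t), and quartile-based Kaplan-Meier survival with
# a two-group log-rank test.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (delegates to \code{stats::p.adjust}); values are
#' validated to lie in [0, 1].  Set \code{method = "bonferroni"} for the
#' more conservative family-wise control.
#'
#' @param p_values numeric vector of raw p-values.
#' @param method "BH" (default) or "bonferroni".
#' @return adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = method)
}

#' Per-gene differential-expression statistics from replicate tables
#'
#' For DE tables that carry replicate expression values instead of
#' precomputed ratio/p columns: the fold ratio is mean(treated)/mean(control)
#' and the raw p-value a two-tailed unpaired Student's t test between the
#' replicate groups.
#'
#' @param de data.frame with columns \code{gene_id}, \code{cell_line},
#'   \code{condition}, \code{replicate}, \code{treated}, \code{control}.
#' @return data.frame with \code{gene_id}, \code{cell_line},
#'   \code{condition}, \code{ratio}, \code{p}.
#' @export
compute_de_stats <- function(de) {
  need <- c("gene_id", "cell_line", "condition", "treated", "control")
  if (!all(need %in% names(de))) {
    stop("replicate DE table lacks column(s): ",
         paste(setdiff(need, names(de)), collapse = ", "))
  }
  key <- interaction(de$gene_id, de$cell_line, de$condition, drop = TRUE)
  rows <- lapply(split(de, key), function(d) {
    tt <- stats::t.test(d$treated, d$control, var.equal = TRUE)
    data.frame(gene_id = d$gene_id[1], cell_line = d$cell_line[1],
               condition = d$condition[1],
               ratio = mean(d$treated) / mean(d$control),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Downregulated gene sets and their Venn partition
#'
#' A gene counts as downregulated under a condition when, in every listed
#' cell line, its treated/control expression ratio is strictly below
#' \code{fold_threshold} and its multiplicity-corrected p-value strictly
#' below \code{alpha}.  Correction is applied per cell line and condition
#' across genes.  For two conditions the Venn partition (specific to each,
#' shared) is reported.
#'
#' @param de data.frame with columns \code{gene_id}, \code{cell_line},
#'   \code{condition}, \code{ratio}, \code{p} (see
#'   \code{\link{compute_de_stats}} for replicate input).
#' @param cell_lines cell lines that must all pass (default: all present).
#' @param conditions conditions to compare (default: all present).
#' @param fold_threshold strict upper bound on the expression ratio
#'   (default 0.65, i.e. reduction by at least 35\%).
#' @param alpha strict upper bound on the corrected p-value (default 0.05).
#' @param method correction method passed to \code{\link{bh_adjust}}.
#' @return list with \code{sets} (named list of gene-id vectors per
#'   condition), \code{venn} (for two conditions: named counts
#'   \code{a_only}, \code{b_only}, \code{shared} plus the gene ids) and
#'   \code{conditions}.
#' @export
downregulated_genes <- function(de, cell_lines = NULL, conditions = NULL,
                                fold_threshold = 0.65, alpha = 0.05,
                                method = "BH") {
  need <- c("gene_id", "cell_line", "condition", "ratio", "p")
  if (!all(need %in% names(de))) {
    stop("DE table lacks column(s): ",
         paste(setdiff(need, names(de)), collapse = ", "))
  }
  if (is.null(cell_lines)) cell_lines <- unique(de$cell_line)
  if (is.null(conditions)) conditions <- unique(de$condition)
  de <- de[de$cell_line %in% cell_lines & de$condition %in% conditions, ]
  genes <- unique(de$gene_id)
  # corrected p per cell line x condition across genes
  grp <- interaction(de$cell_line, de$condition, drop = TRUE)
  de$padj <- stats::ave(de$p, grp, FUN = function(p) bh_adjust(p, method))
  sets <- list()
  for (cond in conditions) {
    passing <- genes
    for (cl in cell_lines) {
      d <- de[de$condition == cond & de$cell_line == cl, ]
      absent <- setdiff(genes, d$gene_id)
      if (length(absent)) {
        stop("gene '", absent[1], "' missing in cell line '", cl,
             "' (condition '", cond, "')")
      }
      ok <- d$gene_id[d$ratio < fold_threshold & d$padj < alpha]
      passing <- intersect(passing, ok)
    }
    sets[[cond]] <- sort(passing)
  }
  venn <- NULL
  if (length(conditions) == 2L) {
    a <- sets[[conditions[1]]]; b <- sets[[conditions[2]]]
    venn <- list(a_only = setdiff(a, b), b_only = setdiff(b, a),
                 shared = intersect(a, b))
    venn$counts <- c(a_only = length(venn$a_only),
                     b_only = length(venn$b_only),
                     shared = length(venn$shared))
  }
  list(sets = sets, venn = venn, conditions = conditions)
}

.drop_missing <- function(x) x[!is.na(x)]

#' Correlation between canonical miRNA and 5'isomiR expression in a cohort
#'
#' @param patients data.frame with columns \code{mir_rpm} and
#'   \code{isomir_rpm} (one row per patient).
#' @param method "pearson" (default) or "spearman".
#' @param log_transform apply log2(x + 1) to both expressions first.
#' @return list with \code{r}, \code{p} (two-sided), \code{n} used and
#'   \code{n_dropped} (patients with missing values).
#' @export
correlate_isoforms <- function(patients, method = c("pearson", "spearman"),
                               log_transform = FALSE) {
  method <- match.arg(method)
  x <- patients$mir_rpm; y <- patients$isomir_rpm
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 patients with both expressions")
  if (log_transform) { x <- log2(x + 1); y <- log2(y + 1) }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant expression vector: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       n_dropped = sum(!keep))
}

#' Two-group comparison of isoform expression (unpaired Student's t test)
#'
#' @param patients patient data.frame.
#' @param grouping name of the grouping column (e.g. "er_status" with
#'   levels positive/negative, or "metastasis" with yes/no); rows with
#'   "unknown" or NA are dropped.
#' @param expression_field which expression column to compare
#'   (e.g. "mir_rpm" or "isomir_rpm").
#' @param log_transform apply log2(x + 1) first.
#' @return list with \code{t}, \code{p} (two-sided), \code{group_means},
#'   \code{group_ns}, \code{direction} (name of the group with the higher
#'   mean).
#' @export
compare_groups <- function(patients, grouping, expression_field,
                           log_transform = FALSE) {
  g <- as.character(patients[[grouping]])
  x <- patients[[expression_field]]
  keep <- !is.na(x) & !is.na(g) & g != "unknown"
  g <- g[keep]; x <- x[keep]
  if (log_transform) x <- log2(x + 1)
  lev <- sort(unique(g))
  if (length(lev) != 2L) stop("grouping must yield exactly two groups, got: ",
                              paste(lev, collapse = ", "))
  x1 <- x[g == lev[1]]; x2 <- x[g == lev[2]]
  if (length(x1) < 2L || length(x2) < 2L) {
    stop("each group needs at least 2 members")
  }
  tt <- stats::t.test(x1, x2, var.equal = TRUE)
  means <- stats::setNames(c(mean(x1), mean(x2)), lev)
  list(t = unname(tt$statistic), p = tt$p.value, group_means = means,
       group_ns = stats::setNames(c(length(x1), length(x2)), lev),
       direction = names(which.max(means)))
}

#' Split patients into upper/lower expression quartile groups
#'
#' Cut points are the first and third quartiles in the median-unbiased
#' convention (\code{quantile} type 8).  Ties go to the lower group: the
#' low group takes \code{x <= Q1}, the high group \code{x > Q3}; the middle
#' half is excluded.
#'
#' @param x numeric expression vector.
#' @param ids patient ids aligned with \code{x}.
#' @param q_type quantile type (default 8).
#' @return list with \code{high}, \code{low}, \code{excluded} id vectors
#'   and the \code{cuts}.
#' @export
quartile_groups <- function(x, ids, q_type = 8) {
  stopifnot(length(x) == length(ids))
  q <- stats::quantile(x, c(0.25, 0.75), type = q_type, names = FALSE)
  if (q[1] == q[2]) stop("degenerate expression distribution: Q1 == Q3")
  low <- ids[x <= q[1]]
  high <- ids[x > q[2]]
  list(high = high, low = low,
       excluded = setdiff(ids, c(high, low)), cuts = q)
}

#' Quartile-based survival analysis
#'
#' Patients in the upper quartile of the chosen expression are 'high', the
#' lower quartile 'low'; the middle half is excluded.  Kaplan-Meier curves
#' are estimated per group and the two groups compared with the log-rank
#' test (observed-versus-expected, chi-square on 1 df).
#'
#' @param patients patient data.frame with \code{patient_id},
#'   \code{survival_time}, \code{event} ("death"/"censored" or 1/0) and the
#'   expression column.
#' @param expression_field which expression column defines the groups.
#' @param q_type quantile convention (see \code{\link{quartile_groups}}).
#' @return list with \code{groups} (high/low/excluded ids),
#'   \code{logrank_statistic}, \code{p}, \code{km} (a
#'   \code{survival::survfit} object for the two groups) and \code{n_events}.
#' @export
quartile_survival <- function(patients, expression_field, q_type = 8) {
  need <- c("patient_id", "survival_time", "event")
  if (!all(need %in% names(patients))) {
    stop("patient table lacks column(s): ",
         paste(setdiff(need, names(patients)), collapse = ", "))
  }
  ev <- patients$event
  if (!is.numeric(ev)) ev <- as.integer(as.character(ev) == "death")
  keep <- !is.na(patients$survival_time) & !is.na(ev) &
    !is.na(patients[[expression_field]])
  d <- patients[keep, ]
  ev <- ev[keep]
  if (nrow(d) < 8L) stop("need at least 8 patients with survival data")
  grp <- quartile_groups(d[[expression_field]], d$patient_id, q_type = q_type)
  sel <- d$patient_id %in% c(grp$high, grp$low)
  dd <- d[sel, ]
  ee <- ev[sel]
  group <- factor(ifelse(dd$patient_id %in% grp$high, "high", "low"),
                  levels = c("low", "high"))
  km <- survival::survfit(survival::Surv(dd$survival_time, ee) ~ group)
  if (sum(ee) == 0L) {
    warning("all observations censored in both groups; log-rank statistic 0")
    return(list(groups = grp, logrank_statistic = 0, p = 1, km = km,
                n_events = 0L))
  }
  sd_ <- survival::survdiff(survival::Surv(dd$survival_time, ee) ~ group)
  list(groups = grp, logrank_statistic = unname(sd_$chisq),
       p = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
       km = km, n_events = sum(ee))
}

#' Read a patient cohort table
#'
#' Expected columns: \code{patient_id}, \code{mir_rpm}, \code{isomir_rpm},
#' \code{er_status} (positive/negative/unknown), \code{metastasis}
#' (yes/no/unknown), \code{survival_time} (days), \code{event}
#' (death/censored).  A column mapping can rename externally supplied
#' layouts (e.g. a clinical supplement export) onto this schema.
#'
#' @param path TSV file path.
#' @param column_map optional named character vector mapping the file's
#'   column names onto the schema, e.g.
#'   \code{c(mir_rpm = "reads.miR.140.3p")}; names are schema fields,
#'   values the file's columns.
#' @return patient data.frame in the package schema.
#' @export
read_patient_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) {
    stop("patient table not found: ", path,
         " (external cohort deposits are not bundled and must be supplied)")
  }
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (field in names(column_map)) {
      src <- column_map[[field]]
      if (!src %in% names(d)) stop("mapped column not in file: ", src)
      d[[field]] <- d[[src]]
    }
  }
  need <- c("patient_id", "mir_rpm", "isomir_rpm")
  if (!all(need %in% names(d))) {
    stop("patient table lacks column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  }
  if (!is.null(d$survival_time) && !is.null(d$event)) {
    has_event <- !is.na(d$event) & d$event != ""
    if (any(has_event & is.na(d$survival_time))) {
      stop("survival_time missing for patients with an event status")
    }
  }
  d
}
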