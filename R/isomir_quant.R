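# Reads -> isoform expression matrix: adapter trimming, exact placement on
# precursor sequences, 5'/3' offset assignment in the d5|d3 notation,
# collapsing of 3' variants into 5'-end groups, counting and rpm.
#
# Everything here is deterministic given its inputs; randomness lives only
# in the synthetic-data generator.

#' Adapter trimming options
#'
#' @param adapter 3' adapter sequence (DNA/RNA; normalized to DNA), or NULL
#'   to skip trimming (length filtering still applies).
#' @param min_overlap minimum adapter prefix length that must match the read
#'   suffix for trimming to trigger (default 6).
#' @param min_length,max_length accepted read length window after trimming
#'   (defaults 15 and 30); reads outside it are rejected with a reason.
#' @return object of class \code{trim_options}.
#' @export
trim_options <- function(adapter = NULL, min_overlap = 6L,
                         min_length = 15L, max_length = 30L) {
  if (!is.null(adapter)) {
    adapter <- normalize_dna(adapter)
    if (nchar(adapter) == 0L) stop("adapter must be non-empty (or NULL)")
    .check_alphabet(adapter, "adapter")
    if (min_overlap < 3L) stop("min_overlap must be >= 3")
  }
  if (min_length > max_length) stop("min_length must be <= max_length")
  structure(list(adapter = adapter, min_overlap = as.integer(min_overlap),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length)),
            class = "trim_options")
}

.trim_one <- function(seq, adapter, min_overlap) {
  L <- nchar(seq)
  A <- nchar(adapter)
  kmax <- min(L, A)
  if (kmax >= min_overlap) {
    for (k in seq.int(kmax, min_overlap)) {
      if (substring(seq, L - k + 1L, L) == substring(adapter, 1L, k)) {
        return(substring(seq, 1L, L - k))
      }
    }
  }
  seq
}

#' Trim the 3' adapter from read sequences
#'
#' The longest read suffix that exactly matches a prefix of the adapter
#' (length >= \code{min_overlap}) is removed; reads without such a suffix
#' are returned unchanged.  Reads whose post-trim length falls outside
#' \code{[min_length, max_length]} are flagged, not dropped.
#'
#' @param sequences character vector of read sequences.
#' @param options a \code{\link{trim_options}} object.
#' @return data.frame with columns \code{sequence} (trimmed), \code{trimmed}
#'   (logical) and \code{status} ("ok", "too_short" or "too_long").
#' @export
trim_adapter <- function(sequences, options) {
  stopifnot(inherits(options, "trim_options"))
  sequences <- toupper(sequences)
  if (is.null(options$adapter)) {
    trimmed <- sequences
    did <- rep(FALSE, length(sequences))
  } else {
    uniq <- unique(sequences)
    cut <- vapply(uniq, .trim_one, character(1),
                  adapter = options$adapter, min_overlap = options$min_overlap)
    trimmed <- unname(cut[sequences])
    did <- trimmed != sequences
  }
  len <- nchar(trimmed)
  status <- rep("ok", length(sequences))
  status[len < options$min_length] <- "too_short"
  status[len > options$max_length] <- "too_long"
  data.frame(sequence = trimmed, trimmed = did, status = status,
             stringsAsFactors = FALSE)
}

#' Find all exact placements of a read on a precursor set
#'
#' Sense strand only (small-RNA libraries are stranded); every exact,
#' possibly overlapping occurrence is reported.
#'
#' @param sequence a single read sequence.
#' @param precursors data.frame with \code{id}, \code{sequence}.
#' @return data.frame with columns \code{precursor_id}, \code{start}
#'   (0-based); zero rows when the read is unmapped.
#' @export
map_read <- function(sequence, precursors) {
  sequence <- normalize_dna(sequence)
  subj <- Biostrings::DNAStringSet(precursors$sequence)
  names(subj) <- precursors$id
  hits <- Biostrings::vmatchPattern(sequence, subj)
  starts <- Biostrings::startIndex(hits)
  n <- lengths(starts)
  data.frame(precursor_id = rep(precursors$id, n),
             start = unlist(starts, use.names = FALSE) - 1L,
             stringsAsFactors = FALSE)
}

#' Render a (d5, d3) offset pair in the d5|d3 notation
#'
#' Nonzero offsets carry an explicit sign, e.g. "+1|-2", "0|+3", "0|0".
#'
#' @param offset5,offset3 integer offsets of the read 5'/3' ends relative to
#'   the annotated mature ends.
#' @return character vector of notation strings.
#' @export
offset_notation <- function(offset5, offset3) {
  f <- function(v) ifelse(v > 0, paste0("+", v), as.character(v))
  paste0(f(offset5), "|", f(offset3))
}

#' Assign 5'/3' offsets to a mapped read
#'
#' Among the mature annotations on the hit precursor, the one minimizing
#' |offset5| is chosen (ties: minimal |offset3|, then the 5p arm).  Reads
#' with |offset5| beyond \code{max_offset5} are not assigned.
#'
#' @param precursor_id,start hit location (0-based start).
#' @param read_length length of the (trimmed) read.
#' @param annotations annotation data.frame (internal layout).
#' @param max_offset5 maximum tolerated |offset5| (default 5).
#' @return one-row data.frame with \code{mirna_name}, \code{precursor_id},
#'   \code{offset5}, \code{offset3}, \code{notation}, or NULL when the
#'   precursor carries no annotation or the offset bound is exceeded.
#' @export
assign_offsets <- function(precursor_id, start, read_length, annotations,
                           max_offset5 = 5L) {
  ann <- annotations[annotations$precursor_id == precursor_id, , drop = FALSE]
  if (nrow(ann) == 0L) return(NULL)
  d5 <- start - ann$start
  d3 <- (start + read_length) - ann$end
  is5p <- grepl("-5p$", ann$mirna_name)
  ord <- order(abs(d5), abs(d3), !is5p)
  i <- ord[1]
  if (abs(d5[i]) > max_offset5) return(NULL)
  data.frame(mirna_name = ann$mirna_name[i], precursor_id = precursor_id,
             offset5 = d5[i], offset3 = d3[i],
             notation = offset_notation(d5[i], d3[i]),
             stringsAsFactors = FALSE)
}

#' Collapse an offset assignment into a 5'-end isoform key
#'
#' 3' variants are neglected: any read of length within the collapse window
#' (default 18-24 nt) is pooled by its 5' end, i.e. keyed by
#' (miRNA name, offset5).  Reads outside the window get no key.
#'
#' @param mirna_name,offset5 assignment fields.
#' @param read_length length of the read.
#' @param length_window inclusive length window (default \code{c(18, 24)}).
#' @return one-row data.frame with \code{mirna_name}, \code{offset5}, or
#'   NULL when the length falls outside the window.
#' @export
collapse_to_isoform <- function(mirna_name, offset5, read_length,
                                length_window = c(18L, 24L)) {
  if (read_length < length_window[1] || read_length > length_window[2]) {
    return(NULL)
  }
  data.frame(mirna_name = mirna_name, offset5 = as.integer(offset5),
             stringsAsFactors = FALSE)
}

# Process one sample's unique (sequence, count) table through
# map -> assign -> collapse.  Returns per-key weights plus audit counters.
.process_sample <- function(seqs, counts, precursors, annotations,
                            max_offset5, length_window) {
  subj <- Biostrings::DNAStringSet(precursors$sequence)
  names(subj) <- precursors$id
  key_name <- character(0); key_off <- integer(0); key_w <- numeric(0)
  n_mapped <- 0; n_assigned <- 0; n_collapsed <- 0
  rejects <- list()
  lib <- 0
  for (i in seq_along(seqs)) {
    s <- seqs[i]; cnt <- counts[i]
    hits <- Biostrings::vmatchPattern(s, subj)
    st <- Biostrings::startIndex(hits)
    nh <- lengths(st)
    if (sum(nh) == 0L) {
      rejects[["unmapped"]] <- c(rejects[["unmapped"]], cnt)
      next
    }
    n_mapped <- n_mapped + cnt
    hit_prec <- rep(names(subj), nh)
    hit_start <- unlist(st, use.names = FALSE) - 1L
    asg <- list()
    for (j in seq_along(hit_prec)) {
      a <- assign_offsets(hit_prec[j], hit_start[j], nchar(s), annotations,
                          max_offset5 = max_offset5)
      if (!is.null(a)) asg[[length(asg) + 1L]] <- a
    }
    if (length(asg) == 0L) {
      rejects[["offset_exceeded"]] <- c(rejects[["offset_exceeded"]], cnt)
      next
    }
    n_assigned <- n_assigned + cnt
    asg <- do.call(rbind, asg)
    keys <- list()
    for (j in seq_len(nrow(asg))) {
      k <- collapse_to_isoform(asg$mirna_name[j], asg$offset5[j], nchar(s),
                               length_window = length_window)
      if (!is.null(k)) {
        k$abs3 <- abs(asg$offset3[j])
        keys[[length(keys) + 1L]] <- k
      }
    }
    if (length(keys) == 0L) {
      rejects[["length_out_of_window"]] <- c(rejects[["length_out_of_window"]],
                                             cnt)
      next
    }
    n_collapsed <- n_collapsed + cnt
    keys <- do.call(rbind, keys)
    # one key per miRNA name: duplicate precursors for the same miRNA count
    # once (closest 5' end, then closest 3' end, wins)
    keys <- keys[order(abs(keys$offset5), keys$abs3), , drop = FALSE]
    keys <- keys[!duplicated(keys$mirna_name), , drop = FALSE]
    w <- cnt / nrow(keys)   # fractional weight across distinct miRNA names
    key_name <- c(key_name, keys$mirna_name)
    key_off <- c(key_off, keys$offset5)
    key_w <- c(key_w, rep(w, nrow(keys)))
    lib <- lib + cnt
  }
  rej <- data.frame(reason = names(rejects),
                    count = vapply(rejects, sum, numeric(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  list(keys = data.frame(mirna_name = key_name, offset5 = key_off,
                         weight = key_w, stringsAsFactors = FALSE),
       library_size = lib, n_mapped = n_mapped, n_assigned = n_assigned,
       n_collapsed = n_collapsed, rejects = rej)
}

#' Quantify isoform expression across samples
#'
#' Runs trim -> map -> assign -> collapse per read and per sample, with
#' fractional weight 1/n for reads assignable to n distinct miRNA names.
#' The rpm denominator for a sample is the total weight of reads that
#' received any isoform key, so rpm sums to exactly 1e6 per sample.
#'
#' @param reads_by_sample named list; each element either a FASTQ(.gz) path
#'   or a data.frame with a \code{sequence} column.
#' @param precursors precursor data.frame.
#' @param annotations mature annotation data.frame (internal layout).
#' @param trim a \code{\link{trim_options}} object.
#' @param max_offset5 maximum |offset5| accepted at assignment (default 5).
#' @param length_window collapse length window (default 18-24 nt).
#' @return object of class \code{isomir_matrix}: list with \code{keys}
#'   (data.frame mirna_name, offset5), \code{samples}, \code{counts} and
#'   \code{rpm} (key x sample matrices), \code{library_sizes}, \code{audit}
#'   (per-sample counters) and \code{rejects}.
#' @export
quantify <- function(reads_by_sample, precursors, annotations,
                     trim = trim_options(), max_offset5 = 5L,
                     length_window = c(18L, 24L)) {
  if (length(reads_by_sample) == 0L) stop("at least one sample is required")
  if (is.null(names(reads_by_sample)) || any(names(reads_by_sample) == "")) {
    stop("reads_by_sample must be a named list")
  }
  if (nrow(precursors) == 0L) stop("empty precursor reference")
  samples <- names(reads_by_sample)
  per <- vector("list", length(samples))
  audit <- list()
  rejects <- list()
  lib <- stats::setNames(numeric(length(samples)), samples)
  for (s in samples) {
    rd <- reads_by_sample[[s]]
    if (is.character(rd)) rd <- read_fastq(rd)
    n_input <- nrow(rd)
    tr <- trim_adapter(rd$sequence, trim)
    keep <- tr$status == "ok"
    for (reason in c("too_short", "too_long")) {
      n <- sum(tr$status == reason)
      if (n > 0) rejects[[length(rejects) + 1L]] <-
          data.frame(sample = s, reason = reason, count = n)
    }
    tab <- table(tr$sequence[keep])
    res <- .process_sample(names(tab), as.numeric(tab), precursors,
                           annotations, max_offset5, length_window)
    if (nrow(res$rejects) > 0) {
      rejects[[length(rejects) + 1L]] <-
        cbind(sample = s, res$rejects)
    }
    if (res$library_size == 0) {
      stop("sample '", s, "' has no reads assigned to any isoform group")
    }
    lib[s] <- res$library_size
    audit[[s]] <- data.frame(
      sample = s, n_input = n_input, n_after_trim = sum(keep),
      n_mapped = res$n_mapped, n_assigned = res$n_assigned,
      n_collapsed = res$n_collapsed, stringsAsFactors = FALSE)
    per[[s]] <- res$keys
  }
  all_keys <- unique(do.call(rbind, lapply(per, function(x)
    x[, c("mirna_name", "offset5")])))
  all_keys <- all_keys[order(all_keys$mirna_name, all_keys$offset5), ,
                       drop = FALSE]
  rownames(all_keys) <- NULL
  key_id <- paste(all_keys$mirna_name, all_keys$offset5)
  counts <- matrix(0, nrow = nrow(all_keys), ncol = length(samples),
                   dimnames = list(key_id, samples))
  for (s in samples) {
    k <- per[[s]]
    if (nrow(k) == 0) next
    agg <- stats::aggregate(weight ~ mirna_name + offset5, data = k, FUN = sum)
    counts[paste(agg$mirna_name, agg$offset5), s] <- agg$weight
  }
  rpm <- sweep(counts, 2, lib, "/") * 1e6
  structure(list(keys = all_keys, samples = samples, counts = counts,
                 rpm = rpm, library_sizes = lib,
                 audit = do.call(rbind, audit),
                 rejects = if (length(rejects)) do.call(rbind, rejects) else
                   data.frame(sample = character(), reason = character(),
                              count = numeric())),
            class = "isomir_matrix")
}

#' @export
print.isomir_matrix <- function(x, ...) {
  cat("isomir_matrix:", nrow(x$keys), "isoform keys x", length(x$samples),
      "samples\n")
  cat("library sizes:", paste(sprintf("%s=%g", x$samples, x$library_sizes),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Convert an isomir_matrix to a tidy rpm table
#' @param x an \code{isomir_matrix}.
#' @return data.frame with \code{mirna_name}, \code{offset5} and one rpm
#'   column per sample.
#' @export
as_rpm_table <- function(x) {
  stopifnot(inherits(x, "isomir_matrix"))
  out <- cbind(x$keys, as.data.frame(x$rpm, check.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Write an isoform expression matrix as TSV
#'
#' Rows are isoform keys (miRNA name plus offset5 in the d5 part of the
#' d5|d3 notation), columns are samples.
#'
#' @param x an \code{isomir_matrix} or a tidy rpm data.frame
#'   (\code{mirna_name}, \code{offset5}, sample columns).
#' @param path output path.
#' @export
write_matrix_tsv <- function(x, path) {
  if (inherits(x, "isomir_matrix")) x <- as_rpm_table(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an isoform rpm matrix TSV
#' @param path path written by \code{\link{write_matrix_tsv}}.
#' @return data.frame with \code{mirna_name}, \code{offset5} and sample
#'   columns.
#' @export
read_matrix_tsv <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("mirna_name", "offset5")
  if (!all(need %in% names(x))) {
    stop("matrix TSV lacks column(s): ",
         paste(setdiff(need, names(x)), collapse = ", "))
  }
  x$offset5 <- as.integer(x$offset5)
  x
}
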