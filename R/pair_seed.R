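# Highly expressed miRNA/5'isomiR pair detection, seed derivation, 3'UTR
# target-site scanning and seed-site enrichment testing.
#
# A 5' shift of one nucleotide shifts the seed (positions 2-8 of the mature
# sequence) by one, so a +1 5'isomiR reads the canonical positions 3-9 and
# recognizes a different 7-mer site in 3'UTRs.

#' The miR-140-3p canonical/5'isomiR pair of mature sequences
#'
#' The canonical hsa-miR-140-3p mature sequence and its +1 5'isomiR, the
#' package's headline worked example.
#'
#' @param rna return RNA (U) rather than DNA (T) alphabet.
#' @return named character vector with elements \code{canonical} and
#'   \code{isomir}.
#' @export
mir140_pair <- function(rna = TRUE) {
  x <- c(canonical = "UACCACAGGGUAGAACCACGG",
         isomir    = "ACCACAGGGUAGAACCACGGAC")
  if (rna) x else normalize_dna(x)
}

#' Extract the seed (positions 2-8) of a mature miRNA sequence
#'
#' @param mature_sequence character vector of mature sequences (length >= 8).
#' @param rna emit RNA alphabet (default FALSE: DNA).
#' @return character vector of 7-mer seeds.
#' @export
seed_of <- function(mature_sequence, rna = FALSE) {
  seqs <- normalize_dna(mature_sequence)
  .check_alphabet(seqs, "mature sequence")
  if (any(nchar(seqs) < 8L)) {
    stop("mature sequence shorter than 8 nt: ",
         paste(mature_sequence[nchar(seqs) < 8L], collapse = ", "))
  }
  seed <- substring(seqs, 2L, 8L)
  if (rna) as_rna(seed) else seed
}

#' Seed of a 5'-shifted isoform of a mature sequence
#'
#' For a +1 5'isomiR the seed equals positions 3-9 of the canonical mature
#' sequence, and so on.
#'
#' @param mature_sequence canonical mature sequence.
#' @param offset5 5' offset of the isoform (default +1); negative offsets
#'   are not derivable from the canonical sequence alone and are an error.
#' @param rna emit RNA alphabet.
#' @return 7-mer seed of the shifted isoform.
#' @export
shifted_seed <- function(mature_sequence, offset5 = 1L, rna = FALSE) {
  if (any(offset5 < 0L)) {
    stop("negative offset5 seeds require the precursor context")
  }
  seed_of(substring(normalize_dna(mature_sequence), offset5 + 1L), rna = rna)
}

#' Target site of a seed: its reverse complement
#'
#' The 7-mer a miRNA seed base-pairs with in a 3'UTR, in the standard
#' Watson-Crick sense.  Alphabet (RNA/DNA) of the input is preserved.
#'
#' @param seed 7-mer seed sequence.
#' @return 7-mer site sequence.
#' @export
target_site_of <- function(seed) {
  if (any(nchar(seed) != 7L)) stop("seed must be a 7-mer")
  is_rna <- grepl("U", toupper(seed))
  dna <- normalize_dna(seed)
  .check_alphabet(dna, "seed")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(dna)))
  ifelse(is_rna, as_rna(rc), rc)
}

#' Scan a 3'UTR for seed-match target sites
#'
#' Reports every (possibly overlapping) exact occurrence of the reverse
#' complement of the seed, in ascending position order.
#'
#' @param utr_sequence a single UTR sequence.
#' @param seed 7-mer seed.
#' @param gene_id gene identifier carried into the result (default NA).
#' @param seed_owner label for the seed's owner, e.g. "canonical" or
#'   "isomir" (default NA).
#' @return data.frame with columns \code{gene_id}, \code{utr_position}
#'   (0-based start of the 7-mer site), \code{site_sequence},
#'   \code{seed_owner}.
#' @export
scan_utr <- function(utr_sequence, seed, gene_id = NA_character_,
                     seed_owner = NA_character_) {
  utr <- normalize_dna(utr_sequence)
  if (nchar(utr) == 0L) stop("empty UTR sequence")
  site <- normalize_dna(target_site_of(seed))
  m <- Biostrings::matchPattern(site, Biostrings::DNAString(utr))
  pos <- BiocGenerics::start(m) - 1L
  data.frame(gene_id = rep(gene_id, length(pos)),
             utr_position = pos,
             site_sequence = rep(site, length(pos)),
             seed_owner = rep(seed_owner, length(pos)),
             stringsAsFactors = FALSE)
}

#' Scan a set of 3'UTRs for canonical and/or isomiR seed sites
#'
#' @param utrs named character vector of UTR sequences.
#' @param seeds named character vector of 7-mer seeds; names become the
#'   \code{seed_owner} labels.
#' @return data.frame of seed matches (see \code{\link{scan_utr}}).
#' @export
scan_utrs <- function(utrs, seeds) {
  stopifnot(length(names(utrs)) == length(utrs),
            length(names(seeds)) == length(seeds))
  out <- list()
  for (owner in names(seeds)) {
    for (g in names(utrs)) {
      hit <- scan_utr(utrs[[g]], seeds[[owner]], gene_id = g,
                      seed_owner = owner)
      if (nrow(hit)) out[[length(out) + 1L]] <- hit
    }
  }
  if (length(out) == 0L) {
    return(data.frame(gene_id = character(), utr_position = integer(),
                      site_sequence = character(), seed_owner = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Criteria for calling a highly expressed miRNA/5'isomiR pair
#'
#' Defaults: mean canonical expression of at least 100 rpm and a mean
#' isomiR:canonical ratio of at least 1:5, with the 5'isomiR at offset +1.
#'
#' @param min_canonical_mean_rpm minimum mean canonical rpm (default 100).
#' @param min_ratio minimum isomiR/canonical ratio of means (default 0.2).
#' @param isomir_offset 5' offset defining the isomiR key (default +1).
#' @return object of class \code{pair_criteria}.
#' @export
pair_criteria <- function(min_canonical_mean_rpm = 100,
                          min_ratio = 0.2, isomir_offset = 1L) {
  stopifnot(min_canonical_mean_rpm > 0, min_ratio > 0)
  structure(list(min_canonical_mean_rpm = min_canonical_mean_rpm,
                 min_ratio = min_ratio,
                 isomir_offset = as.integer(isomir_offset)),
            class = "pair_criteria")
}

#' Detect highly expressed miRNA/5'isomiR pairs in an rpm matrix
#'
#' For every miRNA carrying both an offset-0 key and an isomiR-offset key,
#' computes the per-sample-mean expressions and their ratio
#' (ratio of means, isomiR / canonical) and flags the pair as passing when
#' both criteria hold.  Both passing and failing candidates are returned.
#'
#' @param x an \code{isomir_matrix} or a tidy rpm data.frame
#'   (\code{mirna_name}, \code{offset5}, one column per sample).
#' @param criteria a \code{\link{pair_criteria}} object.
#' @return data.frame with one row per candidate pair: \code{mirna_name},
#'   \code{canonical_mean_rpm}, \code{isomir_mean_rpm}, \code{ratio},
#'   \code{passes}; per-sample rpm vectors are attached as the
#'   \code{"per_sample"} attribute.
#' @export
detect_pairs <- function(x, criteria = pair_criteria()) {
  stopifnot(inherits(criteria, "pair_criteria"))
  if (inherits(x, "isomir_matrix")) x <- as_rpm_table(x)
  sample_cols <- setdiff(names(x), c("mirna_name", "offset5", "seed"))
  if (length(sample_cols) == 0L) stop("rpm matrix has no sample columns")
  canon <- x[x$offset5 == 0L, , drop = FALSE]
  iso <- x[x$offset5 == criteria$isomir_offset, , drop = FALSE]
  shared <- sort(intersect(canon$mirna_name, iso$mirna_name))
  res <- list(); per_sample <- list()
  for (m in shared) {
    cv <- as.numeric(canon[canon$mirna_name == m, sample_cols][1, ])
    iv <- as.numeric(iso[iso$mirna_name == m, sample_cols][1, ])
    cm <- mean(cv); im <- mean(iv)
    ratio <- im / cm
    res[[m]] <- data.frame(
      mirna_name = m, canonical_mean_rpm = cm, isomir_mean_rpm = im,
      ratio = ratio,
      passes = cm >= criteria$min_canonical_mean_rpm &
        ratio >= criteria$min_ratio,
      stringsAsFactors = FALSE)
    per_sample[[m]] <- list(canonical = stats::setNames(cv, sample_cols),
                            isomir = stats::setNames(iv, sample_cols))
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(mirna_name = character(), canonical_mean_rpm = numeric(),
               isomir_mean_rpm = numeric(), ratio = numeric(),
               passes = logical())
  rownames(out) <- NULL
  attr(out, "per_sample") <- per_sample
  out
}

#' Seed-site enrichment among downregulated genes
#'
#' Tests whether genes downregulated by a miRNA species are enriched for
#' genes whose 3'UTR carries at least one exact seed-match site, via a
#' one-sided Fisher exact test on the 2x2 table
#' (downregulated vs rest of background) x (has site vs not).  The
#' background is the gene universe and must contain the downregulated set.
#'
#' @param downregulated_genes character vector of downregulated gene ids.
#' @param background_genes character vector of background gene ids
#'   (including the downregulated ones).
#' @param seed 7-mer seed.
#' @param utrs named character vector of 3'UTR sequences; background genes
#'   without a UTR are dropped with a warning.
#' @return list with \code{odds_ratio}, \code{p_value},
#'   \code{contingency_table} (2x2), \code{n_dropped}.
#' @export
enrichment_test <- function(downregulated_genes, background_genes, seed,
                            utrs) {
  if (length(downregulated_genes) == 0L) {
    stop("empty downregulated gene set")
  }
  if (!all(downregulated_genes %in% background_genes)) {
    stop("downregulated genes must be a subset of the background")
  }
  missing_utr <- setdiff(background_genes, names(utrs))
  if (length(missing_utr)) {
    warning(length(missing_utr), " background gene(s) without UTR dropped")
    background_genes <- setdiff(background_genes, missing_utr)
    downregulated_genes <- setdiff(downregulated_genes, missing_utr)
    if (length(downregulated_genes) == 0L) {
      stop("no downregulated gene retains a UTR")
    }
  }
  site <- normalize_dna(target_site_of(seed))
  has_site <- vapply(background_genes, function(g)
    grepl(site, normalize_dna(utrs[[g]]), fixed = TRUE), logical(1))
  is_down <- background_genes %in% downregulated_genes
  tab <- matrix(c(sum(is_down & has_site), sum(is_down & !has_site),
                  sum(!is_down & has_site), sum(!is_down & !has_site)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("downregulated", "background_only"),
                                c("has_site", "no_site")))
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value,
       contingency_table = tab, n_dropped = length(missing_utr))
}

#' Load the bundled breast cell-line panel rpm fixture
#'
#' Expression (rpm) of six highly expressed miRNA/5'isomiR pairs (twelve
#' isoform rows) across eight breast cell lines, from the public small
#' RNA-seq panel deposited as ArrayExpress E-MTAB-4539.  Ships with the
#' package so the headline pair-detection example runs without downloads.
#'
#' @return data.frame with \code{mirna_name}, \code{offset5}, \code{seed}
#'   and eight cell-line rpm columns.
#' @export
cellline_panel_rpm <- function() {
  path <- system.file("extdata", "cellline_panel_rpm.tsv",
                      package = "isomirpair", mustWork = TRUE)
  read_matrix_tsv(path)
}
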