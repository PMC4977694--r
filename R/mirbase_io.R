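# Readers and writers for the reference / read / table formats the pipeline
# touches.  Internal coordinate convention is 0-based half-open everywhere;
# conversion to/from the GFF3 1-based inclusive convention happens only at
# file boundaries.  Sequences are stored as uppercase DNA (U -> T on input).

#' Normalize a nucleotide sequence to uppercase DNA
#'
#' miRBase mixes RNA (U) and DNA (T) alphabets; internally everything is DNA.
#'
#' @param x character vector of sequences.
#' @return character vector, uppercased with U replaced by T.
#' @export
normalize_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Render a DNA sequence as RNA for human-facing reports
#' @param x character vector of DNA sequences.
#' @return character vector with T replaced by U.
#' @export
as_rna <- function(x) chartr("T", "U", toupper(x))

.check_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside ACGT/U: %s",
                 what, paste(utils::head(x[bad], 3), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Read a precursor (hairpin) FASTA file
#'
#' The first whitespace-separated token of each header is taken as the
#' precursor id (miRBase hairpin headers carry accession fields after it).
#' Sequences are normalized to uppercase DNA.
#'
#' @param path path to a FASTA file.
#' @param min_length minimum accepted precursor length (default 40).
#' @return data.frame with columns \code{id}, \code{sequence}.
#' @export
read_precursor_fasta <- function(path, min_length = 40L) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
  seqs <- normalize_dna(as.character(set))
  if (anyDuplicated(ids)) {
    stop("duplicate precursor id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  .check_alphabet(seqs, "precursor sequence")
  short <- nchar(seqs) < min_length
  if (any(short)) {
    stop("precursor(s) shorter than ", min_length, " nt: ",
         paste(ids[short], collapse = ", "))
  }
  data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
}

#' Write precursors to FASTA
#' @param precursors data.frame with \code{id}, \code{sequence}.
#' @param path output path.
#' @export
write_precursor_fasta <- function(precursors, path) {
  set <- Biostrings::DNAStringSet(precursors$sequence)
  names(set) <- precursors$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Convert GFF3 coordinates (1-based inclusive) to internal (0-based half-open)
#' @param start,end integer vectors of GFF3 coordinates.
#' @return data.frame with columns \code{start}, \code{end} in the internal
#'   convention.
#' @export
gff3_to_internal <- function(start, end) {
  data.frame(start = as.integer(start) - 1L, end = as.integer(end))
}

#' Convert internal coordinates (0-based half-open) to GFF3 (1-based inclusive)
#' @param start,end integer vectors of internal coordinates.
#' @return data.frame with columns \code{start}, \code{end} in GFF3 convention.
#' @export
internal_to_gff3 <- function(start, end) {
  data.frame(start = as.integer(start) + 1L, end = as.integer(end))
}

.validate_annotations <- function(ann, precursors) {
  prec_seq <- stats::setNames(precursors$sequence, precursors$id)
  unknown <- setdiff(ann$precursor_id, names(prec_seq))
  if (length(unknown)) {
    stop("annotation references unknown precursor id(s): ",
         paste(unknown, collapse = ", "))
  }
  plen <- nchar(prec_seq[ann$precursor_id])
  bad <- ann$start < 0L | ann$start >= ann$end | ann$end > plen
  if (any(bad)) {
    stop("annotation coordinates out of range for: ",
         paste(ann$mirna_name[bad], collapse = ", "))
  }
  len <- ann$end - ann$start
  if (any(len < 18L | len > 26L)) {
    stop("mature length outside 18-26 nt for: ",
         paste(ann$mirna_name[len < 18L | len > 26L], collapse = ", "))
  }
  extracted <- substring(prec_seq[ann$precursor_id], ann$start + 1L, ann$end)
  if (!is.null(ann$sequence) && any(!is.na(ann$sequence))) {
    given <- normalize_dna(ann$sequence)
    mism <- !is.na(given) & given != extracted
    if (any(mism)) {
      stop("annotated sequence does not match the precursor substring for: ",
           paste(ann$mirna_name[mism], collapse = ", "))
    }
  }
  ann$sequence <- unname(extracted)
  ann[order(ann$precursor_id, ann$start), c("mirna_name", "precursor_id",
                                            "start", "end", "sequence")]
}

#' Read mature miRNA annotations (GFF3 or TSV)
#'
#' GFF3 input follows the miRBase layout: \code{miRNA} feature rows on
#' precursor seqids, 1-based inclusive coordinates, \code{Name} attribute
#' carrying the mature name.  The TSV fallback has columns
#' \code{mirna_name}, \code{precursor_id}, \code{start}, \code{end}
#' (0-based half-open) and optionally \code{sequence}, which is then checked
#' against the precursor substring.
#'
#' @param path path to a GFF3 (.gff/.gff3) or TSV file.
#' @param precursors data.frame from \code{\link{read_precursor_fasta}}.
#' @param format "auto" (by extension), "gff3" or "tsv".
#' @return data.frame with columns \code{mirna_name}, \code{precursor_id},
#'   \code{start}, \code{end} (0-based half-open) and \code{sequence} filled
#'   from the precursor.
#' @export
read_mature_annotations <- function(path, precursors,
                                    format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "gff3") {
    g <- rtracklayer::import(path)
    g <- g[as.character(g$type) == "miRNA"]
    nm <- if (!is.null(g$Name)) as.character(g$Name) else as.character(g$ID)
    conv <- gff3_to_internal(GenomicRanges::start(g), GenomicRanges::end(g))
    ann <- data.frame(mirna_name = nm,
                      precursor_id = as.character(GenomicRanges::seqnames(g)),
                      start = conv$start, end = conv$end,
                      sequence = NA_character_, stringsAsFactors = FALSE)
  } else {
    ann <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("mirna_name", "precursor_id", "start", "end")
    miss <- setdiff(need, names(ann))
    if (length(miss)) stop("TSV annotation lacks column(s): ",
                           paste(miss, collapse = ", "))
    if (is.null(ann$sequence)) ann$sequence <- NA_character_
    ann$start <- as.integer(ann$start)
    ann$end <- as.integer(ann$end)
  }
  .validate_annotations(ann, precursors)
}

#' Write mature annotations as GFF3 (1-based inclusive)
#' @param annotations data.frame in the internal annotation layout.
#' @param path output path.
#' @export
write_mature_gff3 <- function(annotations, path) {
  conv <- internal_to_gff3(annotations$start, annotations$end)
  rows <- sprintf("%s\t.\tmiRNA\t%d\t%d\t.\t+\t.\tName=%s",
                  annotations$precursor_id, conv$start, conv$end,
                  annotations$mirna_name)
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Write mature annotations as TSV (0-based half-open)
#' @param annotations data.frame in the internal annotation layout.
#' @param path output path.
#' @export
write_mature_tsv <- function(annotations, path) {
  utils::write.table(
    annotations[, c("mirna_name", "precursor_id", "start", "end", "sequence")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Standard 4-line records; gzip input is accepted transparently.  Each
#' record is validated: sequence and quality must have equal length and a
#' truncated trailing record is an error naming the record index.
#'
#' @param path path to a FASTQ or FASTQ.gz file.
#' @return data.frame with columns \code{id}, \code{sequence}, \code{quality}.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  if (n %% 4L != 0L) {
    stop(sprintf("truncated FASTQ record %d in %s", n %/% 4L + 1L, path))
  }
  hdr <- lines[seq(1L, n, 4L)]
  seqs <- lines[seq(2L, n, 4L)]
  plus <- lines[seq(3L, n, 4L)]
  qual <- lines[seq(4L, n, 4L)]
  bad <- !startsWith(hdr, "@") | !startsWith(plus, "+")
  if (any(bad)) {
    stop(sprintf("malformed FASTQ record %d in %s", which(bad)[1], path))
  }
  mism <- nchar(seqs) != nchar(qual)
  if (any(mism)) {
    stop(sprintf("sequence/quality length mismatch in FASTQ record %d of %s",
                 which(mism)[1], path))
  }
  if (any(nchar(seqs) < 1L)) {
    stop("empty sequence in FASTQ record ", which(nchar(seqs) < 1L)[1])
  }
  data.frame(id = sub("^@", "", sub("[ \t].*$", "", hdr)),
             sequence = toupper(seqs), quality = qual,
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#' @param reads data.frame with \code{id}, \code{sequence} and optionally
#'   \code{quality} (defaults to "I" per base).
#' @param path output path; a ".gz" suffix triggers gzip compression.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$quality
  if (is.null(qual)) {
    qual <- vapply(nchar(reads$sequence),
                   function(n) strrep("I", n), character(1))
  }
  stopifnot(all(nchar(qual) == nchar(reads$sequence)))
  out <- as.vector(rbind(paste0("@", reads$id), reads$sequence, "+", qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Read a 3'UTR FASTA file
#' @param path path to a FASTA file of 3'UTR sequences; the first header
#'   token is taken as the gene id.
#' @return named character vector of uppercase DNA sequences.
#' @export
read_utr_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate UTR id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- normalize_dna(as.character(set))
  .check_alphabet(seqs, "UTR sequence")
  stats::setNames(seqs, ids)
}
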