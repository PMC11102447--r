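ANCHOR_GUIDE <- "CCCGAGTCGCGATAA"
ANCHOR_SEG <- "TACCGTTCGTATAGG"

#' Read layout for simulated amplicon sequencing
#'
#' @param read_length length of each read in nt.
#' @param barcode_length barcode length (20 nt by design).
#' @param error_rate per-base substitution error rate.
#' @param quality_char quality symbol used for every base (default `"F"`,
#'   phred 37).
#' @return list of class `read_layout`.
#' @export
read_layout <- function(read_length = 50, barcode_length = 20,
                        error_rate = 0, quality_char = "F") {
  if (read_length < barcode_length + nchar(ANCHOR_GUIDE)) {
    stop("read shorter than barcode + anchor")
  }
  structure(list(read_length = read_length,
                 barcode_length = barcode_length,
                 error_rate = error_rate, quality_char = quality_char),
            class = "read_layout")
}

.mutate_seqs <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n <- nchar(seqs[1])
  chars <- c("A", "C", "G", "T")
  mat <- matrix(unlist(strsplit(seqs, "")), nrow = length(seqs),
                byrow = TRUE)
  hit <- which(matrix(stats::runif(length(mat)) < rate, nrow = nrow(mat)))
  if (length(hit)) {
    old <- mat[hit]
    mat[hit] <- vapply(old, function(b) sample(setdiff(chars, b), 1),
                       character(1))
  }
  apply(mat, 1, paste, collapse = "")
}

#' Emit paired reads for a count table
#'
#' One read pair per counted molecule: the forward read carries the guide
#' barcode immediately upstream of the `CCCGAGTCGCGATAA` anchor, the reverse
#' read carries the segregant barcode immediately upstream of
#' `TACCGTTCGTATAGG`. Remaining positions are filled with a fixed pad so
#' that extraction depends only on barcode + anchor.
#'
#' @param counts a `lineage_counts` object (integer counts).
#' @param layout a [read_layout()].
#' @param timepoint which time point column to emit (1-based index).
#' @param seed integer seed (used when `error_rate > 0`).
#' @return list with character vectors `fwd`, `rev`, `fwd_qual`, `rev_qual`
#'   and the emitting `lineage_id` per read pair.
#' @export
emit_reads <- function(counts, layout = read_layout(), timepoint = 1,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cm <- count_matrix(counts)
  n <- round(cm[, timepoint])
  idx <- rep(seq_len(nrow(counts)), n)
  pad <- function(core) {
    fill <- layout$read_length - nchar(core[1])
    if (fill > 0) paste0(core, strrep("A", fill)) else core
  }
  fwd <- pad(paste0(counts$guide_bc[idx], ANCHOR_GUIDE))
  rev <- pad(paste0(counts$seg_bc[idx], ANCHOR_SEG))
  fwd <- .mutate_seqs(fwd, layout$error_rate)
  rev <- .mutate_seqs(rev, layout$error_rate)
  qual <- strrep(layout$quality_char, layout$read_length)
  list(fwd = fwd, rev = rev,
       fwd_qual = rep(qual, length(fwd)), rev_qual = rep(qual, length(rev)),
       lineage_id = counts$lineage_id[idx])
}

#' Write paired reads to FASTQ files
#'
#' @param reads list from [emit_reads()].
#' @param prefix output path prefix; files `<prefix>_R1.fastq[.gz]` and
#'   `<prefix>_R2.fastq[.gz]` are written.
#' @param gzip compress output.
#' @return invisibly, the two file paths.
#' @export
write_fastq_pair <- function(reads, prefix, gzip = FALSE) {
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- paste0(prefix, c("_R1", "_R2"), ext)
  ids <- sprintf("@read%06d", seq_along(reads$fwd))
  for (i in 1:2) {
    seqs <- if (i == 1) reads$fwd else reads$rev
    quals <- if (i == 1) reads$fwd_qual else reads$rev_qual
    con <- if (gzip) gzfile(paths[i], "w") else file(paths[i], "w")
    writeLines(paste(ids, seqs, "+", quals, sep = "\n"), con)
    close(con)
  }
  invisible(paths)
}

#' Read a FASTQ file into sequences and quality strings
#'
#' @param path FASTQ file (gzip ok).
#' @return list with character vectors `seq` and `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  list(seq = as.character(x),
       qual = as.character(S4Vectors::mcols(x)$qualities))
}

#' Number of distinct unique molecular identifiers of a given length
#'
#' Library preparation tags each fragment with two random 4-mers, i.e. an
#' 8-nt UMI with 4^8 = 65,536 possible sequences.
#'
#' @param length UMI length in nt.
#' @return number of distinct UMI sequences.
#' @export
umi_diversity <- function(length = 8) 4^length
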