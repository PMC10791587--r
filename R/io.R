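# Readers and writers for the plain-text formats used across the workflow:
# TSV or MatrixMarket count matrices with a TSV sample sheet, BED-like
# 3-column interval files (0-based half-open), binding-site tables, FASTA
# mature sequences.

#' Read a count matrix and its sample sheet
#'
#' Counts come either from a TSV (features as rows, first column
#' `feature_id`, one column per sample) or from a MatrixMarket triplet file
#' (`.mtx`), in which case a companion file `<path>.features` must list the
#' feature ids (one per line) and columns are taken in sample-sheet order.
#'
#' When a feature annotation is supplied, features whose
#' `is_first_paralog` is `FALSE` are dropped at load, before normalization:
#' only the first paralog of a mature sequence enters the analysis, and the
#' ordering that defines "first" comes from the annotation, not from this
#' function.
#'
#' @param path counts file (TSV or `.mtx`).
#' @param sample_sheet TSV with the sample-sheet columns (see
#'   [count_matrix()]).
#' @param annotation optional feature annotation `data.frame` with columns
#'   `feature_id` and `is_first_paralog`.
#' @return `count_matrix` with rpmm normalization applied.
#' @export
read_count_matrix <- function(path, sample_sheet, annotation = NULL) {
  samples <- utils::read.delim(sample_sheet, stringsAsFactors = FALSE)
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    feats <- readLines(paste0(path, ".features"))
    if (length(feats) != nrow(m)) {
      stop("feature list length does not match matrix rows")
    }
    rownames(m) <- feats
    if (ncol(m) != nrow(samples)) {
      stop("MatrixMarket columns do not match sample sheet rows")
    }
    colnames(m) <- samples$sample_id
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
  }
  storage.mode(m) <- "double"
  if (!is.null(annotation)) {
    ann <- annotation[match(rownames(m), annotation$feature_id), ]
    drop <- !is.na(ann$is_first_paralog) & !ann$is_first_paralog
    if (any(drop)) {
      message(sprintf("dropping %d non-first paralog feature(s)", sum(drop)))
      m <- m[!drop, , drop = FALSE]
    }
  }
  count_matrix(m, samples)
}

#' Write a count matrix and its sample sheet
#'
#' @param cm `count_matrix`.
#' @param path output TSV for counts.
#' @param sheet_path output TSV for the sample sheet.
#' @return invisibly, `cm`.
#' @export
write_count_matrix <- function(cm, path, sheet_path) {
  tab <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cm$samples, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(cm)
}

#' Read a BED-like interval file
#'
#' Three whitespace-separated columns: feature id, start, end; coordinates
#' are 0-based, half-open (BED convention). Input need not be sorted.
#'
#' @param path interval file.
#' @return named list mapping feature id to a 2-column matrix
#'   (`start`, `end`).
#' @export
read_intervals <- function(path) {
  tab <- utils::read.table(path, col.names = c("feature_id", "start", "end"),
                           stringsAsFactors = FALSE)
  bad <- which(tab$end <= tab$start)
  if (length(bad)) {
    stop(sprintf("empty or inverted interval at line %d: %s %d %d",
                 bad[1], tab$feature_id[bad[1]], tab$start[bad[1]],
                 tab$end[bad[1]]))
  }
  out <- lapply(split(tab[c("start", "end")], tab$feature_id), as.matrix)
  out
}

#' Write an interval map to a BED-like file
#' @param intervals named list as returned by [read_intervals()].
#' @param path output file.
#' @export
write_intervals <- function(intervals, path) {
  rows <- do.call(rbind, lapply(names(intervals), function(f) {
    iv <- intervals[[f]]
    data.frame(feature_id = f, start = iv[, 1], end = iv[, 2])
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(intervals)
}

SITE_TYPES <- c("8mer", "7mer-m8", "7mer-1a")

#' Read a conserved binding-site table
#'
#' TSV with named columns `mirna`, `gene`, `site_type`, `conserved`.
#' Site types are normalized case-insensitively; `"7mer-8m"` is accepted as
#' an alias of `7mer-m8`. Duplicate rows are retained (a gene can carry
#' multiple sites, and multiplicity matters for counting).
#'
#' @param path TSV file.
#' @return data.frame with normalized `site_type` and logical `conserved`.
#' @export
read_site_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna", "gene", "site_type", "conserved")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("site table missing column(s): ",
                         paste(miss, collapse = ", "))
  tab$site_type <- normalize_site_type(tab$site_type)
  tab$conserved <- as.logical(tab$conserved)
  tab
}

normalize_site_type <- function(x) {
  y <- tolower(x)
  y[y == "7mer-8m"] <- "7mer-m8"
  bad <- !(y %in% SITE_TYPES)
  if (any(bad)) stop("unknown site type: ", unique(x[bad])[1])
  y
}

#' Read mature RNA sequences from FASTA
#'
#' Thin wrapper around Biostrings; `T` is converted to `U` so DNA-alphabet
#' FASTA files are accepted.
#'
#' @param path FASTA file.
#' @return named character vector of RNA sequences.
#' @export
read_mature_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required to read FASTA files")
  }
  seqs <- Biostrings::readBStringSet(path)
  out <- chartr("t", "u", chartr("T", "U", toupper(as.character(seqs))))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}
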