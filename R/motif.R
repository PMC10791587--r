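# IUPAC motif scanning of mature miRNA sequences, e.g. the EV-sorting
# EXOmotif CNGGNC, with an allowed mismatch budget.

IUPAC_RNA <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

#' Scan a sequence for an IUPAC motif
#'
#' Reports every offset where the number of positions violating the
#' motif's IUPAC character class is at most `max_mismatch`. DNA input (T)
#' is transparently converted to RNA (U). Hits are sorted by (mismatches,
#' position). No reverse-complement scanning: mature miRNAs are
#' single-stranded.
#'
#' @param sequence RNA (or DNA) string.
#' @param motif IUPAC RNA string (N matches anything; full IUPAC table).
#' @param max_mismatch allowed mismatches (default 0).
#' @return data.frame (position 0-based, mismatches, matched_substring);
#'   zero rows when nothing matches or the sequence is shorter than the
#'   motif.
#' @export
scan_motif <- function(sequence, motif, max_mismatch = 0) {
  seq_u <- chartr("Tt", "Uu", toupper(sequence))
  motif_u <- chartr("Tt", "Uu", toupper(motif))
  mchars <- strsplit(motif_u, "")[[1]]
  bad <- setdiff(mchars, names(IUPAC_RNA))
  if (length(bad)) stop("invalid IUPAC symbol in motif: ", bad[1])
  schars <- strsplit(seq_u, "")[[1]]
  bad_s <- setdiff(schars, c(names(IUPAC_RNA), ""))
  if (length(bad_s)) stop("invalid sequence character: ", bad_s[1])
  k <- length(mchars)
  n <- length(schars)
  if (n < k || k == 0) {
    return(data.frame(position = integer(), mismatches = integer(),
                      matched_substring = character(),
                      stringsAsFactors = FALSE))
  }
  hits <- lapply(0:(n - k), function(pos) {
    window <- schars[pos + seq_len(k)]
    mm <- sum(vapply(seq_len(k), function(i) {
      !(window[i] %in% IUPAC_RNA[[mchars[i]]])
    }, logical(1)))
    if (mm <= max_mismatch) {
      data.frame(position = pos, mismatches = mm,
                 matched_substring = paste(window, collapse = ""),
                 stringsAsFactors = FALSE)
    }
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) {
    return(data.frame(position = integer(), mismatches = integer(),
                      matched_substring = character(),
                      stringsAsFactors = FALSE))
  }
  hits[order(hits$mismatches, hits$position), , drop = FALSE]
}

#' Scan many sequences for a motif
#'
#' @param sequences named character vector (e.g. from
#'   [read_mature_fasta()]).
#' @param motif IUPAC motif.
#' @param max_mismatch allowed mismatches.
#' @return data.frame (feature_id, position, mismatches,
#'   matched_substring).
#' @export
scan_motif_set <- function(sequences, motif, max_mismatch = 0) {
  out <- lapply(names(sequences), function(f) {
    h <- scan_motif(sequences[[f]], motif, max_mismatch)
    if (nrow(h)) cbind(feature_id = f, h, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(feature_id = character(), position = integer(),
                      mismatches = integer(),
                      matched_substring = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
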