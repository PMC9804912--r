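# Alignment handling and per-column conservation scoring.

# Amino-acid exchange groups used by the similarity-class scoring mode.
EXCHANGE_GROUPS <- list(
  c("A", "V", "L", "I", "M"),
  c("F", "Y", "W"),
  c("S", "T"),
  c("D", "E"),
  c("N", "Q"),
  c("K", "R"),
  "C", "H", "G", "P"
)

GAP_CHARS <- c("-", ".")

#' Read a multiple sequence alignment
#'
#' Reads an alignment of amino-acid sequences from a FASTA or Clustal file.
#' All records must have equal (gapped) length; record order is preserved.
#' Record ids are the first whitespace-delimited token of each header.
#'
#' @param path Path to the alignment file.
#' @param format Either `"fasta"` or `"clustal"`.
#' @return An object of class `aa_alignment`: a list with elements `ids`
#'   (character), `seqs` (named character vector of gapped sequences, upper
#'   case) and `n_columns`.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (file.size(path) == 0L) stop("empty alignment file: ", path)
  if (format == "fasta") {
    seqs <- Biostrings::readBStringSet(path)
    if (length(seqs) == 0L) stop("empty alignment: no records in ", path)
    if (length(unique(Biostrings::width(seqs))) > 1L)
      stop("malformed alignment: records differ in length")
    chr <- as.character(seqs)
  } else {
    chr <- parse_clustal(path)
  }
  ids <- sub("\\s.*$", "", names(chr))
  if (any(ids == "") || anyDuplicated(ids))
    stop("record ids must be non-empty and unique")
  new_alignment(ids, toupper(unname(chr)))
}

#' Construct an alignment object from sequences in memory
#'
#' @param ids Character vector of unique record ids.
#' @param seqs Character vector of equal-length gapped sequences.
#' @return An `aa_alignment` object.
#' @export
new_alignment <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs), !anyDuplicated(ids))
  if (length(unique(nchar(seqs))) > 1L)
    stop("malformed alignment: records differ in length")
  seqs <- toupper(seqs)
  names(seqs) <- ids
  structure(list(ids = ids, seqs = seqs, n_columns = nchar(seqs[[1L]])),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("aa_alignment:", length(x$ids), "records x", x$n_columns, "columns\n")
  invisible(x)
}

# Clustal block format: header line, then "<id> <chunk>" rows repeated per
# block; consensus rows (leading whitespace, only * : . symbols) skipped.
parse_clustal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^CLUSTAL", lines[1L], ignore.case = TRUE))
    stop("malformed clustal alignment: missing CLUSTAL header")
  ids <- character()
  seqs <- list()
  for (ln in lines[-1L]) {
    if (grepl("^[[:space:].:*]*$", ln)) next    # blank or consensus row
    m <- regmatches(ln, regexec(
      "^(\\S+)[[:blank:]]+([A-Za-z.~-]+)([[:blank:]]+[0-9]+)?[[:blank:]]*$",
      ln))[[1L]]
    if (length(m) == 0L)
      stop("malformed clustal alignment: cannot parse line: ", ln)
    id <- m[2L]
    if (!id %in% ids) {
      ids <- c(ids, id)
      seqs[[id]] <- ""
    }
    seqs[[id]] <- paste0(seqs[[id]], m[3L])
  }
  if (length(ids) == 0L) stop("empty alignment: no records in ", path)
  out <- unlist(seqs[ids])
  if (length(unique(nchar(out))) > 1L)
    stop("malformed alignment: records differ in length")
  chartr("~.", "--", out)
}

# gapped sequence -> character matrix (records x columns)
aln_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln$seqs), "", fixed = TRUE))
}

ungap <- function(seq) gsub("[-.]", "", seq)

#' Per-residue conservation profile of a reference sequence
#'
#' Scores each non-gap position of the reference sequence by the frequency of
#' its amino acid (or exchange group, in similarity mode) among the non-gap
#' symbols of the alignment column, multiplied by the column's non-gap
#' fraction so that sparse columns cannot score as conserved. Scores are
#' binned into conservation grades 1..9 (9 = most conserved).
#'
#' @param aln An `aa_alignment`.
#' @param ref_id Id of the reference record; positions are numbered 1-based
#'   along its ungapped sequence.
#' @param mode `"identity"` (frequency of the reference letter) or
#'   `"similarity"` (frequency of the reference letter's exchange group:
#'   AVLIM, FYW, ST, DE, NQ, KR, and singleton C, H, G, P).
#' @param binning `"interval"` (default; grade = 1 + floor(9*score), capped
#'   at 9, so grade 9 requires score >= 8/9) or `"quantile"` (9-quantile
#'   binning of the observed scores).
#' @param max_gap_frac Columns with a gap fraction above this are flagged
#'   low-confidence (default 0.5).
#' @return A `conservation_profile`: a data frame with columns `position`,
#'   `aa`, `score`, `grade`, `gap_fraction`, `low_confidence`, `column`
#'   (alignment column index), and attributes `ref_id` and `mode`.
#' @export
compute_conservation <- function(aln, ref_id,
                                 mode = c("identity", "similarity"),
                                 binning = c("interval", "quantile"),
                                 max_gap_frac = 0.5) {
  mode <- match.arg(mode)
  binning <- match.arg(binning)
  if (!ref_id %in% aln$ids) stop("unknown reference id: ", ref_id)
  m <- aln_matrix(aln)
  ref <- m[match(ref_id, aln$ids), ]
  cols <- which(!ref %in% GAP_CHARS)
  n <- nrow(m)
  score <- gap_frac <- numeric(length(cols))
  for (k in seq_along(cols)) {
    col <- m[, cols[k]]
    is_gap <- col %in% GAP_CHARS
    n_nongap <- sum(!is_gap)
    gap_frac[k] <- 1 - n_nongap / n
    target <- ref[cols[k]]
    if (mode == "similarity") {
      grp <- Find(function(g) target %in% g, EXCHANGE_GROUPS)
      if (!is.null(grp)) target <- grp
    }
    score[k] <- if (n_nongap == 0L) 0 else
      sum(col[!is_gap] %in% target) / n_nongap * (n_nongap / n)
  }
  grade <- if (binning == "interval") {
    pmin(9L, 1L + as.integer(floor(score * 9)))
  } else {
    br <- unique(quantile(score, probs = seq(0, 1, by = 1 / 9), names = FALSE))
    if (length(br) < 2L) rep(9L, length(score)) else
      as.integer(cut(score, breaks = br, include.lowest = TRUE,
                     labels = FALSE)) + (9L - (length(br) - 1L))
  }
  out <- data.frame(position = seq_along(cols), aa = ref[cols],
                    score = score, grade = grade, gap_fraction = gap_frac,
                    low_confidence = gap_frac > max_gap_frac,
                    column = cols, stringsAsFactors = FALSE)
  attr(out, "ref_id") <- ref_id
  attr(out, "mode") <- mode
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Map a residue position between aligned sequences
#'
#' Returns the 1-based residue index of `to_id` occupying the same alignment
#' column as residue `pos` of `from_id`, or `NA` if that column is a gap in
#' `to_id`.
#'
#' @param aln An `aa_alignment`.
#' @param from_id,to_id Record ids.
#' @param pos 1-based residue index along the ungapped `from_id` sequence.
#' @return Integer position in `to_id`, or `NA_integer_` for a gap.
#' @export
map_position <- function(aln, from_id, pos, to_id) {
  for (id in c(from_id, to_id))
    if (!id %in% aln$ids) stop("unknown record id: ", id)
  from <- strsplit(aln$seqs[[from_id]], "", fixed = TRUE)[[1L]]
  to <- strsplit(aln$seqs[[to_id]], "", fixed = TRUE)[[1L]]
  from_idx <- cumsum(!from %in% GAP_CHARS)
  n_res <- from_idx[length(from_idx)]
  if (!is.numeric(pos) || pos < 1 || pos > n_res)
    stop("position ", pos, " out of range for ", from_id,
         " (ungapped length ", n_res, ")")
  col <- which(from_idx == pos & !from %in% GAP_CHARS)[1L]
  if (to[col] %in% GAP_CHARS) return(NA_integer_)
  as.integer(sum(!to[seq_len(col)] %in% GAP_CHARS))
}

#' Conserved residues of a given type
#'
#' @param profile A `conservation_profile`.
#' @param aa_set Character vector of one-letter amino-acid codes.
#' @param min_grade Minimum conservation grade (1..9).
#' @return Data frame with columns `position`, `aa`, `grade`, ascending by
#'   position.
#' @export
conserved_residues <- function(profile, aa_set, min_grade = 7L) {
  stopifnot(min_grade >= 1, min_grade <= 9)
  keep <- profile$aa %in% aa_set & profile$grade >= min_grade
  out <- profile[keep, c("position", "aa", "grade")]
  rownames(out) <- NULL
  out[order(out$position), , drop = FALSE]
}

#' Write a conservation profile as a tab-separated table
#'
#' @param profile A `conservation_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conservation <- function(profile, path) {
  write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
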