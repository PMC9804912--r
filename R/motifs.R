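# Local sequence-motif scanning: literal motifs, C2H2 zinc fingers, and
# ligand-column mapping through an alignment.

#' Locate all occurrences of a literal motif
#'
#' Finds every (possibly overlapping) occurrence of `motif` in `seq`.
#'
#' @param seq Amino-acid string.
#' @param motif Non-empty literal motif string.
#' @return Data frame with columns `pattern_id`, `start`, `end` (1-based
#'   inclusive), `matched_text`, ascending by `start`. Zero rows when the
#'   motif is absent.
#' @export
scan_literal <- function(seq, motif) {
  stopifnot(is.character(motif), nchar(motif) >= 1L)
  seq <- toupper(seq); motif <- toupper(motif)
  n <- nchar(seq); m <- nchar(motif)
  starts <- integer()
  if (n >= m)
    starts <- which(vapply(seq_len(n - m + 1L), function(i)
      substr(seq, i, i + m - 1L) == motif, logical(1)))
  data.frame(pattern_id = rep(motif, length(starts)), start = starts,
             end = starts + m - 1L,
             matched_text = rep(motif, length(starts)),
             stringsAsFactors = FALSE)
}

C2H2_HYDRO <- c("L", "I", "V", "M", "F", "Y", "W", "C")

# Try to match the C2H2 pattern C-x(2,4)-C-x(3)-[LIVMFYWC]-x(8)-H-x(3,5)-H
# anchored at position i; leftmost-shortest (smallest x1, then x2).
# Returns the ligand positions (c1, c2, h1, h2) or NULL.
c2h2_at <- function(chars, i) {
  n <- length(chars)
  if (chars[i] != "C") return(NULL)
  for (x1 in 2:4) {
    p1 <- i + x1 + 1L
    if (p1 > n || chars[p1] != "C") next
    p2 <- p1 + 4L                      # hydrophobic anchor after x(3)
    p3 <- p2 + 9L                      # first H after x(8)
    if (p3 > n || !(chars[p2] %in% C2H2_HYDRO) || chars[p3] != "H")
      next
    for (x2 in 3:5) {
      p4 <- p3 + x2 + 1L
      if (p4 <= n && chars[p4] == "H")
        return(c(c1 = i, c2 = p1, h1 = p3, h2 = p4))
    }
  }
  NULL
}

#' Scan for C2H2 zinc-finger motifs
#'
#' Matches the PROSITE-style consensus
#' `C-x(2,4)-C-x(3)-[LIVMFYWC]-x(8)-H-x(3,5)-H` left to right,
#' non-overlapping; at each anchor the shortest match (smallest spacers) is
#' taken.
#'
#' @param seq Amino-acid string.
#' @return Data frame with columns `pattern_id` ("C2H2"), `start`, `end`,
#'   `matched_text`, and the ligand positions `cys1`, `cys2`, `his1`,
#'   `his2` (1-based positions in `seq`).
#' @export
scan_c2h2 <- function(seq) {
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  rows <- list()
  i <- 1L
  while (i <= n) {
    hit <- c2h2_at(chars, i)
    if (is.null(hit)) { i <- i + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      pattern_id = "C2H2", start = i, end = unname(hit["h2"]),
      matched_text = substr(seq, i, hit["h2"]),
      cys1 = unname(hit["c1"]), cys2 = unname(hit["c2"]),
      his1 = unname(hit["h1"]), his2 = unname(hit["h2"]),
      stringsAsFactors = FALSE)
    i <- unname(hit["h2"]) + 1L
  }
  if (length(rows) == 0L)
    return(data.frame(pattern_id = character(), start = integer(),
                      end = integer(), matched_text = character(),
                      cys1 = integer(), cys2 = integer(),
                      his1 = integer(), his2 = integer()))
  do.call(rbind, rows)
}

#' Map zinc-ligand columns of finger-bearing sequences onto a reference
#'
#' For each annotated zinc-ligand position of each motif-bearing sequence
#' (for instance the two cysteines and two histidines of every C2H2 finger
#' of a CTCF ortholog), finds the reference-sequence residue occupying the
#' same alignment column. Ligand columns that are gapped in the reference
#' are omitted.
#'
#' @param aln An `aa_alignment` containing both the reference and the
#'   motif sequences.
#' @param ref_id Id of the reference record.
#' @param motif_ids Ids of the motif-bearing records.
#' @param ligand_positions Optional named list (per motif id) of data
#'   frames with columns `position` (ungapped 1-based) and `class` (one of
#'   `"C"`, `"H"`, `"D/E"`). When `NULL`, ligand positions are derived by
#'   running [scan_c2h2()] on each motif sequence.
#' @return Data frame with columns `ref_position`, `ref_aa`,
#'   `ligand_class`, `source_id`, `source_position`, sorted by
#'   `ref_position` then `source_id` (stable under record permutation).
#' @export
map_ligand_columns <- function(aln, ref_id, motif_ids,
                               ligand_positions = NULL) {
  for (id in c(ref_id, motif_ids))
    if (!id %in% aln$ids) stop("unknown record id: ", id)
  ref_seq <- strsplit(ungap(aln$seqs[[ref_id]]), "", fixed = TRUE)[[1L]]
  rows <- list()
  for (id in motif_ids) {
    lig <- if (!is.null(ligand_positions)) {
      ligand_positions[[id]]
    } else {
      hits <- scan_c2h2(ungap(aln$seqs[[id]]))
      if (nrow(hits) == 0L) next
      data.frame(position = c(hits$cys1, hits$cys2, hits$his1, hits$his2),
                 class = rep(c("C", "C", "H", "H"), each = nrow(hits)),
                 stringsAsFactors = FALSE)
    }
    if (is.null(lig) || nrow(lig) == 0L) next
    for (k in seq_len(nrow(lig))) {
      p <- map_position(aln, id, lig$position[k], ref_id)
      if (is.na(p)) next
      rows[[length(rows) + 1L]] <- data.frame(
        ref_position = p, ref_aa = ref_seq[p],
        ligand_class = lig$class[k], source_id = id,
        source_position = lig$position[k], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(ref_position = integer(), ref_aa = character(),
                      ligand_class = character(), source_id = character(),
                      source_position = integer()))
  out <- do.call(rbind, rows)
  out <- out[order(out$ref_position, out$source_id, out$source_position), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write motif hits as a tab-separated interval table
#'
#' Emits the 1-based inclusive coordinates plus a 0-based half-open column
#' pair (`start0`, `end0`) for interoperability with BED-style tools.
#'
#' @param hits Data frame from [scan_literal()] or [scan_c2h2()].
#' @param path Output path.
#' @param seq_id Label for the sequence column.
#' @return `path`, invisibly.
#' @export
write_motif_report <- function(hits, path, seq_id = "seq") {
  out <- data.frame(seq_id = rep(seq_id, nrow(hits)), hits,
                    start0 = hits$start - 1L, end0 = hits$end,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
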