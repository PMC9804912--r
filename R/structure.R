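# Structure model: parsing, residue chemistry and geometry.

# Side-chain atoms used for first-shell metal coordination.
FUNCTIONAL_ATOMS <- list(
  H = c("ND1", "NE2"),
  C = "SG",
  D = c("OD1", "OD2"),
  E = c("OE1", "OE2"),
  S = "OG"
)

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Construct a structure model from an atom table
#'
#' Low-level constructor used by [read_structure()] and by the synthetic
#' structure generator. Atom records hold one chain.
#'
#' @param atoms Data frame with columns `name` (PDB atom label), `x`, `y`,
#'   `z` (Angstrom), `resno` (1-based residue number), `aa` (one-letter
#'   code) and `chain`.
#' @param domains Optional named list of `c(start, end)` residue windows
#'   (closed intervals); windows must not overlap.
#' @return An object of class `structure_model` with elements `atoms`,
#'   `sequence` (one-letter vector named by residue number) and `domains`.
#' @export
structure_model <- function(atoms, domains = NULL) {
  need <- c("name", "x", "y", "z", "resno", "aa", "chain")
  stopifnot(all(need %in% names(atoms)))
  if (nrow(atoms) == 0L) stop("structure has no atoms")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(atoms$resno < 1L)) stop("residue numbers must be >= 1")
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  resno <- unique(atoms$resno)
  seq_aa <- atoms$aa[match(resno, atoms$resno)]
  names(seq_aa) <- resno
  if (!is.null(domains)) check_domains(domains)
  structure(list(atoms = atoms, sequence = seq_aa, domains = domains),
            class = "structure_model")
}

check_domains <- function(domains) {
  stopifnot(is.list(domains), !is.null(names(domains)))
  w <- t(vapply(domains, function(d) as.numeric(d[1:2]), numeric(2)))
  if (any(w[, 1] > w[, 2])) stop("domain window with start > end")
  if (nrow(w) > 1L) {
    o <- order(w[, 1])
    if (any(w[o[-1], 1] <= w[o[-nrow(w)], 2]))
      stop("domain windows overlap")
  }
  invisible(TRUE)
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", length(x$sequence), "residues,",
      nrow(x$atoms), "atoms\n")
  if (!is.null(x$domains))
    cat("domains:", paste(names(x$domains), collapse = ", "), "\n")
  invisible(x)
}

#' Read a protein structure model
#'
#' Parses a PDB or mmCIF file into a [structure_model()]. Only the first
#' model and (by default) the first chain are used; HETATM records and
#' hydrogens are dropped. Missing side-chain atoms are tolerated (see the
#' functional-atom fallback in [min_functional_distance()]).
#'
#' @param path Path to the structure file.
#' @param format `"pdb"` or `"mmcif"`.
#' @param chain Chain identifier; default is the first chain in the file.
#' @param domains Optional named list of `c(start, end)` residue windows.
#' @return A `structure_model`.
#' @export
read_structure <- function(path, format = c("pdb", "mmcif"), chain = NULL,
                           domains = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "pdb") {
    n_models <- length(grep("^MODEL", readLines(path, warn = FALSE)))
    if (n_models > 1L)
      warning("file contains ", n_models, " models; using the first")
    pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                    error = function(e) stop("cannot parse PDB file: ",
                                             conditionMessage(e),
                                             call. = FALSE))
  } else {
    pdb <- tryCatch(bio3d::read.cif(path, verbose = FALSE),
                    error = function(e) stop("cannot parse mmCIF file: ",
                                             conditionMessage(e),
                                             call. = FALSE))
  }
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !grepl("^H", at$elety), , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms for chain ", chain)
  aa <- suppressWarnings(bio3d::aa321(at$resid))
  aa[is.na(aa) | !aa %in% c(AA_CANONICAL, "X")] <- "X"
  structure_model(
    data.frame(name = at$elety, x = at$x, y = at$y, z = at$z,
               resno = at$resno, aa = aa, chain = at$chain,
               stringsAsFactors = FALSE),
    domains = domains)
}

residue_atoms <- function(s, res) {
  a <- s$atoms[s$atoms$resno == res, , drop = FALSE]
  if (nrow(a) == 0L) stop("residue ", res, " not present in structure")
  a
}

#' Functional-atom coordinates of a residue
#'
#' Returns the coordinates of the residue's metal-coordinating side-chain
#' atoms (His ND1/NE2, Cys SG, Asp OD1/OD2, Glu OE1/OE2, Ser OG). Fallback
#' chain for residues without them: the side-chain heavy atom furthest from
#' CA, then CA itself; the `fallback` attribute records which level was
#' used.
#'
#' @param s A `structure_model`.
#' @param res Residue number.
#' @return Numeric matrix (n x 3) with attribute `fallback` in
#'   `c("functional", "sidechain", "CA")`.
#' @export
functional_coords <- function(s, res) {
  a <- residue_atoms(s, res)
  aa <- a$aa[1L]
  fun <- FUNCTIONAL_ATOMS[[aa]]
  sel <- if (!is.null(fun)) a[a$name %in% fun, , drop = FALSE] else a[0L, ]
  level <- "functional"
  if (nrow(sel) == 0L) {
    side <- a[!a$name %in% BACKBONE_ATOMS, , drop = FALSE]
    ca <- a[a$name == "CA", , drop = FALSE]
    if (nrow(side) > 0L && nrow(ca) == 1L) {
      d <- sqrt((side$x - ca$x)^2 + (side$y - ca$y)^2 + (side$z - ca$z)^2)
      sel <- side[which.max(d), , drop = FALSE]
      level <- "sidechain"
    } else if (nrow(side) > 0L) {
      sel <- side[nrow(side), , drop = FALSE]
      level <- "sidechain"
    } else {
      if (nrow(ca) == 0L) stop("residue ", res, " has no usable atoms")
      sel <- ca
      level <- "CA"
    }
  }
  m <- as.matrix(sel[, c("x", "y", "z")])
  attr(m, "fallback") <- level
  m
}

#' Minimum functional-atom distance between two residues
#'
#' Minimum Euclidean distance over all pairs of functional atoms of the two
#' residues (with the [functional_coords()] fallback chain). Symmetric;
#' zero for a residue against itself.
#'
#' @param s A `structure_model`.
#' @param resA,resB Residue numbers.
#' @return Distance in Angstrom.
#' @export
min_functional_distance <- function(s, resA, resB) {
  if (resA == resB) {
    residue_atoms(s, resA)  # existence check
    return(0)
  }
  a <- functional_coords(s, resA)
  b <- functional_coords(s, resB)
  min(sqrt(pmax(0, outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b))))
}

# pairwise min functional distances for a set of residues
functional_distance_matrix <- function(s, residues) {
  coords <- lapply(residues, functional_coords, s = s)
  n <- length(residues)
  d <- matrix(0, n, n)
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    a <- coords[[i]]; b <- coords[[j]]
    d[i, j] <- d[j, i] <-
      min(sqrt(pmax(0, outer(rowSums(a^2), rowSums(b^2), "+") -
                       2 * a %*% t(b))))
  }
  dimnames(d) <- list(residues, residues)
  d
}

#' Detect disulfide bridges
#'
#' All cysteine pairs whose SG-SG distance is within `sg_cutoff`, paired
#' greedily nearest-first so each cysteine appears in at most one bridge.
#'
#' @param s A `structure_model`.
#' @param sg_cutoff SG-SG distance cutoff in Angstrom (default 2.3; a
#'   typical S-S bond is about 2.05).
#' @return Data frame with columns `res1`, `res2` (`res1 < res2`) and
#'   `distance`, ordered by `res1`.
#' @export
detect_disulfides <- function(s, sg_cutoff = 2.3) {
  sg <- s$atoms[s$atoms$aa == "C" & s$atoms$name == "SG", , drop = FALSE]
  empty <- data.frame(res1 = integer(), res2 = integer(),
                      distance = numeric())
  if (nrow(sg) < 2L) return(empty)
  pairs <- t(combn(seq_len(nrow(sg)), 2L))
  d <- sqrt((sg$x[pairs[, 1]] - sg$x[pairs[, 2]])^2 +
            (sg$y[pairs[, 1]] - sg$y[pairs[, 2]])^2 +
            (sg$z[pairs[, 1]] - sg$z[pairs[, 2]])^2)
  keep <- which(d <= sg_cutoff)
  if (length(keep) == 0L) return(empty)
  keep <- keep[order(d[keep])]
  used <- integer()
  out <- empty
  for (k in keep) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (i %in% used || j %in% used) next
    used <- c(used, i, j)
    r <- sort(c(sg$resno[i], sg$resno[j]))
    out <- rbind(out, data.frame(res1 = r[1], res2 = r[2],
                                 distance = d[k]))
  }
  out[order(out$res1), , drop = FALSE]
}

#' Residue census over a sequence window
#'
#' Counts and lists the residues inside a closed window `[start, end]`
#' whose amino acid belongs to `aa_set`.
#'
#' @param s A `structure_model`.
#' @param window Numeric `c(start, end)`, `1 <= start <= end`.
#' @param aa_set Character vector of one-letter codes.
#' @return List with `count` and `positions` (ascending residue numbers).
#' @export
residue_census <- function(s, window, aa_set) {
  start <- window[1L]; end <- window[2L]
  if (is.na(start) || is.na(end) || start < 1 || start > end)
    stop("degenerate window: need 1 <= start <= end")
  resno <- as.integer(names(s$sequence))
  hit <- resno >= start & resno <= end & s$sequence %in% aa_set
  list(count = sum(hit), positions = resno[hit])
}

cb_coords <- function(s) {
  # CB per residue, CA for glycine or when CB is absent
  resno <- as.integer(names(s$sequence))
  out <- matrix(NA_real_, length(resno), 3L,
                dimnames = list(resno, c("x", "y", "z")))
  for (k in seq_along(resno)) {
    a <- s$atoms[s$atoms$resno == resno[k], , drop = FALSE]
    pick <- a[a$name == "CB", , drop = FALSE]
    if (nrow(pick) == 0L) pick <- a[a$name == "CA", , drop = FALSE]
    if (nrow(pick) == 0L) pick <- a[1L, , drop = FALSE]
    out[k, ] <- c(pick$x[1L], pick$y[1L], pick$z[1L])
  }
  out
}

#' Side-chain burial proxy
#'
#' Number of CB atoms (CA for glycine) of other residues within `radius` of
#' the residue's own CB (CA for glycine). Used as a cheap burial proxy: a
#' residue is called buried when the count reaches the threshold in
#' [search_config()] (default 18 within 10 Angstrom).
#'
#' @param s A `structure_model`.
#' @param res Residue number.
#' @param radius Neighbourhood radius in Angstrom (default 10).
#' @return Integer neighbour count.
#' @export
burial_score <- function(s, res, radius = 10.0) {
  cb <- cb_coords(s)
  i <- match(as.character(res), rownames(cb))
  if (is.na(i)) stop("residue ", res, " not present in structure")
  d <- sqrt(colSums((t(cb) - cb[i, ])^2))
  sum(d[-i] <= radius)
}
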