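# Synthetic data with known ground truth: structures with planted
# tetrahedral coordination sites, alignments with controlled conservation,
# and ICP-MS tables generated from a known true Zn:protein ratio.

TETRAHEDRAL_DIRS <- matrix(c(1, 1, 1,
                             1, -1, -1,
                             -1, 1, -1,
                             -1, -1, 1), ncol = 3, byrow = TRUE) / sqrt(3)

PRIMARY_FUNCTIONAL <- c(H = "ND1", C = "SG", D = "OD1", E = "OE1", S = "OG")

pdb_line <- function(serial, name, aa, resno, xyz) {
  aa3 <- bio3d::aa123(aa)
  element <- substr(name, 1, 1)
  sprintf("ATOM  %5d %4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, sprintf(" %-3s", name), aa3, "A", resno,
          xyz[1], xyz[2], xyz[3], element)
}

#' Generate a synthetic structure with planted coordination sites
#'
#' Builds a single-chain PDB with one ion position per site; the site
#' residues' functional atoms sit 2.1 Angstrom from the ion along
#' tetrahedral directions (so any two coordinating atoms are ~3.4 A
#' apart). Optional hydrophobic shell residues (Leu/Ile/Phe/Val CB atoms
#' at 7.5 A) surround each ion, giving planted sites a polar core inside a
#' hydrophobic exterior. Decoy H/C residues are placed at least
#' `decoy_margin` from every site and from each other, and filler alanines
#' follow a self-avoiding random walk kept clear of all ions. Side chains
#' carry the functional atom, CB and CA only; readers must tolerate the
#' truncation (see [functional_coords()]).
#'
#' @param n_residues Total residue count; must cover all site, shell and
#'   decoy residues.
#' @param sites List of site specs. Each is either a character vector of
#'   2-4 residue types from H/C/D/E/S, or a list with elements `aa`
#'   (character vector), optional `ion` (3-vector, Angstrom) and optional
#'   `residues` (residue numbers for the members).
#' @param n_decoys Number of isolated conserved-looking H/C decoys.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param decoy_margin Minimum distance (Angstrom) between a decoy and any
#'   site or other decoy (default 15, comfortably above the default
#'   pairing radius).
#' @param shell Place 4 hydrophobic shell residues around each ion
#'   (default `TRUE`).
#' @return List with `pdb` (character vector of PDB lines), `atoms` (the
#'   atom table at PDB coordinate precision, as accepted by
#'   [structure_model()]) and `truth` (list with `planted_sites`, `ions`,
#'   `decoys`, `shell`, `conserved_positions` = site members, `seed`).
#' @export
make_structure <- function(n_residues, sites, n_decoys = 0L, seed = 1L,
                           decoy_margin = 15, shell = TRUE) {
  sites <- lapply(sites, function(sp) {
    if (is.character(sp)) sp <- list(aa = sp)
    stopifnot(all(sp$aa %in% names(PRIMARY_FUNCTIONAL)),
              length(sp$aa) >= 2L, length(sp$aa) <= 4L)
    sp
  })
  n_site_res <- sum(lengths(lapply(sites, `[[`, "aa")))
  n_shell <- if (shell) 4L * length(sites) else 0L
  n_special <- n_site_res + n_shell + n_decoys
  if (n_residues < n_special)
    stop("n_residues too small: need at least ", n_special)
  with_seed(seed, {
    ions <- lapply(seq_along(sites), function(i)
      sites[[i]]$ion %||% c(60 * (i - 1), 0, 0))
    # residue-number slots: fixed numbers first, the rest evenly spaced
    fixed <- unlist(lapply(sites, `[[`, "residues"))
    auto_needed <- n_special - length(fixed)
    pool <- setdiff(seq_len(n_residues), fixed)
    slots <- if (auto_needed > 0L)
      pool[unique(round(seq(1, length(pool),
                            length.out = auto_needed)))] else integer()
    if (length(slots) < auto_needed)
      stop("generation error: cannot place ", auto_needed,
           " residues in sequence")
    atoms <- list()
    truth_sites <- list()
    shell_res <- decoy_res <- integer()
    slot_i <- 0L
    take_slot <- function() {
      slot_i <<- slot_i + 1L
      slots[slot_i]
    }
    add_res <- function(resno, aa, fun_xyz, cb_xyz, ca_xyz, fun_name) {
      rows <- list()
      if (!is.null(fun_name))
        rows[[1]] <- data.frame(name = fun_name, x = fun_xyz[1],
                                y = fun_xyz[2], z = fun_xyz[3],
                                resno = resno, aa = aa, chain = "A")
      rows[[length(rows) + 1]] <- data.frame(name = "CB", x = cb_xyz[1],
                                             y = cb_xyz[2], z = cb_xyz[3],
                                             resno = resno, aa = aa,
                                             chain = "A")
      rows[[length(rows) + 1]] <- data.frame(name = "CA", x = ca_xyz[1],
                                             y = ca_xyz[2], z = ca_xyz[3],
                                             resno = resno, aa = aa,
                                             chain = "A")
      atoms[[length(atoms) + 1L]] <<- do.call(rbind, rows)
    }
    for (i in seq_along(sites)) {
      sp <- sites[[i]]
      ion <- ions[[i]]
      members <- integer()
      for (j in seq_along(sp$aa)) {
        resno <- if (!is.null(sp$residues)) sp$residues[j] else take_slot()
        dir <- TETRAHEDRAL_DIRS[j, ]
        add_res(resno, sp$aa[j], ion + 2.1 * dir, ion + 3.5 * dir,
                ion + 4.9 * dir, PRIMARY_FUNCTIONAL[[sp$aa[j]]])
        members <- c(members, resno)
      }
      truth_sites[[i]] <- sort(members)
      if (shell) {
        hydro <- c("L", "I", "F", "V")
        for (j in 1:4) {
          resno <- take_slot()
          dir <- -TETRAHEDRAL_DIRS[j, ]
          add_res(resno, hydro[j], NULL, ion + 7.5 * dir, ion + 8.8 * dir,
                  NULL)
          shell_res <- c(shell_res, resno)
        }
      }
    }
    decoy_spacing <- max(20, decoy_margin + 5)
    for (k in seq_len(n_decoys)) {
      resno <- take_slot()
      aa <- if (k %% 2L == 1L) "H" else "C"
      pos <- c(-(decoy_margin + 10 + decoy_spacing * (k - 1)),
               decoy_margin + 10, 0)
      add_res(resno, aa, pos, pos + c(1.5, 0, 0), pos + c(3.0, 0, 0),
              PRIMARY_FUNCTIONAL[[aa]])
      decoy_res <- c(decoy_res, resno)
    }
    # filler backbone: self-avoiding random walk kept clear of the ions
    keepout <- do.call(rbind, c(ions, list()))
    filler <- setdiff(seq_len(n_residues),
                      c(unlist(truth_sites), shell_res, decoy_res))
    walk <- c(-10, -60, 10)
    for (resno in filler) {
      placed <- FALSE
      for (try in 1:50) {
        step <- rnorm(3)
        cand <- walk + 3.8 * step / sqrt(sum(step^2))
        if (is.null(keepout) ||
            all(sqrt(colSums((t(keepout) - cand)^2)) > 12)) {
          walk <- cand; placed <- TRUE; break
        }
      }
      if (!placed) stop("generation error: filler walk could not avoid sites")
      cbdir <- rnorm(3); cbdir <- cbdir / sqrt(sum(cbdir^2))
      add_res(resno, "A", NULL, walk + 1.5 * cbdir, walk, NULL)
    }
    at <- do.call(rbind, atoms)
    at <- at[order(at$resno, match(at$name, c("CA", "CB"))), , drop = FALSE]
    # round to the PDB coordinate precision so text round-trips exactly
    at$x <- round(at$x, 3); at$y <- round(at$y, 3); at$z <- round(at$z, 3)
    rownames(at) <- NULL
    lines <- vapply(seq_len(nrow(at)), function(r)
      pdb_line(r, at$name[r], at$aa[r], at$resno[r],
               c(at$x[r], at$y[r], at$z[r])), character(1))
    list(pdb = c(lines, "END"), atoms = at,
         truth = list(planted_sites = truth_sites, ions = ions,
                      decoys = decoy_res, shell = shell_res,
                      conserved_positions = sort(unlist(truth_sites)),
                      seed = seed))
  })
}

#' Generate a synthetic ungapped alignment with controlled conservation
#'
#' The reference sequence is copied into `n_seqs` records; conserved
#' positions are kept verbatim in every record, all other positions are
#' substituted independently with probability `sub_rate` (uniformly over
#' the other 19 canonical residues).
#'
#' @param ref Reference amino-acid string.
#' @param n_seqs Number of records (including the reference, written
#'   first).
#' @param conserved_positions Integer positions copied verbatim.
#' @param sub_rate Per-position substitution probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param ref_id Id of the reference record (default `"REF"`).
#' @return List with `fasta` (character vector of FASTA lines),
#'   `alignment` (an `aa_alignment`) and `truth` (list with
#'   `conserved_columns`, `seed`).
#' @export
make_msa <- function(ref, n_seqs, conserved_positions = integer(),
                     sub_rate = 0.3, seed = 1L, ref_id = "REF") {
  stopifnot(sub_rate >= 0, sub_rate <= 1, n_seqs >= 1L)
  ref <- toupper(ref)
  chars <- strsplit(ref, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  stopifnot(all(conserved_positions >= 1), all(conserved_positions <= L))
  with_seed(seed, {
    free <- setdiff(seq_len(L), conserved_positions)
    seqs <- character(n_seqs)
    seqs[1L] <- ref
    for (i in seq_len(n_seqs - 1L) + 1L) {
      row <- chars
      if (length(free) > 0L && sub_rate > 0) {
        hit <- free[runif(length(free)) < sub_rate]
        row[hit] <- vapply(row[hit], function(a)
          sample(setdiff(AA_CANONICAL, a), 1L), character(1))
      }
      seqs[i] <- paste(row, collapse = "")
    }
    ids <- c(ref_id, sprintf("SYN%02d", seq_len(n_seqs - 1L) + 1L))
    fasta <- as.vector(rbind(paste0(">", ids), seqs))
    list(fasta = fasta, alignment = new_alignment(ids, seqs),
         truth = list(conserved_columns = sort(conserved_positions),
                      seed = seed))
  })
}

#' Generate a synthetic ICP-MS sample table from a known true ratio
#'
#' Each analyte's undiluted zinc concentration is
#' `true_ratio * (protein / mw_protein) * mw_zn` perturbed by
#' multiplicative Gaussian noise, then divided by the dilution factor to
#' the instrument scale. Blanks are Gaussian around `blank_level`
#' (SD = `blank_level / 3`), truncated at zero.
#'
#' @param true_ratio True mol Zn per mol protein (>= 0).
#' @param protein_concs Analyte protein concentrations, g/L (defaults span
#'   1.2-2.8 g/L, five samples).
#' @param noise_sd_frac Multiplicative noise SD as a fraction (default
#'   0.05).
#' @param n_blanks Number of blank samples (default 5).
#' @param blank_level Mean blank zinc on the instrument scale, ug/L.
#' @param dilution Dilution factor applied to all samples (default 5).
#' @param seed Integer seed.
#' @param k A [zn_constants()] object.
#' @return Sample data frame (columns as in [read_icpms()]) with a
#'   `truth` attribute recording the generating parameters.
#' @export
make_icpms <- function(true_ratio, protein_concs = c(1.2, 1.6, 2.0, 2.4, 2.8),
                       noise_sd_frac = 0.05, n_blanks = 5L,
                       blank_level = 1.0, dilution = 5, seed = 1L,
                       k = zn_constants()) {
  stopifnot(true_ratio >= 0, noise_sd_frac >= 0, dilution >= 1)
  with_seed(seed, {
    eps <- rnorm(length(protein_concs), 0, noise_sd_frac)
    zn_gL <- true_ratio * (protein_concs / k$mw_protein) * k$mw_zn * (1 + eps)
    zn_gL <- pmax(0, zn_gL)
    analyte <- data.frame(
      id = sprintf("vg%02d", seq_along(protein_concs)), group = "analyte",
      zn_ugL = zn_gL * 1e6 / dilution, dilution = dilution,
      protein_gL = protein_concs, stringsAsFactors = FALSE)
    blanks <- data.frame(
      id = sprintf("blk%02d", seq_len(n_blanks)), group = "blank",
      zn_ugL = pmax(0, rnorm(n_blanks, blank_level, blank_level / 3)),
      dilution = dilution, protein_gL = 0, stringsAsFactors = FALSE)
    out <- rbind(analyte, blanks)
    attr(out, "truth") <- list(true_ratio = true_ratio,
                               noise_sd_frac = noise_sd_frac,
                               blank_level = blank_level, seed = seed)
    out
  })
}
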