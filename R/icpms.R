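# ICP-MS data reduction: dilution correction, blank-derived detection
# limits, molar Zn:protein stoichiometry, nonparametric group comparison.

#' Molecular-weight constants for the stoichiometry calculation
#'
#' Defaults are the theoretical molecular weight of full-length honey bee
#' vitellogenin (201147.7 g/mol) and of the Zn2+ ion (65.30 g/mol).
#'
#' @param mw_protein Protein molecular weight, g/mol.
#' @param mw_zn Zinc molecular weight, g/mol.
#' @return List of class `zn_constants`.
#' @export
zn_constants <- function(mw_protein = 201147.7, mw_zn = 65.30) {
  stopifnot(mw_protein > 0, mw_zn > 0)
  structure(list(mw_protein = mw_protein, mw_zn = mw_zn),
            class = "zn_constants")
}

#' Read an ICP-MS sample table
#'
#' Delimited text (comma- or tab-separated, chosen from the extension)
#' with columns `id`, `group` (`"analyte"` or `"blank"`), `zn_ugL`
#' (measured Zn on the diluted instrument scale, ug/L), `dilution`
#' (dimensionless, >= 1) and `protein_gL` (undiluted protein
#' concentration, g/L; 0 for blanks).
#'
#' @param path Path to the table.
#' @return Validated data frame of samples.
#' @export
read_icpms <- function(path) {
  if (!file.exists(path)) stop("sample table not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  validate_icpms(df)
}

validate_icpms <- function(df) {
  need <- c("id", "group", "zn_ugL", "dilution", "protein_gL")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("sample table lacks columns: ", paste(missing, collapse = ", "))
  if (!all(df$group %in% c("analyte", "blank")))
    stop("group must be 'analyte' or 'blank'")
  if (any(df$zn_ugL < 0) || any(df$protein_gL < 0))
    stop("concentrations must be non-negative")
  if (any(df$dilution < 1)) stop("dilution factors must be >= 1")
  if (any(df$protein_gL[df$group == "blank"] != 0))
    stop("blank samples must have protein_gL = 0")
  df
}

#' Dilution-corrected zinc concentration
#'
#' Measured instrument-scale concentrations multiplied by the per-sample
#' dilution factor, back to the undiluted sample scale.
#'
#' @param samples ICP-MS sample data frame (see [read_icpms()]).
#' @return Numeric vector of corrected Zn concentrations, ug/L.
#' @export
corrected_zn <- function(samples) {
  stopifnot(all(samples$zn_ugL >= 0))
  samples$zn_ugL * samples$dilution
}

#' Blank-derived detection limits
#'
#' LOD = 3 x SD and LOQ = 10 x SD of the blank measurements (sample SD
#' with n-1 denominator), on the instrument scale.
#'
#' @param blanks Either a numeric vector of blank Zn measurements (ug/L)
#'   or a sample data frame from which `group == "blank"` rows are taken.
#' @return List of class `detection_limits` with `lod`, `loq`, `sd`, `n`.
#' @export
detection_limits <- function(blanks) {
  if (is.data.frame(blanks)) blanks <- blanks$zn_ugL[blanks$group == "blank"]
  if (length(blanks) < 2L)
    stop("insufficient blanks: need at least 2, got ", length(blanks))
  s <- sd(blanks)
  if (s == 0) warning("degenerate blanks: all values identical, LOD = LOQ = 0")
  structure(list(lod = 3 * s, loq = 10 * s, sd = s, n = length(blanks)),
            class = "detection_limits")
}

#' Molar Zn:protein ratio
#'
#' `(zn_gL / mw_zn) / (protein_gL / mw_protein)`, i.e. mol Zn per mol
#' protein. Linear in the zinc concentration and inversely linear in the
#' protein concentration.
#'
#' @param zn_gL Zinc concentration, g/L (undiluted scale).
#' @param protein_gL Protein concentration, g/L; must be positive.
#' @param k A [zn_constants()] object.
#' @return Numeric ratio(s), mol/mol.
#' @export
molar_ratio <- function(zn_gL, protein_gL, k = zn_constants()) {
  if (any(protein_gL <= 0))
    stop("protein concentration must be positive for a molar ratio")
  (zn_gL / k$mw_zn) / (protein_gL / k$mw_protein)
}

#' Reduce an ICP-MS sample table to a Zn:protein stoichiometry
#'
#' Applies the dilution correction, computes per-analyte molar ratios,
#' flags samples whose measured Zn falls below the blank-derived LOD or
#' LOQ, and summarizes mean/min/max over the analyte samples. Below-LOD
#' samples are excluded from the summary by default.
#'
#' @param samples ICP-MS sample data frame.
#' @param k A [zn_constants()] object.
#' @param limits A [detection_limits()] object, or `NULL` to derive from
#'   the blank rows (when at least two are present).
#' @param below_lod `"exclude"` (default) or `"keep"`: whether flagged
#'   samples enter the summary statistics.
#' @return List of class `stoichiometry_result` with `samples` (per-sample
#'   table incl. `ratio`, `below_lod`, `below_loq`), `mean`, `min`, `max`,
#'   `n_used`, `limits`, `constants`.
#' @export
summarize_stoichiometry <- function(samples, k = zn_constants(),
                                    limits = NULL,
                                    below_lod = c("exclude", "keep")) {
  below_lod <- match.arg(below_lod)
  samples <- validate_icpms(samples)
  analyte <- samples[samples$group == "analyte", , drop = FALSE]
  if (nrow(analyte) == 0L) stop("no analyte samples in table")
  if (is.null(limits) && sum(samples$group == "blank") >= 2L)
    limits <- detection_limits(samples)
  zn_gL <- corrected_zn(analyte) * 1e-6      # ug/L -> g/L
  analyte$ratio <- molar_ratio(zn_gL, analyte$protein_gL, k)
  analyte$below_lod <- if (is.null(limits)) FALSE else
    analyte$zn_ugL < limits$lod
  analyte$below_loq <- if (is.null(limits)) FALSE else
    analyte$zn_ugL < limits$loq
  used <- if (below_lod == "exclude") !analyte$below_lod else
    rep(TRUE, nrow(analyte))
  r <- analyte$ratio[used]
  structure(list(samples = analyte,
                 mean = if (length(r)) mean(r) else NA_real_,
                 min = if (length(r)) min(r) else NA_real_,
                 max = if (length(r)) max(r) else NA_real_,
                 n_used = sum(used), limits = limits, constants = k),
            class = "stoichiometry_result")
}

#' @export
print.stoichiometry_result <- function(x, ...) {
  cat(sprintf(
    "Zn:protein stoichiometry over %d sample(s): mean %.2f, range %.2f-%.2f mol/mol\n",
    x$n_used, x$mean, x$min, x$max))
  if (!is.null(x$limits))
    cat(sprintf("LOD %.3g ug/L, LOQ %.3g ug/L (blank SD %.3g, n=%d)\n",
                x$limits$lod, x$limits$loq, x$limits$sd, x$limits$n))
  invisible(x)
}

#' Kruskal-Wallis rank test
#'
#' Rank-based H statistic with tie correction and a chi-square upper-tail
#' p-value, for two or more groups. When every observation is identical the
#' statistic is 0 with p = 1.
#'
#' @param groups List of two or more numeric vectors (each non-empty,
#'   total length >= 3).
#' @return List with `H`, `df` and `p.value`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(lengths(groups) >= 1L), sum(lengths(groups)) >= 3L)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p.value = 1))
  kt <- kruskal.test(values, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value)
}

#' Write per-sample and summary stoichiometry tables
#'
#' @param result A `stoichiometry_result`.
#' @param samples_path,summary_path Output TSV paths (either may be
#'   `NULL`).
#' @return `result`, invisibly.
#' @export
write_stoichiometry <- function(result, samples_path = NULL,
                                summary_path = NULL) {
  if (!is.null(samples_path))
    write.table(result$samples, samples_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(summary_path)) {
    sm <- data.frame(mean = result$mean, min = result$min, max = result$max,
                     n_used = result$n_used,
                     lod = if (is.null(result$limits)) NA else
                       result$limits$lod,
                     loq = if (is.null(result$limits)) NA else
                       result$limits$loq,
                     mw_protein = result$constants$mw_protein,
                     mw_zn = result$constants$mw_zn)
    write.table(sm, summary_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(result)
}
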