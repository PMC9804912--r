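# Hydrophobic contrast of a coordination cluster: polar inner shell vs
# hydrophobic outer shell on the Eisenberg consensus scale.

#' Eisenberg consensus hydrophobicity scale
#'
#' The normalized consensus hydrophobicity values (dimensionless) for the
#' 20 canonical residues. Isoleucine and phenylalanine are among the most
#' hydrophobic, arginine the least.
#'
#' @return Named numeric vector over the one-letter codes.
#' @export
eisenberg_scale <- function() {
  c(I =  0.73, F =  0.61, V =  0.54, L =  0.53, W =  0.37,
    M =  0.26, A =  0.25, G =  0.16, C =  0.04, Y =  0.02,
    P = -0.07, T = -0.18, S = -0.26, H = -0.40, E = -0.62,
    N = -0.64, Q = -0.69, D = -0.72, K = -1.10, R = -1.76)
}

#' Hydrophobic contrast of a cluster
#'
#' The cluster centroid is the mean of the members' functional-atom
#' coordinates. Every residue of the structure is assigned to the inner
#' shell if any of its functional atoms or its CB (CA for glycine) lies
#' within `r_inner` of the centroid, to the outer shell if the closest such
#' atom lies in `(r_inner, r_outer]`, and is otherwise ignored; each
#' residue is counted once, in its nearest shell. The contrast is
#' `delta = outer_mean - inner_mean` of the scale values, so a positive
#' delta means a hydrophobic exterior around a polar core - the favourable
#' arrangement for a productive metal site. An empty outer shell yields a
#' missing delta with `undefined = TRUE`.
#'
#' @param cl A `zn_cluster`.
#' @param s A `structure_model`.
#' @param scale Named hydrophobicity scale (default [eisenberg_scale()]).
#' @param r_inner,r_outer Shell radii in Angstrom (defaults 5 and 10);
#'   `r_inner < r_outer` required.
#' @return A list of class `contrast_score` with `cluster_id`,
#'   `inner_mean`, `outer_mean`, `delta`, `inner_n`, `outer_n`,
#'   `undefined`.
#' @export
cluster_contrast <- function(cl, s, scale = eisenberg_scale(),
                             r_inner = 5.0, r_outer = 10.0) {
  stopifnot(r_inner < r_outer, cluster_size(cl) >= 1L)
  member_xyz <- do.call(rbind, lapply(cl$members$position,
                                      functional_coords, s = s))
  centroid <- colMeans(member_xyz)
  resno <- as.integer(names(s$sequence))
  cb <- cb_coords(s)
  d <- vapply(seq_along(resno), function(k) {
    aa <- s$sequence[k]
    xyz <- cb[k, , drop = FALSE]
    if (!is.null(FUNCTIONAL_ATOMS[[aa]])) {
      fc <- tryCatch(functional_coords(s, resno[k]), error = function(e) NULL)
      if (!is.null(fc)) xyz <- rbind(xyz, fc)
    }
    min(sqrt(colSums((t(xyz) - centroid)^2)))
  }, numeric(1))
  known <- s$sequence %in% names(scale)
  inner <- which(d <= r_inner & known)
  outer <- which(d > r_inner & d <= r_outer & known)
  inner_mean <- if (length(inner)) mean(scale[s$sequence[inner]]) else NA_real_
  outer_mean <- if (length(outer)) mean(scale[s$sequence[outer]]) else NA_real_
  undefined <- length(outer) == 0L || length(inner) == 0L
  structure(list(cluster_id = cl$id, inner_mean = inner_mean,
                 outer_mean = outer_mean,
                 delta = if (undefined) NA_real_ else outer_mean - inner_mean,
                 inner_n = length(inner), outer_n = length(outer),
                 undefined = undefined),
            class = "contrast_score")
}

#' @export
print.contrast_score <- function(x, ...) {
  cat(sprintf("contrast %s: inner %.3f (n=%d), outer %.3f (n=%d), delta %s\n",
              ifelse(is.na(x$cluster_id), "<unnamed>", x$cluster_id),
              x$inner_mean, x$inner_n, x$outer_mean, x$outer_n,
              ifelse(x$undefined, "undefined", sprintf("%.3f", x$delta))))
  invisible(x)
}

#' Append contrast scores to a cluster list
#'
#' @param clusters List of `zn_cluster` objects.
#' @param s A `structure_model`.
#' @inheritParams cluster_contrast
#' @return The cluster list with a `contrast` element added to each.
#' @export
score_contrast <- function(clusters, s, scale = eisenberg_scale(),
                           r_inner = 5.0, r_outer = 10.0) {
  lapply(clusters, function(cl) {
    cl$contrast <- cluster_contrast(cl, s, scale, r_inner, r_outer)
    cl
  })
}
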