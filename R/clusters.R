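# Candidate zinc-coordination cluster search:
# conserved H/C seeds -> 3D proximity components -> D/E/S augmentation ->
# crossed-disulfide ZnC4 screen -> classification and domain assignment.

#' Search configuration for the cluster pipeline
#'
#' @param min_grade Minimum conservation grade (1..9) for seed and auxiliary
#'   residues; default 7 approximates the "conserved" band of a 9-grade
#'   colouring.
#' @param d_pair Maximum functional-atom distance (Angstrom) for two
#'   residues to be joined in the proximity graph; default 8. Two ligands
#'   bound to one ion sit within ~4.8 A of each other, but an apo model
#'   needs slack for side-chain rearrangement; documented range 6-12.
#' @param d_aux Maximum functional-atom distance for a conserved D/E/S
#'   auxiliary to join a cluster (default 8).
#' @param seq_adjacency Sequence distance (residues) within which an
#'   auxiliary also qualifies (default 2).
#' @param min_coordinators Minimum cluster size for a full coordination
#'   site (default 4); smaller clusters are reported as sub-minimal.
#' @param burial_radius Radius for the CB-neighbour burial proxy.
#' @param buried_min_neighbors CB-neighbour count at which a residue is
#'   called buried (default 18 within 10 A).
#' @return A list of class `search_config`.
#' @export
search_config <- function(min_grade = 7L, d_pair = 8.0, d_aux = 8.0,
                          seq_adjacency = 2L, min_coordinators = 4L,
                          burial_radius = 10.0, buried_min_neighbors = 18L) {
  cfg <- list(min_grade = as.integer(min_grade), d_pair = d_pair,
              d_aux = d_aux, seq_adjacency = as.integer(seq_adjacency),
              min_coordinators = as.integer(min_coordinators),
              burial_radius = burial_radius,
              buried_min_neighbors = as.integer(buried_min_neighbors))
  stopifnot(all(vapply(cfg, function(v) v > 0, logical(1))),
            cfg$min_coordinators >= 2L, cfg$min_grade <= 9L)
  class(cfg) <- "search_config"
  cfg
}

new_cluster <- function(members, from_znc4 = FALSE) {
  members <- members[order(members$position), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(id = NA_character_, members = members,
                 domain = NA_character_, classification = NA_character_,
                 from_znc4 = from_znc4),
            class = "zn_cluster")
}

#' @export
print.zn_cluster <- function(x, ...) {
  cat(sprintf("cluster %s [%s, %s]: %s\n",
              ifelse(is.na(x$id), "<unnamed>", x$id),
              ifelse(is.na(x$domain), "?", x$domain),
              ifelse(is.na(x$classification), "?", x$classification),
              paste0(x$members$aa, x$members$position, collapse = ", ")))
  invisible(x)
}

cluster_size <- function(cl) nrow(cl$members)

#' Conserved H/C seed residues
#'
#' All histidines and cysteines of the structure whose conservation grade
#' reaches `cfg$min_grade`. The profile numbering must match the structure
#' numbering: if the amino acids disagree at more than 5% of shared
#' positions an alignment-mismatch error is raised.
#'
#' @param s A `structure_model`.
#' @param profile A `conservation_profile` on the same numbering.
#' @param cfg A [search_config()].
#' @return Data frame with columns `position`, `aa`, `role` ("primary"),
#'   `grade`.
#' @export
find_primary_candidates <- function(s, profile, cfg = search_config()) {
  resno <- as.integer(names(s$sequence))
  shared <- intersect(profile$position, resno)
  if (length(shared) > 0L) {
    mism <- mean(profile$aa[match(shared, profile$position)] !=
                   s$sequence[as.character(shared)])
    if (mism > 0.05)
      stop("alignment mismatch: profile and structure disagree at ",
           sprintf("%.1f%%", 100 * mism), " of shared positions")
  }
  hc <- conserved_residues(profile, c("H", "C"), cfg$min_grade)
  hc <- hc[hc$position %in% resno, , drop = FALSE]
  out <- data.frame(position = hc$position, aa = hc$aa,
                    role = rep("primary", nrow(hc)),
                    grade = hc$grade, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Group candidate residues into 3D proximity clusters
#'
#' Builds a graph with an edge between candidates whose minimum
#' functional-atom distance is within `cfg$d_pair` and returns its
#' connected components as clusters, ordered by their lowest member
#' position. Singletons are retained (classified sub-minimal later).
#'
#' @param candidates Data frame as from [find_primary_candidates()].
#' @param s A `structure_model`.
#' @param cfg A [search_config()].
#' @return List of `zn_cluster` objects.
#' @export
build_clusters <- function(candidates, s, cfg = search_config()) {
  if (is.null(candidates) || nrow(candidates) == 0L) return(list())
  d <- functional_distance_matrix(s, candidates$position)
  adj <- d <= cfg$d_pair
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  cls <- unname(lapply(split(seq_len(nrow(candidates)), comp), function(idx)
    new_cluster(candidates[idx, , drop = FALSE])))
  cls[order(vapply(cls, function(cl) min(cl$members$position), numeric(1)))]
}

#' Augment a sub-minimal cluster with conserved D/E/S residues
#'
#' If the cluster has fewer than `cfg$min_coordinators` members, every
#' conserved aspartate/glutamate/serine (grade >= `cfg$min_grade`) lying
#' within `cfg$d_aux` of any member's functional atoms, or within
#' `cfg$seq_adjacency` residues in sequence of a member, is added with role
#' "auxiliary". Clusters already at or above the minimum are returned
#' unchanged.
#'
#' @param cl A `zn_cluster`.
#' @param s A `structure_model`.
#' @param profile A `conservation_profile`.
#' @param cfg A [search_config()].
#' @return The (possibly augmented) `zn_cluster`.
#' @export
augment_cluster <- function(cl, s, profile, cfg = search_config()) {
  if (cluster_size(cl) >= cfg$min_coordinators) return(cl)
  aux <- conserved_residues(profile, c("D", "E", "S"), cfg$min_grade)
  aux <- aux[aux$position %in% as.integer(names(s$sequence)) &
               !aux$position %in% cl$members$position, , drop = FALSE]
  if (nrow(aux) == 0L) return(cl)
  member_pos <- cl$members$position
  member_coords <- lapply(member_pos, functional_coords, s = s)
  qualifies <- vapply(seq_len(nrow(aux)), function(k) {
    p <- aux$position[k]
    if (any(abs(p - member_pos) <= cfg$seq_adjacency)) return(TRUE)
    a <- functional_coords(s, p)
    any(vapply(member_coords, function(b)
      min(sqrt(pmax(0, outer(rowSums(a^2), rowSums(b^2), "+") -
                      2 * a %*% t(b)))) <= cfg$d_aux, logical(1)))
  }, logical(1))
  if (!any(qualifies)) return(cl)
  add <- aux[qualifies, , drop = FALSE]
  members <- rbind(cl$members,
                   data.frame(position = add$position, aa = add$aa,
                              role = "auxiliary", grade = add$grade,
                              stringsAsFactors = FALSE))
  out <- new_cluster(members, from_znc4 = cl$from_znc4)
  out$id <- cl$id; out$domain <- cl$domain
  out
}

#' Detect crossed-disulfide ZnC4 candidates
#'
#' Pairs of disulfide bridges whose four SG atoms are mutually within
#' `cfg$d_pair` form a four-cysteine redox-switch-like cluster (a zinc site
#' interconvertible with the two disulfides under redox change). If a
#' conservation profile is supplied, only bridges whose cysteines reach
#' `cfg$min_grade` are considered. Overlapping bridge pairs are resolved
#' greedily by ascending lowest member position.
#'
#' @param s A `structure_model`.
#' @param profile Optional `conservation_profile`.
#' @param cfg A [search_config()].
#' @param sg_cutoff Disulfide SG-SG cutoff passed to [detect_disulfides()].
#' @return List of `zn_cluster` objects with `from_znc4 = TRUE`.
#' @export
detect_znc4 <- function(s, profile = NULL, cfg = search_config(),
                        sg_cutoff = 2.3) {
  br <- detect_disulfides(s, sg_cutoff)
  if (!is.null(profile) && nrow(br) > 0L) {
    grade_of <- function(p) {
      g <- profile$grade[match(p, profile$position)]
      ifelse(is.na(g), 0L, g)
    }
    br <- br[grade_of(br$res1) >= cfg$min_grade &
               grade_of(br$res2) >= cfg$min_grade, , drop = FALSE]
  }
  if (nrow(br) < 2L) return(list())
  sg <- s$atoms[s$atoms$aa == "C" & s$atoms$name == "SG", , drop = FALSE]
  sg_xyz <- function(res) unlist(sg[match(res, sg$resno), c("x", "y", "z")])
  cand <- list()
  for (i in 1:(nrow(br) - 1L)) for (j in (i + 1L):nrow(br)) {
    res4 <- c(br$res1[i], br$res2[i], br$res1[j], br$res2[j])
    xyz <- t(vapply(res4, sg_xyz, numeric(3)))
    if (max(dist(xyz)) <= cfg$d_pair)
      cand[[length(cand) + 1L]] <- list(bridges = c(i, j),
                                        residues = sort(res4))
  }
  if (length(cand) == 0L) return(list())
  cand <- cand[order(vapply(cand, function(cc) min(cc$residues), numeric(1)))]
  used <- integer()
  out <- list()
  for (cc in cand) {
    if (any(cc$bridges %in% used)) next
    used <- c(used, cc$bridges)
    grade <- if (is.null(profile)) NA_integer_ else
      profile$grade[match(cc$residues, profile$position)]
    out[[length(out) + 1L]] <- new_cluster(
      data.frame(position = cc$residues, aa = "C", role = "primary",
                 grade = grade, stringsAsFactors = FALSE),
      from_znc4 = TRUE)
  }
  out
}

#' Classify a cluster
#'
#' Rule table: `redox-switch-like` for all-cysteine clusters arising from
#' crossed disulfides; `sub-minimal` below `cfg$min_coordinators` members;
#' `structural-like` when at least three members are H/C and the mean
#' burial proxy reaches the buried threshold; `catalytic-like` otherwise
#' (mixed H/C with D/E/S ligands, or a solvent-exposed site).
#'
#' @param cl A `zn_cluster`.
#' @param s A `structure_model`.
#' @param cfg A [search_config()].
#' @return Classification label (character).
#' @export
classify_cluster <- function(cl, s, cfg = search_config()) {
  stopifnot(cluster_size(cl) >= 1L)
  if (isTRUE(cl$from_znc4) && all(cl$members$aa == "C"))
    return("redox-switch-like")
  if (cluster_size(cl) < cfg$min_coordinators) return("sub-minimal")
  n_hc <- sum(cl$members$aa %in% c("H", "C"))
  mean_burial <- mean(vapply(cl$members$position, burial_score, numeric(1),
                             s = s, radius = cfg$burial_radius))
  if (n_hc >= 3L && mean_burial >= cfg$buried_min_neighbors)
    "structural-like" else "catalytic-like"
}

#' Assign a cluster to a structural domain
#'
#' The label of the domain window containing the majority of members; ties
#' are broken by the domain of the lowest member position. Members outside
#' every window vote "unassigned".
#'
#' @param cl A `zn_cluster`.
#' @param s A `structure_model` with `domains` configured.
#' @return Domain label (character).
#' @export
assign_domain <- function(cl, s) {
  if (is.null(s$domains)) return("unassigned")
  label_of <- function(p) {
    for (nm in names(s$domains)) {
      w <- s$domains[[nm]]
      if (p >= w[1] && p <= w[2]) return(nm)
    }
    "unassigned"
  }
  votes <- vapply(cl$members$position, label_of, character(1))
  tab <- table(votes)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1L) return(winners)
  label_of(min(cl$members$position))
}

#' Full zinc-cluster search
#'
#' Runs the complete procedure: conserved H/C seeds, 3D proximity
#' components, D/E/S augmentation of sub-minimal clusters, crossed-disulfide
#' ZnC4 detection, classification and domain assignment. Clusters are named
#' `<domain>.<ordinal>` in ascending order of lowest member position within
#' each domain.
#'
#' @param s A `structure_model`.
#' @param profile A `conservation_profile` on the structure numbering.
#' @param cfg A [search_config()].
#' @param keep_subminimal Keep clusters below `min_coordinators` in the
#'   result (default `TRUE`; they are reported, not silently dropped).
#' @return List of named, classified `zn_cluster` objects ordered by
#'   lowest member position.
#' @export
find_zinc_clusters <- function(s, profile, cfg = search_config(),
                               keep_subminimal = TRUE) {
  cand <- find_primary_candidates(s, profile, cfg)
  cls <- build_clusters(cand, s, cfg)
  cls <- lapply(cls, augment_cluster, s = s, profile = profile, cfg = cfg)
  for (z in detect_znc4(s, profile, cfg)) {
    host <- which(vapply(cls, function(cl)
      all(z$members$position %in% cl$members$position), logical(1)))
    if (length(host) > 0L) {
      cls[[host[1L]]]$from_znc4 <- TRUE
    } else {
      cls[[length(cls) + 1L]] <- z
    }
  }
  if (length(cls) == 0L) return(list())
  cls <- cls[order(vapply(cls, function(cl) min(cl$members$position),
                          numeric(1)))]
  counters <- list()
  for (k in seq_along(cls)) {
    cls[[k]]$classification <- classify_cluster(cls[[k]], s, cfg)
    dom <- assign_domain(cls[[k]], s)
    cls[[k]]$domain <- dom
    counters[[dom]] <- (counters[[dom]] %||% 0L) + 1L
    cls[[k]]$id <- paste0(dom, ".", counters[[dom]])
  }
  if (!keep_subminimal)
    cls <- Filter(function(cl) cl$classification != "sub-minimal", cls)
  cls
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tabulate a cluster list
#'
#' @param clusters List of `zn_cluster` objects.
#' @return Data frame with one row per cluster: `id`, `domain`,
#'   `classification`, `size`, `members` (e.g. `"H20,H113,D143"`),
#'   `min_position`, and contrast columns when present.
#' @export
cluster_report <- function(clusters) {
  if (length(clusters) == 0L)
    return(data.frame(id = character(), domain = character(),
                      classification = character(), size = integer(),
                      members = character(), min_position = integer()))
  do.call(rbind, lapply(clusters, function(cl) {
    row <- data.frame(
      id = cl$id, domain = cl$domain, classification = cl$classification,
      size = cluster_size(cl),
      members = paste0(cl$members$aa, cl$members$position, collapse = ","),
      min_position = min(cl$members$position), stringsAsFactors = FALSE)
    if (!is.null(cl$contrast)) {
      row$inner_mean <- cl$contrast$inner_mean
      row$outer_mean <- cl$contrast$outer_mean
      row$contrast <- cl$contrast$delta
    }
    row
  }))
}

#' Write cluster reports
#'
#' Writes the tabular report as TSV and the full member-level detail as
#' JSON.
#'
#' @param clusters List of `zn_cluster` objects.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the report data frame.
#' @export
write_cluster_report <- function(clusters, tsv_path = NULL,
                                 json_path = NULL) {
  rep <- cluster_report(clusters)
  if (!is.null(tsv_path))
    write.table(rep, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(json_path)) {
    detail <- lapply(clusters, function(cl)
      list(id = cl$id, domain = cl$domain,
           classification = cl$classification,
           from_znc4 = cl$from_znc4, members = cl$members,
           contrast = if (is.null(cl$contrast)) NULL else
             unclass(cl$contrast)))
    jsonlite::write_json(detail, json_path, auto_unbox = TRUE,
                         dataframe = "rows", pretty = TRUE, digits = NA)
  }
  invisible(rep)
}
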