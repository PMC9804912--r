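test_that("primary candidates are the conserved H/C residues only", {
  st <- make_structure(60, sites = list(c("C", "C", "C", "C")),
                       n_decoys = 10, seed = 2)
  s <- structure_model(st$atoms)
  # planted Cys grade 9, decoy H/C grade 3, everything else grade 1
  grades <- rep(1L, length(s$sequence))
  pos <- as.integer(names(s$sequence))
  grades[pos %in% st$truth$planted_sites[[1]]] <- 9L
  grades[pos %in% st$truth$decoys] <- 3L
  prof <- profile_for(s, grades)

  cand <- find_primary_candidates(s, prof, search_config(min_grade = 7))
  expect_equal(sort(cand$position), st$truth$planted_sites[[1]])
  expect_true(all(cand$aa == "C"))
  expect_true(all(cand$role == "primary"))

  # min_grade 1 returns every H/C in the structure
  all_hc <- find_primary_candidates(s, prof, search_config(min_grade = 1))
  expect_equal(sort(all_hc$position),
               sort(c(st$truth$planted_sites[[1]], st$truth$decoys)))

  # no H/C at all -> empty
  s2 <- toy_structure(list(res_block(1, "A", cb = c(0, 0, 0)),
                           res_block(2, "D", fun = c(5, 0, 0))))
  expect_equal(nrow(find_primary_candidates(s2, profile_for(s2),
                                            search_config())), 0L)

  # profile/structure numbering disagreement is an error
  bad <- profile_for(s)
  bad$aa <- rev(bad$aa)
  expect_error(find_primary_candidates(s, bad, search_config()),
               "alignment mismatch")
})

test_that("proximity components form clusters; distant residues stay single", {
  tetrad <- toy_structure(list(
    res_block(1, "C", fun = c(0, 0, 0)),
    res_block(2, "C", fun = c(3, 0, 0)),
    res_block(3, "H", fun = c(0, 3, 0), fun_name = "NE2"),
    res_block(4, "H", fun = c(0, 0, 3), fun_name = "NE2")))
  cand <- find_primary_candidates(tetrad, profile_for(tetrad))
  cls <- build_clusters(cand, tetrad, search_config())
  expect_length(cls, 1L)
  expect_equal(cls[[1]]$members$position, 1:4)

  far <- toy_structure(list(
    res_block(1, "C", fun = c(0, 0, 0)),
    res_block(2, "C", fun = c(25, 0, 0)),
    res_block(3, "H", fun = c(50, 0, 0), fun_name = "NE2")))
  cls2 <- build_clusters(find_primary_candidates(far, profile_for(far)),
                         far, search_config())
  expect_length(cls2, 3L)
  expect_true(all(vapply(cls2, zincsites:::cluster_size, integer(1)) == 1L))

  # two planted tetrads 50+ A apart -> exactly two clusters of 4
  st <- make_structure(50, sites = list(c("C", "C", "C", "C"),
                                        c("H", "H", "C", "C")), seed = 6)
  s <- structure_model(st$atoms)
  cls3 <- build_clusters(find_primary_candidates(s, profile_for(s)),
                         s, search_config())
  expect_length(cls3, 2L)
  expect_equal(lapply(cls3, function(cl) cl$members$position),
               st$truth$planted_sites)
})

test_that("clustering matches a brute-force components oracle", {
  for (seed in 1:6) {
    n <- c(10, 20, 30, 40, 50, 15)[seed]
    s <- random_structure(n, span = 25, seed = seed)
    cand <- find_primary_candidates(s, profile_for(s), search_config())
    cls <- build_clusters(cand, s, search_config())
    got <- lapply(cls, function(cl) cl$members$position)
    d <- outer(seq_len(n), seq_len(n),
               Vectorize(function(i, j) min_functional_distance(s, i, j)))
    comp <- brute_components(d, 8.0)
    want <- unname(lapply(split(seq_len(n), comp), as.integer))
    want <- want[order(vapply(want, min, integer(1)))]
    expect_equal(got, want)
  }
})

test_that("cluster count never increases as d_pair grows", {
  s <- random_structure(30, span = 40, seed = 99)
  cand <- find_primary_candidates(s, profile_for(s), search_config())
  counts <- vapply(c(4, 6, 8, 10, 12), function(dp)
    length(build_clusters(cand, s, search_config(d_pair = dp))),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("sub-minimal clusters gain all qualifying conserved D/E/S", {
  # three His seeds plus two conserved acidic residues within reach
  s <- toy_structure(list(
    res_block(20, "H", fun = c(0, 0, 0), fun_name = "NE2"),
    res_block(113, "H", fun = c(4, 0, 0), fun_name = "NE2"),
    res_block(265, "H", fun = c(0, 4, 0), fun_name = "NE2"),
    res_block(143, "D", fun = c(0, 0, 4)),
    res_block(147, "E", fun = c(3, 3, 3)),
    res_block(400, "D", fun = c(90, 0, 0))))   # out of range
  prof <- profile_for(s)
  cls <- build_clusters(find_primary_candidates(s, prof, search_config()),
                        s, search_config())
  expect_length(cls, 1L)
  aug <- augment_cluster(cls[[1]], s, prof, search_config())
  expect_equal(aug$members$position, c(20L, 113L, 143L, 147L, 265L))
  expect_equal(aug$members$role[aug$members$position %in% c(143, 147)],
               rep("auxiliary", 2))

  # a full-size cluster is never augmented
  tetrad <- toy_structure(list(
    res_block(1, "C", fun = c(0, 0, 0)),
    res_block(2, "C", fun = c(3, 0, 0)),
    res_block(3, "H", fun = c(0, 3, 0), fun_name = "NE2"),
    res_block(4, "H", fun = c(0, 0, 3), fun_name = "NE2"),
    res_block(9, "D", fun = c(1, 1, 1))))
  prof2 <- profile_for(tetrad)
  cl4 <- build_clusters(find_primary_candidates(tetrad, prof2,
                                                search_config()),
                        tetrad, search_config())[[1]]
  expect_equal(augment_cluster(cl4, tetrad, prof2, search_config()), cl4)

  # a pair with nothing in range stays a pair
  pair <- toy_structure(list(
    res_block(1, "H", fun = c(0, 0, 0), fun_name = "NE2"),
    res_block(2, "C", fun = c(3, 0, 0))))
  prof3 <- profile_for(pair)
  clp <- build_clusters(find_primary_candidates(pair, prof3,
                                                search_config()),
                        pair, search_config())[[1]]
  aug2 <- augment_cluster(clp, pair, prof3, search_config())
  expect_equal(aug2$members$position, clp$members$position)
  expect_equal(classify_cluster(aug2, pair), "sub-minimal")

  # sequence adjacency qualifies an auxiliary that is 3D-distant
  seqadj <- toy_structure(list(
    res_block(10, "H", fun = c(0, 0, 0), fun_name = "NE2"),
    res_block(11, "S", fun = c(30, 0, 0)),
    res_block(14, "H", fun = c(3, 0, 0), fun_name = "NE2")))
  prof4 <- profile_for(seqadj)
  cl <- build_clusters(find_primary_candidates(seqadj, prof4,
                                               search_config()),
                       seqadj, search_config())[[1]]
  aug3 <- augment_cluster(cl, seqadj, prof4, search_config())
  expect_true(11 %in% aug3$members$position)
})

test_that("crossed disulfide bridges form a ZnC4 redox-switch cluster", {
  crossing <- toy_structure(list(
    res_block(1687, "C", fun = c(0, 0, 0)),
    res_block(1711, "C", fun = c(0, 0, 2.05)),
    res_block(1715, "C", fun = c(3, 0, 0)),
    res_block(1768, "C", fun = c(3, 0, 2.05))))
  z <- detect_znc4(crossing, cfg = search_config())
  expect_length(z, 1L)
  expect_equal(z[[1]]$members$position, c(1687L, 1711L, 1715L, 1768L))
  expect_true(z[[1]]$from_znc4)
  expect_equal(classify_cluster(z[[1]], crossing), "redox-switch-like")

  apart <- toy_structure(list(
    res_block(1, "C", fun = c(0, 0, 0)),
    res_block(2, "C", fun = c(0, 0, 2.05)),
    res_block(3, "C", fun = c(40, 0, 0)),
    res_block(4, "C", fun = c(40, 0, 2.05))))
  expect_length(detect_znc4(apart, cfg = search_config()), 0L)
})

test_that("classification follows the burial and composition rule table", {
  # buried H/H/H/D tetrad: surround with enough CB neighbours
  centre <- list(
    res_block(1, "H", fun = c(0, 0, 0), fun_name = "NE2"),
    res_block(2, "H", fun = c(3, 0, 0), fun_name = "NE2"),
    res_block(3, "H", fun = c(0, 3, 0), fun_name = "NE2"),
    res_block(4, "D", fun = c(0, 0, 3)))
  set.seed(1)
  packing <- lapply(5:40, function(i) {
    p <- runif(3, -4, 7)
    res_block(i, "A", cb = p, ca = p + c(0.5, 0, 0))
  })
  buried <- toy_structure(c(centre, packing))
  cl <- build_clusters(find_primary_candidates(buried, profile_for(buried)),
                       buried, search_config())[[1]]
  cl <- augment_cluster(cl, buried, profile_for(buried), search_config())
  expect_equal(classify_cluster(cl, buried), "structural-like")

  # exposed mixed-ligand site with a single His
  exposed <- toy_structure(list(
    res_block(1, "H", fun = c(0, 0, 0), fun_name = "NE2"),
    res_block(2, "E", fun = c(3, 0, 0)),
    res_block(3, "S", fun = c(0, 3, 0)),
    res_block(4, "D", fun = c(0, 0, 3))))
  cl2 <- zincsites:::new_cluster(data.frame(
    position = 1:4, aa = c("H", "E", "S", "D"),
    role = c("primary", rep("auxiliary", 3)), grade = 9L))
  expect_equal(classify_cluster(cl2, exposed), "catalytic-like")
})

test_that("domain assignment uses majority vote with low-position ties", {
  dom <- list("bb" = c(1, 326), "ct" = c(1635, 1770))
  s <- toy_structure(list(
    res_block(20, "H", fun = c(0, 0, 0), fun_name = "NE2"),
    res_block(113, "H", fun = c(3, 0, 0), fun_name = "NE2"),
    res_block(265, "H", fun = c(0, 3, 0), fun_name = "NE2"),
    res_block(1687, "C", fun = c(60, 0, 0)),
    res_block(1768, "C", fun = c(63, 0, 0)),
    res_block(900, "H", fun = c(120, 0, 0), fun_name = "NE2")),
    domains = dom)
  mk <- function(pos) zincsites:::new_cluster(data.frame(
    position = pos, aa = unname(s$sequence[as.character(pos)]),
    role = "primary", grade = 9L))
  expect_equal(assign_domain(mk(c(20, 113, 265)), s), "bb")
  expect_equal(assign_domain(mk(c(1687, 1768)), s), "ct")
  expect_equal(assign_domain(mk(900), s), "unassigned")
  # 1-1 tie between bb and ct resolves to the lowest member's domain
  expect_equal(assign_domain(mk(c(265, 1687)), s), "bb")
})

test_that("the full search is deterministic and members obey the grade rule", {
  st <- make_structure(70, sites = list(c("C", "C", "C", "C"),
                                        c("H", "H", "H", "H")),
                       n_decoys = 4, seed = 12)
  s <- structure_model(st$atoms)
  msa <- make_msa(paste(s$sequence, collapse = ""), 25,
                  conserved_positions = c(st$truth$conserved_positions,
                                          st$truth$decoys),
                  sub_rate = 0.7, seed = 13)
  prof <- compute_conservation(msa$alignment, "REF")
  run1 <- find_zinc_clusters(s, prof)
  run2 <- find_zinc_clusters(s, prof)
  expect_identical(run1, run2)
  for (cl in run1) {
    expect_true(all(cl$members$grade >= 7))
    expect_true(all(cl$members$aa[cl$members$role == "primary"]
                    %in% c("H", "C")))
    expect_true(all(cl$members$aa[cl$members$role == "auxiliary"]
                    %in% c("D", "E", "S")))
  }
})

test_that("planted tetrads are recovered with perfect precision and recall", {
  st <- make_structure(80, sites = list(c("C", "C", "C", "C"),
                                        c("H", "H", "C", "C")),
                       n_decoys = 6, seed = 21)
  s <- structure_model(st$atoms)
  msa <- make_msa(paste(s$sequence, collapse = ""), 30,
                  conserved_positions = c(st$truth$conserved_positions,
                                          st$truth$decoys),
                  sub_rate = 0.7, seed = 22)
  prof <- compute_conservation(msa$alignment, "REF")
  cls <- find_zinc_clusters(s, prof)
  found <- lapply(Filter(function(cl) cl$classification != "sub-minimal",
                         cls),
                  function(cl) cl$members$position)
  expect_equal(found[order(vapply(found, min, integer(1)))],
               st$truth$planted_sites)
})
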