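test_that("synthetic PDB text round-trips through the reader", {
  st <- make_structure(20, sites = list(c("C", "C", "C", "C")), seed = 3)
  f <- write_tmp(st$pdb, ".pdb")
  s <- read_structure(f)
  expect_s3_class(s, "structure_model")
  expect_equal(length(s$sequence), 20L)
  site <- st$truth$planted_sites[[1]]
  expect_equal(unname(s$sequence[as.character(site)]), rep("C", 4))

  # empty / unparseable file
  empty <- tempfile(fileext = ".pdb")
  file.create(empty)
  expect_error(read_structure(empty), "")
})

test_that("minimum functional distance is exact, symmetric and zero on self", {
  s <- toy_structure(list(
    res_block(1, "H", fun = c(0, 0, 0), fun_name = "NE2"),
    res_block(2, "C", fun = c(3, 4, 0)),
    res_block(3, "D", fun = c(0, 0, 30))))
  expect_equal(min_functional_distance(s, 1, 2), 5.0)        # 3-4-5 triangle
  expect_equal(min_functional_distance(s, 2, 1), 5.0)
  expect_equal(min_functional_distance(s, 1, 1), 0.0)
  expect_equal(min_functional_distance(s, 1, 3), 30.0)
  expect_error(min_functional_distance(s, 1, 99), "not present")
})

test_that("functional-atom fallback chain covers truncated side chains", {
  s <- toy_structure(list(
    res_block(1, "H", fun = c(0, 0, 0), fun_name = "NE2"),
    res_block(2, "L", cb = c(10, 0, 0), ca = c(11.5, 0, 0)),  # no functional
    res_block(3, "G", ca = c(20, 0, 0))))                     # CA only
  expect_equal(attr(functional_coords(s, 1), "fallback"), "functional")
  expect_equal(attr(functional_coords(s, 2), "fallback"), "sidechain")
  expect_equal(attr(functional_coords(s, 3), "fallback"), "CA")
  expect_equal(min_functional_distance(s, 1, 2), 10.0)
})

test_that("disulfide detection pairs nearest SG atoms once each", {
  s <- toy_structure(list(
    res_block(1, "C", fun = c(0, 0, 0)),
    res_block(2, "C", fun = c(2.05, 0, 0)),
    res_block(3, "C", fun = c(50, 0, 0)),
    res_block(4, "C", fun = c(55, 0, 0))))
  br <- detect_disulfides(s)
  expect_equal(nrow(br), 1L)
  expect_equal(c(br$res1, br$res2), c(1L, 2L))
  expect_equal(br$distance, 2.05)

  # three cysteines in a row: greedy nearest-first, each used once
  s2 <- toy_structure(list(
    res_block(1, "C", fun = c(0, 0, 0)),
    res_block(2, "C", fun = c(2.0, 0, 0)),
    res_block(3, "C", fun = c(4.2, 0, 0))))
  br2 <- detect_disulfides(s2)
  expect_equal(nrow(br2), 1L)
  expect_equal(c(br2$res1, br2$res2), c(1L, 2L))

  # independent of atom ordering in the file
  st <- make_structure(30, sites = list(c("C", "C", "C", "C")), seed = 9)
  f1 <- write_tmp(st$pdb, ".pdb")
  body <- setdiff(st$pdb, "END")
  f2 <- write_tmp(c(rev(body), "END"), ".pdb")
  expect_equal(detect_disulfides(read_structure(f1), sg_cutoff = 4),
               detect_disulfides(read_structure(f2), sg_cutoff = 4))
})

test_that("residue census counts windows and validates them", {
  st <- make_structure(50, sites = list(list(aa = c("H", "H", "H", "H"),
                                             residues = c(5, 12, 20, 33))),
                       n_decoys = 2, seed = 4)
  s <- read_structure(write_tmp(st$pdb, ".pdb"))
  h <- residue_census(s, c(1, 50), "H")
  expect_true(all(c(5, 12, 20, 33) %in% h$positions))
  expect_equal(h$count, length(h$positions))
  # full alphabet over the full sequence returns the sequence length
  full <- residue_census(s, c(1, 50), c(zincsites:::AA_CANONICAL, "X"))
  expect_equal(full$count, length(s$sequence))
  expect_error(residue_census(s, c(5, 4), "H"), "degenerate")
  expect_error(residue_census(s, c(0, 4), "H"), "degenerate")
})

test_that("burial proxy counts CB neighbours within the radius", {
  # 27-residue cubic lattice, 5 A spacing: centre sees all 26 within 10 A
  grid <- expand.grid(x = 0:2, y = 0:2, z = 0:2) * 5
  blocks <- lapply(seq_len(27), function(i)
    res_block(i, "A", cb = as.numeric(grid[i, ]),
              ca = as.numeric(grid[i, ]) + c(0.5, 0, 0)))
  s <- toy_structure(blocks)
  centre <- which(grid$x == 5 & grid$y == 5 & grid$z == 5)
  expect_equal(burial_score(s, centre, radius = 10), 26L)
  # brute-force check on a corner residue
  d <- as.matrix(dist(grid))
  expect_equal(burial_score(s, 1, radius = 10), sum(d[1, -1] <= 10))

  s2 <- toy_structure(list(res_block(1, "A", cb = c(0, 0, 0)),
                           res_block(2, "A", cb = c(11, 0, 0))))
  expect_equal(burial_score(s2, 1, radius = 10), 0L)
  s3 <- toy_structure(list(res_block(1, "A", cb = c(0, 0, 0))))
  expect_equal(burial_score(s3, 1, radius = 10), 0L)
})

test_that("generated structures re-read with functional distances intact", {
  st <- make_structure(40, sites = list(c("C", "C", "C", "C"),
                                        c("H", "D", "E", "S")),
                       n_decoys = 2, seed = 7)
  s_mem <- structure_model(st$atoms)
  s <- read_structure(write_tmp(st$pdb, ".pdb"))
  all_res <- as.integer(names(s$sequence))
  some <- all_res[seq(1, length(all_res), by = 4)]
  for (i in some) for (j in some) if (i < j)
    expect_lt(abs(min_functional_distance(s, i, j) -
                  min_functional_distance(s_mem, i, j)), 1e-3)
  # planted tetrahedral geometry: edge 2*2.1*sqrt(2/3) ~ 3.43, always < 4.2
  for (site in st$truth$planted_sites) {
    pairs <- combn(site, 2)
    for (k in seq_len(ncol(pairs))) {
      d <- min_functional_distance(s, pairs[1, k], pairs[2, k])
      expect_lt(abs(d - 2.1 * sqrt(8 / 3)), 0.01)
      expect_lt(d, 4.2)
    }
  }
})
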