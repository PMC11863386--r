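test_that("superposition recovers exact and noisy rigid motions", {
  s <- make_structure("ref")
  # self-superposition: zero RMSD, identity transform
  self <- superpose(s, s)
  expect_lt(self$rmsd, 1e-10)
  expect_equal(self$rotation, diag(3), tolerance = 1e-10)

  # a known rotation + translation is exactly inverted
  R <- rotation_matrix(c(1, 2, 3), 0.8)
  moved <- transform_structure(s, R, c(4, -2, 7))
  fit <- superpose(moved, s)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(as.matrix(fit$structure$atoms[c("x", "y", "z")]),
               as.matrix(s$atoms[c("x", "y", "z")]), tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)

  # anchor count mismatch is a correspondence error
  s2 <- s; s2$triad_anchor <- s$triad_anchor[1:4]
  expect_error(superpose(s2, s), "correspondence")
})

test_that("noisy superposition agrees with an independent oracle", {
  skip_if_not_installed("bio3d")
  set.seed(44)
  ref <- make_structure("ref")
  noisy <- make_structure("noisy", jitter = 0.1, seed = 2)
  R <- rotation_matrix(c(0, 1, 1), 1.2)
  noisy <- transform_structure(noisy, R, c(-3, 5, 1))
  fit <- superpose(noisy, ref)
  expect_gt(fit$rmsd, 0.01)
  expect_lt(fit$rmsd, 0.5)

  # oracle: bio3d least-squares fit on the same anchor coordinates
  M <- as.matrix(noisy$atoms[noisy$triad_anchor, c("x", "y", "z")])
  Rf <- as.matrix(ref$atoms[ref$triad_anchor, c("x", "y", "z")])
  mob <- as.vector(t(M)); fix <- as.vector(t(Rf))
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = fix, mobile = mob))
  rmsd_oracle <- sqrt(mean(colSums(
    (matrix(fitted, nrow = 3) - t(Rf))^2)))
  expect_equal(fit$rmsd, rmsd_oracle, tolerance = 1e-6)
})

test_that("RMSD is invariant under a global rigid motion of both structures", {
  ref <- make_structure("a")
  mob <- make_structure("b", jitter = 0.2, seed = 3)
  r0 <- superpose(mob, ref)$rmsd
  R <- rotation_matrix(c(1, 0, 2), -0.5)
  r1 <- superpose(transform_structure(mob, R, c(1, 1, 1)),
                  transform_structure(ref, R, c(1, 1, 1)))$rmsd
  expect_equal(r0, r1, tolerance = 1e-10)
})

test_that("charge proxies follow the fixed atom map with exclusions", {
  s <- make_structure("s1")
  p <- collect_proxies(list(s))
  # Lys NZ (+), Asp CG (-), Glu CD (-); His carries no proxy
  expect_equal(nrow(p), 3)
  expect_setequal(p$sign[p$residue_name == "LYS"], "+")
  expect_setequal(p$sign[p$residue_name %in% c("ASP", "GLU")], "-")
  nz <- s$atoms[s$atoms$residue_name == "LYS" &
                  s$atoms$atom_name == "NZ", ]
  expect_equal(p$x[p$residue_name == "LYS"], nz$x)

  # catalytic exclusion removes the residue
  p2 <- collect_proxies(list(s), exclusions = 60L)
  expect_false(60L %in% p2$residue_id)
  expect_equal(nrow(p2), 2)
})

test_that("site clustering equals the radius-graph components oracle", {
  set.seed(50)
  # tight group of 10 and a second group 20 A away
  g1 <- data.frame(structure_id = paste0("s", 1:10),
                   residue_id = 1L, residue_name = "ASP", sign = "-",
                   x = rnorm(10, 0, 0.3), y = rnorm(10, 0, 0.3),
                   z = rnorm(10, 0, 0.3))
  sites <- cluster_sites(g1, radius = 2.5, n_structures = 10)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$member_count, 10)
  expect_equal(sites$occupancy, 1)

  g2 <- g1; g2$x <- g2$x + 20; g2$structure_id <- paste0("t", 1:10)
  two <- cluster_sites(rbind(g1, g2), radius = 2.5, n_structures = 20)
  expect_equal(nrow(two), 2)
  expect_equal(sort(two$member_count), c(10, 10))

  # brute-force oracle on random points: connected components of the
  # graph linking proxies closer than the radius
  skip_if_not_installed("igraph")
  pts <- data.frame(structure_id = paste0("p", 1:40), residue_id = 1L,
                    residue_name = "GLU", sign = "-",
                    x = runif(40, 0, 12), y = runif(40, 0, 12),
                    z = runif(40, 0, 12))
  r <- 2.0
  cl <- cluster_sites(pts, radius = r, n_structures = 40)
  D <- as.matrix(dist(pts[c("x", "y", "z")]))
  gr <- igraph::graph_from_adjacency_matrix(D <= r & D > 0, "undirected")
  comp <- igraph::components(gr)
  expect_equal(nrow(cl), comp$no)
  expect_setequal(cl$member_count, unname(comp$csize))

  # permutation invariance of the input order
  perm <- sample(40)
  cl2 <- cluster_sites(pts[perm, ], radius = r, n_structures = 40)
  o1 <- cl[order(cl$x), ]; o2 <- cl2[order(cl2$x), ]
  expect_equal(o1$x, o2$x, tolerance = 1e-12)
  expect_equal(o1$member_count, o2$member_count)

  # empty input yields an empty result
  expect_equal(nrow(cluster_sites(g1[0, ], radius = 1)), 0)
})

test_that("column conservation maps reference positions gap-aware", {
  seqs <- c(ref = "MKDT-LS", paste0("q", 1:9))
  aln <- c(ref = "MKDT-LS",
           q1 = "MKDTALS", q2 = "MKDSALS", q3 = "MKDTALS",
           q4 = "MKETALS", q5 = "MKDTALS", q6 = "MKDTALS",
           q7 = "MKDTALS", q8 = "MKDTALS", q9 = "MK-TALS")
  path <- write_toy_alignment(as.list(aln))
  # reference position 3 is column 3: 8 D, 1 E, 1 gap among 10 rows
  tab <- column_conservation(path, "ref", 3)
  d <- tab[tab$residue == "D", ]
  expect_equal(d$percent, 100 * 8 / 9)  # gaps excluded from denominator
  expect_equal(d$column, 3)
  expect_equal(sum(tab$percent), 100)
  expect_false(any(tab$low_support))

  # gap rows counted on request
  tabg <- column_conservation(path, "ref", 3, count_gaps = TRUE)
  expect_equal(tabg$percent[tabg$residue == "D"], 80)

  # position mapping skips the reference gap: position 5 is column 6
  tab5 <- column_conservation(path, "ref", 5)
  expect_equal(unique(tab5$column), 6)
  expect_equal(tab5$percent[tab5$residue == "L"], 100)

  # order invariance
  tab_r <- column_conservation(rev(aln), "ref", 3)
  expect_equal(tab_r[order(tab_r$residue), c("residue", "percent")],
               tab[order(tab$residue), c("residue", "percent")])

  # a column with only the reference is flagged low-support
  aln2 <- c(ref = "MA-K", q1 = "M--K", q2 = "M--K")
  tab2 <- column_conservation(write_toy_alignment(as.list(aln2)),
                              "ref", 2)
  expect_equal(tab2$percent, 100)
  expect_equal(tab2$n_counted, 1)
  expect_true(tab2$low_support)

  # asking for a reference gap position errors
  expect_error(column_conservation(path, "ref", 10), "mapping error")
})

test_that("greedy redundancy filter drops near-duplicates", {
  aln <- c(a = "MKDTALS", b = "MKDTALS", c = "MKDTALT",
           d = "WWWWWWW")
  kept <- filter_redundant(aln, max_identity = 0.8)
  expect_setequal(names(kept), c("a", "d"))
  kept2 <- filter_redundant(aln, max_identity = 0.9)
  expect_true("c" %in% names(kept2))
})

test_that("PDB structures load with the His anchor", {
  skip_if_not_installed("bio3d")
  s <- make_structure("pdbtest")
  pdb_path <- tempfile(fileext = ".pdb")
  lines <- vapply(seq_len(nrow(s$atoms)), function(i) {
    a <- s$atoms[i, ]
    sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            i, a$atom_name, a$residue_name, a$residue_id, a$x, a$y, a$z)
  }, character(1))
  writeLines(c(lines, "END"), pdb_path)
  entry <- read_structure_pdb(pdb_path, his_resno = 64)
  expect_s3_class(entry, "structure_entry")
  expect_length(entry$triad_anchor, 6)
  expect_equal(sort(entry$atoms$atom_name[entry$triad_anchor]),
               sort(c("CB", "CG", "ND1", "CD2", "CE1", "NE2")))
  fit <- superpose(entry, s)
  expect_lt(fit$rmsd, 1e-2)
})
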