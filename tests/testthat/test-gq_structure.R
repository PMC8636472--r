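test_that("PDB round-trip preserves atoms, residues, chains and coordinates", {
  s <- build_tetramolecular_gq("TTGGGGT")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_gq_pdb(s, f)
  back <- read_gq_pdb(f)
  expect_identical(nrow(back$atom), nrow(s$atom))
  expect_identical(back$atom$elety, s$atom$elety)
  expect_identical(back$atom$resid, s$atom$resid)
  expect_identical(sort(unique(back$atom$chain)), c("A", "B", "C", "D"))
  expect_equal(back$atom$x, round(s$atom$x, 3))
  expect_equal(back$atom$z, round(s$atom$z, 3))
})

test_that("residue deletion removes atoms and keeps numbering", {
  s <- build_tetramolecular_gq("TTGGGGT")
  s1 <- delete_residues(s, c(1, 2))
  rt <- quadstruct:::.residue_table(s1)
  expect_identical(nrow(rt), 20L)                        # 5 per chain
  expect_identical(sort(unique(rt$resno)), 3:7)          # numbering unchanged
  expect_identical(delete_residues(s, integer(0)), s)
  expect_error(delete_residues(s, 99), "selection")
})

test_that("deleting everything leaves nothing for downstream operations", {
  s <- build_tetramolecular_gq("TTGGGGT")
  gone <- delete_residues(s, 1:7)
  expect_identical(nrow(gone$atom), 0L)
  expect_length(detect_tetrads(gone), 0)
  expect_error(append_residue_3prime(gone, "A"), "chain")
})

test_that("base mutation swaps base atoms on the glycosidic frame", {
  s <- build_tetramolecular_gq("TTGGGGT")
  before <- s$atom
  m <- mutate_base(s, "A", 7, "DG")
  res <- m$atom[m$atom$chain == "A" & m$atom$resno == 7, ]
  expect_identical(unique(res$resid), "DG")
  g_names <- c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4")
  expect_setequal(res$elety[res$elety %in% c(g_names, "O4", "O2", "C7")], g_names)
  expect_identical(length(intersect(res$elety, g_names)), 11L)
  # sugar-phosphate atoms keep their exact coordinates
  sugar <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'")
  old <- before[before$chain == "A" & before$resno == 7 & before$elety %in% sugar, ]
  new <- res[res$elety %in% sugar, ]
  expect_identical(new$x[order(new$elety)], old$x[order(old$elety)])
  # atoms outside the selection are untouched bitwise
  other_old <- before[!(before$chain == "A" & before$resno == 7), ]
  other_new <- m$atom[!(m$atom$chain == "A" & m$atom$resno == 7), ]
  expect_identical(other_new$x, other_old$x)
  expect_identical(other_new$y, other_old$y)
  expect_identical(other_new$z, other_old$z)
})

test_that("identity mutation and 8-bromo-G debromination behave as edits", {
  s <- build_tetramolecular_gq("TTGGGGT")
  expect_identical(mutate_base(s, "A", 3, "DG"), s)   # G -> G is a no-op

  # make residue 3 an 8-bromo-dG, then restore it
  at <- s$atom
  at$resid[at$chain == "A" & at$resno == 3] <- "BGM"
  c8 <- at[at$chain == "A" & at$resno == 3 & at$elety == "C8", ]
  br <- data.frame(elety = "BR", resid = "BGM", chain = "A", resno = 3,
                   x = c8$x + 1.9, y = c8$y, z = c8$z, elesy = "Br",
                   o = 1, b = 0, eleno = 0)
  bgm <- gq_structure(rbind(at, br))
  n0 <- nrow(bgm$atom)
  fixed <- mutate_base(bgm, "A", 3, "DG")
  expect_identical(nrow(fixed$atom), n0 - 1L)
  res <- fixed$atom[fixed$atom$chain == "A" & fixed$atom$resno == 3, ]
  expect_identical(unique(res$resid), "DG")
  expect_false("BR" %in% res$elety)
  # C8 coordinate untouched
  c8_new <- res[res$elety == "C8", ]
  expect_identical(c8_new$x, c8$x)
})

test_that("3' extension appends a complete template nucleotide", {
  s <- build_tetramolecular_gq("TTGGGGT")
  s1 <- s
  for (ch in c("A", "B", "C", "D")) s1 <- append_residue_3prime(s1, ch, "DC")
  rt <- quadstruct:::.residue_table(s1)
  expect_identical(nrow(rt), 32L)                       # +1 per chain
  added <- s1$atom[s1$atom$chain == "B" & s1$atom$resno == 8, ]
  expect_identical(unique(added$resid), "DC")
  expect_identical(nrow(added), 19L)                    # all DC heavy atoms
  expect_true(all(is.finite(c(added$x, added$y, added$z))))
  # new P sits 1.6 A from the old terminal O3'
  o3 <- s$atom[s$atom$chain == "B" & s$atom$resno == 7 & s$atom$elety == "O3'", ]
  p <- added[added$elety == "P", ]
  expect_equal(sqrt((p$x - o3$x)^2 + (p$y - o3$y)^2 + (p$z - o3$z)^2), 1.6,
               tolerance = 1e-6)
  expect_error(append_residue_3prime(s, "Z"), "chain")
})

test_that("strand joining renumbers and records n-1 junctions", {
  # the four-strand fixture taken through the published edit recipe:
  # delete T1/T2, mutate residue 7 T->G, append a 3' DC, then join
  s <- build_tetramolecular_gq("TTGGGGT")
  s <- delete_residues(s, c(1, 2))
  for (ch in c("A", "B", "C", "D")) s <- mutate_base(s, ch, 7, "DG")
  for (ch in c("A", "B", "C", "D")) s <- append_residue_3prime(s, ch, "DC")
  joined <- join_strands(s, c("A", "B", "C", "D"))
  rt <- quadstruct:::.residue_table(joined)
  expect_identical(unique(rt$chain), "A")
  expect_identical(nrow(rt), 24L)
  expect_identical(rt$resno, 1:24)
  expect_identical(nrow(joined$junctions), 3L)
  expect_true(all(joined$junctions$gap_A > 0))
  # per-strand sequence after the edits is G G G G G C
  expect_identical(rt$resid[1:6], c("DG", "DG", "DG", "DG", "DG", "DC"))

  single <- join_strands(build_tetramolecular_gq("TTGGGGT"), "A")
  expect_identical(nrow(quadstruct:::.residue_table(single)), 7L)
  expect_null(single$junctions)
})

test_that("5mC modification renames CpG cytosines and places the methyl", {
  sq <- mc9_22mer()
  gq <- build_ideal_gq(sq)
  n0 <- nrow(gq$atom)
  gm <- add_methyl_cpg(gq, sq)
  expect_identical(nrow(gm$atom), n0 + 3L)
  meth <- unique(gm$atom$resno[gm$atom$resid == "5CM"])
  expect_identical(meth, c(6L, 12L, 18L))               # 1-based CpG cytosines
  for (rn in meth) {
    res <- gm$atom[gm$atom$resno == rn, ]
    c5 <- unlist(res[res$elety == "C5", c("x", "y", "z")])
    c5a <- unlist(res[res$elety == "C5A", c("x", "y", "z")])
    expect_equal(sqrt(sum((c5 - c5a)^2)), 1.50, tolerance = 0.01)
    # out-of-plane deviation of the methyl carbon
    ring <- res[res$elety %in% c("N1", "C2", "N3", "C4", "C5", "C6"), ]
    X <- as.matrix(ring[, c("x", "y", "z")])
    ctr <- colMeans(X)
    nrm <- svd(sweep(X, 2, ctr))$v[, 3]
    expect_lt(abs(sum((c5a - ctr) * nrm)), 0.05)
  }
  expect_identical(add_methyl_cpg(gq, integer(0)), gq)
  expect_error(add_methyl_cpg(gq, 1), "not a DC")       # residue 1 is G
  expect_error(add_methyl_cpg(gq, 5), "CpG")            # C followed by C
})

test_that("tetrad detection finds the expected stacks", {
  gq <- build_ideal_gq(c9_22mer(), "antiparallel")
  tets <- detect_tetrads(gq)
  expect_length(tets, 4)
  expect_identical(vapply(tets, `[[`, integer(1), "stack_index"), 0:3)
  for (tt in tets) {
    expect_identical(nrow(tt$residues), 4L)
    expect_true(all(tt$hbond_dists <= 3.5))
    expect_equal(sqrt(sum(tt$normal^2)), 1, tolerance = 1e-9)
  }
  # 5'-most guanine (residue 1) sits in the stack_index 0 tetrad
  expect_true(1L %in% tets[[1]]$residues$resno)

  expect_length(detect_tetrads(linear_g_structure()), 0)
})

test_that("tetrad count equals tract length for tract lengths 2-5", {
  for (L in 2:5) {
    sq <- oligo_seq(paste0(strrep(paste0(strrep("G", L), "CC"), 3),
                           strrep("G", L)))
    for (topo in c("antiparallel", "parallel"))
      expect_length(detect_tetrads(build_ideal_gq(sq, topo)), L)
  }
})

test_that("breaking one tetrad's Hoogsteen contacts removes exactly that tetrad", {
  gq <- build_ideal_gq(c9_22mer())
  tets <- detect_tetrads(gq)
  # pull each guanine of tetrad 2 radially 5 A away from the quartet centre,
  # which stretches its cyclic donor-acceptor contacts past the cutoff
  victim <- tets[[2]]
  for (k in seq_len(4)) {
    sel <- gq$atom$chain == victim$residues$chain[k] &
      gq$atom$resno == victim$residues$resno[k]
    ctr_res <- colMeans(as.matrix(gq$atom[sel, c("x", "y", "z")]))
    u <- (ctr_res - victim$centroid)
    u <- 5 * u / sqrt(sum(u^2))
    gq$atom$x[sel] <- gq$atom$x[sel] + u[1]
    gq$atom$y[sel] <- gq$atom$y[sel] + u[2]
    gq$atom$z[sel] <- gq$atom$z[sel] + u[3]
  }
  expect_length(detect_tetrads(gq), 3)
})

test_that("tetrad detection is invariant to global rigid motion", {
  gq <- build_ideal_gq(c9_22mer())
  t1 <- detect_tetrads(gq)
  t2 <- detect_tetrads(rotate_structure(gq))
  expect_length(t2, length(t1))
  for (k in seq_along(t1))
    expect_identical(t2[[k]]$residues$resno, t1[[k]]$residues$resno)
})

test_that("inter-plane ion placement adds n-1 potassium ions at midpoints", {
  gq <- build_ideal_gq(c9_22mer())
  tets <- detect_tetrads(gq)
  gi <- place_interplane_ions(gq, tets)
  k <- gi$atom[gi$atom$resid == "K", ]
  expect_identical(nrow(k), 3L)

  two <- detect_tetrads(build_ideal_gq(oligo_seq("GGCCGGCCGGCCGG")))
  expect_length(two, 2)
  g2 <- place_interplane_ions(build_ideal_gq(oligo_seq("GGCCGGCCGGCCGG")), two)
  kk <- g2$atom[g2$atom$resid == "K", ]
  expect_identical(nrow(kk), 1L)
  # equidistant from the two tetrads' O6 centroids
  o6c <- function(s, tt) {
    X <- do.call(rbind, lapply(seq_len(4), function(i) {
      res <- s$atom[s$atom$chain == tt$residues$chain[i] &
                      s$atom$resno == tt$residues$resno[i] &
                      s$atom$elety == "O6", ]
      unlist(res[, c("x", "y", "z")])
    }))
    colMeans(X)
  }
  s2 <- build_ideal_gq(oligo_seq("GGCCGGCCGGCCGG"))
  kpos <- unlist(kk[, c("x", "y", "z")])
  d1 <- sqrt(sum((kpos - o6c(s2, two[[1]]))^2))
  d2 <- sqrt(sum((kpos - o6c(s2, two[[2]]))^2))
  expect_lt(abs(d1 - d2), 0.1)

  expect_warning(place_interplane_ions(gq, tets[1]), "fewer than 2")
})

test_that("idealized models are planar, complete and clash-free", {
  for (topo in c("antiparallel", "parallel")) {
    gq <- build_ideal_gq(c9_22mer(), topo)
    rt <- quadstruct:::.residue_table(gq)
    expect_identical(nrow(rt), 22L)                     # conservation
    expect_identical(count_clashes(gq, 2.0), 0L)
    # per-tetrad buckle of the static model is ~ 0
    buck <- tetrad_buckle_series(static_trajectory(gq, 2))
    expect_true(all(abs(buck$summary$mean) < 0.5))
  }
  expect_error(build_ideal_gq(oligo_seq("GGGGCC")), "topology")
})

test_that("clash counting uses non-bonded heavy-atom pairs", {
  two <- gq_structure(data.frame(
    elety = c("C1'", "C1'"), resid = c("DG", "DG"), chain = "A",
    resno = c(1L, 2L), x = c(0, 1), y = 0, z = 0))
  expect_identical(count_clashes(two, 2.0), 1L)
  one <- gq_structure(two$atom[1, ])
  expect_identical(count_clashes(one), 0L)
  # bonded backbone junction O3'-P is exempt
  bonded <- gq_structure(data.frame(
    elety = c("O3'", "P"), resid = c("DG", "DG"), chain = "A",
    resno = c(1L, 2L), x = c(0, 1.6), y = 0, z = 0))
  expect_identical(count_clashes(bonded, 2.0), 0L)
})
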