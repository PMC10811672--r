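# Hand-computed geometry: residue A's CA at origin, residue B's CA at
# (20,0,0); ligand atoms at (5,0,0) and (5,0,-50) -> min distances 5 and
# 15 exactly (the far atom is never the nearest).
two_residue_case <- function() {
  st <- ca_chain(rbind(c(0, 0, 0), c(20, 0, 0)))
  st$atoms <- rbind(st$atoms, data.frame(
    record = "HETATM", chain = "L", res_name = "LIG", auth_seq_id = 900L,
    ins = "", seq_index = NA_integer_, atom_name = c("C1", "C2"), element = "C",
    x = 5, y = 0, z = c(0, -50), occ = 1, b = 0, is_hetero = TRUE,
    stringsAsFactors = FALSE))
  st
}

test_that("ligand shell selects residues by hand-computed heavy-atom distance", {
  st <- two_residue_case()
  sel <- ligand_shell(st, "LIG", cutoff = 7)
  expect_equal(sel$positions$seq_index, 1L)        # d = 5 in, d = 15 out
  expect_equal(attr(sel, "min_distances"), 5)
  expect_equal(nrow(ligand_shell(st, "LIG", cutoff = 1e-9)$positions), 0)
  expect_equal(ligand_shell(st, "LIG", cutoff = 16)$positions$seq_index, c(1L, 2L))
  expect_equal(sel$label, "shell")
})

test_that("a missing ligand errors naming what is available", {
  st <- two_residue_case()
  expect_error(ligand_shell(st, "HEM"), "LIG")
})

test_that("hydrogens are ignored in shell distances", {
  st <- two_residue_case()
  # hydrogen on residue 2, right next to the ligand atom: must not count
  st$atoms <- rbind(st$atoms, data.frame(
    record = "ATOM", chain = "A", res_name = "ALA", auth_seq_id = 2L,
    ins = "", seq_index = 2L, atom_name = "H", element = "H",
    x = 5.5, y = 0, z = 0, occ = 1, b = 0, is_hetero = FALSE,
    stringsAsFactors = FALSE))
  expect_equal(ligand_shell(st, "LIG", cutoff = 7)$positions$seq_index, 1L)
})

test_that("shell grows monotonically with the cutoff", {
  toy <- make_toy_structure(40, c(4.5, NA, NA, NA, NA, NA, NA, NA, NA, 5.5,
                                  NA, NA, NA, NA, NA, NA, NA, NA, NA, 6.5),
                            seed = 5)
  prev <- integer()
  for (cutoff in c(2, 4, 5, 6, 7, 9, 12)) {
    cur <- ligand_shell(toy$structure, "LIG", cutoff)$positions$seq_index
    expect_true(all(prev %in% cur))
    expect_setequal(cur, toy$true_shell(cutoff))   # generator's planted truth
    prev <- cur
  }
})

test_that("conservation scores are parent-identity column frequencies", {
  rows <- rbind(strsplit("ACDEF", "")[[1]],
                strsplit("ACDEF", "")[[1]],
                strsplit("AC-EF", "")[[1]],
                strsplit("AGDEW", "")[[1]])
  msa <- structure(list(rows = rows, ids = letters[1:4], parent_row = 1L),
                   class = "funcfix_msa")
  prof <- conservation_scores(msa)
  # direct counts on the printed toy: A 4/4, C 3/4, D 3/4 (gap in denominator),
  # E 4/4, F 3/4
  expect_equal(unname(prof$scores), c(1, 0.75, 0.75, 1, 0.75))
  expect_equal(prof$metric_name, "parent_frequency")
  expect_equal(prof$n_effective, c(4L, 4L, 3L, 4L, 4L))
})

test_that("invariant columns score 1 and a parent-only residue scores 1/n", {
  m <- make_toy_msa("AAAA", 8, 1.0, seed = 1)
  expect_equal(unname(conservation_scores(m$msa)$scores), rep(1, 4))
  m2 <- make_toy_msa("WWWW", 8, 1 / 8, seed = 1)
  expect_equal(unname(conservation_scores(m2$msa)$scores), rep(1 / 8, 4))
})

test_that("conservation scores stay in [0,1] for both metrics", {
  for (seed in 1:3) {
    m <- make_toy_msa("MKTAYIAKQRQISFVK", 20,
                      rep(c(1, 0.8, 0.5, 0.25), 4), seed = seed)
    for (metric in c("parent_frequency", "entropy")) {
      sc <- conservation_scores(m$msa, metric = metric)$scores
      expect_true(all(sc >= 0 & sc <= 1))
    }
    # score 1 iff column invariant at the parent residue (default metric)
    sc <- conservation_scores(m$msa)$scores
    invariant <- apply(m$msa$rows, 2, function(col) length(unique(col)) == 1)
    expect_equal(unname(sc == 1), unname(invariant))
  }
})

test_that("top_conserved takes the ceiling count with seq-index tie-break", {
  prof <- structure(list(scores = c(0.9, 0.2, 0.8, 0.5, 0.7, 0.1, 0.95,
                                    0.3, 0.6, 0.4),
                         parent_column = 1:10, n_effective = rep(10L, 10),
                         metric_name = "parent_frequency"),
                    class = "funcfix_conservation")
  expect_equal(nrow(top_conserved(prof, 0)$positions), 0)
  expect_equal(top_conserved(prof, 100)$positions$seq_index, 1:10)
  # explicit sort of the toy profile: top-3 scores 0.95, 0.9, 0.8 at 7, 1, 3
  expect_equal(top_conserved(prof, 30)$positions$seq_index, c(1L, 3L, 7L))
  # ties broken by ascending index: all scores equal, 20% of 10 -> first 2
  tied <- prof; tied$scores <- rep(0.5, 10)
  expect_equal(top_conserved(tied, 20)$positions$seq_index, c(1L, 2L))
})

test_that("conservation selections are nested across 30/50/70 percent", {
  m <- make_toy_msa("MKTAYIAKQRQISFVKSHFS", 20,
                    rep(c(1, 0.85, 0.6, 0.45, 0.3), 4), seed = 9)
  prof <- conservation_scores(m$msa)
  sels <- lapply(c(30, 50, 70), function(p) top_conserved(prof, p)$positions$seq_index)
  expect_true(all(sels[[1]] %in% sels[[2]]))
  expect_true(all(sels[[2]] %in% sels[[3]]))
  expect_equal(lengths(sels), ceiling(c(30, 50, 70) / 100 * 20))
})

test_that("mask union merges provenance and keeps the fixed/free partition", {
  toy <- make_toy_structure(15, seed = 2)
  shell <- residue_selection("A", c(3, 5, 9), "shell")
  cons <- residue_selection("A", c(5, 12), "conserved")
  mask <- build_mask(toy$structure, list(shell, cons), design_chains = "A")
  expect_equal(mask$fixed$seq_index, c(3L, 5L, 9L, 12L))
  expect_equal(mask$sources$provenance[mask$sources$seq_index == 5],
               "conserved,shell")
  # partition invariant: disjoint and exhaustive
  expect_length(intersect(mask$fixed$seq_index, mask$free$seq_index), 0)
  expect_setequal(c(mask$fixed$seq_index, mask$free$seq_index), 1:15)

  # union with the empty selection is the identity
  mask2 <- build_mask(toy$structure,
                      list(shell, residue_selection(character(), integer(), "manual")),
                      design_chains = "A")
  expect_equal(mask2$fixed$seq_index, shell$positions$seq_index)
})

test_that("selections outside the design chains or structure are rejected", {
  toy <- make_toy_structure(10, seed = 2)
  expect_error(build_mask(toy$structure,
                          list(residue_selection("B", 1, "manual")),
                          design_chains = "A"),
               "outside design chains")
  expect_error(build_mask(toy$structure,
                          list(residue_selection("A", 99, "manual")),
                          design_chains = "A"),
               "absent")
})

test_that("fixed-position JSON matches the backend dialect and is byte-stable", {
  toy <- make_toy_structure(10, seed = 2)
  empty <- build_mask(toy$structure, list(), design_chains = "A")
  expect_equal(emit_fixed_positions(empty, "name"), '{"name":{"A":[]}}')
  m <- build_mask(toy$structure, list(residue_selection("A", c(5, 2), "manual")),
                  design_chains = "A")
  expect_equal(emit_fixed_positions(m, "name"), '{"name":{"A":[2,5]}}')
  expect_identical(emit_fixed_positions(m, "name"), emit_fixed_positions(m, "name"))
})

test_that("two-chain masks list every design chain, sorted", {
  atoms <- data.frame(chain = c("B", "B", "B", "B", "B", "B", "B", "A"),
                      auth_seq_id = c(1:7, 1L), seq_index = c(1:7, 1L),
                      x = seq(0, 28, by = 4), y = 0, z = 0)
  st <- hand_structure(atoms)
  m <- build_mask(st, list(residue_selection(c("A", "B", "B"), c(1, 4, 7), "manual")),
                  design_chains = c("A", "B"))
  expect_equal(emit_fixed_positions(m, "name"), '{"name":{"A":[1],"B":[4,7]}}')
})

test_that("mask report counts fixed/free and carries provenance through", {
  toy <- make_toy_structure(10, seed = 2)
  free_mask <- build_mask(toy$structure, list(), design_chains = "A")
  rep0 <- mask_report(free_mask, toy$structure)
  expect_equal(attr(rep0, "n_fixed"), 0)
  expect_equal(attr(rep0, "fraction_fixed"), 0)

  m <- build_mask(toy$structure,
                  list(residue_selection("A", c(1, 4, 6, 9), "shell")),
                  design_chains = "A")
  rep1 <- mask_report(m, toy$structure)
  expect_equal(attr(rep1, "fraction_fixed"), 0.4)
  expect_equal(rep1$seq_index[rep1$provenance == "shell"], c(1L, 4L, 6L, 9L))
  expect_equal(rep1$status[rep1$seq_index == 2], "free")
})
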