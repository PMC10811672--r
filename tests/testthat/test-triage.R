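rot_z <- function(th) matrix(c(cos(th), -sin(th), 0,
                               sin(th), cos(th), 0, 0, 0, 1), 3, byrow = TRUE)
rot_axis <- function(axis, th) {
  axis <- axis / sqrt(sum(axis^2))
  k <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, byrow = TRUE)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

test_that("superposition recovers rigid motions to machine precision", {
  set.seed(42)
  p <- matrix(rnorm(45), 15)
  expect_equal(kabsch_superpose(p, p)$rmsd, 0, tolerance = 1e-12)
  r <- rot_axis(c(1, 2, -0.5), 37 * pi / 180)
  q <- p %*% t(r) + matrix(c(3, -2, 7), 15, 3, byrow = TRUE)
  k <- kabsch_superpose(p, q)
  expect_lt(k$rmsd, 1e-6)
  expect_equal(det(k$rotation), 1, tolerance = 1e-9)
})

test_that("superposition agrees with the brute-force oracle on a scaled square", {
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  q <- 2 * p
  got <- kabsch_superpose(p, q)$rmsd
  # closed form for this symmetric case: sqrt(mean |pc|^2) = sqrt(1/2)
  expect_equal(got, sqrt(0.5), tolerance = 1e-9)
  expect_equal(got, oracle_rigid_rmsd(p, q), tolerance = 1e-3)
})

test_that("superposition rejects reflections and flags collinear input", {
  set.seed(7)
  p <- matrix(rnorm(30), 10)
  q <- p %*% diag(c(1, 1, -1))                    # mirror image
  k <- kabsch_superpose(p, q)
  expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  expect_gt(k$rmsd, 0)
  line <- cbind(seq_len(5), 0, 0)
  expect_true(kabsch_superpose(line, line)$collinear)
  expect_error(kabsch_superpose(p[1:2, ], q[1:2, ]), "under-determined")
})

test_that("superposition matches an independent structural-biology implementation", {
  set.seed(11)
  p <- matrix(rnorm(60), 20)
  q <- p + matrix(rnorm(60, 0, 0.5), 20)
  ours <- kabsch_superpose(p, q)$rmsd
  ref <- bio3d::rmsd(as.numeric(t(p)), as.numeric(t(q)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("ca_rmsd is zero on identical coordinates and invariant to rigid motion", {
  toy <- make_toy_structure(30, seed = 4)
  ref_ca <- as.matrix(toy$structure$atoms[!toy$structure$atoms$is_hetero,
                                          c("x", "y", "z")])
  cand <- design_candidate("self", strrep("A", 30), ref_ca, rep(90, 30))
  expect_equal(ca_rmsd(cand, toy$structure), 0, tolerance = 1e-9)
  moved <- design_candidate("moved", strrep("A", 30),
                            ref_ca %*% t(rot_z(1.1)) +
                              matrix(c(5, 5, 5), 30, 3, byrow = TRUE),
                            rep(90, 30))
  expect_lt(ca_rmsd(moved, toy$structure), 1e-6)
})

test_that("ca_rmsd of sigma-perturbed models approaches sigma*sqrt(3)", {
  toy <- make_toy_structure(200, seed = 4)
  sigma <- 0.4
  set.seed(123)
  vals <- replicate(20, {
    ref_ca <- as.matrix(toy$structure$atoms[!toy$structure$atoms$is_hetero,
                                            c("x", "y", "z")])
    cand <- design_candidate("noisy", strrep("A", 200),
                             ref_ca + matrix(rnorm(600, 0, sigma), 200),
                             rep(90, 200))
    ca_rmsd(cand, toy$structure)
  })
  expect_equal(mean(vals), sigma * sqrt(3), tolerance = 0.03)
})

test_that("region-restricted RMSD superposes and measures on the same subset", {
  toy <- make_toy_structure(40, seed = 4)
  ref_ca <- as.matrix(toy$structure$atoms[!toy$structure$atoms$is_hetero,
                                          c("x", "y", "z")])
  # displace a "loop" (residues 10-20); rest identical
  mod <- ref_ca
  mod[10:20, ] <- mod[10:20, ] + 2
  cand <- design_candidate("loop", strrep("A", 40), mod, rep(90, 40))
  loop <- residue_selection("A", 10:20, "manual")
  rest <- residue_selection("A", c(1:9, 21:40), "manual")
  expect_lt(ca_rmsd(cand, toy$structure, selection = loop), 1e-6)
  expect_lt(ca_rmsd(cand, toy$structure, selection = rest), 1e-6)
  expect_gt(ca_rmsd(cand, toy$structure), 0.5)   # global misfit remains
})

test_that("length mismatches refuse to pair silently", {
  toy <- make_toy_structure(30, seed = 4)
  short <- design_candidate("short", strrep("A", 29),
                            matrix(0, 29, 3), rep(90, 29))
  expect_error(ca_rmsd(short, toy$structure), "pair")
  expect_error(percent_identity("ACDEF", "ACDE"), "length")
})

test_that("percent identity counts positional matches symmetrically", {
  expect_equal(percent_identity("ACDEF", "ACDEF"), 100)
  expect_equal(percent_identity("ACDEF", "ACDFF"), 80)
  expect_equal(percent_identity("AAAA", "GGGG"), 0)
  a <- "MKTAYIAK"; b <- "MKTGYIAW"
  expect_equal(percent_identity(a, b), percent_identity(b, a))
})

test_that("the confidence/RMSD filter matches hand enumeration with strict bounds", {
  toy <- make_toy_structure(50, seed = 6)
  spec <- data.frame(id = paste0("d", 1:5),
                     noise = c(0.10, 0.05, 0.05, 1.20, 0.60),
                     plddt = c(90, 84, 85, 92, 88))
  cands <- make_candidates(toy$structure, spec, seed = 13)
  res <- filter_candidates(cands, toy$structure, plddt_min = 85, rmsd_max = 1.0)
  # hand evaluation of the two strict inequalities per candidate
  rmsds <- vapply(cands, ca_rmsd, 0, reference = toy$structure)
  expected <- spec$plddt > 85 & rmsds < 1.0
  expect_equal(res$pass, expected)
  expect_false(res$pass[3])                      # exactly at 85.0 fails
  expect_match(res$reasons[3], "mean_plddt")
  expect_equal(res$id, spec$id)                  # input order preserved
  expect_true(all(res$reasons[res$pass] == ""))
})

test_that("an 87.5 threshold passes a zero-RMSD model with mean pLDDT 90", {
  toy <- make_toy_structure(30, seed = 6)
  cands <- make_candidates(toy$structure,
                           data.frame(id = "native-like", noise = 0, plddt = 90),
                           seed = 1)
  res <- filter_candidates(cands, toy$structure, plddt_min = 87.5, rmsd_max = 1.0)
  expect_true(res$pass)
})

test_that("filtering is idempotent and monotone in the thresholds", {
  toy <- make_toy_structure(50, seed = 6)
  spec <- data.frame(id = paste0("c", 1:8),
                     noise = runif(8, 0, 1.2) * 0 + seq(0.05, 1.2, length.out = 8),
                     plddt = seq(78, 95, length.out = 8))
  cands <- make_candidates(toy$structure, spec, seed = 3)
  res <- filter_candidates(cands, toy$structure, 85, 1.0)
  passers <- cands[res$pass]
  again <- filter_candidates(passers, toy$structure, 85, 1.0)
  expect_true(all(again$pass))                   # idempotence
  stricter <- filter_candidates(cands, toy$structure, 90, 0.5)
  expect_true(all(stricter$pass <= res$pass))    # monotonicity
  expect_equal(nrow(filter_candidates(list(), toy$structure, 85, 1)), 0)
})

test_that("triage reports sort by pass then confidence and count passes", {
  res <- data.frame(id = c("a", "b", "c", "d"),
                    mean_plddt = c(80, 95, 90, 88),
                    ca_rmsd = c(0.5, 0.4, 2.0, 0.6),
                    identity_to_parent = NA_real_,
                    pass = c(FALSE, TRUE, FALSE, TRUE),
                    reasons = c("x", "", "y", ""))
  class(res) <- c("funcfix_triage", "data.frame")
  f <- withr::local_tempfile(fileext = ".tsv")
  sorted <- triage_report(res, f)
  expect_equal(sorted$id, c("b", "d", "c", "a"))  # manual sort of the 4 rows
  lines <- readLines(f)
  expect_equal(lines[1], "# passed 2 of 4")
  expect_length(lines, 6)

  empty <- res[0, ]
  f2 <- withr::local_tempfile(fileext = ".tsv")
  triage_report(empty, f2)
  expect_equal(readLines(f2)[1], "# passed 0 of 0")
})
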