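# helper: an accepted fit with a chosen distance
fake_fit <- function(d, gi = "H1", gj = "M1", accepted = TRUE, q = 0.01) {
  structure(list(group_i = gi, group_j = gj, sigma = -0.5, distance = d,
                 fit_quality = q, accepted = accepted, m0 = 1),
            class = "crossrelax_fit")
}

test_that("upper-limit calibration applies the protocol tolerance floors", {
  # single ligand proton + receptor methyl, fitted below the floor
  r1 <- calibrate_upper_limit(fake_fit(3.1), ligand_is_methyl = FALSE,
                              receptor_is_methyl = TRUE)
  expect_identical(r1$bound, 5.5)
  expect_identical(r1$bound_type, "upper")
  expect_identical(r1$source, "NOE")
  # two methyl groups
  r2 <- calibrate_upper_limit(fake_fit(4.0), ligand_is_methyl = TRUE,
                              receptor_is_methyl = TRUE)
  expect_identical(r2$bound, 6.5)
  # fitted distance beyond the floor is kept
  r3 <- calibrate_upper_limit(fake_fit(7.0), FALSE, TRUE)
  expect_identical(r3$bound, 7.0)
  # tight protocol adds a tolerance instead of flooring
  r4 <- calibrate_upper_limit(fake_fit(3.1), FALSE, TRUE,
                              protocol = "trim24", trim24_tolerance = 0.5)
  expect_equal(r4$bound, 3.6)
  expect_error(calibrate_upper_limit(fake_fit(3, accepted = FALSE),
                                     FALSE, TRUE), "rejected")
  # proton_group objects work as methyl flags
  pg <- proton_group("Q7", "ligand-methyl", 3)
  expect_identical(calibrate_upper_limit(fake_fit(4), pg,
                                         proton_group("m", "receptor-methyl",
                                                      3))$bound, 6.5)
})

test_that("anti-NOE construction follows the conservative two-sided rule", {
  vis <- data.frame(group_i = c("H1", "M1", "H2"),
                    group_j = c("M2", "H3", "M1"))
  # absent pair, one methyl, both sides have other NOEs -> 3.0 A
  a1 <- build_anti_noe("H1", "M1", FALSE, TRUE, vis)
  expect_identical(a1$bound, 3.0)
  expect_identical(a1$bound_type, "lower")
  expect_identical(a1$source, "anti-NOE")
  # two methyls -> 3.6 A
  a2 <- build_anti_noe("Q7", "M1", TRUE, TRUE,
                       rbind(vis, data.frame(group_i = "Q7", group_j = "M9")))
  expect_identical(a2$bound, 3.6)
  # one side without any other NOE -> nothing emitted
  expect_null(build_anti_noe("H9", "M1", FALSE, TRUE, vis))
  # pair actually present -> error
  expect_error(build_anti_noe("H1", "M2", FALSE, TRUE, vis), "not an anti-NOE")
})

test_that("prochiral pairing recovers geminal pairs and stays injective", {
  ctx <- relaxation_context(10.1e-9, 800)
  expect_length(pair_prochirals(data.frame(res_i = character(),
                                           res_j = character(),
                                           sigma = numeric()),
                                ctx = ctx)$pairs, 0)
  two <- data.frame(res_i = "M1", res_j = "M2",
                    sigma = sigma_from_distance(2.5, ctx))
  expect_identical(pair_prochirals(two, ctx = ctx)$pairs, list(c("M1", "M2")))
  # 6 resonances from 3 geminal pairs (2.5 A) + weak inter-residue peaks
  geminal_d <- 2.5; inter_d <- 5.0
  pk <- rbind(
    data.frame(res_i = c("M1", "M3", "M5"), res_j = c("M2", "M4", "M6"),
               sigma = sigma_from_distance(geminal_d, ctx)),
    data.frame(res_i = c("M1", "M2", "M4"), res_j = c("M3", "M5", "M6"),
               sigma = sigma_from_distance(inter_d, ctx)))
  got <- pair_prochirals(pk, ctx = ctx)$pairs
  expect_setequal(got, list(c("M1", "M2"), c("M3", "M4"), c("M5", "M6")))
  ids <- unlist(got)
  expect_identical(anyDuplicated(ids), 0L)
})

test_that("residue-class constraints restrict candidates and set anchors", {
  resonances <- data.frame(id = c("M1", "M2", "M3"),
                           class = c("Thr", "unknown", "Ala"))
  inventory <- data.frame(id = c("THR1.CG2", "ALA2.CB", "ALA3.CB",
                                 "LEU4.CD1", "LEU4.CD2"),
                          class = c("Thr", "Ala", "Ala", "ILV", "ILV"))
  out <- apply_residue_classes(resonances, inventory)
  expect_identical(out$candidates$M1, "THR1.CG2")
  expect_identical(out$anchors[["M1"]], "THR1.CG2")
  expect_identical(out$candidates$M2, inventory$id)
  # brute-force filter oracle for the Ala case
  expect_identical(out$candidates$M3,
                   inventory$id[inventory$class == "Ala"])
  expect_length(out$candidates$M3, 2)
  expect_error(apply_residue_classes(
    data.frame(id = "M9", class = "Met"), inventory), "infeasible")
})

test_that("restraint-set assembly conserves counts and deduplicates", {
  expect_length(build_restraint_set(), 0)
  noes <- lapply(1:39, function(k)
    distance_restraint(paste0("H", k %% 8 + 1), paste0("M", k), "upper",
                       5.5, source = "NOE", resonance = paste0("M", k)))
  antis <- lapply(1:37, function(k)
    distance_restraint(paste0("H", k %% 8 + 1), paste0("M", k + 50), "lower",
                       3.0, source = "anti-NOE",
                       resonance = paste0("M", k + 50)))
  rs <- build_restraint_set(noes, antis)
  expect_length(rs, 76)
  cts <- attr(rs, "counts")
  expect_identical(unname(cts[["NOE"]] + cts[["anti-NOE"]]), 76L)
  # duplicates removed with a warning
  dup <- noes[c(1, 1, 2, 2, 3)]
  expect_warning(rs2 <- build_restraint_set(dup), "2 duplicate")
  expect_length(rs2, 3)
  # invariants on bounds
  expect_true(all(vapply(rs, function(r)
    if (r$bound_type == "upper") r$bound >= 1.8
    else r$bound %in% c(3.0, 3.6), logical(1))))
})

test_that("distance_restraint enforces its invariants", {
  expect_error(distance_restraint("H1", "M1", "upper", 1.0), "1.8")
  expect_error(distance_restraint("H1", "M1", "lower", 3.3,
                                  source = "anti-NOE"), "3.0 or 3.6")
  expect_error(distance_restraint("H1", character(), "upper", 5.5), "candidate")
  expect_error(proton_group("x", "ligand-proton", multiplicity = 2), "1, 3 or 6")
  expect_error(proton_group("x", "ligand-proton", assigned_to = "m"),
               "receptor-methyl")
})
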