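test_that("assignment enumeration matches brute force", {
  expect_length(enumerate_assignments(list(A = "m1")), 1)
  cs <- list(A = paste0("m", 1:4), B = paste0("m", 1:4), C = paste0("m", 1:4))
  expect_length(enumerate_assignments(cs), 24)
  cs3 <- list(A = paste0("m", 1:3), B = paste0("m", 1:3), C = paste0("m", 1:3))
  anch <- c(A = "m1")
  hyps <- enumerate_assignments(cs3, anchors = anch)
  expect_length(hyps, oracle_count_assignments(cs3, anch))
  expect_true(all(vapply(hyps, function(m) m[["A"]] == "m1", logical(1))))
  # random instances vs the brute-force oracle
  set.seed(9)
  for (rep in 1:8) {
    nr <- sample(2:5, 1); nm <- sample(nr:6, 1)
    cs <- lapply(seq_len(nr), function(i)
      sample(paste0("m", 1:nm), sample(2:nm, 1)))
    names(cs) <- paste0("R", seq_len(nr))
    expect_length(enumerate_assignments(cs), oracle_count_assignments(cs))
  }
  expect_error(enumerate_assignments(cs3, max_count = 2), "max_count")
  expect_error(enumerate_assignments(list(A = character())), "empty candidate")
})

test_that("prochiral pairing constrains enumeration to geminal pairs", {
  cs <- list(R1 = c("a1", "a2", "b1", "b2"), R2 = c("a1", "a2", "b1", "b2"),
             R3 = c("a1", "a2", "b1", "b2"))
  gem <- c(a1 = "a2", a2 = "a1", b1 = "b2", b2 = "b1")
  pairing <- list(c("R1", "R2"))
  hyps <- enumerate_assignments(cs, pairing = pairing, geminal = gem)
  # R1/R2 -> one of 2 pairs x 2 orientations; R3 -> 2 remaining = 8
  expect_length(hyps, 8)
  expect_length(hyps, oracle_count_assignments(cs, pairing = pairing,
                                               geminal = gem))
  for (m in hyps) expect_identical(gem[[m[["R1"]]]], m[["R2"]])
  expect_error(enumerate_assignments(cs, pairing = pairing), "geminal")
})

test_that("target_function matches the naive oracle on random poses", {
  fx <- make_engine_fixture(seed = 42)
  hyp <- stats::setNames(fx$cx$receptor$methyls$id,
                         fx$cx$receptor$methyls$id)  # identity mapping
  set.seed(4)
  for (k in 1:25) {
    par <- c(runif(3, -4, 4), runif(3, -pi, pi), runif(1, -pi, pi))
    got <- target_function(par, fx$restraints, fx$cx$receptor, fx$cx$ligand,
                           hypothesis = hyp)
    want <- oracle_target(par, fx$restraints, fx$cx$receptor, fx$cx$ligand,
                          hyp)
    expect_equal(got$total, want, tolerance = 1e-9)
    expect_equal(got$total,
                 got$upper_violation_sum + got$lower_violation_sum +
                   got$clash_sum, tolerance = 1e-12)
  }
})

test_that("target_function basics: zero when satisfied, quadratic violation", {
  fx <- make_engine_fixture(seed = 42)
  truth_par <- fx$cx$truth$true_par
  rep0 <- target_function(truth_par, fx$restraints, fx$cx$receptor,
                          fx$cx$ligand)
  expect_identical(rep0$total, 0)
  # single upper limit u with d = u + 1 contributes exactly 1.0
  lg <- names(fx$cx$ligand$groups)[1]
  m <- fx$cx$receptor$methyls$id[1]
  d_true <- fx$cx$truth$dist[lg, m]
  r1 <- build_restraint_set(list(distance_restraint(lg, m, "upper",
                                                    max(d_true - 1, 1.8),
                                                    source = "NOE",
                                                    resonance = m)))
  rep1 <- target_function(truth_par, r1, fx$cx$receptor, fx$cx$ligand)
  expect_equal(rep1$upper_violation_sum, (d_true - max(d_true - 1, 1.8))^2,
               tolerance = 1e-9)
  expect_error(target_function(truth_par,
                               build_restraint_set(list(distance_restraint(
                                 "H1", "NOPE", "upper", 5, source = "NOE"))),
                               fx$cx$receptor, fx$cx$ligand),
               "unknown receptor group")
})

test_that("optimize_pose recovers a pose from ground-truth restraints", {
  fx <- make_engine_fixture(seed = 42, tol = 0.5, n_noes = 20)
  pose <- optimize_pose(character(), fx$restraints, fx$cx$receptor,
                        fx$cx$ligand,
                        schedule = anneal_schedule(n_restarts = 12,
                                                   n_steps = 3000),
                        seed = 7)
  expect_lt(pose$target_value, 0.05)
  rmsd <- pose_rmsd(pose, fx$restraints, fx$cx$receptor, fx$cx$ligand,
                    fx$cx$truth$lig_coords)
  expect_lt(rmsd, 1.0)
  # empty restraint set: any clash-free pose scores zero
  p0 <- optimize_pose(character(), build_restraint_set(), fx$cx$receptor,
                      fx$cx$ligand,
                      schedule = anneal_schedule(n_restarts = 4,
                                                 n_steps = 500),
                      seed = 1)
  expect_identical(p0$target_value, 0)
})

test_that("deliberately inconsistent restraints give a certified positive floor", {
  fx <- make_engine_fixture(seed = 42, n_noes = 5)
  lg <- names(fx$cx$ligand$groups)[1]
  m <- fx$cx$receptor$methyls$id[1]
  # upper limit far below the hard-sphere contact distance: with contact
  # r_min = 0.8*(1+1.5) = 2.0 A for H..C, an upper limit of 1.8 A cannot be
  # reached without clashing. 1-D grid over the controlling distance d
  # certifies the floor: min over d of (d-1.8)^2 [d>1.8] + (2.0-d)^2 [d<2.0]
  d_grid <- seq(0.5, 6, by = 1e-4)
  floor_cert <- min((pmax(d_grid - 1.8, 0))^2 + (pmax(2.0 - d_grid, 0))^2)
  expect_gt(floor_cert, 0)
  rs <- build_restraint_set(list(distance_restraint(lg, m, "upper", 1.8,
                                                    source = "NOE",
                                                    resonance = m)))
  pose <- optimize_pose(character(), rs, fx$cx$receptor, fx$cx$ligand,
                        schedule = anneal_schedule(n_restarts = 8,
                                                   n_steps = 2000),
                        seed = 3)
  expect_gte(pose$target_value, floor_cert - 1e-6)
  expect_gt(pose$target_value, 0)
})

test_that("adding a satisfied restraint never increases the optimum", {
  fx <- make_engine_fixture(seed = 42, n_noes = 12)
  sched <- anneal_schedule(n_restarts = 8, n_steps = 1500)
  p1 <- optimize_pose(character(), fx$restraints, fx$cx$receptor,
                      fx$cx$ligand, schedule = sched, seed = 5)
  # a restraint satisfied everywhere (huge bound) cannot raise the optimum
  loose <- distance_restraint(names(fx$cx$ligand$groups)[2],
                              fx$cx$receptor$methyls$id[2], "upper", 50,
                              source = "NOE",
                              resonance = fx$cx$receptor$methyls$id[2])
  rs2 <- build_restraint_set(c(unclass(fx$restraints), list(loose)))
  p2 <- optimize_pose(character(), rs2, fx$cx$receptor, fx$cx$ligand,
                      schedule = sched, seed = 5)
  expect_lte(p2$target_value, p1$target_value + 1e-9)
})

test_that("run_nmr2 is deterministic and reports symmetry ties", {
  fx <- make_engine_fixture(seed = 43, n_noes = 10)
  meth <- fx$cx$receptor$methyls$id
  cs <- list(R1 = meth[1:3], R2 = meth[1:3])
  # relabel restraints onto two resonances so hypotheses matter
  rs <- fx$restraints
  sched <- anneal_schedule(n_restarts = 4, n_steps = 800)
  r1 <- run_nmr2(rs, fx$cx$receptor, fx$cx$ligand, cs,
                 schedule = sched, top_k = 4, seed = 11)
  r2 <- run_nmr2(rs, fx$cx$receptor, fx$cx$ligand, cs,
                 schedule = sched, top_k = 4, seed = 11)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$best_pose$par, r2$best_pose$par)
  # exact symmetry: two candidate methyls at the same coordinates tie
  cx <- fx$cx
  dup <- cx$receptor$methyls[1, ]
  dup$id <- "DUP1.CD1"
  cx$receptor$methyls <- rbind(cx$receptor$methyls, dup)
  lg <- names(cx$ligand$groups)[1]
  rs1 <- build_restraint_set(list(distance_restraint(
    lg, "R1", "upper", max(cx$truth$dist[lg, cx$receptor$methyls$id[1]], 1.8),
    source = "NOE", resonance = "R1")))
  tie <- run_nmr2(rs1, cx$receptor, cx$ligand,
                  list(R1 = c(cx$receptor$methyls$id[1], "DUP1.CD1")),
                  schedule = sched, top_k = 2, seed = 2)
  expect_true(tie$ties)
})

test_that("backbone-restrained refinement obeys its limits", {
  fx <- make_engine_fixture(seed = 42, tol = 0.5, n_noes = 15)
  sched <- anneal_schedule(n_restarts = 10, n_steps = 2500)
  pose <- optimize_pose(character(), fx$restraints, fx$cx$receptor,
                        fx$cx$ligand, schedule = sched, seed = 7)
  # already at (near) zero violations: refinement must not move anything much
  ref <- refine_backbone_restrained(pose, fx$cx$receptor, fx$restraints,
                                    fx$cx$ligand, k = 10)
  expect_lt(max(ref$displacement), 0.05)

  # displace one restrained methyl radially outward (away from the pocket,
  # so its upper limit is violated by construction): refinement moves it
  # back toward the restraint-satisfying position and reduces violations
  cx2 <- fx$cx
  i <- match(fx$restraints[[1]]$resonance, cx2$receptor$methyls$id)
  p <- as.numeric(cx2$receptor$methyls[i, c("x", "y", "z")])
  shift <- 2.5 * p / sqrt(sum(p^2))
  cx2$receptor$methyls[i, c("x", "y", "z")] <-
    cx2$receptor$methyls[i, c("x", "y", "z")] + shift
  rep_before <- target_function(pose, fx$restraints, cx2$receptor,
                                cx2$ligand)
  expect_gt(rep_before$upper_violation_sum, 0.5)
  ref2 <- refine_backbone_restrained(pose, cx2$receptor, fx$restraints,
                                     cx2$ligand, k = 0.05,
                                     region = cx2$receptor$methyls$id[i])
  expect_true(ref2$converged)
  expect_lt(ref2$pose$report$upper_violation_sum +
              ref2$pose$report$lower_violation_sum,
            rep_before$upper_violation_sum + rep_before$lower_violation_sum)
  expect_gt(ref2$displacement[[1]], 0.2)  # moved back toward truth
  # stiff-spring limit: backbone displacement vanishes
  ref3 <- refine_backbone_restrained(pose, cx2$receptor, fx$restraints,
                                     cx2$ligand, k = 1e6,
                                     region = cx2$receptor$methyls$id[i])
  expect_lt(max(ref3$displacement), 0.01)
})
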