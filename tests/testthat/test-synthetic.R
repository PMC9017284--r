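test_that("toy complex generation is deterministic and respects geometry", {
  spec <- synthetic_spec(seed = 5)
  cx1 <- make_toy_complex(spec)
  cx2 <- make_toy_complex(spec)
  expect_identical(cx1$receptor$atoms, cx2$receptor$atoms)
  expect_identical(cx1$truth$lig_coords, cx2$truth$lig_coords)
  expect_identical(nrow(cx1$receptor$methyls), 12L)
  expect_identical(spec$n_pocket_methyls, 12)
  # exhaustive pairwise separation check (geminal partners exempt)
  meth <- cx1$receptor$methyls
  for (i in seq_len(nrow(meth) - 1)) {
    for (j in (i + 1):nrow(meth)) {
      d <- sqrt((meth$x[i] - meth$x[j])^2 + (meth$y[i] - meth$y[j])^2 +
                (meth$z[i] - meth$z[j])^2)
      gem <- identical(meth$geminal[i], meth$id[j])
      if (!gem) expect_gte(d, spec$min_separation - 1e-9)
    }
  }
  # methyls keep clear of the ligand
  lig <- as.matrix(cx1$ligand$atoms[c("x", "y", "z")])
  for (i in seq_len(nrow(meth))) {
    dmin <- min(sqrt(rowSums(sweep(lig, 2,
                                   c(meth$x[i], meth$y[i], meth$z[i]))^2)))
    expect_gte(dmin, spec$min_ligand_clearance - 1e-9)
  }
  expect_error(make_toy_complex(synthetic_spec(seed = 1, shell_radius = 2)),
               "infeasible")
})

test_that("relaxation-matrix simulation reduces to the closed form for two spins", {
  spec <- synthetic_spec(seed = 1, detection_threshold = 0, leak = 1)
  r <- 3.2
  truth <- list(groups = c("A", "B"),
                dist = matrix(c(0, r, r, 0), 2, 2,
                              dimnames = list(c("A", "B"), c("A", "B"))))
  sim <- simulate_noesy(truth, spec)
  ctx <- relaxation_context(spec$tau_c, spec$field_mhz)
  sg <- sigma_from_distance(r, ctx)
  rho <- abs(sg) + spec$leak
  cross <- sim$peaks[sim$peaks$group_i == "A" & sim$peaks$group_j == "B", ]
  expect_equal(cross$intensity,
               oracle_two_spin(cross$mixing_time_s, sg, rho, rho, 1),
               tolerance = 1e-10)
  # zero threshold, zero noise: the single cross pair is visible
  expect_identical(nrow(sim$visibility), 1L)
})

test_that("initial-rate slopes reproduce sigma within 1 percent", {
  # the initial-rate regime requires sigma*t << 1 AND rho*t << 1: check on
  # receptor methyl pairs (moderate rates) at 1 ms
  spec0 <- synthetic_spec(seed = 2)
  spec <- synthetic_spec(seed = 2, mixing_times = c(0.001, 0.005, 0.01),
                         detection_threshold = 0)
  cx <- make_toy_complex(spec0)
  sim <- simulate_noesy(cx, spec)
  ctx <- relaxation_context(spec$tau_c, spec$field_mhz)
  meth <- cx$receptor$methyls$id
  D <- cx$truth$dist
  checked <- 0
  for (i in meth) for (j in meth) {
    if (i >= j || D[i, j] < 2.8 || D[i, j] > 3.6) next
    sg <- abs(sigma_from_distance(D[i, j], ctx))
    row <- sim$peaks[sim$peaks$group_i == i & sim$peaks$group_j == j &
                       sim$peaks$mixing_time_s == 0.001, ]
    if (!nrow(row)) next
    expect_equal(abs(row$intensity) / 0.001, sg, tolerance = 0.01)
    checked <- checked + 1
  }
  expect_gt(checked, 0)
})

test_that("relayed cross peaks are visible, biased and rejected by the filter", {
  spec <- synthetic_spec(seed = 1, detection_threshold = 0.003, leak = 1)
  ctx <- relaxation_context(spec$tau_c, spec$field_mhz)
  # single-bridge relay A - B - C: the relayed (A,C) peak is visible and its
  # two-spin sigma is strongly inflated (fitted distance far below truth)
  d_ab <- 2.6
  dm3 <- matrix(c(0, d_ab, 2 * d_ab,
                  d_ab, 0, d_ab,
                  2 * d_ab, d_ab, 0), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  sim3 <- simulate_noesy(list(groups = c("A", "B", "C"), dist = dm3), spec)
  expect_true(any(sim3$visibility$group_i == "A" &
                    sim3$visibility$group_j == "C"))
  fits3 <- fit_peak_table(as_buildup_curves(sim3$peaks), ctx)
  f_ac3 <- Filter(function(f) setequal(c(f$group_i, f$group_j), c("A", "C")),
                  fits3$cross)[[1]]
  sg_direct <- abs(sigma_from_distance(2 * d_ab, ctx))
  expect_gt(abs(f_ac3$sigma), 3 * sg_direct)  # relay dominates the peak
  # strong spin diffusion (two-bridge chain A - B - D - C): the two-spin fit
  # fails the default quality filter while direct contacts stay accepted
  gap <- 2.2
  ids <- c("A", "B", "D", "C")
  x <- c(0, gap, 2 * gap, 3 * gap)
  dm4 <- abs(outer(x, x, `-`))
  dimnames(dm4) <- list(ids, ids)
  sim4 <- simulate_noesy(list(groups = ids, dist = dm4), spec)
  expect_true(any((sim4$visibility$group_i == "A" &
                     sim4$visibility$group_j == "C") |
                  (sim4$visibility$group_i == "C" &
                     sim4$visibility$group_j == "A")))
  fits4 <- fit_peak_table(as_buildup_curves(sim4$peaks), ctx)
  f_ac4 <- Filter(function(f) setequal(c(f$group_i, f$group_j), c("A", "C")),
                  fits4$cross)[[1]]
  expect_gt(f_ac4$fit_quality, 0.15)
  expect_false(f_ac4$accepted)
  part <- quality_filter(fits4$cross)
  expect_true(any(vapply(part$rejected, function(f)
    setequal(c(f$group_i, f$group_j), c("A", "C")), logical(1))))
  f_ab4 <- Filter(function(f) setequal(c(f$group_i, f$group_j), c("A", "B")),
                  fits4$cross)[[1]]
  expect_true(f_ab4$accepted)
})

test_that("blinding relabels bijectively, emits classes and anchors", {
  spec <- synthetic_spec(seed = 3)
  cx <- make_toy_complex(spec)
  sim <- simulate_noesy(cx, spec)
  b0 <- blind_inputs(cx, sim, n_resonances = 12, n_anchors = 0, seed = 4)
  expect_length(b0$anchors, 0)
  b2 <- blind_inputs(cx, sim, n_resonances = 10, n_anchors = 2, seed = 4)
  # bijection: inverse lookup recovers every resonance
  tm <- b2$truth_mapping
  expect_identical(anyDuplicated(tm), 0L)
  expect_identical(anyDuplicated(names(tm)), 0L)
  expect_length(tm, 10)
  # anchors are the Met and Thr resonances, matching ground truth
  expect_length(b2$anchors, 2)
  meth <- cx$receptor$methyls
  for (a in names(b2$anchors)) {
    expect_identical(b2$anchors[[a]], tm[[a]])
    expect_true(meth$class[meth$id == tm[[a]]] %in% c("Met", "Thr"))
  }
  # classes agree with the generating inventory
  cls <- meth$class[match(tm[b2$resonances$id], meth$id)]
  expect_identical(b2$resonances$class, cls)
  # no receptor ids leak into the blinded tables
  expect_false(any(meth$id %in% c(b2$peaks$group_i, b2$peaks$group_j)))
})

test_that("every emitted anti-NOE is true at noise level zero", {
  for (seed in c(1, 6)) {
    spec <- synthetic_spec(seed = seed)
    cx <- make_toy_complex(spec)
    sim <- simulate_noesy(cx, spec)
    blind <- blind_inputs(cx, sim, seed = spec$seed + 1L)
    prep <- prepare_restraints(cx, sim, blind, spec, n_noes = Inf,
                               n_anti = Inf)
    D <- cx$truth$dist
    tm <- blind$truth_mapping
    antis <- Filter(function(r) r$source == "anti-NOE", prep$restraints)
    expect_gt(length(antis), 0)
    for (r in antis) {
      d_true <- D[r$ligand_group, tm[[r$resonance]]]
      expect_gt(d_true, r$bound)  # zero false lower limits
    }
    # two-sided visibility precondition re-checked
    vis <- blind$visibility
    for (r in antis) {
      expect_false(any((vis$group_i == r$ligand_group &
                          vis$group_j == r$resonance) |
                       (vis$group_j == r$ligand_group &
                          vis$group_i == r$resonance)))
    }
  }
})
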