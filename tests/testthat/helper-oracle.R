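# Independent oracles used across the suite. These deliberately re-implement
# functionality in plain R, separately from the package's compiled core.

# frozen extended-precision reference values (50-digit arithmetic oracle of
# the closed forms, computed once and frozen)
FROZEN_J_800MHZ_10P1NS <- 3.9171522104494257e-12   # J(2*pi*800e6, 10.1 ns), s
FROZEN_SIGMA_2P5A_10NS_800MHZ <- -2.3318124380753337  # s^-1

# closed-form two-spin cross peak (independent of the package's internal)
oracle_two_spin <- function(t, sigma, rho_i, rho_j, m0 = 1) {
  rb <- (rho_i + rho_j) / 2
  dl <- (rho_i - rho_j) / 2
  D <- sqrt(dl^2 + sigma^2)
  if (D == 0) return(-m0 * sigma * t * exp(-rb * t))
  -m0 * (sigma / D) * sinh(D * t) * exp(-rb * t)
}

# naive pose -> ligand coordinates (torsions, then rotation about the
# centroid, then translation); mirrors the documented pose convention
oracle_coords <- function(ligand, par) {
  xyz <- as.matrix(ligand$atoms[c("x", "y", "z")])
  rot_about <- function(p, origin, axis, ang) {
    axis <- axis / sqrt(sum(axis^2))
    v <- p - origin
    v * cos(ang) + pracma_cross(axis, v) * sin(ang) +
      axis * sum(axis * v) * (1 - cos(ang)) + origin
  }
  pracma_cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                                   a[3] * b[1] - a[1] * b[3],
                                   a[1] * b[2] - a[2] * b[1])
  for (k in seq_along(ligand$torsions)) {
    tr <- ligand$torsions[[k]]
    ang <- par[6 + k]
    a <- xyz[tr$axis[1], ]; b <- xyz[tr$axis[2], ]
    for (i in tr$moving) xyz[i, ] <- rot_about(xyz[i, ], a, b - a, ang)
  }
  ctr <- colMeans(xyz)
  rv <- par[4:6]
  th <- sqrt(sum(rv^2))
  if (th > 1e-12) {
    ax <- rv / th
    for (i in seq_len(nrow(xyz)))
      xyz[i, ] <- rot_about(xyz[i, ], ctr, ax, th)
  }
  sweep(xyz, 2, par[1:3], `+`)
}

# naive term-by-term target function evaluator
oracle_target <- function(par, restraints, receptor, ligand, hypothesis,
                          weights = c(upper = 1, lower = 1, clash = 1),
                          radii = c(H = 1.0, C = 1.5, N = 1.4, O = 1.3,
                                    S = 1.7),
                          overlap = 0.8) {
  xyz <- oracle_coords(ligand, par)
  gpos <- t(vapply(ligand$groups, function(ix)
    colMeans(xyz[ix, , drop = FALSE]), numeric(3)))
  rownames(gpos) <- names(ligand$groups)
  meth <- receptor$methyls
  up <- lo <- 0
  for (r in restraints) {
    if (r$source == "intraligand") {
      d <- sqrt(sum((gpos[r$ligand_group, ] - gpos[r$partner_ligand_group, ])^2))
    } else {
      ids <- vapply(r$candidates, function(cc)
        if (cc %in% names(hypothesis)) hypothesis[[cc]] else cc, character(1))
      ids <- unique(ids)
      d6 <- sum(vapply(ids, function(m) {
        row <- meth[meth$id == m, ]
        sum((gpos[r$ligand_group, ] - c(row$x, row$y, row$z))^2)^(-3)
      }, numeric(1)))
      d <- d6^(-1 / 6)
    }
    if (r$bound_type == "upper" && d > r$bound)
      up <- up + weights[["upper"]] * (d - r$bound)^2
    if (r$bound_type == "lower" && d < r$bound)
      lo <- lo + weights[["lower"]] * (r$bound - d)^2
  }
  cl <- 0
  rad_of <- function(e) { r <- radii[toupper(e)]; r[is.na(r)] <- 1.5; unname(r) }
  lr <- rad_of(ligand$atoms$elem) * overlap
  rr <- rad_of(receptor$atoms$elem) * overlap
  for (i in seq_len(nrow(xyz))) {
    d <- sqrt((receptor$atoms$x - xyz[i, 1])^2 +
              (receptor$atoms$y - xyz[i, 2])^2 +
              (receptor$atoms$z - xyz[i, 3])^2)
    rmin <- lr[i] + rr
    hit <- d < rmin
    cl <- cl + weights[["clash"]] * sum((rmin[hit] - d[hit])^2)
  }
  unname(up + lo + cl)
}

# brute-force count of injective assignments consistent with candidate
# sets, anchors and prochiral pairing (enumerates the full product space)
oracle_count_assignments <- function(candidate_sets, anchors = character(),
                                     pairing = NULL, geminal = NULL) {
  res <- sort(names(candidate_sets))
  grids <- lapply(res, function(r) candidate_sets[[r]])
  combos <- do.call(expand.grid,
                    c(stats::setNames(grids, res),
                      list(stringsAsFactors = FALSE)))
  pairs <- if (is.null(pairing)) list()
           else if (inherits(pairing, "prochiral_pairing")) pairing$pairs
           else pairing
  n <- 0L
  for (k in seq_len(nrow(combos))) {
    m <- unlist(combos[k, , drop = FALSE])
    names(m) <- res
    if (anyDuplicated(m)) next
    if (length(anchors) && !all(m[names(anchors)] == anchors)) next
    ok <- TRUE
    for (p in pairs) {
      if (any(p %in% names(anchors))) next
      g <- geminal[[m[[p[1]]]]]
      if (is.null(g) || is.na(g) || g != m[[p[2]]]) { ok <- FALSE; break }
    }
    if (ok) n <- n + 1L
  }
  n
}

# small deterministic toy docking fixture: receptor from the generator,
# restraints straight from true distances
make_engine_fixture <- function(seed = 42, tol = 0.5, n_noes = 20) {
  spec <- synthetic_spec(seed = seed)
  cx <- make_toy_complex(spec)
  D <- cx$truth$dist
  meth <- cx$receptor$methyls$id
  ligg <- names(cx$ligand$groups)
  pairs <- expand.grid(lg = ligg, m = meth, stringsAsFactors = FALSE)
  pairs$d <- mapply(function(a, b) D[a, b], pairs$lg, pairs$m)
  pairs <- pairs[order(pairs$d), ][seq_len(n_noes), ]
  rs <- build_restraint_set(lapply(seq_len(nrow(pairs)), function(k)
    distance_restraint(pairs$lg[k], pairs$m[k], "upper",
                       max(pairs$d[k] + tol, 1.8), source = "NOE",
                       resonance = pairs$m[k])))
  list(spec = spec, cx = cx, restraints = rs)
}
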