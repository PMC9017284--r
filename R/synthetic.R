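# Ground-truth generator: toy binding pocket decorated with methyl groups,
# rigid fragment-like ligand, and full relaxation-matrix NOESY simulation
# (spin diffusion included).

# evaluate code under a temporary RNG seed, restoring the caller's stream
.with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic complex specification
#'
#' The stated world of the synthetic benchmark: a pocket of methyl
#' pseudoatoms on a shell around the pocket center, a rigid fragment-like
#' ligand inside, and a NOESY build-up series on the standard 50-200 ms
#' mixing grid at 800 MHz with a bromodomain-like correlation time.
#'
#' @param composition Residue composition of the pocket,
#'   `c(Met = , Thr = , Ala = , Leu = , Val = )`; Leu/Val contribute two
#'   geminal methyls each.
#' @param tau_c Rotational correlation time, seconds (default 10.1e-9).
#' @param field_mhz Spectrometer proton frequency, MHz.
#' @param mixing_times NOESY mixing times, seconds.
#' @param noise_sd Gaussian noise, fraction of the maximum diagonal
#'   intensity (default 0: noise-free).
#' @param detection_threshold Peak detection cutoff, fraction of the
#'   maximum diagonal intensity.
#' @param leak External relaxation added to every diagonal rate, s^-1.
#' @param shell_radius Mean methyl shell radius, Angstrom.
#' @param shell_jitter Radial jitter of the shell, Angstrom.
#' @param min_separation Minimum distance between (non-geminal) methyl
#'   pseudoatoms, Angstrom.
#' @param min_ligand_clearance Minimum methyl-to-ligand-atom distance when
#'   placing the pocket, Angstrom.
#' @param wall Add a shell of receptor wall pseudoatoms that enclose the
#'   pocket (hard-sphere packing only; they carry no NOEs). Emulates the
#'   steric complementarity of a concave binding site (default `TRUE`).
#' @param wall_opening_deg Half-angle (degrees) of the solvent-exposed
#'   opening left in the wall (default 55).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(composition = c(Met = 1, Thr = 1, Ala = 2,
                                           Leu = 2, Val = 2),
                           tau_c = 10.1e-9, field_mhz = 800,
                           mixing_times = c(0.05, 0.10, 0.15, 0.20),
                           noise_sd = 0, detection_threshold = 0.003,
                           leak = 1, shell_radius = 6.0, shell_jitter = 1.0,
                           min_separation = 3.0, min_ligand_clearance = 2.8,
                           wall = TRUE, wall_opening_deg = 55, seed = 1) {
  if (any(composition < 0) || sum(composition) == 0)
    stop("invalid composition")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(diff(mixing_times) <= 0) || any(mixing_times <= 0))
    stop("mixing times must be positive and strictly increasing")
  n_methyls <- sum(composition[c("Met", "Thr", "Ala")], na.rm = TRUE) +
    2 * sum(composition[c("Leu", "Val")], na.rm = TRUE)
  structure(list(composition = composition, n_pocket_methyls = n_methyls,
                 tau_c = tau_c, field_mhz = field_mhz,
                 mixing_times = mixing_times, noise_sd = noise_sd,
                 detection_threshold = detection_threshold, leak = leak,
                 shell_radius = shell_radius, shell_jitter = shell_jitter,
                 min_separation = min_separation,
                 min_ligand_clearance = min_ligand_clearance,
                 wall = wall, wall_opening_deg = wall_opening_deg,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# rigid fragment-like toy ligand: benzene core, one ring methyl, a two-carbon
# out-of-plane tail ending in a methyl, one rotatable tail torsion. Methyls
# are single pseudoatoms (Q names). 8 proton groups.
.toy_ligand_template <- function() {
  ang <- (0:5) * pi / 3
  ring <- data.frame(name = paste0("C", 1:6), elem = "C",
                     x = 1.39 * cos(ang), y = 1.39 * sin(ang), z = 0)
  arh <- data.frame(name = paste0("H", 1:4), elem = "H",
                    x = 2.47 * cos(ang[c(1, 2, 3, 6)]),
                    y = 2.47 * sin(ang[c(1, 2, 3, 6)]), z = 0)
  # ring methyl on C4 (180 deg), pseudoatom slightly below the plane
  c7 <- data.frame(name = "C7", elem = "C", x = -2.89, y = 0, z = 0)
  q7 <- data.frame(name = "Q7", elem = "C", x = -3.72, y = 0, z = -0.80)
  # tail on C5 (240 deg), bending out of plane
  d5 <- c(cos(ang[5]), sin(ang[5]))
  c8 <- data.frame(name = "C8", elem = "C", x = 1.39 * d5[1] + 1.45 * d5[1],
                   y = 1.39 * d5[2] + 1.45 * d5[2], z = 0.45)
  h5 <- data.frame(name = "H5", elem = "H", x = c8$x - 0.50 * d5[2],
                   y = c8$y + 0.50 * d5[1], z = c8$z + 0.85)
  c9 <- data.frame(name = "C9", elem = "C", x = c8$x + 1.30 * d5[1],
                   y = c8$y + 1.30 * d5[2], z = c8$z + 0.75)
  h6 <- data.frame(name = "H6", elem = "H", x = c9$x + 0.55 * d5[2],
                   y = c9$y - 0.55 * d5[1], z = c9$z + 0.70)
  q8 <- data.frame(name = "Q8", elem = "C", x = c9$x + 1.25 * d5[1],
                   y = c9$y + 1.25 * d5[2], z = c9$z + 0.95)
  atoms <- rbind(ring, arh, c7, q7, c8, h5, c9, h6, q8)
  rownames(atoms) <- NULL
  idx <- function(nm) match(nm, atoms$name)
  groups <- list(H1 = idx("H1"), H2 = idx("H2"), H3 = idx("H3"),
                 H4 = idx("H4"), H5 = idx("H5"), H6 = idx("H6"),
                 Q7 = idx("Q7"), Q8 = idx("Q8"))
  torsions <- list(list(axis = c(idx("C5"), idx("C8")),
                        moving = idx(c("H5", "C9", "H6", "Q8"))))
  ligand_model(atoms, groups = groups, torsions = torsions,
               is_methyl = c(H1 = FALSE, H2 = FALSE, H3 = FALSE, H4 = FALSE,
                             H5 = FALSE, H6 = FALSE, Q7 = TRUE, Q8 = TRUE))
}

.random_rotation <- function() {
  # uniform random rotation from a normalized quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Build a toy receptor pocket / ligand complex with known ground truth
#'
#' Places methyl pseudoatoms of the requested residue composition on a shell
#' around the pocket center (geminal Leu/Val methyl pairs 2.5 Angstrom
#' apart), puts the rigid toy ligand at the center in a random orientation,
#' and checks that the geometry is informative (at least 3 ligand protons
#' within 5 Angstrom of at least 2 methyls each). Deterministic given the
#' spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `toy_complex`: `receptor` ([receptor_model()]),
#'   `ligand` ([ligand_model()], local frame = true placement so the true
#'   pose parameter vector is all zeros), `truth` (list with `groups`,
#'   `dist` full distance matrix, `lig_coords`, `true_par`).
#' @export
make_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  # deterministic retry over derived sub-seeds: rejection sampling of the
  # pocket geometry until the informativeness criteria hold
  last <- NULL
  for (try_k in 0:19) {
    out <- tryCatch(.make_toy_complex_once(spec, spec$seed + try_k * 100003L),
                    error = function(e) e)
    if (!inherits(out, "error")) return(out)
    last <- out
  }
  stop(conditionMessage(last))
}

.make_toy_complex_once <- function(spec, eff_seed) {
  .with_seed(eff_seed, {
    lig <- .toy_ligand_template()
    xyz <- as.matrix(lig$atoms[c("x", "y", "z")])
    xyz <- sweep(xyz, 2, colMeans(xyz))
    xyz <- xyz %*% t(.random_rotation())
    lig$atoms$x <- xyz[, 1]; lig$atoms$y <- xyz[, 2]; lig$atoms$z <- xyz[, 3]

    comp <- spec$composition
    # residue slots: singles then geminal pairs
    slots <- c(rep("MET", comp[["Met"]]), rep("THR", comp[["Thr"]]),
               rep("ALA", comp[["Ala"]]), rep("LEU", comp[["Leu"]]),
               rep("VAL", comp[["Val"]]))
    placed <- matrix(numeric(0), ncol = 3)
    rows <- list()
    resno <- 0L
    ok_point <- function(p) {
      if (min(sqrt(rowSums(sweep(xyz, 2, p)^2))) < spec$min_ligand_clearance)
        return(FALSE)
      if (nrow(placed) &&
          min(sqrt(rowSums(sweep(placed, 2, p)^2))) < spec$min_separation)
        return(FALSE)
      TRUE
    }
    sample_dir <- function() {
      v <- stats::rnorm(3)
      v / sqrt(sum(v^2))
    }
    for (rn in slots) {
      resno <- resno + 1L
      pair <- rn %in% c("LEU", "VAL")
      done <- FALSE
      for (att in 1:2000) {
        dir <- sample_dir()
        rad <- spec$shell_radius + stats::runif(1, -1, 1) * spec$shell_jitter
        if (!pair) {
          p <- dir * rad
          if (ok_point(p)) {
            nm <- switch(rn, MET = "CE", THR = "CG2", ALA = "CB")
            rows[[length(rows) + 1L]] <- data.frame(
              name = nm, elem = "C", resno = resno, resname = rn,
              x = p[1], y = p[2], z = p[3])
            placed <- rbind(placed, p)
            done <- TRUE
            break
          }
        } else {
          tang <- sample_dir()
          tang <- tang - sum(tang * dir) * dir
          tang <- tang / sqrt(sum(tang^2))
          p1 <- dir * rad + tang * 1.25
          p2 <- dir * rad - tang * 1.25
          # geminal partners may be close to each other, not to anyone else
          if (ok_point(p1) && ok_point(p2)) {
            nms <- if (rn == "LEU") c("CD1", "CD2") else c("CG1", "CG2")
            rows[[length(rows) + 1L]] <- data.frame(
              name = nms, elem = "C", resno = resno, resname = rn,
              x = c(p1[1], p2[1]), y = c(p1[2], p2[2]), z = c(p1[3], p2[3]))
            placed <- rbind(placed, p1, p2)
            done <- TRUE
            break
          }
        }
      }
      if (!done)
        stop("infeasible synthetic spec: could not place ", rn,
             " on the shell (too many methyls for the shell radius?)")
    }
    if (isTRUE(spec$wall)) {
      # pocket wall: pseudoatoms on a quasi-uniform sphere grid, pushed
      # outward until they pack against (without clashing) the ligand and
      # the methyl shell; a cap around a random direction stays open
      ndir <- 220
      k <- seq_len(ndir)
      phi <- (1 + sqrt(5)) / 2
      zd <- 1 - (2 * k - 1) / ndir
      th <- 2 * pi * k / phi
      dirs <- cbind(sqrt(1 - zd^2) * cos(th), sqrt(1 - zd^2) * sin(th), zd)
      open_dir <- { v <- stats::rnorm(3); v / sqrt(sum(v^2)) }
      coscap <- cos(spec$wall_opening_deg * pi / 180)
      wall_pts <- list()
      for (w in seq_len(ndir)) {
        d <- dirs[w, ]
        if (sum(d * open_dir) > coscap) next  # solvent opening
        # start deep and back out until clear of the ligand: the wall packs
        # against the ligand envelope (protein matter fills the rest)
        r_w <- spec$shell_radius - 1.8
        for (push in 1:60) {
          p <- d * r_w
          if (min(sqrt(rowSums(sweep(xyz, 2, p)^2))) >= 2.9) break
          r_w <- r_w + 0.25
        }
        p <- d * r_w
        if (min(sqrt(rowSums(sweep(placed, 2, p)^2))) < 2.6) next
        wall_pts[[length(wall_pts) + 1L]] <- p
      }
      if (length(wall_pts)) {
        wp <- do.call(rbind, wall_pts)
        resno <- resno + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          name = "CW", elem = "C", resno = resno, resname = "WAL",
          x = wp[, 1], y = wp[, 2], z = wp[, 3])
      }
    }
    atoms <- do.call(rbind, rows)
    receptor <- receptor_model(atoms, pocket_center = c(0, 0, 0),
                               pocket_radius = spec$shell_radius + 6)

    # informativeness: >= 3 ligand protons within 5 A of >= 2 methyls
    mx <- as.matrix(receptor$methyls[c("x", "y", "z")])
    gpos <- t(vapply(lig$groups, function(ix)
      colMeans(as.matrix(lig$atoms[ix, c("x", "y", "z"), drop = FALSE])),
      numeric(3)))
    near <- vapply(seq_len(nrow(gpos)), function(i)
      sum(sqrt(colSums((t(mx) - gpos[i, ])^2)) <= 5), integer(1))
    if (sum(near >= 2) < 3)
      stop("infeasible synthetic spec: pocket not informative enough ",
           "(need >= 3 ligand protons within 5 A of >= 2 methyls); ",
           "try another seed or a smaller shell_radius")

    ids <- c(receptor$methyls$id, names(lig$groups))
    pos <- rbind(mx, gpos)
    rownames(pos) <- ids
    dist <- as.matrix(stats::dist(pos))
    structure(list(receptor = receptor, ligand = lig,
                   truth = list(groups = ids, dist = dist,
                                lig_coords = xyz,
                                true_par = rep(0, 6 + length(lig$torsions)),
                                is_methyl = c(rep(TRUE, nrow(mx)),
                                              unname(lig$is_methyl)))),
              class = "toy_complex")
  })
}

#' Simulate a NOESY build-up series via the full relaxation matrix
#'
#' Builds the rate matrix R with off-diagonal cross-relaxation rates
#' \eqn{\sigma_{ij}} from the ground-truth distances and diagonal
#' autorelaxation \eqn{\rho_i = \sum_j |\sigma_{ij}| + leak}, propagates
#' \eqn{M(t) = e^{-Rt} M(0)} at each mixing time (so spin diffusion is
#' fully included), adds seeded Gaussian noise, and suppresses peaks below
#' the detection threshold.
#'
#' @param truth Either a `toy_complex` or a list with `groups` (ids) and
#'   `dist` (full symmetric distance matrix, Angstrom).
#' @param spec A [synthetic_spec()].
#' @return List: `peaks` (long-format peak table, both sides of the
#'   diagonal), `visibility` (data.frame `group_i`, `group_j` of visible
#'   cross pairs), `cutoff` (absolute detection cutoff), `sigma` (rate
#'   matrix used).
#' @export
simulate_noesy <- function(truth, spec) {
  if (inherits(truth, "toy_complex")) truth <- truth$truth
  ids <- truth$groups
  D <- truth$dist
  n <- length(ids)
  ctx <- relaxation_context(spec$tau_c, spec$field_mhz)
  sg <- matrix(0, n, n, dimnames = list(ids, ids))
  off <- which(upper.tri(D) | lower.tri(D))
  sg[off] <- sigma_from_distance(D[off], ctx)
  R <- sg
  diag(R) <- rowSums(abs(sg)) + spec$leak
  ev <- eigen(R, symmetric = TRUE)
  if (any(!is.finite(ev$values)))
    stop("relaxation matrix diagonalization failed (degenerate geometry?)")
  ntm <- length(spec$mixing_times)
  inten <- array(0, dim = c(n, n, ntm), dimnames = list(ids, ids, NULL))
  for (k in seq_len(ntm)) {
    t <- spec$mixing_times[k]
    inten[, , k] <- ev$vectors %*% (exp(-ev$values * t) * t(ev$vectors))
  }
  max_diag <- max(vapply(seq_len(ntm), function(k) max(diag(inten[, , k])),
                         numeric(1)))
  cutoff <- spec$detection_threshold * max_diag
  noise <- if (spec$noise_sd > 0)
    .with_seed(spec$seed + 7717L,
               array(stats::rnorm(2 * n * n * ntm, sd = spec$noise_sd * max_diag),
                     dim = c(n, n, 2 * ntm)))
  else array(0, dim = c(n, n, 2 * ntm))

  rows <- list()
  vis <- list()
  for (i in seq_len(n)) {
    yi <- inten[i, i, ] + noise[i, i, seq_len(ntm)]
    if (max(abs(yi)) >= cutoff)
      rows[[length(rows) + 1L]] <- data.frame(
        peak_id = paste0("D_", ids[i]), group_i = ids[i], group_j = ids[i],
        mixing_time_s = spec$mixing_times, intensity = yi, side = "above")
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      y_ab <- inten[i, j, ] + noise[i, j, seq_len(ntm)]
      y_be <- inten[j, i, ] + noise[j, i, ntm + seq_len(ntm)]
      if (max(abs(y_ab)) < cutoff && max(abs(y_be)) < cutoff) next
      pid <- paste0("X_", ids[i], "_", ids[j])
      rows[[length(rows) + 1L]] <- data.frame(
        peak_id = pid, group_i = ids[i], group_j = ids[j],
        mixing_time_s = spec$mixing_times, intensity = y_ab, side = "above")
      rows[[length(rows) + 1L]] <- data.frame(
        peak_id = pid, group_i = ids[j], group_j = ids[i],
        mixing_time_s = spec$mixing_times, intensity = y_be, side = "below")
      vis[[length(vis) + 1L]] <- data.frame(group_i = ids[i],
                                            group_j = ids[j])
    }
  }
  peaks <- do.call(rbind, rows)
  rownames(peaks) <- NULL
  visibility <- if (length(vis)) do.call(rbind, vis)
                else data.frame(group_i = character(), group_j = character())
  list(peaks = peaks, visibility = visibility, cutoff = cutoff, sigma = sg,
       intensities = inten)
}

#' Blind the simulated data for an end-to-end run
#'
#' Strips the receptor methyl assignments: observed receptor resonances are
#' relabeled `M1..Mn` in a seeded random order, residue-type classes are
#' emitted per resonance, and the requested number of anchors (Met then Thr,
#' which are unique in the pocket) is fixed. When `n_resonances` is smaller
#' than the pocket methyl count, the methyls with the weakest ligand NOE
#' evidence are treated as unobserved (their peaks are dropped), so the
#' mapping is injective into a larger methyl set. Ground truth is returned
#' separately for scoring only.
#'
#' @param complex A `toy_complex` from [make_toy_complex()].
#' @param sim Output of [simulate_noesy()].
#' @param n_resonances Number of observed receptor resonances (default 10).
#' @param n_anchors 0, 1 or 2 anchors (Met, then Thr).
#' @param seed Relabeling seed (default: spec seed + 1).
#' @return List: `resonances` (data.frame `id`, `class`), `peaks`,
#'   `visibility` (resonance-labeled), `anchors` (named vector resonance ->
#'   methyl id), `truth_mapping` (resonance -> methyl, for scoring only).
#' @export
blind_inputs <- function(complex, sim, n_resonances = 10, n_anchors = 2,
                         seed = NULL) {
  stopifnot(inherits(complex, "toy_complex"))
  meth <- complex$receptor$methyls
  lig_ids <- names(complex$ligand$groups)
  if (is.null(seed)) seed <- 1L
  if (n_resonances > nrow(meth))
    stop("n_resonances exceeds the pocket methyl count")
  # ligand NOE evidence per methyl: strongest visible ligand cross intensity
  evidence <- vapply(meth$id, function(m) {
    sel <- (sim$peaks$group_i == m & sim$peaks$group_j %in% lig_ids) |
           (sim$peaks$group_j == m & sim$peaks$group_i %in% lig_ids)
    if (!any(sel)) 0 else max(abs(sim$peaks$intensity[sel]))
  }, numeric(1))
  keep <- meth$id
  must <- meth$id[meth$class %in% c("Met", "Thr")]
  if (n_resonances < nrow(meth)) {
    droppable <- setdiff(meth$id[order(evidence, meth$id)], must)
    drop <- droppable[seq_len(nrow(meth) - n_resonances)]
    keep <- setdiff(meth$id, drop)
  }
  labels <- .with_seed(seed, sample(paste0("M", seq_along(keep))))
  names(labels) <- keep
  relabel <- function(x) ifelse(x %in% names(labels), labels[x], x)
  peaks <- sim$peaks
  obs <- (peaks$group_i %in% c(keep, lig_ids)) &
         (peaks$group_j %in% c(keep, lig_ids))
  peaks <- peaks[obs, , drop = FALSE]
  peaks$group_i <- relabel(peaks$group_i)
  peaks$group_j <- relabel(peaks$group_j)
  vis <- sim$visibility
  vobs <- (vis$group_i %in% c(keep, lig_ids)) &
          (vis$group_j %in% c(keep, lig_ids))
  vis <- vis[vobs, , drop = FALSE]
  vis$group_i <- relabel(vis$group_i)
  vis$group_j <- relabel(vis$group_j)
  rownames(peaks) <- rownames(vis) <- NULL
  resonances <- data.frame(id = unname(labels),
                           class = meth$class[match(names(labels), meth$id)],
                           stringsAsFactors = FALSE)
  resonances <- resonances[order(as.integer(sub("^M", "", resonances$id))), ]
  rownames(resonances) <- NULL
  truth_mapping <- stats::setNames(names(labels), unname(labels))
  anchors <- character()
  if (n_anchors >= 1) {
    met <- meth$id[meth$class == "Met"][1]
    if (!is.na(met) && met %in% keep) anchors[labels[[met]]] <- met
  }
  if (n_anchors >= 2) {
    thr <- meth$id[meth$class == "Thr"][1]
    if (!is.na(thr) && thr %in% keep) anchors[labels[[thr]]] <- thr
  }
  list(resonances = resonances, peaks = peaks, visibility = vis,
       anchors = anchors, truth_mapping = truth_mapping[sort(names(truth_mapping))])
}
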