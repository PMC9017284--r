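# The molecular-replacement core: assignment hypothesis enumeration, target
# function, simulated-annealing pose optimization, ranking and refinement.

#' Enumerate assignment hypotheses
#'
#' All injective mappings of unassigned methyl resonances onto receptor
#' methyl groups that respect residue-class candidate sets, fixed anchors,
#' and (optionally) prochiral pairing: a paired pair of resonances must map
#' onto a geminal methyl pair, in either orientation. The number of
#' hypotheses equals the permanent of the candidate bipartite matrix (after
#' pairing contraction).
#'
#' @param candidate_sets Named list: resonance id -> character vector of
#'   candidate receptor methyl ids.
#' @param anchors Named character vector of fixed assignments
#'   (resonance -> methyl); anchored resonances are immutable.
#' @param pairing Optional [pair_prochirals()] result (or list of id pairs).
#' @param geminal Named character vector mapping a methyl id to its geminal
#'   partner (`NA` if none); required when `pairing` has pairs.
#' @param max_count Error out if the hypothesis count exceeds this cap
#'   (default 1e6) with advice to tighten classes or the pocket radius.
#' @return List of named character vectors (resonance -> methyl), each a
#'   complete injective mapping; stable deterministic order.
#' @export
enumerate_assignments <- function(candidate_sets, anchors = character(),
                                  pairing = NULL, geminal = NULL,
                                  max_count = 1e6) {
  res_ids <- sort(names(candidate_sets))
  if (!all(vapply(candidate_sets, length, integer(1)) > 0))
    stop("empty candidate set after class constraints")
  for (a in names(anchors)) {
    if (!a %in% res_ids) stop("anchor for unknown resonance: ", a)
    if (!anchors[[a]] %in% candidate_sets[[a]])
      stop("anchor ", a, " -> ", anchors[[a]],
           " conflicts with its candidate set")
  }
  pairs <- if (inherits(pairing, "prochiral_pairing")) pairing$pairs
           else if (is.null(pairing)) list() else pairing
  pairs <- Filter(function(p) !any(p %in% names(anchors)), pairs)
  if (length(pairs) && is.null(geminal))
    stop("prochiral pairing requires the receptor geminal partner map")
  paired_ids <- unlist(pairs)
  # units: prochiral resonance pairs, then single resonances
  singles <- setdiff(res_ids, c(names(anchors), paired_ids))
  used0 <- unname(anchors)
  # options per unit, computed lazily against the used set during DFS
  unit_opts <- c(
    lapply(pairs, function(p) {
      p <- sort(p)
      ca <- candidate_sets[[p[1]]]; cb <- candidate_sets[[p[2]]]
      opts <- list()
      for (m in ca) {
        g <- geminal[[m]]
        if (!is.null(g) && !is.na(g) && g %in% cb)
          opts[[length(opts) + 1L]] <- stats::setNames(c(m, g), p)
      }
      if (!length(opts))
        stop("prochiral pair ", paste(p, collapse = "/"),
             " has no geminal methyl pair among its candidates")
      opts
    }),
    lapply(singles, function(r)
      lapply(candidate_sets[[r]], function(m) stats::setNames(m, r)))
  )
  count <- 0L
  out <- list()
  assign_dfs <- function(u, used, acc) {
    if (u > length(unit_opts)) {
      count <<- count + 1L
      if (count > max_count)
        stop("hypothesis count exceeds max_count (", max_count,
             "); tighten residue classes, add anchors or reduce the pocket radius")
      out[[count]] <<- acc
      return(invisible())
    }
    for (opt in unit_opts[[u]]) {
      if (any(opt %in% used)) next
      assign_dfs(u + 1L, c(used, unname(opt)), c(acc, opt))
    }
  }
  assign_dfs(1L, used0, anchors)
  lapply(out, function(m) m[res_ids])
}

# ---------------------------------------------------------------------------

#' Compile a docking problem for the compiled-core evaluator
#'
#' Resolves restraints against an assignment hypothesis and packs ligand,
#' receptor and restraint data into the flat structure consumed by the C++
#' target function / annealer. Exposed mainly for testing; normal entry
#' points are [target_function()], [optimize_pose()] and [run_nmr2()].
#'
#' @param restraints A [build_restraint_set()] result (or list of
#'   [distance_restraint()]).
#' @param receptor A [receptor_model()].
#' @param ligand A [ligand_model()].
#' @param hypothesis Named character vector resonance -> methyl id.
#' @param weights Target-function weights `c(upper, lower, clash)`.
#' @param radii Per-element hard-sphere radii, Angstrom.
#' @param overlap_scale Overlap factor applied to radius sums (default 0.8).
#' @return A list (opaque problem object).
#' @export
compile_problem <- function(restraints, receptor, ligand,
                            hypothesis = character(),
                            weights = c(upper = 1, lower = 1, clash = 1),
                            radii = .default_radii, overlap_scale = 0.8) {
  .resolve_hypothesis(
    .compile_base(restraints, receptor, ligand, weights, radii, overlap_scale),
    hypothesis)
}

# hypothesis-independent part: geometry, torsions, clash atoms, restraint
# bounds and candidate *ids* (resolved to methyl indices per hypothesis)
.compile_base <- function(restraints, receptor, ligand,
                          weights = c(upper = 1, lower = 1, clash = 1),
                          radii = .default_radii, overlap_scale = 0.8) {
  grp_names <- names(ligand$groups)
  lig0 <- as.matrix(ligand$atoms[c("x", "y", "z")])
  storage.mode(lig0) <- "double"
  grp_idx <- unlist(ligand$groups, use.names = FALSE)
  grp_off <- cumsum(c(1L, vapply(ligand$groups, length, integer(1))))
  ntor <- length(ligand$torsions)
  tor_axis <- if (ntor) unlist(lapply(ligand$torsions, `[[`, "axis")) else integer()
  tor_idx <- if (ntor) unlist(lapply(ligand$torsions, `[[`, "moving")) else integer()
  tor_off <- cumsum(c(1L, vapply(ligand$torsions, function(t)
    length(t$moving), integer(1))))
  methyl_ids <- receptor$methyls$id
  methyl_xyz <- as.matrix(receptor$methyls[c("x", "y", "z")])
  storage.mode(methyl_xyz) <- "double"
  n_r <- length(restraints)
  r_type <- integer(n_r); r_bound <- numeric(n_r); r_lgrp <- integer(n_r)
  r_cand <- vector("list", n_r)
  for (k in seq_len(n_r)) {
    r <- restraints[[k]]
    gi <- match(r$ligand_group, grp_names)
    if (is.na(gi)) stop("restraint references unknown ligand group: ",
                        r$ligand_group)
    if (r$source == "intraligand") {
      gj <- match(r$partner_ligand_group, grp_names)
      if (is.na(gj)) stop("restraint references unknown ligand group: ",
                          r$partner_ligand_group)
      r_type[k] <- if (r$bound_type == "upper") 3L else 4L
      r_cand[[k]] <- gj  # integer: ligand group index
    } else {
      r_type[k] <- if (r$bound_type == "upper") 1L else 2L
      r_cand[[k]] <- r$candidates  # character: resonance / methyl ids
    }
    r_bound[k] <- r$bound
    r_lgrp[k] <- gi
  }
  elem_rad <- function(e) {
    r <- radii[toupper(e)]
    r[is.na(r)] <- 1.5
    unname(r)
  }
  center <- if (!is.null(receptor$pocket_center)) receptor$pocket_center
            else colMeans(receptor$methyls[c("x", "y", "z")])
  rec_xyz <- as.matrix(receptor$atoms[c("x", "y", "z")])
  storage.mode(rec_xyz) <- "double"
  list(lig0 = lig0, lig_rad = elem_rad(ligand$atoms$elem) * overlap_scale,
       grp_idx = as.integer(grp_idx), grp_off = as.integer(grp_off),
       tor_axis = as.integer(tor_axis), tor_idx = as.integer(tor_idx),
       tor_off = as.integer(tor_off),
       methyl_xyz = methyl_xyz, methyl_ids = methyl_ids,
       rec_xyz = rec_xyz,
       rec_rad = elem_rad(receptor$atoms$elem) * overlap_scale,
       r_type = r_type, r_bound = as.numeric(r_bound),
       r_lgrp = as.integer(r_lgrp), r_cand = r_cand,
       weights = as.numeric(weights[c("upper", "lower", "clash")]),
       center = as.numeric(center),
       n_torsions = ntor)
}

# resolve candidate ids against an assignment hypothesis -> partner index
# arrays consumed by the compiled core
.resolve_hypothesis <- function(base, hypothesis = character()) {
  n_r <- length(base$r_type)
  parts <- vector("list", n_r)
  for (k in seq_len(n_r)) {
    cand <- base$r_cand[[k]]
    if (is.numeric(cand)) {  # intraligand partner group
      parts[[k]] <- as.integer(cand)
    } else {
      hit <- match(cand, names(hypothesis))
      mapped <- ifelse(is.na(hit), cand, unname(hypothesis)[hit])
      idx <- match(unique(mapped), base$methyl_ids)
      if (anyNA(idx))
        stop("restraint references unknown receptor group(s): ",
             paste(unique(mapped)[is.na(idx)], collapse = ", "))
      parts[[k]] <- idx
    }
  }
  base$r_partner <- as.integer(unlist(parts))
  base$r_poff <- as.integer(cumsum(c(1L, lengths(parts))))
  base
}

# use full receptor atoms for clash when the model carries real atoms
.problem_with_full_clash <- function(prob, receptor, radii = .default_radii,
                                     overlap_scale = 0.8) {
  at <- receptor$atoms
  prob$rec_xyz <- as.matrix(at[c("x", "y", "z")])
  storage.mode(prob$rec_xyz) <- "double"
  r <- radii[toupper(at$elem)]
  r[is.na(r)] <- 1.5
  prob$rec_rad <- unname(r) * overlap_scale
  prob
}

#' Complex pose
#'
#' @param par Pose parameter vector `[tx, ty, tz, rx, ry, rz, torsions...]`
#'   (translation Angstrom, rotation vector, torsion angles rad).
#' @param target_value Target-function value (unitless, >= 0).
#' @param report Per-component target report.
#' @return Object of class `complex_pose`.
#' @export
complex_pose <- function(par, target_value = NA_real_, report = NULL) {
  structure(list(par = as.numeric(par), target_value = target_value,
                 report = report),
            class = "complex_pose")
}

#' @export
print.complex_pose <- function(x, ...) {
  cat(sprintf("<complex_pose> target = %.4g, %d parameters\n",
              x$target_value, length(x$par)))
  invisible(x)
}

#' Ligand coordinates of a pose
#' @param pose A [complex_pose()].
#' @param restraints,receptor,ligand The docking inputs.
#' @param hypothesis Assignment used to compile the problem (only geometry
#'   is needed, so any valid hypothesis works).
#' @return natoms x 3 coordinate matrix.
#' @export
pose_ligand_coords <- function(pose, restraints, receptor, ligand,
                               hypothesis = character()) {
  # only the geometry is needed; compile without restraints so unresolved
  # resonance labels cannot get in the way
  prob <- compile_problem(build_restraint_set(), receptor, ligand)
  par <- if (inherits(pose, "complex_pose")) pose$par else as.numeric(pose)
  cpp_ligand_coords(par, prob)
}

#' Evaluate the target function of a pose
#'
#' Sum of squared upper-limit violations \eqn{(d-u)^2} for \eqn{d > u},
#' squared lower-limit violations \eqn{(l-d)^2} for \eqn{d < l}, and a
#' hard-sphere repulsion penalty \eqn{\sum (r_{min}-d)^2} over atom pairs
#' closer than their scaled contact distance. Ambiguous restraints are
#' evaluated at the \eqn{(\sum d^{-6})^{-1/6}} effective distance over the
#' candidates selected by the assignment hypothesis.
#'
#' @inheritParams compile_problem
#' @param pose A [complex_pose()] (or bare parameter vector).
#' @return List of class `target_report`: `upper_violation_sum`,
#'   `lower_violation_sum`, `clash_sum`, `total`, and per-restraint
#'   `violations` / `distances` (Angstrom).
#' @export
target_function <- function(pose, restraints, receptor, ligand,
                            hypothesis = character(),
                            weights = c(upper = 1, lower = 1, clash = 1)) {
  par <- if (inherits(pose, "complex_pose")) pose$par else as.numeric(pose)
  prob <- compile_problem(restraints, receptor, ligand, hypothesis, weights)
  rep <- cpp_pose_report(par, prob)
  structure(rep, class = "target_report")
}

#' @export
print.target_report <- function(x, ...) {
  cat(sprintf("<target_report> total %.4g (upper %.4g, lower %.4g, clash %.4g)\n",
              x$total, x$upper_violation_sum, x$lower_violation_sum,
              x$clash_sum))
  invisible(x)
}

#' Annealing schedule for the pose search
#'
#' @param n_restarts Independent annealing restarts (default 50).
#' @param n_steps Metropolis steps per restart.
#' @param t_start,t_end Geometric cooling endpoints (target-function units).
#' @param step_trans,step_rot,step_tor Move sizes: Angstrom, radians,
#'   radians.
#' @param box_radius Start poses are drawn uniformly in a cube of this
#'   half-width around the pocket center, Angstrom.
#' @param polish Run a deterministic derivative-free local refinement on the
#'   annealed best pose.
#' @return List of schedule parameters.
#' @export
anneal_schedule <- function(n_restarts = 50, n_steps = 2000, t_start = 5,
                            t_end = 0.005, step_trans = 1.0, step_rot = 0.4,
                            step_tor = 0.5, box_radius = 6, polish = TRUE) {
  list(n_restarts = n_restarts, n_steps = n_steps, t_start = t_start,
       t_end = t_end, step_trans = step_trans, step_rot = step_rot,
       step_tor = step_tor, box_radius = box_radius, polish = polish)
}

.polish_pose <- function(par, prob) {
  fn <- function(p) cpp_pose_energy(p, prob)
  opt <- stats::optim(par, fn, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
  opt2 <- stats::optim(opt$par, fn, method = "BFGS",
                       control = list(maxit = 100, reltol = 1e-12))
  if (opt2$value <= opt$value) opt2 else opt
}

#' Optimize the ligand pose under one assignment hypothesis
#'
#' Multi-start simulated annealing over rigid-body degrees of freedom and
#' ligand torsions, followed by deterministic local polishing. Deterministic
#' for a given seed (the master seed fans out to per-restart streams as
#' `seed * 1000003 + restart`).
#'
#' @inheritParams compile_problem
#' @param schedule An [anneal_schedule()].
#' @param seed Integer master seed.
#' @return A [complex_pose()] with its `target_report`. A pose with
#'   non-finite target is reported with `target_value = Inf` (failed
#'   hypothesis), not as an error.
#' @export
optimize_pose <- function(hypothesis, restraints, receptor, ligand,
                          schedule = anneal_schedule(), seed = 1,
                          weights = c(upper = 1, lower = 1, clash = 1),
                          .prob = NULL) {
  prob <- if (!is.null(.prob)) .prob
          else compile_problem(restraints, receptor, ligand, hypothesis,
                               weights)
  ann <- cpp_anneal(prob, schedule$n_restarts, schedule$n_steps,
                    schedule$t_start, schedule$t_end, schedule$step_trans,
                    schedule$step_rot, schedule$step_tor,
                    schedule$box_radius, as.double(seed))
  par <- ann$par
  if (isTRUE(schedule$polish) && is.finite(ann$energy) && ann$energy > 0) {
    pol <- .polish_pose(par, prob)
    if (pol$value < ann$energy) par <- pol$par
  }
  rep <- cpp_pose_report(par, prob)
  val <- if (is.finite(rep$total)) rep$total else Inf
  complex_pose(par, val, structure(rep, class = "target_report"))
}

.serialize_mapping <- function(m) paste(names(m), m, sep = ">", collapse = ";")

#' Run the NMR molecular replacement engine
#'
#' Enumerates assignment hypotheses, optimizes the ligand pose under each,
#' and ranks hypotheses by their best target-function value. A cheap
#' screening schedule scores every hypothesis first; the best `top_k` are
#' re-optimized with the full schedule. The winner's mapping is reported as
#' the inferred methyl assignment. Ranking ties are broken lexicographically
#' on the serialized mapping and reported explicitly.
#'
#' @inheritParams compile_problem
#' @param candidate_sets,anchors,pairing,geminal Passed to
#'   [enumerate_assignments()].
#' @param schedule Full [anneal_schedule()] for the refinement stage.
#' @param screen_schedule Cheap schedule for the screening stage.
#' @param top_k Number of screened hypotheses refined with the full
#'   schedule.
#' @param n_ensemble Number of top poses retained in the result.
#' @param seed Master seed; hypothesis `h` derives its stream from
#'   `seed + h`.
#' @param max_count Hypothesis-count cap (see [enumerate_assignments()]).
#' @return Object of class `nmr2_result`: `table` (data.frame of hypothesis,
#'   target, stage), `assignment` (winning mapping), `best_pose`, `ensemble`
#'   (list of poses), `ties` (logical), `n_hypotheses`.
#' @export
run_nmr2 <- function(restraints, receptor, ligand, candidate_sets,
                     anchors = character(), pairing = NULL, geminal = NULL,
                     schedule = anneal_schedule(),
                     screen_schedule = anneal_schedule(n_restarts = 4,
                                                       n_steps = 400,
                                                       polish = FALSE),
                     top_k = 20, n_ensemble = 10, seed = 1,
                     weights = c(upper = 1, lower = 1, clash = 1),
                     max_count = 1e6) {
  hyps <- enumerate_assignments(candidate_sets, anchors, pairing, geminal,
                                max_count = max_count)
  n <- length(hyps)
  if (!n) stop("no assignment hypotheses to evaluate")
  keys <- vapply(hyps, .serialize_mapping, character(1))
  ord0 <- order(keys)
  hyps <- hyps[ord0]; keys <- keys[ord0]
  base <- .compile_base(restraints, receptor, ligand, weights)
  poses <- lapply(seq_len(n), function(h)
    optimize_pose(hyps[[h]], restraints, receptor, ligand,
                  schedule = screen_schedule, seed = seed + h,
                  weights = weights,
                  .prob = .resolve_hypothesis(base, hyps[[h]])))
  screen <- vapply(poses, function(p) p$target_value, numeric(1))
  refine_idx <- order(screen, keys)[seq_len(min(top_k, n))]
  target <- screen
  stage <- rep("screen", n)
  for (h in refine_idx) {
    p <- optimize_pose(hyps[[h]], restraints, receptor, ligand,
                       schedule = schedule, seed = seed + h,
                       weights = weights,
                       .prob = .resolve_hypothesis(base, hyps[[h]]))
    if (p$target_value <= target[h]) {  # keep the better of the two runs
      poses[[h]] <- p
      target[h] <- p$target_value
    }
    stage[h] <- "refined"
  }
  if (all(!is.finite(target)))
    return(structure(list(table = data.frame(), assignment = NULL,
                          best_pose = NULL, ensemble = list(), ties = NA,
                          n_hypotheses = n, failed = TRUE),
                     class = "nmr2_result"))
  ord <- order(target, keys)
  tbl <- data.frame(rank = seq_len(n), hypothesis = keys[ord],
                    target = target[ord], stage = stage[ord],
                    stringsAsFactors = FALSE)
  best_h <- ord[1]
  ties <- n > 1 && isTRUE(abs(target[ord[2]] - target[ord[1]]) <= 1e-9)
  ens_idx <- ord[stage[ord] == "refined"][seq_len(min(n_ensemble,
                                                      sum(stage == "refined")))]
  structure(list(table = tbl, assignment = hyps[[best_h]],
                 best_pose = poses[[best_h]],
                 ensemble = poses[ens_idx], ties = ties, n_hypotheses = n,
                 failed = FALSE),
            class = "nmr2_result")
}

#' @export
print.nmr2_result <- function(x, ...) {
  if (isTRUE(x$failed)) {
    cat("<nmr2_result> FAILED: no hypothesis produced a finite target\n")
    return(invisible(x))
  }
  cat(sprintf("<nmr2_result> %d hypotheses; best target %.4g%s\n",
              x$n_hypotheses, x$table$target[1],
              if (isTRUE(x$ties)) " (TIE with runner-up)" else ""))
  cat("winning assignment:\n")
  m <- x$assignment
  for (r in names(m)) cat(sprintf("  %s -> %s\n", r, m[[r]]))
  invisible(x)
}

#' Backbone-restrained pose refinement
#'
#' Gradient-based minimization of the target function in which selected
#' receptor methyl pseudoatoms (a binding-site loop) are allowed to move
#' under harmonic positional restraints \eqn{k |x - x_0|^2}, jointly with
#' the ligand pose. This is a simplified vacuum analog of explicit-solvent
#' restrained refinement: it lets a flexible loop bend toward the ligand to
#' relieve residual NOE violations while staying near its starting
#' coordinates.
#'
#' @inheritParams compile_problem
#' @param pose A converged [complex_pose()] from [optimize_pose()].
#' @param k Harmonic force constant per methyl, target units / Angstrom^2.
#' @param region Character vector of methyl ids allowed to move (default:
#'   all).
#' @return List of class `refined_pose`: `pose` (refined), `receptor`
#'   (receptor with displaced methyls), `displacement` (per-methyl,
#'   Angstrom), `converged`. On divergence the input pose is returned with a
#'   warning.
#' @export
refine_backbone_restrained <- function(pose, receptor, restraints, ligand,
                                       hypothesis = character(), k = 10,
                                       region = NULL,
                                       weights = c(upper = 1, lower = 1,
                                                   clash = 1)) {
  prob0 <- compile_problem(restraints, receptor, ligand, hypothesis, weights)
  ids <- receptor$methyls$id
  move <- if (is.null(region)) seq_along(ids) else match(region, ids)
  if (any(is.na(move))) stop("unknown methyl id(s) in region")
  x0 <- prob0$methyl_xyz
  # clash-atom rows backing the moved methyls (may be absent for
  # proton-averaged pseudoatoms of an all-atom receptor)
  atom_key <- paste(receptor$atoms$resname, receptor$atoms$resno,
                    receptor$atoms$name, sep = "\r")
  meth_key <- paste(receptor$methyls$resname, receptor$methyls$resno,
                    sub("^.*\\.", "", receptor$methyls$id), sep = "\r")
  atom_row <- match(meth_key, atom_key)
  npose <- length(pose$par)
  fn <- function(p) {
    prob <- prob0
    disp <- matrix(p[-seq_len(npose)], ncol = 3)
    prob$methyl_xyz[move, ] <- x0[move, ] + disp
    ar <- atom_row[move]
    prob$rec_xyz[ar[!is.na(ar)], ] <- prob$methyl_xyz[move, , drop = FALSE][!is.na(ar), ]
    cpp_pose_energy(p[seq_len(npose)], prob) + k * sum(disp^2)
  }
  par0 <- c(pose$par, rep(0, 3 * length(move)))
  e0 <- fn(par0)
  opt <- stats::optim(par0, fn, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-10))
  if (!is.finite(opt$value) || opt$value > e0 + 1e-9) {
    warning("refinement diverged; returning the input pose")
    return(structure(list(pose = pose, receptor = receptor,
                          displacement = stats::setNames(rep(0, length(move)),
                                                         ids[move]),
                          converged = FALSE),
                     class = "refined_pose"))
  }
  disp <- matrix(opt$par[-seq_len(npose)], ncol = 3)
  rec2 <- receptor
  rec2$methyls[move, c("x", "y", "z")] <-
    rec2$methyls[move, c("x", "y", "z")] + disp
  prob <- prob0
  prob$methyl_xyz[move, ] <- x0[move, ] + disp
  ar <- atom_row[move]
  prob$rec_xyz[ar[!is.na(ar)], ] <- prob$methyl_xyz[move, , drop = FALSE][!is.na(ar), ]
  rep <- cpp_pose_report(opt$par[seq_len(npose)], prob)
  structure(list(pose = complex_pose(opt$par[seq_len(npose)], rep$total,
                                     structure(rep, class = "target_report")),
                 receptor = rec2,
                 displacement = stats::setNames(sqrt(rowSums(disp^2)),
                                                ids[move]),
                 converged = TRUE),
            class = "refined_pose")
}

#' Heavy-atom RMSD between a pose and reference ligand coordinates
#'
#' Computed in the receptor frame without refitting (the receptor defines
#' the common frame).
#'
#' @inheritParams pose_ligand_coords
#' @param ref_coords natoms x 3 reference coordinate matrix (e.g. the
#'   ground-truth ligand placement).
#' @return RMSD in Angstrom over non-hydrogen atoms.
#' @export
pose_rmsd <- function(pose, restraints, receptor, ligand, ref_coords,
                      hypothesis = character()) {
  xyz <- pose_ligand_coords(pose, restraints, receptor, ligand, hypothesis)
  heavy <- ligand_heavy_atoms(ligand)
  sqrt(mean(rowSums((xyz[heavy, , drop = FALSE] -
                       ref_coords[heavy, , drop = FALSE])^2)))
}
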