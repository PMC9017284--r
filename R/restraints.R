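# Restraint calibration: ambiguous upper limits with methyl-dependent
# tolerance floors, conservative anti-NOE lower limits, prochiral methyl
# pairing and residue-type class constraints.

#' Proton group descriptor
#'
#' @param id Group identifier.
#' @param kind One of `"ligand-proton"`, `"ligand-methyl"`, `"receptor-methyl"`.
#' @param multiplicity Number of equivalent protons: 1 (single proton),
#'   3 (methyl) or 6 (paired prochiral pseudo-group).
#' @param residue_class For receptor methyls: `"Met"`, `"Thr"`, `"Ala"`,
#'   `"ILV"` or `"unknown"`.
#' @param assigned_to Receptor methyl-group id when the resonance is
#'   assigned, else `NA`.
#' @return Object of class `proton_group`.
#' @export
proton_group <- function(id, kind = c("ligand-proton", "ligand-methyl",
                                      "receptor-methyl"),
                         multiplicity = 1,
                         residue_class = "unknown", assigned_to = NA_character_) {
  kind <- match.arg(kind)
  if (!multiplicity %in% c(1, 3, 6)) stop("multiplicity must be 1, 3 or 6")
  if (!is.na(assigned_to) && kind != "receptor-methyl")
    stop("assigned_to may be set only for receptor-methyl groups")
  structure(list(id = as.character(id), kind = kind,
                 multiplicity = multiplicity,
                 residue_class = residue_class, assigned_to = assigned_to),
            class = "proton_group")
}

is_methyl_group <- function(g) {
  if (inherits(g, "proton_group"))
    g$kind %in% c("ligand-methyl", "receptor-methyl")
  else isTRUE(g)
}

#' Ambiguous distance restraint
#'
#' @param ligand_group Ligand proton-group id.
#' @param candidates Character vector of candidate receptor methyl-group ids
#'   (or resonance ids prior to assignment); singleton when unambiguous.
#'   `NULL`/empty for intraligand restraints.
#' @param bound_type `"upper"` or `"lower"`.
#' @param bound Limit in Angstrom.
#' @param source `"NOE"`, `"anti-NOE"` or `"intraligand"`.
#' @param resonance Receptor resonance id the restraint refers to (resolved
#'   to a methyl by an assignment hypothesis), or `NA` for intraligand.
#' @param partner_ligand_group Second ligand group for intraligand restraints.
#' @return Object of class `distance_restraint`.
#' @export
distance_restraint <- function(ligand_group, candidates, bound_type, bound,
                               source = c("NOE", "anti-NOE", "intraligand"),
                               resonance = NA_character_,
                               partner_ligand_group = NA_character_) {
  source <- match.arg(source)
  if (!bound_type %in% c("upper", "lower")) stop("bound_type must be upper/lower")
  if (bound_type == "upper" && bound < 1.8)
    stop("upper bounds below 1.8 Angstrom are not physical")
  if (source == "anti-NOE" && !isTRUE(all.equal(bound, 3.0)) &&
      !isTRUE(all.equal(bound, 3.6)))
    stop("anti-NOE lower limits must be 3.0 or 3.6 Angstrom")
  if (source == "intraligand" && is.na(partner_ligand_group))
    stop("intraligand restraints need a partner_ligand_group")
  if (source != "intraligand" && (is.null(candidates) || !length(candidates)))
    stop("intermolecular restraints need a non-empty candidate set")
  structure(list(ligand_group = as.character(ligand_group),
                 candidates = as.character(if (is.null(candidates)) character() else candidates),
                 bound_type = bound_type, bound = bound, source = source,
                 resonance = as.character(resonance),
                 partner_ligand_group = as.character(partner_ligand_group)),
            class = "distance_restraint")
}

#' @export
print.distance_restraint <- function(x, ...) {
  partner <- if (x$source == "intraligand") x$partner_ligand_group
             else paste0(x$resonance, " {", paste(x$candidates, collapse = ","), "}")
  cat(sprintf("<distance_restraint> %s .. %s  %s %.2f A (%s)\n", x$ligand_group,
              partner, if (x$bound_type == "upper") "<=" else ">=",
              x$bound, x$source))
  invisible(x)
}

#' Calibrate an upper-limit restraint from an accepted NOE fit
#'
#' Converts an accepted cross-relaxation fit into an ambiguous upper-limit
#' restraint. Under the tolerant methyl-labeling protocol (`"brd4"`) the
#' limit is the fitted distance floored at a large tolerance: 5.5 Angstrom
#' when a single ligand proton is involved in the NOE and 6.5 Angstrom when
#' two methyl groups are involved; no lower limit is emitted. Under the
#' tighter protocol (`"trim24"`) the limit is the fitted distance plus a
#' small calibration tolerance with no floor.
#'
#' @param fit An accepted `crossrelax_fit` carrying a distance.
#' @param ligand_is_methyl,receptor_is_methyl Logical flags (or
#'   [proton_group()] objects) for the two sides of the NOE.
#' @param protocol `"brd4"` (tolerant floors, default) or `"trim24"`.
#' @param floors Tolerance floors in Angstrom,
#'   `c(single = 5.5, two_methyl = 6.5)`.
#' @param trim24_tolerance Additive calibration tolerance for the tight
#'   protocol, Angstrom.
#' @param ligand_group,resonance Identifiers for the restraint; default to
#'   the fit's `group_i` / `group_j`.
#' @param candidates Candidate receptor methyl ids (defaults to the
#'   resonance id itself, to be resolved later by class constraints /
#'   assignment).
#' @return A [distance_restraint()] with `bound_type = "upper"`.
#' @export
calibrate_upper_limit <- function(fit, ligand_is_methyl, receptor_is_methyl,
                                  protocol = c("brd4", "trim24"),
                                  floors = c(single = 5.5, two_methyl = 6.5),
                                  trim24_tolerance = 0.5,
                                  ligand_group = fit$group_i,
                                  resonance = fit$group_j,
                                  candidates = resonance) {
  protocol <- match.arg(protocol)
  if (!inherits(fit, "crossrelax_fit")) stop("fit must be a crossrelax_fit")
  if (!isTRUE(fit$accepted) || is.na(fit$distance))
    stop("refusing to calibrate a rejected fit (no reliable distance): ",
         fit$group_i, "-", fit$group_j)
  both_methyl <- is_methyl_group(ligand_is_methyl) &&
    is_methyl_group(receptor_is_methyl)
  bound <- if (protocol == "brd4") {
    floor_a <- if (both_methyl) floors[["two_methyl"]] else floors[["single"]]
    max(fit$distance, floor_a)
  } else {
    fit$distance + trim24_tolerance
  }
  distance_restraint(ligand_group, candidates, "upper", bound,
                     source = "NOE", resonance = resonance)
}

#' Construct a conservative anti-NOE lower limit
#'
#' A missing cross peak between two resonances is interpreted as an anti-NOE
#' only when both resonances exhibit visible NOE cross peaks with other
#' partners; then the absence can be attributed to a large distance rather
#' than to dynamics or artifacts. Accepted anti-NOEs become lower limits of
#' 3.0 Angstrom when one methyl group is involved and 3.6 Angstrom when two
#' methyl groups are involved.
#'
#' @param ligand_group,resonance Ids of the (absent) pair, ligand side and
#'   receptor side.
#' @param ligand_is_methyl,receptor_is_methyl Flags or [proton_group()]s.
#' @param visibility Data.frame of visible pairs with columns `group_i`,
#'   `group_j` (order irrelevant).
#' @param limits Lower limits, `c(one_methyl = 3.0, two_methyl = 3.6)`.
#' @param candidates Candidate receptor methyl ids (default the resonance id).
#' @return A [distance_restraint()] (`bound_type = "lower"`), or `NULL`
#'   when the conservative acceptance rule is not met.
#' @export
build_anti_noe <- function(ligand_group, resonance, ligand_is_methyl,
                           receptor_is_methyl, visibility,
                           limits = c(one_methyl = 3.0, two_methyl = 3.6),
                           candidates = resonance) {
  vis_i <- visibility$group_i
  vis_j <- visibility$group_j
  pair_present <- any((vis_i == ligand_group & vis_j == resonance) |
                      (vis_i == resonance & vis_j == ligand_group))
  if (pair_present)
    stop("not an anti-NOE: the pair ", ligand_group, "-", resonance,
         " is present in the peak table")
  has_other <- function(id, other) {
    any((vis_i == id & vis_j != other) | (vis_j == id & vis_i != other))
  }
  if (!has_other(ligand_group, resonance) || !has_other(resonance, ligand_group))
    return(NULL)
  n_methyl <- is_methyl_group(ligand_is_methyl) + is_methyl_group(receptor_is_methyl)
  bound <- if (n_methyl >= 2) limits[["two_methyl"]] else limits[["one_methyl"]]
  distance_restraint(ligand_group, candidates, "lower", bound,
                     source = "anti-NOE", resonance = resonance)
}

#' Pair prochiral methyl resonances from protein-protein NOEs
#'
#' Greedily pairs mutually strongest partners in the receptor methyl-methyl
#' peak list, provided the cross peak exceeds the strong-NOE threshold. The
#' default threshold corresponds to the cross-relaxation rate of a 3.0
#' Angstrom contact (the geminal methyl-methyl distance in Leu/Val is
#' essentially constant), when a [relaxation_context()] is supplied and the
#' peak list carries fitted `sigma` values; otherwise pass `threshold`
#' explicitly on the intensity scale of the `value` column.
#'
#' @param peaks Data.frame with columns `res_i`, `res_j` and either `sigma`
#'   or `value` (strength; absolute value is used).
#' @param ctx Optional [relaxation_context()] used to derive the default
#'   sigma threshold.
#' @param threshold Strong-NOE threshold (absolute value).
#' @param strong_distance Distance defining "strong" when deriving the
#'   threshold from `ctx` (default 3.0 Angstrom).
#' @return Object of class `prochiral_pairing`: list of unordered id pairs;
#'   each resonance appears in at most one pair.
#' @export
pair_prochirals <- function(peaks, ctx = NULL, threshold = NULL,
                            strong_distance = 3.0) {
  if (is.null(threshold)) {
    if (is.null(ctx))
      stop("supply either a relaxation_context or an explicit threshold")
    threshold <- abs(sigma_from_distance(strong_distance, ctx))
  }
  pairs <- list()
  if (nrow(peaks)) {
    val <- abs(if ("sigma" %in% names(peaks)) peaks$sigma else peaks$value)
    df <- data.frame(i = as.character(peaks$res_i),
                     j = as.character(peaks$res_j), v = val,
                     stringsAsFactors = FALSE)
    df <- df[df$i != df$j & df$v >= threshold, , drop = FALSE]
    # collapse duplicate orientations, keep strongest
    key <- apply(cbind(pmin(df$i, df$j), pmax(df$i, df$j)), 1, paste,
                 collapse = "\r")
    if (nrow(df)) {
      df <- do.call(rbind, lapply(split(df, key), function(d)
        d[which.max(d$v), , drop = FALSE]))
      df <- df[order(-df$v, df$i, df$j), , drop = FALSE]
      # descending-strength greedy = iterated mutual-strongest matching
      used <- character()
      for (k in seq_len(nrow(df))) {
        a <- df$i[k]; b <- df$j[k]
        if (a %in% used || b %in% used) next
        pairs[[length(pairs) + 1L]] <- sort(c(a, b))
        used <- c(used, a, b)
      }
    }
  }
  structure(list(pairs = pairs), class = "prochiral_pairing")
}

#' Restrict resonance candidate sets by residue-type class
#'
#' Each unassigned methyl resonance carries a residue-type class (from
#' constant-time HSQC sign patterns or TOCSY; classification itself is an
#' input here). Its candidate receptor methyls are restricted to methyls of
#' the matching class; resonances classed Met or Thr whose class has exactly
#' one member in the binding site become fixed anchors.
#'
#' @param resonances Data.frame with columns `id`, `class`
#'   (`Met`/`Thr`/`Ala`/`ILV`/`unknown`).
#' @param receptor_methyls Data.frame with columns `id`, `class` describing
#'   the binding-site methyl inventory.
#' @return List with `candidates` (named list of character vectors) and
#'   `anchors` (named character vector of forced assignments).
#' @export
apply_residue_classes <- function(resonances, receptor_methyls) {
  all_ids <- as.character(receptor_methyls$id)
  candidates <- list()
  anchors <- character()
  for (k in seq_len(nrow(resonances))) {
    rid <- as.character(resonances$id[k])
    cls <- as.character(resonances$class[k])
    cand <- if (is.na(cls) || cls == "unknown") all_ids
            else all_ids[receptor_methyls$class == cls]
    if (!length(cand))
      stop("infeasible class: resonance ", rid, " is classed ", cls,
           " but the binding site has no ", cls, " methyl")
    if (cls %in% c("Met", "Thr") && length(cand) == 1L)
      anchors[rid] <- cand
    candidates[[rid]] <- cand
  }
  list(candidates = candidates, anchors = anchors)
}

restraint_key <- function(r) {
  paste(r$ligand_group, paste(sort(r$candidates), collapse = "+"),
        r$bound_type, r$partner_ligand_group, r$resonance,
        format(r$bound, digits = 10), sep = "\r")
}

#' Assemble the full restraint set
#'
#' One upper limit per accepted intermolecular NOE, one lower limit per
#' accepted anti-NOE, one (unambiguous) upper limit per intraligand NOE.
#' Duplicate entries (same ligand group, candidate set and bound type) are
#' removed with a warning; counts are otherwise conserved.
#'
#' @param noe_restraints,anti_noe_restraints,intraligand_restraints Lists of
#'   [distance_restraint()] objects (any may be empty or `NULL`).
#' @return Object of class `restraint_set`: list of restraints plus a count
#'   summary attribute.
#' @export
build_restraint_set <- function(noe_restraints = list(),
                                anti_noe_restraints = list(),
                                intraligand_restraints = list()) {
  all <- c(noe_restraints, anti_noe_restraints, intraligand_restraints)
  all <- Filter(Negate(is.null), all)
  if (length(all) && !all(vapply(all, inherits, logical(1), "distance_restraint")))
    stop("all inputs must be distance_restraint objects")
  keys <- vapply(all, restraint_key, character(1))
  dup <- duplicated(keys)
  if (any(dup)) {
    warning(sum(dup), " duplicate restraint(s) removed")
    all <- all[!dup]
  }
  counts <- table(factor(vapply(all, function(r) r$source, character(1)),
                         levels = c("NOE", "anti-NOE", "intraligand")))
  structure(all, class = "restraint_set", counts = counts)
}

#' @export
print.restraint_set <- function(x, ...) {
  cts <- attr(x, "counts")
  cat(sprintf("<restraint_set> %d restraints (%d NOE upper, %d anti-NOE lower, %d intraligand)\n",
              length(x), cts[["NOE"]], cts[["anti-NOE"]], cts[["intraligand"]]))
  invisible(x)
}
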