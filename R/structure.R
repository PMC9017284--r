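# Receptor and ligand structural models, methyl-group detection, PDB / SDF
# input and output.

# methyl carbon templates: residue -> carbon atom names
.methyl_templates <- list(
  ALA = "CB", THR = "CG2", VAL = c("CG1", "CG2"), LEU = c("CD1", "CD2"),
  ILE = c("CD1", "CG2"), MET = "CE")

.residue_class <- c(ALA = "Ala", THR = "Thr", VAL = "ILV", LEU = "ILV",
                    ILE = "ILV", MET = "Met")

# geminal partner of a methyl carbon within the same residue (Leu/Val)
.geminal_map <- c(CG1 = "CG2", CG2 = "CG1", CD1 = "CD2", CD2 = "CD1")

# default hard-sphere radii by element, Angstrom (scaled by the overlap
# factor at problem-compilation time)
.default_radii <- c(H = 1.0, C = 1.5, N = 1.4, O = 1.3, S = 1.7)

#' Receptor model with methyl-group inventory
#'
#' Builds a receptor model from an atom table, detecting methyl groups from
#' residue/atom-name templates (Ala CB, Thr CG2, Val CG1/CG2, Leu CD1/CD2,
#' Ile CD1/CG2, Met CE). The methyl pseudoatom sits at the mean position of
#' the three methyl protons when they are present in the atom table, else at
#' the methyl carbon. Optionally the inventory is restricted to methyls
#' within `pocket_radius` of `pocket_center` (binding-site focus).
#'
#' @param atoms Data.frame with columns `elem`, `name`, `resno`, `resname`,
#'   `x`, `y`, `z` (Angstrom).
#' @param pocket_center Numeric length-3 pocket center, or `NULL` to keep
#'   all methyls.
#' @param pocket_radius Radius of the binding-site sphere, Angstrom
#'   (default 12).
#' @return An object of class `receptor_model` with elements `atoms`,
#'   `methyls` (data.frame: `id`, `resno`, `resname`, `class`, `geminal`,
#'   `x`, `y`, `z`), `pocket_center`.
#' @export
receptor_model <- function(atoms, pocket_center = NULL, pocket_radius = 12) {
  stopifnot(all(c("elem", "name", "resno", "resname", "x", "y", "z") %in%
                  names(atoms)))
  if (any(!is.finite(as.matrix(atoms[c("x", "y", "z")]))))
    stop("receptor coordinates must be finite")
  meth <- list()
  for (k in seq_len(nrow(atoms))) {
    rn <- toupper(atoms$resname[k])
    an <- toupper(atoms$name[k])
    tmpl <- .methyl_templates[[rn]]
    if (is.null(tmpl) || !an %in% tmpl) next
    # methyl protons share the carbon's name with H prefix (e.g. CD1 -> HD1#)
    hpat <- paste0("^H", substring(an, 2))
    same_res <- atoms$resno == atoms$resno[k] & toupper(atoms$resname) == rn
    hyd <- atoms[same_res & grepl(hpat, toupper(atoms$name)) &
                   toupper(atoms$elem) == "H", , drop = FALSE]
    pos <- if (nrow(hyd) == 3L) colMeans(hyd[c("x", "y", "z")])
           else c(x = atoms$x[k], y = atoms$y[k], z = atoms$z[k])
    gem <- if (an %in% names(.geminal_map)) .geminal_map[[an]] else NA_character_
    meth[[length(meth) + 1L]] <- data.frame(
      id = sprintf("%s%d.%s", rn, atoms$resno[k], an),
      resno = atoms$resno[k], resname = rn,
      class = .residue_class[[rn]],
      geminal = if (!is.na(gem) && rn %in% c("VAL", "LEU"))
        sprintf("%s%d.%s", rn, atoms$resno[k], gem) else NA_character_,
      x = pos[[1]], y = pos[[2]], z = pos[[3]],
      stringsAsFactors = FALSE)
  }
  methyls <- if (length(meth)) do.call(rbind, meth) else
    data.frame(id = character(), resno = integer(), resname = character(),
               class = character(), geminal = character(),
               x = numeric(), y = numeric(), z = numeric())
  methyls <- methyls[!duplicated(methyls$id), , drop = FALSE]
  if (!is.null(pocket_center)) {
    d <- sqrt((methyls$x - pocket_center[1])^2 +
              (methyls$y - pocket_center[2])^2 +
              (methyls$z - pocket_center[3])^2)
    methyls <- methyls[d <= pocket_radius, , drop = FALSE]
  }
  rownames(methyls) <- NULL
  structure(list(atoms = atoms, methyls = methyls,
                 pocket_center = pocket_center),
            class = "receptor_model")
}

#' @export
print.receptor_model <- function(x, ...) {
  cat(sprintf("<receptor_model> %d atoms, %d methyl groups\n",
              nrow(x$atoms), nrow(x$methyls)))
  invisible(x)
}

#' Ligand model
#'
#' @param atoms Data.frame with columns `name`, `elem`, `x`, `y`, `z`
#'   (reference-conformer coordinates, Angstrom).
#' @param groups Named list: proton-group id -> integer atom indices (a
#'   methyl group lists its three protons, or one pseudoatom). If `NULL`,
#'   every hydrogen becomes its own group named after the atom.
#' @param torsions List of rotatable torsions, each
#'   `list(axis = c(a, b), moving = <indices>)`: the `moving` atoms rotate
#'   about the a->b bond.
#' @param is_methyl Named logical, which groups are methyls; defaults to
#'   groups with 3 atoms or whose id starts with "Q".
#' @return Object of class `ligand_model`.
#' @export
ligand_model <- function(atoms, groups = NULL, torsions = list(),
                         is_methyl = NULL) {
  stopifnot(all(c("name", "elem", "x", "y", "z") %in% names(atoms)))
  if (is.null(groups)) {
    hy <- which(toupper(atoms$elem) == "H")
    groups <- as.list(hy)
    names(groups) <- atoms$name[hy]
  }
  if (is.null(is_methyl))
    is_methyl <- vapply(seq_along(groups), function(i)
      length(groups[[i]]) >= 3 || startsWith(names(groups)[i], "Q"),
      logical(1))
  names(is_methyl) <- names(groups)
  for (tr in torsions)
    stopifnot(length(tr$axis) == 2, length(tr$moving) >= 1)
  structure(list(atoms = atoms, groups = groups, torsions = torsions,
                 is_methyl = is_methyl),
            class = "ligand_model")
}

#' @export
print.ligand_model <- function(x, ...) {
  cat(sprintf("<ligand_model> %d atoms, %d proton groups, %d rotatable torsions\n",
              nrow(x$atoms), length(x$groups), length(x$torsions)))
  invisible(x)
}

#' Heavy-atom indices of a ligand model
#' @param ligand A [ligand_model()].
#' @return Integer vector of non-hydrogen atom indices.
#' @export
ligand_heavy_atoms <- function(ligand) which(toupper(ligand$atoms$elem) != "H")

# ---------------------------------------------------------------------------
# PDB input / output (fixed-width v3 ATOM/HETATM records)

.parse_pdb_atoms <- function(lines, path = "<pdb>") {
  sel <- grepl("^(ATOM  |HETATM)", lines)
  lines <- lines[sel]
  lineno <- which(sel)
  if (!length(lines)) stop("no ATOM/HETATM records in ", path)
  sub_trim <- function(s, a, b) trimws(substring(s, a, b))
  num <- function(s, a, b, what, i) {
    v <- suppressWarnings(as.numeric(sub_trim(s, a, b)))
    if (any(is.na(v)))
      stop("malformed ", what, " in PDB record at line ",
           lineno[which(is.na(v))[1]], " of ", path)
    v
  }
  name <- sub_trim(lines, 13, 16)
  altloc <- substring(lines, 17, 17)
  resname <- sub_trim(lines, 18, 20)
  chain <- substring(lines, 22, 22)
  resno <- as.integer(num(lines, 23, 26, "residue number", NULL))
  icode <- substring(lines, 27, 27)
  x <- num(lines, 31, 38, "x coordinate")
  y <- num(lines, 39, 46, "y coordinate")
  z <- num(lines, 47, 54, "z coordinate")
  elem <- sub_trim(lines, 77, 78)
  guess <- toupper(substring(gsub("[0-9]", "", name), 1, 1))
  elem <- ifelse(elem == "", guess, toupper(elem))
  df <- data.frame(name = name, elem = elem, resno = resno,
                   resname = resname, chain = chain, altloc = altloc,
                   icode = icode, x = x, y = y, z = z,
                   stringsAsFactors = FALSE)
  # altloc / insertion-code resolution: first occurrence wins
  key <- paste(df$chain, df$resno, df$resname, df$name, sep = "\r")
  df <- df[!duplicated(key), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a receptor structure from PDB
#'
#' Parses ATOM/HETATM records (first occurrence wins for alternate locations
#' and insertion codes) and builds the methyl inventory via
#' [receptor_model()].
#'
#' @param path PDB file path.
#' @param pocket_center,pocket_radius Passed to [receptor_model()].
#' @return A `receptor_model`.
#' @export
read_receptor_pdb <- function(path, pocket_center = NULL, pocket_radius = 12) {
  atoms <- .parse_pdb_atoms(readLines(path, warn = FALSE), path)
  rec <- receptor_model(atoms, pocket_center, pocket_radius)
  if (!nrow(rec$methyls))
    stop("no methyl groups found in ", path,
         " (expected Ala/Thr/Val/Leu/Ile/Met methyl carbons)")
  rec
}

#' Write an atom table (or pose ensemble) as PDB
#'
#' @param atoms Data.frame with `name`, `elem`, `resno`, `resname`, `x`,
#'   `y`, `z` (optional `chain`).
#' @param path Output path.
#' @param model Optional MODEL number; when supplied, MODEL/ENDMDL records
#'   are emitted (append mode used for model > 1).
#' @return The path, invisibly.
#' @export
write_pdb <- function(atoms, path, model = NULL) {
  chain <- if ("chain" %in% names(atoms)) atoms$chain else "A"
  recs <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                  seq_len(nrow(atoms)),
                  ifelse(nchar(atoms$name) < 4, paste0(" ", atoms$name),
                         atoms$name),
                  atoms$resname, chain, atoms$resno,
                  atoms$x, atoms$y, atoms$z, atoms$elem)
  out <- recs
  if (!is.null(model)) out <- c(sprintf("MODEL     %4d", model), recs, "ENDMDL")
  append <- !is.null(model) && model > 1
  con <- file(path, if (append) "a" else "w")
  writeLines(c(out, if (is.null(model)) "END"), con)
  close(con)
  invisible(path)
}

#' Read a ligand from PDB or SDF
#'
#' PDB ligands are parsed like receptors; SDF (MDL V2000) files use the
#' counts line and atom block. Proton groups default to one group per
#' hydrogen (see [ligand_model()]).
#'
#' @param path File path; format chosen by extension (`.sdf` vs `.pdb`).
#' @param groups,torsions Passed to [ligand_model()].
#' @return A `ligand_model`.
#' @export
read_ligand <- function(path, groups = NULL, torsions = list()) {
  if (grepl("\\.sdf$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) < 4) stop("truncated SDF file: ", path)
    counts <- lines[4]
    natoms <- as.integer(substring(counts, 1, 3))
    if (is.na(natoms) || natoms < 1) stop("malformed SDF counts line in ", path)
    ablock <- lines[5:(4 + natoms)]
    atoms <- data.frame(
      x = as.numeric(substring(ablock, 1, 10)),
      y = as.numeric(substring(ablock, 11, 20)),
      z = as.numeric(substring(ablock, 21, 30)),
      elem = toupper(trimws(substring(ablock, 32, 34))),
      stringsAsFactors = FALSE)
    atoms$name <- paste0(atoms$elem, seq_len(nrow(atoms)))
  } else {
    atoms <- .parse_pdb_atoms(readLines(path, warn = FALSE), path)
  }
  ligand_model(atoms, groups = groups, torsions = torsions)
}

#' Write a ligand pose ensemble as multi-MODEL PDB
#'
#' @param poses List of `complex_pose` objects (see [optimize_pose()]).
#' @param ligand The [ligand_model()].
#' @param receptor The [receptor_model()] used to compile poses.
#' @param restraints The restraint set the poses were computed against.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pose_ensemble <- function(poses, ligand, receptor, restraints, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(poses)) {
    xyz <- pose_ligand_coords(poses[[m]], restraints, receptor, ligand)
    atoms <- ligand$atoms
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
    atoms$resno <- 1L; atoms$resname <- "LIG"
    recs <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                    seq_len(nrow(atoms)),
                    ifelse(nchar(atoms$name) < 4, paste0(" ", atoms$name),
                           atoms$name),
                    atoms$resname, "L", atoms$resno,
                    atoms$x, atoms$y, atoms$z, atoms$elem)
    writeLines(c(sprintf("MODEL     %4d", m), recs, "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}
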