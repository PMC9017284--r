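# Restraint file interchange (CYANA-dialect .upl/.lol), run configuration
# and logging.

# decompose a methyl id like "MET920.CE" into (resno, resname, atom);
# plain resonance ids (e.g. "M3") are written with resno 0, resname RES
.decompose_id <- function(id) {
  m <- regmatches(id, regexec("^([A-Za-z]{3})([0-9]+)\\.(\\S+)$", id))[[1]]
  if (length(m) == 4)
    list(resno = as.integer(m[3]), resname = toupper(m[2]), atom = m[4])
  else list(resno = 0L, resname = "RES", atom = id)
}

.compose_id <- function(resno, resname, atom) {
  if (resname == "RES" && resno == 0L) atom
  else if (resname == "LIG") atom
  else sprintf("%s%d.%s", resname, resno, atom)
}

#' Write distance restraints as CYANA-dialect .upl / .lol files
#'
#' Upper limits go to the `.upl` file, lower limits to the `.lol` file.
#' Fixed-width columns: residue-number residue-name atom-name (ligand side),
#' then the receptor side, then the bound in Angstrom. An ambiguous
#' restraint is written as one line per candidate, grouped by a shared
#' `#R<k>` identifier carrying the source tag. [read_restraints()] inverts
#' the format losslessly.
#'
#' @param restraints A `restraint_set` (or list of [distance_restraint()]).
#' @param upl_path,lol_path Output paths.
#' @return Invisibly, `c(upl_path, lol_path)`.
#' @export
write_restraints <- function(restraints, upl_path, lol_path) {
  upl <- c("# upper limit distance restraints (Angstrom)")
  lol <- c("# lower limit distance restraints (Angstrom)")
  for (k in seq_along(restraints)) {
    r <- restraints[[k]]
    lg <- .decompose_id(r$ligand_group)
    partners <- if (r$source == "intraligand") r$partner_ligand_group
                else r$candidates
    for (p in partners) {
      pd <- if (r$source == "intraligand")
        list(resno = 1L, resname = "LIG", atom = p) else .decompose_id(p)
      line <- sprintf("%4d %-4s %-5s %4d %-4s %-5s %7.2f  #R%d %s %s",
                      1L, "LIG", lg$atom, pd$resno, pd$resname, pd$atom,
                      r$bound, k, r$source, r$resonance)
      if (r$bound_type == "upper") upl <- c(upl, line) else lol <- c(lol, line)
    }
  }
  writeLines(upl, upl_path)
  writeLines(lol, lol_path)
  invisible(c(upl_path, lol_path))
}

.read_restraint_file <- function(path, bound_type) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (ln in lines) {
    main <- sub("\\s*#.*$", "", ln)
    tag <- sub("^.*#", "", ln)
    f <- strsplit(trimws(main), "\\s+")[[1]]
    tg <- strsplit(trimws(tag), "\\s+")[[1]]
    if (length(f) != 7) stop("malformed restraint line in ", path, ": ", ln)
    out[[length(out) + 1L]] <- data.frame(
      lig = f[3], resno = as.integer(f[4]), resname = f[5], atom = f[6],
      bound = as.numeric(f[7]), rid = tg[1], source = tg[2],
      resonance = if (length(tg) >= 3) tg[3] else NA_character_,
      bound_type = bound_type, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Read restraints written by [write_restraints()]
#'
#' @param upl_path,lol_path Paths written by [write_restraints()]; either
#'   may be missing/empty.
#' @return A `restraint_set`.
#' @export
read_restraints <- function(upl_path = NULL, lol_path = NULL) {
  df <- rbind(if (!is.null(upl_path) && file.exists(upl_path))
                .read_restraint_file(upl_path, "upper"),
              if (!is.null(lol_path) && file.exists(lol_path))
                .read_restraint_file(lol_path, "lower"))
  if (is.null(df)) return(build_restraint_set())
  res <- lapply(split(df, factor(df$rid, levels = unique(df$rid))), function(d) {
    if (d$source[1] == "intraligand")
      distance_restraint(d$lig[1], NULL, d$bound_type[1], d$bound[1],
                         source = "intraligand",
                         partner_ligand_group = d$atom[1])
    else
      distance_restraint(d$lig[1],
                         vapply(seq_len(nrow(d)), function(i)
                           .compose_id(d$resno[i], d$resname[i], d$atom[i]),
                           character(1)),
                         d$bound_type[1], d$bound[1], source = d$source[1],
                         resonance = d$resonance[1])
  })
  sources <- vapply(res, function(r) r$source, character(1))
  build_restraint_set(res[sources == "NOE"], res[sources == "anti-NOE"],
                      res[sources == "intraligand"])
}

# ---------------------------------------------------------------------------
# run configuration

.config_defaults <- function() list(
  protocol = "brd4",
  upper_floor_single = 5.5, upper_floor_two_methyl = 6.5,
  anti_noe_one_methyl = 3.0, anti_noe_two_methyl = 3.6,
  trim24_tolerance = 0.5,
  fit_threshold = 0.15,
  pocket_radius = 12,
  tau_c = 10.1e-9, field_mhz = 800,
  n_restarts = 50, n_steps = 2000, top_k = 20,
  seed = 1)

.config_ranges <- list(
  protocol = c("brd4", "trim24"),
  upper_floor_single = c(1.8, 20), upper_floor_two_methyl = c(1.8, 20),
  anti_noe_one_methyl = c(0, 10), anti_noe_two_methyl = c(0, 10),
  trim24_tolerance = c(0, 5), fit_threshold = c(1e-6, 1),
  pocket_radius = c(1, 100), tau_c = c(1e-10, 1e-6),
  field_mhz = c(100, 1500), n_restarts = c(1, 1e4), n_steps = c(10, 1e7),
  top_k = c(1, 1e5), seed = c(-2^31, 2^31))

#' Run configuration
#'
#' Structured key-value configuration with documented defaults (tolerance
#' floors 5.5/6.5 Angstrom, anti-NOE limits 3.0/3.6 Angstrom). Unknown keys
#' and out-of-range values are rejected. Serialized as JSON by
#' [write_run_config()] / [read_run_config()].
#'
#' @param ... Overrides of the defaults (see `nmr2:::.config_defaults()`).
#' @return List of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- .config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  for (k in names(cfg)) {
    rng <- .config_ranges[[k]]
    v <- cfg[[k]]
    if (k == "protocol") {
      if (!v %in% rng) stop("protocol must be one of: ", paste(rng, collapse = ", "))
    } else if (!is.numeric(v) || length(v) != 1 || v < rng[1] || v > rng[2]) {
      stop("configuration value out of range for ", k, ": ", v)
    } else {
      cfg[[k]] <- as.numeric(v)  # canonical storage mode for round trips
    }
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @param path File path (JSON).
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

# machine-readable run log: config hash + seed + version, enough to
# reproduce a run bit-identically
.write_run_log <- function(cfg, seed, path, extra = list()) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_run_config(cfg, tmp)
  log <- c(list(config = unclass(cfg),
                config_md5 = unname(tools::md5sum(tmp)),
                seed = seed,
                package_version = as.character(utils::packageVersion("nmr2")),
                timestamp = format(Sys.time(), tz = "UTC")),
           extra)
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# command-line surface

.cli_usage <- function() {
  cat("usage: nmr2 <subcommand> [options]\n",
      "subcommands:\n",
      "  simulate   --seed N --out DIR [--noise SD]\n",
      "             write synthetic peaks.csv/visibility.csv/receptor.pdb/ligand.pdb\n",
      "  fit        --peaks FILE --tau-c SEC --field MHZ --out FILE\n",
      "             fit build-up curves, write fits CSV\n",
      "  restraints --seed N --out DIR\n",
      "             simulate + fit + calibrate, write restraints.upl/.lol\n",
      "  dock       --seed N --out DIR [--no-anti-noes]\n",
      "             full benchmark run, write report.json + ensemble.pdb\n",
      "  run-all    alias of dock\n", sep = "")
}

.cli_parse <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) return(NULL)
    key <- substring(a, 3)
    if (key %in% c("no-anti-noes")) {
      opts[[key]] <- TRUE
      i <- i + 1
    } else {
      if (i + 1 > length(args)) return(NULL)
      opts[[key]] <- args[i + 1]
      i <- i + 2
    }
  }
  opts
}

#' Command-line entry point
#'
#' Subcommands `simulate`, `fit`, `restraints`, `dock`, `run-all`. Returns
#' the exit status (0 success, 2 usage/validation error) rather than
#' calling `quit()`, so it is testable in-process; a wrapper script can use
#' `quit(status = nmr2_main())`.
#'
#' @param args Character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly.
#' @export
nmr2_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  fail <- function(...) {
    message("error: ", ...)
    .cli_usage()
    invisible(2L)
  }
  if (!length(args)) return(fail("no subcommand"))
  sub <- args[1]
  opts <- .cli_parse(args[-1])
  if (is.null(opts)) return(fail("bad arguments"))
  known_flags <- list(
    simulate = c("seed", "out", "noise"),
    fit = c("peaks", "tau-c", "field", "out"),
    restraints = c("seed", "out"),
    dock = c("seed", "out", "no-anti-noes"),
    `run-all` = c("seed", "out", "no-anti-noes"))
  if (!sub %in% names(known_flags)) return(fail("unknown subcommand: ", sub))
  bad <- setdiff(names(opts), known_flags[[sub]])
  if (length(bad)) return(fail("unknown flag(s): --",
                               paste(bad, collapse = ", --")))
  status <- tryCatch({
    switch(sub,
      simulate = .cli_simulate(opts),
      fit = .cli_fit(opts),
      restraints = .cli_restraints(opts),
      dock = , `run-all` = .cli_dock(opts))
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}

.cli_need <- function(opts, keys) {
  miss <- setdiff(keys, names(opts))
  if (length(miss))
    stop("missing required flag(s): --", paste(miss, collapse = ", --"))
}

.cli_simulate <- function(opts) {
  .cli_need(opts, c("seed", "out"))
  seed <- as.integer(opts$seed)
  out <- opts$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  spec <- synthetic_spec(seed = seed,
                         noise_sd = if (!is.null(opts$noise))
                           as.numeric(opts$noise) else 0)
  cx <- make_toy_complex(spec)
  sim <- simulate_noesy(cx, spec)
  write_peak_table(sim$peaks, file.path(out, "peaks.csv"))
  utils::write.table(sim$visibility, file.path(out, "visibility.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  write_pdb(cx$receptor$atoms, file.path(out, "receptor.pdb"))
  lat <- cx$ligand$atoms
  lat$resno <- 1L; lat$resname <- "LIG"
  write_pdb(lat, file.path(out, "ligand.pdb"))
  jsonlite::write_json(
    list(groups = cx$truth$groups, true_par = cx$truth$true_par,
         lig_coords = cx$truth$lig_coords, dist = cx$truth$dist),
    file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA,
    matrix = "rowmajor")
  .write_run_log(run_config(seed = seed, tau_c = spec$tau_c,
                            field_mhz = spec$field_mhz),
                 seed, file.path(out, "run_log.json"),
                 extra = list(subcommand = "simulate"))
  0L
}

.cli_fit <- function(opts) {
  .cli_need(opts, c("peaks", "out"))
  peaks <- read_peak_table(opts$peaks)
  tau_c <- if (!is.null(opts[["tau-c"]])) as.numeric(opts[["tau-c"]]) else 10.1e-9
  field <- if (!is.null(opts$field)) as.numeric(opts$field) else 800
  ctx <- relaxation_context(tau_c, field)
  fits <- fit_peak_table(as_buildup_curves(peaks), ctx)
  cr <- fits$cross
  df <- data.frame(
    group_i = vapply(cr, `[[`, character(1), "group_i"),
    group_j = vapply(cr, `[[`, character(1), "group_j"),
    sigma = vapply(cr, `[[`, numeric(1), "sigma"),
    distance = vapply(cr, `[[`, numeric(1), "distance"),
    fit_quality = vapply(cr, `[[`, numeric(1), "fit_quality"),
    accepted = vapply(cr, `[[`, logical(1), "accepted"))
  utils::write.table(df, opts$out, sep = ",", row.names = FALSE, quote = FALSE)
  0L
}

.cli_restraints <- function(opts) {
  .cli_need(opts, c("seed", "out"))
  seed <- as.integer(opts$seed)
  out <- opts$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  spec <- synthetic_spec(seed = seed)
  cx <- make_toy_complex(spec)
  sim <- simulate_noesy(cx, spec)
  blind <- blind_inputs(cx, sim, seed = spec$seed + 1L)
  prep <- prepare_restraints(cx, sim, blind, spec)
  write_restraints(prep$restraints, file.path(out, "restraints.upl"),
                   file.path(out, "restraints.lol"))
  0L
}

.cli_dock <- function(opts) {
  .cli_need(opts, c("seed", "out"))
  seed <- as.integer(opts$seed)
  out <- opts$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  bench <- run_benchmark(seed = seed,
                         use_anti_noes = is.null(opts[["no-anti-noes"]]))
  res <- bench$result
  report <- list(
    n_hypotheses = res$n_hypotheses,
    winning_assignment = as.list(res$assignment),
    best_target = res$table$target[1],
    ties = res$ties,
    rmsd_to_truth = bench$rmsd,
    assignment_correct = bench$assignment_correct,
    hypothesis_table = utils::head(res$table, 25))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_pose_ensemble(res$ensemble, bench$complex$ligand,
                      bench$complex$receptor, bench$restraints,
                      file.path(out, "ensemble.pdb"))
  .write_run_log(run_config(seed = seed), seed,
                 file.path(out, "run_log.json"),
                 extra = list(subcommand = "dock",
                              rmsd_to_truth = bench$rmsd))
  0L
}
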