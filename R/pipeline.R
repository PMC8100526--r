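#' @include AllClasses.R traj-io.R interactions.R dissociation.R
NULL

.configKeys <- c(
  "structure", "occupancy_table", "table_dialect", "force_inputs",
  "ligand_chain", "receptor_chain", "ligand_selection", "receptor_selection",
  "hbond_dist", "hbond_angle", "saltbridge_dist", "use_salt_bridges",
  "heavy_atom_fallback", "no_superpose", "probe", "sasa_points",
  "epsilon", "helix_a", "helix_b", "beta_switch", "reference_atom",
  "reference_force", "force_labels", "out_dir", "seed"
)

#' Read and validate a run configuration
#'
#' The configuration is a single YAML file; unknown keys are rejected.
#' Flags given in \code{overrides} (e.g. from a command line) replace the
#' file values.
#'
#' @param path YAML config file, or NULL to start from defaults.
#' @param overrides named list of overriding values.
#' @return validated named list of class \code{mechanobond_config}.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) cfg <- list()
  }
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  bad <- setdiff(names(cfg), .configKeys)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         "; known keys: ", paste(.configKeys, collapse = ", "))
  defaults <- list(
    table_dialect = "auto", ligand_chain = "A", receptor_chain = "B",
    hbond_dist = 3.5, hbond_angle = 30, saltbridge_dist = 4.0,
    use_salt_bridges = FALSE, heavy_atom_fallback = FALSE,
    no_superpose = FALSE, probe = 1.4, sasa_points = 960L,
    epsilon = 0.025, reference_force = 0, out_dir = ".", seed = 1L
  )
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  num <- c("hbond_dist", "hbond_angle", "saltbridge_dist", "probe",
           "epsilon", "reference_force")
  for (nm in num) {
    cfg[[nm]] <- as.numeric(cfg[[nm]])
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] < 0)
      stop("config key '", nm, "' must be a non-negative number")
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "mechanobond_config"
  cfg
}

.writeManifest <- function(cfg, path, extra = list()) {
  man <- c(list(
    package = "MechanoBond",
    package_version = as.character(utils::packageVersion("MechanoBond")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra, unclass(cfg))
  yaml::write_yaml(man, path)
  invisible(path)
}

.ligRecSelections <- function(cfg, traj) {
  ligExpr <- if (!is.null(cfg$ligand_selection)) cfg$ligand_selection
             else paste("chain", cfg$ligand_chain)
  recExpr <- if (!is.null(cfg$receptor_selection)) cfg$receptor_selection
             else paste("chain", cfg$receptor_chain)
  list(ligand = selectAtoms(traj, ligExpr),
       receptor = selectAtoms(traj, recExpr))
}

#' Single-trajectory occupancy analysis workflow
#'
#' Reads a multi-model PDB (or, alternatively, an occupancy table when
#' detection is to be skipped), detects interface hydrogen bonds
#' (optionally salt bridges), and writes the occupancy table, the
#' dissociation report, the per-frame H-bond count series, the superposed
#' C-alpha RMSD series, the buried-SASA series, and a run manifest to
#' \code{out_dir}.
#'
#' @param config a config list from \code{\link{readRunConfig}} (or a path
#'   to a YAML file).
#' @return invisible list of the produced objects and file paths.
#' @export
runOccupancyAnalysis <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outs <- list()
  if (!is.null(cfg$occupancy_table)) {
    tab <- readOccupancyTable(cfg$occupancy_table, dialect = cfg$table_dialect)
  } else if (!is.null(cfg$structure)) {
    traj <- readStructure(cfg$structure)
    sel <- .ligRecSelections(cfg, traj)
    crit <- hbondCriteria(cfg$hbond_dist, cfg$hbond_angle)
    sb <- if (isTRUE(cfg$use_salt_bridges))
      saltBridgeCriteria(cfg$saltbridge_dist) else NULL
    bp <- bondPresence(traj, sel$ligand, sel$receptor, hbond = crit,
                       saltBridge = sb,
                       useHeavyAtomFallback = isTRUE(cfg$heavy_atom_fallback))
    nhb <- hbondCountSeries(traj, sel$ligand, sel$receptor, crit,
                            useHeavyAtomFallback =
                              isTRUE(cfg$heavy_atom_fallback))
    utils::write.table(
      data.frame(frame = seq_along(nhb$counts), n_hb = nhb$counts),
      file.path(cfg$out_dir, "nhb_series.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    ca <- selectAtoms(traj, "name CA")
    if (length(ca@indices) >= 3) {
      rmsd <- caRmsdSeries(traj, ca, superpose = !isTRUE(cfg$no_superpose))
      utils::write.table(
        data.frame(frame = seq_along(rmsd), ca_rmsd = rmsd),
        file.path(cfg$out_dir, "rmsd_series.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      outs$rmsd <- rmsd
    }
    bsasa <- buriedSASASeries(traj, sel$ligand, sel$receptor,
                              probe = cfg$probe,
                              nPoints = as.integer(cfg$sasa_points))
    utils::write.table(
      data.frame(frame = seq_along(bsasa), buried_sasa = bsasa),
      file.path(cfg$out_dir, "buried_sasa_series.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    outs$nhb <- nhb; outs$buriedSASA <- bsasa
    if (nrow(bp@keys) == 0) {
      ## empty interface: P_D = 1 by definition, no classification
      utils::write.table(
        data.frame(condition = "trajectory", n_bonds = 0L, P_D = 1,
                   f_D = NA_real_, sum_omega = 0),
        file.path(cfg$out_dir, "dissociation.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      .writeManifest(cfg, file.path(cfg$out_dir, "manifest.yaml"),
                     list(n_bonds = 0L))
      return(invisible(c(outs, list(PD = 1, outDir = cfg$out_dir))))
    }
    tab <- occupancyFromPresence(bp, condition = "trajectory")
  } else {
    stop("config must provide either 'structure' or 'occupancy_table'")
  }
  writeOccupancyTable(tab, file.path(cfg$out_dir, "occupancy.tsv"))
  rep <- dissociationReport(tab)
  utils::write.table(rep, file.path(cfg$out_dir, "dissociation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  perRes <- do.call(rbind, lapply(conditions(tab), function(cc) {
    d <- complexDissociation(tab, cc)
    if (nrow(d@perResidue)) cbind(condition = cc, d@perResidue) else NULL
  }))
  if (!is.null(perRes))
    utils::write.table(perRes,
                       file.path(cfg$out_dir, "residue_probabilities.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  .writeManifest(cfg, file.path(cfg$out_dir, "manifest.yaml"),
                 list(conditions = as.list(conditions(tab))))
  invisible(c(outs, list(table = tab, report = rep, outDir = cfg$out_dir)))
}

#' Multi-force panel analysis workflow
#'
#' Takes per-force inputs -- either \code{force_inputs} (a named list
#' mapping force labels in pN to multi-model PDB paths) or a single
#' force-panel \code{occupancy_table} whose conditions are forces -- and
#' writes the per-force occupancy table, the f_D and Sigma-omega versus
#' force report, the per-bond response classification, the transition
#' forces, and a segmented Pearson table split at the f_D transition.
#' Helix / beta-switch metrics are emitted when the respective residue
#' intervals are configured and trajectories are given.
#'
#' @param config a config list from \code{\link{readRunConfig}} (or a path
#'   to a YAML file).
#' @return invisible list with the occupancy table, dissociation report,
#'   classification, and transition forces.
#' @export
runForcePanel <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg$occupancy_table)) {
    tab <- readOccupancyTable(cfg$occupancy_table, dialect = cfg$table_dialect)
  } else if (!is.null(cfg$force_inputs)) {
    crit <- hbondCriteria(cfg$hbond_dist, cfg$hbond_angle)
    tabs <- list()
    for (lab in names(cfg$force_inputs)) {
      traj <- readStructure(cfg$force_inputs[[lab]])
      sel <- .ligRecSelections(cfg, traj)
      bp <- bondPresence(traj, sel$ligand, sel$receptor, hbond = crit,
                         useHeavyAtomFallback =
                           isTRUE(cfg$heavy_atom_fallback))
      tabs[[lab]] <- occupancyFromPresence(bp, condition = lab)@records
    }
    ## union of keys: bonds unseen under a force get occupancy 0 there
    allr <- do.call(rbind, tabs)
    key <- paste(allr$ligand_chain, allr$ligand_resid, allr$ligand_resname,
                 allr$receptor_chain, allr$receptor_resid,
                 allr$receptor_resname, allr$donor_atom, allr$acceptor_atom,
                 allr$kind, sep = "|")
    uk <- !duplicated(key)
    full <- do.call(rbind, lapply(names(tabs), function(lab) {
      tmpl <- allr[uk, , drop = FALSE]
      tmpl$condition <- lab
      tmpl$occupancy <- 0
      have <- key[allr$condition == lab]
      hit <- match(key[uk], have)
      tmpl$occupancy[!is.na(hit)] <-
        allr$occupancy[allr$condition == lab][hit[!is.na(hit)]]
      tmpl
    }))
    tab <- new("OccupancyTable", records = full)
  } else {
    stop("config must provide 'occupancy_table' or 'force_inputs'")
  }
  forces <- suppressWarnings(as.numeric(conditions(tab)))
  if (any(is.na(forces)))
    stop("force-panel conditions must be numeric force labels; got: ",
         paste(conditions(tab), collapse = ", "))
  if (length(forces) < 3)
    stop("force panel needs >= 3 force levels, got ", length(forces))
  forces <- sort(forces)
  writeOccupancyTable(tab, file.path(cfg$out_dir, "occupancy_panel.tsv"))
  rep <- dissociationReport(tab, referenceForce = cfg$reference_force)
  rep <- rep[order(as.numeric(rep$condition)), ]
  utils::write.table(rep, file.path(cfg$out_dir, "dissociation_panel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cls <- classifyOccupancyTable(tab, epsilon = cfg$epsilon)
  utils::write.table(cls, file.path(cfg$out_dir, "classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tfD <- transitionForce(as.numeric(rep$condition), rep$f_D, mode = "min")
  tNHB <- transitionForce(as.numeric(rep$condition), rep$sum_omega,
                          mode = "max")
  trans <- data.frame(
    metric = c("f_D", "sum_omega"), mode = c("min", "max"),
    force = c(tfD$force, tNHB$force), value = c(tfD$value, tNHB$value),
    tied = c(tfD$tied, tNHB$tied))
  utils::write.table(trans, file.path(cfg$out_dir, "transitions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sp <- cbind(metric = "f_D",
              segmentedPearson(as.numeric(rep$condition), rep$f_D,
                               tfD$force))
  sp2 <- cbind(metric = "sum_omega",
               segmentedPearson(as.numeric(rep$condition), rep$sum_omega,
                                tNHB$force))
  utils::write.table(rbind(sp, sp2),
                     file.path(cfg$out_dir, "segmented_pearson.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .writeManifest(cfg, file.path(cfg$out_dir, "manifest.yaml"),
                 list(forces = as.list(forces)))
  invisible(list(table = tab, report = rep, classification = cls,
                 transitions = trans, outDir = cfg$out_dir))
}
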