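# End-to-end reproduction pipeline: load -> (optional pocket extraction)
# -> encode -> fit -> orient -> project -> group -> logos -> composition
# profiles, with structured stage logging on stderr and deterministic
# tab-separated outputs.

config_defaults <- function() {
  list(
    dataset = "bundled",
    include_isotypes_in_fit = FALSE,
    centering = "centered",
    assignment = "refined",
    isotype_assignment = "quadrant",
    pdb = NULL,
    ligand = NULL,
    cutoff = 5.0,
    t_values = seq(-2, 2, by = 0.5),
    outdir = NULL,
    seed = 1L
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list; applies defaults, rejects
#' unknown keys (naming the offender) and checks types, ranges and file
#' existence.
#'
#' @param config Path to a YAML file, or a named list of options.  Known
#'   keys: `dataset` (only `"bundled"`), `include_isotypes_in_fit`,
#'   `centering` (`"centered"`/`"raw"`), `assignment`
#'   (`"refined"`/`"quadrant"`), `isotype_assignment`
#'   (`"quadrant"`/`"nearest-centroid"`), `pdb`, `ligand`, `cutoff`,
#'   `t_values`, `outdir`, `seed`.
#' @return Object of class `pipeline_config` (a completed option list).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  defaults <- config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown configuration key: \"", unknown[[1L]], "\"", call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (!identical(cfg$dataset, "bundled")) {
    stop("dataset must be \"bundled\"", call. = FALSE)
  }
  if (!is.logical(cfg$include_isotypes_in_fit)) {
    stop("include_isotypes_in_fit must be logical", call. = FALSE)
  }
  if (!cfg$centering %in% c("centered", "raw")) {
    stop("centering must be \"centered\" or \"raw\"", call. = FALSE)
  }
  if (!cfg$assignment %in% c("refined", "quadrant")) {
    stop("assignment must be \"refined\" or \"quadrant\"", call. = FALSE)
  }
  if (!cfg$isotype_assignment %in% c("quadrant", "nearest-centroid")) {
    stop("isotype_assignment must be \"quadrant\" or \"nearest-centroid\"",
         call. = FALSE)
  }
  if (!is.numeric(cfg$cutoff) || cfg$cutoff <= 0) {
    stop("cutoff must be a positive distance", call. = FALSE)
  }
  if (!is.null(cfg$pdb) && !file.exists(cfg$pdb)) {
    stop("pdb file not found: ", cfg$pdb, call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full binding-site PCA reproduction
#'
#' Executes the complete analysis on the bundled 125-sequence dataset:
#' loads the records, one-hot encodes them, fits the covariance PCA (by
#' default on the 117 non-isotype records), orients PC1/PC2 biologically,
#' projects all 125 sequences, partitions the fitted records into groups
#' A-D (default: quadrant-seeded centroid refinement), assigns the held
#' out human isotypes (default: by quadrant), computes per-family and
#' per-group sequence logos, the dominant between-group substitutions,
#' and the PC1/PC2 composition-deviation profiles.  If `config$outdir` is
#' set, writes `projections.tsv`, `groups.tsv`, `logos/<name>.tsv`,
#' `transitions.tsv`, `composition_pc1.tsv`, `composition_pc2.tsv` and a
#' `manifest.json` that suffices to re-execute the run bit-identically.
#'
#' @param config A `pipeline_config`, or anything [validate_config()]
#'   accepts.
#' @return A result bundle: list with `records`, `model`, `projections`
#'   (records + pc1/pc2), `groups` (records + assigned group + method),
#'   `family_logos`, `group_logos`, `transitions`, `composition`,
#'   `contacts` (if a PDB was given), `manifest`.
#' @export
run_full_analysis <- function(config = list()) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  t0 <- Sys.time()

  records <- load_bundled_dataset(include_isotypes = TRUE)
  stage_log("load", "%d records (%d isotype rows)", nrow(records),
            sum(records$family == "isotype"))

  contacts <- NULL
  if (!is.null(config$pdb)) {
    model_struct <- read_structure(config$pdb)
    contacts <- extract_contact_residues(model_struct, config$ligand,
                                         cutoff = config$cutoff)
    stage_log("extract-site", "%d contact residues at %.1f A",
              nrow(contacts), config$cutoff)
  }

  fit_records <- if (config$include_isotypes_in_fit) records
                 else records[records$family != "isotype", , drop = FALSE]
  enc_fit <- onehot_encode(fit_records)
  model <- fit_pca(enc_fit)
  model <- orient_axes(model, fit_records)
  stage_log("fit", "PCA on %d records; lambda1=%.3f lambda2=%.3f; flips=%s",
            enc_fit$M, model$values[[1L]], model$values[[2L]],
            paste(model$flips, collapse = ","))

  enc_all <- onehot_encode(records)
  proj <- project(model, enc_all, k = 1:2, centering = config$centering)
  stage_log("project", "%d records projected (%s mode)", nrow(proj),
            config$centering)

  fit_idx <- if (config$include_isotypes_in_fit) seq_len(nrow(records))
             else which(records$family != "isotype")
  proj_fit <- proj[fit_idx, , drop = FALSE]
  attr(proj_fit, "oriented") <- attr(proj, "oriented")
  training <- switch(config$assignment,
                     refined = refine_groups(proj_fit),
                     quadrant = assign_quadrant(proj_fit))
  group <- character(nrow(records))
  method <- character(nrow(records))
  group[fit_idx] <- training$group
  method[fit_idx] <- training$method
  out_idx <- setdiff(seq_len(nrow(records)), fit_idx)
  if (length(out_idx) > 0L) {
    proj_out <- proj[out_idx, , drop = FALSE]
    attr(proj_out, "oriented") <- attr(proj, "oriented")
    held <- switch(config$isotype_assignment,
                   quadrant = assign_quadrant(proj_out),
                   `nearest-centroid` = assign_nearest_centroid(proj_out,
                                                                training))
    group[out_idx] <- held$group
    method[out_idx] <- held$method
  }
  groups <- records
  groups$published_group <- groups$group
  groups$group <- group
  groups$method <- method
  groups$pc1 <- proj[, 1L]
  groups$pc2 <- proj[, 2L]
  stage_log("assign", "groups: %s",
            paste(names(table(group)), table(group), sep = "=",
                  collapse = " "))

  fams <- unique(records$table)
  family_logos <- setNames(lapply(fams, function(f) {
    logo_matrix(records[records$table == f, , drop = FALSE])
  }), fams)
  group_logos <- setNames(lapply(c("A", "B", "C", "D"), function(g) {
    logo_matrix(groups[groups$group == g, , drop = FALSE])
  }), c("A", "B", "C", "D"))
  transitions <- list(
    A_vs_C = dominant_transitions(group_logos$A, group_logos$C),
    C_vs_D = dominant_transitions(group_logos$C, group_logos$D)
  )
  stage_log("logos", "%d family logos, 4 group logos; A~C transitions: %d",
            length(family_logos), nrow(transitions$A_vs_C))

  composition <- list(
    pc1 = composition_profile(model, 1L, config$t_values),
    pc2 = composition_profile(model, 2L, config$t_values)
  )

  manifest <- list(
    package = "pocketpca",
    version = as.character(utils::packageVersion("pocketpca")),
    config = config_manifest(config),
    n_fit = enc_fit$M,
    n_projected = nrow(proj),
    pc_flips = model$flips,
    eigenvalues_top5 = signif(head(model$values, 5L), 8)
  )

  if (!is.null(config$outdir)) {
    write_bundle(config$outdir, records, proj, groups, family_logos,
                 group_logos, transitions, composition, manifest)
    stage_log("write", "outputs under %s", config$outdir)
  }
  stage_log("done", "completed in %.2f s",
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(records = records, model = model,
                 projections = groups[, c("organism", "family", "accession",
                                          "pbs_string", "pc1", "pc2")],
                 groups = groups, family_logos = family_logos,
                 group_logos = group_logos, transitions = transitions,
                 composition = composition, contacts = contacts,
                 manifest = manifest))
}

config_manifest <- function(config) {
  cfg <- unclass(config)
  cfg$t_values <- as.numeric(cfg$t_values)
  cfg$outdir <- NULL  # run-location independent: reruns stay byte-identical
  cfg[!vapply(cfg, is.null, logical(1L))]
}

write_bundle <- function(outdir, records, proj, groups, family_logos,
                         group_logos, transitions, composition, manifest) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "logos"), showWarnings = FALSE)
  write_projection_table(records, proj, file.path(outdir, "projections.tsv"))
  gout <- data.frame(
    organism = groups$organism, family = groups$family,
    accession = groups$accession, pbs_string = groups$pbs_string,
    pc1 = sprintf("%.6f", groups$pc1), pc2 = sprintf("%.6f", groups$pc2),
    group = groups$group, method = groups$method,
    published_group = groups$published_group, anomaly = groups$anomaly,
    stringsAsFactors = FALSE
  )
  write.table(gout, file.path(outdir, "groups.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (nm in names(family_logos)) {
    write_logo_table(family_logos[[nm]],
                     file.path(outdir, "logos", paste0(nm, ".tsv")))
  }
  for (nm in names(group_logos)) {
    write_logo_table(group_logos[[nm]],
                     file.path(outdir, "logos", paste0("group_", nm, ".tsv")))
  }
  tr <- rbind(
    cbind(pair = "A_vs_C", as.data.frame(transitions$A_vs_C)),
    cbind(pair = "C_vs_D", as.data.frame(transitions$C_vs_D))
  )
  tr$score <- sprintf("%.6f", tr$score)
  write.table(tr, file.path(outdir, "transitions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (k in c("pc1", "pc2")) {
    cp <- as.data.frame(composition[[k]])
    cp$deviation <- sprintf("%.6f", cp$deviation)
    write.table(cp, file.path(outdir, paste0("composition_", k, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}
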