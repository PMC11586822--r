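# End-to-end orchestration: featurize both partners, obtain (or train) the
# interaction-energy ensemble, anneal, rank sites, refine, and write the
# refined complexes plus a machine-readable report.

#' Pipeline configuration
#'
#' Defaults follow the method's chosen hyperparameters: two WL updates,
#' 10 Angstrom pair-formation distance, coarse-grained target distance
#' d0 = 5 Angstrom (4 Angstrom at refinement), 64 annealing runs, three
#' reported sites.
#'
#' @param output_dir where refined complexes and the report are written.
#' @param n_wl number of WL updates.
#' @param formation_distance pair-formation cutoff (Angstrom).
#' @param params coarse-stage [loss_params()].
#' @param refine_params refinement [loss_params()] (all-atom contact scale).
#' @param schedule [anneal_schedule()].
#' @param n_runs independent annealing runs.
#' @param n_sites candidate sites to report.
#' @param site_threshold agglomerative clustering threshold (Angstrom).
#' @param restrict_radius refinement COM restraint (Angstrom).
#' @param refine_steps refinement proposals per site.
#' @param seed master seed.
#' @param registry_mode `"internal"` or `"external"` feature providers.
#' @param train training options (epochs, folds, n_configs for the
#'   oracle-generated set when no model or data is supplied).
#' @param top_residues number of top contributing residues in the report.
#' @export
run_config <- function(output_dir = tempfile("nanodock_"), n_wl = 2,
                       formation_distance = 10.0,
                       params = loss_params(d0 = 5.0),
                       refine_params = loss_params(d0 = 4.0),
                       schedule = anneal_schedule(), n_runs = 64,
                       n_sites = 3, site_threshold = 10,
                       restrict_radius = 8, refine_steps = 2000, seed = 1,
                       registry_mode = "internal",
                       train = list(epochs = 150, folds = 5,
                                    n_configs = 150),
                       top_residues = 10) {
  cfg <- list(output_dir = output_dir, n_wl = n_wl,
              formation_distance = formation_distance, params = params,
              refine_params = refine_params, schedule = schedule,
              n_runs = n_runs, n_sites = n_sites,
              site_threshold = site_threshold,
              restrict_radius = restrict_radius,
              refine_steps = refine_steps, seed = seed,
              registry_mode = registry_mode, train = train,
              top_residues = top_residues)
  class(cfg) <- "run_config"
  cfg
}

top_phi_residues <- function(pose, cluster, graph, phi, pair_cutoff, k) {
  heads <- apply_pose(cluster$head_centroids, pose, cluster$com)
  D <- cross_dist(heads, graph$ca)
  contrib <- colSums(phi * (D <= pair_cutoff))
  ord <- order(-contrib)
  ord <- ord[contrib[ord] > 0]
  ord <- utils::head(ord, k)
  data.frame(chain_id = graph$labels$chain_id[ord],
             residue_id = graph$labels$residue_id[ord],
             residue_name = graph$labels$residue_name[ord],
             phi_sum = contrib[ord], stringsAsFactors = FALSE)
}

#' Run the four-stage placement pipeline
#'
#' Featurization, pairwise interaction-energy prediction, coarse-grained
#' annealing placement, and restricted all-atom refinement. With no trained
#' model and no training data, configurations are sampled from the
#' synthetic oracle (requires per-residue charges on `protein`) and the
#' ensemble is trained first.
#'
#' @param protein a [make_protein()] result, or a list with `cp`
#'   (coarse_protein) and `atoms`, or a PDB path.
#' @param cluster a featurized `cluster_model`, or c(structure, topology)
#'   paths.
#' @param config a [run_config()].
#' @param model optional pre-trained `interaction_ensemble`.
#' @param training optional list of labelled `pair_batch` objects.
#' @param verbose print stage progress.
#' @return list with `sites`, `refined`, `report`, `graph`, `table`,
#'   `model`, and the written file paths.
#' @export
run_pipeline <- function(protein, cluster, config = run_config(),
                         model = NULL, training = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(protein)) {
    atoms <- read_protein(protein)
    protein <- list(cp = extract_coarse_protein(atoms), atoms = atoms)
  }
  if (is.character(cluster)) cluster <- read_cluster(cluster[1], cluster[2])
  if (is.null(cluster$ligand_features)) cluster <- featurize_cluster(cluster)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  nd_msg(verbose, "stage 1/4: featurization")
  graph <- build_graph(protein$cp)
  graph <- compute_node_features(
    graph, atoms = protein$atoms,
    registry = default_feature_registry(mode = config$registry_mode))
  graph <- wl_update(graph, n_updates = config$n_wl)

  nd_msg(verbose, "stage 2/4: interaction-energy prediction")
  if (is.null(model)) {
    if (is.null(training)) {
      if (is.null(protein$charges))
        stop("no model, no training data, and no bead charges to run the ",
             "synthetic oracle: cannot train")
      training <- sample_configurations(
        graph, protein, cluster, n_configs = config$train$n_configs,
        seed = config$seed, formation_distance = config$formation_distance)
    }
    model <- train_interaction_model(
      training, seed = config$seed, epochs = config$train$epochs,
      folds = config$train$folds, verbose = verbose)
  }
  tab <- interaction_table(model, graph, cluster)

  nd_msg(verbose, "stage 3/4: coarse-grained annealing placement")
  runs <- anneal(protein$cp, cluster, tab$phi, params = config$params,
                 schedule = config$schedule, n_runs = config$n_runs,
                 seed = config$seed, verbose = verbose)
  sites <- select_sites(runs, protein$cp, cluster, tab$energy,
                        n = config$n_sites,
                        threshold = config$site_threshold,
                        pair_cutoff = config$params$pair_cutoff)

  nd_msg(verbose, "stage 4/4: restricted all-atom refinement")
  refined <- list()
  files <- character()
  site_reports <- list()
  for (i in seq_along(sites$sites)) {
    s <- sites$sites[[i]]
    ref <- refine_pose(protein$atoms, graph, cluster, s$pose, tab$phi,
                       params = config$refine_params,
                       restrict_radius = config$restrict_radius,
                       n_steps = config$refine_steps,
                       seed = config$seed + 100 + i)
    refined[[i]] <- ref
    path <- file.path(config$output_dir, sprintf("site_%d_complex.pdb", i))
    write_complex(protein$atoms, cluster, ref$pose, path)
    files <- c(files, path)
    site_reports[[i]] <- list(
      rank = i, member_count = s$count,
      predicted_energy = s$energy,
      refined_loss = ref$loss, refined_min_dist = ref$min_dist,
      feasible = ref$feasible,
      com = round(ref$com, 3),
      top_residues = top_phi_residues(ref$pose, cluster, graph, tab$phi,
                                      config$params$pair_cutoff,
                                      config$top_residues))
  }
  report <- list(seed = config$seed,
                 config_hash = config_hash(unclass(config)[
                   setdiff(names(config), "output_dir")]),
                 n_sites = length(site_reports),
                 sites = site_reports)
  report_path <- file.path(config$output_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = 6,
                       dataframe = "rows")
  list(sites = sites, refined = refined, report = report, graph = graph,
       table = tab, model = model,
       files = c(files, report = report_path))
}
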